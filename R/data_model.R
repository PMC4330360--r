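#' Transcript-level expression dataset for isoform-pair analysis
#'
#' The central container consumed by all downstream functions. Holds a
#' transcript-by-sample TPM matrix, the transcript-to-gene map, two-class
#' sample labels, optional patient pairing and a PSI (relative isoform
#' abundance) matrix recomputed from the TPM.
#'
#' @param expr numeric matrix, transcripts x samples; either TPM values or
#'   estimated read counts (see `values`). Row names are transcript ids,
#'   column names sample ids; both must be unique.
#' @param gene_of named character vector mapping every transcript id to a
#'   gene id.
#' @param class_of named character vector mapping every sample id to one of
#'   exactly two class labels.
#' @param class_levels length-2 character vector designating class1
#'   (the "normal"-like reference) and class2 (the "tumor"-like class).
#'   Defaults to `c("normal", "tumor")` when those are the labels present,
#'   otherwise to the sorted unique labels.
#' @param pairing optional data.frame with columns `patient`, `class1`,
#'   `class2` giving the matched sample id of each class per patient.
#' @param values `"tpm"` if `expr` already holds TPM, `"counts"` if it holds
#'   read counts to be converted with `lengths`.
#' @param lengths named numeric vector of transcript lengths in nt; required
#'   when `values = "counts"`.
#' @param symbol optional named logical vector per transcript (or gene):
#'   TRUE where an accepted gene symbol exists. Used by [filter_genes()].
#'
#' @return An object of class `"ExpressionDataset"`: a list with elements
#'   `tpm`, `psi`, `gene_of`, `class_of`, `class_levels`, `pairing`,
#'   `symbol_ok`.
#' @export
expression_dataset <- function(expr, gene_of, class_of,
                               class_levels = NULL, pairing = NULL,
                               values = c("tpm", "counts"), lengths = NULL,
                               symbol = NULL) {
  values <- match.arg(values)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix must carry transcript row names and sample column names")
  if (anyDuplicated(rownames(expr)))
    stop("duplicate transcript ids in expression matrix")
  if (anyDuplicated(colnames(expr)))
    stop("duplicate sample ids in expression matrix")
  if (any(expr < 0)) stop("expression values must be non-negative")

  tids <- rownames(expr)
  sids <- colnames(expr)
  if (!all(tids %in% names(gene_of)))
    stop("transcripts without a gene mapping: ",
         paste(utils::head(setdiff(tids, names(gene_of)), 5), collapse = ", "))
  gene_of <- gene_of[tids]
  if (!all(sids %in% names(class_of)))
    stop("samples without a class label: ",
         paste(utils::head(setdiff(sids, names(class_of)), 5), collapse = ", "))
  class_of <- as.character(class_of[sids])
  names(class_of) <- sids
  labs <- sort(unique(class_of))
  if (length(labs) != 2L)
    stop("exactly 2 class labels required, got ", length(labs), ": ",
         paste(labs, collapse = ", "))
  if (is.null(class_levels)) {
    class_levels <- if (setequal(labs, c("normal", "tumor")))
      c("normal", "tumor") else labs
  }
  if (!setequal(class_levels, labs) || length(class_levels) != 2L)
    stop("class_levels must be a permutation of the observed labels")

  if (values == "counts") {
    tpm <- compute_tpm(expr, lengths)
  } else {
    tpm <- expr
  }

  if (!is.null(pairing)) {
    pairing <- as.data.frame(pairing)
    need <- c("patient", "class1", "class2")
    if (!all(need %in% names(pairing)))
      stop("pairing needs columns patient, class1, class2")
    bad <- !(pairing$class1 %in% sids) | !(pairing$class2 %in% sids)
    if (any(bad)) stop("pairing references unknown samples")
    if (any(class_of[pairing$class1] != class_levels[1L]) ||
        any(class_of[pairing$class2] != class_levels[2L]))
      stop("pairing columns must hold class1/class2 samples respectively")
  }

  ds <- structure(list(
    tpm = tpm,
    psi = compute_psi(tpm, gene_of),
    gene_of = gene_of,
    class_of = class_of,
    class_levels = class_levels,
    pairing = pairing,
    symbol_ok = symbol
  ), class = "ExpressionDataset")
  ds
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d transcripts, %d genes, %d samples (%s: %d, %s: %d)\n",
              nrow(x$tpm), length(unique(x$gene_of)), ncol(x$tpm),
              x$class_levels[1], sum(x$class_of == x$class_levels[1]),
              x$class_levels[2], sum(x$class_of == x$class_levels[2])))
  if (!is.null(x$pairing))
    cat(sprintf("  %d patient pairs\n", nrow(x$pairing)))
  invisible(x)
}

#' Convert estimated read counts to TPM
#'
#' TPM_t = 1e6 * (c_t / l_t) / sum_u (c_u / l_u), per sample. Columns of
#' all-zero counts yield all-zero TPM with a warning.
#'
#' @param counts non-negative numeric matrix, transcripts x samples.
#' @param lengths named numeric vector of positive transcript lengths (nt)
#'   covering every row of `counts`.
#' @return numeric matrix of TPM values with the same dimnames; every
#'   non-degenerate column sums to 1e6.
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  tids <- rownames(counts)
  if (is.null(tids)) stop("counts must have transcript row names")
  missing <- setdiff(tids, names(lengths))
  if (length(missing))
    stop("no length for transcript(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  len <- as.numeric(lengths[tids])
  if (any(!is.finite(len)) || any(len <= 0))
    stop("transcript lengths must be positive")
  rate <- counts / len
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("all-zero sample column(s): ",
            paste(colnames(counts)[zero], collapse = ", "))
    tot[zero] <- 1 # divide-by-one; columns stay zero
  }
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Compute PSI (relative isoform abundance) from TPM
#'
#' PSI_ts = TPM_ts / sum over the gene's transcripts of TPM in sample s.
#' When a gene's total TPM in a sample is zero, all of the gene's PSI
#' entries in that sample are `NA` (not 0): no relative abundance is
#' defined there, and downstream correlations drop such samples pairwise.
#'
#' @param tpm non-negative numeric matrix, transcripts x samples, with
#'   transcript row names.
#' @param gene_of named character vector, transcript -> gene id.
#' @return numeric matrix of PSI values in \[0, 1\] or `NA`.
#' @export
compute_psi <- function(tpm, gene_of) {
  tpm <- as.matrix(tpm)
  if (any(tpm < 0)) stop("tpm must be non-negative")
  g <- as.factor(as.character(gene_of[rownames(tpm)]))
  # per-gene per-sample totals, expanded back to transcript rows
  tot <- rowsum(tpm, g, reorder = FALSE)
  tot_row <- tot[as.integer(g), , drop = FALSE]
  psi <- tpm / tot_row
  psi[tot_row == 0] <- NA_real_
  dimnames(psi) <- dimnames(tpm)
  psi
}

#' Drop single-isoform genes and genes lacking an accepted symbol
#'
#' Genes with fewer than two quantified transcripts carry no isoform-pair
#' information and are removed. When the dataset carries a per-transcript
#' symbol flag, transcripts of genes flagged as lacking an accepted gene
#' symbol are removed too; without the flag that filter is skipped with a
#' warning.
#'
#' @param dataset an [expression_dataset()].
#' @return a filtered `ExpressionDataset` (PSI recomputed).
#' @export
filter_genes <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  keep <- rep(TRUE, nrow(dataset$tpm))
  if (!is.null(dataset$symbol_ok)) {
    ok <- dataset$symbol_ok[rownames(dataset$tpm)]
    ok[is.na(ok)] <- FALSE
    keep <- keep & as.logical(ok)
  } else {
    warning("no gene-symbol flag present; skipping the symbol filter")
  }
  g <- dataset$gene_of[keep]
  multi <- names(which(table(g) >= 2L))
  keep <- keep & dataset$gene_of %in% multi
  if (!any(keep)) {
    warning("no multi-isoform genes remain after filtering")
  }
  tpm <- dataset$tpm[keep, , drop = FALSE]
  structure(list(
    tpm = tpm,
    psi = compute_psi(tpm, dataset$gene_of[keep]),
    gene_of = dataset$gene_of[keep],
    class_of = dataset$class_of,
    class_levels = dataset$class_levels,
    pairing = dataset$pairing,
    symbol_ok = if (is.null(dataset$symbol_ok)) NULL else dataset$symbol_ok[keep]
  ), class = "ExpressionDataset")
}

#' Samples belonging to each class
#' @param dataset an `ExpressionDataset`.
#' @return list with character vectors `class1` and `class2`.
#' @export
class_samples <- function(dataset) {
  list(class1 = names(dataset$class_of)[dataset$class_of == dataset$class_levels[1L]],
       class2 = names(dataset$class_of)[dataset$class_of == dataset$class_levels[2L]])
}
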