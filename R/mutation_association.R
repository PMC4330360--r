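# closed-interval intersection on one chromosome
.hits_span <- function(mut, chrom, start, end) {
  mut$chrom == chrom & mut$start <= end & mut$end >= start
}

.transcript_lengths <- function(structures) {
  w <- structures$exons$end - structures$exons$start + 1
  tapply(w, structures$exons$transcript_id, sum)
}

# median mature-transcript length per gene (genes with >= 2 isoforms)
.gene_median_lengths <- function(structures) {
  tl <- .transcript_lengths(structures)
  tr <- structures$transcripts
  g <- tr$gene_id[match(names(tl), tr$transcript_id)]
  multi <- names(which(table(g) >= 2L))
  med <- tapply(tl[g %in% multi], g[g %in% multi], stats::median)
  stats::setNames(as.numeric(med), names(med))
}

#' Samples carrying a mutation overlapping a switch's transcripts
#'
#' A sample is included when at least one of its mutations intersects
#' (closed 1-based intervals) the union of the two isoforms' transcript
#' spans (`scope = "transcript"`) or the gene's span over all its
#' transcripts (`scope = "gene"`).
#'
#' @param tumor_isoform,normal_isoform transcript ids of the switch.
#' @param mutations a [mutation_table()].
#' @param structures a [transcript_structures()] object covering both
#'   isoforms.
#' @param scope `"transcript"` or `"gene"`.
#' @param protein_affecting_only restrict to mutation classes that change
#'   the protein (nonsense, missense, frameshift, indel, splice-site).
#' @return character vector of sample ids.
#' @export
mutated_samples <- function(tumor_isoform, normal_isoform, mutations,
                            structures, scope = c("transcript", "gene"),
                            protein_affecting_only = FALSE) {
  scope <- match.arg(scope)
  stopifnot(inherits(structures, "TranscriptStructures"))
  tr <- structures$transcripts
  rows <- tr[tr$transcript_id %in% c(tumor_isoform, normal_isoform), ]
  miss <- setdiff(c(tumor_isoform, normal_isoform), rows$transcript_id)
  if (length(miss))
    stop("no structure for transcript(s): ", paste(miss, collapse = ", "))
  mut <- mutations
  if (protein_affecting_only)
    mut <- mut[mut$class %in% PROTEIN_AFFECTING, , drop = FALSE]
  if (scope == "gene") {
    gid <- rows$gene_id[1L]
    rows <- tr[tr$gene_id == gid, , drop = FALSE]
    rows <- data.frame(chrom = rows$chrom[1L], start = min(rows$start),
                       end = max(rows$end))
  }
  hit <- rep(FALSE, nrow(mut))
  for (r in seq_len(nrow(rows)))
    hit <- hit | .hits_span(mut, rows$chrom[r], rows$start[r], rows$end[r])
  unique(mut$sample[hit])
}

#' Jaccard index of switch and mutation sample sets
#'
#' J = |M intersect S| / |M union S|; 0 (with a warning) when both sets
#' are empty.
#'
#' @param S samples carrying the switch.
#' @param M samples carrying a mutation.
#' @return J in \[0, 1\].
#' @export
jaccard_association <- function(S, M) {
  u <- union(S, M)
  if (!length(u)) {
    warning("empty union of switch and mutation sample sets; J = 0")
    return(0)
  }
  length(intersect(S, M)) / length(u)
}

#' Mutual information of two binary sample indicators
#'
#' Plug-in mutual information (bits) of switch presence and mutation
#' presence over a universe of N samples, with 0 log 0 := 0.
#'
#' @param S,M sample-id sets (subsets of the universe).
#' @param universe character vector of all samples, or a single integer N
#'   (then S and M must be counted within it: sets are intersected with
#'   the universe when it is a character vector).
#' @return MI >= 0 in bits; 0 exactly when the 2x2 table is a product.
#' @export
mutual_information_association <- function(S, M, universe) {
  if (is.numeric(universe) && length(universe) == 1L) {
    N <- as.integer(universe)
    ns <- length(S); nm <- length(M); nsm <- length(intersect(S, M))
  } else {
    N <- length(universe)
    S <- intersect(S, universe); M <- intersect(M, universe)
    ns <- length(S); nm <- length(M); nsm <- length(intersect(S, M))
  }
  if (N < 1L) stop("empty universe")
  n <- c(nsm, ns - nsm, nm - nsm, N - ns - nm + nsm)  # joint 2x2 counts
  p <- n / N
  ps <- c(ns, N - ns) / N
  pm <- c(nm, N - nm) / N
  pe <- c(ps[1] * pm[1], ps[1] * pm[2], ps[2] * pm[1], ps[2] * pm[2])
  terms <- ifelse(p > 0, p * log2(p / pe), 0)
  max(sum(terms), 0)
}

#' Mutual-exclusion score
#'
#' mx = 2 min(n10, n01) / N, where n10 counts samples with the switch but
#' no mutation and n01 samples with a mutation but no switch. High values
#' indicate that switches and mutations tend to occur in disjoint
#' samples.
#'
#' @param n10,n01 non-negative integers with n10 + n01 <= N.
#' @param N universe size.
#' @return mx in \[0, 1\].
#' @export
mutual_exclusion <- function(n10, n01, N) {
  stopifnot(n10 >= 0, n01 >= 0, n10 + n01 <= N, N >= 1)
  2 * min(n10, n01) / N
}

#' Length-matched background genes
#'
#' Selects the `n_background` genes nearest to the target gene in median
#' isoform length (sum of exon widths per transcript, median over the
#' gene's transcripts), among genes with >= 2 isoforms; deterministic
#' ties broken by gene id.
#'
#' @param gene target gene id.
#' @param structures a [transcript_structures()] object.
#' @param n_background number of genes to select (default 100).
#' @return character vector of gene ids.
#' @export
length_matched_genes <- function(gene, structures, n_background = 100L) {
  med <- .gene_median_lengths(structures)
  if (!gene %in% names(med)) stop("gene not in structures (or single-isoform): ", gene)
  cand <- med[setdiff(names(med), gene)]
  if (length(cand) < n_background) {
    warning("only ", length(cand), " candidate background genes available")
    n_background <- length(cand)
  }
  d <- abs(cand - med[[gene]])
  names(cand)[order(d, names(cand))][seq_len(n_background)]
}

#' z-score of an observed statistic against background values
#'
#' @param observed the statistic for the switch of interest.
#' @param background numeric vector of the same statistic over background
#'   genes.
#' @return z = (observed - mean) / sd; `NA` with attribute
#'   `degenerate = TRUE` when the background has zero variance.
#' @export
background_zscore <- function(observed, background) {
  s <- stats::sd(background)
  if (!is.finite(s) || s == 0) {
    z <- NA_real_
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  (observed - mean(background)) / s
}

# Mann-Whitney with exact distribution for small groups, tie-corrected
# normal approximation otherwise; all-tied input returns p = 1.
.mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) {
    p <- NA_real_
    attr(p, "empty_group") <- TRUE
    return(p)
  }
  if (length(unique(c(x, y))) == 1L) return(1)
  exact <- length(x) <= 8L && length(y) <= 8L && !anyDuplicated(c(x, y))
  suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                      correct = TRUE)$p.value)
}

#' Test PSI differences between mutated and non-mutated tumor samples
#'
#' Per tumor sample, dPSI = PSI(tumor isoform) - PSI(normal isoform);
#' the distributions of dPSI in mutated versus non-mutated tumor samples
#' are compared with a two-sided Mann-Whitney test. With
#' `paired_delta = TRUE`, dPSI is instead the tumor-minus-matched-normal
#' difference of the tumor isoform's PSI per patient.
#'
#' @param switch one-row data.frame or list with `tumor_isoform`,
#'   `normal_isoform`.
#' @param dataset an `ExpressionDataset`.
#' @param mutated character vector of mutated sample ids.
#' @param paired_delta use the per-patient paired definition (requires
#'   pairing).
#' @return two-sided p-value; `NA` with attribute `empty_group` when one
#'   group is empty.
#' @export
delta_psi_mutation_test <- function(switch, dataset, mutated,
                                    paired_delta = FALSE) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  ti <- switch$tumor_isoform; ni <- switch$normal_isoform
  if (paired_delta) {
    if (is.null(dataset$pairing)) stop("paired_delta requires pairing")
    dpsi <- dataset$psi[ti, dataset$pairing$class2] -
            dataset$psi[ti, dataset$pairing$class1]
    names(dpsi) <- dataset$pairing$class2
  } else {
    tum <- class_samples(dataset)$class2
    dpsi <- dataset$psi[ti, tum] - dataset$psi[ni, tum]
  }
  dpsi <- dpsi[!is.na(dpsi)]
  .mann_whitney(dpsi[names(dpsi) %in% mutated],
                dpsi[!names(dpsi) %in% mutated])
}

#' Full mutation-association statistics per switch
#'
#' For every switch computes: the sample sets S (switch present, by the
#' occurrence rule) and M (mutation overlapping the switch transcripts),
#' the Jaccard index J and its z-score against `n_background`
#' length-matched genes, the mutual information (bits) and its z-score,
#' the mutual-exclusion score mx (computed on protein-affecting
#' mutations) and its z-score, and the Mann-Whitney p-value for dPSI
#' between mutated and non-mutated tumor samples, with
#' Benjamini-Hochberg adjustment across switches.
#'
#' The sample universe is restricted to samples with both expression and
#' mutation data (`universe`; defaults to all tumor samples of the
#' dataset). Background genes use their gene span for the mutation
#' overlap.
#'
#' @param switches data.frame from [detect_switches()].
#' @param dataset an `ExpressionDataset`.
#' @param mutations a [mutation_table()].
#' @param structures a [transcript_structures()] object.
#' @param scope mutation overlap scope for the switch transcripts,
#'   `"transcript"` (default) or `"gene"`.
#' @param protein_affecting_only restrict J/MI to protein-affecting
#'   mutation classes (mx always uses them).
#' @param n_background background genes per switch (default 100).
#' @param universe sample ids with mutation data (default: tumor
#'   samples).
#' @return data.frame with one row per switch: `gene`, `tumor_isoform`,
#'   `normal_isoform`, `n_switch`, `n_mutated`, `jaccard`, `j_zscore`,
#'   `mutual_information`, `mi_zscore`, `mx`, `mx_zscore`,
#'   `delta_psi_pvalue`, `bh_adjusted_pvalue`.
#' @export
mutation_association <- function(switches, dataset, mutations, structures,
                                 scope = c("transcript", "gene"),
                                 protein_affecting_only = FALSE,
                                 n_background = 100L, universe = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (is.null(universe)) universe <- class_samples(dataset)$class2
  N <- length(universe)
  occ <- switch_occurrence_matrix(switches, dataset$tpm[, universe, drop = FALSE])
  med <- .gene_median_lengths(structures)
  pa_mut <- mutations[mutations$class %in% PROTEIN_AFFECTING, , drop = FALSE]
  tr <- structures$transcripts
  gene_span <- function(gid) {
    rows <- tr[tr$gene_id == gid, , drop = FALSE]
    list(chrom = rows$chrom[1L], start = min(rows$start), end = max(rows$end))
  }
  bg_M <- function(gid, mut) {
    sp <- gene_span(gid)
    unique(mut$sample[.hits_span(mut, sp$chrom, sp$start, sp$end)])
  }
  out <- vector("list", nrow(switches))
  for (r in seq_len(nrow(switches))) {
    ti <- switches$tumor_isoform[r]; ni <- switches$normal_isoform[r]
    S <- universe[occ[r, ] == 1L]
    M <- intersect(mutated_samples(ti, ni, mutations, structures, scope,
                                   protein_affecting_only), universe)
    M_pa <- intersect(mutated_samples(ti, ni, pa_mut, structures, scope),
                      universe)
    J <- jaccard_association(S, M)
    MI <- mutual_information_association(S, M, universe)
    n10 <- length(setdiff(S, M_pa)); n01 <- length(setdiff(M_pa, S))
    mx <- mutual_exclusion(n10, n01, N)
    bg_genes <- length_matched_genes(switches$gene[r], structures,
                                     min(n_background, length(med) - 1L))
    mut_for_jmi <- if (protein_affecting_only) pa_mut else mutations
    bg_j <- bg_mi <- bg_mx <- numeric(length(bg_genes))
    for (b in seq_along(bg_genes)) {
      Mb <- intersect(bg_M(bg_genes[b], mut_for_jmi), universe)
      bg_j[b] <- suppressWarnings(jaccard_association(S, Mb))
      bg_mi[b] <- mutual_information_association(S, Mb, universe)
      Mb_pa <- intersect(bg_M(bg_genes[b], pa_mut), universe)
      bg_mx[b] <- mutual_exclusion(length(setdiff(S, Mb_pa)),
                                   length(setdiff(Mb_pa, S)), N)
    }
    p <- delta_psi_mutation_test(switches[r, ], dataset, M)
    out[[r]] <- data.frame(
      gene = switches$gene[r], tumor_isoform = ti, normal_isoform = ni,
      n_switch = length(S), n_mutated = length(M),
      jaccard = J, j_zscore = as.numeric(background_zscore(J, bg_j)),
      mutual_information = MI,
      mi_zscore = as.numeric(background_zscore(MI, bg_mi)),
      mx = mx, mx_zscore = as.numeric(background_zscore(mx, bg_mx)),
      delta_psi_pvalue = as.numeric(p),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res$bh_adjusted_pvalue <- stats::p.adjust(res$delta_psi_pvalue, "BH")
  rownames(res) <- NULL
  res
}
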