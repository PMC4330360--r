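#' Within-sample expression rankings
#'
#' Ranks every transcript within each sample (column), rank 1 = lowest
#' expression, average ranks for ties. These rankings feed the S2
#' tie-breaking score.
#'
#' @param tpm numeric matrix, transcripts x samples.
#' @return matrix of the same shape holding within-sample ranks.
#' @export
sample_rankings <- function(tpm) {
  apply(as.matrix(tpm), 2L, rank, ties.method = "average")
}

.resolve_classes <- function(labels, class_levels) {
  labels <- as.character(labels)
  labs <- sort(unique(labels))
  if (length(labs) != 2L) stop("exactly 2 classes required")
  if (is.null(class_levels)) {
    class_levels <- if (setequal(labs, c("normal", "tumor")))
      c("normal", "tumor") else labs
  }
  if (!setequal(class_levels, labs)) stop("class_levels do not match labels")
  list(is1 = labels == class_levels[1L], is2 = labels == class_levels[2L],
       levels = class_levels)
}

#' Reversal score S1 for one oriented isoform pair
#'
#' S1 = P(x_i > x_j | C1) + P(x_i < x_j | C2) - 1, the consistency of the
#' expression-order reversal between the two classes. Frequencies are
#' computed over all samples of each class. Under the default `"strict"`
#' tie policy, tied samples (including both-zero) count in the denominator
#' but in neither numerator, so unexpressed pairs are penalized; under
#' `"half"` each tie contributes 0.5 to both order frequencies.
#'
#' @param x_i,x_j numeric expression vectors for the two isoforms over the
#'   same samples.
#' @param labels class label per sample.
#' @param class_levels optional length-2 vector fixing (class1, class2).
#' @param tie_policy `"strict"` (default) or `"half"`.
#' @return S1 in \[-1, 1\].
#' @export
score_s1 <- function(x_i, x_j, labels, class_levels = NULL,
                     tie_policy = c("strict", "half")) {
  tie_policy <- match.arg(tie_policy)
  if (length(x_i) != length(x_j) || length(x_i) != length(labels))
    stop("x_i, x_j and labels must have equal length")
  cl <- .resolve_classes(labels, class_levels)
  n1 <- sum(cl$is1); n2 <- sum(cl$is2)
  if (n1 < 1L || n2 < 1L) stop("need >=1 sample per class")
  gt <- x_i > x_j; lt <- x_i < x_j
  w <- if (tie_policy == "half") 0.5 else 0
  tie <- !gt & !lt
  p1 <- (sum(gt & cl$is1) + w * sum(tie & cl$is1)) / n1
  p2 <- (sum(lt & cl$is2) + w * sum(tie & cl$is2)) / n2
  p1 + p2 - 1
}

#' Rank-difference score S2 for one isoform pair
#'
#' The absolute difference between the two classes of the mean
#' within-sample rank difference of the pair:
#' `|mean_C1(r_i - r_j) - mean_C2(r_i - r_j)|`. Used only to break S1
#' ties in the ranking; direction-invariant by the outer absolute value.
#'
#' @param r_i,r_j within-sample ranks of the two isoforms (see
#'   [sample_rankings()]) over the same samples.
#' @param labels class label per sample.
#' @param class_levels optional length-2 vector fixing (class1, class2).
#' @return S2 >= 0.
#' @export
score_s2 <- function(r_i, r_j, labels, class_levels = NULL) {
  if (length(r_i) != length(r_j) || length(r_i) != length(labels))
    stop("r_i, r_j and labels must have equal length")
  cl <- .resolve_classes(labels, class_levels)
  d <- r_i - r_j
  abs(mean(d[cl$is1]) - mean(d[cl$is2]))
}

# binary entropy (bits) of the split (a, b); 0 when a + b == 0
.h2 <- function(a, b) {
  n <- a + b
  p <- ifelse(n > 0, a / n, 0)
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  ifelse(n > 0, -(plogp(p) + plogp(1 - p)), 0)
}

#' Information gain of a single isoform-pair rule
#'
#' The reduction in class entropy (bits) obtained by splitting the
#' training samples by the rule's vote. The rule votes class1 when the
#' tumor isoform is expressed below the normal isoform and class2
#' otherwise (ties vote class2).
#'
#' @param rule list or one-row data.frame with `tumor_isoform` and
#'   `normal_isoform` transcript ids.
#' @param dataset an `ExpressionDataset` containing both isoforms.
#' @return IG in bits, in \[0, H(class)\].
#' @export
information_gain <- function(rule, dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  ti <- rule$tumor_isoform; ni <- rule$normal_isoform
  if (!ti %in% rownames(dataset$tpm) || !ni %in% rownames(dataset$tpm))
    stop("rule isoforms not present in dataset")
  vote_normal <- dataset$tpm[ti, ] < dataset$tpm[ni, ]
  is1 <- dataset$class_of == dataset$class_levels[1L]
  n1 <- sum(is1); n2 <- sum(!is1); n <- n1 + n2
  a1 <- sum(vote_normal & is1); a2 <- sum(vote_normal & !is1)
  .h2(n1, n2) -
    ((a1 + a2) / n) * .h2(a1, a2) -
    ((n - a1 - a2) / n) * .h2(n1 - a1, n2 - a2)
}

# Precomputed per-pair order tables. Everything that depends only on the
# expression matrix -- not on the class labels -- is computed once here so
# that cross-validation folds and label permutations reduce to small
# matrix products.
#
# mode "isoform": all unordered same-gene transcript pairs.
# mode "gene":    all unordered cross-feature pairs (classic gene-level
#                 top-scoring-pairs); caller handles disjoint selection.
.pair_tables <- function(dataset, mode = c("isoform", "gene")) {
  mode <- match.arg(mode)
  X <- dataset$tpm
  tid <- rownames(X)
  if (mode == "isoform") {
    idx <- split(seq_along(tid), dataset$gene_of)
    idx <- idx[lengths(idx) >= 2L]
    if (!length(idx)) stop("no multi-isoform genes in dataset; run filter_genes()?")
    pairs <- do.call(rbind, lapply(idx, function(ii) {
      cmb <- utils::combn(ii, 2L)
      cbind(i = cmb[1L, ], j = cmb[2L, ])
    }))
    gene <- rep(names(idx), vapply(idx, function(ii) choose(length(ii), 2L),
                                   numeric(1)))
  } else {
    if (length(tid) > 3000L)
      stop("gene mode enumerates all cross pairs; too many features (",
           length(tid), ")")
    cmb <- utils::combn(seq_along(tid), 2L)
    pairs <- cbind(i = cmb[1L, ], j = cmb[2L, ])
    gene <- paste(tid[pairs[, "i"]], tid[pairs[, "j"]], sep = ":")
  }
  Xi <- X[pairs[, "i"], , drop = FALSE]
  Xj <- X[pairs[, "j"], , drop = FALSE]
  R <- sample_rankings(X)
  list(
    gene = gene,
    iso_i = tid[pairs[, "i"]],
    iso_j = tid[pairs[, "j"]],
    GT = (Xi > Xj) + 0,
    LT = (Xi < Xj) + 0,
    D = R[pairs[, "i"], , drop = FALSE] - R[pairs[, "j"], , drop = FALSE],
    samples = colnames(X)
  )
}

# Score every pair for a given class split (0/1 masks over the table's
# sample columns, possibly a subset). Returns one row per pair with the
# orientation that maximizes S1 (on an exact orientation tie the
# first-listed transcript is kept as the normal isoform).
.score_pairs <- function(tab, is1, is2, tie_policy = "strict") {
  n1 <- sum(is1); n2 <- sum(is2)
  cGT1 <- as.vector(tab$GT %*% is1); cLT1 <- as.vector(tab$LT %*% is1)
  cGT2 <- as.vector(tab$GT %*% is2); cLT2 <- as.vector(tab$LT %*% is2)
  t1 <- n1 - cGT1 - cLT1; t2 <- n2 - cGT2 - cLT2
  w <- if (tie_policy == "half") 0.5 else 0
  s1_fwd <- (cGT1 + w * t1) / n1 + (cLT2 + w * t2) / n2 - 1
  s1_rev <- (cLT1 + w * t1) / n1 + (cGT2 + w * t2) / n2 - 1
  fwd <- s1_fwd >= s1_rev
  s1 <- ifelse(fwd, s1_fwd, s1_rev)
  d1 <- as.vector(tab$D %*% is1) / n1
  d2 <- as.vector(tab$D %*% is2) / n2
  s2 <- abs(d1 - d2)
  # In the S1-maximizing argument order the first isoform sits higher in
  # class1, so it is the *normal* isoform; the rule lists the tumor
  # isoform (higher in class2) first. Vote "normal" iff the tumor
  # isoform is strictly below the normal isoform.
  a1 <- ifelse(fwd, cGT1, cLT1)  # class1 samples voting normal
  a2 <- ifelse(fwd, cGT2, cLT2)  # class2 samples voting normal
  n <- n1 + n2
  ig <- .h2(n1, n2) -
    ((a1 + a2) / n) * .h2(a1, a2) -
    ((n - a1 - a2) / n) * .h2(n1 - a1, n2 - a2)
  data.frame(
    gene = tab$gene,
    tumor_isoform = ifelse(fwd, tab$iso_j, tab$iso_i),
    normal_isoform = ifelse(fwd, tab$iso_i, tab$iso_j),
    s1 = s1, s2 = s2, ig = ig,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# per-gene best pair then global sort: S1 desc, S2 desc, gene asc
.reduce_ranking <- function(scores, mode = "isoform") {
  scores <- scores[scores$s1 >= 0, , drop = FALSE]
  if (!nrow(scores)) {
    scores$rank <- integer(0)
    return(scores)
  }
  ord <- order(-scores$s1, -scores$s2, scores$gene, scores$tumor_isoform)
  scores <- scores[ord, , drop = FALSE]
  if (mode == "isoform") {
    scores <- scores[!duplicated(scores$gene), , drop = FALSE]
  } else {
    # classic kTSP: greedy disjoint pairs down the sorted list
    used <- character(0)
    keep <- logical(nrow(scores))
    for (r in seq_len(nrow(scores))) {
      f <- c(scores$tumor_isoform[r], scores$normal_isoform[r])
      if (!any(f %in% used)) {
        keep[r] <- TRUE
        used <- c(used, f)
      }
    }
    scores <- scores[keep, , drop = FALSE]
  }
  ord <- order(-scores$s1, -scores$s2, scores$gene)
  scores <- scores[ord, , drop = FALSE]
  scores$rank <- seq_len(nrow(scores))
  rownames(scores) <- NULL
  scores
}

#' Rank isoform pairs by reversal consistency
#'
#' Evaluates every unordered same-gene isoform pair in the orientation
#' that maximizes S1, keeps the best pair per gene (by S1, then S2), and
#' sorts globally by S1 descending, S2 descending, gene id ascending.
#' Pairs whose best-orientation S1 is negative (possible only when ties
#' dominate under the strict policy, the all-tie degenerate case reaching
#' S1 = -1) carry no reversal evidence and are excluded.
#'
#' In `mode = "gene"` every cross-feature pair is evaluated (classic
#' gene-level top-scoring-pairs on a [gene_level_dataset()]), and pairs
#' are selected greedily down the sorted list so that each feature
#' appears in at most one listed pair.
#'
#' @param dataset an `ExpressionDataset` (gene-filtered for isoform mode).
#' @param tie_policy `"strict"` (default) or `"half"`, see [score_s1()].
#' @param mode `"isoform"` (same-gene pairs) or `"gene"` (all pairs,
#'   disjoint selection).
#' @return data.frame with columns `gene`, `tumor_isoform`,
#'   `normal_isoform`, `s1`, `s2`, `ig`, `rank`.
#' @export
rank_pairs <- function(dataset, tie_policy = c("strict", "half"),
                       mode = c("isoform", "gene")) {
  tie_policy <- match.arg(tie_policy)
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "ExpressionDataset"))
  tab <- .pair_tables(dataset, mode)
  is1 <- as.numeric(dataset$class_of[tab$samples] == dataset$class_levels[1L])
  is2 <- 1 - is1
  .reduce_ranking(.score_pairs(tab, is1, is2, tie_policy), mode)
}
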