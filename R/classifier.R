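#' Majority-voting isoform-pair classifier
#'
#' Bundles an ordered, odd-length list of isoform-pair rules with the two
#' class labels. Each rule votes class1 ("normal") when its tumor isoform
#' is expressed below its normal isoform and class2 ("tumor") otherwise;
#' the sample is assigned the most-voted class. With k odd no vote tie is
#' possible.
#'
#' @param rules data.frame with columns `gene`, `tumor_isoform`,
#'   `normal_isoform` (extra score columns are kept); odd number of rows,
#'   all genes distinct.
#' @param class_levels length-2 character vector (class1, class2).
#' @return object of class `"PairClassifier"`.
#' @export
pair_classifier <- function(rules, class_levels) {
  rules <- as.data.frame(rules)
  stopifnot(all(c("gene", "tumor_isoform", "normal_isoform") %in% names(rules)),
            length(class_levels) == 2L)
  k <- nrow(rules)
  if (k < 1L || k %% 2L == 0L)
    stop("number of rules must be odd and >= 1, got ", k)
  if (anyDuplicated(rules$gene))
    stop("classifier rules must come from distinct genes")
  structure(list(rules = rules, class_levels = class_levels, k = k),
            class = "PairClassifier")
}

#' @export
print.PairClassifier <- function(x, ...) {
  cat(sprintf("PairClassifier: k = %d rules (%s vs %s)\n", x$k,
              x$class_levels[1], x$class_levels[2]))
  print(x$rules[, c("gene", "tumor_isoform", "normal_isoform")], ...)
  invisible(x)
}

#' Evaluate a single isoform-pair rule on one sample
#'
#' Rule semantics: if the tumor isoform has lower expression than the
#' normal isoform the vote is class1 ("normal"); otherwise -- including
#' exact expression ties such as both isoforms at zero -- the vote is
#' class2 ("tumor", the "else" branch).
#'
#' @param rule list or one-row data.frame with `tumor_isoform`,
#'   `normal_isoform`.
#' @param expr named numeric vector of one sample's expression.
#' @param class_levels length-2 vector (class1, class2); defaults to
#'   `c("normal", "tumor")`.
#' @return the voted class label.
#' @export
evaluate_rule <- function(rule, expr, class_levels = c("normal", "tumor")) {
  ti <- rule$tumor_isoform; ni <- rule$normal_isoform
  if (!ti %in% names(expr) || !ni %in% names(expr))
    stop("isoform absent from sample: ",
         paste(setdiff(c(ti, ni), names(expr)), collapse = ", "))
  if (expr[[ti]] < expr[[ni]]) class_levels[1L] else class_levels[2L]
}

#' Classify one sample by majority voting
#'
#' @param model a [pair_classifier()].
#' @param expr named numeric vector of one sample's expression covering
#'   every rule isoform.
#' @return list with `class` (winning label) and `votes` (the winner's
#'   vote count).
#' @export
classify_sample <- function(model, expr) {
  stopifnot(inherits(model, "PairClassifier"))
  votes <- vapply(seq_len(model$k), function(r)
    evaluate_rule(model$rules[r, ], expr, model$class_levels), character(1))
  n2 <- sum(votes == model$class_levels[2L])
  if (n2 * 2L > model$k)
    list(class = model$class_levels[2L], votes = n2)
  else
    list(class = model$class_levels[1L], votes = model$k - n2)
}

#' Classify every sample of an expression matrix
#'
#' @param model a [pair_classifier()].
#' @param tpm numeric matrix, transcripts x samples.
#' @return data.frame with columns `sample`, `predicted`, `votes`.
#' @export
classify_samples <- function(model, tpm) {
  stopifnot(inherits(model, "PairClassifier"))
  tpm <- as.matrix(tpm)
  miss <- setdiff(c(model$rules$tumor_isoform, model$rules$normal_isoform),
                  rownames(tpm))
  if (length(miss)) stop("isoform absent from matrix: ",
                         paste(miss, collapse = ", "))
  # vote class2 unless tumor isoform strictly below normal isoform
  vt <- tpm[model$rules$tumor_isoform, , drop = FALSE] >=
        tpm[model$rules$normal_isoform, , drop = FALSE]
  n2 <- colSums(vt)
  tumor_wins <- n2 * 2L > model$k
  data.frame(
    sample = colnames(tpm),
    predicted = ifelse(tumor_wins, model$class_levels[2L], model$class_levels[1L]),
    votes = as.integer(ifelse(tumor_wins, n2, model$k - n2)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Confusion counts for predicted vs true class labels
#'
#' @param predicted,truth character vectors of class labels.
#' @param positive the label counted as positive (default: the most
#'   frequent truth label's complement is not assumed -- pass explicitly
#'   for reporting; the accuracy value is symmetric either way).
#' @return list with integer fields `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, truth, positive) {
  stopifnot(length(predicted) == length(truth))
  list(TP = sum(predicted == positive & truth == positive),
       TN = sum(predicted != positive & truth != positive),
       FP = sum(predicted == positive & truth != positive),
       FN = sum(predicted != positive & truth == positive))
}

#' Classification accuracy from confusion counts
#'
#' accuracy = (TP + TN) / (TP + TN + FN + FP). Symmetric with respect to
#' which class is designated positive.
#'
#' @param counts list or vector with `TP`, `TN`, `FP`, `FN`.
#' @return accuracy in \[0, 1\].
#' @export
accuracy <- function(counts) {
  tot <- counts$TP + counts$TN + counts$FP + counts$FN
  if (is.null(tot) || tot == 0) stop("no evaluated samples")
  (counts$TP + counts$TN) / tot
}

#' Blind test of a classifier on held-out samples
#'
#' Evaluates the model on samples disjoint from training, all sharing one
#' known class, and reports the fraction correctly labeled together with
#' the per-sample count of rules voting the expected class (the
#' histogram of correct votes).
#'
#' @param model a [pair_classifier()].
#' @param tpm expression matrix of the held-out samples.
#' @param expected_class the true class label of every sample.
#' @return list with `fraction_correct`, `vote_histogram` (table over
#'   0..k correct votes) and `per_sample` data.frame.
#' @export
blind_test <- function(model, tpm, expected_class) {
  stopifnot(inherits(model, "PairClassifier"),
            expected_class %in% model$class_levels)
  tpm <- as.matrix(tpm)
  vt <- tpm[model$rules$tumor_isoform, , drop = FALSE] >=
        tpm[model$rules$normal_isoform, , drop = FALSE]
  votes_tumor <- colSums(vt)
  correct_votes <- if (expected_class == model$class_levels[2L])
    votes_tumor else model$k - votes_tumor
  pred <- classify_samples(model, tpm)
  per_sample <- data.frame(sample = colnames(tpm),
                           predicted = pred$predicted,
                           correct_votes = as.integer(correct_votes),
                           stringsAsFactors = FALSE)
  hist <- table(factor(correct_votes, levels = 0:model$k))
  list(fraction_correct = mean(pred$predicted == expected_class),
       vote_histogram = hist,
       per_sample = per_sample)
}

#' Collapse a dataset to gene-level expression
#'
#' Gene expression is the sum of the member transcripts' TPM per sample.
#' The result is an `ExpressionDataset` whose features are genes (each
#' mapping to itself), suitable for classic gene-level
#' top-scoring-pairs ranking via `rank_pairs(..., mode = "gene")`.
#'
#' @param dataset an `ExpressionDataset`.
#' @return gene-level `ExpressionDataset`.
#' @export
gene_level_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  g <- as.factor(dataset$gene_of[rownames(dataset$tpm)])
  gx <- rowsum(dataset$tpm, g, reorder = TRUE)
  gids <- rownames(gx)
  expression_dataset(gx, stats::setNames(gids, gids), dataset$class_of,
                     class_levels = dataset$class_levels,
                     pairing = dataset$pairing, values = "tpm")
}
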