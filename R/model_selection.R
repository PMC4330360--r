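#' Leave-one-pair-out cross-validation
#'
#' One fold per patient: the patient's tumor and normal samples are held
#' out, the full isoform-pair ranking is recomputed on the remaining
#' samples, and the top-k majority-voting classifiers (k = 1, 3, ...,
#' k_max) are evaluated on the held-out pair. Reported per k is the mean
#' accuracy over folds. Folds are deterministic given the pairing order.
#'
#' @param dataset an `ExpressionDataset` with `pairing` defined
#'   (>= 3 patient pairs).
#' @param k_max largest model size to evaluate (default 11; capped at the
#'   number of available pairs per fold).
#' @param tie_policy passed to the ranking, see [score_s1()].
#' @return object of class `"CrossValResult"`: list with `k` (odd sizes),
#'   `mean_accuracy` (named by k), `fold_accuracy` (folds x k matrix),
#'   `fold_rankings` (list of per-fold ranking data.frames), `k_opt`.
#' @export
cross_validate <- function(dataset, k_max = 11L,
                           tie_policy = c("strict", "half")) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (is.null(dataset$pairing))
    stop("cross_validate needs patient pairing; supply a labels file with ",
         "a patient column or a pairing data.frame")
  if (nrow(dataset$pairing) < 3L) stop("need >= 3 patient pairs")
  tab <- .pair_tables(dataset, "isoform")
  cls <- dataset$class_of[tab$samples]
  base1 <- as.numeric(cls == dataset$class_levels[1L])
  base2 <- 1 - base1
  ks <- seq(1L, max(1L, k_max), by = 2L)
  folds <- nrow(dataset$pairing)
  acc <- matrix(NA_real_, folds, length(ks),
                dimnames = list(dataset$pairing$patient, ks))
  rankings <- vector("list", folds)
  for (f in seq_len(folds)) {
    held <- c(dataset$pairing$class1[f], dataset$pairing$class2[f])
    in_train <- as.numeric(!(tab$samples %in% held))
    rk <- .reduce_ranking(.score_pairs(tab, base1 * in_train,
                                       base2 * in_train, tie_policy))
    rankings[[f]] <- rk
    test_tpm <- dataset$tpm[, held, drop = FALSE]
    truth <- dataset$class_of[held]
    for (ki in seq_along(ks)) {
      k <- min(ks[ki], nrow(rk) - (1 - nrow(rk) %% 2L))
      if (k < 1L) next
      model <- pair_classifier(rk[seq_len(k), ], dataset$class_levels)
      pred <- classify_samples(model, test_tpm)
      acc[f, ki] <- mean(pred$predicted == truth)
    }
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  names(mean_acc) <- ks
  structure(list(k = ks, mean_accuracy = mean_acc, fold_accuracy = acc,
                 fold_rankings = rankings,
                 k_opt = select_k_opt(mean_acc)),
            class = "CrossValResult")
}

#' @export
print.CrossValResult <- function(x, ...) {
  cat("Cross-validation (leave-one-pair-out):\n")
  print(round(x$mean_accuracy, 4))
  cat("k_opt =", x$k_opt, "\n")
  invisible(x)
}

#' Select the optimal model size
#'
#' Returns the smallest (odd) k achieving the highest mean accuracy.
#' Accuracies within 1e-10 of the maximum are treated as ties to avoid
#' float artifacts.
#'
#' @param mean_accuracy numeric vector of per-k mean accuracies, named by
#'   the (odd) k values.
#' @return the selected k, integer.
#' @export
select_k_opt <- function(mean_accuracy) {
  if (!length(mean_accuracy)) stop("empty accuracy table")
  ks <- as.integer(names(mean_accuracy))
  if (any(is.na(ks))) stop("mean_accuracy must be named by k")
  best <- mean_accuracy >= max(mean_accuracy, na.rm = TRUE) - 1e-10
  min(ks[which(best)])
}

#' Build the final classifier from the global ranking
#'
#' Takes the top `k_opt` pairs of the full-training-data ranking as the
#' minimal predictive model.
#'
#' @param dataset an `ExpressionDataset`.
#' @param k_opt odd model size (typically from [cross_validate()]).
#' @param ranking optional precomputed [rank_pairs()] result.
#' @param tie_policy passed to [rank_pairs()] when `ranking` is NULL.
#' @return a [pair_classifier()].
#' @export
build_final_model <- function(dataset, k_opt, ranking = NULL,
                              tie_policy = c("strict", "half")) {
  tie_policy <- match.arg(tie_policy)
  if (is.null(ranking)) ranking <- rank_pairs(dataset, tie_policy)
  if (nrow(ranking) < k_opt)
    stop("global ranking has ", nrow(ranking), " pairs, fewer than k_opt = ",
         k_opt)
  pair_classifier(ranking[seq_len(k_opt), ], dataset$class_levels)
}
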