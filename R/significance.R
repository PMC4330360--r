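#' Label-permutation null for pair scores
#'
#' For each of `n_perm` uniform random permutations of the class labels
#' (class sizes preserved; pairing ignored), the pair scoring is rerun
#' and the top S1 -- the score of the pair that would head the permuted
#' ranking -- and the maximum IG over pairs are recorded. The
#' significance thresholds are the maxima of the two recorded lists
#' (max-statistic family-wise control). Degenerate all-tie datasets,
#' where every pair's best-orientation S1 is negative under the strict
#' tie policy, are reported explicitly via `degenerate = TRUE`.
#'
#' A single seeded generator draws permutation i's labels sequentially,
#' so runs are reproducible and prefix-stable in `n_perm`.
#'
#' @param dataset an `ExpressionDataset` with >= 2 samples per class.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer RNG seed.
#' @param tie_policy see [score_s1()].
#' @return object of class `"PermutationNull"`: list with `n_perm`,
#'   `max_s1`, `max_ig` (per-permutation vectors), `s1_threshold`,
#'   `ig_threshold`, `seed`, `degenerate`.
#' @export
permutation_test <- function(dataset, n_perm = 1000L, seed = 1L,
                             tie_policy = c("strict", "half")) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (n_perm < 1L) stop("n_perm must be >= 1")
  cls <- dataset$class_of
  if (min(table(cls)) < 2L) stop("need >= 2 samples per class")
  tab <- .pair_tables(dataset, "isoform")
  lab <- cls[tab$samples]
  max_s1 <- numeric(n_perm)
  max_ig <- numeric(n_perm)
  degenerate <- logical(n_perm)
  set.seed(seed)
  for (p in seq_len(n_perm)) {
    perm <- sample(lab)
    is1 <- as.numeric(perm == dataset$class_levels[1L])
    sc <- .score_pairs(tab, is1, 1 - is1, tie_policy)
    listed <- sc$s1 >= 0  # pairs that would enter the permuted ranking
    if (any(listed)) {
      max_s1[p] <- max(sc$s1[listed])
      max_ig[p] <- max(sc$ig[listed])
    } else {
      max_s1[p] <- -1
      max_ig[p] <- 0
      degenerate[p] <- TRUE
    }
  }
  structure(list(n_perm = n_perm, max_s1 = max_s1, max_ig = max_ig,
                 s1_threshold = max(max_s1), ig_threshold = max(max_ig),
                 seed = seed, degenerate = any(degenerate)),
            class = "PermutationNull")
}

#' @export
print.PermutationNull <- function(x, ...) {
  cat(sprintf("PermutationNull: %d permutations (seed %d)\n", x$n_perm, x$seed))
  cat(sprintf("  S1 threshold = %.4f, IG threshold = %.4f\n",
              x$s1_threshold, x$ig_threshold))
  if (x$degenerate)
    cat("  note: some permutations were fully degenerate (all pairs tied)\n")
  invisible(x)
}

#' Filter a ranking to significant pairs
#'
#' A pair is significant when both its S1 and its IG strictly exceed the
#' corresponding permutation maxima. Empirical p-values
#' `(1 + #permutations >= observed) / (n_perm + 1)` are attached for
#' transparency; the selection itself uses only the max-threshold rule.
#'
#' @param ranking a [rank_pairs()] data.frame.
#' @param null a [permutation_test()] result computed on the same dataset.
#' @return the significant subset of `ranking` with extra columns
#'   `p_s1`, `p_ig`.
#' @export
significant_pairs <- function(ranking, null) {
  stopifnot(inherits(null, "PermutationNull"))
  keep <- ranking$s1 > null$s1_threshold & ranking$ig > null$ig_threshold
  out <- ranking[keep, , drop = FALSE]
  if (nrow(out)) {
    out$p_s1 <- vapply(out$s1, function(v)
      (1 + sum(null$max_s1 >= v)) / (null$n_perm + 1), numeric(1))
    out$p_ig <- vapply(out$ig, function(v)
      (1 + sum(null$max_ig >= v)) / (null$n_perm + 1), numeric(1))
  } else {
    out$p_s1 <- numeric(0)
    out$p_ig <- numeric(0)
  }
  rownames(out) <- NULL
  out
}

#' Subtype one-vs-pool recurrence analysis
#'
#' Repeatedly subsamples a balanced comparison of one target subtype
#' against a pool of the other subtypes (`group_size` target samples vs
#' `pool_per_other` from each other subtype), ranks isoform pairs and
#' runs the permutation test on each subsample, and records how often
#' each oriented pair is significant. Pairs significant in more than
#' `freq_cutoff` of the iterations form the recurrence model (odd count
#' enforced by truncation).
#'
#' @param dataset an `ExpressionDataset`; only its class2 ("tumor")
#'   samples are used.
#' @param subtype_of named character vector: subtype label per tumor
#'   sample.
#' @param target the subtype compared against the pool.
#' @param n_iter number of subsampling iterations (default 100).
#' @param group_size target-subtype samples drawn per iteration.
#' @param pool_per_other samples drawn from each other subtype.
#' @param n_perm permutations per iteration.
#' @param seed integer RNG seed.
#' @param freq_cutoff recurrence frequency required for the model
#'   (default 0.8).
#' @param tie_policy see [score_s1()].
#' @return object of class `"SubtypeRecurrence"`: list with `frequency`
#'   (data.frame per pair: counts, frequency, mean s1), `n_iter`,
#'   `model` (a [pair_classifier()] or NULL), `group_size`,
#'   `pool_per_other`.
#' @export
subtype_recurrence <- function(dataset, subtype_of, target, n_iter = 100L,
                               group_size = 45L, pool_per_other = 15L,
                               n_perm = 100L, seed = 1L, freq_cutoff = 0.8,
                               tie_policy = c("strict", "half")) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(inherits(dataset, "ExpressionDataset"))
  tumor <- names(dataset$class_of)[dataset$class_of == dataset$class_levels[2L]]
  subtype_of <- subtype_of[intersect(names(subtype_of), tumor)]
  groups <- split(names(subtype_of), subtype_of)
  if (!target %in% names(groups)) stop("unknown target subtype: ", target)
  if (length(groups[[target]]) < group_size)
    stop("target subtype has ", length(groups[[target]]),
         " samples, need ", group_size)
  others <- setdiff(names(groups), target)
  short <- others[vapply(groups[others], length, integer(1)) < pool_per_other]
  if (length(short))
    stop("subtype(s) with fewer than ", pool_per_other, " samples: ",
         paste(short, collapse = ", "))
  set.seed(seed)
  counts <- new.env(parent = emptyenv())
  s1sum <- new.env(parent = emptyenv())
  for (it in seq_len(n_iter)) {
    grp <- sample(groups[[target]], group_size)
    pool <- unlist(lapply(groups[others], sample, pool_per_other),
                   use.names = FALSE)
    sel <- c(pool, grp)
    cls <- stats::setNames(c(rep("pool", length(pool)),
                             rep(target, length(grp))), sel)
    sub <- expression_dataset(dataset$tpm[, sel, drop = FALSE],
                              dataset$gene_of, cls,
                              class_levels = c("pool", target))
    rk <- rank_pairs(sub, tie_policy)
    null <- permutation_test(sub, n_perm = n_perm,
                             seed = sample.int(.Machine$integer.max, 1L),
                             tie_policy = tie_policy)
    sig <- significant_pairs(rk, null)
    for (r in seq_len(nrow(sig))) {
      key <- paste(sig$gene[r], sig$tumor_isoform[r], sig$normal_isoform[r],
                   sep = "\t")
      counts[[key]] <- get0(key, envir = counts, ifnotfound = 0L) + 1L
      s1sum[[key]] <- get0(key, envir = s1sum, ifnotfound = 0) + sig$s1[r]
    }
  }
  keys <- ls(counts)
  freq <- if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
    data.frame(gene = parts[, 1L], tumor_isoform = parts[, 2L],
               normal_isoform = parts[, 3L],
               n_significant = vapply(keys, function(k) counts[[k]], integer(1)),
               frequency = vapply(keys, function(k) counts[[k]], integer(1)) / n_iter,
               mean_s1 = vapply(keys, function(k) s1sum[[k]] / counts[[k]],
                                numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(gene = character(0), tumor_isoform = character(0),
               normal_isoform = character(0), n_significant = integer(0),
               frequency = numeric(0), mean_s1 = numeric(0))
  }
  freq <- freq[order(-freq$frequency, -freq$mean_s1, freq$gene), , drop = FALSE]
  rownames(freq) <- NULL
  model <- NULL
  hit <- freq[freq$frequency > freq_cutoff, , drop = FALSE]
  hit <- hit[!duplicated(hit$gene), , drop = FALSE]
  if (nrow(hit)) {
    k <- nrow(hit) - (1L - nrow(hit) %% 2L)  # largest odd <= nrow
    model <- pair_classifier(hit[seq_len(k), ], c("pool", target))
  }
  structure(list(frequency = freq, n_iter = n_iter, model = model,
                 group_size = group_size, pool_per_other = pool_per_other,
                 target = target, freq_cutoff = freq_cutoff),
            class = "SubtypeRecurrence")
}
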