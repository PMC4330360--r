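# Brute-force oracles, kept deliberately independent of the package's
# vectorized scoring path: explicit per-sample loops and naive sorts.

oracle_s1 <- function(xi, xj, labels, lev = c("normal", "tumor"),
                      tie_policy = "strict") {
  w <- if (tie_policy == "half") 0.5 else 0
  c1 <- labels == lev[1]; c2 <- labels == lev[2]
  p1 <- (sum(xi[c1] > xj[c1]) + w * sum(xi[c1] == xj[c1])) / sum(c1)
  p2 <- (sum(xi[c2] < xj[c2]) + w * sum(xi[c2] == xj[c2])) / sum(c2)
  p1 + p2 - 1
}

oracle_s2 <- function(tpm, i, j, labels, lev = c("normal", "tumor")) {
  R <- apply(tpm, 2, rank)
  d <- R[i, ] - R[j, ]
  abs(mean(d[labels == lev[1]]) - mean(d[labels == lev[2]]))
}

oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

oracle_ig <- function(vote_normal, labels) {
  H <- oracle_entropy(table(labels))
  Hn <- if (any(vote_normal)) oracle_entropy(table(labels[vote_normal])) else 0
  Ht <- if (any(!vote_normal)) oracle_entropy(table(labels[!vote_normal])) else 0
  H - mean(vote_normal) * Hn - mean(!vote_normal) * Ht
}

# exhaustive same-gene pair enumeration, both orientations, naive sort
oracle_rank_pairs <- function(ds, tie_policy = "strict") {
  X <- ds$tpm
  lev <- ds$class_levels
  lab <- ds$class_of[colnames(X)]
  rows <- list()
  for (g in sort(unique(as.character(ds$gene_of)))) {
    tids <- rownames(X)[ds$gene_of == g]
    if (length(tids) < 2) next
    cand <- list()
    for (a in seq_along(tids)) for (b in seq_along(tids)) if (a < b) {
      xa <- X[tids[a], ]; xb <- X[tids[b], ]
      s_ab <- oracle_s1(xa, xb, lab, lev, tie_policy)
      s_ba <- oracle_s1(xb, xa, lab, lev, tie_policy)
      if (s_ab >= s_ba) {
        normal <- tids[a]; tumor <- tids[b]; s1 <- s_ab
      } else {
        normal <- tids[b]; tumor <- tids[a]; s1 <- s_ba
      }
      cand[[length(cand) + 1]] <- data.frame(
        gene = g, tumor_isoform = tumor, normal_isoform = normal, s1 = s1,
        s2 = oracle_s2(X, tids[a], tids[b], lab, lev),
        ig = oracle_ig(X[tumor, ] < X[normal, ], lab),
        stringsAsFactors = FALSE)
    }
    cand <- do.call(rbind, cand)
    cand <- cand[cand$s1 >= 0, , drop = FALSE]
    if (!nrow(cand)) next
    cand <- cand[order(-cand$s1, -cand$s2, cand$tumor_isoform), , drop = FALSE]
    rows[[g]] <- cand[1, ]
  }
  if (!length(rows))
    return(data.frame(gene = character(0), tumor_isoform = character(0),
                      normal_isoform = character(0), s1 = numeric(0),
                      s2 = numeric(0), ig = numeric(0), rank = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(-out$s1, -out$s2, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# random small instance with integer expression (plenty of ties and zeros)
random_dataset <- function(seed, max_genes = 10, max_iso = 5,
                           max_per_class = 6) {
  set.seed(seed)
  G <- sample(2:max_genes, 1)
  n1 <- sample(2:max_per_class, 1)
  n2 <- sample(2:max_per_class, 1)
  k <- sample(2:max_iso, G, replace = TRUE)
  gid <- sprintf("g%02d", seq_len(G))
  tid <- unlist(lapply(seq_len(G), function(g)
    sprintf("%s.t%d", gid[g], seq_len(k[g]))), use.names = FALSE)
  gene_of <- stats::setNames(rep(gid, k), tid)
  samples <- c(sprintf("n%02d", seq_len(n1)), sprintf("t%02d", seq_len(n2)))
  class_of <- stats::setNames(c(rep("normal", n1), rep("tumor", n2)), samples)
  repeat {
    X <- matrix(sample(0:6, length(tid) * (n1 + n2), replace = TRUE),
                length(tid), dimnames = list(tid, samples))
    if (all(colSums(X) > 0)) break
  }
  expression_dataset(X, gene_of, class_of, values = "tpm")
}

# tiny hand-buildable dataset: 3 genes x 2 isoforms, perfect planted
# reversal in gene gA, constant order in gB, noise-free
toy_dataset <- function(n1 = 4, n2 = 4, paired = (n1 == n2)) {
  samples <- c(sprintf("n%d", seq_len(n1)), sprintf("t%d", seq_len(n2)))
  class_of <- stats::setNames(c(rep("normal", n1), rep("tumor", n2)), samples)
  X <- rbind(
    gA.t1 = c(rep(10, n1), rep(40, n2)),  # tumor isoform of the switch
    gA.t2 = c(rep(40, n1), rep(10, n2)),  # normal isoform
    gB.t1 = c(rep(30, n1), rep(30, n2)),
    gB.t2 = c(rep(5, n1), rep(5, n2)),
    gC.t1 = c(seq_len(n1) + 10, seq_len(n2) + 10),
    gC.t2 = c(seq_len(n1) + 20, seq_len(n2) + 5)
  )
  colnames(X) <- samples
  gene_of <- stats::setNames(rep(c("gA", "gB", "gC"), each = 2), rownames(X))
  pairing <- NULL
  if (paired)
    pairing <- data.frame(patient = sprintf("p%d", seq_len(n1)),
                          class1 = sprintf("n%d", seq_len(n1)),
                          class2 = sprintf("t%d", seq_len(n1)),
                          stringsAsFactors = FALSE)
  expression_dataset(X, gene_of, class_of, pairing = pairing, values = "tpm")
}
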