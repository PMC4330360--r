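test_that("rule evaluation follows the else-goes-to-tumor semantics", {
  rule <- list(tumor_isoform = "a", normal_isoform = "b")
  expect_equal(evaluate_rule(rule, c(a = 2, b = 5)), "normal")
  expect_equal(evaluate_rule(rule, c(a = 5, b = 2)), "tumor")
  expect_equal(evaluate_rule(rule, c(a = 3, b = 3)), "tumor")
  expect_equal(evaluate_rule(rule, c(a = 0, b = 0)), "tumor")
  expect_error(evaluate_rule(rule, c(a = 1)), "absent")
})

test_that("majority voting with odd k selects the most voted class", {
  rules <- data.frame(gene = c("g1", "g2", "g3"),
                      tumor_isoform = c("g1.a", "g2.a", "g3.a"),
                      normal_isoform = c("g1.b", "g2.b", "g3.b"))
  model <- pair_classifier(rules, c("normal", "tumor"))
  # votes (tumor, tumor, normal) -> tumor with 2 votes
  expr <- c(g1.a = 9, g1.b = 1, g2.a = 9, g2.b = 1, g3.a = 1, g3.b = 9)
  res <- classify_sample(model, expr)
  expect_equal(res$class, "tumor")
  expect_equal(res$votes, 2)
  # k = 1: the single rule decides
  m1 <- pair_classifier(rules[1, ], c("normal", "tumor"))
  expect_equal(classify_sample(m1, expr)$class, "tumor")
  expect_equal(classify_sample(m1, c(g1.a = 1, g1.b = 9))$class, "normal")
  # unanimous k = 5
  rules5 <- data.frame(gene = paste0("g", 1:5),
                       tumor_isoform = paste0("g", 1:5, ".a"),
                       normal_isoform = paste0("g", 1:5, ".b"))
  m5 <- pair_classifier(rules5, c("normal", "tumor"))
  e5 <- stats::setNames(rep(c(1, 9), 5), rbind(rules5$tumor_isoform,
                                               rules5$normal_isoform))
  res5 <- classify_sample(m5, e5)
  expect_equal(res5$class, "normal")
  expect_equal(res5$votes, 5)
  # even k rejected
  expect_error(pair_classifier(rules[1:2, ], c("normal", "tumor")), "odd")
  expect_error(pair_classifier(rbind(rules, rules[1:2, ]),
                               c("normal", "tumor")), "distinct genes")
})

test_that("classify_samples agrees with per-sample classification", {
  ds <- toy_dataset()
  model <- build_final_model(ds, 1)
  batch <- classify_samples(model, ds$tpm)
  solo <- vapply(colnames(ds$tpm), function(s)
    classify_sample(model, ds$tpm[, s])$class, character(1))
  expect_equal(batch$predicted, unname(solo))
  expect_equal(batch$predicted, unname(ds$class_of[batch$sample]))
})

test_that("accuracy is (TP+TN)/total and symmetric in the positive class", {
  expect_equal(accuracy(list(TP = 3, TN = 4, FP = 0, FN = 1)), 0.875)
  expect_equal(accuracy(list(TP = 5, TN = 5, FP = 0, FN = 0)), 1.0)
  expect_error(accuracy(list(TP = 0, TN = 0, FP = 0, FN = 0)), "no evaluated")
  set.seed(4)
  for (i in 1:50) {
    n <- sample(2:30, 1)
    pred <- sample(c("normal", "tumor"), n, replace = TRUE)
    truth <- sample(c("normal", "tumor"), n, replace = TRUE)
    a_t <- accuracy(confusion_counts(pred, truth, positive = "tumor"))
    a_n <- accuracy(confusion_counts(pred, truth, positive = "normal"))
    expect_identical(a_t, a_n)
    expect_equal(a_t, mean(pred == truth))
  }
})

test_that("blind test reports fraction correct and the correct-vote histogram", {
  ds <- toy_dataset()
  rules <- data.frame(gene = c("gA", "gB", "gC"),
                      tumor_isoform = c("gA.t1", "gB.t1", "gC.t1"),
                      normal_isoform = c("gA.t2", "gB.t2", "gC.t2"))
  model <- pair_classifier(rules, ds$class_levels)
  tum <- ds$tpm[, class_samples(ds)$class2]
  # every tumor sample fulfills all three rules
  bt <- blind_test(model, tum, "tumor")
  expect_equal(bt$fraction_correct, 1.0)
  expect_equal(unname(bt$vote_histogram["3"]), ncol(tum))
  direct <- vapply(seq_len(ncol(tum)), function(s)
    classify_sample(model, tum[, s])$class == "tumor", logical(1))
  expect_equal(bt$fraction_correct, mean(direct))
  # sample fulfilling 1 of 3 rules is counted incorrect, histogram at 1
  one_rule <- c(gA.t1 = 9, gA.t2 = 1,  # tumor vote
                gB.t1 = 1, gB.t2 = 9,  # normal vote
                gC.t1 = 1, gC.t2 = 9)  # normal vote
  bt1 <- blind_test(model, matrix(one_rule, ncol = 1,
                                  dimnames = list(names(one_rule), "x")),
                    "tumor")
  expect_equal(bt1$fraction_correct, 0)
  expect_equal(unname(bt1$vote_histogram["1"]), 1L)
})

test_that("gene-level collapse sums transcript TPM and supports classic kTSP", {
  ds <- toy_dataset()
  gds <- gene_level_dataset(ds)
  expect_equal(unname(gds$tpm["gA", ]),
               unname(colSums(ds$tpm[c("gA.t1", "gA.t2"), ])))
  # single-isoform gene passes through unchanged
  X <- rbind(ds$tpm, solo.t1 = rep(3, 8))
  g <- c(ds$gene_of, solo.t1 = "gSolo")
  ds2 <- expression_dataset(X, g, ds$class_of, values = "tpm")
  gds2 <- gene_level_dataset(ds2)
  expect_equal(unname(gds2$tpm["gSolo", ]), rep(3, 8))

  # tiny instance: gene-pair ranking equals a brute-force kTSP oracle
  set.seed(88)
  GX <- matrix(sample(1:50, 4 * 6), 4, 6,
               dimnames = list(paste0("G", 1:4), paste0("s", 1:6)))
  cls <- stats::setNames(rep(c("normal", "tumor"), each = 3), paste0("s", 1:6))
  gds3 <- expression_dataset(GX, stats::setNames(paste0("G", 1:4),
                                                 paste0("G", 1:4)),
                             cls, values = "tpm")
  got <- rank_pairs(gds3, mode = "gene")
  # oracle: enumerate all cross pairs, both orientations, greedy disjoint
  cand <- list()
  for (a in 1:3) for (b in (a + 1):4) {
    fa <- paste0("G", a); fb <- paste0("G", b)
    s_ab <- oracle_s1(GX[fa, ], GX[fb, ], cls)
    s_ba <- oracle_s1(GX[fb, ], GX[fa, ], cls)
    tumor <- if (s_ab >= s_ba) fb else fa
    normal <- if (s_ab >= s_ba) fa else fb
    cand[[length(cand) + 1]] <- data.frame(
      tumor_isoform = tumor, normal_isoform = normal,
      s1 = max(s_ab, s_ba), s2 = oracle_s2(GX, fa, fb, cls))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[cand$s1 >= 0, ]
  cand <- cand[order(-cand$s1, -cand$s2), ]
  used <- character(0); keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    f <- c(cand$tumor_isoform[r], cand$normal_isoform[r])
    if (!any(f %in% used)) { keep[r] <- TRUE; used <- c(used, f) }
  }
  cand <- cand[keep, ]
  expect_equal(got$tumor_isoform, cand$tumor_isoform)
  expect_equal(got$normal_isoform, cand$normal_isoform)
  expect_equal(got$s1, cand$s1)
})
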