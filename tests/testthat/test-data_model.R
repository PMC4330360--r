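test_that("compute_tpm matches the per-sample length-normalized formula", {
  counts <- matrix(c(10, 20), 2, 1, dimnames = list(c("a", "b"), "s1"))
  lens <- c(a = 1000, b = 2000)
  expect_equal(unname(compute_tpm(counts, lens)[, 1]), c(5e5, 5e5))

  counts2 <- matrix(c(30, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(compute_tpm(counts2, c(a = 1000, b = 1000))[, 1]),
               c(7.5e5, 2.5e5))

  set.seed(11)
  cnt <- matrix(rpois(5 * 3, 40), 5, 3,
                dimnames = list(paste0("t", 1:5), paste0("s", 1:3)))
  lens5 <- stats::setNames(sample(500:3000, 5), paste0("t", 1:5))
  got <- compute_tpm(cnt, lens5)
  # independent hand computation, column by column
  for (s in 1:3) {
    rate <- cnt[, s] / lens5[rownames(cnt)]
    expect_equal(got[, s], 1e6 * rate / sum(rate))
  }
  expect_equal(unname(colSums(got)), rep(1e6, 3), tolerance = 1e-6)
})

test_that("compute_tpm flags degenerate columns and missing lengths", {
  counts <- matrix(c(0, 0, 3, 1), 2, 2,
                   dimnames = list(c("a", "b"), c("empty", "ok")))
  expect_warning(tpm <- compute_tpm(counts, c(a = 100, b = 100)), "empty")
  expect_equal(unname(tpm[, "empty"]), c(0, 0))
  expect_error(compute_tpm(counts, c(a = 100)), "b")
})

test_that("compute_psi normalizes within genes and leaves zero genes missing", {
  tpm <- matrix(c(30, 10, 0, 0, 7), 5, 1,
                dimnames = list(paste0("t", 1:5), "s1"))
  gene_of <- c(t1 = "g1", t2 = "g1", t3 = "g2", t4 = "g2", t5 = "g3")
  psi <- compute_psi(tpm, gene_of)
  expect_equal(unname(psi[c("t1", "t2"), 1]), c(0.75, 0.25))
  expect_true(all(is.na(psi[c("t3", "t4"), 1])))
  expect_equal(unname(psi["t5", 1]), 1.0)
})

test_that("PSI gene blocks sum to 1 where defined and lie in [0, 1]", {
  for (seed in 1:5) {
    ds <- random_dataset(seed)
    psi <- ds$psi
    expect_true(all(psi >= 0 & psi <= 1, na.rm = TRUE))
    for (g in unique(ds$gene_of)) {
      block <- psi[names(ds$gene_of)[ds$gene_of == g], , drop = FALSE]
      sums <- colSums(block)
      expect_true(all(is.na(sums) | abs(sums - 1) < 1e-9))
    }
  }
})

test_that("PSI after TPM is invariant under global scaling of a sample's counts", {
  set.seed(3)
  cnt <- matrix(rpois(12, 30), 4, 3,
                dimnames = list(paste0("t", 1:4), paste0("s", 1:3)))
  lens <- stats::setNames(rep(1000, 4), paste0("t", 1:4))
  gene_of <- stats::setNames(rep(c("g1", "g2"), each = 2), paste0("t", 1:4))
  psi1 <- compute_psi(compute_tpm(cnt, lens), gene_of)
  cnt2 <- cnt
  cnt2[, 2] <- cnt2[, 2] * 7
  psi2 <- compute_psi(compute_tpm(cnt2, lens), gene_of)
  expect_equal(psi1, psi2)
})

test_that("filter_genes drops single-isoform genes and symbol-less genes", {
  tid <- c("a1", "b1", "b2", "c1", "c2", "c3")
  gene_of <- stats::setNames(rep(c("gA", "gB", "gC"), c(1, 2, 3)), tid)
  X <- matrix(1, 6, 4, dimnames = list(tid, paste0("s", 1:4)))
  cls <- stats::setNames(rep(c("normal", "tumor"), each = 2), paste0("s", 1:4))
  ds <- expression_dataset(X, gene_of, cls, values = "tpm")
  expect_warning(f <- filter_genes(ds), "symbol")
  expect_setequal(unique(unname(f$gene_of)), c("gB", "gC"))

  sym <- stats::setNames(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), tid)
  ds2 <- expression_dataset(X, gene_of, cls, values = "tpm", symbol = sym)
  f2 <- filter_genes(ds2)
  expect_setequal(unique(unname(f2$gene_of)), "gB")

  ds3 <- expression_dataset(X[1, , drop = FALSE], gene_of[1], cls,
                            values = "tpm")
  expect_warning(expect_warning(f3 <- filter_genes(ds3)), "no multi-isoform")
  expect_equal(nrow(f3$tpm), 0)
})

test_that("dataset construction validates labels, duplicates and pairing", {
  X <- matrix(1, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
  g <- c(a = "g1", b = "g1")
  cls3 <- stats::setNames(c("x", "y", "z", "x"), paste0("s", 1:4))
  expect_error(expression_dataset(X, g, cls3, values = "tpm"), "2 class")
  cls <- stats::setNames(rep(c("normal", "tumor"), 2), paste0("s", 1:4))
  expect_error(expression_dataset(X, g[1], cls, values = "tpm"), "gene mapping")
  bad_pair <- data.frame(patient = "p1", class1 = "s1", class2 = "nope")
  expect_error(expression_dataset(X, g, cls, pairing = bad_pair,
                                  values = "tpm"), "unknown samples")
})

test_that("fixture files round-trip through the readers", {
  sim <- simulate_isoform_data(simulation_config(
    n_genes = 20, n_patient_pairs = 4, n_switch_genes = 2, seed = 42))
  dir <- withr::local_tempdir()
  write_fixture(sim, dir)

  ex <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(ex$expr, sim$dataset$tpm, tolerance = 1e-12)
  expect_equal(ex$gene_of, sim$dataset$gene_of)

  lb <- read_labels(file.path(dir, "labels.tsv"))
  expect_equal(lb$class_of[names(sim$dataset$class_of)], sim$dataset$class_of)
  expect_equal(lb$pairing$patient, sim$dataset$pairing$patient)

  mut <- read_mutations(file.path(dir, "mutations.tsv"))
  expect_equal(nrow(mut), nrow(sim$mutations))
  expect_equal(nrow(data.table::fread(file.path(dir, "truth_genes.tsv"))),
               sim$config$n_genes)
})

test_that("labels with three classes are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tclass", "s1\ta", "s2\tb", "s3\tc"), f)
  expect_error(read_labels(f), "exactly 2 classes")
})

test_that("GTF round trip recovers exon structure and spans", {
  skip_if_not_installed("rtracklayer")
  sim <- simulate_isoform_data(simulation_config(
    n_genes = 6, n_patient_pairs = 3, n_switch_genes = 1, seed = 5))
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(sim$structures, f)
  st <- read_gtf(f)
  expect_equal(nrow(st$exons), nrow(sim$structures$exons))
  orig <- sim$structures$transcripts
  got <- st$transcripts[match(orig$transcript_id, st$transcripts$transcript_id), ]
  expect_equal(got$start, orig$start)
  expect_equal(got$end, orig$end)
  # spans equal min/max exon bounds
  for (tid in got$transcript_id[1:3]) {
    e <- st$exons[st$exons$transcript_id == tid, ]
    tr <- got[got$transcript_id == tid, ]
    expect_equal(tr$start, min(e$start))
    expect_equal(tr$end, max(e$end))
  }
})
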