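# minimal structures: three genes side by side on chr1, two isoforms each
assoc_structures <- function() {
  tr <- data.frame(
    transcript_id = c("gA.t1", "gA.t2", "gB.t1", "gB.t2", "gC.t1", "gC.t2"),
    gene_id = rep(c("gA", "gB", "gC"), each = 2),
    chrom = "chr1", strand = "+",
    start = c(1000, 1100, 5000, 5050, 9000, 9100),
    end = c(2000, 1800, 6000, 6200, 9900, 9500))
  ex <- data.frame(
    transcript_id = tr$transcript_id,
    start = tr$start, end = tr$end)  # single-exon isoforms
  transcript_structures(tr, ex)
}

test_that("mutation overlap respects transcript vs gene scope", {
  st <- assoc_structures()
  mut <- mutation_table(data.frame(
    sample = c("s1", "s2", "s3", "s4"),
    chrom = "chr1",
    start = c(1500, 1850, 30000, 5500),
    end = c(1500, 1850, 30000, 5500),
    class = c("missense", "missense", "missense", "synonymous")))
  # inside an exon of gA.t1 only -> s1; 1850 inside t1 span but not t2
  expect_setequal(mutated_samples("gA.t1", "gA.t2", mut, st), c("s1", "s2"))
  # far downstream -> excluded
  expect_false("s3" %in% mutated_samples("gA.t1", "gA.t2", mut, st))
  # gene scope covers the whole gene span
  expect_setequal(mutated_samples("gA.t1", "gA.t2", mut, st, scope = "gene"),
                  c("s1", "s2"))
  # protein-affecting filter drops the synonymous hit in gB
  expect_equal(mutated_samples("gB.t1", "gB.t2", mut, st), "s4")
  expect_length(mutated_samples("gB.t1", "gB.t2", mut, st,
                                protein_affecting_only = TRUE), 0)
  expect_error(mutated_samples("nope", "gA.t2", mut, st), "no structure")
})

test_that("gene scope includes intronic positions between isoform exons", {
  tr <- data.frame(transcript_id = c("gD.t1", "gD.t2"), gene_id = "gD",
                   chrom = "chr2", strand = "+",
                   start = c(100, 100), end = c(1000, 1000))
  ex <- data.frame(transcript_id = c("gD.t1", "gD.t1", "gD.t2"),
                   start = c(100, 800, 100), end = c(200, 1000, 250))
  st <- transcript_structures(tr, ex)
  mut <- mutation_table(data.frame(sample = "sx", chrom = "chr2",
                                   start = 500, end = 500,
                                   class = "missense"))
  # 500 falls in an intron of t1 but inside both transcript spans
  expect_equal(mutated_samples("gD.t1", "gD.t2", mut, st), "sx")
  expect_equal(mutated_samples("gD.t1", "gD.t2", mut, st, scope = "gene"), "sx")
})

test_that("jaccard index follows |M&S|/|M|S|", {
  expect_equal(jaccard_association(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(jaccard_association(c("a", "b"), c("c", "d")), 0.0)
  expect_equal(jaccard_association(c("a", "b", "c", "d", "e"),
                                   c("d", "e", "f", "g", "h")), 0.25)
  expect_warning(j0 <- jaccard_association(character(0), character(0)),
                 "empty union")
  expect_equal(j0, 0)
})

test_that("mutual information matches the plug-in formula on random tables", {
  # independent indicators built as an exact product table over 20 samples
  u <- sprintf("s%02d", 1:20)
  S <- u[1:10]                        # P(S) = 1/2
  M <- u[c(1:5, 11:15)]               # P(M) = 1/2, P(S & M) = 1/4
  expect_equal(mutual_information_association(S, M, u), 0.0)
  # identical indicators covering half the samples: MI = H(S) = 1 bit
  expect_equal(mutual_information_association(S, S, u), 1.0)
  set.seed(14)
  for (i in 1:25) {
    N <- sample(4:30, 1)
    un <- sprintf("x%02d", 1:N)
    S <- sample(un, sample(0:N, 1))
    M <- sample(un, sample(0:N, 1))
    a <- length(intersect(S, M)); b <- length(S) - a
    c_ <- length(M) - a; d <- N - a - b - c_
    tab <- c(a, b, c_, d) / N
    ps <- (a + b) / N; pm <- (a + c_) / N
    pe <- c(ps * pm, ps * (1 - pm), (1 - ps) * pm, (1 - ps) * (1 - pm))
    expected <- sum(ifelse(tab > 0, tab * log2(tab / pe), 0))
    expect_equal(mutual_information_association(S, M, un), expected,
                 tolerance = 1e-12)
    expect_gte(mutual_information_association(S, M, un), 0)
  }
})

test_that("mutual exclusion score is 2 min(n10, n01)/N", {
  expect_equal(mutual_exclusion(5, 5, 10), 1.0)
  expect_equal(mutual_exclusion(4, 0, 10), 0.0)
  expect_equal(mutual_exclusion(3, 1, 10), 0.2)
  expect_error(mutual_exclusion(6, 6, 10))
})

test_that("background z-scores are deterministic and flag zero variance", {
  expect_equal(background_zscore(0.3, c(0.05, 0.1, 0.15)), 4.0)
  expect_equal(background_zscore(0.1, c(0.05, 0.1, 0.15)), 0.0)
  z <- background_zscore(0.5, rep(0.2, 10))
  expect_true(is.na(z))
  expect_true(attr(z, "degenerate"))
})

test_that("length-matched background selection is nearest-by-median-length", {
  sim <- simulate_isoform_data(simulation_config(
    n_genes = 30, n_patient_pairs = 3, n_switch_genes = 1, seed = 91))
  st <- sim$structures
  target <- "G0001"
  bg <- length_matched_genes(target, st, 10)
  expect_length(bg, 10)
  expect_false(target %in% bg)
  # selected genes are no farther than any unselected gene
  tl <- tapply(st$exons$end - st$exons$start + 1, st$exons$transcript_id, sum)
  g <- st$transcripts$gene_id[match(names(tl), st$transcripts$transcript_id)]
  med <- tapply(tl, g, median)
  d <- abs(med - med[[target]])
  expect_lte(max(d[bg]), min(d[setdiff(names(d), c(bg, target))]))
  expect_warning(length_matched_genes(target, st, 100), "candidate")
})

test_that("Mann-Whitney p-values follow the exact small-sample distribution", {
  # complete separation, 3 vs 3: two-sided exact p = 2/choose(6,3) = 0.1
  ds <- toy_dataset(n1 = 3, n2 = 3)
  X <- ds$tpm
  X["gA.t1", 4:6] <- c(30, 35, 40)  # tumor samples, distinct dPSI
  X["gA.t2", 4:6] <- c(10, 9, 8)
  ds <- expression_dataset(X, ds$gene_of, ds$class_of,
                           pairing = ds$pairing, values = "tpm")
  sw <- list(tumor_isoform = "gA.t1", normal_isoform = "gA.t2")
  # mutated = the 2 tumor samples with the largest dPSI? use separation:
  p <- delta_psi_mutation_test(sw, ds, mutated = c("t3"))
  expect_true(is.numeric(p))
  # direct check of the engine on separated groups
  expect_equal(isopair:::.mann_whitney(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(isopair:::.mann_whitney(rep(1, 4), rep(1, 5)), 1)
  pe <- isopair:::.mann_whitney(numeric(0), c(1, 2))
  expect_true(is.na(pe) && attr(pe, "empty_group"))
  # large groups: tie-corrected normal approximation agrees with wilcox
  set.seed(2)
  x <- rnorm(20); y <- rnorm(20) + 0.5
  expect_equal(isopair:::.mann_whitney(x, y),
               suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                   correct = TRUE)$p.value))
})

test_that("planted mutation co-occurrence yields elevated Jaccard z-scores", {
  zs <- numeric(5)
  zs_null <- numeric(5)
  for (i in 1:5) {
    sim <- simulate_isoform_data(simulation_config(
      n_genes = 120, n_patient_pairs = 25, n_switch_genes = 5,
      penetrance = 0.95, seed = 100 + i))
    ds <- sim$dataset
    planted <- sim$truth$genes[sim$truth$genes$is_switch, ]
    sw <- data.frame(gene = planted$gene,
                     tumor_isoform = planted$tumor_isoform,
                     normal_isoform = planted$normal_isoform)
    res <- mutation_association(sw, ds, sim$mutations, sim$structures,
                                n_background = 50)
    zs[i] <- mean(res$j_zscore, na.rm = TRUE)
    # independence: associate each switch with an unrelated mutated gene
    other <- sim$truth$genes$gene[!sim$truth$genes$is_switch]
    shuffled_mut <- sim$mutations
    map <- stats::setNames(sample(other, length(unique(shuffled_mut$gene))),
                           unique(shuffled_mut$gene))
    # move every mutation to a random non-switch gene's locus
    tr <- sim$structures$transcripts
    for (g in unique(shuffled_mut$gene)) {
      rows <- shuffled_mut$gene == g
      tg <- tr[tr$gene_id == map[[g]], ]
      shuffled_mut$chrom[rows] <- tg$chrom[1]
      shuffled_mut$start[rows] <- min(tg$start)
      shuffled_mut$end[rows] <- min(tg$start)
      shuffled_mut$gene[rows] <- map[[g]]
    }
    res0 <- mutation_association(sw, ds, shuffled_mut, sim$structures,
                                 n_background = 50)
    zs_null[i] <- mean(res0$j_zscore, na.rm = TRUE)
  }
  expect_gte(mean(zs), 2)
  expect_lte(abs(mean(zs_null)), 0.5)
})

test_that("the association table is complete and BH-adjusted", {
  sim <- simulate_isoform_data(simulation_config(
    n_genes = 60, n_patient_pairs = 10, n_switch_genes = 3, seed = 61))
  planted <- sim$truth$genes[sim$truth$genes$is_switch, ]
  sw <- data.frame(gene = planted$gene,
                   tumor_isoform = planted$tumor_isoform,
                   normal_isoform = planted$normal_isoform)
  res <- mutation_association(sw, sim$dataset, sim$mutations,
                              sim$structures, n_background = 20)
  expect_equal(nrow(res), 3)
  expect_true(all(res$jaccard >= 0 & res$jaccard <= 1))
  expect_true(all(res$mx >= 0 & res$mx <= 1))
  expect_true(all(res$mutual_information >= 0))
  expect_equal(res$bh_adjusted_pvalue,
               stats::p.adjust(res$delta_psi_pvalue, "BH"))
  expect_true(all(res$bh_adjusted_pvalue >= res$delta_psi_pvalue - 1e-12))
})
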