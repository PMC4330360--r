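#' Configuration for the synthetic paired-cohort generator
#'
#' Defaults describe the reference simulation used throughout the
#' package's validation: a paired two-class cohort of 30 patients over
#' 1000 multi-isoform genes, 50 of which carry a planted isoform switch
#' expressed in 95% of tumor samples, with log-normal expression noise,
#' mild zero-inflation, and somatic mutations co-occurring with planted
#' switches (P(mut|switch) = 0.5 vs P(mut|no switch) = 0.02).
#'
#' @param n_genes number of genes.
#' @param isoforms_per_gene length-2 integer range; isoform counts are
#'   drawn uniformly from it.
#' @param n_patient_pairs matched normal+tumor patients.
#' @param n_unpaired_tumor additional unpaired tumor samples (blind-test
#'   material).
#' @param n_switch_genes genes with a planted switch.
#' @param penetrance probability that a tumor sample exhibits a planted
#'   reversal.
#' @param base_tpm scale of gene-level expression (TPM-like, before
#'   renormalization).
#' @param dispersion sdlog of the multiplicative log-normal noise.
#' @param zero_inflation probability of zeroing any expression value.
#' @param subtypes optional character vector of tumor subtype labels,
#'   assigned round-robin to tumor samples.
#' @param n_subtype_switch_genes genes whose planted reversal occurs only
#'   in tumor samples of `subtype_target`.
#' @param subtype_target subtype carrying the exclusive switches
#'   (default: first of `subtypes`).
#' @param mutation_model NULL to skip mutations, or a list with
#'   `p_switch` (mutation probability in samples exhibiting the planted
#'   switch), `p_nonswitch` (in other samples, for planted genes) and
#'   `p_background` (per-sample rate for a random subset of non-planted
#'   genes).
#' @param seed integer RNG seed.
#' @return validated list of class `"SimulationConfig"`.
#' @export
simulation_config <- function(n_genes = 1000L,
                              isoforms_per_gene = c(2L, 4L),
                              n_patient_pairs = 30L,
                              n_unpaired_tumor = 0L,
                              n_switch_genes = 50L,
                              penetrance = 0.95,
                              base_tpm = 50,
                              dispersion = 0.5,
                              zero_inflation = 0.05,
                              subtypes = NULL,
                              n_subtype_switch_genes = 0L,
                              subtype_target = NULL,
                              mutation_model = list(p_switch = 0.5,
                                                    p_nonswitch = 0.02,
                                                    p_background = 0.02),
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              isoforms_per_gene = as.integer(isoforms_per_gene),
              n_patient_pairs = as.integer(n_patient_pairs),
              n_unpaired_tumor = as.integer(n_unpaired_tumor),
              n_switch_genes = as.integer(n_switch_genes),
              penetrance = penetrance, base_tpm = base_tpm,
              dispersion = dispersion, zero_inflation = zero_inflation,
              subtypes = subtypes,
              n_subtype_switch_genes = as.integer(n_subtype_switch_genes),
              subtype_target = subtype_target,
              mutation_model = mutation_model, seed = as.integer(seed))
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  if (length(cfg$isoforms_per_gene) != 2L || cfg$isoforms_per_gene[1L] < 2L ||
      diff(cfg$isoforms_per_gene) < 0L)
    stop("isoforms_per_gene must be an increasing range with minimum >= 2")
  if (cfg$n_switch_genes + cfg$n_subtype_switch_genes > cfg$n_genes)
    stop("more planted switch genes than genes")
  for (p in c(cfg$penetrance, cfg$zero_inflation))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (cfg$n_patient_pairs < 1L) stop("need >= 1 patient pair")
  if (cfg$n_subtype_switch_genes > 0L && is.null(cfg$subtypes))
    stop("subtype switches require subtypes")
  if (!is.null(cfg$subtypes) && is.null(cfg$subtype_target))
    cfg$subtype_target <- cfg$subtypes[1L]
  if (!is.null(cfg$mutation_model)) {
    mm <- cfg$mutation_model
    if (!all(c("p_switch", "p_nonswitch", "p_background") %in% names(mm)))
      stop("mutation_model needs p_switch, p_nonswitch, p_background")
    if (any(unlist(mm) < 0 | unlist(mm) > 1))
      stop("mutation probabilities must lie in [0, 1]")
  }
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a paired two-class cohort with planted isoform switches
#'
#' Generates transcript-level TPM for matched normal/tumor samples.
#' Every gene receives a log-normal expression level and a decreasing
#' isoform-proportion profile shared by both classes; for planted switch
#' genes the two top-ranked isoforms swap their mean proportions in each
#' affected tumor sample (Bernoulli with probability `penetrance`),
#' keeping gene-level expression unchanged so the signal is purely a
#' splicing reversal. Multiplicative log-normal noise and Bernoulli
#' zero-inflation are applied, then each sample column is renormalized
#' to 1e6 (TPM). Transcript structures (exons on synthetic chromosomes)
#' are emitted for mutation overlap and GFF export, and mutations are
#' drawn per the two-rate co-occurrence model on planted genes plus a
#' background rate on a matching number of non-planted genes.
#' Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list of class `"IsoformSimulation"` with elements `dataset`
#'   (an `ExpressionDataset`), `mutations` (a [mutation_table()] or
#'   NULL), `structures` (a [transcript_structures()] object), `truth`
#'   (list: `genes` data.frame with planted-pair ids per gene,
#'   `switch_flags` switch-gene x tumor-sample 0/1 matrix,
#'   `subtype_of` named vector or NULL), and `config`.
#' @export
simulate_isoform_data <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  G <- config$n_genes
  k_iso <- sample(seq(config$isoforms_per_gene[1L], config$isoforms_per_gene[2L]),
                  G, replace = TRUE)
  gid <- sprintf("G%04d", seq_len(G))
  tid <- unlist(lapply(seq_len(G), function(g)
    sprintf("%s.i%d", gid[g], seq_len(k_iso[g]))), use.names = FALSE)
  gene_of <- stats::setNames(rep(gid, k_iso), tid)
  TT <- length(tid)

  np <- config$n_patient_pairs
  normal_s <- sprintf("P%03d.N", seq_len(np))
  tumor_s <- c(sprintf("P%03d.T", seq_len(np)),
               if (config$n_unpaired_tumor > 0L)
                 sprintf("U%03d.T", seq_len(config$n_unpaired_tumor)))
  samples <- c(normal_s, tumor_s)
  class_of <- stats::setNames(c(rep("normal", length(normal_s)),
                                rep("tumor", length(tumor_s))), samples)
  pairing <- data.frame(patient = sprintf("P%03d", seq_len(np)),
                        class1 = normal_s, class2 = sprintf("P%03d.T", seq_len(np)),
                        stringsAsFactors = FALSE)

  subtype_of <- NULL
  if (!is.null(config$subtypes))
    subtype_of <- stats::setNames(
      rep(config$subtypes, length.out = length(tumor_s)), tumor_s)

  # gene expression scale and decreasing isoform proportions
  gene_level <- stats::rlnorm(G, meanlog = log(config$base_tpm), sdlog = 1)
  props <- lapply(seq_len(G), function(g) {
    p <- sort(stats::rexp(k_iso[g]) + 0.1, decreasing = TRUE)
    p / sum(p)
  })

  n_sw <- config$n_switch_genes
  n_sub <- config$n_subtype_switch_genes
  planted <- sample.int(G, n_sw + n_sub)
  switch_genes <- planted[seq_len(n_sw)]
  subtype_genes <- if (n_sub > 0L) planted[n_sw + seq_len(n_sub)] else integer(0)

  # Planted genes model a genuine dominant-isoform switch: a clearly
  # dominant isoform (PSI ~ 0.55-0.7) swapping with a solid second
  # isoform (PSI ~ 0.15-0.25), in an adequately expressed gene, so the
  # reversal is a change of the most abundant isoform rather than a
  # reshuffle of trace transcripts.
  for (g in planted) {
    k <- k_iso[g]
    w <- c(stats::runif(1, 5.5, 7.5), stats::runif(1, 1.6, 2.0),
           if (k > 2L) stats::runif(k - 2L, 0.1, 0.8))
    props[[g]] <- w / sum(w)
    gene_level[g] <- max(gene_level[g], config$base_tpm / 2)
  }

  # per-tumor-sample reversal events for each planted gene
  all_planted <- c(switch_genes, subtype_genes)
  flags <- matrix(0L, length(all_planted), length(tumor_s),
                  dimnames = list(gid[all_planted], tumor_s))
  for (i in seq_along(all_planted)) {
    g <- all_planted[i]
    eligible <- if (g %in% subtype_genes)
      subtype_of[tumor_s] == config$subtype_target else rep(TRUE, length(tumor_s))
    flags[i, ] <- as.integer(eligible &
      stats::runif(length(tumor_s)) < config$penetrance)
  }

  # mean matrix: swap the two top isoforms' proportions in flagged samples
  offsets <- c(0L, cumsum(k_iso))
  mu <- matrix(0, TT, length(samples), dimnames = list(tid, samples))
  for (g in seq_len(G)) {
    rows <- offsets[g] + seq_len(k_iso[g])
    mu[rows, ] <- gene_level[g] * props[[g]]
  }
  for (i in seq_along(all_planted)) {
    g <- all_planted[i]
    r1 <- offsets[g] + 1L  # dominant isoform (normal isoform)
    r2 <- offsets[g] + 2L  # second isoform (tumor isoform)
    hit <- tumor_s[flags[i, ] == 1L]
    if (length(hit)) {
      tmp <- mu[r1, hit]
      mu[r1, hit] <- mu[r2, hit]
      mu[r2, hit] <- tmp
    }
  }

  x <- mu
  if (config$dispersion > 0)
    x <- x * matrix(stats::rlnorm(TT * length(samples), 0, config$dispersion),
                    TT, length(samples))
  if (config$zero_inflation > 0)
    x[matrix(stats::runif(TT * length(samples)) < config$zero_inflation,
             TT, length(samples))] <- 0
  tot <- colSums(x)
  tot[tot == 0] <- 1
  tpm <- sweep(x, 2L, tot, "/") * 1e6

  structures <- .simulate_structures(gid, tid, gene_of)

  mutations <- NULL
  if (!is.null(config$mutation_model)) {
    mm <- config$mutation_model
    recs <- list()
    tr <- structures$transcripts
    gspan <- do.call(rbind, lapply(split(tr, tr$gene_id), function(d)
      data.frame(gene = d$gene_id[1L], chrom = d$chrom[1L],
                 start = min(d$start), end = max(d$end))))
    draw <- function(gene, sample) {
      sp <- gspan[gspan$gene == gene, ]
      pos <- sample.int(sp$end - sp$start + 1L, 1L) + sp$start - 1L
      data.frame(sample = sample, chrom = sp$chrom, start = pos, end = pos,
                 class = sample(MUTATION_CLASSES, 1L,
                                prob = c(2, 8, 2, 2, 3, 1, 1)),
                 gene = gene, stringsAsFactors = FALSE)
    }
    for (i in seq_along(all_planted)) {
      g <- gid[all_planted[i]]
      for (s in seq_along(tumor_s)) {
        p <- if (flags[i, s] == 1L) mm$p_switch else mm$p_nonswitch
        if (stats::runif(1) < p) recs[[length(recs) + 1L]] <- draw(g, tumor_s[s])
      }
    }
    n_bg_genes <- min(G - length(all_planted), length(all_planted))
    bg_genes <- setdiff(seq_len(G), all_planted)
    if (n_bg_genes > 0L) {
      bg_genes <- sample(bg_genes, n_bg_genes)
      for (g in gid[bg_genes]) for (s in tumor_s)
        if (stats::runif(1) < mm$p_background)
          recs[[length(recs) + 1L]] <- draw(g, s)
    }
    mutations <- if (length(recs)) mutation_table(do.call(rbind, recs))
    else mutation_table(data.frame(sample = character(0), chrom = character(0),
                                   start = integer(0), end = integer(0),
                                   class = character(0), gene = character(0)))
  }

  dataset <- expression_dataset(tpm, gene_of, class_of,
                                class_levels = c("normal", "tumor"),
                                pairing = pairing, values = "tpm")
  genes_truth <- data.frame(
    gene = gid,
    is_switch = seq_len(G) %in% switch_genes,
    is_subtype_switch = seq_len(G) %in% subtype_genes,
    tumor_isoform = ifelse(seq_len(G) %in% all_planted,
                           sprintf("%s.i2", gid), NA_character_),
    normal_isoform = ifelse(seq_len(G) %in% all_planted,
                            sprintf("%s.i1", gid), NA_character_),
    stringsAsFactors = FALSE)
  structure(list(dataset = dataset, mutations = mutations,
                 structures = structures,
                 truth = list(genes = genes_truth, switch_flags = flags,
                              subtype_of = subtype_of),
                 config = config),
            class = "IsoformSimulation")
}

# synthetic genomic layout: genes laid out sequentially on 5 chromosomes,
# each isoform 1-3 exons inside the gene's 5 kb window
.simulate_structures <- function(gid, tid, gene_of) {
  G <- length(gid)
  chrom_of <- sprintf("chr%d", (seq_len(G) - 1L) %% 5L + 1L)
  slot <- (seq_len(G) - 1L) %/% 5L
  gstart <- slot * 10000L + 1L
  names(chrom_of) <- names(gstart) <- gid
  tr <- list(); ex <- list()
  for (t in tid) {
    g <- gene_of[[t]]
    n_ex <- sample.int(3L, 1L)
    width <- sample(200:600, n_ex, replace = TRUE)
    gaps <- sample(100:400, n_ex, replace = TRUE)
    starts <- gstart[[g]] + cumsum(c(sample.int(500L, 1L), (width + gaps)[-n_ex]))
    ends <- starts + width - 1L
    tr[[t]] <- data.frame(transcript_id = t, gene_id = g,
                          chrom = chrom_of[[g]], strand = "+",
                          start = min(starts), end = max(ends),
                          stringsAsFactors = FALSE)
    ex[[t]] <- data.frame(transcript_id = t, start = starts, end = ends,
                          stringsAsFactors = FALSE)
  }
  transcript_structures(do.call(rbind, tr), do.call(rbind, ex))
}

#' Write a simulated cohort as a plain-text fixture
#'
#' Emits `expression.tsv` (TPM, transcript/gene/symbol columns),
#' `labels.tsv` (sample/class/patient), `annotation.gtf`,
#' `mutations.tsv` (when present) and `truth_genes.tsv` into `dir`.
#' Reading the files back reproduces the in-memory objects.
#'
#' @param sim an [simulate_isoform_data()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "IsoformSimulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  expr <- data.frame(transcript = rownames(ds$tpm),
                     gene = as.character(ds$gene_of[rownames(ds$tpm)]),
                     symbol = as.character(ds$gene_of[rownames(ds$tpm)]),
                     stringsAsFactors = FALSE)
  expr <- cbind(expr, as.data.frame(ds$tpm))
  write_tsv(expr, file.path(dir, "expression.tsv"))
  pat <- rep(NA_character_, ncol(ds$tpm))
  names(pat) <- colnames(ds$tpm)
  if (!is.null(ds$pairing)) {
    pat[ds$pairing$class1] <- ds$pairing$patient
    pat[ds$pairing$class2] <- ds$pairing$patient
  }
  labels <- data.frame(sample = colnames(ds$tpm),
                       class = as.character(ds$class_of[colnames(ds$tpm)]),
                       patient = ifelse(is.na(pat), "", pat),
                       stringsAsFactors = FALSE)
  write_tsv(labels, file.path(dir, "labels.tsv"))
  write_gtf(sim$structures, file.path(dir, "annotation.gtf"))
  if (!is.null(sim$mutations))
    write_tsv(as.data.frame(sim$mutations), file.path(dir, "mutations.tsv"))
  write_tsv(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  invisible(dir)
}
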