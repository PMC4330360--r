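#' Detect isoform switches among significant pairs
#'
#' An isoform switch is a significant pair for which the change affects
#' the most abundant isoform: beyond significance, the pair must show
#' (i) S1 > `min_s1` (at the default 0.5, a relative-order change in more
#' than 75% of the samples), (ii) Spearman anti-correlation of the two
#' isoforms' PSI values below `max_rho` across samples, and (iii) for
#' each isoform, mean TPM above `min_tpm` in the tumor samples or in the
#' normal samples.
#'
#' The correlation is computed on PSI (not TPM) across the paired
#' tumor+normal samples jointly (all samples when no pairing is
#' present), dropping samples with missing PSI pairwise; pairs with
#' fewer than 3 complete observations are dropped with a warning.
#'
#' @param sig_pairs data.frame of significant pairs
#'   (see [significant_pairs()]).
#' @param dataset the `ExpressionDataset` the pairs were derived from.
#' @param min_s1 minimum S1 (default 0.5, exclusive).
#' @param max_rho maximum Spearman rho (default -0.8, exclusive).
#' @param min_tpm minimum class-mean TPM (default 1, exclusive).
#' @return data.frame of switch records: the pair columns plus
#'   `spearman_rho`, `mean_tpm_tumor_iso_tumor`,
#'   `mean_tpm_tumor_iso_normal`, `mean_tpm_normal_iso_tumor`,
#'   `mean_tpm_normal_iso_normal`.
#' @export
detect_switches <- function(sig_pairs, dataset, min_s1 = 0.5,
                            max_rho = -0.8, min_tpm = 1.0) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (!nrow(sig_pairs)) {
    out <- sig_pairs
    out$spearman_rho <- numeric(0)
    return(out)
  }
  corr_samples <- if (!is.null(dataset$pairing))
    c(dataset$pairing$class1, dataset$pairing$class2)
  else names(dataset$class_of)
  s <- class_samples(dataset)
  rho <- numeric(nrow(sig_pairs))
  nobs <- integer(nrow(sig_pairs))
  m <- matrix(NA_real_, nrow(sig_pairs), 4L,
              dimnames = list(NULL, c("mean_tpm_tumor_iso_tumor",
                                      "mean_tpm_tumor_iso_normal",
                                      "mean_tpm_normal_iso_tumor",
                                      "mean_tpm_normal_iso_normal")))
  for (r in seq_len(nrow(sig_pairs))) {
    ti <- sig_pairs$tumor_isoform[r]
    ni <- sig_pairs$normal_isoform[r]
    pi_t <- dataset$psi[ti, corr_samples]
    pi_n <- dataset$psi[ni, corr_samples]
    ok <- !is.na(pi_t) & !is.na(pi_n)
    nobs[r] <- sum(ok)
    rho[r] <- if (sum(ok) >= 3L)
      suppressWarnings(stats::cor(pi_t[ok], pi_n[ok], method = "spearman"))
    else NA_real_
    m[r, ] <- c(mean(dataset$tpm[ti, s$class2]),
                mean(dataset$tpm[ti, s$class1]),
                mean(dataset$tpm[ni, s$class2]),
                mean(dataset$tpm[ni, s$class1]))
  }
  dropped <- nobs < 3L
  if (any(dropped))
    warning(sum(dropped), " pair(s) dropped: fewer than 3 complete PSI ",
            "observations for correlation")
  # both isoforms must exceed min_tpm on average in at least one class
  tumor_iso_ok <- pmax(m[, 1L], m[, 2L]) > min_tpm
  normal_iso_ok <- pmax(m[, 3L], m[, 4L]) > min_tpm
  keep <- !dropped & sig_pairs$s1 > min_s1 & !is.na(rho) & rho < max_rho &
    tumor_iso_ok & normal_iso_ok
  out <- cbind(sig_pairs, spearman_rho = rho, as.data.frame(m))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(out$s1 > min_s1), all(out$spearman_rho < max_rho))
  out
}

#' Classify the protein-level impact of a switch
#'
#' Maps each switch to one of five categories by comparing the coding
#' status and coding-sequence identity of its two isoforms: both
#' non-coding ("no CDS"), only the tumor isoform coding ("no normal
#' CDS"), only the normal isoform coding ("no tumor CDS"), both coding
#' with identical CDS ("no protein affected"), or both coding with
#' different CDS ("protein affected"). Isoforms absent from the
#' annotation yield "unknown".
#'
#' @param switches data.frame with `tumor_isoform`, `normal_isoform`.
#' @param cds data.frame with columns `transcript_id` and `cds_id`
#'   (a CDS identity key, e.g. a sequence hash; `NA` = non-coding).
#' @return character vector of categories, one per switch.
#' @export
classify_protein_impact <- function(switches, cds) {
  cds <- as.data.frame(cds)
  stopifnot(all(c("transcript_id", "cds_id") %in% names(cds)))
  key <- stats::setNames(cds$cds_id, cds$transcript_id)
  vapply(seq_len(nrow(switches)), function(r) {
    ti <- switches$tumor_isoform[r]
    ni <- switches$normal_isoform[r]
    if (!ti %in% names(key) || !ni %in% names(key)) return("unknown")
    ct <- key[[ti]]; cn <- key[[ni]]
    if (is.na(ct) && is.na(cn)) "no CDS"
    else if (is.na(cn)) "no normal CDS"
    else if (is.na(ct)) "no tumor CDS"
    else if (ct == cn) "no protein affected"
    else "protein affected"
  }, character(1))
}

#' Switch occurrence across samples
#'
#' Binary switch-by-sample matrix: entry 1 when the sample satisfies the
#' switch's tumor-orientation rule, i.e. the tumor isoform is not
#' expressed below the normal isoform (rule semantics: ties fall to the
#' tumor branch).
#'
#' @param switches data.frame with `gene`, `tumor_isoform`,
#'   `normal_isoform`.
#' @param tpm expression matrix covering the samples of interest.
#' @return integer matrix, switches x samples, rownames
#'   `gene:tumor_isoform:normal_isoform`.
#' @export
switch_occurrence_matrix <- function(switches, tpm) {
  tpm <- as.matrix(tpm)
  occ <- (tpm[switches$tumor_isoform, , drop = FALSE] >=
          tpm[switches$normal_isoform, , drop = FALSE]) + 0L
  rownames(occ) <- paste(switches$gene, switches$tumor_isoform,
                         switches$normal_isoform, sep = ":")
  occ
}
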