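---
title: "Detecting isoform switches with rank-reversal pair scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting isoform switches with rank-reversal pair scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopair)
```

## The problem and the model

A gene that expresses several transcript isoforms can change *which*
isoform dominates between conditions — an isoform switch — without any
change in overall gene expression. In tumor/normal comparisons such
switches are interesting precisely because they are invisible to
gene-level differential expression. `isopair` detects them from
transcript-level abundances by asking a rank question rather than a
magnitude question: for a pair of isoforms $I_{g,1}, I_{g,2}$ of gene
$g$, how consistently does their relative expression order *reverse*
between the two sample classes $C_1$ (normal) and $C_2$ (tumor)?

The score of an oriented pair is

$$S_1(I_i, I_j) = P(I_i > I_j \mid C_1) + P(I_i < I_j \mid C_2) - 1,$$

where the probabilities are empirical frequencies of the two relative
orders within each class. $S_1 = 1$ is a perfect reversal; $S_1 = 0$
means the order carries no class information. Because the comparison is
within a sample, $S_1$ — and everything built on it — is invariant
under any strictly monotone per-sample transform of expression, which
is why no between-sample normalization beyond TPM is applied.

Ties are frequent in RNA-seq transcript quantification (many
transcripts have zero estimated reads), so tied samples — including
both isoforms at zero — count in the denominator but in neither
numerator under the default `"strict"` tie policy. This deliberately
penalizes pairs of unexpressed transcripts: a pair that is mostly
0-vs-0 cannot accumulate reversal evidence. An alternative `"half"`
policy (ties split 0.5/0.5) is available for comparison. A side effect
of the strict policy is that a pair's best-orientation $S_1$ can be
negative when ties dominate (reaching $-1$ when every sample is tied);
such pairs carry no evidence and are excluded from rankings.

$S_1$ ties are broken by $S_2$, the absolute between-class difference
of the mean within-sample rank difference of the two isoforms (ranks
computed per sample across all transcripts, average ranks for ties).
Each listed pair also carries its information gain (IG): the reduction,
in bits, of the class entropy achieved by splitting samples on the
pair's rule vote.

Each ranked pair doubles as a classification rule, written with the
tumor isoform first: if the tumor isoform is expressed *below* the
normal isoform the sample votes "normal", otherwise — including exact
ties — "tumor" (the rule's `else` branch; we take it literally since
the tie case is otherwise undefined). A classifier is an odd number
$k$ of such rules from distinct genes combined by simple majority
voting; odd $k$ makes vote ties impossible.

## From ranking to switches

The pipeline (`run_pipeline()`, or the `isopair.R` CLI in
`inst/cli/`) proceeds:

1. **Ranking** (`rank_pairs()`): every same-gene isoform pair is scored
   in the orientation maximizing $S_1$; one pair per gene is kept (best
   by $S_1$, then $S_2$) and the list is sorted by $S_1$ desc, $S_2$
   desc, gene id asc — fully deterministic.
2. **Model selection** (`cross_validate()`): leave-one-pair-out
   cross-validation over patients — each fold holds out one patient's
   tumor+normal pair, recomputes the full ranking on the rest, and
   evaluates the top-$k$ classifiers ($k = 1, 3, \dots, k_{max}$) on
   the held-out pair. $k_{opt}$ is the smallest $k$ attaining the
   maximal mean accuracy (equality judged at $10^{-10}$ to avoid float
   artifacts); the final model is the top $k_{opt}$ pairs of the
   full-data ranking.
3. **Significance** (`permutation_test()`): class labels are permuted
   (class sizes preserved, pairing ignored) `n_perm` = 1000 times; each
   permutation records the top pair's $S_1$ and the maximum IG. A pair
   is significant only if its $S_1$ *and* IG strictly exceed the
   respective permutation maxima — a max-statistic rule controlling
   family-wise error at roughly $1/(n_{perm}+1)$. We read the
   conjunction ("S1 and IG larger than the maximum ones") as AND.
   Because the significance criterion uses only these maxima, the
   per-permutation cross-validation is not re-run — only the ranking
   is recomputed, which gives identical selections at a fraction of
   the cost.
4. **Switch filters** (`detect_switches()`): among significant pairs,
   a switch must have $S_1 > 0.5$ (a reversal in more than 75% of
   samples), Spearman correlation of the two isoforms' PSI values
   below $-0.8$, and each isoform's mean TPM above 1 in tumor or in
   normal samples. PSI (a transcript's TPM divided by its gene's total
   TPM) is the right scale for the correlation: for a two-isoform gene
   the PSIs are exactly complementary, so a genuine switch
   anti-correlates perfectly. The correlation uses the paired samples
   jointly (the samples the pair machinery was trained on), dropping
   pairwise the samples where PSI is undefined, with at least 3
   complete observations required.
5. **Mutation association** (`mutation_association()`): per switch,
   the sample sets $S$ (switch present, by the rule) and $M$ (a
   somatic mutation overlapping either isoform's span) are compared by
   the Jaccard index $J = |M \cap S| / |M \cup S|$, mutual information
   in bits, and the mutual-exclusion score
   $mx = 2\min(n_{10}, n_{01})/N$ (computed on protein-affecting
   mutation classes). Each statistic gets a z-score against the 100
   genes nearest in median isoform length (sum of exon widths per
   transcript, median per gene; nearest-by-absolute-difference with
   gene-id tie-break — the matching rule is our choice, as is using
   the gene span for background overlap since background genes have no
   designated pair). Per-sample $\Delta$PSI (tumor-isoform PSI minus
   normal-isoform PSI, in tumor samples) is compared between mutated
   and non-mutated samples with a two-sided Mann–Whitney test (exact
   for groups of ≤8 without ties, tie-corrected normal approximation
   otherwise), Benjamini–Hochberg-adjusted across switches.

### Choices where the design was open

* **Missing PSI, not zero.** A gene with zero total TPM in a sample has
  *undefined* relative isoform abundance; coding it as 0 (or 0.5) would
  manufacture anti-correlation. Such entries are `NA` and are dropped
  pairwise from correlations.
* **Fold unit.** "Leaving out one sample from each class" is
  interpreted in the paired design as leaving out one *patient's*
  matched pair, making folds deterministic given the pairing order.
* **Final model pairs.** The model's pair identities come from the
  full-data ranking, not from any single fold's ranking; the folds only
  choose $k_{opt}$.
* **$k_{max}$** defaults to 11: published rank-reversal models are
  small, and accuracy curves flatten well before that.
* **Abundance filter reading.** ">1 TPM across either tumor or normal
  samples" is read per isoform: each isoform's class-mean TPM must
  exceed the cutoff in at least one class (possibly different classes
  for the two isoforms).
* **Gene mode.** For comparison with gene-level rank classifiers, the
  dataset can be collapsed to per-gene TPM sums
  (`gene_level_dataset()`); ranking then pairs any two genes and keeps
  disjoint pairs greedily down the sorted list, since "one pair per
  gene" has no meaning across genes.
* **Orientation ties.** If both orientations of a pair give the same
  $S_1$ (only possible with ties), the first-listed transcript is kept
  as the normal isoform — an arbitrary but deterministic choice.

## What the synthetic generator emulates

`simulate_isoform_data()` produces the paired two-class cohorts used
throughout the tests. Its defaults are the package's reference
conditions: 1000 genes with 2–4 isoforms, 30 patient pairs, 50 planted
switch genes with penetrance 0.95, log-normal expression noise
(sdlog 0.5), 5% zero-inflation, and mutations co-occurring with planted
switches at $P(\text{mut}\mid\text{switch}) = 0.5$ versus
$P(\text{mut}\mid\text{no switch}) = 0.02$.

Per gene, a log-normal expression level (median 50 TPM-equivalents) is
split across isoforms by a decreasing proportion profile shared by both
classes. A planted switch gene gets a genuinely dominant profile — top
isoform around PSI 0.55–0.7, second isoform 0.15–0.25, ratio ≥ 2.75 —
and, in each tumor sample independently with probability equal to the
penetrance, the two top isoforms *swap their mean proportions*. The
swap keeps gene-level expression exactly constant, isolating the
splicing signal from any expression signal: gene-level classifiers see
nothing where isoform-level classifiers see everything. Noise and
zero-inflation are applied after the swap, then each sample is
renormalized to $10^6$, which produces exactly the non-monotone,
tie-rich rankings the strict tie policy exists for. Transcript
structures are laid out on five synthetic chromosomes (1–3 exons per
isoform) so mutation overlap and GFF export run on realistic
coordinates; mutations are placed uniformly within gene spans.

What the generator does **not** emulate: library-size and GC biases,
batch effects, correlated noise across genes, realistic isoform-count
and length distributions, intra-tumor heterogeneity, or mutation
hotspots. Passing tests therefore demonstrate the *statistical
machinery* — scoring, calibration, power, recovery — under the model's
own assumptions, not performance on any real cohort.

## Problem sizes used in validation

The validation suite runs, at fixed seeds:

* exact agreement of $S_1$/$S_2$/IG and the full ranking with
  brute-force enumeration oracles on 1000 random instances (≤10 genes,
  ≤5 isoforms, ≤12 samples, integer expression rich in ties);
* full recovery on the reference cohort (all 50 planted pairs above
  all non-planted pairs; switch sensitivity and precision ≥ 0.9 with
  `n_perm` = 200);
* calibration on 20 null cohorts (300 genes, 30 pairs, `n_perm` = 100):
  at least 95% yield no significant pair, and mean cross-validation
  accuracy sits within 3 binomial SD of 0.5. Within one null dataset
  the fold accuracies are strongly correlated (folds share all but one
  patient) and per-fold selection is adversarial — the top training
  pair tends to be one whose exceptions concentrate in the held-out
  patient — so single-replicate CV accuracy swings widely around 0.5
  (sd ≈ 0.09 at this size) even though its expectation is exactly 0.5
  by exchangeability; averaging replicates is essential;
* detection power non-decreasing over 4, 8, 16 and 32 patient pairs at
  penetrance 0.9 — at these settings power climbs from ~0 at 4 pairs
  to ~1 at 16, echoing the rule of thumb that a dozen-plus sample
  pairs are needed for significant calls;
* mutation co-occurrence: mean Jaccard z-score ≥ 2 under the planted
  two-rate model and |mean z| ≤ 0.5 after relocating mutations to
  unrelated genes; Mann–Whitney p-values uniform under random mutation
  assignment.

`scripts/acceptance.R` recomputes the same quantities end to end from
a single `--seed` (null-calibration and mutation-association runs use
10 replicates there).

## A small worked run

```{r example}
sim <- simulate_isoform_data(simulation_config(
  n_genes = 100, n_patient_pairs = 20, n_switch_genes = 5, seed = 42))
ds <- sim$dataset
ranking <- rank_pairs(ds)
head(ranking, 5)

null <- permutation_test(ds, n_perm = 100, seed = 43)
sig <- significant_pairs(ranking, null)
switches <- detect_switches(sig, ds)
switches[, c("gene", "tumor_isoform", "normal_isoform", "s1", "spearman_rho")]

cv <- cross_validate(ds, k_max = 5)
cv
```

## Known limitations

* The permutation test recomputes only the ranking per permutation;
  the (statistically equivalent for the thresholds, much slower)
  variant that reruns cross-validation per permutation is not
  implemented.
* Cross-gene isoform pairs are not considered in isoform mode; the
  method sees only within-gene reversals.
* The mutation module tests co-occurrence and exclusion, not
  causality; z-scores inherit whatever length-related biases survive
  the median-length matching.
* With very small cohorts (a handful of pairs) the permutation maxima
  saturate and nothing can be called significant — a property of the
  max-statistic design, not a bug.
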