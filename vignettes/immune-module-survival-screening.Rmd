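---
title: "Immune transcript modules and median-split survival screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune transcript modules and median-split survival screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The procedure

The package implements a screening pipeline for asking whether immune
gene-expression programs in bulk tumor transcriptomes predict patient
survival, and what genomic differences separate immune-rich from immune-poor
tumors.

1. **Module construction.** For each immune *marker* gene (a CD antigen,
   cytokine, or hematopoietic transcription factor), compute the Pearson
   correlation of the marker with every transcript across a reference panel
   of purified immune-cell and whole-blood profiles, and keep the 100 most
   positively correlated transcripts as that marker's *module*. The marker
   correlates 1.0 with itself and is always a member. Negatively correlated
   transcripts are never used. All correlations are computed on the stored
   log2(RPM + 1) scale without re-normalization.
2. **Module clustering and annotation.** Markers of the same cell type yield
   near-identical modules, so modules are grouped by the fraction of shared
   genes: Ward agglomerative clustering (`hclust`, `ward.D`) on distance
   `1 - overlap`, and hypergeometric enrichment of every module against
   reference gene-set collections with Benjamini-Hochberg correction within
   each collection (FDR < 0.05 for a "top term").
3. **Survival screening.** Each tumor sample is scored by the *median*
   expression of a module's genes; the cohort is split at the cohort median
   of that score (samples at or below the median are `lo`, strictly above
   are `hi`); the two strata are compared with the two-group log-rank test
   (1 df), and the continuous score's prognostic value is summarized by
   Harrell's concordance index. Optionally, follow-up is first truncated at
   a common horizon (1825 days) by administrative censoring.
4. **Permutation nulls.** Because hundreds of modules are screened per
   cohort, significance is calibrated empirically rather than by analytic
   multiple-testing correction: (a) random equal-sized *sample* partitions
   re-test the same survival data with meaningless labels; (b) random
   size-matched *gene sets* re-run the genuine scoring machinery with
   meaningless gene identities. Counts of tests below 1e-3 and 5e-3 are
   compared with the nominal expectation (`n_tests * alpha`), and
   significant modules are consolidated by counting connected components of
   the >25%-overlap graph and by retaining only themes supported by at least
   two significant modules sharing a cluster or a summary annotation term.
5. **Genomic scans.** Given a hi/lo partition, each gene of a copy-number
   (or expression/protein) table is compared between strata with the
   two-sided Wilcoxon rank-sum test; results are ordered along the genome
   (chromosomes 1..22, X, Y, then start position) and contrasted with the
   same scan under random partitions. "Peaks" are maximal runs of at least
   `min_run = 3` contiguous genes with p below 1e-3.

## Statistical components and conventions

* **Log-rank.** Implemented as a vectorized multi-partition engine
  (`logrank_many`): at each distinct event time the observed hi-group event
  count, its conditional expectation and its hypergeometric variance are
  accumulated; `chisq = (sum(O - E))^2 / sum(V)` with p from a 1-df
  chi-square. A single pass evaluates thousands of random partitions, which
  is what makes 1,000-permutation nulls per cohort routine. The statistic is
  numerically identical to `survival::survdiff`, which the test suite uses
  as an independent oracle.
* **Kaplan-Meier.** Product-limit curves via `survival::survfit`.
* **Concordance.** Harrell's C with the pair convention that a pair is
  comparable exactly when the smaller observed time carries an event —
  tied observed times are never comparable; score ties count 1/2. Higher
  score is treated as higher risk, and both the raw and the orientation-free
  `max(C, 1 - C)` are reported, because a module can legitimately be
  protective or deleterious. On tie-free data the value coincides with
  `survival::concordance` (asserted in tests); on tied times the
  conventions differ slightly, and the package follows its stated pair rule.
* **Wilcoxon rank-sum.** `stats::wilcox.test`: exact distribution when both
  groups have at most 10 values and no ties; otherwise midranks with
  tie-corrected variance and continuity correction. When the pooled values
  have zero rank variance the statistic sits at its null center and p = 1.
* **Hypergeometric enrichment.** Upper tail `P(X >= k)` via `phyper`, after
  intersecting both the module and the annotation set with the universe.
  The enrichment universe is the full gene list of the reference panel the
  modules were built from, intersected with each collection's gene space.
* **Cluster-number selection.** The number of clusters is chosen by cutting
  the Ward tree at every k in 2..30 and maximizing the mean silhouette
  width (`cluster::silhouette`), with ties to the smaller k; a fixed k is
  also accepted. This replaces a model-based criterion with a deterministic,
  dependency-light rule; on well-separated collections the two agree.
* **Summary terms.** Cluster summary annotations are rule-derived (most
  frequent top term among member modules; ties to the smallest FDR, then
  name) rather than manually assigned, so they are reproducible.

## Determinism and tie-breaking

Every stochastic component takes an explicit seed and is a pure function of
(parameters, seed); generators restore the caller's RNG state. Sub-streams
(reference panel, cohort, copy-number, random sets, random partitions) are
derived deterministically from the single pipeline seed. Ranking ties in
module construction break by descending correlation then ascending gene id;
equal-score samples go to `lo`; at odd n, random partitions give `hi` the
extra sample. Degenerate cases (module coverage below 50%, constant scores,
zero events, no comparable pairs) produce recorded *skip* signals rather
than errors, so a screen always reports a complete grid.

## The synthetic-data generator

The generator exists so that every downstream stage can be tested against a
known ground truth; it emulates the *statistical assumptions* of the
analysis, not the full complexity of tumor RNAseq:

* **Reference panel.** Each cell-type block shares a latent per-sample
  factor; member genes load on it so that the pairwise within-block
  correlation is about `within_block_corr` (default 0.6) at `noise_sd = 1`,
  and the designated marker carries the largest loading. Background genes
  are independent noise. Values sit on a baseline of 6 log2(RPM + 1) units
  and are clipped at 0. Defaults: 5 blocks of 100 genes, 1,000 background
  genes, 336 panel samples (a realistic purified-immune-panel size).
* **Tumor cohorts.** Each sample draws an infiltrate fraction
  `f ~ Uniform(0, 1)`; block genes gain `infiltrate_slope * f` (default 2
  log2 units across the range) so the median module score is monotone in
  `f`. Survival is exponential proportional hazards with a *binary*
  covariate: hazard `baseline_hazard * exp(beta)` for the above-median-`f`
  half (defaults: baseline 1/1000 events/day, i.e. median survival ~2
  years). Censoring is the minimum of an independent exponential (rate
  1/2000/day) and an administrative 3,650-day cutoff, emulating
  date-of-last-visit censoring; these defaults give roughly 60% observed
  deaths. `beta = -1` plants a melanoma-like protective infiltrate,
  `beta = +1` a deleterious one, `beta = 0` the null.
* **Copy number.** Gene-level values are Normal(0, 0.3) around the
  copy-neutral log2 ratio; a contiguous run of `region_span` genes (default
  30) is shifted down by `loss_depth` (default 1) in carrier samples, drawn
  with probability 0.8 from the low-infiltrate half and 0.1 from the high
  half — a deletion *enriched in*, not exclusive to, immune-poor tumors.
  Genes are laid out 100 per synthetic chromosome at fixed spacing.

What the generator deliberately does **not** model: negative-binomial count
noise, tumor purity and deconvolution, batch effects, non-proportional
hazards, subclonal or focal-amplification copy-number structure, and any
dependence between censoring and outcome. Passing tests therefore
demonstrate that the machinery recovers planted structure under its own
assumptions — not that those assumptions hold in any real cohort.

The infiltrate-to-expression link is linear on the log2 scale; this is an
explicit simplification (recorded in `truth.json`) chosen to keep the
module score monotone in the infiltrate without committing to an unknown
real-world dose-response shape.

## Problem sizes used by the test and acceptance runs

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen for statistical resolution: null calibration uses
cohorts of n = 200 with 1,000 random partitions each (400 replicate cohorts
in the acceptance script, so the reported mean count at p < 1e-3 has a
Monte-Carlo standard error near 0.05); recovery checks use 100 seeds of
n = 300 cohorts with `|beta| = 1` and a 30-gene planted deletion in a
300-gene scan. Collections in end-to-end runs use a handful of markers
rather than hundreds; module construction cost is linear in markers and
the statistics are unchanged.

## Known limitations

* The median split discards within-half dose information; the concordance
  index on the continuous score partially compensates, but no Cox
  modelling, covariate adjustment, or competing-risk handling is provided.
* Cluster-count selection by silhouette can choose a different k than a
  model-based criterion on the same data; the cut is deterministic and the
  linkage record is kept so any k can be re-cut.
* The random-gene-set null is reported, never used as the primary null:
  single genes can carry prognostic value irrespective of set membership,
  so random sample partitions are the cleaner null for the survival
  machinery.
* Scans apply no multiple-testing correction by design; false-positive
  assessment is delegated to the random-partition contrast, and peak calls
  are a formalized (`min_run` contiguous significant genes) but simple
  notion of a region.
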