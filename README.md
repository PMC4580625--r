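# immunomod

Immune transcript modules and median-split survival screening for tumor
cohorts.

Tumors differ widely in the amount and kind of immune infiltrate they carry,
and in whether that infiltrate predicts how long patients survive. This
package implements a marker-anchored screening pipeline for that question,
aimed at computational biologists working with bulk tumor expression,
clinical follow-up, and gene-level copy-number tables:

1. **Modules.** For each immune marker gene *m* (CD antigens, cytokines,
   hematopoietic transcription factors), compute Pearson correlations
   *r(m, g)* against every transcript *g* across a reference panel of
   purified immune-cell profiles, and keep the top 100 most positively
   correlated transcripts as the module `m.mod` (the marker itself included
   at *r* = 1).
2. **Screen.** Score each tumor sample by the median log2(RPM + 1)
   expression of the module's genes, split the cohort at the cohort median
   (ties to `lo`), and compare the strata with the two-group log-rank test:
   χ² = (Σ(O − E))² / ΣV over distinct event times, 1 df. Harrell's
   concordance index C of the continuous score (higher score = higher risk;
   C = 0.5 is uninformative) summarizes prognostic value.
3. **Calibrate.** Empirical nulls instead of analytic correction: counts of
   significant tests at p < 1e-3 and 5e-3 under (a) random equal-sized
   sample partitions and (b) random size-matched gene sets, compared with
   the nominal *n*·α; significant modules consolidated by connected
   components of the >25%-gene-overlap graph.
4. **Scan.** Per-gene two-sided Wilcoxon rank-sum tests between the hi and
   lo strata of copy-number, expression or protein tables, ordered along
   the genome (Manhattan view) and contrasted with random-partition
   controls; peaks are runs of ≥3 contiguous genes below p = 1e-3.

A synthetic-data generator with planted coexpression blocks, an
infiltrate-driven proportional-hazards survival effect, and a contiguous
copy-number deletion makes the whole pipeline testable end to end; see the
methods vignette (`vignettes/immune-module-survival-screening.Rmd`) for the
model and its assumptions.

## Worked example

```r
library(immunomod)

# reference panel with 3 planted immune cell types, 336 samples
ref <- generate_reference_panel(n_blocks = 3, genes_per_block = 100,
                                n_background_genes = 500, n_samples = 336,
                                seed = 1)
modules <- build_all_modules(ref$expr, ref$markers)
modules
#> <module_collection> 3 derived modules (sizes 100-100), 300 distinct genes
modules[["MK1.mod"]]
#> <gene_module> MK1.mod: 100 genes, r in [0.618, 1.000]

# melanoma-like cohort: high infiltrate protective (log hazard ratio -1)
coh <- generate_tumor_cohort(n_samples = 300, reference_truth = ref$truth,
                             beta = -1, seed = 2)
res <- screen(coh$expr, coh$clinical, modules, cohort = "melanoma_like")
res
#> <screen_matrix> 3 module x cohort tests (0 skipped)
#>          cohort n_tested n_skipped sig_1e3 sig_5e3 mean_concordance_sig
#> 1 melanoma_like        3         0       3       3            0.6330002

s <- module_score(coh$expr, modules[["MK1.mod"]])
logrank_test(coh$clinical, median_partition(s, "module:MK1.mod"))
#> <survival_test> chisq = 44.067 (1 df), p = 3.17e-11, n = 150 hi / 150 lo, hi protective
```

All three planted modules split survival at p < 1e-3, the high-infiltrate
half survives longer (as planted), and the oriented concordance of 0.63
says the continuous module score ranks risk well above chance. The same
partition then drives the genome scan:

```r
cn <- generate_cnv_profiles(coh$truth, seed = 3)   # 30-gene planted loss
part <- median_partition(s, "module:MK1.mod")
cmp <- compare_to_random(cn$cnv, part, cn$positions, n_random = 1, seed = 4)
cmp
#> <scan_comparison> 400 genes at p < 0.001: module 30 vs random 0; 1 peak region(s)
cmp$peaks
#>   chrom   start     end n_genes        min_p first_gene last_gene
#> 1     1 1270000 1560000      30 1.076325e-25   CNG00028  CNG00057
```

The module partition finds exactly the 30 planted deleted genes as one
contiguous peak; the matched random partition finds nothing.

End-to-end runs from a single YAML config (`run_screen_pipeline()`,
`run_scan_pipeline()`, or the thin CLI at `inst/cli/immunomod.R`) write
`modules.gmt`, overlap/cluster/annotation tables, `screen.tsv`, null
summaries and genome scans, each stamped with the seed and config hash;
fixed-seed reruns are byte-identical apart from the log.

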