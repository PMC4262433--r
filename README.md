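# tagstore

Quantification of lipid-droplet (LD) and triacylglycerol (TAG) storage and
turnover in procyclic *Trypanosoma brucei* — an R implementation of the
analysis pipeline behind oleate-feeding experiments, for parasitologists
and lipid biologists who want the published summary analyses as tested,
reusable code.

Procyclic trypanosomes fed with oleate build up lipid droplets; three
independent assays (confocal LD counting, flow cytometry of
BODIPY-stained cells, TAG densitometry on TLC plates) should agree on the
induction factor. After oleate withdrawal, the central question is whether
the store is catabolized or merely diluted by cell division. The package
covers:

* **Synthetic data** (`study_config()`, `gen_*()`) — seeded generators for
  every input table (per-cell LD counts, flow intensities, growth curves,
  decay series, TAG species tables, two-genotype proteomes, enzyme
  activities, TLC lanes), calibrated to the published summary statistics.
* **Fold-change quantification** (`fold_change()`, `summarize_counts()`,
  `concordance_report()`) — ratio-of-means estimates with small-sample
  expanded percentile bootstrap CIs, and a three-modality concordance
  check.
* **Growth kinetics** (`fit_exponential_growth()`) — log-linear fit giving
  the specific growth rate μ and doubling time T_d = ln2/μ.
* **Turnover model** (`predict_dilution()`, `predict_with_basal()`,
  `fit_turnover()`, `net_catabolism_test()`, `decay_report()`) — the
  division-dilution null model S(t) = S₀·2^(−t/T_d), its kinetic extension
  dS/dt = s − (μ + k)S with basal plateau B and catabolic rate k ≥ 0, and
  a Holm-corrected one-sided test of whether measurements ever fall below
  the calculated dilution curve.
* **Lipidomics** (`parse_species_label()`, `normalize_to_standard()`,
  `aggregate_by_class()`, `compare_conditions()`) — TAG species label
  parsing (e.g. `54:3` = 54 acyl carbons, 3 double bonds), internal
  standard normalization (TAG 17:0/17:0/17:0), isomer aggregation into
  carbon:double-bond classes.
* **Proteome ratios** (`filter_quantifiable()`, `abundance_ratio()`,
  `classify_two_fold()`, `unchanged_proteome_check()`) — label-free WT/KO
  comparison with the minimum-2-peptides rule, floored ratios for ablated
  proteins, 2-fold band classification.
* **Enzyme enrichment** (`enrichment_factor()`, `genotype_contrast()`,
  `glucose_contrast()`) — specific-activity bookkeeping for glycosome
  fractionation with error propagation.

See `vignettes/storage-turnover.Rmd` for the models, assumptions and
numerical choices.

## Worked example

Estimate the LD-count induction fold from three synthetic replicate
populations, then run the full turnover analysis:

```r
library(tagstore)

ld <- sapply(0:2, function(i) {
  cfg <- study_config(seed = 1 + i)
  c(mean(gen_ld_counts(cfg, "fed")$count),
    mean(gen_ld_counts(cfg, "unfed")$count))
})
fold_change(ld[1, ], ld[2, ], seed = 1)
#> fold change 4.69  [4.64, 4.74] 95% bootstrap CI (1000 resamples, seed 1)

cfg <- study_config(seed = 1)
decay_report(gen_decay_experiment(cfg), gen_growth_curve(cfg), seed = 1)
#> == Stored-lipid decay analysis ==
#> doubling time 12.3 h (mu = 0.05617 /h, residual SE 0.049, n = 9)
#> turnover fit (mu fixed at 0.05617 /h):
#>   basal b = 0.2334  [0.1968, 0.3618]
#>   catabolic k = 0 /h  [0, 0.01039]
#>   synthesis s = b(mu+k) = 0.01311 /h
#>   weighted RSS 28.86 (k pinned to 0: 28.86, delta 0)
#>  time_h measured      sem predicted   p p_holm significantly_below
#>       0   1.0000 0.050638    1.0000 0.5      1               FALSE
#>       4   0.8840 0.011216    0.7988 1.0      1               FALSE
#>       8   0.7187 0.016847    0.6380 1.0      1               FALSE
#>      12   0.6714 0.014021    0.5097 1.0      1               FALSE
#>      16   0.5357 0.005510    0.4071 1.0      1               FALSE
#>      24   0.4362 0.003902    0.2597 1.0      1               FALSE
#>      32   0.3513 0.006902    0.1657 1.0      1               FALSE
#> verdict: no net catabolism (alpha = 0.05, Holm-adjusted)
```

The fold change says fed cells carry ~4.7× the LD count of unfed cells.
In the decay analysis, the fitted catabolic rate is 0 (CI touching the
boundary), the measured signal never falls significantly below the
dilution prediction, and the series plateaus at the basal level b ≈ 0.23
maintained by ongoing uptake and synthesis — i.e. division dilution fully
accounts for the decay.

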