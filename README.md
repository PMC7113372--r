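# spliceMod

Modulator-dependent RBP regulation of alternative splicing.

An RNA-binding protein (RBP) bound near a skipped exon shapes that exon's
inclusion level (PSI), and across a patient cohort this shows up as a
correlation between RBP expression and PSI. spliceMod screens for
**triplets** — (modulator, RBP, skipped-exon event) — in which a third
gene's expression *changes* that relationship, and classifies each
significant triplet into one of six modulation modes (attenuates/enhances
exon exclusion or inclusion, or inverts the direction).

For one triplet the model is

    Y_target = β0 + β1·X_rbp + β2·X_m + β3·X_rbp·X_m + ε

and a modulator effect means β3 ≠ 0. Each variable is discretized by
tertiles (lower third → 0, upper third → 1, middle third and missing →
NULL); samples with any NULL label are dropped, leaving the eight joint
label cells. β3 is then estimated as the difference-in-differences of
upper-tertile inclusion proportions over the four (RBP, modulator) cells,

    β̂3 = p̂11 − p̂10 − p̂01 + p̂00,   z = β̂3 / √( Σ p̂(1−p̂)/n ),

tested with a two-sided normal tail and selected under joint
Benjamini–Hochberg control (default FDR ≤ 0.01). Selected triplets are
classified by comparing the RBP–PSI Pearson correlation in the
modulator-low vs modulator-high sample thirds (PCC_low / PCC_high):
AEE, AEI, EEE, EEI, ExonIE, ExonEI.

The package covers the whole path from raw inputs to summaries:

- **I/O** — expression/PSI TSV matrices, MISO-style three-exon event ids
  (`chr:s:e:strand@chr:s:e:strand@chr:s:e:strand`), eCLIP narrowPeak/BED
  files, GTF exon enumeration, fixed-format triplet tables.
- **Filters** — gene expression (mean log2(CPM+1) ≥ 1), event quality
  (PSI prevalence, completeness, CV), RBP/modulator independence screen.
- **Target map** — peak enrichment/p-value filter, replicate and
  cell-line union, ±300 bp windows around the skipped exon, interval
  overlap (GenomicRanges).
- **Screen and classifier** — tertile discretization, interaction fit, BH
  selection, group-wise correlations, six-category rule table.
- **Summaries** — per-RBP category counts, top modulators, modulator
  pattern matrix, hierarchical modulator clustering, co-expression matrix.
- **Synthetic cohorts** — a fully seeded generator
  (`simulateCohort()`/`emitFixtureFiles()`) with planted effects per
  category, so everything is testable with no data download.

## Worked example

```r
library(spliceMod)

cfg <- simConfig(n_samples = 480, n_rbps = 2, n_modulators = 8,
                 n_events = 20, fraction_planted = 0.5, seed = 7)
cohort <- simulateCohort(cfg)
cohort
#> TripletCohort
#>   expression: 10 genes x 480 samples
#>   PSI: 20 events x 480 samples
#>   targets: 20 assignments; truth rows: 20 (10 planted)

res <- screenTriplets(cohortExpr(cohort), cohortPsi(cohort),
                      cohortTargets(cohort), sprintf("MOD%04d", 1:8))
ann <- annotateTriplets(res, cohortExpr(cohort), cohortPsi(cohort))
ann[, c("modulator", "rbp", "beta3", "q", "pcc_low", "pcc_high", "category")]
#>   modulator    rbp      beta3            q    pcc_low   pcc_high category
#> 1   MOD0005 RBP001  1.6121654 2.517314e-58 -0.7034757  0.7132067   ExonEI
#> 2   MOD0001 RBP002 -1.5574960 5.961636e-53  0.6817643 -0.6748094   ExonIE
#> 3   MOD0003 RBP002 -0.4057471 5.553362e-03 -0.4866156 -0.8222197      EEE
```

Three triplets clear FDR ≤ 0.01 — all three are planted ones (precision 1
here; the remaining planted effects are milder and fall below this strict
threshold at 160 tests). Reading the first row: when MOD0005 is lowly
expressed, RBP001 expression correlates negatively with the target's PSI
(r = −0.70, exon exclusion), but in the MOD0005-high third the correlation
inverts to +0.71 — an exclusion-to-inclusion inversion (ExonEI), matching
the planted category. `categoryCounts(ann)`, `topModulators(ann)`,
`modulatorPatternMatrix(ann)` and `clusterModulators()` aggregate larger
result sets.

The same analysis runs end-to-end from files via `runPipeline("config.yaml")`
or the CLI wrapper (`inst/scripts/splicemod.R` with subcommands `simulate`,
`filter`, `map-targets`, `screen`, `classify`, `summarize`, `run-all`).

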