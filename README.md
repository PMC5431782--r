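# niptkit

Read-count analysis for whole-genome non-invasive prenatal testing
(NIPT). Cell-free DNA in maternal plasma is a mixture of maternal DNA
and a small fetal (placental) fraction *ff*; a fetal trisomy raises the
sequencing-read fraction of the affected chromosome by roughly
*ff*/2 — typically well under 5%. Detecting that shift requires tight
control of the between-sample variation in read counts. `niptkit`
implements the full analysis stack for laboratories and method
developers working with shallow whole-genome NIPT data:

* **Binning** — primary, mapped, non-duplicate alignments counted into
  50,000-bp autosomal bins, forward and reverse strand separately
  (`bin_counts_from_alignments()`, `gc_track_from_fasta()`).
* **Variation reduction** — peak correction (removal of bins whose
  coverage deviates >1.96 SD from their chromosome in ≥95% of
  controls), weighted-bin and LOESS GC corrections (span 0.75,
  degree 2), and chi-squared-based variation reduction (χ²VR), which
  down-weights bins whose between-control variance exceeds the
  chi-squared expectation (Z > 3.5), whatever the origin of the bias.
* **Trisomy prediction** — four statistics:
  * standard Z-score: `z = (of_s − mean(of_ctrl)) / sd(of_ctrl)` on the
    chromosomal fraction `of` over all autosomes;
  * MAD-based Z-score: the SD replaced by `1.4826 · MAD` for outlier
    tolerance;
  * NCV: Z-score of the ratio target/denominator chromosomes, the
    denominator subset chosen exhaustively to minimize the control CV;
  * regression-based Z-score (RBZ): four disjoint forward-selected sets
    of four strand-level chromosome-fraction predictors each;
    `z = (of/ef − 1) / sd_j(of_j/ef_j)` with `ef` the regression
    prediction, called only when all four sets exceed the threshold.
* **Match QC** — the mean over controls of the summed squared
  chromosomal-fraction differences (chromosomes 13/18/21 excluded),
  with a mean + 3 SD cutoff calibrated leave-one-out on a training set;
  flags samples for which the control group is not representative.
* **Simulation** — `simulate_cohort()` generates bin-count cohorts with
  GC bias (including run-to-run slope variation), coverage peaks,
  overdispersed bins, correlated chromosome factors, strand skew,
  negative-binomial noise and expectation-level trisomies, so every
  stage is testable without sequencing data.
* **Pipeline/CLI** — `run_pipeline()` and the `niptkit` script
  (`inst/cli/niptkit`) with subcommands `bin`, `simulate`, `correct`,
  `qc`, `predict`, `compare`, driven by a YAML/JSON config.

The control-group coefficient of variation (CV = SD/mean) of the
statistic is the figure of merit throughout: together with the fetal
fraction it determines sensitivity, `sens = Φ((ff/2)/CV − 3)` at the
z > 3 call threshold (99.7% confidence level).

## Worked example

Simulate an Illumina-like cohort (100 controls, two trisomy-21 cases at
8% fetal fraction), apply LOESS GC correction followed by χ²VR, check
control-group representativeness, and predict:

```r
library(niptkit)

sim <- simulate_cohort(sim_config(seed = 7, n_controls = 100, n_cases = 2))
corrected <- apply_corrections(sim$controls, sim$cases,
                               corrections = c("gc_loess", "chi2vr"),
                               gc = sim$gc)

corrected$log$chi2vr
#> <chi_square_correction> df = 99; 949 bin(s) corrected at Z > 3.5; 28 zero-mean bin(s) skipped

cutoff <- calibrate_cutoff(corrected$controls)
match_qc_overall(corrected$targets[[1]], corrected$controls, as.numeric(cutoff))
#> <match_qc_report> case_001: overall 9.535e-06 vs cutoff 1.038e-05 -> PASS

standard_zscore(corrected$targets[[1]], corrected$controls, 21)
#> <trisomy_result> case_001 chr21 [zscore]: z = 13.03, control CV = 0.00299, call = TRUE

mod <- rbz_train(corrected$controls, 21)
rbz_zscore(corrected$targets[[1]], corrected$controls, mod)
#> <trisomy_result> case_001 chr21 [rbz]: z = 21.16/19.74/18.99/19.37, control CV = 0.00182, call = TRUE
```

Reading the output: χ²VR corrected 949 of 2,897 bins whose
between-control variation exceeded the chi-squared expectation (the
cohort plants GC-slope variation and 1% overdispersed bins). The case
passes Match QC (its fraction pattern fits the control group), the
standard Z-score of 13.0 at a control CV of 0.30% calls the trisomy,
and the RBZ — whose regression models cancel correlated chromosome-level
variation, control CV 0.18% — calls it unanimously in all four predictor
sets. `estimate_fetal_fraction(z, cv)` here returns 0.078, recovering
the planted 8%.

## Scope

Autosomes only; alignment, duplicate marking and sex-chromosome or
microdeletion analysis are out of scope. See
`vignettes/niptkit-methods.Rmd` for the statistical model, parameter
choices and limitations.
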