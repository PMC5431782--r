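---
title: "niptkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{niptkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Shallow whole-genome sequencing of cell-free DNA from maternal plasma
detects fetal trisomies through a small excess of reads on the affected
chromosome: if the fetal fraction is $ff$, the expected chromosomal
read fraction scales by $1 + ff/2$ (only half of the placental genome
copies are supernumerary). With $ff$ commonly 2–15%, the signal is a
relative shift of 1–7% in a fraction whose counting noise at 10–20
million reads is already ~0.2%, and whose systematic between-sample
variation (GC bias, coverage peaks, run effects) is several times
larger. Everything in this package is about measuring that shift
against a control group of non-trisomy pregnancies with the smallest
possible control-group coefficient of variation (CV = SD/mean), because
at the one-sided call threshold $z > 3$ the theoretical sensitivity is
$\Phi\!\left(\frac{ff/2}{CV} - 3\right)$.

Only autosomes are analyzed; the sample unit is the 50,000-bp bin with
forward- and reverse-strand read counts kept separately.

# Corrections

All corrections learn their parameters from the control group (or, for
the GC corrections, from the sample itself) and are applied identically
to controls and analyzed samples; a sample can therefore never shape
its own correction through its putative trisomy. When stacked, the
order is fixed: peak → GC → χ²VR.

## Normalization

Counts are made comparable across sequencing depths by scaling each
sample's strand-summed bin counts with the factor
(mean bin count over all control bins and samples)/(mean bin count of
the sample). All downstream statistics are fractions or ratios and are
invariant to this overall scale, which is verified as a property test
(multiplying any sample's counts by $c > 0$ changes nothing).

## Peak correction

Per control sample and chromosome, a bin *deviates* when its
strand-summed count falls outside mean ± 1.96 SD of that chromosome's
bins in that sample; bins deviating in ≥ 95% of controls are removed
(zeroed on both strands) in controls and analyzed samples alike. The
two thresholds are the method's definition, not tunables we fitted.
Deviation is evaluated on strand-summed counts (the strand split is a
binomial thinning and carries no independent information here), and
"removal" is implemented as zeroing so bin geometry stays fixed; zeroed
bins are automatically excluded from later GC-weight estimation because
GC corrections ignore read-free bins.

## GC corrections

Both methods estimate, per sample, how coverage depends on the bin's GC
fraction, and rescale counts to the global mean; both ignore bins with
no reads or undefined (all-N) base composition, and both scale the two
strand counts of a bin by the same factor, preserving strand ratios.

* **Weighted-bin**: bins are grouped into GC intervals of 0.1
  percentage points; an interval's weight is its mean coverage divided
  by the mean coverage of all eligible bins; counts are divided by the
  weight. An interval with weight 0 would be left unchanged (flagged);
  this cannot arise for eligible bins, which have reads by definition,
  but the guard is kept for corrected (real-valued) inputs.
* **LOESS**: a locally weighted polynomial regression of count on GC
  (tricube weights, span 0.75, local degree 2 — the R defaults of
  `stats::loess`, which is also the smoother those settings were quoted
  from) is fitted per sample; counts are multiplied by
  (global mean)/(fitted value). Non-positive fitted values leave the
  bin unchanged and are recorded. At least 50 eligible bins are
  required for a stable fit.

## Chi-squared variation reduction (χ²VR)

For each bin $i$, with normalized counts $on_{ij}$ over controls $j$
and their mean $\mu_i$:
$$\Sigma\chi^2_i = \sum_j \frac{(\mu_i - on_{ij})^2}{\mu_i}, \qquad
  z_i = \frac{\Sigma\chi^2_i - df}{\sqrt{2\,df}}, \quad df = n-1.$$
Bins with $z_i > 3.5$ have their normalized counts divided by
$\Sigma\chi^2_i/df$ in the controls *and* every analyzed sample; other
bins are untouched. The display form of the statistic sums the
per-control chi-squared terms over controls (the prose definition);
bins with $\mu_i = 0$ cannot be scored, are left unchanged, and are
counted in the correction object. Output counts are corrected
*normalized* counts: every downstream statistic is scale-invariant, and
keeping the normalized scale keeps $\mu$ consistent with the statistic
that produced the correction. The 3.5 threshold is part of the method's
definition (empirically, chi-squared probability plots of real bin
counts follow the expectation up to about that Z).

# Predictors

All four predictors consume strand-summed counts for the target
chromosome; candidate predictors for the regression method are
strand-level, because several chromosomes show small but consistent
strand imbalances worth exploiting. Chromosomes 13, 18 and 21 are never
used as predictors or denominators, so a trisomy in one target cannot
distort another target's prediction. Calls are one-sided at $z > 3$;
the Shapiro–Wilk p-value of the control statistic is always computed
and a value ≤ 0.05 sets a `non_normal_controls` flag rather than
aborting, so method comparisons can still run.

* **Standard Z**: fraction of all autosomal reads (target included in
  the denominator — it is part of "all autosomes").
* **MAD-based Z**: center = median, scale = $1.4826 \cdot$ MAD (median
  of absolute deviations from the median); $1.4826 = 1/\Phi^{-1}(3/4)$
  makes the scale estimate the SD of a normal distribution. The
  reported CV is the robust analogue scale/median. Note the MAD-z and
  standard z do not coincide on symmetric control sets in general —
  their centers do, their scales differ by $sd/(1.4826\,\mathrm{MAD})$.
* **NCV**: exhaustive search over all denominator subsets of size ≤ 4
  of the 19 candidate autosomes (5,035 combinations), minimizing the
  control CV of the target/denominator ratio. The size-4 cap is a
  pragmatic bound: a full $2^{19}$ search adds nothing and the cap
  keeps training near-instant. Selection on the evaluation controls is
  optimistically biased; train on a separate set where that matters.
* **RBZ**: forward selection (greedy, adjusted $R^2$ criterion) of 4
  predictors per set, 4 sets, candidates = per-chromosome per-strand
  fractions with the all-autosome denominator. Within a set, both
  strands of a chosen chromosome become ineligible; across sets, used
  predictors are removed from the pool, so an aberration in one
  predictor chromosome can corrupt at most one of the four models
  ("independent" sets interpreted as disjoint predictor sets).
  $z = (of/ef - 1)/\mathrm{sd}_j(of_j/ef_j)$; the spread may be
  computed on the training controls (in-sample, slightly optimistic,
  the default behaviour when passing them) or on held-out controls
  (unbiased) — `rbz_zscore()` takes the reference group explicitly.
  After in-sample least squares the mean residual $of - ef$ is exactly
  0; the mean *ratio* $of/ef$ is 1 only up to a curvature term of order
  the squared residual CV, which is why tests assert the residual
  identity rather than the folklore ratio identity. A trisomy is called
  only when all four sets exceed the threshold; partial exceedance sets
  a `conflicting_models` flag, a deliberate false-positive guard.

`estimate_fetal_fraction(z, cv) = 2 z \cdot cv` inverts the
$1 + ff/2$ shift model; it is accurate to the extent the target's own
contribution to the denominator is small (≈1.7% relative damping for
chr21).

# Match QC

Representativeness of the control group for a given sample is scored as
$\sum_k (of_{ks} - of_{kj})^2$ over the 19 autosomes excluding
13/18/21 (excluded from numerator and denominator, so a trisomy cannot
fail QC by itself), averaged over controls. The cutoff is calibrated on
a training set as mean + 3 SD of each training sample's
leave-one-out overall score; leave-one-out because a self-comparison
contributes an exact zero and would bias the calibration downward. The
pass/fail decision is taken on the overall (averaged) score;
per-control scores are reported for diagnostics. A passing score does
not prove the controls are representative; an exceeding score does
indicate the analysis is unreliable.

# The simulator: what it emulates, and what it does not

`simulate_cohort()` generates per-bin expected counts
$$\lambda_{is} = \bar\lambda \cdot g_s(gc_i) \cdot p_i \cdot f_s \cdot
  m_{c(i),s} \cdot (1 + ff/2 \cdot [\text{case, } c(i)=\text{target}]),$$
then draws counts (negative binomial by default) and splits strands
binomially. The defaults are the stated world of the package's tests:

| parameter | default | rationale |
|---|---|---|
| genome | hg19 autosome lengths / 20 (≈2,900 bins of 50 kb) | small enough for fast tests, preserves chromosome-size hierarchy |
| `mean_bin_count` | 4,400 | keeps the *total* autosomal read count at the realistic ~12.5 M despite the scaled genome, so chromosome-level counting noise (~0.2% for chr21) is realistic |
| GC per bin | Beta(mean 0.41, concentration 100), per-chromosome mean offsets SD 0.02 | human-like 50-kb GC spread and between-chromosome GC differences |
| `gc_bias` | linear, slope 1, per-sample slope SD 0.4 | a mild static GC curve plus run-to-run GC-bias variation — the dominant, correctable source of chromosome-level variation in uncorrected data (uncorrected standard-Z CV ≈ 0.5%, in line with real uncorrected cohorts) |
| `peak_bins` | 10 bins at 5× coverage | repeat-like coverage peaks |
| `overdispersed_bins` | 1% of bins, 10× variance | bin-level overdispersion for χ²VR to find |
| noise | negative binomial, 15% extra-Poisson variance | pure Poisson would make χ²VR trivially silent |
| chromosome factors | rank 2, loading SD 0.005 | residual correlated "biological" variation not attributable to GC |
| `sample_factor_sd` | 0.15 (log-normal) | sequencing-depth spread between samples |
| `strand_skew_sd` | 0.005 | small consistent per-chromosome strand imbalance (what makes strand-level predictors informative) |
| `fetal_fraction` | 0.08 | a typical fetal fraction |

Undefined-GC bins (1%) carry no reads, exercising the "ignored bins"
paths. Trisomies are applied at expectation level (not by read
resampling) for exact control of the planted effect size. A fixed seed
reproduces a cohort bit-identically.

What the simulator does **not** emulate: mappability structure and
repeat families (peaks are placed uniformly), fragment-length biology,
batch structure beyond a single GC slope per sample, maternal copy-number
variants, and any sex-chromosome signal. A green test therefore
establishes algorithmic correctness and statistical calibration under
the stated noise model — not clinical performance.

# Numerical and testing choices

* Bins are 0-based half-open `[kB, (k+1)B)`; a read belongs to the bin
  of its 0-based leftmost mapping position. The last bin of a
  chromosome may be short (`ceiling(len/B)` bins).
* MAPQ filtering is off by default (`bwa aln` default output gives
  multi-mappers MAPQ 0; how they were handled upstream is unknowable,
  so it is the caller's choice).
* Counts are stored as reals because corrections rescale bins; raw
  counting yields integers, and TSV serialization round-trips integers
  bit-identically and reals to 1e-9 relative.
* χ²VR calibration tests use a Poisson background: under the default
  homogeneous 15% extra-Poisson noise the chi-squared null is violated
  for *every* bin and a "false flag rate" is not well defined.
* Null-calibration tests use large (1,000-sample) reference groups:
  with realistic 200-sample groups the z-scores carry irreducible
  finite-reference offset/scale noise of several percent, which a KS
  test at 1,000 replicates would detect even for a perfect
  implementation.
* The CV-ordering property (RBZ ≤ NCV ≤ standard Z) is evaluated on
  uncorrected data, where the correlated GC-driven variation that those
  methods are designed to cancel is present; after GC+χ²VR correction
  all methods converge toward the counting-noise floor and the ordering
  ties.
* Where the regression/NCV models are trained and evaluated on the same
  controls (the pipeline default), the resulting CVs are mildly
  optimistic — the known overfitting behaviour of these estimators;
  train/test splitting is available and used in the calibration tests.

# Limitations

Monosomy detection (z < −3) is out of scope, as are microdeletions,
segmental events, fetal-fraction estimation from sex chromosomes or
fragment sizes, and mosaicism. The pipeline assumes the upstream BAM is
sorted, indexed and duplicate-marked. Control groups below ~50 samples
make all CV estimates noisy (the RBZ flags groups under 50).
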