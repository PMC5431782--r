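#' Simulation configuration for synthetic bin-count cohorts
#'
#' Describes a cohort generator that emulates the statistical structure
#' whole-genome NIPT corrections and predictors are designed for: a
#' GC-dependent multiplicative coverage bias, a few extreme-coverage
#' "peak" bins, a subset of bins with between-sample overdispersion,
#' per-sample total-coverage factors, low-rank between-chromosome
#' coverage correlation, per-chromosome strand skew, and trisomy cases
#' whose target-chromosome expectation is scaled by `1 + ff/2`.
#'
#' Defaults state a deliberately realistic world: a genome scaled to
#' 1/20 of hg19 (about 2,900 bins of 50 kb) at a mean bin count keeping
#' the full Illumina-like total of ~12.5 million autosomal reads, mild
#' negative-binomial noise (15% extra-Poisson variance), 1% of bins with
#' 10-fold variance inflation, ten 5x coverage peaks, a linear GC slope
#' whose steepness varies from sample to sample (run-to-run GC bias, the
#' dominant chromosome-level variation in uncorrected NIPT data), and a
#' fetal fraction of 8%.
#'
#' @param seed Mandatory integer seed; cohorts are bit-reproducible.
#' @param n_controls,n_cases Control and case sample counts.
#' @param target_chromosome Trisomic chromosome of the cases.
#' @param fetal_fraction Fetal fraction in `[0, 0.3]` (0.08 = 8%).
#' @param reference_lengths Chromosome lengths (default
#'   [scaled_autosome_lengths()] at scale 20).
#' @param bin_size Bin width in bp.
#' @param mean_bin_count Expected strand-summed reads per bin at the GC
#'   center.
#' @param gc_bias List: `type` one of `"linear"` (multiplier
#'   `1 + slope*(gc - center)`), `"quadratic_dip"`
#'   (`1 - curvature*(gc - center)^2`) or `"none"`; optional `slope_sd`
#'   jitters the slope per sample (run-to-run GC bias variation).
#' @param gc List describing the GC track: Beta-distributed per-bin GC
#'   with `mean`, `concentration`, per-chromosome mean offsets
#'   (`chrom_offset_sd`) and a proportion of undefined (all-N-like) bins
#'   that carry no reads.
#' @param peak_bins List `n`, `magnitude`: bins with `magnitude`-fold
#'   expected coverage.
#' @param overdispersed_bins List `proportion`, `inflation`: bins whose
#'   between-sample count variance is `inflation`-fold the noise model's
#'   baseline variance.
#' @param inter_chromosome_correlation List `rank`, `strength`: per-sample
#'   latent factors with N(0, strength) chromosome loadings, inducing
#'   correlated chromosome-level coverage.
#' @param noise List `type` in `"nb"`, `"poisson"`, `"none"`; for `"nb"`,
#'   `extra_var` is the extra-Poisson variance fraction.
#' @param sample_factor_sd Log-normal SD of per-sample total-coverage
#'   factors.
#' @param strand_skew_sd SD of per-chromosome forward-strand probability
#'   offsets around 0.5.
#' @param case_fraction_shift Optional list `chromosomes`, `magnitude`:
#'   cases get the listed chromosomes' expectation scaled by
#'   `1 + magnitude` (a systematic, non-trisomy mismatch, for Match QC
#'   experiments).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_controls = 200L,
                       n_cases = 10L,
                       target_chromosome = 21L,
                       fetal_fraction = 0.08,
                       reference_lengths = scaled_autosome_lengths(20),
                       bin_size = 50000,
                       mean_bin_count = 4400,
                       gc_bias = list(type = "linear", slope = 1,
                                      slope_sd = 0.4),
                       gc = list(mean = 0.41, concentration = 100,
                                 chrom_offset_sd = 0.02,
                                 undefined_prop = 0.01),
                       peak_bins = list(n = 10L, magnitude = 5),
                       overdispersed_bins = list(proportion = 0.01,
                                                 inflation = 10),
                       inter_chromosome_correlation = list(rank = 2L,
                                                           strength = 0.005),
                       noise = list(type = "nb", extra_var = 0.15),
                       sample_factor_sd = 0.15,
                       strand_skew_sd = 0.005,
                       case_fraction_shift = NULL) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(n_controls >= 3L, n_cases >= 0L,
            fetal_fraction >= 0, fetal_fraction <= 0.3,
            mean_bin_count > 0, bin_size >= 1)
  if (!target_chromosome %in% 1:22)
    stop("target_chromosome must be an autosome")
  noise$type <- match.arg(noise$type, c("nb", "poisson", "none"))
  if (noise$type == "nb" &&
      (is.null(noise$extra_var) || noise$extra_var <= 0))
    stop("nb noise needs extra_var > 0")
  gc_bias$type <- match.arg(gc_bias$type,
                            c("linear", "quadratic_dip", "none"))
  stopifnot(peak_bins$n >= 0, peak_bins$magnitude > 0,
            overdispersed_bins$proportion >= 0,
            overdispersed_bins$proportion < 1,
            overdispersed_bins$inflation >= 1,
            inter_chromosome_correlation$rank >= 0,
            inter_chromosome_correlation$strength >= 0,
            sample_factor_sd >= 0, strand_skew_sd >= 0,
            gc$undefined_prop >= 0, gc$undefined_prop < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed ", x$seed, ": ", x$n_controls, " controls + ",
      x$n_cases, " cases (chr", x$target_chromosome, " trisomy at ff = ",
      x$fetal_fraction, "), noise ", x$noise$type, "\n", sep = "")
  invisible(x)
}

.gc_multiplier <- function(gc_bias, center) {
  switch(gc_bias$type,
         none = function(gc, slope_jitter = 0) rep(1, length(gc)),
         linear = function(gc, slope_jitter = 0)
           pmax(1 + (gc_bias$slope + slope_jitter) * (gc - center), 0.05),
         quadratic_dip = function(gc, slope_jitter = 0) {
           curv <- if (is.null(gc_bias$curvature)) 20 else gc_bias$curvature
           pmax(1 - curv * (gc - center)^2, 0.05)
         })
}

.make_gc_track_impl <- function(config) {
  geom <- bin_geometry(config$reference_lengths, config$bin_size)
  chroms <- as.integer(names(geom$lengths))
  offs <- stats::rnorm(length(chroms), 0, config$gc$chrom_offset_sd)
  names(offs) <- as.character(chroms)
  mean_c <- pmin(pmax(config$gc$mean + offs[as.character(geom$chrom)],
                      0.15), 0.85)
  conc <- config$gc$concentration
  gc <- stats::rbeta(n_bins(geom), mean_c * conc, (1 - mean_c) * conc)
  n_undef <- floor(config$gc$undefined_prop * n_bins(geom))
  undef <- if (n_undef > 0) sample.int(n_bins(geom), n_undef) else integer()
  gc[undef] <- NA_real_
  list(track = gc_track(geom, gc), chrom_offsets = offs,
       undefined_bins = sort(undef))
}

#' Generate a synthetic GC track
#'
#' Per-bin GC fractions drawn from a Beta distribution (default mean
#' 0.41, matching the human-genome-like spread at 50 kb), with
#' per-chromosome mean offsets and a small planted proportion of
#' undefined bins.
#'
#' @param config A [sim_config()].
#' @return A [gc_track()].
#' @export
make_gc_track <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(as.integer(config$seed),
                   .make_gc_track_impl(config))$track
}

#' Simulate a synthetic NIPT cohort
#'
#' Generates control and case samples from the generative model described
#' in [sim_config()]. Per bin i and sample s, the expected count is
#' `mean_bin_count * gc_mult(gc_i) * peak_i * f_s * m_{chrom(i),s}`
#' (times `1 + ff/2` on the cases' target chromosome), counts are drawn
#' from the configured noise model (overdispersed bins get an extra
#' unit-mean Gamma multiplier per sample), and each count is split into
#' forward/reverse strands with a per-chromosome strand probability.
#'
#' @param config A [sim_config()].
#' @return A list with `controls` (a [control_group()]), `cases` (list of
#'   [binned_sample()]), `gc` (the [gc_track()]) and `truth`, a record of
#'   every planted parameter (peak and overdispersed bin indices,
#'   chromosome loadings, strand skews, per-sample factors, GC curve).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(as.integer(config$seed), .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(config) {
  gcgen <- .make_gc_track_impl(config)
  track <- gcgen$track
  geom <- track$geometry
  nb <- n_bins(geom)
  chroms <- as.integer(names(geom$lengths))
  gc_mult <- .gc_multiplier(config$gc_bias, config$gc$mean)

  defined <- track$defined_mask
  base <- rep(0, nb)
  base[defined] <- config$mean_bin_count *
    gc_mult(track$gc_fraction[defined])

  # peaks: extreme-coverage bins (repeat-like)
  peak_idx <- integer()
  if (config$peak_bins$n > 0) {
    peak_idx <- sort(sample(which(defined),
                            min(config$peak_bins$n, sum(defined))))
    base[peak_idx] <- base[peak_idx] * config$peak_bins$magnitude
  }

  # overdispersed bins: extra unit-mean Gamma multiplier per sample whose
  # variance is set so total variance = inflation x the noise baseline
  extra <- if (config$noise$type == "nb") config$noise$extra_var else 0
  od_idx <- integer()
  od_var <- numeric()
  if (config$overdispersed_bins$proportion > 0) {
    pool <- setdiff(which(defined), peak_idx)
    n_od <- floor(config$overdispersed_bins$proportion * nb)
    od_idx <- sort(sample(pool, min(n_od, length(pool))))
    od_var <- (config$overdispersed_bins$inflation - 1) * (1 + extra) /
      base[od_idx]
  }

  # low-rank chromosome coverage factors
  rank <- config$inter_chromosome_correlation$rank
  loadings <- matrix(stats::rnorm(length(chroms) * max(rank, 1L), 0,
                                  config$inter_chromosome_correlation$strength),
                     nrow = length(chroms),
                     dimnames = list(as.character(chroms), NULL))
  if (rank == 0L) loadings[] <- 0

  skew <- pmin(pmax(stats::rnorm(length(chroms), 0, config$strand_skew_sd),
                    -0.05), 0.05)
  names(skew) <- as.character(chroms)
  p_fwd <- 0.5 + skew[as.character(geom$chrom)]

  target_bins <- geom$chrom == config$target_chromosome
  shift_bins <- NULL
  if (!is.null(config$case_fraction_shift))
    shift_bins <- geom$chrom %in%
      as.integer(config$case_fraction_shift$chromosomes)

  n_total <- config$n_controls + config$n_cases
  sample_factors <- if (config$sample_factor_sd > 0)
    exp(stats::rnorm(n_total, 0, config$sample_factor_sd) -
          config$sample_factor_sd^2 / 2) else rep(1, n_total)
  chrom_mult_mat <- matrix(1, length(chroms), n_total,
                           dimnames = list(as.character(chroms), NULL))
  slope_jitters <- if (!is.null(config$gc_bias$slope_sd) &&
                       config$gc_bias$slope_sd > 0)
    stats::rnorm(n_total, 0, config$gc_bias$slope_sd) else rep(0, n_total)

  gen_sample <- function(s, id, is_case) {
    if (max(rank, 0L) > 0L) {
      u <- stats::rnorm(max(rank, 1L))
      m <- pmax(1 + as.numeric(loadings %*% u), 0.2)
    } else m <- rep(1, length(chroms))
    names(m) <- as.character(chroms)
    chrom_mult_mat[, s] <<- m
    lam <- base
    if (slope_jitters[s] != 0) {
      lam <- rep(0, nb)
      lam[defined] <- config$mean_bin_count *
        gc_mult(track$gc_fraction[defined], slope_jitters[s])
      lam[peak_idx] <- lam[peak_idx] * config$peak_bins$magnitude
    }
    lam <- lam * sample_factors[s] * m[as.character(geom$chrom)]
    if (is_case) {
      lam[target_bins] <- lam[target_bins] * (1 + config$fetal_fraction / 2)
      if (!is.null(shift_bins))
        lam[shift_bins] <- lam[shift_bins] *
          (1 + config$case_fraction_shift$magnitude)
    }
    if (length(od_idx))
      lam[od_idx] <- lam[od_idx] *
        stats::rgamma(length(od_idx), shape = 1 / od_var, rate = 1 / od_var)
    pos <- lam > 0
    count <- numeric(nb)
    count[pos] <- switch(config$noise$type,
      nb = stats::rnbinom(sum(pos), mu = lam[pos], size = lam[pos] / extra),
      poisson = stats::rpois(sum(pos), lam[pos]),
      none = round(lam[pos]))
    if (config$noise$type == "none") {
      fwd <- round(count * p_fwd)
    } else {
      fwd <- numeric(nb)
      fwd[pos] <- stats::rbinom(sum(pos), count[pos], p_fwd[pos])
    }
    binned_sample(id, geom, fwd, count - fwd)
  }

  controls <- lapply(seq_len(config$n_controls), function(s)
    gen_sample(s, sprintf("ctrl_%03d", s), FALSE))
  cases <- lapply(seq_len(config$n_cases), function(k)
    gen_sample(config$n_controls + k, sprintf("case_%03d", k), TRUE))

  truth <- list(
    peak_bins = peak_idx,
    overdispersed_bins = od_idx,
    overdispersed_var = od_var,
    chrom_loadings = loadings,
    chrom_multipliers = chrom_mult_mat,
    strand_skew = skew,
    sample_factors = sample_factors,
    gc_slope_jitters = slope_jitters,
    gc_chrom_offsets = gcgen$chrom_offsets,
    undefined_bins = gcgen$undefined_bins,
    fetal_fraction = config$fetal_fraction,
    target_chromosome = config$target_chromosome,
    case_fraction_shift = config$case_fraction_shift)

  list(controls = control_group(controls,
                                description = sprintf("simulated (seed %d)",
                                                      as.integer(config$seed))),
       cases = cases,
       gc = track,
       truth = truth,
       config = config)
}
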