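#' Normalize bin counts against a control group
#'
#' Scales a sample's strand-summed bin counts so its mean bin count
#' equals the control group's grand mean bin count: the normalization
#' factor is (mean bin count over all control bins and samples) / (mean
#' bin count of the sample). Multiplying a sample's counts by any c > 0
#' leaves the result unchanged.
#'
#' @param sample A [binned_sample()].
#' @param controls A [control_group()] or list of samples.
#' @return Numeric vector of per-bin normalized strand-summed counts.
#' @export
normalize_counts <- function(sample, controls) {
  controls <- as_control_group(controls)
  if (!same_geometry(sample$geometry, controls$samples[[1L]]$geometry))
    stop("sample and controls must share bin geometry")
  normalized_bin_counts(sample, grand_mean_bin_count(controls))
}

#' Chi-squared-based variation reduction
#'
#' Down-weights bins whose between-control variation exceeds the
#' chi-squared expectation. Per bin, counts are normalized against the
#' control group, the chi-squared statistic `sum_j (mu - on_j)^2 / mu`
#' is summed over the controls (`mu` = mean normalized count of the bin),
#' and transformed to a Z-score `(sum_chisq - df) / sqrt(2 df)` with
#' `df = n_controls - 1`. Normalized counts in bins with Z above
#' `z_threshold` are divided by `sum_chisq / df` in the controls and in
#' every target sample; other bins are untouched. Correction factors are
#' learned from the controls only, and both strands of a bin are scaled
#' by the same factor, so strand ratios are preserved. Output counts are
#' corrected *normalized* counts; all downstream fraction-based
#' statistics are invariant to that overall scaling.
#'
#' Bins whose mean normalized count is zero cannot be scored and are left
#' uncorrected (recorded in the returned object).
#'
#' @param controls A [control_group()] or list of at least 3 samples.
#' @param targets List of [binned_sample()] objects to correct with the
#'   factors learned from the controls (may be empty).
#' @param z_threshold Z-score above which a bin is corrected (default 3.5).
#' @return A list with `controls` (corrected [control_group()]), `targets`
#'   (corrected list) and `correction`, an object of class
#'   `chi_square_correction` carrying `sum_chisq`, `df`, `z_bin`,
#'   `correction_factor` (1 where uncorrected), `z_threshold`,
#'   `n_corrected` and `zero_mu_bins`.
#' @export
chi_squared_vr <- function(controls, targets = list(), z_threshold = 3.5) {
  controls <- as_control_group(controls)
  if (inherits(targets, "binned_sample")) targets <- list(targets)
  df <- controls$n - 1L
  if (df < 2L) stop("chi-squared variation reduction needs df >= 2 (>= 3 controls)")
  g <- controls$samples[[1L]]$geometry
  for (t in targets)
    if (!same_geometry(g, t$geometry))
      stop("target ", t$sample_id, " does not share the control bin geometry")

  grand <- grand_mean_bin_count(controls)
  on_mat <- vapply(controls$samples,
                   function(s) normalized_bin_counts(s, grand),
                   numeric(n_bins(g)))
  mu <- rowMeans(on_mat)

  zero_mu <- mu <= 0
  sum_chisq <- rep(0, n_bins(g))
  if (any(!zero_mu))
    sum_chisq[!zero_mu] <-
      rowSums((mu[!zero_mu] - on_mat[!zero_mu, , drop = FALSE])^2) /
      mu[!zero_mu]
  z_bin <- (sum_chisq - df) / sqrt(2 * df)
  z_bin[zero_mu] <- NA_real_

  corrected <- !zero_mu & z_bin > z_threshold
  factor <- rep(1, n_bins(g))
  factor[corrected] <- sum_chisq[corrected] / df

  correction <- structure(
    list(sum_chisq = sum_chisq, df = df, z_bin = z_bin,
         correction_factor = factor, z_threshold = z_threshold,
         mu = mu, n_corrected = sum(corrected),
         zero_mu_bins = which(zero_mu)),
    class = "chi_square_correction")

  apply_one <- function(s) {
    # normalized per-strand counts, then divide flagged bins
    f_norm <- grand / mean(bin_totals(s))
    set_counts(s,
               s$counts_fwd * f_norm / factor,
               s$counts_rev * f_norm / factor,
               append_trail = "chi2vr")
  }
  ctrl_corrected <- lapply(controls$samples, apply_one)
  tgt_corrected <- lapply(targets, apply_one)
  list(controls = control_group(ctrl_corrected, controls$description),
       targets = tgt_corrected,
       correction = correction)
}

#' @export
print.chi_square_correction <- function(x, ...) {
  cat("<chi_square_correction> df = ", x$df, "; ", x$n_corrected,
      " bin(s) corrected at Z > ", x$z_threshold,
      if (length(x$zero_mu_bins))
        paste0("; ", length(x$zero_mu_bins), " zero-mean bin(s) skipped"),
      "\n", sep = "")
  invisible(x)
}

#' Peak correction
#'
#' Removes bins of consistently extreme coverage (typically repeat-driven
#' peaks). Within each control sample and chromosome, a bin deviates if
#' its strand-summed count lies outside mean +/- `sd_threshold` standard
#' deviations of that chromosome's bins in that sample. Bins deviating in
#' at least `consistency` of the controls are flagged and zeroed on both
#' strands in the controls and in every target sample.
#'
#' @param controls A [control_group()] or list of at least 3 samples.
#' @param targets List of samples to which the flagged-bin removal is
#'   also applied.
#' @param sd_threshold SD multiple defining deviation (default 1.96).
#' @param consistency Fraction of controls that must deviate (default 0.95).
#' @return A list with `controls`, `targets` and `mask`, an object of
#'   class `peak_mask` (`flagged` logical per bin, plus the thresholds).
#' @export
peak_correct <- function(controls, targets = list(),
                         sd_threshold = 1.96, consistency = 0.95) {
  controls <- as_control_group(controls)
  if (inherits(targets, "binned_sample")) targets <- list(targets)
  g <- controls$samples[[1L]]$geometry
  for (t in targets)
    if (!same_geometry(g, t$geometry))
      stop("target ", t$sample_id, " does not share the control bin geometry")
  chrom <- g$chrom
  for (cn in unique(chrom))
    if (sum(chrom == cn) < 2L)
      stop("chromosome ", cn, " has fewer than 2 bins; cannot peak-correct")

  deviates <- vapply(controls$samples, function(s) {
    tot <- bin_totals(s)
    m <- stats::ave(tot, chrom, FUN = mean)
    sd_ <- stats::ave(tot, chrom, FUN = stats::sd)
    abs(tot - m) > sd_threshold * sd_
  }, logical(n_bins(g)))
  flagged <- rowMeans(deviates) >= consistency

  mask <- structure(list(flagged = flagged, sd_threshold = sd_threshold,
                         consistency = consistency,
                         n_flagged = sum(flagged)),
                    class = "peak_mask")
  zero_bins <- function(s) {
    fwd <- s$counts_fwd; rev <- s$counts_rev
    fwd[flagged] <- 0; rev[flagged] <- 0
    set_counts(s, fwd, rev, append_trail = "peak")
  }
  list(controls = control_group(lapply(controls$samples, zero_bins),
                                controls$description),
       targets = lapply(targets, zero_bins),
       mask = mask)
}

#' @export
print.peak_mask <- function(x, ...) {
  cat("<peak_mask> ", x$n_flagged, " bin(s) flagged (|dev| > ",
      x$sd_threshold, " SD in >= ", 100 * x$consistency,
      "% of controls)\n", sep = "")
  invisible(x)
}

# Shared GC eligibility: bins with reads, defined GC, on both strands
gc_eligible <- function(sample, gc) {
  if (!same_geometry(sample$geometry, gc$geometry))
    stop("sample and GC track must share bin geometry")
  bin_totals(sample) > 0 & gc$defined_mask
}

#' Weighted-bin GC correction
#'
#' Corrects GC bias using the average coverage of bins with similar GC
#' content: bins are grouped into GC intervals of `interval_width`
#' (default 0.1 GC percentage points, i.e. 0.001 in fraction units), each
#' interval's weight is its mean strand-summed coverage divided by the
#' mean coverage of all eligible bins, and each bin's counts (both
#' strands) are divided by its interval's weight. Bins with no reads or
#' undefined GC are ignored: excluded from weight estimation and left
#' unchanged. Weights are computed per sample.
#'
#' @param sample A [binned_sample()].
#' @param gc A [gc_track()] on the same geometry.
#' @param interval_width GC-fraction interval width (default 0.001 =
#'   0.1 GC%).
#' @return The corrected [binned_sample()]; attribute `"gc_weights"`
#'   carries the per-interval weights, attribute `"skipped_bins"` any
#'   eligible bins left unchanged because their interval weight was 0.
#' @export
gc_correct_bin <- function(sample, gc, interval_width = 0.001) {
  eligible <- gc_eligible(sample, gc)
  if (!any(eligible))
    stop("no bins with reads and defined GC; cannot GC-correct")
  tot <- bin_totals(sample)
  interval <- floor(gc$gc_fraction / interval_width + 1e-9)
  global_mean <- mean(tot[eligible])
  w_tab <- c(tapply(tot[eligible], interval[eligible], mean)) / global_mean

  w <- rep(1, length(tot))
  key <- as.character(interval[eligible])
  w[eligible] <- w_tab[key]
  skipped <- which(eligible & (!is.finite(w) | w <= 0))
  w[skipped] <- 1
  out <- set_counts(sample, sample$counts_fwd / w, sample$counts_rev / w,
                    append_trail = "gc_bin")
  attr(out, "gc_weights") <- w_tab
  attr(out, "skipped_bins") <- skipped
  out
}

#' LOESS GC correction
#'
#' Fits a locally weighted polynomial regression (tricube weights,
#' default span 0.75, local degree 2 — R's `stats::loess` defaults) of
#' strand-summed bin count on GC fraction over eligible bins (reads > 0,
#' GC defined), then rescales each eligible bin by (global mean eligible
#' count) / (fitted count at the bin's GC), applied proportionally to
#' both strands. Bins whose fitted value is not positive are left
#' unchanged and recorded. Ineligible bins are untouched.
#'
#' @param sample A [binned_sample()].
#' @param gc A [gc_track()] on the same geometry.
#' @param span LOESS span (default 0.75).
#' @param degree Local polynomial degree (default 2).
#' @param min_bins Minimum number of eligible bins (default 50).
#' @return The corrected [binned_sample()]; attribute `"skipped_bins"`
#'   lists eligible bins left unchanged (non-positive fit).
#' @export
gc_correct_loess <- function(sample, gc, span = 0.75, degree = 2,
                             min_bins = 50) {
  eligible <- gc_eligible(sample, gc)
  if (sum(eligible) < min_bins)
    stop("only ", sum(eligible), " eligible bins (< ", min_bins,
         "); cannot fit LOESS GC correction")
  tot <- bin_totals(sample)
  d <- data.frame(count = tot[eligible], gc = gc$gc_fraction[eligible])
  fit <- stats::loess(count ~ gc, data = d, span = span, degree = degree,
                      family = "gaussian")
  fitted_vals <- stats::predict(fit, newdata = d)
  ratio <- rep(1, length(tot))
  ok <- is.finite(fitted_vals) & fitted_vals > 0
  ratio[which(eligible)[ok]] <- mean(d$count) / fitted_vals[ok]
  skipped <- which(eligible)[!ok]
  out <- set_counts(sample, sample$counts_fwd * ratio,
                    sample$counts_rev * ratio,
                    append_trail = "gc_loess")
  attr(out, "skipped_bins") <- skipped
  out
}

#' Apply an ordered set of corrections to controls and targets
#'
#' Convenience wrapper running any subset of the corrections in the
#' canonical order peak -> GC -> chi-squared, regardless of the order
#' given. At most one GC method may be requested.
#'
#' @param controls A [control_group()] or list of samples.
#' @param targets List of samples corrected alongside the controls.
#' @param corrections Character subset of
#'   `c("peak", "gc_bin", "gc_loess", "chi2vr")`.
#' @param gc A [gc_track()], required when a GC method is requested.
#' @param z_threshold,sd_threshold,consistency,span,degree,gc_interval_width
#'   Tuning parameters forwarded to the individual corrections.
#' @return List with `controls`, `targets` and `log` (per-correction
#'   diagnostic objects).
#' @export
apply_corrections <- function(controls, targets = list(),
                              corrections = character(), gc = NULL,
                              z_threshold = 3.5, sd_threshold = 1.96,
                              consistency = 0.95, span = 0.75, degree = 2,
                              gc_interval_width = 0.001) {
  controls <- as_control_group(controls)
  if (inherits(targets, "binned_sample")) targets <- list(targets)
  known <- c("peak", "gc_bin", "gc_loess", "chi2vr")
  bad <- setdiff(corrections, known)
  if (length(bad))
    stop("unknown correction(s): ", paste(bad, collapse = ", "))
  if (all(c("gc_bin", "gc_loess") %in% corrections))
    stop("at most one GC-correction method may be used")
  corrections <- known[known %in% corrections]  # canonical order
  log <- list()
  if ("peak" %in% corrections) {
    res <- peak_correct(controls, targets, sd_threshold, consistency)
    controls <- res$controls; targets <- res$targets
    log$peak <- res$mask
  }
  gc_method <- intersect(c("gc_bin", "gc_loess"), corrections)
  if (length(gc_method)) {
    if (is.null(gc))
      stop("GC correction requested but no gc track supplied")
    fn <- if (gc_method == "gc_bin") {
      function(s) gc_correct_bin(s, gc, interval_width = gc_interval_width)
    } else {
      function(s) gc_correct_loess(s, gc, span = span, degree = degree)
    }
    controls <- control_group(lapply(controls$samples, fn),
                              controls$description)
    targets <- lapply(targets, fn)
    log[[gc_method]] <- "per-sample GC weights; see sample attributes"
  }
  if ("chi2vr" %in% corrections) {
    res <- chi_squared_vr(controls, targets, z_threshold = z_threshold)
    controls <- res$controls; targets <- res$targets
    log$chi2vr <- res$correction
  }
  list(controls = controls, targets = targets, log = log)
}
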