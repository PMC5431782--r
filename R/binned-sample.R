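#' Construct a binned sample
#'
#' The central data container: per-bin forward- and reverse-strand read
#' counts for one sample over a fixed autosomal bin geometry. Raw
#' counting yields integers; corrections rescale bins, so counts are
#' stored as non-negative reals. The `correction_trail` records, in
#' order, every correction applied (`"peak"`, `"gc_bin"`, `"gc_loess"`,
#' `"chi2vr"`).
#'
#' @param sample_id Sample identifier (scalar character).
#' @param geometry A [bin_geometry()].
#' @param counts_fwd,counts_rev Numeric vectors of per-bin counts, one
#'   entry per bin of `geometry`, both the same length, all values >= 0.
#' @param correction_trail Character vector of applied corrections
#'   (default none).
#' @return An object of class `binned_sample`.
#' @export
binned_sample <- function(sample_id, geometry, counts_fwd, counts_rev,
                          correction_trail = character()) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (!inherits(geometry, "bin_geometry"))
    stop("geometry must be a bin_geometry")
  counts_fwd <- as.numeric(counts_fwd)
  counts_rev <- as.numeric(counts_rev)
  nb <- n_bins(geometry)
  if (length(counts_fwd) != nb || length(counts_rev) != nb)
    stop("counts_fwd and counts_rev must each have one entry per bin (",
         nb, ")")
  if (anyNA(counts_fwd) || anyNA(counts_rev) ||
      any(counts_fwd < 0) || any(counts_rev < 0))
    stop("counts must be non-negative and non-missing")
  structure(
    list(sample_id = sample_id,
         geometry = geometry,
         counts_fwd = counts_fwd,
         counts_rev = counts_rev,
         correction_trail = as.character(correction_trail)),
    class = "binned_sample")
}

#' @export
print.binned_sample <- function(x, ...) {
  cat("<binned_sample> ", x$sample_id, ": ",
      format(round(total_reads(x)), big.mark = ","), " reads in ",
      n_bins(x$geometry), " bins",
      if (length(x$correction_trail))
        paste0(" [", paste(x$correction_trail, collapse = " -> "), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Strand-summed per-bin counts
#'
#' @param sample A [binned_sample()].
#' @return Numeric vector of forward + reverse counts per bin.
#' @export
bin_totals <- function(sample) sample$counts_fwd + sample$counts_rev

#' Total autosomal read count of a sample
#'
#' @param sample A [binned_sample()].
#' @return Scalar numeric.
#' @export
total_reads <- function(sample) sum(sample$counts_fwd) + sum(sample$counts_rev)

# Replace both strand count vectors, preserving class/geometry/trail.
set_counts <- function(sample, fwd, rev, append_trail = NULL) {
  sample$counts_fwd <- fwd
  sample$counts_rev <- rev
  if (!is.null(append_trail))
    sample$correction_trail <- c(sample$correction_trail, append_trail)
  sample
}

# Per-chromosome strand counts: 2-column matrix (fwd, rev), rows named by
# the autosomes present in the geometry.
chrom_counts <- function(sample) {
  m <- rowsum(cbind(fwd = sample$counts_fwd, rev = sample$counts_rev),
              group = sample$geometry$chrom, reorder = TRUE)
  rownames(m) <- as.character(sort(unique(sample$geometry$chrom)))
  m
}

# Batched per-chromosome counts over a list of samples:
# list(fwd = chrom x sample matrix, rev = ..., tot = ...).
chrom_count_matrix <- function(samples) {
  stopifnot(length(samples) > 0L)
  g <- samples[[1L]]$geometry
  fwd <- vapply(samples, function(s) {
    rowsum(s$counts_fwd, g$chrom, reorder = TRUE)[, 1L]
  }, numeric(length(unique(g$chrom))))
  rev <- vapply(samples, function(s) {
    rowsum(s$counts_rev, g$chrom, reorder = TRUE)[, 1L]
  }, numeric(length(unique(g$chrom))))
  rn <- as.character(sort(unique(g$chrom)))
  rownames(fwd) <- rn
  rownames(rev) <- rn
  colnames(fwd) <- colnames(rev) <- vapply(samples, `[[`, "", "sample_id")
  list(fwd = fwd, rev = rev, tot = fwd + rev)
}

#' Construct a control group
#'
#' An ordered collection of non-trisomy reference samples sharing bin
#' geometry and correction history, together with the per-bin mean of
#' their normalized counts (the expected normalized count used by the
#' chi-squared variation reduction).
#'
#' @param samples List of [binned_sample()] objects (at least 3), all with
#'   identical geometry and `correction_trail`.
#' @param description Free-text description of the group.
#' @return An object of class `control_group` with elements `samples`,
#'   `n`, `mu` (per-bin mean normalized strand-summed count),
#'   `description` and `correction_trail`.
#' @export
control_group <- function(samples, description = "") {
  if (inherits(samples, "binned_sample")) samples <- list(samples)
  stopifnot(is.list(samples))
  if (length(samples) < 3L)
    stop("a control group needs at least 3 samples")
  ok <- vapply(samples, inherits, TRUE, what = "binned_sample")
  if (!all(ok)) stop("samples must all be binned_sample objects")
  g <- samples[[1L]]$geometry
  trail <- samples[[1L]]$correction_trail
  for (s in samples[-1L]) {
    if (!same_geometry(g, s$geometry))
      stop("all control samples must share bin geometry")
    if (!identical(trail, s$correction_trail))
      stop("all control samples must share the same correction_trail")
  }
  grp <- structure(
    list(samples = samples,
         n = length(samples),
         mu = NULL,
         description = description,
         correction_trail = trail),
    class = "control_group")
  grp$mu <- rowMeans(vapply(samples, function(s)
    normalized_bin_counts(s, grand_mean_bin_count(samples)),
    numeric(n_bins(g))))
  grp
}

#' @export
print.control_group <- function(x, ...) {
  cat("<control_group> ", x$n, " samples, ",
      n_bins(x$samples[[1L]]$geometry), " bins",
      if (length(x$correction_trail))
        paste0(" [", paste(x$correction_trail, collapse = " -> "), "]"),
      if (nzchar(x$description)) paste0(" - ", x$description),
      "\n", sep = "")
  invisible(x)
}

as_control_group <- function(x, description = "") {
  if (inherits(x, "control_group")) x else control_group(x, description)
}

# Mean bin count over all bins and all control samples (the numerator of
# the Eq.-1 normalization factor).
grand_mean_bin_count <- function(samples) {
  if (inherits(samples, "control_group")) samples <- samples$samples
  mean(vapply(samples, function(s) mean(bin_totals(s)), 0))
}

# Strand-summed counts scaled so the sample's mean bin count equals
# `grand_mean`.
normalized_bin_counts <- function(sample, grand_mean) {
  tot <- bin_totals(sample)
  m <- mean(tot)
  if (m <= 0) stop("sample ", sample$sample_id, " has zero total read count")
  tot * (grand_mean / m)
}
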