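MATCHQC_EXCLUDED <- c(13L, 18L, 21L)

# chromosomal fraction vectors with 13/18/21 excluded from numerator set
# and denominator; rows = chromosomes, cols = samples
.matchqc_fractions <- function(samples) {
  cm <- chrom_count_matrix(samples)$tot
  keep <- !(as.integer(rownames(cm)) %in% MATCHQC_EXCLUDED)
  if (!any(keep)) stop("no non-target autosomes in geometry")
  cm <- cm[keep, , drop = FALSE]
  den <- colSums(cm)
  if (any(den <= 0)) stop("zero autosomal read count (excluding 13/18/21)")
  sweep(cm, 2L, den, "/")
}

#' Match QC score between two samples
#'
#' Sum of squared differences of the chromosomal fractions between a
#' sample and one control over the autosomes excluding chromosomes 13,
#' 18 and 21 (which are also excluded from the fraction denominator so a
#' trisomy cannot distort the score). Zero iff the two fraction patterns
#' are identical; symmetric in its arguments. Apply the same variation
#' reduction to both samples first.
#'
#' @param sample,control [binned_sample()] objects on the same geometry
#'   with the same correction trail.
#' @return Scalar score >= 0.
#' @export
match_qc_score <- function(sample, control) {
  if (!same_geometry(sample$geometry, control$geometry))
    stop("samples must share bin geometry")
  if (!identical(sample$correction_trail, control$correction_trail))
    stop("samples must share the same correction_trail")
  f <- .matchqc_fractions(list(sample, control))
  sum((f[, 1L] - f[, 2L])^2)
}

#' Overall Match QC score against a control group
#'
#' Mean of the per-control Match QC scores. The sample passes when the
#' overall score does not exceed the cutoff (mean + 3 SD of the training
#' controls' own leave-one-out scores, see [calibrate_cutoff()]): a
#' score above the cutoff indicates the control group is not
#' representative of the sample and any trisomy prediction against it is
#' unreliable.
#'
#' @param sample A [binned_sample()].
#' @param controls A [control_group()] or list of samples.
#' @param cutoff Calibrated cutoff; `NA` (default) leaves `passed` NA.
#' @return An object of class `match_qc_report`: `per_control_score`,
#'   `overall_score`, `cutoff`, `passed`, `excluded_chromosomes`,
#'   `correction_trail`.
#' @export
match_qc_overall <- function(sample, controls, cutoff = NA_real_) {
  controls <- as_control_group(controls)
  if (!identical(sample$correction_trail, controls$correction_trail))
    stop("sample and controls must share the same correction_trail")
  f <- .matchqc_fractions(c(list(sample), controls$samples))
  d <- f[, -1L, drop = FALSE] - f[, 1L]
  per <- stats::setNames(colSums(d^2),
                         vapply(controls$samples, `[[`, "", "sample_id"))
  structure(
    list(sample_id = sample$sample_id,
         per_control_score = per,
         overall_score = mean(per),
         cutoff = cutoff,
         passed = if (is.na(cutoff)) NA else mean(per) <= cutoff,
         excluded_chromosomes = MATCHQC_EXCLUDED,
         correction_trail = sample$correction_trail),
    class = "match_qc_report")
}

#' @export
print.match_qc_report <- function(x, ...) {
  cat("<match_qc_report> ", x$sample_id, ": overall ",
      signif(x$overall_score, 4),
      if (!is.na(x$cutoff))
        paste0(" vs cutoff ", signif(x$cutoff, 4), " -> ",
               if (isTRUE(x$passed)) "PASS" else "FAIL"),
      "\n", sep = "")
  invisible(x)
}

#' Calibrate the Match QC cutoff from a training control group
#'
#' Each training sample is scored (overall Match QC) against the
#' remaining training samples (leave-one-out, so the zero self-score
#' never biases the mean down); the cutoff is the mean of those scores
#' plus three times their SD. About 99.7% of samples drawn from the
#' training distribution then fall below it.
#'
#' @param training A [control_group()] or list of samples.
#' @return Scalar cutoff; attribute `"training_scores"` carries the
#'   per-sample leave-one-out overall scores.
#' @export
calibrate_cutoff <- function(training) {
  training <- as_control_group(training)
  f <- .matchqc_fractions(training$samples)
  n <- ncol(f)
  scores <- vapply(seq_len(n), function(j) {
    d <- f[, -j, drop = FALSE] - f[, j]
    mean(colSums(d^2))
  }, 0)
  cutoff <- mean(scores) + 3 * stats::sd(scores)
  attr(cutoff, "training_scores") <- stats::setNames(
    scores, vapply(training$samples, `[[`, "", "sample_id"))
  cutoff
}

#' Control-group coefficient of variation and normality
#'
#' CV (SD/mean, sample SD) of the control samples' target-chromosome
#' fraction, plus the Shapiro-Wilk p-value of those fractions. The
#' control group should only be used for Z-score prediction when the
#' fractions are normally distributed (p > 0.05).
#'
#' @param controls A [control_group()] or list of samples.
#' @param target Target chromosome.
#' @param denominator Denominator chromosome set (default all autosomes).
#' @return List with `cv` and `shapiro_p`.
#' @export
control_cv <- function(controls, target, denominator = NULL) {
  controls <- as_control_group(controls)
  of <- .fractions(controls$samples, target, denominator)
  list(cv = stats::sd(of) / mean(of), shapiro_p = .shapiro_p(of))
}
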