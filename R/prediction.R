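AUTOSOMES <- 1:22
TRISOMY_TARGETS <- c(13L, 18L, 21L)

#' Observed chromosomal fraction
#'
#' Fraction of strand-summed reads on the target chromosome relative to
#' the reads on a denominator chromosome set. For the standard Z-score
#' the denominator is all autosomes (target included); NCV uses a
#' selected subset; Match QC and the regression predictors exclude
#' chromosomes 13, 18 and 21.
#'
#' @param sample A [binned_sample()].
#' @param target Target chromosome (1-22).
#' @param denominator Integer vector of denominator chromosomes; default
#'   all autosomes present in the sample's geometry.
#' @return Scalar fraction.
#' @export
chromosomal_fraction <- function(sample, target, denominator = NULL) {
  cc <- chrom_counts(sample)
  tot <- cc[, "fwd"] + cc[, "rev"]
  target <- as.integer(target)
  if (!as.character(target) %in% names(tot))
    stop("target chromosome ", target, " not in sample geometry")
  if (is.null(denominator)) denominator <- as.integer(names(tot))
  denominator <- as.character(as.integer(denominator))
  if (!length(denominator) || !all(denominator %in% names(tot)))
    stop("invalid denominator chromosome set")
  den <- sum(tot[denominator])
  if (den <= 0) stop("denominator read count is zero")
  unname(tot[as.character(target)] / den)
}

# --- internal fraction machinery over sample lists ---------------------

# target/denominator fractions for a list of samples, via one batched
# per-chromosome count matrix
.fractions <- function(samples, target, denominator = NULL) {
  single <- inherits(samples, "binned_sample")
  if (single) samples <- list(samples)
  cm <- chrom_count_matrix(samples)$tot
  if (is.null(denominator)) denominator <- as.integer(rownames(cm))
  dkey <- as.character(as.integer(denominator))
  if (!all(dkey %in% rownames(cm))) stop("invalid denominator chromosome set")
  den <- colSums(cm[dkey, , drop = FALSE])
  if (any(den <= 0)) stop("denominator read count is zero")
  cm[as.character(as.integer(target)), ] / den
}

.shapiro_p <- function(x) {
  if (length(x) < 3L || length(x) > 5000L || stats::sd(x) == 0)
    return(NA_real_)
  stats::shapiro.test(x)$p.value
}

.trisomy_result <- function(method, target, sample_id, z, control_cv,
                            shapiro_p, correction_trail,
                            z_call = 3, extra_flags = character()) {
  flags <- extra_flags
  if (!is.na(shapiro_p) && shapiro_p <= 0.05)
    flags <- c(flags, "non_normal_controls")
  structure(
    list(method = method, target = as.integer(target),
         sample_id = sample_id, z = z, control_cv = control_cv,
         shapiro_p = shapiro_p, call = all(z > z_call),
         flags = flags, correction_trail = correction_trail),
    class = "trisomy_result")
}

#' @export
print.trisomy_result <- function(x, ...) {
  cat("<trisomy_result> ", x$sample_id, " chr", x$target, " [", x$method,
      "]: z = ", paste(round(x$z, 2), collapse = "/"),
      ", control CV = ", signif(x$control_cv, 3),
      ", call = ", x$call,
      if (length(x$flags)) paste0(" (", paste(x$flags, collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

# Common driver for the fraction-based Z-scores. `center_scale` maps the
# control fractions to list(center, scale, cv, extra_flags).
.fraction_zscore <- function(samples, controls, target, denominator,
                             method, center_scale, z_call = 3) {
  controls <- as_control_group(controls)
  single <- inherits(samples, "binned_sample")
  if (single) samples <- list(samples)
  for (s in samples) {
    if (!same_geometry(s$geometry, controls$samples[[1L]]$geometry))
      stop("sample ", s$sample_id, " does not share the control bin geometry")
    if (!identical(s$correction_trail, controls$correction_trail))
      stop("sample ", s$sample_id,
           " has a different correction_trail than the controls")
  }
  of_ctrl <- .fractions(controls$samples, target, denominator)
  cs <- center_scale(of_ctrl)
  if (cs$scale <= 0)
    stop(method, ": control fraction spread is zero; cannot compute Z")
  sp <- .shapiro_p(of_ctrl)
  of_s <- .fractions(samples, target, denominator)
  res <- lapply(seq_along(samples), function(i)
    .trisomy_result(method, target, samples[[i]]$sample_id,
                    z = (of_s[[i]] - cs$center) / cs$scale,
                    control_cv = cs$cv, shapiro_p = sp,
                    correction_trail = samples[[i]]$correction_trail,
                    z_call = z_call, extra_flags = cs$extra_flags))
  if (single) res[[1L]] else res
}

#' Standard Z-score trisomy prediction
#'
#' `z = (of_s - mean(of_controls)) / sd(of_controls)` where `of` is the
#' target chromosome's fraction of all autosomal reads (sample SD, n-1).
#' The control-fraction normality gate (Shapiro-Wilk, p > 0.05) is
#' evaluated and reported; failure sets the `non_normal_controls` flag
#' but does not abort. A trisomy is called (one-sided) at `z > z_call`.
#'
#' @param samples A [binned_sample()] or list of them.
#' @param controls A [control_group()] or list of >= 3 samples.
#' @param target Target chromosome (typically 13, 18 or 21).
#' @param z_call Call threshold (default 3, the 99.7% confidence level).
#' @return A `trisomy_result` (or list of them): `z`, `control_cv`
#'   (SD/mean of control fractions), `shapiro_p`, `call`, `flags`.
#' @export
standard_zscore <- function(samples, controls, target, z_call = 3) {
  .fraction_zscore(samples, controls, target, denominator = NULL,
                   method = "zscore", z_call = z_call,
                   center_scale = function(of) {
                     m <- mean(of); s <- stats::sd(of)
                     list(center = m, scale = s, cv = s / m,
                          extra_flags = character())
                   })
}

#' MAD-based Z-score trisomy prediction
#'
#' As [standard_zscore()] but robust to control outliers: the center is
#' the median of the control fractions and the scale is 1.4826 times the
#' median absolute deviation (median of |of_j - median(of)|), the
#' consistency factor that makes the MAD estimate the SD of a normal
#' distribution.
#'
#' @inheritParams standard_zscore
#' @return A `trisomy_result`; `control_cv` is the robust analogue
#'   scale/median.
#' @export
mad_zscore <- function(samples, controls, target, z_call = 3) {
  .fraction_zscore(samples, controls, target, denominator = NULL,
                   method = "mad_z", z_call = z_call,
                   center_scale = function(of) {
                     med <- stats::median(of)
                     scale <- 1.4826 * stats::median(abs(of - med))
                     if (scale <= 0)
                       stop("MAD of control fractions is zero")
                     list(center = med, scale = scale, cv = scale / med,
                          extra_flags = character())
                   })
}

#' Select an NCV denominator chromosome set
#'
#' Exhaustively searches all non-empty subsets (up to
#' `max_denominator_size` chromosomes) of the autosomes excluding 13, 18,
#' 21 and the target, and returns the subset minimizing the control-group
#' coefficient of variation of target / subset-total read-count ratio.
#' Run this on a training set; selection on the evaluation controls is
#' optimistically biased.
#'
#' @param controls A [control_group()] or list of samples (the training
#'   set).
#' @param target Target chromosome.
#' @param max_denominator_size Largest subset searched (default 4).
#' @return An object of class `ncv_model`: `target`, `denominator`
#'   (integer vector), `cv_train`, `n_candidates`, `correction_trail`.
#' @export
ncv_train <- function(controls, target, max_denominator_size = 4) {
  controls <- as_control_group(controls)
  cm <- chrom_count_matrix(controls$samples)$tot
  target <- as.integer(target)
  cand <- setdiff(as.integer(rownames(cm)), c(TRISOMY_TARGETS, target))
  if (!length(cand)) stop("no candidate denominator chromosomes")
  tvec <- cm[as.character(target), ]
  best <- list(cv = Inf, denominator = integer())
  n_candidates <- 0L
  for (k in seq_len(min(max_denominator_size, length(cand)))) {
    subs <- utils::combn(cand, k)
    for (j in seq_len(ncol(subs))) {
      den <- colSums(cm[as.character(subs[, j]), , drop = FALSE])
      ratio <- tvec / den
      cv <- stats::sd(ratio) / mean(ratio)
      n_candidates <- n_candidates + 1L
      if (cv < best$cv) best <- list(cv = cv, denominator = subs[, j])
    }
  }
  structure(list(target = target, denominator = best$denominator,
                 cv_train = best$cv, n_candidates = n_candidates,
                 correction_trail = controls$correction_trail),
            class = "ncv_model")
}

#' @export
print.ncv_model <- function(x, ...) {
  cat("<ncv_model> chr", x$target, " / {",
      paste(x$denominator, collapse = ","), "}: training CV ",
      signif(x$cv_train, 3), " (best of ", x$n_candidates,
      " candidates)\n", sep = "")
  invisible(x)
}

#' Normalized chromosome value (NCV) Z-score
#'
#' [standard_zscore()] computed on the ratio of the target chromosome's
#' reads to the reads of a selected denominator chromosome set (see
#' [ncv_train()]).
#'
#' @inheritParams standard_zscore
#' @param denominator An `ncv_model` from [ncv_train()] or an integer
#'   vector of denominator chromosomes.
#' @return A `trisomy_result`.
#' @export
ncv_zscore <- function(samples, controls, target, denominator, z_call = 3) {
  if (inherits(denominator, "ncv_model")) {
    if (denominator$target != as.integer(target))
      stop("ncv_model was trained for chromosome ", denominator$target)
    denominator <- denominator$denominator
  }
  .fraction_zscore(samples, controls, target, denominator = denominator,
                   method = "ncv", z_call = z_call,
                   center_scale = function(of) {
                     m <- mean(of); s <- stats::sd(of)
                     list(center = m, scale = s, cv = s / m,
                          extra_flags = character())
                   })
}

# --- regression-based Z-score ------------------------------------------

# strand-level predictor fractions: chrom k strand fwd/rev counts over
# the total (both-strand) autosomal count; chromosomes 13/18/21 excluded
.rbz_predictor_matrix <- function(samples) {
  cm <- chrom_count_matrix(samples)
  total <- colSums(cm$tot)
  chroms <- setdiff(as.integer(rownames(cm$tot)), TRISOMY_TARGETS)
  cols <- list()
  for (k in chroms) {
    cols[[paste0("chr", k, "_fwd")]] <- cm$fwd[as.character(k), ] / total
    cols[[paste0("chr", k, "_rev")]] <- cm$rev[as.character(k), ] / total
  }
  X <- do.call(cbind, cols)
  rownames(X) <- colnames(cm$tot)
  X
}

.adj_r2 <- function(y, X) {
  fit <- stats::lm.fit(cbind(1, X), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y); p <- ncol(X)
  1 - (1 - (1 - rss / tss)) * (n - 1) / (n - p - 1)
}

#' Train regression-based Z-score predictor sets
#'
#' Builds four disjoint predictor sets of four strand-level chromosome
#' fractions each, by stepwise forward selection maximizing the adjusted
#' R-squared of a linear model for the target chromosome's autosomal
#' fraction. Forward and reverse strand fractions are separate candidate
#' predictors (several chromosomes show small but consistent strand
#' imbalances); the target fraction itself uses both strands combined.
#' Chromosomes 13, 18 and 21 are never predictors; within a set at most
#' one predictor per chromosome is allowed; predictors used by one set
#' are removed from the candidate pool of later sets, so an aberration in
#' a predictor chromosome can corrupt at most one of the four models.
#'
#' @param controls A [control_group()] or list of at least 10 samples
#'   (a `small_control_group` flag is set below 50).
#' @param target Target chromosome (13, 18 or 21).
#' @param n_sets,set_size Number of predictor sets and predictors per set
#'   (defaults 4 and 4).
#' @return An object of class `rbz_model_set`; each of the `sets` holds
#'   the predictor names, coefficients, adjusted R-squared and the
#'   in-sample control spread of observed/expected fraction ratios.
#' @export
rbz_train <- function(controls, target, n_sets = 4, set_size = 4) {
  controls <- as_control_group(controls)
  if (controls$n < 10L)
    stop("regression-based Z-score needs at least 10 controls")
  flags <- if (controls$n < 50L) "small_control_group" else character()
  of <- .fractions(controls$samples, target)   # all-autosome denominator
  X <- .rbz_predictor_matrix(controls$samples)
  pool <- colnames(X)
  pred_chrom <- function(nm) as.integer(sub("^chr(\\d+)_.*$", "\\1", nm))

  sets <- vector("list", n_sets)
  for (si in seq_len(n_sets)) {
    selected <- character()
    for (step in seq_len(set_size)) {
      cand <- setdiff(pool, selected)
      cand <- cand[!(pred_chrom(cand) %in% pred_chrom(selected))]
      if (!length(cand))
        stop("candidate predictor pool exhausted before ", n_sets,
             " sets of ", set_size, " predictors")
      scores <- vapply(cand, function(nm)
        .adj_r2(of, X[, c(selected, nm), drop = FALSE]), 0)
      selected <- c(selected, cand[[which.max(scores)]])
    }
    Xs <- X[, selected, drop = FALSE]
    fit <- stats::lm(of ~ ., data = as.data.frame(Xs))
    ef <- unname(stats::fitted(fit))
    ratio <- of / ef
    sets[[si]] <- list(
      predictors = selected,
      chromosomes = pred_chrom(selected),
      intercept = unname(stats::coef(fit)[1L]),
      coefficients = stats::setNames(unname(stats::coef(fit)[-1L]), selected),
      adj_r2 = summary(fit)$adj.r.squared,
      ratio_mean = mean(ratio),
      residual_ratio_sd = stats::sd(ratio))
    pool <- setdiff(pool, selected)
  }
  structure(list(target = as.integer(target), sets = sets,
                 n_controls = controls$n,
                 correction_trail = controls$correction_trail,
                 trained_on = controls$description, flags = flags),
            class = "rbz_model_set")
}

#' @export
print.rbz_model_set <- function(x, ...) {
  cat("<rbz_model_set> chr", x$target, ", ", length(x$sets),
      " predictor sets (", x$n_controls, " controls)\n", sep = "")
  for (i in seq_along(x$sets)) {
    s <- x$sets[[i]]
    cat("  set ", i, ": ", paste(s$predictors, collapse = " + "),
        "  adjR2 = ", round(s$adj_r2, 4),
        "  CV = ", signif(s$residual_ratio_sd, 3), "\n", sep = "")
  }
  invisible(x)
}

# expected fraction for each sample under one predictor set
.rbz_ef <- function(set, X) {
  as.numeric(set$intercept + X[, set$predictors, drop = FALSE] %*%
               set$coefficients)
}

#' Regression-based Z-score (RBZ)
#'
#' For each of the model's predictor sets, the expected target fraction
#' `ef` of the sample is computed from the set's linear model and the
#' statistic is `(of/ef - 1) / sd_j(of_j/ef_j)`, the denominator being
#' the spread of observed/expected ratios over the supplied reference
#' controls (sample SD, n-1). Because the control-group mean of `of/ef`
#' is one after in-sample regression, that SD equals the control CV. A
#' trisomy is called only when all sets exceed `z_call`; partial
#' exceedance sets the `conflicting_models` flag (a warning sign of a
#' possible false positive).
#'
#' Passing controls held out from training gives an unbiased (non
#' overfit) reference spread; passing the training controls reproduces
#' the in-sample behaviour.
#'
#' @inheritParams standard_zscore
#' @param model An `rbz_model_set` from [rbz_train()], trained on data
#'   with the same correction trail.
#' @return A `trisomy_result` whose `z` has one entry per predictor set;
#'   `control_cv` is the first set's ratio spread.
#' @export
rbz_zscore <- function(samples, controls, model, z_call = 3) {
  stopifnot(inherits(model, "rbz_model_set"))
  controls <- as_control_group(controls)
  single <- inherits(samples, "binned_sample")
  if (single) samples <- list(samples)
  if (!identical(controls$correction_trail, model$correction_trail))
    stop("controls correction_trail differs from the model's training trail")
  for (s in samples)
    if (!identical(s$correction_trail, model$correction_trail))
      stop("sample ", s$sample_id,
           " correction_trail differs from the model's training trail")

  of_ctrl <- .fractions(controls$samples, model$target)
  Xc <- .rbz_predictor_matrix(controls$samples)
  of_s <- .fractions(samples, model$target)
  Xs <- .rbz_predictor_matrix(samples)

  per_set <- lapply(model$sets, function(set) {
    ef_c <- .rbz_ef(set, Xc)
    if (any(ef_c <= 0)) stop("non-positive expected fraction in controls")
    ratio_c <- of_ctrl / ef_c
    ef_s <- .rbz_ef(set, Xs)
    if (any(ef_s <= 0)) stop("non-positive expected fraction for sample")
    list(sd = stats::sd(ratio_c), shapiro = .shapiro_p(ratio_c),
         z = (of_s / ef_s - 1) / stats::sd(ratio_c))
  })
  zmat <- vapply(per_set, `[[`, numeric(length(samples)), "z")
  if (length(samples) == 1L) zmat <- matrix(zmat, nrow = 1L)
  sds <- vapply(per_set, `[[`, 0, "sd")
  sp <- suppressWarnings(min(vapply(per_set, `[[`, 0, "shapiro"),
                             na.rm = TRUE))
  if (!is.finite(sp)) sp <- NA_real_

  res <- lapply(seq_along(samples), function(i) {
    z <- stats::setNames(zmat[i, ], paste0("set", seq_along(model$sets)))
    extra <- model$flags
    if (any(z > z_call) && !all(z > z_call))
      extra <- c(extra, "conflicting_models")
    .trisomy_result("rbz", model$target, samples[[i]]$sample_id,
                    z = z, control_cv = sds[[1L]], shapiro_p = sp,
                    correction_trail = samples[[i]]$correction_trail,
                    z_call = z_call, extra_flags = extra)
  })
  if (single) res[[1L]] else res
}

#' Estimate fetal fraction from a trisomy Z-score
#'
#' Inverts the trisomy fraction-shift model (a trisomic chromosome's
#' fraction scales by `1 + ff/2`): `ff = 2 * z * cv`.
#'
#' @param z Trisomy Z-score.
#' @param control_cv Control-group coefficient of variation of the same
#'   statistic.
#' @return Estimated fetal fraction (0.10 = 10%).
#' @export
estimate_fetal_fraction <- function(z, control_cv) {
  stopifnot(is.finite(z), is.finite(control_cv), control_cv > 0)
  2 * z * control_cv
}

#' Theoretical trisomy detection sensitivity
#'
#' Under the normal model, a trisomy at fetal fraction `ff` shifts the
#' expected Z-score to `(ff/2)/cv`, so the probability of exceeding the
#' call threshold is `pnorm((ff/2)/cv - z_call)`. Monotone decreasing in
#' `cv` and increasing in `ff`.
#'
#' @param control_cv Control-group CV of the statistic.
#' @param fetal_fraction Fetal fraction (0.10 = 10%).
#' @param z_call Call threshold (default 3).
#' @return Sensitivity in `[0, 1]`.
#' @export
theoretical_sensitivity <- function(control_cv, fetal_fraction, z_call = 3) {
  stopifnot(control_cv > 0, fetal_fraction >= 0)
  stats::pnorm((fetal_fraction / 2) / control_cv - z_call)
}
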