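# --- chromosomal fractions ---------------------------------------------

test_that("chromosomal fractions behave and are scale invariant", {
  g <- geom22()
  equal <- make_sample("eq", g, rep(100, 22))
  expect_equal(chromosomal_fraction(equal, 21), 1 / 22)
  s <- fraction_sample("s", c(`21` = 0.03), total = 10000)
  expect_equal(chromosomal_fraction(s, 21), 0.03)
  s2 <- make_sample("s2", g, bin_totals(s) * 7.3)
  expect_equal(chromosomal_fraction(s2, 21), 0.03)
  # restricted denominator
  expect_equal(chromosomal_fraction(equal, 21, denominator = c(1, 2)),
               0.5)
  expect_error(chromosomal_fraction(equal, 21, denominator = integer()),
               "denominator")
})

# --- standard and MAD Z-scores -----------------------------------------

zctrl <- function(fracs) {
  lapply(seq_along(fracs), function(j)
    fraction_sample(paste0("c", j), c(`21` = fracs[j])))
}

test_that("standard Z-score matches the hand-computed fixture", {
  ctl <- zctrl(c(0.030, 0.031, 0.032))
  r0 <- standard_zscore(fraction_sample("at_mean", c(`21` = 0.031)), ctl, 21)
  expect_equal(r0$z, 0, tolerance = 1e-9)
  r <- standard_zscore(fraction_sample("s", c(`21` = 0.034)), ctl, 21)
  expect_equal(r$z, 3.0, tolerance = 1e-9)        # (0.034-0.031)/0.001
  expect_equal(r$control_cv, 0.001 / 0.031, tolerance = 1e-9)
  expect_false(r$call)                             # one-sided, z > 3 strictly
  r_hi <- standard_zscore(fraction_sample("hi", c(`21` = 0.0341)), ctl, 21)
  expect_true(r_hi$call)
  # zero spread -> error
  expect_error(standard_zscore(fraction_sample("s", c(`21` = 0.034)),
                               zctrl(rep(0.031, 3)), 21),
               "spread is zero")
})

test_that("MAD-based Z-score follows the three-step MAD recipe and resists outliers", {
  fr <- c(0.030, 0.031, 0.032, 0.100)             # one gross outlier
  ctl <- zctrl(fr)
  s <- fraction_sample("s", c(`21` = 0.034))
  # independent oracle: median / absolute deviations / median
  med <- stats::median(fr)
  mad_manual <- stats::median(abs(fr - med))
  expect_equal(med, 0.0315)
  expect_equal(mad_manual, 0.001)
  r_mad <- mad_zscore(s, ctl, 21)
  expect_equal(r_mad$z, (0.034 - med) / (1.4826 * mad_manual),
               tolerance = 1e-9)
  # the outlier wrecks the SD-based z but barely moves the MAD-based one
  r_std <- standard_zscore(s, ctl, 21)
  expect_lt(r_std$z, 0)                           # dragged below the mean
  expect_gt(r_mad$z, 1.5)
})

test_that("for symmetric two-point control sets the two Z-scores share a center", {
  # center(median) = center(mean); scales differ by sd / (1.4826 * MAD)
  fr <- c(0.030, 0.030, 0.032, 0.032)
  ctl <- zctrl(fr)
  s <- fraction_sample("s", c(`21` = 0.0335))
  r_std <- standard_zscore(s, ctl, 21)
  r_mad <- mad_zscore(s, ctl, 21)
  expect_equal(r_mad$z * 1.4826 * 0.001, r_std$z * stats::sd(fr),
               tolerance = 1e-9)
})

test_that("a non-normal control distribution is flagged, not fatal", {
  withr::local_seed(77)
  fr <- c(rep(0.030, 12), rep(0.045, 8)) + stats::rnorm(20, 0, 1e-5)
  r <- standard_zscore(fraction_sample("s", c(`21` = 0.034)), zctrl(fr), 21)
  expect_lt(r$shapiro_p, 0.05)
  expect_true("non_normal_controls" %in% r$flags)
})

# --- NCV ----------------------------------------------------------------

test_that("NCV training finds a perfectly proportional denominator", {
  withr::local_seed(31)
  g <- geom22()
  ctl <- lapply(1:12, function(j) {
    t21 <- stats::runif(1, 900, 1100)
    tot <- rep(1000, 22)
    tot[21] <- t21
    tot[7] <- 2 * t21                 # chr7 exactly proportional to chr21
    tot[-c(7, 21)] <- tot[-c(7, 21)] + stats::rnorm(20, 0, 20)
    make_sample(paste0("c", j), g, tot)
  })
  mod <- ncv_train(ctl, 21)
  expect_equal(mod$denominator, 7L)
  expect_equal(mod$cv_train, 0, tolerance = 1e-12)
  # search space: sum_{k=1..4} C(19, k) subsets of the 19 candidates
  expect_equal(mod$n_candidates,
               sum(choose(19, 1:4)))              # 5035
})

test_that("NCV beats the all-autosome fraction on correlated cohorts", {
  sim <- default_sim()
  mod <- ncv_train(sim$controls, 21)
  expect_lte(mod$cv_train, control_cv(sim$controls, 21)$cv)
  # z-scoring through the model reproduces the standard form on the ratio
  r <- ncv_zscore(sim$cases[[1]], sim$controls, 21, mod)
  of_ctrl <- vapply(sim$controls$samples, chromosomal_fraction,
                    0, target = 21, denominator = mod$denominator)
  of_s <- chromosomal_fraction(sim$cases[[1]], 21,
                               denominator = mod$denominator)
  expect_equal(r$z, (of_s - mean(of_ctrl)) / stats::sd(of_ctrl),
               tolerance = 1e-9)
  expect_error(ncv_zscore(sim$cases[[1]], sim$controls, 13, mod),
               "trained for chromosome")
})

# --- RBZ ----------------------------------------------------------------

test_that("RBZ forward selection recovers planted predictors incl. negative ones", {
  ctl <- rbz_planted_cohort()
  mod <- rbz_train(ctl, 21)
  set1 <- mod$sets[[1]]
  expect_setequal(set1$predictors,
                  c("chr2_fwd", "chr5_fwd", "chr9_fwd", "chr16_fwd"))
  expect_gt(set1$adj_r2, 0.999)
  expect_lt(set1$coefficients[["chr5_fwd"]], 0)   # negative correlation used
  # structural: within-set chromosomes distinct, across-set predictors disjoint
  for (s in mod$sets)
    expect_equal(anyDuplicated(s$chromosomes), 0L)
  all_preds <- unlist(lapply(mod$sets, `[[`, "predictors"))
  expect_equal(anyDuplicated(all_preds), 0L)
  # least-squares identity: in-sample mean residual of - ef is exactly 0,
  # hence mean(of/ef) = 1 up to the (tiny) residual/ef curvature term
  of <- vapply(ctl, chromosomal_fraction, 0, target = 21)
  X <- .rbz_predictor_matrix(ctl)
  for (s in mod$sets) {
    ef <- .rbz_ef(s, X)
    expect_equal(mean(of - ef), 0, tolerance = 1e-12)
    expect_equal(s$ratio_mean, 1, tolerance = 1e-3)
  }
})

test_that("RBZ z-scores score observed/expected ratios against control spread", {
  ctl <- rbz_planted_cohort()
  mod <- rbz_train(ctl, 21)
  # an in-distribution sample scores |z| modestly on every set
  r <- rbz_zscore(ctl[[3]], ctl, mod)
  expect_length(r$z, 4)
  expect_false(r$call)
  # a modest chr21 excess is seen only by the informative set ->
  # conflicting models, no call (the false-positive warning policy)
  shift_by <- function(f) {
    fwd <- ctl[[3]]$counts_fwd; rev <- ctl[[3]]$counts_rev
    fwd[21] <- fwd[21] * f; rev[21] <- rev[21] * f
    binned_sample("shift", ctl[[3]]$geometry, fwd, rev)
  }
  r2 <- rbz_zscore(shift_by(1.04), ctl, mod)
  expect_gt(r2$z[["set1"]], 3)
  expect_false(r2$call)
  expect_true("conflicting_models" %in% r2$flags)
  # a gross excess drives all four sets past 3 -> unanimous call
  r3 <- rbz_zscore(shift_by(1.5), ctl, mod)
  expect_true(all(r3$z > 3))
  expect_true(r3$call)
  # correction-trail mismatch is refused
  tr <- ctl[[1]]
  tr$correction_trail <- "gc_loess"
  expect_error(rbz_zscore(tr, ctl, mod), "correction_trail")
  expect_error(rbz_train(ctl[1:5], 21), "at least 10")
})

test_that("RBZ never uses chromosomes 13/18/21 as predictors", {
  sim <- default_sim()
  for (tgt in c(13L, 18L, 21L)) {
    mod <- rbz_train(sim$controls, tgt)
    chroms <- unlist(lapply(mod$sets, `[[`, "chromosomes"))
    expect_length(intersect(chroms, c(13L, 18L, 21L)), 0)
  }
})

# --- scale invariance across all predictors ----------------------------

test_that("all four predictors ignore global rescaling of a sample", {
  sim <- default_sim()
  ctl <- sim$controls
  case <- sim$cases[[1]]
  scaled <- binned_sample("scaled", case$geometry, case$counts_fwd * 4.7,
                          case$counts_rev * 4.7)
  ncv_mod <- ncv_train(ctl, 21)
  rbz_mod <- rbz_train(ctl, 21)
  pairs <- list(
    c(standard_zscore(case, ctl, 21)$z, standard_zscore(scaled, ctl, 21)$z),
    c(mad_zscore(case, ctl, 21)$z, mad_zscore(scaled, ctl, 21)$z),
    c(ncv_zscore(case, ctl, 21, ncv_mod)$z,
      ncv_zscore(scaled, ctl, 21, ncv_mod)$z))
  for (p in pairs) expect_equal(p[1], p[2], tolerance = 1e-12)
  expect_equal(rbz_zscore(case, ctl, rbz_mod)$z,
               rbz_zscore(scaled, ctl, rbz_mod)$z, tolerance = 1e-12)
})

# --- fetal fraction and theoretical sensitivity ------------------------

test_that("fetal-fraction estimate inverts the trisomy shift model", {
  expect_equal(estimate_fetal_fraction(0, 0.004), 0)
  expect_equal(estimate_fetal_fraction(12.5, 0.004), 0.10)
  # self-consistency with the sensitivity model at the detection boundary
  expect_equal(theoretical_sensitivity(0.004,
                                       estimate_fetal_fraction(3, 0.004)),
               0.5)
})

test_that("theoretical sensitivity is monotone with the right limits", {
  expect_equal(theoretical_sensitivity(0.01, 0.06), 0.5)   # ff/2 = 3 cv
  expect_gt(theoretical_sensitivity(1e-6, 0.06), 1 - 1e-12)
  cvs <- c(0.002, 0.004, 0.008, 0.016)
  sens <- vapply(cvs, theoretical_sensitivity, 0, fetal_fraction = 0.08)
  expect_true(all(diff(sens) < 0))                 # decreasing in cv
  ffs <- c(0.02, 0.04, 0.08, 0.16)
  sens_ff <- vapply(ffs, function(f)
    theoretical_sensitivity(0.01, f), 0)
  expect_true(all(diff(sens_ff) > 0))              # increasing in ff
})
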