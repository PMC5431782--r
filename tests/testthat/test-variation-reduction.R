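# --- Eq. 1 normalization ------------------------------------------------

test_that("normalization rescales to the controls' grand mean bin count", {
  g <- make_geom(c(`1` = 200), bin_size = 100)
  ctl <- list(make_sample("c1", g, c(150, 250)),   # mean 200
              make_sample("c2", g, c(100, 300)),   # mean 200
              make_sample("c3", g, c(300, 100)))   # mean 200
  # sample mean equals the grand mean -> factor 1
  s_eq <- make_sample("s0", g, c(180, 220))
  expect_equal(normalize_counts(s_eq, ctl), c(180, 220))
  # grand mean 200, sample mean 100 -> every count doubled
  s_half <- make_sample("s1", g, c(80, 120))
  expect_equal(normalize_counts(s_half, ctl), c(160, 240))
  # scaling a sample by any c > 0 leaves the result invariant
  for (c_mult in c(0.2, 3, 117)) {
    s_scaled <- make_sample("s2", g, c(80, 120) * c_mult)
    expect_equal(normalize_counts(s_scaled, ctl), c(160, 240))
  }
  expect_error(normalize_counts(make_sample("z", g, c(0, 0)), ctl),
               "zero total")
})

# --- Eq. 2-3 chi-squared variation reduction ---------------------------

test_that("chi-squared statistics match hand-computed Eq. 2-3 values", {
  # all controls at mu: sum chisq 0, z = -df/sqrt(2 df), untouched
  fx <- chi2_fixture(c(100, 100, 100))
  res <- chi_squared_vr(fx)
  expect_equal(res$correction$sum_chisq, c(0, 0))
  expect_equal(res$correction$z_bin, rep(-2 / sqrt(4), 2))
  expect_equal(res$correction$correction_factor, c(1, 1))

  # (100, 121, 79): sum chisq 8.82, z 3.41 <= 3.5 -> untouched
  fx <- chi2_fixture(c(100, 121, 79))
  res <- chi_squared_vr(fx)
  expect_equal(res$correction$sum_chisq[1], 8.82, tolerance = 1e-9)
  expect_equal(res$correction$df, 2L)
  expect_equal(res$correction$z_bin[1], 3.41, tolerance = 1e-9)
  expect_equal(res$correction$correction_factor[1], 1)
  # untouched normalized counts equal the input (factor-1 normalization)
  expect_equal(bin_totals(res$controls$samples[[2]])[1], 121)
})

test_that("bins above the Z threshold are divided by sum-chisq/df everywhere", {
  fx <- chi2_fixture(c(100, 130, 70))
  tgt <- make_sample("t", fx[[1]]$geometry, c(90, 110))  # mean 100 -> factor 1
  res <- chi_squared_vr(fx, list(tgt))
  expect_equal(res$correction$sum_chisq[1], 18, tolerance = 1e-12)
  expect_equal(res$correction$z_bin[1], 8, tolerance = 1e-12)
  expect_equal(res$correction$correction_factor[1], 9)
  # a target count of 90 in that bin becomes 10
  expect_equal(bin_totals(res$targets[[1]])[1], 10, tolerance = 1e-12)
  # controls corrected with the same factor
  expect_equal(bin_totals(res$controls$samples[[2]])[1], 130 / 9,
               tolerance = 1e-12)
  # both strands scaled identically (strand ratio preserved)
  t1 <- res$targets[[1]]
  expect_equal(t1$counts_fwd[1], t1$counts_rev[1])
  expect_identical(t1$correction_trail, "chi2vr")
})

test_that("chi2vr skips zero-mean bins, requires df >= 2, ignores control order", {
  g <- make_geom(c(`1` = 300), bin_size = 100)
  ctl <- list(make_sample("c1", g, c(100, 130, 0)),
              make_sample("c2", g, c(100, 70, 0)),
              make_sample("c3", g, c(100, 100, 0)))
  res <- chi_squared_vr(ctl)
  expect_equal(res$correction$zero_mu_bins, 3L)
  expect_true(is.na(res$correction$z_bin[3]))
  expect_equal(res$correction$correction_factor[3], 1)
  expect_error(chi_squared_vr(ctl[1:2]), "at least 3|df")

  # relabeling/permuting controls changes nothing
  res_perm <- chi_squared_vr(ctl[c(3, 1, 2)])
  expect_equal(res_perm$correction$sum_chisq, res$correction$sum_chisq)
  expect_equal(res_perm$correction$correction_factor,
               res$correction$correction_factor)
})

test_that("chi2vr reduces planted overdispersion and is nearly idempotent", {
  sim <- simulate_cohort(sim_config(
    seed = 7301, n_controls = 60, n_cases = 0,
    reference_lengths = scaled_autosome_lengths(80),
    mean_bin_count = 1000, noise = list(type = "poisson"),
    gc_bias = list(type = "none", slope_sd = 0),
    inter_chromosome_correlation = list(rank = 0L, strength = 0),
    peak_bins = list(n = 0L, magnitude = 1),
    overdispersed_bins = list(proportion = 0.02, inflation = 10)))
  res <- chi_squared_vr(sim$controls)
  planted <- sim$truth$overdispersed_bins
  flagged <- which(res$correction$correction_factor > 1)
  expect_gt(length(intersect(flagged, planted)) / length(planted), 0.9)
  # corrected planted bins lose between-control variance
  var_of <- function(grp, bins) {
    m <- vapply(grp$samples, function(s) bin_totals(s)[bins],
                numeric(length(bins)))
    mean(apply(m, 1, stats::var))
  }
  expect_lt(var_of(res$controls, planted), var_of(sim$controls, planted))
  # re-running on corrected data flags (weakly) fewer bins
  res2 <- chi_squared_vr(res$controls)
  expect_lte(res2$correction$n_corrected, res$correction$n_corrected)
})

# --- peak correction ----------------------------------------------------

test_that("peak correction flags only consistent extreme bins", {
  g <- make_geom(c(`1` = 2100), bin_size = 100)   # 21 bins
  base <- rep(100, 21)
  peaky <- base; peaky[5] <- 1000
  ctl <- lapply(1:4, function(j) make_sample(paste0("c", j), g, peaky))
  tgt <- make_sample("t", g, base + 7)
  res <- peak_correct(ctl, list(tgt))
  expect_equal(which(res$mask$flagged), 5L)
  expect_equal(bin_totals(res$controls$samples[[1]])[5], 0)
  expect_equal(bin_totals(res$targets[[1]])[5], 0)
  expect_equal(bin_totals(res$targets[[1]])[-5], rep(107, 20))
  expect_identical(res$targets[[1]]$correction_trail, "peak")

  # constant chromosome: SD = 0 -> nothing flagged
  ctl_flat <- lapply(1:4, function(j) make_sample(paste0("f", j), g, base))
  expect_equal(sum(peak_correct(ctl_flat)$mask$flagged), 0L)
})

test_that("a bin extreme in fewer than 95% of controls is kept", {
  g <- make_geom(c(`1` = 2100), bin_size = 100)
  base <- rep(100, 21)
  peaky <- base; peaky[3] <- 1000
  # extreme in 9 of 10 controls = 90% < 95%
  ctl <- c(lapply(1:9, function(j) make_sample(paste0("c", j), g, peaky)),
           list(make_sample("c10", g, base)))
  expect_equal(sum(peak_correct(ctl)$mask$flagged), 0L)
  # extreme in 10/10 -> flagged
  ctl[[10]] <- make_sample("c10", g, peaky)
  expect_equal(which(peak_correct(ctl)$mask$flagged), 3L)
})

test_that("peak correction refuses chromosomes with fewer than 2 bins", {
  g <- make_geom(c(`1` = 100, `2` = 500), bin_size = 100)
  ctl <- lapply(1:3, function(j)
    make_sample(paste0("c", j), g, rep(10, 6)))
  expect_error(peak_correct(ctl), "fewer than 2 bins")
})

# --- weighted-bin GC correction ----------------------------------------

test_that("bin GC correction divides by interval weights (hand fixture)", {
  g <- make_geom(c(`1` = 400), bin_size = 100)
  gc <- gc_track(g, c(0.3004, 0.3006, 0.5001, 0.5009))  # two 0.1% intervals
  s <- make_sample("s", g, c(150, 150, 50, 50))         # global mean 100
  out <- gc_correct_bin(s, gc)
  expect_equal(bin_totals(out), rep(100, 4), tolerance = 1e-12)
  w <- attr(out, "gc_weights")
  expect_equal(sort(unname(w)), c(0.5, 1.5))
  expect_identical(out$correction_trail, "gc_bin")
  # identical coverage -> identity
  s_flat <- make_sample("f", g, rep(80, 4))
  expect_equal(bin_totals(gc_correct_bin(s_flat, gc)), rep(80, 4))
})

test_that("bin GC correction ignores zero-count and undefined-GC bins", {
  g <- make_geom(c(`1` = 500), bin_size = 100)
  gc <- gc_track(g, c(0.30, 0.30, 0.50, 0.50, NA))
  s <- make_sample("s", g, c(150, 150, 50, 0, 80))
  out <- gc_correct_bin(s, gc)
  # eligible: bins 1,2,3 -> global mean (150+150+50)/3
  gm <- mean(c(150, 150, 50))
  expect_equal(bin_totals(out)[1:2], rep(150 / (150 / gm), 2))
  expect_equal(bin_totals(out)[3], 50 / (50 / gm))
  # ignored bins unchanged
  expect_equal(bin_totals(out)[4:5], c(0, 80))
})

test_that("bin GC correction conserves totals on symmetric fixtures", {
  # equal bin counts per interval: sum of corrected = sum of raw
  g <- make_geom(c(`1` = 600), bin_size = 100)
  gc <- gc_track(g, c(0.30, 0.30, 0.40, 0.40, 0.50, 0.50))
  s <- make_sample("s", g, c(150, 150, 100, 100, 50, 50))
  out <- gc_correct_bin(s, gc)
  expect_equal(sum(bin_totals(out)), sum(bin_totals(s)), tolerance = 1e-12)
})

# --- LOESS GC correction ------------------------------------------------

test_that("LOESS GC correction is identity on flat data, flattens linear bias", {
  withr::local_seed(551)
  n <- 1000
  g <- make_geom(c(`1` = n * 100), bin_size = 100)
  gc_vals <- stats::runif(n, 0.3, 0.6)
  gc <- gc_track(g, gc_vals)

  flat <- make_sample("flat", g, rep(200, n))
  out_flat <- gc_correct_loess(flat, gc)
  expect_equal(bin_totals(out_flat), rep(200, n), tolerance = 1e-6)
  expect_identical(out_flat$correction_trail, "gc_loess")

  # exactly linear bias: corrected counts ~ constant, residual slope ~ 0
  biased <- make_sample("lin", g, 100 * (1 + (gc_vals - 0.5)))
  out <- gc_correct_loess(biased, gc)
  corrected <- bin_totals(out)
  slope_raw <- stats::coef(stats::lm(bin_totals(biased) ~ gc_vals))[2]
  slope_cor <- stats::coef(stats::lm(corrected ~ gc_vals))[2]
  expect_lt(abs(slope_cor), abs(slope_raw) / 100)
  # global mean preserved by construction of the rescaling
  expect_equal(mean(corrected), mean(bin_totals(biased)), tolerance = 1e-3)
})

test_that("GC corrections attenuate count-GC correlation on noisy bias", {
  sim <- simulate_cohort(sim_config(
    seed = 8112, n_controls = 3, n_cases = 0,
    reference_lengths = scaled_autosome_lengths(80),
    mean_bin_count = 1000, noise = list(type = "poisson"),
    gc_bias = list(type = "linear", slope = 1.5, slope_sd = 0),
    inter_chromosome_correlation = list(rank = 0L, strength = 0),
    peak_bins = list(n = 0L, magnitude = 1),
    overdispersed_bins = list(proportion = 0, inflation = 1),
    sample_factor_sd = 0))
  s <- sim$controls$samples[[1]]
  gc <- sim$gc
  ok <- gc$defined_mask
  cor_raw <- abs(stats::cor(bin_totals(s)[ok], gc$gc_fraction[ok]))
  for (fn in list(gc_correct_bin, gc_correct_loess)) {
    out <- fn(s, gc)
    cor_cor <- abs(stats::cor(bin_totals(out)[ok], gc$gc_fraction[ok]))
    expect_lt(cor_cor, cor_raw / 5)
  }
})

test_that("LOESS GC correction enforces the minimum-bin precondition", {
  g <- make_geom(c(`1` = 1000), bin_size = 100)
  gc <- gc_track(g, seq(0.3, 0.6, length.out = 10))
  s <- make_sample("s", g, rep(10, 10))
  expect_error(gc_correct_loess(s, gc), "eligible bins")
  expect_no_error(gc_correct_loess(s, gc, min_bins = 10))
})

# --- stacking / apply_corrections --------------------------------------

test_that("apply_corrections normalizes order and rejects double GC", {
  sim <- small_sim()
  expect_error(apply_corrections(sim$controls,
                                 corrections = c("gc_bin", "gc_loess"),
                                 gc = sim$gc),
               "one GC-correction")
  expect_error(apply_corrections(sim$controls, corrections = "gc_loess"),
               "no gc track")
  res <- apply_corrections(sim$controls, sim$cases,
                           corrections = c("chi2vr", "gc_loess", "peak"),
                           gc = sim$gc)
  # canonical order peak -> GC -> chi2vr regardless of request order
  expect_identical(res$controls$correction_trail,
                   c("peak", "gc_loess", "chi2vr"))
  expect_identical(res$targets[[1]]$correction_trail,
                   c("peak", "gc_loess", "chi2vr"))
})
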