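# Shared fixture builders. Everything is generated in code; simulated
# cohorts used by several test files are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# tiny geometry: named lengths, small bins
make_geom <- function(lengths, bin_size = 100) {
  bin_geometry(lengths, bin_size = bin_size)
}

# sample from explicit strand-summed per-bin counts (split half/half)
make_sample <- function(id, geom, tot, trail = character()) {
  binned_sample(id, geom, tot / 2, tot / 2, correction_trail = trail)
}

# 22-autosome geometry with one bin per chromosome
geom22 <- function() {
  cached("geom22", bin_geometry(
    stats::setNames(rep(50000, 22), as.character(1:22)), bin_size = 50000))
}

# sample whose chromosomal fractions (over all autosomes) are exactly
# `fracs` (named by chromosome), at the given total read count
fraction_sample <- function(id, fracs, total = 1e6) {
  g <- geom22()
  f <- rep(0, 22)
  names(f) <- as.character(1:22)
  f[names(fracs)] <- fracs
  rest <- setdiff(names(f), names(fracs))
  f[rest] <- (1 - sum(fracs)) / length(rest)
  make_sample(id, g, as.numeric(f) * total)
}

# deterministic multi-chromosome geometry for mid-size tests
geom_mid <- function() {
  cached("geom_mid",
         bin_geometry(stats::setNames(rep(2e6, 22), as.character(1:22)),
                      bin_size = 50000))  # 40 bins per chromosome
}

# default simulated cohort, shared across test files
default_sim <- function() {
  cached("default_sim", simulate_cohort(sim_config(seed = 424241)))
}

# small, fast cohort for property tests
small_sim <- function(seed = 99, ...) {
  simulate_cohort(sim_config(
    seed = seed, n_controls = 40, n_cases = 2,
    reference_lengths = scaled_autosome_lengths(80),
    mean_bin_count = 1000, ...))
}

# chi-squared fixture: controls whose per-sample means are equal (so the
# Eq.-1 normalization factor is exactly 1); bin 1 takes `bin1`, bin 2 the
# mirrored values
chi2_fixture <- function(bin1) {
  g <- make_geom(c(`1` = 200), bin_size = 100)
  m <- mean(bin1)
  lapply(seq_along(bin1), function(j)
    make_sample(paste0("c", j), g, c(bin1[j], 2 * m - bin1[j])))
}

# cohort in which the target fraction is an exact linear function of four
# planted strand-level predictor fractions (chr5 with negative sign);
# chromosomes 13/18 (never predictor candidates) absorb the remainder
rbz_planted_cohort <- function(n = 80, noise_sd = 1e-5, seed = 904) {
  withr::with_seed(seed, {
    g <- geom22()
    total <- 1e6
    planted <- c(2, 5, 9, 16)
    coefs <- c(0.25, -0.30, 0.20, 0.15)
    lapply(seq_len(n), function(j) {
      x <- stats::rnorm(4, 0.02, 0.002)
      of21 <- 0.013 + sum(coefs * (x - 0.02)) + stats::rnorm(1, 0, noise_sd)
      fwd <- rep(NA_real_, 22)
      rev <- rep(0.005, 22)
      fwd[planted] <- x
      fwd[21] <- of21 - 0.005
      filler <- setdiff(1:22, c(planted, 13, 18, 21))
      fwd[filler] <- 0.03 + stats::rnorm(length(filler), 0, 1e-4)
      rest <- (1 - sum(rev) - sum(fwd[c(planted, filler, 21)])) / 2
      fwd[c(13, 18)] <- rest
      binned_sample(sprintf("p%03d", j), g, fwd * total, rev * total)
    })
  })
}

expect_samples_equal <- function(a, b, tolerance = 0) {
  if (tolerance == 0) {
    expect_identical(a$counts_fwd, b$counts_fwd)
    expect_identical(a$counts_rev, b$counts_rev)
  } else {
    expect_equal(a$counts_fwd, b$counts_fwd, tolerance = tolerance)
    expect_equal(a$counts_rev, b$counts_rev, tolerance = tolerance)
  }
  expect_identical(a$correction_trail, b$correction_trail)
}

# SAM text fixture -> sorted, indexed BAM; returns BAM path
make_test_bam <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "toy.sam")
  rd <- function(qname, flag, rname, pos)
    paste(qname, flag, rname, pos, 60, "4M", "*", 0, 0, "ACGT", "IIII",
          sep = "\t")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:120000",
    "@SQ\tSN:chr2\tLN:60000",
    rd("a", 0, "chr1", 11),        # 0-based 10     -> chr1 bin 0, fwd
    rd("b", 1024, "chr1", 21),     # duplicate      -> excluded
    rd("h", 256, "chr1", 101),     # secondary      -> excluded
    rd("c", 0, "chr1", 50000),     # 0-based 49999  -> chr1 bin 0, fwd
    rd("d", 0, "chr1", 50001),     # 0-based 50000  -> chr1 bin 1, fwd
    rd("e", 0, "chr1", 60011),     # 0-based 60010  -> chr1 bin 1, fwd
    rd("f", 16, "chr2", 6)         # 0-based 5      -> chr2 bin 0, rev
  ), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "toy"),
                          overwrite = TRUE, indexDestination = TRUE)
  bam
}

make_test_fasta <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fa <- file.path(dir, "toy.fa")
  writeLines(c(
    ">1",
    strrep("G", 100),                      # bin 0: GC = 1
    strrep("ACGT", 25),                    # bin 1: GC = 0.5
    strrep("N", 100),                      # bin 2: undefined
    ">chr2 description text",
    paste0(strrep("A", 50), strrep("G", 50))  # bin 0: GC = 0.5
  ), fa)
  fa
}
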