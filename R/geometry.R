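#' Autosome lengths of human genome build GRCh37/hg19
#'
#' Chromosome lengths (bp) for autosomes 1-22 of GRCh37, the reference
#' build commonly used in whole-genome NIPT. Used as the default bin
#' geometry and, scaled down, by the simulator.
#'
#' @return Named numeric vector, names `"1"`..`"22"`.
#' @export
hg19_autosome_lengths <- function() {
  c(`1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566)
}

#' Down-scaled autosome lengths for simulation
#'
#' hg19 autosome lengths divided by `scale`, keeping relative chromosome
#' sizes. A scale of 20 gives ~2,900 bins of 50 kb genome-wide, small
#' enough for fast simulation while preserving the chromosome-size
#' hierarchy that fraction-based statistics depend on.
#'
#' @param scale Positive divisor applied to every chromosome length.
#' @return Named numeric vector of lengths.
#' @export
scaled_autosome_lengths <- function(scale = 20) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  round(hg19_autosome_lengths() / scale)
}

# Normalize chromosome labels: accepts "chr1"/"1"/1 -> integer 1..22,
# NA for anything that is not an autosome.
normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x))
  n <- suppressWarnings(as.integer(x))
  n[!(n %in% 1:22)] <- NA_integer_
  n
}

#' Bin geometry for fixed-size autosomal bins
#'
#' Partitions each autosome into half-open bins `[k*B, (k+1)*B)` of
#' `bin_size` bp; the last (possibly short) bin is kept, so each
#' chromosome has `ceiling(length / bin_size)` bins. Coordinates are
#' 0-based throughout.
#'
#' @param reference_lengths Named numeric vector of chromosome lengths in
#'   bp; names may be `"1"` or `"chr1"` style, restricted to autosomes
#'   1-22 (a subset is allowed, e.g. for test fixtures).
#' @param bin_size Bin width in bp (default 50,000).
#' @return An object of class `bin_geometry`: a list with `bin_size`,
#'   `lengths` (named by autosome number), and per-bin vectors `chrom`
#'   (integer) and `bin_start` (0-based bp).
#' @export
bin_geometry <- function(reference_lengths, bin_size = 50000) {
  stopifnot(is.numeric(bin_size), length(bin_size) == 1L, bin_size >= 1)
  if (is.null(names(reference_lengths)) || length(reference_lengths) == 0L)
    stop("reference_lengths must be a named vector of chromosome lengths")
  chrom <- normalize_chrom(names(reference_lengths))
  if (anyNA(chrom))
    stop("reference_lengths contains non-autosomal chromosome(s): ",
         paste(names(reference_lengths)[is.na(chrom)], collapse = ", "))
  if (anyDuplicated(chrom))
    stop("duplicated chromosome in reference_lengths")
  len <- as.numeric(reference_lengths)
  if (any(!is.finite(len)) || any(len < 1))
    stop("chromosome lengths must be positive")
  ord <- order(chrom)
  chrom <- chrom[ord]
  len <- len[ord]
  n_bins <- ceiling(len / bin_size)
  geom <- list(
    bin_size = as.numeric(bin_size),
    lengths = stats::setNames(len, as.character(chrom)),
    chrom = rep(chrom, n_bins),
    bin_start = unlist(lapply(n_bins, function(n) (seq_len(n) - 1)), use.names = FALSE) * as.numeric(bin_size)
  )
  class(geom) <- "bin_geometry"
  geom
}

#' @export
print.bin_geometry <- function(x, ...) {
  cat("<bin_geometry> ", length(unique(x$chrom)), " autosomes, ",
      length(x$chrom), " bins of ", format(x$bin_size, big.mark = ","),
      " bp\n", sep = "")
  invisible(x)
}

n_bins <- function(geom) length(geom$chrom)

same_geometry <- function(a, b) {
  isTRUE(all.equal(a$bin_size, b$bin_size)) &&
    identical(a$chrom, b$chrom) &&
    isTRUE(all.equal(a$bin_start, b$bin_start))
}
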