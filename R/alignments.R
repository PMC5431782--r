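#' Count aligned reads into fixed-size autosomal bins
#'
#' Reads a coordinate-sorted, indexed BAM and counts primary, mapped,
#' non-duplicate alignments on autosomes 1-22 into half-open bins
#' `[k*bin_size, (k+1)*bin_size)` by 0-based leftmost mapping position,
#' keeping forward- and reverse-strand counts separate.
#'
#' @param alignment_file Path to an indexed BAM file.
#' @param reference_lengths Named chromosome lengths (bp); `NULL` (default)
#'   takes the autosomes from the BAM header. `"chr1"` and `"1"` naming
#'   are both accepted.
#' @param bin_size Bin width in bp (default 50,000).
#' @param min_mapq Minimum mapping quality; alignments below it are
#'   dropped. Default 0 (no filter), matching default-settings `bwa aln`
#'   output where multi-mappers carry MAPQ 0.
#' @param sample_id Sample identifier; defaults to the BAM file name.
#' @return A [binned_sample()] of integer-valued counts.
#' @export
bin_counts_from_alignments <- function(alignment_file,
                                       reference_lengths = NULL,
                                       bin_size = 50000,
                                       min_mapq = 0,
                                       sample_id = NULL) {
  if (!file.exists(alignment_file))
    stop("alignment file not found: ", alignment_file)
  bai <- paste0(alignment_file, ".bai")
  bai2 <- sub("\\.bam$", ".bai", alignment_file)
  if (!file.exists(bai) && !file.exists(bai2))
    stop("BAM index (.bai) not found for ", alignment_file,
         "; sort and index the file first")
  if (is.null(sample_id))
    sample_id <- sub("\\.bam$", "", basename(alignment_file))

  if (is.null(reference_lengths)) {
    hdr <- Rsamtools::scanBamHeader(alignment_file)[[1L]]$targets
    keep <- !is.na(normalize_chrom(names(hdr)))
    if (!any(keep))
      stop("no autosomal chromosomes (1-22) found in BAM header of ",
           alignment_file)
    reference_lengths <- hdr[keep]
  }
  geom <- bin_geometry(reference_lengths, bin_size)

  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags,
                                   what = c("rname", "pos", "strand", "mapq"))
  aln <- Rsamtools::scanBam(alignment_file, param = param)[[1L]]

  chrom <- normalize_chrom(aln$rname)
  keep <- !is.na(chrom) & !is.na(aln$pos) &
    chrom %in% as.integer(names(geom$lengths))
  if (min_mapq > 0) {
    mq <- aln$mapq
    mq[is.na(mq)] <- 0L
    keep <- keep & mq >= min_mapq
  }
  if (!any(keep))
    stop("no retained alignments in ", alignment_file,
         " (empty samples are never processed)")
  chrom <- chrom[keep]
  pos0 <- aln$pos[keep] - 1L           # BAM pos is 1-based; bins are 0-based
  fwd <- aln$strand[keep] == "+"

  bin_in_chrom <- floor(pos0 / bin_size)
  # drop reads whose position exceeds the declared chromosome length
  max_bin <- ceiling(geom$lengths[as.character(chrom)] / bin_size) - 1
  ok <- bin_in_chrom <= max_bin
  chrom <- chrom[ok]; bin_in_chrom <- bin_in_chrom[ok]; fwd <- fwd[ok]
  if (!length(chrom))
    stop("no retained alignments in ", alignment_file,
         " fall inside the declared reference lengths")

  # global bin index: offset of chromosome + bin within chromosome
  chroms <- as.integer(names(geom$lengths))
  nb_per <- as.integer(ceiling(geom$lengths / bin_size))
  offset <- stats::setNames(cumsum(c(0L, nb_per[-length(nb_per)])),
                            as.character(chroms))
  idx <- offset[as.character(chrom)] + bin_in_chrom + 1L

  counts_fwd <- tabulate(idx[fwd], nbins = n_bins(geom))
  counts_rev <- tabulate(idx[!fwd], nbins = n_bins(geom))
  binned_sample(sample_id, geom, counts_fwd, counts_rev)
}

#' Construct a GC track
#'
#' @param geometry A [bin_geometry()].
#' @param gc_fraction Per-bin GC fraction in `[0,1]`, `NA` where the bin's
#'   base composition is unknown (e.g. all-N reference sequence).
#' @return An object of class `gc_track` with `geometry`, `gc_fraction`
#'   and `defined_mask` (TRUE where GC is known).
#' @export
gc_track <- function(geometry, gc_fraction) {
  if (!inherits(geometry, "bin_geometry"))
    stop("geometry must be a bin_geometry")
  gc_fraction <- as.numeric(gc_fraction)
  if (length(gc_fraction) != n_bins(geometry))
    stop("gc_fraction must have one entry per bin")
  ok <- is.na(gc_fraction) | (gc_fraction >= 0 & gc_fraction <= 1)
  if (!all(ok)) stop("gc_fraction values must lie in [0,1] or be NA")
  structure(list(geometry = geometry,
                 gc_fraction = gc_fraction,
                 defined_mask = !is.na(gc_fraction)),
            class = "gc_track")
}

#' @export
print.gc_track <- function(x, ...) {
  cat("<gc_track> ", n_bins(x$geometry), " bins, ",
      sum(!x$defined_mask), " undefined; mean GC ",
      round(mean(x$gc_fraction, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Per-bin GC content from a reference FASTA
#'
#' GC fraction of each bin computed over unambiguous bases,
#' `(G+C)/(A+C+G+T)`; bins containing no unambiguous base (e.g. all N)
#' are marked undefined and are ignored by the GC corrections.
#'
#' @param reference Path to a FASTA file containing the autosomes of the
#'   bin geometry (sequence names `"1"` or `"chr1"` style).
#' @param bin_size Bin width in bp (default 50,000).
#' @param reference_lengths Optional named lengths restricting/defining
#'   the geometry; default: all autosomal sequences in the FASTA at their
#'   full length.
#' @return A [gc_track()].
#' @export
gc_track_from_fasta <- function(reference, bin_size = 50000,
                                reference_lengths = NULL) {
  if (!file.exists(reference)) stop("FASTA not found: ", reference)
  seqs <- Biostrings::readDNAStringSet(reference)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  chrom <- normalize_chrom(names(seqs))
  seqs <- seqs[!is.na(chrom)]
  chrom <- chrom[!is.na(chrom)]
  if (!length(seqs)) stop("no autosomal sequences (1-22) in ", reference)
  names(seqs) <- as.character(chrom)
  if (is.null(reference_lengths))
    reference_lengths <- stats::setNames(Biostrings::width(seqs), names(seqs))
  geom <- bin_geometry(reference_lengths, bin_size)
  missing <- setdiff(names(geom$lengths), names(seqs))
  if (length(missing))
    stop("chromosome(s) missing from FASTA: ", paste(missing, collapse = ", "))

  gc <- rep(NA_real_, n_bins(geom))
  for (c_name in names(geom$lengths)) {
    s <- seqs[[c_name]]
    len <- geom$lengths[[c_name]]
    if (length(s) < len)
      stop("FASTA sequence ", c_name, " shorter (", length(s),
           ") than declared length ", len)
    nb <- ceiling(len / bin_size)
    starts <- (seq_len(nb) - 1) * bin_size + 1
    ends <- pmin(starts + bin_size - 1, len)
    v <- Biostrings::Views(s, start = starts, end = ends)
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    acgt <- rowSums(freq)
    frac <- ifelse(acgt > 0, (freq[, "C"] + freq[, "G"]) / acgt, NA_real_)
    gc[geom$chrom == as.integer(c_name)] <- frac
  }
  gc_track(geom, gc)
}
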