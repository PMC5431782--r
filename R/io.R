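#' Write a binned sample to TSV
#'
#' Stable text serialization: comment header lines carry the sample id,
#' bin size and correction trail, followed by a tab-separated table with
#' columns `chrom`, `bin_start` (0-based bp), `count_fwd`, `count_rev`.
#' Integer counts round-trip bit-identically; corrected (real) counts are
#' written with full double precision.
#'
#' @param sample A [binned_sample()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bin_matrix <- function(sample, path) {
  stopifnot(inherits(sample, "binned_sample"))
  g <- sample$geometry
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("#sample_id: ", sample$sample_id),
    paste0("#bin_size: ", format(g$bin_size, scientific = FALSE)),
    paste0("#reference_lengths: ",
           paste(sprintf("%s=%s", names(g$lengths),
                         format(g$lengths, scientific = FALSE, trim = TRUE)),
                 collapse = ",")),
    paste0("#corrections: ", paste(sample$correction_trail, collapse = ",")),
    "chrom\tbin_start\tcount_fwd\tcount_rev"), con)
  df <- data.frame(chrom = g$chrom,
                   bin_start = format(g$bin_start, scientific = FALSE,
                                      trim = TRUE),
                   count_fwd = format(sample$counts_fwd, digits = 17,
                                      scientific = FALSE, trim = TRUE),
                   count_rev = format(sample$counts_rev, digits = 17,
                                      scientific = FALSE, trim = TRUE))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a binned sample from TSV
#'
#' Inverse of [write_bin_matrix()]. Malformed rows, negative counts and
#' non-autosomal chromosomes are rejected with the offending line number.
#'
#' @param path File written by [write_bin_matrix()].
#' @return A [binned_sample()].
#' @export
read_bin_matrix <- function(path) {
  if (!file.exists(path)) stop("bin matrix not found: ", path)
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(paste0("^#", key, ": ?"), header, value = TRUE)
    if (!length(m)) return(NULL)
    sub(paste0("^#", key, ": ?"), "", m[[1L]])
  }
  sample_id <- get_field("sample_id")
  if (is.null(sample_id)) sample_id <- basename(path)
  bin_size <- as.numeric(get_field("bin_size"))
  if (!length(bin_size) || is.na(bin_size))
    stop(path, ": missing or invalid #bin_size header")
  rl_str <- get_field("reference_lengths")
  if (is.null(rl_str) || !nzchar(rl_str))
    stop(path, ": missing #reference_lengths header")
  parts <- strsplit(strsplit(rl_str, ",")[[1L]], "=")
  reference_lengths <- stats::setNames(
    as.numeric(vapply(parts, `[`, "", 2L)),
    vapply(parts, `[`, "", 1L))
  trail_str <- get_field("corrections")
  trail <- if (is.null(trail_str) || !nzchar(trail_str)) character()
           else strsplit(trail_str, ",")[[1L]]

  body_idx <- which(!grepl("^#", lines) & nzchar(lines))
  if (!length(body_idx)) stop(path, ": no data rows")
  first <- body_idx[[1L]]
  if (!identical(lines[first], "chrom\tbin_start\tcount_fwd\tcount_rev"))
    stop(path, ": line ", first, ": unexpected column header")
  rows <- body_idx[-1L]
  fields <- strsplit(lines[rows], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad))
    stop(path, ": line ", rows[bad[[1L]]], ": expected 4 tab-separated fields")
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  chrom <- normalize_chrom(m[, 1L])
  if (anyNA(chrom))
    stop(path, ": line ", rows[which(is.na(chrom))[1L]],
         ": unknown chromosome '", m[which(is.na(chrom))[1L], 1L], "'")
  bin_start <- suppressWarnings(as.numeric(m[, 2L]))
  cf <- suppressWarnings(as.numeric(m[, 3L]))
  cr <- suppressWarnings(as.numeric(m[, 4L]))
  bad <- which(is.na(bin_start) | is.na(cf) | is.na(cr))
  if (length(bad))
    stop(path, ": line ", rows[bad[[1L]]], ": non-numeric field")
  bad <- which(cf < 0 | cr < 0)
  if (length(bad))
    stop(path, ": line ", rows[bad[[1L]]], ": negative count")

  geom <- bin_geometry(reference_lengths, bin_size)
  if (length(chrom) != n_bins(geom) ||
      !all(chrom == geom$chrom) ||
      !isTRUE(all.equal(bin_start, geom$bin_start)))
    stop(path, ": rows do not match the declared bin geometry")
  binned_sample(sample_id, geom, cf, cr, correction_trail = trail)
}

#' Write / read a GC track as TSV
#'
#' Columns `chrom`, `bin_start`, `gc` (empty field where undefined).
#'
#' @param gc A [gc_track()].
#' @param path File path.
#' @return `path` (write) or a [gc_track()] (read).
#' @export
write_gc_track <- function(gc, path) {
  stopifnot(inherits(gc, "gc_track"))
  g <- gc$geometry
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(paste0("#bin_size: ",
                      format(g$bin_size, scientific = FALSE)),
               paste0("#reference_lengths: ",
                      paste(sprintf("%s=%s", names(g$lengths),
                                    format(g$lengths, scientific = FALSE,
                                           trim = TRUE)),
                            collapse = ",")),
               "chrom\tbin_start\tgc"), con)
  gcs <- ifelse(is.na(gc$gc_fraction), "",
                format(gc$gc_fraction, digits = 17, trim = TRUE))
  utils::write.table(
    data.frame(g$chrom, format(g$bin_start, scientific = FALSE, trim = TRUE),
               gcs),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gc_track
#' @export
read_gc_track <- function(path) {
  if (!file.exists(path)) stop("gc track not found: ", path)
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  bs <- as.numeric(sub("^#bin_size: ?", "",
                       grep("^#bin_size:", header, value = TRUE)[1L]))
  rl_str <- sub("^#reference_lengths: ?", "",
                grep("^#reference_lengths:", header, value = TRUE)[1L])
  parts <- strsplit(strsplit(rl_str, ",")[[1L]], "=")
  rl <- stats::setNames(as.numeric(vapply(parts, `[`, "", 2L)),
                        vapply(parts, `[`, "", 1L))
  geom <- bin_geometry(rl, bs)
  body <- lines[!grepl("^#", lines) & nzchar(lines)][-1L]
  fields <- strsplit(body, "\t", fixed = TRUE)
  gc <- vapply(fields, function(f)
    if (length(f) < 3L || !nzchar(f[[3L]])) NA_real_ else as.numeric(f[[3L]]),
    0)
  if (length(gc) != n_bins(geom))
    stop(path, ": rows do not match the declared bin geometry")
  gc_track(geom, gc)
}

#' Read reference chromosome lengths from a YAML file
#'
#' The file maps chromosome names (`"1"` or `"chr1"`) to lengths in bp.
#'
#' @param path YAML file path.
#' @return Named numeric vector usable as `reference_lengths`.
#' @export
read_reference_lengths <- function(path) {
  if (!file.exists(path)) stop("reference-lengths file not found: ", path)
  x <- yaml::read_yaml(path)
  if (!is.list(x) || is.null(names(x)))
    stop(path, ": expected a mapping of chromosome -> length")
  stats::setNames(as.numeric(unlist(x)), names(x))
}

#' Write a correction log to TSV
#'
#' Flattens the diagnostic objects returned by [apply_corrections()]
#' into one row per affected bin: columns `chrom`, `bin_start`, `method`
#' and `value` (the removal flag for peak correction, the division
#' factor for the chi-squared correction).
#'
#' @param log The `log` element of an [apply_corrections()] result.
#' @param geometry The [bin_geometry()] the corrections were run on.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_correction_log <- function(log, geometry, path) {
  rows <- list()
  if (!is.null(log$peak)) {
    idx <- which(log$peak$flagged)
    if (length(idx))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = geometry$chrom[idx], bin_start = geometry$bin_start[idx],
        method = "peak", value = "removed")
  }
  if (!is.null(log$chi2vr)) {
    idx <- which(log$chi2vr$correction_factor > 1)
    if (length(idx))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = geometry$chrom[idx], bin_start = geometry$bin_start[idx],
        method = "chi2vr",
        value = format(log$chi2vr$correction_factor[idx], digits = 10))
    if (length(log$chi2vr$zero_mu_bins))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = geometry$chrom[log$chi2vr$zero_mu_bins],
        bin_start = geometry$bin_start[log$chi2vr$zero_mu_bins],
        method = "chi2vr", value = "zero_mu_skipped")
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(chrom = integer(), bin_start = numeric(),
                        method = character(), value = character())
  utils::write.table(df[order(df$chrom, df$bin_start), ], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a trained prediction model to JSON
#'
#' Writes an [ncv_train()] or [rbz_train()] model (predictors /
#' denominator, coefficients, control spread, correction trail) as JSON.
#'
#' @param model An `ncv_model` or `rbz_model_set`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "ncv_model")) {
    out <- list(type = "ncv", target = model$target,
                denominator = model$denominator,
                cv_train = model$cv_train,
                correction_trail = model$correction_trail)
  } else if (inherits(model, "rbz_model_set")) {
    out <- list(type = "rbz", target = model$target,
                n_controls = model$n_controls,
                correction_trail = model$correction_trail,
                sets = lapply(model$sets, function(s)
                  list(predictors = s$predictors,
                       intercept = s$intercept,
                       coefficients = as.list(s$coefficients),
                       adj_r2 = s$adj_r2,
                       residual_ratio_sd = s$residual_ratio_sd)))
  } else stop("unsupported model class")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a table of trisomy results to TSV
#'
#' One row per (sample, target, method); regression-based Z-scores occupy
#' four columns `z1..z4`, the other methods fill `z1` only.
#'
#' @param results List of `trisomy_result` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  rows <- lapply(results, function(r) {
    z <- rep(NA_real_, 4L)
    z[seq_along(r$z)] <- r$z
    data.frame(sample_id = r$sample_id, target = r$target,
               method = r$method,
               z1 = z[1L], z2 = z[2L], z3 = z[3L], z4 = z[4L],
               cv = r$control_cv, shapiro_p = r$shapiro_p,
               call = r$call,
               flags = paste(r$flags, collapse = ";"),
               correction_trail = paste(r$correction_trail, collapse = ","),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
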