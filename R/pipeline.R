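config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("niptkit_config_error",
                                             "error", "condition")))
}
data_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("niptkit_data_error",
                                             "error", "condition")))
}

#' Build a validated pipeline configuration
#'
#' Normalizes and checks the configuration driving [run_pipeline()]:
#' either file-based input (`bin_matrices` + `controls` TSV paths, an
#' optional `gc_track`) or a `simulate` block of [sim_config()] fields;
#' an ordered subset of corrections (at most one GC method, order
#' normalized to peak -> GC -> chi-squared); prediction methods; target
#' chromosomes; thresholds; a seed and an output directory.
#'
#' @param x A named list or the path of a YAML/JSON config file.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) config_error("config file not found: ", x)
    x <- if (grepl("\\.json$", x)) jsonlite::read_json(x, simplifyVector = TRUE)
         else yaml::read_yaml(x)
  }
  if (!is.list(x)) config_error("config must be a list or a config file path")
  cfg <- list(
    seed = x$seed,
    out_dir = x$out_dir,
    input = x$input,
    simulate = x$simulate,
    corrections = as.character(x$corrections %||% character()),
    methods = as.character(x$methods %||% c("zscore", "mad_z", "ncv", "rbz")),
    targets = as.integer(x$targets %||% c(13L, 18L, 21L)),
    match_qc = isTRUE(x$match_qc %||% TRUE),
    compare = isTRUE(x$compare %||% FALSE),
    write_corrected = isTRUE(x$write_corrected %||% FALSE),
    thresholds = utils::modifyList(
      list(z_call = 3, z_threshold = 3.5, sd_threshold = 1.96,
           consistency = 0.95, span = 0.75, degree = 2,
           gc_interval_width = 0.001, ncv_max_denominator = 4),
      as.list(x$thresholds %||% list())))
  known <- c("peak", "gc_bin", "gc_loess", "chi2vr")
  bad <- setdiff(cfg$corrections, known)
  if (length(bad))
    config_error("unknown correction(s): ", paste(bad, collapse = ", "))
  if (all(c("gc_bin", "gc_loess") %in% cfg$corrections))
    config_error("a maximum of one GC-correction method may be used")
  cfg$corrections <- known[known %in% cfg$corrections]
  badm <- setdiff(cfg$methods, c("zscore", "mad_z", "ncv", "rbz"))
  if (length(badm))
    config_error("unknown method(s): ", paste(badm, collapse = ", "))
  if (!all(cfg$targets %in% 1:22))
    config_error("targets must be autosomes 1-22")
  if (is.null(cfg$seed)) config_error("config needs a seed")
  if (is.null(cfg$input) && is.null(cfg$simulate))
    config_error("config needs either an 'input' or a 'simulate' block")
  if (!is.null(cfg$input)) {
    if (is.null(cfg$input$controls) || length(cfg$input$controls) < 3L)
      config_error("input$controls must list at least 3 bin-matrix files")
    if (any(c("gc_bin", "gc_loess") %in% cfg$corrections) &&
        is.null(cfg$input$gc_track))
      config_error("GC correction requested but input$gc_track missing")
  }
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Control-group CV comparison across correction combinations
#'
#' The engine behind correction/prediction benchmark figures: for every
#' combination of zero or more of the requested corrections (at most one
#' GC method, canonical order) and every requested prediction method and
#' target chromosome, reports the control-group CV and Shapiro-Wilk
#' p-value of the method's control statistic (fraction CV for the
#' standard and MAD Z-scores, selected-denominator ratio CV for NCV,
#' observed/expected ratio spread for RBZ).
#'
#' @param controls A [control_group()] or sample list (uncorrected).
#' @param gc A [gc_track()] (required if a GC method is in the pool).
#' @param targets Integer target chromosomes.
#' @param methods Subset of `c("zscore","mad_z","ncv","rbz")`.
#' @param corrections_pool Corrections whose combinations are explored.
#' @param thresholds Named list of tuning parameters (see
#'   [pipeline_config()]).
#' @return `data.frame` with columns `corrections`, `target`, `method`,
#'   `cv`, `shapiro_p`.
#' @export
cv_comparison_table <- function(controls, gc = NULL,
                                targets = c(13L, 18L, 21L),
                                methods = c("zscore", "mad_z", "ncv", "rbz"),
                                corrections_pool = c("gc_loess", "chi2vr"),
                                thresholds = list()) {
  controls <- as_control_group(controls)
  th <- utils::modifyList(
    list(z_threshold = 3.5, sd_threshold = 1.96, consistency = 0.95,
         span = 0.75, degree = 2, gc_interval_width = 0.001,
         ncv_max_denominator = 4), thresholds)
  pool <- unique(corrections_pool)
  combos <- list(character())
  for (co in pool)
    combos <- c(combos, lapply(combos, function(x) c(x, co)))
  combos <- Filter(function(x) !all(c("gc_bin", "gc_loess") %in% x), combos)

  rows <- list()
  for (combo in combos) {
    corrected <- apply_corrections(
      controls, list(), corrections = combo, gc = gc,
      z_threshold = th$z_threshold, sd_threshold = th$sd_threshold,
      consistency = th$consistency, span = th$span, degree = th$degree,
      gc_interval_width = th$gc_interval_width)$controls
    label <- if (length(combo)) paste(combo, collapse = "+") else "none"
    for (tgt in targets) {
      for (m in methods) {
        stat <- switch(m,
          zscore = {
            x <- control_cv(corrected, tgt)
            c(x$cv, x$shapiro_p)
          },
          mad_z = {
            of <- .fractions(corrected$samples, tgt)
            med <- stats::median(of)
            c(1.4826 * stats::median(abs(of - med)) / med, .shapiro_p(of))
          },
          ncv = {
            mod <- ncv_train(corrected, tgt,
                             max_denominator_size = th$ncv_max_denominator)
            of <- .fractions(corrected$samples, tgt, mod$denominator)
            c(mod$cv_train, .shapiro_p(of))
          },
          rbz = {
            mod <- rbz_train(corrected, tgt)
            c(mod$sets[[1L]]$residual_ratio_sd, NA_real_)
          })
        rows[[length(rows) + 1L]] <- data.frame(
          corrections = label, target = tgt, method = m,
          cv = stat[[1L]], shapiro_p = stat[[2L]])
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the whole flow deterministically from a config: load (or
#' simulate) binned controls and samples, apply the configured
#' variation-reduction steps in canonical order, compute Match QC
#' reports against the corrected controls, run the requested trisomy
#' predictors for every target chromosome, optionally produce the CV
#' comparison table, and write all result tables (TSV/JSON, carrying the
#' correction trail and a config hash) into `out_dir`.
#'
#' @param config A [pipeline_config()], a named list, or a config file
#'   path.
#' @return Invisibly, a list with `results` (list of `trisomy_result`),
#'   `results_table`, `match_qc`, `cv_table`, `controls`, `samples`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  if (!is.null(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  gc_trk <- NULL
  if (!is.null(cfg$input)) {
    load_one <- function(p) tryCatch(read_bin_matrix(p),
                                     error = function(e)
                                       data_error(conditionMessage(e)))
    controls <- control_group(lapply(cfg$input$controls, load_one),
                              description = "file input")
    samples <- lapply(cfg$input$bin_matrices %||% character(), load_one)
    if (!is.null(cfg$input$gc_track))
      gc_trk <- tryCatch(read_gc_track(cfg$input$gc_track),
                         error = function(e)
                           data_error(conditionMessage(e)))
  } else {
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    sim <- simulate_cohort(do.call(sim_config, sim_args))
    controls <- sim$controls
    samples <- sim$cases
    gc_trk <- sim$gc
  }

  th <- cfg$thresholds
  raw_controls <- controls
  corrected <- apply_corrections(
    controls, samples, corrections = cfg$corrections, gc = gc_trk,
    z_threshold = th$z_threshold, sd_threshold = th$sd_threshold,
    consistency = th$consistency, span = th$span, degree = th$degree,
    gc_interval_width = th$gc_interval_width)
  controls <- corrected$controls
  samples <- corrected$targets

  match_qc <- NULL
  if (cfg$match_qc && length(samples)) {
    cutoff <- calibrate_cutoff(controls)
    match_qc <- lapply(samples, match_qc_overall, controls = controls,
                       cutoff = as.numeric(cutoff))
  }

  results <- list()
  if (length(samples)) {
    for (tgt in cfg$targets) {
      for (m in cfg$methods) {
        res <- switch(m,
          zscore = standard_zscore(samples, controls, tgt,
                                   z_call = th$z_call),
          mad_z = mad_zscore(samples, controls, tgt, z_call = th$z_call),
          ncv = {
            mod <- ncv_train(controls, tgt,
                             max_denominator_size = th$ncv_max_denominator)
            ncv_zscore(samples, controls, tgt, mod, z_call = th$z_call)
          },
          rbz = {
            mod <- rbz_train(controls, tgt)
            rbz_zscore(samples, controls, mod, z_call = th$z_call)
          })
        results <- c(results, res)
      }
    }
  }

  cv_table <- NULL
  if (cfg$compare)
    cv_table <- cv_comparison_table(
      raw_controls, gc = gc_trk,
      targets = cfg$targets, methods = cfg$methods,
      corrections_pool = if (length(cfg$corrections)) cfg$corrections
                         else c("gc_loess", "chi2vr"),
      thresholds = th)

  results_table <- NULL
  if (!is.null(cfg$out_dir)) {
    cfg_plain <- unclass(cfg)
    cfg_json <- file.path(cfg$out_dir, "config.json")
    jsonlite::write_json(cfg_plain, cfg_json, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    # hash identifies the analysis, not where it is written
    hash_tmp <- tempfile(fileext = ".json")
    jsonlite::write_json(cfg_plain[setdiff(names(cfg_plain), "out_dir")],
                         hash_tmp, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    cfg_md5 <- unname(tools::md5sum(hash_tmp))
    unlink(hash_tmp)
    provenance <- c(
      paste0("config_md5: ", cfg_md5),
      paste0("correction_trail: ",
             paste(controls$correction_trail, collapse = ",")))
    writeLines(provenance, file.path(cfg$out_dir, "provenance.txt"))
    if (length(results)) {
      results_table <- file.path(cfg$out_dir, "results.tsv")
      write_results_table(results, results_table)
    }
    if (!is.null(match_qc)) {
      qc_df <- do.call(rbind, lapply(match_qc, function(q)
        data.frame(sample_id = q$sample_id,
                   overall_score = q$overall_score,
                   cutoff = q$cutoff, passed = q$passed)))
      utils::write.table(qc_df, file.path(cfg$out_dir, "match_qc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        lapply(match_qc, function(q) q[c("sample_id", "overall_score",
                                         "cutoff", "passed")]),
        file.path(cfg$out_dir, "match_qc.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    if (!is.null(cv_table))
      utils::write.table(cv_table, file.path(cfg$out_dir,
                                             "cv_comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (cfg$write_corrected) {
      mat_dir <- file.path(cfg$out_dir, "corrected")
      dir.create(mat_dir, showWarnings = FALSE)
      for (s in c(controls$samples, samples))
        write_bin_matrix(s, file.path(mat_dir,
                                      paste0(s$sample_id, ".tsv")))
    }
  }

  invisible(list(results = results, results_table = results_table,
                 match_qc = match_qc, cv_table = cv_table,
                 controls = controls, samples = samples,
                 out_dir = cfg$out_dir))
}
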