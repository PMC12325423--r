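#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis so a run is fully described
#' by one object (and its log): preprocessing, thin-limit selection, fit
#' options, factor sweep range and diagnostics settings.
#'
#' @param manifest data.frame of sample records (see [sample_records()]);
#'   must carry `eem_path` unless in-memory EEMs are passed to
#'   [run_pipeline()].
#' @param blank an [eem()], a path to one, or `NULL` to skip subtraction.
#' @param scatter a [scatter_band_config()].
#' @param thin_threshold thin-limit DF cutoff (default 0.0025).
#' @param overrides sample ids kept despite exceeding the threshold.
#' @param fit a [fit_options()].
#' @param F_range factor counts to sweep (default 1:7).
#' @param window_fraction discrepancy-map window (default 0.10).
#' @param score_level equal-score comparison level (default 1000).
#' @param reference_source source id used as the concentration-ratio
#'   denominator, or `NULL` to skip ratio estimation.
#' @param outdir output directory, or `NULL` for an in-memory run.
#' @param seed master seed (propagated into `fit`).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(manifest, blank = NULL,
                            scatter = scatter_band_config(),
                            thin_threshold = 0.0025,
                            overrides = character(0),
                            fit = fit_options(),
                            F_range = 1:7,
                            window_fraction = 0.10,
                            score_level = 1000,
                            reference_source = NULL,
                            outdir = NULL,
                            seed = 1L) {
  stopifnot(is.data.frame(manifest))
  if (nrow(manifest) == 0L) stop("manifest is empty", call. = FALSE)
  fit$seed <- as.integer(seed)
  structure(list(manifest = manifest, blank = blank, scatter = scatter,
                 thin_threshold = thin_threshold, overrides = overrides,
                 fit = fit, F_range = F_range,
                 window_fraction = window_fraction, score_level = score_level,
                 reference_source = reference_source, outdir = outdir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

load_pipeline_eems <- function(config, eems) {
  records <- sample_records(config$manifest)
  if (is.null(eems)) {
    if (!"eem_path" %in% names(records))
      stop("manifest lacks eem_path and no in-memory EEMs were given",
           call. = FALSE)
    eems <- lapply(records$eem_path, read_eem)
    names(eems) <- records$sample_id
  } else {
    missing <- setdiff(records$sample_id, names(eems))
    if (length(missing))
      stop(sprintf("no EEM supplied for sample(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    eems <- eems[records$sample_id]
  }
  blank <- config$blank
  if (is.character(blank)) blank <- read_eem(blank)
  list(records = records, eems = eems, blank = blank)
}

#' Run the full EEM-PARAFAC pipeline
#'
#' Stages: preprocess every EEM (blank subtraction, scatter excision, gap
#' interpolation), select thin-limit samples, stack them, sweep the factor
#' count, pick the working model via [choose_factor_count()], and compute
#' diagnostics (discrepancy maps with RMA regression,
#' per-sample RMSE, score-DF curves and, when a reference source is set,
#' equal-score concentration ratios). With `config$outdir` set, all tables
#' are written as CSV, the discrepancy maps as EEM-format CSVs, and a run
#' log of the effective parameters; a `RUN_COMPLETE` marker is written last
#' so aborted runs are recognisable.
#'
#' @param config a [pipeline_config()].
#' @param eems optional named list of in-memory [eem()]s (by `sample_id`),
#'   bypassing `eem_path` reads.
#' @return A list of class `"pipeline_result"`: `records`, `selection`,
#'   `tensor`, `sweep`, `best_F`, `model`, `diagnostics` (list with `maps`,
#'   `per_sample`, `curves`, `ratios`), `log` (character).
#' @export
run_pipeline <- function(config, eems = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  inp <- load_pipeline_eems(config, eems)
  say("samples: %d", nrow(inp$records))
  say("scatter bands: R1 +%g/-%g, R2 +%g/-%g, Rm1 +%g/-%g, Rm2 +%g/-%g, shift %g cm-1",
      config$scatter$rayleigh1$above, config$scatter$rayleigh1$below,
      config$scatter$rayleigh2$above, config$scatter$rayleigh2$below,
      config$scatter$raman1$above, config$scatter$raman1$below,
      config$scatter$raman2$above, config$scatter$raman2$below,
      config$scatter$raman_shift)
  pre <- lapply(seq_along(inp$eems), function(i) {
    tryCatch(preprocess_eem(inp$eems[[i]], inp$blank, config$scatter),
             error = function(e)
               stop(sprintf("preprocess failed for sample '%s': %s",
                            inp$records$sample_id[i], conditionMessage(e)),
                    call. = FALSE))
  })
  names(pre) <- inp$records$sample_id
  sel <- select_thin_limit(inp$records, config$thin_threshold, config$overrides)
  say("thin limit DF <= %g: kept %d of %d (%d override(s))",
      config$thin_threshold, nrow(sel$included), nrow(inp$records),
      sum(sel$report$reason == "override"))
  if (nrow(sel$included) == 0L)
    stop("selection stage kept no samples", call. = FALSE)
  tensor <- stack_eems(pre[sel$included$sample_id], sel$included)
  sweep <- model_sweep(tensor, config$F_range, config$fit)
  best_F <- choose_factor_count(sweep$table)
  model <- sweep$models[[as.character(best_F)]]
  say("best F = %d (core consistency %.1f%%, RSS %.4g)", best_F,
      model$core_consistency, model$rss)
  maps <- discrepancy_maps(tensor, reconstruct_parafac(model),
                           window_fraction = config$window_fraction,
                           em = tensor$em, ex = tensor$ex)
  persample <- per_sample_fit(model, tensor)
  curves <- score_df_curves(model)
  ratios <- NULL
  if (!is.null(config$reference_source)) {
    f1 <- Filter(function(cv) cv$factor_id == 1L, curves$curves)
    ratios <- tryCatch(
      concentration_ratio_at_score(f1, config$score_level,
                                   config$reference_source),
      error = function(e) { say("ratio estimation skipped: %s",
                                conditionMessage(e)); NULL })
  }
  res <- structure(list(records = inp$records, selection = sel,
                        preprocessed = pre, tensor = tensor, sweep = sweep,
                        best_F = best_F, model = model,
                        diagnostics = list(maps = maps, per_sample = persample,
                                           curves = curves, ratios = ratios),
                        log = log, config = config),
                   class = "pipeline_result")
  if (!is.null(config$outdir)) write_pipeline_result(res, config$outdir)
  res
}

write_pipeline_result <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  w(res$sweep$table, "sweep.csv")
  w(res$selection$report, "exclusion_report.csv")
  m <- res$model
  loadB <- data.frame(emission_nm = m$em, m$B)
  names(loadB)[-1L] <- sprintf("factor%d", seq_len(m$F))
  w(loadB, "loadings_emission.csv")
  loadC <- data.frame(excitation_nm = m$ex, m$C)
  names(loadC)[-1L] <- sprintf("factor%d", seq_len(m$F))
  w(loadC, "loadings_excitation.csv")
  sc <- data.frame(sample_id = m$samples$sample_id, DF = m$samples$DF, m$A)
  names(sc)[-(1:2)] <- sprintf("factor%d", seq_len(m$F))
  w(sc, "scores.csv")
  w(res$diagnostics$per_sample, "per_sample_fit.csv")
  maps <- res$diagnostics$maps
  for (nm in c("bias", "rmse", "sd"))
    write_eem(eem(ex = maps$ex, em = maps$em, x = maps[[nm]]),
              file.path(outdir, sprintf("discrepancy_%s.csv", nm)))
  if (!is.null(res$diagnostics$ratios))
    w(data.frame(source_id = names(res$diagnostics$ratios),
                 ratio = as.numeric(res$diagnostics$ratios)),
      "concentration_ratios.csv")
  summary_lines <- c(res$log,
                     sprintf("rma slope %.6g intercept %.6g r2 %.6g",
                             maps$rma$slope, maps$rma$intercept, maps$rma$r2),
                     sprintf("seed %d", res$config$seed))
  writeLines(summary_lines, file.path(outdir, "run_log.txt"))
  writeLines("complete", file.path(outdir, "RUN_COMPLETE"))
  invisible(outdir)
}

#' Fit sweeps on named sample subsets
#'
#' Runs the preprocessing and thin-limit selection once, then fits a factor
#' sweep per named subset (e.g. LAB only, LAB+rivers, all samples) and
#' reports factor matching of each subset's best model against the first
#' subset's, tracking factor persistence as datasets grow.
#'
#' @param config a [pipeline_config()].
#' @param subsets named list of character vectors of `sample_id`s.
#' @param eems optional in-memory EEMs as in [run_pipeline()].
#' @return List of class `"subset_runs"`: per subset, `sweep`, `best_F`,
#'   `model`; plus `matching` (vs the first subset).
#' @export
subset_runs <- function(config, subsets, eems = NULL) {
  stopifnot(inherits(config, "pipeline_config"),
            is.list(subsets), length(subsets) >= 1, !is.null(names(subsets)))
  inp <- load_pipeline_eems(config, eems)
  unknown <- setdiff(unique(unlist(subsets)), inp$records$sample_id)
  if (length(unknown))
    stop(sprintf("unknown sample id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  pre <- lapply(inp$eems, preprocess_eem, blank = inp$blank,
                config = config$scatter)
  names(pre) <- inp$records$sample_id
  out <- list()
  for (nm in names(subsets)) {
    ids <- subsets[[nm]]
    recs <- inp$records[inp$records$sample_id %in% ids, , drop = FALSE]
    sel <- select_thin_limit(recs, config$thin_threshold, config$overrides)
    if (nrow(sel$included) < 2L)
      stop(sprintf("subset '%s' keeps fewer than 2 samples", nm), call. = FALSE)
    tensor <- stack_eems(pre[sel$included$sample_id], sel$included)
    sweep <- model_sweep(tensor, config$F_range, config$fit)
    best_F <- choose_factor_count(sweep$table)
    out[[nm]] <- list(sweep = sweep, best_F = best_F,
                      model = sweep$models[[as.character(best_F)]])
  }
  ref <- out[[1L]]$model
  matching <- lapply(out[-1L], function(o) match_factors(ref, o$model))
  structure(c(out, list(matching = matching)), class = "subset_runs")
}
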