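#' Read and write cohort tables
#'
#' Tab-delimited text with one header row; columns `subject_id`, `age`,
#' `sex`, `dominance`, `fma_2w`, `fma_3m`, `mep_status`, `cortical_flag`
#' (plus any extras such as `side`). `read_cohort` validates presence and
#' numeric parsing of the required columns and reports the offending column
#' on failure.
#'
#' @param records cohort data frame.
#' @param path file path.
#' @return `read_cohort` returns the validated data frame.
#' @export
write_cohort <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("subject_id", "age", "sex", "dominance", "fma_2w",
                "fma_3m", "mep_status", "cortical_flag")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cohort table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  numeric_cols <- c("age", "sex", "dominance", "fma_2w", "fma_3m",
                    "cortical_flag")
  for (cn in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (any(is.na(v) & !is.na(df[[cn]])))
      stop("parse error in column '", cn, "': non-numeric value '",
           df[[cn]][which(is.na(v))[1]], "'", call. = FALSE)
    df[[cn]] <- v
  }
  for (cn in intersect(c("fma_2w", "fma_3m"), names(df)))
    df[[cn]] <- as.integer(df[[cn]])
  bad <- !df$mep_status %in% c("positive", "negative", "unmeasured")
  if (any(bad))
    stop("parse error in column 'mep_status': '", df$mep_status[bad][1],
         "'", call. = FALSE)
  df
}

#' Write / read a delimited results table
#'
#' @param df data frame.
#' @param path file path (tab-delimited text with header).
#' @return `read_results` returns the data frame.
#' @export
write_results <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Damage-measure table for a cohort
#'
#' Computes the six structural damage measures for every subject: the
#' control CST territory (average over controls) and disconnectomes are
#' derived from the control streamline sets, the patient CST territory from
#' each subject's own streamlines. Loads and volumes are in weighted mm^3.
#'
#' @param cohort a [synthetic_cohort] (or any list with `records`,
#'   `imaging`, `patient_streamlines`, `config`).
#' @param control_sets list of control [streamline_set].
#' @param geometry optional [phantom_geometry]; derived from the cohort
#'   config by default.
#' @param weighted_fa passed to [compute_fa_asymmetry].
#' @return data frame: `subject_id` plus the six measure columns.
#' @export
cohort_damage_measures <- function(cohort, control_sets, geometry = NULL,
                                   weighted_fa = TRUE) {
  cfg <- cohort$config
  if (is.null(geometry))
    geometry <- phantom_geometry(cfg$grid_shape, cfg$voxel_size)
  grid <- geometry$waypoints$left[[1]]
  indexed_controls <- lapply(control_sets, index_streamlines, grid = grid)
  control_terr <- control_cst_territory(indexed_controls,
                                        geometry$waypoints)
  rows <- lapply(cohort$records$subject_id, function(id) {
    pat_terr <- patient_cst_territory(
      index_streamlines(cohort$patient_streamlines[[id]], grid),
      geometry$waypoints)
    m <- compute_all_measures(cohort$imaging[[id]], pat_terr, control_terr,
                              indexed_controls, weighted_fa = weighted_fa)
    cbind(data.frame(subject_id = id, stringsAsFactors = FALSE),
          as.data.frame(m))
  })
  do.call(rbind, rows)
}

#' Fit the model family under every stratification strategy
#'
#' Merges records, measures and stratum labels, then fits the 13-model
#' family to the whole group and to each stratum of each strategy.
#' Unmeasured subjects are excluded from the neurophysiological strategy
#' (but kept everywhere else); strata too small for a model produce skipped
#' rows.
#'
#' @param records cohort data frame (see [read_cohort]).
#' @param measures damage-measure table (see [cohort_damage_measures]).
#' @param strata stratum assignments (see [assign_strata]).
#' @return list with `results` (named: `whole` = results table; each
#'   strategy = named list of per-stratum results tables), `fits` (same
#'   shape, holding [model_fit] lists) and `data` (the merged analysis
#'   table).
#' @export
fit_all_strategies <- function(records, measures, strata) {
  data <- merge(merge(records, measures, by = "subject_id"),
                strata, by = "subject_id")
  data <- data[order(data$subject_id), , drop = FALSE]
  strategies <- c("initial_impairment", "lesion_location",
                  "neurophysiological", "proportional_recovery")
  whole <- fit_stratum_models(data)
  results <- list(whole = whole$results)
  fits <- list(whole = whole$fits)
  for (strat in strategies) {
    lvls <- levels(factor(data[[strat]]))
    lvls <- setdiff(lvls, "unmeasured")
    res_l <- fit_l <- list()
    for (lv in lvls) {
      sub <- data[data[[strat]] == lv, , drop = FALSE]
      if (nrow(sub) == 0L) next
      f <- fit_stratum_models(sub)
      res_l[[lv]] <- f$results
      fit_l[[lv]] <- f$fits
    }
    results[[strat]] <- res_l
    fits[[strat]] <- fit_l
  }
  list(results = results, fits = fits, data = data)
}

flatten_results <- function(results) {
  rows <- list()
  add <- function(strategy, stratum, tab) {
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(strategy = strategy, stratum = stratum,
                 stringsAsFactors = FALSE), tab)
  }
  add("whole", "all", results$whole)
  for (strat in setdiff(names(results), "whole"))
    for (lv in names(results[[strat]]))
      add(strat, lv, results[[strat]][[lv]])
  do.call(rbind, rows)
}

#' Run the full stratified-prediction pipeline
#'
#' Simulate -> measures -> stratify -> fit -> report: generates a synthetic
#' cohort and control streamlines, computes the six damage measures,
#' assigns the four stratification strategies, fits the 13-model family per
#' stratum, and aggregates best-model errors into the stratified summary
#' table. Fully deterministic given `config$seed`.
#'
#' @param config a [synthetic_config].
#' @param params a [prr_parameters].
#' @param out_dir optional directory; when given, the cohort table, measures
#'   table, stratum assignments, per-model fit table, summary table and a
#'   machine-readable JSON summary are written there as delimited text.
#' @param mep_denominator passed to [build_table3].
#' @return list with `cohort`, `measures`, `strata`, `fits` (see
#'   [fit_all_strategies]), `model_table` (flat per-model results),
#'   `table3` (per-stratum best models) and `aggregates` (per-strategy
#'   overall MSEs and percentages).
#' @export
run_pipeline <- function(config = synthetic_config(),
                         params = prr_parameters(), out_dir = NULL,
                         mep_denominator = "measured") {
  cohort <- generate_cohort(config)
  controls <- generate_control_streamlines(config)
  measures <- cohort_damage_measures(cohort, controls)
  strata <- assign_strata(cohort$records, params)
  fitted <- fit_all_strategies(cohort$records, measures, strata)
  t3 <- build_table3(fitted$results, mep_denominator = mep_denominator)
  model_table <- flatten_results(fitted$results)

  out <- list(cohort = cohort, measures = measures, strata = strata,
              fits = fitted, model_table = model_table,
              table3 = t3$table, aggregates = t3$aggregates)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort$records, file.path(out_dir, "cohort.tsv"))
    write_results(measures, file.path(out_dir, "measures_mm3.tsv"))
    write_results(strata, file.path(out_dir, "strata.tsv"))
    write_results(model_table, file.path(out_dir, "model_fits.tsv"))
    write_results(t3$table, file.path(out_dir, "best_models.tsv"))
    write_results(t3$aggregates, file.path(out_dir, "overall_mse.tsv"))
    jsonlite::write_json(
      list(seed = config$seed,
           n_patients = config$n_patients,
           n_controls = config$n_controls,
           package_version = as.character(
             utils::packageVersion("strokestrat")),
           aggregates = t3$aggregates),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}
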