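TREND_HEADER <- "time_s,icp_mmhg,map_mmhg,amp_mmhg,valid"

#' Write a trend series to CSV
#'
#' Interchange format: header `time_s,icp_mmhg,map_mmhg,amp_mmhg,valid`,
#' `valid` coded 0/1, absent channels written as empty fields. Numeric cells
#' are printed with 17 significant digits so the write-read round trip is
#' lossless for doubles.
#'
#' @param series a [trend_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trend_csv <- function(series, path) {
  stopifnot(inherits(series, "trend_series"))
  n <- length(series)
  tt <- series$t0 + (seq_len(n) - 1) * series$sample_interval_s
  fmt <- function(x) if (is.null(x)) rep("", n) else sprintf("%.17g", x)
  lines <- paste(sprintf("%.17g", tt), fmt(series$icp), fmt(series$map),
                 fmt(series$amp), as.integer(series$valid), sep = ",")
  writeLines(c(TREND_HEADER, lines), path)
  invisible(path)
}

parse_numeric_column <- function(x, name, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !(is.na(x) | x == ""))
  if (length(bad))
    stop(sprintf("%s: non-numeric value in column '%s' at line %d",
                 path, name, bad[1] + 1L), call. = FALSE)
  out
}

#' Read a trend series from CSV
#'
#' Validates the exact header, strictly increasing time and uniform sample
#' spacing (tolerance 1e-6 s). A channel whose column is entirely empty
#' loads as absent; indices that need it then fail with a clear error
#' rather than being silently imputed.
#'
#' @param path CSV file written by [write_trend_csv()] (or an equivalent
#'   monitor export).
#' @return a [trend_series()].
#' @export
read_trend_csv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!identical(header, TREND_HEADER))
    stop(sprintf("%s: line 1: expected header '%s'", path, TREND_HEADER),
         call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  if (nrow(df) == 0L) stop(sprintf("%s: no data rows", path), call. = FALSE)
  tt <- parse_numeric_column(df$time_s, "time_s", path)
  if (anyNA(tt)) stop(sprintf("%s: missing time value at line %d",
                              path, which(is.na(tt))[1] + 1L), call. = FALSE)
  if (length(tt) > 1L) {
    dts <- diff(tt)
    if (any(dts <= 0))
      stop(sprintf("%s: time not strictly increasing at line %d",
                   path, which(dts <= 0)[1] + 2L), call. = FALSE)
    if (max(dts) - min(dts) > 1e-6)
      stop(sprintf("%s: non-uniform sample spacing (%.9g vs %.9g s)",
                   path, min(dts), max(dts)), call. = FALSE)
    dt <- stats::median(dts)
  } else dt <- 1
  load_channel <- function(col, name) {
    if (all(is.na(df[[col]]) | df[[col]] == "")) return(NULL)
    x <- parse_numeric_column(df[[col]], name, path)
    if (anyNA(x))
      stop(sprintf("%s: missing value in column '%s' at line %d",
                   path, name, which(is.na(x))[1] + 1L), call. = FALSE)
    x
  }
  icp <- load_channel("icp_mmhg", "icp_mmhg")
  if (is.null(icp)) stop(sprintf("%s: ICP column is empty", path), call. = FALSE)
  vr <- parse_numeric_column(df$valid, "valid", path)
  if (anyNA(vr) || !all(vr %in% c(0, 1)))
    stop(sprintf("%s: column 'valid' must be 0/1", path), call. = FALSE)
  trend_series(icp = icp,
               map = load_channel("map_mmhg", "map_mmhg"),
               amp = load_channel("amp_mmhg", "amp_mmhg"),
               valid = vr == 1,
               sample_interval_s = dt, t0 = tt[1])
}

#' Write / read a cohort covariate table
#' @param covariates data.frame from [cohort_covariates()].
#' @param path CSV path.
#' @return `path` invisibly / the data.frame.
#' @export
write_covariates_csv <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_covariates_csv
#' @export
read_covariates_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' End-to-end pipeline configuration
#'
#' Bundles the cohort specification, index parameters, the per-variable test
#' assignment and the ROC settings. Unknown names in `tests` or
#' `roc_directions` are rejected at [run_pipeline()] time.
#'
#' @param cohort a [cohort_spec()].
#' @param segment_hours,threshold,prx_window_s,rap_window_s,corr_step_s,min_valid_fraction,min_window_valid
#'   index-engine parameters; see [hourly_indices()].
#' @param tests variable -> test map; see [default_table1_tests()].
#' @param roc_directions variable -> direction; see
#'   [default_roc_directions()].
#' @param ci_method,level AUC confidence-interval settings.
#' @param write_trends also write each patient's full trend CSV (off by
#'   default; 3-day recordings are large).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            segment_hours = 1, threshold = 20,
                            prx_window_s = 300, rap_window_s = 240,
                            corr_step_s = 60,
                            min_valid_fraction = 0.5, min_window_valid = 0.75,
                            tests = default_table1_tests(),
                            roc_directions = default_roc_directions(),
                            ci_method = "delong", level = 0.95,
                            write_trends = FALSE) {
  structure(list(cohort = cohort, segment_hours = segment_hours,
                 threshold = threshold, prx_window_s = prx_window_s,
                 rap_window_s = rap_window_s, corr_step_s = corr_step_s,
                 min_valid_fraction = min_valid_fraction,
                 min_window_valid = min_window_valid,
                 tests = tests, roc_directions = roc_directions,
                 ci_method = ci_method, level = level,
                 write_trends = write_trends),
            class = "pipeline_config")
}

#' Hash of the semantically meaningful pipeline configuration
#' @param config a [pipeline_config()].
#' @return md5 hex string; changes iff a meaningful field changes.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config), control = "exact"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' simulate -> hourly indices -> patient aggregation -> baseline comparison
#' table -> ROC ranking, with every stage output written as CSV under
#' `out_dir` plus a human-readable report and a JSON run log (timestamp,
#' config hash, master seed, per-stage record counts, and every excluded
#' patient or dropped segment with its reason). Deterministic: the same
#' config produces bitwise-identical CSVs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `covariates`, `hourly`, `patients`,
#'   `table1`, `roc`, `log`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()

  cohort <- simulate_cohort(config$cohort)
  cov <- cohort_covariates(cohort)
  write_covariates_csv(cov, file.path(out_dir, "covariates.csv"))
  if (isTRUE(config$write_trends)) {
    tdir <- file.path(out_dir, "trends")
    dir.create(tdir, showWarnings = FALSE)
    for (r in cohort)
      write_trend_csv(r$series, file.path(tdir, paste0(r$patient_id, ".csv")))
  }

  hourly_all <- list()
  dropped_segments <- 0L
  for (r in cohort) {
    hi <- hourly_indices(r$series, segment_hours = config$segment_hours,
                         threshold = config$threshold,
                         prx_window_s = config$prx_window_s,
                         rap_window_s = config$rap_window_s,
                         corr_step_s = config$corr_step_s,
                         min_valid_fraction = config$min_valid_fraction,
                         min_window_valid = config$min_window_valid)
    dropped_segments <- dropped_segments + sum(!is.finite(hi$mean_icp))
    hourly_all[[r$patient_id]] <- cbind(patient_id = r$patient_id, hi)
  }
  hourly_df <- do.call(rbind, c(hourly_all, make.row.names = FALSE))
  write_indices_csv(hourly_df, file.path(out_dir, "hourly_indices.csv"))

  excluded <- list()
  patient_rows <- lapply(cohort, function(r) {
    hi <- hourly_all[[r$patient_id]]
    pi_ <- withCallingHandlers(patient_indices(hi),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(pi_)) {
      excluded[[length(excluded) + 1L]] <<- list(
        patient_id = r$patient_id,
        reason = "no segment reached the minimum valid fraction")
      return(NULL)
    }
    cbind(data.frame(patient_id = r$patient_id, group = r$group,
                     age = r$age, sex = r$sex, gcs = r$gcs,
                     hematoma_ml = r$hematoma_ml, gos = r$gos), pi_)
  })
  patients <- do.call(rbind, patient_rows[!vapply(patient_rows, is.null,
                                                  logical(1))])
  if (is.null(patients) || nrow(patients) == 0L)
    stop("comparison stage: no analysable patients ",
         "(every segment fell below the minimum valid fraction)",
         call. = FALSE)
  write_indices_csv(patients, file.path(out_dir, "patient_indices.csv"))

  table1 <- build_table1(patients, config$tests)
  utils::write.csv(as.data.frame(table1),
                   file.path(out_dir, "table1.csv"), row.names = FALSE)
  roc_tab <- rank_predictors(patients, config$roc_directions,
                             ci_method = config$ci_method,
                             level = config$level)
  utils::write.csv(roc_tab, file.path(out_dir, "roc_summary.csv"),
                   row.names = FALSE)
  for (cv in attr(roc_tab, "curves"))
    utils::write.csv(cv$curve,
                     file.path(out_dir, sprintf("roc_points_%s.csv",
                                                cv$variable)),
                     row.names = FALSE)
  write_report(table1, roc_tab, file.path(out_dir, "report.txt"))

  log <- list(
    timestamp = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = config_hash(config),
    master_seed = config$cohort$seed,
    n_patients = length(cohort),
    n_patients_analysed = nrow(patients),
    n_segments_total = nrow(hourly_df),
    n_segments_dropped = dropped_segments,
    excluded_patients = excluded,
    warnings = if (dropped_segments > 0)
      sprintf("%d segment(s) below the minimum valid fraction",
              dropped_segments) else character(0))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(covariates = cov, hourly = hourly_df, patients = patients,
                 table1 = table1, roc = roc_tab, log = log))
}

# Missing values serialize as empty fields, never 0.
write_indices_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

write_report <- function(table1, roc_tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sink(con)
  print(table1)
  cat("\nPrognostic discrimination (poor outcome), by AUC:\n")
  for (i in seq_len(nrow(roc_tab)))
    cat(sprintf("  %-12s AUC %.3f (95%% CI %.3f-%.3f, %s, %s)\n",
                roc_tab$variable[i], roc_tab$auc[i], roc_tab$ci_low[i],
                roc_tab$ci_high[i], roc_tab$ci_method[i],
                roc_tab$direction[i]))
  sink()
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Mirrors the [pipeline_config()] / [cohort_spec()] / [group_spec()] /
#' [sim_config()] fields one-to-one in nested blocks (`cohort:` with
#' `good:`/`poor:` each optionally holding a `sim:` block). Unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known_top <- c("cohort", "segment_hours", "threshold", "prx_window_s",
                 "rap_window_s", "corr_step_s", "min_valid_fraction",
                 "min_window_valid", "tests", "roc_directions", "ci_method",
                 "level", "write_trends")
  unknown <- setdiff(names(y), known_top)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  build_group <- function(g, default) {
    if (is.null(g)) return(default)
    known_g <- setdiff(names(formals(group_spec)), "sim")
    unknown <- setdiff(names(g), c(known_g, "sim"))
    if (length(unknown))
      stop(sprintf("unknown group key(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    sim <- if (is.null(g$sim)) default$sim else {
      unknown_s <- setdiff(names(g$sim), names(formals(sim_config)))
      if (length(unknown_s))
        stop(sprintf("unknown sim key(s): %s",
                     paste(unknown_s, collapse = ", ")), call. = FALSE)
      do.call(sim_config, utils::modifyList(unclass(default$sim), g$sim))
    }
    args <- utils::modifyList(unclass(default), g[setdiff(names(g), "sim")])
    args$sim <- sim
    do.call(group_spec, args)
  }
  ch <- y$cohort %||% list()
  unknown_c <- setdiff(names(ch), c("n_good", "n_poor", "seed", "good", "poor"))
  if (length(unknown_c))
    stop(sprintf("unknown cohort key(s): %s", paste(unknown_c, collapse = ", ")),
         call. = FALSE)
  spec <- cohort_spec(
    n_good = ch$n_good %||% 27, n_poor = ch$n_poor %||% 26,
    good = build_group(ch$good, default_good_group()),
    poor = build_group(ch$poor, default_poor_group()),
    seed = ch$seed %||% 1L)
  args <- y[setdiff(names(y), "cohort")]
  if (!is.null(args$tests)) args$tests <- unlist(args$tests)
  if (!is.null(args$roc_directions))
    args$roc_directions <- unlist(args$roc_directions)
  do.call(pipeline_config, c(list(cohort = spec), args))
}
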