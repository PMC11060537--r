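# ---- file I/O and the end-to-end pipeline -----------------------------------

#' Read and write long-format trial logs
#'
#' The interchange format is plain CSV with one row per trial and columns
#' `participant_id, time_point, block_index, condition, trial_index,
#' trial_type, sample, target, first_response_correct, latency_ms, practice`
#' (`trial_index`, `sample` and `target` are optional on input). Condition
#' and trial-type labels are case-normalised; latencies are written to three
#' decimal places and must be strictly positive on input. Malformed rows are
#' rejected with their row numbers.
#'
#' @param path File path.
#' @param trials Trial table to write.
#' @param column_map Optional named character vector mapping this schema's
#'   column names to the names used in the file (for ingesting generic
#'   experiment-builder exports), e.g. `c(latency_ms = "response_time")`.
#' @return `read_trial_log()`: the validated trial data.frame.
#'   `write_trial_log()`: the path, invisibly.
#' @export
read_trial_log <- function(path, column_map = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map))
    names(raw)[match(column_map, names(raw))] <- names(column_map)
  required <- c("participant_id", "time_point", "block_index", "condition",
                "trial_type", "first_response_correct", "latency_ms",
                "practice")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("trial log ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  raw$condition <- tolower(trimws(raw$condition))
  bad <- which(!raw$condition %in% c("consistent", "inconsistent"))
  if (length(bad))
    stop("invalid condition value(s) at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  raw$trial_type <- tolower(trimws(raw$trial_type))
  raw$trial_type <- sub("^don'?t", "dont", raw$trial_type)
  bad <- which(!raw$trial_type %in% TRIAL_TYPES)
  if (length(bad))
    stop("invalid trial_type value(s) at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  lat <- suppressWarnings(as.numeric(raw$latency_ms))
  bad <- which(is.na(lat) | lat <= 0)
  if (length(bad))
    stop("non-numeric or non-positive latency at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  raw$latency_ms <- lat
  raw$practice <- as.logical(raw$practice)
  raw$first_response_correct <- as.logical(raw$first_response_correct)
  raw$time_point <- as.integer(raw$time_point)
  raw$block_index <- as.integer(raw$block_index)
  raw
}

#' @rdname read_trial_log
#' @export
write_trial_log <- function(trials, path) {
  .check_trials(trials)
  out <- trials
  out$latency_ms <- round(out$latency_ms, 3)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable threshold of the scoring pipeline with the
#' simulation settings and seed. The defaults are the published FT-IRAP
#' values: trials above 10,000 ms removed, trials at 300 ms or less counted
#' as fast guesses, exclusion above a 10% fast-trial fraction or below 80%
#' block accuracy, D clamped to [-2, 2], Bonferroni over 4 trial types.
#'
#' @param seed Master seed for simulation.
#' @param cohort A [cohort_config()] used when no trial log is supplied.
#' @param params An [rt_params()] used when simulating.
#' @param truth Truth grid used when simulating.
#' @param max_latency_ms,fast_ms,max_fast_fraction,min_accuracy,clamp,
#'   dysphoria_cutoff,bonferroni_m Threshold overrides.
#' @param sd_scope Pooled-SD convention for [compute_dscores()].
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, cohort = cohort_config(seed = seed),
                            params = rt_params(),
                            truth = default_truth_grid(),
                            max_latency_ms = 10000, fast_ms = 300,
                            max_fast_fraction = 0.10, min_accuracy = 0.80,
                            clamp = 2, dysphoria_cutoff = 16L,
                            bonferroni_m = 4L, sd_scope = "trial_type") {
  .assert_pos(max_latency_ms, "max_latency_ms")
  .assert_pos(fast_ms, "fast_ms")
  if (max_fast_fraction <= 0 || max_fast_fraction >= 1)
    stop("max_fast_fraction must lie in (0, 1)", call. = FALSE)
  structure(list(seed = seed, cohort = cohort, params = params,
                 truth = truth, max_latency_ms = max_latency_ms,
                 fast_ms = fast_ms, max_fast_fraction = max_fast_fraction,
                 min_accuracy = min_accuracy, clamp = clamp,
                 dysphoria_cutoff = dysphoria_cutoff,
                 bonferroni_m = bonferroni_m, sd_scope = sd_scope),
            class = "pipeline_config")
}

# mean (SD) grid by group x time x trial type, Table-2 style
.dscore_grid <- function(dscores, groups) {
  d <- merge(dscores, groups, by = "participant_id")
  agg <- aggregate(d$d, by = list(group = d$group, time_point = d$time_point,
                                  trial_type = d$trial_type),
                   FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                       n = length(v)))
  out <- data.frame(agg[, 1:3], mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                    n = agg$x[, "n"], stringsAsFactors = FALSE)
  out[order(out$group, out$time_point,
            match(out$trial_type, TRIAL_TYPES)), , drop = FALSE]
}

#' Run the full analysis pipeline
#'
#' Executes simulate (when no data are supplied) -> filter -> exclude ->
#' score -> analyse -> report. The analysis stage fits the baseline trial
#' type x group split-plot ANOVA at time 1 and, when later time points
#' exist, the change-score ANCOVAs (square-root-transformed CESD-R total as
#' covariate) with Bonferroni post-hoc group comparisons per trial type. A
#' statistical stage that fails (e.g. empty cells) is skipped with its error
#' recorded in `report$errors`; everything else still runs.
#'
#' @param config A [pipeline_config()].
#' @param trials Optional trial log (data.frame or CSV path); simulated from
#'   `config` when absent.
#' @param participants Optional participant table (data.frame or CSV path)
#'   with `participant_id`, `group` and, for the ANCOVAs, `cesdr_total` or
#'   item columns `c01..c20`.
#' @param output_dir Optional directory; when given, `dscores.csv`,
#'   `exclusions.csv`, `anova_tables.csv`, `posthoc.csv`,
#'   `marginal_means.csv` and (when simulating) the cohort files are
#'   written there.
#' @return Object of class `"ftirap_report"`: stage counts, the Table-2
#'   style mean (SD) grid, fitted models, post-hoc tables and provenance.
#' @export
run_pipeline <- function(config = pipeline_config(), trials = NULL,
                         participants = NULL, output_dir = NULL) {
  simulated <- is.null(trials)
  if (simulated) {
    cohort <- simulate_cohort(config$cohort, config$params, config$truth)
    trials <- cohort$trials
    participants <- cohort$participants
  } else {
    if (is.character(trials)) trials <- read_trial_log(trials)
    if (is.character(participants))
      participants <- utils::read.csv(participants, stringsAsFactors = FALSE)
  }
  if (is.null(participants) || !"group" %in% names(participants))
    stop("participant table with a 'group' column is required",
         call. = FALSE)

  n_in <- nrow(trials)
  kept <- filter_trials(trials, max_latency_ms = config$max_latency_ms)
  removed <- attr(kept, "removed")
  stopifnot(nrow(kept) + nrow(removed) == n_in)

  excl <- apply_exclusions(kept,
                           participants =
                             as.character(participants$participant_id),
                           fast_ms = config$fast_ms,
                           max_fast_fraction = config$max_fast_fraction,
                           min_accuracy = config$min_accuracy)
  keep_ids <- excl$participant_id[!excl$excluded]
  if (!length(keep_ids))
    stop("every participant was excluded; nothing to analyse",
         call. = FALSE)
  retained <- kept[as.character(kept$participant_id) %in% keep_ids, ,
                   drop = FALSE]
  dscores <- compute_dscores(retained, clamp = config$clamp,
                             sd_scope = config$sd_scope)

  groups <- participants[, c("participant_id", "group")]
  groups$participant_id <- as.character(groups$participant_id)
  grid <- .dscore_grid(dscores, groups)

  # covariate: sqrt CESD-R total (from items if needed)
  cov_tab <- NULL
  if ("cesdr_total" %in% names(participants)) {
    cov_tab <- data.frame(
      participant_id = as.character(participants$participant_id),
      cesdr_sqrt = sqrt_transform(participants$cesdr_total),
      stringsAsFactors = FALSE)
  } else if (all(paste0("c", sprintf("%02d", 1:20)) %in%
                   names(participants))) {
    items <- as.matrix(participants[, paste0("c", sprintf("%02d", 1:20))])
    cov_tab <- data.frame(
      participant_id = as.character(participants$participant_id),
      cesdr_sqrt = sqrt_transform(rowSums(items)),
      stringsAsFactors = FALSE)
  }

  models <- list()
  posthoc <- list()
  mmeans <- list()
  errors <- character()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      message("analysis stage '", name, "' failed: ", conditionMessage(e))
      NULL
    })
  }

  tps <- sort(unique(dscores$time_point))
  base <- merge(dscores[dscores$time_point == tps[1], ], groups,
                by = "participant_id")
  base$value <- base$d
  models$baseline <- run_stage("baseline", splitplot_anova(
    base, value = "value", within = "trial_type", between = "group",
    id = "participant_id"))
  mmeans$baseline <- run_stage("baseline_means", marginal_means(base))

  for (tp in setdiff(tps, tps[1])) {
    lab <- paste0("change_t", tps[1], "_t", tp)
    ch <- change_scores(dscores[dscores$time_point == tps[1], ],
                        dscores[dscores$time_point == tp, ])
    ch <- merge(ch, groups, by = "participant_id")
    if (!is.null(cov_tab)) {
      ch <- merge(ch, cov_tab, by = "participant_id")
      models[[lab]] <- run_stage(lab, splitplot_anova(
        ch, value = "value", within = "trial_type", between = "group",
        id = "participant_id", covariate = "cesdr_sqrt"))
    } else {
      models[[lab]] <- run_stage(lab, splitplot_anova(
        ch, value = "value", within = "trial_type", between = "group",
        id = "participant_id"))
    }
    posthoc[[lab]] <- run_stage(paste0(lab, "_posthoc"),
                                posthoc_group_tests(ch,
                                                    m = config$bonferroni_m))
    mmeans[[lab]] <- run_stage(paste0(lab, "_means"), marginal_means(ch))
  }

  report <- structure(list(
    counts = list(participants_in = nrow(participants),
                  participants_excluded = sum(excl$excluded),
                  participants_retained = length(keep_ids),
                  trials_in = n_in, trials_removed = nrow(removed),
                  trials_retained = nrow(kept)),
    exclusions = excl, dscores = dscores, dscore_grid = grid,
    models = models, posthoc = posthoc, marginal_means = mmeans,
    errors = errors, simulated = simulated,
    provenance = list(seed = config$seed,
                      config_hash = .config_hash(config),
                      version = as.character(utils::packageVersion("ftirap")),
                      timepoints = tps)),
    class = "ftirap_report")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(dscores, file.path(output_dir, "dscores.csv"),
                     row.names = FALSE)
    utils::write.csv(excl[, setdiff(names(excl), "failing_blocks")],
                     file.path(output_dir, "exclusions.csv"),
                     row.names = FALSE)
    anova_rows <- do.call(rbind, lapply(names(models), function(nm)
      if (!is.null(models[[nm]]))
        cbind(model = nm, models[[nm]]$table)))
    if (!is.null(anova_rows))
      utils::write.csv(anova_rows, file.path(output_dir, "anova_tables.csv"),
                       row.names = FALSE)
    ph_rows <- do.call(rbind, lapply(names(posthoc), function(nm)
      if (!is.null(posthoc[[nm]])) cbind(model = nm, posthoc[[nm]])))
    if (!is.null(ph_rows))
      utils::write.csv(ph_rows, file.path(output_dir, "posthoc.csv"),
                       row.names = FALSE)
    mm_rows <- do.call(rbind, lapply(names(mmeans), function(nm)
      if (!is.null(mmeans[[nm]])) cbind(model = nm, mmeans[[nm]])))
    if (!is.null(mm_rows))
      utils::write.csv(mm_rows, file.path(output_dir, "marginal_means.csv"),
                       row.names = FALSE)
    if (simulated) {
      write_trial_log(trials, file.path(output_dir, "trials.csv"))
      utils::write.csv(participants,
                       file.path(output_dir, "participants.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(seed = config$seed,
                                params = unclass(config$params),
                                truth = config$truth),
                           file.path(output_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  report
}

# stable short hash of the numeric/choice content of a config
.config_hash <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "truth")]),
               collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %%
            .Machine$integer.max)
}

#' @export
print.ftirap_report <- function(x, ...) {
  cat("FT-IRAP pipeline report",
      if (x$simulated) "(simulated cohort)" else "(recorded data)", "\n")
  with(x$counts, cat(sprintf(
    "participants: %d in, %d excluded, %d analysed\ntrials: %d in, %d removed, %d retained\n",
    participants_in, participants_excluded, participants_retained,
    trials_in, trials_removed, trials_retained)))
  cat("\nMean (SD) D by group, time and trial type:\n")
  g <- x$dscore_grid
  g$cell <- sprintf("%.2f (%.2f)", g$mean, g$sd)
  wide <- stats::reshape(g[, c("group", "time_point", "trial_type", "cell")],
                         idvar = c("group", "time_point"),
                         timevar = "trial_type", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  print(wide, row.names = FALSE)
  for (nm in names(x$models)) {
    if (is.null(x$models[[nm]])) next
    cat("\n--- ", nm, " ---\n", sep = "")
    print(x$models[[nm]])
  }
  if (length(x$errors))
    cat("\nfailed stages:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
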