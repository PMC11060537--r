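# ---- D-score algorithm ------------------------------------------------------
#
# Standard latency-based D scoring for the four-block FT-IRAP:
#   1. drop practice trials and trials slower than 10,000 ms;
#   2. exclude a participant outright if more than 10% of their remaining
#      test trials are 300 ms or faster, or if any single test block falls
#      below 80% first-response accuracy;
#   3. per participant and time point, average latencies in each of the 16
#      (block x trial type) cells;
#   4. per trial type and block pair (blocks 1-2, blocks 3-4), divide the
#      inconsistent-minus-consistent cell-mean difference by the sample SD of
#      that trial type's raw latencies pooled over the two blocks;
#   5. average the two pair scores and clamp to [-2, 2]. Positive D =
#      optimistic orientation.
#
# All thresholds are arguments so sensitivity analyses are possible; the
# defaults are the standard published values. Tie handling is strict as
# printed: exactly 10,000 ms is retained, exactly 300 ms counts as fast,
# exactly 10% fast trials is retained, exactly 80% accuracy is retained.

.trial_cols <- c("participant_id", "time_point", "block_index", "condition",
                 "trial_type", "first_response_correct", "latency_ms",
                 "practice")

.check_trials <- function(trials) {
  missing <- setdiff(.trial_cols, names(trials))
  if (length(missing))
    stop("trial table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(trials)
}

#' Remove practice trials and over-long latencies
#'
#' Drops practice trials and trials with latencies above `max_latency_ms`
#' (strictly greater; a trial at exactly the cutoff is retained). Row order
#' is preserved and the removals are recorded in the `"removed"` attribute.
#'
#' @param trials Long-format trial table (see [read_trial_log()] for the
#'   schema).
#' @param max_latency_ms Upper latency cutoff in ms.
#' @return The retained trials; `attr(, "removed")` is a data.frame of the
#'   dropped rows with a `removal_reason` column (`"practice"` or
#'   `"slow_trial"`).
#' @export
filter_trials <- function(trials, max_latency_ms = 10000) {
  .check_trials(trials)
  practice <- as.logical(trials$practice)
  slow <- trials$latency_ms > max_latency_ms
  drop <- practice | slow
  removed <- trials[drop, , drop = FALSE]
  if (nrow(removed))
    removed$removal_reason <- ifelse(practice[drop], "practice", "slow_trial")
  kept <- trials[!drop, , drop = FALSE]
  attr(kept, "removed") <- removed
  kept
}

#' Participant-level exclusion rules
#'
#' Applies the two participant-level rules to already-filtered test trials:
#' a participant's entire data set (all time points) is excluded if more than
#' `max_fast_fraction` of their retained trials have latencies of
#' `fast_ms` or less, or if first-response accuracy is below `min_accuracy`
#' in any single test block at any time point. Boundary cases are retained
#' (exactly 10% fast, exactly 80% accuracy).
#'
#' @param trials Filtered trial table ([filter_trials()] output).
#' @param participants Optional character vector of participant ids expected
#'   in the data; ids with no retained trials are excluded with reason
#'   `"fast_trials"` and a warning.
#' @param fast_ms Fast-guess latency bound (ms, inclusive).
#' @param max_fast_fraction Largest tolerated fast-trial proportion.
#' @param min_accuracy Smallest tolerated per-block accuracy.
#' @return Data.frame with one row per participant: `participant_id`,
#'   `excluded`, `reason` (`"none"`, `"fast_trials"` or
#'   `"block_accuracy"`), `fast_trial_fraction`, `n_failing_blocks`, and a
#'   `failing_blocks` list-column of data.frames (`time_point`,
#'   `block_index`, `accuracy`).
#' @export
apply_exclusions <- function(trials, participants = NULL, fast_ms = 300,
                             max_fast_fraction = 0.10, min_accuracy = 0.80) {
  .check_trials(trials)
  ids <- unique(as.character(trials$participant_id))
  if (is.null(participants)) participants <- ids
  participants <- as.character(participants)

  pid <- as.character(trials$participant_id)
  agg <- rowsum(cbind(fast = as.numeric(trials$latency_ms <= fast_ms), n = 1),
                pid)
  idx <- match(participants, rownames(agg))
  n_tr <- ifelse(is.na(idx), 0, agg[idx, "n"])
  n_fast <- ifelse(is.na(idx), 0, agg[idx, "fast"])
  frac <- ifelse(n_tr > 0, n_fast / n_tr, NA_real_)

  bkey <- paste(as.character(trials$participant_id), trials$time_point,
                trials$block_index, sep = "\r")
  acc <- rowsum(cbind(ok = as.numeric(trials$first_response_correct), n = 1),
                bkey)
  block_acc <- acc[, "ok"] / acc[, "n"]
  parts <- do.call(rbind, strsplit(rownames(acc), "\r", fixed = TRUE))
  fail <- block_acc < min_accuracy
  fail_df <- data.frame(participant_id = parts[, 1],
                        time_point = as.integer(parts[, 2]),
                        block_index = as.integer(parts[, 3]),
                        accuracy = block_acc,
                        stringsAsFactors = FALSE)[fail, , drop = FALSE]

  out <- data.frame(participant_id = participants,
                    excluded = FALSE, reason = "none",
                    fast_trial_fraction = frac,
                    n_failing_blocks = 0L,
                    stringsAsFactors = FALSE)
  out$failing_blocks <- rep(list(fail_df[0, ]), nrow(out))
  for (i in seq_len(nrow(out))) {
    fb <- fail_df[fail_df$participant_id == out$participant_id[i], ,
                  drop = FALSE]
    out$failing_blocks[[i]] <- fb
    out$n_failing_blocks[i] <- nrow(fb)
  }

  no_data <- n_tr == 0
  if (any(no_data)) {
    warning("participant(s) with zero retained trials excluded: ",
            paste(participants[no_data], collapse = ", "), call. = FALSE)
    out$excluded[no_data] <- TRUE
    out$reason[no_data] <- "fast_trials"
  }
  too_fast <- !no_data & frac > max_fast_fraction
  out$excluded[too_fast] <- TRUE
  out$reason[too_fast] <- "fast_trials"
  bad_acc <- !out$excluded & out$n_failing_blocks > 0
  out$excluded[bad_acc] <- TRUE
  out$reason[bad_acc] <- "block_accuracy"
  rownames(out) <- NULL
  out
}

#' Per-block trial-type mean latencies
#'
#' The 16 cell means (4 blocks x 4 trial types) for one participant at one
#' time point. Cells with no retained trials are returned with `NA` mean and
#' zero count.
#'
#' @param trials Filtered trials of a single participant and time point.
#' @return Data.frame with `block_index`, `trial_type`, `mean_latency_ms`,
#'   `n`; 16 rows.
#' @export
cell_means <- function(trials) {
  .check_trials(trials)
  if (length(unique(paste(trials$participant_id, trials$time_point))) > 1L)
    stop("cell_means() expects one participant at one time point",
         call. = FALSE)
  grid <- expand.grid(block_index = 1:4, trial_type = TRIAL_TYPES,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  key <- paste(trials$block_index, trials$trial_type, sep = "\r")
  agg <- rowsum(cbind(sum = trials$latency_ms, n = 1), key)
  gkey <- paste(grid$block_index, grid$trial_type, sep = "\r")
  idx <- match(gkey, rownames(agg))
  grid$n <- ifelse(is.na(idx), 0L, agg[idx, "n"])
  grid$mean_latency_ms <- ifelse(grid$n > 0, agg[idx, "sum"] / grid$n,
                                 NA_real_)
  grid[, c("block_index", "trial_type", "mean_latency_ms", "n")]
}

#' Compute D scores per trial type
#'
#' Runs steps 3-5 of the scoring algorithm (cell means, normalised pair
#' differences, pair averaging and clamping) for every participant and time
#' point present in the filtered trial table, fully vectorised. Blocks 1-2
#' form pair 1 and blocks 3-4 pair 2; each pair must contain one consistent
#' and one inconsistent block.
#'
#' A pair whose two cells are not both populated yields `NA` for that trial
#' type with a warning naming the affected participant/time/trial type; a
#' pair whose pooled SD is zero yields a pair score of 0 with a warning.
#'
#' @param trials Filtered trial table (all participants; see
#'   [filter_trials()]).
#' @param clamp Half-width of the admissible D range.
#' @param sd_scope `"trial_type"` (default): the pair's divisor is the sample
#'   SD of that trial type's raw latencies pooled over the two blocks.
#'   `"block_pair"`: divisor pools all trial types' latencies of the two
#'   blocks instead.
#' @return Data.frame with one row per participant x time point x trial
#'   type: `participant_id`, `time_point`, `trial_type`, `pair1_d`,
#'   `pair2_d`, `d_unclamped`, `d`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_per_group = c(pst = 2,
#'                                                         neutral = 2),
#'                                         n_timepoints = 1, seed = 7,
#'                                         include_questionnaires = FALSE))
#' head(compute_dscores(filter_trials(cohort$trials)))
#' @export
compute_dscores <- function(trials, clamp = 2,
                            sd_scope = c("trial_type", "block_pair")) {
  .check_trials(trials)
  sd_scope <- match.arg(sd_scope)
  if (!nrow(trials))
    return(data.frame(participant_id = character(), time_point = integer(),
                      trial_type = character(), pair1_d = numeric(),
                      pair2_d = numeric(), d_unclamped = numeric(),
                      d = numeric(), stringsAsFactors = FALSE))

  pid <- as.character(trials$participant_id)
  tp <- as.integer(trials$time_point)
  pair <- (as.integer(trials$block_index) + 1L) %/% 2L
  cond <- as.character(trials$condition)
  lat <- as.numeric(trials$latency_ms)

  # cell means per (participant, time, trial type, pair, condition)
  ckey <- paste(pid, tp, trials$trial_type, pair, cond, sep = "\r")
  cagg <- rowsum(cbind(sum = lat, n = 1), ckey)
  cmean <- setNames(cagg[, "sum"] / cagg[, "n"], rownames(cagg))

  # pooled SD per (participant, time, [trial type], pair), combined sample SD
  skey <- if (sd_scope == "trial_type")
    paste(pid, tp, trials$trial_type, pair, sep = "\r")
  else
    paste(pid, tp, pair, sep = "\r")
  sagg <- rowsum(cbind(s1 = lat, s2 = lat^2, n = 1), skey)
  sn <- sagg[, "n"]
  svar <- ifelse(sn > 1,
                 pmax(0, (sagg[, "s2"] - sagg[, "s1"]^2 / sn) / (sn - 1)),
                 NA_real_)
  ssd <- setNames(sqrt(svar), rownames(sagg))

  grid <- unique(data.frame(participant_id = pid, time_point = tp,
                            stringsAsFactors = FALSE))
  grid <- grid[order(grid$participant_id, grid$time_point), , drop = FALSE]
  full <- merge(grid,
                expand.grid(trial_type = TRIAL_TYPES, pair = 1:2,
                            stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE),
                by = NULL)
  mk <- function(cond) paste(full$participant_id, full$time_point,
                             full$trial_type, full$pair, cond, sep = "\r")
  m_con <- cmean[mk("consistent")]
  m_inc <- cmean[mk("inconsistent")]
  sk <- if (sd_scope == "trial_type")
    paste(full$participant_id, full$time_point, full$trial_type, full$pair,
          sep = "\r")
  else
    paste(full$participant_id, full$time_point, full$pair, sep = "\r")
  psd <- ssd[sk]

  pair_d <- (m_inc - m_con) / psd
  zero_sd <- !is.na(m_inc) & !is.na(m_con) & !is.na(psd) & psd == 0
  if (any(zero_sd)) {
    warning("zero pooled SD; pair D set to 0 for: ",
            paste(unique(paste(full$participant_id, full$time_point,
                               full$trial_type)[zero_sd]), collapse = "; "),
            call. = FALSE)
    pair_d[zero_sd] <- 0
  }
  missing_cell <- is.na(m_inc) | is.na(m_con)
  if (any(missing_cell)) {
    warning("empty latency cell(s); D undefined for: ",
            paste(unique(paste(full$participant_id, full$time_point,
                               full$trial_type)[missing_cell]),
                  collapse = "; "), call. = FALSE)
    pair_d[missing_cell] <- NA_real_
  }

  wide <- full[full$pair == 1L, c("participant_id", "time_point",
                                  "trial_type")]
  wide$pair1_d <- pair_d[full$pair == 1L]
  wide$pair2_d <- pair_d[full$pair == 2L]
  wide$d_unclamped <- (wide$pair1_d + wide$pair2_d) / 2
  wide$d <- pmin(clamp, pmax(-clamp, wide$d_unclamped))
  rownames(wide) <- NULL
  wide
}

#' Score a trial log end to end
#'
#' Convenience wrapper chaining [filter_trials()], [apply_exclusions()] and
#' [compute_dscores()] on the retained participants.
#'
#' @param trials Raw long-format trial table (practice rows included).
#' @param ... Threshold overrides passed to the three stages
#'   (`max_latency_ms`, `fast_ms`, `max_fast_fraction`, `min_accuracy`,
#'   `clamp`, `sd_scope`).
#' @return List with `dscores` (retained participants only), `exclusions`
#'   (the full [apply_exclusions()] report) and `removed_trials`.
#' @export
score_trials <- function(trials, max_latency_ms = 10000, fast_ms = 300,
                         max_fast_fraction = 0.10, min_accuracy = 0.80,
                         clamp = 2, sd_scope = "trial_type") {
  kept <- filter_trials(trials, max_latency_ms = max_latency_ms)
  excl <- apply_exclusions(kept, fast_ms = fast_ms,
                           max_fast_fraction = max_fast_fraction,
                           min_accuracy = min_accuracy)
  keep_ids <- excl$participant_id[!excl$excluded]
  retained <- kept[as.character(kept$participant_id) %in% keep_ids, ,
                   drop = FALSE]
  scores <- compute_dscores(retained, clamp = clamp, sd_scope = sd_scope)
  list(dscores = scores, exclusions = excl,
       removed_trials = attr(kept, "removed"))
}
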