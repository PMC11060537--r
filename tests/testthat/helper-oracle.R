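# Brute-force single-pass reimplementation of the D algorithm, kept
# deliberately naive (explicit loops, mean()/sd() on subsets) so it is an
# independent oracle for the vectorised pipeline.
oracle_dscores <- function(trials, clamp = 2) {
  out <- NULL
  for (p in unique(trials$participant_id)) {
    for (tp in unique(trials$time_point[trials$participant_id == p])) {
      sub <- trials[trials$participant_id == p & trials$time_point == tp, ]
      for (tt in TRIAL_TYPES) {
        pair_d <- c(NA_real_, NA_real_)
        for (pr in 1:2) {
          blocks <- if (pr == 1) c(1, 2) else c(3, 4)
          seg <- sub[sub$trial_type == tt & sub$block_index %in% blocks, ]
          con <- seg$latency_ms[seg$condition == "consistent"]
          inc <- seg$latency_ms[seg$condition == "inconsistent"]
          if (length(con) == 0 || length(inc) == 0) next
          s <- sd(c(con, inc))
          pair_d[pr] <- if (s == 0) 0 else (mean(inc) - mean(con)) / s
        }
        d <- mean(pair_d)
        out <- rbind(out, data.frame(
          participant_id = p, time_point = tp, trial_type = tt,
          d = max(-clamp, min(clamp, d)), stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# hand-built trial table: one participant, 4 blocks alternating C/I, with a
# chosen latency vector per (block, trial type) cell
make_trials <- function(cells, participant_id = "P1", time_point = 1,
                        first = "consistent", correct = TRUE) {
  rows <- NULL
  for (b in seq_along(cells)) {
    cond <- if ((b %% 2) == 1) first else setdiff(
      c("consistent", "inconsistent"), first)
    for (tt in names(cells[[b]])) {
      lat <- cells[[b]][[tt]]
      if (!length(lat)) next
      rows <- rbind(rows, data.frame(
        participant_id = participant_id, time_point = time_point,
        block_index = b, condition = cond, trial_type = tt,
        first_response_correct = correct, latency_ms = lat,
        practice = FALSE, stringsAsFactors = FALSE))
    }
  }
  rows
}

# random small-but-complete trial table for property tests
random_trials <- function(seed, n_participants = 2) {
  set.seed(seed)
  rows <- NULL
  for (p in seq_len(n_participants)) {
    first <- sample(c("consistent", "inconsistent"), 1)
    cells <- lapply(1:4, function(b)
      setNames(lapply(TRIAL_TYPES, function(tt)
        round(runif(sample(2:6, 1), 300, 3000), 1)), TRIAL_TYPES))
    rows <- rbind(rows, make_trials(cells, sprintf("P%d", p), 1, first))
  }
  rows
}
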