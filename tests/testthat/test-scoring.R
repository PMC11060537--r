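test_that("trial filter removes practice and over-long trials, preserving order", {
  tr <- make_trials(list(
    list("expect-positive" = c(600, 10500, 800)),
    list("expect-positive" = c(700, 10000))))
  tr$practice[1] <- TRUE
  kept <- filter_trials(tr)
  expect_equal(kept$latency_ms, c(800, 700, 10000))  # 10,000 exactly stays
  removed <- attr(kept, "removed")
  expect_equal(removed$removal_reason, c("practice", "slow_trial"))
  # empty input passes through
  expect_equal(nrow(filter_trials(tr[0, ])), 0L)
})

test_that("fast-trial exclusion uses a strict 10% rule on retained trials", {
  base <- random_trials(1, n_participants = 1)
  # 96-trial session: force exact trial counts
  sched <- ftirap_schedule(seed = 3)
  tr <- make_trials(lapply(1:4, function(b) setNames(
    lapply(TRIAL_TYPES, function(tt) rep(1000, 6)), TRIAL_TYPES)))
  stopifnot(nrow(tr) == 96)
  # 10 of 96 fast trials: 10.4% > 10% -> excluded
  tr10 <- tr; tr10$latency_ms[1:10] <- 300      # exactly 300 counts as fast
  rep10 <- apply_exclusions(tr10)
  expect_true(rep10$excluded)
  expect_equal(rep10$reason, "fast_trials")
  expect_equal(rep10$fast_trial_fraction, 10 / 96)
  # exactly 10% is retained (use 10 fast of 100 by padding is impossible at
  # 96 trials, so check on a 40-trial table: 4/40 = 10%)
  tr40 <- make_trials(list(
    list("expect-positive" = c(rep(250, 4), rep(900, 16))),
    list("expect-positive" = rep(900, 20))))
  rep40 <- apply_exclusions(tr40)
  expect_false(rep40$excluded)
  expect_equal(rep40$fast_trial_fraction, 0.10)
})

test_that("block accuracy below 80% excludes; exactly 80% is retained", {
  tr <- make_trials(lapply(1:4, function(b) setNames(
    lapply(TRIAL_TYPES, function(tt) rep(1000, 6)), TRIAL_TYPES)))
  # block 2: 19/24 correct = 79.2% -> excluded
  bad <- tr
  bad$first_response_correct[which(bad$block_index == 2)[1:5]] <- FALSE
  rep_bad <- apply_exclusions(bad)
  expect_true(rep_bad$excluded)
  expect_equal(rep_bad$reason, "block_accuracy")
  fb <- rep_bad$failing_blocks[[1]]
  expect_equal(fb$block_index, 2L)
  expect_equal(fb$accuracy, 19 / 24)
  # 20/24 min per block = exactly 80% everywhere -> retained
  edge <- tr
  for (b in 1:4)
    edge$first_response_correct[which(edge$block_index == b)[1:4]] <- FALSE
  expect_false(apply_exclusions(edge)$excluded)
})

test_that("participants with no retained trials are excluded with a warning", {
  tr <- make_trials(list(list("expect-positive" = c(600, 700))))
  expect_warning(rep0 <- apply_exclusions(tr, participants = c("P1", "P2")),
                 "zero retained")
  expect_false(rep0$excluded[rep0$participant_id == "P1"])
  expect_true(rep0$excluded[rep0$participant_id == "P2"])
  expect_equal(rep0$reason[rep0$participant_id == "P2"], "fast_trials")
})

test_that("cell means produce the 16-cell grid with flagged gaps", {
  tr <- make_trials(lapply(1:4, function(b) setNames(
    lapply(TRIAL_TYPES, function(tt) c(600, 800)), TRIAL_TYPES)))
  cm <- cell_means(tr)
  expect_equal(nrow(cm), 16L)
  expect_true(all(cm$mean_latency_ms == 700))
  expect_true(all(cm$n == 2))
  # drop one cell entirely
  gap <- tr[!(tr$block_index == 3 & tr$trial_type == "expect-negative"), ]
  cmg <- cell_means(gap)
  miss <- cmg[cmg$block_index == 3 & cmg$trial_type == "expect-negative", ]
  expect_equal(miss$n, 0L)
  expect_true(is.na(miss$mean_latency_ms))
  expect_error(cell_means(rbind(tr, make_trials(list(list(
    "expect-positive" = 500)), participant_id = "P9"))), "one participant")
})

test_that("pair D reproduces the hand-computed example", {
  cells <- lapply(1:4, function(b) setNames(
    lapply(TRIAL_TYPES, function(tt)
      if ((b %% 2) == 1) c(500, 600, 700) else c(800, 900, 1000)),
    TRIAL_TYPES))
  tr <- make_trials(cells, first = "consistent")
  sc <- compute_dscores(tr)
  # 300 / sd(500,600,700,800,900,1000) = 300 / 187.083 = 1.6036
  expect_equal(sc$pair1_d, rep(300 / sd(c(5:10 * 100)), 4), tolerance = 1e-12)
  expect_equal(sc$d, sc$pair1_d, tolerance = 1e-12)
})

test_that("relabelling consistent and inconsistent negates every score", {
  tr <- random_trials(7, n_participants = 3)
  sc <- compute_dscores(tr)
  flipped <- tr
  flipped$condition <- ifelse(tr$condition == "consistent", "inconsistent",
                              "consistent")
  sc2 <- compute_dscores(flipped)
  expect_equal(sc2$pair1_d, -sc$pair1_d, tolerance = 1e-12)
  expect_equal(sc2$pair2_d, -sc$pair2_d, tolerance = 1e-12)
  expect_equal(sc2$d_unclamped, -sc$d_unclamped, tolerance = 1e-12)
})

test_that("D is invariant to latency rescaling and pair-wide shifts", {
  tr <- random_trials(13, n_participants = 2)
  sc <- compute_dscores(tr)
  scaled <- tr
  scaled$latency_ms <- tr$latency_ms * 3.7
  expect_equal(compute_dscores(scaled)$d_unclamped, sc$d_unclamped,
               tolerance = 1e-12)
  # adding a constant to every latency of both blocks of a pair moves the
  # cell means together and leaves the pooled SD untouched
  shifted <- tr
  shifted$latency_ms <- tr$latency_ms + 250
  expect_equal(compute_dscores(shifted)$d_unclamped, sc$d_unclamped,
               tolerance = 1e-10)
})

test_that("identical condition distributions give near-zero D and zero SD gives 0", {
  flat <- make_trials(lapply(1:4, function(b) setNames(
    lapply(TRIAL_TYPES, function(tt) rep(750, 6)), TRIAL_TYPES)))
  expect_warning(sc <- compute_dscores(flat), "zero pooled SD")
  expect_true(all(sc$d == 0))
})

test_that("empty cells yield NA with a diagnosable warning", {
  tr <- random_trials(21, n_participants = 1)
  tr <- tr[!(tr$trial_type == "expect-negative" & tr$block_index == 2), ]
  expect_warning(sc <- compute_dscores(tr), "empty latency cell")
  expect_true(is.na(sc$d[sc$trial_type == "expect-negative"]))
  expect_true(all(!is.na(sc$d[sc$trial_type != "expect-negative"])))
})

test_that("vectorised pipeline matches the brute-force oracle on random data", {
  for (seed in 1:200) {
    tr <- random_trials(seed, n_participants = sample(1:2, 1))
    got <- compute_dscores(tr)
    want <- oracle_dscores(tr)
    got <- got[order(got$participant_id, got$trial_type), ]
    want <- want[order(want$participant_id, want$trial_type), ]
    expect_equal(got$d, want$d, tolerance = 1e-10)
  }
})

test_that("emitted D panels always respect the clamp bound", {
  # with equal cells |D| is bounded below 2 by construction, so an
  # unbalanced cell pattern is needed to push the raw score past the bound
  tr <- make_trials(list(
    list("expect-positive" = 500),
    list("expect-positive" = c(5000, 5001, 5002, 5003, 5004)),
    list("expect-positive" = 500),
    list("expect-positive" = c(5000, 5001, 5002, 5003, 5004))))
  sc <- suppressWarnings(compute_dscores(tr))  # only one type populated
  expect_true(all(abs(sc$d) <= 2, na.rm = TRUE))
  ep <- sc[sc$trial_type == "expect-positive", ]
  expect_gt(ep$d_unclamped, 2)   # raw value survives in the panel
  expect_equal(ep$d, 2)
})

test_that("a seeded cohort of 82 with 9 violators leaves 73 survivors", {
  cfg <- cohort_config(n_per_group = c(pst = 41, neutral = 41),
                       n_timepoints = 1, seed = 730,
                       n_fast_violators = 1, n_accuracy_violators = 8,
                       include_questionnaires = FALSE)
  cohort <- simulate_cohort(cfg)
  res <- score_trials(cohort$trials)
  expect_equal(sum(res$exclusions$excluded), 9L)
  expect_equal(sum(!res$exclusions$excluded), 73L)
  reasons <- res$exclusions$reason[res$exclusions$excluded]
  expect_equal(sum(reasons == "fast_trials"), 1L)
  expect_equal(sum(reasons == "block_accuracy"), 8L)
})
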