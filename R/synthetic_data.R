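# ---- generative model for FT-IRAP latencies --------------------------------
#
# One trial's recorded latency (time from trial onset to the eventual correct
# response) is modelled as
#
#   L = U(0, fast_guess_max)                  with prob fast_guess_rate
#     = X + B * G                             otherwise
#
# X ~ Normal(base_mean -/+ delta/2, base_sd) truncated below at floor_ms
# (consistent blocks get the faster mean when the participant's true D is
# positive), B ~ Bernoulli(error_rate) marks a wrong first response and G ~
# Gamma(penalty_shape, penalty_scale) is the retry delay added before the
# correct key is finally pressed.
#
# The participant-level shift delta is not a free parameter: it is calibrated
# so that the population value of the D estimator actually computed by
# compute_dscores() — difference of 6-trial cell means divided by the
# combined 12-trial sample SD, averaged over two block pairs — equals the
# requested true D. See .dscore_calibration().

#' Latency-model parameters for the synthetic generator
#'
#' Defaults are chosen to produce plausible IRAP-scale latencies: block mean
#' RTs a little under the 2 s feedback target, right-skewed error-retry
#' penalties, and a small fast-guess contamination rate that exercises the
#' 300 ms exclusion rule without dominating the data.
#'
#' @param base_mean_ms Mean of the Gaussian latency core (ms).
#' @param base_sd_ms SD of the Gaussian latency core (ms).
#' @param floor_ms Lower truncation bound of the Gaussian core (ms). Must be
#'   below `base_mean_ms`; with the defaults the truncated mass is < 1e-4 so
#'   the calibration moments treat it as negligible.
#' @param error_rate Probability that the first response is wrong, in which
#'   case a Gamma retry delay is added to the recorded latency.
#' @param penalty_shape,penalty_scale Shape and scale (ms) of the Gamma retry
#'   delay.
#' @param fast_guess_rate Probability that a trial's latency is replaced by an
#'   anticipatory fast guess, uniform on (0, `fast_guess_max_ms`).
#' @param fast_guess_max_ms Upper bound of the fast-guess distribution (ms).
#' @return Object of class `"rt_params"` (a named list).
#' @export
rt_params <- function(base_mean_ms = 1800, base_sd_ms = 400, floor_ms = 250,
                      error_rate = 0.03, penalty_shape = 2,
                      penalty_scale = 300, fast_guess_rate = 0.005,
                      fast_guess_max_ms = 300) {
  .assert_pos(base_mean_ms, "base_mean_ms")
  .assert_pos(base_sd_ms, "base_sd_ms")
  .assert_pos(floor_ms, "floor_ms")
  .assert_pos(penalty_shape, "penalty_shape")
  .assert_pos(penalty_scale, "penalty_scale")
  .assert_pos(fast_guess_max_ms, "fast_guess_max_ms")
  .assert_prob(error_rate, "error_rate")
  .assert_prob(fast_guess_rate, "fast_guess_rate")
  if (floor_ms >= base_mean_ms)
    stop("floor_ms must be below base_mean_ms", call. = FALSE)
  structure(list(base_mean_ms = base_mean_ms, base_sd_ms = base_sd_ms,
                 floor_ms = floor_ms, error_rate = error_rate,
                 penalty_shape = penalty_shape, penalty_scale = penalty_scale,
                 fast_guess_rate = fast_guess_rate,
                 fast_guess_max_ms = fast_guess_max_ms),
            class = "rt_params")
}

# population mean offset and variance of the non-fast-guess latency
# (Gaussian core + Bernoulli-Gamma retry penalty), ignoring floor truncation
.latency_moments <- function(params) {
  p <- params$error_rate
  k <- params$penalty_shape
  th <- params$penalty_scale
  pen_mean <- p * k * th
  pen_var <- p * (k * th^2 + (k * th)^2) - pen_mean^2
  list(mean = params$base_mean_ms + pen_mean,
       var = params$base_sd_ms^2 + pen_var)
}

# mean, variance and excess kurtosis of the full latency mixture (Gaussian
# core + Bernoulli-Gamma retry penalty, fast-guess replacement), at the
# condition midpoint and ignoring floor truncation
.mixture_moments <- function(params) {
  p <- params$error_rate
  k <- params$penalty_shape
  th <- params$penalty_scale
  q <- params$fast_guess_rate
  fg <- params$fast_guess_max_ms
  # Bernoulli-Gamma raw then central moments
  m1 <- p * k * th
  m2 <- p * k * (k + 1) * th^2
  m3 <- p * k * (k + 1) * (k + 2) * th^3
  m4 <- p * k * (k + 1) * (k + 2) * (k + 3) * th^4
  c2 <- m2 - m1^2
  c3 <- m3 - 3 * m1 * m2 + 2 * m1^3
  c4 <- m4 - 4 * m1 * m3 + 6 * m1^2 * m2 - 3 * m1^4
  # non-fast-guess component: independent sum, cumulants add
  mean_a <- params$base_mean_ms + m1
  k2a <- params$base_sd_ms^2 + c2
  k3a <- c3
  k4a <- c4 - 3 * c2^2
  c2a <- k2a
  c3a <- k3a
  c4a <- k4a + 3 * k2a^2
  # fast-guess component: uniform(0, fg)
  mean_u <- fg / 2
  c2u <- fg^2 / 12
  c3u <- 0
  c4u <- fg^4 / 80
  # two-component mixture central moments
  mu <- (1 - q) * mean_a + q * mean_u
  da <- mean_a - mu
  du <- mean_u - mu
  mu2 <- (1 - q) * (c2a + da^2) + q * (c2u + du^2)
  mu4 <- (1 - q) * (c4a + 4 * c3a * da + 6 * c2a * da^2 + da^4) +
    q * (c4u + 4 * c3u * du + 6 * c2u * du^2 + du^4)
  list(mean = mu, var = mu2, kurt_ex = mu4 / mu2^2 - 3)
}

# With equal cell sizes n1 = n2 and n = 2 * n1 latencies in a pair, the pair
# score is an exact monotone transform of the two-sample t statistic:
#
#   D_pair = c0 * t / sqrt(n - 2 + t^2),  c0 = sqrt(n * (n - 1) / (n1 * n2)),
#
# with t noncentral-t distributed (df n - 2, noncentrality lambda =
# shift / (sigma_w * sqrt(2 / n1))) under within-cell normality. E[D_pair]
# is therefore a smooth odd function g(lambda), evaluated here by
# Gauss-Hermite x chi-square quadrature and inverted through a monotone
# spline. Note |D_pair| < c0 (about 1.915 at 6 trials per cell): extreme
# true values near the clamp bound are not representable by any shift.

.calib_cache <- new.env(parent = emptyenv())

# E[ V / sqrt(V^2 + W) ] for V ~ N(lambda, 1) and W the pooled
# sum-of-squares / sigma^2. Under normality W ~ chisq(nu); non-normal
# latencies inflate Var(W) through their excess kurtosis, so W is modelled
# as a Gamma with mean nu and variance 2*nu + kurt_ex * nu^2 / n_total.
.ratio_expectation <- function(lambda, nu, kurt_ex = 0, n_total = nu + 2L,
                               n_nodes = 48L) {
  # Hermite nodes via Golub-Welsch on the Jacobi matrix
  j <- sqrt(seq_len(n_nodes - 1L) / 2)
  J <- diag(0, n_nodes)
  J[cbind(seq_len(n_nodes - 1L), seq_len(n_nodes - 1L) + 1L)] <- j
  J[cbind(seq_len(n_nodes - 1L) + 1L, seq_len(n_nodes - 1L))] <- j
  eh <- eigen(J, symmetric = TRUE)
  z <- eh$values
  wz <- eh$vectors[1, ]^2                       # normalised: sum = 1
  u <- (seq_len(256L) - 0.5) / 256L             # W via quantile grid
  var_w <- 2 * nu + kurt_ex * nu^2 / n_total
  w <- stats::qgamma(u, shape = nu^2 / var_w, scale = var_w / nu)
  vapply(lambda, function(l) {
    v <- l + sqrt(2) * z
    sum(wz * rowMeans(outer(v, w, function(v, w) v / sqrt(v^2 + w))))
  }, numeric(1))
}

# memoised inverse calibration for one cell size and latency-mixture excess
# kurtosis: returns spline functions d <-> lambda
.calib_inverse <- function(n1, kurt_ex = 0) {
  key <- paste(n1, signif(kurt_ex, 4))
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  n <- 2L * n1
  c0 <- sqrt(n * (n - 1) / (n1 * n1))
  lam <- seq(0, 40, by = 0.25)
  d <- c0 * .ratio_expectation(lam, nu = n - 2L, kurt_ex = kurt_ex,
                               n_total = n)
  fwd <- stats::splinefun(lam, d, method = "hyman")
  inv <- stats::splinefun(d, lam, method = "hyman")
  fn <- list(inverse = inv, forward = fwd, d_max = max(d), c0 = c0)
  .calib_cache[[key]] <- fn
  fn
}

#' Calibrated latency shift for a target true D
#'
#' Maps a ground-truth D value onto the consistent/inconsistent latency mean
#' shift `delta` that makes the expected value of the finite-cell D
#' estimator (as computed by [compute_dscores()] from `trials_per_cell`
#' latencies per block and trial type) equal to `true_d`. The mapping
#' accounts for:
#' \itemize{
#' \item the estimator's exact sampling form: with equal cells the pair
#'   score is `c0 * t / sqrt(n - 2 + t^2)` for a noncentral two-sample t,
#'   whose expectation is computed by quadrature and inverted;
#' \item the observed-latency mixture: error-retry penalties widen the
#'   within-cell SD, and fast guesses both widen it and dilute the mean
#'   shift by `1 - fast_guess_rate`.
#' }
#' Within-cell normality is assumed when computing the expectation; the
#' contamination components make the true distribution mildly non-normal,
#' which leaves a residual bias well below the Monte-Carlo resolution of the
#' package's recovery checks. Because `|pair D| < c0` by construction,
#' `|true_d|` beyond the representable expectation (about 1.9 at 6 trials
#' per cell) is rejected.
#'
#' @param true_d Numeric vector of target D values.
#' @param params An [rt_params()] object.
#' @param trials_per_cell Trials per (block, trial type) cell; 6 in the
#'   standard 24-trial block design.
#' @return List with `delta` (inconsistent-minus-consistent population mean
#'   difference of the Gaussian core, ms), `mix_mean` and `mix_sd`
#'   (per-condition latency mixture moments at the shift midpoint), and
#'   `lambda` (the implied noncentrality per pair).
#' @export
dscore_calibration <- function(true_d, params = rt_params(),
                               trials_per_cell = 6L) {
  if (any(abs(true_d) > 2)) stop("|true_d| must be <= 2", call. = FALSE)
  q <- params$fast_guess_rate
  mix <- .mixture_moments(params)
  cal <- .calib_inverse(as.integer(trials_per_cell), mix$kurt_ex)
  if (any(abs(true_d) >= cal$d_max))
    stop("requested |true_d| >= ", signif(cal$d_max, 4),
         " is outside the representable range at this cell size",
         call. = FALSE)
  lambda <- sign(true_d) * cal$inverse(abs(true_d))
  big_delta <- lambda * sqrt(mix$var) * sqrt(2 / trials_per_cell)
  delta <- big_delta / (1 - q)          # fast guesses dilute the mean shift
  list(delta = delta, mix_mean = mix$mean, mix_sd = sqrt(mix$var),
       lambda = lambda)
}

# truncated-normal draws via inverse CDF (vectorised over mean). When the
# mean sits many SDs below the floor the truncated mass collapses onto the
# floor and pnorm saturates; the non-finite inverse-CDF values that produces
# are exactly floor-valued draws.
.rtnorm_floor <- function(n, mean, sd, floor, rng) {
  lo <- stats::pnorm((floor - mean) / sd)
  u <- .rng_eval(rng, runif(n, lo, 1))
  x <- mean + sd * stats::qnorm(u)
  x[!is.finite(x)] <- floor
  pmax(x, floor)
}

#' Simulate FT-IRAP trial latencies and first-response accuracy
#'
#' Draws independent trials of one trial type under given block conditions,
#' with the latency shift calibrated so the population D equals `true_d` (see
#' [dscore_calibration()]).
#'
#' @param condition Character vector (recycled against `n`) of
#'   `"consistent"` / `"inconsistent"` labels, or a single value.
#' @param n Number of trials; defaults to `length(condition)`.
#' @param true_d Target ground-truth D for this trial type.
#' @param params An [rt_params()] object.
#' @param seed Integer seed, or `rng` an existing stream.
#' @param rng Internal RNG stream (overrides `seed`).
#' @return Data.frame with columns `condition`, `latency_ms`,
#'   `first_response_correct`.
#' @export
simulate_trials <- function(condition, n = length(condition), true_d = 0,
                            params = rt_params(), seed = 1L, rng = NULL) {
  if (is.null(rng)) rng <- .new_rng(seed)
  condition <- rep_len(condition, n)
  sgn <- ifelse(condition == "consistent", -1, 1)
  if (anyNA(match(condition, c("consistent", "inconsistent"))))
    stop("condition must be consistent or inconsistent", call. = FALSE)
  calib <- dscore_calibration(true_d, params)
  .sim_latency(sgn, rep_len(calib$delta, n), params, rng)
}

# core sampler: sgn is -1 (consistent) / +1 (inconsistent) per trial,
# delta the calibrated full shift per trial
.sim_latency <- function(sgn, delta, params, rng) {
  n <- length(sgn)
  mu <- params$base_mean_ms + sgn * delta / 2
  lat <- .rtnorm_floor(n, mu, params$base_sd_ms, params$floor_ms, rng)
  err <- .rng_eval(rng, runif(n)) < params$error_rate
  n_err <- sum(err)
  if (n_err > 0)
    lat[err] <- lat[err] + .rng_eval(rng, rgamma(n_err, params$penalty_shape,
                                                 scale = params$penalty_scale))
  fg <- .rng_eval(rng, runif(n)) < params$fast_guess_rate
  n_fg <- sum(fg)
  if (n_fg > 0)
    lat[fg] <- .rng_eval(rng, runif(n_fg, 0, params$fast_guess_max_ms))
  data.frame(condition = ifelse(sgn < 0, "consistent", "inconsistent"),
             latency_ms = lat,
             first_response_correct = !err,
             stringsAsFactors = FALSE)
}

# ---- truth panels -----------------------------------------------------------

#' Ground-truth D grid for a simulated study
#'
#' A truth grid assigns one true D value per group, time point and trial
#' type. `default_truth_grid()` returns the study-scale configuration: two
#' groups (`pst`, `neutral`), three time points, with values equal to the
#' observed group-mean D scores of the motivating study — including the
#' intervention effect concentrated on don't-expect-negative trials at Times
#' 2-3 of the `pst` group. `flat_truth_grid()` builds a grid from a single
#' baseline profile plus an optional additive group effect, which is the
#' natural configuration for null-calibration and power experiments.
#'
#' @param groups Character vector of group labels.
#' @param n_timepoints Number of sessions per participant.
#' @param baseline Named numeric vector of length 4 (one value per
#'   [TRIAL_TYPES] entry) used at every group/time cell.
#' @param group_effect Value added to `baseline` for `effect_group` on
#'   `effect_trial_type` at `effect_times`.
#' @param effect_group,effect_trial_type,effect_times Where the effect is
#'   applied.
#' @return Data.frame with columns `group`, `time_point`, `trial_type`,
#'   `true_d`.
#' @export
default_truth_grid <- function() {
  vals <- rbind(
    c(0.65, -0.06, 0.15, 0.05),   # pst t1
    c(0.72, -0.22, 0.09, 0.26),   # pst t2
    c(0.51, -0.19, 0.09, 0.21),   # pst t3
    c(0.51, -0.25, 0.11, 0.27),   # neutral t1
    c(0.44, -0.24, 0.19, 0.12),   # neutral t2
    c(0.44, -0.27, 0.05, 0.15))   # neutral t3
  data.frame(group = rep(c("pst", "neutral"), each = 12L),
             time_point = rep(rep(1:3, each = 4L), times = 2L),
             trial_type = rep(TRIAL_TYPES, times = 6L),
             true_d = as.vector(t(vals)),
             stringsAsFactors = FALSE)
}

#' @rdname default_truth_grid
#' @export
flat_truth_grid <- function(groups = c("pst", "neutral"), n_timepoints = 3L,
                            baseline = c("expect-positive" = 0,
                                         "expect-negative" = 0,
                                         "dont-expect-positive" = 0,
                                         "dont-expect-negative" = 0),
                            group_effect = 0, effect_group = groups[1],
                            effect_trial_type = "dont-expect-negative",
                            effect_times = seq_len(n_timepoints)[-1]) {
  baseline <- baseline[TRIAL_TYPES]
  if (anyNA(baseline))
    stop("'baseline' must name all four trial types", call. = FALSE)
  grid <- expand.grid(trial_type = TRIAL_TYPES,
                      time_point = seq_len(n_timepoints),
                      group = groups, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$true_d <- baseline[grid$trial_type]
  hit <- grid$group == effect_group & grid$trial_type == effect_trial_type &
    grid$time_point %in% effect_times
  grid$true_d[hit] <- grid$true_d[hit] + group_effect
  if (any(abs(grid$true_d) > 2))
    stop("|true_d| must be <= 2 everywhere in the grid", call. = FALSE)
  grid[, c("group", "time_point", "trial_type", "true_d")]
}

# ---- cohort configuration and simulation ------------------------------------

#' Configuration of a simulated FT-IRAP cohort
#'
#' Defaults reproduce the design of the motivating study: 36 + 37
#' participants in two groups, three FT-IRAP administrations each, CESD-R
#' totals with mean 19.9, SD 13.0 and right skew 0.73, and first-block
#' condition counterbalanced across participants.
#'
#' @param n_per_group Named integer vector of group sizes (names are group
#'   labels).
#' @param n_timepoints Sessions per participant.
#' @param seed Master seed; all cohort randomness derives from it.
#' @param sd_between Between-participant SD of true D around the grid value
#'   (individual differences in implicit orientation).
#' @param cesdr_mean,cesdr_sd,cesdr_skew Target moments of the CESD-R total
#'   distribution (drawn from a moment-matched shifted gamma, rounded and
#'   clipped to 0-80).
#' @param dysphoria_cutoff Total at or above which the dysphoria flag is set.
#' @param n_fast_violators Participants seeded to violate the fast-trial
#'   (>10% of trials at 300 ms or less) exclusion rule.
#' @param n_accuracy_violators Participants seeded to violate the 80%
#'   block-accuracy rule.
#' @param include_questionnaires Generate CESD-R items, VAMS and task
#'   ratings? Disable for large scoring-only simulation studies.
#' @return Object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_per_group = c(pst = 36L, neutral = 37L),
                          n_timepoints = 3L, seed = 1L, sd_between = 0.30,
                          cesdr_mean = 19.9, cesdr_sd = 13.0,
                          cesdr_skew = 0.73, dysphoria_cutoff = 16L,
                          n_fast_violators = 0L, n_accuracy_violators = 0L,
                          include_questionnaires = TRUE) {
  if (is.null(names(n_per_group)))
    names(n_per_group) <- c("pst", "neutral")[seq_along(n_per_group)]
  if (any(n_per_group < 2L))
    stop("need at least 2 participants per group", call. = FALSE)
  structure(list(n_per_group = n_per_group, n_timepoints = n_timepoints,
                 seed = seed, sd_between = sd_between,
                 cesdr_mean = cesdr_mean, cesdr_sd = cesdr_sd,
                 cesdr_skew = cesdr_skew, dysphoria_cutoff = dysphoria_cutoff,
                 n_fast_violators = n_fast_violators,
                 n_accuracy_violators = n_accuracy_violators,
                 include_questionnaires = include_questionnaires),
            class = "cohort_config")
}

# skewed totals: shifted gamma matched to (mean, sd, skew), rounded, clipped.
# With the default parameters ~5% of draws clip at 0, lifting the mean by
# well under one point.
.sim_cesdr_totals <- function(n, mean, sd, skew, rng) {
  if (skew <= 0) {
    tot <- .rng_eval(rng, rnorm(n, mean, sd))
  } else {
    shape <- (2 / skew)^2
    scale <- sd / sqrt(shape)
    shift <- mean - shape * scale
    tot <- shift + .rng_eval(rng, rgamma(n, shape, scale = scale))
  }
  pmin(80L, pmax(0L, as.integer(round(tot))))
}

# uniform composition of `total` over 20 items capped at 4: choose `total`
# of the 80 unit slots without replacement
.sim_cesdr_items <- function(total, rng) {
  slots <- .rng_eval(rng, sample.int(80L, total))
  tabulate((slots - 1L) %/% 4L + 1L, nbins = 20L)
}

.vams_defaults <- function() {
  list(pst = list(pos_mean = c(66.97, 69.83, 70.72, 76.53),
                  pos_sd = c(15.45, 21.67, 21.67, 16.57),
                  neg_mean = c(21.14, 19.25, 17.69, 16.31),
                  neg_sd = c(18.24, 21.47, 17.56, 17.55),
                  vividness = c(4.39, 1.05), emotionality = c(4.00, 1.64)),
       neutral = list(pos_mean = c(67.95, 65.95, 73.84, 73.08),
                      pos_sd = c(14.75, 16.66, 16.36, 18.71),
                      neg_mean = c(21.19, 22.73, 16.78, 17.00),
                      neg_sd = c(16.33, 17.78, 14.88, 17.10),
                      vividness = c(4.44, 1.46), emotionality = c(1.20, 1.27)))
}

#' Simulate one FT-IRAP session
#'
#' Produces one trial record per scheduled trial, with latencies drawn from
#' the calibrated generative model for the participant's true D profile.
#'
#' @param participant_id Identifier copied into every record.
#' @param time_point Session number (1-based).
#' @param schedule Data.frame from [ftirap_schedule()] (practice rows, if
#'   present, are simulated too and keep their flag).
#' @param true_d Named numeric vector: true D per trial type.
#' @param params An [rt_params()] object (per-participant overrides allowed).
#' @param seed Integer seed, or `rng` an existing stream.
#' @param rng Internal RNG stream (overrides `seed`).
#' @return Data.frame of trial records (schedule columns plus
#'   `participant_id`, `time_point`, `latency_ms`,
#'   `first_response_correct`).
#' @export
simulate_session <- function(participant_id, time_point, schedule,
                             true_d, params = rt_params(), seed = 1L,
                             rng = NULL) {
  if (is.null(rng)) rng <- .new_rng(seed)
  true_d <- true_d[TRIAL_TYPES]
  if (anyNA(true_d))
    stop("'true_d' must name all four trial types", call. = FALSE)
  calib <- dscore_calibration(true_d, params)
  delta <- calib$delta[match(schedule$trial_type, TRIAL_TYPES)]
  sgn <- ifelse(schedule$condition == "consistent", -1, 1)
  sim <- .sim_latency(sgn, delta, params, rng)
  out <- schedule
  out$participant_id <- participant_id
  out$time_point <- as.integer(time_point)
  out$latency_ms <- sim$latency_ms
  out$first_response_correct <- sim$first_response_correct
  out[, c("participant_id", "time_point", "block_index", "condition",
          "trial_index", "trial_type", "sample", "target",
          "first_response_correct", "latency_ms", "practice")]
}

#' Simulate a full FT-IRAP cohort
#'
#' Generates, per participant: a group label, one scored FT-IRAP session per
#' time point (first-block condition counterbalanced within group), a CESD-R
#' item vector whose total follows the configured skewed distribution, four
#' VAMS positive/negative readings, vividness and emotionality ratings, age
#' and gender. Participant-level true D values are the truth-grid cell values
#' plus a Normal(0, `sd_between`) individual deviation (clipped to the D
#' range), and are returned so recovery can be checked against ground truth.
#'
#' @param config A [cohort_config()].
#' @param params An [rt_params()] object shared by all regular participants.
#' @param truth Truth grid (see [default_truth_grid()]); must cover every
#'   group and time point in the config.
#' @param stimuli Stimulus set used for the schedules.
#' @return Object of class `"ftirap_cohort"`: list with `trials`
#'   (long-format trial log), `participants` (one row per participant),
#'   `truth` (per-participant true D values) and `config`/`params` echoes.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_per_group = c(pst = 3,
#'                                                         neutral = 3),
#'                                         n_timepoints = 1, seed = 42))
#' nrow(cohort$trials)  # 6 participants x 96 trials
#' @export
simulate_cohort <- function(config = cohort_config(), params = rt_params(),
                            truth = default_truth_grid(),
                            stimuli = ftirap_stimuli()) {
  groups <- names(config$n_per_group)
  need <- expand.grid(group = groups,
                      time_point = seq_len(config$n_timepoints),
                      trial_type = TRIAL_TYPES, stringsAsFactors = FALSE)
  key <- function(g, t, tt) paste(g, t, tt, sep = "\r")
  truth_val <- setNames(truth$true_d,
                        key(truth$group, truth$time_point, truth$trial_type))
  if (anyNA(truth_val[key(need$group, need$time_point, need$trial_type)]))
    stop("truth grid does not cover every group/time/trial-type cell",
         call. = FALSE)

  rng <- .new_rng(config$seed)
  n_total <- sum(config$n_per_group)
  ids <- sprintf("P%03d", seq_len(n_total))
  group <- rep(groups, times = config$n_per_group)

  # seeded violators, spread over the whole cohort
  violator <- rep("none", n_total)
  nv <- config$n_fast_violators + config$n_accuracy_violators
  if (nv > 0) {
    pick <- unique(round(seq(1, n_total, length.out = nv)))
    while (length(pick) < nv) pick <- union(pick, .rng_eval(rng,
      sample.int(n_total, 1L)))
    violator[pick[seq_len(config$n_fast_violators)]] <- "fast"
    if (config$n_accuracy_violators > 0)
      violator[pick[config$n_fast_violators + # nolint
                      seq_len(config$n_accuracy_violators)]] <- "accuracy"
  }

  child <- .rng_child_seeds(rng, n_total)
  trials <- vector("list", n_total)
  truth_rows <- vector("list", n_total)
  part_rows <- vector("list", n_total)
  counterbalance <- c("consistent", "inconsistent")
  vams_def <- .vams_defaults()

  for (i in seq_len(n_total)) {
    prng <- .new_rng(child[i])
    g <- group[i]
    p_i <- params
    if (violator[i] == "fast") p_i$fast_guess_rate <- 0.25
    if (violator[i] == "accuracy") p_i$error_rate <- 0.50
    # individual deviation shared across time points, per trial type
    dev <- .rng_eval(prng, rnorm(4L, 0, config$sd_between))
    first <- counterbalance[(i - 1L) %% 2L + 1L]
    # individual deviations are clipped to the calibration's representable
    # range (just under the c0 bound of the estimator), not the clamp bound
    cap <- .calib_inverse(6L, .mixture_moments(p_i)$kurt_ex)$d_max - 1e-6
    sess <- vector("list", config$n_timepoints)
    tp_truth <- vector("list", config$n_timepoints)
    for (tp in seq_len(config$n_timepoints)) {
      d_tp <- truth_val[key(g, tp, TRIAL_TYPES)] + dev
      d_tp <- pmin(cap, pmax(-cap, d_tp))
      names(d_tp) <- TRIAL_TYPES
      sched <- ftirap_schedule(stimuli, first_block_condition = first,
                               seed = .rng_child_seeds(prng, 1L))
      sess[[tp]] <- simulate_session(ids[i], tp, sched, d_tp, p_i, rng = prng)
      tp_truth[[tp]] <- data.frame(participant_id = ids[i], group = g,
                                   time_point = tp, trial_type = TRIAL_TYPES,
                                   true_d = unname(d_tp),
                                   stringsAsFactors = FALSE)
    }
    trials[[i]] <- do.call(rbind, sess)
    truth_rows[[i]] <- do.call(rbind, tp_truth)

    row <- data.frame(participant_id = ids[i], group = g,
                      stringsAsFactors = FALSE)
    if (config$include_questionnaires) {
      vd <- vams_def[[if (g %in% names(vams_def)) g else 1L]]
      tot <- .sim_cesdr_totals(1L, config$cesdr_mean, config$cesdr_sd,
                               config$cesdr_skew, prng)
      items <- .sim_cesdr_items(tot, prng)
      row[paste0("c", sprintf("%02d", 1:20))] <- as.list(items)
      row$cesdr_total <- tot
      row$dysphoria <- tot >= config$dysphoria_cutoff
      for (occ in 1:4) {
        row[[paste0("vams_pos_", occ)]] <- min(100, max(0,
          .rng_eval(prng, rnorm(1, vd$pos_mean[occ], vd$pos_sd[occ]))))
        row[[paste0("vams_neg_", occ)]] <- min(100, max(0,
          .rng_eval(prng, rnorm(1, vd$neg_mean[occ], vd$neg_sd[occ]))))
      }
      row$vividness <- min(6, max(0, round(.rng_eval(prng,
        rnorm(1, vd$vividness[1], vd$vividness[2])))))
      row$emotionality <- min(6, max(0, round(.rng_eval(prng,
        rnorm(1, vd$emotionality[1], vd$emotionality[2])))))
      row$age <- min(50, max(18, round(.rng_eval(prng, rnorm(1, 22.8, 7.6)))))
      row$gender <- if (.rng_eval(prng, runif(1)) <
                          (if (g == "pst") 28 / 36 else 31 / 37))
        "female" else "male"
      row$treatment_status <- c("current", "previous", "never")[
        1L + findInterval(.rng_eval(prng, runif(1)),
                          cumsum((if (g == "pst") c(2, 9) else c(3, 8)) /
                                   sum(config$n_per_group[g])))]
    }
    part_rows[[i]] <- row
  }

  structure(list(trials = do.call(rbind, trials),
                 participants = do.call(rbind, part_rows),
                 truth = do.call(rbind, truth_rows),
                 config = config, params = params),
            class = "ftirap_cohort")
}
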