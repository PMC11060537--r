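# ---- change scores, post-hoc tests and summary statistics -------------------

#' Within-participant change scores between two D-score panels
#'
#' Subtracts panel `a` values from panel `b` values per participant and
#' trial type (`b - a`; pass the baseline as `a`). Participants present in
#' only one panel are dropped with a warning.
#'
#' @param panel_a,panel_b D-score panels as returned by [compute_dscores()]
#'   (columns `participant_id`, `trial_type`, `d`), e.g. two time points of
#'   the same cohort.
#' @return Data.frame `participant_id`, `trial_type`, `value` (= d_b - d_a).
#' @export
change_scores <- function(panel_a, panel_b) {
  for (p in list(panel_a, panel_b))
    if (!all(c("participant_id", "trial_type", "d") %in% names(p)))
      stop("panels need columns participant_id, trial_type, d",
           call. = FALSE)
  only <- union(setdiff(panel_a$participant_id, panel_b$participant_id),
                setdiff(panel_b$participant_id, panel_a$participant_id))
  if (length(only))
    warning("dropping participant(s) present in one panel only: ",
            paste(unique(only), collapse = ", "), call. = FALSE)
  m <- merge(panel_a[, c("participant_id", "trial_type", "d")],
             panel_b[, c("participant_id", "trial_type", "d")],
             by = c("participant_id", "trial_type"),
             suffixes = c("_a", "_b"))
  out <- data.frame(participant_id = m$participant_id,
                    trial_type = m$trial_type,
                    value = m$d_b - m$d_a,
                    stringsAsFactors = FALSE)
  out[order(out$participant_id, match(out$trial_type, TRIAL_TYPES)), ,
      drop = FALSE]
}

#' Pooled-variance two-sample t test (raw data or summaries)
#'
#' Either supply two raw vectors, or the two groups' `(mean, sd, n)`
#' summaries. Degrees of freedom are `n1 + n2 - 2`.
#'
#' @param x,y Raw observations per group (ignored if summaries given).
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries.
#' @return List with `t`, `df`, `p` (two-sided), `mean_diff`, `pooled_sd`.
#' @examples
#' group_t_test(mean1 = 20.06, sd1 = 12.87, n1 = 36,
#'              mean2 = 19.78, sd2 = 13.27, n2 = 37)$t  # 0.09
#' @export
group_t_test <- function(x = NULL, y = NULL, mean1 = NULL, sd1 = NULL,
                         n1 = NULL, mean2 = NULL, sd2 = NULL, n2 = NULL) {
  if (!is.null(x)) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in each group", call. = FALSE)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  t <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean_diff = mean1 - mean2, pooled_sd = sp)
}

#' Per-level Bonferroni-corrected group comparisons
#'
#' For each within-subject level, compares the two groups with a
#' pooled-variance t test, reports Cohen's d (mean difference divided by the
#' pooled SD) and Bonferroni-adjusted p values (`min(1, m * p)`), and group
#' means with 95% confidence intervals built from the per-level pooled SD.
#'
#' @param data Long outcome data: columns `participant_id`, `group`,
#'   `trial_type` (or any within-level column named by `within`), `value`.
#' @param m Number of comparisons used for the correction; defaults to the
#'   number of within levels, so four trial types give the conventional
#'   corrected alpha of .0125.
#' @param within Name of the within-level column.
#' @return Data.frame, one row per within level x group, with the test
#'   statistics repeated across the two group rows: `t`, `df`, `p_raw`,
#'   `p_bonferroni`, `cohens_d`, and per-group `mean`, `ci_lo`, `ci_hi`.
#' @export
posthoc_group_tests <- function(data, m = NULL, within = "trial_type") {
  groups <- unique(as.character(data$group))   # order of appearance
  if (length(groups) != 2L) stop("need exactly two groups", call. = FALSE)
  levs <- unique(as.character(data[[within]]))
  if (is.null(m)) m <- length(levs)
  mm <- marginal_means(data, within = within)
  rows <- lapply(levs, function(lv) {
    x <- data$value[data[[within]] == lv & data$group == groups[1]]
    y <- data$value[data[[within]] == lv & data$group == groups[2]]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      tt <- list(t = NA_real_, df = length(x) + length(y) - 2, p = NA_real_,
                 mean_diff = mean(x) - mean(y), pooled_sd = 0)
      d <- NA_real_
    } else {
      tt <- group_t_test(x, y)
      d <- tt$mean_diff / tt$pooled_sd
    }
    cells <- mm[mm[[within]] == lv, , drop = FALSE]
    data.frame(within_level = lv, group = cells$group,
               t = tt$t, df = tt$df, p_raw = tt$p,
               p_bonferroni = pmin(1, m * tt$p),
               cohens_d = d, mean = cells$mean,
               ci_lo = cells$ci_lo, ci_hi = cells$ci_hi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction (the convention matching
#' the reported group-comparison statistics); df = (rows-1)(cols-1).
#'
#' @param counts Matrix (or object coercible to one) of nonnegative integer
#'   counts.
#' @return List with `chi2`, `df`, `p`.
#' @examples
#' chi_square_2xk(matrix(c(28, 8, 31, 6), 2, byrow = TRUE))$chi2  # 0.42
#' @export
chi_square_2xk <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal; table is degenerate", call. = FALSE)
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Pearson correlation with two-sided t-based p value
#'
#' @param x,y Numeric vectors, `n >= 3`, nonconstant.
#' @return List with `r`, `n`, `p`; constant input yields `NA` with a
#'   warning.
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; correlation undefined", call. = FALSE)
    return(list(r = NA_real_, n = length(x), p = NA_real_))
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), n = length(x), p = ct$p.value)
}

#' Marginal means with pooled-variance confidence intervals
#'
#' Per (group, within level) cell mean with a 95% CI of
#' `mean +/- t(N - 2, .975) * s_pooled / sqrt(n_group)`, where `s_pooled`
#' pools the two groups' variances within that level (`N` = total subjects).
#'
#' @param data Long outcome data (`group`, within-level column, `value`).
#' @param within Name of the within-level column.
#' @param conf Confidence level.
#' @return Data.frame: within level, `group`, `n`, `mean`, `sd`,
#'   `pooled_sd`, `ci_lo`, `ci_hi`.
#' @export
marginal_means <- function(data, within = "trial_type", conf = 0.95) {
  groups <- unique(as.character(data$group))   # order of appearance
  if (length(groups) != 2L) stop("need exactly two groups", call. = FALSE)
  levs <- unique(as.character(data[[within]]))
  rows <- lapply(levs, function(lv) {
    x <- data$value[data[[within]] == lv & data$group == groups[1]]
    y <- data$value[data[[within]] == lv & data$group == groups[2]]
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2 || n2 < 2) stop("need n >= 2 per group", call. = FALSE)
    sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
                 (n1 + n2 - 2))
    tcrit <- stats::qt(1 - (1 - conf) / 2, n1 + n2 - 2)
    out <- data.frame(within_level = lv, group = groups,
                      n = c(n1, n2), mean = c(mean(x), mean(y)),
                      sd = c(stats::sd(x), stats::sd(y)), pooled_sd = sp,
                      stringsAsFactors = FALSE)
    out$ci_lo <- out$mean - tcrit * sp / sqrt(out$n)
    out$ci_hi <- out$mean + tcrit * sp / sqrt(out$n)
    names(out)[1] <- within
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
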