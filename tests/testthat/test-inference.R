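# long-format helper: n1 + n2 subjects, k within levels, optional covariate
make_long <- function(n1, n2, k = 4, seed = 1, covariate = FALSE) {
  set.seed(seed)
  n <- n1 + n2
  d <- expand.grid(participant_id = sprintf("s%03d", seq_len(n)),
                   trial_type = paste0("w", seq_len(k)),
                   stringsAsFactors = FALSE)
  d$group <- rep(rep(c("pst", "neutral"), c(n1, n2)), times = k)
  d$value <- rnorm(nrow(d)) + rep(rnorm(n), times = k)  # subject effects
  if (covariate) {
    cv <- data.frame(participant_id = sprintf("s%03d", seq_len(n)),
                     cov = runif(n, 1, 9), stringsAsFactors = FALSE)
    d <- merge(d, cv)
  }
  d
}

test_that("split-plot layout reproduces the conventional degrees of freedom", {
  d <- make_long(36, 37, k = 4, seed = 2, covariate = TRUE)
  plain <- splitplot_anova(d, within = "trial_type")
  expect_equal(plain$table$df1[plain$table$effect == "trial_type"], 3L)
  expect_equal(plain$table$df2[plain$table$effect == "trial_type"], 213L)
  expect_equal(plain$table$df2[plain$table$effect == "group"], 71L)
  anc <- splitplot_anova(d, within = "trial_type", covariate = "cov")
  expect_equal(anc$table$df2[anc$table$effect == "trial_type"], 210L)
  expect_equal(anc$table$df2[anc$table$effect == "trial_type:cov"], 210L)
  expect_equal(anc$table$df2[anc$table$effect == "group"], 70L)
  # the 2-level within design used for mood scores
  d2 <- make_long(36, 37, k = 2, seed = 3, covariate = TRUE)
  anc2 <- splitplot_anova(d2, within = "trial_type", covariate = "cov")
  expect_equal(anc2$table$df2[anc2$table$effect == "trial_type"], 70L)
})

test_that("ANOVA and ANCOVA tables match car's type-III univariate tests", {
  for (seed in 1:5) {
    d <- make_long(9, 12, k = 4, seed = seed, covariate = TRUE)
    wide <- stats::reshape(d, idvar = c("participant_id", "group", "cov"),
                           timevar = "trial_type", direction = "wide")
    Y <- as.matrix(wide[, paste0("value.w", 1:4)])
    idata <- data.frame(tt = factor(paste0("w", 1:4)))
    fit_c <- car::Anova(lm(Y ~ group + cov, data = wide,
                           contrasts = list(group = "contr.sum")),
                        idata = idata, idesign = ~tt, type = 3)
    ref <- suppressWarnings(summary(fit_c,
      multivariate = FALSE))$univariate.tests
    fit <- splitplot_anova(d, within = "trial_type", covariate = "cov")
    tab <- fit$table
    pick <- function(eff) tab[tab$effect == eff, ]
    for (pair in list(c("group", "group"), c("cov", "cov"),
                      c("tt", "trial_type"), c("group:tt",
                                               "trial_type:group"),
                      c("cov:tt", "trial_type:cov"))) {
      expect_equal(pick(pair[2])$SS, ref[pair[1], "Sum Sq"],
                   tolerance = 1e-8)
      expect_equal(pick(pair[2])$F, ref[pair[1], "F value"],
                   tolerance = 1e-8)
      expect_equal(unname(pick(pair[2])$df2), unname(ref[pair[1], "den Df"]))
    }
  }
})

test_that("stratum sums of squares add up to the total", {
  for (seed in 4:6) {
    d <- make_long(8, 8, k = 3, seed = seed)
    fit <- splitplot_anova(d, within = "trial_type")
    expect_equal(fit$ss_between_stratum + fit$ss_within_stratum,
                 fit$ss_total, tolerance = 1e-8)
    # balanced no-covariate case: components exhaust their strata
    tab <- fit$table
    expect_equal(tab$SS[tab$effect == "group"] + fit$error$SS[1],
                 fit$ss_between_stratum, tolerance = 1e-8)
    within_ss <- sum(tab$SS[tab$effect != "group"]) + fit$error$SS[2]
    expect_equal(within_ss, fit$ss_within_stratum, tolerance = 1e-8)
  }
})

test_that("with one within level per contrast F equals the squared pooled t", {
  set.seed(11)
  # two groups, two within levels: the interaction F must equal t^2 on the
  # within-subject differences
  d <- make_long(10, 13, k = 2, seed = 11)
  fit <- splitplot_anova(d, within = "trial_type")
  w <- stats::reshape(d, idvar = c("participant_id", "group"),
                      timevar = "trial_type", direction = "wide")
  diff <- w$value.w1 - w$value.w2
  tt <- group_t_test(diff[w$group == "pst"], diff[w$group == "neutral"])
  intx <- fit$table[fit$table$effect == "trial_type:group", ]
  expect_equal(intx$F, tt$t^2, tolerance = 1e-10)
  expect_equal(intx$df2, tt$df)
  # group main effect F is the squared t on subject means
  mu <- (w$value.w1 + w$value.w2) / 2
  tg <- group_t_test(mu[w$group == "pst"], mu[w$group == "neutral"])
  expect_equal(fit$table$F[fit$table$effect == "group"], tg$t^2,
               tolerance = 1e-10)
})

test_that("degenerate designs are rejected with a diagnosis", {
  d <- make_long(6, 6, k = 3, seed = 9, covariate = TRUE)
  d$cov <- 5
  expect_error(splitplot_anova(d, within = "trial_type", covariate = "cov"),
               "constant")
  one <- make_long(6, 6, k = 3, seed = 9)
  one$group <- "pst"
  expect_error(splitplot_anova(one, within = "trial_type"), "2 groups")
  drop1 <- make_long(6, 6, k = 3, seed = 9)[-1, ]
  expect_warning(splitplot_anova(drop1, within = "trial_type"),
                 "incomplete")
})

test_that("partial eta squared lies in [0,1] and matches its definition", {
  d <- make_long(7, 7, k = 4, seed = 15)
  fit <- splitplot_anova(d, within = "trial_type")
  tab <- fit$table
  expect_true(all(tab$partial_eta_sq >= 0 & tab$partial_eta_sq <= 1))
  err <- ifelse(tab$effect == "group", fit$error$SS[1], fit$error$SS[2])
  expect_equal(tab$partial_eta_sq, tab$SS / (tab$SS + err), tolerance = 1e-12)
})

test_that("summary statistics reproduce the published group comparisons", {
  # CESD-R means/SDs by group
  tt <- group_t_test(mean1 = 20.06, sd1 = 12.87, n1 = 36,
                     mean2 = 19.78, sd2 = 13.27, n2 = 37)
  expect_equal(round(tt$t, 2), 0.09)
  expect_equal(tt$df, 71)
  # gender split by group, Pearson chi-square without Yates correction
  cs <- chi_square_2xk(matrix(c(28, 8, 31, 6), 2, byrow = TRUE))
  expect_equal(round(cs$chi2, 2), 0.42)
  expect_equal(cs$df, 1L)
  # expect-positive baseline cell: mean .65, SDs .47/.37, n 36/37
  set.seed(8)
  mk <- function(m, s, n) m + s * scale(rnorm(n))[, 1]
  df <- data.frame(
    participant_id = sprintf("s%02d", 1:73),
    group = rep(c("pst", "neutral"), c(36, 37)),
    trial_type = "expect-positive",
    value = c(mk(0.65, 0.47, 36), mk(0.51, 0.37, 37)))
  mm <- marginal_means(df)
  pst <- mm[mm$group == "pst", ]
  expect_equal(round(pst$ci_lo, 2), 0.51)
  expect_equal(round(pst$ci_hi, 2), 0.79)
})

test_that("t tests agree across interfaces and with the Welch limit", {
  set.seed(23)
  x <- rnorm(20, 1); y <- rnorm(25, 0.4)
  raw <- group_t_test(x, y)
  summ <- group_t_test(mean1 = mean(x), sd1 = sd(x), n1 = 20,
                       mean2 = mean(y), sd2 = sd(y), n2 = 25)
  expect_equal(raw$t, summ$t, tolerance = 1e-12)
  expect_equal(raw$p, t.test(x, y, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
  expect_equal(group_t_test(x, x)$t, 0)
  # equal variances and n: Welch reduces to the pooled test
  y2 <- rnorm(20, 0, sd(x))
  expect_equal(group_t_test(x, y2)$t, unname(t.test(x, y2)$statistic),
               tolerance = 1e-6)
})

test_that("chi-square behaves on degenerate and proportional tables", {
  prop <- outer(c(40, 80), c(0.25, 0.75))
  expect_equal(chi_square_2xk(prop)$chi2, 0, tolerance = 1e-12)
  expect_error(chi_square_2xk(matrix(c(0, 0, 3, 4), 2)), "marginal")
  # 2x2 chi-square equals the squared two-proportion z statistic
  tab <- matrix(c(12, 20, 25, 15), 2)
  p1 <- tab[1, 1] / sum(tab[1, ]); p2 <- tab[2, 1] / sum(tab[2, ])
  pp <- sum(tab[, 1]) / sum(tab)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / sum(tab[1, ]) +
                                           1 / sum(tab[2, ])))
  expect_equal(chi_square_2xk(tab)$chi2, z^2, tolerance = 1e-10)
})

test_that("pearson_r matches cor.test and handles edge cases", {
  set.seed(4)
  x <- rnorm(40); y <- 2 * x
  expect_equal(pearson_r(x, y)$r, 1, tolerance = 1e-12)
  z <- rnorm(40)
  expect_equal(pearson_r(x, z)$r, pearson_r(z, x)$r)
  expect_lt(abs(pearson_r(x, z)$r), 3 / sqrt(40))
  expect_warning(out <- pearson_r(x, rep(1, 40)), "constant")
  expect_true(is.na(out$r))
})

test_that("change scores subtract panels and are antisymmetric", {
  t1 <- data.frame(participant_id = rep(c("a", "b"), each = 4),
                   trial_type = rep(TRIAL_TYPES, 2),
                   d = c(0.05, 0.1, -0.2, 0.4, 0.3, 0, 0.1, -0.1))
  t2 <- t1
  t2$d <- t1$d + c(0.21, rep(0.05, 7))
  ch <- change_scores(t1, t2)
  expect_equal(ch$value[ch$participant_id == "a" &
                          ch$trial_type == "expect-positive"], 0.21)
  rev <- change_scores(t2, t1)
  expect_equal(rev$value, -ch$value)
  expect_equal(change_scores(t1, t1)$value, rep(0, 8))
  extra <- rbind(t2, data.frame(participant_id = "c",
                                trial_type = TRIAL_TYPES, d = 0))
  expect_warning(ch2 <- change_scores(t1, extra), "one panel only")
  expect_equal(sort(unique(ch2$participant_id)), c("a", "b"))
})

test_that("post-hoc tests implement Bonferroni and Cohen's d conventions", {
  set.seed(33)
  d <- make_long(15, 15, k = 4, seed = 33)
  ph <- posthoc_group_tests(d, within = "trial_type")
  expect_true(all(ph$p_bonferroni >= ph$p_raw))
  expect_true(all(ph$p_bonferroni <= 1))
  expect_equal(ph$p_bonferroni, pmin(1, 4 * ph$p_raw), tolerance = 1e-12)
  # d = 1 for unit separation at unit pooled SD
  df2 <- data.frame(participant_id = sprintf("s%02d", 1:40),
                    group = rep(c("pst", "neutral"), each = 20),
                    trial_type = "w1", value = 0)
  df2$value <- c(scale(rnorm(20))[, 1] + 1, scale(rnorm(20))[, 1])
  ph2 <- posthoc_group_tests(df2, m = 4, within = "trial_type")
  expect_equal(unique(ph2$cohens_d), 1, tolerance = 1e-12)
  # equal means give t = 0, d = 0
  df2$value <- rep(c(1, 2), 20)
  ph3 <- posthoc_group_tests(df2, m = 4, within = "trial_type")
  expect_equal(unique(ph3$t), 0)
  expect_equal(unique(ph3$cohens_d), 0)
})

test_that("marginal means have pooled CIs with the expected width behaviour", {
  df <- data.frame(participant_id = sprintf("s%02d", 1:40),
                   group = rep(c("pst", "neutral"), each = 20),
                   trial_type = "w1",
                   value = rep(c(1, 2), each = 20))
  mm <- marginal_means(df)
  expect_equal(mm$ci_lo, mm$mean)      # zero variance -> zero width
  set.seed(5)
  mk_mm <- function(n) {
    d <- data.frame(participant_id = sprintf("s%03d", seq_len(2 * n)),
                    group = rep(c("pst", "neutral"), each = n),
                    trial_type = "w1",
                    value = c(scale(rnorm(n))[, 1], scale(rnorm(n))[, 1]))
    mm <- marginal_means(d)
    mm$ci_hi[1] - mm$ci_lo[1]
  }
  w20 <- mk_mm(20); w80 <- mk_mm(80)
  expect_equal(w20 / w80, sqrt(80 / 20), tolerance = 0.05)
})
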