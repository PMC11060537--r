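# ---- CESD-R, VAMS and covariate diagnostics --------------------------------

#' Score a CESD-R response
#'
#' Sums the 20 items (each 0-4) into a 0-80 total and flags dysphoria at the
#' configurable cutoff. The 16-point cutoff is the common CESD screening
#' convention for subclinical depressive symptomatology.
#'
#' @param items Integer vector of exactly 20 item responses in 0..4.
#' @param dysphoria_cutoff Total at or above which the dysphoria flag is set.
#' @return List with `items`, `total`, `dysphoria`.
#' @examples
#' score_cesdr(rep(1, 20))$total  # 20
#' @export
score_cesdr <- function(items, dysphoria_cutoff = 16L) {
  if (length(items) != 20L)
    stop("CESD-R needs exactly 20 items, got ", length(items), call. = FALSE)
  bad <- which(is.na(items) | items != as.integer(items) |
                 items < 0 | items > 4)
  if (length(bad))
    stop("CESD-R item(s) out of range 0..4 at position(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  total <- sum(as.integer(items))
  list(items = as.integer(items), total = total,
       dysphoria = total >= dysphoria_cutoff)
}

#' Square-root transform for right-skewed covariates
#'
#' Elementwise square root, with validation; used on CESD-R totals before
#' they enter an ANCOVA as a covariate.
#'
#' @param values Nonnegative numeric vector.
#' @return `sqrt(values)`.
#' @export
sqrt_transform <- function(values) {
  if (any(is.na(values)) || any(values < 0))
    stop("sqrt_transform() requires nonnegative, non-missing values",
         call. = FALSE)
  sqrt(values)
}

#' Skewness and kurtosis diagnostics with standard errors
#'
#' Sample-adjusted (Fisher-Pearson corrected) skewness and excess kurtosis
#' with their normal-theory standard errors,
#' \deqn{SE_{skew} = \sqrt{6n(n-1)/((n-2)(n+1)(n+3))}}
#' \deqn{SE_{kurt} = 2\, SE_{skew} \sqrt{(n^2-1)/((n-3)(n+5))},}
#' and the Z ratios statistic/SE used to judge whether a covariate needs
#' transforming (|Z| > 2 is the usual flag at moderate n).
#'
#' @param values Numeric vector, `n >= 4`.
#' @return List with `n`, `skewness`, `se_skewness`, `z_skewness`,
#'   `kurtosis`, `se_kurtosis`, `z_kurtosis`. Constant input yields `NA`
#'   statistics with finite SEs.
#' @examples
#' moment_diagnostics(rnorm(73))$se_skewness  # 0.281
#' @export
moment_diagnostics <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  se_skew <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  se_kurt <- 2 * se_skew * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
  if (stats::sd(values) == 0) {
    sk <- ku <- NA_real_
  } else {
    sk <- e1071::skewness(values, type = 2)
    ku <- e1071::kurtosis(values, type = 2)
  }
  list(n = n, skewness = sk, se_skewness = se_skew, z_skewness = sk / se_skew,
       kurtosis = ku, se_kurtosis = se_kurt, z_kurtosis = ku / se_kurt)
}

#' Validate a VAMS reading
#'
#' Both scales are 0-100 marks on a 100 mm line; values are accepted as
#' pre-measured reals.
#'
#' @param positive,negative Numeric scalars in 0..100.
#' @param occasion Measurement occasion, 1..4.
#' @return List with `occasion`, `positive`, `negative`.
#' @export
vams_record <- function(positive, negative, occasion = 1L) {
  if (!occasion %in% 1:4) stop("occasion must be 1..4", call. = FALSE)
  for (v in c(positive, negative))
    if (is.na(v) || v < 0 || v > 100)
      stop("VAMS values must lie in [0, 100]", call. = FALSE)
  list(occasion = as.integer(occasion), positive = positive,
       negative = negative)
}
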