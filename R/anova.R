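# ---- split-plot (mixed) ANOVA / ANCOVA --------------------------------------
#
# One between-subjects factor (group), one within-subjects factor, optional
# continuous covariate. Classical univariate mixed-model decomposition in two
# strata:
#
#   between stratum: subject means regressed on group (+ covariate);
#     error = subjects within groups, df N - p
#   within stratum: orthonormal within-subject contrast scores regressed on
#     the same between design; the intercept carries the within main effect,
#     group the within x group interaction, the covariate its interaction
#     with the within factor; error df (k - 1)(N - p)
#
# Sums of squares are Type III (sum-to-zero coding, each term dropped from
# the full model), the covariate enters uncentered, and no sphericity
# correction is applied, which together reproduce the SPSS-style integer
# degrees of freedom conventional in this literature: within-effect error df
# (k-1)(N-2) without covariate and (k-1)(N-3) with one covariate, for two
# groups.

.rss <- function(X, Y) {
  if (ncol(X) == 0L) return(colSums(as.matrix(Y)^2))
  colSums(as.matrix(qr.resid(qr(X), Y))^2)
}

#' Fit a split-plot ANOVA or ANCOVA
#'
#' @param data Long-format data.frame: one row per subject x within level.
#' @param value Name of the outcome column.
#' @param within Name of the within-subjects factor column.
#' @param between Name of the between-subjects (group) column.
#' @param id Name of the subject identifier column.
#' @param covariate Optional name of a subject-level continuous covariate
#'   column; when given, its main effect and its interaction with the within
#'   factor are added (ANCOVA).
#' @return Object of class `"splitplot_aov"` with an `anova`-style effect
#'   table (`SS`, `df1`, `df2`, `F`, `p`, `partial_eta_sq`), the stratum
#'   error terms, cell means, and bookkeeping used by the methods.
#' @examples
#' d <- expand.grid(id = paste0("s", 1:10), w = c("a", "b"))
#' d$group <- rep(c("g1", "g2"), each = 1, length.out = nrow(d))
#' d$y <- rnorm(nrow(d))
#' fit <- splitplot_anova(d, value = "y", within = "w", between = "group",
#'                        id = "id")
#' fit$table
#' @export
splitplot_anova <- function(data, value = "value", within = "within_level",
                            between = "group", id = "participant_id",
                            covariate = NULL) {
  need <- c(value, within, between, id, covariate)
  missing <- setdiff(need, names(data))
  if (length(missing))
    stop("data is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- data.frame(id = as.character(data[[id]]),
                   group = as.character(data[[between]]),
                   w = as.character(data[[within]]),
                   y = as.numeric(data[[value]]),
                   stringsAsFactors = FALSE)
  if (!is.null(covariate)) df$x <- as.numeric(data[[covariate]])

  levels_w <- unique(df$w)
  k <- length(levels_w)
  if (k < 2L) stop("need at least 2 within-subject levels", call. = FALSE)

  # complete cases only: every subject must supply every within level once
  tab <- table(df$id, df$w)
  if (any(tab > 1L))
    stop("duplicate rows for some subject x within-level cells",
         call. = FALSE)
  complete <- rownames(tab)[rowSums(tab) == k]
  if (length(complete) < length(unique(df$id))) {
    warning("dropping ", length(unique(df$id)) - length(complete),
            " subject(s) with incomplete within-level data", call. = FALSE)
    df <- df[df$id %in% complete, , drop = FALSE]
  }

  subj <- unique(df[, c("id", "group", if (!is.null(covariate)) "x")])
  if (anyDuplicated(subj$id))
    stop("group or covariate varies within subject", call. = FALSE)
  n <- nrow(subj)
  groups <- sort(unique(subj$group))
  g <- length(groups)
  if (g < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(subj$group) < 2L))
    stop("need at least 2 subjects per group", call. = FALSE)
  if (!is.null(covariate) && stats::var(subj$x) == 0)
    stop("covariate is constant; ANCOVA design is singular", call. = FALSE)

  # wide outcome matrix, subjects x within levels
  Y <- matrix(NA_real_, n, k, dimnames = list(subj$id, levels_w))
  Y[cbind(match(df$id, subj$id), match(df$w, levels_w))] <- df$y
  if (anyNA(Y)) stop("missing outcome values", call. = FALSE)

  # between design with sum-to-zero group coding
  gf <- factor(subj$group, levels = groups)
  G <- stats::contr.sum(g)[as.integer(gf), , drop = FALSE]
  X_full <- cbind(`(Intercept)` = 1, G)
  cols <- list(intercept = 1L, group = 1L + seq_len(g - 1L))
  if (!is.null(covariate)) {
    X_full <- cbind(X_full, cov = subj$x)
    cols$cov <- ncol(X_full)
  }
  p <- ncol(X_full)

  # ---- between stratum (scaled subject means) ----
  u <- rowMeans(Y)
  rss_full_b <- .rss(X_full, u)
  ss_between <- function(drop_cols)
    k * (.rss(X_full[, -drop_cols, drop = FALSE], u) - rss_full_b)
  between_tab <- data.frame(
    effect = c(between, if (!is.null(covariate)) covariate),
    SS = c(ss_between(cols$group),
           if (!is.null(covariate)) ss_between(cols$cov)),
    df1 = c(g - 1L, if (!is.null(covariate)) 1L),
    stringsAsFactors = FALSE)
  err_b <- c(SS = k * rss_full_b, df = n - p)

  # ---- within stratum (orthonormal contrast scores) ----
  C <- stats::contr.poly(k)                    # orthonormal columns
  M <- Y %*% C
  rss_full_w <- .rss(X_full, M)
  ss_within <- function(drop_cols)
    sum(.rss(X_full[, -drop_cols, drop = FALSE], M) - rss_full_w)
  within_tab <- data.frame(
    effect = c(within, paste(within, between, sep = ":"),
               if (!is.null(covariate)) paste(within, covariate, sep = ":")),
    SS = c(ss_within(cols$intercept), ss_within(cols$group),
           if (!is.null(covariate)) ss_within(cols$cov)),
    df1 = c(k - 1L, (k - 1L) * (g - 1L), if (!is.null(covariate)) k - 1L),
    stringsAsFactors = FALSE)
  err_w <- c(SS = sum(rss_full_w), df = (k - 1L) * (n - p))

  finish <- function(tab, err) {
    tab$df2 <- err[["df"]]
    tab$F <- (tab$SS / tab$df1) / (err[["SS"]] / err[["df"]])
    tab$p <- stats::pf(tab$F, tab$df1, tab$df2, lower.tail = FALSE)
    tab$partial_eta_sq <- tab$SS / (tab$SS + err[["SS"]])
    tab
  }
  table <- rbind(finish(between_tab, err_b), finish(within_tab, err_w))
  rownames(table) <- NULL

  grand <- mean(Y)
  cellmeans <- do.call(rbind, lapply(groups, function(gr)
    colMeans(Y[subj$group == gr, , drop = FALSE])))
  rownames(cellmeans) <- groups

  structure(list(
    table = table,
    error = data.frame(stratum = c("between", "within"),
                       SS = c(err_b[["SS"]], err_w[["SS"]]),
                       df = c(err_b[["df"]], err_w[["df"]])),
    ss_total = sum((Y - grand)^2),
    ss_between_stratum = k * sum((u - mean(u))^2),
    ss_within_stratum = sum(M^2),
    dims = list(n = n, k = k, g = g, p = p),
    levels = list(within = levels_w, between = groups),
    cell_means = cellmeans,
    vars = list(value = value, within = within, between = between, id = id,
                covariate = covariate),
    call = match.call()),
    class = "splitplot_aov")
}

#' @export
print.splitplot_aov <- function(x, digits = 4, ...) {
  v <- x$vars
  cat("Split-plot ", if (is.null(v$covariate)) "ANOVA" else "ANCOVA", ": ",
      v$value, " ~ ", v$between, " x ", v$within,
      if (!is.null(v$covariate)) paste0(" + ", v$covariate), "\n", sep = "")
  cat(sprintf("%d subjects (%s), %d within levels\n\n", x$dims$n,
              paste(x$levels$between, collapse = " vs "), x$dims$k))
  tab <- x$table
  tab$SS <- signif(tab$SS, digits)
  tab$F <- round(tab$F, 2)
  tab$p <- signif(tab$p, 3)
  tab$partial_eta_sq <- round(tab$partial_eta_sq, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.splitplot_aov <- function(object, ...) object$table

#' @export
coef.splitplot_aov <- function(object, ...) object$cell_means
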