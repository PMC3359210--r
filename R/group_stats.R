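as_group_list <- function(scores) {
  if (is.data.frame(scores))
    stop("pass a named list of numeric vectors; see compare_groups() for data frames")
  if (!is.list(scores) || length(scores) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    names(scores) <- paste0("group", seq_along(scores))
  lapply(scores, as.numeric)
}

#' One-way analysis of variance over grouped scores
#'
#' Standard between/within decomposition of per-image quantification
#' scores grouped by condition, fitted with [stats::aov()]. The F
#' statistic is `ms_between / ms_within` with `(k - 1, N - k)` degrees of
#' freedom.
#'
#' @param scores named list of numeric vectors, one per group.
#' @return object of class `anova_table`: `ss_between`, `ss_within`,
#'   `ss_total`, `df_between`, `df_within`, `ms_between`, `ms_within`,
#'   `F`, `p`, `k`, `n_per_group`, `group_means`, `degenerate` (TRUE when
#'   the within-group variance is zero and F is undefined).
#' @export
one_way_anova <- function(scores) {
  g <- as_group_list(scores)
  k <- length(g)
  n_i <- lengths(g)
  if (any(n_i < 1L)) stop("every group needs at least one observation")
  N <- sum(n_i)
  if (N <= k)
    stop("no residual degrees of freedom (need N > k)", call. = FALSE)
  df <- data.frame(score = unlist(g, use.names = FALSE),
                   group = factor(rep(names(g), n_i)))
  fit <- stats::aov(score ~ group, data = df)
  # anova.lm warns on a perfect fit; that case is flagged as degenerate below
  an <- suppressWarnings(stats::anova(fit))
  ss_b <- an$`Sum Sq`[1]; ss_w <- an$`Sum Sq`[2]
  ms_w <- an$`Mean Sq`[2]
  # zero within-group variance up to rounding noise in the decomposition
  degenerate <- ms_w <= 1e-10 * max(ss_b + ss_w, .Machine$double.xmin)
  structure(list(ss_between = ss_b, ss_within = ss_w,
                 ss_total = ss_b + ss_w,
                 df_between = an$Df[1], df_within = an$Df[2],
                 ms_between = an$`Mean Sq`[1], ms_within = ms_w,
                 F = if (degenerate) NA_real_ else an$`F value`[1],
                 p = if (degenerate) NA_real_ else an$`Pr(>F)`[1],
                 k = k, n_per_group = n_i,
                 group_means = vapply(g, mean, 0),
                 degenerate = degenerate),
            class = "anova_table")
}

#' ANOVA table from printed sums of squares
#'
#' Completes an ANOVA table given the sums of squares and degrees of
#' freedom (as printed in a publication): mean squares, F ratio and the
#' upper-tail p-value.
#'
#' @param ss_between,df_between,ss_within,df_within scalars.
#' @return an `anova_table` (without group-level fields).
#' @export
anova_from_ss <- function(ss_between, df_between, ss_within, df_within) {
  ms_b <- ss_between / df_between
  ms_w <- ss_within / df_within
  Fv <- ms_b / ms_w
  structure(list(ss_between = ss_between, ss_within = ss_within,
                 ss_total = ss_between + ss_within,
                 df_between = df_between, df_within = df_within,
                 ms_between = ms_b, ms_within = ms_w, F = Fv,
                 p = stats::pf(Fv, df_between, df_within, lower.tail = FALSE),
                 k = df_between + 1L, n_per_group = NULL,
                 group_means = NULL, degenerate = ms_w <= 0),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  cat("One-way ANOVA\n")
  m <- rbind(
    `Between groups` = c(x$ss_between, x$df_between, x$ms_between, x$F,
                         x$p),
    `Within groups`  = c(x$ss_within, x$df_within, x$ms_within, NA, NA),
    Total            = c(x$ss_total, x$df_between + x$df_within, NA, NA, NA))
  colnames(m) <- c("Sum Sq", "df", "Mean Sq", "F", "p")
  print(round(m, 4), na.print = "")
  if (isTRUE(x$degenerate)) cat("(zero within-group variance: F undefined)\n")
  invisible(x)
}

pairwise_frame <- function(g, ms_within, df_within, p_fun) {
  nm <- names(g)
  means <- vapply(g, mean, 0)
  n_i <- lengths(g)
  pairs <- utils::combn(length(g), 2)
  res <- lapply(seq_len(ncol(pairs)), function(c0) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    se <- sqrt(ms_within * (1 / n_i[i] + 1 / n_i[j]))
    d <- means[i] - means[j]
    data.frame(group_i = nm[i], group_j = nm[j],
               mean_diff = d, std_error = se,
               p = p_fun(d, se), row.names = NULL)
  })
  do.call(rbind, res)
}

#' Pairwise LSD (least significant difference) comparisons
#'
#' Unadjusted pairwise t tests using the pooled within-group variance
#' from the ANOVA: `t = mean_diff / se` with
#' `se = sqrt(ms_within (1/n_i + 1/n_j))` and `df_within` degrees of
#' freedom; p-values are two-sided.
#'
#' @param scores named list of numeric vectors.
#' @param ms_within,df_within pooled variance and residual df; computed
#'   with [one_way_anova()] when omitted.
#' @return data frame with columns `group_i`, `group_j`, `mean_diff`,
#'   `std_error`, `p`.
#' @export
lsd_comparisons <- function(scores, ms_within = NULL, df_within = NULL) {
  g <- as_group_list(scores)
  if (is.null(ms_within) || is.null(df_within)) {
    an <- one_way_anova(g)
    if (an$degenerate)
      stop("zero within-group variance: tests undefined", call. = FALSE)
    ms_within <- an$ms_within; df_within <- an$df_within
  }
  if (ms_within <= 0) stop("zero within-group variance: tests undefined")
  pairwise_frame(g, ms_within, df_within, function(d, se)
    2 * stats::pt(-abs(d) / se, df_within))
}

#' Pairwise Tukey HSD comparisons
#'
#' Family-wise-error-controlled pairwise comparisons using the
#' studentized range distribution with `k` groups and `df_within`
#' residual degrees of freedom:
#' `q = |mean_diff| / sqrt(ms_within (1/n_i + 1/n_j) / 2)` (the
#' Tukey-Kramer form, exact for balanced designs). Tail probabilities come
#' from [stats::ptukey()].
#'
#' @inheritParams lsd_comparisons
#' @return data frame with columns `group_i`, `group_j`, `mean_diff`,
#'   `std_error`, `p`.
#' @export
tukey_comparisons <- function(scores, ms_within = NULL, df_within = NULL) {
  g <- as_group_list(scores)
  if (is.null(ms_within) || is.null(df_within)) {
    an <- one_way_anova(g)
    if (an$degenerate)
      stop("zero within-group variance: tests undefined", call. = FALSE)
    ms_within <- an$ms_within; df_within <- an$df_within
  }
  if (ms_within <= 0) stop("zero within-group variance: tests undefined")
  k <- length(g)
  pairwise_frame(g, ms_within, df_within, function(d, se) {
    q <- abs(d) / (se / sqrt(2))
    stats::ptukey(q, k, df_within, lower.tail = FALSE)
  })
}

#' Full group comparison report
#'
#' Runs the one-way ANOVA plus both post hoc procedures over a score
#' table, the validation workflow for pipeline scores grouped by
#' condition.
#'
#' @param scores data frame, or named list of numeric vectors.
#' @param group_col,score_col column names when `scores` is a data frame.
#' @return list with `anova` (`anova_table`), `lsd`, `tukey` (pairwise
#'   data frames) and `means` (group means and standard errors, for a
#'   means plot).
#' @export
compare_groups <- function(scores, group_col = "group", score_col = "score") {
  if (is.data.frame(scores)) {
    scores <- split(scores[[score_col]], scores[[group_col]])
  }
  g <- as_group_list(scores)
  an <- one_way_anova(g)
  means <- data.frame(
    group = names(g),
    mean = vapply(g, mean, 0),
    se = vapply(g, function(x) stats::sd(x) / sqrt(length(x)), 0),
    n = lengths(g), row.names = NULL)
  list(anova = an,
       lsd = lsd_comparisons(g, an$ms_within, an$df_within),
       tukey = tukey_comparisons(g, an$ms_within, an$df_within),
       means = means)
}

#' Format a p-value the way 3-decimal reports print it
#'
#' @param p numeric p-values.
#' @return character vector: three decimals, or `"< 0.001"` below that.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "< 0.001", sprintf("%.3f", round(p, 3)))
}
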