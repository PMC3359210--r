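# groups with the published means and symmetric within-group deviations
# calibrated so the pooled within-group sum of squares is exact
reconstructed_groups <- function(means = c(p63 = 0, BRCA1 = 15.29,
                                           Scr = 30.869),
                                 ss_within = 98.022) {
  a <- sqrt(ss_within / 6)          # 3 groups x 2 squared deviations each
  lapply(means, function(m) c(m - a, m, m + a))
}

test_that("identical groups give zero between-group variation", {
  an <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(an$ss_between, 0)
  expect_equal(an$F, 0)
})

test_that("reconstructed published table matches its printed statistics", {
  g <- reconstructed_groups()
  an <- one_way_anova(g)
  expect_equal(an$ss_within, 98.022, tolerance = 1e-9)
  expect_equal(an$ms_within, 16.337, tolerance = 1e-4)
  expect_equal(an$df_between, 2L, ignore_attr = TRUE)
  expect_equal(an$df_within, 6L, ignore_attr = TRUE)
  expect_equal(an$F, 43.75, tolerance = 1e-2)
  expect_lt(an$p, 0.001)
})

test_that("one observation per group has no residual df and errors", {
  expect_error(one_way_anova(list(a = 1, b = 2, c = 3)), "degrees of freedom")
})

test_that("zero within-group variance flags the F ratio", {
  an <- one_way_anova(list(a = c(1, 1, 1), b = c(2, 2, 2)))
  expect_true(an$degenerate)
  expect_true(is.na(an$F))
  expect_error(lsd_comparisons(list(a = c(1, 1), b = c(2, 2))), "undefined")
})

test_that("sums of squares decompose on random inputs", {
  set.seed(31)
  for (trial in 1:100) {
    g <- random_groups(k = sample(2:5, 1), n = sample(2:8, 1),
                       mean_spread = runif(1, 0, 4))
    an <- one_way_anova(g)
    expect_equal(an$ss_total, an$ss_between + an$ss_within,
                 tolerance = 1e-9)
  }
})

test_that("F is invariant to shifting and scaling all scores", {
  set.seed(17)
  g <- random_groups()
  an <- one_way_anova(g)
  an_shift <- one_way_anova(lapply(g, `+`, 100))
  an_scale <- one_way_anova(lapply(g, `*`, 7))
  expect_equal(an_shift$F, an$F, tolerance = 1e-9)
  expect_equal(an_scale$F, an$F, tolerance = 1e-9)
})

test_that("pairwise standard error and p-values match the published table", {
  g <- reconstructed_groups()
  an <- one_way_anova(g)
  lsd <- lsd_comparisons(g, an$ms_within, an$df_within)
  tuk <- tukey_comparisons(g, an$ms_within, an$df_within)
  expect_equal(unique(round(lsd$std_error, 2)), 3.3)
  expect_equal(lsd$std_error, rep(sqrt(2 * 16.337 / 3), 3),
               tolerance = 1e-4)

  pair <- function(df, i, j) df[df$group_i == i & df$group_j == j, ]
  # p63 vs BRCA1: diff -15.29 (p-values checked to the printed 3 decimals)
  expect_equal(pair(lsd, "p63", "BRCA1")$mean_diff, -15.29, tolerance = 1e-9)
  expect_lt(abs(pair(lsd, "p63", "BRCA1")$p - 0.004), 1e-3)
  expect_lt(abs(pair(tuk, "p63", "BRCA1")$p - 0.008), 2e-3)
  # BRCA1 vs Scr: diff -15.579
  expect_equal(pair(lsd, "BRCA1", "Scr")$mean_diff, -15.579,
               tolerance = 1e-9)
  expect_lt(abs(pair(lsd, "BRCA1", "Scr")$p - 0.003), 1e-3)
  # p63 vs Scr: diff -30.869
  expect_lt(pair(tuk, "p63", "Scr")$p, 0.001)
  expect_lt(pair(lsd, "p63", "Scr")$p, 0.001)
})

test_that("a zero mean difference gives p = 1 and sign antisymmetry holds", {
  g <- list(a = c(-1, 0, 1), b = c(-1, 0, 1), c = c(9, 10, 11))
  lsd <- lsd_comparisons(g)
  expect_equal(lsd$p[lsd$group_i == "a" & lsd$group_j == "b"], 1)
  tuk <- tukey_comparisons(g)
  expect_equal(tuk$p[tuk$group_i == "a" & tuk$group_j == "b"], 1)
  # mean_diff(i,j) = -mean_diff(j,i) by construction of the mean
  expect_equal(lsd$mean_diff[1], mean(g$a) - mean(g$b))
})

test_that("Tukey p is at least the LSD p on random balanced designs", {
  set.seed(47)
  for (trial in 1:100) {
    g <- random_groups(k = 3, n = 5, mean_spread = runif(1, 0, 3))
    an <- one_way_anova(g)
    lsd <- lsd_comparisons(g, an$ms_within, an$df_within)
    tuk <- tukey_comparisons(g, an$ms_within, an$df_within)
    expect_true(all(tuk$p >= lsd$p - 1e-12))
  }
})

test_that("post hoc results agree with the base-R reference routes", {
  set.seed(53)
  g <- random_groups(k = 4, n = 6)
  df <- data.frame(score = unlist(g),
                   group = factor(rep(names(g), lengths(g))))
  # Tukey vs stats::TukeyHSD
  ref <- stats::TukeyHSD(stats::aov(score ~ group, df))$group
  tuk <- tukey_comparisons(g)
  for (r in seq_len(nrow(tuk))) {
    key <- paste0(tuk$group_j[r], "-", tuk$group_i[r])
    expect_equal(tuk$p[r], ref[key, "p adj"], tolerance = 1e-6)
    expect_equal(-tuk$mean_diff[r], ref[key, "diff"], tolerance = 1e-9)
  }
  # LSD vs pairwise.t.test with no correction
  refp <- stats::pairwise.t.test(df$score, df$group,
                                 p.adjust.method = "none")$p.value
  lsd <- lsd_comparisons(g)
  for (r in seq_len(nrow(lsd))) {
    pij <- refp[lsd$group_j[r], lsd$group_i[r]]
    if (is.na(pij)) pij <- refp[lsd$group_i[r], lsd$group_j[r]]
    expect_equal(lsd$p[r], pij, tolerance = 1e-9)
  }
})

test_that("ANOVA from printed sums of squares completes the table", {
  an <- anova_from_ss(1429.6, 2, 98.022, 6)
  expect_equal(an$ms_between, 714.8)
  expect_equal(an$ms_within, 16.337)
  expect_equal(an$F, 714.8 / 16.337, tolerance = 1e-9)
  expect_lt(an$p, 0.001)
  expect_equal(an$ss_total, 1527.622)
})

test_that("compare_groups accepts a score table and reports all pieces", {
  set.seed(61)
  g <- random_groups()
  df <- data.frame(score = unlist(g),
                   group = rep(names(g), lengths(g)))
  rep_ <- compare_groups(df)
  expect_s3_class(rep_$anova, "anova_table")
  expect_equal(nrow(rep_$lsd), 3)
  expect_equal(nrow(rep_$tukey), 3)
  expect_equal(rep_$means$n, rep(5L, 3), ignore_attr = TRUE)
  expect_equal(format_p(c(0.0004, 0.0081)), c("< 0.001", "0.008"))
})
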