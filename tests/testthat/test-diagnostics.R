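# Agreement and diagnostic-performance statistics.

test_that("relative error follows its definition", {
  expect_equal(relative_error(0.9, 0.8), 0.125)
  expect_equal(relative_error(0.73, 0.73), 0)
  expect_error(relative_error(0.9, 0), "positive")
  tab <- random_paired_table(n = 25, seed = 2)
  expect_equal(mean(abs(relative_error(tab$ffr_computed,
                                       tab$ffr_reference))),
               mean(abs((tab$ffr_computed - tab$ffr_reference) /
                          tab$ffr_reference)), tolerance = 1e-15)
})

test_that("Bland-Altman reproduces the definitional formulas", {
  same <- paired_ffr_table(c("a", "b", "c"), c(0.7, 0.8, 0.9),
                           c(0.7, 0.8, 0.9))
  ba0 <- bland_altman(same)
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  off <- paired_ffr_table(c("a", "b", "c"), c(0.7, 0.8, 0.9),
                          c(0.73, 0.83, 0.93))
  ba1 <- bland_altman(off)
  expect_equal(ba1$bias, 0.03, tolerance = 1e-12)
  expect_equal(ba1$loa_high - ba1$loa_low, 0, tolerance = 1e-12)
  tab <- random_paired_table(n = 40, seed = 7)
  ba <- bland_altman(tab)
  d <- tab$ffr_computed - tab$ffr_reference
  expect_equal(ba$bias, mean(d), tolerance = 1e-15)
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$bias, mean(tab$ffr_computed) - mean(tab$ffr_reference),
               tolerance = 1e-12)
  expect_error(bland_altman(paired_ffr_table("a", 0.8, 0.8)), "2 rows")
})

# helper: build a table realizing exact confusion counts
table_from_counts <- function(tp, fn, tn, fp) {
  ref <- c(rep(0.70, tp + fn), rep(0.90, tn + fp))
  comp <- c(rep(0.70, tp), rep(0.90, fn), rep(0.90, tn), rep(0.70, fp))
  paired_ffr_table(sprintf("v%03d", seq_along(ref)), ref, comp)
}

test_that("confusion metrics recover designed counts", {
  perfect <- table_from_counts(tp = 10, fn = 0, tn = 20, fp = 0)
  m <- confusion_metrics(perfect)
  expect_equal(unlist(m[c("sensitivity", "specificity", "ppv", "npv",
                          "accuracy")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1,
                 accuracy = 1))
  m2 <- confusion_metrics(table_from_counts(tp = 6, fn = 2, tn = 9,
                                            fp = 3))
  expect_equal(m2$sensitivity, 6 / 8)
  expect_equal(m2$specificity, 9 / 12)
  expect_equal(m2$ppv, 6 / 9)
  expect_equal(m2$npv, 9 / 11)
  expect_equal(m2$accuracy, 15 / 20)
  expect_equal(m2$prevalence, 8 / 20)
  expect_equal(m2$youden_j, 6 / 8 + 9 / 12 - 1, tolerance = 1e-12)
})

test_that("single-class reference tables are rejected by name", {
  allpos <- paired_ffr_table(c("a", "b"), c(0.7, 0.75), c(0.7, 0.9))
  expect_error(confusion_metrics(allpos), "no negative")
  allneg <- paired_ffr_table(c("a", "b"), c(0.9, 0.95), c(0.7, 0.9))
  expect_error(confusion_metrics(allneg), "no positive")
  expect_error(roc_analysis(allpos), "no negative")
})

test_that("accuracy identity holds on random tables", {
  for (seed in 1:10) {
    tab <- random_paired_table(n = 30, seed = seed)
    labels <- tab$ffr_reference <= 0.80
    if (!any(labels) || all(labels)) next
    m <- confusion_metrics(tab)
    expect_equal(m$accuracy,
                 m$prevalence * m$sensitivity +
                   (1 - m$prevalence) * m$specificity, tolerance = 1e-12)
  }
})

test_that("AUC equals exhaustive concordant-pair counting", {
  tab <- paired_ffr_table(
    sprintf("v%02d", 1:10),
    c(0.72, 0.78, 0.60, 0.79, 0.75, 0.85, 0.90, 0.83, 0.95, 0.88),
    c(0.70, 0.82, 0.65, 0.74, 0.84, 0.88, 0.92, 0.80, 0.91, 0.79))
  roc <- roc_analysis(tab)
  pos <- tab$ffr_computed[tab$ffr_reference <= 0.80]
  neg <- tab$ffr_computed[tab$ffr_reference > 0.80]
  pairs <- outer(pos, neg, function(p, n) (p < n) + 0.5 * (p == n))
  expect_equal(roc$auc, mean(pairs), tolerance = 1e-12)
  expect_true(roc$auc_ci[1] <= roc$auc && roc$auc <= roc$auc_ci[2])
})

test_that("AUC is invariant under monotone transforms of the scores", {
  tab <- random_paired_table(n = 50, seed = 3)
  base <- roc_analysis(tab)$auc
  warped <- paired_ffr_table(tab$vessel_id, tab$ffr_reference,
                             tab$ffr_computed^3 / 2)
  expect_equal(roc_analysis(warped)$auc, base, tolerance = 1e-12)
})

test_that("perfect separation and permuted labels bracket the AUC", {
  sep <- table_from_counts(tp = 8, fn = 0, tn = 12, fp = 0)
  expect_equal(roc_analysis(sep)$auc, 1)
  set.seed(99)
  n <- 400
  ref <- c(rep(0.7, n / 2), rep(0.9, n / 2))
  comp <- sample(seq(0.4, 1.0, length.out = n))  # independent of labels
  tab <- paired_ffr_table(sprintf("v%03d", 1:n), ref, comp)
  auc <- roc_analysis(tab)$auc
  se <- sqrt(1 / 12 * (1 / (n / 2) + 1 / (n / 2)))  # null AUC SE approx
  expect_lt(abs(auc - 0.5), 3 * se)
})

test_that("optimal cut-off maximizes Youden with ties toward 0.80", {
  tab <- paired_ffr_table(
    sprintf("v%02d", 1:8),
    c(0.70, 0.72, 0.75, 0.78, 0.85, 0.88, 0.90, 0.95),
    c(0.60, 0.65, 0.70, 0.74, 0.86, 0.88, 0.91, 0.94))
  roc <- roc_analysis(tab)
  # any cut in [0.74, 0.86) separates perfectly; observed candidates are
  # 0.74 and 0.86-: closest observed value to 0.80 wins
  expect_equal(roc$youden_at_cutoff, 1)
  expect_equal(roc$optimal_cutoff, 0.74)
})

test_that("Pearson r and its Fisher-z interval match the oracle", {
  x <- c(0.62, 0.70, 0.74, 0.78, 0.81, 0.83, 0.86, 0.90, 0.93, 0.97)
  y <- c(0.60, 0.74, 0.70, 0.80, 0.78, 0.85, 0.84, 0.91, 0.90, 0.99)
  tab <- paired_ffr_table(sprintf("v%02d", 1:10), x, y)
  pc <- pearson_with_ci(tab)
  r_def <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pc$r, r_def, tolerance = 1e-12)
  z <- atanh(r_def); se <- 1 / sqrt(10 - 3)
  expect_equal(pc$ci_low, tanh(z - qnorm(0.975) * se), tolerance = 1e-9)
  expect_equal(pc$ci_high, tanh(z + qnorm(0.975) * se), tolerance = 1e-9)
  ident <- paired_ffr_table(c("a", "b", "c"), c(0.7, 0.8, 0.9),
                            c(0.7, 0.8, 0.9))
  expect_equal(pearson_with_ci(ident)$r, 1)
  anti <- paired_ffr_table(c("a", "b", "c"), c(0.7, 0.8, 0.9),
                           c(0.9, 0.8, 0.7))
  expect_equal(pearson_with_ci(anti)$r, -1)
})

test_that("the full report is internally consistent", {
  tab <- random_paired_table(n = 60, seed = 12)
  rep <- diagnostics_report(tab)
  expect_s3_class(rep, "ffr_diagnostics")
  expect_equal(rep$confusion$n, 60)
  expect_true(rep$roc$auc >= 0 && rep$roc$auc <= 1)
  expect_true(rep$pearson$r >= -1 && rep$pearson$r <= 1)
  expect_true(rep$bland_altman$loa_low <= rep$bland_altman$bias)
  expect_true(rep$bland_altman$bias <= rep$bland_altman$loa_high)
  expect_output(print(rep), "Diagnostic performance")
})
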