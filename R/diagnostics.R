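# Agreement and diagnostic-performance statistics for paired
# computed-vs-invasive FFR tables: Pearson correlation (Fisher-z CI),
# Bland-Altman limits of agreement, relative error, confusion-matrix
# metrics at the 0.80 threshold, and ROC/AUC with a DeLong CI.
# Positive class = ischemic = FFR <= threshold, inclusive, throughout.

#' Construct a paired FFR table
#'
#' @param vessel_id Vessel identifiers.
#' @param ffr_reference Reference (invasive) FFR values in (0, 1.5).
#' @param ffr_computed Computed FFR values in (0, 1.5).
#' @return A data.frame of class `paired_ffr`.
#' @export
paired_ffr_table <- function(vessel_id, ffr_reference, ffr_computed) {
  n <- length(vessel_id)
  if (length(ffr_reference) != n || length(ffr_computed) != n)
    stop("vessel_id, ffr_reference and ffr_computed must have equal length")
  if (anyNA(ffr_reference) || anyNA(ffr_computed))
    stop("paired FFR table must not contain missing values")
  if (any(ffr_reference <= 0 | ffr_reference >= 1.5) ||
      any(ffr_computed <= 0 | ffr_computed >= 1.5))
    stop("FFR values must lie in (0, 1.5)")
  structure(data.frame(vessel_id = as.character(vessel_id),
                       ffr_reference = ffr_reference,
                       ffr_computed = ffr_computed,
                       stringsAsFactors = FALSE),
            class = c("paired_ffr", "data.frame"))
}

#' Read a paired FFR CSV
#'
#' Expects columns `vessel_id`, `ffr_invasive`, `ffr_computed`.
#'
#' @param path CSV file path.
#' @return A `paired_ffr` table.
#' @export
read_paired_ffr <- function(path) {
  if (!file.exists(path)) stop("paired FFR file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vessel_id", "ffr_invasive", "ffr_computed")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("paired FFR CSV ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$ffr_invasive) | !is.finite(df$ffr_computed))
  if (length(bad))
    stop("paired FFR CSV ", path, ": non-numeric or missing value at row ",
         bad[1L])
  paired_ffr_table(df$vessel_id, df$ffr_invasive, df$ffr_computed)
}

#' Relative error of computed versus reference values
#'
#' `(computed - reference) / reference`, vectorized.
#'
#' @param computed Computed values.
#' @param reference Reference values; must be positive.
#' @return Relative errors.
#' @export
relative_error <- function(computed, reference) {
  if (any(reference <= 0))
    stop("relative_error: reference values must be positive")
  (computed - reference) / reference
}

#' Bland-Altman agreement analysis
#'
#' Bias = mean(computed - reference); 95% limits of agreement =
#' bias +/- 1.96 SD of the differences.
#'
#' @param table A `paired_ffr` table with at least 2 rows.
#' @return List with `bias`, `loa_low`, `loa_high`, `sd_diff`.
#' @export
bland_altman <- function(table) {
  stopifnot(inherits(table, "paired_ffr"))
  if (nrow(table) < 2) stop("bland_altman requires at least 2 rows")
  d <- table$ffr_computed - table$ffr_reference
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s)
}

.binary_labels <- function(values, threshold) values <= threshold

#' Confusion-matrix metrics at an FFR threshold
#'
#' Both columns are dichotomized at `value <= threshold` (positive =
#' ischemic); reports sensitivity, specificity, PPV, NPV, accuracy,
#' prevalence and the Youden index (also truncated to 2 decimals, the
#' convention used when quoting it).
#'
#' @param table A `paired_ffr` table whose reference column contains both
#'   classes.
#' @param threshold Diagnostic threshold (default 0.80, inclusive).
#' @return List of metrics plus the raw `tp`, `fp`, `tn`, `fn` counts.
#' @export
confusion_metrics <- function(table, threshold = 0.80) {
  stopifnot(inherits(table, "paired_ffr"))
  truth <- .binary_labels(table$ffr_reference, threshold)
  pred <- .binary_labels(table$ffr_computed, threshold)
  if (!any(truth))
    stop("reference labels contain no positive (ischemic, FFR <= ",
         threshold, ") vessels")
  if (all(truth))
    stop("reference labels contain no negative (FFR > ", threshold,
         ") vessels")
  tp <- sum(truth & pred); fn <- sum(truth & !pred)
  tn <- sum(!truth & !pred); fp <- sum(!truth & pred)
  n <- length(truth)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  list(sensitivity = sens, specificity = spec,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       accuracy = (tp + tn) / n, prevalence = (tp + fn) / n,
       youden_j = sens + spec - 1,
       youden_j_2dp = trunc((sens + spec - 1) * 100) / 100,
       tp = tp, fp = fp, tn = tn, fn = fn, n = n)
}

#' ROC analysis of computed FFR against reference ischemia labels
#'
#' Empirical ROC of the computed FFR (lower values indicate disease)
#' against the reference dichotomized at `label_threshold`; AUC by the
#' trapezoidal rule with a DeLong 95% CI.  The optimal operating cut-off
#' is the observed computed-FFR value maximizing sensitivity +
#' specificity (Youden), ties resolved toward the value closest to 0.80.
#'
#' @param table A `paired_ffr` table with both classes present.
#' @param label_threshold Reference dichotomization threshold
#'   (default 0.80).
#' @return List with `auc`, `auc_ci` (length-2), `optimal_cutoff`,
#'   `youden_at_cutoff`.
#' @export
roc_analysis <- function(table, label_threshold = 0.80) {
  stopifnot(inherits(table, "paired_ffr"))
  truth <- .binary_labels(table$ffr_reference, label_threshold)
  if (!any(truth) || all(truth))
    stop("ROC analysis requires both classes in the reference labels; ",
         if (!any(truth)) "no positive" else "no negative",
         " (FFR <= ", label_threshold, ") vessels present")
  roc <- pROC::roc(response = factor(truth, levels = c(FALSE, TRUE)),
                   predictor = table$ffr_computed,
                   direction = ">",  # controls (non-ischemic) have higher FFR
                   levels = c(FALSE, TRUE), quiet = TRUE)
  auc <- as.numeric(pROC::auc(roc))
  # DeLong variance degenerates for perfectly separating scores; the CI
  # then collapses onto the AUC and pROC warns, which is expected here
  ci <- tryCatch(
    suppressWarnings(
      as.numeric(pROC::ci.auc(roc, method = "delong"))[c(1, 3)]),
    error = function(e) c(NA_real_, NA_real_))
  # Youden-optimal observed cut-off, inclusive classification
  cand <- sort(unique(table$ffr_computed))
  j <- vapply(cand, function(cut) {
    pred <- table$ffr_computed <= cut
    sens <- sum(truth & pred) / sum(truth)
    spec <- sum(!truth & !pred) / sum(!truth)
    sens + spec - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)
  cutoff <- cand[best][which.min(abs(cand[best] - 0.80))]
  list(auc = auc, auc_ci = ci, optimal_cutoff = cutoff,
       youden_at_cutoff = max(j))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param table A `paired_ffr` table with at least 3 rows and nonzero
#'   variance in both columns.
#' @return List with `r`, `ci_low`, `ci_high`, `p_value`.
#' @export
pearson_with_ci <- function(table) {
  stopifnot(inherits(table, "paired_ffr"))
  if (nrow(table) < 3) stop("pearson_with_ci requires at least 3 rows")
  if (stats::sd(table$ffr_reference) == 0 ||
      stats::sd(table$ffr_computed) == 0)
    stop("pearson_with_ci: zero variance in a column")
  ct <- stats::cor.test(table$ffr_computed, table$ffr_reference,
                        method = "pearson", conf.level = 0.95)
  list(r = unname(ct$estimate), ci_low = ct$conf.int[1],
       ci_high = ct$conf.int[2], p_value = ct$p.value)
}

#' Full diagnostics report for a paired FFR table
#'
#' Bundles correlation, Bland-Altman agreement, relative-error summary,
#' confusion metrics at the threshold and ROC analysis.
#'
#' @param table A `paired_ffr` table.
#' @param threshold Diagnostic threshold (default 0.80).
#' @return An object of class `ffr_diagnostics`.
#' @export
diagnostics_report <- function(table, threshold = 0.80) {
  stopifnot(inherits(table, "paired_ffr"))
  rel <- relative_error(table$ffr_computed, table$ffr_reference)
  structure(list(
    n = nrow(table), threshold = threshold,
    pearson = pearson_with_ci(table),
    bland_altman = bland_altman(table),
    mean_abs_relative_error = mean(abs(rel)),
    mean_relative_error = mean(rel),
    confusion = confusion_metrics(table, threshold),
    roc = roc_analysis(table, threshold)), class = "ffr_diagnostics")
}

#' @export
print.ffr_diagnostics <- function(x, ...) {
  cat(sprintf("Diagnostic performance (n = %d vessels, threshold %.2f)\n",
              x$n, x$threshold))
  cat(sprintf("  Pearson r = %.3f (95%% CI %.3f-%.3f)\n",
              x$pearson$r, x$pearson$ci_low, x$pearson$ci_high))
  ba <- x$bland_altman
  cat(sprintf("  Bland-Altman bias = %.4f (LoA %.4f to %.4f)\n",
              ba$bias, ba$loa_low, ba$loa_high))
  cat(sprintf("  Mean |relative error| = %.4f\n",
              x$mean_abs_relative_error))
  cm <- x$confusion
  cat(sprintf("  Sens %.2f%%  Spec %.2f%%  PPV %.1f%%  NPV %.1f%%  Acc %.1f%%\n",
              100 * cm$sensitivity, 100 * cm$specificity, 100 * cm$ppv,
              100 * cm$npv, 100 * cm$accuracy))
  cat(sprintf("  Prevalence %.2f%% (%d/%d); Youden J = %.4f (%.2f to 2 dp)\n",
              100 * cm$prevalence, cm$tp + cm$fn, cm$n, cm$youden_j,
              cm$youden_j_2dp))
  cat(sprintf("  AUC = %.3f (95%% CI %.3f-%.3f), optimal cut-off %.3f\n",
              x$roc$auc, x$roc$auc_ci[1], x$roc$auc_ci[2],
              x$roc$optimal_cutoff))
  invisible(x)
}
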