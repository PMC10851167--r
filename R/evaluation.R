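# Evaluation surface: ROC/AUC, confusion metrics, decision curve analysis,
# net reclassification improvement with patient-level bootstrap, and the
# stratified train/test split convention.

#' Area under the ROC curve by pair counting
#'
#' AUC = (concordant pairs + ties/2) / (n1 * n0), identical to the
#' trapezoidal area under the empirical ROC and to U / (n1 * n0) for the
#' Mann-Whitney U of scores.
#'
#' @param scores numeric scores (higher = more event-like).
#' @param y 0/1 labels.
#' @return scalar AUC.
#' @export
roc_auc <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop_mdafm("both classes required for AUC")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' @param scores,y as in [roc_auc()].
#' @return data.frame with `fpr`, `tpr`, `threshold` (descending).
#' @export
roc_curve <- function(scores, y) {
  y <- as.integer(y)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  # collapse tied thresholds to their last row
  keep <- c(diff(ss) != 0, TRUE)
  data.frame(fpr = c(0, fp[keep] / sum(y == 0)),
             tpr = c(0, tp[keep] / sum(y == 1)),
             threshold = c(Inf, ss[keep]))
}

#' Confusion counts from thresholded probabilities
#'
#' @param prob probabilities; @param y 0/1 labels;
#' @param threshold decision threshold (predict positive iff `prob >=`).
#' @return list of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(prob, y, threshold = 0.5) {
  y <- as.integer(y); pred <- prob >= threshold
  structure(list(tp = sum(pred & y == 1), fp = sum(pred & y == 0),
                 fn = sum(!pred & y == 1), tn = sum(!pred & y == 0)),
            class = "confusion_counts")
}

#' Confusion-matrix metrics
#'
#' Sensitivity, specificity, accuracy, PPV and NPV from raw counts. A metric
#' whose denominator is zero is reported as `NA` with an `undefined`
#' attribute naming it, rather than propagating NaN.
#'
#' @param c a `confusion_counts` or list with `tp`, `fp`, `fn`, `tn`.
#' @return named numeric vector.
#' @export
#' @examples
#' confusion_metrics(list(tp = 27, fp = 16, fn = 12, tn = 64))
confusion_metrics <- function(c) {
  with(c, {
    if (any(c(tp, fp, fn, tn) < 0)) stop_mdafm("counts must be nonnegative")
    safe <- function(num, den) if (den > 0) num / den else NA_real_
    out <- c(sensitivity = safe(tp, tp + fn),
             specificity = safe(tn, tn + fp),
             accuracy = safe(tp + tn, tp + fp + fn + tn),
             ppv = safe(tp, tp + fp),
             npv = safe(tn, tn + fn))
    undef <- names(out)[is.na(out)]
    if (length(undef)) attr(out, "undefined") <- undef
    out
  })
}

#' Decision curve analysis
#'
#' At each threshold probability `pt` patients with `prob >= pt` are treated;
#' net benefit is `TP/n - (FP/n) * pt / (1 - pt)`. The treat-all curve uses
#' all-positive classification and the treat-none curve is identically zero.
#'
#' @param prob probabilities in `[0, 1]`.
#' @param y 0/1 labels.
#' @param thresholds grid in `[0, 1)` (default 0.00-0.99 by 0.01).
#' @return `dca_curve` data.frame: `threshold`, `net_benefit_model`,
#'   `net_benefit_all`, `net_benefit_none`.
#' @export
decision_curve <- function(prob, y, thresholds = seq(0, 0.99, by = 0.01)) {
  if (any(thresholds < 0 | thresholds >= 1))
    stop_mdafm("thresholds must lie in [0, 1)")
  if (any(prob < 0 | prob > 1)) stop_mdafm("probabilities must lie in [0, 1]")
  y <- as.integer(y); n <- length(y)
  ev <- sum(y == 1); nev <- n - ev
  rows <- vapply(thresholds, function(pt) {
    w <- pt / (1 - pt)
    cc <- confusion_counts(prob, y, pt)
    c(model = cc$tp / n - (cc$fp / n) * w,
      all = ev / n - (nev / n) * w)
  }, numeric(2))
  structure(data.frame(threshold = thresholds,
                       net_benefit_model = rows["model", ],
                       net_benefit_all = rows["all", ],
                       net_benefit_none = 0),
            class = c("dca_curve", "data.frame"))
}

#' Net reclassification improvement between two models
#'
#' Continuous variant:
#' `NRI = [P(new > old | event) - P(new < old | event)] +
#'        [P(new < old | non-event) - P(new > old | non-event)]`.
#' Categorical variant compares the 0.5-cut classifications instead of raw
#' scores. The confidence interval is a seeded percentile bootstrap over
#' patients and the p-value comes from the normal approximation using the
#' bootstrap standard error.
#'
#' @param scores_new,scores_old aligned score vectors.
#' @param y 0/1 labels.
#' @param variant `"continuous"` (default) or `"categorical"`.
#' @param n_boot bootstrap resamples (default 2000; below 100 a warning is
#'   recorded on the result).
#' @param seed bootstrap seed.
#' @param conf confidence level (default 0.95).
#' @return `nri_result`: `nri`, `ci_low`, `ci_high`, `p_value`, `variant`,
#'   `n_boot`, `warnings`.
#' @export
nri <- function(scores_new, scores_old, y,
                variant = c("continuous", "categorical"),
                n_boot = 2000L, seed = 1L, conf = 0.95) {
  variant <- match.arg(variant)
  y <- as.integer(y)
  if (length(scores_new) != length(scores_old) ||
      length(scores_new) != length(y))
    stop_mdafm("scores_new, scores_old and y must have equal length")
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) < 2L)
    stop_mdafm("y must contain both classes, coded 0/1")
  warnings <- character(0)
  if (n_boot < 100L)
    warnings <- c(warnings, sprintf("n_boot=%d below 100", n_boot))
  point <- nri_statistic(scores_new, scores_old, y, variant)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    ix <- sample.int(length(y), replace = TRUE)
    if (length(unique(y[ix])) < 2L) return(NA_real_)
    nri_statistic(scores_new[ix], scores_old[ix], y[ix], variant)
  }, numeric(1)))
  boot <- boot[!is.na(boot)]
  a <- (1 - conf) / 2
  ci <- if (length(boot)) unname(quantile(boot, c(a, 1 - a))) else c(NA, NA)
  se <- if (length(boot) > 1L) sd(boot) else NA
  p <- if (is.na(se) || se == 0) {
    if (point == 0) 1 else 0   # degenerate bootstrap distribution
  } else 2 * pnorm(-abs(point) / se)
  structure(list(nri = point, ci_low = min(ci[1], point),
                 ci_high = max(ci[2], point), p_value = min(p, 1),
                 variant = variant, n_boot = n_boot, warnings = warnings),
            class = "nri_result")
}

nri_statistic <- function(new, old, y, variant) {
  if (variant == "categorical") {
    new <- as.numeric(new >= 0.5); old <- as.numeric(old >= 0.5)
  }
  up <- new > old; down <- new < old
  ev <- y == 1
  (mean(up[ev]) - mean(down[ev])) + (mean(down[!ev]) - mean(up[!ev]))
}

#' Stratified train/test split of patient IDs
#'
#' Class proportions are preserved within one patient per class; the total
#' test size is `round(test_fraction * n)` exactly, allocated across classes
#' by largest remainder. Deterministic given the seed.
#'
#' @param patient_ids character vector.
#' @param y 0/1 labels aligned with `patient_ids`.
#' @param test_fraction fraction held out (default 0.27, the ~7:3
#'   convention that sends 44 of 163 patients to the test set).
#' @param seed RNG seed.
#' @return list with `train` and `test` ID vectors.
#' @export
#' @examples
#' s <- stratified_split(sprintf("P%03d", 1:163),
#'                       rep(c(0, 1), c(110, 53)), 0.27, seed = 1)
#' lengths(s)  # 119 train, 44 test
stratified_split <- function(patient_ids, y, test_fraction = 0.27, seed = 1L) {
  check_prob(test_fraction, "test_fraction")
  y <- as.integer(y)
  if (length(patient_ids) != length(y)) stop_mdafm("id/label length mismatch")
  if (length(unique(y)) < 2L) stop_mdafm("both classes required")
  n <- length(y)
  n_test <- round(test_fraction * n)
  cls <- sort(unique(y))
  raw <- vapply(cls, function(cl) test_fraction * sum(y == cl), numeric(1))
  base <- floor(raw)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  } else if (rem < 0) {
    cut <- order(raw - base)[seq_len(-rem)]
    base[cut] <- base[cut] - 1
  }
  test_ids <- with_seed(seed, unlist(lapply(seq_along(cls), function(i) {
    ids <- patient_ids[y == cls[i]]
    sample(ids, base[i])
  })))
  list(train = setdiff(patient_ids, test_ids), test = sort(test_ids))
}

#' Full evaluation report for one model on one split
#'
#' @param prob predicted probabilities.
#' @param y 0/1 labels.
#' @param threshold decision threshold (default 0.5).
#' @param dca_thresholds DCA grid.
#' @return `evaluation_report`: `auc`, `counts`, `metrics` (rounded to 4
#'   decimals alongside raw values), `dca`, `n`.
#' @export
evaluate_model <- function(prob, y, threshold = 0.5,
                           dca_thresholds = seq(0, 0.99, by = 0.01)) {
  cc <- confusion_counts(prob, y, threshold)
  met <- confusion_metrics(cc)
  structure(list(auc = roc_auc(prob, y),
                 counts = cc,
                 metrics = met,
                 metrics_rounded = round(met, 4),
                 dca = decision_curve(prob, y, dca_thresholds),
                 threshold = threshold, n = length(y)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report (n=%d): AUC %.4f | sens %.4f spec %.4f acc %.4f ppv %.4f npv %.4f\n",
              x$n, x$auc, x$metrics["sensitivity"], x$metrics["specificity"],
              x$metrics["accuracy"], x$metrics["ppv"], x$metrics["npv"]))
  invisible(x)
}
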