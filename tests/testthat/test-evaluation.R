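test_that("roc_auc: perfect ranking, full ties, and the worked example", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.4, 6), rep(c(0, 1), 3)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("pair-counting AUC equals trapezoidal ROC area and scales to U", {
  withr::with_seed(44, {
    for (rep in 1:25) {
      n <- sample(10:200, 1)
      y <- rbinom(n, 1, 0.4)
      if (length(unique(y)) < 2) next
      s <- round(rnorm(n), sample(1:3, 1))  # induce ties
      a <- roc_auc(s, y)
      expect_equal(a, auc_trapezoid(s, y), tolerance = 1e-12)
      expect_equal(a, auc_oracle(s, y), tolerance = 1e-12)
      # cross-module consistency with the Mann-Whitney U statistic
      u <- mann_whitney_u(s[y == 0], s[y == 1])$u
      expect_equal(a * sum(y == 1) * sum(y == 0), u, tolerance = 1e-9)
    }
  })
})

test_that("confusion_metrics reproduces printed fractions and handles symmetry", {
  m <- confusion_metrics(list(tp = 27, fp = 16, fn = 12, tn = 64))
  expect_equal(round(m[["sensitivity"]], 4), 0.6923)
  expect_equal(round(m[["specificity"]], 4), 0.8000)
  expect_equal(round(m[["accuracy"]], 4), 0.7647)
  expect_equal(round(m[["ppv"]], 4), 0.6279)
  expect_equal(round(m[["npv"]], 4), 0.8421)
  # all-equal counts give 0.5 everywhere
  expect_true(all(confusion_metrics(list(tp = 5, fp = 5, fn = 5, tn = 5)) == 0.5))
  # zero denominator flagged, not NaN
  z <- confusion_metrics(list(tp = 0, fp = 0, fn = 3, tn = 7))
  expect_true(is.na(z[["ppv"]]))
  expect_identical(attr(z, "undefined"), "ppv")
})

test_that("decision_curve: treat-all at pt=0 equals prevalence; formula check", {
  withr::with_seed(3, {
    y <- rep(c(1, 0), c(3, 7))
    prob <- c(0.9, 0.8, 0.25, 0.3, 0.1, 0.15, 0.05, 0.4, 0.18, 0.12)
    dc <- decision_curve(prob, y)
    expect_equal(dc$net_benefit_all[dc$threshold == 0], 0.3)
    expect_true(all(dc$net_benefit_none == 0))
    # n=10, TP=3, FP=2 at pt=0.2 -> 0.3 - 0.2*0.25 = 0.25
    cc <- confusion_counts(prob, y, 0.2)
    expect_identical(c(cc$tp, cc$fp), c(3L, 2L))
    expect_equal(dc$net_benefit_model[dc$threshold == 0.2], 0.25)
    expect_error(decision_curve(prob, y, thresholds = c(0.5, 1)), "\\[0, 1\\)")
    expect_error(decision_curve(prob * 2, y), "\\[0, 1\\]")
  })
})

test_that("nri: identity, hand-counted example, antisymmetry", {
  withr::with_seed(5, {
    y <- rep(c(1, 0), c(5, 6))
    s <- runif(11)
    self <- nri(s, s, y, n_boot = 200, seed = 1)
    expect_identical(self$nri, 0)
    expect_true(self$ci_low <= 0 && self$ci_high >= 0)
    # events: 2 up, 1 down of 3; non-events: 1 up, 1 down of 4 -> 1/3
    y2 <- c(1, 1, 1, 0, 0, 0, 0)
    old <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
    new <- c(0.7, 0.8, 0.3, 0.6, 0.4, 0.5, 0.5)
    r <- nri(new, old, y2, n_boot = 200, seed = 2)
    expect_equal(r$nri, 1 / 3, tolerance = 1e-12)
    r_rev <- nri(old, new, y2, n_boot = 200, seed = 2)
    expect_equal(r_rev$nri, -1 / 3, tolerance = 1e-12)
    # categorical variant uses the 0.5 cut: old classifies all positive
    # (0.5 >= 0.5); new down-classifies one event and one non-event
    rc <- nri(new, old, y2, variant = "categorical", n_boot = 150, seed = 3)
    expect_equal(rc$nri, (0 - 1) / 3 + (1 - 0) / 4, tolerance = 1e-12)
    expect_error(nri(new, old[-1], y2[-1]), "equal length")
    expect_true(length(nri(new, old, y2, n_boot = 50, seed = 1)$warnings) > 0)
  })
})

test_that("self-comparison bootstrap CI contains 0 in >= 94/100 repetitions", {
  withr::with_seed(10, {
    y <- rbinom(60, 1, 0.35)
    y[1:2] <- c(0, 1)
    s <- runif(60)
    hits <- vapply(1:100, function(i) {
      sh <- s + rnorm(60, sd = 1e-9)   # degenerate-tie guard
      r <- nri(sh, sh, y, n_boot = 150, seed = i)
      r$ci_low <= 0 && r$ci_high >= 0
    }, logical(1))
    expect_gte(sum(hits), 94)
  })
})

test_that("stratified_split: printed sizes, determinism, partition, balance", {
  ids <- sprintf("P%03d", 1:163)
  y <- rep(c(0, 1), c(110, 53))
  s <- stratified_split(ids, y, 0.27, seed = 4)
  expect_length(s$train, 119)
  expect_length(s$test, 44)
  expect_identical(s, stratified_split(ids, y, 0.27, seed = 4))
  expect_setequal(c(s$train, s$test), ids)
  expect_length(intersect(s$train, s$test), 0)
  # class proportions preserved within one patient per class
  for (cl in 0:1) {
    n_cl <- sum(y == cl)
    in_test <- sum(y[match(s$test, ids)] == cl)
    expect_lte(abs(in_test - 0.27 * n_cl), 1)
  }
  expect_error(stratified_split(ids, y, 1.2), "\\(0, 1\\)")
})

test_that("evaluate_model assembles AUC, counts, rounded metrics and DCA", {
  withr::with_seed(21, {
    y <- rbinom(80, 1, 0.4)
    y[1:2] <- c(0, 1)
    prob <- plogis(rnorm(80) + y)
    ev <- evaluate_model(prob, y)
    expect_equal(ev$auc, roc_auc(prob, y))
    expect_identical(ev$metrics_rounded, round(ev$metrics, 4))
    expect_s3_class(ev$dca, "dca_curve")
    expect_identical(ev$n, 80L)
  })
})
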