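test_that("mann_whitney_u matches enumeration and tie conventions", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 9)
  expect_equal(r$p, 0.1)
  # identical multisets: U = n^2 / 2 by full-tie symmetry
  x <- c(2, 2, 5, 7)
  expect_equal(mann_whitney_u(x, x)$u, length(x)^2 / 2)
  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
})

test_that("large-sample U and p agree with the brute-force oracle", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      x0 <- round(rnorm(30), 1)  # rounding induces ties
      x1 <- round(rnorm(30, 0.3), 1)
      r <- mann_whitney_u(x0, x1)
      expect_equal(r$u, u_oracle(x0, x1), tolerance = 1e-10)
      # independent tie-corrected normal-approximation oracle
      n0 <- 30; n1 <- 30; n <- 60
      ties <- table(c(x0, x1))
      v <- n0 * n1 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
      z <- (abs(r$u - n0 * n1 / 2) - 0.5) / sqrt(v)
      expect_equal(r$p, 2 * pnorm(-z), tolerance = 1e-10)
    }
  })
})

test_that("mw_filter keeps significant features with a floor fallback", {
  withr::with_seed(21, {
    X <- matrix(rnorm(150 * 300), 150, 300)
    y <- rep(c(0, 1), c(100, 50))
    # expected survivor count under pure noise ~ alpha * p
    survivors <- mean(vapply(1:20, function(s) {
      Xs <- withr::with_seed(s, matrix(rnorm(150 * 300), 150, 300))
      sum(mdafm:::mw_columns(Xs, y)$p < 0.05)
    }, numeric(1)))
    expect_gt(survivors, 0.05 * 300 * 0.6)
    expect_lt(survivors, 0.05 * 300 * 1.6)
    # fallback pads to the floor with the smallest p-values
    flt <- mw_filter(X, y, alpha = 0.05, floor = 100)
    expect_length(flt$indices, 100)
    expect_true(all(flt$p[flt$indices] <= sort(flt$p)[100] + 1e-15))
    # a perfect separator survives with the smallest p
    X2 <- cbind(X, sep = y + 0)
    flt2 <- mw_filter(X2, y, alpha = 0.05, floor = 10)
    expect_true(301 %in% flt2$indices)
    expect_equal(which.min(flt2$p), 301L)
    # alpha = 1 keeps everything
    expect_length(mw_filter(X, y, alpha = 1, floor = 1)$indices, 300)
  })
  expect_error(mw_filter(matrix(1:10, 5), rep(1, 5)), "single class")
})

test_that("mrmr_select is greedy, redundancy-aware and deterministic", {
  withr::with_seed(5, {
    n <- 200
    a <- rnorm(n); b <- rnorm(n)
    y <- as.integer(a + 0.5 * b + rnorm(n, sd = 0.8) > 0)
    X <- cbind(A = a, Adup = a, B = b)
    # k=1: the max-relevance feature (A or its copy; tie breaks to index 1)
    expect_identical(mrmr_select(X, y, 1)$order, 1L)
    # k=2: A then B, never the exact duplicate of A
    expect_identical(mrmr_select(X, y, 2)$order, c(1L, 3L))
    # exhaustive check of the greedy criterion at step 2 (correlation scale)
    sel <- mrmr_select(X, y, 2)
    rel <- abs(cor(X, y))
    red <- abs(cor(X))[, 1]
    scores <- rel - red; scores[1] <- -Inf
    expect_identical(sel$order[2], unname(which.max(scores)))
    # k = all candidates returns everything in greedy order
    expect_setequal(mrmr_select(X, y, 3)$order, 1:3)
    expect_error(mrmr_select(X, y, 4), "exceeds")
    # constant feature: relevance 0, never first
    Xc <- cbind(X, const = 1)
    expect_equal(mrmr_select(Xc, y, 4)$relevance[4], 0)
  })
})

test_that("select_phase_features returns k indices and reapplies without refit", {
  co <- small_cohort(seed = 9, n = 140, p = 80)
  tr <- 1:100; te <- 101:140
  sel <- select_phase_features(co$features$AP[tr, ], co$labels[tr],
                               k = 20, floor = 40)
  expect_length(sel$selected_indices, 20)
  expect_false(anyDuplicated(sel$selected_indices) > 0)
  Xte <- apply_selection(sel, co$features$AP[te, ])
  expect_identical(dim(Xte), c(40L, 20L))
  expect_identical(Xte, co$features$AP[te, sel$selected_indices])
  # no test-set leakage: fitting is a function of training rows alone
  sel2 <- select_phase_features(co$features$AP[tr, ], co$labels[tr],
                                k = 20, floor = 40)
  expect_identical(rlang::hash(sel$selected_indices),
                   rlang::hash(sel2$selected_indices))
})

test_that("selection is invariant to row permutation", {
  co <- small_cohort(seed = 2, n = 90, p = 50)
  perm <- withr::with_seed(1, sample(90))
  s1 <- select_phase_features(co$features$PVP, co$labels, k = 10, floor = 25)
  s2 <- select_phase_features(co$features$PVP[perm, ], co$labels[perm],
                              k = 10, floor = 25)
  expect_identical(s1$selected_indices, s2$selected_indices)
})

test_that("planted informative columns are recovered", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      n <- 400
      X <- matrix(rnorm(n * 120), n, 120)
      y <- as.integer(rowSums(X[, 1:10]) + rnorm(n, sd = 2) > 0)
      sel <- select_phase_features(X, y, k = 30, floor = 60)
      sum(sel$selected_indices <= 10)
    })
  }, numeric(1))
  expect_gte(mean(hits), 8)
})

test_that("selection results serialize to JSON and back", {
  co <- small_cohort(seed = 14, n = 60, p = 30)
  sel <- select_phase_features(co$features$PCP, co$labels, k = 8, floor = 15)
  path <- withr::local_tempfile(fileext = ".json")
  selection_to_json(sel, path)
  back <- selection_from_json(path)
  expect_identical(as.integer(back$selected_indices), sel$selected_indices)
  expect_identical(apply_selection(back, co$features$PCP),
                   apply_selection(sel, co$features$PCP))
})
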