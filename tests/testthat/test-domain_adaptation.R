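test_that("rbf_mmd2 matches the double-loop oracle on small instances", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      n <- sample(2:8, 1); m <- sample(2:8, 1); d <- sample(1:3, 1)
      X <- matrix(rnorm(n * d), n, d); Y <- matrix(rnorm(m * d), m, d)
      sig <- runif(2, 0.5, 3)
      expect_equal(rbf_mmd2(X, Y, mmd_config(bandwidths = sig)),
                   mmd2_oracle(X, Y, sig), tolerance = 1e-12)
      expect_equal(rbf_mmd2(X, Y, mmd_config(bandwidths = sig,
                                             estimator = "unbiased")),
                   mmd2_oracle(X, Y, sig, "unbiased"), tolerance = 1e-12)
    }
  })
})

test_that("biased MMD basics: identity, symmetry, nonnegativity, closed form", {
  withr::with_seed(8, {
    X <- matrix(rnorm(24), 8, 3); Y <- matrix(rnorm(15), 5, 3)
    cfg <- mmd_config(bandwidths = c(0.7, 1.3))
    expect_lt(abs(rbf_mmd2(X, X, cfg)), 1e-12)
    expect_equal(rbf_mmd2(X, Y, cfg), rbf_mmd2(Y, X, cfg), tolerance = 1e-12)
    expect_gte(rbf_mmd2(X, Y, cfg), -1e-12)
  })
  # single-point closed form: 2 - 2 exp(-1/2)
  expect_equal(rbf_mmd2(matrix(0, 1, 1), matrix(1, 1, 1),
                        mmd_config(bandwidths = 1)),
               2 - 2 * exp(-1 / 2), tolerance = 1e-12)
  expect_error(rbf_mmd2(matrix(1, 2, 2), matrix(1, 2, 3)), "column count")
  expect_error(rbf_mmd2(matrix(1, 1, 1), matrix(1, 1, 1),
                        mmd_config(estimator = "unbiased")), "at least 2")
})

test_that("same-distribution MMD sits below its permutation null", {
  withr::with_seed(17, {
    X <- matrix(rnorm(500 * 4), 500, 4)
    Y <- matrix(rnorm(500 * 4), 500, 4)
    cfg <- mmd_config(bandwidths = median_heuristic_bandwidth(X, Y))
    obs <- rbf_mmd2(X, Y, cfg)
    pooled <- rbind(X, Y)
    null <- vapply(1:200, function(i) {
      ix <- sample.int(1000, 500)
      rbf_mmd2(pooled[ix, ], pooled[-ix, ], cfg)
    }, numeric(1))
    expect_lt(obs, quantile(null, 0.95))
  })
})

test_that("median heuristic: single pair, homogeneity, duplication invariance", {
  two <- matrix(c(0, 2), 2, 1)
  expect_equal(median_heuristic_bandwidth(two)^2, 2, tolerance = 1e-12)
  withr::with_seed(4, {
    X <- matrix(rnorm(30), 10, 3)
    s <- median_heuristic_bandwidth(X)
    expect_equal(median_heuristic_bandwidth(3 * X), 3 * s, tolerance = 1e-10)
    expect_equal(median_heuristic_bandwidth(rbind(X, X)), s, tolerance = 1e-10)
  })
  expect_error(median_heuristic_bandwidth(matrix(1, 3, 2)), "identical")
})

test_that("identity initialization: epochs = 0 mapping is the identity", {
  withr::with_seed(3, {
    S <- matrix(rnorm(40 * 6), 40, 6); T <- matrix(rnorm(40 * 6), 40, 6)
    map <- fit_adaptation(S, T, epochs = 0, seed = 5)
    expect_equal(apply_adaptation(map, S), S, tolerance = 1e-12,
                 ignore_attr = TRUE)
    # application is a deterministic row-wise map
    map2 <- fit_adaptation(S, T, epochs = 30, seed = 5)
    Z1 <- apply_adaptation(map2, S)
    expect_identical(Z1, apply_adaptation(map2, S))
    perm <- sample(40)
    expect_equal(apply_adaptation(map2, S[perm, ]), Z1[perm, ],
                 tolerance = 1e-12)
  })
})

test_that("matched distributions: training does not degrade, map stays near identity", {
  withr::with_seed(23, {
    S <- matrix(rnorm(100 * 10), 100, 10)
    T <- matrix(rnorm(100 * 10), 100, 10)
    map <- fit_adaptation(S, T, epochs = 150, seed = 7)
    expect_lte(map$final_mmd2, 2 * map$initial_mmd2)
    Z <- apply_adaptation(map, S)
    expect_lt(mean(abs(Z - S)), 0.1 * sd(S))
  })
})

test_that("constant-offset shift is recovered", {
  withr::with_seed(41, {
    d <- 25
    T <- matrix(rnorm(120 * d), 120, d)
    delta <- rnorm(d)
    S <- matrix(rnorm(120 * d), 120, d) + rep(delta, each = 120)
    # 600 epochs: Adam displacement per parameter is bounded by ~epochs*lr,
    # and unit-normal offsets have coordinates up to ~2.5. The noise-floor
    # stop is disabled: this experiment measures recovery against the target
    # SAMPLE mean, which sits below the distribution-level floor.
    map <- fit_adaptation(S, T, epochs = 600, seed = 2, stop_at_floor = FALSE)
    expect_lte(map$final_mmd2, 0.1 * map$initial_mmd2)
    Z <- apply_adaptation(map, S)
    err <- sqrt(sum((colMeans(Z) - colMeans(T))^2))
    expect_lt(err, 0.1 * sqrt(sum(delta^2)))
    expect_gt(length(map$training_log), 1)
  })
})

test_that("fuse concatenates blocks in PCP|AP|PVP order with block identity", {
  withr::with_seed(2, {
    pcp <- matrix(rnorm(50), 5, 10); ap <- matrix(rnorm(50), 5, 10)
    pvp <- matrix(rnorm(50), 5, 10)
    fz <- fuse(pcp, ap, pvp)
    expect_identical(dim(fz$matrix), c(5L, 30L))
    expect_identical(fz$matrix[, 11:20], ap)
    expect_false(fz$adapted)
    # untrained mappings leave fusion equal to simple concatenation
    map <- fit_adaptation(pcp, ap, epochs = 0)
    fz2 <- fuse(apply_adaptation(map, pcp), ap,
                apply_adaptation(fit_adaptation(pvp, ap, epochs = 0), pvp),
                adapted = TRUE)
    expect_equal(fz2$matrix, fz$matrix, tolerance = 1e-12)
    expect_error(fuse(pcp[1:4, ], ap, pvp), "row count")
  })
})
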