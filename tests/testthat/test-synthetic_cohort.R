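test_that("cohort generation is seed-deterministic and shape-consistent", {
  cfg <- synthetic_config(n_patients = 50, n_features_per_phase = 30,
                          n_latent = 6, n_informative = 3, seed = 42)
  a <- generate_feature_cohort(cfg)
  b <- generate_feature_cohort(cfg)
  expect_identical(a$features, b$features)
  expect_identical(a$labels, b$labels)
  expect_setequal(names(a$features), c("PCP", "AP", "PVP"))
  for (ph in names(a$features)) {
    expect_equal(dim(a$features[[ph]]), c(50, 30))
    expect_identical(rownames(a$features[[ph]]), a$patient_ids)
  }
  expect_true(all(a$labels %in% 0:1))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_patients = 0), "positive integer")
  expect_error(synthetic_config(prevalence = 1.2), "\\(0, 1\\)")
  expect_error(synthetic_config(n_informative = 9, n_latent = 4),
               "must not exceed")
  expect_error(synthetic_config(shift_scale = 0), "shift_scale")
  expect_error(synthetic_config(n_latent = 40, n_features_per_phase = 20),
               "must not exceed")
})

test_that("unshifted PCP is distributionally indistinguishable from AP (permutation MMD)", {
  co <- generate_feature_cohort(synthetic_config(
    n_patients = 120, n_features_per_phase = 25, n_latent = 6,
    n_informative = 3, shift_loc = 0, shift_scale = 1, seed = 5))
  X <- co$features$PCP; Y <- co$features$AP
  cfg <- mmd_config(bandwidths = median_heuristic_bandwidth(X, Y))
  obs <- rbf_mmd2(X, Y, cfg)
  pooled <- rbind(X, Y)
  null <- withr::with_seed(99, vapply(1:200, function(i) {
    ix <- sample.int(nrow(pooled), nrow(X))
    rbf_mmd2(pooled[ix, ], pooled[-ix, ], cfg)
  }, numeric(1)))
  expect_lt(obs, quantile(null, 0.95))
})

test_that("empirical prevalence matches the target within the exact binomial 99% interval", {
  co <- generate_feature_cohort(synthetic_config(
    n_patients = 2000, n_features_per_phase = 10, n_latent = 4,
    n_informative = 2, prevalence = 0.33, seed = 8))
  k <- sum(co$labels)
  bounds <- qbinom(c(0.005, 0.995), 2000, 0.33)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("oracle logistic fit on the latent achieves held-out AUC > 0.8", {
  co <- generate_feature_cohort(synthetic_config(seed = 13,
                                                 n_features_per_phase = 50))
  n <- length(co$labels)
  tr <- seq_len(floor(0.7 * n)); te <- setdiff(seq_len(n), tr)
  q <- co$config$n_informative
  fit <- suppressWarnings(
    glm(co$labels[tr] ~ co$latent[tr, seq_len(q)], family = binomial))
  pred <- drop(cbind(1, co$latent[te, seq_len(q)]) %*% coef(fit))
  expect_gt(roc_auc(pred, co$labels[te]), 0.8)
})

test_that("MMD(PCP, AP) increases with shift_loc in expectation", {
  mean_mmd <- function(loc) {
    mean(vapply(1:20, function(s) {
      co <- generate_feature_cohort(synthetic_config(
        n_patients = 80, n_features_per_phase = 15, n_latent = 5,
        n_informative = 3, shift_loc = loc, shift_scale = 1, seed = s))
      rbf_mmd2(co$features$PCP, co$features$AP,
               mmd_config(bandwidths = 2))
    }, numeric(1)))
  }
  vals <- vapply(c(0, 0.5, 1, 2), mean_mmd, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("noise columns carry no label signal (uniform Mann-Whitney p-values)", {
  ps <- unlist(lapply(1:4, function(s) {
    co <- generate_feature_cohort(synthetic_config(
      n_patients = 150, n_features_per_phase = 80, n_latent = 8,
      n_informative = 4, seed = s))
    X <- co$features$AP[, 9:80]   # pure-noise columns sit after the latents
    mw_filter(X, co$labels, alpha = 1, floor = 1)$p
  }))
  # rank-based p-values are discrete, so tie warnings are expected
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("cohort CSV round-trip preserves features and labels", {
  co <- small_cohort(seed = 3, n = 20, p = 8)
  dir <- withr::local_tempdir()
  paths <- write_cohort_csv(co, dir)
  for (ph in c("PCP", "AP", "PVP")) {
    back <- read_phase_matrix(paths[[ph]])
    expect_equal(back, co$features[[ph]], tolerance = 1e-12)
  }
  lab <- read.csv(paths$labels)
  expect_identical(as.integer(lab$label), as.integer(co$labels))
})

test_that("ROI volumes: mask geometry, NIfTI round-trip, margin precondition", {
  dir <- withr::local_tempdir()
  vols <- generate_roi_volumes(2, shape = c(40, 40, 21), spacing_mm = c(1, 1, 2),
                               seed = 4, out_dir = dir)
  v <- vols[[1]]
  # analytic ellipsoid voxelization count equals the mask sum
  ctr <- v$center; r <- v$radii_mm; sp <- v$spacing_mm
  cnt <- 0L
  for (i in 1:40) for (j in 1:40) for (k in 1:21) {
    d2 <- ((i - ctr[1]) * sp[1] / r[1])^2 + ((j - ctr[2]) * sp[2] / r[2])^2 +
      ((k - ctr[3]) * sp[3] / r[3])^2
    if (d2 <= 1) cnt <- cnt + 1L
  }
  expect_identical(sum(v$mask_array), as.numeric(cnt))
  # centered ellipsoid: max-area slice is the central slice
  expect_identical(unname(select_three_slices(v$mask_array)[2]), 11L)
  # round-trip through the NIfTI layer
  rt <- read_nifti(v$volume[["AP"]])
  expect_equal(rt$data, v$arrays$AP, tolerance = 1e-6)
  expect_equal(rt$spacing_mm, sp, tolerance = 1e-6)
  mk <- read_nifti(v$mask)
  expect_identical(mk$data, v$mask_array)
  # margin that cannot fit
  expect_error(generate_roi_volumes(1, shape = c(10, 10, 10)),
               "cannot contain")
})
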