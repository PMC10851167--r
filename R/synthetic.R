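#' Configuration for the synthetic multi-phase cohort generator
#'
#' The generator emulates the statistical skeleton of a three-phase
#' (pre-contrast PCP, arterial AP, portal-venous PVP) deep-feature cohort:
#' a shared low-dimensional latent tumor state drives a binary
#' microvascular-invasion label and, through phase-specific rotations of the
#' same informative subspace, the informative feature columns of each phase.
#' PCP and PVP are additionally pushed through a global affine distribution
#' shift relative to AP, making AP the natural target domain for adaptation.
#'
#' @param n_patients number of patients (default 163, a realistic
#'   single-institution HCC cohort size).
#' @param n_features_per_phase feature columns per phase (default 3904, the
#'   dimensionality of the deep-feature extractor).
#' @param n_latent latent tumor-state dimensions (default 32).
#' @param n_informative latent dimensions carrying label signal (default 8).
#' @param prevalence target event rate (default 0.33, mirroring the ~32.8%
#'   MVI rate of the motivating cohort).
#' @param shift_loc additive offset applied to PCP and PVP features
#'   (default 1, about 0.7 column SD — an enhancement-like location shift).
#' @param shift_scale multiplicative scale applied to PCP and PVP features
#'   (default 1.5).
#' @param noise_sd SD of feature noise added to informative columns
#'   (default 1, noise at signal scale).
#' @param seed integer RNG seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 163L, n_features_per_phase = 3904L,
                             n_latent = 32L, n_informative = 8L,
                             prevalence = 0.33, shift_loc = 1,
                             shift_scale = 1.5, noise_sd = 0.5, seed = 1L) {
  cfg <- list(
    n_patients = check_count(n_patients, "n_patients"),
    n_features_per_phase = check_count(n_features_per_phase,
                                       "n_features_per_phase"),
    n_latent = check_count(n_latent, "n_latent"),
    n_informative = check_count(n_informative, "n_informative"),
    prevalence = check_prob(prevalence, "prevalence"),
    shift_loc = shift_loc,
    shift_scale = shift_scale,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  if (cfg$n_informative > cfg$n_latent)
    stop_mdafm("n_informative (%d) must not exceed n_latent (%d)",
               cfg$n_informative, cfg$n_latent)
  if (cfg$n_latent > cfg$n_features_per_phase)
    stop_mdafm("n_latent (%d) must not exceed n_features_per_phase (%d)",
               cfg$n_latent, cfg$n_features_per_phase)
  if (!is.numeric(cfg$shift_scale) || cfg$shift_scale <= 0)
    stop_mdafm("shift_scale must be > 0")
  if (cfg$noise_sd < 0) stop_mdafm("noise_sd must be >= 0")
  class(cfg) <- "synthetic_config"
  cfg
}

# Intercept of the label model solved by bisection so that the empirical mean
# of sigmoid(eta + b) over the drawn latents matches the target prevalence.
solve_intercept <- function(eta, prevalence, tol = 1e-10) {
  f <- function(b) mean(plogis(eta + b)) - prevalence
  lo <- -40; hi <- 40
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

random_rotation <- function(p) {
  q <- qr.Q(qr(matrix(rnorm(p * p), p, p)))
  # fix signs so the decomposition is unique and seed-stable across BLAS
  q %*% diag(sign(diag(q) + (diag(q) == 0)), p)
}

#' Generate a synthetic multi-phase feature cohort
#'
#' Draws latent tumor states `z ~ N(0, I)`, labels
#' `y ~ Bernoulli(sigmoid(w.z + b))` with the intercept `b` bisected so the
#' empirical prevalence matches the configured one, and per-phase feature
#' matrices whose first `n_latent` columns are a phase-specific random
#' rotation of `z` plus Gaussian noise, padded with pure-noise columns.
#' PCP and PVP are then transformed by `x -> shift_scale * x + shift_loc`
#' (AP untouched).
#'
#' @param config a [synthetic_config()].
#' @return a `multi_phase_cohort`: list with `features` (named list of
#'   patient-by-feature matrices for PCP, AP, PVP), `labels` (0/1 vector),
#'   `patient_ids`, `latent` (the latent matrix, kept for oracle checks),
#'   and `config`.
#' @export
#' @examples
#' co <- generate_feature_cohort(synthetic_config(n_patients = 40,
#'   n_features_per_phase = 20, n_latent = 5, n_informative = 3, seed = 7))
#' dim(co$features$AP)
generate_feature_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    p <- config$n_features_per_phase
    m <- config$n_latent
    z <- matrix(rnorm(n * m), n, m)
    w <- c(rep(1, config$n_informative), rep(0, m - config$n_informative))
    eta <- drop(z %*% w)
    b <- solve_intercept(eta, config$prevalence)
    y <- rbinom(n, 1L, plogis(eta + b))
    ids <- sprintf("P%04d", seq_len(n))
    phases <- c("PCP", "AP", "PVP")
    # relative informative-signal amplitude per phase: the arterial phase is
    # the most informative single phase in this application, followed by the
    # portal-venous and pre-contrast phases
    phase_gain <- c(PCP = 0.6, AP = 1, PVP = 0.8)
    q <- config$n_informative
    v <- min(3L * q, m)   # informative view columns (deep features are
    rest <- m - v         # many correlated views of few latent factors)
    feats <- lapply(phases, function(ph) {
      # phases share the informative latent subspace but observe it through
      # independent unit-norm mixing with independent noise: three
      # complementary noisy views of the same tumor state
      G <- matrix(rnorm(q * v), q, v)
      G <- sweep(G, 2L, sqrt(colSums(G^2)), `/`)
      loaded_inf <- phase_gain[[ph]] * z[, seq_len(q), drop = FALSE] %*% G
      loaded_rest <- if (rest > 0) {
        z[, q + seq_len(rest), drop = FALSE] %*% random_rotation(rest)
      } else NULL
      loaded <- cbind(loaded_inf, loaded_rest) +
        matrix(rnorm(n * m, sd = config$noise_sd), n, m)
      x <- cbind(loaded, matrix(rnorm(n * (p - m)), n, p - m))
      if (ph != "AP") x <- config$shift_scale * x + config$shift_loc
      dimnames(x) <- list(ids, sprintf("%s_f%04d", ph, seq_len(p)))
      x
    })
    names(feats) <- phases
    structure(list(features = feats, labels = y, patient_ids = ids,
                   latent = z, intercept = b, config = config),
              class = "multi_phase_cohort")
  })
}

#' @export
print.multi_phase_cohort <- function(x, ...) {
  cat(sprintf("multi_phase_cohort: %d patients x %d features/phase, prevalence %.3f\n",
              length(x$labels), ncol(x$features$AP), mean(x$labels)))
  invisible(x)
}

#' Write a cohort to per-phase CSV feature tables plus a labels CSV
#'
#' Tables follow the external contract: header row of feature IDs, first
#' column `patient_id`. A JSON sidecar records the generator configuration.
#'
#' @param cohort a `multi_phase_cohort`.
#' @param dir output directory (created if missing).
#' @return named list of written paths, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (ph in names(cohort$features)) {
    p <- file.path(dir, sprintf("features_%s.csv", ph))
    write_phase_matrix(cohort$features[[ph]], p)
    paths[[ph]] <- p
  }
  lp <- file.path(dir, "labels.csv")
  write.csv(data.frame(patient_id = cohort$patient_ids,
                       label = cohort$labels),
            lp, row.names = FALSE)
  paths$labels <- lp
  jp <- file.path(dir, "cohort_config.json")
  jsonlite::write_json(unclass(cohort$config), jp, auto_unbox = TRUE,
                       digits = NA)
  paths$config <- jp
  invisible(paths)
}

#' Write / read a single-phase feature matrix as CSV
#'
#' @param x patient-by-feature numeric matrix with dimnames.
#' @param path CSV path.
#' @return `write_phase_matrix`: the path invisibly; `read_phase_matrix`:
#'   the matrix with patient IDs as rownames.
#' @export
write_phase_matrix <- function(x, path) {
  df <- data.frame(patient_id = rownames(x), x, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phase_matrix
#' @export
read_phase_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Generate toy three-phase ROI volumes with ellipsoidal lesions
#'
#' Each subject gets one ellipsoidal lesion on a noisy soft-tissue
#' background; the mask is the exact ellipsoid voxelization, and the three
#' phase variants differ by a deterministic intensity offset emulating
#' contrast enhancement. Volumes and masks are written as NIfTI.
#'
#' @param n number of subjects.
#' @param shape voxel grid dimensions (length 3).
#' @param spacing_mm voxel size in mm (length 3).
#' @param seed RNG seed.
#' @param out_dir output directory.
#' @param margin_mm in-plane margin that must fit around the lesion
#'   (default 10, i.e. the 1 cm ROI extension).
#' @return list per subject: `volume` paths (named by phase), `mask` path,
#'   `center`, `radii_mm`, plus the arrays themselves.
#' @export
generate_roi_volumes <- function(n, shape = c(48L, 48L, 24L),
                                 spacing_mm = c(1, 1, 2), seed = 1L,
                                 out_dir = tempfile("roi"),
                                 margin_mm = 10) {
  n <- check_count(n, "n")
  stopifnot(length(shape) == 3L, length(spacing_mm) == 3L,
            all(spacing_mm > 0))
  shape <- as.integer(shape)
  extent_mm <- shape * spacing_mm
  min_r <- 4
  # lesion radius + margin must fit in-plane around a centered lesion
  if (any(extent_mm[1:2] < 2 * (min_r + margin_mm) + 2 * spacing_mm[1:2]) ||
      extent_mm[3] < 2 * min_r + 2 * spacing_mm[3])
    stop_mdafm(paste0("volume of %s mm cannot contain a %g mm lesion plus a ",
                      "%g mm margin"),
               paste(round(extent_mm), collapse = "x"), min_r, margin_mm)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  phase_offset <- c(PCP = 20, AP = 60, PVP = 40)  # HU enhancement emulation
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      # radii in mm, bounded so lesion + margin stays inside the grid
      max_r_xy <- pmin(extent_mm[1:2] / 2 - margin_mm - spacing_mm[1:2], 12)
      max_r_z <- min(extent_mm[3] / 2 - spacing_mm[3], 10)
      radii <- c(runif(2, min_r, pmax(max_r_xy, min_r + 0.5)),
                 runif(1, min_r, max(max_r_z, min_r + 0.5)))
      center <- (shape + 1) / 2  # voxel coordinates; symmetric by design
      coords_mm <- lapply(1:3, function(a) (seq_len(shape[a]) - center[a]) *
                            spacing_mm[a])
      d2 <- outer(outer((coords_mm[[1]] / radii[1])^2,
                        (coords_mm[[2]] / radii[2])^2, `+`),
                  (coords_mm[[3]] / radii[3])^2, `+`)
      mask <- array(as.numeric(d2 <= 1), dim = shape)
      background <- 40 + array(rnorm(prod(shape), sd = 8), dim = shape)
      mask_path <- file.path(out_dir, sprintf("sub%03d_mask.nii.gz", i))
      write_nifti(mask, mask_path, spacing_mm, datatype = "uint8")
      vols <- list(); vol_paths <- character(0)
      for (ph in names(phase_offset)) {
        v <- background + mask * phase_offset[[ph]]
        p <- file.path(out_dir, sprintf("sub%03d_%s.nii.gz", i, ph))
        write_nifti(v, p, spacing_mm, datatype = "float32")
        vols[[ph]] <- v; vol_paths[ph] <- p
      }
      list(volume = vol_paths, mask = mask_path, arrays = vols,
           mask_array = mask, center = center, radii_mm = radii,
           spacing_mm = spacing_mm)
    })
  })
}
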