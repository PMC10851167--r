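# Kernel maximum mean discrepancy between feature samples. The biased
# V-statistic estimator (nonnegative, smooth) is the adaptation training
# loss; the unbiased U-statistic is available for diagnostics.

#' MMD estimator configuration
#'
#' @param bandwidths positive kernel bandwidths (sigma), or NULL to use the
#'   median heuristic scaled by `multipliers` at evaluation time.
#' @param multipliers multipliers applied to the median-heuristic bandwidth
#'   (default `c(0.25, 0.5, 1, 2, 4)`).
#' @param estimator `"biased"` or `"unbiased"`.
#' @return `mmd_config` object.
#' @export
mmd_config <- function(bandwidths = NULL,
                       multipliers = c(0.25, 0.5, 1, 2, 4),
                       estimator = c("biased", "unbiased")) {
  estimator <- match.arg(estimator)
  if (!is.null(bandwidths)) {
    if (length(bandwidths) < 1L || any(bandwidths <= 0))
      stop_mdafm("bandwidths must be positive")
  }
  if (length(multipliers) < 1L || any(multipliers <= 0))
    stop_mdafm("multipliers must be positive")
  structure(list(bandwidths = bandwidths, multipliers = multipliers,
                 estimator = estimator),
            class = "mmd_config")
}

pairwise_sqdist <- function(X, Y) {
  xs <- rowSums(X^2); ys <- rowSums(Y^2)
  d2 <- outer(xs, ys, `+`) - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  d2
}

#' Median-heuristic kernel bandwidth
#'
#' `sigma^2` is half the median of positive pairwise squared Euclidean
#' distances over the pooled sample (zero distances between duplicated
#' points are excluded, which makes the heuristic invariant to duplicating
#' the sample).
#'
#' @param X,Y sample matrices (rows = observations) with equal column count;
#'   `Y` may be NULL to pool only `X`.
#' @return bandwidth `sigma` (scalar).
#' @export
median_heuristic_bandwidth <- function(X, Y = NULL) {
  Z <- rbind(X, Y)
  if (nrow(Z) < 2L) stop_mdafm("need at least 2 pooled points")
  d2 <- pairwise_sqdist(Z, Z)
  d2 <- d2[upper.tri(d2)]
  d2 <- d2[d2 > 0]
  if (length(d2) == 0L) stop_mdafm("all pooled points are identical")
  sqrt(median(d2) / 2)
}

resolve_bandwidths <- function(X, Y, config) {
  if (!is.null(config$bandwidths)) return(config$bandwidths)
  median_heuristic_bandwidth(X, Y) * config$multipliers
}

#' Squared kernel MMD between two samples
#'
#' Gaussian RBF kernel `k(a, b) = exp(-||a - b||^2 / (2 sigma^2))`, summed
#' over the bandwidth list. The biased estimator is
#' `mean k(X,X) + mean k(Y,Y) - 2 mean k(X,Y)` and is nonnegative up to
#' roundoff; the unbiased estimator excludes diagonal terms and may be
#' negative.
#'
#' @param X,Y sample matrices with equal column count.
#' @param config an [mmd_config()].
#' @return scalar squared MMD.
#' @export
rbf_mmd2 <- function(X, Y, config = mmd_config()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop_mdafm("X and Y must share column count")
  n <- nrow(X); m <- nrow(Y)
  if (n < 1L || m < 1L) stop_mdafm("need at least one row per sample")
  if (config$estimator == "unbiased" && (n < 2L || m < 2L))
    stop_mdafm("unbiased estimator needs at least 2 rows per sample")
  sigmas <- resolve_bandwidths(X, Y, config)
  dxx <- pairwise_sqdist(X, X); dyy <- pairwise_sqdist(Y, Y)
  dxy <- pairwise_sqdist(X, Y)
  total <- 0
  for (s in sigmas) {
    kxx <- exp(-dxx / (2 * s^2)); kyy <- exp(-dyy / (2 * s^2))
    kxy <- exp(-dxy / (2 * s^2))
    if (config$estimator == "biased") {
      total <- total + mean(kxx) + mean(kyy) - 2 * mean(kxy)
    } else {
      total <- total +
        (sum(kxx) - n) / (n * (n - 1)) +
        (sum(kyy) - m) / (m * (m - 1)) - 2 * mean(kxy)
    }
  }
  total
}
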