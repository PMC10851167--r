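# Ensemble sparse Bayesian extreme learning machine. Each base is a random
# single-hidden-layer feature map (uniform [-1,1] input weights and biases,
# sigmoid activation) whose output weights are fitted by sparse Bayesian
# linear regression with automatic relevance determination (ARD): per-weight
# Gaussian priors whose precisions are evidence-maximized, pruning hidden
# units whose precision diverges. Bases differ only in their random weights;
# scores are averaged and squashed through a logistic link.
#
# Inputs are standardized with a single global (scalar) training-set mean
# and SD rather than per column: per-column standardization would itself
# silently re-align per-feature distribution shifts between phases, which is
# the adaptation stage's job, and would make the fusion comparison
# meaningless (see the methods vignette).

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Hidden-layer feature map of one ELM base
#'
#' @param X n-by-d matrix (already standardized by the caller).
#' @param base an `elm_base` (element of a fitted ensemble).
#' @return n-by-L activation matrix, values in (0, 1).
#' @export
hidden_map <- function(X, base) {
  if (ncol(X) != ncol(base$input_weights))
    stop_mdafm("base expects %d input columns, got %d",
               ncol(base$input_weights), ncol(X))
  sigmoid(sweep(tcrossprod(X, base$input_weights), 2L, base$biases, `+`))
}

#' Sparse Bayesian linear regression with ARD (evidence maximization)
#'
#' Fits `t ~ H beta` under per-coefficient Gaussian priors with precisions
#' `alpha`; an intercept column of ones is prepended internally. The
#' fixed-point loop updates, over the active set,
#' `Sigma = (sigma^-2 H'H + diag(alpha))^-1`, `mu = sigma^-2 Sigma H' t`,
#' `gamma_j = 1 - alpha_j Sigma_jj`, `alpha_j <- gamma_j / mu_j^2`,
#' `sigma^2 <- ||t - H mu||^2 / (n - sum gamma)`, pruning coefficients whose
#' precision exceeds `prune_threshold`. With `ard = FALSE` the precisions are
#' frozen at `alpha0` (a plain ridge-regularized ELM, the classical ELM
#' baseline).
#'
#' @param H n-by-L design matrix (without intercept).
#' @param t numeric targets (class labels coded -1/+1 upstream).
#' @param max_iter iteration cap (default 500).
#' @param tol relative alpha-change convergence tolerance (default 1e-4).
#' @param prune_threshold precision above which a weight is pruned
#'   (default 1e8).
#' @param ard if FALSE, skip precision updates (ridge mode).
#' @param alpha0 initial (or frozen) precision (default 1e-2).
#' @param sigma2 initial noise variance (default 0.1).
#' @return list: `weights` (length L+1, intercept first, pruned entries
#'   exactly 0), `ard_precisions`, `noise_variance`, `active` (logical),
#'   `iterations`.
#' @export
sparse_bayes_linreg <- function(H, t, max_iter = 500L, tol = 1e-4,
                                prune_threshold = 1e8, ard = TRUE,
                                alpha0 = 1e-2, sigma2 = 0.1) {
  n <- nrow(H)
  if (n < 2L) stop_mdafm("need n > 1 observations")
  Phi <- cbind(`(intercept)` = 1, H)
  p <- ncol(Phi)
  alpha <- rep(alpha0, p)
  active <- rep(TRUE, p)
  mu_full <- rep(0, p)
  it <- 0L
  repeat {
    it <- it + 1L
    A <- which(active)
    if (length(A) == 0L) break
    PhiA <- Phi[, A, drop = FALSE]
    M <- crossprod(PhiA) / sigma2 + diag(alpha[A], length(A))
    Sigma <- tryCatch(chol2inv(chol(M)), error = function(e) {
      chol2inv(chol(M + diag(1e-10, length(A))))
    })
    mu <- drop(Sigma %*% crossprod(PhiA, t)) / sigma2
    if (!ard) {
      mu_full[] <- 0; mu_full[A] <- mu
      break
    }
    gamma <- 1 - alpha[A] * diag(Sigma)
    gamma <- pmin(pmax(gamma, 0), 1)
    alpha_new <- ifelse(mu^2 > 1e-300, gamma / mu^2, Inf)
    resid <- t - drop(PhiA %*% mu)
    denom <- n - sum(gamma)
    if (denom > 1e-8) sigma2 <- max(sum(resid^2) / denom, 1e-12)
    prev <- alpha[A]
    alpha[A] <- alpha_new
    drop_now <- alpha[A] > prune_threshold
    active[A[drop_now]] <- FALSE
    kept <- !drop_now
    rel <- if (any(kept))
      max(abs(log(pmin(alpha_new[kept], prune_threshold)) -
              log(pmin(prev[kept], prune_threshold))))
    else 0
    mu_full[] <- 0; mu_full[A] <- ifelse(drop_now, 0, mu)
    if ((rel < tol && !any(drop_now)) || it >= max_iter) break
  }
  # final refit so the returned mean solves the active-set normal equations
  # for the returned precisions exactly
  A <- which(active)
  if (ard && length(A) > 0L) {
    PhiA <- Phi[, A, drop = FALSE]
    M <- crossprod(PhiA) / sigma2 + diag(alpha[A], length(A))
    Sigma <- tryCatch(chol2inv(chol(M)), error = function(e)
      chol2inv(chol(M + diag(1e-10, length(A)))))
    mu_full[] <- 0
    mu_full[A] <- drop(Sigma %*% crossprod(PhiA, t)) / sigma2
  }
  list(weights = mu_full, ard_precisions = alpha,
       noise_variance = sigma2, active = active, iterations = it)
}

#' Fit an ensemble sparse Bayesian extreme learning machine
#'
#' @param X n-by-d training matrix.
#' @param y 0/1 labels (regressed as -1/+1 targets).
#' @param L hidden units per base (default 200).
#' @param B ensemble size (default 10).
#' @param seed global seed; base seeds are derived per base index.
#' @param ard ARD on (sparse Bayesian) or off (ridge ELM baseline).
#' @param prune_threshold,tol,max_iter passed to [sparse_bayes_linreg()].
#' @param threshold_mode `"fixed"` (decision threshold 0.5) or `"youden"`
#'   (Youden J maximized on training probabilities).
#' @param standardize `"global"` (scalar train mean/SD; default) or
#'   `"per-feature"`.
#' @param weight_scale half-width of the uniform input-weight distribution;
#'   `NULL` (default) uses fan-in scaling `1/sqrt(d)` so hidden
#'   pre-activations have unit-order spread; set to 1 for the classical
#'   `U[-1, 1]` convention.
#' @return `esbelm_ensemble` object.
#' @export
fit_esbelm <- function(X, y, L = 200L, B = 10L, seed = 1L, ard = TRUE,
                       prune_threshold = 1e8, tol = 1e-4, max_iter = 500L,
                       threshold_mode = c("fixed", "youden"),
                       standardize = c("global", "per-feature"),
                       weight_scale = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  standardize <- match.arg(standardize)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop_mdafm("labels contain a single class")
  L <- check_count(L, "L"); B <- check_count(B, "B")
  d <- ncol(X)
  if (standardize == "global") {
    center <- mean(X); scale_ <- sd(as.vector(X))
  } else {
    center <- colMeans(X); scale_ <- apply(X, 2L, sd)
  }
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  Xs <- standardize_input(X, center, scale_, standardize)
  tt <- 2 * y - 1
  ws <- weight_scale %||% (1 / sqrt(d))
  bases <- lapply(seq_len(B), function(b) {
    bs <- derive_seed(seed, sprintf("esbelm-base-%03d", b))
    wb <- with_seed(bs, list(
      W = matrix(runif(L * d, -ws, ws), L, d),
      b = runif(L, -1, 1)))
    base <- list(input_weights = wb$W, biases = wb$b, activation = "sigmoid",
                 seed = bs)
    Hm <- hidden_map(Xs, base)
    fit <- sparse_bayes_linreg(Hm, tt, max_iter = max_iter, tol = tol,
                               prune_threshold = prune_threshold, ard = ard)
    base$output_weights <- fit$weights
    base$ard_precisions <- fit$ard_precisions
    base$pruned_mask <- !fit$active
    base$noise_variance <- fit$noise_variance
    class(base) <- "elm_base"
    base
  })
  model <- structure(list(bases = bases, aggregation = "mean-score",
                          link = "logistic", decision_threshold = 0.5,
                          center = center, scale = scale_,
                          standardize = standardize, L = L, B = B,
                          ard = ard, seed = seed),
                     class = "esbelm_ensemble")
  if (threshold_mode == "youden") {
    pr <- predict_score(model, X)
    model$decision_threshold <- youden_threshold(pr, y)
  }
  model
}

standardize_input <- function(X, center, scale_, mode) {
  if (mode == "global") (X - center) / scale_
  else sweep(sweep(X, 2L, center, `-`), 2L, scale_, `/`)
}

youden_threshold <- function(prob, y) {
  cand <- sort(unique(prob))
  j <- vapply(cand, function(ct) {
    pred <- prob >= ct
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

base_raw_score <- function(base, Xs) {
  Hm <- hidden_map(Xs, base)
  drop(cbind(1, Hm) %*% base$output_weights)
}

#' Predict event probabilities from a fitted ensemble
#'
#' Probability = logistic(mean over bases of the raw regression score).
#'
#' @param model an `esbelm_ensemble`.
#' @param X matrix with the training input dimension.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_score <- function(model, X) {
  stopifnot(inherits(model, "esbelm_ensemble"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$bases[[1]]$input_weights))
    stop_mdafm("model expects %d columns, got %d",
               ncol(model$bases[[1]]$input_weights), ncol(X))
  Xs <- standardize_input(X, model$center, model$scale, model$standardize)
  scores <- vapply(model$bases, base_raw_score, numeric(nrow(Xs)), Xs = Xs)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = nrow(Xs))
  sigmoid(rowMeans(scores))
}

#' @export
predict.esbelm_ensemble <- function(object, newdata,
                                    type = c("prob", "class"), ...) {
  type <- match.arg(type)
  pr <- predict_score(object, newdata)
  if (type == "prob") pr else as.integer(pr >= object$decision_threshold)
}

#' @export
print.esbelm_ensemble <- function(x, ...) {
  pruned <- mean(vapply(x$bases, function(b) mean(b$pruned_mask), numeric(1)))
  cat(sprintf("esbelm_ensemble: B=%d bases, L=%d hidden, ard=%s, mean pruned %.1f%%\n",
              x$B, x$L, x$ard, 100 * pruned))
  invisible(x)
}
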