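# Per-phase feature selection: Mann-Whitney U prefilter followed by greedy
# minimum-redundancy maximum-relevance selection down to k features.
# Both primitives are authored here (rather than wrapping wilcox.test)
# because the U statistic is also the cross-module consistency anchor for
# the AUC implementation: AUC * n1 * n0 == U with ties averaged.

#' Mann-Whitney U test (class-1 vs class-0)
#'
#' `U` counts pairs where a class-1 value exceeds a class-0 value, with ties
#' counted as 1/2. The two-sided p-value uses exact enumeration of all label
#' assignments when `n0 + n1 <= 12`, otherwise the normal approximation with
#' continuity and tie correction.
#'
#' @param x0 numeric values of class-0 samples.
#' @param x1 numeric values of class-1 samples.
#' @return list with `u` and `p`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 9, exact p = 0.1
mann_whitney_u <- function(x0, x1) {
  n0 <- length(x0); n1 <- length(x1)
  if (n0 == 0L || n1 == 0L) stop_mdafm("both groups must be nonempty")
  pooled <- c(x0, x1)
  r <- rank(pooled)
  u <- sum(r[(n0 + 1):(n0 + n1)]) - n1 * (n1 + 1) / 2
  mu <- n0 * n1 / 2
  if (n0 + n1 <= 12L) {
    # exact two-sided p over all C(n, n1) label assignments
    combos <- utils::combn(n0 + n1, n1)
    us <- apply(combos, 2L, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
    dev <- abs(u - mu)
    p <- mean(abs(us - mu) >= dev - 1e-12)
  } else {
    n <- n0 + n1
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n0 * n1 / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) return(list(u = u, p = 1))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-max(z, 0))
  }
  list(u = u, p = min(p, 1))
}

# vectorized per-column U and p for a matrix; same conventions as
# mann_whitney_u with the large-sample path (used by the filter).
mw_columns <- function(X, y) {
  n0 <- sum(y == 0); n1 <- sum(y == 1); n <- n0 + n1
  res <- vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    r <- rank(v)
    u <- sum(r[y == 1]) - n1 * (n1 + 1) / 2
    mu <- n0 * n1 / 2
    ties <- table(v)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n0 * n1 / 12 * (n + 1 - tie_term)
    p <- if (sigma2 <= 0) 1 else 2 * pnorm(-max((abs(u - mu) - 0.5) / sqrt(sigma2), 0))
    c(u, min(p, 1))
  }, numeric(2))
  list(u = res[1, ], p = res[2, ])
}

#' Mann-Whitney significance prefilter
#'
#' Keeps features with two-sided p below `alpha`; if fewer than `floor`
#' survive, the `floor` smallest-p features are kept instead (so the greedy
#' stage always has enough candidates).
#'
#' @param X patient-by-feature matrix.
#' @param y 0/1 labels.
#' @param alpha significance threshold (default 0.05).
#' @param floor minimum number of candidates (default 500).
#' @return list with `indices` (candidate columns, ascending), `u`, `p`.
#' @export
mw_filter <- function(X, y, alpha = 0.05, floor = 500L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop_mdafm("labels contain a single class")
  if (length(y) != nrow(X)) stop_mdafm("label length != row count")
  mw <- mw_columns(X, y)
  keep <- which(mw$p < alpha)
  floor <- min(floor, ncol(X))
  if (length(keep) < floor) keep <- order(mw$p)[seq_len(floor)]
  list(indices = sort(keep), u = mw$u, p = mw$p)
}

#' Greedy minimum-redundancy maximum-relevance selection
#'
#' Forward selection maximizing `relevance(f; y) - mean redundancy(f, S)`
#' where redundancy is the absolute Pearson correlation with
#' already-selected features. Reported relevance is the one-way ANOVA F
#' statistic of the feature against the binary label; inside the greedy
#' score the equivalent absolute point-biserial correlation `|r(f, y)|` is
#' used instead, because the F statistic is unbounded while redundancy is
#' bounded by 1 — on the raw F scale the redundancy penalty could never veto
#' an exact duplicate of an already-selected strong feature. The two are
#' monotonically related at fixed n, so the first pick (max relevance) is
#' identical either way. The first pick is the maximum-relevance feature;
#' ties break to the lowest column index; constant features get relevance 0
#' and redundancy 0 against constants.
#'
#' @param X candidate patient-by-feature matrix.
#' @param y 0/1 labels.
#' @param k number of features to select (default 200).
#' @param variant `"difference"` (default) or `"quotient"` combination of
#'   relevance and redundancy.
#' @return list with `order` (selected column indices, greedy order),
#'   `relevance` (per-candidate F statistics).
#' @export
mrmr_select <- function(X, y, k = 200L, variant = c("difference", "quotient")) {
  variant <- match.arg(variant)
  p <- ncol(X); n <- nrow(X)
  k <- check_count(k, "k")
  if (k > p) stop_mdafm("k (%d) exceeds candidate count (%d)", k, p)
  y <- as.numeric(y)
  sds <- apply(X, 2L, sd)
  const <- sds == 0 | !is.finite(sds)
  r_y <- rep(0, p)
  ok <- !const
  if (any(ok)) r_y[ok] <- suppressWarnings(abs(cor(X[, ok, drop = FALSE], y)))
  r_y[!is.finite(r_y)] <- 0
  relevance <- r_y^2 * (n - 2) / pmax(1 - r_y^2, 1e-12)  # ANOVA F for binary y
  selected <- integer(0)
  red_sum <- rep(0, p)       # sum of |cor| with selected features
  remaining <- rep(TRUE, p)
  Xs <- scale(X)             # for fast correlation updates
  Xs[, const] <- 0
  for (step in seq_len(k)) {
    score <- if (step == 1L) r_y
             else if (variant == "difference") r_y - red_sum / length(selected)
             else r_y / pmax(red_sum / length(selected), 1e-12)
    score[!remaining] <- -Inf
    pick <- unname(which.max(score))   # which.max breaks ties to lowest index
    selected <- c(selected, pick)
    remaining[pick] <- FALSE
    if (step < k) {
      cors <- abs(drop(crossprod(Xs, Xs[, pick])) / (n - 1))
      cors[!is.finite(cors)] <- 0
      red_sum <- red_sum + cors
    }
  }
  list(order = selected, relevance = relevance)
}

#' Fit the per-phase selection cascade (Mann-Whitney filter then mRMR)
#'
#' Fit on training rows only; the result reapplies to new data by column
#' indexing, with no refit.
#'
#' @param X training patient-by-feature matrix for one phase.
#' @param y 0/1 training labels.
#' @param k features to keep (default 200).
#' @param alpha,floor prefilter parameters, see [mw_filter()].
#' @param variant mRMR variant, see [mrmr_select()].
#' @return `selection_result`: `selected_indices` (columns of `X`, greedy
#'   order), `u_statistics`, `p_values`, `relevance_scores` (on candidates),
#'   `fitted_on` (rownames of `X`), `k`, `alpha`.
#' @export
select_phase_features <- function(X, y, k = 200L, alpha = 0.05, floor = 500L,
                                  variant = "difference") {
  flt <- mw_filter(X, y, alpha, floor)
  k_eff <- min(k, length(flt$indices))
  mr <- mrmr_select(X[, flt$indices, drop = FALSE], y, k_eff, variant)
  structure(list(selected_indices = flt$indices[mr$order],
                 u_statistics = flt$u, p_values = flt$p,
                 relevance_scores = mr$relevance,
                 candidate_indices = flt$indices,
                 fitted_on = rownames(X) %||% as.character(seq_len(nrow(X))),
                 k = k_eff, alpha = alpha),
            class = "selection_result")
}

#' Apply a fitted selection to a (new) feature matrix
#'
#' @param sel a `selection_result`.
#' @param X matrix with the same column space the selection was fitted on.
#' @return `X` restricted to the selected columns, in greedy order.
#' @export
apply_selection <- function(sel, X) {
  stopifnot(inherits(sel, "selection_result"))
  if (max(sel$selected_indices) > ncol(X))
    stop_mdafm("matrix has %d columns; selection expects at least %d",
               ncol(X), max(sel$selected_indices))
  X[, sel$selected_indices, drop = FALSE]
}

#' Serialize / deserialize a selection result as JSON
#'
#' @param sel a `selection_result`.
#' @param path JSON path.
#' @return `selection_to_json`: path invisibly; `selection_from_json`: the
#'   restored `selection_result`.
#' @export
selection_to_json <- function(sel, path) {
  out <- unclass(sel)
  out$fitted_on_hash <- rlang::hash(sel$fitted_on)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname selection_to_json
#' @export
selection_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj[c("selected_indices", "u_statistics", "p_values",
                  "relevance_scores", "candidate_indices", "fitted_on",
                  "k", "alpha")],
            class = "selection_result")
}
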