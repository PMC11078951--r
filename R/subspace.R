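#' Single-unit count matrices for a site
#'
#' Spike counts of each neuron of a site group in non-overlapping windows
#' (20 ms by default), time-ordered.
#'
#' @param raster A `spike_raster`.
#' @param neurons Global neuron ids of the group (e.g. [site_neurons()]).
#' @param bin Window length, ms.
#' @param span Optional `c(t0, t1)` ms restriction.
#' @return Integer matrix, one row per window, one column per neuron.
#' @export
sua_matrix <- function(raster, neurons, bin = 20, span = NULL) {
  if (is.null(span)) span <- raster$span
  n_win <- floor((span[2] - span[1]) / bin)
  keep <- raster$id %in% neurons & raster$t >= span[1] &
    raster$t < span[1] + n_win * bin
  w <- floor((raster$t[keep] - span[1]) / bin) + 1L
  j <- match(raster$id[keep], neurons)
  M <- matrix(0L, n_win, length(neurons))
  if (any(keep)) {
    idx <- (j - 1L) * n_win + w
    cnt <- tabulate(idx, nbins = n_win * length(neurons))
    M <- matrix(as.integer(cnt), n_win, length(neurons))
  }
  M
}

#' State-conditioned fluctuations of count matrices
#'
#' Removes, per neuron, the mean count of the state each window resides in,
#' leaving the within-state fluctuations used by the communication-subspace
#' regressions. Conditioning on state prevents the On/Off mean difference
#' from masquerading as cross-area correlation.
#'
#' @param X Count matrix (windows x neurons).
#' @param state Logical (or factor) state label per window.
#' @return Matrix of fluctuations, same shape; column means within each
#'   state are exactly zero.
#' @export
state_conditioned_fluctuations <- function(X, state) {
  stopifnot(nrow(X) == length(state))
  out <- X * 0
  for (s in unique(state)) {
    rows <- state == s
    if (sum(rows) < 2 * ncol(X))
      warning(sprintf("state %s has fewer than 2p rows", s))
    mu <- colMeans(X[rows, , drop = FALSE])
    out[rows, ] <- sweep(X[rows, , drop = FALSE], 2, mu)
  }
  out
}

# contiguous-block fold assignment (time-respecting)
block_folds <- function(n, folds) {
  rep(seq_len(folds), each = ceiling(n / folds), length.out = n)
}

ridge_coef <- function(X, Y, lambda) {
  p <- ncol(X)
  solve(crossprod(X) + lambda * diag(p), crossprod(X, Y))
}

# prediction performance 1 - NSE, averaged over target neurons and rows
perf_of <- function(Y, Yhat) {
  nse <- mean((Y - Yhat)^2) / mean(sweep(Y, 2, colMeans(Y))^2)
  1 - nse
}

#' Cross-validated ridge regression between two areas' fluctuations
#'
#' Fits `Y = X B` by ridge regression, `B = (X'X + lambda I)^{-1} X'Y`.
#' Performance is `1 - NSE` (normalized squared error, averaged over target
#' neurons and held-out rows). `lambda` is the largest value whose mean
#' cross-validated performance is within one SEM (across folds) of the
#' best -- the usual one-SEM rule. Folds are contiguous time blocks to
#' limit autocorrelation leakage.
#'
#' @param X,Y Fluctuation matrices (windows x neurons).
#' @param lambda_grid Ridge penalties (default logarithmic, 1e-2 to 1e3).
#' @param folds Number of cross-validation folds.
#' @return A `regression_fit`: `B` (refit on all rows at the chosen
#'   `lambda`), `lambda`, per-lambda CV performance and SEM, and the CV
#'   performance at the chosen `lambda` (`performance`).
#' @export
ridge_fit <- function(X, Y, lambda_grid = 10^seq(-2, 3, length.out = 20),
                      folds = 10) {
  stopifnot(nrow(X) == nrow(Y), all(lambda_grid > 0))
  n <- nrow(X)
  fold <- block_folds(n, folds)
  perf <- matrix(NA_real_, folds, length(lambda_grid))
  for (f in seq_len(folds)) {
    tr <- fold != f
    XtX <- crossprod(X[tr, , drop = FALSE])
    XtY <- crossprod(X[tr, , drop = FALSE], Y[tr, , drop = FALSE])
    for (j in seq_along(lambda_grid)) {
      B <- solve(XtX + lambda_grid[j] * diag(ncol(X)), XtY)
      perf[f, j] <- perf_of(Y[!tr, , drop = FALSE],
                            X[!tr, , drop = FALSE] %*% B)
    }
  }
  mp <- colMeans(perf)
  sem <- apply(perf, 2, stats::sd) / sqrt(folds)
  best <- which.max(mp)
  ok <- which(mp >= mp[best] - sem[best])
  j_star <- max(ok)   # largest lambda within one SEM of the best
  fit <- list(B = ridge_coef(X, Y, lambda_grid[j_star]),
              lambda = lambda_grid[j_star],
              performance = mp[j_star], sem = sem[j_star],
              cv_performance = mp, cv_sem = sem,
              lambda_grid = lambda_grid, folds = folds)
  class(fit) <- "regression_fit"
  fit
}

#' Reduced-rank regression through the ridge predictions
#'
#' `B_RRR = B_rdg V V'`, where `V` holds the top `m` principal components
#' of the ridge predictions `X B_rdg` on the training rows. Test rows are
#' projected with the training-fold `V` (no leakage). At `m = p` the fit
#' equals the full ridge regression exactly.
#'
#' @param X,Y Fluctuation matrices.
#' @param m Rank (number of predictive dimensions).
#' @param lambda Ridge penalty (e.g. from [ridge_fit()]).
#' @param folds Number of CV folds; `folds = 0` fits on all rows and
#'   reports in-sample performance.
#' @return A `regression_fit` with `B`, `m`, CV `performance` and `sem`.
#' @export
reduced_rank_fit <- function(X, Y, m, lambda, folds = 10) {
  p <- ncol(Y)
  if (m < 1 || m > p) stop("rank m outside [1, p]")
  rrr_B <- function(Xtr, Ytr) {
    B <- ridge_coef(Xtr, Ytr, lambda)
    Yhat <- Xtr %*% B
    V <- svd(Yhat, nu = 0, nv = m)$v[, seq_len(m), drop = FALSE]
    B %*% V %*% t(V)
  }
  if (folds == 0) {
    B <- rrr_B(X, Y)
    perf <- perf_of(Y, X %*% B)
    return(structure(list(B = B, m = m, lambda = lambda, performance = perf,
                          sem = 0), class = "regression_fit"))
  }
  fold <- block_folds(nrow(X), folds)
  perf <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    B <- rrr_B(X[tr, , drop = FALSE], Y[tr, , drop = FALSE])
    perf_of(Y[!tr, , drop = FALSE], X[!tr, , drop = FALSE] %*% B)
  }, numeric(1))
  structure(list(B = rrr_B(X, Y), m = m, lambda = lambda,
                 performance = mean(perf),
                 sem = stats::sd(perf) / sqrt(folds)),
            class = "regression_fit")
}

#' Performance curve over ranks and the communication-subspace dimension
#'
#' @param X,Y Fluctuation matrices.
#' @param m_range Ranks to evaluate.
#' @param lambda Ridge penalty; `NULL` selects it with [ridge_fit()].
#' @param folds CV folds.
#' @return List: `curve` (data frame `m`, `performance`, `sem`), `full`
#'   (full-model CV performance and sem), `lambda`, and `m_star`, the
#'   smallest rank whose performance is within one CV-SEM of the full model.
#' @export
subspace_analysis <- function(X, Y, m_range = 1:10, lambda = NULL,
                              folds = 10) {
  if (is.null(lambda)) {
    fr <- ridge_fit(X, Y, folds = folds)
    lambda <- fr$lambda
    full_perf <- fr$performance
    full_sem <- fr$sem
  } else {
    fr <- reduced_rank_fit(X, Y, ncol(Y), lambda, folds)
    full_perf <- fr$performance
    full_sem <- fr$sem
  }
  curve <- data.frame(m = m_range, performance = NA_real_, sem = NA_real_)
  for (i in seq_along(m_range)) {
    r <- reduced_rank_fit(X, Y, m_range[i], lambda, folds)
    curve$performance[i] <- r$performance
    curve$sem[i] <- r$sem
  }
  list(curve = curve, full = c(performance = full_perf, sem = full_sem),
       lambda = lambda,
       m_star = subspace_dimension(curve, full_perf, full_sem))
}

#' Number of predictive dimensions
#'
#' The smallest rank whose mean cross-validated performance is within one
#' cross-validation SEM of the full-model performance.
#'
#' @param curve Data frame with `m`, `performance`, `sem`.
#' @param full_performance Full ridge model CV performance.
#' @param full_sem Its CV SEM (used when a rank's own SEM is zero).
#' @return Integer rank `m_star` (NA when no rank qualifies).
#' @export
subspace_dimension <- function(curve, full_performance, full_sem = 0) {
  tol <- pmax(curve$sem, full_sem)
  ok <- curve$performance >= full_performance - tol
  if (!any(ok)) return(NA_integer_)
  as.integer(curve$m[which(ok)[1]])
}
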