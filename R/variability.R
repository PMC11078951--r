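#' Coefficient of variation of inter-spike intervals
#'
#' @param raster A `spike_raster`.
#' @param neurons Global neuron ids to include (default: all excitatory).
#' @param min_spikes Neurons with fewer spikes are excluded (reported).
#' @return List: per-neuron `cv`, the population `mean`, and the number of
#'   excluded neurons.
#' @export
cv_isi <- function(raster, neurons = NULL, min_spikes = 3) {
  if (is.null(neurons))
    neurons <- which(raster$labels$type == "e")
  tl <- split(raster$t, factor(raster$id, levels = neurons))
  cv <- vapply(tl, function(ts) {
    if (length(ts) < min_spikes) return(NA_real_)
    isi <- diff(ts)
    stats::sd(isi) / mean(isi)
  }, numeric(1))
  list(cv = cv, mean = mean(cv, na.rm = TRUE),
       n_excluded = sum(is.na(cv)))
}

#' Fano factor of spike counts in non-overlapping windows
#'
#' Variance over mean of per-window spike counts (window length 50 ms by
#' default), per neuron, averaged over neurons. Neurons with zero mean
#' count are excluded and reported.
#'
#' @param raster A `spike_raster`.
#' @param neurons Global neuron ids (default: all excitatory).
#' @param window Counting window, ms.
#' @param span Optional `c(t0, t1)` restriction, ms.
#' @return List: per-neuron `fano`, population `mean`, `n_excluded`.
#' @export
fano <- function(raster, neurons = NULL, window = 50, span = NULL) {
  if (is.null(neurons))
    neurons <- which(raster$labels$type == "e")
  if (is.null(span)) span <- raster$span
  n_win <- floor((span[2] - span[1]) / window)
  if (n_win < 20)
    warning("fewer than 20 counting windows: Fano estimate is noisy")
  M <- sua_matrix(raster, neurons, bin = window, span = span)
  mu <- colMeans(M)
  v <- apply(M, 2, stats::var)
  f <- ifelse(mu > 0, v / mu, NA_real_)
  list(fano = f, mean = mean(f, na.rm = TRUE), n_excluded = sum(mu == 0))
}

# per-trial, per-neuron spike-count tensor: trials x neurons x time points,
# counts in `window` ms windows whose left edges step by `step` ms
trial_counts <- function(trials, neurons, window = 50, step = 10) {
  n_tp <- floor((diff(trials[[1]]$span) - window) / step) + 1
  arr <- array(0L, c(length(trials), length(neurons), n_tp))
  for (tr in seq_along(trials)) {
    r <- trials[[tr]]
    keep <- r$id %in% neurons
    ts <- r$t[keep] - r$span[1]
    id <- match(r$id[keep], neurons)
    for (tp in seq_len(n_tp)) {
      lo <- (tp - 1) * step
      sel <- ts >= lo & ts < lo + window
      if (any(sel))
        arr[tr, , tp] <- arr[tr, , tp] +
          tabulate(id[sel], nbins = length(neurons))
    }
  }
  arr
}

#' Mean-matched time-resolved Fano factor
#'
#' Across-trial spike-count mean and variance per neuron and time point for
#' each condition; a common ("greatest common") distribution of mean counts
#' is formed as the bin-wise minimum of the mean-count histograms across all
#' (time point, condition) cells, and at each time point neurons are
#' randomly subsampled to match it. The Fano factor is the least-squares
#' slope of variance against mean over the matched subset, averaged over
#' `resamples` subsamples. Matching removes the trivial effect of firing-
#' rate differences between conditions on the Fano factor.
#'
#' @param trials_by_cond Named list of conditions (e.g. `uncued`, `cued`),
#'   each a list of `spike_raster` trials aligned to stimulus onset.
#' @param neurons Global neuron ids of the site group.
#' @param window Counting window, ms.
#' @param step Time-point step, ms.
#' @param resamples Number of matched subsamples per time point.
#' @param n_bins Histogram bins for the mean-count matching.
#' @param seed Seed for the subsampling.
#' @return List per condition: vector of mean-matched Fano factors per time
#'   point; plus `time` (window left edges, ms).
#' @export
mean_matched_fano <- function(trials_by_cond, neurons, window = 50,
                              step = 10, resamples = 100, n_bins = 20,
                              seed = 1) {
  counts <- lapply(trials_by_cond, trial_counts, neurons = neurons,
                   window = window, step = step)
  n_tp <- dim(counts[[1]])[3]
  mus <- lapply(counts, function(a) apply(a, c(2, 3), mean))
  vars <- lapply(counts, function(a) apply(a, c(2, 3), stats::var))
  rng <- range(unlist(mus))
  if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1e-9
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  binof <- function(m) pmin(pmax(findInterval(m, brk,
                                              rightmost.closed = TRUE), 1L),
                            n_bins)
  # greatest common mean-count histogram across (time, condition)
  hists <- array(0L, c(n_bins, n_tp, length(counts)))
  for (ci in seq_along(counts)) {
    for (tp in seq_len(n_tp)) {
      hists[, tp, ci] <- tabulate(binof(mus[[ci]][, tp]), nbins = n_bins)
    }
  }
  common <- apply(hists, 1, min)
  if (sum(common) < 2)
    stop("mean-matched histogram is empty: conditions do not overlap")

  out <- lapply(seq_along(counts), function(ci) {
    f_tp <- numeric(n_tp)
    for (tp in seq_len(n_tp)) {
      m <- mus[[ci]][, tp]
      v <- vars[[ci]][, tp]
      b <- binof(m)
      f_rs <- with_seed(seed + 1000L * ci + tp, {
        vapply(seq_len(resamples), function(r) {
          pick <- unlist(lapply(which(common > 0), function(bb) {
            cand <- which(b == bb)
            if (length(cand) <= common[bb]) cand
            else sample(cand, common[bb])
          }))
          mm <- m[pick]
          vv <- v[pick]
          # least-squares slope through the origin of variance vs mean
          sum(mm * vv) / sum(mm * mm)
        }, numeric(1))
      })
      f_tp[tp] <- mean(f_rs)
    }
    f_tp
  })
  names(out) <- names(trials_by_cond)
  out$time <- seq(0, by = step, length.out = n_tp)
  out
}

#' Time-resolved noise correlation across trials
#'
#' Pearson correlation of across-trial spike counts for every neuron pair
#' of the site group, per time point, averaged over pairs. Pairs with zero
#' variance at a time point are skipped.
#'
#' @inheritParams mean_matched_fano
#' @param trials List of `spike_raster` trials (one condition).
#' @return List: `r` (mean pairwise correlation per time point), `time`.
#' @export
noise_correlation <- function(trials, neurons, window = 50, step = 10) {
  if (length(trials) < 20)
    warning("fewer than 20 trials: noise-correlation estimates are noisy")
  a <- trial_counts(trials, neurons, window, step)
  n_tp <- dim(a)[3]
  r <- numeric(n_tp)
  for (tp in seq_len(n_tp)) {
    M <- a[, , tp]
    keep <- apply(M, 2, stats::sd) > 0
    if (sum(keep) < 2) {
      r[tp] <- NA_real_
      next
    }
    C <- stats::cor(M[, keep, drop = FALSE])
    r[tp] <- mean(C[upper.tri(C)])
  }
  list(r = r, time = seq(0, by = step, length.out = n_tp))
}
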