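#' Shuffle-corrected phase-amplitude coupling (modulation index)
#'
#' Band-passes the signal at a phase band and an amplitude band, extracts
#' Hilbert phase and amplitude, bins the phase into `n_bins` intervals, and
#' measures how far the phase-conditioned mean amplitude distribution
#' deviates from uniform: `MI = 1 - H(p) / log(N)` where `H` is the Shannon
#' entropy of the normalized amplitude-per-phase-bin distribution. Chance
#' coupling is removed by subtracting the mean MI over `n_shuffles` random
#' permutations of the amplitude series (the corrected MI can therefore be
#' slightly negative).
#'
#' @param signal A [continuous_signal()] (50 s recommended) or numeric.
#' @param phase_band,amp_band Band edges, Hz.
#' @param n_bins Number of phase bins.
#' @param n_shuffles Number of amplitude shuffles.
#' @param seed Seed for the shuffles.
#' @param fs Sampling rate for bare vectors.
#' @return List: `mi` (corrected), `mi_raw`, `mi_shuffle` (vector), and the
#'   phase-bin amplitude profile.
#' @export
pac_mi <- function(signal, phase_band, amp_band, n_bins = 20,
                   n_shuffles = 200, seed = 1, fs = 1000) {
  ph <- narrowband_phase(signal, phase_band, fs)$phase
  am <- narrowband_phase(signal, amp_band, fs)$amplitude
  bin <- findInterval(ph, seq(-pi, pi, length.out = n_bins + 1),
                      rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), n_bins)
  mi_of <- function(a) {
    A <- tapply(a, factor(bin, levels = seq_len(n_bins)), mean)
    if (anyNA(A)) {
      # empty phase bin: merge with a neighbour by carrying its mean
      warning("empty phase bin merged with neighbour")
      A <- stats::approx(which(!is.na(A)), A[!is.na(A)],
                         xout = seq_len(n_bins), rule = 2)$y
    }
    p <- A / sum(A)
    1 - (-sum(p * log(p))) / log(n_bins)
  }
  mi_raw <- mi_of(am)
  mi_sh <- with_seed(seed, vapply(seq_len(n_shuffles), function(i)
    mi_of(sample(am)), numeric(1)))
  list(mi = mi_raw - mean(mi_sh), mi_raw = mi_raw, mi_shuffle = mi_sh)
}

#' Comodulogram over a grid of phase and amplitude frequencies
#'
#' @inheritParams pac_mi
#' @param phase_freqs,amp_freqs Band centers, Hz.
#' @param phase_bw,amp_bw Band half-widths, Hz.
#' @return Matrix of corrected MI values (phase frequency x amplitude
#'   frequency).
#' @export
comodulogram <- function(signal, phase_freqs = seq(2, 10, 1),
                         amp_freqs = seq(30, 100, 10), phase_bw = 1,
                         amp_bw = 10, n_bins = 20, n_shuffles = 200,
                         seed = 1, fs = 1000) {
  out <- matrix(NA_real_, length(phase_freqs), length(amp_freqs),
                dimnames = list(phase_freqs, amp_freqs))
  for (i in seq_along(phase_freqs)) {
    for (j in seq_along(amp_freqs)) {
      out[i, j] <- pac_mi(signal,
                          phase_freqs[i] + c(-phase_bw, phase_bw),
                          amp_freqs[j] + c(-amp_bw, amp_bw),
                          n_bins, n_shuffles, seed + 1000L * i + j, fs)$mi
    }
  }
  out
}

#' State-conditioned phase-locking value between two MUA signals
#'
#' Filters both signals into `[f_c - 5, f_c + 5]` Hz, extracts Hilbert
#' phases, and computes the mean resultant length of the phase difference
#' over the samples selected by `mask` (e.g. S-On or S-Off epochs). Spurious
#' locking induced by the band-pass filter is removed by subtracting the
#' mean PLV of `n_shuffles` surrogate pairs in which each signal is
#' permuted across time (turning it into white noise) before filtering.
#'
#' @param sig1,sig2 MUA [continuous_signal()]s (1 ms bins) or numerics.
#' @param f_c Center frequency, Hz.
#' @param mask Logical vector selecting samples; `NULL` means all.
#' @param n_shuffles Surrogate count.
#' @param seed Seed for the surrogates.
#' @param fs Sampling rate for bare vectors.
#' @return List: `plv` (corrected), `plv_raw`, `plv_shuffle_mean`.
#' @export
plv <- function(sig1, sig2, f_c, mask = NULL, n_shuffles = 200, seed = 1,
                fs = 1000) {
  x1 <- sig_values(sig1)
  x2 <- sig_values(sig2)
  stopifnot(length(x1) == length(x2))
  if (is.null(mask)) mask <- rep(TRUE, length(x1))
  if (sum(mask) < 500)
    warning("fewer than 500 samples selected: PLV estimate is unstable")
  band <- c(f_c - 5, f_c + 5)
  plv_of <- function(a, b) {
    p1 <- narrowband_phase(a, band, fs)$phase
    p2 <- narrowband_phase(b, band, fs)$phase
    Mod(mean(exp(1i * (p1[mask] - p2[mask]))))
  }
  raw <- plv_of(x1, x2)
  sh <- with_seed(seed, vapply(seq_len(n_shuffles), function(i)
    plv_of(sample(x1), sample(x2)), numeric(1)))
  list(plv = raw - mean(sh), plv_raw = raw, plv_shuffle_mean = mean(sh))
}

#' PLV curve over gamma-band center frequencies and joint states
#'
#' @inheritParams plv
#' @param joint Factor from [joint_states()].
#' @param f_centers Center frequencies, Hz.
#' @param states Which joint states to evaluate.
#' @return Data frame with columns `f_c`, `state`, `plv`, `plv_raw`.
#' @export
plv_curve <- function(sig1, sig2, joint, f_centers = seq(30, 120, 10),
                      states = c("S-On", "S-Off"), n_shuffles = 200,
                      seed = 1) {
  out <- expand.grid(f_c = f_centers, state = states,
                     stringsAsFactors = FALSE)
  out$plv <- out$plv_raw <- NA_real_
  for (i in seq_len(nrow(out))) {
    m <- joint == out$state[i]
    r <- plv(sig1, sig2, out$f_c[i], m, n_shuffles, seed + i)
    out$plv[i] <- r$plv
    out$plv_raw[i] <- r$plv_raw
  }
  out
}

# embedding rows of (target future, source past, target past) that lie
# entirely inside one masked epoch
te_embeddings <- function(source, target, u, k, l, mask) {
  n <- length(target)
  t_idx <- seq_len(n - 1)                     # t, predicting t+1
  lo <- pmin(t_idx - k + 1, t_idx + 1 - u - l + 1)
  valid <- lo >= 1
  # every sample in [lo, t+1] must be masked (embeddings do not straddle
  # epoch boundaries)
  cs <- c(0, cumsum(mask))
  span_ok <- rep(FALSE, length(t_idx))
  span_ok[valid] <- (cs[t_idx[valid] + 2] - cs[lo[valid]]) ==
    (t_idx[valid] + 2 - lo[valid])
  t_use <- t_idx[span_ok]
  if (!length(t_use)) return(NULL)
  X <- matrix(target[t_use + 1], ncol = 1)
  Z <- matrix(sapply(seq_len(k), function(j) target[t_use - k + j]), ncol = k)
  Y <- matrix(sapply(seq_len(l), function(j) source[t_use + 1 - u - l + j]),
              ncol = l)
  list(X = X, Y = Y, Z = Z)
}

#' Transfer entropy between MUA signals (Kraskov estimator)
#'
#' Estimates `TE = H(T_{t+1} | T_t^k) - H(T_{t+1} | T_t^k, S_{t+1-u}^l)` --
#' the reduction in uncertainty about the target's next sample from the
#' source's past at delay `u` -- as a conditional mutual information with
#' the Kraskov-Stoegbauer-Grassberger nearest-neighbour estimator
#' (Frenzel-Pompe conditioning, max-norm, `k_nn` neighbours). Embedding
#' vectors are built only from samples whose whole history window lies
#' inside a single masked epoch. A tiny seeded jitter (1e-8 of the signal
#' SD) breaks the ties that discrete-valued MUA would otherwise produce.
#'
#' @param source,target MUA [continuous_signal()]s at 1 kHz or numerics.
#' @param u Source-target delay, ms (samples).
#' @param mask Logical epoch mask; `NULL` means the whole recording.
#' @param k,l Target / source history lengths (1-8).
#' @param k_nn Number of nearest neighbours.
#' @param seed Seed for the tie-breaking jitter.
#' @return TE in nats (estimator noise can make it slightly negative).
#' @export
transfer_entropy <- function(source, target, u = 10, mask = NULL, k = 1,
                             l = 1, k_nn = 4, seed = 1) {
  s <- sig_values(source)
  tg <- sig_values(target)
  stopifnot(length(s) == length(tg), u >= 1, k >= 1, l >= 1)
  if (is.null(mask)) mask <- rep(TRUE, length(s))
  emb <- te_embeddings(s, tg, u, k, l, mask)
  if (is.null(emb) || nrow(emb$X) < 1000)
    stop("fewer than 1000 valid embedding vectors")
  jit <- function(M, scale, offset) {
    M + matrix(with_seed(seed + offset, stats::runif(length(M), 0, scale)),
               nrow(M))
  }
  sc <- 1e-8 * max(stats::sd(tg), stats::sd(s), 1e-12)
  .ksg_cmi(jit(emb$X, sc, 1L), jit(emb$Y, sc, 2L), jit(emb$Z, sc, 3L),
           as.integer(k_nn))
}

#' TE as a function of delay
#'
#' @inheritParams transfer_entropy
#' @param delays Delays to evaluate, ms.
#' @return Data frame `u`, `te`.
#' @export
te_curve <- function(source, target, delays = 1:20, mask = NULL, k = 1,
                     l = 1, k_nn = 4, seed = 1) {
  te <- vapply(delays, function(u)
    transfer_entropy(source, target, u, mask, k, l, k_nn, seed),
    numeric(1))
  data.frame(u = delays, te = te)
}

#' Ragwitz-style history selection
#'
#' Exhaustive search over `(k, l)` in `[1, kl_max]^2` minimizing the
#' one-step locally-constant (nearest-neighbour) prediction error of the
#' target from the joint embedding; ties break toward smaller `(k, l)`.
#'
#' @inheritParams transfer_entropy
#' @param kl_max Largest history length scanned.
#' @param n_eval Evaluation subsample size for the predictor error.
#' @return List `k`, `l`, and the error matrix.
#' @export
select_history <- function(source, target, u = 10, mask = NULL, kl_max = 8,
                           k_nn = 4, n_eval = 2000, seed = 1) {
  s <- sig_values(source)
  tg <- sig_values(target)
  if (is.null(mask)) mask <- rep(TRUE, length(s))
  err <- matrix(Inf, kl_max, kl_max)
  for (k in seq_len(kl_max)) {
    for (l in seq_len(kl_max)) {
      emb <- te_embeddings(s, tg, u, k, l, mask)
      if (is.null(emb) || nrow(emb$X) < 1000) next
      E <- cbind(emb$Z, emb$Y)
      err[k, l] <- .local_predictor_mse(E, as.numeric(emb$X),
                                        as.integer(k_nn),
                                        as.integer(n_eval),
                                        as.integer(seed))
    }
  }
  best <- which(err == min(err), arr.ind = TRUE)
  best <- best[order(best[, 1] + best[, 2], best[, 1]), , drop = FALSE][1, ]
  list(k = unname(best[1]), l = unname(best[2]), error = err)
}
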