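#' Parameters of the Levy-walker reduced model
#'
#' A random walker with momentum models the wave packet's center: position
#' follows `dx = gamma b(x) dt + beta v dt + gamma^{1/alpha} dL^alpha`,
#' momentum follows `dv = beta b(x) dt`, where `L^alpha` is symmetric
#' alpha-stable Levy motion whose increments over `dt` have scale
#' `dt^{1/alpha}`. Time is measured in seconds (dt = 1 ms = 0.001).
#'
#' @param alpha Tail index of the stable law (1 < alpha <= 2).
#' @param gamma Noise/drift strength.
#' @param beta Damping (momentum) coefficient; responsible for the theta-
#'   band oscillation of the trajectory.
#' @param dt Integration step, seconds.
#' @param half_width Half-width of the periodic plane, grid units.
#' @param trial_duration Trial length, seconds.
#' @param trials Number of trials.
#' @return A `walker_params` list.
#' @export
walker_params <- function(alpha = 1.2, gamma = 100, beta = 1, dt = 0.001,
                          half_width = 32, trial_duration = 200,
                          trials = 20) {
  stopifnot(alpha > 1, alpha <= 2, gamma > 0, beta > 0, dt > 0)
  p <- as.list(environment())
  class(p) <- "walker_params"
  p
}

#' Potential-well landscape
#'
#' Quadratic wells truncated at radius `sigma_p`:
#' `rho_i(x) = (D_s + D_a) (||x - x_p||^2 / sigma_p^2 - 1)` inside the
#' well, 0 outside, so `rho <= 0` everywhere and continuous at the rim.
#' The standard two-well configuration mirrors the two-input circuit
#' geometry: one well at the center (the cued stimulus) and one at the
#' corner. Attention deepens the center well via `D_a1`.
#'
#' @param D_s Stimulus depth of each well.
#' @param D_a1 Attention depth added to the first (center) well, 0-50.
#' @param sigma_p Well radius, grid units.
#' @param centers List of well centers.
#' @param alpha Tail index (enters the drift prefactor
#'   `Gamma(alpha - 1) / Gamma(alpha / 2)^2`).
#' @return A `potential_landscape`.
#' @export
potential_landscape <- function(D_s = 50, D_a1 = 0, sigma_p = 15,
                                centers = list(c(0, 0), c(-32, -32)),
                                alpha = 1.2) {
  depth <- c(D_s + D_a1, rep(D_s, length(centers) - 1))
  wells <- cbind(do.call(rbind, centers), depth)
  colnames(wells) <- c("x", "y", "depth")
  l <- list(wells = wells, sigma_p = sigma_p, D_a1 = D_a1,
            prefactor = gamma(alpha - 1) / gamma(alpha / 2)^2)
  class(l) <- "potential_landscape"
  l
}

#' Potential value at positions
#' @param x Two-column matrix (or length-2 vector) of positions.
#' @param landscape A [potential_landscape()].
#' @param L Domain period.
#' @return Numeric potential values (<= 0).
#' @export
potential_at <- function(x, landscape, L = 64) {
  x <- matrix(x, ncol = 2)
  rho <- numeric(nrow(x))
  sp2 <- landscape$sigma_p^2
  for (w in seq_len(nrow(landscape$wells))) {
    d2 <- torus_distance(x, matrix(landscape$wells[w, 1:2], nrow(x), 2,
                                   byrow = TRUE), L)^2
    inside <- d2 < sp2
    rho[inside] <- rho[inside] +
      landscape$wells[w, 3] * (d2[inside] / sp2 - 1)
  }
  rho
}

#' Drift field of the walker
#'
#' `b(x) = -grad(rho(x)) * Gamma(alpha-1) / Gamma(alpha/2)^2`: inside a
#' well the gradient is `2 depth (x - x_p) / sigma_p^2` (periodic
#' displacement), outside all wells the drift vanishes.
#'
#' @inheritParams potential_at
#' @return Two-column matrix of drift vectors.
#' @export
drift <- function(x, landscape, L = 64) {
  x <- matrix(x, ncol = 2)
  b <- matrix(0, nrow(x), 2)
  sp2 <- landscape$sigma_p^2
  for (w in seq_len(nrow(landscape$wells))) {
    ctr <- matrix(landscape$wells[w, 1:2], nrow(x), 2, byrow = TRUE)
    dxy <- torus_delta(ctr, x, L)
    d2 <- rowSums(dxy^2)
    inside <- d2 < sp2
    g <- -2 * landscape$wells[w, 3] / sp2 * landscape$prefactor
    b[inside, ] <- b[inside, ] + g * dxy[inside, , drop = FALSE]
  }
  b
}

#' Symmetric alpha-stable increments
#'
#' Chambers-Mallows-Stuck draws from `SaS(alpha, scale)`; at `alpha = 2`
#' the law reduces to a Gaussian with standard deviation
#' `scale * sqrt(2)`.
#'
#' @param n Number of draws.
#' @param alpha Tail index (1, 2].
#' @param scale Scale parameter (e.g. `dt^{1/alpha}` for an increment over
#'   `dt`).
#' @param seed Integer seed.
#' @return Numeric vector of draws.
#' @export
sample_sas_step <- function(n, alpha, scale = 1, seed = 1) {
  if (alpha <= 1 || alpha > 2) stop("tail index must lie in (1, 2]")
  .rsas(as.integer(n), alpha, scale, as.integer(seed))
}

#' Integrate the Levy walker
#'
#' Euler-Maruyama at `dt`; positions wrap periodically (the wells mirror
#' the two-input circuit geometry, which lives on a torus). Momentum is
#' integrated exactly as written (no decay).
#'
#' @param params A [walker_params()].
#' @param landscape A [potential_landscape()].
#' @param seed Integer seed.
#' @param x0 Initial position; `NULL` draws it uniformly on the plane.
#' @return A `walker_trajectory`: data frame `t` (s), `x`, `y` sampled
#'   every step.
#' @export
integrate_walker <- function(params, landscape, seed = 1, x0 = NULL) {
  L <- 2 * params$half_width
  if (is.null(x0))
    x0 <- with_seed(seed * 19L + 5L, stats::runif(2, -params$half_width,
                                                  params$half_width))
  n_steps <- round(params$trial_duration / params$dt)
  res <- .levy_kernel(as.integer(n_steps), params$dt, params$alpha,
                      params$gamma, params$beta, landscape$wells,
                      landscape$sigma_p, landscape$prefactor,
                      numeric(0), numeric(0), 0, 1, 0, landscape$D_a1, L,
                      0L, x0[1], x0[2], 1L, as.integer(seed))
  structure(data.frame(t = seq(0, by = params$dt, length.out = n_steps),
                       x = res$traj[, 1], y = res$traj[, 2]),
            params = params, class = c("walker_trajectory", "data.frame"))
}

#' Firing-rate field around the walker
#'
#' `r(x) = A_r exp(-||x - x_t||^2 / (2 sigma_r^2)) + A_0(x)`: a Gaussian
#' bump riding on the walker plus a baseline that increases with the
#' attention depth inside the center well,
#' `A_0 = A_b - 0.2 D_a1 (||x - x_p1||^2 / sigma_p^2 - 1)` there and `A_b`
#' elsewhere.
#'
#' @param walker_pos Length-2 walker position.
#' @param positions Two-column matrix of neuron positions.
#' @param landscape A [potential_landscape()].
#' @param A_r Bump amplitude, Hz.
#' @param sigma_r Bump width, grid units.
#' @param A_b Baseline rate, Hz.
#' @param L Domain period.
#' @return Rates in Hz.
#' @export
rate_field_at <- function(walker_pos, positions, landscape, A_r = 20,
                          sigma_r = 12, A_b = 3, L = 64) {
  positions <- matrix(positions, ncol = 2)
  d2 <- torus_distance(positions, matrix(walker_pos, nrow(positions), 2,
                                         byrow = TRUE), L)^2
  A0 <- rep(A_b, nrow(positions))
  if (landscape$D_a1 > 0) {
    d21 <- torus_distance(positions,
                          matrix(landscape$wells[1, 1:2], nrow(positions), 2,
                                 byrow = TRUE), L)^2
    sp2 <- landscape$sigma_p^2
    inside <- d21 < sp2
    A0[inside] <- A_b - 0.2 * landscape$D_a1 * (d21[inside] / sp2 - 1)
  }
  A_r * exp(-d2 / (2 * sigma_r^2)) + A0
}

#' Inhomogeneous Poisson spikes from per-neuron rate series
#'
#' Bernoulli thinning per time step (one draw per neuron and step,
#' probability `rate * dt`), which approximates a Poisson process when
#' `rate * dt` is small; larger values trigger a warning.
#'
#' @param rates Matrix of rates, time steps x neurons, Hz.
#' @param dt Step, seconds.
#' @param seed Integer seed.
#' @return List: `id`, `t` (seconds) of the generated spikes.
#' @export
generate_spikes <- function(rates, dt = 0.001, seed = 1) {
  stopifnot(all(rates >= 0))
  if (any(rates * dt > 1))
    warning("rate * dt exceeds 1: multi-spike bins are truncated")
  hit <- with_seed(seed, matrix(stats::runif(length(rates)),
                                nrow(rates)) < rates * dt)
  idx <- which(hit, arr.ind = TRUE)
  list(id = idx[, 2], t = (idx[, 1] - 0.5) * dt)
}

# neuron lattice of the reduced model: full 64 x 64 grid
walker_lattice <- function(half_width = 32) {
  s <- seq(-half_width + 0.5, half_width - 0.5, by = 1)
  as.matrix(expand.grid(x = s, y = s))
}

#' Variability and correlation of the walker model's spiking
#'
#' Runs `trials` independent walker trials per attention depth, generates
#' Poisson spikes for the 80 lattice neurons within 5 grid points of the
#' center, counts them in non-overlapping 55 ms windows, and reports the
#' per-neuron Fano factor (variance/mean over windows, averaged over
#' neurons then trials) and the mean pairwise Pearson correlation of the
#' window counts.
#'
#' @param params A [walker_params()].
#' @param depths Attention-depth ladder `D_a1` (added to the 50-deep
#'   center well).
#' @param window Counting window, ms.
#' @param radius Neuron-selection radius around the center, grid points.
#' @param seed Integer seed (each trial uses an offset sub-seed).
#' @param keep_on_durations Also return center-well dwell (On) durations,
#'   defined as episodes with the walker within 10 grid points of the
#'   center.
#' @return Data frame per depth: `D_a1`, `fano`, `fano_se`, `noise_cor`,
#'   `noise_cor_se`, and optionally `mean_on_ms`.
#' @export
walker_variability <- function(params = walker_params(), depths = 0,
                               window = 55, radius = 5, seed = 1,
                               keep_on_durations = FALSE) {
  L <- 2 * params$half_width
  lat <- walker_lattice(params$half_width)
  d_ctr <- torus_distance(lat, matrix(0, nrow(lat), 2), L)
  sel <- lat[d_ctr < radius, , drop = FALSE]
  n_steps <- round(params$trial_duration / params$dt)
  win_steps <- round(window / (params$dt * 1000))

  rows <- lapply(depths, function(Da) {
    land <- potential_landscape(D_a1 = Da, alpha = params$alpha)
    f_tr <- numeric(params$trials)
    r_tr <- numeric(params$trials)
    on_tr <- numeric(params$trials)
    for (tr in seq_len(params$trials)) {
      sub_seed <- (seed * 1009L + round(Da) * 97L + tr) %% 2147483647L
      x0 <- with_seed(sub_seed, stats::runif(2, -params$half_width,
                                             params$half_width))
      res <- .levy_kernel(as.integer(n_steps), params$dt, params$alpha,
                          params$gamma, params$beta, land$wells,
                          land$sigma_p, land$prefactor, sel[, 1], sel[, 2],
                          20, 12, 3, Da, L, as.integer(win_steps),
                          x0[1], x0[2],
                          if (keep_on_durations) 1L else 0L,
                          as.integer(sub_seed))
      cnt <- res$counts
      mu <- colMeans(cnt)
      v <- apply(cnt, 2, stats::var)
      f_tr[tr] <- mean(ifelse(mu > 0, v / mu, NA), na.rm = TRUE)
      C <- suppressWarnings(stats::cor(cnt))
      r_tr[tr] <- mean(C[upper.tri(C)], na.rm = TRUE)
      if (keep_on_durations) {
        d <- torus_distance(cbind(res$traj[, 1], res$traj[, 2]),
                            matrix(0, nrow(res$traj), 2), L)
        runs <- rle(d < 10)
        on_tr[tr] <- if (any(runs$values))
          mean(runs$lengths[runs$values]) * params$dt * 1000 else 0
      }
    }
    out <- data.frame(D_a1 = Da, fano = mean(f_tr),
                      fano_se = stats::sd(f_tr) / sqrt(params$trials),
                      noise_cor = mean(r_tr),
                      noise_cor_se = stats::sd(r_tr) / sqrt(params$trials))
    if (keep_on_durations) out$mean_on_ms <- mean(on_tr)
    out
  })
  do.call(rbind, rows)
}
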