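#' Simulate the two-area spiking network
#'
#' Forward-Euler integration (default dt = 0.1 ms) of the conductance-based
#' LIF network with spike-frequency adaptation, double-exponential synapses,
#' delayed recurrent/inter-areal transmission, and independent external
#' Poisson drive. Initial membrane potentials are uniform in [-85, -50] mV.
#'
#' The local field potential proxy is recorded online at 1 kHz for each
#' requested site as the Gaussian-distance-weighted sum, over excitatory
#' neurons of the site's area, of the absolute intra-areal excitatory,
#' inter-areal excitatory, and intra-areal inhibitory synaptic currents.
#' Per-neuron current decompositions (needed to form the LFP proxy off-line
#' with [lfp_proxy()]) can be recorded for a subset of neurons at 1 kHz.
#'
#' @param geometry A [network_geometry()].
#' @param synapses A `synapse_table` from [sample_connectivity()].
#' @param params A [neuron_params()].
#' @param stimulus A [stimulus_field()].
#' @param cue A [cue_modulation()]; when enabled it reshapes the adaptation
#'   increments of area-2 excitatory neurons.
#' @param duration Simulated time, ms.
#' @param dt Integration step, ms. Synaptic delays are rounded to the
#'   nearest step (never below one step).
#' @param seed Integer seed for initial conditions and Poisson drive
#'   (independent sub-streams; connectivity has its own seed).
#' @param lfp_sites List of site centers at which to record the LFP proxy;
#'   each entry `list(center = c(x, y), area = 1)`.
#' @param sigma_lfp Spatial scale of the LFP weighting, grid units.
#' @param record_neurons Global neuron ids whose current decomposition and
#'   adaptation conductance are kept at 1 kHz (memory scales with
#'   `length(record_neurons) * duration`).
#' @return A `circuit_sim` object: `$raster` (a [spike_raster()]),
#'   `$lfp` (list of [continuous_signal()]s), `$currents` (matrices
#'   `I_e_intra`, `I_e_inter`, `I_i_intra`, `g_k` of size ms x recorded),
#'   and the echoed configuration.
#' @export
simulate_network <- function(geometry, synapses, params = neuron_params(),
                             stimulus = stimulus_field(),
                             cue = cue_modulation(enabled = FALSE),
                             duration = 1000, dt = 0.1, seed = 1,
                             lfp_sites = list(), sigma_lfp = 7,
                             record_neurons = integer(0)) {
  stopifnot(duration > 0, dt > 0)
  lab <- geometry_labels(geometry)
  xy <- as.matrix(geometry_coords(geometry))
  N <- geometry$N

  gL <- ifelse(lab$type == "e", params$g_L_e, params$g_L_i)
  dgk <- numeric(N)
  dgk[lab$type == "e" & lab$area == 1] <- params$dgk_e1
  e2 <- which(lab$type == "e" & lab$area == 2)
  cue2 <- cue
  cue2$dgk_base <- params$dgk_e2
  dgk[e2] <- cue_adaptation_profile(xy[e2, , drop = FALSE], cue2, geometry$L)

  lam_bg <- rep(stimulus$lambda_bg, N)
  lam_sti <- numeric(N)
  e1 <- which(lab$type == "e" & lab$area == 1)
  lam_sti[e1] <- stimulus_rate(xy[e1, , drop = FALSE], stimulus,
                               geometry$L) - stimulus$lambda_bg
  epochs <- stimulus$epochs
  if (is.null(epochs)) epochs <- matrix(c(0, duration), 1, 2)

  # delays rounded to the integration step grid (documented behaviour);
  # warn only when a delay collapses below a single step
  dsteps <- pmax(1L, as.integer(round(synapses$delay / dt)))
  if (length(dsteps) && any(synapses$delay < dt / 2))
    warning("delays shorter than half a step were rounded up to one step")

  # channel: 0 exc intra, 1 exc inter, 2 inh intra
  pre_type <- lab$type[synapses$pre]
  intra <- lab$area[synapses$pre] == lab$area[synapses$post]
  chan <- ifelse(pre_type == "e", ifelse(intra, 0L, 1L), 2L)

  # CSR by presynaptic neuron
  ord <- order(synapses$pre)
  ptr <- c(0L, cumsum(tabulate(synapses$pre, nbins = N)))

  v0 <- with_seed(seed * 101L + 3L, runif(N, -85, -50))

  lfp_w <- matrix(0, N, max(length(lfp_sites), 0))
  for (s in seq_along(lfp_sites)) {
    site <- lfp_sites[[s]]
    a <- if (is.null(site$area)) 1L else site$area
    es <- which(lab$type == "e" & lab$area == a)
    d <- torus_distance(xy[es, , drop = FALSE],
                        matrix(site$center, length(es), 2, byrow = TRUE),
                        geometry$L)
    lfp_w[es, s] <- exp(-d^2 / (2 * sigma_lfp^2))
  }

  res <- .sim_kernel(ptr, synapses$post[ord] - 1L, synapses$weight[ord],
                     dsteps[ord], chan[ord], lam_bg, lam_sti, epochs, dgk, gL,
                     lab$type == "e", v0, duration, dt,
                     params[c("C", "V_L", "v_T", "v_r", "V_k", "V_rev_i",
                              "tau_k", "tau_r", "tau_d_e", "tau_d_i",
                              "tau_ref", "ext_w")],
                     lfp_w, as.integer(record_neurons) - 1L,
                     as.integer(seed %% .Machine$integer.max))

  raster <- spike_raster(id = res$spike_id + 1L, t = res$spike_t,
                         geometry = geometry, span = c(0, duration))
  lfp <- lapply(seq_along(lfp_sites), function(s)
    continuous_signal(res$lfp[, s], fs = 1000, kind = "LFP",
                      site = lfp_sites[[s]]))
  currents <- NULL
  if (length(record_neurons)) {
    currents <- list(I_e_intra = res$I_e_intra, I_e_inter = res$I_e_inter,
                     I_i_intra = res$I_i_intra, g_k = res$g_k, V = res$V,
                     neurons = as.integer(record_neurons))
  }
  structure(list(raster = raster, lfp = lfp, currents = currents,
                 geometry = geometry, seed = seed, dt = dt,
                 duration = duration, stimulus = stimulus, cue = cue),
            class = "circuit_sim")
}

#' @export
print.circuit_sim <- function(x, ...) {
  cat(sprintf("circuit_sim: %.1f s, %d spikes from %d neurons (seed %d)\n",
              x$duration / 1000, length(x$raster$t), x$geometry$N, x$seed))
  invisible(x)
}

#' Spike raster container
#'
#' Per-neuron spike times with area/type labels and lattice coordinates.
#'
#' @param id Integer vector of global neuron ids, one entry per spike.
#' @param t Spike times in ms (same length as `id`).
#' @param geometry The [network_geometry()] the ids refer to.
#' @param span Recording span `c(t0, t1)` in ms.
#' @return A `spike_raster`.
#' @export
spike_raster <- function(id, t, geometry, span) {
  ord <- order(t)
  r <- list(id = as.integer(id[ord]), t = as.numeric(t[ord]),
            geometry = geometry, span = as.numeric(span),
            labels = geometry_labels(geometry),
            coords = as.matrix(geometry_coords(geometry)))
  class(r) <- "spike_raster"
  r
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike_raster: %d spikes over [%.0f, %.0f] ms, %d neurons\n",
              length(x$t), x$span[1], x$span[2], x$geometry$N))
  invisible(x)
}

# spike times of one neuron
raster_times <- function(raster, neuron) raster$t[raster$id == neuron]

# subset a raster to a set of neurons (ids kept global)
raster_subset <- function(raster, neurons) {
  keep <- raster$id %in% neurons
  r <- raster
  r$id <- raster$id[keep]
  r$t <- raster$t[keep]
  r
}

#' Mean firing rates per population
#'
#' @param raster A `spike_raster`.
#' @param by `"group"` for e/i by area, or `"neuron"` for per-neuron rates.
#' @param window Optional `c(t0, t1)` ms restriction.
#' @return Named vector of rates in Hz (group mode), or a data frame.
#' @export
firing_rates <- function(raster, by = c("group", "neuron"), window = NULL) {
  by <- match.arg(by)
  t <- raster$t
  id <- raster$id
  if (!is.null(window)) {
    keep <- t >= window[1] & t < window[2]
    t <- t[keep]
    id <- id[keep]
    dur <- (window[2] - window[1]) / 1000
  } else dur <- diff(raster$span) / 1000
  counts <- tabulate(id, nbins = raster$geometry$N)
  lab <- raster$labels
  if (by == "neuron") {
    return(data.frame(neuron = seq_len(raster$geometry$N), area = lab$area,
                      type = lab$type, rate = counts / dur))
  }
  grp <- paste0(lab$type, lab$area)
  tapply(counts / dur, grp, mean)[c("e1", "i1", "e2", "i2")]
}
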