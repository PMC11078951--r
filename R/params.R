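#' Biophysical neuron parameters
#'
#' Conductance-based leaky integrate-and-fire parameters shared by all
#' neurons, with type-specific leak conductances and synaptic decay
#' constants. Spike-frequency adaptation is a potassium conductance that is
#' incremented at every spike of an excitatory neuron and decays with
#' `tau_k`; inhibitory neurons carry no adaptation.
#'
#' @param C Membrane capacitance, nF.
#' @param g_L_e,g_L_i Leak conductance, nS, excitatory / inhibitory.
#' @param V_L Leak reversal potential, mV.
#' @param v_T Spike threshold, mV.
#' @param v_r Reset potential, mV.
#' @param tau_ref Absolute refractory period, ms.
#' @param V_k Adaptation (potassium) reversal potential, mV.
#' @param tau_k Adaptation decay constant, ms.
#' @param dgk_e1,dgk_e2 Adaptation conductance increment per spike, nS, for
#'   excitatory neurons of area 1 and area 2.
#' @param tau_r Synaptic rise constant, ms (shared by both transmitter types).
#' @param tau_d_e,tau_d_i Synaptic decay constants, ms.
#' @param V_rev_e,V_rev_i Synaptic reversal potentials, mV.
#' @param ext_w Synaptic weight of external Poisson inputs, nS.
#' @return A `neuron_params` list.
#' @export
neuron_params <- function(C = 0.25, g_L_e = 16.7, g_L_i = 25, V_L = -70,
                          v_T = -50, v_r = -70, tau_ref = 4, V_k = -85,
                          tau_k = 60, dgk_e1 = 1.9, dgk_e2 = 6.5,
                          tau_r = 1, tau_d_e = 5, tau_d_i = 4.5,
                          V_rev_e = 0, V_rev_i = -80, ext_w = 5) {
  stopifnot(v_r < v_T, tau_r > 0, tau_d_e > 0, tau_d_i > 0, tau_k > 0,
            tau_ref > 0, C > 0, g_L_e > 0, g_L_i > 0)
  p <- as.list(environment())
  class(p) <- "neuron_params"
  p
}

#' Distance-dependent connectivity rule
#'
#' Connection probabilities decay exponentially with periodic distance,
#' `P = P0 * exp(-d / tau_P)`, per projection class. Intra-areal synaptic
#' weights are drawn per postsynaptic neuron around `J / sqrt(K_in)` so that
#' coupling scales inversely with the square root of the realized indegree;
#' inter-areal weights are drawn around a fixed mean, are excitatory-sourced
#' only, and originate from a randomly designated half of each excitatory
#' group. Delays are uniform in [0.5, 2.5] ms within an area and [8, 10] ms
#' between areas.
#'
#' @param scale Spatial scale factor applied to the probability decay
#'   constants (use `geometry$scale` for scaled-down lattices).
#' @param weight_cv Standard deviation of sampled weights as a fraction of
#'   their mean.
#' @param inter_source_frac Fraction of each excitatory group designated as
#'   inter-areal source neurons.
#' @return A `connectivity_rule` with one row per projection class
#'   (`proj` = pre group then post group, e.g. `"e1e2"` projects from e1 to
#'   e2), columns `P0`, `tau_P`, `Wbar` (nS) and delay ranges.
#' @export
connectivity_rule <- function(scale = 1, weight_cv = 0.05,
                              inter_source_frac = 0.5) {
  cls <- data.frame(
    proj = c("e1e1", "e1i1", "i1e1", "i1i1",
             "e2e2", "e2i2", "i2e2", "i2i2",
             "e1e2", "e1i2", "e2e1", "e2i1"),
    P0   = c(0.8057, 0.6964, 0.4088, 0.5663,
             0.8057, 0.6964, 0.4088, 0.5663,
             0.4, 0.4, 0.4, 0.4),
    tau_P = c(7.5, 9.5, 19, 19,
              7.5, 9.5, 19, 19,
              8, 8, 8, 8) * scale,
    Wbar = c(7.857, 10.847, 35.534, 45,
             11, 13.805, 41.835, 50,
             3.656, 3.656, 0.578, 0.578),
    stringsAsFactors = FALSE
  )
  cls$pre_type <- substr(cls$proj, 1, 1)
  cls$pre_area <- as.integer(substr(cls$proj, 2, 2))
  cls$post_type <- substr(cls$proj, 3, 3)
  cls$post_area <- as.integer(substr(cls$proj, 4, 4))
  cls$intra <- cls$pre_area == cls$post_area
  r <- list(classes = cls, weight_cv = weight_cv,
            inter_source_frac = inter_source_frac,
            delay_intra = c(0.5, 2.5), delay_inter = c(8, 10))
  class(r) <- "connectivity_rule"
  r
}

#' External Poisson drive: homogeneous background plus Gaussian inputs
#'
#' Every neuron receives an independent Poisson spike train at
#' `lambda_bg` Hz through excitatory synapses of weight `ext_w`. Visual
#' inputs add Gaussian-profiled rate bumps, restricted to excitatory neurons
#' of area 1: `lambda_sti(y) = sum_l c_l * lambda_bg * exp(-||y - y_l||^2 /
#' (2 sigma_sti^2))` with periodic distance.
#'
#' @param inputs List of inputs, each `list(center = c(x, y), contrast = c)`.
#'   `input_preset("center")` and `input_preset("two")` give the standard
#'   one-input (center, contrast 0.25) and two-input (center + corner)
#'   configurations.
#' @param lambda_bg Background rate, Hz.
#' @param sigma_sti Spatial width of each input, grid units.
#' @param epochs Two-column matrix of (start, end) times in ms during which
#'   the inputs are on; `NULL` means always on.
#' @return A `stimulus_field`.
#' @export
stimulus_field <- function(inputs = list(), lambda_bg = 1600, sigma_sti = 6,
                           epochs = NULL) {
  for (inp in inputs) {
    stopifnot(length(inp$center) == 2, inp$contrast >= 0)
  }
  s <- list(inputs = inputs, lambda_bg = lambda_bg, sigma_sti = sigma_sti,
            epochs = epochs)
  class(s) <- "stimulus_field"
  s
}

#' @rdname stimulus_field
#' @param which `"none"`, `"center"` (one input at the origin) or `"two"`
#'   (center plus corner), all with contrast 0.25.
#' @param contrast Input contrast (dimensionless multiple of `lambda_bg`).
#' @export
input_preset <- function(which = c("none", "center", "two"), contrast = 0.25) {
  which <- match.arg(which)
  switch(which,
    none = list(),
    center = list(list(center = c(0, 0), contrast = contrast)),
    two = list(list(center = c(0, 0), contrast = contrast),
               list(center = c(-32, -32), contrast = contrast)))
}

#' External drive rate at a lattice position
#'
#' @param position Length-2 coordinate (or 2-column matrix) of the neuron.
#' @param stimulus A [stimulus_field()].
#' @param L Domain period (64 for the full lattice).
#' @param area,type Area and type of the target neuron; inputs only reach
#'   excitatory neurons of area 1, every other neuron gets `lambda_bg`.
#' @return Poisson drive rate in Hz.
#' @export
stimulus_rate <- function(position, stimulus, L = 64, area = 1, type = "e") {
  position <- matrix(position, ncol = 2)
  rate <- rep(stimulus$lambda_bg, nrow(position))
  if (area != 1 || type != "e") return(rate)
  for (inp in stimulus$inputs) {
    if (inp$contrast < 0) stop("negative stimulus contrast")
    d <- torus_distance(position,
                        matrix(inp$center, nrow(position), 2, byrow = TRUE), L)
    rate <- rate + inp$contrast * stimulus$lambda_bg *
      exp(-d^2 / (2 * stimulus$sigma_sti^2))
  }
  rate
}

#' Cue-triggered modulation of spike-frequency adaptation
#'
#' A top-down attention cue is modeled as a local reduction of the
#' adaptation increment of area-2 excitatory neurons, mimicking
#' acetylcholine release near the cued location. The reduction follows a
#' plateau profile (product of two sigmoids of the distance to the cue
#' center): essentially flat within `R_att` and falling off over `sigma_att`.
#'
#' @param enabled Is the cue present?
#' @param dgk_base Baseline adaptation increment of area-2 excitatory
#'   neurons, nS.
#' @param dgk_modu Maximum reduction at the cue center, nS.
#' @param center Cued location, grid coordinates.
#' @param R_att Plateau radius of the profile, grid units.
#' @param sigma_att Sharpness of the profile edge, grid units.
#' @return A `cue_modulation`.
#' @export
cue_modulation <- function(enabled = FALSE, dgk_base = 6.5, dgk_modu = 6,
                           center = c(0, 0), R_att = 8.2, sigma_att = 2.2) {
  stopifnot(dgk_modu <= dgk_base, dgk_modu >= 0, sigma_att > 0, R_att > 0)
  m <- as.list(environment())
  class(m) <- "cue_modulation"
  m
}

# plateau profile: product of two sigmoids of the distance to the cue center,
# ~1 for d < R_att and falling to 0 over a few sigma_att
att_profile <- function(d, R_att, sigma_att) {
  (1 / (1 + exp(-(d + R_att) / sigma_att))) *
    (1 - 1 / (1 + exp(-(d - R_att) / sigma_att)))
}

#' Adaptation increment under a cue
#'
#' @param position Coordinates (length-2 or 2-column matrix) of area-2
#'   excitatory neurons.
#' @param cue A [cue_modulation()].
#' @param L Domain period.
#' @return Adaptation increment `dgk` (nS) at each position: the baseline
#'   minus the profile-weighted reduction, normalized so the full reduction
#'   is attained at the cue center.
#' @export
cue_adaptation_profile <- function(position, cue, L = 64) {
  position <- matrix(position, ncol = 2)
  if (!cue$enabled) return(rep(cue$dgk_base, nrow(position)))
  d <- torus_distance(position,
                      matrix(cue$center, nrow(position), 2, byrow = TRUE), L)
  f <- att_profile(d, cue$R_att, cue$sigma_att)
  f0 <- att_profile(0, cue$R_att, cue$sigma_att)
  cue$dgk_base - cue$dgk_modu * f / f0
}
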