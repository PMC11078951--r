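#' Scenario configuration
#'
#' Maps a named scenario to the complete parameter closure needed to run
#' it: geometry, connectivity rule, stimulus, cue, duration, and seeds.
#' Every printed constant of the model is a default of the underlying
#' constructors; a scenario only toggles inputs, cue, or disconnection.
#'
#' @param scenario One of `"spontaneous"`, `"one-input"`, `"two-input"`,
#'   `"uncued"`, `"cued"`, `"disconnect-ff"`, `"disconnect-fb"`,
#'   `"levy-walker"`.
#' @param duration Simulated/recorded time, ms (per trial for trial-based
#'   scenarios).
#' @param seed Master seed (connectivity and drive derive sub-streams).
#' @param half_width Geometry half-width (32 = full size).
#' @param trials Number of trials for trial-based scenarios.
#' @param out Optional output path for [run_scenario()] bundles (.rds).
#' @return An `experiment_config`.
#' @export
experiment_config <- function(scenario = c("spontaneous", "one-input",
                                           "two-input", "uncued", "cued",
                                           "disconnect-ff", "disconnect-fb",
                                           "levy-walker"),
                              duration = 10000, seed = 1, half_width = 32,
                              trials = 1, out = NULL) {
  scenario <- match.arg(scenario)
  cfg <- list(scenario = scenario, duration = duration, seed = seed,
              half_width = half_width, trials = trials, out = out)
  class(cfg) <- "experiment_config"
  cfg
}

#' Run a scenario end to end
#'
#' Builds the network (or walker), simulates, derives the scenario's
#' standard observables (rates, MUA at the relevant sites, On/Off labels,
#' joint states), and returns everything in a bundle with a manifest
#' recording seeds and configuration, so any derived statistic traces back
#' to its provenance. If `config$out` is set the bundle is saved as .rds.
#'
#' @param config An [experiment_config()].
#' @return A `scenario_bundle` list: `manifest`, plus scenario-dependent
#'   elements (`sim`/`trials`, `mua`, `states`, `rates`, or the walker
#'   `variability` table).
#' @export
run_scenario <- function(config) {
  manifest <- list(scenario = config$scenario, seed = config$seed,
                   duration = config$duration, trials = config$trials,
                   half_width = config$half_width,
                   package_version = as.character(utils::packageVersion("wavecomm")))
  if (config$scenario == "levy-walker") {
    wp <- walker_params()
    tab <- walker_variability(wp, depths = seq(0, 50, 10),
                              seed = config$seed, keep_on_durations = TRUE)
    bundle <- list(manifest = manifest, variability = tab)
  } else if (config$duration <= 0) {
    bundle <- list(manifest = manifest, empty = TRUE)
  } else {
    g <- network_geometry(config$half_width)
    rule <- connectivity_rule(g$scale)
    syn <- sample_connectivity(g, rule, seed = config$seed)
    if (config$scenario == "disconnect-ff")
      syn <- disconnect_interareal(syn, "bottom-up")
    if (config$scenario == "disconnect-fb")
      syn <- disconnect_interareal(syn, "top-down")
    inputs <- switch(config$scenario,
      "one-input" = input_preset("center"),
      "two-input" = , "uncued" = , "cued" = input_preset("two"),
      input_preset("none"))
    sti <- stimulus_field(inputs = inputs)
    cue <- cue_modulation(enabled = config$scenario == "cued")
    sim <- simulate_network(g, syn, stimulus = sti, cue = cue,
                            duration = config$duration,
                            seed = config$seed + 1L,
                            lfp_sites = list(list(center = c(0, 0), area = 1)))
    m1 <- mua(sim$raster, c(0, 0), area = 1)
    m2 <- mua(sim$raster, c(0, 0), area = 2)
    s1 <- detect_on_off(m1)
    s2 <- detect_on_off(m2)
    bundle <- list(manifest = manifest, sim = sim,
                   rates = firing_rates(sim$raster),
                   mua = list(area1 = m1, area2 = m2),
                   states = list(area1 = s1, area2 = s2,
                                 joint = joint_states(s1, s2)))
  }
  class(bundle) <- "scenario_bundle"
  if (!is.null(config$out)) saveRDS(bundle, config$out)
  bundle
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat(sprintf("scenario_bundle: %s (seed %d)\n", x$manifest$scenario,
              x$manifest$seed))
  invisible(x)
}

#' Simulate stimulus-evoked trials
#'
#' Presents the stimulus for `stim_ms` per trial with randomized
#' inter-trial intervals (uniform 800-1500 ms); returns one aligned
#' `spike_raster` per trial (onset at 0). With `cue = TRUE` the adaptation
#' reduction is active from 2000 ms before the first trial onward.
#'
#' @param geometry,synapses,params Network as in [simulate_network()].
#' @param inputs Input list (see [input_preset()]).
#' @param n_trials Number of trials.
#' @param stim_ms Stimulus duration per trial, ms.
#' @param trial_ms Analyzed trial length from onset, ms.
#' @param cue Logical: cued condition?
#' @param seed Integer seed.
#' @return List of `spike_raster` trials plus the full-session raster as
#'   an attribute.
#' @export
simulate_trials <- function(geometry, synapses, params = neuron_params(),
                            inputs = input_preset("two"), n_trials = 5,
                            stim_ms = 600, trial_ms = 600, cue = FALSE,
                            seed = 1) {
  gaps <- with_seed(seed * 23L + 9L, stats::runif(n_trials, 800, 1500))
  lead <- if (cue) 2000 else gaps[1]
  onsets <- lead + c(0, cumsum(rep(stim_ms, n_trials - 1) +
                                 gaps[-1]))
  total <- onsets[n_trials] + max(trial_ms, stim_ms) + 200
  epochs <- cbind(onsets, onsets + stim_ms)
  sti <- stimulus_field(inputs = inputs, epochs = epochs)
  sim <- simulate_network(geometry, synapses, params, sti,
                          cue_modulation(enabled = cue),
                          duration = total, seed = seed)
  trials <- lapply(seq_len(n_trials), function(i) {
    keep <- sim$raster$t >= onsets[i] & sim$raster$t < onsets[i] + trial_ms
    spike_raster(sim$raster$id[keep], sim$raster$t[keep] - onsets[i],
                 geometry, c(0, trial_ms))
  })
  attr(trials, "session") <- sim
  attr(trials, "onsets") <- onsets
  trials
}
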