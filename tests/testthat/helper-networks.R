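# shared small-network simulations, built once per test run
.wc_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .wc_cache)) {
    assign(key, force(expr), envir = .wc_cache)
  }
  get(key, envir = .wc_cache)
}

# scaled-down two-area network (16 x 16 excitatory lattices per area)
small_net <- function() {
  cached("small_net", {
    g <- network_geometry(8)
    syn <- sample_connectivity(g, connectivity_rule(scale = g$scale), seed = 11)
    list(g = g, syn = syn)
  })
}

small_sim <- function() {
  cached("small_sim", {
    nw <- small_net()
    suppressWarnings(simulate_network(nw$g, nw$syn, duration = 3000, seed = 12,
                                      lfp_sites = list(list(center = c(0, 0),
                                                            area = 1))))
  })
}
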