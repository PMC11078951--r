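#' Sample the synaptic connectivity of the two-area network
#'
#' Every ordered neuron pair of each projection class is connected
#' independently with probability `P0 * exp(-d / tau_P)` (periodic distance,
#' no self-connections). Intra-areal weights are Gaussian per postsynaptic
#' neuron with mean `J / sqrt(K_in_j)`, where `K_in_j` is the neuron's
#' realized indegree for that class and `J` is set so the class-wide mean
#' weight equals the prescribed `Wbar`; inter-areal weights are Gaussian
#' around `Wbar` directly. Only a designated random half of each excitatory
#' group projects between areas. Delays are uniform per class.
#'
#' @param geometry A [network_geometry()].
#' @param rule A [connectivity_rule()]; pass
#'   `connectivity_rule(scale = geometry$scale)` for scaled-down lattices.
#' @param seed Integer seed; the connectivity stream is independent of the
#'   simulation streams so a network can be held fixed across conditions.
#' @return A `synapse_table`: integer vectors `pre`, `post` (global neuron
#'   ids), `weight` (nS), `delay` (ms), `class` (projection label), plus the
#'   inter-areal source designation as an attribute.
#' @export
sample_connectivity <- function(geometry, rule = connectivity_rule(geometry$scale),
                                seed = 1) {
  cls <- rule$classes
  if (any(cls$tau_P <= 0)) stop("non-positive connection decay constant")
  if (any(cls$P0 > 1 | cls$P0 < 0)) stop("peak probability outside [0, 1]")
  off <- geometry$offset
  coords <- list(e = as.matrix(geometry$exc), i = as.matrix(geometry$inh))
  if (geometry$N == 0 || geometry$N_e == 0) {
    return(empty_synapse_table())
  }

  # inter-areal source subsets, drawn once with the connectivity stream
  sources <- with_seed(seed * 7L + 1L, list(
    e1 = sort(sample.int(geometry$N_e, round(rule$inter_source_frac * geometry$N_e))),
    e2 = sort(sample.int(geometry$N_e, round(rule$inter_source_frac * geometry$N_e)))
  ))

  parts <- vector("list", nrow(cls))
  for (ci in seq_len(nrow(cls))) {
    cl <- cls[ci, ]
    pre_xy <- coords[[cl$pre_type]]
    post_xy <- coords[[cl$post_type]]
    allowed <- rep(TRUE, nrow(pre_xy))
    if (!cl$intra) {
      allowed[] <- FALSE
      allowed[sources[[paste0("e", cl$pre_area)]]] <- TRUE
    }
    same_pop <- cl$intra && cl$pre_type == cl$post_type
    pr <- .sample_pairs(pre_xy[, 1], pre_xy[, 2], post_xy[, 1], post_xy[, 2],
                        cl$P0, cl$tau_P, geometry$L, allowed, same_pop,
                        as.integer((seed %% 65011) * 131 + ci))
    n_syn <- length(pr$pre)
    if (n_syn == 0) {
      parts[[ci]] <- NULL
      next
    }
    w <- with_seed(seed * 13L + ci, {
      if (cl$intra) {
        K <- tabulate(pr$post, nbins = nrow(post_xy))
        J <- cl$Wbar * sum(K) / sum(sqrt(K[K > 0]))
        mu <- J / sqrt(K[pr$post])
        rnorm(n_syn, mean = mu, sd = rule$weight_cv * mu)
      } else {
        rnorm(n_syn, mean = cl$Wbar, sd = rule$weight_cv * cl$Wbar)
      }
    })
    dl <- with_seed(seed * 17L + ci, {
      rng <- if (cl$intra) rule$delay_intra else rule$delay_inter
      runif(n_syn, rng[1], rng[2])
    })
    parts[[ci]] <- data.frame(
      pre = pr$pre + off[[paste0(cl$pre_type, cl$pre_area)]],
      post = pr$post + off[[paste0(cl$post_type, cl$post_area)]],
      weight = pmax(w, 0),
      delay = dl,
      class = cl$proj,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, parts)
  syn <- list(pre = tab$pre, post = tab$post, weight = tab$weight,
              delay = tab$delay, class = tab$class)
  attr(syn, "sources") <- sources
  attr(syn, "geometry_half_width") <- geometry$half_width
  class(syn) <- "synapse_table"
  syn
}

empty_synapse_table <- function() {
  syn <- list(pre = integer(0), post = integer(0), weight = numeric(0),
              delay = numeric(0), class = character(0))
  class(syn) <- "synapse_table"
  syn
}

#' @export
print.synapse_table <- function(x, ...) {
  cat(sprintf("synapse_table: %d synapses, %d projection classes\n",
              length(x$pre), length(unique(x$class))))
  if (length(x$pre)) print(table(x$class))
  invisible(x)
}

#' @export
length.synapse_table <- function(x) length(x$pre)

#' Remove inter-areal projections
#'
#' Mimics inactivating distant sources of feedforward (bottom-up, area 1 to
#' area 2) or feedback (top-down, area 2 to area 1) input; intra-areal
#' synapses are untouched.
#'
#' @param synapses A `synapse_table`.
#' @param direction `"bottom-up"`, `"top-down"`, or `"both"`.
#' @return The filtered `synapse_table`.
#' @export
disconnect_interareal <- function(synapses,
                                  direction = c("bottom-up", "top-down", "both")) {
  direction <- match.arg(direction)
  drop_cls <- switch(direction,
    "bottom-up" = c("e1e2", "e1i2"),
    "top-down" = c("e2e1", "e2i1"),
    "both" = c("e1e2", "e1i2", "e2e1", "e2i1"))
  keep <- !(synapses$class %in% drop_cls)
  out <- lapply(unclass(synapses), function(v) v[keep])
  attr(out, "sources") <- attr(synapses, "sources")
  attr(out, "geometry_half_width") <- attr(synapses, "geometry_half_width")
  class(out) <- "synapse_table"
  out
}
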