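#' Network geometry of one cortical area pair
#'
#' Both areas tile the same periodic square `[-hw, hw) x [-hw, hw)`.
#' Excitatory neurons sit on a unit lattice at half-integer coordinates
#' (1 grid point is roughly 7 um of cortex); inhibitory neurons sit on a
#' lattice with twice the spacing, so each area holds `N_e` excitatory and
#' `N_e / 4` inhibitory cells.
#'
#' @param half_width Half-width of the square domain in grid units. The
#'   default 32 gives the full-size 64 x 64 excitatory lattice (4096 cells
#'   per area); smaller powers of two (e.g. 16) give the proportionally
#'   scaled-down geometry used for fast tests, in which the connectivity
#'   footprints and input widths returned by [connectivity_rule()] and
#'   [stimulus_field()] should be scaled by `half_width / 32`.
#' @return An object of class `network_geometry`: lattice coordinates for
#'   both populations of both areas, population sizes, and global neuron id
#'   offsets (ordering: e1, i1, e2, i2).
#' @export
network_geometry <- function(half_width = 32) {
  stopifnot(half_width >= 4, half_width %% 2 == 0)
  hw <- half_width
  ex <- seq(-hw + 0.5, hw - 0.5, by = 1)
  ix <- seq(-hw + 1, hw - 1, by = 2)
  exc <- expand.grid(x = ex, y = ex)
  inh <- expand.grid(x = ix, y = ix)
  N_e <- nrow(exc)
  N_i <- nrow(inh)
  stopifnot(N_i == N_e / 4)
  g <- list(
    half_width = hw,
    L = 2 * hw,
    scale = hw / 32,
    N_e = N_e,
    N_i = N_i,
    N = 2 * (N_e + N_i),
    exc = exc,
    inh = inh,
    # global id offsets for groups e1, i1, e2, i2
    offset = c(e1 = 0L, i1 = N_e, e2 = N_e + N_i, i2 = 2L * N_e + N_i)
  )
  class(g) <- "network_geometry"
  g
}

#' @export
print.network_geometry <- function(x, ...) {
  cat(sprintf(
    "network_geometry: 2 areas on [%d, %d)^2 (periodic), %d exc + %d inh per area\n",
    -x$half_width, x$half_width, x$N_e, x$N_i))
  invisible(x)
}

# coordinates (x, y) of every neuron in global id order e1, i1, e2, i2
geometry_coords <- function(geometry) {
  rbind(geometry$exc, geometry$inh, geometry$exc, geometry$inh)
}

# area (1/2) and type ("e"/"i") per global id
geometry_labels <- function(geometry) {
  data.frame(
    area = rep(c(1L, 1L, 2L, 2L), c(geometry$N_e, geometry$N_i,
                                    geometry$N_e, geometry$N_i)),
    type = rep(c("e", "i", "e", "i"), c(geometry$N_e, geometry$N_i,
                                        geometry$N_e, geometry$N_i)),
    stringsAsFactors = FALSE
  )
}

#' Periodic (wrap-around) distance on the square torus
#'
#' @param a,b Two-column matrices (or length-2 vectors) of coordinates.
#' @param L Period of the domain (side length), e.g. 64 for the full lattice.
#' @return Vector of Euclidean distances under the minimal-image convention.
#' @export
torus_distance <- function(a, b, L) {
  a <- matrix(a, ncol = 2)
  b <- matrix(b, ncol = 2)
  dx <- abs(a[, 1] - b[, 1])
  dy <- abs(a[, 2] - b[, 2])
  dx <- pmin(dx, L - dx)
  dy <- pmin(dy, L - dy)
  sqrt(dx^2 + dy^2)
}

# minimal-image displacement b - a on the torus
torus_delta <- function(a, b, L) {
  d <- (b - a + L / 2) %% L - L / 2
  d
}

#' Neurons of a local site group
#'
#' Global ids of the neurons of one population within `radius` grid points
#' (periodic distance) of a site center. With the defaults (radius 5,
#' excitatory) the full-size lattice yields the standard 80-neuron group
#' used for MUA, On/Off detection, and the subspace analyses.
#'
#' @param geometry A [network_geometry()].
#' @param center Site center, grid coordinates.
#' @param radius Radius, grid points.
#' @param area Area (1 or 2).
#' @param type Population type, `"e"` or `"i"`.
#' @return Integer vector of global neuron ids.
#' @export
site_neurons <- function(geometry, center, radius = 5, area = 1, type = "e") {
  grp <- paste0(type, area)
  coords <- if (type == "e") geometry$exc else geometry$inh
  d <- torus_distance(as.matrix(coords), matrix(center, nrow(coords), 2,
                                                byrow = TRUE), geometry$L)
  which(d < radius) + geometry$offset[[grp]]
}

# restore-on-exit seeding so package internals do not disturb the caller's RNG
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
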