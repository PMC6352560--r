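# Shape descriptors: radius of gyration, inertia-tensor eccentricity,
# radial density profile.

#' Radius of gyration
#'
#' Root-mean-square (mass-weighted by default) distance of particles from
#' the center of mass.
#'
#' @param system A `particle_system` with coordinates.
#' @param weighting `"mass"` (default) or `"number"` (every particle
#'   counted equally).
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(system, weighting = c("mass", "number")) {
  weighting <- match.arg(weighting)
  stopifnot_coords(system)
  w <- if (weighting == "mass") system$particles$mass else
    rep(1, nrow(system$particles))
  tot <- sum(w)
  if (tot <= 0) stop("total weight must be positive", call. = FALSE)
  com <- colSums(system$coords * w) / tot
  rel <- sweep(system$coords, 2, com)
  sqrt(sum(w * rowSums(rel^2)) / tot)
}

# Mass-weighted inertia tensor about the COM, plus the gyration tensor
# (used for degeneracy detection).
inertia_tensor <- function(system, weighting = "mass") {
  w <- if (weighting == "mass") system$particles$mass else
    rep(1, nrow(system$particles))
  com <- colSums(system$coords * w) / sum(w)
  rel <- sweep(system$coords, 2, com)
  gyr <- crossprod(rel * w, rel)            # sum w * r (x) r
  inertia <- diag(3) * sum(w * rowSums(rel^2)) - gyr
  list(inertia = inertia, gyration = gyr, com = com)
}

#' Eccentricity from the tri-axial moments of inertia
#'
#' `1 - I_min / I_average` over the three principal moments of the
#' mass-weighted inertia tensor: 0 for a body with three equal principal
#' moments (e.g. a sphere or cube), approaching 1 for strongly aspherical
#' bodies. Invariant under rigid rotation, translation and uniform scaling.
#'
#' @param system A `particle_system` with at least 3 non-collinear
#'   particles.
#' @param weighting `"mass"` or `"number"`.
#' @return Dimensionless eccentricity in `[0, 1)`.
#' @export
eccentricity <- function(system, weighting = c("mass", "number")) {
  weighting <- match.arg(weighting)
  stopifnot_coords(system)
  if (nrow(system$particles) < 3L) {
    stop("eccentricity needs at least 3 particles", call. = FALSE)
  }
  tens <- inertia_tensor(system, weighting)
  gyr_ev <- eigen(tens$gyration, symmetric = TRUE, only.values = TRUE)$values
  if (gyr_ev[2] < 1e-10 * max(gyr_ev[1], 1e-300)) {
    stop("degenerate (collinear) configuration: eccentricity undefined",
         call. = FALSE)
  }
  mom <- eigen(tens$inertia, symmetric = TRUE, only.values = TRUE)$values
  1 - min(mom) / mean(mom)
}

#' Full shape result
#'
#' @param system A `particle_system` with coordinates.
#' @param weighting `"mass"` or `"number"`.
#' @return A `shape_result` list: `rg`, `eccentricity`,
#'   `principal_moments` (ascending, Da A^2), `i_average`,
#'   `center_of_mass`.
#' @export
shape_descriptors <- function(system, weighting = c("mass", "number")) {
  weighting <- match.arg(weighting)
  stopifnot_coords(system)
  tens <- inertia_tensor(system, weighting)
  mom <- sort(eigen(tens$inertia, symmetric = TRUE, only.values = TRUE)$values)
  structure(list(
    rg = radius_of_gyration(system, weighting),
    eccentricity = eccentricity(system, weighting),
    principal_moments = mom,
    i_average = mean(mom),
    center_of_mass = tens$com
  ), class = "shape_result")
}

#' Radial density profile about the center of mass
#'
#' Shell mass divided by shell volume in fixed-width radial bins. The
#' summed shell masses always equal the total mass (the outermost bin is
#' extended to the farthest particle).
#'
#' @param system A `particle_system`, or a list of systems (replicates or
#'   frames) whose binned densities are averaged on a common grid.
#' @param bin_width Radial bin width in Angstrom (default 5).
#' @param r_max Outer radius; defaults to the farthest particle over all
#'   frames.
#' @return A `radial_profile` list: `bin_edges`, `bin_mid`, `density`
#'   (Da/A^3), `number_density` (1/A^3), `shell_mass`, `frames_averaged`.
#' @export
radial_density_profile <- function(system, bin_width = 5, r_max = NULL) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  systems <- if (inherits(system, "particle_system")) list(system) else system
  lapply(systems, stopifnot_coords)
  radii <- lapply(systems, function(s) {
    com <- center_of_mass(s)
    row_norms(sweep(s$coords, 2, com))
  })
  if (is.null(r_max)) r_max <- max(vapply(radii, max, numeric(1L)))
  edges <- seq(0, r_max + bin_width, by = bin_width)
  nb <- length(edges) - 1L
  vol <- (4 / 3) * pi * (edges[-1L]^3 - edges[-length(edges)]^3)
  acc_mass <- matrix(0, length(systems), nb)
  acc_num <- matrix(0, length(systems), nb)
  for (f in seq_along(systems)) {
    idx <- pmin(pmax(findInterval(radii[[f]], edges,
                                  rightmost.closed = TRUE), 1L), nb)
    acc_mass[f, ] <- vapply(seq_len(nb), function(b) {
      sum(systems[[f]]$particles$mass[idx == b])
    }, numeric(1L))
    acc_num[f, ] <- tabulate(idx, nb)
  }
  structure(list(
    bin_edges = edges,
    bin_mid = (edges[-1L] + edges[-length(edges)]) / 2,
    density = colMeans(acc_mass) / vol,
    number_density = colMeans(acc_num) / vol,
    shell_mass = colMeans(acc_mass),
    frames_averaged = length(systems)
  ), class = "radial_profile")
}
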