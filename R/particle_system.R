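# ParticleSystem: the labeled coordinate container every descriptor consumes.
#
# Representation: a plain list with
#   particles : data.frame, one row per particle, columns
#               id, tag, mass (Da), radius (Angstrom), charge (e),
#               chain_id, unit_index, segment_type (HARD/PCL/PLA),
#               hb_class (PCL/PLA), hbond_role
#               (donor_heavy/donor_hydrogen/acceptor/none), backbone (logical)
#   coords    : N x 3 matrix (Angstrom), NA until a generator assigns them
#   bonds, angles, torsions, out_of_plane : integer index matrices
#               (rows are tuples into particles)
#   segment_markers : data.frame(chain_id, scope, segment_type, start, end)
#               with `scope` "chain" or "segment"; start/end are particle ids
#               of the junction (nitrogen) markers
#   box       : optional length-3 vector of box edge lengths (Angstrom)

#' Construct a particle system
#'
#' Assembles the labeled container used by every descriptor: a particle table,
#' coordinates, bonded index tuples and junction (end-to-end) markers.
#'
#' @param particles data.frame of per-particle labels (see Details).
#' @param coords `N x 3` numeric matrix of coordinates in Angstrom, or `NULL`
#'   when coordinates are still to be generated.
#' @param bonds,angles,torsions,out_of_plane Integer matrices of bonded index
#'   tuples (2, 3, 4 and 4 columns); row indices refer to `particles` rows.
#' @param segment_markers data.frame of chain/segment junction marker pairs.
#' @param box Optional numeric length-3 box edge lengths (Angstrom).
#' @details Required particle columns: `id`, `tag`, `mass`, `radius`,
#'   `charge`, `chain_id`, `unit_index`, `segment_type`, `hb_class`,
#'   `hbond_role`, `backbone`. Masses are in Da, lengths in Angstrom,
#'   charges in elementary charge units.
#' @return An object of class `particle_system`.
#' @export
particle_system <- function(particles, coords = NULL,
                            bonds = NULL, angles = NULL, torsions = NULL,
                            out_of_plane = NULL, segment_markers = NULL,
                            box = NULL) {
  required <- c("id", "tag", "mass", "radius", "charge", "chain_id",
                "unit_index", "segment_type", "hb_class", "hbond_role",
                "backbone")
  missing_cols <- setdiff(required, names(particles))
  if (length(missing_cols)) {
    stop("particles is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("id", "chain_id", "unit_index")) {
    particles[[col]] <- as.integer(particles[[col]])
  }
  for (col in c("mass", "radius", "charge")) {
    particles[[col]] <- as.numeric(particles[[col]])
  }
  particles$backbone <- as.logical(particles$backbone)
  rownames(particles) <- NULL
  n <- nrow(particles)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3) {
      stop("coords must be an N x 3 matrix matching particles", call. = FALSE)
    }
    dimnames(coords) <- NULL
  }
  sys <- structure(list(
    particles = particles,
    coords = coords,
    bonds = int_tuples(bonds, 2L),
    angles = int_tuples(angles, 3L),
    torsions = int_tuples(torsions, 4L),
    out_of_plane = int_tuples(out_of_plane, 4L),
    segment_markers = segment_markers,
    box = box
  ), class = "particle_system")
  sys
}

int_tuples <- function(m, k) {
  if (is.null(m) || NROW(m) == 0L) {
    return(matrix(integer(0), ncol = k))
  }
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (ncol(m) != k) stop("tuple matrix must have ", k, " columns", call. = FALSE)
  dimnames(m) <- NULL
  m
}

#' @export
print.particle_system <- function(x, ...) {
  n <- nrow(x$particles)
  nch <- length(unique(x$particles$chain_id))
  cat(sprintf("particle_system: %d particles, %d chain(s)\n", n, nch))
  comp <- table(x$particles$segment_type)
  cat("  segment types:", paste(sprintf("%s=%d", names(comp), comp),
                                collapse = ", "), "\n")
  cat(sprintf("  coordinates: %s; bonds: %d; markers: %d\n",
              if (is.null(x$coords)) "none" else "assigned",
              nrow(x$bonds),
              if (is.null(x$segment_markers)) 0L else nrow(x$segment_markers)))
  if (!is.null(x$box)) {
    cat(sprintf("  box: %.1f x %.1f x %.1f Angstrom\n",
                x$box[1], x$box[2], x$box[3]))
  }
  invisible(x)
}

has_coords <- function(system) {
  !is.null(system$coords) && !anyNA(system$coords)
}

stopifnot_coords <- function(system) {
  if (!inherits(system, "particle_system")) {
    stop("expected a particle_system", call. = FALSE)
  }
  if (!has_coords(system)) {
    stop("system has no (complete) coordinates; generate or load them first",
         call. = FALSE)
  }
}

#' Center of mass of a particle system
#' @param system A `particle_system` with coordinates.
#' @return Numeric length-3 vector (Angstrom).
#' @export
center_of_mass <- function(system) {
  stopifnot_coords(system)
  m <- system$particles$mass
  tot <- sum(m)
  if (tot <= 0) stop("total mass must be positive", call. = FALSE)
  colSums(system$coords * m) / tot
}

#' Total mass of a system or chain topology
#' @param x A `particle_system` or `chain_topology`.
#' @return Total mass in Da.
#' @export
total_mass <- function(x) sum(x$particles$mass)

#' Apply a rigid (or affine) transform to all coordinates
#'
#' @param system A `particle_system` with coordinates.
#' @param rotation 3x3 matrix applied on the right of row coordinates.
#' @param translation length-3 vector added after rotation.
#' @param scale length-1 or length-3 per-axis scale factors applied first.
#' @return The transformed system.
#' @export
transform_system <- function(system, rotation = diag(3),
                             translation = c(0, 0, 0), scale = 1) {
  stopifnot_coords(system)
  xyz <- system$coords
  if (!all(scale == 1)) {
    xyz <- sweep(xyz, 2, rep(scale, length.out = 3), `*`)
  }
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, `+`)
  system$coords <- xyz
  system
}

# Index helper: rows of particles for given particle ids (ids are unique).
match_ids <- function(system, ids) {
  idx <- match(ids, system$particles$id)
  if (anyNA(idx)) stop("unknown particle id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}
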