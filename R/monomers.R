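# Monomer specifications for the soft-segment chemistry.
#
# The repeat units are the polyester building blocks of the soft segments:
#   PCL  -O-(CH2)5-CO-   (C6H10O2, 114.14 Da per repeat)
#   PLA  -O-CH(CH3)-CO-  (C3H4O2,   72.06 Da per repeat)
# At the default "united" resolution CH/CH2/CH3 groups are single beads whose
# masses include their hydrogens; ester and carbonyl oxygens are flagged as
# hydrogen-bond acceptors. An "explicit" expansion with all hydrogens is
# available for bookkeeping checks.

ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)
ELEMENT_RADIUS <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52)
UNITED_RADIUS <- c(CH = 1.85, CH2 = 1.90, CH3 = 1.95)

#' Define a monomer specification
#'
#' @param name Identifier, e.g. `"PCL"`.
#' @param heavy_atom_count,hydrogen_count Non-negative atom counts per repeat.
#' @param mass Repeat mass in Da.
#' @param donor_sites,acceptor_sites Hydrogen-bond donor/acceptor site counts.
#' @param beads data.frame describing the united-resolution bead expansion
#'   (columns `tag`, `element`, `mass`, `radius`, `backbone`, `parent`,
#'   `hbond_role`, `n_hydrogens`); `parent` is the within-repeat backbone bead
#'   index a branch bead hangs from (NA for backbone beads).
#' @return A `monomer_spec` object.
#' @export
monomer_spec <- function(name, heavy_atom_count, hydrogen_count, mass,
                         donor_sites = 0L, acceptor_sites = 0L, beads) {
  stopifnot(heavy_atom_count >= 0, hydrogen_count >= 0, mass > 0,
            donor_sites >= 0, acceptor_sites >= 0)
  if (!missing(beads)) {
    bead_mass <- sum(beads$mass)
    if (abs(bead_mass - mass) > 0.01) {
      stop(sprintf("bead masses sum to %.3f Da but spec mass is %.3f Da",
                   bead_mass, mass), call. = FALSE)
    }
    if (nrow(beads) != heavy_atom_count) {
      stop("united beads must map one-to-one onto heavy atoms", call. = FALSE)
    }
    if (sum(beads$n_hydrogens) != hydrogen_count) {
      stop("bead hydrogen counts do not sum to hydrogen_count", call. = FALSE)
    }
  }
  structure(list(name = name,
                 heavy_atom_count = as.integer(heavy_atom_count),
                 hydrogen_count = as.integer(hydrogen_count),
                 mass = mass,
                 donor_sites = as.integer(donor_sites),
                 acceptor_sites = as.integer(acceptor_sites),
                 beads = beads),
            class = "monomer_spec")
}

monomer_beads <- function(tag, element, backbone, parent, hbond_role,
                          n_hydrogens) {
  mass <- ifelse(element %in% names(ELEMENT_MASS),
                 ELEMENT_MASS[element], NA_real_) +
    n_hydrogens * ELEMENT_MASS[["H"]]
  radius <- ifelse(tag %in% names(UNITED_RADIUS),
                   UNITED_RADIUS[tag], ELEMENT_RADIUS[element])
  data.frame(tag = tag, element = element, mass = as.numeric(mass),
             radius = as.numeric(radius), backbone = backbone,
             parent = parent, hbond_role = hbond_role,
             n_hydrogens = as.integer(n_hydrogens),
             stringsAsFactors = FALSE)
}

#' Built-in monomer library
#'
#' @return Named list of `monomer_spec` objects for the PCL and PLA repeat
#'   units at united resolution.
#' @export
default_monomers <- function() {
  # PCL repeat -O-(CH2)5-CO-: backbone O,C,C,C,C,C,C(=O); branch carbonyl O
  pcl <- monomer_beads(
    tag = c("O_ester", "CH2", "CH2", "CH2", "CH2", "CH2", "C_carb", "O_carb"),
    element = c("O", "C", "C", "C", "C", "C", "C", "O"),
    backbone = c(rep(TRUE, 7), FALSE),
    parent = c(rep(NA_integer_, 7), 7L),
    hbond_role = c("acceptor", rep("none", 5), "none", "acceptor"),
    n_hydrogens = c(0L, 2L, 2L, 2L, 2L, 2L, 0L, 0L))
  # PLA repeat -O-CH(CH3)-CO-: backbone O,CH,C(=O); branches CH3, carbonyl O
  pla <- monomer_beads(
    tag = c("O_ester", "CH", "C_carb", "CH3", "O_carb"),
    element = c("O", "C", "C", "C", "O"),
    backbone = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    parent = c(NA_integer_, NA_integer_, NA_integer_, 2L, 3L),
    hbond_role = c("acceptor", "none", "none", "none", "acceptor"),
    n_hydrogens = c(0L, 1L, 0L, 3L, 0L))
  list(
    PCL = monomer_spec("PCL", heavy_atom_count = 8L, hydrogen_count = 10L,
                       mass = sum(pcl$mass), donor_sites = 0L,
                       acceptor_sites = 2L, beads = pcl),
    PLA = monomer_spec("PLA", heavy_atom_count = 5L, hydrogen_count = 4L,
                       mass = sum(pla$mass), donor_sites = 0L,
                       acceptor_sites = 2L, beads = pla)
  )
}

#' Expand a monomer into its particle table
#'
#' @param spec A `monomer_spec`.
#' @param explicit_hydrogens If `TRUE`, emit one particle per hydrogen
#'   (attached to its heavy bead) instead of folding hydrogen mass into
#'   united beads.
#' @return data.frame with columns `tag`, `element`, `mass`, `radius`,
#'   `backbone`, `parent`, `hbond_role`.
#' @export
monomer_particles <- function(spec, explicit_hydrogens = FALSE) {
  b <- spec$beads
  if (!explicit_hydrogens) {
    return(b[, c("tag", "element", "mass", "radius", "backbone", "parent",
                 "hbond_role")])
  }
  rows <- vector("list", nrow(b))
  out <- b
  out$mass <- out$mass - out$n_hydrogens * ELEMENT_MASS[["H"]]
  out$radius <- ifelse(out$element %in% names(ELEMENT_RADIUS),
                       ELEMENT_RADIUS[out$element], out$radius)
  out <- out[, c("tag", "element", "mass", "radius", "backbone", "parent",
                 "hbond_role")]
  hydrogens <- do.call(rbind, lapply(seq_len(nrow(b)), function(i) {
    nh <- b$n_hydrogens[i]
    if (nh == 0L) return(NULL)
    data.frame(tag = rep("H", nh), element = "H",
               mass = ELEMENT_MASS[["H"]], radius = ELEMENT_RADIUS[["H"]],
               backbone = FALSE, parent = i, hbond_role = "none",
               stringsAsFactors = FALSE)
  }))
  rbind(out, hydrogens)
}
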