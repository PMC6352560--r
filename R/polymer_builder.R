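# Polymer chain construction: labeled WDPU-like block-copolymer topologies.
#
# A chain alternates hard-segment junction blocks and polyester soft
# segments:
#
#   [N..pads..N] soft_1 [N..pads..N] soft_2 ... soft_S [N..pads..N]
#
# Every soft segment is flanked by two urethane-type nitrogen junction beads
# carrying donor roles (with an explicit polar hydrogen each); these
# nitrogens are the end-to-end markers. The hard-segment interiors are
# padded with generic CH2-like beads so the chain meets an explicit
# per-chain particle-count target (default 3070): the full hard-segment
# chemistry is not modeled, only its bookkeeping and donor geometry.

#' Composition preset for a WDPU chain
#'
#' The two shipped presets mix poly(caprolactone) (PCL) and polylactide
#' (PLA) soft segments at a 3:1 molar ratio (75% PCL); they differ only in
#' the lactide form tag (D,L vs L), which downstream generator presets map
#' to different stiffness/packing parameters.
#'
#' @param preset_name One of `"PCL75DL25"`, `"PCL75LL25"`, `"custom"`.
#' @param pcl_fraction,pla_fraction Molar fractions of the soft-segment
#'   slots; must sum to 1. Both shipped presets use 0.75/0.25.
#' @param pla_form_tag `"DL"` or `"L"`.
#' @param repeating_units_per_chain Number of repeating units (default 4).
#' @param soft_segments_per_unit Soft segments per repeating unit (default 2).
#' @param particles_per_chain Per-chain particle-count target met by padding
#'   hard segments (default 3070).
#' @param pcl_repeats_per_segment,pla_repeats_per_segment Polyester repeats
#'   per soft segment; the defaults (18 and 28) put each segment near the
#'   2000 Da molar-mass target.
#' @param chain_mode `"mixed"` (each chain carries both segment types, the
#'   default) or `"blend"` (homo-soft-segment chains blended at the chain
#'   level by [assemble_unit_cell()]).
#' @return A `composition_preset` object.
#' @export
composition_preset <- function(preset_name = c("PCL75DL25", "PCL75LL25",
                                               "custom"),
                               pcl_fraction = 0.75,
                               pla_fraction = 1 - pcl_fraction,
                               pla_form_tag = NULL,
                               repeating_units_per_chain = 4L,
                               soft_segments_per_unit = 2L,
                               particles_per_chain = 3070L,
                               pcl_repeats_per_segment = 18L,
                               pla_repeats_per_segment = 28L,
                               chain_mode = c("mixed", "blend")) {
  preset_name <- match.arg(preset_name)
  chain_mode <- match.arg(chain_mode)
  if (preset_name == "PCL75DL25") pla_form_tag <- pla_form_tag %||% "DL"
  if (preset_name == "PCL75LL25") pla_form_tag <- pla_form_tag %||% "L"
  if (preset_name != "custom" &&
      (abs(pcl_fraction - 0.75) > 1e-12 || abs(pla_fraction - 0.25) > 1e-12)) {
    stop("shipped presets fix the 3:1 PCL:PLA molar ratio", call. = FALSE)
  }
  if (abs(pcl_fraction + pla_fraction - 1) > 1e-9) {
    stop("pcl_fraction + pla_fraction must equal 1", call. = FALSE)
  }
  if (repeating_units_per_chain < 1L) {
    stop("repeating_units_per_chain must be >= 1", call. = FALSE)
  }
  structure(list(preset_name = preset_name,
                 pcl_fraction = pcl_fraction,
                 pla_fraction = pla_fraction,
                 pla_form_tag = pla_form_tag %||% "DL",
                 repeating_units_per_chain = as.integer(repeating_units_per_chain),
                 soft_segments_per_unit = as.integer(soft_segments_per_unit),
                 particles_per_chain = as.integer(particles_per_chain),
                 pcl_repeats_per_segment = as.integer(pcl_repeats_per_segment),
                 pla_repeats_per_segment = as.integer(pla_repeats_per_segment),
                 chain_mode = chain_mode),
            class = "composition_preset")
}

PAD_BEAD <- list(tag = "HSB", mass = 14.027, radius = 1.90)
N_BEAD <- list(tag = "N", mass = 14.007, radius = 1.55)
H_BEAD <- list(tag = "HN", mass = 1.008, radius = 1.20)

#' Build one labeled chain topology
#'
#' Fills the soft-segment slots of the preset 75%/25% with PCL/PLA (slot
#' positions of the minority PLA segments are drawn from the seeded stream),
#' flanks every soft segment with donor-role nitrogen junction beads, and
#' pads hard-segment interiors to meet the preset's per-chain particle
#' count. Hard-segment particles inherit the class (`hb_class`) of the soft
#' segment they precede, so every particle maps to a PCL- or PLA-class
#' segment for hydrogen-bond classification.
#'
#' @param preset A [composition_preset()].
#' @param seed Integer seed controlling PLA slot placement.
#' @param chain_id Integer chain identifier stamped on every particle.
#' @param monomers Monomer library, see [default_monomers()].
#' @return A `chain_topology`: particle table plus bonds/angles/torsions/
#'   out-of-plane index tuples and segment end markers.
#' @export
build_chain_topology <- function(preset, seed = 1L, chain_id = 1L,
                                 monomers = default_monomers()) {
  stopifnot(inherits(preset, "composition_preset"))
  n_slots <- preset$repeating_units_per_chain * preset$soft_segments_per_unit
  n_pcl <- preset$pcl_fraction * n_slots
  if (abs(n_pcl - round(n_pcl)) > 1e-9) {
    stop(sprintf(paste0("pcl_fraction %.3f is not representable in %d ",
                        "soft-segment slots (%.2f slots)"),
                 preset$pcl_fraction, n_slots, n_pcl), call. = FALSE)
  }
  n_pcl <- as.integer(round(n_pcl))
  n_pla <- n_slots - n_pcl

  slot_types <- rep("PCL", n_slots)
  if (n_pla > 0L) {
    pla_slots <- with_seed(seed, sample.int(n_slots, n_pla))
    slot_types[pla_slots] <- "PLA"
  }

  pcl_rep <- monomer_particles(monomers$PCL)
  pla_rep <- monomer_particles(monomers$PLA)
  seg_sizes <- ifelse(slot_types == "PCL",
                      nrow(pcl_rep) * preset$pcl_repeats_per_segment,
                      nrow(pla_rep) * preset$pla_repeats_per_segment)
  n_blocks <- n_slots + 1L
  hard_min <- 4L * n_blocks                  # 2 N + 2 H per block
  pads_total <- preset$particles_per_chain - sum(seg_sizes) - hard_min
  if (pads_total < 0L) {
    stop(sprintf(paste0("particles_per_chain = %d is smaller than the %d ",
                        "particles required by the soft segments and ",
                        "junctions"),
                 preset$particles_per_chain, sum(seg_sizes) + hard_min),
         call. = FALSE)
  }
  pads_per_block <- rep(pads_total %/% n_blocks, n_blocks)
  extra <- pads_total %% n_blocks
  if (extra > 0L) pads_per_block[seq_len(extra)] <- pads_per_block[seq_len(extra)] + 1L

  # assemble rows; `parent` < 0 marks a branch bead hanging from backbone
  # bead at global index abs(parent); backbone beads bond sequentially.
  rows <- vector("list", 2L * n_blocks + n_slots)
  ri <- 0L
  unit_of_slot <- ceiling(seq_len(n_slots) / preset$soft_segments_per_unit)

  hard_block <- function(k) {
    npad <- pads_per_block[k + 1L]
    class_slot <- min(k + 1L, n_slots)
    hbc <- slot_types[class_slot]
    unit <- unit_of_slot[class_slot]
    tag <- c(N_BEAD$tag, H_BEAD$tag, rep(PAD_BEAD$tag, npad),
             N_BEAD$tag, H_BEAD$tag)
    data.frame(
      tag = tag,
      mass = c(N_BEAD$mass, H_BEAD$mass, rep(PAD_BEAD$mass, npad),
               N_BEAD$mass, H_BEAD$mass),
      radius = c(N_BEAD$radius, H_BEAD$radius, rep(PAD_BEAD$radius, npad),
                 N_BEAD$radius, H_BEAD$radius),
      unit_index = unit,
      segment_type = "HARD",
      hb_class = hbc,
      hbond_role = c("donor_heavy", "donor_hydrogen", rep("none", npad),
                     "donor_heavy", "donor_hydrogen"),
      backbone = c(TRUE, FALSE, rep(TRUE, npad), TRUE, FALSE),
      branch_off = c(0L, -1L, rep(0L, npad), 0L, -1L),
      stringsAsFactors = FALSE)
  }

  soft_block <- function(s) {
    rep_tmpl <- if (slot_types[s] == "PCL") pcl_rep else pla_rep
    nrep <- if (slot_types[s] == "PCL") preset$pcl_repeats_per_segment else
      preset$pla_repeats_per_segment
    one <- data.frame(
      tag = rep_tmpl$tag, mass = rep_tmpl$mass, radius = rep_tmpl$radius,
      unit_index = unit_of_slot[s], segment_type = slot_types[s],
      hb_class = slot_types[s], hbond_role = rep_tmpl$hbond_role,
      backbone = rep_tmpl$backbone,
      # offset (in rows) back to the backbone parent within the repeat
      branch_off = ifelse(is.na(rep_tmpl$parent), 0L,
                          rep_tmpl$parent - seq_len(nrow(rep_tmpl))),
      stringsAsFactors = FALSE)
    one[rep(seq_len(nrow(one)), nrep), , drop = FALSE]
  }

  for (k in 0:n_slots) {
    ri <- ri + 1L
    rows[[ri]] <- hard_block(k)
    if (k < n_slots) {
      ri <- ri + 1L
      rows[[ri]] <- soft_block(k + 1L)
    }
  }
  particles <- do.call(rbind, rows[seq_len(ri)])
  rownames(particles) <- NULL
  n <- nrow(particles)
  particles$id <- seq_len(n)
  particles$charge <- 0
  particles$chain_id <- as.integer(chain_id)
  particles$element <- NULL

  # bonds: successive backbone beads, plus branch beads to their parents
  bb <- which(particles$backbone)
  bonds_bb <- cbind(bb[-length(bb)], bb[-1L])
  br <- which(particles$branch_off != 0L)
  bonds_br <- cbind(br + particles$branch_off[br], br)
  bonds <- rbind(bonds_bb, bonds_br)
  particles$branch_off <- NULL

  terms <- derive_bonded_terms(bonds, n)

  # segment markers: nitrogens flanking each soft slot, plus whole chain
  n_idx <- which(particles$tag == "N")
  # nitrogens come in per-block pairs: block k contributes n_idx[2k+1], n_idx[2k+2]
  seg_markers <- data.frame(
    chain_id = as.integer(chain_id),
    scope = c("chain", rep("segment", n_slots)),
    segment_type = c("ALL", slot_types),
    start = c(n_idx[1L], n_idx[2L * seq_len(n_slots)]),
    end = c(n_idx[length(n_idx)], n_idx[2L * seq_len(n_slots) + 1L]),
    stringsAsFactors = FALSE)

  structure(list(
    particles = particles[, c("id", "tag", "mass", "radius", "charge",
                              "chain_id", "unit_index", "segment_type",
                              "hb_class", "hbond_role", "backbone")],
    bonds = int_tuples(bonds, 2L),
    angles = terms$angles,
    torsions = terms$torsions,
    out_of_plane = terms$out_of_plane,
    segment_markers = seg_markers,
    preset = preset,
    slot_types = slot_types,
    seed = as.integer(seed)
  ), class = "chain_topology")
}

# Enumerate angles, torsions and out-of-plane tuples from a bond list.
derive_bonded_terms <- function(bonds, n) {
  nb <- split(c(bonds[, 2L], bonds[, 1L]), c(bonds[, 1L], bonds[, 2L]))
  deg_atoms <- as.integer(names(nb))
  angles <- list(); torsions <- list(); oop <- list()
  ai <- 0L; oi <- 0L
  for (j in deg_atoms) {
    nbs <- nb[[as.character(j)]]
    if (length(nbs) >= 2L) {
      cmb <- utils::combn(sort(nbs), 2L)
      ai <- ai + 1L
      angles[[ai]] <- cbind(cmb[1L, ], j, cmb[2L, ])
    }
    if (length(nbs) == 3L) {
      oi <- oi + 1L
      s <- sort(nbs)
      oop[[oi]] <- matrix(c(s[1L], j, s[2L], s[3L]), 1L, 4L)
    }
  }
  ti <- 0L
  for (r in seq_len(nrow(bonds))) {
    j <- bonds[r, 1L]; k <- bonds[r, 2L]
    js <- setdiff(nb[[as.character(j)]], k)
    ks <- setdiff(nb[[as.character(k)]], j)
    if (length(js) && length(ks)) {
      grid <- expand.grid(i = js, l = ks)
      grid <- grid[grid$i != grid$l, , drop = FALSE]
      if (nrow(grid)) {
        ti <- ti + 1L
        torsions[[ti]] <- cbind(grid$i, j, k, grid$l)
      }
    }
  }
  list(angles = int_tuples(do.call(rbind, angles), 3L),
       torsions = int_tuples(do.call(rbind, torsions), 4L),
       out_of_plane = int_tuples(do.call(rbind, oop), 4L))
}

#' @export
print.chain_topology <- function(x, ...) {
  cat(sprintf("chain_topology (%s): %d particles, %.1f Da\n",
              x$preset$preset_name, nrow(x$particles), total_mass(x)))
  cat("  soft-segment slots:", paste(x$slot_types, collapse = " "), "\n")
  invisible(x)
}

#' Count particles in a chain topology
#'
#' @param chain A `chain_topology` (or any object with a `particles` table).
#' @return Integer particle count, with the total mass (Da) attached as
#'   attribute `"total_mass"`.
#' @export
count_particles <- function(chain) {
  n <- nrow(chain$particles)
  structure(as.integer(n), total_mass = sum(chain$particles$mass))
}

#' Assemble chain topologies into one (coordinate-less) system
#'
#' Concatenates `n_chains` chains with uniquely remapped chain ids and
#' index tuples; coordinates are left unset for the generator to fill.
#'
#' @param chains A single `chain_topology` or a list of them. A single
#'   chain is replicated `n_chains` times.
#' @param n_chains Number of chains in the cell (default: length of the list).
#' @return A `particle_system` without coordinates.
#' @export
assemble_unit_cell <- function(chains, n_chains = NULL) {
  if (inherits(chains, "chain_topology")) chains <- list(chains)
  if (is.null(n_chains)) n_chains <- length(chains)
  if (n_chains < 1L) stop("n_chains must be >= 1", call. = FALSE)
  if (length(chains) == 1L && n_chains > 1L) {
    chains <- rep(chains, n_chains)
  }
  if (length(chains) != n_chains) {
    stop("length(chains) must be 1 or n_chains", call. = FALSE)
  }
  offset <- 0L
  parts <- vector("list", n_chains)
  bonds <- vector("list", n_chains); angles <- vector("list", n_chains)
  tors <- vector("list", n_chains); oops <- vector("list", n_chains)
  markers <- vector("list", n_chains)
  for (i in seq_len(n_chains)) {
    ch <- chains[[i]]
    p <- ch$particles
    p$id <- p$id + offset
    p$chain_id <- i
    parts[[i]] <- p
    bonds[[i]] <- ch$bonds + offset
    angles[[i]] <- ch$angles + offset
    tors[[i]] <- ch$torsions + offset
    oops[[i]] <- ch$out_of_plane + offset
    m <- ch$segment_markers
    m$chain_id <- i
    m$start <- m$start + offset
    m$end <- m$end + offset
    markers[[i]] <- m
    offset <- offset + nrow(p)
  }
  particle_system(
    particles = do.call(rbind, parts),
    bonds = do.call(rbind, bonds),
    angles = do.call(rbind, angles),
    torsions = do.call(rbind, tors),
    out_of_plane = do.call(rbind, oops),
    segment_markers = do.call(rbind, markers))
}

#' Replicate a cell along the three axes
#'
#' Tiles the system `nx` x `ny` x `nz` times using its box vectors; chain
#' ids are remapped uniquely and all labels preserved.
#'
#' @param system A `particle_system` with a `box`.
#' @param nx,ny,nz Positive replication counts.
#' @return The replicated `particle_system`.
#' @export
replicate_cell <- function(system, nx = 1L, ny = 1L, nz = 1L) {
  stopifnot(inherits(system, "particle_system"))
  if (any(c(nx, ny, nz) < 1L)) stop("replication counts must be >= 1",
                                    call. = FALSE)
  if (is.null(system$box)) {
    stop("system has no bounding box; set `box` before replicating",
         call. = FALSE)
  }
  images <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L,
                        iz = seq_len(nz) - 1L)
  n_img <- nrow(images)
  if (n_img == 1L) return(system)
  n <- nrow(system$particles)
  n_chain <- length(unique(system$particles$chain_id))
  parts <- vector("list", n_img); coords <- vector("list", n_img)
  bonds <- vector("list", n_img); angles <- vector("list", n_img)
  tors <- vector("list", n_img); oops <- vector("list", n_img)
  markers <- vector("list", n_img)
  for (g in seq_len(n_img)) {
    off <- (g - 1L) * n
    p <- system$particles
    p$id <- p$id + off
    p$chain_id <- p$chain_id + (g - 1L) * n_chain
    parts[[g]] <- p
    if (!is.null(system$coords)) {
      shift <- c(images$ix[g], images$iy[g], images$iz[g]) * system$box
      coords[[g]] <- sweep(system$coords, 2, shift, `+`)
    }
    bonds[[g]] <- system$bonds + off
    angles[[g]] <- system$angles + off
    tors[[g]] <- system$torsions + off
    oops[[g]] <- system$out_of_plane + off
    if (!is.null(system$segment_markers)) {
      m <- system$segment_markers
      m$chain_id <- m$chain_id + (g - 1L) * n_chain
      m$start <- m$start + off
      m$end <- m$end + off
      markers[[g]] <- m
    }
  }
  particle_system(
    particles = do.call(rbind, parts),
    coords = if (is.null(system$coords)) NULL else do.call(rbind, coords),
    bonds = do.call(rbind, bonds),
    angles = do.call(rbind, angles),
    torsions = do.call(rbind, tors),
    out_of_plane = do.call(rbind, oops),
    segment_markers = if (is.null(system$segment_markers)) NULL else
      do.call(rbind, markers),
    box = system$box * c(nx, ny, nz))
}
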