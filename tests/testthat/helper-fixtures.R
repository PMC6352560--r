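# Shared fixtures: small chains, bare point-cloud systems, toy presets.

# A bare labeled system from a coordinate matrix (single chain, all-PCL).
point_system <- function(coords, mass = 12, radius = 1.7, chain_id = 1L,
                         tag = "C") {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  particle_system(
    data.frame(id = seq_len(n), tag = tag, mass = mass, radius = radius,
               charge = 0, chain_id = as.integer(chain_id), unit_index = 1L,
               segment_type = "PCL", hb_class = "PCL", hbond_role = "none",
               backbone = TRUE),
    coords)
}

# Small custom preset: 2 soft slots (1 PCL + 1 PLA), tiny segments.
tiny_preset <- function(particles_per_chain = 40L) {
  composition_preset("custom", pcl_fraction = 0.5,
                     repeating_units_per_chain = 1L,
                     soft_segments_per_unit = 2L,
                     particles_per_chain = particles_per_chain,
                     pcl_repeats_per_segment = 1L,
                     pla_repeats_per_segment = 2L)
}

# Mid-sized 75/25 preset used for generator tests (fast but realistic).
small_wdpu_preset <- function(particles_per_chain = 300L) {
  composition_preset("custom", pcl_fraction = 0.75,
                     repeating_units_per_chain = 2L,
                     soft_segments_per_unit = 2L,
                     particles_per_chain = particles_per_chain,
                     pcl_repeats_per_segment = 3L,
                     pla_repeats_per_segment = 4L)
}

# Random labeled donor/acceptor soup for H-bond detector tests: n_donor
# N-H pairs and n_acc acceptor oxygens scattered in a box of edge `edge`.
random_hbond_system <- function(seed, n_donor = 30L, n_acc = 60L,
                                edge = 18) {
  set.seed(seed)
  n <- 2L * n_donor + n_acc
  role <- c(rep(c("donor_heavy", "donor_hydrogen"), n_donor),
            rep("acceptor", n_acc))
  tagv <- c(rep(c("N", "HN"), n_donor), rep("O_carb", n_acc))
  coords <- matrix(runif(3L * n, 0, edge), n, 3L)
  # hydrogens sit 1 A from their donor
  for (k in seq_len(n_donor)) {
    i_d <- 2L * k - 1L
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    coords[2L * k, ] <- coords[i_d, ] + u
  }
  bonds <- cbind(seq(1L, 2L * n_donor, by = 2L), seq(2L, 2L * n_donor, by = 2L))
  particle_system(
    data.frame(id = seq_len(n), tag = tagv, mass = 14, radius = 1.5,
               charge = 0,
               chain_id = rep(seq_len(max(1L, n %/% 20L)), length.out = n),
               unit_index = 1L, segment_type = "HARD",
               hb_class = sample(c("PCL", "PLA"), n, replace = TRUE),
               hbond_role = role, backbone = TRUE),
    coords, bonds = bonds)
}

# A small perturbed chain system exercising every bonded CVFF term type.
cvff_test_system <- function(seed, jitter = 0.05,
                             particles_per_chain = 31L) {
  pre <- tiny_preset(particles_per_chain)
  ch <- build_chain_topology(pre, seed = seed)
  sys <- assemble_unit_cell(ch, 1)
  co <- sample_chain_conformation(ch, persistence = 0.3, seed = seed + 1L)
  set.seed(seed + 2L)
  sys$coords <- unclass(co) + matrix(rnorm(3 * nrow(ch$particles),
                                           sd = jitter), ncol = 3)
  sys
}

# Rigid rotation + translation applied to a system.
rigid_move <- function(system, seed = 1L) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  rot <- wdpunano:::rotation_about(ax, runif(1, 0, 2 * pi))
  transform_system(system, rotation = rot, translation = rnorm(3, sd = 20))
}
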