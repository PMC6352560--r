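# Synthetic nanoparticle generator: seeded assemblies with controllable
# size, radial density profile, shape anisotropy, chain stiffness, and
# planted hydrogen-bond geometries.
#
# Chains are placed rigidly (rotation + translation only), so per-chain
# end-to-end distances calibrated at the sampler level survive packing
# exactly. Chain centers are laid out by stratified (quantile) radii drawn
# from the target radial mass profile along quasi-uniform (Fibonacci)
# directions under a seeded random global rotation: ensembles of this kind
# report very small replicate-to-replicate dispersion, and the stratified
# layout reproduces that while keeping every coordinate seed-reproducible.

#' Generator configuration
#'
#' @param seed Integer master seed; every random draw in the generator
#'   derives from it.
#' @param n_chains Number of chains in the assembly (default 10).
#' @param preset A [composition_preset()].
#' @param bond_length Backbone bond length in Angstrom.
#' @param persistence Chain persistence parameter c in `[-1, 1]`
#'   (see [sample_chain_conformation()]).
#' @param density_profile Named vector `c(core_density=, core_radius=,
#'   decay_radius=)`: a plateau at `core_density` (Da/A^3) out to
#'   `core_radius`, decaying linearly to zero at `decay_radius` (Angstrom).
#' @param anisotropy Per-axis scale factors applied to final coordinates.
#' @param planted_hbonds List `(count, d_DA, angle)`: donor-H-acceptor
#'   triads repositioned to satisfy the geometric criterion.
#' @param decoy_hbonds List `(count, mode)` with `mode` one of
#'   `"distance"`, `"angle"`, `"both_alternating"`: near-miss triads
#'   violating exactly one criterion each.
#' @param end_to_end_rel_sd Relative sd of the targeted per-chain
#'   end-to-end draw.
#' @param sampler_mode `"targeted"` or `"free"` chain sampling.
#' @param min_separation Soft excluded-volume distance for the chain walk
#'   (Angstrom; 0 disables).
#' @param hbond_d_cut,hbond_angle_cut Detection cutoffs the planted
#'   geometries must respect (Angstrom, degrees).
#' @return A `generator_config` object.
#' @export
generator_config <- function(seed = 1L,
                             n_chains = 10L,
                             preset = composition_preset("PCL75DL25"),
                             bond_length = 1.5,
                             persistence = 0,
                             density_profile = c(core_density = 0.05,
                                                 core_radius = 50,
                                                 decay_radius = 115),
                             anisotropy = c(1, 1, 1),
                             planted_hbonds = list(count = 0L, d_DA = 2.8,
                                                   angle = 10),
                             decoy_hbonds = list(count = 0L,
                                                 mode = "distance"),
                             end_to_end_rel_sd = 0.002,
                             sampler_mode = "targeted",
                             min_separation = 0,
                             hbond_d_cut = 3.0,
                             hbond_angle_cut = 30) {
  dp <- density_profile
  if (!all(c("core_density", "core_radius", "decay_radius") %in% names(dp))) {
    stop("density_profile needs core_density, core_radius, decay_radius",
         call. = FALSE)
  }
  if (dp[["core_radius"]] >= dp[["decay_radius"]]) {
    stop("core_radius must be smaller than decay_radius", call. = FALSE)
  }
  if (any(anisotropy <= 0)) stop("anisotropy factors must be > 0",
                                 call. = FALSE)
  if (planted_hbonds$count > 0) {
    if (planted_hbonds$d_DA > hbond_d_cut ||
        planted_hbonds$angle > hbond_angle_cut) {
      stop("planted geometries must satisfy the detection cutoffs",
           call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_chains = as.integer(n_chains),
                 preset = preset, bond_length = bond_length,
                 persistence = persistence, density_profile = dp,
                 anisotropy = anisotropy, planted_hbonds = planted_hbonds,
                 decoy_hbonds = decoy_hbonds,
                 end_to_end_rel_sd = end_to_end_rel_sd,
                 sampler_mode = sampler_mode,
                 min_separation = min_separation,
                 hbond_d_cut = hbond_d_cut,
                 hbond_angle_cut = hbond_angle_cut),
            class = "generator_config")
}

# Target radial mass profile: plateau then linear decay to zero.
profile_density <- function(r, dp) {
  rho0 <- dp[["core_density"]]; a <- dp[["core_radius"]]
  b <- dp[["decay_radius"]]
  ifelse(r <= a, rho0, ifelse(r >= b, 0, rho0 * (b - r) / (b - a)))
}

# Quantile radii of the mass distribution implied by the profile.
profile_quantile_radii <- function(q, dp, r_cap = Inf) {
  b <- min(dp[["decay_radius"]], r_cap)
  grid <- seq(0, b, length.out = 2048L)
  w <- profile_density(grid, dp) * grid^2
  cw <- cumsum(w)
  if (cw[length(cw)] <= 0) return(rep(0, length(q)))
  cw <- cw / cw[length(cw)]
  stats::approx(cw, grid, xout = q, rule = 2, ties = "ordered")$y
}

# Analytic radius of gyration of the target profile (mass-weighted).
profile_rg <- function(dp) {
  grid <- seq(0, dp[["decay_radius"]], length.out = 4096L)
  w <- profile_density(grid, dp) * grid^2
  sqrt(sum(w * grid^2) / sum(w))
}

#' Pack chains into a nanoparticle assembly
#'
#' Samples one conformation per chain, then places chains rigidly with
#' stratified radial centers matching the target density profile and
#' quasi-uniform directions; anisotropy is applied as a final per-axis
#' scaling. Errors if the requested profile would exceed random close
#' packing of the beads.
#'
#' @param chains A `chain_topology` or list of them (recycled to
#'   `config$n_chains`).
#' @param config A [generator_config()].
#' @return An `assembly`: list with `system` (a `particle_system`),
#'   `provenance` (the config) and `ground_truth` (per-chain end-to-end
#'   distances as planted, the analytic profile Rg, and any planted
#'   hydrogen bonds).
#' @export
pack_assembly <- function(chains, config) {
  stopifnot(inherits(config, "generator_config"))
  system <- assemble_unit_cell(chains, config$n_chains)
  n_chains <- config$n_chains
  dp <- config$density_profile

  # feasibility: beads at random close packing inside the profile volume
  vol_beads <- sum((4 / 3) * pi * system$particles$radius^3)
  vol_profile <- (4 / 3) * pi * dp[["decay_radius"]]^3
  if (vol_beads > 0.64 * vol_profile) {
    stop(sprintf(paste0("infeasible density: bead volume %.3g A^3 exceeds ",
                        "close packing of the %.3g A^3 profile volume"),
                 vol_beads, vol_profile), call. = FALSE)
  }

  chain_rows <- split(seq_len(nrow(system$particles)),
                      system$particles$chain_id)
  topo_list <- if (inherits(chains, "chain_topology")) {
    rep(list(chains), n_chains)
  } else if (length(chains) == 1L) rep(chains, n_chains) else chains

  confs <- vector("list", n_chains)
  e2e_truth <- numeric(n_chains)
  for (i in seq_len(n_chains)) {
    confs[[i]] <- sample_chain_conformation(
      topo_list[[i]], persistence = config$persistence,
      seed = child_seed(config$seed, i),
      bond_length = config$bond_length,
      mode = config$sampler_mode,
      end_to_end_rel_sd = config$end_to_end_rel_sd,
      min_separation = config$min_separation)
    e2e_truth[i] <- attr(confs[[i]], "end_to_end")
  }

  coords <- matrix(NA_real_, nrow(system$particles), 3L)
  with_seed(child_seed(config$seed, 0L), {
    # chain extents (max distance from chain COM) decide radial capping
    extents <- numeric(n_chains)
    centered <- vector("list", n_chains)
    for (i in seq_len(n_chains)) {
      xyz <- confs[[i]]
      m <- topo_list[[i]]$particles$mass
      com <- colSums(xyz * m) / sum(m)
      xyz <- sweep(xyz, 2, com)
      centered[[i]] <- xyz
      extents[i] <- max(row_norms(xyz))
    }
    q <- (seq_len(n_chains) - 0.5) / n_chains
    radii <- profile_quantile_radii(q, dp)
    # largest chains to the smallest radii, then cap inside the profile
    ord <- order(extents, decreasing = TRUE)
    assign_r <- numeric(n_chains)
    assign_r[ord] <- sort(radii)
    assign_r <- pmin(assign_r,
                     pmax(0, dp[["decay_radius"]] - 0.55 * extents))
    dirs <- fibonacci_sphere(n_chains) %*% t(random_rotation())
    dirs <- dirs[sample.int(n_chains), , drop = FALSE]
    for (i in seq_len(n_chains)) {
      rot <- random_rotation()
      placed <- centered[[i]] %*% t(rot)
      placed <- sweep(placed, 2, assign_r[i] * dirs[i, ], `+`)
      coords[chain_rows[[as.character(i)]], ] <- placed
    }
  })

  if (!all(config$anisotropy == 1)) {
    coords <- sweep(coords, 2, config$anisotropy, `*`)
  }
  # center on the COM and set a bounding box
  m_all <- system$particles$mass
  coords <- sweep(coords, 2, colSums(coords * m_all) / sum(m_all))
  system$coords <- coords
  system$box <- apply(coords, 2, function(v) diff(range(v))) + 4

  assembly <- structure(list(
    system = system,
    provenance = config,
    ground_truth = list(end_to_end = e2e_truth,
                        profile_rg = profile_rg(dp),
                        planted_hbonds = NULL,
                        decoy_hbonds = NULL)
  ), class = "assembly")
  if (config$planted_hbonds$count > 0 || config$decoy_hbonds$count > 0) {
    assembly <- plant_hbond_geometries(
      assembly, config$planted_hbonds, config$decoy_hbonds,
      seed = child_seed(config$seed, 9999L),
      d_cut = config$hbond_d_cut, angle_cut = config$hbond_angle_cut)
  }
  assembly
}

#' @export
print.assembly <- function(x, ...) {
  cat("nanoparticle assembly\n")
  print(x$system)
  gt <- x$ground_truth
  cat(sprintf("  ground truth: %d chain end-to-end value(s), %s planted H-bond(s)\n",
              length(gt$end_to_end),
              if (is.null(gt$planted_hbonds)) "0" else nrow(gt$planted_hbonds)))
  invisible(x)
}

#' Plant hydrogen-bond geometries into an assembly
#'
#' Repositions `planted$count` donor-H-acceptor triads so each satisfies
#' the geometric criterion, plants `decoys$count` near-miss triads that
#' violate exactly one criterion, and then displaces any remaining
#' accidental donor/acceptor contacts so the detected set equals the
#' planted set exactly. Ground truth is recorded as bookkeeping, not
#' re-measured.
#'
#' @param assembly An `assembly` with coordinates.
#' @param planted List `(count, d_DA, angle)`; `d_DA` in Angstrom, `angle`
#'   the deviation of D-H...A from linearity in degrees.
#' @param decoys List `(count, mode)` with mode `"distance"`, `"angle"` or
#'   `"both_alternating"`.
#' @param seed Integer seed.
#' @param d_cut,angle_cut Detection cutoffs.
#' @return The assembly with updated coordinates and ground truth.
#' @export
plant_hbond_geometries <- function(assembly,
                                   planted = list(count = 0L, d_DA = 2.8,
                                                  angle = 10),
                                   decoys = list(count = 0L,
                                                 mode = "distance"),
                                   seed = 1L, d_cut = 3.0, angle_cut = 30) {
  stopifnot(inherits(assembly, "assembly"))
  system <- assembly$system
  stopifnot_coords(system)
  p <- system$particles
  n_plant <- planted$count %||% 0L
  n_decoy <- decoys$count %||% 0L

  dh <- donor_hydrogen_map(system)
  donors <- dh$donor
  acceptors <- which(p$hbond_role == "acceptor")
  if (length(donors) < n_plant + n_decoy) {
    stop(sprintf("need %d donor sites but only %d are labeled",
                 n_plant + n_decoy, length(donors)), call. = FALSE)
  }
  if (length(acceptors) < n_plant + n_decoy) {
    stop(sprintf("need %d acceptor sites but only %d are labeled",
                 n_plant + n_decoy, length(acceptors)), call. = FALSE)
  }

  with_seed(seed, {
    pick_d <- sample(seq_along(donors), n_plant + n_decoy)
    pick_a <- sample(seq_along(acceptors), n_plant + n_decoy)
    sel_d <- donors[pick_d]; sel_h <- dh$hydrogen[pick_d]
    sel_a <- acceptors[pick_a]

    place_triad <- function(i_d, i_h, i_a, d_da, dev_deg) {
      # keep the donor; move its hydrogen and the acceptor so that
      # |DA| = d_da and the D-H...A deviation from linearity is dev_deg
      u <- unit(stats::rnorm(3))          # D -> H direction
      system$coords[i_h, ] <<- system$coords[i_d, ] + 1.01 * u
      dev <- dev_deg * pi / 180
      cosd <- cos(dev)
      t_ <- -1.01 * cosd + sqrt((1.01 * cosd)^2 - 1.01^2 + d_da^2)
      e1 <- perp_unit(u)
      ha <- cos(dev) * u + sin(dev) * e1   # angle dev away from D->H dir
      system$coords[i_a, ] <<- system$coords[i_h, ] + t_ * ha
    }

    truth_rows <- vector("list", n_plant)
    for (k in seq_len(n_plant)) {
      place_triad(sel_d[k], sel_h[k], sel_a[k], planted$d_DA, planted$angle)
      truth_rows[[k]] <- data.frame(
        donor_id = p$id[sel_d[k]], hydrogen_id = p$id[sel_h[k]],
        acceptor_id = p$id[sel_a[k]],
        d_DA = planted$d_DA, angle = planted$angle)
    }
    decoy_rows <- vector("list", n_decoy)
    for (k in seq_len(n_decoy)) {
      j <- n_plant + k
      mode_k <- if (identical(decoys$mode, "both_alternating")) {
        if (k %% 2L == 1L) "distance" else "angle"
      } else decoys$mode
      if (mode_k == "distance") {
        d_da <- d_cut * 1.05; dev <- 0
      } else {
        d_da <- planted$d_DA %||% 2.8; dev <- angle_cut * 1.25
      }
      place_triad(sel_d[j], sel_h[j], sel_a[j], d_da, dev)
      decoy_rows[[k]] <- data.frame(
        donor_id = p$id[sel_d[j]], hydrogen_id = p$id[sel_h[j]],
        acceptor_id = p$id[sel_a[j]],
        d_DA = d_da, angle = dev, violates = mode_k)
    }
    truth <- if (n_plant) do.call(rbind, truth_rows) else NULL
    decoy_truth <- if (n_decoy) do.call(rbind, decoy_rows) else NULL

    # sterilize: break accidental contacts until detection == planted set
    planted_keys <- if (n_plant) {
      paste(truth$donor_id, truth$hydrogen_id, truth$acceptor_id)
    } else character(0)
    triad_acceptors <- p$id[sel_a]
    for (iter in seq_len(40L)) {
      det <- detect_hbonds(system, d_cut = d_cut, angle_cut = angle_cut,
                           classify = FALSE)
      det_keys <- if (nrow(det)) {
        paste(det$donor_id, det$hydrogen_id, det$acceptor_id)
      } else character(0)
      extra <- det[!(det_keys %in% planted_keys), , drop = FALSE]
      if (!nrow(extra) && setequal(det_keys, planted_keys)) break
      if (!nrow(extra)) {
        stop("planted hydrogen bond lost during sterilization", call. = FALSE)
      }
      for (r in seq_len(nrow(extra))) {
        i_a <- match_ids(system, extra$acceptor_id[r])
        i_d <- match_ids(system, extra$donor_id[r])
        if (extra$acceptor_id[r] %in% triad_acceptors) {
          # acceptor belongs to a triad: re-azimuth that whole triad
          j <- match(extra$acceptor_id[r], p$id[sel_a])
          geom <- if (j <= n_plant) {
            list(d = planted$d_DA, a = planted$angle)
          } else {
            dr <- decoy_rows[[j - n_plant]]
            list(d = dr$d_DA, a = dr$angle)
          }
          place_triad(sel_d[j], sel_h[j], sel_a[j], geom$d, geom$a)
        } else {
          # free acceptor: push it radially away from the donor
          away <- system$coords[i_a, ] - system$coords[i_d, ]
          away <- if (vnorm(away) < 1e-9) unit(stats::rnorm(3)) else unit(away)
          system$coords[i_a, ] <- system$coords[i_d, ] +
            away * (d_cut * 1.3 + stats::runif(1L, 0, 0.5))
        }
      }
      if (iter == 40L) {
        stop("could not sterilize accidental hydrogen-bond contacts",
             call. = FALSE)
      }
    }
    assembly$system <- system
    assembly$ground_truth$planted_hbonds <- truth
    assembly$ground_truth$decoy_hbonds <- decoy_truth
  })
  assembly
}

#' Generate a complete assembly from a configuration
#'
#' Convenience wrapper: builds the chain topology from the preset, packs
#' the assembly, and plants hydrogen bonds if configured.
#'
#' @param config A [generator_config()].
#' @return An `assembly`.
#' @export
generate_assembly <- function(config) {
  chain <- build_chain_topology(config$preset, seed = config$seed)
  pack_assembly(chain, config)
}

#' Calibrate a generator preset to a target statistic
#'
#' Tunes the monotone control parameter (persistence for the mean chain
#' end-to-end distance, the density-profile radial scale for the assembly
#' radius of gyration) by bracketed secant iteration until generated
#' ensembles reproduce the target within tolerance, measuring each iterate
#' with the descriptor code over `n_seeds` seeded replicates.
#'
#' @param target_stat `"mean_end_to_end"` or `"rg"`.
#' @param target_value Target in Angstrom.
#' @param config Starting [generator_config()].
#' @param tolerance Relative tolerance on the achieved mean (default 0.005).
#' @param max_iter Maximum secant iterations.
#' @param n_seeds Replicates per measurement (default 5).
#' @return The calibrated `generator_config`, with attributes
#'   `achieved` (measured mean), `iterations` and `measurements`.
#' @export
calibrate_preset <- function(target_stat = c("mean_end_to_end", "rg"),
                             target_value, config, tolerance = 0.005,
                             max_iter = 20L, n_seeds = 5L) {
  target_stat <- match.arg(target_stat)
  stopifnot(target_value > 0)
  chain <- build_chain_topology(config$preset, seed = config$seed)
  n_bonds <- sum(chain$particles$backbone) - 1L

  if (target_stat == "mean_end_to_end") {
    lo <- -0.985; hi <- 0.99995
    r_lo <- mean_end_to_end(n_bonds, config$bond_length, lo)
    r_hi <- mean_end_to_end(n_bonds, config$bond_length, hi)
    if (target_value < r_lo || target_value > r_hi) {
      stop(sprintf(paste0("target %.2f A outside the achievable end-to-end ",
                          "range [%.2f, %.2f] A (collapsed globule to ",
                          "rigid rod)"), target_value, r_lo, r_hi),
           call. = FALSE)
    }
    measure <- function(c_) {
      cfg <- config; cfg$persistence <- c_
      vals <- vapply(seq_len(n_seeds), function(s) {
        mean(vapply(seq_len(config$n_chains), function(i) {
          conf <- sample_chain_conformation(
            chain, persistence = c_,
            seed = child_seed(child_seed(config$seed, 100L + s), i),
            bond_length = cfg$bond_length, mode = cfg$sampler_mode,
            end_to_end_rel_sd = cfg$end_to_end_rel_sd,
            min_separation = cfg$min_separation)
          attr(conf, "end_to_end")
        }, numeric(1L)))
      }, numeric(1L))
      mean(vals)
    }
    # closed-form inversion as the first iterate
    f <- function(c_) mean_end_to_end(n_bonds, config$bond_length, c_) -
      target_value
    x0 <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    set_par <- function(cfg, x) { cfg$persistence <- x; cfg }
    bounds <- c(lo, hi)
  } else {
    measure <- function(s_) {
      cfg <- scale_profile(config, s_)
      vals <- vapply(seq_len(n_seeds), function(s) {
        cfg_s <- cfg; cfg_s$seed <- child_seed(config$seed, 200L + s)
        asm <- pack_assembly(chain, cfg_s)
        radius_of_gyration(asm$system)
      }, numeric(1L))
      mean(vals)
    }
    x0 <- 1
    set_par <- function(cfg, x) scale_profile(cfg, x)
    bounds <- c(0.02, 50)
  }

  history <- data.frame(x = numeric(0), value = numeric(0))
  x1 <- x0
  y1 <- measure(x1)
  history <- rbind(history, data.frame(x = x1, value = y1))
  if (abs(y1 - target_value) <= tolerance * target_value) {
    out <- set_par(config, x1)
    attr(out, "achieved") <- y1
    attr(out, "iterations") <- 1L
    attr(out, "measurements") <- history
    return(out)
  }
  # second iterate: proportional correction, then secant
  x2 <- if (target_stat == "rg") {
    min(max(x1 * target_value / y1, bounds[1]), bounds[2])
  } else {
    f2 <- function(c_) mean_end_to_end(n_bonds, config$bond_length, c_) -
      target_value * (mean_end_to_end(n_bonds, config$bond_length, x1) / y1)
    tryCatch(stats::uniroot(f2, bounds, tol = 1e-10)$root,
             error = function(e) (x1 + bounds[2]) / 2)
  }
  for (it in 2:max_iter) {
    y2 <- measure(x2)
    history <- rbind(history, data.frame(x = x2, value = y2))
    if (abs(y2 - target_value) <= tolerance * target_value) {
      out <- set_par(config, x2)
      attr(out, "achieved") <- y2
      attr(out, "iterations") <- it
      attr(out, "measurements") <- history
      return(out)
    }
    if (abs(y2 - y1) < 1e-12) break
    x_new <- x2 + (target_value - y2) * (x2 - x1) / (y2 - y1)
    x_new <- min(max(x_new, bounds[1]), bounds[2])
    x1 <- x2; y1 <- y2; x2 <- x_new
  }
  stop(sprintf(paste0("calibration did not reach %.3f within %.1f%% in %d ",
                      "iterations (best %.3f)"), target_value,
               100 * tolerance, max_iter,
               history$value[which.min(abs(history$value - target_value))]),
       call. = FALSE)
}

scale_profile <- function(config, s) {
  dp <- config$density_profile
  dp[["core_radius"]] <- dp[["core_radius"]] * s
  dp[["decay_radius"]] <- dp[["decay_radius"]] * s
  config$density_profile <- dp
  config
}
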