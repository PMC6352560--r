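# Consistent valence force field (CVFF) evaluation over user-supplied
# parameter tables.
#
# Potential terms:
#   bond          Morse          D_b (1 - exp(-alpha (b - b0)))^2
#   angle         harmonic       H_t (theta - theta0)^2
#   torsion       cosine         H_p (1 + s cos(n phi))
#   out-of-plane  Wilson angle   H_x chi^2
#   cross         F_bb' (b-b0)(b'-b0'), F_tt' (t-t0)(t'-t0'),
#                 F_bt (b-b0)(t-t0), F_ptt' cos(phi) (t-t0)(t'-t0'),
#                 F_xx' chi chi'
#   nonbonded     LJ  eps ((r*/r)^12 - 2 (r*/r)^6)  and
#                 Coulomb  C q_i q_j / (eps_r r)
#
# Parameter VALUES are not shipped (a deliberately non-physical toy table
# is bundled for tests; see toy_ff_params()). Nonbonded exclusions follow
# the CVFF-era convention: 1-2 and 1-3 excluded, 1-4 included at full
# weight. Cross-term pairings: bond-bond and bond-angle within each angle;
# angle-angle over angle pairs sharing a central atom; torsion with its two
# flanking angles; out-of-plane pairs whose central atoms are bonded.

COULOMB_K <- 332.0637  # kcal A / (mol e^2)

#' Construct a CVFF parameter set
#'
#' Each table is a data.frame whose type columns (`i`, `j`, ...) match
#' particle tags; `"*"` is a wildcard. More specific entries (fewer
#' wildcards) win.
#'
#' @param bonds data.frame `i, j, D, alpha, b0` (kcal/mol, 1/A, A).
#' @param angles data.frame `i, j, k, H, theta0` (kcal/mol/rad^2, degrees).
#' @param torsions data.frame `i, j, k, l, H, n, s` (kcal/mol, integer,
#'   +/-1).
#' @param out_of_plane data.frame `i, j, k, l, H` with `j` central
#'   (kcal/mol/rad^2).
#' @param cross Named list of cross-term force constants `F_bb`, `F_tt`,
#'   `F_bt`, `F_ptt`, `F_xx` (scalars; 0 disables a term).
#' @param nonbonded data.frame `type, eps, rstar` (kcal/mol, A).
#' @param charges Optional named vector of per-tag charges (e); particle
#'   charges in the system win when nonzero.
#' @param dielectric Relative dielectric constant (default 1).
#' @return An `ff_params` object.
#' @export
ff_params <- function(bonds, angles, torsions = NULL, out_of_plane = NULL,
                      cross = list(F_bb = 0, F_tt = 0, F_bt = 0,
                                   F_ptt = 0, F_xx = 0),
                      nonbonded, charges = NULL, dielectric = 1) {
  if (any(bonds$D < 0) || any(angles$H < 0) ||
      (!is.null(torsions) && any(torsions$H < 0))) {
    stop("force constants D and H must be non-negative", call. = FALSE)
  }
  if (any(nonbonded$rstar <= 0)) stop("r* must be positive", call. = FALSE)
  defaults <- list(F_bb = 0, F_tt = 0, F_bt = 0, F_ptt = 0, F_xx = 0)
  cross <- utils::modifyList(defaults, as.list(cross))
  structure(list(bonds = bonds, angles = angles, torsions = torsions,
                 out_of_plane = out_of_plane, cross = cross,
                 nonbonded = nonbonded, charges = charges,
                 dielectric = dielectric),
            class = "ff_params")
}

#' Read CVFF parameters from a YAML file
#' @param path YAML file with keys `bonds`, `angles`, `torsions`,
#'   `out_of_plane`, `cross`, `nonbonded`, `dielectric`.
#' @return An `ff_params` object.
#' @export
read_ff_params <- function(path) {
  y <- yaml::read_yaml(path)
  as_df <- function(x) if (is.null(x)) NULL else
    do.call(rbind, lapply(x, function(row) as.data.frame(row)))
  ff_params(bonds = as_df(y$bonds), angles = as_df(y$angles),
            torsions = as_df(y$torsions),
            out_of_plane = as_df(y$out_of_plane),
            cross = y$cross %||% list(),
            nonbonded = as_df(y$nonbonded),
            charges = unlist(y$charges),
            dielectric = y$dielectric %||% 1)
}

#' Bundled toy parameter set (non-physical, for tests and examples)
#'
#' A small self-consistent table with wildcard types. The values are NOT
#' fitted to any chemistry; they exist to exercise every term of the
#' functional form.
#' @return An `ff_params` object.
#' @export
toy_ff_params <- function() {
  read_ff_params(system.file("extdata", "toy_cvff.yaml",
                             package = "wdpunano", mustWork = TRUE))
}

# --- parameter resolution -------------------------------------------------

resolve_params <- function(table, type_cols, query, what) {
  # query: character matrix, one row per tuple
  n <- nrow(query)
  out <- integer(n)
  tt <- as.matrix(table[, type_cols, drop = FALSE])
  for (r in seq_len(n)) {
    q <- query[r, ]
    best <- -1L; best_row <- NA_integer_
    for (e in seq_len(nrow(tt))) {
      ent <- tt[e, ]
      fwd <- all(ent == q | ent == "*")
      rev <- all(ent == rev(q) | ent == "*")
      if (fwd || rev) {
        score <- max(if (fwd) sum(ent == q) else -1L,
                     if (rev) sum(ent == rev(q)) else -1L)
        if (score > best) { best <- score; best_row <- e }
      }
    }
    if (is.na(best_row)) {
      stop(sprintf("no %s parameters for type tuple (%s)", what,
                   paste(q, collapse = ", ")), call. = FALSE)
    }
    out[r] <- best_row
  }
  out
}

# --- internal coordinates with gradients ----------------------------------

# bond length and gradient wrt its two atoms
coord_bond <- function(x1, x2) {
  d <- x1 - x2
  b <- vnorm(d)
  list(value = b, g1 = d / b, g2 = -d / b)
}

coord_angle <- function(xi, xj, xk) {
  u <- xi - xj; v <- xk - xj
  nu <- vnorm(u); nv <- vnorm(v)
  uh <- u / nu; vh <- v / nv
  ct <- sum(uh * vh)
  ct <- min(max(ct, -1), 1)
  theta <- acos(ct)
  st <- sqrt(max(1 - ct^2, 1e-14))
  gi <- (ct * uh - vh) / (nu * st)
  gk <- (ct * vh - uh) / (nv * st)
  list(value = theta, gi = gi, gj = -(gi + gk), gk = gk)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# dihedral angle and gradients (atoms 1-2-3-4)
coord_dihedral <- function(x1, x2, x3, x4) {
  b1 <- x2 - x1; b2 <- x3 - x2; b3 <- x4 - x3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  nb2 <- vnorm(b2)
  m1 <- cross3(n1, b2 / nb2)
  x_ <- sum(n1 * n2); y_ <- sum(m1 * n2)
  phi <- atan2(y_, x_)
  sn1 <- sum(n1 * n1); sn2 <- sum(n2 * n2)
  g1 <- nb2 / sn1 * n1
  g4 <- -nb2 / sn2 * n2
  f12 <- sum(b1 * b2) / (nb2^2)
  f32 <- sum(b3 * b2) / (nb2^2)
  g2 <- -(1 + f12) * g1 + f32 * g4
  g3 <- f12 * g1 - (1 + f32) * g4
  list(value = phi, g1 = g1, g2 = g2, g3 = g3, g4 = g4)
}

# Wilson out-of-plane angle: tuple (i, j, k, l) with j central; chi is the
# angle between bond j->l and the plane (i, j, k).
coord_wilson <- function(xi, xj, xk, xl) {
  a <- xi - xj; b <- xk - xj; u <- xl - xj
  n <- cross3(a, b)
  nn <- vnorm(n); nu <- vnorm(u)
  nh <- n / nn; uh <- u / nu
  s <- sum(nh * uh)
  s <- min(max(s, -1), 1)
  chi <- asin(s)
  denom <- sqrt(max(1 - s^2, 1e-12))
  c_u <- (nh - s * uh) / nu       # ds/du
  c_n <- (uh - s * nh) / nn       # ds/dn
  g_a <- cross3(b, c_n)           # ds/da
  g_b <- cross3(c_n, a)           # ds/db
  gi <- g_a / denom
  gk <- g_b / denom
  gl <- c_u / denom
  list(value = chi, gi = gi, gj = -(gi + gk + gl), gk = gk, gl = gl)
}

# --- evaluation -----------------------------------------------------------

cvff_eval <- function(system, params, want_forces = FALSE) {
  stopifnot_coords(system)
  if (!inherits(params, "ff_params")) stop("params must be ff_params",
                                           call. = FALSE)
  xyz <- system$coords
  tags <- system$particles$tag
  n <- nrow(xyz)
  forces <- if (want_forces) matrix(0, n, 3L) else NULL
  addf <- function(idx, g) {
    # g: list of gradients dE/dx per atom; force is the negative gradient
    for (q in seq_along(idx)) {
      forces[idx[q], ] <<- forces[idx[q], ] - g[[q]]
    }
  }
  br <- list(bond = 0, angle = 0, torsion = 0, out_of_plane = 0,
             cross_bb = 0, cross_tt = 0, cross_bt = 0, cross_ptt = 0,
             cross_xx = 0, lj = 0, coulomb = 0)

  # cache internal coordinates keyed by tuple for cross terms
  bonds <- system$bonds
  angles <- system$angles
  torsions <- system$torsions
  oops <- system$out_of_plane

  bond_geo <- vector("list", nrow(bonds))
  bond_par <- NULL
  if (nrow(bonds)) {
    q <- cbind(tags[bonds[, 1L]], tags[bonds[, 2L]])
    rows <- resolve_params(params$bonds, c("i", "j"), q, "bond")
    bond_par <- params$bonds[rows, , drop = FALSE]
    for (r in seq_len(nrow(bonds))) {
      geo <- coord_bond(xyz[bonds[r, 1L], ], xyz[bonds[r, 2L], ])
      bond_geo[[r]] <- geo
      D <- bond_par$D[r]; al <- bond_par$alpha[r]; b0 <- bond_par$b0[r]
      ex <- exp(-al * (geo$value - b0))
      br$bond <- br$bond + D * (1 - ex)^2
      if (want_forces) {
        dEdb <- 2 * D * (1 - ex) * al * ex
        addf(bonds[r, ], list(dEdb * geo$g1, dEdb * geo$g2))
      }
    }
  }

  angle_geo <- vector("list", nrow(angles))
  angle_par <- NULL
  if (nrow(angles)) {
    q <- cbind(tags[angles[, 1L]], tags[angles[, 2L]], tags[angles[, 3L]])
    rows <- resolve_params(params$angles, c("i", "j", "k"), q, "angle")
    angle_par <- params$angles[rows, , drop = FALSE]
    for (r in seq_len(nrow(angles))) {
      geo <- coord_angle(xyz[angles[r, 1L], ], xyz[angles[r, 2L], ],
                         xyz[angles[r, 3L], ])
      angle_geo[[r]] <- geo
      H <- angle_par$H[r]; t0 <- angle_par$theta0[r] * pi / 180
      dt <- geo$value - t0
      br$angle <- br$angle + H * dt^2
      if (want_forces) {
        dEdt <- 2 * H * dt
        addf(angles[r, ], list(dEdt * geo$gi, dEdt * geo$gj, dEdt * geo$gk))
      }
    }
  }

  tor_geo <- vector("list", nrow(torsions))
  if (nrow(torsions)) {
    q <- cbind(tags[torsions[, 1L]], tags[torsions[, 2L]],
               tags[torsions[, 3L]], tags[torsions[, 4L]])
    rows <- resolve_params(params$torsions, c("i", "j", "k", "l"), q,
                           "torsion")
    tor_par <- params$torsions[rows, , drop = FALSE]
    for (r in seq_len(nrow(torsions))) {
      geo <- coord_dihedral(xyz[torsions[r, 1L], ], xyz[torsions[r, 2L], ],
                            xyz[torsions[r, 3L], ], xyz[torsions[r, 4L], ])
      tor_geo[[r]] <- geo
      H <- tor_par$H[r]; nn <- tor_par$n[r]; s <- tor_par$s[r]
      br$torsion <- br$torsion + H * (1 + s * cos(nn * geo$value))
      if (want_forces) {
        dEdp <- -H * s * nn * sin(nn * geo$value)
        addf(torsions[r, ], list(dEdp * geo$g1, dEdp * geo$g2,
                                 dEdp * geo$g3, dEdp * geo$g4))
      }
    }
  }

  oop_geo <- vector("list", nrow(oops))
  if (nrow(oops)) {
    q <- cbind(tags[oops[, 1L]], tags[oops[, 2L]], tags[oops[, 3L]],
               tags[oops[, 4L]])
    oop_tab <- params$out_of_plane
    if (is.null(oop_tab)) {
      stop("topology has out-of-plane tuples but no out_of_plane parameters",
           call. = FALSE)
    }
    rows <- resolve_params(oop_tab, c("i", "j", "k", "l"), q, "out-of-plane")
    oop_par <- oop_tab[rows, , drop = FALSE]
    for (r in seq_len(nrow(oops))) {
      geo <- coord_wilson(xyz[oops[r, 1L], ], xyz[oops[r, 2L], ],
                          xyz[oops[r, 3L], ], xyz[oops[r, 4L], ])
      oop_geo[[r]] <- geo
      H <- oop_par$H[r]
      br$out_of_plane <- br$out_of_plane + H * geo$value^2
      if (want_forces) {
        dEdx <- 2 * H * geo$value
        addf(oops[r, ], list(dEdx * geo$gi, dEdx * geo$gj, dEdx * geo$gk,
                             dEdx * geo$gl))
      }
    }
  }

  # ---- cross terms (keyed off the cached coordinates) ----
  cr <- params$cross
  if (nrow(angles)) {
    # map angle r -> its two bonds (i-j) and (j-k) by row in `bonds`
    bond_key <- paste(pmin(bonds[, 1L], bonds[, 2L]),
                      pmax(bonds[, 1L], bonds[, 2L]))
    bond_row <- function(a, b) match(paste(min(a, b), max(a, b)), bond_key)
    for (r in seq_len(nrow(angles))) {
      i <- angles[r, 1L]; j <- angles[r, 2L]; k <- angles[r, 3L]
      r1 <- bond_row(i, j); r2 <- bond_row(j, k)
      if (is.na(r1) || is.na(r2)) next
      g1 <- bond_geo[[r1]]; g2 <- bond_geo[[r2]]
      db1 <- g1$value - bond_par$b0[r1]
      db2 <- g2$value - bond_par$b0[r2]
      if (cr$F_bb != 0) {
        br$cross_bb <- br$cross_bb + cr$F_bb * db1 * db2
        if (want_forces) {
          addf(bonds[r1, ], list(cr$F_bb * db2 * g1$g1,
                                 cr$F_bb * db2 * g1$g2))
          addf(bonds[r2, ], list(cr$F_bb * db1 * g2$g1,
                                 cr$F_bb * db1 * g2$g2))
        }
      }
      if (cr$F_bt != 0) {
        ga <- angle_geo[[r]]
        t0 <- angle_par$theta0[r] * pi / 180
        dt <- ga$value - t0
        br$cross_bt <- br$cross_bt + cr$F_bt * (db1 + db2) * dt
        if (want_forces) {
          addf(bonds[r1, ], list(cr$F_bt * dt * g1$g1, cr$F_bt * dt * g1$g2))
          addf(bonds[r2, ], list(cr$F_bt * dt * g2$g1, cr$F_bt * dt * g2$g2))
          dEdt <- cr$F_bt * (db1 + db2)
          addf(angles[r, ], list(dEdt * ga$gi, dEdt * ga$gj, dEdt * ga$gk))
        }
      }
    }
    if (cr$F_tt != 0 && nrow(angles) > 1L) {
      centers <- angles[, 2L]
      for (ctr in unique(centers)) {
        rows_c <- which(centers == ctr)
        if (length(rows_c) < 2L) next
        prs <- utils::combn(rows_c, 2L)
        for (pcol in seq_len(ncol(prs))) {
          ra <- prs[1L, pcol]; rb <- prs[2L, pcol]
          ga <- angle_geo[[ra]]; gb <- angle_geo[[rb]]
          dta <- ga$value - angle_par$theta0[ra] * pi / 180
          dtb <- gb$value - angle_par$theta0[rb] * pi / 180
          br$cross_tt <- br$cross_tt + cr$F_tt * dta * dtb
          if (want_forces) {
            addf(angles[ra, ], list(cr$F_tt * dtb * ga$gi,
                                    cr$F_tt * dtb * ga$gj,
                                    cr$F_tt * dtb * ga$gk))
            addf(angles[rb, ], list(cr$F_tt * dta * gb$gi,
                                    cr$F_tt * dta * gb$gj,
                                    cr$F_tt * dta * gb$gk))
          }
        }
      }
    }
  }
  if (cr$F_ptt != 0 && nrow(torsions) && nrow(angles)) {
    angle_key <- paste(angles[, 1L], angles[, 2L], angles[, 3L])
    angle_row <- function(a, b, c_) {
      match(TRUE, angle_key == paste(a, b, c_) |
              angle_key == paste(c_, b, a))
    }
    for (r in seq_len(nrow(torsions))) {
      i <- torsions[r, 1L]; j <- torsions[r, 2L]
      k <- torsions[r, 3L]; l <- torsions[r, 4L]
      ra <- angle_row(i, j, k); rb <- angle_row(j, k, l)
      if (is.na(ra) || is.na(rb)) next
      ga <- angle_geo[[ra]]; gb <- angle_geo[[rb]]
      gp <- tor_geo[[r]]
      dta <- ga$value - angle_par$theta0[ra] * pi / 180
      dtb <- gb$value - angle_par$theta0[rb] * pi / 180
      cphi <- cos(gp$value)
      br$cross_ptt <- br$cross_ptt + cr$F_ptt * cphi * dta * dtb
      if (want_forces) {
        dEdp <- -cr$F_ptt * sin(gp$value) * dta * dtb
        addf(torsions[r, ], list(dEdp * gp$g1, dEdp * gp$g2,
                                 dEdp * gp$g3, dEdp * gp$g4))
        dEta <- cr$F_ptt * cphi * dtb
        addf(angles[ra, ], list(dEta * ga$gi, dEta * ga$gj, dEta * ga$gk))
        dEtb <- cr$F_ptt * cphi * dta
        addf(angles[rb, ], list(dEtb * gb$gi, dEtb * gb$gj, dEtb * gb$gk))
      }
    }
  }
  if (cr$F_xx != 0 && nrow(oops) > 1L) {
    # couple out-of-plane pairs whose central atoms are bonded
    ctrs <- oops[, 2L]
    bkey <- paste(pmin(bonds[, 1L], bonds[, 2L]),
                  pmax(bonds[, 1L], bonds[, 2L]))
    prs <- utils::combn(seq_len(nrow(oops)), 2L)
    for (pcol in seq_len(ncol(prs))) {
      ra <- prs[1L, pcol]; rb <- prs[2L, pcol]
      key <- paste(min(ctrs[ra], ctrs[rb]), max(ctrs[ra], ctrs[rb]))
      if (!(key %in% bkey)) next
      ga <- oop_geo[[ra]]; gb <- oop_geo[[rb]]
      br$cross_xx <- br$cross_xx + cr$F_xx * ga$value * gb$value
      if (want_forces) {
        addf(oops[ra, ], list(cr$F_xx * gb$value * ga$gi,
                              cr$F_xx * gb$value * ga$gj,
                              cr$F_xx * gb$value * ga$gk,
                              cr$F_xx * gb$value * ga$gl))
        addf(oops[rb, ], list(cr$F_xx * ga$value * gb$gi,
                              cr$F_xx * ga$value * gb$gj,
                              cr$F_xx * ga$value * gb$gk,
                              cr$F_xx * ga$value * gb$gl))
      }
    }
  }

  # ---- nonbonded: all pairs minus 1-2 / 1-3 exclusions ----
  excl <- new.env(hash = TRUE)
  mark <- function(a, b) {
    assign(paste(min(a, b), max(a, b)), TRUE, envir = excl)
  }
  if (nrow(bonds)) for (r in seq_len(nrow(bonds))) {
    mark(bonds[r, 1L], bonds[r, 2L])
  }
  if (nrow(angles)) for (r in seq_len(nrow(angles))) {
    mark(angles[r, 1L], angles[r, 3L])
  }
  qv <- system$particles$charge
  if (!is.null(params$charges)) {
    fill <- qv == 0 & tags %in% names(params$charges)
    qv[fill] <- params$charges[tags[fill]]
  }
  nb_rows <- resolve_params(params$nonbonded, "type",
                            matrix(tags, ncol = 1L), "nonbonded")
  eps_i <- params$nonbonded$eps[nb_rows]
  rst_i <- params$nonbonded$rstar[nb_rows]
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (exists(paste(i, j), envir = excl, inherits = FALSE)) next
        dvec <- xyz[i, ] - xyz[j, ]
        r_ <- vnorm(dvec)
        # geometric-mean combination
        eps <- sqrt(eps_i[i] * eps_i[j])
        rst <- (rst_i[i] + rst_i[j]) / 2
        sr6 <- (rst / r_)^6
        e_lj <- eps * (sr6^2 - 2 * sr6)
        br$lj <- br$lj + e_lj
        e_c <- 0
        if (qv[i] != 0 && qv[j] != 0) {
          e_c <- COULOMB_K * qv[i] * qv[j] / (params$dielectric * r_)
          br$coulomb <- br$coulomb + e_c
        }
        if (want_forces) {
          dEdr <- eps * (-12 * sr6^2 + 12 * sr6) / r_ - e_c / r_
          g <- dEdr * dvec / r_
          forces[i, ] <- forces[i, ] - g
          forces[j, ] <- forces[j, ] + g
        }
      }
    }
  }

  br$total <- br$bond + br$angle + br$torsion + br$out_of_plane +
    br$cross_bb + br$cross_tt + br$cross_bt + br$cross_ptt + br$cross_xx +
    br$lj + br$coulomb
  list(breakdown = structure(br, class = "energy_breakdown"),
       forces = forces)
}

#' Evaluate the CVFF energy of a system
#'
#' @param system A `particle_system` with coordinates and bonded tuples.
#' @param params An [ff_params()] parameter set.
#' @return An `energy_breakdown`: named list of per-term energies
#'   (kcal/mol) and their `total`.
#' @export
evaluate_energy <- function(system, params) {
  cvff_eval(system, params, want_forces = FALSE)$breakdown
}

#' Evaluate analytic CVFF forces
#'
#' @inheritParams evaluate_energy
#' @return An `N x 3` matrix of forces (kcal/mol/A), the negative analytic
#'   gradient of [evaluate_energy()].
#' @export
evaluate_forces <- function(system, params) {
  cvff_eval(system, params, want_forces = TRUE)$forces
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("CVFF energy breakdown (kcal/mol)\n")
  for (nm in names(x)) {
    if (x[[nm]] != 0 || nm == "total") {
      cat(sprintf("  %-13s %14.6f\n", nm, x[[nm]]))
    }
  }
  invisible(x)
}

#' Relax a system by line-searched steepest descent
#'
#' Monotone non-increasing energy: each step moves along the force
#' direction with backtracking until the energy decreases; stops when the
#' gradient norm falls below `tol` or after `max_steps`.
#'
#' @param system A `particle_system` with coordinates.
#' @param params An [ff_params()] set.
#' @param max_steps Maximum descent steps (default 200).
#' @param tol Convergence threshold on the max force component
#'   (kcal/mol/A, default 1e-4).
#' @param step0 Initial trial step (Angstrom, default 0.05).
#' @return The relaxed system, with attributes `energy_trace` (the
#'   monotone energy sequence) and `converged`.
#' @export
relax_system <- function(system, params, max_steps = 200L, tol = 1e-4,
                         step0 = 0.05) {
  ev <- cvff_eval(system, params, want_forces = TRUE)
  e <- ev$breakdown$total
  if (!is.finite(e)) stop("starting energy is not finite", call. = FALSE)
  trace <- e
  converged <- FALSE
  step <- step0
  for (it in seq_len(max_steps)) {
    f <- ev$forces
    fmax <- max(abs(f))
    if (fmax <= tol) { converged <- TRUE; break }
    dir <- f / fmax
    accepted <- FALSE
    for (ls in seq_len(30L)) {
      trial <- system
      trial$coords <- system$coords + step * dir
      ev_t <- cvff_eval(trial, params, want_forces = TRUE)
      e_t <- ev_t$breakdown$total
      if (is.finite(e_t) && e_t <= e) {
        system <- trial; ev <- ev_t; e <- e_t
        trace <- c(trace, e)
        step <- step * 1.5
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) { converged <- max(abs(ev$forces)) <= tol * 10; break }
  }
  if (!is.finite(e)) stop("energy diverged during relaxation", call. = FALSE)
  attr(system, "energy_trace") <- trace
  attr(system, "converged") <- converged
  system
}
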