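# Independent oracles: brute-force H-bond search, naive CVFF re-summation,
# closed-form two-sphere accessible area.

# O(N^3)-style brute force over all (donor, hydrogen, acceptor) triples.
brute_force_hbonds <- function(system, d_cut = 3.0, angle_cut = 30) {
  p <- system$particles
  xyz <- system$coords
  out <- list(); m <- 0L
  for (i_h in seq_len(nrow(p))) {
    if (p$hbond_role[i_h] != "donor_hydrogen") next
    for (i_d in seq_len(nrow(p))) {
      if (p$hbond_role[i_d] != "donor_heavy") next
      bonded <- any((system$bonds[, 1] == i_d & system$bonds[, 2] == i_h) |
                      (system$bonds[, 1] == i_h & system$bonds[, 2] == i_d))
      if (!bonded) next
      for (i_a in seq_len(nrow(p))) {
        if (p$hbond_role[i_a] != "acceptor") next
        if (i_a == i_d || i_a == i_h) next
        d_da <- sqrt(sum((xyz[i_d, ] - xyz[i_a, ])^2))
        if (d_da > d_cut) next
        v1 <- xyz[i_d, ] - xyz[i_h, ]
        v2 <- xyz[i_a, ] - xyz[i_h, ]
        ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        dev <- 180 - acos(min(max(ct, -1), 1)) * 180 / pi
        if (dev > angle_cut) next
        m <- m + 1L
        out[[m]] <- c(p$id[i_d], p$id[i_h], p$id[i_a])
      }
    }
  }
  if (!m) return(character(0))
  sort(vapply(out, paste, character(1L), collapse = " "))
}

# Term-by-term CVFF re-summation, written independently of the package
# internals (recomputes every internal coordinate from scratch).
naive_cvff_energy <- function(system, params) {
  xyz <- system$coords
  tags <- system$particles$tag
  look <- function(tab, cols, types) {
    best <- -1; row <- NA
    for (e in seq_len(nrow(tab))) {
      ent <- unlist(tab[e, cols])
      for (qq in list(types, rev(types))) {
        if (all(ent == qq | ent == "*")) {
          sc <- sum(ent == qq)
          if (sc > best) { best <- sc; row <- e }
        }
      }
    }
    tab[row, ]
  }
  ang <- function(a, b, c_) {
    u <- xyz[a, ] - xyz[b, ]; v <- xyz[c_, ] - xyz[b, ]
    acos(min(max(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1))
  }
  dih <- function(a, b, c_, d) {
    b1 <- xyz[b, ] - xyz[a, ]; b2 <- xyz[c_, ] - xyz[b, ]
    b3 <- xyz[d, ] - xyz[c_, ]
    cr <- function(x, y) c(x[2] * y[3] - x[3] * y[2],
                           x[3] * y[1] - x[1] * y[3],
                           x[1] * y[2] - x[2] * y[1])
    n1 <- cr(b1, b2); n2 <- cr(b2, b3)
    m1 <- cr(n1, b2 / sqrt(sum(b2^2)))
    atan2(sum(m1 * n2), sum(n1 * n2))
  }
  wils <- function(i, j, k, l) {
    a <- xyz[i, ] - xyz[j, ]; b <- xyz[k, ] - xyz[j, ]; u <- xyz[l, ] - xyz[j, ]
    cr <- function(x, y) c(x[2] * y[3] - x[3] * y[2],
                           x[3] * y[1] - x[1] * y[3],
                           x[1] * y[2] - x[2] * y[1])
    n <- cr(a, b)
    asin(min(max(sum(n * u) / sqrt(sum(n^2) * sum(u^2)), -1), 1))
  }
  e_bond <- 0; b0_of <- numeric(nrow(system$bonds))
  for (r in seq_len(nrow(system$bonds))) {
    i <- system$bonds[r, 1]; j <- system$bonds[r, 2]
    pr <- look(params$bonds, c("i", "j"), tags[c(i, j)])
    b <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    b0_of[r] <- pr$b0
    e_bond <- e_bond + pr$D * (1 - exp(-pr$alpha * (b - pr$b0)))^2
  }
  e_angle <- 0; t0_of <- numeric(nrow(system$angles))
  for (r in seq_len(nrow(system$angles))) {
    a <- system$angles[r, ]
    pr <- look(params$angles, c("i", "j", "k"), tags[a])
    t0_of[r] <- pr$theta0 * pi / 180
    e_angle <- e_angle + pr$H * (ang(a[1], a[2], a[3]) - t0_of[r])^2
  }
  e_tor <- 0
  if (nrow(system$torsions)) for (r in seq_len(nrow(system$torsions))) {
    tq <- system$torsions[r, ]
    pr <- look(params$torsions, c("i", "j", "k", "l"), tags[tq])
    e_tor <- e_tor + pr$H * (1 + pr$s * cos(pr$n * dih(tq[1], tq[2], tq[3], tq[4])))
  }
  e_oop <- 0
  if (nrow(system$out_of_plane)) for (r in seq_len(nrow(system$out_of_plane))) {
    o <- system$out_of_plane[r, ]
    pr <- look(params$out_of_plane, c("i", "j", "k", "l"), tags[o])
    e_oop <- e_oop + pr$H * wils(o[1], o[2], o[3], o[4])^2
  }
  cr <- params$cross
  e_bb <- 0; e_bt <- 0
  bond_key <- paste(pmin(system$bonds[, 1], system$bonds[, 2]),
                    pmax(system$bonds[, 1], system$bonds[, 2]))
  for (r in seq_len(nrow(system$angles))) {
    a <- system$angles[r, ]
    r1 <- match(paste(min(a[1], a[2]), max(a[1], a[2])), bond_key)
    r2 <- match(paste(min(a[2], a[3]), max(a[2], a[3])), bond_key)
    db1 <- sqrt(sum((xyz[system$bonds[r1, 1], ] - xyz[system$bonds[r1, 2], ])^2)) - b0_of[r1]
    db2 <- sqrt(sum((xyz[system$bonds[r2, 1], ] - xyz[system$bonds[r2, 2], ])^2)) - b0_of[r2]
    dt <- ang(a[1], a[2], a[3]) - t0_of[r]
    e_bb <- e_bb + cr$F_bb * db1 * db2
    e_bt <- e_bt + cr$F_bt * (db1 + db2) * dt
  }
  e_tt <- 0
  ctr <- system$angles[, 2]
  for (u in unique(ctr)) {
    rows <- which(ctr == u)
    if (length(rows) < 2) next
    for (a1 in seq_along(rows)) for (a2 in seq_along(rows)) {
      if (a1 >= a2) next
      ra <- rows[a1]; rb <- rows[a2]
      aa <- system$angles[ra, ]; ab <- system$angles[rb, ]
      e_tt <- e_tt + cr$F_tt *
        (ang(aa[1], aa[2], aa[3]) - t0_of[ra]) *
        (ang(ab[1], ab[2], ab[3]) - t0_of[rb])
    }
  }
  e_ptt <- 0
  if (nrow(system$torsions)) {
    akey <- paste(system$angles[, 1], system$angles[, 2], system$angles[, 3])
    arow <- function(a, b, c_) match(TRUE, akey == paste(a, b, c_) |
                                       akey == paste(c_, b, a))
    for (r in seq_len(nrow(system$torsions))) {
      tq <- system$torsions[r, ]
      ra <- arow(tq[1], tq[2], tq[3]); rb <- arow(tq[2], tq[3], tq[4])
      if (is.na(ra) || is.na(rb)) next
      e_ptt <- e_ptt + cr$F_ptt * cos(dih(tq[1], tq[2], tq[3], tq[4])) *
        (ang(tq[1], tq[2], tq[3]) - t0_of[ra]) *
        (ang(tq[2], tq[3], tq[4]) - t0_of[rb])
    }
  }
  e_xx <- 0
  if (nrow(system$out_of_plane) > 1) {
    oo <- system$out_of_plane
    for (a1 in seq_len(nrow(oo) - 1)) for (a2 in (a1 + 1):nrow(oo)) {
      key <- paste(min(oo[a1, 2], oo[a2, 2]), max(oo[a1, 2], oo[a2, 2]))
      if (!(key %in% bond_key)) next
      e_xx <- e_xx + cr$F_xx * wils(oo[a1, 1], oo[a1, 2], oo[a1, 3], oo[a1, 4]) *
        wils(oo[a2, 1], oo[a2, 2], oo[a2, 3], oo[a2, 4])
    }
  }
  excl <- c(paste(pmin(system$bonds[, 1], system$bonds[, 2]),
                  pmax(system$bonds[, 1], system$bonds[, 2])),
            paste(pmin(system$angles[, 1], system$angles[, 3]),
                  pmax(system$angles[, 1], system$angles[, 3])))
  qv <- system$particles$charge
  if (!is.null(params$charges)) {
    fl <- qv == 0 & tags %in% names(params$charges)
    qv[fl] <- params$charges[tags[fl]]
  }
  e_lj <- 0; e_c <- 0
  n <- nrow(xyz)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (paste(i, j) %in% excl) next
    pr_i <- look(params$nonbonded, "type", tags[i])
    pr_j <- look(params$nonbonded, "type", tags[j])
    r_ <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    eps <- sqrt(pr_i$eps * pr_j$eps); rst <- (pr_i$rstar + pr_j$rstar) / 2
    e_lj <- e_lj + eps * ((rst / r_)^12 - 2 * (rst / r_)^6)
    if (qv[i] != 0 && qv[j] != 0) {
      e_c <- e_c + 332.0637 * qv[i] * qv[j] / (params$dielectric * r_)
    }
  }
  e_bond + e_angle + e_tor + e_oop + e_bb + e_tt + e_bt + e_ptt + e_xx +
    e_lj + e_c
}

# Closed-form accessible area of two overlapping spheres (union of two
# probe-extended spheres), via spherical caps.
two_sphere_union_area <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  if (d <= abs(R1 - R2)) return(4 * pi * max(R1, R2)^2)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}
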