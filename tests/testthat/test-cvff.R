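test_that("bonded terms vanish at the equilibrium geometry", {
  # one Morse bond at b0, far from anything else
  sys <- point_system(rbind(c(0, 0, 0), c(1.5, 0, 0)))
  sys$bonds <- rbind(c(1L, 2L))
  par <- toy_ff_params()
  par$nonbonded$eps <- 0
  e <- evaluate_energy(sys, par)
  expect_equal(e$bond, 0, tolerance = 1e-12)
  expect_equal(e$total, 0, tolerance = 1e-12)
  # a three-bead angle at theta0 with both bonds at b0
  t0 <- 109.5 * pi / 180
  xyz <- rbind(c(1.5, 0, 0), c(0, 0, 0),
               1.5 * c(cos(t0), sin(t0), 0))
  sys3 <- point_system(xyz)
  sys3$bonds <- rbind(c(1L, 2L), c(2L, 3L))
  sys3$angles <- rbind(c(1L, 2L, 3L))
  e3 <- evaluate_energy(sys3, par)
  expect_equal(e3$bond + e3$angle + e3$cross_bb + e3$cross_bt, 0,
               tolerance = 1e-10)
})

test_that("the LJ minimum equals -eps at r = r*", {
  sys <- point_system(rbind(c(0, 0, 0), c(3.6, 0, 0)))
  par <- toy_ff_params()
  e <- evaluate_energy(sys, par)
  expect_equal(e$lj, -0.12, tolerance = 1e-12)
  expect_equal(e$total, e$lj)
})

test_that("the breakdown total equals the sum of its components", {
  sys <- cvff_test_system(31L)
  e <- evaluate_energy(sys, toy_ff_params())
  parts <- unlist(e[setdiff(names(e), "total")])
  expect_equal(e$total, sum(parts), tolerance = 1e-10 * abs(e$total))
})

test_that("energies match an independent naive re-summation", {
  par <- toy_ff_params()
  for (s in c(11L, 23L)) {
    sys <- cvff_test_system(s, particles_per_chain = 33L)
    e <- evaluate_energy(sys, par)
    expect_equal(e$total, naive_cvff_energy(sys, par),
                 tolerance = 1e-10 * max(1, abs(e$total)))
  }
})

test_that("analytic forces match central finite differences", {
  par <- toy_ff_params()
  for (s in c(5L, 6L)) {
    sys <- cvff_test_system(s, particles_per_chain = 31L)
    f <- evaluate_forces(sys, par)
    h <- 1e-5
    scale <- max(abs(f))
    worst <- 0
    for (i in seq_len(nrow(sys$coords))) {
      for (k in 1:3) {
        sp <- sys; sp$coords[i, k] <- sp$coords[i, k] + h
        sm <- sys; sm$coords[i, k] <- sm$coords[i, k] - h
        fd <- -(evaluate_energy(sp, par)$total -
                  evaluate_energy(sm, par)$total) / (2 * h)
        worst <- max(worst, abs(f[i, k] - fd))
      }
    }
    expect_lt(worst / scale, 1e-6)
    # net force on an isolated system vanishes
    expect_equal(max(abs(colSums(f))), 0, tolerance = 1e-8 * scale)
  }
})

test_that("energy is invariant under rigid motion", {
  sys <- cvff_test_system(41L)
  par <- toy_ff_params()
  e0 <- evaluate_energy(sys, par)$total
  e1 <- evaluate_energy(rigid_move(sys, seed = 2), par)$total
  expect_equal(e1, e0, tolerance = 1e-9 * abs(e0))
})

test_that("unresolved parameters raise an error naming the tuple", {
  sys <- point_system(rbind(c(0, 0, 0), c(1.4, 0, 0)), tag = "XX")
  sys$bonds <- rbind(c(1L, 2L))
  par <- toy_ff_params()
  par$bonds <- par$bonds[par$bonds$i != "*", , drop = FALSE]
  expect_error(evaluate_energy(sys, par), "XX")
})

test_that("relaxation is monotone and finds known minima", {
  par <- toy_ff_params()
  par$nonbonded$eps <- 0
  # stretched Morse bond relaxes to b0
  sys <- point_system(rbind(c(0, 0, 0), c(2.4, 0, 0)))
  sys$bonds <- rbind(c(1L, 2L))
  out <- relax_system(sys, par, max_steps = 400, tol = 1e-6)
  expect_equal(dist(out$coords)[1], 1.5, tolerance = 1e-3)
  expect_true(all(diff(attr(out, "energy_trace")) <= 1e-12))
  # LJ dimer from 1.3 r* returns to r*
  par2 <- toy_ff_params()
  dimer <- point_system(rbind(c(0, 0, 0), c(1.3 * 3.6, 0, 0)))
  out2 <- relax_system(dimer, par2, max_steps = 400, tol = 1e-7)
  expect_equal(dist(out2$coords)[1], 3.6, tolerance = 1e-3)
  expect_true(all(diff(attr(out2, "energy_trace")) <= 1e-12))
})
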