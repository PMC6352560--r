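test_that("rigid-rod limit reaches the contour length exactly", {
  ch <- build_chain_topology(tiny_preset(60L), seed = 1)
  for (mode in c("free", "targeted")) {
    co <- sample_chain_conformation(ch, persistence = 1, seed = 5,
                                    mode = mode)
    expect_equal(attr(co, "end_to_end"), attr(co, "contour"),
                 tolerance = 1e-9)
  }
})

test_that("free walks at zero persistence obey the freely-jointed-chain law", {
  n_bonds <- 50L; b <- 1.5
  set.seed(101)
  r2 <- replicate(2000, {
    w <- wdpunano:::correlated_walk(n_bonds, b, 0)
    sum((w[n_bonds + 1, ] - w[1, ])^2)
  })
  expect_equal(mean(r2), n_bonds * b^2, tolerance = 0.05)
})

test_that("mean end-to-end increases strictly with persistence", {
  ch <- build_chain_topology(tiny_preset(60L), seed = 1)
  pts <- c(-0.5, 0, 0.4, 0.8)
  means <- vapply(pts, function(c_) {
    mean(vapply(1:20, function(s) {
      attr(sample_chain_conformation(ch, persistence = c_, seed = s),
           "end_to_end")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # and tracks the closed form in targeted mode
  nb <- sum(ch$particles$backbone) - 1L
  expect_equal(means, mean_end_to_end(nb, 1.5, pts), tolerance = 0.01)
})

test_that("conformations are seed-deterministic and respect the contour bound", {
  ch <- build_chain_topology(tiny_preset(80L), seed = 2)
  a <- sample_chain_conformation(ch, persistence = 0.3, seed = 7)
  b <- sample_chain_conformation(ch, persistence = 0.3, seed = 7)
  expect_identical(a, b)
  for (s in 1:10) {
    co <- sample_chain_conformation(ch, persistence = runif(1, -0.8, 0.9),
                                    seed = s)
    expect_lte(attr(co, "end_to_end"), attr(co, "contour") + 1e-9)
    expect_false(anyNA(co))
  }
})

test_that("soft excluded volume errors name the congested bead", {
  ch <- build_chain_topology(tiny_preset(200L), seed = 2)
  expect_error(
    sample_chain_conformation(ch, persistence = -0.98, seed = 1,
                              min_separation = 3.5, max_retries = 3),
    "clearance")
})
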