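# A minimal hand-placed donor/H/acceptor triple builder.
triple_system <- function(d_da, dev_deg, chain_a = 1L,
                          class_d = "PCL", class_a = "PCL") {
  dev <- dev_deg * pi / 180
  h <- c(1.0, 0, 0)
  cosd <- cos(dev)
  t_ <- -1 * cosd + sqrt(cosd^2 - 1 + d_da^2)
  acc <- h + t_ * c(cos(dev), sin(dev), 0)
  particle_system(
    data.frame(id = 1:3, tag = c("N", "HN", "O_carb"),
               mass = c(14, 1, 16), radius = 1.5, charge = 0,
               chain_id = c(1L, 1L, chain_a), unit_index = 1L,
               segment_type = "HARD",
               hb_class = c(class_d, class_d, class_a),
               hbond_role = c("donor_heavy", "donor_hydrogen", "acceptor"),
               backbone = c(TRUE, FALSE, TRUE)),
    rbind(c(0, 0, 0), h, acc),
    bonds = rbind(c(1L, 2L)))
}

test_that("boundary geometries are accepted and rejected per the criteria", {
  expect_identical(nrow(detect_hbonds(triple_system(2.9, 0))), 1L)
  rec <- detect_hbonds(triple_system(2.9, 0))
  expect_equal(rec$d_DA, 2.9, tolerance = 1e-9)
  expect_equal(rec$angle, 0, tolerance = 1e-6)
  expect_identical(nrow(detect_hbonds(triple_system(3.05, 0))), 0L)
  expect_identical(nrow(detect_hbonds(triple_system(2.9, 31))), 0L)
  expect_identical(nrow(detect_hbonds(triple_system(2.9, 29))), 1L)
})

test_that("grid-accelerated detection equals the brute-force oracle", {
  for (s in 1:50) {
    sys <- random_hbond_system(seed = 1000 + s,
                               n_donor = sample(10:40, 1),
                               n_acc = sample(20:80, 1),
                               edge = runif(1, 10, 25))
    det <- detect_hbonds(sys, classify = FALSE)
    got <- sort(with(det, paste(donor_id, hydrogen_id, acceptor_id)))
    want <- brute_force_hbonds(sys)
    expect_identical(got, want)
  }
})

test_that("detection is invariant under rigid motion", {
  sys <- random_hbond_system(seed = 77, n_donor = 25, n_acc = 50, edge = 14)
  det0 <- detect_hbonds(sys, classify = FALSE)
  det1 <- detect_hbonds(rigid_move(sys, seed = 5), classify = FALSE)
  expect_identical(with(det0, paste(donor_id, hydrogen_id, acceptor_id)),
                   with(det1, paste(donor_id, hydrogen_id, acceptor_id)))
})

test_that("systems without labeled hydrogens warn and return empty", {
  sys <- point_system(matrix(rnorm(30), 10, 3))
  expect_warning(res <- detect_hbonds(sys), "no donor hydrogens")
  expect_identical(nrow(res), 0L)
})

test_that("classification partitions detected bonds by class and chain", {
  recs <- rbind(
    detect_hbonds(triple_system(2.8, 5, chain_a = 1L, class_d = "PCL",
                                class_a = "PCL")),
    detect_hbonds(triple_system(2.8, 5, chain_a = 2L, class_d = "PLA",
                                class_a = "PLA")),
    detect_hbonds(triple_system(2.8, 5, chain_a = 2L, class_d = "PCL",
                                class_a = "PLA")))
  sys <- triple_system(2.8, 5)  # only used for label fallback; rows carry labels
  counts <- classify_hbonds(recs, sys)
  expect_identical(unname(counts$by_category),
                   c(1L, 1L, 1L))
  expect_identical(counts$total, 3L)
  expect_identical(sum(counts$by_category), counts$total)
  expect_identical(sum(counts$by_scope), counts$total)
  expect_identical(unname(counts$by_scope["intramolecular"]), 1L)
})

test_that("planted bookkeeping counts appear in the right categories", {
  # 10 PCL-PCL + 5 PLA-PLA hand-built records
  rec_list <- c(
    lapply(1:10, function(i) detect_hbonds(
      triple_system(2.7, 3, class_d = "PCL", class_a = "PCL"))),
    lapply(1:5, function(i) detect_hbonds(
      triple_system(2.7, 3, class_d = "PLA", class_a = "PLA"))))
  recs <- do.call(rbind, rec_list)
  counts <- classify_hbonds(recs, triple_system(2.7, 3))
  expect_identical(unname(counts$by_category),
                   c(10L, 5L, 0L))
})

test_that("all-intrachain records yield zero intermolecular counts", {
  recs <- detect_hbonds(triple_system(2.8, 5, chain_a = 1L))
  counts <- classify_hbonds(recs, triple_system(2.8, 5))
  expect_identical(unname(counts$by_scope["intermolecular"]), 0L)
})
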