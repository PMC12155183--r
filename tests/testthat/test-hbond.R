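test_that("dimer detection applies all three criteria", {
  pp <- potential_params()
  crit <- hbond_criteria()
  b <- detect_hbonds(make_dimer_frame(0.28, alpha_deg = 5), pp, crit)
  expect_equal(nrow(b), 1)
  expect_equal(b$donor, 1)
  expect_equal(b$acceptor, 2)
  expect_lt(b$energy, -8)
  expect_lt(b$r_oh, 0.25)
  expect_lt(b$alpha, 30)

  # bend the donor O-H 45 degrees off the O..O line: criterion (iii) fails
  b2 <- detect_hbonds(make_dimer_frame(0.28, alpha_deg = 45), pp, crit)
  expect_equal(nrow(b2), 0)

  # stretch so R_OH > 0.25 nm: criterion (ii) fails
  b3 <- detect_hbonds(make_dimer_frame(0.36), pp, crit)
  expect_true(all(b3$r_oh >= 0.25) || nrow(b3) == 0)
  expect_equal(nrow(b3), 0)

  # energetic criterion alone can veto: demand an impossible energy
  b4 <- detect_hbonds(make_dimer_frame(0.28), pp,
                      hbond_criteria(energy_max = -100))
  expect_equal(nrow(b4), 0)

  expect_error(detect_hbonds(make_dimer_frame(0.28), params = NULL),
               "potential")
})

test_that("bond-count histogram pools high counts but keeps the exact mean", {
  empty <- data.frame(donor = integer(0), h_site = integer(0),
                      acceptor = integer(0))
  h0 <- bond_count_histogram(empty, 5)
  expect_equal(unname(h0$percent["0"]), 100)
  expect_equal(h0$mean_nhb, 0)
  expect_equal(sum(h0$percent), 100)

  lat <- generate_lattice_network(2, bond_removal_p = 0, seed = 1)
  h4 <- bond_count_histogram(lat$bonds, lat$n_molecules)
  expect_equal(unname(h4$percent["4"]), 100)
  expect_equal(h4$mean_nhb, 4)

  # a molecule with 6 bonds lands in the 5-bin but the mean stays exact
  bonds6 <- data.frame(donor = c(1, 1, 2, 3, 4, 5, 6),
                       h_site = c(1, 2, 1, 1, 1, 1, 1),
                       acceptor = c(2, 3, 4, 1, 1, 1, 1))
  h6 <- bond_count_histogram(bonds6, 6)
  deg <- hbond_degrees(bonds6, 6)
  expect_equal(max(deg$degree), 6)
  expect_gt(unname(h6$percent["5"]), 0)
  expect_equal(h6$mean_nhb, sum(deg$degree) / 6)
})

test_that("degree bookkeeping: histogram mass equals twice the bond count", {
  set.seed(77)
  for (k in 1:25) {
    n <- sample(5:20, 1)
    bonds <- random_bond_table(n, p = runif(1, 0.05, 0.6))
    deg <- hbond_degrees(bonds, n)
    expect_equal(sum(deg$degree), 2 * nrow(bonds))
    h <- bond_count_histogram(bonds, n)
    expect_equal(sum(h$percent), 100)
    expect_equal(h$mean_nhb, 2 * nrow(bonds) / n)
  }
})

test_that("connected components match brute-force reachability", {
  # worked example: bonds {1-2, 2-3}, {4-5} on 6 molecules
  bonds <- data.frame(donor = c(1, 2, 4), h_site = c(1, 1, 1),
                      acceptor = c(2, 3, 5))
  cl <- hbond_components(bonds, 6)
  expect_equal(sort(cl$sizes, decreasing = TRUE), c(3, 2, 1))
  expect_equal(cl$mean_cluster, 2)
  expect_equal(cl$mean_molecule, (9 + 4 + 1) / 6)

  none <- hbond_components(data.frame(donor = integer(0), h_site = integer(0),
                                      acceptor = integer(0)), 5)
  expect_equal(none$sizes, rep(1, 5))

  full <- data.frame(donor = c(1, 2, 3, 4), h_site = 1, acceptor = c(2, 3, 4, 1))
  expect_equal(hbond_components(full, 4)$sizes, 4)

  set.seed(12)
  for (k in 1:100) {
    n <- sample(4:20, 1)
    bonds <- random_bond_table(n, p = runif(1, 0.05, 0.7))
    got <- sort(hbond_components(bonds, n)$sizes, decreasing = TRUE)
    want <- brute_components(cbind(bonds$donor, bonds$acceptor), n)
    expect_equal(got, want)
  }
})

test_that("patch detection matches the exhaustive four-bonded oracle", {
  lat <- generate_lattice_network(2, bond_removal_p = 0, seed = 1)
  pd <- patch_distribution(lat$bonds, lat$n_molecules)
  expect_equal(pd$sizes, lat$n_molecules)
  expect_equal(pd$distribution$probability, 1)
  expect_equal(pd$fraction_in_patches, 1)

  sparse <- data.frame(donor = c(1, 2), h_site = 1, acceptor = c(2, 3))
  pd0 <- patch_distribution(sparse, 5)
  expect_equal(length(pd0$sizes), 0)
  expect_equal(pd0$mean_n4, 0)
  expect_equal(pd0$fraction_in_patches, 0)

  set.seed(13)
  for (k in 1:150) {
    n <- sample(6:15, 1)
    bonds <- random_bond_table(n, p = runif(1, 0.2, 0.9))
    got <- sort(patch_distribution(bonds, n)$sizes, decreasing = TRUE)
    want <- sort(brute_patches(bonds, n), decreasing = TRUE)
    if (length(want) == 0) {
      expect_equal(length(got), 0)
    } else {
      expect_equal(got, want)
    }
  }
})

test_that("the bifurcated-inclusion flag relaxes the four-bonded definition", {
  # molecule 1: 2 donor + 3 acceptor bonds -> excluded strictly, included
  # under the relaxed rule
  bonds <- data.frame(
    donor = c(1, 1, 2, 3, 4, 5, 6, 2, 3),
    h_site = c(1, 2, 1, 1, 1, 1, 1, 2, 2),
    acceptor = c(2, 3, 1, 1, 1, 4, 5, 6, 6))
  strict <- patch_distribution(bonds, 6)
  relaxed <- patch_distribution(bonds, 6, include_bifurcated = TRUE)
  expect_false(strict$four_bonded[1])
  expect_true(relaxed$four_bonded[1])
})

test_that("percolation check compares the largest cluster to the threshold", {
  one <- hbond_components(data.frame(donor = 1:399, h_site = 1,
                                     acceptor = 2:400), 400)
  pc <- percolation_check(one, 400)
  expect_true(pc$percolating)
  expect_equal(pc$largest_fraction, 1)

  # two clusters of 200: below the default 0.95 threshold
  half <- data.frame(donor = c(1:199, 201:399), h_site = 1,
                     acceptor = c(2:200, 202:400))
  pc2 <- percolation_check(hbond_components(half, 400), 400)
  expect_false(pc2$percolating)
  expect_equal(pc2$largest_fraction, 0.5)

  # diluted lattice: fraction equals the brute-force largest component
  lat <- generate_lattice_network(2, bond_removal_p = 0.1, seed = 8)
  cl <- hbond_components(lat$bonds, lat$n_molecules)
  want <- brute_components(cbind(lat$bonds$donor, lat$bonds$acceptor),
                           lat$n_molecules)[1]
  expect_equal(percolation_check(cl, lat$n_molecules)$largest_fraction,
               want / lat$n_molecules)
})

test_that("frame-averaged statistics are internally consistent", {
  run <- small_liquid_run()
  st <- hbond_statistics(run$trajectory, frame_stride = 500)
  expect_equal(sum(st$histogram$percent), 100, tolerance = 1e-9)
  expect_gte(st$mean_largest_fraction, 0)
  expect_lte(st$mean_largest_fraction, 1)
  expect_equal(nrow(st$per_frame), st$n_frames)
  expect_true(all(st$per_frame$mean_nhb >= 0))
})
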