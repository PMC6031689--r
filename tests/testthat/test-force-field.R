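test_that("harmonic bond matches its closed form and numerical gradient", {
  expect_equal(harmonic_bond(1, 100, 1), list(energy = 0, force = 0))
  expect_equal(harmonic_bond(1.1, 100, 1)$energy, 1.0, tolerance = 1e-12)
  withr::with_seed(4, {
    for (i in 1:50) {
      k <- runif(1, 1, 200); r0 <- runif(1, 0.5, 3); r <- runif(1, 0.3, 4)
      h <- 1e-6
      fd <- -(harmonic_bond(r + h, k, r0)$energy -
                harmonic_bond(r - h, k, r0)$energy) / (2 * h)
      expect_equal(harmonic_bond(r, k, r0)$force, fd, tolerance = 1e-5)
    }
  })
})

test_that("LJ pair truncates, shifts, and matches its numerical gradient", {
  expect_equal(lj_pair(2.5, 1, 1, 2.5), list(energy = 0, force = 0))
  expect_equal(lj_pair(3.0, 1, 1, 2.5), list(energy = 0, force = 0))
  m <- lj_pair(2^(1 / 6), 0.7, 1, Inf)
  expect_equal(m$energy, -0.7, tolerance = 1e-12)
  expect_equal(m$force, 0, tolerance = 1e-9)
  withr::with_seed(5, {
    for (i in 1:100) {
      eps <- runif(1, 0.1, 3); sig <- runif(1, 0.8, 2)
      r <- runif(1, 0.85 * sig, 2.4 * sig)
      h <- 1e-7
      fd <- -(lj_pair(r + h, eps, sig, 2.5 * sig)$energy -
                lj_pair(r - h, eps, sig, 2.5 * sig)$energy) / (2 * h)
      expect_equal(lj_pair(r, eps, sig, 2.5 * sig)$force, fd,
                   tolerance = 1e-5 * max(1, abs(fd)))
    }
  })
})

test_that("shell pair potential is zero beyond cutoff and -eps for an aligned pair", {
  ff <- force_field(np_eps = 4, np_rmin = 2, np_rcut = 3.2, np_theta0 = 0)
  far <- np_pair(c(3.3, 0, 0), c(0, 0, 1), c(0, 0, 1), ff)
  expect_equal(far$energy, 0)
  expect_equal(far$force_j, c(0, 0, 0))
  # side-by-side beads, parallel normals perpendicular to rhat, at rmin
  al <- np_pair(c(2, 0, 0), c(0, 0, 1), c(0, 0, 1), ff)
  expect_equal(al$energy, -4, tolerance = 1e-9)
  expect_error(np_pair(c(2, 0, 0), c(0, 0, 1.01), c(0, 0, 1), ff),
               "unit length")
})

test_that("shell pair forces and torques match finite differences", {
  ff <- force_field(np_eps = 3, np_rmin = 2.2, np_rcut = 4, np_mu = 3,
                    np_zeta = 4, np_theta0 = 0.25)
  h <- 1e-6
  uof <- function(rv, ni, nj)
    np_pair(rv, ni / sqrt(sum(ni^2)), nj / sqrt(sum(nj^2)), ff)$energy
  withr::with_seed(6, {
    nbad_f <- 0; nbad_g <- 0
    for (t in 1:1000) {
      rv <- rnorm(3); rv <- rv / sqrt(sum(rv^2)) * runif(1, 1.4, 4.2)
      ni <- rnorm(3); ni <- ni / sqrt(sum(ni^2))
      nj <- rnorm(3); nj <- nj / sqrt(sum(nj^2))
      res <- np_pair(rv, ni, nj, ff)
      fd <- vapply(1:3, function(k) {
        e <- c(0, 0, 0); e[k] <- h
        (uof(rv + e, ni, nj) - uof(rv - e, ni, nj)) / (2 * h)
      }, numeric(1))
      if (max(abs(res$force_j + fd)) > 1e-5) nbad_f <- nbad_f + 1
      gd <- vapply(1:3, function(k) {
        e <- c(0, 0, 0); e[k] <- h
        (uof(rv, ni + e, nj) - uof(rv, ni - e, nj)) / (2 * h)
      }, numeric(1))
      gproj <- -(res$gn_i - sum(res$gn_i * ni) * ni)
      if (max(abs(gproj - gd)) > 1e-5) nbad_g <- nbad_g + 1
    }
    expect_identical(nbad_f, 0)
    expect_identical(nbad_g, 0)
  })
})

test_that("assembled forces match the all-pairs reference and obey Newton's third law", {
  ff <- force_field(np_eps = 2, np_rmin = 1.4, np_rcut = 2.6, sigma_lj = 1.2,
                    lj_cutoff = 3, eps_polymer_np = 0.3, np_theta0 = 0.1)
  for (seed in 1:6) {
    sys <- random_mixed_system(n_poly = 35, n_np = 25, box = 14, seed = seed)
    res <- compute_forces(sys, ff)
    ref <- brute_forces(sys, ff)
    expect_lt(abs(res$potential_energy - ref$energy), 1e-9)
    expect_lt(max(abs(res$forces - ref$forces)), 1e-9)
    # no tethers here: pair forces sum to zero
    expect_lt(max(abs(colSums(res$forces))), 1e-8 * nrow(sys$positions))
    expect_lt(abs(sum(res$breakdown) - res$potential_energy), 1e-9)
  }
})

test_that("energy is invariant under rigid translation and rotation", {
  ff <- force_field(np_eps = 2, np_rmin = 1.4, np_rcut = 2.6, sigma_lj = 1.2,
                    lj_cutoff = 3)
  sys <- random_mixed_system(n_poly = 20, n_np = 20, box = 14, seed = 9,
                             with_bonds = FALSE)
  e0 <- compute_forces(sys, ff)$potential_energy
  # translation (with rewrap)
  s2 <- sys
  s2$positions <- gelperm:::wrap_coords(sys$positions + 3.123, sys$box_length)
  expect_equal(compute_forces(s2, ff)$potential_energy, e0, tolerance = 1e-9)
  # rotation about the box center by 90 degrees (keeps the cube invariant)
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  c0 <- rep(sys$box_length / 2, 3)
  s3 <- sys
  s3$positions <- sweep(sweep(sys$positions, 2, c0) %*% t(R), 2, c0, "+")
  s3$positions <- gelperm:::wrap_coords(s3$positions, sys$box_length)
  s3$normals <- sys$normals %*% t(R)
  expect_equal(compute_forces(s3, ff)$potential_energy, e0, tolerance = 1e-9)
})

test_that("a displaced node bead feels the tether restoring force", {
  net <- build_network(network_spec(30, 9.5, bead_spacing = 1.8,
                                    tether_k = 10))
  i <- net$tether_index[1]
  net$positions[i, 1] <- net$positions[i, 1] + 0.3
  f <- compute_forces(net, force_field(tether_k = 10))
  # tether contribution: -2 k d along x (bond/LJ forces also act; isolate by
  # subtracting the same system with tether_k = 0)
  f0 <- compute_forces(net, force_field(tether_k = 0))
  expect_equal(f$forces[i, 1] - f0$forces[i, 1], -2 * 10 * 0.3,
               tolerance = 1e-9)
})

test_that("stiffer shells pay more energy for the same deformation", {
  m <- build_np_shell(10, 2.5)
  dimpled <- m$bead_positions
  push <- dimpled[, 3] > 4
  dimpled[push, ] <- dimpled[push, ] * 0.85
  cost <- vapply(c(2, 4, 8, 16), function(e) {
    ff <- force_field(np_eps = e, np_rmin = 2.33, np_rcut = 4.15)
    en <- function(p) {
      sys <- empty_system(30)
      n <- nrow(p)
      sys$positions <- gelperm:::wrap_coords(p + 15, 30)
      sys$unwrapped <- p + 15
      sys$velocities <- matrix(0, n, 3)
      sys$normals <- m$bead_normals
      sys$bead_type <- rep("np_bead", n)
      sys$np_id <- rep(1L, n)
      sys$masses <- rep(1, n)
      sys$rigid <- FALSE
      compute_forces(sys, ff)$potential_energy
    }
    en(dimpled) - en(m$bead_positions)
  }, numeric(1))
  expect_true(all(diff(cost) > 0))
})

test_that("boxes smaller than twice the interaction range are rejected", {
  sys <- random_mixed_system(n_poly = 5, n_np = 0, box = 6, seed = 1)
  expect_error(compute_forces(sys, force_field(lj_cutoff = 5)), "twice")
})
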