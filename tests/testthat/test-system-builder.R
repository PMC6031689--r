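test_that("chain count follows 3 n^2 and nodes sit at every 3-fiber crossing", {
  for (n in c(2, 3, 6, 8)) {
    spec <- network_spec(box_length = 16.3 * n, mesh_size = 16.3)
    expect_equal(spec$n_cells, n)
    net <- build_network(spec)
    expect_equal(chain_count(net), 3L * n^2)
    # every node bead is shared by three fibers: bond degree 6
    deg <- tabulate(c(net$bonds[, 1], net$bonds[, 2]),
                    nbins = nrow(net$positions))
    expect_equal(sum(deg == 6), n^3)
    expect_true(all(deg[net$bead_type == "polymer"] == 2))
  }
})

test_that("the printed full-scale geometry gives 108 chains and 216 nodes", {
  net <- build_network(network_spec(98, 16))
  expect_identical(chain_count(net), 108L)
  expect_identical(sum(net$bead_type == "node"), 216L)
})

test_that("a single-cell lattice degenerates to 3 chains and 1 node", {
  net <- build_network(network_spec(10, 9.5, bead_spacing = 2))
  expect_identical(chain_count(net), 3L)
  expect_identical(sum(net$bead_type == "node"), 1L)
})

test_that("fibers close periodically and bonds rest at the generated spacing", {
  net <- build_network(network_spec(49, 16))
  s <- net$meta$spacing_eff
  expect_true(all(abs(net$bonds[, 4] - s) < 1e-9))
  # realized bond lengths equal the rest length (undistorted lattice)
  d <- net$positions[net$bonds[, 2], ] - net$positions[net$bonds[, 1], ]
  d <- d - net$box_length * round(d / net$box_length)
  expect_true(all(abs(sqrt(rowSums(d^2)) - s) < 1e-9))
  # wrapping any bead by the box maps back onto the bead set
  shifted <- gelperm:::wrap_coords(net$positions + net$box_length,
                                   net$box_length)
  expect_equal(shifted, net$positions, tolerance = 1e-12)
})

test_that("invalid network specs are rejected", {
  expect_error(network_spec(49, 16, bead_spacing = -1), "positive")
  expect_error(network_spec(49, 16, bead_spacing = 20), "box_length > mesh_size")
  expect_error(network_spec(10, 12), "box_length > mesh_size")
})

test_that("spherical shells are radius-exact, quasi-uniform, outward-oriented", {
  m <- build_np_shell(10, 1.0)
  r <- sqrt(rowSums(m$bead_positions^2))
  expect_true(all(abs(r - 5) < 1e-9))
  expect_gte(nrow(m$bead_positions), 251)
  expect_lte(nrow(m$bead_positions), 377)
  expect_lt(sqrt(sum(colMeans(m$bead_normals)^2)), 0.05)
  nn <- sqrt(rowSums(m$bead_normals^2))
  expect_true(all(abs(nn - 1) < 1e-9))
  expect_error(build_np_shell(10, 6), "fewer than 12")
})

test_that("rigid ellipsoids preserve the reference-sphere volume", {
  for (ar in c(2, 3)) {
    m <- build_rigid_ellipsoid(10, ar, 2)
    a <- 5 * ar^(2 / 3); b <- 5 * ar^(-1 / 3)
    expect_equal(max(abs(m$bead_positions[, 1])), a, tolerance = 0.05)
    expect_equal((4 / 3) * pi * a * b^2, (4 / 3) * pi * 5^3,
                 tolerance = 1e-9)
    # beads satisfy the ellipsoid equation
    q <- (m$bead_positions[, 1] / a)^2 + (m$bead_positions[, 2] / b)^2 +
      (m$bead_positions[, 3] / b)^2
    expect_true(all(abs(q - 1) < 1e-9))
  }
  m1 <- build_rigid_ellipsoid(10, 1, 2)
  expect_equal(sqrt(rowSums(m1$bead_positions^2)), rep(5, nrow(m1$bead_positions)),
               tolerance = 1e-9)
  expect_error(build_rigid_ellipsoid(10, 0.5), "aspect_ratio")
})

test_that("place_nps respects clearance, is seeded, and count 0 is identity", {
  net <- build_network(network_spec(30, 9.5, bead_spacing = 1.8))
  expect_identical(place_nps(net, build_np_shell(6, 1.5), 0), net)

  sys <- place_nps(net, build_np_shell(6, 1.5), 3, min_clearance = 1.5,
                   seed = 11)
  expect_identical(length(sys$rigid), 3L)
  validate_bead_system(sys)
  # brute-force clearance check of NP beads against network beads
  np <- which(sys$bead_type == "np_bead")
  host <- which(sys$bead_type != "np_bead")
  for (k in 1:3) {
    beads <- sys$positions[np[sys$np_id[np] == k], , drop = FALSE]
    for (d in 1:3) {
      dd <- outer(beads[, d], sys$positions[host, d], "-")
      dd <- dd - sys$box_length * round(dd / sys$box_length)
      r2 <- if (d == 1) dd^2 else r2 + dd^2
    }
    expect_gte(sqrt(min(r2)), 1.5)
  }
  # NP bead sets are disjoint
  expect_false(any(duplicated(np[order(sys$np_id[np])])))

  sys2 <- place_nps(net, build_np_shell(6, 1.5), 3, min_clearance = 1.5,
                    seed = 11)
  expect_identical(sys, sys2)
  sys3 <- place_nps(net, build_np_shell(6, 1.5), 3, min_clearance = 1.5,
                    seed = 12)
  expect_false(identical(sys$positions, sys3$positions))
  # the network part is seed-independent
  expect_identical(sys$positions[host, ], sys3$positions[host, ])

  expect_error(
    place_nps(net, build_np_shell(6, 1.5), 500, min_clearance = 2, seed = 1,
              max_attempts = 600),
    "attempts")
})
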