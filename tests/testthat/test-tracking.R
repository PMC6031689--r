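test_that("track MSD matches explicit loops, zero and 3-4-5 cases", {
  n_fr <- 6
  still <- tibble::tibble(particle_id = rep(1:2, each = n_fr),
                          frame = rep(0:(n_fr - 1), 2),
                          t_s = rep(0:(n_fr - 1), 2) * 0.1,
                          x_um = 0, y_um = 0)
  attr(still, "frame_interval") <- 0.1
  expect_equal(track_msd(still, 0.2)$ensemble, 0)

  walk <- tibble::tibble(particle_id = 1L, frame = 0:4, t_s = (0:4) * 0.1,
                         x_um = 3 * (0:4), y_um = 4 * (0:4))
  attr(walk, "frame_interval") <- 0.1
  expect_equal(track_msd(walk, 0.1)$ensemble, 25)

  withr::with_seed(20, {
    trk <- generate_tracks(n_particles = 7, frame_interval = 0.05,
                           duration = 1, localization_sd = 0, seed = 5)
    got <- track_msd(trk, lag = 0.2)
    # explicit reference: per particle over all origins, then mean over n
    ref <- sapply(split(trk, trk$particle_id), function(d) {
      l <- 4
      o <- seq_len(nrow(d) - l)
      mean((d$x_um[o + l] - d$x_um[o])^2 + (d$y_um[o + l] - d$y_um[o])^2)
    })
    expect_equal(got$per_particle$msd, unname(ref), tolerance = 1e-12)
    expect_equal(got$ensemble, mean(ref), tolerance = 1e-12)
  })
  expect_error(track_msd(walk, 0.13), "whole number")
  expect_error(track_msd(walk, 5), "duration")
})

test_that("Brownian tracks reproduce the 2D Einstein relation", {
  trk <- generate_tracks(n_particles = 100, d_spec = 0.2,
                         localization_sd = 0, seed = 42)
  expect_equal(track_msd(trk, lag = 1)$ensemble, 4 * 0.2 * 1,
               tolerance = 0.1 * 0.8)
})

test_that("effective diffusivity is MSD over 4t", {
  fake <- list(per_particle = tibble::tibble(particle_id = 1:2,
                                             msd = c(1, 0), n_obs = 10L))
  d <- effective_diffusivity(fake, time_scale = 1)
  expect_identical(d$d_eff, c(0.25, 0))

  trk <- generate_tracks(n_particles = 100, d_spec = 0.05,
                         localization_sd = 0, seed = 7)
  d <- effective_diffusivity(trk, time_scale = 1)
  expect_equal(attr(d, "ensemble"), 0.05, tolerance = 0.1)
})

test_that("the D_eff distribution reports the threshold fraction", {
  all_fast <- deff_distribution(rep(1, 50))
  expect_identical(all_fast$fraction_above, 1)
  expect_error(deff_distribution(numeric(0)), "empty")

  # planted mixture with a known 4.7% fast fraction
  withr::with_seed(11, {
    n <- 1000
    fast <- runif(n) < 0.047
    d <- ifelse(fast, 10^runif(n, -0.9, 0.5), 10^runif(n, -3, -1.2))
    dist <- deff_distribution(d, threshold = 0.1)
    se <- sqrt(0.047 * 0.953 / n)
    expect_lt(abs(dist$fraction_above - 0.047), 4 * se + 0.01)
  })
})

test_that("the track generator is seeded and models noise and confinement", {
  a <- generate_tracks(n_particles = 10, seed = 3)
  b <- generate_tracks(n_particles = 10, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, generate_tracks(n_particles = 10, seed = 4)))
  expect_identical(nrow(a), 10L * (as.integer(10 / 0.0326) + 1L))

  # localization noise inflates MSD by an additive 4 sd^2
  base <- generate_tracks(n_particles = 150, d_spec = 0.02,
                          localization_sd = 0, seed = 9)
  noisy <- generate_tracks(n_particles = 150, d_spec = 0.02,
                           localization_sd = 0.05, seed = 9)
  lag1 <- attr(base, "frame_interval")
  infl <- track_msd(noisy, lag1)$ensemble - track_msd(base, lag1)$ensemble
  expect_equal(infl, 4 * 0.05^2, tolerance = 0.25 * 4 * 0.05^2)

  # confinement: long-time MSD plateaus at ~R^2 (order of magnitude)
  conf <- generate_tracks(n_particles = 60, d_spec = 1,
                          confinement_radius = 0.5, localization_sd = 0,
                          duration = 5, seed = 13)
  plateau <- track_msd(conf, lag = 4)$ensemble
  expect_gt(plateau, 0.5^2 / 3)
  expect_lt(plateau, 3 * 0.5^2)

  # parameter recovery: slope of MSD over 4 returns the planted D
  trk <- generate_tracks(n_particles = 100, d_spec = 0.08,
                         localization_sd = 0, seed = 21)
  lags <- attr(trk, "frame_interval") * (1:10)
  ms <- vapply(lags, function(l) track_msd(trk, l)$ensemble, numeric(1))
  Dhat <- unname(coef(lm(ms ~ lags))[2] / 4)
  expect_equal(Dhat, 0.08, tolerance = 0.1 * 0.08)

  expect_error(generate_tracks(frame_interval = 0), "positive")
})
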