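test_that("MSD handles static, ballistic, and random-walk motion", {
  F <- 50
  still <- array(3.7, c(F, 2, 3))
  m <- msd_3d(still)
  expect_true(all(m$msd == 0))

  t <- 0:(F - 1)
  ball <- array(0, c(F, 1, 3))
  ball[, 1, 1] <- 2 * t           # x = v t with v = 2
  m <- msd_3d(ball)
  expect_equal(m$msd, (2 * m$lag)^2, tolerance = 1e-12)

  # pure random walk: MSD(l) = 3 s^2 l
  errs <- vapply(1:3, function(seed) {
    withr::with_seed(seed, {
      steps <- array(rnorm(999 * 20 * 3, sd = 0.5), c(999, 20, 3))
      walk <- array(0, c(1000, 20, 3))
      walk[-1, , ] <- apply(steps, c(2, 3), cumsum)
      m <- msd_3d(walk, lags = 1:20)
      mean(abs(m$msd / (3 * 0.25 * m$lag) - 1))
    })
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})

test_that("MSD equals the explicit two-loop reference", {
  withr::with_seed(12, {
    x <- array(cumsum(rnorm(40 * 3 * 3, sd = 0.3)), c(40, 3, 3))
    m <- msd_3d(x, lags = c(1, 2, 5, 13))
    expect_equal(m$msd, brute_msd(x, c(1, 2, 5, 13)), tolerance = 1e-12)
  })
})

test_that("wrapped input is rejected", {
  x <- array(0, c(10, 1, 3))
  x[, 1, 1] <- c(0, 1, 2, 24, 0, 1, 24, 2, 1, 0)   # jumps across a 25-box
  expect_error(msd_3d(x, box = 25), "unwrapped")
})

test_that("diffusivity is the fitted slope over six", {
  m <- tibble::tibble(lag = 1:100, msd = 3.0 * (1:100))
  fit <- fit_diffusivity(m, window = c(1, 100))
  expect_identical(fit$diffusivity, fit$slope / 6)
  expect_equal(fit$diffusivity, 0.5, tolerance = 1e-12)

  withr::with_seed(2, {
    lag <- seq(0.1, 1000, by = 0.1)
    noisy <- tibble::tibble(lag = lag, msd = 6 * 0.1 * lag + rnorm(length(lag), sd = 1))
    nfit <- fit_diffusivity(noisy, window = c(0, 1000))
    expect_equal(nfit$diffusivity, 0.1, tolerance = 0.05)
  })
  expect_error(fit_diffusivity(m, window = c(500, 600)), "fewer than 2")

  # invariance under joint time and window rescaling
  m2 <- tibble::tibble(lag = m$lag * 10, msd = m$msd)
  fit2 <- fit_diffusivity(m2, window = c(10, 1000))
  expect_equal(fit2$diffusivity * 10, fit$diffusivity, tolerance = 1e-9)
})

test_that("contact counts follow the 3-sigma bead-level definition", {
  # one NP bead near one polymer bead at controlled distances
  mk <- function(d) {
    frames <- array(0, c(1, 2, 3))
    frames[1, 1, ] <- c(10, 10, 10)
    frames[1, 2, ] <- c(10 + d, 10, 10)
    manual_trajectory(frames, c("polymer", "np_bead"), c(NA, 1L), box = 40)
  }
  expect_identical(contact_counts(mk(2.9))$contacts, 1L)
  expect_identical(contact_counts(mk(3.1))$contacts, 0L)

  # NP bead within range of 5 polymer beads: 1 in bead mode, 5 in pair mode
  frames <- array(0, c(1, 6, 3))
  frames[1, 1, ] <- c(10, 10, 10)
  for (k in 1:5) frames[1, 1 + k, ] <- c(10 + 0.4 * k, 10, 10)
  tr <- manual_trajectory(frames, c("np_bead", rep("polymer", 5)),
                          c(1L, rep(NA, 5)), box = 40)
  expect_identical(contact_counts(tr)$contacts, 1L)
  expect_identical(contact_counts(tr, count = "pairs")$contacts, 5L)
})

test_that("contact counts equal a brute-force double loop", {
  withr::with_seed(31, {
    N <- 120; Fn <- 4; box <- 20
    frames <- array(runif(Fn * N * 3) * box, c(Fn, N, 3))
    type <- sample(c("polymer", "node", "np_bead"), N, replace = TRUE)
    npid <- ifelse(type == "np_bead",
                   sample(1:3, N, replace = TRUE), NA_integer_)
    tr <- manual_trajectory(frames, type, npid, box)
    tr$rigid <- rep(FALSE, 3)
    got <- contact_counts(tr, cutoff = 3)
    for (f in 1:Fn) for (np in 1:3) {
      cnt <- 0L
      for (i in which(type == "np_bead" & npid == np)) {
        touched <- FALSE
        for (j in which(type != "np_bead")) {
          d <- frames[f, i, ] - frames[f, j, ]
          d <- d - box * round(d / box)
          if (sum(d^2) < 9) touched <- TRUE
        }
        if (touched) cnt <- cnt + 1L
      }
      expect_identical(got$contacts[got$time == f - 1 & got$np == np], cnt)
    }
  })
})

test_that("gyration shape metrics recover symmetry, AR, and degeneracy", {
  # octahedral shell: exactly isotropic gyration tensor
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1)) * 5
  sh <- shape_metrics(array(oct, c(1, 6, 3))[, , , drop = FALSE])
  expect_equal(sh$ar, 1, tolerance = 1e-6)

  m <- build_rigid_ellipsoid(10, 2, 1.0)
  sh <- shape_metrics(array(m$bead_positions,
                            c(1, nrow(m$bead_positions), 3)))
  expect_equal(sh$ar, 2, tolerance = 0.02 * 2)

  line <- cbind(seq_len(8), 0, 0)
  sh <- shape_metrics(array(line, c(1, 8, 3)))
  expect_true(sh$degenerate)
  expect_true(is.na(sh$ar))
})
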