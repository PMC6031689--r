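#' Generate synthetic 2D multi-particle-tracking data
#'
#' Emulates a fluorescence multi-particle-tracking acquisition: each
#' particle gets a diffusivity drawn from a heterogeneous distribution
#' (by default a log-normal mixture of a slow, gel-hindered majority and a
#' fast sub-population, spanning the sub-0.1 to above-0.1 um^2/s range),
#' performs 2D Brownian steps with per-axis variance `2 D dt`, is blurred by
#' Gaussian localization noise, and is optionally reflected inside a
#' confinement disk. Defaults mirror a typical acquisition: 100 particles,
#' 32.6 ms frame interval, 10 s movies, ~10 nm localization error.
#'
#' @param n_particles Number of tracks.
#' @param frame_interval Frame interval (s).
#' @param duration Movie duration (s).
#' @param d_spec Diffusivity distribution: either a function `(n) -> D`
#'   (um^2/s), a single number, or the default mixture list with fields
#'   `fraction_fast`, `median_slow`, `median_fast`, `sdlog_slow`,
#'   `sdlog_fast`.
#' @param localization_sd Localization noise standard deviation per axis
#'   (um).
#' @param confinement_radius Optional reflecting disk radius (um).
#' @param seed Integer seed; the track set is reproducible for a given seed.
#' @return A `track_set` tibble with columns `particle_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`; the per-particle true diffusivities are kept in
#'   attribute `true_d`.
#' @export
#' @examples
#' trk <- generate_tracks(n_particles = 20, seed = 7)
#' dplyr::count(trk, particle_id)
generate_tracks <- function(n_particles = 100, frame_interval = 0.0326,
                            duration = 10,
                            d_spec = list(fraction_fast = 0.05,
                                          median_slow = 0.005,
                                          median_fast = 0.3,
                                          sdlog_slow = 0.9,
                                          sdlog_fast = 0.5),
                            localization_sd = 0.01,
                            confinement_radius = NULL, seed = 1) {
  if (frame_interval <= 0 || duration <= 0)
    stop("frame_interval and duration must be positive")
  n_frames <- floor(duration / frame_interval) + 1L
  withr::with_seed(seed, {
    d_true <- if (is.function(d_spec)) {
      d_spec(n_particles)
    } else if (is.numeric(d_spec) && length(d_spec) == 1) {
      rep(d_spec, n_particles)
    } else {
      fast <- runif(n_particles) < d_spec$fraction_fast
      exp(ifelse(fast,
                 rnorm(n_particles, log(d_spec$median_fast),
                       d_spec$sdlog_fast),
                 rnorm(n_particles, log(d_spec$median_slow),
                       d_spec$sdlog_slow)))
    }
    if (any(d_true < 0)) stop("diffusivities must be non-negative")

    tracks <- purrr::map(seq_len(n_particles), function(p) {
      sdstep <- sqrt(2 * d_true[p] * frame_interval)
      dx <- c(0, rnorm(n_frames - 1, sd = sdstep))
      dy <- c(0, rnorm(n_frames - 1, sd = sdstep))
      x <- cumsum(dx); y <- cumsum(dy)
      if (!is.null(confinement_radius)) {
        R <- confinement_radius
        for (i in seq2(2, n_frames)) {
          r <- sqrt(x[i]^2 + y[i]^2)
          if (r > R) {            # reflect radially across the boundary
            s <- (2 * R - r) / r
            x[i:n_frames] <- x[i:n_frames] + (s - 1) * x[i]
            y[i:n_frames] <- y[i:n_frames] + (s - 1) * y[i]
          }
        }
      }
      if (localization_sd > 0) {
        x <- x + rnorm(n_frames, sd = localization_sd)
        y <- y + rnorm(n_frames, sd = localization_sd)
      }
      tibble::tibble(particle_id = p, frame = seq_len(n_frames) - 1L,
                     t_s = (seq_len(n_frames) - 1L) * frame_interval,
                     x_um = x, y_um = y)
    })
    out <- dplyr::bind_rows(tracks)
    structure(out, class = c("track_set", class(out)),
              frame_interval = frame_interval, duration = duration,
              n_particles = n_particles, true_d = d_true)
  })
}

seq2 <- function(from, to) if (to < from) integer(0) else seq(from, to)

track_frame_interval <- function(tracks) {
  fi <- attr(tracks, "frame_interval")
  if (!is.null(fi)) return(fi)
  dt <- diff(tracks$t_s[tracks$particle_id == tracks$particle_id[1]])
  if (length(dt) == 0 || max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("track times must be uniform")
  dt[1]
}

#' Per-particle and ensemble 2D MSD at a time lag
#'
#' `MSD_t = sum[(x_t - x_0)^2 + (y_t - y_0)^2] / n` over the tracked
#' particles: each particle's squared 2D displacement at the requested lag
#' (averaged over all valid time origins within its track by default), then
#' the ensemble mean over the `n` particles. Tracks shorter than the lag are
#' skipped.
#'
#' @param tracks A `track_set` (or any tibble with `particle_id`, `t_s`,
#'   `x_um`, `y_um`).
#' @param lag Time lag (s); snapped to the nearest whole number of frames
#'   (rejected if that changes the lag by more than 5%, e.g. a 1 s lag on a
#'   32.6 ms grid uses 31 frames = 1.011 s) and no longer than the longest
#'   track.
#' @param multi_origin Average each track over all time origins (default)
#'   or use its first frame only.
#' @return List with `per_particle` (tibble `particle_id`, `msd`, `n_obs`)
#'   and `ensemble` (the mean over particles, um^2).
#' @export
track_msd <- function(tracks, lag, multi_origin = TRUE) {
  dt <- track_frame_interval(tracks)
  lf <- as.integer(round(lag / dt))
  if (lf < 1 || abs(lf * dt - lag) > 0.05 * lag)
    stop("lag must be a whole number of frame intervals (within 5%)")
  per <- tracks |>
    dplyr::group_by(.data$particle_id) |>
    dplyr::group_modify(function(d, key) {
      F <- nrow(d)
      if (F <= lf) return(tibble::tibble(msd = NA_real_, n_obs = 0L))
      o <- if (multi_origin) seq_len(F - lf) else 1L
      dx <- d$x_um[o + lf] - d$x_um[o]
      dy <- d$y_um[o + lf] - d$y_um[o]
      tibble::tibble(msd = mean(dx^2 + dy^2), n_obs = length(o))
    }) |>
    dplyr::ungroup()
  kept <- per[!is.na(per$msd), ]
  if (nrow(kept) == 0) stop("lag is beyond every track duration")
  structure(list(per_particle = kept, ensemble = mean(kept$msd)),
            realized_lag = lf * dt)
}

#' Per-particle effective diffusivity at a time scale
#'
#' `D_eff = MSD(t) / (4 t)` per particle at the stated time scale (2D), and
#' the ensemble mean over the `n` particles.
#'
#' @param x A `track_set`, or the result of [track_msd()].
#' @param time_scale Time scale t (s); default 1.
#' @param ... Passed to [track_msd()] when `x` is a track set.
#' @return A `deff_result` tibble (`particle_id`, `msd`, `d_eff`) with the
#'   ensemble mean in attribute `ensemble`.
#' @export
effective_diffusivity <- function(x, time_scale = 1, ...) {
  if (inherits(x, "track_set") ||
      (is.data.frame(x) && "x_um" %in% names(x))) {
    x <- track_msd(x, lag = time_scale, ...)
  }
  per <- x$per_particle
  dt <- attr(x, "realized_lag") %||% time_scale
  per$d_eff <- per$msd / (4 * dt)
  structure(per, class = c("deff_result", class(per)),
            ensemble = mean(per$d_eff), time_scale = time_scale)
}

#' Distribution of effective diffusivities and threshold fraction
#'
#' Histogram of `log10(D_eff)` (zeros and negatives are binned separately
#' and excluded from the log histogram) together with the fraction of
#' particles whose `D_eff` strictly exceeds the threshold.
#'
#' @param d_eff Numeric vector of per-particle effective diffusivities
#'   (um^2/s), or a [effective_diffusivity()] result.
#' @param threshold Mobility threshold (um^2/s); default 0.1.
#' @param bins Histogram bin count.
#' @return A `deff_distribution` list: `histogram` (tibble `mid`, `count`),
#'   `fraction_above`, `n`, `n_nonpositive`, `threshold`.
#' @export
deff_distribution <- function(d_eff, threshold = 0.1, bins = 30) {
  if (is.data.frame(d_eff)) d_eff <- d_eff$d_eff
  if (length(d_eff) == 0) stop("empty input")
  pos <- d_eff[d_eff > 0]
  h <- if (length(pos) > 0) {
    br <- seq(min(log10(pos)) - 1e-9, max(log10(pos)) + 1e-9,
              length.out = bins + 1)
    cnt <- tabulate(findInterval(log10(pos), br, rightmost.closed = TRUE),
                    nbins = bins)
    tibble::tibble(mid = (br[-1] + br[-length(br)]) / 2, count = cnt)
  } else {
    tibble::tibble(mid = numeric(0), count = integer(0))
  }
  structure(
    list(histogram = h,
         fraction_above = mean(d_eff > threshold),
         n = length(d_eff), n_nonpositive = sum(d_eff <= 0),
         threshold = threshold),
    class = "deff_distribution")
}

#' @export
print.deff_distribution <- function(x, ...) {
  cat(sprintf("<deff_distribution> n = %d, %.1f%% above %.3g um^2/s\n",
              x$n, 100 * x$fraction_above, x$threshold))
  invisible(x)
}
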