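#' Ensemble mean-squared displacement of NP centroids (3D)
#'
#' `MSD(t) = <(x_t - x_0)^2 + (y_t - y_0)^2 + (z_t - z_0)^2>`, averaged over
#' all particles and (by default) all valid time origins on the stored frame
#' grid. Coordinates must be unwrapped; wrapped input is rejected by a
#' heuristic (any single-frame jump larger than half the box).
#'
#' @param x An `md_trajectory` (NP centroids are used), or an F x P x 3
#'   array / F x 3 matrix of unwrapped coordinates.
#' @param times Frame times (tau); taken from the trajectory when `x` is an
#'   `md_trajectory`.
#' @param lags Time lags (tau) at which to evaluate; default every frame
#'   spacing up to half the span (longer lags average too few time origins
#'   for a stable estimate).
#' @param multi_origin Average over all time origins (default) or use the
#'   first frame only.
#' @param box Optional box length used by the wrapped-input heuristic.
#' @param np Optional subset of particle indices.
#' @return An `msd_result`: tibble with columns `lag`, `msd`, `n_obs`, and
#'   attributes `n_particles`, `times`.
#' @export
msd_3d <- function(x, times = NULL, lags = NULL, multi_origin = TRUE,
                   box = NULL, np = NULL) {
  if (inherits(x, "md_trajectory")) {
    if (is.null(box)) box <- x$box_length
    times <- x$times
    x <- x$np_centroids
  }
  if (is.matrix(x)) x <- array(x, c(nrow(x), 1, ncol(x)))
  stopifnot(length(dim(x)) == 3, dim(x)[3] == 3)
  if (!is.null(np)) x <- x[, np, , drop = FALSE]
  F <- dim(x)[1]; P <- dim(x)[2]
  if (is.null(times)) times <- seq_len(F) - 1
  stopifnot(length(times) == F, all(diff(times) > 0))
  if (!is.null(box)) {
    jumps <- abs(x[-1, , , drop = FALSE] - x[-F, , , drop = FALSE])
    if (any(jumps > box / 2))
      stop("input looks wrapped: a single-frame jump exceeds box/2; ",
           "msd_3d needs unwrapped coordinates")
  }
  dtf <- times[2] - times[1]
  if (is.null(lags)) lags <- dtf * seq_len(max(1, floor(0.5 * (F - 1))))
  lag_frames <- round(lags / dtf)
  lag_frames <- lag_frames[lag_frames >= 1 & lag_frames <= F - 1]
  msd <- numeric(length(lag_frames))
  nob <- integer(length(lag_frames))
  for (q in seq_along(lag_frames)) {
    l <- lag_frames[q]
    if (multi_origin) {
      d <- x[(1 + l):F, , , drop = FALSE] - x[1:(F - l), , , drop = FALSE]
    } else {
      d <- x[1 + l, , , drop = FALSE] - x[1, , , drop = FALSE]
    }
    msd[q] <- mean(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2)
    nob[q] <- prod(dim(d)[1:2])
  }
  out <- tibble::tibble(lag = lag_frames * dtf, msd = msd, n_obs = nob)
  structure(out, class = c("msd_result", class(out)),
            n_particles = P, frame_interval = dtf,
            span = times[F] - times[1])
}

#' Fit the diffusivity from an MSD curve
#'
#' Ordinary least-squares fit of MSD versus time lag over the window; the
#' slope `k` gives the 3D diffusivity `D = k / 6`.
#'
#' @param msd An [msd_3d()] result (or any data frame with `lag` and `msd`).
#' @param window Length-2 lag window (tau). Defaults to the final quarter of
#'   the available lags, the proportional analogue of the long-lag fit used
#'   at full scale.
#' @return A `diffusivity_fit` list: `diffusivity` (sigma^2/tau), `slope`,
#'   `intercept`, `window`, `n_lags`.
#' @export
fit_diffusivity <- function(msd, window = NULL) {
  stopifnot(all(c("lag", "msd") %in% names(msd)))
  if (is.null(window)) window <- c(0.75, 1) * max(msd$lag)
  keep <- msd$lag >= window[1] & msd$lag <= window[2]
  if (sum(keep) < 2)
    stop("fit window contains fewer than 2 lags")
  fit <- lm(msd ~ lag, data = msd[keep, ])
  k <- unname(coef(fit)[2])
  structure(
    list(diffusivity = k / 6, slope = k, intercept = unname(coef(fit)[1]),
         window = window, n_lags = sum(keep)),
    class = "diffusivity_fit")
}

#' @export
print.diffusivity_fit <- function(x, ...) {
  cat(sprintf("<diffusivity_fit> D = %.4g sigma^2/tau (slope %.4g over %d lags in [%.4g, %.4g] tau)\n",
              x$diffusivity, x$slope, x$n_lags, x$window[1], x$window[2]))
  invisible(x)
}

#' Count NP beads in contact with the polymer network
#'
#' A shell bead is in contact when at least one polymer or node bead lies
#' within `cutoff` under the minimum-image convention; each shell bead
#' counts at most once per frame (`count = "beads"`). `count = "pairs"`
#' switches to counting every bead-bead pair within the cutoff.
#'
#' @param traj An `md_trajectory`.
#' @param cutoff Contact distance (sigma); default 3.
#' @param count `"beads"` (default) or `"pairs"`.
#' @return A `contact_series` tibble with columns `time`, `np`, `contacts`.
#' @export
contact_counts <- function(traj, cutoff = 3, count = c("beads", "pairs")) {
  count <- match.arg(count)
  stopifnot(inherits(traj, "md_trajectory"))
  n_np <- length(traj$rigid)
  m <- contact_counts_cpp(traj$wrapped, bead_type_code(traj$bead_type),
                          ifelse(is.na(traj$np_id), 0L,
                                 as.integer(traj$np_id)),
                          n_np, traj$box_length, cutoff,
                          count == "pairs")
  out <- tibble::tibble(
    time = rep(traj$times, times = n_np),
    np = rep(seq_len(n_np), each = length(traj$times)),
    contacts = as.vector(m))
  structure(out, class = c("contact_series", class(out)), cutoff = cutoff,
            count = count)
}

gyration_eigen <- function(p) {
  c0 <- colMeans(p)
  d <- sweep(p, 2, c0)
  G <- crossprod(d) / nrow(d)
  eigen(G, symmetric = TRUE, only.values = TRUE)$values
}

#' Gyration-tensor shape metrics of each NP over time
#'
#' Per NP and frame, the gyration tensor of the (unwrapped) shell bead
#' positions about their centroid; the aspect ratio is
#' `sqrt(largest / smallest eigenvalue)`. Frames whose smallest eigenvalue
#' is below `degenerate_tol` times the largest (coplanar/collinear bead
#' sets) are flagged and get `NA` aspect ratio.
#'
#' @param traj An `md_trajectory`, or an F x B x 3 array of bead positions
#'   of a single NP.
#' @param degenerate_tol Relative eigenvalue threshold for degeneracy.
#' @return A `shape_series` tibble: `time`, `np`, `ar`, `lambda1` <=
#'   `lambda2` <= `lambda3`, `degenerate`.
#' @export
shape_metrics <- function(traj, degenerate_tol = 1e-8) {
  if (inherits(traj, "md_trajectory")) {
    n_np <- length(traj$rigid)
    times <- traj$times
    rows <- list()
    for (k in seq_len(n_np)) {
      idx <- which(!is.na(traj$np_id) & traj$np_id == k)
      if (length(idx) < 4) stop("need at least 4 beads per NP")
      sub <- traj$unwrapped[, idx, , drop = FALSE]
      ev <- t(vapply(seq_along(times), function(f)
        rev(gyration_eigen(sub[f, , ])), numeric(3)))  # ascending
      rows[[k]] <- tibble::tibble(
        time = times, np = k,
        lambda1 = ev[, 1], lambda2 = ev[, 2], lambda3 = ev[, 3])
    }
    out <- dplyr::bind_rows(rows)
  } else {
    stopifnot(length(dim(traj)) == 3, dim(traj)[2] >= 4)
    ev <- t(vapply(seq_len(dim(traj)[1]), function(f)
      rev(gyration_eigen(traj[f, , ])), numeric(3)))
    out <- tibble::tibble(time = seq_len(dim(traj)[1]) - 1, np = 1L,
                          lambda1 = ev[, 1], lambda2 = ev[, 2],
                          lambda3 = ev[, 3])
  }
  out$degenerate <- out$lambda1 < degenerate_tol * out$lambda3
  out$ar <- ifelse(out$degenerate, NA_real_,
                   sqrt(out$lambda3 / out$lambda1))
  out <- out[, c("time", "np", "ar", "lambda1", "lambda2", "lambda3",
                 "degenerate")]
  structure(out, class = c("shape_series", class(out)))
}
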