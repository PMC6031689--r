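#' Tidy an MSD result
#'
#' @param x An [msd_3d()] result.
#' @param ... Unused.
#' @return A plain tibble with `lag`, `msd`, `n_obs`.
#' @export
tidy.msd_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("lag", "msd", "n_obs")])
}

#' One-row summary of an MSD result
#'
#' @param x An [msd_3d()] result.
#' @param ... Unused.
#' @export
glance.msd_result <- function(x, ...) {
  tibble::tibble(n_lags = nrow(x), n_particles = attr(x, "n_particles"),
                 max_lag = max(x$lag), max_msd = max(x$msd))
}

#' One-row summary of a diffusivity fit
#'
#' @param x A [fit_diffusivity()] result.
#' @param ... Unused.
#' @export
glance.diffusivity_fit <- function(x, ...) {
  tibble::tibble(diffusivity = x$diffusivity, slope = x$slope,
                 intercept = x$intercept, window_lo = x$window[1],
                 window_hi = x$window[2], n_lags = x$n_lags)
}

#' Per-NP summary of a contact series
#'
#' @param x A [contact_counts()] result.
#' @param ... Unused.
#' @return Tibble with per-NP mean and sd of the contact counts.
#' @export
tidy.contact_series <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$np) |>
    dplyr::summarise(mean_contacts = mean(.data$contacts),
                     sd_contacts = sd(.data$contacts), .groups = "drop")
}

#' Per-NP summary of a shape series
#'
#' @param x A [shape_metrics()] result.
#' @param ... Unused.
#' @export
tidy.shape_series <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$np) |>
    dplyr::summarise(mean_ar = mean(.data$ar, na.rm = TRUE),
                     sd_ar = sd(.data$ar, na.rm = TRUE),
                     max_ar = max(.data$ar, na.rm = TRUE), .groups = "drop")
}

#' Per-run tidy view of an experiment
#'
#' @param x A [run_experiment()] result.
#' @param ... Unused.
#' @export
tidy.gel_experiment <- function(x, ...) x$runs

#' Class-level summary of an experiment
#'
#' @param x A [run_experiment()] result.
#' @param ... Unused.
#' @export
glance.gel_experiment <- function(x, ...) x$class_summary
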