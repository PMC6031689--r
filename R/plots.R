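#' Plot an MSD curve
#'
#' Log-log ensemble MSD versus time lag.
#'
#' @param object An [msd_3d()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msd_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$lag, y = .data$msd)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time lag (tau)", y = "MSD (sigma^2)") +
    ggplot2::theme_minimal()
}

#' Plot per-NP contact counts over time
#'
#' @param object A [contact_counts()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contact_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$contacts,
                               color = factor(.data$np))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time (tau)", y = "beads in contact", color = "NP") +
    ggplot2::theme_minimal()
}

#' Plot per-NP aspect-ratio traces
#'
#' @param object A [shape_metrics()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shape_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$ar,
                               color = factor(.data$np))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time (tau)", y = "aspect ratio", color = "NP") +
    ggplot2::theme_minimal()
}

#' Plot a log10 effective-diffusivity distribution
#'
#' @param object A [deff_distribution()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.deff_distribution <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = log10(object$threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = "log10 D_eff (um^2/s)", y = "particles") +
    ggplot2::theme_minimal()
}

#' Plot experiment MSD curves by rigidity class
#'
#' @param object A [run_experiment()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gel_experiment <- function(object, ...) {
  ggplot2::ggplot(object$msd_curves,
                  ggplot2::aes(x = .data$lag, y = .data$msd,
                               color = .data$class,
                               group = interaction(.data$class, .data$seed))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "time lag (tau)", y = "MSD (sigma^2)",
                  color = "class") +
    ggplot2::theme_minimal()
}

#' Plot 2D particle tracks
#'
#' @param tracks A [generate_tracks()] track set.
#' @param max_tracks Number of tracks to draw.
#' @return A ggplot.
#' @export
plot_tracks <- function(tracks, max_tracks = 20) {
  keep <- tracks$particle_id %in% unique(tracks$particle_id)[
    seq_len(min(max_tracks, length(unique(tracks$particle_id))))]
  ggplot2::ggplot(tracks[keep, ],
                  ggplot2::aes(x = .data$x_um, y = .data$y_um,
                               group = .data$particle_id,
                               color = factor(.data$particle_id))) +
    ggplot2::geom_path(show.legend = FALSE, alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}
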