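# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a landscape grid into a long tibble
#'
#' @param x A `landscape_grid`.
#' @param ... Unused.
#' @return Tibble with `theta_wing_deg`, `pitch_deg`, `roll_deg`, `z_com_mm`,
#'   `energy_mJ`.
#' @export
tidy.landscape_grid <- function(x, ...) {
  nodes <- expand.grid(pitch_deg = x$pitch, roll_deg = x$roll)
  tibble::tibble(
    theta_wing_deg = x$theta_wing,
    pitch_deg = nodes$pitch_deg, roll_deg = nodes$roll_deg,
    z_com_mm = as.vector(x$z_com), energy_mJ = as.vector(x$energy))
}

#' One-row summary of a landscape grid
#' @param x A `landscape_grid`.
#' @param ... Unused.
#' @export
glance.landscape_grid <- function(x, ...) {
  mins <- find_minima(x)
  tibble::tibble(
    theta_wing_deg = x$theta_wing, n_pitch = length(x$pitch),
    n_roll = length(x$roll), min_energy_mJ = min(x$energy),
    max_energy_mJ = max(x$energy), n_minima = nrow(mins),
    plateau = any(mins$plateau))
}

#' @export
tidy.barrier_curves <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x)[c("theta_wing_deg", "pitch_barrier_mJ",
                           "roll_barrier_mJ")],
    -"theta_wing_deg", names_to = "direction", values_to = "barrier_mJ") |>
    dplyr::mutate(direction = sub("_barrier_mJ", "", .data$direction))
}

#' @export
tidy.attempt_ensemble <- function(x, ...) x$attempts

#' @export
glance.attempt_ensemble <- function(x, ...) {
  tibble::tibble(
    theta_wing_deg = x$params$theta_wing, theta_leg_deg = x$params$theta_leg,
    probability = x$probability,
    mean_attempts = mean(x$attempts_to_success$attempts),
    prop_righted = mean(x$attempts_to_success$righted),
    roll_barrier_mJ = x$roll_barrier_mJ, n_trials = x$params$n)
}

#' Heat-map of a potential energy landscape
#' @param object A `landscape_grid`.
#' @param ... Unused.
#' @export
autoplot.landscape_grid <- function(object, ...) {
  df <- tidy(object)
  mins <- find_minima(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$pitch_deg, .data$roll_deg)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$energy_mJ)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$energy_mJ),
                          colour = "grey80", linewidth = 0.2) +
    ggplot2::geom_point(data = mins, ggplot2::aes(.data$pitch, .data$roll),
                        colour = "white", size = 1.5) +
    ggplot2::scale_fill_viridis_c(name = "E (mJ)") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "body pitch (deg)", y = "body roll (deg)",
      title = sprintf("Potential energy landscape, wing opening %g deg",
                      object$theta_wing))
}

#' Polar plot of a directional barrier profile
#' @param object A `barrier_profile`.
#' @param ... Unused.
#' @export
autoplot.barrier_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$psi_deg, .data$barrier_mJ)) +
    ggplot2::geom_line() +
    ggplot2::coord_polar(start = pi / 2, direction = -1) +
    ggplot2::labs(x = "escape direction psi (deg)", y = "barrier (mJ)",
                  title = "Escape barrier by direction in pitch-roll space")
}

#' Pitch and roll barriers versus wing opening angle
#' @param object A `barrier_curves` tibble.
#' @param ... Unused.
#' @export
autoplot.barrier_curves <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$theta_wing_deg, .data$barrier_mJ,
                               colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(pitch = "#3366cc", roll = "#cc3333")) +
    ggplot2::labs(x = "wing opening angle (deg)", y = "barrier (mJ)",
                  colour = NULL)
}

#' Pitch and roll kinetic energy over time
#' @param object An `energy_trace`.
#' @param ... Unused.
#' @export
autoplot.energy_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), -"time_s",
                            names_to = "direction", values_to = "ke_mJ")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$ke_mJ,
                                   colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "kinetic energy (mJ)", colour = NULL)
}

#' Attempt-level kinetic energy draws against the roll barrier
#' @param object An `attempt_ensemble`.
#' @param ... Unused.
#' @export
autoplot.attempt_ensemble <- function(object, ...) {
  ggplot2::ggplot(object$attempts,
                  ggplot2::aes(.data$ke_roll_mJ, fill = .data$success)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.7) +
    ggplot2::geom_vline(xintercept = object$roll_barrier_mJ,
                        linetype = "dashed") +
    ggplot2::labs(x = "roll kinetic energy (mJ)", y = "attempts",
                  fill = "success")
}
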