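#' Plot a dose-response curve
#'
#' @param object A `lac_dose_response`.
#' @param ... Unused.
#' @return A ggplot object (steady LacY vs external lactose, log x-axis).
#' @importFrom ggplot2 autoplot
#' @export
autoplot.lac_dose_response <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$L_ext_mM, y = .data$Y_nM)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "external lactose (mM)",
                  y = "steady-state LacY (molecules)",
                  title = paste0("Dose-response (", attr(object, "variant"),
                                 ")")) +
    ggplot2::theme_minimal()
}

#' Plot stationary copy-number distributions
#'
#' @param object A `lac_stationary`.
#' @param ... Unused.
#' @return A ggplot object (probability vs count, one panel per species).
#' @export
autoplot.lac_stationary <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$count, y = .data$probability)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~species, scales = "free") +
    ggplot2::labs(x = "molecules per cell", y = "probability",
                  title = paste0("Stationary distributions (",
                                 object$config$variant, ")")) +
    ggplot2::theme_minimal()
}

#' Plot switch-time distributions
#'
#' @param object A `lac_switch`.
#' @param ... Unused.
#' @return A ggplot object (histograms of turn-on and turn-off times).
#' @export
autoplot.lac_switch <- function(object, ...) {
  long <- tidyr::pivot_longer(object$times,
                              cols = c("turn_on_min", "turn_off_min"),
                              names_to = "transition", values_to = "t_min")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_min)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::facet_wrap(~transition, scales = "free") +
    ggplot2::labs(x = "first-passage time (min)", y = "runs",
                  title = paste0("Switch times (", object$config$variant,
                                 ")")) +
    ggplot2::theme_minimal()
}

#' Plot a stochastic trajectory
#'
#' @param traj A `lac_trajectory` from [simulate_lac()].
#' @param species Which columns to draw.
#' @return A ggplot object (counts vs time).
#' @export
plot_trajectory <- function(traj, species = c("n_I", "n_Y")) {
  long <- tidyr::pivot_longer(traj, cols = dplyr::all_of(species),
                              names_to = "species", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_min, y = .data$count,
                                     colour = .data$species)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (min)", y = "molecules per cell") +
    ggplot2::theme_minimal()
}

#' @importFrom generics glance
#' @export
glance.lac_dose_response <- function(x, ...) {
  tibble::tibble(
    variant = attr(x, "variant"),
    n_points = nrow(x),
    Y_repressed_nM = min(x$Y_nM),
    Y_plateau_nM = max(x$Y_nM)
  )
}

#' @export
tidy.lac_stationary <- function(x, ...) x$summary

#' @export
glance.lac_stationary <- function(x, ...) {
  tibble::tibble(
    variant = x$config$variant,
    label = x$config$label,
    duration_min = x$config$duration,
    burn_in_min = x$config$burn_in,
    n_events = x$config$n_events
  )
}

#' @export
tidy.lac_switch <- function(x, ...) x$summary

#' @export
glance.lac_switch <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    variant = x$config$variant,
    n_runs = x$config$n_runs,
    turn_on_mean = s$mean[s$statistic == "turn_on"],
    turn_on_sd = s$sd[s$statistic == "turn_on"],
    turn_off_mean = s$mean[s$statistic == "turn_off"],
    turn_off_sd = s$sd[s$statistic == "turn_off"],
    n_censored = sum(s$n_censored)
  )
}
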