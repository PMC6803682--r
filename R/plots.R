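# ggplot2 graphics for the main result types; depth axes run downwards, as
# oceanographic convention demands.

#' Plot an optimal migration pattern
#'
#' Daily depth trajectories of the three stages at the optimum, midnight to
#' midnight, depth increasing downwards; dotted lines mark the unfavorable
#' zone boundaries.
#'
#' @param object A [dvm_optimize()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dvm_optimum <- function(object, ...) {
  prof <- dplyr::bind_rows(lapply(c("Y", "J", "A"), function(s) {
    out <- trajectory_profile(object$strategy[[s]])
    out$stage <- s
    out
  }))
  prof$stage <- factor(prof$stage, levels = c("Y", "J", "A"),
                       labels = c("CI-III", "CIV-V", "CVI"))
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$t, y = .data$depth,
                                     colour = .data$stage)) +
    ggplot2::geom_hline(yintercept = c(object$params$h_u, object$params$h_d),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::scale_y_reverse(limits = c(object$params$h_max, 0)) +
    ggplot2::labs(x = "time of day (0 = midnight)", y = "depth (m)",
                  colour = "stage",
                  title = sprintf("optimal DVM, J = %.4g", object$J)) +
    ggplot2::theme_minimal()
}

#' Plot a parameter scan
#'
#' Adult night-time and daytime depths against the scanned parameter.
#'
#' @param object A [dvm_scan()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dvm_scan <- function(object, ...) {
  tb <- tidy(object)
  long <- dplyr::bind_rows(
    tibble::tibble(value = tb$value, depth = tb$H0_A, which = "night (H_A0)"),
    tibble::tibble(value = tb$value, depth = tb$H1_A, which = "day (H_A1)")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$depth,
                                     colour = .data$which)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = attr(object, "parameter"), y = "depth (m)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot competing-strategy densities
#'
#' Log population density of each strategy through time.
#'
#' @param object A [simulate_selection()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dvm_selection <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$time, y = .data$log_density,
                               colour = factor(.data$strategy))) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "time (days)", y = "log density",
                  colour = "strategy") +
    ggplot2::theme_minimal()
}
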