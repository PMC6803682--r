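#' Vertical phytoplankton (food) profile
#'
#' Sigmoidal decrease of phytoplankton density with depth,
#' `P(h) = P0 (tanh(-sigma (h - h_p)) + 1) / 2`: close to `P0` near the
#' surface, half-maximum at `h_p`, and vanishing below the euphotic zone.
#'
#' @param h Depth, m (vectorised, must be nonnegative).
#' @param params A [dvm_params()] object.
#' @return Food density in ug C / l, in `[0, P0]`.
#' @examples
#' phytoplankton_density(40, dvm_params())  # half-maximum: 15
#' @export
phytoplankton_density <- function(h, params) {
  check_depth(h)
  params$P0 * (tanh(-params$sigma * (h - params$h_p)) + 1) / 2
}

# dimensionless depth shape shared by both metabolic costs; 1 near the
# surface, 1/2 at h_m, -> 0 below the oxygen-poor transition
metabolic_shape <- function(h, params) {
  if (params$const_cost) return(rep(1, length(h)))
  (tanh(-params$sigma_m * (h - params$h_m)) + 1) / 2
}

# Holling type II per-capita feeding response (per unit of C1 W^0.8)
holling_response <- function(h, params) {
  P <- params$P0 * (tanh(-params$sigma * (h - params$h_p)) + 1) / 2
  P / (1 + params$alpha * P)
}

#' Basal metabolic cost at depth
#'
#' Depth-dependent basal cost in ug C per individual per day. The per-hour
#' maximal adult cost `m_A` is scaled allometrically to weight `W`
#' (`(W / W_A)^0.8`), converted to a daily rate, and modulated by the
#' sigmoidal oxygen-driven depth shape with half-maximum at `h_m`.
#'
#' @inheritParams phytoplankton_density
#' @param W Body weight, ug C (positive).
#' @return Cost in ug C / ind / day.
#' @examples
#' p <- dvm_params()
#' basal_metabolic_rate(p$h_m, p$W_A, p)  # half-maximum: 24 * 0.05 / 2 = 0.6
#' @export
basal_metabolic_rate <- function(h, W, params) {
  check_depth(h); check_weight(W)
  24 * params$m_A * (W / params$W_A)^0.8 * metabolic_shape(h, params)
}

#' Active metabolic cost at depth
#'
#' As [basal_metabolic_rate()], with the larger amplitude `M_A0` of active
#' swimming; the depth shape is the same, so the active-to-basal ratio is
#' depth-independent.
#'
#' @inheritParams basal_metabolic_rate
#' @return Cost in ug C / ind / day.
#' @export
active_metabolic_rate <- function(h, W, params) {
  check_depth(h); check_weight(W)
  24 * params$M_A0 * (W / params$W_A)^0.8 * metabolic_shape(h, params)
}

#' Allometric weight scaling of a reference rate
#'
#' Scales a rate known at a reference weight to another body weight with the
#' 0.8 mass exponent: `ref_value * (W / W_ref)^0.8`.
#'
#' @param W Target body weight, ug C.
#' @param ref_value Rate at the reference weight.
#' @param W_ref Reference weight, ug C.
#' @return The scaled rate.
#' @examples
#' allometric_scale(25, 1.1, 110)  # juvenile grazing rate, about 0.336 l/day
#' @export
allometric_scale <- function(W, ref_value, W_ref) {
  check_weight(W); check_weight(W_ref)
  ref_value * (W / W_ref)^0.8
}

#' Extra mortality in the unfavorable zones
#'
#' Additional mortality from the warm near-surface layer (above `h_u`) and
#' the hypoxic deep layer (below `h_d`):
#' `A(h) = delta_u (tanh(-sigma_u (h - h_u)) + 1) + delta_d (tanh(sigma_d (h - h_d)) + 1)`.
#' Tends to `2 delta_u` towards the surface and `2 delta_d` at depth, and is
#' negligible between the zones.
#'
#' @inheritParams phytoplankton_density
#' @return Mortality rate, 1/day, in `[0, 2 (delta_u + delta_d)]`.
#' @export
unfavorable_zone_mortality <- function(h, params) {
  check_depth(h)
  params$delta_u * (tanh(-params$sigma_u * (h - params$h_u)) + 1) +
    params$delta_d * (tanh(params$sigma_d * (h - params$h_d)) + 1)
}

#' Instantaneous visual-predation mortality
#'
#' Risk from visual predators, decreasing with depth like the light field
#' (same sigmoid as the food profile) and following the diel light cycle
#' `(1 - cos(2 pi t))`: zero at midnight (`t = 0`), maximal at midday
#' (`t = 0.5`). Normalised so that the maximum over depth and time equals
#' `gamma_i`. With `params$avg_predation` the diel factor is replaced by its
#' daily mean (1).
#'
#' @inheritParams phytoplankton_density
#' @param t Time of day as a fraction in `[0, 1]` (0 = midnight).
#' @param gamma_i Maximal predation mortality for the stage, 1/day.
#' @return Instantaneous mortality rate, 1/day.
#' @examples
#' predation_mortality_rate(10, 0.5, 0.8, dvm_params())  # near-maximal
#' @export
predation_mortality_rate <- function(h, t, gamma_i, params) {
  check_depth(h)
  if (any(t < 0 | t > 1)) stop("`t` must lie in [0, 1]", call. = FALSE)
  diel <- if (params$avg_predation) 1 else (1 - cos(2 * pi * t))
  gamma_i * (tanh(-params$sigma * (h - params$h_p)) + 1) * diel / 4
}

#' Tabulate the water-column environment
#'
#' Evaluates all depth profiles on a grid, ready for plotting or export: food
#' density, adult basal metabolic cost, daily-mean predation risk (for
#' `gamma = gamma_A`) and unfavorable-zone mortality.
#'
#' @param params A [dvm_params()] object.
#' @param depths Depth grid, m.
#' @return A tibble with columns `depth`, `food`, `basal_cost`,
#'   `predation_risk`, `zone_mortality`.
#' @export
environment_profiles <- function(params, depths = seq(0, params$h_max, by = 0.5)) {
  tibble::tibble(
    depth = depths,
    food = phytoplankton_density(depths, params),
    basal_cost = basal_metabolic_rate(depths, params$W_A, params),
    predation_risk = params$gamma_A *
      (tanh(-params$sigma * (depths - params$h_p)) + 1) / 4,
    zone_mortality = unfavorable_zone_mortality(depths, params)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the water-column environment
#'
#' Depth profiles of food, metabolic cost, predation risk and zone mortality,
#' each rescaled to its maximum, with depth increasing downwards.
#'
#' @param object A `dvm_params` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dvm_params <- function(object, ...) {
  prof <- environment_profiles(object)
  long <- tidyr_pivot(prof)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$depth,
                                     colour = .data$profile)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "relative magnitude", y = "depth (m)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (avoids importing tidyr for one call)
tidyr_pivot <- function(prof) {
  vars <- c("food", "basal_cost", "predation_risk", "zone_mortality")
  out <- lapply(vars, function(v) {
    x <- prof[[v]]
    tibble::tibble(depth = prof$depth, profile = v,
                   value = if (max(x) > 0) x / max(x) else x)
  })
  dplyr::bind_rows(out)
}

check_depth <- function(h) {
  if (any(!is.finite(h)) || any(h < 0))
    stop("depth `h` must be finite and nonnegative", call. = FALSE)
  invisible(h)
}
check_weight <- function(W) {
  if (any(!is.finite(W)) || any(W <= 0))
    stop("weight `W` must be finite and positive", call. = FALSE)
  invisible(W)
}
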