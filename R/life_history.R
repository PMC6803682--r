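# Life-history integration: maps one stage's daily trajectory to the scalar
# coefficients of the fitness equation. Stationary segments contribute in
# closed form; the only numerical quadrature left is the predation risk on
# the two ramps, where the depth sigmoid multiplies the diel light factor
# (composite Gauss-Legendre, panels sized to the sigmoid width).

# Daily integrals over one trajectory:
#   feed : int P/(1+alpha P) S_i dt          (feeding response, shallow only)
#   basal: int shape_m(h) dt                 (basal-cost depth shape)
#   activ: int shape_m(h) S_i1 dt            (active-cost depth shape)
#   zone : int A(h) dt                       (unfavorable-zone mortality)
#   pred : int (tanh(-sigma (h - h_p)) + 1) (1 - cos 2 pi t) / 4 dt
stage_integrals <- function(traj, params) {
  if (!traj$migrating) {
    H <- traj$H0
    shp <- metabolic_shape(H, params)
    pred_sh <- tanh(-params$sigma * (H - params$h_p)) + 1
    # the diel light factor (1 - cos 2 pi t) integrates to 1 over a day
    return(list(feed = holling_response(H, params),
                basal = shp, activ = shp,
                zone = unfavorable_zone_mortality(H, params),
                pred = pred_sh / 4))
  }
  H0 <- traj$H0; H1 <- traj$H1; dH <- H1 - H0
  t0 <- traj$t0; t1 <- traj$t1; t2 <- traj$t2; t3 <- traj$t3
  sh_dur <- t0 + (1 - t3)
  dp_dur <- t2 - t1
  down_dur <- t1 - t0
  up_dur <- t3 - t2

  feed <- holling_response(H0, params) * sh_dur

  # metabolic depth shape: closed form on every segment
  if (params$const_cost) {
    basal <- 1
    activ <- sh_dur + up_dur
  } else {
    ramp_mean <- (anti_sigmoid_down(H1, params$sigma_m, params$h_m) -
                  anti_sigmoid_down(H0, params$sigma_m, params$h_m)) / dH
    basal <- metabolic_shape(H0, params) * sh_dur +
      metabolic_shape(H1, params) * dp_dur +
      ramp_mean * (down_dur + up_dur)
    activ <- metabolic_shape(H0, params) * sh_dur + ramp_mean * up_dur
  }

  zone_ramp_mean <- (anti_zone(H1, params) - anti_zone(H0, params)) / dH
  zone <- unfavorable_zone_mortality(H0, params) * sh_dur +
    unfavorable_zone_mortality(H1, params) * dp_dur +
    zone_ramp_mean * (down_dur + up_dur)

  pred_shape <- function(h) tanh(-params$sigma * (h - params$h_p)) + 1
  if (params$avg_predation) {
    pred <- pred_shape(H0) * sh_dur + pred_shape(H1) * dp_dur +
      (anti_sigmoid_down(H1, params$sigma, params$h_p) -
       anti_sigmoid_down(H0, params$sigma, params$h_p)) / dH *
        2 * (down_dur + up_dur)
  } else {
    pred <- pred_shape(H0) * (diel_factor_integral(0, t0) +
                              diel_factor_integral(t3, 1)) +
      pred_shape(H1) * diel_factor_integral(t1, t2)
    n_panel <- max(1L, min(12L, ceiling(dH * params$sigma / 2)))
    gd <- gl_nodes_ramp(t0, t1, n_panel)
    gu <- gl_nodes_ramp(t2, t3, n_panel)
    hd <- H0 + traj$c_down_day * (gd$x - t0)
    hu <- H1 - traj$c_up_day * (gu$x - t2)
    pred <- pred +
      sum(gd$w * pred_shape(hd) * (1 - cos(2 * pi * gd$x))) +
      sum(gu$w * pred_shape(hu) * (1 - cos(2 * pi * gu$x)))
  }
  list(feed = feed, basal = basal, activ = activ, zone = zone, pred = pred / 4)
}

#' Daily net energy gain along a trajectory
#'
#' Integrates assimilated food intake minus basal and active metabolic costs
#' over one daily cycle, for an individual of weight `W`:
#' `int [eps alpha(W) P/(1 + alpha P) S - m_b(h, W) - M(h, W) S1] dt`
#' in ug C per individual per day. Stationary segments are evaluated in
#' closed form; ramps by composite Gauss-Legendre quadrature / closed-form
#' depth antiderivatives.
#'
#' @param traj A [dvm_trajectory()].
#' @param W Body weight, ug C.
#' @param eps Assimilation efficiency in (0, 1].
#' @param params A [dvm_params()] object.
#' @return Net energy, ug C / ind / day (may be negative).
#' @export
daily_net_energy <- function(traj, W, eps, params) {
  check_weight(W)
  W^0.8 * growth_coefficient(traj, eps, params)
}

#' Specific growth constant of a stage
#'
#' Because grazing and both metabolic costs share the `W^0.8` allometry, the
#' daily growth rate factorises as `dW/dt = kappa W^0.8` with a
#' trajectory-dependent constant
#' `kappa = eps C1 F - C2 B - C3 A` (feeding, basal and active daily
#' integrals). `kappa <= 0` marks a non-maturing (infeasible) strategy.
#'
#' @inheritParams daily_net_energy
#' @return The per-day growth constant `kappa` (units ug C^0.2 / day).
#' @export
growth_coefficient <- function(traj, eps, params) {
  ii <- stage_integrals(traj, params)
  eps * params$C1 * ii$feed - params$C2 * ii$basal - params$C3 * ii$activ
}

#' Daily fecundity of the adult trajectory
#'
#' Eggs produced per female per day: the adult daily net energy surplus
#' divided by the egg weight, `b = max(0, E_net / W_0)` (adult weight is
#' constant at `W_A`). A female in energy deficit produces no eggs; the
#' clipping is recorded in the `"clipped"` attribute.
#'
#' @param traj_A Adult [dvm_trajectory()].
#' @param params A [dvm_params()] object.
#' @return Eggs per female per day, with attribute `clipped`.
#' @export
fecundity <- function(traj_A, params) {
  net <- daily_net_energy(traj_A, params$W_A, params$eps_A, params)
  b <- max(0, net / params$W_0)
  attr(b, "clipped") <- net < 0
  b
}

#' Daily mortality rate of a stage
#'
#' Time-averages the instantaneous mortality over the daily cycle:
#' visual predation (depth sigmoid times diel light factor), unfavorable-zone
#' mortality, and the constant natural mortality:
#' `a_i = int [gamma_i (tanh(-sigma(h - h_p)) + 1)(1 - cos 2 pi t)/4 + A(h) + gamma_i0] dt`.
#'
#' @inheritParams daily_net_energy
#' @param gamma_i Maximal visual-predation mortality, 1/day.
#' @param gamma_i0 Natural mortality, 1/day.
#' @return Mortality rate, 1/day (at least `gamma_i0`).
#' @export
stage_mortality <- function(traj, gamma_i, gamma_i0, params) {
  ii <- stage_integrals(traj, params)
  gamma_i * ii$pred + ii$zone + gamma_i0
}

#' Time to grow between two weights
#'
#' Exact solution of `dW/dt = kappa W^0.8`:
#' `tau = (W_end^0.2 - W_start^0.2) / (0.2 kappa)`. Returns `Inf` when
#' `kappa <= 0` (the stage never matures).
#'
#' @param W_start,W_end Start and end weights, ug C (`W_end >= W_start > 0`).
#' @param kappa Growth constant from [growth_coefficient()].
#' @return Maturation time in days.
#' @examples
#' maturation_time(1.2, 25, 0.1)
#' @export
maturation_time <- function(W_start, W_end, kappa) {
  check_weight(W_start); check_weight(W_end)
  if (W_end < W_start) stop("`W_end` must be at least `W_start`", call. = FALSE)
  if (kappa <= 0) return(Inf)
  (W_end^0.2 - W_start^0.2) / (0.2 * kappa)
}

#' Life-history rates of a full strategy
#'
#' Assembles the scalar coefficients of the fitness equation from the three
#' stage trajectories: fecundity `b`, stage mortalities `a_Y`, `a_J`, `a_A`,
#' and the cumulative ages `tau_1` (young juveniles reach `W_J`), `tau_2`
#' (adult weight `W_A` reached) and `tau_3 = tau_2 + T0` (end of
#' reproduction). A strategy is `feasible` when both juvenile stages grow
#' (`kappa > 0`), adulthood is reached within `params$max_age`, and the
#' adult has an energy surplus (`b > 0`); `status` names the first failure.
#'
#' @param strategy A [dvm_strategy()].
#' @param params A [dvm_params()] object.
#' @return A one-row tibble with columns `b`, `a_Y`, `a_J`, `a_A`, `tau_1`,
#'   `tau_2`, `tau_3`, `kappa_Y`, `kappa_J`, `b_clipped`, `feasible`,
#'   `status`.
#' @export
compute_stage_rates <- function(strategy, params) {
  stopifnot(inherits(strategy, "dvm_strategy"))
  kY <- growth_coefficient(strategy$Y, params$eps_Y, params)
  kJ <- growth_coefficient(strategy$J, params$eps_J, params)
  b <- fecundity(strategy$A, params)
  tau1 <- maturation_time(params$W_Y, params$W_J, kY)
  tau2 <- tau1 + maturation_time(params$W_J, params$W_A, kJ)
  tau3 <- tau2 + params$T0
  status <- if (kY <= 0 || kJ <= 0) "non_maturing"
    else if (tau2 > params$max_age) "overdue"
    else if (b <= 0) "starving"
    else "ok"
  clipped <- isTRUE(attr(b, "clipped"))
  tibble::tibble(
    b = as.numeric(b),
    a_Y = stage_mortality(strategy$Y, params$gamma_Y, params$gamma_Y0, params),
    a_J = stage_mortality(strategy$J, params$gamma_J, params$gamma_J0, params),
    a_A = stage_mortality(strategy$A, params$gamma_A, params$gamma_A0, params),
    tau_1 = tau1, tau_2 = tau2, tau_3 = tau3,
    kappa_Y = kY, kappa_J = kJ,
    b_clipped = clipped,
    feasible = status == "ok",
    status = status
  )
}
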