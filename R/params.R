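#' Model parameters for the zooplankton DVM model
#'
#' Single source of truth for every model constant: the water-column
#' environment (food, metabolic-cost, predation and unfavorable-zone
#' profiles), stage traits (weights, grazing, efficiencies, mortalities),
#' migration speeds and numerical controls. Defaults describe a typical
#' north-eastern Black Sea summer water column for *Calanus euxinus*
#' (lower unfavorable boundary `h_d = 140` m, upper boundary `h_u = 20` m).
#'
#' All rates are stored per day: per-hour metabolic costs are converted at
#' construction (`x 24`), migration speeds are given in m/h and stored in
#' m/day, and the day is the unit of time throughout (`t` in `[0, 1]` is one
#' daily cycle, ages and maturation times are in days).
#'
#' The allometric constants of the weight-scaling law `rate = C W^0.8` are
#' calibrated from the adult reference values so that each weight-dependent
#' rate evaluated at `W = W_A` equals its adult value:
#' `C1 = alpha_A / W_A^0.8` (grazing, l/day), `C2 = 24 m_A / W_A^0.8` and
#' `C3 = 24 M_A0 / W_A^0.8` (basal and active cost, ug C/day).
#'
#' The half-maximum depth of the metabolic profile defaults to
#' `h_m = h_d - delta_hm`: the metabolic relief experienced at depth is tied
#' to the oxygen regime, whose sharp drop sits just above the lower
#' unfavorable boundary. Supplying `h_m` explicitly decouples it from `h_d`.
#'
#' @param P0 Maximal phytoplankton density, ug C / l.
#' @param sigma Steepness of the food (and light) profile, 1/m.
#' @param h_p Half-maximum chlorophyll depth, m.
#' @param m_A Maximal adult basal metabolic cost, ug C / ind / h.
#' @param M_A0 Maximal adult active metabolic cost, ug C / ind / h.
#' @param sigma_m Steepness of the metabolic-cost profile, 1/m.
#' @param delta_hm Offset of the metabolic half-maximum depth above the lower
#'   unfavorable boundary, m; used when `h_m` is not given.
#' @param h_m Metabolic half-maximum depth, m, or `NULL` to derive it as
#'   `h_d - delta_hm`.
#' @param h_d,h_u Lower and upper unfavorable-zone boundaries, m.
#' @param delta_d,delta_u Unfavorable-zone mortality amplitudes, 1/day
#'   (the asymptotic extra mortality deep in a zone is `2 * delta`).
#' @param sigma_d,sigma_u Transition steepness of the zone boundaries, 1/m.
#' @param gamma_Y,gamma_J,gamma_A Maximal visual-predation mortality per
#'   stage, 1/day (value at the surface at midday).
#' @param gamma_Y0,gamma_J0,gamma_A0 Natural (predation-independent)
#'   mortality per stage, 1/day.
#' @param W_A,W_J,W_Y Adult, older-juvenile and young-juvenile minimal
#'   carbon weights, ug C.
#' @param W_0 Egg carbon weight, ug C.
#' @param alpha_A Adult per-individual grazing rate, l/day.
#' @param alpha Inverse half-saturation density of the feeding response,
#'   l / ug C.
#' @param eps_Y,eps_J,eps_A Assimilation efficiencies, dimensionless in
#'   (0, 1].
#' @param T0 Adult reproductive period, days.
#' @param c_down,c_up Descent and ascent speeds, m/h.
#' @param h_max Maximum admissible depth (domain bound), m.
#' @param R Density-dependence coefficient of the population model. It is
#'   strategy-independent, so it rescales fitness without changing the
#'   ranking of strategies; kept at 1 by default.
#' @param max_age Maximum development age, days: strategies that do not reach
#'   adult weight within this age are infeasible. The species modelled are
#'   effectively annual.
#' @param const_cost If `TRUE`, metabolic costs are depth-independent (held
#'   at their maxima everywhere): the hypothetical scenario used to isolate
#'   the role of the metabolic depth gradient.
#' @param avg_predation If `TRUE`, the diel light factor of the predation
#'   risk is replaced by its daily mean, making predation constant in time
#'   (but still depth-dependent).
#'
#' @return An object of class `dvm_params`: a validated list with the fields
#'   above plus the derived constants `h_m`, `c_down_day`, `c_up_day`, `C1`,
#'   `C2`, `C3`.
#' @examples
#' params <- dvm_params()
#' params$h_m            # 128 m: follows the lower unfavorable boundary
#' winter <- dvm_params(h_d = 80, h_u = 5)
#' @export
dvm_params <- function(P0 = 30, sigma = 0.125, h_p = 40,
                       m_A = 0.05, M_A0 = 0.13, sigma_m = 0.065,
                       delta_hm = 12, h_m = NULL,
                       h_d = 140, h_u = 20,
                       delta_d = 2, delta_u = 0.5,
                       sigma_d = 0.2, sigma_u = 0.2,
                       gamma_Y = 0.8, gamma_J = 0.8, gamma_A = 0.8,
                       gamma_Y0 = 0.1, gamma_J0 = 0, gamma_A0 = 0,
                       W_A = 110, W_J = 25, W_Y = 1.2, W_0 = 0.25,
                       alpha_A = 1.1, alpha = 0.05,
                       eps_Y = 0.7, eps_J = 0.7, eps_A = 0.7,
                       T0 = 40, c_down = 45, c_up = 45,
                       h_max = 200, R = 1, max_age = 365,
                       const_cost = FALSE, avg_predation = FALSE) {
  h_m_explicit <- !is.null(h_m)
  if (!h_m_explicit) h_m <- h_d - delta_hm
  p <- list(
    P0 = P0, sigma = sigma, h_p = h_p,
    m_A = m_A, M_A0 = M_A0, sigma_m = sigma_m,
    delta_hm = delta_hm, h_m = h_m,
    h_d = h_d, h_u = h_u,
    delta_d = delta_d, delta_u = delta_u,
    sigma_d = sigma_d, sigma_u = sigma_u,
    gamma_Y = gamma_Y, gamma_J = gamma_J, gamma_A = gamma_A,
    gamma_Y0 = gamma_Y0, gamma_J0 = gamma_J0, gamma_A0 = gamma_A0,
    W_A = W_A, W_J = W_J, W_Y = W_Y, W_0 = W_0,
    alpha_A = alpha_A, alpha = alpha,
    eps_Y = eps_Y, eps_J = eps_J, eps_A = eps_A,
    T0 = T0, c_down = c_down, c_up = c_up,
    h_max = h_max, R = R, max_age = max_age,
    const_cost = isTRUE(const_cost), avg_predation = isTRUE(avg_predation),
    h_m_explicit = h_m_explicit
  )
  validate_dvm_params(p)
  p$c_down_day <- 24 * c_down
  p$c_up_day <- 24 * c_up
  p$C1 <- alpha_A / W_A^0.8
  p$C2 <- 24 * m_A / W_A^0.8
  p$C3 <- 24 * M_A0 / W_A^0.8
  structure(p, class = "dvm_params")
}

validate_dvm_params <- function(p) {
  chk <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  pos <- c("P0", "sigma", "h_p", "m_A", "M_A0", "sigma_m", "sigma_d",
           "sigma_u", "W_A", "W_J", "W_Y", "W_0", "alpha_A", "alpha",
           "T0", "c_down", "c_up", "h_max", "R", "max_age")
  for (nm in pos) chk(is.numeric(p[[nm]]) && length(p[[nm]]) == 1 && p[[nm]] > 0,
                      paste0("`", nm, "` must be a positive scalar"))
  nneg <- c("h_d", "h_u", "delta_d", "delta_u", "gamma_Y", "gamma_J",
            "gamma_A", "gamma_Y0", "gamma_J0", "gamma_A0")
  for (nm in nneg) chk(is.numeric(p[[nm]]) && length(p[[nm]]) == 1 && p[[nm]] >= 0,
                       paste0("`", nm, "` must be a nonnegative scalar"))
  chk(p$h_u < p$h_d, "`h_u` must lie above `h_d` (h_u < h_d)")
  chk(p$h_d <= p$h_max, "`h_d` must not exceed `h_max`")
  chk(p$h_m < p$h_d, "`h_m` must lie above `h_d` (h_m < h_d)")
  chk(p$W_Y < p$W_J && p$W_J < p$W_A, "weights must satisfy W_Y < W_J < W_A")
  chk(p$W_0 < p$W_Y, "egg weight `W_0` must be below `W_Y`")
  for (nm in c("eps_Y", "eps_J", "eps_A"))
    chk(p[[nm]] > 0 && p[[nm]] <= 1, paste0("`", nm, "` must be in (0, 1]"))
  invisible(p)
}

#' Update model parameters, re-deriving dependent constants
#'
#' Like calling [dvm_params()] with modified arguments: changing `h_d` also
#' moves the metabolic half-maximum depth `h_m = h_d - delta_hm` unless `h_m`
#' was set explicitly when the object was created (or is set here).
#'
#' @param params A `dvm_params` object.
#' @param ... Named parameters to replace.
#' @return A new `dvm_params` object.
#' @examples
#' p <- update_dvm_params(dvm_params(), h_d = 100)
#' p$h_m  # 88
#' @export
update_dvm_params <- function(params, ...) {
  stopifnot(inherits(params, "dvm_params"))
  new <- list(...)
  bad <- setdiff(names(new), names(formals(dvm_params)))
  if (length(bad) > 0)
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  args <- params[names(formals(dvm_params))]
  args$h_m <- if (params$h_m_explicit) params$h_m else NULL
  args[names(new)] <- new
  do.call(dvm_params, args)
}

#' @export
print.dvm_params <- function(x, ...) {
  cat("<dvm_params>\n")
  cat(sprintf("  food:      P0 = %g ugC/l, sigma = %g /m, h_p = %g m\n",
              x$P0, x$sigma, x$h_p))
  cat(sprintf("  metabolism: m_A = %g, M_A0 = %g ugC/ind/h, h_m = %g m (sigma_m = %g)%s\n",
              x$m_A, x$M_A0, x$h_m, x$sigma_m,
              if (x$const_cost) " [depth-independent]" else ""))
  cat(sprintf("  zones:     h_u = %g m (delta_u = %g), h_d = %g m (delta_d = %g)\n",
              x$h_u, x$delta_u, x$h_d, x$delta_d))
  cat(sprintf("  predation: gamma = %g/%g/%g /day (Y/J/A)%s\n",
              x$gamma_Y, x$gamma_J, x$gamma_A,
              if (x$avg_predation) " [time-averaged]" else ""))
  cat(sprintf("  weights:   W_0 = %g, W_Y = %g, W_J = %g, W_A = %g ugC\n",
              x$W_0, x$W_Y, x$W_J, x$W_A))
  cat(sprintf("  grazing:   alpha_A = %g l/day, alpha = %g l/ugC, eps = %g/%g/%g\n",
              x$alpha_A, x$alpha, x$eps_Y, x$eps_J, x$eps_A))
  cat(sprintf("  timing:    T0 = %g d, max_age = %g d, speeds %g/%g m/h\n",
              x$T0, x$max_age, x$c_down, x$c_up))
  invisible(x)
}

# per-stage accessors used throughout the package
stage_gamma <- function(params, stage)
  switch(stage, Y = params$gamma_Y, J = params$gamma_J, A = params$gamma_A)
stage_gamma0 <- function(params, stage)
  switch(stage, Y = params$gamma_Y0, J = params$gamma_J0, A = params$gamma_A0)
stage_eps <- function(params, stage)
  switch(stage, Y = params$eps_Y, J = params$eps_J, A = params$eps_A)
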