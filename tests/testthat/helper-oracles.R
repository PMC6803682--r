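# Shared fixtures and independent numerical oracles used across the suite.

default_params <- function(...) dvm_params(...)

# random admissible trajectory under the default parameters
random_trajectory <- function(params = default_params()) {
  H0 <- runif(1, 0, 60)
  H1 <- if (runif(1) < 0.2) H0 else runif(1, H0, min(params$h_max, H0 + 140))
  ramp <- (H1 - H0) / params$c_down_day
  t0 <- runif(1, 0, max(0.02, 0.5 - ramp - 0.02))
  dvm_trajectory(H0, H1, t0, c_down = params$c_down, c_up = params$c_up)
}

# trapezoidal quadrature of f(t) over [a, b]
trapz_fun <- function(f, a, b, n = 20000) {
  if (b - a < 1e-12) return(0)
  t <- seq(a, b, length.out = n + 1)
  y <- f(t)
  (b - a) / n * (sum(y) - (y[1] + y[n + 1]) / 2)
}

# brute-force daily integral respecting the segment kinks: the integrand is
# integrated separately over each trajectory phase so that trapezoidal
# convergence is not spoiled by indicator discontinuities
trapz_daily <- function(f, traj, n = 20000) {
  brk <- sort(unique(pmin(pmax(
    c(0, traj$t0, traj$t1, traj$t2, traj$t3, 1), 0), 1)))
  tot <- 0
  for (i in seq_len(length(brk) - 1)) {
    mid_n <- max(50, ceiling(n * (brk[i + 1] - brk[i])))
    tot <- tot + trapz_fun(f, brk[i] + 1e-12, brk[i + 1] - 1e-12, mid_n)
  }
  tot
}

# independent mortality oracle from the exported pointwise profiles
oracle_stage_mortality <- function(traj, gamma_i, gamma_i0, params, n = 1e5) {
  trapz_daily(function(t) {
    h <- depth_at(traj, t)
    predation_mortality_rate(h, t, gamma_i, params) +
      unfavorable_zone_mortality(h, params)
  }, traj, n) + gamma_i0
}

# independent growth-constant oracle
oracle_growth_coefficient <- function(traj, eps, params, n = 1e5) {
  trapz_daily(function(t) {
    h <- depth_at(traj, t)
    P <- phytoplankton_density(h, params)
    shape <- if (params$const_cost) 1 else
      (tanh(-params$sigma_m * (h - params$h_m)) + 1) / 2
    eps * params$C1 * P / (1 + params$alpha * P) * feeding_indicator(traj, t) -
      params$C2 * shape - params$C3 * shape * active_indicator(traj, t)
  }, traj, n)
}

# RK4 integration of dW/dt = kappa W^0.8 until W_end, fixed step
oracle_maturation_rk4 <- function(W_start, W_end, kappa, dt = 0.001) {
  f <- function(W) kappa * W^0.8
  W <- W_start
  t <- 0
  while (W < W_end) {
    k1 <- f(W); k2 <- f(W + dt / 2 * k1); k3 <- f(W + dt / 2 * k2)
    k4 <- f(W + dt * k3)
    W_new <- W + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (W_new >= W_end) {
      # linear sub-step to the crossing
      return(t + dt * (W_end - W) / (W_new - W))
    }
    W <- W_new
    t <- t + dt
  }
  t
}

# grid + bisection root of the characteristic equation, independent of the
# package's closed-form solver: the renewal form of the equation,
#   u(lambda) = b exp(-a0 tau1 - a1 (tau2 - tau1)) *
#                 int_{tau2}^{tau3} exp(-lambda theta - a2 (theta - tau2)) dtheta - 1,
# is evaluated with brute-force quadrature of the age integral (in log space
# so deeply subcritical cases do not overflow), scanned on a lambda grid for
# its single sign change, and refined by bisection. The root is a root of
# the characteristic equation (the factored root -a2/R is the other one).
oracle_fitness_bisection <- function(a0, a1, a2, b, tau1, tau2, tau3, R = 1,
                                     n_quad = 20000) {
  theta <- seq(tau2, tau3, length.out = n_quad + 1)
  wq <- rep((tau3 - tau2) / n_quad, n_quad + 1)
  wq[c(1, n_quad + 1)] <- wq[1] / 2
  log_u <- function(lam) {
    ex <- -lam * theta - a2 * (theta - tau2)
    m <- max(ex)
    log(b) - a0 * tau1 - a1 * (tau2 - tau1) + m + log(sum(wq * exp(ex - m)))
  }
  lo <- -5; hi <- 5
  while (log_u(lo) < 0) lo <- 2 * lo
  while (log_u(hi) > 0) hi <- 2 * hi
  for (k in 1:200) {
    m <- (lo + hi) / 2
    if (log_u(m) > 0) lo <- m else hi <- m
    if (hi - lo < 1e-13) break
  }
  (lo + hi) / 2 / R
}
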