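test_that("segment-decomposition integrals match brute-force quadrature", {
  p <- default_params()
  withr::with_seed(21, {
    for (i in 1:12) {
      tr <- random_trajectory(p)
      a_pkg <- stage_mortality(tr, p$gamma_J, 0.02, p)
      a_ora <- oracle_stage_mortality(tr, p$gamma_J, 0.02, p)
      expect_equal(a_pkg, a_ora, tolerance = 1e-6)
      k_pkg <- growth_coefficient(tr, p$eps_J, p)
      k_ora <- oracle_growth_coefficient(tr, p$eps_J, p)
      expect_equal(k_pkg, k_ora, tolerance = 2e-6 * max(1, abs(k_ora)))
    }
  })
})

test_that("integrals also match under constant costs and averaged predation", {
  withr::with_seed(22, {
    for (pp in list(default_params(const_cost = TRUE),
                    default_params(avg_predation = TRUE))) {
      for (i in 1:6) {
        tr <- random_trajectory(pp)
        expect_equal(stage_mortality(tr, 0.8, 0.1, pp),
                     oracle_stage_mortality(tr, 0.8, 0.1, pp),
                     tolerance = 1e-6)
        expect_equal(growth_coefficient(tr, 0.7, pp),
                     oracle_growth_coefficient(tr, 0.7, pp),
                     tolerance = 2e-6)
      }
    }
  })
})

test_that("net energy has the closed-form Holling intake at a feeding station", {
  # stationary at the half-maximum food depth with all costs switched off:
  # intake is eps * alpha_A * P / (1 + alpha P) = 0.7 * 1.1 * 15 / 1.75
  p <- default_params(m_A = 1e-12, M_A0 = 1e-12)
  tr <- dvm_trajectory(p$h_p)
  expect_equal(daily_net_energy(tr, p$W_A, p$eps_A, p),
               0.7 * 1.1 * 15 / (1 + 0.05 * 15), tolerance = 1e-9)
  expect_equal(daily_net_energy(tr, p$W_A, p$eps_A, p), 6.6, tolerance = 1e-9)
  # far below the food and metabolic layers everything vanishes
  deep <- dvm_trajectory(195)
  expect_equal(daily_net_energy(deep, p$W_A, p$eps_A, default_params()), 0,
               tolerance = 1e-3)
})

test_that("fecundity divides the net energy by egg weight and clips at zero", {
  p <- default_params()
  trA <- dvm_trajectory(33, 122, t0 = 0.2)
  b <- fecundity(trA, p)
  expect_equal(as.numeric(b),
               daily_net_energy(trA, p$W_A, p$eps_A, p) / p$W_0)
  expect_false(attr(b, "clipped"))
  # b scales as 1 / W_0
  p2 <- update_dvm_params(p, W_0 = p$W_0 / 2)
  expect_equal(as.numeric(fecundity(trA, p2)), 2 * as.numeric(b))
  # a permanently deep trajectory starves: clipped to zero
  b0 <- fecundity(dvm_trajectory(150), p)
  expect_equal(as.numeric(b0), 0)
  expect_true(attr(b0, "clipped"))
})

test_that("constant-depth mortality reduces to its closed form", {
  p <- default_params()
  tr <- dvm_trajectory(p$h_p)  # at h_p the depth sigmoid is exactly 1
  a <- stage_mortality(tr, 0.8, 0, p)
  expect_equal(a, 0.8 / 4 + unfavorable_zone_mortality(p$h_p, p),
               tolerance = 1e-10)
  # daytime-deep residence lowers predation vs staying shallow all day
  mig <- dvm_trajectory(35, 120, t0 = 0.2)
  stat <- dvm_trajectory(35)
  expect_lt(stage_mortality(mig, 0.8, 0, p), stage_mortality(stat, 0.8, 0, p))
  # mortality never drops below the natural rate
  withr::with_seed(23, {
    for (i in 1:10) {
      tr <- random_trajectory(p)
      expect_gte(stage_mortality(tr, 0.8, 0.1, p), 0.1)
    }
  })
})

test_that("maturation time is the exact power-law solution", {
  expect_equal(maturation_time(25, 25, 0.1), 0)
  expect_equal(maturation_time(1.2, 25, 0.2),
               maturation_time(1.2, 25, 0.1) / 2)
  expect_equal(maturation_time(1.2, 25, -0.05), Inf)
  # matches RK4 integration of dW/dt = kappa W^0.8 to 6 significant digits
  for (kappa in c(0.05, 0.11)) {
    tau <- maturation_time(1.2, 25, kappa)
    tau_rk4 <- oracle_maturation_rk4(1.2, 25, kappa)
    expect_equal(tau, tau_rk4, tolerance = 1e-6)
  }
  expect_error(maturation_time(25, 1.2, 0.1), "at least")
})

test_that("stage rates assemble the fitness coefficients consistently", {
  p <- default_params()
  s <- dvm_strategy(Y = dvm_trajectory(33),
                    J = dvm_trajectory(34, 121, 0.2),
                    A = dvm_trajectory(33, 122, 0.2))
  r <- compute_stage_rates(s, p)
  expect_equal(r$tau_3 - r$tau_2, p$T0)
  expect_equal(r$tau_1, maturation_time(p$W_Y, p$W_J, r$kappa_Y))
  expect_true(r$feasible)
  # identical Y and J trajectories see the same environment: equal kappas
  s2 <- dvm_strategy(Y = s$J, J = s$J, A = s$A)
  r2 <- compute_stage_rates(s2, p)
  expect_equal(r2$kappa_Y, r2$kappa_J)
  # kappa is linear in the assimilation efficiency at fixed trajectory
  k1 <- growth_coefficient(s$J, 0.6, p)
  k2 <- growth_coefficient(s$J, 0.8, p)
  kmid <- growth_coefficient(s$J, 0.7, p)
  expect_equal(kmid, (k1 + k2) / 2, tolerance = 1e-12)
  # a non-maturing strategy is flagged, not an error
  deep <- dvm_strategy(Y = dvm_trajectory(180), J = dvm_trajectory(180),
                       A = dvm_trajectory(180))
  rd <- compute_stage_rates(deep, p)
  expect_false(rd$feasible)
  expect_equal(rd$status, "non_maturing")
  expect_equal(rd$tau_1, Inf)
})
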