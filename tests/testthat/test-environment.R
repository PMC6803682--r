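test_that("phytoplankton profile has the right anchors and monotonicity", {
  p <- default_params()
  expect_equal(phytoplankton_density(p$h_p, p), p$P0 / 2)
  expect_equal(phytoplankton_density(0, p),
               p$P0 * (tanh(0.125 * 40) + 1) / 2, tolerance = 1e-12)
  expect_lt(phytoplankton_density(200, p), 1e-15 * p$P0)
  h <- seq(0, 200, by = 0.5)
  Ph <- phytoplankton_density(h, p)
  expect_true(all(diff(Ph) <= 0))
  expect_true(all(diff(Ph[h <= 100]) < 0))  # strict until tanh saturates
  expect_true(all(Ph >= 0 & Ph <= p$P0))
  expect_error(phytoplankton_density(-1, p), "nonnegative")
})

test_that("metabolic rates: half-maximum at h_m, x24 day conversion, allometry", {
  p <- default_params()
  expect_equal(basal_metabolic_rate(p$h_m, p$W_A, p), 24 * p$m_A / 2)
  expect_equal(active_metabolic_rate(p$h_m, p$W_A, p), 24 * p$M_A0 / 2)
  expect_equal(active_metabolic_rate(p$h_m, p$W_A, p), 1.56)
  # deep water: costs vanish
  expect_lt(basal_metabolic_rate(p$h_max, p$W_A, p),
            0.01 * basal_metabolic_rate(0, p$W_A, p))
  # weight W_A / 2^1.25 gives exactly half the adult cost at any depth
  W_half <- p$W_A / 2^1.25
  for (h in c(0, 50, 128)) {
    expect_equal(basal_metabolic_rate(h, W_half, p),
                 basal_metabolic_rate(h, p$W_A, p) / 2, tolerance = 1e-12)
  }
  # active/basal ratio is depth-independent (same profile shape)
  h <- seq(0, 195, by = 5)
  ratio <- active_metabolic_rate(h, 30, p) / basal_metabolic_rate(h, 30, p)
  expect_equal(ratio, rep(p$M_A0 / p$m_A, length(h)), tolerance = 1e-12)
  expect_error(basal_metabolic_rate(10, 0, p), "positive")
})

test_that("allometric scaling is the 0.8 power law", {
  expect_equal(allometric_scale(110, 1.1, 110), 1.1)
  expect_equal(allometric_scale(25, 1.1, 110), 1.1 * (25 / 110)^0.8)
  expect_equal(allometric_scale(25, 1.1, 110), 0.3362, tolerance = 1e-3)
  # multiplicative: scale(aW)/scale(W) = a^0.8
  expect_equal(allometric_scale(2 * 30, 1, 30) / allometric_scale(30, 1, 30),
               2^0.8, tolerance = 1e-12)
})

test_that("unfavorable-zone mortality is delta at each boundary and ~0 between", {
  p <- default_params()
  expect_equal(unfavorable_zone_mortality(p$h_u, p), p$delta_u,
               tolerance = 1e-8)
  expect_equal(unfavorable_zone_mortality(p$h_d, p), p$delta_d,
               tolerance = 1e-8)
  expect_lt(unfavorable_zone_mortality(80, p), 1e-4)
  # limits: 2 delta_u at the surface, 2 delta_d at depth
  expect_equal(unfavorable_zone_mortality(0, p), 2 * p$delta_u,
               tolerance = 1e-3)
  h <- seq(0, 200, by = 1)
  A <- unfavorable_zone_mortality(h, p)
  expect_true(all(A >= 0 & A <= 2 * (p$delta_u + p$delta_d)))
})

test_that("predation risk follows the diel light cycle", {
  p <- default_params()
  expect_equal(predation_mortality_rate(30, 0, 0.8, p), 0)
  expect_equal(predation_mortality_rate(0, 0.5, 0.8, p), 0.8,
               tolerance = 1e-3)
  # time average at fixed depth equals gamma (tanh + 1) / 4
  h <- 35
  avg <- trapz_fun(function(t) predation_mortality_rate(h, t, 0.8, p), 0, 1,
                   n = 5e4)
  expect_equal(avg, 0.8 * (tanh(-p$sigma * (h - p$h_p)) + 1) / 4,
               tolerance = 1e-6)
  expect_error(predation_mortality_rate(10, 1.5, 0.8, p), "\\[0, 1\\]")
})

test_that("parameter validation enforces the geometric and weight orderings", {
  expect_error(dvm_params(h_u = 150, h_d = 140), "h_u")
  expect_error(dvm_params(W_J = 200), "W_Y < W_J < W_A")
  expect_error(dvm_params(eps_A = 1.5), "eps_A")
  expect_error(dvm_params(P0 = -3), "P0")
  # h_m defaults to h_d - delta_hm and follows h_d unless explicit
  p <- dvm_params(h_d = 100)
  expect_equal(p$h_m, 88)
  expect_equal(update_dvm_params(p, h_d = 120)$h_m, 108)
  p2 <- dvm_params(h_m = 70)
  expect_equal(update_dvm_params(p2, h_d = 120)$h_m, 70)
})
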