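# synthetic stage rates for simulator unit tests (chosen supercritical or
# subcritical as each test needs; not derived from any optimisation)
synth_rates <- function(b = 8, a_Y = 0.3, a_J = 0.05, a_A = 0.05,
                        tau_1 = 25, tau_2 = 60, tau_3 = 100) {
  tibble::tibble(b = b, a_Y = a_Y, a_J = a_J, a_A = a_A,
                 tau_1 = tau_1, tau_2 = tau_2, tau_3 = tau_3)
}

test_that("without reproduction the cohort decays as stage-wise exponentials", {
  # start from adults only: every cohort is and stays in the adult stage
  # (mortality a_A) for the whole horizon, so decay is a single exponential
  r <- synth_rates(b = 0, a_Y = 0.2, a_J = 0.1, a_A = 0.05,
                   tau_1 = 50, tau_2 = 80, tau_3 = 120)
  sim <- simulate_selection(r, horizon = 20, dtau = 0.05, record_every = 100,
                            init = "adults_only")
  s <- sim$series
  n0 <- s$density[s$time == 0]
  n10 <- s$density[s$time == 10]
  n20 <- s$density[s$time == 20]
  expect_equal(log(n10 / n0), -0.05 * 10, tolerance = 1e-10)
  expect_equal(log(n20 / n10), -0.05 * 10, tolerance = 1e-10)
})

test_that("uncoupled growth rate matches the characteristic-equation root", {
  r <- synth_rates()
  f <- solve_fitness(r$a_Y, r$a_J, r$a_A, r$b, r$tau_1, r$tau_2, r$tau_3)
  sim <- simulate_selection(r, horizon = 1200, dtau = 0.05, record_every = 40)
  lam_hat <- growth_rate(sim, 1, window = c(700, 1200))
  expect_equal(lam_hat, f$J * 1, tolerance = 0.01 * max(abs(f$J), 0.01))
})

test_that("halving the age step changes the measured growth rate by < 0.2%", {
  r <- synth_rates(b = 5, a_A = 0.08)
  lam <- vapply(c(0.1, 0.05), function(dt) {
    sim <- simulate_selection(r, horizon = 900, dtau = dt, record_every = 50)
    growth_rate(sim, 1, window = c(500, 900))
  }, 0)
  expect_lt(abs(lam[2] - lam[1]) / max(abs(lam[2]), 1e-6), 0.002)
})

test_that("density-dependent coupling bounds a growing population", {
  # supercritical synthetic rates: grows without coupling
  r <- synth_rates(b = 5, a_Y = 0.1, a_J = 0.02, a_A = 0.05,
                   tau_1 = 15, tau_2 = 40, tau_3 = 100)
  f <- solve_fitness(r$a_Y, r$a_J, r$a_A, r$b, r$tau_1, r$tau_2, r$tau_3)
  expect_gt(f$J, 0)
  sim <- simulate_selection(r, horizon = 3000, dtau = 0.1, coupled = TRUE,
                            record_every = 50)
  y <- sim$y$y
  expect_true(all(is.finite(y)) && all(y >= 0))
  # bounded near the carrying level y* = J R, not growing without limit
  late <- y[sim$y$time > 2000]
  expect_lt(max(late), 10 * f$J)
  expect_gt(min(late), f$J / 10)
})

test_that("identical strategies keep a constant ratio; order is irrelevant", {
  r2 <- dplyr::bind_rows(synth_rates(), synth_rates())
  sim <- simulate_selection(r2, horizon = 400, dtau = 0.1)
  s1 <- sim$series[sim$series$strategy == 1, ]
  s2 <- sim$series[sim$series$strategy == 2, ]
  expect_equal(s1$log_density, s2$log_density, tolerance = 1e-12)
  chk <- ranking_check(sim, 1, 2)
  expect_false(isTRUE(chk$verdict))
  # permuting strategies permutes the series and nothing else
  ra <- synth_rates(); rb <- synth_rates(b = 5)
  simab <- simulate_selection(dplyr::bind_rows(ra, rb), horizon = 300, dtau = 0.1)
  simba <- simulate_selection(dplyr::bind_rows(rb, ra), horizon = 300, dtau = 0.1)
  expect_equal(simab$series$log_density[simab$series$strategy == 1],
               simba$series$log_density[simba$series$strategy == 2],
               tolerance = 1e-12)
})

test_that("pairwise competition follows the fitness ordering and is antisymmetric", {
  ra <- synth_rates(b = 10)
  rb <- synth_rates(b = 4)   # same mortalities, lower fecundity: less fit
  Ja <- solve_fitness(ra$a_Y, ra$a_J, ra$a_A, ra$b, ra$tau_1, ra$tau_2, ra$tau_3)$J
  Jb <- solve_fitness(rb$a_Y, rb$a_J, rb$a_A, rb$b, rb$tau_1, rb$tau_2, rb$tau_3)$J
  expect_gt(Ja, Jb)
  sim <- simulate_selection(dplyr::bind_rows(ra, rb), horizon = 4000, dtau = 0.1,
                            record_every = 100)
  expect_true(isTRUE(ranking_check(sim, k_fit = 1, k_unfit = 2,
                                   burn_frac = 0.3)$verdict))
  expect_false(isTRUE(ranking_check(sim, k_fit = 2, k_unfit = 1,
                                    burn_frac = 0.3)$verdict))
})

test_that("the shared coupling term does not alter density ratios", {
  r2 <- dplyr::bind_rows(synth_rates(b = 10), synth_rates(b = 7))
  unc <- simulate_selection(r2, horizon = 300, dtau = 0.1, coupled = FALSE)
  cou <- simulate_selection(r2, horizon = 300, dtau = 0.1, coupled = TRUE,
                            y0 = 0.05)
  lr_unc <- unc$series$log_density[unc$series$strategy == 1] -
    unc$series$log_density[unc$series$strategy == 2]
  lr_cou <- cou$series$log_density[cou$series$strategy == 1] -
    cou$series$log_density[cou$series$strategy == 2]
  expect_equal(lr_unc, lr_cou, tolerance = 1e-8)
})

test_that("the verdict is robust to the initial age distribution", {
  ra <- synth_rates(b = 10); rb <- synth_rates(b = 4)
  for (init in c("uniform_young", "uniform_all", "adults_only")) {
    sim <- simulate_selection(dplyr::bind_rows(ra, rb), horizon = 4000,
                              dtau = 0.1, init = init, record_every = 100)
    expect_true(isTRUE(ranking_check(sim, 1, 2, burn_frac = 0.3)$verdict),
                label = init)
  }
})

test_that("random feasible strategies are admissible, reproducible and ranked", {
  p <- default_params()
  rs1 <- random_strategies(6, p, seed = 5)
  rs2 <- random_strategies(6, p, seed = 5)
  expect_equal(rs1, rs2)
  expect_true(all(rs1$feasible))
  expect_true(all(rs1$b > 0 & rs1$tau_2 <= p$max_age))
  expect_true(all(is.finite(rs1$J)))
})
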