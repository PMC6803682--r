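test_that("characteristic residual vanishes at its analytic roots", {
  # with b = 0 the equation reduces to J = -a2 / R
  expect_equal(characteristic_residual(-0.3, 0.4, 0.1, 0.3, 0, 20, 60, 100), 0)
  # with a2 = 0, J = 0 makes the bracket vanish
  expect_equal(characteristic_residual(0, 0.4, 0.1, 0, 5, 20, 60, 100), 0)
  # continuous and decreasing to -Inf for large J (RHS bounded)
  Fs <- vapply(seq(0, 50, length.out = 200), characteristic_residual,
               0, a0 = 0.1, a1 = 0.1, a2 = 0.1, b = 5,
               tau1 = 10, tau2 = 30, tau3 = 70)
  expect_lt(Fs[200], -40)
  expect_error(characteristic_residual(0, 0.1, 0.1, 0.1, 5, 30, 10, 70),
               "tau1 < tau2 < tau3")
})

test_that("solve_fitness returns the degenerate and textbook roots exactly", {
  f0 <- solve_fitness(a0 = 0.2, a1 = 0.1, a2 = 0.3, b = 0,
                      tau1 = 10, tau2 = 40, tau3 = 80, R = 1)
  expect_equal(f0$J, -0.3)
  expect_true(f0$degenerate)
  # stage-free case J = 2 (exp(-J) - exp(-2J)); bisection value ~ 0.4682
  f <- solve_fitness(0, 0, 0, b = 2, tau1 = 0.5, tau2 = 1, tau3 = 2)
  J_oracle <- oracle_fitness_bisection(0, 0, 0, 2, 0.5, 1, 2)
  expect_equal(f$J, J_oracle, tolerance = 1e-6)
  expect_equal(f$J, 0.4682, tolerance = 1e-3)
  expect_true(f$converged)
  expect_lt(abs(f$residual), 1e-10)
})

test_that("solve_fitness agrees with grid bisection on 100 random inputs", {
  withr::with_seed(31, {
    for (i in 1:100) {
      a0 <- runif(1, 0, 0.6); a1 <- runif(1, 0, 0.3); a2 <- runif(1, 0, 0.4)
      b <- runif(1, 0.5, 40)
      tau1 <- runif(1, 5, 40)
      tau2 <- tau1 + runif(1, 5, 60)
      tau3 <- tau2 + runif(1, 20, 60)
      f <- solve_fitness(a0, a1, a2, b, tau1, tau2, tau3)
      J_oracle <- oracle_fitness_bisection(a0, a1, a2, b, tau1, tau2, tau3)
      expect_equal(f$J, J_oracle, tolerance = 1e-6)
      expect_lt(abs(f$residual), 1e-10)
    }
  })
})

test_that("fitness responds monotonically to fecundity and mortality", {
  base <- list(a0 = 0.3, a1 = 0.05, a2 = 0.05, b = 8,
               tau1 = 25, tau2 = 60, tau3 = 100)
  J <- function(args) do.call(solve_fitness, args)$J
  expect_gt(J(utils::modifyList(base, list(b = 12))), J(base))
  for (a in c("a0", "a1", "a2")) {
    up <- utils::modifyList(base, stats::setNames(list(base[[a]] + 0.1), a))
    expect_lte(J(up), J(base))
  }
})

test_that("rescaling R rescales J without changing the ranking", {
  withr::with_seed(32, {
    for (i in 1:10) {
      a <- runif(3, 0, 0.4)
      b <- runif(2, 1, 30)
      taus <- sort(runif(3, 10, 150))
      J1 <- solve_fitness(a[1], a[2], a[3], b[1], taus[1], taus[2], taus[3], R = 1)$J
      J2 <- solve_fitness(a[1], a[2], a[3], b[2], taus[1], taus[2], taus[3], R = 1)$J
      J1s <- solve_fitness(a[1], a[2], a[3], b[1], taus[1], taus[2], taus[3], R = 2)$J
      J2s <- solve_fitness(a[1], a[2], a[3], b[2], taus[1], taus[2], taus[3], R = 2)$J
      expect_equal(J1s, J1 / 2, tolerance = 1e-9)
      expect_equal(sign(J1 - J2), sign(J1s - J2s))
    }
  })
})

test_that("deeply subcritical inputs are solved without overflow", {
  # survival factors of order exp(-20): the log-space solver must not fail
  f <- solve_fitness(a0 = 0.5, a1 = 0.3, a2 = 0.2, b = 3,
                     tau1 = 40, tau2 = 120, tau3 = 160)
  expect_true(f$converged)
  expect_true(f$J < 0 && f$J > -1)
  expect_lt(abs(f$residual), 1e-10)
})
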