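test_that("ratio fixed points solve the quadratic exactly in simple cases", {
  # one-way switching factorizes: roots 0 and (delta_mu - a)/a
  fp <- ratio_fixed_points(env_params(2, 0.2, a = 0.2, b = 0))
  expect_equal(fp$r_stable, 8)
  expect_equal(fp$r_unstable, 0)
  # tiny symmetric switching: stable root ~ delta_mu / a
  fp2 <- ratio_fixed_points(env_params(2, 0.2, a = 1e-6, b = 1e-6))
  expect_equal(fp2$r_stable, 1.8e6, tolerance = 1e-5)
  expect_lte(fp2$r_unstable, 0)
  expect_error(ratio_fixed_points(env_params(2, 0.2, a = 0, b = 1e-3)),
               "positive")
})

test_that("the ratio ODE flow is attracted to the stable fixed point", {
  # rhs positive below r_stable, negative above (checked on a grid)
  env <- env_params(2, 0.2, a = 1e-3, b = 1e-2)
  fp <- ratio_fixed_points(env)
  rhs <- function(r) -env$a * r^2 + (1.8 - env$a + env$b) * r + env$b
  below <- seq(max(fp$r_unstable + 1e-6, 0), fp$r_stable * 0.99,
               length.out = 25)
  above <- seq(fp$r_stable * 1.01, fp$r_stable * 10, length.out = 25)
  expect_true(all(rhs(below) > 0))
  expect_true(all(rhs(above) < 0))
})

test_that("steady-state structure has the small-switching leading order", {
  env <- env_params(2, 0.2, a = 1.8e-6, b = 1e-4, label = "growth")
  ss <- steady_state_structure(env)
  expect_equal(ss$persister_fraction, 1e-6, tolerance = 1e-4)
  expect_equal(ss$effective_rate, 2 - 1.8e-6)
  expect_equal(ss$relaxation_rate, 1.8, tolerance = 1e-3)
  # consistency persister_fraction = 1/(1 + ratio_star) in growth
  expect_equal(ss$persister_fraction, 1 / (1 + ss$ratio_star),
               tolerance = 1e-15)
  # symmetric case a = b, mu_n = -mu_p: fraction a / (2 mu_n)
  sym <- steady_state_structure(env_params(1, -1, 1e-4, 1e-4,
                                           label = "growth"))
  expect_equal(sym$persister_fraction, 1e-4 / 2, tolerance = 1e-3)
  # stress orientation mirrors
  envs <- env_params(-4, -0.4, a = 1e-4, b = 1e-5, label = "stress")
  sss <- steady_state_structure(envs)
  expect_equal(sss$ratio_star, 3.6 / 1e-5)
  expect_equal(sss$effective_rate, -(0.4 + 1e-5))
  expect_warning(steady_state_structure(env_params(2, 0.2, 0.5, 1e-3)),
                 "small-switching")
})

test_that("effective rate deviates from the dominant eigenvalue only at
           second order in the switching rates", {
  for (a in 10^(-6:-3)) for (b in 10^(-6:-3)) {
    env <- env_params(2, 0.2, a, b, label = "growth")
    ss <- suppressWarnings(steady_state_structure(env))
    lam <- dominant_eigenpair(env)$rate
    expect_lt(abs(ss$effective_rate - lam), 10 * a * b / 1.8)
  }
})

test_that("stationary-phase persister fraction is the switching balance", {
  expect_equal(stationary_phase_fraction(switching_rates(1e-3, 1e-3)), 0.5)
  expect_equal(stationary_phase_fraction(switching_rates(1e-6, 1e-4)),
               1e-6 / (1e-6 + 1e-4))
  expect_error(stationary_phase_fraction(switching_rates(0, 0)), "undefined")
  # capacity-model long-time limit reproduces it (enlarged rates so the
  # slow approach to the switching balance completes within the window)
  env <- env_params(2, 0.2, a = 5e-3, b = 5e-2, label = "growth",
                    carrying_capacity = 1e9)
  tr <- integrate_capacity(env, population_state(1e3, 1), seq(50, 300, 50))
  frac <- tr$p[nrow(tr)] / tr$total[nrow(tr)]
  expect_equal(frac, stationary_phase_fraction(switching_rates(5e-3, 5e-2)),
               tolerance = 0.05)
})

test_that("logistic ratio is exact at the fixed point and converges to it", {
  env <- env_params(2, 0.2, 1e-5, 1e-3, label = "growth")
  r_star <- 1.8 / 1e-5
  expect_equal(logistic_ratio(c(0, 1, 10), r_star, env),
               rep(r_star, 3), tolerance = 1e-14)
  expect_equal(logistic_ratio(50, 1, env), r_star, tolerance = 1e-6)
  expect_equal(logistic_ratio(0, 7, env), 7)
  expect_error(logistic_ratio(1, -1, env), "non-negative")
})

test_that("logistic approximation error shrinks linearly with the
           switching rates", {
  errs <- vapply(c(1e-4, 1e-5, 1e-6), function(s) {
    env <- env_params(2, 0.2, s, s, label = "growth")
    tv <- seq(0, 15, length.out = 61)
    max(abs(logistic_ratio(tv, 1, env) / oracle_ratio(env, 1, tv) - 1))
  }, numeric(1))
  expect_lt(errs[3], 0.01)
  expect_lt(errs[2], errs[1] / 8)
  expect_lt(errs[3], errs[2] / 8)
})

test_that("growth- and stress-condition formulas map onto each other under
           the exchange symmetry", {
  # swapping condition, a <-> b and the subpopulation roles must give
  # identical oriented quantities
  g <- env_params(2, 0.2, a = 3e-4, b = 7e-5, label = "growth")
  s <- env_params(-2, -0.2, a = 7e-5, b = 3e-4, label = "stress")
  fg <- ratio_fixed_points(g)
  fs <- ratio_fixed_points(s)
  expect_equal(fg$r_stable, fs$r_stable, tolerance = 1e-14)
  expect_equal(fg$r_unstable, fs$r_unstable, tolerance = 1e-14)
  tv <- c(0.5, 2, 8)
  expect_equal(logistic_ratio(tv, 2, g), logistic_ratio(tv, 2, s),
               tolerance = 1e-14)
})

test_that("averaged subpopulation rates match exact trajectories and merge
           at long times", {
  env <- env_params(2, 0.2, 0, 0)
  avg0 <- average_subpop_growth(5, env, r0 = 1)
  expect_equal(avg0$rate_normal, 2)
  expect_equal(avg0$rate_persister, 0.2)

  pars <- demo_params()
  st <- population_state(1, 1)
  for (tt in c(5, 15)) {
    avg <- average_subpop_growth(tt, pars$growth, r0 = 1)
    ex <- propagate_exact(pars$growth, st, tt)
    expect_equal(avg$rate_normal, log(ex$n) / tt, tolerance = 0.01)
    expect_equal(avg$rate_persister, log(ex$p) / tt, tolerance = 0.01)
  }
  # stress orientation
  avg_s <- average_subpop_growth(5, pars$stress, r0 = 1)
  ex_s <- propagate_exact(pars$stress, st, 5)
  expect_equal(avg_s$rate_normal, log(ex_s$n) / 5, tolerance = 0.01)
  expect_equal(avg_s$rate_persister, log(ex_s$p) / 5, tolerance = 0.01)
  # long times: both approach the effective rate of the total population
  # (the transient enters the average as log(ratio_star/r0)/t, so the
  # window must be long against that)
  avg_inf <- average_subpop_growth(2e4, pars$growth, r0 = 1)
  lam <- dominant_eigenpair(pars$growth)$rate
  expect_equal(avg_inf$rate_normal, lam, tolerance = 1e-3)
  expect_equal(avg_inf$rate_persister, lam, tolerance = 1e-3)
})

test_that("double-exponential total matches limits and the exact dynamics", {
  env1 <- env_params(2, 0.2, 0, 1e-3)
  expect_equal(total_double_exponential(c(1, 3), 5, 0, env1),
               5 * exp(2 * c(1, 3)))
  pars <- demo_params()
  expect_equal(total_double_exponential(0, 3, 4, pars$stress), 7)
  expect_error(total_double_exponential(1, -1, 1, pars$stress),
               "non-negative")
  expect_error(double_exponential_components(1, 1,
                                             env_params(1, 1, 0, 0)),
               "degenerate")
  # killing-curve accuracy over 15 h from the steady growth structure
  r0 <- 1.8 / 1e-5
  tv <- seq(0, 15, length.out = 61)
  Nde <- total_double_exponential(tv, r0, 1, pars$stress)
  Nex <- vapply(tv, function(tt) {
    st <- propagate_exact(pars$stress, population_state(r0, 1), tt)
    st$n + st$p
  }, numeric(1))
  expect_lt(max(abs(Nde / Nex - 1)), 0.02)
})

test_that("average total growth rate matches the exact rate and its limits", {
  env0 <- env_params(2, 0.2, 0, 1e-9)
  expect_equal(average_total_growth(c(1, 7), env0, r0 = Inf), c(2, 2),
               tolerance = 1e-8)
  pars <- demo_params()
  for (tt in c(5, 15)) {
    got <- average_total_growth(tt, pars$growth, r0 = 1)
    ex <- propagate_exact(pars$growth, population_state(0.5, 0.5), tt)
    expect_equal(got, log((ex$n + ex$p) / 1) / tt, tolerance = 0.01)
  }
  # long-time limit in growth: the effective steady-state rate
  expect_equal(average_total_growth(4000, pars$growth, r0 = 1),
               2 - 1e-5, tolerance = 1e-3)
})
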