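pars <- demo_params()
sw <- switching_rates(1e-5, 1e-3)

test_that("transition times behave at their boundaries and limits", {
  expect_warning(t0 <- transition_time_stress(1, pars$gaps, sw),
                 "persister-dominated")
  expect_equal(t0, 0)
  expect_warning(transition_time_growth(0.5, pars$gaps, sw),
                 "normal-dominated")
  # stated limit: r0 = exp(delta_kappa * 5) gives 5 h
  expect_equal(transition_time_stress(exp(3.6 * 5), pars$gaps, sw,
                                      form = "limit"), 5)
  expect_equal(transition_time_growth(exp(1.8 * 4), pars$gaps, sw,
                                      form = "limit"), 4)
})

test_that("transition times match the exact subpopulation-equality crossing", {
  r0 <- 1.8 / 1e-5    # steady growth structure
  Ts <- transition_time_stress(r0, pars$gaps, sw)
  f <- function(tt) {
    st <- propagate_exact(pars$stress, population_state(r0, 1), tt)
    log(st$n / st$p)
  }
  Tx <- stats::uniroot(f, c(0.01, 14), tol = 1e-12)$root
  expect_equal(Ts, Tx, tolerance = 0.05)

  rg <- 3.6 / 1e-3    # steady stress structure
  Tg <- transition_time_growth(rg, pars$gaps, sw)
  g <- function(tt) {
    st <- propagate_exact(pars$growth, population_state(1, rg), tt)
    log(st$p / st$n)
  }
  Tgx <- stats::uniroot(g, c(0.01, 14), tol = 1e-12)$root
  expect_equal(Tg, Tgx, tolerance = 0.05)
})

test_that("transition times are monotone in the initial ratio and the gaps", {
  r0s <- c(10, 100, 1e4)
  Ts <- vapply(r0s, transition_time_stress, numeric(1), pars$gaps, sw)
  expect_true(all(diff(Ts) > 0))
  gaps2 <- make_rate_gaps(1.8, 7.2)      # larger delta_kappa
  expect_lt(transition_time_stress(100, gaps2, sw),
            transition_time_stress(100, pars$gaps, sw))
  Tg <- vapply(r0s, transition_time_growth, numeric(1), pars$gaps, sw)
  expect_true(all(diff(Tg) > 0))
  gaps3 <- make_rate_gaps(3.6, 3.6)      # larger delta_mu
  expect_lt(transition_time_growth(100, gaps3, sw),
            transition_time_growth(100, pars$gaps, sw))
})

test_that("structure equilibration happens after the total-curve kink and
           matches the numeric inflection", {
  eq <- equilibration_times(pars$gaps, sw)
  st <- steady_transition_times(pars$gaps, sw)
  expect_gt(eq$T_s_prime, st$T_s)
  expect_gt(eq$T_g_prime, st$T_g)
  # numeric inflection of d log n / dt on the exact killing curve
  r0 <- 1.8 / 1e-5
  tv <- seq(0.01, 14, by = 0.01)
  lgn <- vapply(tv, function(tt)
    log(propagate_exact(pars$stress, population_state(r0, 1), tt)$n),
    numeric(1))
  t_inflect <- tv[which.max(diff(diff(lgn))) + 1L]
  expect_equal(eq$T_s_prime, t_inflect, tolerance = 0.05)
  # switching rates 10x smaller delay equilibration by log(10)/delta_kappa
  # (at fixed pre-shift ratio, chosen well above the unstable fixed point
  # -a/delta_kappa so only the stable-ratio shift matters)
  eq_small <- equilibration_times(pars$gaps, switching_rates(1e-6, 1e-4),
                                  r0_stress = 1e3)
  eq_ref <- equilibration_times(pars$gaps, sw, r0_stress = 1e3)
  expect_equal(eq_small$T_s_prime - eq_ref$T_s_prime, log(10) / 3.6,
               tolerance = 0.05)
})

test_that("steady-state transition times invert exactly and scale as
           expected", {
  st <- steady_transition_times(pars$gaps, sw)
  inv <- infer_switching_rates(pars$gaps, st$T_s, st$T_g)
  expect_equal(inv$a_hat, 1e-5, tolerance = 1e-12)
  expect_equal(inv$b_hat, 1e-3, tolerance = 1e-12)
  # a -> a/10 delays the kill-curve kink by log(10)/delta_kappa
  st10 <- steady_transition_times(pars$gaps, switching_rates(1e-6, 1e-3))
  expect_equal(st10$T_s - st$T_s, log(10) / 3.6, tolerance = 1e-12)
  # consistency with the crossing-time route at the steady pre-shift ratio
  Ts_full <- transition_time_stress(1.8 / 1e-5, pars$gaps, sw)
  expect_equal(st$T_s, Ts_full, tolerance = 0.01)
  # T_s = 0 boundary: inversion returns the combined rate gap
  inv0 <- infer_switching_rates(pars$gaps, 0, st$T_g)
  expect_equal(inv0$a_hat, 1.8 * 3.6 / (1.8 + 3.6))
  expect_error(steady_transition_times(pars$gaps, switching_rates(0, 1e-3)),
               "positive switching")
})

test_that("double-exponential fits recover noiseless curves to high accuracy", {
  r0 <- 1.8 / 1e-5
  tv <- seq(0, 15, length.out = 40)
  cmp <- double_exponential_components(r0 * 1e3, 1e3, pars$stress)
  df <- data.frame(time_h = tv,
                   cfu_total = total_double_exponential(tv, r0 * 1e3, 1e3,
                                                        pars$stress))
  fit <- fit_double_exponential(df, "stress")
  expect_false(fit$degenerate)
  expect_equal(fit$rate_fast, cmp$rate_fast, tolerance = 1e-3)
  expect_equal(fit$rate_slow, cmp$rate_slow, tolerance = 1e-3)
  expect_equal(fit$amp_fast, cmp$amp_fast, tolerance = 1e-3)
  expect_equal(fit$amp_slow, cmp$amp_slow, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-12)
})

test_that("single-exponential data are flagged degenerate", {
  df <- data.frame(time_h = 0:10, cfu_total = 1e6 * exp(-2 * (0:10)))
  fit <- fit_double_exponential(df, "stress")
  expect_true(fit$degenerate)
  expect_lt(fit$amp_slow / fit$amp_fast, 1e-6)
  expect_equal(fit$rate_fast, -2, tolerance = 1e-8)
})

test_that("fits tolerate realistic plating noise", {
  r0 <- 1.8 / 1e-5
  tv <- seq(0, 15, length.out = 30)
  mean_counts <- total_double_exponential(tv, r0 * 1e3, 1e3, pars$stress)
  cmp <- double_exponential_components(r0 * 1e3, 1e3, pars$stress)
  set.seed(7)
  df <- data.frame(time_h = tv,
                   cfu_total = mean_counts * 10^rnorm(length(tv), 0, 0.05))
  fit <- fit_double_exponential(df, "stress")
  expect_equal(fit$rate_fast, cmp$rate_fast, tolerance = 0.1)
  expect_equal(fit$rate_slow, cmp$rate_slow, tolerance = 0.1)
  expect_equal(fit$amp_fast, cmp$amp_fast, tolerance = 0.25)
  expect_equal(fit$amp_slow, cmp$amp_slow, tolerance = 0.25)
})

test_that("the located transition matches the analytic time and is scale
           invariant", {
  r0 <- 1.8 / 1e-5
  tv <- seq(0, 15, length.out = 40)
  mk <- function(scale) data.frame(
    time_h = tv,
    cfu_total = scale * total_double_exponential(tv, r0, 1, pars$stress))
  fit1 <- fit_double_exponential(mk(1), "stress")
  t1 <- locate_transition(fit1)
  expect_equal(t1, transition_time_stress(r0, pars$gaps, sw),
               tolerance = 0.05)
  fit2 <- fit_double_exponential(mk(1e7), "stress")
  expect_equal(locate_transition(fit2), t1, tolerance = 1e-6)
  # equal amplitudes cross at the origin
  fit1$amp_slow <- fit1$amp_fast
  fit1$t_origin <- 0
  expect_equal(locate_transition(fit1), 0)
  fit1$rate_slow <- fit1$rate_fast
  expect_error(locate_transition(fit1), "equal")
})

test_that("the full pipeline recovers the switching rates from noiseless
           synthetic shift curves", {
  for (ab in list(c(1e-5, 1e-3), c(1e-6, 1e-4), c(1e-3, 1e-6))) {
    inf <- pipeline_recover(ab[1], ab[2])
    expect_equal(inf$a_hat, ab[1], tolerance = 0.25)
    expect_equal(inf$b_hat, ab[2], tolerance = 0.25)
  }
})
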