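# Long-time growth in periodically alternating growth/stress environments.
#
# The authoritative route is the Floquet one: the per-cycle propagator
# M = P_s(t_s) P_g(t_g) is a positive 2x2 matrix whose dominant eigenvalue
# Lambda gives the long-time average per-capita growth rate
# lambda_bar = log(Lambda)/(t_g + t_s), independent of the initial state.
# The closed form valid when both phases are long enough for the population
# structure to reach its steady state in each condition is
#   lambda_bar (t_g+t_s) = (mu_n - a) t_g - (kappa_p + b) t_s
#                          - log(delta_c/a) - log(delta_c/b)
# i.e. exponential gain/loss at the per-condition effective rates minus two
# structure-reset penalties, delta_kappa*T_s and delta_mu*T_g, paid at the
# shifts (delta_c is the combined rate gap of shift_experiments.R).

#' Specification of a periodic growth/stress cycle
#'
#' @param t_g Growth-phase duration (hours, > 0).
#' @param t_s Stress-phase duration (hours, > 0).
#' @param env_g Growth-condition [env_params()] (positive growth-rate gap).
#' @param env_s Stress-condition [env_params()] (positive death-rate gap).
#' @return Object of class `"cycle_spec"`.
#' @examples
#' pars <- demo_params()
#' cs <- cycle_spec(15, 15, pars$growth, pars$stress)
#' @export
cycle_spec <- function(t_g, t_s, env_g, env_s) {
  stopifnot(is.numeric(t_g), is.finite(t_g), t_g > 0,
            is.numeric(t_s), is.finite(t_s), t_s > 0)
  env_g <- as_env_params(env_g)
  env_s <- as_env_params(env_s)
  gaps <- rate_gaps(env_g, env_s)   # validates both gaps are positive
  structure(list(t_g = t_g, t_s = t_s, env_g = env_g, env_s = env_s,
                 gaps = gaps),
            class = "cycle_spec")
}

as_cycle_spec <- function(spec) {
  if (!inherits(spec, "cycle_spec"))
    stop("expected a 'cycle_spec' object", call. = FALSE)
  spec
}

#' Replace the switching rates of both environments of a cycle
#'
#' The switching machinery is a property of the organism, so optimization
#' over switching rates varies (a, b) jointly in both environments.
#'
#' @param spec A [cycle_spec()].
#' @param a,b New switching rates (1/hour).
#' @return A new `cycle_spec`.
#' @export
with_switching <- function(spec, a, b) {
  spec <- as_cycle_spec(spec)
  eg <- spec$env_g; es <- spec$env_s
  cycle_spec(spec$t_g, spec$t_s,
             env_params(eg$mu_n, eg$mu_p, a, b, eg$label, eg$carrying_capacity),
             env_params(es$mu_n, es$mu_p, a, b, es$label, es$carrying_capacity))
}

#' Per-cycle propagator matrix
#'
#' `M = P_s(t_s) %*% P_g(t_g)`: one growth phase followed by one stress
#' phase, both via the exact phase propagators. Positive matrix whenever
#' both switching rates are positive.
#'
#' @param spec A [cycle_spec()] (infinite carrying capacities).
#' @return 2x2 matrix (ordering `[n, p]`).
#' @export
cycle_propagator <- function(spec) {
  spec <- as_cycle_spec(spec)
  phase_propagator(spec$env_s, spec$t_s) %*%
    phase_propagator(spec$env_g, spec$t_g)
}

#' Long-time growth rate in a periodic environment
#'
#' Dominant-eigenvalue (Floquet) cycle growth rate, the subpopulation ratio
#' at the growth -> stress boundary in the periodic regime, the number of
#' cycles needed to converge to that regime from a balanced start, and the
#' steady-structure closed form `lambda_bar_closed` (valid when both phases
#' are long enough to equilibrate the population structure; `NA` when a
#' switching rate is zero).
#'
#' @param spec A [cycle_spec()].
#' @param ratio_tol Per-cycle relative change of the boundary ratio below
#'   which the periodic regime is declared converged (default 1e-8).
#' @return List of class `"cycle_growth_result"` with `lambda_bar`,
#'   `lambda_bar_closed`, `boundary_ratio` (n/p at the growth -> stress
#'   boundary), `n_cycles_to_converge`, `periodicity_residual`.
#' @export
cycle_growth_rate <- function(spec, ratio_tol = 1e-8) {
  spec <- as_cycle_spec(spec)
  M <- cycle_propagator(spec)
  tr <- M[1L, 1L] + M[2L, 2L]
  # discriminant in the cancellation-free form (off-diagonal product >= 0
  # for a propagator of the switching model)
  disc <- sqrt((M[1L, 1L] - M[2L, 2L])^2 + 4 * M[1L, 2L] * M[2L, 1L])
  Lambda <- (tr + disc) / 2
  period <- spec$t_g + spec$t_s
  lambda_bar <- log(Lambda) / period
  # eigenvector of M = state at the start of the growth phase
  v <- if (M[1L, 2L] != 0) c(M[1L, 2L], Lambda - M[1L, 1L])
       else if (Lambda - M[2L, 2L] != 0) c(Lambda - M[2L, 2L], M[2L, 1L])
       else c(1, 0)
  v <- abs(v)
  u <- phase_propagator(spec$env_g, spec$t_g) %*% v
  boundary_ratio <- u[1L] / u[2L]
  # cycles to reach the periodic regime from a balanced population
  w <- c(1, 1); n_cyc <- 0L; res <- Inf
  prev <- NA_real_
  while (n_cyc < 10000L) {
    w <- as.numeric(M %*% w)
    w <- w / max(w)
    n_cyc <- n_cyc + 1L
    r <- w[1L] / w[2L]
    if (!is.na(prev) && is.finite(r) && abs(r / prev - 1) < ratio_tol) break
    prev <- r
  }
  res <- if (!is.na(prev) && is.finite(prev)) abs(w[1L] / w[2L] / prev - 1)
         else NA_real_
  closed <- cycle_growth_rate_closed(spec)
  structure(list(lambda_bar = lambda_bar, lambda_bar_closed = closed,
                 boundary_ratio = boundary_ratio,
                 n_cycles_to_converge = n_cyc,
                 periodicity_residual = res),
            class = "cycle_growth_result")
}

#' Closed-form cycle growth rate (long-duration regime)
#'
#' Steady-structure closed form: per-condition effective rates weighted by
#' the phase durations minus the two structure-reset penalties
#' `log(delta_c/a)` and `log(delta_c/b)` paid after each shift. Valid when
#' both phases are long enough that the population structure equilibrates
#' within each condition.
#'
#' @param spec A [cycle_spec()].
#' @return Average per-capita growth rate over one cycle (1/hour), `NA` if
#'   either switching rate is zero.
#' @export
cycle_growth_rate_closed <- function(spec) {
  spec <- as_cycle_spec(spec)
  a <- spec$env_g$a; b <- spec$env_g$b
  if (a <= 0 || b <= 0) return(NA_real_)
  dc <- combined_gap(spec$gaps)
  ((spec$env_g$mu_n - a) * spec$t_g + (spec$env_s$mu_p - b) * spec$t_s -
      log(dc / a) - log(dc / b)) / (spec$t_g + spec$t_s)
}

#' Closed-form optimal switching rates
#'
#' Leading-order maximizers of the steady-structure cycle growth rate: the
#' optimal switching rates track the inverse environmental durations,
#' `a_opt ~ 1/t_g`, `b_opt ~ 1/t_s`, with correction terms evaluated at
#' zero switching rates:
#' `a_opt = 1/(t_g + 2(1/delta_kappa - 1/delta_mu))` and
#' `b_opt = 1/(t_s + 2(1/delta_mu - 1/delta_kappa))`. Valid for long
#' environmental durations; a warning is emitted when either phase is
#' shorter than 3 relaxation times of its condition.
#'
#' @param spec A [cycle_spec()].
#' @return List of class `"optimal_switching"` with `a_opt`, `b_opt`,
#'   `achieved_rate` (closed-form rate at the optimum), `interior_maximum`.
#' @export
optimal_switching_closed_form <- function(spec) {
  spec <- as_cycle_spec(spec)
  dmu <- spec$gaps$delta_mu; dka <- spec$gaps$delta_kappa
  if (spec$t_g < 3 / dmu || spec$t_s < 3 / dka)
    warning("environmental durations are short compared to the structure ",
            "relaxation times; the long-duration closed form may not apply",
            call. = FALSE)
  den_a <- spec$t_g + 2 * (1 / dka - 1 / dmu)
  den_b <- spec$t_s + 2 * (1 / dmu - 1 / dka)
  if (den_a <= 0 || den_b <= 0)
    stop("durations too short for the long-duration closed form ",
         "(corrected denominator not positive)", call. = FALSE)
  a_opt <- 1 / den_a
  b_opt <- 1 / den_b
  achieved <- cycle_growth_rate_closed(with_switching(spec, a_opt, b_opt))
  structure(list(a_opt = a_opt, b_opt = b_opt, achieved_rate = achieved,
                 interior_maximum = TRUE, method = "closed_form"),
            class = "optimal_switching")
}

#' Numerically optimal switching rates
#'
#' Maximizes the Floquet cycle growth rate over the switching rates (a, b),
#' varied jointly in both environments, by a deterministic log-spaced grid
#' scan followed by one Nelder-Mead refinement from the best grid point.
#' When the grid maximum sits on the lower boundary of the scanned box the
#' result is flagged as non-interior (no refinement is attempted there; the
#' growth rate then decreases with increasing switching rate and vanishing
#' switching is favoured).
#'
#' @param spec A [cycle_spec()].
#' @param bounds Length-2 positive vector: scan box `[lo, hi]` for both
#'   rates (default `c(1e-6, 1)` /h).
#' @param n_grid Grid points per axis (default 40).
#' @return List of class `"optimal_switching"` with `a_opt`, `b_opt`,
#'   `achieved_rate` (Floquet rate), `interior_maximum`.
#' @export
optimal_switching_numeric <- function(spec, bounds = c(1e-6, 1),
                                      n_grid = 40L) {
  spec <- as_cycle_spec(spec)
  stopifnot(length(bounds) == 2L, all(bounds > 0), bounds[1L] < bounds[2L],
            n_grid >= 4L)
  objective <- function(a, b) {
    lb <- cycle_growth_rate(with_switching(spec, a, b))$lambda_bar
    if (!is.finite(lb)) stop("non-finite cycle growth rate at a=", a,
                             ", b=", b, call. = FALSE)
    lb
  }
  grid <- exp(seq(log(bounds[1L]), log(bounds[2L]), length.out = n_grid))
  vals <- outer(grid, grid, Vectorize(objective))
  best <- arrayInd(which.max(vals), dim(vals))
  a_best <- grid[best[1L]]; b_best <- grid[best[2L]]
  interior <- best[1L] > 1L && best[2L] > 1L
  if (interior) {
    lo <- log(bounds[1L]); hi <- log(bounds[2L])
    opt <- stats::optim(log(c(a_best, b_best)),
                        function(lp) {
                          if (any(lp < lo) || any(lp > hi)) return(1e6)
                          -objective(exp(lp[1L]), exp(lp[2L]))
                        },
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 500))
    a_best <- exp(opt$par[1L]); b_best <- exp(opt$par[2L])
    achieved <- -opt$value
  } else {
    achieved <- vals[best]
  }
  structure(list(a_opt = a_best, b_opt = b_best, achieved_rate = achieved,
                 interior_maximum = interior, method = "floquet_grid"),
            class = "optimal_switching")
}

#' @export
print.optimal_switching <- function(x, ...) {
  cat(sprintf("<optimal_switching> (%s)\n", x$method))
  cat(sprintf("  a_opt = %.4g /h, b_opt = %.4g /h%s\n", x$a_opt, x$b_opt,
              if (isTRUE(x$interior_maximum)) "" else "  [boundary maximum]"))
  cat(sprintf("  achieved rate = %.6g /h\n", x$achieved_rate))
  invisible(x)
}

#' Cycle growth rate as a function of a common switching rate
#'
#' Convenience table for optimal-switching curves: the Floquet cycle
#' growth rate evaluated along a = b = s for a vector of switching rates.
#'
#' @param spec A [cycle_spec()].
#' @param rates Vector of switching rates (1/hour).
#' @return Data frame with columns `switching_rate` and `lambda_bar`.
#' @export
switching_rate_scan <- function(spec, rates = 10^seq(-6, -1, length.out = 26)) {
  spec <- as_cycle_spec(spec)
  stopifnot(all(rates > 0))
  data.frame(
    switching_rate = rates,
    lambda_bar = vapply(rates, function(s)
      cycle_growth_rate(with_switching(spec, s, s))$lambda_bar, numeric(1L)))
}

#' Periodic dynamics with a finite carrying capacity
#'
#' Integrates repeated growth/stress cycles with a finite carrying capacity
#' in the growth environment. When the capacity-free cycle growth rate is
#' positive the population saturates: the per-cycle peak approaches K and
#' the per-cycle log growth of the total population approaches zero; under
#' net decay the capacity is irrelevant and the dynamics match the
#' unbounded analysis.
#'
#' @param spec A [cycle_spec()] whose `env_g` may carry a finite
#'   `carrying_capacity` (the stress environment must not).
#' @param state0 Initial [population_state()].
#' @param n_cycles Number of cycles to simulate.
#' @param samples_per_phase Output samples per phase.
#' @return List with `trajectory` (the sampled dynamics) and `summary`
#'   (per-cycle data frame: `cycle`, `N_start`, `N_end`, `N_peak`,
#'   `log_growth`).
#' @export
capacity_cycle_behavior <- function(spec, state0, n_cycles,
                                    samples_per_phase = 25L) {
  spec <- as_cycle_spec(spec)
  stopifnot(is.numeric(n_cycles), n_cycles >= 1L)
  if (is.finite(spec$env_s$carrying_capacity))
    stop("carrying capacity is modeled in the growth environment only",
         call. = FALSE)
  phases <- rep(list(list(env = spec$env_g, duration = spec$t_g),
                     list(env = spec$env_s, duration = spec$t_s)),
                n_cycles)
  traj <- simulate_protocol(phases, state0,
                            samples_per_phase = samples_per_phase)
  period <- spec$t_g + spec$t_s
  t0 <- as_population_state(state0)$t
  cyc <- pmin(floor((traj$time_h - t0 - 1e-12) / period) + 1L, n_cycles)
  cyc[traj$time_h <= t0] <- 1L
  ends <- vapply(seq_len(n_cycles), function(i) {
    seg <- traj[cyc == i, ]
    seg$total[nrow(seg)]
  }, numeric(1L))
  peaks <- vapply(seq_len(n_cycles), function(i) max(traj$total[cyc == i]),
                  numeric(1L))
  starts <- c(traj$total[1L], ends[-n_cycles])
  summary <- data.frame(cycle = seq_len(n_cycles),
                        N_start = starts, N_end = ends, N_peak = peaks,
                        log_growth = log(ends / starts))
  list(trajectory = traj, summary = summary)
}
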