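# Small-switching-rate approximation layer.
#
# The oriented subpopulation ratio R (n/p in growth, p/n under stress)
# satisfies a Riccati equation
#   dR/dt = -alpha R^2 + (delta - alpha + beta) R + beta
# whose two fixed points are the roots of
#   alpha R^2 - (delta - alpha + beta) R - beta = 0.
# The lower root R0 is <= 0 (unstable), the upper root R* is > 0 (stable),
# and the exact solution relaxes to R* at rate gamma = alpha (R* - R0)
# = sqrt((delta - alpha + beta)^2 + 4 alpha beta).  For small switching
# rates, R* ~ delta/alpha, R0 ~ 0 and gamma ~ delta, which reduces the
# dynamics to a plain logistic equation for R.

# Cancellation-safe roots of alpha x^2 + Bq x + C with Bq = -(delta-alpha+beta),
# C = -beta.  Root product C/alpha <= 0, so one root is >= 0, one <= 0.
ratio_quadratic_roots <- function(delta, alpha, beta) {
  if (alpha <= 0)
    stop("oriented ratio quadratic needs a positive majority->minority ",
         "switching rate (a in growth orientation, b in stress orientation)",
         call. = FALSE)
  B <- -(delta - alpha + beta)
  C <- -beta
  disc <- B * B - 4 * alpha * C      # = gamma^2 >= B^2, always non-negative
  s <- sqrt(disc)
  q <- -(B + sign(B + (B == 0)) * s) / 2
  r1 <- q / alpha
  r2 <- if (q != 0) C / q else 0
  c(lower = min(r1, r2), upper = max(r1, r2))
}

#' Fixed points of the subpopulation-ratio dynamics
#'
#' Exact roots of the quadratic fixed-point equation of the oriented ratio
#' (n/p in growth, p/n under stress), computed cancellation-safely. The
#' upper root is the stable steady-state ratio; the lower root is unstable
#' and non-positive.
#'
#' @param env An [env_params()] object.
#' @return List of class `"ratio_fixed_points"` with `r_stable`,
#'   `r_unstable`, `relaxation_rate` (the exact linearization rate
#'   `alpha * (r_stable - r_unstable)`), `condition` and `orientation`.
#' @examples
#' ratio_fixed_points(env_params(2, 0.2, a = 0.2, b = 0))$r_stable  # 8
#' @export
ratio_fixed_points <- function(env) {
  ov <- oriented_view(as_env_params(env))
  r <- ratio_quadratic_roots(ov$delta, ov$alpha, ov$beta)
  structure(list(r_unstable = unname(r["lower"]),
                 r_stable = unname(r["upper"]),
                 relaxation_rate = ov$alpha * unname(r["upper"] - r["lower"]),
                 condition = ov$condition,
                 orientation = if (ov$condition == "growth") "n/p" else "p/n"),
            class = "ratio_fixed_points")
}

warn_small_switching <- function(ov, threshold = 0.1) {
  if (max(ov$alpha, ov$beta) > threshold * ov$delta)
    warning(sprintf(paste0("switching rates (a=%g, b=%g) exceed %g%% of the ",
                           "rate gap (%g /h); small-switching approximations ",
                           "may be inaccurate"),
                    ov$alpha, ov$beta, 100 * threshold, ov$delta),
            call. = FALSE)
  invisible(NULL)
}

#' Steady-state population structure for small switching rates
#'
#' Leading-order structure of the population in one condition: the stable
#' oriented ratio `delta/alpha` (n/p ~ delta_mu/a in growth, p/n ~
#' delta_kappa/b under stress), the persister fraction, the relaxation rate
#' towards the steady state, and the effective long-time growth/decay rate
#' of the total population (`mu_n - a` in growth, `-(kappa_p + b)` under
#' stress). A warning is emitted outside the small-switching regime (either
#' switching rate above `warn_threshold` times the rate gap).
#'
#' @param env An [env_params()] object.
#' @param gaps Optional [rate_gaps()]; when supplied, the relevant gap
#'   overrides the one computed from `env` (useful when the environment pair
#'   is characterized jointly).
#' @param warn_threshold Fraction of the rate gap above which the
#'   small-switching warning fires (default 0.1).
#' @return List of class `"steady_state_structure"` with `ratio_star`,
#'   `persister_fraction`, `relaxation_rate`, `effective_rate`, `condition`.
#' @export
steady_state_structure <- function(env, gaps = NULL, warn_threshold = 0.1) {
  env <- as_env_params(env)
  ov <- oriented_view(env)
  if (!is.null(gaps)) {
    gaps <- as_rate_gaps(gaps)
    ov$delta <- if (ov$condition == "growth") gaps$delta_mu else gaps$delta_kappa
  }
  if (ov$delta <= 0)
    stop("rate gap is not positive: condition mislabeled?", call. = FALSE)
  warn_small_switching(ov, warn_threshold)
  ratio_star <- ov$delta / ov$alpha
  pf <- if (ov$condition == "growth") 1 / (1 + ratio_star)
        else ratio_star / (1 + ratio_star)
  gamma <- sqrt((ov$delta - ov$alpha + ov$beta)^2 + 4 * ov$alpha * ov$beta)
  structure(list(ratio_star = ratio_star,
                 persister_fraction = pf,
                 relaxation_rate = gamma,
                 effective_rate = ov$mu_major - ov$alpha,
                 condition = ov$condition),
            class = "steady_state_structure")
}

#' Persister fraction of a non-growing (stationary-phase) population
#'
#' With growth shut down, the population structure is set purely by the
#' balance of two-way phenotype switching: the persister fraction is
#' a/(a + b), typically orders of magnitude above the exponential-phase
#' value a/delta_mu.
#'
#' @param sw A [switching_rates()] object (or an [env_params()], whose
#'   switching rates are used).
#' @return Persister fraction in (0, 1).
#' @export
stationary_phase_fraction <- function(sw) {
  sw <- as_switching_rates(sw)
  if (sw$a + sw$b <= 0)
    stop("persister fraction undefined for a = b = 0", call. = FALSE)
  sw$a / (sw$a + sw$b)
}

# Logistic solution R(t) = R1 R* / (R1 + (R* - R1) e^{-gamma t}), written
# with e^{-gamma t} so that long times cannot overflow.
logistic_solution <- function(t, r1, r_star, gamma) {
  e <- exp(-gamma * t)
  r1 * r_star / (r1 + (r_star - r1) * e)
}

#' Logistic approximation of the subpopulation ratio
#'
#' Closed-form solution of the logistic reduction of the ratio dynamics for
#' small switching rates: the oriented ratio (n/p in growth, p/n under
#' stress) relaxes from `r0` to the approximate fixed point `delta/alpha` at
#' rate `delta` (the rate gap). Exact at t = 0.
#'
#' @param t Time(s) in hours.
#' @param r0 Initial oriented ratio (>= 0); n/p in growth, p/n under stress.
#' @param env An [env_params()] object.
#' @param exact If `TRUE`, use the exact fixed points and relaxation rate of
#'   the ratio equation instead of their leading-order approximations
#'   (the exact solution of the ratio dynamics).
#' @return Oriented ratio at the requested times.
#' @export
logistic_ratio <- function(t, r0, env, exact = FALSE) {
  stopifnot(is.numeric(t), all(is.finite(t)))
  if (!(is.numeric(r0) && length(r0) == 1L && is.finite(r0) && r0 >= 0))
    stop("'r0' must be a non-negative number", call. = FALSE)
  ov <- oriented_view(as_env_params(env))
  if (!exact) {
    if (ov$alpha <= 0)
      stop("logistic reduction needs a positive oriented switching rate",
           call. = FALSE)
    return(logistic_solution(t, r0, ov$delta / ov$alpha, ov$delta))
  }
  fp <- ratio_quadratic_roots(ov$delta, ov$alpha, ov$beta)
  r_star <- unname(fp["upper"]); r_0 <- unname(fp["lower"])
  gamma <- ov$alpha * (r_star - r_0)
  k <- (r0 - r_star) / (r0 - r_0)
  e <- k * exp(-gamma * t)
  (r_star - r_0 * e) / (1 - e)
}

# log( (r_star - r1 + r1 e^{gamma t}) / r_star ), evaluated without overflow:
# equals log1p( r1 (e^{gamma t} - 1) / r_star ) for moderate t and
# gamma t + log(r1/r_star) + log1p((r_star - r1) e^{-gamma t} / r1) for large.
log_logistic_gain <- function(t, r1, r_star, gamma) {
  x <- gamma * t
  small <- x < 500
  out <- numeric(length(t))
  out[small] <- log1p(r1 * expm1(x[small]) / r_star)
  if (any(!small))
    out[!small] <- x[!small] + log(r1 / r_star) +
      log1p((r_star - r1) * exp(-x[!small]) / r1)
  out
}

#' Time-averaged effective growth rates of the two subpopulations
#'
#' Closed-form time averages (over `[t0, t]`) of the effective per-capita
#' rates of each subpopulation, including the switching fluxes, based on the
#' logistic form of the oriented ratio. In growth orientation the normal
#' subpopulation grows at `mu_n - a + b / F(t)` and the persister
#' subpopulation at `mu_p - b + a F(t)`; the time averages involve the
#' closed-form integrals of `F` and `1/F`. Both averages approach the
#' common effective rate of the total population at long times.
#'
#' @param t End of the averaging window (hours; may be a vector).
#' @param env An [env_params()] object.
#' @param r0 Oriented ratio at `t0` (n/p in growth, p/n under stress).
#' @param t0 Start of the averaging window (default 0).
#' @return List with `rate_normal` and `rate_persister` (1/hour), aligned
#'   with `t`.
#' @export
average_subpop_growth <- function(t, env, r0, t0 = 0) {
  stopifnot(is.numeric(t), all(is.finite(t)), all(t > t0))
  env <- as_env_params(env)
  ov <- oriented_view(env)
  if (ov$alpha <= 0 && ov$beta <= 0) {
    # no switching: both subpopulations evolve independently
    return(list(rate_normal = rep(env$mu_n, length(t)),
                rate_persister = rep(env$mu_p, length(t))))
  }
  if (!(is.numeric(r0) && is.finite(r0) && r0 > 0))
    stop("'r0' must be a positive oriented ratio", call. = FALSE)
  r_star <- ov$delta / ov$alpha
  gamma <- ov$delta
  # S(t) = int_0^t R dt = (1/alpha) log((r_star - r0 + r0 e^{gamma t})/r_star)
  S <- function(tt) log_logistic_gain(tt, r0, r_star, gamma) / ov$alpha
  # I(t) = int_0^t dt/R = t/r_star + (r_star - r0)(1 - e^{-gamma t})/(r0 r_star gamma)
  I <- function(tt) tt / r_star +
    (r_star - r0) * (-expm1(-gamma * tt)) / (r0 * r_star * gamma)
  dt <- t - t0
  mean_R <- (S(t) - S(t0)) / dt
  mean_invR <- (I(t) - I(t0)) / dt
  rate_major <- ov$mu_major - ov$alpha + ov$beta * mean_invR
  rate_minor <- ov$mu_minor - ov$beta + ov$alpha * mean_R
  if (ov$condition == "growth")
    list(rate_normal = rate_major, rate_persister = rate_minor)
  else
    list(rate_normal = rate_minor, rate_persister = rate_major)
}

#' Double-exponential amplitudes and rates of the total population
#'
#' First-order (in the switching rates) closed form of the total population:
#' `N(t) = amp_fast exp(rate_fast t) + amp_slow exp(rate_slow t)` with
#' component rates `mu_n - a` and `mu_p - b`. The amplitude cross terms
#' account for the switching flux between the subpopulations; the t = 0
#' value is exactly `n0 + p0`. "Fast" labels the normal-cell component
#' (faster growth in growth media, faster death under stress).
#'
#' @param n0,p0 Initial subpopulation sizes (>= 0).
#' @param env An [env_params()] object.
#' @return List with `amp_fast`, `amp_slow`, `rate_fast`, `rate_slow`.
#' @export
double_exponential_components <- function(n0, p0, env) {
  if (!(is.numeric(n0) && is.finite(n0) && n0 >= 0) ||
      !(is.numeric(p0) && is.finite(p0) && p0 >= 0))
    stop("initial counts must be non-negative", call. = FALSE)
  env <- as_env_params(env)
  lam_n <- env$mu_n - env$a
  lam_p <- env$mu_p - env$b
  D <- lam_n - lam_p
  if (abs(D) < 1e-12 * max(abs(lam_n), abs(lam_p), 1))
    stop("component rates are degenerate (mu_n - a == mu_p - b); the ",
         "double-exponential form does not apply", call. = FALSE)
  cross <- (env$a * n0 + env$b * p0) / D
  list(amp_fast = n0 + cross, amp_slow = p0 - cross,
       rate_fast = lam_n, rate_slow = lam_p)
}

#' Double-exponential total population
#'
#' Evaluates the small-switching closed form of N(t) (see
#' [double_exponential_components()]); under stress this is the classic
#' biphasic killing curve, in growth media the biphasic regrowth curve.
#'
#' @param t Time(s) in hours.
#' @param n0,p0 Initial subpopulation sizes.
#' @param env An [env_params()] object.
#' @return Total population at `t`.
#' @export
total_double_exponential <- function(t, n0, p0, env) {
  stopifnot(is.numeric(t), all(is.finite(t)))
  cmp <- double_exponential_components(n0, p0, env)
  cmp$amp_fast * exp(cmp$rate_fast * t) + cmp$amp_slow * exp(cmp$rate_slow * t)
}

#' Time-averaged growth rate of the total population
#'
#' Closed-form average per-capita rate of the total population,
#' `log(N(t)/N(0))/t`, with N(t) given by the double-exponential form. The
#' initial state is specified through the oriented ratio `r0` (n/p in
#' growth, p/n under stress); the result does not depend on the absolute
#' population size.
#'
#' @param t Time(s) in hours (> 0).
#' @param env An [env_params()] object.
#' @param r0 Initial oriented ratio (> 0, or `Inf` for a pure
#'   majority-phenotype population).
#' @return Average per-capita rate (1/hour), aligned with `t`.
#' @export
average_total_growth <- function(t, env, r0) {
  stopifnot(is.numeric(t), all(is.finite(t)), all(t > 0))
  env <- as_env_params(env)
  ov <- oriented_view(env)
  if (!(is.numeric(r0) && length(r0) == 1L && r0 >= 0))
    stop("'r0' must be a non-negative ratio (possibly Inf)", call. = FALSE)
  frac_minor <- 1 / (1 + r0)           # r0 = Inf -> 0
  frac_major <- 1 - frac_minor
  if (ov$condition == "growth") {
    n0 <- frac_major; p0 <- frac_minor
  } else {
    n0 <- frac_minor; p0 <- frac_major
  }
  cmp <- double_exponential_components(n0, p0, env)
  # log(N(t)) via the dominant component to stay finite at large |rate * t|
  lead <- if (cmp$rate_fast >= cmp$rate_slow) "fast" else "slow"
  a1 <- cmp[[paste0("amp_", lead)]]
  r1 <- cmp[[paste0("rate_", lead)]]
  a2 <- cmp[[paste0("amp_", setdiff(c("fast", "slow"), lead))]]
  r2 <- cmp[[paste0("rate_", setdiff(c("fast", "slow"), lead))]]
  logN <- if (a1 > 0) {
    log(a1) + r1 * t + log1p(pmax(a2 / a1 * exp((r2 - r1) * t), -1 + 1e-300))
  } else {
    log(a1 * exp(r1 * t) + a2 * exp(r2 * t))
  }
  logN / t
}
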