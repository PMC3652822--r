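# Observables of medium-shift experiments.
#
# After a growth -> stress shift the total population decays biphasically;
# the kink sits at the time T_s where the two subpopulations are equal in
# size.  Tracking the oriented ratio G = p/n through its exact dynamics
# (including the small negative unstable fixed point G0 ~ -a/delta_kappa
# that the naive logistic drops) and solving G(T) = 1 gives, for a
# population shifted at the steady growth structure r0 = delta_mu/a,
#   T_s = log(delta_c / a) / delta_kappa,
#   T_g = log(delta_c / b) / delta_mu,
# with the combined rate delta_c = delta_mu delta_kappa/(delta_mu+delta_kappa).
# These invert exactly to a = delta_c exp(-delta_kappa T_s),
# b = delta_c exp(-delta_mu T_g).

combined_gap <- function(gaps) {
  gaps <- as_rate_gaps(gaps)
  gaps$delta_mu * gaps$delta_kappa / (gaps$delta_mu + gaps$delta_kappa)
}

# Time at which the oriented ratio, started at r1 < target, reaches `target`
# under the exact ratio dynamics (fixed points r_star/r_0, rate gamma).
ratio_crossing_time <- function(r1, target, r_star, r_0, gamma) {
  if (r1 >= target) return(0)
  if (target >= r_star) return(Inf)
  log(((r_star - r1) * (target - r_0)) /
        ((r_star - target) * (r1 - r_0))) / gamma
}

oriented_ratio_params <- function(delta, alpha, beta) {
  fp <- ratio_quadratic_roots(delta, alpha, beta)
  r_star <- unname(fp["upper"]); r_0 <- unname(fp["lower"])
  list(r_star = r_star, r_0 = r_0, gamma = alpha * (r_star - r_0))
}

#' Transition time of the biphasic killing curve
#'
#' Time after a growth -> stress shift at which the normal and persister
#' subpopulations are equal in size, i.e. the kink between the fast- and
#' slow-decaying phases of the killing curve. The default (`form = "full"`)
#' solves the exact ratio dynamics for p/n = 1; `form = "limit"` returns the
#' large-ratio limit `log(r0)/delta_kappa`.
#'
#' @param r0 n/p ratio at the moment of antibiotic addition (> 1 for a
#'   normal-majority population; values <= 1 return 0 with a warning).
#' @param gaps A [rate_gaps()] object.
#' @param sw A [switching_rates()] object (or [env_params()]).
#' @param form `"full"` (exact ratio-dynamics crossing) or `"limit"`.
#' @return Transition time T_s in hours.
#' @examples
#' pars <- demo_params()
#' transition_time_stress(1.8e5, pars$gaps, switching_rates(1e-5, 1e-3))
#' @export
transition_time_stress <- function(r0, gaps, sw, form = c("full", "limit")) {
  form <- match.arg(form)
  gaps <- as_rate_gaps(gaps)
  sw <- as_switching_rates(sw)
  if (!(is.numeric(r0) && is.finite(r0) && r0 > 0))
    stop("'r0' must be a positive finite ratio", call. = FALSE)
  if (r0 <= 1) {
    warning("population already persister-dominated at the shift (r0 <= 1); ",
            "transition time is 0", call. = FALSE)
    return(0)
  }
  if (form == "limit") return(log(r0) / gaps$delta_kappa)
  # stress orientation: ratio G = p/n, (alpha, beta) = (b, a)
  op <- oriented_ratio_params(gaps$delta_kappa, sw$b, sw$a)
  ratio_crossing_time(1 / r0, 1, op$r_star, op$r_0, op$gamma)
}

#' Transition time of the biphasic regrowth curve
#'
#' Time after a stress -> growth shift at which the two subpopulations are
#' equal, i.e. the kink between the slow- and fast-growing phases of the
#' regrowth curve. Mirror of [transition_time_stress()] under the
#' growth/stress exchange symmetry.
#'
#' @param r0 p/n ratio at the moment of antibiotic removal (> 1 for a
#'   persister-dominated population).
#' @inheritParams transition_time_stress
#' @return Transition time T_g in hours.
#' @export
transition_time_growth <- function(r0, gaps, sw, form = c("full", "limit")) {
  form <- match.arg(form)
  gaps <- as_rate_gaps(gaps)
  sw <- as_switching_rates(sw)
  if (!(is.numeric(r0) && is.finite(r0) && r0 > 0))
    stop("'r0' must be a positive finite ratio", call. = FALSE)
  if (r0 <= 1) {
    warning("population already normal-dominated at the shift (r0 <= 1); ",
            "transition time is 0", call. = FALSE)
    return(0)
  }
  if (form == "limit") return(log(r0) / gaps$delta_mu)
  # growth orientation: ratio F = n/p, (alpha, beta) = (a, b)
  op <- oriented_ratio_params(gaps$delta_mu, sw$a, sw$b)
  ratio_crossing_time(1 / r0, 1, op$r_star, op$r_0, op$gamma)
}

#' Equilibration times of the population structure
#'
#' The subpopulation ratio reaches its new steady state later than the kink
#' in the total-population curve. The equilibration time is the inflection
#' point of the time-dependent per-capita rate of the (initially dominant)
#' subpopulation, which sits at the midpoint of the logistic relaxation of
#' the oriented ratio: T' is the time at which the ratio reaches
#' `(r_star + r_unstable)/2`.
#'
#' @param gaps A [rate_gaps()] object.
#' @param sw A [switching_rates()] object (or [env_params()]).
#' @param r0_stress n/p ratio at the growth -> stress shift (default: the
#'   steady growth-structure `delta_mu/a`).
#' @param r0_growth p/n ratio at the stress -> growth shift (default: the
#'   steady stress-structure `delta_kappa/b`).
#' @return List with `T_s_prime` and `T_g_prime` (hours); each is at least
#'   the corresponding transition time.
#' @export
equilibration_times <- function(gaps, sw, r0_stress = NULL, r0_growth = NULL) {
  gaps <- as_rate_gaps(gaps)
  sw <- as_switching_rates(sw)
  if (is.null(r0_stress)) r0_stress <- gaps$delta_mu / sw$a
  if (is.null(r0_growth)) r0_growth <- gaps$delta_kappa / sw$b
  stopifnot(r0_stress > 0, r0_growth > 0)
  ts <- {
    op <- oriented_ratio_params(gaps$delta_kappa, sw$b, sw$a)
    ratio_crossing_time(1 / r0_stress, (op$r_star + op$r_0) / 2,
                        op$r_star, op$r_0, op$gamma)
  }
  tg <- {
    op <- oriented_ratio_params(gaps$delta_mu, sw$a, sw$b)
    ratio_crossing_time(1 / r0_growth, (op$r_star + op$r_0) / 2,
                        op$r_star, op$r_0, op$gamma)
  }
  list(T_s_prime = ts, T_g_prime = tg)
}

#' Transition times from a steady pre-shift population
#'
#' Closed-form transition times assuming the subpopulation ratio has reached
#' its steady state in the preceding environment:
#' `T_s = log(delta_c/a)/delta_kappa` and `T_g = log(delta_c/b)/delta_mu`,
#' where `delta_c = delta_mu*delta_kappa/(delta_mu + delta_kappa)` is the
#' combined rate gap. These are the relations inverted by
#' [infer_switching_rates()].
#'
#' @param gaps A [rate_gaps()] object.
#' @param sw A [switching_rates()] object (or [env_params()]).
#' @return List of class `"transition_times"` with `T_s`, `T_g` (hours).
#' @export
steady_transition_times <- function(gaps, sw) {
  gaps <- as_rate_gaps(gaps)
  sw <- as_switching_rates(sw)
  if (sw$a <= 0 || sw$b <= 0)
    stop("steady-state transition times need positive switching rates",
         call. = FALSE)
  dc <- combined_gap(gaps)
  structure(list(T_s = log(dc / sw$a) / gaps$delta_kappa,
                 T_g = log(dc / sw$b) / gaps$delta_mu),
            class = "transition_times")
}

#' Infer the switching rates from measured transition times
#'
#' Exact algebraic inverse of [steady_transition_times()]: given the
#' growth/death-rate gaps and the transition times of the two shift
#' experiments, the switching rates are
#' `a = delta_c exp(-delta_kappa T_s)` and `b = delta_c exp(-delta_mu T_g)`
#' with `delta_c` the combined rate gap. Only total-population count curves
#' are needed to measure `T_s` and `T_g`.
#'
#' @param gaps A [rate_gaps()] object (positive gaps).
#' @param T_s Transition time of the killing curve (hours, >= 0).
#' @param T_g Transition time of the regrowth curve (hours, >= 0).
#' @return List of class `"switching_inference"` with `a_hat`, `b_hat`
#'   (1/hour) and an `inputs` record.
#' @export
infer_switching_rates <- function(gaps, T_s, T_g) {
  gaps <- as_rate_gaps(gaps)
  stopifnot(is.numeric(T_s), is.finite(T_s), T_s >= 0,
            is.numeric(T_g), is.finite(T_g), T_g >= 0)
  dc <- combined_gap(gaps)
  structure(list(a_hat = dc * exp(-gaps$delta_kappa * T_s),
                 b_hat = dc * exp(-gaps$delta_mu * T_g),
                 inputs = list(delta_mu = gaps$delta_mu,
                               delta_kappa = gaps$delta_kappa,
                               T_s = T_s, T_g = T_g)),
            class = "switching_inference")
}

#' @export
print.switching_inference <- function(x, ...) {
  cat(sprintf("<switching_inference> a_hat = %.4g /h, b_hat = %.4g /h\n",
              x$a_hat, x$b_hat))
  cat(sprintf("  from T_s = %.4g h, T_g = %.4g h (delta_mu = %g, delta_kappa = %g /h)\n",
              x$inputs$T_s, x$inputs$T_g, x$inputs$delta_mu,
              x$inputs$delta_kappa))
  invisible(x)
}

# -- double-exponential fitting --------------------------------------------

extract_curve <- function(curve) {
  df <- as.data.frame(curve)
  if (!all(c("time_h", "cfu_total") %in% names(df))) {
    if (all(c("time_h", "total") %in% names(df)))
      df$cfu_total <- df$total
    else
      stop("curve must have columns 'time_h' and 'cfu_total'", call. = FALSE)
  }
  df <- df[is.finite(df$time_h) & is.finite(df$cfu_total), ]
  if (nrow(df) < 6L)
    stop("need at least 6 finite time points to fit", call. = FALSE)
  if (any(df$cfu_total <= 0))
    stop("counts must be positive for log-scale fitting", call. = FALSE)
  df[order(df$time_h), c("time_h", "cfu_total")]
}

# Deterministic initializer: slope of log-counts over the first and last
# thirds of the curve, amplitudes by linear back-projection to t = 0.
biexp_initializer <- function(tt, ly) {
  n <- length(tt)
  i1 <- seq_len(max(3L, floor(n / 3)))
  i2 <- seq(n - max(3L, floor(n / 3)) + 1L, n)
  f1 <- stats::lm.fit(cbind(1, tt[i1]), ly[i1])$coefficients
  f2 <- stats::lm.fit(cbind(1, tt[i2]), ly[i2])$coefficients
  list(early = c(log_amp = unname(f1[1L]), rate = unname(f1[2L])),
       late = c(log_amp = unname(f2[1L]), rate = unname(f2[2L])))
}

#' Fit a double-exponential to a count curve
#'
#' Nonlinear least squares of
#' `N(t) = amp_fast exp(rate_fast t) + amp_slow exp(rate_slow t)` to
#' a CFU time course, on log10 counts (homoscedastic loss matching the
#' multiplicative structure of plating noise; set `log_scale = FALSE` for a
#' raw-count loss). The initializer is deterministic: component rates from
#' the slopes of the first and last thirds of the log-count curve,
#' amplitudes by back-projection. Data that are effectively
#' single-exponential are detected and returned flagged (`degenerate =
#' TRUE`) with a vanishing slow amplitude.
#'
#' @param curve A count table (see [generate_shift_curves()]) or any data
#'   frame with columns `time_h` and `cfu_total` (positive counts, >= 6
#'   points).
#' @param condition `"stress"` (killing curve: fast component decays
#'   faster) or `"growth"` (regrowth curve: fast component grows faster).
#' @param log_scale Fit on log10 counts (default `TRUE`).
#' @return List of class `"double_exp_fit"` with `amp_fast`, `amp_slow`,
#'   `rate_fast`, `rate_slow`, `rss` (residual sum of squares on log10
#'   counts), `degenerate`, `condition`.
#' @export
fit_double_exponential <- function(curve, condition = c("stress", "growth"),
                                   log_scale = TRUE) {
  condition <- match.arg(condition)
  df <- extract_curve(curve)
  tt <- df$time_h - df$time_h[1L]
  ly <- log(df$cfu_total)          # natural log internally
  ini <- biexp_initializer(tt, ly)
  # single-exponential degeneracy: a straight line reproduces the log curve
  lin <- stats::lm.fit(cbind(1, tt), ly)
  if (sqrt(mean(lin$residuals^2)) < 1e-10) {
    amp <- exp(unname(lin$coefficients[1L]))
    rate <- unname(lin$coefficients[2L])
    return(structure(list(amp_fast = amp, amp_slow = amp * 1e-12,
                          rate_fast = rate, rate_slow = rate / 2,
                          rss = sum((lin$residuals / log(10))^2),
                          degenerate = TRUE, condition = condition,
                          t_origin = df$time_h[1L]),
                     class = "double_exp_fit"))
  }
  # orientation: under stress the early phase is the fast component, in
  # growth media the late phase is
  if (condition == "stress") {
    fast0 <- ini$early; slow0 <- ini$late
  } else {
    fast0 <- ini$late; slow0 <- ini$early
  }
  par0 <- c(uf = unname(fast0["log_amp"]), us = unname(slow0["log_amp"]),
            rf = unname(fast0["rate"]), rs = unname(slow0["rate"]))
  model_log <- function(p, tvec) {
    m1 <- p[["uf"]] + p[["rf"]] * tvec
    m2 <- p[["us"]] + p[["rs"]] * tvec
    top <- pmax(m1, m2)
    top + log(exp(m1 - top) + exp(m2 - top))
  }
  resid_fn <- if (log_scale) {
    function(p) model_log(p, tt) - ly
  } else {
    function(p) exp(model_log(p, tt)) - df$cfu_total
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  if (!(fit$info %in% 1:4))
    stop("double-exponential fit did not converge (nls.lm info = ",
         fit$info, "): ", fit$message,
         "; initializer was (", paste(signif(par0, 4), collapse = ", "), ")",
         call. = FALSE)
  p <- fit$par
  comp <- data.frame(amp = exp(c(p[["uf"]], p[["us"]])),
                     rate = c(p[["rf"]], p[["rs"]]))
  comp <- comp[order(abs(comp$rate), decreasing = TRUE), ]  # fast = larger |rate|
  rss_log10 <- sum((model_log(p, tt) - ly)^2) / log(10)^2
  rel_sep <- abs(comp$rate[1L] - comp$rate[2L]) /
    max(abs(comp$rate[1L]), abs(comp$rate[2L]))
  degenerate <- rel_sep < 1e-3 || comp$amp[2L] / comp$amp[1L] < 1e-9
  structure(list(amp_fast = comp$amp[1L], amp_slow = comp$amp[2L],
                 rate_fast = comp$rate[1L], rate_slow = comp$rate[2L],
                 rss = rss_log10, degenerate = degenerate,
                 condition = condition, t_origin = df$time_h[1L]),
            class = "double_exp_fit")
}

#' @export
print.double_exp_fit <- function(x, ...) {
  cat(sprintf("<double_exp_fit> (%s curve%s)\n", x$condition,
              if (isTRUE(x$degenerate)) ", degenerate" else ""))
  cat(sprintf("  fast: amp = %.4g, rate = %.4g /h\n", x$amp_fast, x$rate_fast))
  cat(sprintf("  slow: amp = %.4g, rate = %.4g /h\n", x$amp_slow, x$rate_slow))
  cat(sprintf("  rss(log10) = %.3g\n", x$rss))
  invisible(x)
}

#' Locate the biphasic transition from a fitted curve
#'
#' Time (measured from the start of the fitted curve) at which the two
#' fitted exponential components are equal in size — the data-driven
#' estimate of the transition time between the two phases:
#' `t* = log(amp_slow/amp_fast) / (rate_fast - rate_slow)` relative to the
#' fit's internal origin (its first observation), reported on the time axis
#' of the fitted data (so if the data's `time_h` is measured from the
#' environmental shift, the result is hours since the shift).
#' Invariant under uniform rescaling of all counts.
#'
#' @param fit A `"double_exp_fit"` (with distinct component rates).
#' @return Crossing time in hours.
#' @export
locate_transition <- function(fit) {
  stopifnot(inherits(fit, "double_exp_fit"))
  if (fit$rate_fast == fit$rate_slow)
    stop("component rates are equal; transition undefined", call. = FALSE)
  log(fit$amp_slow / fit$amp_fast) / (fit$rate_fast - fit$rate_slow) +
    fit$t_origin
}

#' Full switching-rate inference from a pair of shift curves
#'
#' End-to-end pipeline on total-count data: fit the killing curve and the
#' regrowth curve with the double-exponential form, read the rate gaps off
#' the fitted component rates, locate the two transitions and invert for
#' the switching rates. A warning is emitted when the fitted pre-shift
#' ratio suggests the shift happened before the population structure was
#' stationary (amplitude ratio more than 2x away from the steady
#' structure implied by the inferred rates).
#'
#' @param stress_curve Count table of the growth -> stress experiment
#'   (post-shift segment, time re-based to the shift).
#' @param growth_curve Count table of the stress -> growth experiment
#'   (post-shift segment).
#' @param gaps Optional [rate_gaps()]; by default the gaps are taken from
#'   the fitted component rates (`|rate_fast - rate_slow|` of each curve).
#' @return A `"switching_inference"` with the two fits attached
#'   (`$fit_stress`, `$fit_growth`).
#' @export
infer_from_curves <- function(stress_curve, growth_curve, gaps = NULL) {
  fs <- fit_double_exponential(stress_curve, "stress")
  fg <- fit_double_exponential(growth_curve, "growth")
  if (is.null(gaps))
    gaps <- make_rate_gaps(abs(fg$rate_fast - fg$rate_slow),
                           abs(fs$rate_fast - fs$rate_slow))
  T_s <- locate_transition(fs)
  T_g <- locate_transition(fg)
  inf <- infer_switching_rates(gaps, T_s, T_g)
  # component ratio back-projected from the fit origin (first observation)
  # to the shift time; ~ pre-shift n/p up to switching-flux terms
  ratio_pre <- fs$amp_fast / fs$amp_slow *
    exp(-(fs$rate_fast - fs$rate_slow) * fs$t_origin)
  ratio_star <- gaps$delta_mu / inf$a_hat
  if (is.finite(ratio_pre) && ratio_pre > 0 &&
      (ratio_pre / ratio_star > 2 || ratio_star / ratio_pre > 2))
    warning("pre-shift population ratio appears more than 2x away from the ",
            "steady growth structure; the steady-state inversion may be ",
            "biased", call. = FALSE)
  inf$fit_stress <- fs
  inf$fit_growth <- fg
  inf
}
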