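#' Environment parameters for the two-phenotype switching model
#'
#' Bundles the per-phenotype net growth rates, the two phenotype switching
#' rates and an optional carrying capacity for one environmental condition.
#' A single signed net rate is used per phenotype: under stress the net rates
#' are negative and the corresponding death rates are exposed as the derived
#' values `kappa_n = -mu_n`, `kappa_p = -mu_p` (see [kappa_rates()]).
#'
#' @param mu_n Net per-capita rate of normal cells (1/hour). Negative under
#'   stress (antibiotic killing).
#' @param mu_p Net per-capita rate of persister cells (1/hour).
#' @param a Switching rate normal -> persister (1/hour, >= 0).
#' @param b Switching rate persister -> normal (1/hour, >= 0).
#' @param label Condition label. `"growth"` or `"stress"` select the
#'   orientation conventions explicitly; any other label (or `NULL`) lets the
#'   condition be inferred from the sign structure (`mu_n > mu_p` => growth).
#' @param carrying_capacity Carrying capacity K of the environment (cells),
#'   `Inf` (default) for unbounded exponential dynamics.
#'
#' @return An object of class `"env_params"`: a list with fields `mu_n`,
#'   `mu_p`, `a`, `b`, `label`, `carrying_capacity`.
#' @examples
#' growth <- env_params(mu_n = 2, mu_p = 0.2, a = 1e-5, b = 1e-3,
#'                      label = "growth")
#' stress <- env_params(mu_n = -4, mu_p = -0.4, a = 1e-5, b = 1e-3,
#'                      label = "stress")
#' kappa_rates(stress)
#' @export
env_params <- function(mu_n, mu_p, a, b, label = NULL,
                       carrying_capacity = Inf) {
  for (nm in c("mu_n", "mu_p", "a", "b")) {
    v <- get(nm, inherits = FALSE)
    if (!(is.numeric(v) && length(v) == 1L && is.finite(v)))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (a < 0 || b < 0)
    stop("switching rates 'a' and 'b' must be non-negative", call. = FALSE)
  if (!(is.numeric(carrying_capacity) && length(carrying_capacity) == 1L &&
        !is.na(carrying_capacity) && carrying_capacity > 0))
    stop("'carrying_capacity' must be a positive number or Inf", call. = FALSE)
  structure(
    list(mu_n = as.numeric(mu_n), mu_p = as.numeric(mu_p),
         a = as.numeric(a), b = as.numeric(b),
         label = if (is.null(label)) NA_character_ else as.character(label),
         carrying_capacity = as.numeric(carrying_capacity)),
    class = "env_params")
}

#' @export
print.env_params <- function(x, ...) {
  cond <- tryCatch(env_condition(x), error = function(e) NA_character_)
  cat(sprintf("<env_params> %s condition%s\n",
              ifelse(is.na(cond), "unclassified", cond),
              if (!is.na(x$label)) paste0(" ('", x$label, "')") else ""))
  cat(sprintf("  mu_n = %g /h, mu_p = %g /h\n", x$mu_n, x$mu_p))
  cat(sprintf("  a (n->p) = %g /h, b (p->n) = %g /h\n", x$a, x$b))
  if (is.finite(x$carrying_capacity))
    cat(sprintf("  carrying capacity K = %g cells\n", x$carrying_capacity))
  invisible(x)
}

#' Death rates under stress
#'
#' Derived read-only view of an environment's rates as death rates,
#' `kappa = -mu`. Meaningful for stress conditions where net rates are
#' negative.
#'
#' @param env An [env_params()] object.
#' @return Named numeric vector `c(kappa_n, kappa_p)` (1/hour).
#' @export
kappa_rates <- function(env) {
  env <- as_env_params(env)
  c(kappa_n = -env$mu_n, kappa_p = -env$mu_p)
}

as_env_params <- function(env) {
  if (!inherits(env, "env_params"))
    stop("expected an 'env_params' object; see env_params()", call. = FALSE)
  env
}

#' Classify an environment as growth or stress
#'
#' Uses the explicit `"growth"`/`"stress"` label when present, otherwise
#' infers the condition from the rate ordering: normal cells outgrow
#' persisters (`mu_n > mu_p`) in growth media, and die faster
#' (`mu_n < mu_p`) under stress.
#'
#' @param env An [env_params()] object.
#' @return `"growth"` or `"stress"`.
#' @export
env_condition <- function(env) {
  env <- as_env_params(env)
  if (!is.na(env$label) && env$label %in% c("growth", "stress"))
    return(env$label)
  if (env$mu_n > env$mu_p) return("growth")
  if (env$mu_n < env$mu_p) return("stress")
  stop("cannot classify condition: mu_n == mu_p and no growth/stress label",
       call. = FALSE)
}

# Oriented view of the ratio dynamics for one condition.
# The oriented ratio R is majority/minority for the condition: R = n/p in
# growth, R = p/n under stress.  Its ODE is
#   dR/dt = -alpha R^2 + (delta - alpha + beta) R + beta
# with (alpha, beta) = (a, b), delta = mu_n - mu_p in growth and
# (alpha, beta) = (b, a), delta = mu_p - mu_n under stress.
oriented_view <- function(env) {
  env <- as_env_params(env)
  cond <- env_condition(env)
  if (cond == "growth") {
    list(condition = "growth", delta = env$mu_n - env$mu_p,
         alpha = env$a, beta = env$b,
         mu_major = env$mu_n, mu_minor = env$mu_p)
  } else {
    list(condition = "stress", delta = env$mu_p - env$mu_n,
         alpha = env$b, beta = env$a,
         mu_major = env$mu_p, mu_minor = env$mu_n)
  }
}

#' Growth- and death-rate gaps of a growth/stress environment pair
#'
#' @param env_growth Growth-condition [env_params()] (requires
#'   `mu_n > mu_p`, i.e. a positive growth-rate gap `delta_mu`).
#' @param env_stress Stress-condition [env_params()] (requires
#'   `kappa_n > kappa_p`, i.e. a positive death-rate gap `delta_kappa`).
#' @return Object of class `"rate_gaps"`: list with `delta_mu` and
#'   `delta_kappa` (1/hour).
#' @export
rate_gaps <- function(env_growth, env_stress) {
  dmu <- as_env_params(env_growth)$mu_n - as_env_params(env_growth)$mu_p
  dka <- as_env_params(env_stress)$mu_p - as_env_params(env_stress)$mu_n
  make_rate_gaps(dmu, dka)
}

#' Construct rate gaps directly
#'
#' @param delta_mu Growth-rate difference `mu_n - mu_p` in the growth
#'   condition (1/hour, > 0).
#' @param delta_kappa Death-rate difference `kappa_n - kappa_p` under stress
#'   (1/hour, > 0).
#' @return Object of class `"rate_gaps"`.
#' @export
make_rate_gaps <- function(delta_mu, delta_kappa) {
  stopifnot(is.numeric(delta_mu), is.finite(delta_mu),
            is.numeric(delta_kappa), is.finite(delta_kappa))
  if (delta_mu <= 0)
    stop("delta_mu must be > 0 (condition mislabeled?)", call. = FALSE)
  if (delta_kappa <= 0)
    stop("delta_kappa must be > 0 (condition mislabeled?)", call. = FALSE)
  structure(list(delta_mu = as.numeric(delta_mu),
                 delta_kappa = as.numeric(delta_kappa)),
            class = "rate_gaps")
}

as_rate_gaps <- function(gaps) {
  if (!inherits(gaps, "rate_gaps"))
    stop("expected a 'rate_gaps' object; see rate_gaps()", call. = FALSE)
  gaps
}

#' Switching-rate pair
#'
#' Light-weight container for the two phenotype switching rates.
#'
#' @param a Switching rate normal -> persister (1/hour, >= 0).
#' @param b Switching rate persister -> normal (1/hour, >= 0).
#' @return Object of class `"switching_rates"`.
#' @export
switching_rates <- function(a, b) {
  stopifnot(is.numeric(a), is.finite(a), is.numeric(b), is.finite(b))
  if (a < 0 || b < 0)
    stop("switching rates must be non-negative", call. = FALSE)
  structure(list(a = as.numeric(a), b = as.numeric(b)),
            class = "switching_rates")
}

as_switching_rates <- function(sw) {
  if (inherits(sw, "env_params")) return(switching_rates(sw$a, sw$b))
  if (!inherits(sw, "switching_rates"))
    stop("expected a 'switching_rates' object", call. = FALSE)
  sw
}

#' Population state
#'
#' A snapshot (t, n, p) of both subpopulations.
#'
#' @param n Normal-cell count (>= 0).
#' @param p Persister count (>= 0).
#' @param t Time in hours (default 0).
#' @return Object of class `"population_state"`.
#' @export
population_state <- function(n, p, t = 0) {
  stopifnot(is.numeric(n), is.finite(n), is.numeric(p), is.finite(p),
            is.numeric(t), is.finite(t))
  if (n < 0 || p < 0) stop("counts must be non-negative", call. = FALSE)
  structure(list(t = as.numeric(t), n = as.numeric(n), p = as.numeric(p)),
            class = "population_state")
}

as_population_state <- function(state) {
  if (inherits(state, "population_state")) return(state)
  if (is.numeric(state) && !is.null(names(state)) &&
      all(c("n", "p") %in% names(state)))
    return(population_state(state[["n"]], state[["p"]],
                            t = if ("t" %in% names(state)) state[["t"]] else 0))
  stop("expected a 'population_state' (or named vector with n, p)",
       call. = FALSE)
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> t = %g h: n = %g, p = %g (N = %g)\n",
              x$t, x$n, x$p, x$n + x$p))
  invisible(x)
}

#' Canonical demonstration parameters
#'
#' A growth/stress environment pair in the range reported for *E. coli*:
#' growth rates 2 and 0.2 /h for normal cells and persisters, stress death
#' rates 4 and 0.4 /h, switching rates a = 1e-5 /h (normal -> persister) and
#' b = 1e-3 /h (persister -> normal). These are the package's reference
#' conditions for shift-experiment examples and tests.
#'
#' @param a,b Optional switching-rate overrides (applied to both
#'   environments; the switching machinery is a property of the organism,
#'   not of the medium).
#' @return List with elements `growth` and `stress` ([env_params()]) and
#'   `gaps` ([rate_gaps()]).
#' @export
demo_params <- function(a = 1e-5, b = 1e-3) {
  growth <- env_params(mu_n = 2, mu_p = 0.2, a = a, b = b, label = "growth")
  stress <- env_params(mu_n = -4, mu_p = -0.4, a = a, b = b, label = "stress")
  list(growth = growth, stress = stress, gaps = rate_gaps(growth, stress))
}
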