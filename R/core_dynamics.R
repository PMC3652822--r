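#' Rate matrix of the linear two-state model
#'
#' The linear switching dynamics of normal (n) and persister (p) cells,
#' dn/dt = mu_n n - a n + b p and dp/dt = mu_p p + a n - b p, written as
#' d(n, p)/dt = M (n, p). Ordering is `[n, p]`.
#'
#' @param env An [env_params()] object.
#' @return A 2x2 numeric matrix with dimnames `c("n", "p")`.
#' @examples
#' rate_matrix(env_params(2, 0.2, a = 0.2, b = 0))
#' @export
rate_matrix <- function(env) {
  env <- as_env_params(env)
  matrix(c(env$mu_n - env$a, env$a, env$b, env$mu_p - env$b),
         nrow = 2L, dimnames = list(c("n", "p"), c("n", "p")))
}

# Spectral pieces of the 2x2 rate matrix: mean rate m, half-gap q >= 0
# (always real because the off-diagonal product a*b is non-negative),
# eigenvalues m +- q.
rate_matrix_spectrum <- function(env) {
  env <- as_env_params(env)
  m11 <- env$mu_n - env$a
  m22 <- env$mu_p - env$b
  m <- (m11 + m22) / 2
  d <- (m11 - m22) / 2
  q <- sqrt(d * d + env$a * env$b)
  list(m = m, d = d, q = q, lambda1 = m + q, lambda2 = m - q)
}

# sinh(x)/x with a series fallback near 0 (relative error < 1e-16 for |x|<1e-4)
sinhc <- function(x) {
  ifelse(abs(x) < 1e-4, 1 + x * x / 6 * (1 + x * x / 20), sinh(x) / x)
}

#' Exact propagator matrix exp(M t) of one environment
#'
#' Closed-form matrix exponential of the 2x2 rate matrix via its spectral
#' projectors,
#' `exp(Mt) = e^{l1 t} (M - l2 I)/(l1 - l2) + e^{l2 t} (l1 I - M)/(l1 - l2)`.
#' For the switching-model matrix every term of this decomposition is
#' non-negative, so no cancellation occurs even when one eigenmode is many
#' orders of magnitude below the other; nearly degenerate eigenvalues
#' (`q dt` small) fall back to a scaled Taylor form.
#'
#' @param env An [env_params()] object with infinite carrying capacity.
#' @param dt Time span in hours (>= 0).
#' @return 2x2 propagator matrix (ordering `[n, p]`).
#' @export
phase_propagator <- function(env, dt) {
  env <- as_env_params(env)
  stopifnot(is.numeric(dt), length(dt) == 1L, is.finite(dt), dt >= 0)
  if (is.finite(env$carrying_capacity))
    stop("exact propagation requires infinite carrying capacity; ",
         "use integrate_capacity()", call. = FALSE)
  sp <- rate_matrix_spectrum(env)
  M <- rate_matrix(env)
  x <- sp$q * dt
  if (x < 1e-4) {
    # nearly degenerate eigenvalues: e^{mt}(cosh(x) I + t sinhc(x)(M - mI));
    # all correction terms are O(x), far from cancellation
    P <- exp(sp$m * dt) *
      (cosh(x) * diag(2) + dt * sinhc(x) * (M - sp$m * diag(2)))
  } else {
    e1 <- exp(sp$lambda1 * dt)
    e2 <- exp(sp$lambda2 * dt)
    w <- 2 * sp$q
    # projector weights q +- d are >= 0; the smaller one is recovered from
    # (q - d)(q + d) = a b so that it vanishes exactly when a b does (a
    # direct q + d rounds at ~1e-16 and the dominant mode amplifies that
    # by e^{2 q t})
    ab <- env$a * env$b
    if (sp$d >= 0) {
      qpd <- sp$q + sp$d
      qmd <- if (qpd > 0) ab / qpd else 0
    } else {
      qmd <- sp$q - sp$d
      qpd <- ab / qmd
    }
    P <- matrix(c((e1 * qpd + e2 * qmd) / w,
                  env$a * (e1 - e2) / w,
                  env$b * (e1 - e2) / w,
                  (e1 * qmd + e2 * qpd) / w),
                nrow = 2L)
  }
  dimnames(P) <- dimnames(M)
  P
}

#' Propagate the exact solution of the two-state model
#'
#' Evolves a population state over `dt` hours in a constant environment using
#' the closed-form matrix exponential of the linear model (the model's exact
#' solution). Linear in the initial state and exact to machine precision,
#' including nearly degenerate eigenvalues.
#'
#' @param env An [env_params()] object (infinite carrying capacity).
#' @param state0 Initial [population_state()] (or named vector with `n`, `p`).
#' @param dt Time span in hours (>= 0).
#' @return A [population_state()] at time `state0$t + dt`.
#' @examples
#' st <- propagate_exact(env_params(2, 0.2, 1e-5, 1e-3),
#'                       population_state(n = 1e3, p = 1), dt = 15)
#' @export
propagate_exact <- function(env, state0, dt) {
  state0 <- as_population_state(state0)
  P <- phase_propagator(env, dt)
  v <- P %*% c(state0$n, state0$p)
  # the propagator of a Metzler matrix is non-negative; clip the tiny
  # negative round-off that can appear when a component underflows
  population_state(max(v[1L], 0), max(v[2L], 0), t = state0$t + dt)
}

#' Dominant eigenvalue and population structure
#'
#' Largest-real-part eigenvalue of the rate matrix (the long-time per-capita
#' growth/decay rate of the total population) together with the n/p ratio of
#' the associated eigenvector (the stationary population structure; strictly
#' positive by Perron-Frobenius when both switching rates are positive).
#'
#' @param env An [env_params()] object (infinite carrying capacity).
#' @return List with `rate` (1/hour) and `structure` (n/p ratio; may be 0 or
#'   `Inf` when one switching rate vanishes).
#' @export
dominant_eigenpair <- function(env) {
  env <- as_env_params(env)
  sp <- rate_matrix_spectrum(env)
  # eigenvector for lambda1 from either row; q + d = lambda1 - m22,
  # q - d = lambda1 - m11 are both >= 0, pick the better conditioned form
  structure_np <- if (env$a == 0 && env$b == 0) {
    if (sp$d > 0) Inf else if (sp$d < 0) 0 else 1
  } else if (sp$q + sp$d >= sp$q - sp$d) {
    if (env$a > 0) (sp$q + sp$d) / env$a else Inf
  } else {
    if (sp$q - sp$d > 0) env$b / (sp$q - sp$d) else Inf
  }
  list(rate = sp$lambda1, structure = structure_np)
}

new_trajectory <- function(df, phases = NULL) {
  stopifnot(all(c("time_h", "n", "p", "total", "phase_label") %in% names(df)))
  structure(df, class = c("trajectory", "data.frame"), phases = phases)
}

#' Simulate a multi-phase environmental protocol
#'
#' Piecewise propagation through a sequence of environments (e.g. 15 h
#' growth followed by 15 h antibiotic stress), with continuity of (n, p) at
#' the environment boundaries. Environments with infinite carrying capacity
#' are propagated exactly; finite-capacity phases are integrated numerically
#' via [integrate_capacity()].
#'
#' @param envs List of phases; each element is `list(env = <env_params>,
#'   duration = <hours>)`.
#' @param state0 Initial [population_state()].
#' @param samples_per_phase Number of sample times per phase (>= 2).
#' @return A `trajectory`: data frame with columns `time_h`, `n`, `p`,
#'   `total`, `phase_label` and a `phases` attribute recording the phase
#'   boundaries.
#' @examples
#' pars <- demo_params()
#' tr <- simulate_protocol(list(list(env = pars$growth, duration = 15),
#'                              list(env = pars$stress, duration = 15)),
#'                         population_state(n = 100, p = 1))
#' @export
simulate_protocol <- function(envs, state0, samples_per_phase = 50L) {
  if (!is.list(envs) || length(envs) == 0L)
    stop("empty protocol: 'envs' must be a non-empty list of phases",
         call. = FALSE)
  stopifnot(samples_per_phase >= 2L)
  state <- as_population_state(state0)
  rows <- list(data.frame(time_h = state$t, n = state$n, p = state$p,
                          total = state$n + state$p,
                          phase_label = NA_character_))
  boundaries <- data.frame(phase = integer(), label = character(),
                           t_start = numeric(), t_end = numeric())
  t0 <- state$t
  for (i in seq_along(envs)) {
    ph <- envs[[i]]
    if (!is.list(ph) || is.null(ph$env) || is.null(ph$duration))
      stop("each phase must be list(env = , duration = )", call. = FALSE)
    env <- as_env_params(ph$env)
    dur <- ph$duration
    if (!(is.numeric(dur) && is.finite(dur) && dur > 0))
      stop("phase durations must be positive", call. = FALSE)
    lab <- if (!is.na(env$label)) env$label else paste0("phase", i)
    t_loc <- seq(0, dur, length.out = samples_per_phase)[-1L]
    if (is.finite(env$carrying_capacity)) {
      tr <- integrate_capacity(env, state, t_grid = t_loc)
      seg <- data.frame(time_h = t0 + tr$time_h, n = tr$n, p = tr$p,
                        total = tr$total, phase_label = lab)
      last <- nrow(tr)
      state <- population_state(tr$n[last], tr$p[last], t = t0 + dur)
    } else {
      seg <- do.call(rbind, lapply(t_loc, function(tt) {
        st <- propagate_exact(env, state, tt)
        data.frame(time_h = t0 + tt, n = st$n, p = st$p,
                   total = st$n + st$p, phase_label = lab)
      }))
      state <- propagate_exact(env, state, dur)
      state$t <- t0 + dur
    }
    rows[[i + 1L]] <- seg
    boundaries <- rbind(boundaries,
                        data.frame(phase = i, label = lab,
                                   t_start = t0, t_end = t0 + dur))
    t0 <- t0 + dur
  }
  df <- do.call(rbind, rows)
  df$phase_label[1L] <- df$phase_label[2L]
  rownames(df) <- NULL
  new_trajectory(df, phases = boundaries)
}

#' Integrate the model with a finite carrying capacity
#'
#' Numerical integration of the two-state dynamics with environment carrying
#' capacity K: every *positive* net-rate (growth) term is multiplied by
#' (1 - N/K) where N = n + p; death and switching terms are unmodified. As
#' the population approaches K, growth stalls and the subpopulation ratio
#' relaxes from the growth balance (p/n ~ a/delta_mu) to the pure switching
#' balance p/n = a/b of stationary phase.
#'
#' @param env An [env_params()] with finite `carrying_capacity` (an infinite
#'   K is accepted and reduces to the exact exponential dynamics).
#' @param state0 Initial [population_state()].
#' @param t_grid Increasing vector of output times (hours, relative to
#'   `state0$t`).
#' @param rtol,atol Solver tolerances (defaults 1e-10 / 1e-12; the
#'   integrator doubles as the reference oracle elsewhere).
#' @return A `trajectory` data frame (columns `time_h`, `n`, `p`, `total`,
#'   `phase_label`); `time_h` is relative to `state0$t`.
#' @export
integrate_capacity <- function(env, state0, t_grid,
                               rtol = 1e-10, atol = 1e-12) {
  env <- as_env_params(env)
  state0 <- as_population_state(state0)
  stopifnot(is.numeric(t_grid), length(t_grid) >= 1L, all(is.finite(t_grid)))
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("'t_grid' must be strictly increasing", call. = FALSE)
  if (any(t_grid < 0)) stop("'t_grid' must be non-negative", call. = FALSE)
  K <- env$carrying_capacity
  rhs <- function(t, y, parms) {
    n <- y[1L]; p <- y[2L]
    lim <- if (is.finite(K)) max(1 - (n + p) / K, 0) else 1
    gn <- if (env$mu_n > 0) env$mu_n * lim else env$mu_n
    gp <- if (env$mu_p > 0) env$mu_p * lim else env$mu_p
    list(c(gn * n - env$a * n + env$b * p,
           gp * p + env$a * n - env$b * p))
  }
  times <- if (t_grid[1L] > 0) c(0, t_grid) else t_grid
  out <- deSolve::lsoda(y = c(state0$n, state0$p), times = times, func = rhs,
                        parms = NULL, rtol = rtol, atol = atol)
  out <- as.data.frame(out)
  names(out) <- c("time", "n", "p")
  if (t_grid[1L] > 0) out <- out[-1L, , drop = FALSE]
  df <- data.frame(time_h = out$time, n = pmax(out$n, 0), p = pmax(out$p, 0),
                   total = pmax(out$n, 0) + pmax(out$p, 0),
                   phase_label = if (!is.na(env$label)) env$label else "phase1")
  rownames(df) <- NULL
  new_trajectory(df)
}

#' Write / read a trajectory as CSV
#'
#' Plain CSV with header `time_h,n,p,total,phase_label`, UTF-8, `.` decimal
#' separator.
#'
#' @param traj A `trajectory` (from [simulate_protocol()] or
#'   [integrate_capacity()]).
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a `trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.csv(as.data.frame(traj)[, c("time_h", "n", "p", "total",
                                           "phase_label")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "n", "p", "total", "phase_label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("trajectory file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.unsorted(df$time_h, strictly = TRUE))
    stop("trajectory times must be strictly increasing", call. = FALSE)
  if (any(df$n < 0 | df$p < 0))
    stop("trajectory counts must be non-negative", call. = FALSE)
  new_trajectory(df[, need])
}
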