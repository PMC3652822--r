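# Independent numerical oracles used across the suite.

# Adaptive high-accuracy integration of the two-state model in log space
# (log n, log p), so that the solver's absolute tolerance certifies
# *relative* accuracy on counts spanning many decades. Requires positive
# initial counts.
oracle_integrate <- function(env, state0, dt, rtol = 1e-12, atol = 1e-12) {
  state0 <- persistdyn::population_state(state0[["n"]], state0[["p"]])
  rhs <- function(t, y, parms) {
    list(c(env$mu_n - env$a + env$b * exp(y[2] - y[1]),
           env$mu_p - env$b + env$a * exp(y[1] - y[2])))
  }
  out <- deSolve::lsoda(c(log(state0$n), log(state0$p)), c(0, dt), rhs,
                        NULL, rtol = rtol, atol = atol)
  c(n = exp(out[2, 2]), p = exp(out[2, 3]))
}

# Oriented subpopulation ratio along the exact dynamics.
oracle_ratio <- function(env, r0, tvec) {
  cond <- persistdyn::env_condition(env)
  vapply(tvec, function(tt) {
    st <- if (cond == "growth")
      persistdyn::propagate_exact(env, persistdyn::population_state(r0, 1), tt)
    else
      persistdyn::propagate_exact(env, persistdyn::population_state(1, r0), tt)
    if (cond == "growth") st$n / st$p else st$p / st$n
  }, numeric(1L))
}

# Parameter grid spanning the magnitudes reported for persistence rates:
# growth rates up to 2 /h, persister rates up to 0.2 /h, switching
# 1e-6 .. 1e-1 /h, plus stress (negative-rate) combinations and
# near-degenerate eigenvalue cases.
oracle_param_grid <- function() {
  grid <- expand.grid(mu_n = c(2, 1.24, -4, -0.5),
                      mu_p = c(0.2, 0.05, -0.4),
                      a = c(1e-6, 1e-3, 1e-1),
                      b = c(1e-4, 1e-1),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$mu_n != grid$mu_p, ]
  degen <- data.frame(mu_n = c(1, 0.5, 2),
                      mu_p = c(1, 0.5 - 1e-9, 2 - 2e-4),
                      a = c(1e-4, 1e-4, 1e-4),
                      b = c(1e-4, 1e-4, 1e-4))
  rbind(grid, degen)
}

# Full shift-experiment inference pipeline on synthetic curves with known
# switching rates: generate both shift protocols, fit the post-shift
# segments, locate the transitions, invert for (a, b).
pipeline_recover <- function(a, b, noise = NULL, points_per_phase = 30L) {
  pars <- persistdyn::demo_params(a, b)
  st0 <- persistdyn::population_state(1e8 * b / (a + b), 1e8 * a / (a + b))
  kill <- persistdyn::generate_shift_curves(pars$growth, pars$stress, 15, 15,
                                            st0, points_per_phase, noise)
  regrow <- persistdyn::generate_shift_curves(pars$stress, pars$growth, 15, 15,
                                              st0, points_per_phase, noise)
  s1 <- kill[kill$phase_label == "stress", ]
  s1$time_h <- s1$time_h - 15
  s2 <- regrow[regrow$phase_label == "growth", ]
  s2$time_h <- s2$time_h - 15
  suppressWarnings(persistdyn::infer_from_curves(s1, s2))
}
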