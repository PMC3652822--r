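# persistdyn

Population dynamics of bacterial persistence: exact solutions,
small-switching-rate asymptotics, shift-experiment observables with
switching-rate inference, and growth in periodically switching
environments.

## The problem

When a bacterial culture is treated with a bactericidal antibiotic, a small
phenotypic subpopulation — the persisters — survives and regrows the
culture after the drug is removed, without any genetic resistance. Cells
switch stochastically between a fast-growing, drug-sensitive normal state
and a slow-growing, drug-tolerant persister state. The population-level
signature is a *biphasic* killing curve: fast decay while normal cells die,
then slow decay carried by the persisters. Because single-cell switching
events are rare and hard to observe, the practical route to the switching
parameters runs through exactly such population-scale growth and killing
curves — and this package provides the modeling and inference machinery for
that route.

## The model

Normal cells $n$ and persisters $p$ in a given environment:

$$
\dot n = \mu_n n - a\,n + b\,p, \qquad
\dot p = \mu_p p + a\,n - b\,p,
$$

with per-phenotype net rates $\mu_n$, $\mu_p$ (negative under stress; death
rates $\kappa = -\mu$) and switching rates $a$ (normal → persister) and $b$
(persister → normal). Key derived quantities, all implemented with
closed forms and validated against exact propagation:

| Quantity | Expression (small switching) | Function |
|---|---|---|
| Exponential-phase persister fraction | $a/\Delta\mu$ | `steady_state_structure()` |
| Stationary-phase ratio $p/n$ | $a/b$ | `stationary_phase_fraction()`, `integrate_capacity()` |
| Kill-curve kink time | $T_s = \log(\tilde\Delta/a)/\Delta\kappa$ | `steady_transition_times()` |
| Regrowth kink time | $T_g = \log(\tilde\Delta/b)/\Delta\mu$ | `steady_transition_times()` |
| Switching-rate inversion | $a = \tilde\Delta e^{-\Delta\kappa T_s}$, $b = \tilde\Delta e^{-\Delta\mu T_g}$ | `infer_switching_rates()` |
| Periodic-cycle growth rate | $\log \Lambda_1(P_s P_g)/(t_g+t_s)$ | `cycle_growth_rate()` |
| Optimal switching rates | $a_{\rm opt} \approx 1/t_g$, $b_{\rm opt} \approx 1/t_s$ | `optimal_switching_numeric()` |

where $\Delta\mu$ and $\Delta\kappa$ are the growth- and death-rate gaps
between the phenotypes and
$\tilde\Delta = \Delta\mu\Delta\kappa/(\Delta\mu+\Delta\kappa)$ is their
combined rate. See the methods vignette
(`vignettes/persistence-dynamics.Rmd`) for the derivations, conventions and
numerical choices.

## Worked example: infer switching rates from a pair of shift experiments

Simulate the two canonical protocols (15 h growth then 15 h antibiotic;
15 h antibiotic then 15 h regrowth) with known rates and 5% lognormal
plating noise, fit the biphasic curves, and invert for the switching rates:

```r
library(persistdyn)

pars <- demo_params()          # mu_n = 2, mu_p = 0.2, kappa_n = 4,
                               # kappa_p = 0.4, a = 1e-5, b = 1e-3 (/h)
st0  <- population_state(n = 1e8, p = 556)   # ~steady growth structure

kill   <- generate_shift_curves(pars$growth, pars$stress, 15, 15, st0,
           points_per_phase = 30,
           noise = noise_model("lognormal", sigma = 0.05, seed = 1))
regrow <- generate_shift_curves(pars$stress, pars$growth, 15, 15, st0,
           points_per_phase = 30,
           noise = noise_model("lognormal", sigma = 0.05, seed = 2))

# post-shift segments, time measured from the shift
s1 <- subset(kill,   phase_label == "stress"); s1$time_h <- s1$time_h - 15
s2 <- subset(regrow, phase_label == "growth"); s2$time_h <- s2$time_h - 15

infer_from_curves(s1, s2)
#> <switching_inference> a_hat = 9.045e-06 /h, b_hat = 0.0008522 /h
#>   from T_s = 3.191 h, T_g = 3.832 h (delta_mu = 1.90463, delta_kappa = 3.71142 /h)
```

Both switching rates come back within ~15% of the true values
(`a = 1e-5`, `b = 1e-3`) from noisy total counts alone: the fitted kink
times `T_s`, `T_g` are the observable, and the rate gaps are read off the
fitted fast/slow exponents. The noiseless analytic kinks for these
parameters are `T_s = 3.249 h`, `T_g = 3.939 h`
(`steady_transition_times()`), and the exponential-phase persister
fraction is `5.56e-06` (`steady_state_structure()`).

Periodic environments, optimal bet-hedging:

```r
spec <- cycle_spec(100, 100, demo_params(1e-3, 1e-3)$growth,
                             demo_params(1e-3, 1e-3)$stress)
optimal_switching_numeric(spec, n_grid = 24)
#> <optimal_switching> (floquet_grid)
#>   a_opt = 0.01014 /h, b_opt = 0.01003 /h
#>   achieved rate = 0.742167 /h
```

The optimal switching rates track the inverse environmental durations
(`1/t_g = 1/t_s = 0.01 /h`) — switch roughly once per residence time — and
the optimum disappears when one environmental phase is short
(`switching_rate_scan()` then decreases monotonically).

A small CLI wraps these workflows
(`system.file("cli", "persistdyn.R", package = "persistdyn")`, verbs
`simulate` / `generate` / `fit` / `infer` / `periodic` / `optimize`).

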