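---
title: "Modeling bacterial persistence: two-phenotype population dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bacterial persistence: two-phenotype population dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persistdyn)
```

## The model

Bacterial persistence is phenotypic, not genetic: a small subpopulation of
slow-growing persister cells survives antibiotic treatment and regenerates a
drug-sensitive population once the stress is removed. `persistdyn`
implements the standard linear two-state description of this phenomenon.
Normal cells ($n$) and persisters ($p$) grow or die with per-capita net
rates $\mu_n$ and $\mu_p$ that depend on the environment, and interconvert
stochastically with rates $a$ (normal $\to$ persister) and $b$ (persister
$\to$ normal):

$$
\dot n = \mu_n n - a\,n + b\,p, \qquad
\dot p = \mu_p p + a\,n - b\,p .
$$

Two environments matter in practice. In **growth** media $\mu_n > \mu_p
\ge 0$ and we write $\Delta\mu = \mu_n - \mu_p$ for the growth-rate gap. In
**stress** (bactericidal antibiotic) both net rates are negative; we expose
the death rates $\kappa = -\mu$ and the death-rate gap
$\Delta\kappa = \kappa_n - \kappa_p > 0$ (normal cells die faster). A single
signed rate per phenotype is the only stored representation — `kappa_rates()`
is a derived view — so there is no chance of a sign mismatch between
duplicate parameterizations.

The model is linear, so its propagator over a time span $t$ is the matrix
exponential of
$$
M = \begin{pmatrix} \mu_n - a & b \\ a & \mu_p - b \end{pmatrix},
$$
which `propagate_exact()` evaluates in closed form (see *Numerical choices*).
Everything else in the package — asymptotics, shift observables, periodic
environments — is tested against this exact solution or against an adaptive
ODE integration of the same equations.

## Small-switching asymptotics

Measured switching rates are tiny compared to growth and death rates
(for *E. coli*, $a \sim 10^{-6}\,$/h against $\mu_n \sim 2\,$/h), and every
useful closed form in the package exploits this. The central object is the
oriented subpopulation ratio — majority over minority for the current
condition, $F = n/p$ in growth and $G = p/n$ under stress. It obeys a
Riccati equation,
$$
\dot R = -\alpha R^2 + (\Delta - \alpha + \beta) R + \beta,
$$
with $(\alpha, \beta) = (a, b)$, $\Delta = \Delta\mu$ in growth and
$(\alpha, \beta) = (b, a)$, $\Delta = \Delta\kappa$ under stress. The two
conditions map onto each other by this exchange rule, so each formula is
implemented once, in oriented form. The ratio has an unstable fixed point
$R_0 \le 0$ and a stable one $R^\star > 0$ (the roots of the quadratic,
`ratio_fixed_points()`), and relaxes between them at rate
$\gamma = \alpha(R^\star - R_0) = \sqrt{(\Delta-\alpha+\beta)^2 +
4\alpha\beta}$. For small switching, $R^\star \approx \Delta/\alpha$,
$R_0 \approx 0$ and $\gamma \approx \Delta$, which turns the dynamics into
a plain logistic equation; `logistic_ratio()` evaluates its solution, and
the package's convergence tests confirm that its error shrinks linearly as
the switching rates are scaled down.

Consequences exposed as functions:

* `steady_state_structure()` — steady ratio $\Delta/\alpha$, persister
  fraction ($\approx a/\Delta\mu$ in exponential growth), relaxation rate,
  and the effective long-time rate of the total population
  ($\mu_n - a$ in growth, $-(\kappa_p + b)$ under stress). The deviation of
  these leading-order rates from the exact dominant eigenvalue is
  quadratic in the switching rates ($\sim ab/\Delta$), and a test asserts
  that bound across a parameter grid.
* `stationary_phase_fraction()` — with growth shut down (carrying
  capacity reached) the structure is set by the switching balance alone,
  $p/n = a/b$: persister levels are orders of magnitude above the
  exponential-phase value $a/\Delta\mu$ without any regulatory response,
  enriched by the factor $\Delta\mu/b$.
* `total_double_exponential()` — to first order in the switching rates the
  total population is a sum of two exponentials with rates $\mu_n - a$ and
  $\mu_p - b$; the amplitude cross terms $\pm(a n_0 + b p_0)/
  (\lambda_f - \lambda_s)$ carry the switching flux. Under stress this is
  the classic biphasic killing curve.
* `average_subpop_growth()`, `average_total_growth()` — window-averaged
  per-capita rates, from the closed-form integrals of $R$ and $1/R$ along
  the logistic solution. Both subpopulation averages converge to the same
  effective rate, but only like $\log(R^\star/R_1)/t$, which is why the
  long-time tests use windows much longer than that transient.

## Shift experiments and switching-rate inference

After a growth $\to$ stress shift the killing curve has a kink at the time
$T_s$ where the two subpopulations are equal; after a stress $\to$ growth
shift the regrowth curve has the mirror kink at $T_g$. Solving the exact
ratio dynamics for $R(T) = 1$ gives `transition_time_stress()` /
`transition_time_growth()`; the familiar large-ratio limit
$T_s \approx \log(r_0)/\Delta\kappa$ is available as `form = "limit"`.

A subtlety worth recording: starting from the steady growth structure
$r_0 = \Delta\mu/a$, the naive logistic (which drops the unstable fixed
point $G_0 \approx -a/\Delta\kappa$) misplaces the kink by
$\log(1 + \Delta\mu/\Delta\kappa)/\Delta\kappa$ — a 30–50% bias on an
inferred switching rate for typical rate gaps. Keeping $G_0$, the
steady-shift transition times come out as
$$
T_s = \frac{1}{\Delta\kappa}\log\frac{\tilde\Delta}{a}, \qquad
T_g = \frac{1}{\Delta\mu}\log\frac{\tilde\Delta}{b}, \qquad
\tilde\Delta = \frac{\Delta\mu\,\Delta\kappa}{\Delta\mu + \Delta\kappa},
$$
with the *combined* rate gap $\tilde\Delta$ (`steady_transition_times()`).
These invert exactly,
$a = \tilde\Delta e^{-\Delta\kappa T_s}$ and
$b = \tilde\Delta e^{-\Delta\mu T_g}$ (`infer_switching_rates()`), and the
package's end-to-end recovery tests — simulate both shift protocols, fit
the double exponential, locate the kinks, invert — recover switching rates
across $10^{-6}$–$10^{-3}$/h to within a fraction of a percent on
noiseless curves precisely because the prefactor is $\tilde\Delta$ and not
$\Delta\mu$.

The population *structure* equilibrates later than the kink:
`equilibration_times()` returns the inflection point of the time-dependent
per-capita rate of the initially dominant subpopulation, which sits at the
midpoint of the logistic relaxation, delayed relative to $T_s$ by roughly
$\log(G^\star)/\Delta\kappa$ — the balance between persisters outlasting
normal cells and back-switching regenerating them.

`fit_double_exponential()` performs the data-facing step: nonlinear least
squares of the two-component model on log10 counts (homoscedastic loss on
the log scale, matching the multiplicative structure of CFU plating noise;
a raw-count loss is available via `log_scale = FALSE`). The initializer is
deterministic and derivative-free — component rates from the slopes of the
first and last thirds of the log-count curve, amplitudes by back-projection
— so a fit is reproducible given the data. Effectively single-exponential
data are detected up front (a straight-line fit of the log counts with
residual spread below $10^{-10}$) and returned flagged rather than pushed
through a degenerate two-component optimization. `locate_transition()`
defines the data-driven kink as the equality of the two *fitted*
components, consistent with the subpopulation-equality definition of the
transition time; curvature-based estimators were deliberately left out.
`infer_from_curves()` chains the pieces and warns when the back-projected
pre-shift component ratio is more than 2-fold away from the steady
structure implied by the inferred rates, since the inversion formulas
assume the shift happened from a stationary structure.

## Periodic environments

For an environment alternating between a growth phase of length $t_g$ and a
stress phase of length $t_s$, the long-time growth rate is defined through
the per-cycle propagator $M = P_s(t_s) P_g(t_g)$:
$\bar\lambda = \log \Lambda_1 / (t_g + t_s)$ with $\Lambda_1$ its dominant
eigenvalue (`cycle_growth_rate()`). This Floquet route is the package's
authoritative definition — it needs no validity regime — while the
steady-structure closed form
$$
\bar\lambda\,(t_g + t_s) = (\mu_n - a)\,t_g - (\kappa_p + b)\,t_s
  - \log\frac{\tilde\Delta}{a} - \log\frac{\tilde\Delta}{b}
$$
is reported alongside (`lambda_bar_closed`): exponential gain and loss at
the per-condition effective rates minus two structure-reset penalties,
$\Delta\kappa T_s$ and $\Delta\mu T_g$, paid after each shift. It is valid
when both phases are long enough for the structure to equilibrate, and the
tests check that its error against the Floquet route shrinks monotonically
as the durations grow.

Maximizing the closed form over the switching rates gives
$a_{\rm opt} \approx 1/t_g$ and $b_{\rm opt} \approx 1/t_s$ — switch about
once per residence time — with correction terms
$a_{\rm opt} = 1/(t_g + 2(1/\Delta\kappa - 1/\Delta\mu))$ (and mirrored for
$b$) that the package evaluates at zero switching rates, where they are
parameter-independent; solving the implicit version self-consistently
changes the answer at the sub-percent level in the long-duration regime and
was not worth a nonlinear solve. `optimal_switching_numeric()` is the
authoritative check: a deterministic 40x40 log-spaced grid over
$[10^{-6}, 1]$/h followed by a single Nelder–Mead refinement from the best
grid point — no stochastic restarts, so results are exactly reproducible.
When the grid maximum lies on the lower boundary the result is flagged
non-interior: that is the regime (one short environmental duration) where
the cycle growth rate decreases monotonically with the switching rate and
phenotype switching is unprofitable.

With a finite carrying capacity $K$ in the growth environment
(`capacity_cycle_behavior()`), net-growth cycles saturate: the per-cycle
peak approaches $K$, and the long-term growth rate approaches zero; under
net decay the capacity never engages and the unbounded analysis applies
unchanged.

## Carrying capacity

The stationary-phase extension multiplies every *positive* net-rate
(growth) term by $(1 - N/K)$, $N = n + p$; death and switching terms are
untouched. This is the standard logistic modification of the growth terms
only: crowding throttles division, it does not slow killing or phenotype
switching. `integrate_capacity()` solves the resulting nonlinear system
with `deSolve::lsoda` at tolerances (rtol $10^{-10}$, atol $10^{-12}$)
tight enough for the integrator to double as a reference oracle. The
approach of $p/n$ to the stationary balance $a/b$ happens at rate $a + b$,
which is extremely slow at physiological switching rates — demonstrations
and tests of the stationary-phase limit therefore use enlarged switching
rates so the balance is reached within a few hundred simulated hours; the
limit itself is rate-independent.

## Parameters and defaults

* Time unit: **hours**, throughout, matching how persistence rates are
  reported; not configurable.
* `demo_params()`: growth $\mu_n = 2$, $\mu_p = 0.2$/h (the range reported
  for *E. coli*); stress $\kappa_n = 4$, $\kappa_p = 0.4$/h (an order of
  magnitude between the death rates, a typical bactericidal contrast);
  switching $a = 10^{-5}$, $b = 10^{-3}$/h, inside the
  $10^{-6}$–$10^{-1}$/h span of reported persister switching rates. These
  are the package's canonical shift-experiment conditions; both transition
  times then fall inside a 15 h observation window, which is what makes
  the two-phase protocols informative.
* Small-switching warnings fire when $a$ or $b$ exceeds 10% of the
  relevant rate gap (`warn_threshold`, configurable): the expansions carry
  relative errors of order $\alpha/\Delta$, and 10% is where those become
  material. This is a warning, not an error, because no sharp validity
  bound exists.
* Default measurement noise in the generator is lognormal with
  $\sigma = 0.1$ on log10 counts — roughly the replicate scatter of serial
  dilution plating; the deterministic model itself is noiseless.

## Numerical choices

* **Propagator**: spectral-projector form
  $e^{Mt} = e^{\lambda_1 t} (M - \lambda_2 I)/(\lambda_1 - \lambda_2) +
  e^{\lambda_2 t} (\lambda_1 I - M)/(\lambda_1 - \lambda_2)$. For this
  Metzler matrix every term is non-negative, so the subdominant mode is
  computed without cancellation even when the modes differ by dozens of
  orders of magnitude (a cosh/sinh formulation loses up to ten digits
  there). The projector weights $q \pm d$ are themselves recovered from
  $(q-d)(q+d) = ab$ so that the coupling vanishes *exactly* when $ab = 0$;
  nearly degenerate eigenvalues ($q\,t < 10^{-4}$) use a scaled Taylor
  form. The same cancellation-free discriminant
  $\sqrt{(M_{11}-M_{22})^2 + 4 M_{12} M_{21}}$ is used for the cycle
  propagator's eigenvalues.
* **Quadratic roots** of the ratio fixed-point equation use the
  $q = -(B + \mathrm{sign}(B)\sqrt{B^2 - 4AC})/2$ scheme; the root product
  is $-\beta/\alpha \le 0$, so one root is always non-negative and one
  non-positive.
* **Reference integration** (tests and the acceptance script) is done in
  log space, $(\log n, \log p)$: an absolute solver tolerance then
  certifies *relative* accuracy on counts spanning ~50 decades over 30 h,
  which a raw-count integration with any fixed absolute tolerance cannot.
* **Overflow discipline**: logistic solutions are written in terms of
  $e^{-\gamma t}$, long-time log-gains via `log1p`-based log-sum-exp, and
  the average-total-growth rate through the dominant component, so
  window lengths of thousands of hours are safe. The propagator itself is
  limited only by `exp` overflow of the dominant mode
  ($\lambda_1 t \lesssim 700$).

## What the synthetic generator does and does not emulate

`generate_shift_curves()` / `generate_periodic_curves()` produce exactly
the deterministic model dynamics with multiplicative observation noise
(lognormal on log10 counts, or Poisson colony counts at a plated
fraction). All randomness flows from one recorded seed, drawn from a
private RNG stream so the caller's RNG state is untouched; identical seeds
give identical tables. The generator does **not** emulate demographic
stochasticity (relevant when persister numbers are small), adaptive or
stress-induced switching, inoculum-history effects, antibiotic
pharmacokinetics, or plate detection limits. Passing the package's
recovery tests therefore shows that the inference pipeline is correct and
noise-robust *under the model's own assumptions* — not that real kill
curves are free of those complications; on real data the model serves as
the null against which such deviations are detected.

## Problem sizes used in the tests

The shipped test suite and acceptance script run the propagator-vs-oracle
comparison over a 72-point parameter grid spanning 30 h windows, the
recovery pipeline over a 4x4 grid of switching-rate pairs (30 points per
phase, 15 h per phase), 20-cycle capacity simulations, and a 24x24
optimization grid. These sizes were chosen so the whole suite documents
the package's claims in seconds while leaving every comparison at least an
order of magnitude away from its tolerance.

## Known limitations

* Exactly two phenotypes; no multi-state or continuum generalizations.
* Deterministic dynamics only — no demographic-noise simulation.
* Strictly periodic environments; stochastic environment durations are out
  of scope.
* Switching rates are environment-independent constants, so SOS-induced or
  otherwise condition-dependent persistence appears only as a deviation
  from this null model.
* Fit uncertainty is reported as residuals only; no bootstrap or Bayesian
  intervals.
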