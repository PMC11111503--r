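---
title: "Time-variant gain drift-diffusion models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-variant gain drift-diffusion models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urgencyddm)
```

## The model

In a two-alternative reaction-time task, a decision variable $X$ integrates
noisy evidence from $x_0 = 0$ until it reaches an absorbing threshold at
$+Z$ (the correct choice, for positive drift) or $-Z$ (the error), with
$Z = 1$ fixed. The standard drift-diffusion model (DDM) uses a constant
drift $\mu$ and noise $\sigma$:

$$dX = \mu\,dt + \sqrt{dt}\,\sigma\,\eta, \qquad \eta \sim \mathcal N(0, 1).$$

`urgencyddm` implements the time-variant gain extension in which a
logistic *gain* (urgency) signal $\gamma(t)$ multiplies the drift rate,
the noise term, or both:

$$dX = \mu_{\mathrm{init}}\,\gamma(t)\,dt +
       \sqrt{dt}\,\gamma(t)\,\sigma_{\mathrm{init}}\,\eta,$$

with $\mu_{\mathrm{init}} = k c$ for motion coherence $c \in [0, 1]$ and
$\sigma_{\mathrm{init}} = \sigma_0\sqrt{1 + |c|}$ (or just $\sigma_0$ when
the coherence dependence is removed). The gain is a logistic function of
time constrained to equal 1 at stimulus onset,

$$\gamma(t) = \frac{s_y e^{s_x (t - d)}}{1 + e^{s_x (t - d)}}
            + \frac{1 + (1 - s_y) e^{-s_x d}}{1 + e^{-s_x d}},$$

with offset $d$ (s), slope $s_x$ (1/s) and amplitude scale $s_y$. The
package evaluates the algebraically equivalent sigmoid form
$\gamma(t) = s_y \sigma(s_x(t-d)) + \sigma(s_x d) + (1-s_y)\sigma(-s_x d)$,
which cannot overflow for large $s_x(t - d)$; $\gamma(0) = 1$ then holds
exactly in floating point, and $s_x = 0$ gives $\gamma \equiv 1$ — the
constant-gain limit in which the model collapses to the standard DDM.

Four cases place the gain differently (`model_case()`):

| case | gain on drift | gain on noise | noise depends on $c$ |
|------|---------------|---------------|----------------------|
| I    | yes           | yes           | yes                  |
| II   | yes           | yes           | no                   |
| III  | no            | yes           | no                   |
| IV   | yes           | no            | no                   |

The observed response time is $RT = t_{\mathrm{decision}} +
t_{\mathrm{residual}}$ with a Gaussian residual (non-decision) time of
mean `t_res_mean` and sd `t_res_sd`, truncated at zero. Every case has the
same seven free parameters $(k, \sigma_0, d, s_x, s_y,
\bar t_{\mathrm{res}}, \sigma_{\mathrm{res}})$; threshold and starting
point are fixed, so AIC $= 14 - 2\log L$ for all cases
(`aic_from_nll()`).

The qualitative signature that motivates the case comparison: a rising
gain on the *noise only* (case III) makes late decisions more error-prone,
so mean error RT exceeds mean correct RT; a rising gain on the *drift
only* (case IV) strengthens the signal over time, so late decisions are
more often correct and errors are fast. With constant gain the two means
are equal at a given signal-to-noise ratio.

## Predicted RT distributions: the Fokker-Planck solver

`solve_fptd()` forward-solves the Fokker-Planck equation of the diffusion
between the absorbing boundaries: time-dependent advection $\mu(t)$ and
diffusion $\sigma(t)^2/2$, delta initial condition at 0. Numerical
choices, in order of importance:

* **Scharfetter-Gummel (exponential-fitting) spatial discretization.**
  During optimization the search visits strongly advection-dominated
  corners (large $k$, tiny $\sigma_0$) where central differencing
  oscillates and produces spurious densities that a likelihood search
  will happily exploit. The Scharfetter-Gummel weights
  $B(\pm\mathrm{Pe})$, $B(z) = z/(e^z - 1)$, reduce to central
  differencing at small cell Peclet number (second-order accurate where
  the science happens) and to upwinding at large Peclet
  (positivity-friendly everywhere).
* **Crank-Nicolson stepping with coefficients frozen at each step's
  midpoint time**, unconditionally stable for the time-varying
  coefficients; the first two steps use backward Euler (Rannacher
  start-up) to damp the oscillations a delta initial condition otherwise
  induces, and steps with cell Peclet $> 2$ also use backward Euler,
  which is monotone there.
* **Boundary fluxes from the discrete flux into the absorbing ghost
  nodes**, evaluated on the same $\theta$-weighted density the update
  uses. Absorbed plus surviving mass then balances to machine precision
  by construction; the package's conservation checks bound the total
  error (including flux clamping at 0) below $10^{-3}$.
* **Grid defaults** `dt = 0.01` s, horizon `t_max = 5` s, `nx = 201`
  interior points: the fitting convention of the original task-modelling
  literature; `nx` odd so the starting point is a grid node. On this grid
  the solver reproduces the constant-coefficient closed forms — accuracy
  $1/(1 + e^{-2\mu Z/\sigma^2})$ to $\sim 10^{-5}$ and mean decision time
  $(Z/\mu)\tanh(\mu Z/\sigma^2)$ to $\sim 10^{-3}$ s — and halving both
  steps moves predicted accuracy by under $5 \times 10^{-4}$.
* **Residual-time convolution** (`convolve_residual()`) uses a
  bin-integrated Gaussian kernel on the same time grid, truncated below
  $t = 0$ and renormalized per boundary, so each boundary keeps its
  absorbed mass; `t_res_sd = 0` degenerates to an exact shift. Mass still
  inside the boundaries at the horizon is *censored*: it is reported as
  survival, excluded from the likelihood normalization, and never
  attributed to either choice.

## The Monte-Carlo simulator

`simulate_trials()` integrates single trials by Euler-Maruyama with the
same midpoint-frozen coefficients as the solver and adds a truncated
Gaussian residual draw. Discrete-time monitoring of a continuous barrier
systematically overestimates first-passage times by $O(\sqrt{dt})$
(the path can cross and return between grid points), which at
`dt = 0.01` s is a ~20 ms bias — far larger than the solver's error. The
simulator therefore applies the Broadie-Glasserman-Kou continuity
correction, monitoring an effective barrier $Z - 0.5826\,\sigma(t)
\sqrt{dt}$, and assigns crossings to the step midpoint. This removes the
leading-order bias without bridge sampling; measured agreement with the
solver (Kolmogorov-Smirnov distance per boundary, $n = 10^5$ trials) is
$\le 0.01$ at `dt = 0.01` and $\le 0.007$ at `dt = 0.0025`. The
solver-vs-simulator equivalence check runs at coherence 0.05 on a shared
`dt = 0.0025` grid: a per-boundary empirical KS distance has a sampling
floor of about $0.87/\sqrt{n_{\mathrm{boundary}}}$, so the comparison
point must land at least ~30k of the 100k trials on *each* boundary.

Reproducibility is by a single seeded R RNG stream per call (R has no
splittable generators); the same seed reproduces the identical trial
table bitwise.

## Fitting

`negloglik_robust()` scores each decided trial by the model RT density at
its (choice, RT), linearly interpolated on the solver grid and floored at
$\varepsilon = 10^{-10}$. The floor is the robustness mechanism: an
outlier RT in a region of zero model density contributes
$-\log\varepsilon \approx 23$ nats instead of $+\infty$, so single
contaminant trials cannot dominate the loss. The floor is configurable
(`eps`); the likelihood itself is the full joint distribution of choices
and RTs, not a summary-statistic loss.

`fit_case()` replicates the multi-run protocol: `n_runs` independent
optimizations (default 18) with derived seeds, each a differential
evolution search (rand/1/bin; population $15 \times 7 = 105$, $F = 0.8$,
$CR = 0.9$, up to 500 generations, stopping when the population cost
spread falls below $10^{-6}$) over the seven parameters within box
bounds, followed by a bounded L-BFGS-B polish of that run's solution
(`polish = TRUE`). The polish descends within the basin the stochastic
search found — run-to-run variability, which the multi-run protocol
exists to average over, is preserved, while each reported run is actually
at its local optimum. Default bounds ($k \le 50$, $\sigma_0 \in [0.01,
5]$, $d \le 5$ s, $s_x \le 20$ 1/s, $s_y \le 20$,
$\bar t_{\mathrm{res}} \le 1$ s, $\sigma_{\mathrm{res}} \le 0.5$ s) are a
package choice bracketing all preset gain shapes; they are documented
rather than estimated.

Each run records its robust NLL, AIC and the summary-statistic *squared
error*: the sum over coherence levels of squared differences in accuracy,
mean correct RT and mean error RT between model and data
(`squared_error()`; terms with undefined data means are skipped). The
selected best run is the one with the smallest squared error, ties broken
by lower NLL. The squared-error definition is a package decision — the
quantity is named but not defined in the task-modelling literature this
package follows — and is deliberately simple and auditable.

Group-level fitting is assumed throughout: trials are pooled over
subjects before fitting.

## Model comparison

`compare_cases()` assembles the per-case squared-error and AIC
distributions over runs and applies both the Kruskal-Wallis omnibus test
and Tukey HSD pairwise comparisons to each (runs treated as independent
observations), ranks cases by mean squared error (ties stable-sorted by
label), and reports min-max normalized parameters of each case's best run
(`normalize_params()`; a parameter constant across cases maps to 0.5 —
any constant is equally far from both endpoints, and 0.5 keeps it visibly
mid-scale in plots). Both test families are computed because significance
claims can reasonably attach to either loss surface; the report carries
both. The statistical tests delegate to `stats::kruskal.test()` and
`stats::TukeyHSD()`.

## Synthetic species-like data

`species_preset()` fixes, per species label, a coherence grid, an RT
analysis window, and a generating specification with known ground truth:

* `rat_like` — case IV, $k = 3.5$, $\sigma_0 = 1$, gain $d = 0.4$ s,
  $s_x = 5$ 1/s, $s_y = 4$, residual $0.25 \pm 0.05$ s; coherences
  10-50%; window $(0.1, 2.5)$ s. Errors are reliably *faster* than
  correct responses at every coherence.
* `monkey_like` — case II, $k = 10$, $\sigma_0 = 1$, $d = 0.35$,
  $s_x = 6$, $s_y = 3$, residual $0.3 \pm 0.05$ s; the standard
  0-51.2% doubling grid; window $(0.1, 1.65)$ s. Errors are *slower*
  than correct responses at low-to-mid coherences.
* `human_like` — case II with a small-amplitude gain ($s_y = 0.1$,
  $s_x = 2$, $d = 0.5$; $|\gamma - 1| < 0.08$ over the response window),
  $k = 7$, residual $0.35 \pm 0.07$ s; coherences 2-50%; window
  $(0.1, 2.5)$ s. Error and correct means differ by under 50 ms.

The windows and the named RT-density coherences (3.2%/12.8% monkey,
2%/12% human, 10%/50% rat) follow the source task family; the full grids
and the ground-truth parameter values are package choices committed as
fixtures and selected once to satisfy the orderings above (accuracies run
from near-chance at the hardest coherence to 0.95+ at the easiest, and
RTs fall in the species' windows). The default 2,000 trials per coherence
gives smooth empirical RT densities. `filter_rt_window()` applies the
analysis window (closed on both ends — the boundary convention is a
documented package choice), drops undecided trials, and appends to the
table's provenance attribute.

What the generator deliberately does **not** emulate: inter-subject
variability (a single generating parameter set stands for the pooled
group), lapses/contaminant RTs, response bias, and across-trial parameter
variability. Passing recovery tests on these data therefore show the
pipeline is self-consistent — they do not show that real data satisfy the
model's assumptions.

## Problem sizes and what the shipped checks show

The package's heavier self-checks run at deliberately chosen sizes: the
solver-simulator agreement sweep uses $10^5$ trials per case preset;
parameter recovery fits case IV to 20,000 case-IV trials (4,000 at each
of 5 coherences) with 6 optimization runs (population 60, up to 150
generations plus polish), recovering $k$ and $\sigma_0$ within 10%; the
end-to-end model selection check generates 5,000 rat-like trials and fits
all four cases with 6 runs each (population 24, 40 generations plus
polish), which suffices for case IV to win on mean squared error by a
factor of about 2.5 over the nearest competitor. These reduced search settings are the package's
choice of demonstration scale; for real analyses use the defaults
(18 runs, population 105, 500 generations).

## Known limitations

* The likelihood floor is a minimal robustness device; it is not a
  mixture model of contaminants, and very heavy contamination will still
  bias fits.
* Undecided-at-horizon mass is censored rather than modelled; datasets
  with many non-responses need a different convention.
* $k$ trades off against the gain amplitude $s_y$ along a shallow
  likelihood ridge (the gain is pinned to 1 only at $t = 0$);
  under-converged runs land on this ridge, which is why the multi-run
  protocol with polish, not a single run, is the supported interface.
* Biased starting points, across-trial drift variability and collapsing
  bounds are out of scope by design.
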