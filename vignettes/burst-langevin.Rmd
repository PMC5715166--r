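---
title: "Burst-aware Langevin simulation of gene expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst-aware Langevin simulation of gene expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstsim)
```

## The model

`burstsim` simulates the standard three-stage model of stochastic gene
expression. A gene switches between an inactive and an active state
(telegraph process), the active gene transcribes mRNA, and mRNA is
translated into protein; every species degrades first-order:

$$\frac{dg}{dt} = k_g\,(n-g) - \gamma_g\,g,\qquad
  \frac{dm}{dt} = k_m\,g - \gamma_m\,m,\qquad
  \frac{dp}{dt} = k_p\,m - \gamma_p\,p,$$

with $g$ the number of active copies out of $n$ (default 1), and all six
rate constants in units of inverse time (`gene_params()`). Throughout the
package's examples the protein lifetime sets the clock
($\gamma_p = 1$).

When the active state is short-lived ($\gamma_g \gg \gamma_m$) the mRNA
made during one activation arrives effectively at once: a *transcriptional
burst*. Its size is geometric with mean
$\bar b_m = k_m/(k_g+\gamma_g)$ — the kinetically consistent definition,
which makes burst frequency $\times$ burst size $/\ \gamma_m$ reproduce the
exact mean mRNA; the historical small-$k_g$ form $k_m/\gamma_g$ is kept
only as `mrna_burst_size_legacy()`. Likewise, a short-lived mRNA
($\gamma_m \gg \gamma_p$) delivers its whole translational output as a
*protein burst* of geometric mean size $\bar b_p = k_p/\gamma_m$. The two
timescale ratios define four regimes (`classify_regime()`, threshold 10,
boundary equality counting as bursting): mRNA bursts only, protein bursts
only, both, or neither.

## Burst production moments

Over a leap $\tau$ the number of molecules produced is a compound sum:
$e$ burst events of random sizes $b_l$. With events and sizes independent,

$$\Delta_y(\tau) = \bar e_y\,\bar b_y,\qquad
  \sigma^2_{\Delta y}(\tau) = \bar e_y\,\sigma^2_{b} + \sigma^2_{e}\,\bar b_y^2 ,$$

which `compose_burst_variance()` exposes directly (any event/size
distribution can be plugged in — the extension point for, say,
chromatin-modulated burst timing). With Poisson events and geometric sizes
this gives the regime-specific rows returned by `production_moments()`;
in the both-bursts case the protein burst-event count inherits the mRNA
production variance, giving
$\sigma^2_{\Delta p} = k_g \bar b_m \tau\, \bar b_p\,(2\bar b_m\bar b_p + 2\bar b_p + 1)$.

```{r}
gp <- preset("fig1")$params   # k_g 5, gamma_g 95: b_m = 2, b_p = 10
production_moments("BOTH_BURSTS", gp, tau = 0.03)[c("delta", "sd")]
```

## The Langevin updates

Each regime has an Euler–Maruyama update in which the production term is a
single Gaussian draw with the moments above, and degradation is the usual
chemical-Langevin Gaussian with mean and variance $\gamma_y y \tau$:

* **mRNA bursts** — track $(m, p)$; $m$ gets the burst draw, $p$ plain
  CLE translation/degradation; the gene state is never simulated.
* **both bursts** — track only $p$; one draw absorbs gene *and* mRNA noise.
* **protein bursts** — track $(g, p)$; the gene advances as a jump process
  and $p$ gets the burst draw at rate $g\,k_m$ with size $\bar b_p$.
* **no bursts** — plain CLE on all species, provided for completeness only;
  the exact simulator is the right tool there and `bl_simulate()` says so.

All increments are rounded to the nearest integer (half away from zero),
so states stay integer-valued.

### Step-size selection

`select_tau()` implements a tau-leaping controller with a burst-aware
bound. For a burst channel with production rate $R$ (molecules/time) and
mean size $\bar b$, the bound is $\max(\varepsilon y,\ \bar b)/R$: when
$\varepsilon y$ is small this still admits one whole burst per step instead
of degenerating into one-molecule steps. (We additionally floor the
numerator at 1 so that sub-molecular "bursts" $\bar b < 1$ fall back to the
classical $\max(\varepsilon y, 1)$ rule; no bundled preset is affected.)
Non-burst channels use the classical mean and variance bounds
$\max(\varepsilon y,1)/|\sum_j \nu_j a_j|$ and
$\max(\varepsilon y,1)^2/\sum_j \nu_j^2 a_j$. The default
$\varepsilon = 0.03$ is the common tau-leaping choice
(`step_config()`).

**Critical reactions.** Gene switching channels are always critical, and
any degradation channel of a species below `n_critical = 10` copies
becomes critical. A candidate time $\tau_c \sim
\mathrm{Exp}(\sum a_{\mathrm{crit}})$ is drawn; if $\tau_c$ undercuts the
leap bound, the non-critical channels are propagated over $\tau_c$ and
exactly one critical event (chosen proportionally to propensity) fires.
This interleaving keeps low-copy dynamics near-exact — it is why the
scheme stays accurate down to mean protein counts of a few molecules. The
burst-production channel itself is never classified critical; bursts are
precisely what the $\tau$ bound already handles.

**Half-$\tau$ retry.** If a committed step would drive a count negative
(typically a degradation overshoot at low copy number), the draws are
discarded, $\tau$ is halved and the step redrawn, up to `max_halvings`
(20). A critical event scheduled at $\tau_c$ is dropped on retry — it is
no longer due within $\tau_c/2$, and the exponential clock is memoryless.

### Removing negative production

A Gaussian production draw can round negative (with the reference
parameters at $\tau = 0.03$: mean 3, SD $\approx 13.5$, about a 40% chance,
`negative_production_fraction()`). Truncating such draws would inflate the
mean; applying them would act as spurious degradation. Instead a deficit
accumulator (`apply_negative_accumulator()`) stores the negative total and
offsets it against later draws: applied production is always
$\ge 0$, and applied + final deficit $=$ raw exactly — the mean is
preserved while the unphysical downward spikes disappear. The accumulator
is per species and only commits with the step.

### Randomness

Both integrators consume R's RNG in a fixed documented order (production
then degradation, per species, gene events via the critical channel), so
`set.seed()` — or the `seed` argument — reproduces any trajectory bit for
bit. The simulation loops are compiled (Rcpp); `select_tau()` and
`langevin_step()` expose the identical per-step logic in R and the test
suite cross-checks the two.

## Steady-state moments

`steady_state_moments()` gives the closed-form stationary mean and
variance. The exact (linear noise approximation) protein variance is

$$\sigma^2_{p} = \bar p\,\big(F_0\,\bar b_m\,\bar b_{p0} + \bar b_{p0} + 1\big),
 \qquad \bar b_{p0} = \frac{k_p}{\gamma_m + \gamma_p},$$

with correction fractions $F_0, F_1, F_2 \in (0, 1]$ that tend to 1 under
timescale separation. The regime approximations drop those fractions
(and use $\bar b_p$ where $\gamma_m \gg \gamma_p$); they are exactly the
stationary variances of the corresponding Langevin equations.
`variance_error_map()` scans $(\gamma_g, \gamma_m)$ at fixed burst sizes
and reports the normalized SD error of the approximation against the exact
value: $+12.5\%$ at the corner of the mRNA-burst region, under $6.5\%$
everywhere in the both-bursts region, under $5\%$ in the protein-burst
region, zero where nothing bursts (no approximation is made there). Since
the default map holds $k_g \bar b_m \bar b_p$ fixed, $\bar p = 100$ across
the whole map. The map grid (50 × 50, logarithmic over
$\gamma_g \in [1, 10^3]$, $\gamma_m \in [1, 10^2]$) is our choice; the
error surface is smooth, so the resolution only matters near region
boundaries, and the region maxima sit at corners that the default grids
contain exactly.

## The regulated two-gene network

`regulated_network()` couples an upstream protein $p_1$ to a downstream
gene through a Hill function with threshold $K$ and coefficient $n_H$
(negative $n_H$ = activation), plus a leak rate $k_l$. We treat $k_l$ as a
*leak transcription rate* added to the Hill-modulated transcription:
effective transcription while active is $k_{m2} H(p_1) + k_l$, hence an
effective downstream mRNA burst size
$(k_{m2} H(p_1) + k_l)/(k_{g2} + \gamma_{g2})$. With the bundled network
preset this reproduces the documented fully-activated level
($5 \cdot (260/105) \cdot 10 \approx 124$, basal $\approx 29$); reading
$k_l$ as a burst size instead would contradict those levels, which is why
the rate reading is adopted. Both simulators use the same convention, so
it cancels from every Langevin-vs-exact comparison. In the Langevin
network driver both genes run in both-bursts mode; $p_1$ is held constant
within a step ($\tau$ is the minimum of both species' bounds), and
upstream noise reaches $p_2$ only through the simulated $p_1$ trajectory —
no analytic cross-covariance is added.

## Validation protocols and problem sizes

The drivers in `ensemble_steady_state()` support two stationary-sampling
protocols. *Replicas* runs independent trajectories (seeds
`seed_base + 0, 1, ...`) from the rounded deterministic fixed point and
reads each at `t_relax` (default $20/\gamma_p$ — at least twenty times the
slowest relaxation time in every bundled preset); it yields independent
points and histograms. *Time-average* runs one long trajectory and
accumulates exact time integrals of $p$ and $p^2$ after burn-in, with
standard errors from 50 batch means; for mean/SD comparisons it extracts
far more information per simulated event. The grid experiments
(`mean_error_grid()`, `network_error_grid()`) therefore default to the
time-average protocol, with per-cell averaging windows sized *a priori*
from the closed-form variances so that the Monte-Carlo stderr of the mean
is a small fraction of the error bounds under test (relative targets
0.2–0.5%) and every cell integrates over at least 2000 correlation times,
i.e. at least as much information as 2000 independent replicas. Monte-Carlo
stderr is reported per cell and folded into every tolerance in the test
suite. The bimodal and histogram comparisons use the replica protocol
(800–2000 replicas), and the switching-dynamics comparison uses 400–2000
trajectories per simulator on a 0.25-lifetime sampling grid.

What the bundled presets emulate — and what they do not: they are the
parameter sets of the validation figures of the source study
(burst sizes 1–30 and 1–100, protein means 3–15000, a repression network
with threshold 200 and Hill coefficient 3, a transient activation pulse).
They probe intrinsic noise of the fixed-form model only: no extrinsic
noise, no cell division or growth dilution, no chromatin-state waiting
times, no resource competition between genes. Agreement on these presets
shows the integrator reproduces the model's statistics, not that the model
captures any particular organism.

## Numerical choices and limitations

* Production *and* degradation draws are rounded to nearest integer; the
  rounding convention at half-integers is away from zero, so a draw of
  exactly $-0.5$ counts as negative production.
* Degradation uses the Gaussian CLE form in all Langevin modes; explicit
  event/size sampling of bursts is available in spirit through the exact
  simulator, which is the reference everywhere.
* In the protein-burst and no-burst modes (gene tracked), $\tau$ is also
  capped at $0.1/\max(k_g, \gamma_g)$ so the gene is effectively constant
  within a step even between critical events.
* The Langevin scheme's stationary SD inherits the burst-approximation
  bias (up to $\approx 14\%$ near regime margins, e.g. at
  $k_g \sim \gamma_g$); its *mean* is accurate to within $\sim 2\%$
  whenever the mean protein count is at least a few molecules. Below that,
  the Gaussian production approximation degrades and the exact simulator
  should be used.
* Fano factors below 1 (sub-Poissonian noise) cannot arise in this model
  family; the geometric burst-size assumption is built in, with
  `compose_burst_variance()` as the seam for replacing it.
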