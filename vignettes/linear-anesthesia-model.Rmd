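---
title: "A linear excitatory-inhibitory population model of anesthetic EEG spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A linear excitatory-inhibitory population model of anesthetic EEG spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anespec)
```

## The model

`anespec` analyses the spatially constant mode of a two-population neural
field: mean excitatory and inhibitory post-synaptic potentials coupled
through sigmoidal firing rates, with single-exponential synaptic responses of
decay times $\tau_1$ (excitatory) and $\tau_2$ (inhibitory). Small
fluctuations $(x, y)$ of the two potentials about a stationary state obey the
linear system

$$
\tau_1 \dot x = (N_1 - 1)\,x - N_1\, y + \gamma(t), \qquad
\tau_2 \dot y = N_2\, x - (N_2 + 1)\, y,
$$

where $N_1, N_2 \ge 0$ are the dimensionless synaptic gains (efficacy
$\times$ rate-function slope $\times$ total kernel weight) and $\gamma$ is
white noise, $\langle\gamma(t)\gamma(t')\rangle = 2D\,\delta(t-t')$, acting
on the excitatory line only. The excitatory fluctuation $x(t)$ is the EEG
proxy: scalp potentials are dominated by currents at the (more numerous,
apically aligned) excitatory synapses.

Propofol prolongs the decay of inhibitory GABA$_A$ post-synaptic currents
while leaving the response amplitude roughly constant, so the charge
transfer grows. With the concentration factor $p \ge 1$ ($p = 1$ drug-free)
this is modelled as

$$
\tau_2(p) = \tau_2(1)\,p, \qquad N_2(p) = N_2(1)\,p .
$$

`effective_params()` applies this scaling; the switch `scale_N2 = FALSE`
freezes the gain and scales only the decay time, because one strand of the
stability discussion implicitly assumes a $p$-independent $N_2$. The default
scales both.

The biophysical layer beneath the gains (`stationary_state` functions
`solve_fixed_point()`, `gains_from_fixed_point()`) solves the scalar
fixed-point equation for the effective potential $V_- = V_e^0 - V_i^0$ and
differentiates the rate functions there. No published numeric values exist
for the efficacies, kernels or sigmoid slopes at this level, so it is
validated by self-consistency (all bracketed roots returned, analytic vs
central-difference derivatives); headline analyses parameterize
`model_params()` directly with gain/decay-time values. The logistic family
is the default rate function, the standard choice in the neural-field
literature; an identity family supports analytically solvable checks.

## Stability geometry

The $2\times2$ system matrix has trace
$\mathrm{Tr} = (N_1-1)/\tau_1 - (N_2+1)/\tau_2$ and determinant
$\det = (N_2 - N_1 + 1)/(\tau_1\tau_2)$. Eigenvalues $R \pm i\Omega$ follow
from the characteristic polynomial; the package always computes
$\Omega^2 = \det - \mathrm{Tr}^2/4$, which is algebraically identical to the
expanded form in the reduced variables

$$
a = (N_1-1)^2,\quad b = N_1 N_2 - N_1 + N_2 + 1,\quad c = (N_2+1)^2 :
\qquad
\Omega^2 = \frac{1}{4\tau_1^2}\left( \frac{2b\,\tau_1}{\tau_2} - a -
\frac{c\,\tau_1^2}{\tau_2^2}\right).
$$

Complex eigenvalues therefore exist exactly for ratios $r = \tau_2/\tau_1$
strictly between the roots of $a r^2 - 2 b r + c = 0$ (`focus_band()`), a
non-empty interval iff $b^2 > ac$. The trace changes sign at
$r = \sqrt{c/a} = (N_2+1)/(N_1-1)$, which is the *geometric mean* of the two
band edges and hence always interior to a non-degenerate band: stable foci
occupy the band's lower part, and stability can only be lost when
$N_1 > 1$.

Differentiating $\Omega^2(r)$ gives a unique interior maximum at
$r^\ast = c/b$ with $\omega_m = \sqrt{b^2/c - a}\,/(2\tau_1)$
(`max_frequency()`). Some presentations quote the inverted ratio $b/c$ for
the argmax; direct differentiation and a grid-plus-golden-section
maximization oracle both give $c/b$, which the package uses. A further
consequence of the geometric-mean identity is that $c/b < \sqrt{c/a}$
whenever the band exists, so along the stable range the eigenfrequency
*always* rises to the interior turning point $c/b$ and falls beyond it
(`omega_monotonicity()` classifies this by sign-sampling, not by formula; a
monotonic branch is retained in code but cannot trigger for a valid band).

`hopf_locus()` inverts the threshold relations: on the trace-zero locus
$\Omega^2\tau_1^2 = (N_2 - N_1 + 1)(N_1-1)/(N_2+1)$ increases in $N_2$
toward the supremum $N_1 - 1$, so a requested frequency $f$ is attainable
iff $(2\pi f \tau_1)^2 < N_1 - 1$; the solver brackets $N_2$ with
`uniroot()` (tolerance $10^{-12}$) and reports the locus point
$(N_1, N_2, \tau_2)$, verified downstream by eigendecomposition.

## The analytic spectrum and its peak

For a stable focus the Green's function of $x$ is
$G_{11}(t) = e^{Rt}\left(\frac{R - Z}{\Omega}\sin\Omega t + \cos\Omega t\right)\Theta(t)$
with $Z = -(N_2+1)/\tau_2 < 0$; it jumps to 1 at $t = 0^+$ and rings at
$\Omega$ with damping $|R|$. The noise convention places $\gamma$ directly
on $\dot x$ (no extra $1/\tau_1$ factor), the same convention the simulator
uses, so analytic and estimated spectra are directly comparable. The
two-sided spectral density per rad/s is

$$
S(\omega) = \frac{D}{\pi}\,
\frac{Z^2 + \omega^2}{(M - \omega^2)^2 + 4R^2\omega^2},
\qquad M = R^2 + \Omega^2 .
$$

Setting $dS/d\omega^2 = 0$ gives a single quadratic in $u = \omega^2$ whose
admissible root is

$$
\Omega_\text{peak}^2 = -Z^2 + \sqrt{(M + Z^2)^2 - 4 Z^2 R^2},
$$

an interior maximum whenever the right-hand side is positive, i.e.
$R^4 + 2R^2(\Omega^2 - Z^2) + \Omega^2(\Omega^2 + 2Z^2) > 0$; otherwise the
density is maximal at $\omega = 0$ (`peak_frequency()`). A frequently quoted
alternative expression,
$\Omega_\text{peak}^2 = \Omega^2 + R^2\bigl(1 - 4Z^2/(M+Z^2)\bigr)$, agrees
with the true argmax only in the weak-damping limit $R \to 0^-$ (both tend
to $\Omega$) and deviates already at order $R^2$; at the alpha-band
reference point below it gives 54.97 rad/s where the density actually peaks
at 55.28 rad/s. It is provided as `peak_frequency_printed()` for comparison
but carries no analytical weight. `peak_frequency_grid()` (dense grid of
$10^5$ points refined by golden section) is the independent oracle; closed
form and grid agree to $10^{-6}$ relative on a thousand random foci in the
test suite.

How the peak moves with $(R, \Omega)$ at fixed $Z$ is computed by central
finite differences of the closed form (`peak_gradient_signs()`), because the
printed inequality conditions for these signs are unusable (one is
tautological). Two verified regimes: for $\Omega \gg |Z|$ the peak sits just
above $\Omega$ and relaxes *down* onto it as damping vanishes
($\partial\Omega_\text{peak}/\partial\Omega > 0$,
$\partial\Omega_\text{peak}/\partial R < 0$), while for moderate
$\Omega \sim |Z|$ both derivatives are positive. The claim that both signs
are positive at large $\Omega$ does not survive differentiation of either
peak expression and is not asserted anywhere.

Conservation is checked two ways that never share code:
`spectrum_variance()` integrates $S$ by adaptive quadrature with the
analytic $D/(\pi\omega^2)$ tail beyond the cutoff, and
`lyapunov_variance()` solves $AP + PA^\top + \mathrm{diag}(2D, 0) = 0$ via
the Kronecker system; they agree to $10^{-6}$ relative on all stable
fixtures.

## Anesthetic response and the critical factor $p_0$

Under the joint scaling, increasing $p$ weakens the damping monotonically
for $N_1 > 1$ — every sweep drives the system toward the oscillatory
instability, whose onset $p^\ast$ (`instability_onset()`) is refined by
bisection on the trace to $10^{-10}$. The closed-form critical factor

$$
p_0 = \bigl(N_2(1) + \tau_2(1)(N_1-1)/\tau_1\bigr)^{-1}
$$

classifies the frequency response (`classify_regime()`): $p_0 < 1$ predicts
$d\Omega^2/dp > 0$ for all $p$; $p_0 \ge 1$ predicts a non-increasing
interval $1 \le p \le p_0$. At the stability-threshold ratio the closed form
reduces algebraically to $p_0 = 1/(2N_2(1)+1) < 1$: near-threshold systems
always shift their ringing frequency upward with concentration.

The package deliberately runs a second, independent track: the exact
derivative of $\Omega^2(p) = \det(p) - \mathrm{Tr}(p)^2/4$ under the joint
scaling is

$$
\frac{d\Omega^2}{dp} = \frac{1}{\tau_2(1)\,p^2}
\left(\frac{N_1 - 1}{\tau_1} - R(p)\right),
$$

which is strictly positive for any stable focus with $N_1 > 1$ — it never
vanishes, so the numerical track (`p0_numeric()`, central differences plus
root refinement) generically reports *no* critical point even where the
closed-form track predicts a decrease interval. The two tracks rest on
different intermediate algebra and cannot both be right; rather than guess,
every report carries both values and an agreement flag, and the
classification rule binds to the closed-form track. The `figure_data("p0_plane")`
export tabulates both sign fields side by side.

`sweep_p()` runs the whole pipeline per concentration (default grid
$p \in [1, 1.3]$, step 0.01 — the clinically reasonable range); entries
beyond $p^\ast$ are flagged invalid rather than extrapolated.
`covariation_check()` tests the headline prediction: on every stable sweep
interval where the peak power rises, the peak frequency rises too. This
holds on all random fixtures exercised in the suite.

## Stochastic simulation and spectral estimation

`euler_maruyama()` integrates the system with the first-order
Euler-Maruyama scheme (the compiled core is a two-line recursion; noise
increments $\kappa\sqrt{\Delta t}\,\eta_n$ are drawn from R's seeded RNG, so
runs are reproducible bit for bit). Defaults are the headline experiment:
$\Delta t = 0.05$ ms, 200 s, $\kappa = 0.01$ mV, display trace
$x(t) + V_e^0$ with $V_e^0 = -60$ mV. The noise strength maps to the
analytic intensity as $D = \kappa^2/2$, which makes the
$\langle\gamma\gamma\rangle = 2D\delta$ convention and the per-step
increment consistent; this link is a modelling convention of the package
(`noise_D` is set explicitly wherever it matters).

Two numerical properties of the explicit scheme matter for validation and
are the reason the deterministic-limit tests choose their own step: the
scheme under-damps by $\approx \Omega^2\Delta t/2$ and advances phase with a
relative error $\approx |R|\Delta t$. The test suite bounds both below 1% of
the quantity being recovered.

`welch_psd()` averages Hann-windowed, demeaned segment periodograms,
normalized so the spectral integral equals the time-domain variance
(density per Hz, one-sided). The default 10 s segments resolve 0.1 Hz. For
*peak-location* comparisons the package uses 2 s segments instead: the
analytic peak at the alpha-band reference point has half-width
$|R|/2\pi \approx 0.9$ Hz, and an argmax over 0.1 Hz bins inside such a
broad peak wanders by several bins from seed to seed no matter how long the
run; matching the bin width (0.5 Hz) to the peak width is the usual
bias-variance trade for broad spectral peaks and brings the seed-to-seed
scatter under one bin at 50-200 s. `compare_spectra()` reports the peak
offset in bins, the integrated-power ratio and band powers (delta 1-4,
alpha 8-13, beta 13-30 Hz — conventional boundaries, configurable).

## Reference parameterization and worked numbers

The alpha-band reference point used throughout the documentation and tests
is $N_1 = 1.1$, $N_2(1) = 0.2236$, $\tau_1 = 2$ ms, $\tau_2(1) = 20$ ms:

```{r}
mp <- model_params(1.1, 0.2236, 0.002, 0.02, noise_D = 0.01^2 / 2)
eigen_closed_form(jacobian_summary(mp))
sc <- transfer_scalars(mp)
c(peak_rad_s = peak_frequency(sc), peak_hz = peak_frequency(sc) / (2 * pi))
sweep_p(mp)[c(1, 21, 31), ]
attr(sweep_p(mp), "p_star")
```

Damping $-5.59$ s$^{-1}$, ringing at 8.80 Hz, spectral peak at 8.80 Hz,
instability onset near $p^\ast \approx 1.288$; between $p = 1$ and the
onset both the peak power and the peak frequency rise. A companion
parameterization with $N_2(1) = 0.25128$ (decay-time ratio 10) rings at
9.74 Hz; its published description places it in the delta band, which its
own gain/decay values contradict — the package reproduces the values
verbatim and reports whatever band results.

## Numerical choices and degenerate inputs

* Internal units are SI seconds and rad/s; user-facing summaries also print
  Hz. Complex pairs are always reported with $\Omega \ge 0$.
* `sq_a`, `sq_b`, `sq_c` name the reduced gain variables to avoid collision
  with the synaptic efficacies, which the field also calls $a$.
* Degenerate double roots ($\det = \mathrm{Tr}^2/4$) are classified
  `stable_node` with $\Omega = 0$; the Green's function switches to the
  $(1 + (R-Z)t)e^{Rt}$ limit branch.
* The $\omega = 0$ boundary of the peak search is itself a stationary point
  of the (even) density, so the grid oracle keeps 0 unless an interior
  candidate wins by more than $10^{-9}$ relative — otherwise floating-point
  ties would report spurious tiny peaks.
* Fixture generation (`generate_fixtures()`) rejection-samples gains and
  $\tau_1$, then places $\tau_2/\tau_1$ by rule: uniformly over the stable
  part of the focus band (0.5% relative margin off the edges, where the
  eigenpair is ill-conditioned), exactly on the trace-zero locus, or
  outside the band. Placement is verified by the independent
  eigendecomposition classifier in the tests.
* Problem sizes in the shipped suite: $10^3$ fixtures for the eigen and
  peak dual-path checks, $10^2$ for variance conservation and sweep
  properties, 200 s simulations for spectral comparisons, 50 s for
  seed-scatter measurements.

## What the synthetic data does and does not show

The generator emulates the model's own study conditions — random stable
parameter sets and the reference gain/decay values — not empirical EEG. It
contains no 1/f background, no measurement forward model, no transients,
no multi-rhythm superposition, and the noise is white. Passing tests
therefore demonstrate internal consistency of the analytics and the
simulator under the model's assumptions; they say nothing about fits to
recorded anesthesia EEG. Known structural limits: a single two-population
module describes one rhythm only (no coexisting delta and alpha peaks),
axonal delays and spatially resolved modes are outside scope, and $p$ is an
abstract scaling factor, not a pharmacokinetic concentration.
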