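---
title: "Models and methods behind chemorace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chemorace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemorace)
```

## The scientific question

*E. coli* navigates chemical gradients by biasing a run-and-tumble walk:
near-straight runs at speed $u \simeq 15\,\mu$m/s interrupted by brief
reorientations with mean scattering cosine
$\langle\cos\varphi\rangle \simeq 0.3$. The tumbling machinery adapts: after
a step of attractant the tumbling frequency relaxes back to its pre-stimulus
value. Adaptation is *precise* for aspartate (sensed mainly by Tar) but not
for serine (sensed mainly by Tsr), whose background concentration lengthens
runs persistently — roughly 2.1-fold at 3 mM relative to the
$\simeq 1.15$ s attractant-free mean. `chemorace` implements the
linear-response theory of how this (im)precision affects the speed of
gradient climbing, an agent-based simulator of bacteria racing up
microfluidic channel gradients, a drift–diffusion continuum counterpart, and
the trajectory/front statistics used to quantify both, together with a
synthetic-data generator so that the entire pipeline is testable without any
external data.

## Linear-response theory (`theory_core`)

The impulse response of the running probability to a unit concentration
pulse is modelled by the bilobed kernel

$$K(t) = K_0\,\lambda e^{-\lambda t}\Big[\lambda t -
  \tfrac{1-A}{2}(\lambda t)^2\Big],$$

whose time integral is $K_0 A$: the adaptation-defect parameter $A$
quantifies the imbalance of the positive and negative lobes, with $A = 0$
precise adaptation and $A \simeq 0.03$ the serine-like defect. In a shallow
static gradient the drift velocity is $v = \chi\,\partial_x c$ with

$$\chi = \frac{\alpha u^2}{3\sigma^2}\int_0^\infty e^{-\sigma t}K(t)\,dt
       = \frac{K_0 u^2\alpha}{3\sigma^2}\,
         \frac{\lambda^2(\sigma + A\lambda)}{(\sigma+\lambda)^3},$$

where $\alpha = (1-\langle\cos\varphi\rangle)/\tau_r$ and
$\sigma = 2D_{rot} + \alpha$ are the tumbling and total direction
decorrelation rates (three-dimensional convention; the $1/3$ is the 3-D
projection factor). Both the quadrature form (any kernel) and the closed
form are implemented and cross-checked to $10^{-8}$ relative over random
parameters. The bracket is maximized over the memory rate at
$\lambda^* = 2\sigma/(1-3A)$; the ratio of maximized brackets at
$A = 0.03$ versus $A = 0$ is $\sigma$-independent and equals $1.0628$,
i.e. a $\approx 6.3\%$ velocity advantage from breaking adaptation. The
comparison convention (each $A$ at its own optimal $\lambda$) is a package
decision: the bracket-ratio definition is the only one that is parameter-free
and scale-invariant, and it lands in the 6–7% range conventionally rounded
to "about 7%".

The kernel amplitude depends on the motor operating point through

$$K_0 \propto \frac{a(1-a)\,h'(y)\,(1-y)}{h(y)(1-h(y))},\qquad
  y = \frac{a}{a+K},$$

with $a$ the CheA-P fraction, $y$ the CheY-P fraction and $h(y)$ the
clockwise-bias motor curve. For a Hill curve
$h = [1+(y/y_0)^{-H}]^{-1}$ the expression collapses to $HK(1-a)$ (maximal
at zero activity); for the allosteric form
$h = 1/[1 + C((1+y/K_1)/(1+y/K_2))^n]$, $K_1 > K_2$, the amplitude peaks at
an interior activity below one half. The proportionality constant is fixed
to 1: this amplitude is used only for shape and argmax statements and is
never mixed with the µM-calibrated amplitude of the sensing kernels. The
allosteric defaults ($C=4$, $n=6$, $K_1=0.5$, $K_2=0.1$, $K=0.3$) were
chosen once as a generic conformational-spread-like parameterization and
verified to satisfy the interior-peak property; nothing downstream depends
on their exact values.

## Agent-based simulator (`rt_simulator`)

Agents carry a position, a unit direction, a run/tumble phase and a sensing
state. Per time step (default $dt = 0.02$ s, enforced
$dt \le 0.02\,\min(\tau_r, 1/\lambda)$):

* **Runs** advance the position by $u\,dt$ and diffuse the direction on the
  unit sphere so that $\langle d(t)\!\cdot\!d(0)\rangle = e^{-2D_{rot}t}$.
* **Sensing** convolves the locally sampled concentration with the kernel.
  The bilobed kernel is exactly representable by three exponential-filter
  states (moments of $e^{-\lambda t}$), updated by a closed-form recursion
  with the concentration held constant over the step — no history buffers,
  and in a uniform concentration the output converges exactly to the kernel
  integral times the concentration, $Q_{ss} = K_0 A c$.
* **Tumbling** occurs at rate
  $r = \mathrm{clip}\big((1-Q)/\tau_{loc},\,0,\,10/\tau_{loc}\big)$, where
  $\tau_{loc} = \tau_r\,m(c)$ and $m(c)$ is the measured run-time
  modulation curve (piecewise log-linear between anchors, clamped outside).
  The rate law is one consistent microscopic realization of the linear
  kernel response; its drift was verified against the closed-form $\chi$
  (below). Tumbles are instantaneous by default (the decorrelation rate
  $\alpha$ carries no tumble-time correction); a finite duration is
  available and used by the assay generator.
* **Reorientation** draws $\cos\varphi$ from the linear-tilt density
  $(1+b\cos\varphi)/2$ with $b = 3\langle\cos\varphi\rangle$ — the simplest
  one-parameter family on $[-1,1]$ matching the only measured quantity, the
  mean cosine (hence $\langle\cos\varphi\rangle \le 1/3$; the measured 0.3
  is inside).

**Double-counting guard.** A non-adapted kernel ($A>0$) shifts the *steady*
tumbling rate, which is the same physiology the measured modulation $m(c)$
reports. When a measured modulation is supplied, the sensing model therefore
rescales the local baseline by $(1-Q_{ss}(c))$ (`dc_comp`), so the realized
steady-state run time in a uniform medium is exactly $\tau_r m(c)$ while
the full kernel still drives the response to motion. With `dc_comp` off the
raw rate law is exactly the object the closed-form $\chi$ describes; that is
the configuration used for theory validation.

**Weber-type sensing.** Along a linear gradient spanning three decades the
response amplitude cannot stay fixed. In `weber` mode the amplitude is
evaluated at the agent's current background,
$K_{0,\mathrm{eff}}(c) = K_0\,c_{ref}/(c+c_{eps})$ with defaults
$c_{ref} = 100$, $c_{eps} = 1$ µM — a local linearization of a relative
(fold-change) response. The functional form is a package decision; only the
qualitative consequence (sensitivity falls as bacteria climb) is used.

**Validation against the theory.** `validate_against_theory()` measures the
ensemble drift in a shallow linear gradient (absolute sensing, $m\equiv 1$)
and compares it to $\chi\,\partial_x c$. Agreement holds in the genuinely
linear regime; two documented nonlinearity scales are monitored and reported
as a warning metric: the dynamic response $K_0\,|\partial_x c|\,u/\lambda$
and, for $A>0$, the background response $K_0 A c_0$ (a large value shifts
the local baseline run time, so the local $\chi$ no longer equals the
$\tau_r$-evaluated one; at $K_0 A c_0 = 0.15$ the excess reaches tens of
percent, at $\le 0.075$ it is within Monte-Carlo error).

**Race assay.** The lateral channel is a 4000 × 725 × 300 µm box: linear
gradients 0→1 mM, reflecting side walls, an absorbing reservoir at
$x = L$, and an entry face at $x = 0$ through which agents are injected by
a Poisson source at the one-way kinetic flux $n_0 u A_\perp/4$ of the
maintained injection-channel density $n_0$ (default
$4\times10^{7}$ bacteria/ml) with cosine-law inward directions; agents
wandering back across the entry face leave the system and are counted, as
are absorbed ones (the bookkeeping conserves the total). New agents enter
adapted to the entry concentration. Snapshots of in-channel positions are
recorded every 5 simulated minutes.

## Continuum model (`continuum_model`)

The 1-D (cross-section homogenized) density obeys
$\partial_t\rho = \partial_x(D\,\partial_x\rho) - \partial_x(v\rho)$ with
$D = u^2/(3\sigma)$, $v = \chi\,\partial_x c$, a maintained source density
$\rho(0) = \rho_0$ and an absorbing reservoir $\rho(L) = 0$. The solver is
a Crank–Nicolson finite-volume scheme with central face fluxes; the grid is
auto-refined until the cell Péclet number $|v|\,\Delta x/D < 2$, and face
fluxes are bookkept so the discrete mass balance holds to round-off. The
stationary profile is computed independently by the quadrature form
$\rho(x) = J\int_x^L e^{\Phi(x)-\Phi(s)}/D(s)\,ds$,
$\Phi = \int v/D$, which for constant coefficients reduces to
$\rho = (J/v)(1-e^{v(x-L)/D})$ — the oracle used in the tests (the solver
matches it to better than $10^{-3}$ relative).

The continuum rank-$k$ front $x_k(t)$, defined by inverting the progression
function $N(x,t) = \int_x^L\rho$, reproduces the saturation mechanism:
while all bacteria advance, the front advances with them; once absorption
into the reservoir balances injection the density becomes stationary, the
progression function freezes, and $x_k$ plateaus, deeper ranks plateauing
farther back.

`consumption_distortion()` bounds the bending of the linear gradient by
bacterial uptake: the steady balance $D_{attr}c'' = q\rho_b$ with pinned
end concentrations gives, for uniform $\rho_b$, a parabolic deviation with
midpoint magnitude $q\rho_b L^2/(8D_{attr})$. The headline scalar is the
midpoint deviation relative to the midpoint linear value: the entry-side
ratio diverges trivially as the linear profile goes to zero and is not a
useful summary. At the experimental density the relative distortion is
below $10^{-6}$ — negligible, which is why the transport solve never
couples back onto the gradient.

## Trajectory analysis (`track_analysis`)

Segmentation labels a frame interval a tumble when its speed falls below
`speed_frac_threshold` (default 0.5) times the track median — with an
absolute 2 µm/s floor that catches non-motile stretches — or when the
direction change exceeds `turn_threshold` (default 1 rad/frame); runs are
the maximal complements, and runs touching the track ends are censored.
At the default 10 Hz and 0.3 µm localization noise, raw per-frame speeds
carry ≈4 µm/s of noise, so positions are smoothed by a 3-frame running
mean before thresholding (detection only; reported times stay on the frame
grid). Estimators apply documented corrections, each testable in isolation:

* **Run times**: half a frame interval restored per detected boundary, and
  a left-truncation floor (two frame intervals by default at 10 Hz, the
  shortest detectable run) subtracted from the mean — exact for exponential
  run times, for which $E[T \mid T > c] = c + \tau$. Fold changes are
  always taken against a baseline *measured by the same pipeline* (the
  attractant-free assay), so residual multiplicative detection bias cancels
  — this mirrors the experimental normalization to the ≈1.15 s
  attractant-free mean.
* **Run speeds**: per-bacterium root-mean-square frame displacement inside
  runs (boundary intervals excluded), de-biased by the known localization
  variance ($4\sigma_{loc}^2$ per displacement), corrected for finite-frame
  chord shortening by rotational diffusion (<1% at 10 Hz), and — only for
  true 3-D-projected tracks — multiplied by the stereological
  $\sqrt{3/2}$ ($E[\sin^2\theta] = 2/3$). Population mean and SD are over
  per-bacterium means, matching the assay's error-bar convention.
* **Turn angles**: the mean tumble cosine is estimated as a noise-corrected
  ratio of displacement dot products around each detected tumble, with a
  one-frame guard band absorbing boundary placement uncertainty. The naive
  mean of per-event angle cosines is biased low by ≈0.1 under these noise
  levels; the dot-product ratio is unbiased under projection (verified by
  simulation) up to a small (−0.02) rotational-diffusion lag.

## Synthetic data (`synthetic_data`)

The generator emulates the two assay types with the statistical structure
the analysis assumes, under the study conditions: homogeneous tracking
assays (uniform attractant; 10 Hz; 0.3 µm localization noise; fixed 0.2 s
tumbles so stops are visible to speed filtering; per-bacterium speeds
$\mathcal{N}(15, 5.5^2)$ µm/s truncated at 2, matching the printed 5–6 µm/s
population SDs; 120 s tracks, long enough that the $\sim\tau^2/T$
end-censoring bias of completed-run averages is below the noise floor) and
five-replicate race assays (full channel geometry, 2 h default duration,
5-minute snapshots, replicate seeds derived from the master seed).

Tracking assays are generated as *quasi-planar* (near-surface) swimming:
the tumble-angle cosine law is unchanged (random sign in the plane) and the
in-plane angular diffusion is set so the direction correlation decays at
the same $e^{-2D_{rot}t}$ as the 3-D walk. This emulates what 2-D tracking
microscopy actually images — bacteria swimming along the coverslip. A naive
projection of isotropic 3-D swimming would contain runs pointing near the
optical axis with arbitrarily small projected speed, which fragment under
any threshold segmentation; no real 2-D pipeline faces that regime. The
race simulation remains fully 3-D.

Condition presets encode the four experimental arms. The modulation anchors
are the measured normalized run times (serine: 1.0 at 1 µM → 2.1 at 3 mM;
aspartate with 30 µM serine background: 1.7 at 1 µM → 2.1 at 100 µM,
clamped outside since the background dominates below 1 µM); presets
reproduce them exactly at the anchors by construction (`dc_comp`). Kernels:
aspartate $A = 0$ (precise), serine $A = 0.03$, aspartate+background
$A = 0.03$ (the background breaks adaptation to aspartate; the defect
magnitude is a package decision, set equal to serine's). Two amplitudes are
package calibrations, not measurements: $K_{0,asp} = 0.04/\mu$M, set so the
simulated aspartate front advances at order 1 µm/s, and
$K_{0,ser} = 3 K_{0,asp}$, encoding the strain's stronger sensitivity to
serine (Tsr outnumbers Tar roughly 2–3:1) at the level needed for the four
arms to separate in front slope; absolute front speeds therefore carry no
quantitative meaning here — only the ordering
serine > aspartate+background > aspartate > no-gradient control does.

## What passing tests do and do not show

The generator draws exponential run times, a fixed tumble duration, a
single-mode speed distribution, uncorrelated Gaussian localization noise
and perfectly linear static gradients. Real data add run-time
heterogeneity beyond exponential, speed–tumble correlations, imaging
artifacts (the experimental stitched frames superimpose 20 exposures, which
can duplicate moving bacteria — ignored here), flow disturbances near the
junction, and growth. Recovery of generator ground truth therefore
validates the estimators and the internal consistency of theory, simulator
and continuum model — not the biology of any particular dataset.

## Problem sizes and numerical choices

Deterministic tolerances: kernel quadrature to $10^{-12}$ absolute on
$[0, 40/\lambda]$; closed-vs-quadrature $\chi$ to $10^{-8}$ relative;
PDE steady state to $10^{-3}$; amplitude argmax by a 2001-point grid scan
refined by golden-section search. Endpoints of the amplitude formula are
evaluated at $a = 10^{-9}$ and $1-10^{-9}$. Seeds fix every random stream;
identical configurations are bit-reproducible.

Stochastic checks run at sizes chosen to keep the whole suite fast while
leaving clear statistical margins: tracking assays with 300–500 tracks of
120 s; theory-vs-simulation drift at 5000 agents × 300 s per parameter
point (gradient 0.01 µM/µm, backgrounds keeping both nonlinearity metrics
≤ 0.075); races for the ordering check at entry density
$10^{-5}/\mu$m³ (a quarter of the experimental density — order statistics
shift back but ordering and separations are preserved, as verified at both
scales) over 35 min with slopes fitted on the first 30 min at rank
$k = 40$ — the deepest of the three experimental ranks, least dominated by
the diffusive tail of the front — five replicates per arm.

## Known limitations

* The rate law $r = (1-Q)/\tau_{loc}$ is one microscopic choice consistent
  with the linear kernel; alternatives (e.g. exponential rate modulation)
  coincide at linear order only.
* Theory agreement for $A > 0$ is restricted to small background response
  $K_0 A c_0$; outside it the measured point-release drift exceeds the
  local-linear prediction for real physical reasons (baseline run-time
  drift along the gradient).
* The Weber form, the tumble-angle family beyond its mean, the
  aspartate+background defect magnitude and the µM amplitude calibrations
  are package decisions; conclusions that depend on them are qualitative.
* No hydrodynamics, growth, division, cell–cell interaction, or coupling of
  consumption back onto the gradient.
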