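---
title: "Seasonal flux attenuation in an explicit-detritus ocean model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal flux attenuation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seapump)
```

## The model

`seapump` studies how seasonal variability in particle-flux attenuation and
sinking speed shapes organic-carbon export, transfer efficiency (TE) and
nutrient distributions. Its core is the Martin power law
$F(z) = F(z_0)\,(z/z_0)^{-b}$, which is the exact annually averaged steady
state of an advection–reaction balance for detritus sinking with a
depth-linear speed $w(z) = a z$ and decaying at a constant rate
$\lambda$, with $b = \lambda/a$. An explicit-detritus model therefore
*imposes* an exponent $b^{\mathrm{model}}$ through $a = \lambda/b$; the
exponent *diagnosed* by fitting the power law to simulated fluxes is an
emergent property and equals the imposed one only without circulation.

Seasonality enters as a cosine perturbation of the imposed exponent,

$$b(t,\varphi) \;=\; b_{\mathrm{ref}} \mp \delta b \,
  \cos\!\left(\tfrac{2\pi t}{T} + \tfrac{\theta\pi}{6}\right),$$

with the minus sign in the Northern Hemisphere, plus sign in the Southern
(the cycle follows local seasons) and no perturbation on the equator; the
year has $T = 360$ days (twelve 30-day months) and $\theta$ is a phase in
months. The sinking coefficient becomes $A(t) = \lambda / b(t)$ and the
sinking speed $W(z,t) = A(t)\,z$. Because $1/b$ is convex, the annual mean
of $A$ is biased fast,

$$\overline{A} = \frac{\lambda}{\sqrt{b_{\mathrm{ref}}^2 - \delta b^2}}
  \;\ge\; \frac{\lambda}{b_{\mathrm{ref}}},$$

so a symmetric seasonal cycle in $b$ acts, on annual average, like a
*smaller* constant exponent: for $b_{\mathrm{ref}} = 1.388$ and
$\delta b = 0.6\,b_{\mathrm{ref}}$, $\overline{A} \approx 0.045$ d$^{-1}$
and the equivalent exponent is $\lambda/\overline{A} \approx 1.110$. These
identities are verified against numerical quadrature in the test suite.

Diagnostics use a fixed export depth of 120 m and transfer depth of
1080 m (both exact layer interfaces), local TE $= \bar F_{1080}/\bar
F_{120}$, global integrals restricted to columns at least 1080 m deep, and
Redfield conversion (C:N:P = 106:16:1, carbon molar mass 12.011 g mol⁻¹)
to Pg C yr⁻¹.

## Ecosystem formulation

The source model family does not reprint its ecosystem equations, so a
canonical five-compartment NPZD-DOP formulation is implemented and every
parameter is exposed in `ecosystem_params()`:

* growth: Smith-function light limitation
  $\alpha I / \sqrt{\mu_{\max}^2 + (\alpha I)^2}$ times Monod nutrient
  limitation $P/(K_N + P)$, confined to the two euphotic layers (top
  120 m);
* grazing: Holling-III, $g_{\max} P^2/(K_P^2 + P^2) Z$, assimilated with
  efficiency $\gamma_Z$, the rest egested to detritus;
* losses: linear + quadratic phytoplankton mortality, quadratic
  zooplankton closure; a fraction $\sigma_{\mathrm{DOP}}$ of all
  non-grazing losses is routed to a slow DOP pool
  ($\lambda_{\mathrm{DOP}} = 1/360$ d⁻¹), the rest to detritus;
* remineralisation: detritus to phosphate at $\lambda = 0.05$ d⁻¹ (the
  same $\lambda$ as the attenuation law — only this rate and the sinking
  law are fixed by the flux-attenuation analysis), DOP to phosphate at
  $\lambda_{\mathrm{DOP}}$.

The five tendencies sum to zero in every cell; biology moves phosphorus
between pools but never creates it. Defaults
($\mu_{\max} = g_{\max} = 2$ d⁻¹, $K_N = 0.03$ mmol P m⁻³, etc.) are
conventional calibrations, flagged as defaults rather than source-fixed
values.

## Numerical choices

**Sinking scheme.** Fluxes are first-order in space, but the concentration
at each layer's bottom interface is reconstructed from the layer mean
assuming the within-layer steady shape $c(z) \propto z^{-(b+1)}$ implied
by $w = Az$ and decay $\lambda$. With this reconstruction the discrete
no-circulation steady state reproduces the Martin profile *exactly*,
interface by interface — a plain upwind evaluation at the interface depth
overestimates the 15-layer transfer (120→1080 m) by a factor of about
three at $b = 1.388$, which is what the "prevent overestimation of
fluxes" treatment in the source model family addresses. The instantaneous
exponent (which varies seasonally and by hemisphere) enters the
reconstruction, so the scheme follows the seasonal cycle. Sub-stepping
caps the per-substep export of any layer at 90 % of its inventory;
sinking through the seafloor is remineralised into the bottom cell's
phosphate (no burial).

**Unsplit local update.** Ecosystem tendencies and sinking increments are
computed from the same post-transport state and applied together. A
sequential (split) update biases the steady flux profile by $O(\Delta t)$
(≈5 % in TE at $\Delta t = 0.5$ d); the simultaneous update's fixed point
satisfies the exact rate balance at any step size. Transport remains
operator-split ahead of the local terms, which is harmless in the
no-circulation limit and standard practice otherwise.

**Positivity.** A conservative per-cell limiter scales a cell's whole
tendency vector (preserving the zero sum, hence conservation) whenever a
pool would go negative; head-room for the sinking increment is reserved by
limiting against the post-sinking detritus. The alternative of an
analytic-exponential detritus decay inside the step was rejected because
it reintroduces the splitting bias; the limiter makes the explicit update
clip-free at $\Delta t \le 0.5$ d.

**Time stepping.** Default $\Delta t = 0.5$ d (must divide the 30-day
month). Monthly transport operators are applied incrementally each step,
linearly interpolated between the two nearest mid-months. Total
phosphorus is conserved to $<10^{-12}$ relative over decades in closed
configurations; this is asserted property-style in the tests.

**Convergence.** A run counts as converged when the largest change of any
tracer's annual-mean global concentration between consecutive years,
normalised by the global-mean *total phosphorus* concentration, drops
below `convergence_tol` ($10^{-4}$ by default). The common scale is
deliberate: a vanishing pool (e.g. residual zooplankton decaying
algebraically under its quadratic closure) would otherwise stall a
per-tracer relative criterion indefinitely. The source analysis uses a
fixed 3000-year spin-up on the real transport matrices; the desk-scale
stand-in converges in 10–20 years because the synthetic circulation is
fast and the grid coarse, and `n_years_max` remains a config knob.

## Synthetic world: what it emulates, and what not

**Forcing.** Clear-sky daily-integrated astronomical insolation (solar
constant 1361 W m⁻², obliquity 23.44°) on the 360-day year; day 0 is
1 January and the Southern-Hemisphere summer solstice sits at the
day-360/0 boundary, matching the $\theta = 0$ phase convention. Light
decays exponentially in the water column (0.04 m⁻¹, PAR fraction 0.4).
No clouds, albedo, ice, or diurnal cycle: only the shape and phase of the
seasonal light cycle matter for phasing the bloom against the seasonal
attenuation cycle.

**Circulation.** Twelve monthly sparse operators built from two parts:
(i) vertical homogenisation over a seasonal mixed layer, sinusoidal
between 50 m and a winter maximum, deepest two months after the local
winter solstice (the observed lag) and scaled by $|\sin\varphi|$ so the
tropics stay stratified; (ii) a fixed meridional overturning
streamfunction (20 Sv per hemisphere, upwelling at low latitudes,
poleward surface flow, high-latitude downwelling), discretised upwind
from streamfunction differences so the face transports are exactly
non-divergent. Operators are non-negative, preserve uniform fields, and
conserve volume-weighted mass to machine precision; these contracts are
enforced at build time and re-checked when operators are loaded from
disk.

**Calibration.** The mixing strength is the one genuinely free dial, and
it was set against the *reference state* the source analysis prints for
its non-seasonal $b = 1.388$ run — a circulation boost of diagnosed TE to
about 0.066 (≈40 % above the Martin value 0.047) — giving
$\kappa_{\mathrm{mix}} = 0.05$ d⁻¹ and a 300 m winter mixed layer. The
resulting reference world has TE 0.067, $F_{120}$ 4.9 and $F_{1080}$
0.33 Pg C yr⁻¹ (printed reference: 0.066, 5.5, 0.31) and PP 34 Pg C yr⁻¹
(printed: 52). The seasonal experiments were run *after* this calibration
and not adjusted further.

**What a green directional test establishes.** On the calibrated
hemisphere-symmetric smoke world, seasonality in $b$ raises global TE and
the 1080-m flux for every phase, the boost is largest at $\theta = 6$
(sinking-speed maximum coinciding with the bloom) with the same phase
ordering ($\theta = 0 < 3 < 9 < 6$) as the source experiments, diagnosed
TE exceeds the Martin value under circulation, and the layer-wise
fractional transfer exceeds the power-law expectation in the upper
mesopelagic. These are directions, not magnitudes: the real experiments
use 2.8° transport matrices from a general circulation model, which are
out of scope here.

**Known departure.** In this scaled-down world, primary production under
$\theta = 0$ (fast sinking in winter, slow in summer) comes out *above*
the non-seasonal reference, whereas the source experiments find a
(marginal, −0.2 % against the equivalent-b reference) decrease for every
phase. The mechanism is visible in the model: slow summer sinking retains
detritus and regenerated phosphate in the euphotic zone exactly when
light is plentiful, and in a 15-column world with a vigorous synthetic
overturning this fertilisation outweighs the deep-sequestration loss.
The corresponding acceptance expectation is asserted as stated and left
red rather than weakened.

## Design decisions on open points

* **$\theta$ is any real number of months**, not just $\{0,3,6,9\}$; it
  enters only as $\theta\pi/6$.
* **$\delta b$ is configured as a fraction of $b_{\mathrm{ref}}$** (the
  notation used throughout the experiment design), with `delta_b` as an
  absolute-value escape hatch. $\delta b = b_{\mathrm{ref}}$ is allowed
  for evaluating $b(t)$ but rejected wherever $A(t)$ is needed, because
  $A$ diverges at the zero crossing.
* **Seasonal-$\lambda$ variants**: `lambda_only` (λ varies with the same
  cosine, $b$ fixed) and `constant_a` (λ and $b$ vary in proportion, so
  $a$ is constant in time) reproduce the two sensitivity variants of the
  source analysis.
* **TE depths**: the transfer-efficiency formula is sometimes written
  with 1000 m, but every printed value uses the 1080/120 ratio;
  `martin_te()` defaults to (1080, 120) and exposes both depths.
* **Emergent-b fit**: unweighted least squares of $\ln F$ on $\ln z$ over
  interfaces in [120, 1080] m inclusive; the RMS log-residual is
  reported so alternative protocols can be compared.
* **Single-column mode** (`column_config()`): circulation off plus a
  gentle whole-column phosphate restoring (rate 1/50 d⁻¹, target
  0.5 mmol P m⁻³). A truly closed column exports phosphorus irreversibly
  and runs down to extinction, so no sustained cycle exists; restoring
  stands in for the missing resupply at the surface and absorbs the
  bottom accumulation at depth. It deliberately breaks conservation and
  is excluded from the conservation tests. With it, the column converges
  in ~8 years and the annual-mean fluxes fit the Martin curve with the
  imposed exponent to better than 0.1 %.
* **Stated inconsistencies in the source**: the printed "20 % faster"
  for $0.045/0.036$ (exactly 25 %), the 1080-m sinking-speed extrema
  computed from rounded exponent endpoints, a TE of 0.088 for
  $b = 1.110$ where the formula gives 0.0873, and transit times to
  5000 m under seasonal $b$ that do not follow from $\ln(z_2/z_1)/a$ at
  the stated extremes. The exact closed forms are implemented; tests
  compare printed values at one unit in the last printed digit.

## Limitations

Single particle class (no slow/fast split), no temperature- or
oxygen-dependent remineralisation, no ballast effects, cosine-only
seasonality, seasonal $b$ applied instantaneously and uniformly at all
depths (particles do not "carry" their $b$ with them), no real
bathymetry or observational climatology, and a zonally uniform synthetic
circulation that cannot reproduce basin-scale TE patterns — only their
existence under circulation and their disappearance without it.
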