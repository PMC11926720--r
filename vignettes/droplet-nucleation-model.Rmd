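---
title: "Nucleation of confined perfluorocarbon nanodroplets: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleation of confined perfluorocarbon nanodroplets: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropnuc)
```

## The physical problem

A perfluoropentane (PFP) nanodroplet at body temperature is a metastable
liquid: its bulk boiling point (29 °C) lies below 37 °C, but the Laplace
pressure of its interface keeps the interior pressurized above the
saturation pressure. A rarefactional ultrasound half-cycle pulls the
internal liquid pressure down; once deep enough into the metastable
window, a vapor embryo can nucleate homogeneously. This package computes
when that happens — the initial nucleation threshold (INT) — for a
droplet embedded in *elastic tissue* rather than in water.

The mechanical picture is a concentric three-layer system (vapor embryo,
liquid droplet, tissue). Opening a bubble of volume $V_1$ compresses the
droplet and displaces the tissue; linearizing both responses gives two
springs in series with effective modulus $K = K_2 K_3/(K_2+K_3)$ and an
elastic back-pressure $K (R_1/R_{20})^3$ on the liquid. That term adds a
$+\gamma X^6$ contribution to the classical nucleation work.

## Model components and assumptions

**Redlich–Kwong equation of state.** Isotherms
$P = RT/(V-b) - a\alpha(T)/(V(V+b))$ with $\alpha = (T/T_c)^{-1/2}$ and
corresponding-states parameters from $T_c = 420$ K, $P_c = 2.045$ MPa.
The liquid spinodal is taken as the liquid-branch *local minimum* of the
isotherm ($\partial P/\partial V = 0$ with positive curvature). A
second-derivative criterion is sometimes quoted for the spinodal, but
for a cubic EOS the stability limit of the liquid branch is the
first-derivative zero, and only that criterion reproduces the reference
value of −5.26 MPa at 310 K (we compute −5.2445 MPa, 0.3% off, within
the 1% acceptance band). With these constants the package does *not*
reproduce some published spinodal values at 294, 302 and 343 K
(−7.41/−6.32/−2.53 MPa; we get −6.97/−6.08/−2.27 MPa); whatever
constants produced those values are not recoverable, so across
temperature only monotonicity is asserted.

**Metastability-scaled surface tension.** The capillarity approximation
($\sigma_1 = \sigma_\infty$) overestimates the barrier badly. We scale
by the metastability degree $\delta = (P_{sat}-P_2)/(P_{sat}-P_{spin})$:
$\sigma_1 = \sigma_\infty(T)\,[(1-\delta)(1+\delta/2)^2]^{1/3}$, which
interpolates from the flat-interface value at saturation to zero at the
spinodal. $\delta < 0$ (compressed liquid) is algebraically valid and
returned with a warning; $\delta > 1$ raises a classed error
(`dropnuc_beyond_spinodal`) because the liquid is then unstable, not
metastable. $\sigma_1$ is always evaluated at the *bubble-free* liquid
pressure $P_{2wo}$: metastability is a property of the pre-nucleation
liquid, while the elastic correction concerns the with-bubble state and
enters only through the work landscape.

**Dimensionless work landscape.**
$w(X;\gamma) = 3X^2 - 2X^3 + \gamma X^6$ in units of
$W_{1wo} = (4\pi/3)\sigma_1 R_{1wo}^{*2}$. The elastic term follows from
integrating the back-pressure over the bubble volume,
$\int_0^{V_1} K\,v/V_{20}\,dv = K V_1^2/(2 V_{20})$, and
nondimensionalizing. Four exact anchors pin this form: stationary
points solve $1 - X + \gamma X^4 = 0$; the maximum/minimum pair
coalesces at $\gamma_l = 27/256 \approx 0.1055$ with $X = 4/3$; the
arrested bubble is iso-energetic with the droplet at $\gamma_n = 1/16$
with $X = 2$; and no stationary point survives at $\gamma = 0.2$
(super-stabilization). All four are regression-tested to $10^{-10}$
against the package's numeric solvers.

**Kinetics.** $J = J_0\exp(-W^*/k_BT)$ with the standard CNT prefactor
$J_0 = (\rho_2/m)\sqrt{2\sigma_1/(\pi m)}$. The prefactor's published
rendering is ambiguous; we use the literature-standard unit-correct
form and expose it as a plain function. Because the threshold depends
on $J_0$ only through $\ln J_0$, any defensible prefactor moves the INT
by well under 15%. The molecular mass uses a molar mass of
0.28803 kg/mol (C5F12), a documented constant not printed in the source
material. The vapor partial pressure is taken as $P_{sat}(T_0)$ with no
Kelvin/Poynting correction; dissolved O2 and CO2 add
$\sum K_i C_{gi} = 0.559$ MPa via Henry's law. The chemical-potential
term of the dimensional work vanishes at the critical radius (chemical
equilibrium) and is not represented off-critical.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `R20` | 140 | nm | baseline droplet radius |
| `sigma2` | 56 (uncoated) / 14 (lipid-coated) | mN/m | droplet–tissue interfacial tension |
| `T0` | 310 | K | physiological temperature |
| `K2` | 2.2 | GPa | droplet bulk modulus, water-like |
| `K3` | 0–0.67 | MPa | tissue bulk modulus; `K3 = 4G/3` from shear modulus |
| `Pc_conf` | 0 | Pa | static confinement pressure (see below) |
| `f` | 5 | MHz | drive frequency |
| `tau_divisor` | 10 | – | window `tau = 1/(tau_divisor f)` |
| `Psat` | 135 | kPa | saturation pressure at `T0`; per-T values must be supplied by the user |
| `laplace_factor` | 1 | – | `Plap = factor·sigma2/R20` |

Notes on deliberately exposed conventions:

- **Laplace pressure** uses $\sigma_2/R_{20}$, not the textbook
  $2\sigma_2/R$. That is the convention of the model this package
  implements; `laplace_factor = 2` is available for sensitivity studies.
- **Window convention.** The steady-nucleation window is
  $\tau = 1/(10f)$ (the fraction of the period where the trough is
  roughly flat). The *critical-rate* reference value
  $J^* \approx 4.4\times10^{26}\,\mathrm{m^{-3}s^{-1}}$ for a 140 nm
  droplet at 5 MHz is only consistent with $\tau = 1/f$, so
  `critical_rate()` takes `tau` explicitly and both conventions are
  first-class.
- **`Pc_conf`.** Published probability curves show the droplet resting
  pressure increasing with $K_3$, producing INT shifts of order 1 MPa.
  That effect is not derivable from the equations implemented here
  (at these parameters $\gamma \sim 10^{-7}$, moving the threshold by
  fractions of a pascal). `Pc_conf` is an explicit free knob that adds a
  static confinement pressure to $P_{2wo}$ and shifts the INT
  one-for-one, letting users emulate that behavior without the package
  asserting an unpublished formula.
- **Direction of the σ2 effect.** The implementation follows the
  threshold equation: a larger interfacial tension raises the Laplace
  pressure, hence raises the INT; coated droplets (14 mN/m) nucleate at
  lower amplitude. (Some prose summaries state the opposite sign.)

## Numerical choices

- Spinodal: sign change of the analytic $dP/dV$ bracketed on a 4000-point
  log grid in $(1.01b, 50b)$, refined by bisection to relative tolerance
  $10^{-10}$. Verified against a $10^5$-point brute-force grid to 0.5%
  across $(0.55 T_c, 0.99 T_c)$.
- Work-curve stationary points: `polyroot` on the quartic, Newton
  polish, closed-form fallback $X = (4\gamma)^{-1/3}$ at the degenerate
  double root where Newton converges only linearly.
- Threshold: $\Sigma$ is monotone in $|P_{at}|$ and the spinodal bounds
  the bracket, so Brent/bisection on
  $[P_{spin} - P_0 - P_{lap} - P_{c,conf} + 1\,\mathrm{Pa},\,0]$ is
  guaranteed. The absolute tolerance is $10^{-3}$ Pa — tighter than
  strictly needed for the pressure, but required so that
  $\Sigma(P_{at}^*) = 0.5 \pm 10^{-6}$ (the local slope is
  $\sim 2.6\times10^{-5}$/Pa). Domain errors inside the bracket
  (no vapor drive, super-stabilized landscape) are mapped to
  $\Sigma = 0$, which is their physical meaning.
- The rate is *not* globally monotone in tension: within the last
  ~5 kPa above the spinodal, where $W^* < k_BT/6$, the
  $\sqrt{\sigma_1}$ prefactor dependence overturns the trend.
  Thresholds never live there ($W^* \approx 25 k_BT$), but
  monotonicity tests stop short of the spinodal for this reason.
- The Maxwell equal-area construction (`rk_saturation_pressure`) is
  provided but never substituted for the user-supplied `Psat`: the model
  treats `Psat` as an input, and the package refuses to extrapolate the
  single-temperature preset across temperatures.

## The field mapper: what it does and does not establish

`linear_focused_field()` evaluates a Rayleigh-type diffraction integral
over a spherically focused bowl (radius of curvature 60 mm, F-number 1
by default) with a small C++ kernel, and applies tissue attenuation
($\alpha_0 f^y$, default 0.5 dB cm$^{-1}$ MHz$^{-1}$ beyond a 30 mm
water path) as an axial-depth amplitude factor. Against the closed-form
on-axis bowl solution the lossless profile agrees to <1%. The source
surface pressure (default 0.2 MPa; 0.3 MPa in the shipped examples) is
a free parameter, as the reference simulations' drive and medium
parameters are unpublished.

This is a deliberate stand-in for a nonlinear full-wave (Westervelt)
simulation. It preserves the *structural* facts used by the tests:
focal gain and its frequency scaling, axial elongation of the focal
region (length ≥ width), pre-focal peak shift under attenuation,
super-level-set nesting of nucleation areas across droplet sizes, and
shrinkage of achievable areas with attenuation. It does not reproduce
nonlinear waveform distortion, superharmonic focusing, or absolute
focal dimensions — published region sizes are out of scope by design.

A subtlety worth recording: with a fixed source pressure, a higher
frequency focuses *more* sharply (gain $\propto f$), which can outweigh
extra attenuation. The frequency-comparison property test therefore
equalizes the lossless focal drive (source pressure $\propto 1/f$)
before asserting that attenuation makes the 5 MHz region no larger than
the 1 MHz one.

## Known limitations

- Published INT magnitudes (e.g. 4.1 MPa for a coated 200 nm droplet,
  4.75 MPa for 280 nm) and the liquid pressure −3.77 MPa at threshold
  are not reproduced by the printed equations; an independent
  fixed-point oracle agrees with this package's solver to <0.1% and
  both land ~0.3–0.9 MPa above those figures (baseline INT 5.01 MPa,
  $P_2^* = -4.51$ MPa). These published numbers are treated as
  order-of-magnitude cross-checks, not targets.
- The shear-to-bulk conversion is exactly $K_3 = 4G/3$; a published
  mapping (G = 0.43 MPa → K3 = 0.67 MPa) that implies a different
  factor is not reproduced, though K3 may always be given directly.
- No viscosity (elasticity dominates at nanosecond nucleation
  timescales), no thermal deposition or temperature-rise coupling, no
  heterogeneous nucleation, no post-nucleation growth or recondensation.
- Multi-temperature studies require a user-supplied $P_{sat}(T)$ table;
  the test suite uses (294, 302, 310, 343) K with
  (70, 101.3, 135, 400) kPa, a physically plausible PFP vapor-pressure
  ladder chosen once for ordering checks only.

## Reproducibility

Every solver in the package is deterministic; there is no RNG anywhere
in the pipeline (test-suite property checks draw their *cases* from a
seeded RNG). CLI runs write a JSON manifest echoing the fully resolved
configuration; feeding a manifest back reproduces the artifacts
bit-identically.
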