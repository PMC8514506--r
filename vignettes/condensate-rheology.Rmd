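---
title: "Micro-rheology and interfacial tension of condensate droplets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-rheology and interfacial tension of condensate droplets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otrheo)
```

Phase-separated biomolecular condensates are viscoelastic fluids: shear
stress inside them relaxes at a finite rate rather than instantaneously.
This package implements the complete optical-tweezer analysis chain that
measures that viscoelasticity and its consequences — trap calibration,
oscillatory micro-rheology, constitutive-model fitting, interfacial
tension micro-tensiometry, and the comparison of measured droplet-fusion
times against the viscocapillary prediction.  Because raw instrument
traces for such experiments are rarely public, the package also contains
a first-class synthetic-data generator that produces every input the
analysis consumes from known ground truth, which is how the test suite
exercises the pipeline end to end.

All internal units are pN, µm and s.  In this system 1 Pa = 1 pN/µm² and
1 Pa·s = 1 pN·s/µm², so moduli, viscosities, stiffnesses (pN/µm) and
tensions (pN/µm) combine without conversion factors.  Thermal energy
defaults to `kbt_room()` = 4.116e-3 pN·µm (298.15 K).

## The constitutive model

The medium is described by the Burgers model: two Maxwell elements in
parallel, with relaxation modulus

$$G(t) = \frac{\eta_0}{\tau_0} e^{-t/\tau_0} +
         \frac{\eta_1}{\tau_1} e^{-t/\tau_1},$$

and elastic and viscous moduli

$$G'(\omega) = \frac{\omega^2\tau_0\eta_0}{1+(\omega\tau_0)^2} +
               \frac{\omega^2\tau_1\eta_1}{1+(\omega\tau_1)^2},\qquad
  G''(\omega) = \frac{\omega\eta_0}{1+(\omega\tau_0)^2} +
                \frac{\omega\eta_1}{1+(\omega\tau_1)^2}.$$

The fast pair ($\eta_0,\tau_0$) reflects conformational dynamics of
individual macromolecules; the slow pair ($\eta_1,\tau_1$) reflects
reconfiguration of the transient network — breaking and reforming of
inter-molecular contacts.  $\tau_0 = 0$ is an explicit algebraic branch
(a Newtonian fast component contributing $\omega\eta_0$ to $G''$ and
nothing to $G'$), not a small-number hack, because some condensates are
measurably of this type.  The zero-shear viscosity is
$\eta = \eta_0 + \eta_1 = \lim_{\omega\to 0} G''(\omega)/\omega$.  The
crossover frequency $\omega_x$, where $G'(\omega_x) = G''(\omega_x)$,
is found by sign-change bracketing on a log grid over
$[10^{-6}/\tau_1,\,10^{6}/\max(\tau_0, 10^{-6}\tau_1)]$ followed by
bisection on $\log\omega$ to $10^{-12}$ relative precision; a tangency
without sign change counts as no crossover, and a dominant Newtonian
component legitimately has none.  Note that $1/\omega_x$ tracks the
network time $\tau_1$ only while $\eta_0/\eta_1$ is small; as the fast
amplitude grows the crossover migrates toward $\tau_0$.

### Fitting the model

`fit_burgers()` minimises the SEM-weighted joint sum of squares over
$G'$ and $G''$.  Where SEMs are absent it uses $1/\mathrm{value}^2$
weights (constant relative error), falling back to the same row's $G''$
as the scale for non-positive $G'$ rows so that exactly-Newtonian data
remain fittable.  Two-timescale fits are multimodal, so the optimiser
(Levenberg–Marquardt on log-parameters) is restarted from eight
deterministic initial points spanning relaxation times $1/\omega$ at the
top, middle and bottom of the measured band, plus a start with $\tau_0$
at its lower bound; the best optimum wins and ties cannot arise because
the deviance comparison is strict.  A fitted $\tau_0$ landing on its
bound ($10^{-8}/\omega_{\max}$) is reported as exactly 0.  Standard
errors come from the Jacobian at the optimum, mapped back to the natural
scale by the delta method; they are `NA` when the Hessian is singular
(e.g. for parameters at bounds, where the slow component's time is
unidentified if its amplitude vanishes).  Negative-$G'$ rows are kept,
flagged, and removed only via the explicit `drop_flagged` argument —
transparency over silent cleaning.

## Trap physics and calibration

A bead of radius $a$ in a medium with modulus $G^*$ feels the medium as
a frequency-dependent spring and dashpot,
$6\pi a G^*(\omega) = \kappa_m + i\omega\xi_m$ (the generalised Stokes
relation).  Held by a harmonic trap of stiffness $\kappa_t$, its thermal
position fluctuations have the overdamped one-sided spectrum

$$P_x(\omega) = \frac{2 k_B T\, \xi_m(\omega)}
  {\left(\kappa_t+\kappa_m(\omega)\right)^2 +
   \left(\omega\,\xi_m(\omega)\right)^2},$$

normalised so that the variance equals $\frac{1}{\pi}\int_0^\infty P_x\,
d\omega$.  For a Newtonian medium this is the Lorentzian of a Brownian
harmonic oscillator with corner $\omega_c = \kappa_t/6\pi\eta a$, which
is the basis of the classic water calibration
(`stiffness_from_corner()`).  Inertia is neglected throughout: the
inertial corner of a micron bead in a ≥0.3 Pa·s medium is far above the
experimental band.

Passive spectra are fitted with a stretched Lorentzian
$P_V(0)/[(\omega/\omega_{\mathrm{eff}})^\alpha + 1]$, $\alpha \in
(1,3]$, in log-density space after averaging into log-spaced bins
(12 per decade; periodogram noise is multiplicative, and log-binning
also equalises weight per decade).  Only bins within a factor
`dynamic_range` (default 50) of the spectral peak enter the fit: the
stretched Lorentzian is a corner-local model, and including
floor-dominated deep-tail bins drives $\alpha$ toward its singular
bound 1, where the calibration identities below blow up
($\sin(\pi/\alpha) \to 0$).  Both the binning and the range cut can be
disabled, which the exact-recovery tests use.

The active–passive calibration determines the detector conversion
$\epsilon$ (µm/V) and $\kappa_t$ jointly from the passive volt-unit
spectrum and one low-frequency sinusoidal drive:

$$\epsilon = \frac{(\alpha/2)\sin(\pi/\alpha)\,
  \frac{\omega/\omega_{\mathrm{eff}}}
       {(\omega/\omega_{\mathrm{eff}})^\alpha+1}\; X_{t0}}
  {F_{V0}\,\sin\Delta},\qquad
  \kappa_t = \frac{\alpha\sin(\pi/\alpha)\,k_BT}
  {\omega_{\mathrm{eff}}\,P_V(0)\,\epsilon^2},$$

the second being the equipartition integral of the fitted spectrum.  At
$\alpha = 2$ it reduces to the familiar Lorentzian identity
$\kappa_t\epsilon^2 = 2k_BT/(\omega_c P_V(0))$.  The drive is kept at
low frequency (0.2 Hz in the droplet tests, 1 Hz in water at 1 µm
amplitude — at small amplitudes the drive force in water is comparable
to thermal force noise).

### Equipartition and the unresolved fast variance

One subtlety deserves record.  Thermodynamics fixes the equilibrium
position variance of a trapped bead in any fluid at exactly
$k_BT/\kappa_t$ — the medium exerts no static restoring force.  But the
overdamped in-band spectrum above integrates to less than that whenever
the medium has instantaneous elasticity ($\kappa_m(\infty) =
6\pi a(\eta_0/\tau_0 + \eta_1/\tau_1) > 0$): the balance of the variance
physically resides in fast vibrational motion at the (neglected)
inertial resonance, hundreds of kHz for a micron bead, far above any
realistic sampling band.  In sampled real data that unresolved power
appears as a flat noise-like floor.  The passive-trace generator
therefore synthesises the in-band spectrum exactly and adds a white
component carrying exactly the missing variance, so that the sample
variance of a synthetic trace is $k_BT/\kappa_t$ in expectation — the
identity on which the calibration rests.  The floor can be disabled
(`equipartition_floor = FALSE`) to obtain a trace whose spectrum is the
bare in-band target, which is what the bin-by-bin synthesis-fidelity
test checks.  Traces are synthesised in the frequency domain
(independent complex Gaussian coefficients with variance proportional to
the target density, Hermitian symmetry, inverse FFT): the target
spectrum is realised exactly, with no time-stepping discretisation bias,
and output is bit-reproducible for a given seed.

With the textbook-form identities applied to these synthetic droplet
spectra — which are genuinely not stretched Lorentzians — the
calibration estimator carries irreducible shape-model error.  Its
dispersion, measured over 24 seeds at the test settings (120 s passive
trace at 1 kHz, 12 Welch segments, 0.2 Hz drive for 60 s, pK:H-like
medium), is about 12% for $\kappa_t$ and 6% for $\epsilon$, essentially
unbiased; the fixed-seed round-trip tests assert recovery within 30%
and 15%, roughly two-and-a-half spreads.  In a Newtonian (water-like)
medium the estimator is much cleaner (≈6% and 3%), and its replicate
spread is verified to stay under the ~11% bead-to-bead spread seen
experimentally.

## Oscillatory rheology

Driven trap and force traces are fitted to cosines at the commanded
frequency — known exactly, so the fit is linear least squares on
$\{\cos\omega t, \sin\omega t, 1\}$ — giving amplitudes $X_{t0}$,
$F_{t0}$ and the phase lead $\Delta$.  With
$\Upsilon = F_{t0}/(\kappa_t X_{t0})$ the moduli follow from the force
balance on the bead:

$$G'(\omega) = \frac{F_{t0}}{6\pi a X_{t0}}
  \frac{\cos\Delta - \Upsilon}{(\cos\Delta-\Upsilon)^2+\sin^2\Delta},
  \qquad
  G''(\omega) = \frac{F_{t0}}{6\pi a X_{t0}}
  \frac{\sin\Delta}{(\cos\Delta-\Upsilon)^2+\sin^2\Delta}.$$

$\Upsilon \ge 1$ or $\sin\Delta \le 0$ are hard errors (an
over-capacity force amplitude or a non-dissipative phase indicate an
inconsistent calibration), while a negative extracted $G'$ is flagged
but preserved.  Replicate droplets measured on a shared frequency grid
are aggregated to means with standard errors of the mean, which become
the weights of the Burgers fit.

The test suite verifies the exact inverse identity: noise-free
simulated driven traces, run through the cosine fits and the
amplitude-phase formulas, reproduce the generating $G^*$ to $10^{-9}$,
and the full chain through `fit_burgers()` recovers all four
parameters to $10^{-6}$.

## Interfacial tension

**Stretching.**  A droplet suspended between two trapped beads at its
poles is pulled at constant speed $v$ (trap 2 fixed).  Force traces are
smoothed by a 64-ms moving average (edge half-windows are excluded from
the subsequent fit, so a linear ramp stays exactly linear) and fitted
for slopes $f_1, f_2$; the system spring constant is $\chi_{sys0} =
\frac{(f_2-f_1)/2}{v}$, and the droplet's own spring constant follows
from three springs in series, $1/\chi_0 = 1/\chi_{sys0} - 1/\kappa_{t1}
- 1/\kappa_{t2}$.  The tension is
$\gamma = \frac{1}{\pi}\left[\ln(R/a - 1) + 0.68\right]\chi_0$, the
exact inverse of the pole-geometry factor
$\chi_0 = \frac{\pi\,\alpha(\theta_0)}{2}\gamma$ with
$1/\alpha(\theta_0) = -0.5\ln\theta_0 + 0.34$ and $\theta_0 = a/(R-a)$,
valid for $\theta_0 \le 0.5$ (enforced as a domain error).  Signed $v$
handles retraction runs: both slopes flip and the same $\chi_{sys0}$
results, mirroring the experimental observation that stretch and
retract give the same spring constant.  The analysis uses only slopes,
so the initial bead separation never needs a numeric value.

**Rupture.**  Pulling a trapped bead through the interface ruptures the
surface at a peak force balancing the tension around the bead equator,
$F_{rup} = 2\pi a f \gamma$, with $f$ an empirical constant (1.1)
absorbing adhesive pull-back — the bead acts as a micro-scale Wilhelmy
probe.  A trace qualifies as a rupture only if the smoothed force drops
by at least half after its maximum; when the peak reaches a configured
instrument force limit only a lower bound on $\gamma$ is reported.

## Fusion dynamics and the viscocapillary comparison

Fusion times are proportional to droplet radius; `fit_fusion_speed()`
fits $\tau_{fu} = s\,R$ through the origin (an intercept is available
for diagnostics but off by default, because the proportionality is the
established empirical law).  A Newtonian droplet would fuse in
$\tau_{fu}^N = 1.97\,\eta R/\gamma$.  At a reference radius (3 µm by
default) `derived_metrics()` assembles the comparison: the
geometric-mean timescale $\tau_{fu}^* = \sqrt{\tau_{fu}\tau_{fu}^N}$,
whose inverse estimates the shear rate during fusion; the ratio
$\tau_1/\tau_{fu}^*$ of shear relaxation to deformation; the
effective-viscosity ratio $\eta_{\mathrm{eff}}/\eta =
\tau_{fu}/\tau_{fu}^N$; the percent deviation $200\,|\tau_{fu} -
\tau_{fu}^N|/(\tau_{fu} + \tau_{fu}^N)$ (symmetric, against the
arithmetic mean — the definition that reproduces the published derived
columns at printed precision); and the relative viscosity against water
($\eta_w$ = 8.9e-4 Pa·s).  Droplets with $\eta_{\mathrm{eff}}/\eta$
above $1 + 0.05$ are classified shear-thickening, below $1 - 0.05$
shear-thinning, and Newtonian between — the 5% band absorbs input
rounding.

## The synthetic-data generator

Every generator is a pure function of its parameters and a mandatory
seed; identical inputs give bit-identical outputs.  It emulates:

- passive thermal traces (spectral synthesis as above);
- driven trace pairs, whose force amplitude and phase solve the
  trap–medium balance exactly, with optional thermal force noise equal
  to $\kappa_t$ times a passive position trace (the same spectral
  origin a detector would see) — the noise-free branch makes no
  stochastic calls;
- stretching ramps from the forward tension geometry with additive
  Gaussian force noise;
- rupture ramps peaking at $2\pi a f\gamma$ with a seed-randomised
  rupture moment;
- fusion datasets $\tau_{fu,i} = s R_i + \varepsilon_i$, truncated
  positive, radii restricted to the measured 0.8–8 µm range.

It does **not** emulate hydrodynamic memory, bead polydispersity,
detector filtering/aliasing artifacts, drift, or droplet shape dynamics
during fusion (only the $\tau_{fu} \propto R$ law).  Passing tests
therefore demonstrate correctness of the analysis chain under the
model's own assumptions, not robustness to every instrumental
pathology of real traces.

### Built-in condensate fixtures

Four parameter sets (`condensate_presets()`) anchor the synthetic
experiments, one per condensate type studied, reproducing the measured
zero-shear viscosities (0.30, 0.53, 3.75, 10.1 Pa·s), slow relaxation
times (45, 125, 72, 396 ms), tensions (57.1, 67.0, 73.4, 106 pN/µm) and
inverse fusion speeds.  The split of each total viscosity between fast
and slow components is not fully determined by those numbers; it is
fixed once so that S:P has a Newtonian fast component ($\tau_0 = 0$),
S:L is the only type with $\eta_0/\eta_1 > 1$, the others keep
$\eta_0/\eta_1$ below ~0.5, and fast times are 5–35-fold shorter than
slow ones — the qualitative constraints the measurements establish.
Oscillation traces default to 10 s at 1 kHz at every drive frequency
(≥5 periods at 0.5 Hz, ≥25 samples per period at 40 Hz); trap
stiffness is 310 pN/µm (1850 pN/µm for the stiff S:L case), drive
amplitude 1 µm.

```{r presets}
condensate_presets()[["P:H"]]$params
```

## Worked example

```{r pipeline}
out <- run_pipeline(seed = 1, quiet = TRUE)
as.data.frame(out$table)[, c("name", "eta_pa_s", "gamma_pn_um",
                             "tau_fu_ms", "tau_fu_N_ms", "eta_eff_ratio",
                             "regime")]
```

Each row is one synthetic condensate run through the entire chain:
moduli extraction and Burgers fit (`eta_pa_s`), stretching analysis
(`gamma_pn_um`), fusion-speed fit scaled to R = 3 µm (`tau_fu_ms`),
the viscocapillary prediction (`tau_fu_N_ms`), and their ratio with its
shear-thinning/thickening classification.

## Problem sizes and runtime

The test suite runs in well under a minute on one core.  Monte-Carlo
checks use 20–200 repetitions at 4k–100k samples per trace; the
calibration round trips use 120 s (droplet) and 8 s at 131 kHz (water)
passive traces; the full four-condensate pipeline (21 driven traces of
10^4 samples per condensate, plus stretching and fusion) takes about a
second.  These sizes were chosen so that Monte-Carlo error sits well
below every assertion tolerance while the whole suite stays quick to
iterate on.

## Known limitations

- The stretched Lorentzian is a descriptive, not mechanistic, model of
  droplet spectra; on strongly two-timescale media its parameters are
  estimator-dependent (binning, fit range), which is why the
  calibration identities carry the dispersion quoted above.
- The geometry factor for stretching is first-order in the pole angle
  and enforced only for $\theta_0 \le 0.5$.
- The rupture constant $f$ = 1.1 is an empirical calibration, not
  derived; rupture tensions inherit its uncertainty.
- Fusion analysis uses only the proportional law; no neck-growth
  hydrodynamics are modelled.
- CSV (with metadata header comments) is the only trace interchange
  format; instrument-vendor containers are out of scope.
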