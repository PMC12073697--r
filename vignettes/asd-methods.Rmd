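---
title: "Models and numerical methods for amorphous solid dispersion analysis"
author: "asdtherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods for amorphous solid dispersion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asdtherm)
```

`asdtherm` analyses drug–polymer amorphous solid dispersions (ASDs) along
two complementary routes: dielectric relaxation spectroscopy, which probes
molecular mobility, and modulated calorimetry, which probes the state
(glass transition) and phase (solubility) behaviour. This vignette is the
package's account of the underlying models, of the numerical decisions
taken where the methods literature leaves them open, and of what the
synthetic-data round trips do and do not demonstrate.

## 1. Conduction-free dielectric loss

A dielectric isotherm records the complex permittivity
$\varepsilon^*(F) = \varepsilon'(F) - i\varepsilon''(F)$ over frequency.
In supercooled drug/polymer blends the structural ($\alpha$) relaxation
is usually buried at low frequency under ohmic conduction
($\varepsilon''_{\mathrm{cond}} = \sigma/(\varepsilon_0\omega)$) and
electrode polarisation (EP). Because the ohmic term contributes only to
the imaginary part, a loss estimate built from the real part alone is
conduction-free:

$$\varepsilon''_{\mathrm{der}}
  = -\frac{\pi}{2}\,\frac{\partial \varepsilon'(\omega)}{\partial \ln\omega}.$$

This approximation is accurate for broad peaks such as the $\alpha$
relaxation, and it sharpens overlapping modes, which is what makes
two-component deconvolution practical. EP is *not* removed — it
contaminates $\varepsilon'$ as well — so fitting windows must exclude
the low-frequency EP rise; `fit_hn()` takes the window as an argument.

**Numerical estimator.** `log_derivative()` resamples $\varepsilon'$
onto a uniform $\log_{10}F$ grid (20 points/decade by default), fits a
local cubic polynomial over a sliding 5-point window, and takes its
analytic slope at the window centre; edges use one-sided windows and the
result is interpolated back onto the measured frequencies. A cubic
rather than quadratic local fit is used deliberately: the quadratic
Savitzky–Golay slope carries a bias of $0.567\,h^2 f'''$ that amounts to
$-1.5\%$ at the peak of a Debye loss on a 20 points/decade grid, while
the cubic slope is biased only at $O(h^4)$ (measured $\sim 10^{-4}$
relative on the same grid). The price is a higher noise gain; for noisy
sweeps the recommended settings are resampling at the native sweep
density (`points_per_decade = 10`) with a 7-point window, which the
noisy round-trip tests use.

`normalize_loss()` returns
$\varepsilon''_{\mathrm{der}}/\varepsilon'$, the quantity of choice when
comparing powder samples whose capacitor filling differs; like
$\tan\delta$, the normalisation shifts apparent peak positions towards
higher frequency, so normalised and raw peak times are reported
separately and never mixed in one Arrhenius data set.
`modulus_transform()` gives $M^* = 1/\varepsilon^*$, whose imaginary
part is insensitive to EP and is used to confirm that a low-frequency
shoulder is a genuine relaxation and not a conduction artefact.

## 2. Havriliak–Negami deconvolution

Each relaxation mode is modelled by the empirical Havriliak–Negami form

$$\varepsilon^*(\omega) = \varepsilon_\infty +
  \frac{\Delta\varepsilon}{\bigl(1 + (i\omega\tau_{HN})^{\alpha}\bigr)^{\beta}},
  \qquad 0 < \alpha, \beta \le 1,$$

with $\alpha$ controlling symmetric broadening and $\beta$ asymmetry
(the exponent convention with $\beta$ outside the bracket is the
standard one). The loss peak sits at the closed-form frequency

$$\omega_{\max} = \tau_{HN}^{-1}
  \left[\frac{\sin\bigl(\pi\alpha/(2\beta+2)\bigr)}
             {\sin\bigl(\pi\alpha\beta/(2\beta+2)\bigr)}\right]^{1/\alpha},$$

which reduces to $1/\tau_{HN}$ in the Debye case and agrees with
brute-force maximisation to at least four significant digits (tested).
Relaxation times are always reported as
$\tau_{\max} = 1/\omega_{\max} = 1/(2\pi F_{\max})$.

**Fitting.** `fit_hn()` fits one or two modes to either the raw loss
$\varepsilon''$ or to $\varepsilon''_{\mathrm{der}}$. In the latter case
the model curve is the *analytic* logarithmic derivative of the HN form,
$(\pi/2)\,\alpha\beta\,\Delta\varepsilon\,
\mathrm{Re}\!\left[u(1+u)^{-\beta-1}\right]$ with
$u = (i\omega\tau)^{\alpha}$, so model and data are commensurate.
Which of the two targets the practitioner prefers is an open question in
the field; both are supported and give the same parameters on clean data
(tested to 1% on noiseless single-mode spectra).

Optimisation is bounded Levenberg–Marquardt (`minpack.lm`) on
$(\log_{10}\Delta\varepsilon, \log_{10}\tau, \alpha, \beta)$ per mode.
Starting values are seeded from the highest local maxima of the target
curve (peak height $\times 4/\pi$ estimates $\Delta\varepsilon$, the
Debye relation); a single maximum is split by $\pm 1$ decade in $\tau$
for a two-mode fit, and three jittered restarts under a fixed seed guard
against local minima. Two conventions matter:

* $\varepsilon_\infty$ never enters either loss target, so it is
  recovered afterwards as the mean offset between the measured
  $\varepsilon'$ and the real part of the fitted modes — exact on
  noiseless data.
* $\alpha = 1$ or $\beta = 1$ are legitimate shapes (Cole–Cole, Debye),
  so the `at_bounds` flag fires only for pins at the *technical* bounds
  (strength, $\tau$ range, lower shape bounds). Noisy fits frequently
  and harmlessly touch $\beta = 1$.

Modes are ordered by descending $\tau$ and labelled `alpha1`
(low-frequency, polymer-richer phase) and `alpha2` (high-frequency,
drug-richer phase).

## 3. VTFH dynamics, dynamic Tg, fragility

Relaxation-time series $\log_{10}\tau_{\max}(T)$ are fitted by the
Vogel–Tammann–Fulcher–Hesse law

$$\log_{10}\tau = \log_{10}\tau_\infty + \frac{B}{\ln 10\,(T - T_0)}$$

with all temperatures in Kelvin internally (conversion constant 273.15;
file and report values are degC throughout). $\log_{10}\tau_\infty$ is
fixed at $-14$ by default — a phonon attempt time, and the convention
that makes $B$ and $T_0$ comparable across compositions when some blends
have few low-frequency points. The fit is unweighted least squares in
$\log_{10}\tau$; it requires at least 4 points spanning at least 20 degC.

Derived quantities are closed forms: the dynamic glass transition
$T_{g,\mathrm{DRS}} = T_0 + B/\bigl((\log_{10}\tau_{\mathrm{ref}} + 14)\ln 10\bigr)$
at the conventional $\tau_{\mathrm{ref}} = 100$ s (a named, overridable
constant — 10–1000 s conventions exist), and the fragility

$$m = \left.\frac{d\log_{10}\tau}{d(T_g/T)}\right|_{T_g}
    = \frac{B\,T_g}{\ln 10\,(T_g - T_0)^2},$$

verified against the defining numerical slope to $10^{-6}$. Values
outside the empirical 16–170 range trigger a warning. One row of the
packaged reference VTFH table is internally inconsistent — its tabulated
dynamic Tg lies 2.3 degC from the closed form implied by its own
$(B, T_0)$ — and is excluded from the self-consistency regression test;
all other rows close within 0.5 degC and 2 m-units.

**Composition readback.** At fixed temperature, $\log_{10}\tau$ is
monotone in drug content across a set of reference VTFH curves, so a
measured relaxation time locates the composition of an unknown amorphous
phase. `estimate_composition()` interpolates $\log_{10}\tau$ linearly in
composition and inverts; linear interpolation is the simplest monotone
choice and matches the graphical readback practice the method emulates.
The estimate is bracketed by the two neighbouring reference
compositions, and queries outside the envelope are clamped with a
warning rather than extrapolated.

`track_recrystallization()` chains two-mode fits through a time series
at fixed temperature, warm-starting each fit from the previous time
point (with a cold restart on failure and a one-mode refit when the
two-mode fit pins at technical bounds), and flags violations of the
expected monotone decay of the drug-rich component's strength.

## 4. Calorimetry: tangent construction and mixing rules

`extract_glass_transition()` locates the Cp-jump as the peak of the
smoothed temperature derivative of the reversible specific heat
(quadratic local fit whose window covers about 2 degC of data — matched
to the few-degC width of a real glass transition). The midpoint is the
parabolically refined derivative maximum; flanking linear baselines are
fitted over 10 degC windows placed beyond 1.5 times the step's 10%-width
(a logistic step still carries 2.6% of its height where its derivative
has fallen to 10%, so fitting baselines immediately adjacent would bias
$\Delta C_p$ low by $\sim$5–6%); $\Delta C_p$ is the baseline difference
extrapolated to the midpoint, and onset/end are the intersections of the
baselines with the midpoint tangent. Peaks are accepted above a slope
threshold (default $0.005\ \mathrm{J\,g^{-1}\,{}^\circ C^{-2}}$ or
$6\times$ the robust noise level, whichever is larger) and merged unless
separated by both 8 degC and a derivative valley below half the smaller
peak — noise ripples on a step's flanks therefore never split it, while
two genuine transitions 40 degC apart are reported as a
`multiple_transitions` list. The construction is exactly invariant to
uniform baseline offsets (tested).

Blend glass transitions follow the Gordon–Taylor law; `gt_fit()`
optimises $K$ only, with the pure-component endpoints fixed and excluded
from the residual because the curve passes through them identically.
The Couchman–Karasz ratio $K_{CK} = \Delta C_{p,\mathrm{polymer}} /
\Delta C_{p,\mathrm{drug}}$ is the athermal-solution prediction;
uncertainty is propagated by min–max bounds and symmetrised. A fitted
$K_{GT}$ above $K_{CK}$ signals attractive drug–polymer interactions.
`gt_invert()` is the exact algebraic inverse (the law is linear in $x$
after cross-multiplication), which is what converts an
annealing-equilibrated Tg into a saturation composition
(`latreche_points()`).

Recrystallisation exotherms are converted by enthalpy accounting: with
drug load $x$ and measured $\Delta H_{cr}$ per gram of drug, the
crystallised fraction is $f = \Delta H_{cr}/\Delta H_{\mathrm{ref}}$
(reference: the fully crystallising pure amorphous drug), and mass
balance gives the residual amorphous composition
$x_{\mathrm{rem}} = x(1-f)/\bigl(x(1-f) + (1-x)\bigr)$. Fractions up to
1.05 are clamped to 1 with a warning; larger values are treated as an
inconsistency error rather than silently truncated.

## 5. Flory–Huggins solubility and the phase-and-state diagram

The solubility (liquidus) of the crystalline drug in the polymer is
modelled by

$$\frac{\Delta H_m}{R}\left(\frac{1}{T_m} - \frac{1}{T}\right)
 = \ln\phi + \Bigl(1 - \frac{1}{\lambda}\Bigr)(1-\phi) + \chi(1-\phi)^2,$$

with $\phi$ the drug volume fraction from the component densities and
$\lambda$ the polymer/drug molar volume ratio. The interaction parameter
$\chi$ is fitted as temperature-independent. Three numerical choices:

* **Objective.** The residual (LHS $-$ RHS) is *affine in* $\chi$ with
  coefficient $-(1-\phi)^2$, so least squares over the implicit residual
  has a closed-form solution; `fit_chi()` uses it (and the tests confirm
  a brute-force 1-d minimisation lands on the same value to $10^{-7}$).
  An objective in temperature space would require a root solve inside
  the loss and is not linear in $\chi$; the residual objective is
  adopted as the canonical one.
* **Root solving.** `solve_solubility_temperature()` exploits that the
  LHS is strictly increasing in $T$ while the RHS is constant: the root
  is unique and bracketed bisection (`uniroot`) on
  $[T_m - 200, T_m + 50]$ degC suffices, with a no-solution report when
  the residual does not change sign.
* **Extrapolation flag.** Dissolution equilibration is impractically
  slow at low temperature, so solubility temperatures outside the
  annealing range used for the $\chi$ fit (120–140 degC by default) are
  tabulated but flagged `extrapolated`.

`build_phase_diagram()` tabulates the Gordon–Taylor state curve
(optionally with a $K$ band, e.g. the Couchman–Karasz min–max) and the
solubility curve on an $x$ grid (step 0.01), and
`classify_state()` partitions the $(x, T)$ plane: above the solubility
curve the liquid is undersaturated and stable; between the blend Tg and
the solubility curve it is supersaturated and will recrystallise when
mobility allows; below Tg the blend is glassy, and additionally flagged
supersaturated when it also sits below the solubility curve — the state
in which kinetic arrest is the only protection. Points within 0.05 degC
of a curve are labelled `boundary` with both neighbouring states
reported.

## 6. What the synthetic generators emulate — and what they do not

`dielectric_scenario()` is a forward model of a broadband sweep:
HN modes whose $\tau(T)$ follows per-mode VTFH laws, relaxation
strengths affine in temperature, an ohmic term
$c_{\mathrm{cond}}/\omega$ in the loss, EP as a two-parameter power law
$a(i\omega)^{-s}$ split into its standard real/imaginary parts, and
multiplicative Gaussian noise. The default scenario mirrors a 90 wt.%
drug dispersion: a minority slow component ($B = 2356$ K,
$T_0 = 2.0$ degC, $\Delta\varepsilon = 0.75$) and a majority fast
component ($B = 1759$ K, $T_0 = 11.2$ degC, $\Delta\varepsilon = 3$),
swept 0.1 Hz–1 MHz at 10 points/decade over 85–150 degC isotherms — the
standard instrument protocol. The 1:4 strength ratio encodes that the
slow phase is very much the minority; the shape exponents
($\alpha = 0.85$, $\beta = 0.7$) are typical of structural relaxations.
Noise defaults to 1% relative, a realistic figure for packed-powder
capacitors. Two generator conventions are deliberate: noise multiplies
the relaxation signal (HN + EP) *before* the ohmic term is added, so
subtracting a conduction-free twin recovers $c_{\mathrm{cond}}/\omega$
exactly (a regression anchor); and per-isotherm noise seeds derive
deterministically from the scenario seed and the temperature, making
every generator a pure function of (scenario, seed).

`thermo_scenario()` builds reversible-Cp scans from an affine baseline,
logistic Cp-jumps (slope $\Delta C_p/(4w)$ at the midpoint) and Gaussian
peaks integrating exactly to a stated enthalpy.
`gen_recrystallization_series()` couples the spectral generator to a
monotone composition path: the drug-rich mode's strength is scaled by
the amorphous drug fraction implied by mass balance and both modes'
relaxation times ride the same reference-curve interpolation that the
composition readback inverts.

What passing the round trips does **not** show about real data: the
generators contain no Maxwell–Wagner–Sillars interfacial polarisation,
no secondary ($\beta/\gamma$) relaxations overlapping the high-frequency
flank, no capacitance drift from powder coalescence, no moisture
effects, and no nucleation-and-growth kinetics — the composition path is
imposed, not predicted. Conclusions about those phenomena require real
spectra.

## 7. Problem sizes, tolerances, limitations

The regression suite runs entirely on generated data: isotherm series of
6–7 temperatures at 71 frequency points, thermograms of ~1400 points,
recrystallisation series of 9 time steps, and the packaged blend tables
(7 compositions, 5 annealing points, 9 VTFH rows). Documented closure
tolerances, all verified in the tests: noiseless single-HN recovery
within 1%; two-mode relaxation times within 5%; noiseless
derive–fit–VTFH round trips within 5% on $(B, T_0)$; with 1%
multiplicative noise, within 10% (using native-grid differentiation, a
7-point window and warm-started fits); logistic Cp-steps within
0.2 degC and 2%; tracker composition estimates within 0.05.

Known limitations: minority-component VTFH parameters are only
recoverable to $\sim$10–15% at 1% noise — at the information limit of a
1:4 deconvolution, as the fit standard errors correctly indicate; fast
components leave the 1 MHz window above $\sim$110 degC in drug-rich
scenarios, so high-temperature points must be excluded from VTFH fits;
literature Tg tables rounded to 1 degC limit how precisely $K_{GT}$ can
be pinned (leave-one-out refits of the packaged table span 0.70–0.85);
and $\chi$ is treated as temperature-independent over a 20 degC fitting
window — extrapolations of the solubility curve to room temperature are
qualitative.
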