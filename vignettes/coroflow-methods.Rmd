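---
title: "Methods: a reduced-order model of coronary stenosis hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reduced-order model of coronary stenosis hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coroflow)
```

`coroflow` studies how the degree (DS), location and eccentricity of a
proximal stenosis in the main coronary arteries shape pressure, flow and
wall-shear metrics. This vignette is the package's own account of the model:
what is simulated, how it is calibrated, which numerical choices were made
where the design was genuinely open, and what the results do and do not say.
All quantities are CGS — cm, s, dyne/cm² (1 mmHg = 1333.22 dyne/cm²),
cm³/s, dyne·s/cm⁵, cm⁵/dyne — with blood treated as Newtonian
(μ = 0.04 dyne·s/cm², ρ = 1.06 g/mL).

## Parametric lesion geometry

Each vessel is described by its healthy reference diameter and a lesion
length of about 1.3 diameters (LM 0.70/0.50, LAD 0.62/0.44, LCX 0.50/0.36,
RCA 0.63/0.45 cm lesion/diameter). A diameter stenosis fraction `ds` sets
the throat exactly: `d = D(1 − ds)`, `A_s = π/4 d²`, so the area ratio is
`(1 − ds)²`. `throat_table()` reproduces the printed reference dimensions
of all 4 vessels × 8 DS levels at their printed rounding.

Open design points, resolved as follows:

* **Constriction shape.** Only the throat size and lesion length are
  constrained, not the exact profile. We use the single-parameter C¹ shape
  `s(z′) = cos²(π z′ / 2)` over the lesion half-span, applied to the radius
  reduction and (for eccentric lesions) to the lumen-centre offset. Any
  smooth monotone taper with the same throat gives the same network physics;
  the cosine-squared form keeps the surface area analytically integrable for
  mesh verification.
* **Eccentricity.** The stenotic lumen stays a perfect circle; the eccentric
  variant displaces its centre by the local radius reduction so the lumen is
  tangent to the healthy wall (offset + radius = reference radius throughout
  the lesion), with the plaque grown from the fixed azimuth θ = π. Since no
  azimuthal information exists in a 0D network, concentric and eccentric
  lesions share identical cross-sectional areas — eccentricity matters for
  the exported surfaces and any imported 3D fields, not for the network
  solution.
* **Lesion placement and segment lengths.** Lesions sit centred in the
  proximal third of the vessel (shifted inward when the lesion would
  protrude past the inlet). Healthy segment lengths are typical-anatomy
  defaults (LM 1, LAD 10, LCX 8, RCA 10 cm), configurable in
  `vessel_spec()`; they only enter through small Poiseuille resistances
  (≤ 1% of outlet resistance), so their exact values are immaterial.

Surface meshes are structured tube triangulations; total area converges at
second order to the analytic surface-of-revolution area (the test suite
checks an error ratio near 4 per resolution doubling). STL (binary) and VTP
(ASCII XML) export/import round-trip vertex counts and areas.

## Boundary circuits and calibration

The aortic outlet is a three-element Windkessel: proximal resistance `Rp`,
compliance `C`, distal resistance `Rd`, with `Rd : Rp = 0.91 : 0.09` of the
total `Pmean/Q`. Each coronary outlet is the standard intramyocardial
circuit — inlet —`Ra`— node a (`Ca` to ground) —`Ra_micro`— node b (`Cim`
referenced to the intramyocardial pressure `Pim(t)`) —`Rv`— venous
reference. Systolic `Pim` compresses `Cim` and impedes inflow; its release
in diastole draws flow. That mechanism, not the aortic pressure pulse, is
what makes left coronary flow diastolic-dominant.

Calibration (all arguments of `default_calibration()`):

* cardiac output 5 L/min, mean aortic pressure 93 mmHg, period 1 s,
  systolic fraction 0.35 — resting healthy-adult values;
* coronary flow 4% of cardiac output, LCA:RCA = 2:1, LAD:LCX by Murray's
  law on the reference diameters (`Q ∝ d³`);
* each outlet's total resistance anchored by its target flow,
  `R_i = Pmean / Q_i` (equivalently `R_cor : R_aorta = Q_aorta : Q_cor`);
  coronary split Ra : Ra-micro : Rv = 0.32 : 0.52 : 0.16, the conventional
  coronary-circuit proportion;
* compliances: the stated vascular compliance constant of
  0.001 cm⁵/dyne is assigned to the aortic Windkessel — at ~0.75 mL/mmHg it
  is an aortic-scale compliance, and placing it on a single coronary outlet
  would shunt the intramyocardial forcing through node a and destroy the
  systolic impediment entirely. Coronary outlets instead share a total bed
  compliance of 1 × 10⁻⁴ cm⁵/dyne (coronary-circuit literature scale),
  distributed by flow share and split Ca : Cim = 0.11 : 0.89 per the stated
  ratio. `split_compliance()` remains a pure ratio utility with the
  0.001 default.
* `Pim`: C¹ sine-squared pulse peaking at left-ventricular pressure
  (120 mmHg) for LM/LAD/LCX outlets and at right-ventricular pressure for
  the RCA (scale 0.2 — RV systolic pressure is about one fifth of LV; a
  larger scale would exceed the aortic pulse pressure and erase the RCA's
  systolic first peak). The pulse leads ejection by 80 ms
  (isovolumic contraction), which is what produces the physiologic
  waveform morphology; leads of 50–80 ms behave equivalently.
* reference pressures `Pv = Pref = 0`: only pressure differences enter FFR
  and waveform shapes. An optional hyperemic mode multiplies the coronary
  microcirculatory resistance by 0.24 (adenosine vasodilation) for the
  classical hyperemic FFR; the resting ratio is the default and is what the
  package reports.

## The synthetic inlet waveform

`make_inlet_waveform()` is a piecewise-sinusoidal template: half-sine
ejection over the systolic fraction, a 5%-of-peak reverse dip at valve
closure, and a low diastolic hump (4% of peak — in the aortic root diastolic
flow is essentially coronary inflow). The sampled series is renormalised so
its discrete periodic mean equals the target cardiac output exactly. The
generator is calibrated only by qualitative physiology: with the default
network it must produce a diastolic-dominant LCA waveform and a two-peak RCA
waveform (asserted as a smoke test); no published numeric trace is fitted.
Optional band-limited noise (seeded, off by default) lets users roughen the
template; a digitized waveform can be passed directly wherever a waveform is
accepted.

What the generator does *not* emulate: beat-to-beat variability, heart-rate
dependence of the systolic fraction, and wave propagation (the 0D network
has no wave speed). Passing tests therefore demonstrate correct circuit
physics and numerics, not patient realism.

## Network assembly and the stenosis element

The tree is aortic root → {aortic Windkessel, LM, RCA}; LM → {LAD, LCX}.
Each vessel contributes one Poiseuille resistance computed from its healthy
radius over its full length (a proximal/distal split around the lesion would
be in series with it and collapses to the same 0D equations, so a single
element is used); inertance (`ρL/A`) is available but off by default — the
outlet circuits are resistive-capacitive and the added stiffness buys no
accuracy at 2 ms steps. A lesion adds the empirical two-term loss

`ΔP = Kv · 8μL_s/(π r_t⁴) · Q + Kt · (ρ/2)(1/A_s − 1/A_0)² · Q|Q|`

with `Kv = 1` (the viscous term is then exactly the throat's Poiseuille
resistance over the lesion length, so the law reduces to Poiseuille as
`A_s → A_0`) and `Kt = 1.52`, the classical empirical expansion-loss
coefficient. The law is odd in `Q`, so flow reversal needs no special
treatment. At `ds = 0` no element is created and the healthy network is
recovered exactly. The coefficients are global defaults, never adjusted per
case.

## Time integration

The network is a small differential-algebraic system: branch flows and node
pressures are algebraic, outlet capacitor pressures are states. Each step
solves the coupled system implicitly — BDF2 with a backward-Euler first
step — and Newton iteration handles the `Q|Q|` loss (relative tolerance
1e-8 on the update, at most 20 iterations; the Jacobian differs from the
constant linear matrix only on the stenosis diagonal, so two or three
iterations suffice). Junction mass conservation is therefore satisfied to
solver precision (≤ 1e-6 relative, tested at every step).

The run protocol is 12 cycles × 500 steps (2 ms); the reported convergence
metric is the maximum over monitored inlet/outlet pressures of the largest
within-cycle change relative to the cycle-mean magnitude, with a 1%
tolerance. States start from the resistive (DC) solution at the mean
inflow, with the myocardial state offset by the mean intramyocardial
pressure — with this initialisation all 57 sweep cases converge below 1%
within the protocol. Because the myocardial compliance has a multi-second
time constant, strict periodicity (capacitor mean currents < 10⁻³ of
throughflow) needs more than 12 cycles from rest; for linear (lesion-free)
networks `solve_transient(init = "periodic")` instead computes the exact
periodic state as the fixed point of the affine cycle map, which the
charge-conservation test uses. The BDF2 solution matches an adaptive stiff
integrator within 0.5% on a two-outlet test network, and halving the step
changes mean pressures by well under 0.5%.

## Hemodynamic metrics

* **FFR**: time-averaged distal over aortic-root pressure across the final
  cycle, measured at the stenosed vessel's distal node (its junction or
  outlet interface — the measurement plane is not standardised, and any
  plane distal of the lesion differs only by the small healthy Poiseuille
  drop). Resting Pd/Pa is reported by default (the simulations model rest);
  the hyperemic mode exists but is not used for the headline results.
* **WSS reduction**: `τ(z, t) = 4μQ(t)/(π r(z)³)`, the quasi-steady
  Poiseuille wall shear mapped uniformly onto each mesh ring (eccentric
  meshes reuse the ring value; azimuthal asymmetry is beyond a 0D model).
* **TAWSS** is the time average of |τ| (the printed definition is ambiguous
  between average-of-magnitude and magnitude-of-average; the former is the
  standard TAWSS and is consistent with the OSI denominator).
  **OSI** `= 0.5(1 − |∫τ|/∫|τ|) ∈ [0, 0.5]`, defined as 0 where the shear
  vanishes identically. Both use trapezoidal quadrature on the solver grid
  (second order, exact for the closed-form test waveforms to rounding).
* **Abnormal areas** sum triangle areas where the vertex-mean metric is
  strictly below 4 (low TAWSS), strictly above 40 dyne/cm² (high TAWSS) or
  strictly above 0.2 (high OSI) — strict inequalities mirror the printed
  thresholds; vertex-mean classification is the simplest convergent rule,
  and boundary triangles whose mean straddles a threshold are genuinely
  ambiguous at mesh resolution.

The synthetic field generator builds cylinder fields from
`mean + amplitude·cos` band waveforms, whose TAWSS/OSI have closed forms,
and returns analytic ground truth alongside; its ground-truth areas use the
band span as represented on the mesh (the ring range inside the band), so
arbitrary user bands remain exactly scoreable. At the default resolution
(401 × 48) the quantifier recovers these areas within 2% (in practice
~0.1%, dominated by the chord-vs-arc circumference factor), and within 1%
after doubling.

## The sweep and what it shows

`run_sweep(make_sweep_fixture())` runs the full design — 4 vessels × DS
{10…70%} × {concentric, eccentric} + normal, 57 deterministic cases — and
tabulates FFR by DS, peak-flow reductions against the normal model (LCA
peak; RCA first characteristic peak, i.e. the first interior local maximum
after cycle start), abnormal areas and convergence. Re-running reproduces
the tables byte for byte. Under the default calibration every mild case
(DS ≤ 50%) keeps resting Pd/Pa above 0.95, with the minimum attained by the
50% lesions; severe (70%) lesions visibly deform the waveforms and depress
FFR toward 0.9.

Known limitations, stated plainly:

* The 70% DS peak-flow reductions are surrogate quantities: a single global
  loss coefficient cannot reproduce a 3D FEM's exact partition between the
  LM lesion (which carries the combined LCA flow, quadratically penalised)
  and the RCA lesion (smaller through-flow at its systolic first peak). The
  package reports what the untuned reduced-order model computes.
* Absolute abnormal TAWSS/OSI area magnitudes require vortex-resolving 3D
  CFD; the quasi-steady reduction produces no recirculation and no
  low-shear pockets behind the throat. The quantifier itself is exact (see
  above) and applies unchanged to imported 3D fields (`import_wss_field()`,
  VTP or CSV, with mandatory unit declaration).
* Problem sizes used throughout the tests — 12 × 500 transient steps,
  57-case sweep, 121 × 32 post-processing meshes (401 × 48 for the
  synthetic-field checks) — are the package defaults chosen to resolve the
  physics at desk scale; all are arguments, and doubling any of them is a
  supported (slower) configuration.
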