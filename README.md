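# coroflow

Reduced-order (0D) hemodynamics of coronary artery stenosis.

Mild coronary stenoses (diameter stenosis below 50%) are classified as
non-obstructive, yet they already reshape the local hemodynamic environment
— low and high wall shear stress and oscillatory, direction-reversing flow
are all linked to plaque initiation, injury and thrombosis. `coroflow` is an
R toolkit for studying how the degree, location and eccentricity of a
stenosis in the four main coronary arteries (LM, LAD, LCX, RCA) affect
pressure, flow and wall-shear metrics, at desk scale: parametric lesion
geometry, a pulsatile lumped-parameter network in place of 3D CFD, and a
quantitative metrics engine that also accepts externally computed surface
WSS fields.

It is aimed at cardiovascular modellers and methods-minded clinicians who
want a transparent, scriptable baseline model — every parameter is a
function argument with a physiologic default, and the whole experiment is a
deterministic pipeline of tibble-returning functions.

## The model

* **Geometry.** Each vessel is a tube of reference diameter `D` carrying one
  lesion of length `L_s` (about 1.3 `D`). A degree of diameter stenosis `ds`
  narrows the throat to `d = D (1 − ds)`, hence throat area
  `A_s = π/4 · d²` and area ratio `(1 − ds)²`. The constriction follows a
  C¹ cosine-squared shape; eccentric lesions displace the lumen centre until
  it is tangent to the healthy wall. Surfaces are exported/imported as STL
  or VTP.
* **Network.** Aortic root → {three-element Windkessel (RCR) aortic outlet,
  LM, RCA}; LM → {LAD, LCX}. Vessels are Poiseuille resistances
  (`8 μ L / π r⁴`, with μ = 0.04 dyne·s/cm², ρ = 1.06 g/mL); a lesion adds
  the empirical two-term loss
  `ΔP = Kv · 8 μ L_s/(π r_t⁴) · Q + Kt · ρ/2 · (1/A_s − 1/A_0)² · Q|Q|`
  (Kv = 1, Kt = 1.52). Coronary outlets use the intramyocardial-pressure
  lumped circuit (Ra, Ra-micro, Rv, Ca, Cim, Pim(t)), which reproduces the
  systolically impeded, diastolic-dominant left coronary flow and the
  two-peak right coronary waveform. Calibration follows
  `Rd + Rp = P_mean / Q_aorta` and `R_cor : R_aorta = Q_aorta : Q_cor`, with
  ratios Rd:Rp = 0.91:0.09 and Ca:Cim = 0.11:0.89.
* **Solver.** Fixed-step BDF2 (backward-Euler start) on the network DAE,
  Newton iteration on the stenosis loss; 12 cardiac cycles × 500 steps with
  the cycle-to-cycle inlet/outlet pressure change reported against a 1%
  tolerance; the final cycle is the result.
* **Metrics.** FFR = mean distal / mean aortic pressure;
  `TAWSS = (1/T)∫|τ| dt`; `OSI = 0.5 (1 − |∫τ dt| / ∫|τ| dt)`; abnormal
  areas sum the surface where TAWSS < 4, TAWSS > 40 dyne/cm² or OSI > 0.2.

## Worked example

```r
library(coroflow)

# a 50% concentric LM stenosis: throat dimensions...
throat_metrics(stenosis_spec("LM", ds = 0.5))
#> # A tibble: 1 × 4
#>   vessel    ds diameter   area
#>   <chr>  <dbl>    <dbl>  <dbl>
#> 1 LM       0.5     0.25 0.0491

# ...and the full transient case: geometry -> network -> BDF2 -> metrics
case <- run_case("LM", ds = 0.5, settings = sweep_settings())
dplyr::select(case$record, vessel, ds, ffr, lca_peak, rca_first_peak,
              convergence, converged)
#> # A tibble: 1 × 7
#>   vessel    ds   ffr lca_peak rca_first_peak convergence converged
#>   <chr>  <dbl> <dbl>    <dbl>          <dbl>       <dbl> <lgl>
#> 1 LM       0.5 0.987     2.64           1.88   0.0000668 TRUE
```

The throat area of 0.049 cm² is the printed reference value for a 50% LM
lesion. The resting mean Pd/Pa of 0.987 says this mild lesion is nowhere
near the 0.8 ischemia threshold, while the LCA peak flow (2.64 cm³/s, in
diastole) is already slightly below the healthy model's 2.69 cm³/s. The run
converged: the last cycle differed from its predecessor by 0.007%.

The full experiment — 4 vessels × 7 DS levels × 2 eccentricities + the
normal baseline — is one call:

```r
sweep <- run_sweep(make_sweep_fixture(), out_dir = "results")
autoplot(sweep, "ffr")
```

which writes `ffr_by_ds.csv`, `peak_reductions.csv` and
`abnormal_areas_by_ds.csv`. A thin CLI wrapper with the same behaviour is
installed at `inst/cli/coroflow`.

## Limitations

The network model is zero-dimensional: it cannot form recirculation zones,
vortices or azimuthal shear asymmetry, so absolute abnormal-area magnitudes
of 3D CFD are out of reach (the quasi-steady Poiseuille WSS reduction is
provided for qualitative fields, and the area quantifier works on imported
3D results). See the methods vignette (`vignettes/coroflow-methods.Rmd`)
for the full account of the model, its calibration and its numerical
choices.
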