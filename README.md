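# iustherm

Forward simulation and treatment-planning engine for thermal ablation
with **catheter-based interstitial ultrasound** applicators — linear
arrays of 1-4 sectored tubular transducers (10 mm × 1.5 mm OD,
6.5-9 MHz) inside a water-cooled 2.4 mm implant catheter, as used for
focal ablation of prostate cancer and other soft-tissue targets.

The package is aimed at thermal-therapy modelers and medical physicists
who need to predict ablation zones for device placement and parameter
selection. It implements the complete acoustic-biothermal chain:

* **Acoustics** — sectored tubular-source intensity
  `I = I0 (r0/r) exp(-2 α f (r - r0))`, collimated to each element's
  axial span, with volumetric deposition `Q = 2 α f I` superposed over
  elements and applicators.
* **Bioheat** — explicit FDTD solution of the Pennes equation
  `ρc ∂T/∂t = k∇²T − ω_b C_b (T − T_b) + Q` (0.5 mm / 0.1 s defaults,
  stability-checked), with convective catheter/urethral cooling
  `k ∂T/∂n = h (T_w − T)`, adiabatic domain edges, and irreversible
  perfusion shutdown where the thermal dose reaches 300 CEM43 min.
* **Dose & metrics** — Sapareto-Dewey CEM43 accumulation
  (`R = 0.25 / 0.5` below/at 43 °C), lethal-contour extraction at
  240/600 min, and zone metrology in the applicator frame (`d1` radial,
  `d2` width, `d3` length, volume) plus ROI temperature statistics.
* **Control** — binary (bang-bang) power regulation and latching
  pilot-point treatment termination at virtual temperature monitoring
  points, updated at 1 s.
* **Planning I/O** — parameter-sweep lookup tables, gzip NRRD volume
  export/import, YAML scene configs, STL voxelization, seeded synthetic
  pelvic anatomy, and a small CLI (`exec/iustherm`).

## Worked example

A two-element 180° applicator driven at 12 W/cm² for 3 minutes (plus the
standard 2-minute cooldown) in a perfused 3 cm prostate-tissue block:

```r
library(iustherm)

model <- makeGenericModel(extent = 0.03, spacing = 1e-3)
ap    <- placeApplicator(2, I0 = 12, sector = 180, rotation = 0,
                         center = c(0, 0, 0))
res   <- runTreatment(model, ap,
                      solverConfig(heatingTime = 3, cooldown = 2),
                      perfusion = 2.5)
res
#> TreatmentResult: 3.0 min sonication + 2.0 min cooldown, 1 applicator(s)
#>   peak temperature 57.3 degC (end of sonication), peak dose 1.12e+04 min CEM43

ablationMetrics(res)
#>   threshold d1_cm d2_cm d3_cm volume_cm3
#> 1       240  0.75   1.1   1.9      0.944
#> 2       600  0.75   0.9   1.7      0.568
```

Reading the output: the TD43 ≥ 240 min contour (complete necrosis)
reaches 0.75 cm outward along the sector bisector (`d1`), is 1.1 cm wide
across it (`d2`), spans 1.9 cm along the catheter (`d3` — the two
10 mm elements plus conduction margins, shortened by the cooled
catheter track), and encloses 0.94 cm³; the conservative 600 min core
is nested inside it. Directionality is visible in the half-moon cross
section: tissue behind the inactive sector stays below lethal dose.
A monitoring point 8 mm off-axis on the bisector reaches 49.9 °C at the
end of sonication:

```r
roiTemperatureStats(res@endOfHeating, points = list(TMP1 = c(0.008, 0, 0)))$tmp
#>     TMP1
#> 49.87926
```

Feedback control, urethral cooling, synthetic multi-structure anatomy,
lookup-table sweeps and NRRD/CSV export are described in the methods
vignette (`vignettes/iustherm-methods.Rmd`) and the function reference.

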