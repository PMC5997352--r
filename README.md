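# atrialab

**Pulmonary-vein electrophysiology, fibrosis and atrial-fibrillation
inducibility on idealized atrial surfaces.**

Catheter ablation of persistent atrial fibrillation (AF) by pulmonary-vein
isolation (PVI) works for some patients and not others, and it is hard to
tell in advance which. The electrophysiology of the pulmonary veins (PVs)
themselves — their action potential duration (APD), conduction velocity
(CV), fiber arrangement and degree of interstitial fibrosis — plausibly
controls both how easily PV ectopic beats induce AF and whether the drivers
that sustain it live in the antral PV region that PVI excludes.

`atrialab` is an R package for exploring those mechanisms *in silico* at
desk scale. It provides:

- an **idealized left-atrial surface generator**: a disc-shaped LA body with
  four tubular PV sleeves, ostial-distal distance fields
  `d = g_j / (g_j + g_d)` from graph geodesics to the junction/distal rims,
  six literature-motivated PV fiber arrangements, PVI lesion bands, and
  synthetic LGE-intensity fields (CARP-style `.pts/.elem/.lon` and legacy
  VTK I/O);
- the **Courtemanche–Ramirez–Nattel human atrial ionic model** (compiled,
  Rush–Larsen) with persistent-AF remodelling (ICaL ×0.3, Ito ×0.5,
  IKur ×0.5), global gNa ×2 and gK1 ×0.8, and a calibrated regional
  parameter table (LA body vs PV), plus a Mitchell–Schaeffer surrogate
  ~50× faster for whole-battery screens;
- an **anisotropic monodomain solver** on triangulated surfaces: P1 finite
  elements with per-element tensors σ = σ_t I + (σ_l − σ_t) f fᵀ, implicit
  diffusion, optional bilayer coupling, and interstitial fibrosis as
  no-flux barriers built by node splitting along stochastically selected
  edge networks (longitudinal edges 4× more likely, density scaled by the
  distance parameter or LGE intensity);
- **clinical-style protocols**: a 32-protocol extrastimulus inducibility
  battery (8 coupling intervals × 4 veins over continuous sinus pacing),
  induction detection, in-silico PVI (lesion conductivity 0.001 S/m) with
  TERMINATION / MACROREENTRY / LA-rotor outcome classification, and exact
  McNemar statistics for paired protocol outcomes;
- **phase-singularity analysis**: FFT-Hilbert phase, per-element
  topological charge, trajectory tracking, PS density maps and the
  **PV PS density ratio** (PV-region PS count over total PS count), the
  predictor of PVI success.

See the methods vignette (`vignettes/atrialab-methods.Rmd`) for the models,
numerical choices and calibration rationale.

## Worked example

Single-cell anchors of the composed membrane models:

```r
library(atrialab)

pv <- steadyStateApd(makeRegionParams("LSPV"), cl = 1000, nBeats = 20,
                     dt = 0.02)
pv$apd90
#> [1] 179.04
la <- steadyStateApd(makeRegionParams("LA_BODY"), cl = 200, nBeats = 40,
                     dt = 0.02)
c(la$apd90, la$captured1to1)
#> [1] 173.14  1.00
```

The baseline PV cell repolarises in ~179 ms at cycle length 1000 ms (the
clinical baseline is 181 ms); the LA-body cell, driven hard at cycle
length 200 ms, reaches ~173 ms with stable 1:1 capture (capture status is
always reported because the diastolic interval at this rate is only ~25 ms).
Scaling the PV inward-rectifier conductance over the clinical range
k ∈ [0.5, 2.5] spans APDs of ~197 down to ~106 ms.

A reduced inducibility experiment on the idealized atrium with the fast
surrogate model:

```r
gp <- geometryParams(bodyRadius = 20,
                     veinRadius = c(LSPV = 4, LIPV = 3.5, RSPV = 4.5,
                                    RIPV = 3.8),
                     veinLength = c(LSPV = 10, LIPV = 8, RSPV = 6,
                                    RIPV = 7),
                     veinCenter = rbind(LSPV = c(-10, 7.5),
                                        LIPV = c(-10, -7.5),
                                        RSPV = c(10, 7.5),
                                        RIPV = c(10, -7.5)),
                     edgeLength = 1, lesionClearance = 2.5)
mesh <- generateIdealizedAtrium(gp)
cond <- conductivityField(mesh)   # sigma_l tuned so planar CV = 0.67 m/s

# PV APD longer than LA APD is protective: nothing induces
bat <- runBattery(mesh, cond, model = "surrogate",
                  mult = buildSurrogateMultipliers(mesh, pvApdScale = 1.1))
inducibilityRatio(bat$induced)
#> [1] 0
```

Tissue-level CV follows the conductivity divisors used to span the
clinical PV range (0.28–0.67 m/s for divisors 5…1):

```r
strand <- generateStrandMesh(40, 8, 0.34)
strandCv(0.1746, strand = strand, probeGap = 20)            # baseline
#> [1] 0.6701514
strandCv(0.1746, strand = strand, divisor = 5, probeGap = 20)
#> [1] 0.2816998
```

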