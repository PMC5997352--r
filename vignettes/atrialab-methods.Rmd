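---
title: "Methods: pulmonary-vein electrophysiology, fibrosis and AF inducibility at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulmonary-vein electrophysiology, fibrosis and AF inducibility at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model overview

`atrialab` is an in-silico laboratory for a single scientific question: how
do the electrophysiological properties of the pulmonary veins (PVs) — action
potential duration (APD), conduction velocity (CV), fiber architecture and
interstitial fibrosis — shape the inducibility of atrial fibrillation from
PV ectopic beats, the location of the drivers that sustain it, and the
outcome of pulmonary-vein isolation (PVI)?

The pipeline has five layers, each usable on its own:

1. **Synthetic geometry** (`generateIdealizedAtrium`): an idealized
   left-atrial surface — a disc-shaped body with four tubular PV sleeves —
   replaces patient-derived meshes, which are not distributable. Every
   downstream stage (distance fields, fiber rules, fibrosis, lesion sets,
   analysis regions) is defined on this geometry exactly as it would be on
   a patient mesh.
2. **Membrane models**: the Courtemanche–Ramirez–Nattel (CRN) human atrial
   ionic model (21 state variables) with persistent-AF remodelling, and a
   Mitchell–Schaeffer two-variable surrogate for cheap whole-battery
   experiments.
3. **Monodomain solver** (`runSimulation`): anisotropic reaction–diffusion
   on the triangulated surface, with fiber-based conductivity tensors and
   no-flux fibrosis barriers.
4. **Protocols** (`runBattery`, `runPviExperiment`): a clinical-style
   extrastimulus battery, induction detection, in-silico PVI and outcome
   classification.
5. **Phase analysis** (`detectPs`, `psDensity`, `pvPsDensityRatio`): rotor
   cores are phase singularities (PSs) of the transmembrane voltage; their
   spatial density, split by an anatomical PV/LA/RA partition, is the
   primary readout.

## Membrane models and the regional parameter table

The CRN model is implemented from its published formulation (Rush–Larsen
updates for the 13 Hodgkin–Huxley gates, forward Euler for voltage,
calcium-release gates and concentrations; `dt` = 0.02 ms for single cells,
0.05 ms in tissue). The resting state reproduces the published resting
potential (−81.2 mV) and the unmodified model paces to an APD90 near 300 ms
at cycle length (CL) 1000 ms, both used as sanity anchors in the tests.

Electrical remodelling of persistent AF is applied as conductance
multipliers on the published values: ICaL ×0.3, Ito ×0.5, IKur ×0.5,
composed with two global modifiers — sodium conductance ×2 (realistic
upstroke velocity in tissue) and IK1 ×0.8 (clinical restitution). Regional
electrophysiology (LA body vs PV sleeves) is a further multiplier set. The
full composition lives in one versioned, human-readable table
(`inst/extdata/ionic_regions_v1.tsv`, accessor `ionicTable()`), so corrected
or alternative parameterisations are data edits, not code edits.

The primary sources for the regional factors do not publish a complete
table, so the regional rows are *calibrated* against three measured
anchors: the baseline PV cell paces to APD90 ≈ 181 ms at CL 1000 ms; the LA
body cell is measured at CL 200 ms against a 185 ms target; and scaling the
PV IK1 conductance by k ∈ [0.5, 2.5] spans the clinically reported PV APD
range of roughly 190 down to 100 ms. Three properties of the calibrated
table are worth knowing:

* The PV row (IK1 ×0.89, IKr ×1.52, IKs ×1.62, Ito ×1.54, IKur ×1.26,
  ICaL ×0.79, INaCa ×0.96) is qualitatively consistent with reported PV
  cellular electrophysiology (reduced inward rectifier, larger delayed
  rectifiers). An IK1-only PV modification cannot satisfy all three anchors
  simultaneously — APD(k) is convex in k, while the anchors demand a nearly
  flat response below k = 1 and a steep one above — which is why several
  currents participate.
* The LA row (IKr ×0.70, ICaL ×1.10, Ito ×0.80) saturates at APD90 ≈
  173–174 ms at CL 200 ms with stable 1:1 capture. Pushing the composed
  model toward 185 ms at this extreme rate (diastolic interval ≈ 15 ms)
  triggers APD alternans and then loss of capture, so the calibration stops
  at the longest *stable* APD; `steadyStateApd()` logs capture status and
  convergence for exactly this reason.
* APD90 is measured on the final beat after 20 conditioning beats, from the
  maximum-upstroke-slope time to 90% repolarisation relative to the beat's
  own amplitude, with linear interpolation between samples; the stimulus is
  a 2 ms pulse at twice diastolic threshold (20 µA/µF).

The surrogate is a Mitchell–Schaeffer excitable model (u, h;
τ_in = 0.3 ms, τ_out = 6 ms, τ_open = 120 ms, τ_close = 150 ms,
u_gate = 0.13), mapped to millivolts as V = −80 + 100u so every analysis
threshold applies unchanged. `calibrateSurrogate()` adjusts τ_close to a
target APD (secant iteration); an IK1-like multiplier field k maps to a 1/k
scaling of τ_close. The surrogate runs roughly 50–60× faster than CRN per
step at the same `dt` and is the default engine for whole-battery sweeps.

## Monodomain solver

The monodomain equation is discretised with linear (P1) finite elements on
the triangulated surface. Each element carries the tensor
σ = σ_t I + (σ_l − σ_t) f fᵀ in its plane (f the unit fiber vector);
diffusivity is D = σ/(β C_m) with surface-to-volume ratio β = 1.4×10⁵ 1/m
and C_m = 0.01 F/m². Time stepping is first-order operator splitting:
membrane substeps (Rush–Larsen/Euler) followed by one implicit (backward
Euler) diffusion solve with a Cholesky factorisation computed once per run.
Pure Neumann boundaries make the stiffness rows sum to zero, so a spatially
uniform state is preserved to 10⁻¹⁰ — a property test.

Two numerical choices matter at the working resolution of 0.34 mm:

* **Consistent vs lumped mass.** With a lumped mass matrix, the planar CV
  of a divisor-5 wave (slow conduction) falls ~20% below its continuum
  value at 0.34 mm; with the consistent P1 mass matrix (the default) the
  measured CVs track the continuum √σ law within a few percent at 0.34 mm
  and ~1% at 0.1 mm. `massLumping = TRUE` remains available for speed.
* **Conductivity tuning.** The study's baseline tissue conductivities were
  tuned to clinical activation maps that are unavailable here; instead the
  baseline σ_l is tuned (by `tuneStrandConductivity`, using CV ∝ √σ as a
  fixed-point iteration) so a fiber-aligned planar wave on a
  40 mm × 8 mm, 0.34 mm strand propagates at 0.67 m/s with the composed LA
  membrane model. The result, σ_l = 0.1746 S/m with a fixed 4:1 anisotropy
  (2:1 CV anisotropy), is the package default; dividing both conductivities
  by 5 then yields 0.28 m/s, matching the reported PV CV range of
  0.28–0.67 m/s for divisors 5…1.

Interstitial fibrosis is *microstructural decoupling*, not diffuse
conductivity scaling: selected mesh edges become no-flux barriers by node
splitting. Interior nodes of each connected decoupled-edge network are
duplicated, one copy per side of the crack (element fans are partitioned by
the crack edges), while network endpoints remain shared — a crack tip, not
a hole. Zeroing cross-edge conductance instead would not create a true
discontinuity at P1 order, which is why splitting is used. A full-width
crack blocks a planar wave; a crack with a gap does not (both are tests).

Bilayer (endo/epi) meshes couple node pairs resistively with a rate
constant (default 0.5 1/ms scaled by nodal area) chosen to keep the
endo–epi activation delay on a test patch below a few ms; the idealized
geometry is single-layer by default, and all protocols run identically on
either.

## Idealized geometry

The default geometry is a 35 mm-radius disc with four PV sleeves (ostial
radii 6–8 mm, sleeve lengths 10–20 mm) at ±18 mm laterally, a sinoatrial
(SAN) stimulus patch on the inferior body edge, an appendage (LAA) label
patch, and two PVI lesion bands, each an annulus enclosing one ipsilateral
vein pair at 4 mm clearance. The body is a regular triangular lattice at
the target edge length; ostia are carved and their rims projected onto the
ostial circles; sleeves are regular cylindrical rings stitched to the rims
by a greedy "zipper" triangulation. The default mesh hits the 0.34 mm
target mean edge length within well under 5% and has the Euler
characteristic of a disc with four holes (χ = −3). The right atrium is
omitted (all pacing protocols stimulate the SAN patch or the veins), so the
RA analysis region is empty — scaled-down results must be read as LA + PV
physiology only.

Per vein, the ostial–distal **distance parameter** is
d = g_j / (g_j + g_d), where g_j and g_d are graph-geodesic (Dijkstra)
distances to the junction and distal rims computed along mesh edges
restricted to the vein. The raw quotient g_j/g_d is unbounded, whereas this
normalisation is a [0, 1] coordinate with exact boundary values — every
consumer (IK1 gradients, conductivity gradients, fiber rotation, fibrosis
density) treats it as such. Graph geodesics (rather than exact polyhedral
geodesics) are accurate to the metrication error of the lattice, a
relative few percent; the in-plane gradient of d defines the longitudinal
direction of a vein and its perpendicular the circumferential one, so
"circumferential" is precisely "tangent to the level sets of d".

Six PV fiber arrangements are implemented on top of this frame (circular;
spiralling 45°; circular endo with longitudinal epi; a 90° circumferential
to longitudinal rotation along d, identical on both layers; that rotation
on the epi with circular endo; and the rotation plus chaotic disorder at
the junction, Gaussian angle noise with standard deviation σ₀ (1 − d),
σ₀ = 45° by default — the source describes "standard Gaussian" disorder
scaled by distance from the distal boundary without fixing the scale, so
σ₀ is configurable). Case 0 is the generator's own default (uniform body
fibers, circumferential sleeves).

**Synthetic LGE.** Population-averaged or patient LGE-MRI intensity maps
drive body fibrosis in the original study but are not available; the
generator provides three stand-ins (`generateSyntheticLge`): `uniform`,
`pv_graded` (intensity rises with d — the histological pattern of denser
distal PV fibrosis), and `patchy` (seeded smooth Gaussian blobs,
correlation length 5 mm by default). These are labelled synthetic
throughout and reproduce only the *spatial statistics* a fibrosis model
needs (normalized [0, 1] intensity, smooth patches), not any patient
distribution.

## Fibrosis selection

Each eligible edge is selected independently with probability
p = ρ · w_field(e) · w_angle(θ), clamped at 1 (clamping is counted and
reported). w_field is the mean of the distance parameter (PV variant) or
the mean normalized LGE intensity (body variant) over the edge's
endpoints. w_angle(θ) = 1 + (A − 1) cos²θ interpolates from 1 for edges
transverse to the local fiber to A = 4 for longitudinal edges — the
reported 4:1 longitudinal:transverse likelihood, exact at both endpoints;
cos² is the smoothest such interpolation and the source fixes only the
endpoints. ρ is a free calibration knob (the source reports "moderate" and
"high" PV fibrosis without numbers; defaults 0.15 and 0.3). Edges are
processed in canonical (min, max) index order under one seeded RNG draw,
so selections are portable and bit-reproducible.

## Protocols

**Inducibility battery.** Sinus rhythm is continuous SAN-patch pacing at
CL 700 ms. Each protocol adds five ectopic beats at CL 160 ms in one vein,
the first beat one coupling interval (CI) after the onset of the second
sinus beat; the standard battery crosses CI ∈ {200, 240, …, 480} ms with
the four veins (32 protocols, vein-major, CI-ascending). The ectopic site
is a 1.5 mm-radius node patch in the distal third of the vein (the source
marks sites only graphically). Whether sinus pacing pauses during the
train is unstated; it continues here.

**Induction criterion.** The source never defines "resulting in reentry".
The operational definition — the largest free parameter in the package —
is: self-sustained activity beyond T_sustain = 1000 ms after the last
ectopic stimulus, evidenced by (a) a PS trajectory living ≥ 300 ms in the
post-stimulus window, or (b) any node activating ≥ 3 times there *in
excess of* the sinus beats still being paced (sinus pacing continues
through the observation window, so paced activations are discounted, and
the transient ~100 ms wavebreak PS pairs that a sinus wavefront sheds
when it collides with refractory ostial tissue do not count as reentry).
Both sub-criteria are logged on every outcome; T_sustain, the lifetime
threshold and the excess-activation count are configurable. The inducibility ratio is
the induced fraction, reported to two decimals as in the source tables
(12/32 → 0.38, 1/32 → 0.03).

**PVI.** Eligibility requires ≥ 2 s of sustained arrhythmia
post-initiation (initiation = first detected PS after the last stimulus).
PVI sets both conductivities to 0.001 S/m on every element touching a
lesion band, 2 s post-initiation; activity 1 s later is classified as
TERMINATION (all nodes within 5 mV of rest, no activations in the final
200 ms), LA_ROTORS (≥ 1 sustained PS — trajectory lifetime ≥ 500 ms,
configurable — in the LA body) or MACROREENTRY (persisting activity
without sustained PSs; the cycle-length periodicity of activation along
the reentrant path is measured and recorded with 10% tolerance). The
classes are mutually exclusive and exhaustive by construction and each is
exercised by an analytic fixture in the tests.

**Paired statistics.** Gradient-vs-homogeneous comparisons on the same 32
protocols use McNemar's test: exact two-sided binomial on the discordant
pairs (p = 1 when none), with a continuity-corrected χ² variant behind a
flag. The exact variant is verified against a combinatorial enumeration
oracle for all discordant totals ≤ 12.

## Phase analysis

Phase is the angle of the analytic signal (FFT-based Hilbert transform) of
V minus its temporal mean, per node, with no pre-filtering by default; a
100 ms guard band at each end of the analysis window is flagged and
excluded from detection. PSs are detected per element by topological
charge: the wrapped phase differences around the ordered corners sum to
2π × (winding number), which on a triangle is always −1, 0 or +1. Corner
order follows the mesh orientation, so chirality is comparable across
frames and runs; an independent check unwraps the phase along arbitrary
closed node loops and compares the loop winding number with the enclosed
charge sum. Trajectories are greedy nearest-neighbour links (max jump
5 mm/frame, same chirality). The PS density map counts events within
R = 2.5 mm of each node per ms of window (the cited density method's
details are not in the source; fixed-radius counting is the simplest
estimator consistent with it, and R is configurable). The **PV PS density
ratio** is the PV-region event count over the total event count, with the
PV region defined topologically: lesion-band nodes plus every
connected component (after removing the lesion nodes) that contains a
vein node — i.e., "enclosed by, and including, the PVI lines". "Count" is
ambiguous between events and trajectories in the source; events are used,
with the trajectory-based alternative available.

## Default analysis windows and problem sizes

The analysis window defaults mirror the study design (start 2 s
post-initiation, 10 s length) and shrink to what a record contains, with a
log. The package's own test and acceptance runs use desk-scale problem
sizes chosen to keep the full suite in the tens of minutes on one CPU:
batteries run the surrogate model on a 20 mm-radius idealized atrium at
1.0 mm edges (~2000 nodes), CV measurements use CRN on
40 × 8 mm strands at 0.34 mm (~3300 nodes) and √σ-law checks a
20 × 2 mm strand at 0.1 mm, and single-cell anchors use the full CRN
model. These sizes are the package's reference configuration, not a claim
that the full-paper scale (bilayer bi-atrial patient meshes, tens of
seconds of fibrillation) is reproduced; whole-atria inducibility values
at that scale are expected to differ quantitatively.

## What the synthetic geometry does and does not emulate

Reproduced: the PV sleeve topology and dimensions, ostial-distal gradient
coordinate, the six fiber arrangements, lesion-enclosed analysis regions,
distance/LGE-weighted anisotropic fibrosis, and the pacing anatomy (SAN
patch, distal-vein ectopic sites). Not reproduced: patient anatomical
variability (PV areas/lengths drive inducibility differences in the
source), the right atrium and inter-atrial connections, wall-thickness
(bilayer transmural) heterogeneity unless the bilayer option is enabled,
trabeculated structures, and real LGE distributions. Tests passing on this
geometry validate the algorithms and their couplings, not patient-level
predictions.

## Known limitations

* The LA APD anchor at CL 200 ms is reachable only to ~174 ms with stable
  1:1 capture in this composed CRN variant; the discrepancy (≈ 11 ms,
  within the acceptance band) is documented above and in the calibration
  notes rather than hidden by measuring an alternans beat.
* The induction criterion and PS-sustainment threshold are free
  parameters; whole-battery inducibility ratios are sensitive to them at
  full scale.
* The surrogate model reproduces APD and CV after calibration but not CRN
  restitution or rate adaptation; surrogate batteries are qualitative
  screens.
* Graph geodesics make the distance parameter and the fiber frames exact
  only up to lattice metrication (a few percent; ~0.1 rad on fiber
  angles at 1 mm edges).
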