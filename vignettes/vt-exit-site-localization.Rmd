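---
title: "Simulation-driven localization of post-infarct VT exit sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-driven localization of post-infarct VT exit sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Catheter ablation of post-infarct ventricular tachycardia (VT) targets the
*exit site*: the point where the re-entrant wavefront leaves the protected
isthmus between scar lobes and captures healthy myocardium, producing the
earliest systolic activation of the beat. Locating that point non-invasively,
from the 12-lead surface ECG or from the electrograms (EGMs) an implanted
device already records, would shorten and de-risk the invasive procedure —
and is the only option when VT cannot be safely induced and mapped.

`vtlocalizer` implements a desk-scale version of a simulation-driven
strategy for this task: simulate a large library of focal paced beats and
figure-of-eight VT beats on virtual ventricular anatomies together with
their ECGs and device EGMs, train a regressor that maps the multichannel
traces to the exit site expressed in universal ventricular coordinates
(UVC), transfer-learn from the cheap paced beats to the expensive VT beats,
and quantify accuracy as the localization error (LE) — the Euclidean
distance in mm between the predicted and true exit site.

## Pipeline and models

### Virtual anatomy

Patient imaging is replaced by a parametric left ventricle: a thick wall
between two truncated prolate ellipsoids (defaults: endocardial long axis
90 mm, endocardial short semi-axis 25 mm, wall 10 mm, 70% of the ellipsoid
height retained), meshed into tetrahedra at a target edge length through a
structured layer/ring/sector grid. The epicardial apex sits at the origin
with the long axis along +z. A cohort of "virtual patients" is drawn by
perturbing axes and wall thickness by up to ±10% and jittering electrode
placements by up to ±10 mm (`make_cohort()`, `build_anatomy()`), emulating
the anatomical and lead-position variability between real patients.

Myofiber orientation uses the standard rule-based transmural helix: the
local circumferential direction is rotated about the transmural axis by an
angle interpolated linearly in wall depth from +60° (endocardium) to −60°
(epicardium). Both angles are parameters.

### Coordinates

On this geometry the three UVC coordinates have closed forms: `z` is the
normalized long-axis position (0 at the apex node, 1 on the base plane),
`rho` the transmural layer fraction (0 endocardium, 1 epicardium), and
`phi` the azimuth about the long axis measured from the septal reference
direction, wrapped to (−π, π], positive toward the anterior wall. The
general construction of such coordinates on patient meshes solves
Laplace–Dirichlet problems; on the idealized ellipsoid the closed forms
have identical semantics with no PDE machinery, which is why we use them.

Nearest-node lookup back to Cartesian space minimizes
`sqrt(dz² + drho² + (dphi/pi)²)` — the rotational weight makes a half turn
count as one unit, comparable to the full apicobasal range. The 17-segment
AHA partition is assigned from `(z, phi)` with fixed ring boundaries
(apex cap z < 0.2, apical < 0.45, mid < 0.7, basal ≥ 0.7) and sector
tables anchored so φ = 0 lies mid-anteroseptum.

### Activation

Excitation spread is modelled with an anisotropic eikonal solver on the
mesh edge graph: each edge is traversed at speed
`mult · sqrt((cv_long cosθ)² + (cv_trans sinθ)²)` with θ the edge-to-fiber
angle, and arrival times are Dijkstra shortest paths (igraph) from the
pacing or exit source. Defaults `cv_long = 0.6`, `cv_trans = 0.24` m/s are
standard healthy-myocardium values. An edge shared by several elements
takes its fastest incident traversal, so one conductive neighbour suffices
for local conduction.

A graph metric slightly overestimates continuum travel times (paths are
restricted to edges); the package asserts the overestimate stays below 15%
along quasi-straight paths and treats the graph metric as its own exact
ground truth everywhere else — the localizer learns and is evaluated on the
same metric, so this bias does not leak into LE.

Transmembrane traces are synthesized by shifting a stereotyped
piecewise-linear action potential (rest −85 mV, plateau +20 mV, upstroke
2 ms, APD 280 ms, repolarization 40 ms) by each node's activation time.
Only the first 350 ms after beat onset is stored — the depolarization
sequence that carries the localization information.

### Substrate and VT beats

A virtual infarct is two transmural inexcitable lobes (velocity multiplier
0) framing a slow corridor (multiplier 0.25, rotational half-width
0.08 rad) in UVC space, centered in a chosen AHA segment with seeded
jitter; lobe half-extents default to 0.12 in z and 0.25 rad in φ. A VT
beat is modelled as a single eikonal activation initiated at the exit
site — the excitable node at the seed-chosen corridor mouth — on the
scarred substrate. This reproduces the observable the localizer sees (one
QRS-like systolic sequence sweeping around both lobes per cycle) without
simulating sustained re-entry; the circuit's cycle length (through-corridor
transit plus the return path around the scar) is reported as metadata and
falls in the physiological 200–450 ms window for mid-ventricular circuits,
with basal circuits running somewhat longer return paths.

### Forward model

Extracellular potentials use the homogeneous infinite-volume-conductor
pseudo-ECG: the potential at electrode x is the sum over elements of
`vol · ∇Vm · ∇(1/‖x − c‖)` with element-wise linear shape-function
gradients. This drops torso inhomogeneity but preserves the
source-to-sensor geometry that localization exploits; the gain constant is
1 because traces are z-score normalized per channel before storage or
training. The operator is precomputed once per anatomy as a
channels-by-nodes matrix, making each beat a single matrix product.

Surface channels are the standard 12 leads (Wilson central terminal
reference) plus four vector combinations: X = V6 − V1, Y = aVF,
Z = V2 − (V6 + I)/2, M = V1 + V2 + V3 − V4 − V5 − V6 — declared,
configurable approximations of orthogonal-axis and precordial-balance
combinations, since no canonical set exists for this augmentation. Device
channels are eight bipoles using every electrode of a generic implanted
device (RV tip–ring, LV1–LV2, LV2–LV3, LV3–LV4 near field; RV coil–can,
SVC coil–can, RV–SVC coil, LV4–can far field). Every channel is a zero-sum
electrode combination, asserted at construction, so all outputs are
reference-invariant.

### Localizer

The regressor maps a beat's channels × 350 ms window to
`(z, rho, sin φ, cos φ)`. The sine/cosine pair handles the rotational
wraparound: two sites straddling the φ = ±π seam have nearly identical
targets instead of a spurious full-turn error. The reference architecture
is deliberately small and fully specified in code: block-average temporal
downsampling (factor 10), flattening, two 96-unit ReLU encoder layers, a
32-unit head layer, and a linear 4-output layer, trained with minibatch
Adam (lr 1e-3, batch 64) on the mean-squared error of the 4-vector
(components are comparably scaled: z, rho in [0,1], sin/cos in [−1,1]).
A seeded validation split drives early stopping; the best-validation-epoch
parameters are kept, and the returned parameters always come from a
trained epoch. ECG and EGM modes are separate models throughout.

Transfer learning re-trains part of the network on VT beats:
`freeze_encoder` (default) freezes both encoder layers and adapts the
head; `freeze_all_but_last` trains only the output layer; `none` is
ordinary continued training. Frozen tensors are asserted bit-identical
after fine-tuning. A convolutional encoder would be the conventional
choice at production scale; at this problem size a dense encoder over
downsampled windows trains in seconds on one CPU, is exactly reproducible,
and leaves the architecture a drop-in config object.

### Evaluation protocols

Two held-out protocols quantify generalization, rotating over the cohort:

* **Scenario 1** (*seen pacing, unseen VT*): the base model trains on paced
  beats of all anatomies including the held-out one; transfer learning
  excludes the held-out anatomy's VT beats; testing uses exactly those.
* **Scenario 2** (*fully unseen*): the held-out anatomy is excluded from
  both stages.

Per-case LE tables, pooled and across-anatomy summaries (mean, population
standard deviation — matching "mean ± sd" conventions — min, max, n) and
17-segment hit-rate reports are persisted; leakage audits over the sample
manifests are part of the result object and the test suite. Scenario 1 is
expected to outperform Scenario 2; the package asserts this only as a
majority vote across the five held-out rotations (each with its own seed),
not per rotation — re-running the entire pipeline several times for the
same qualitative check would multiply runtime for no extra insight.

## What the generator does and does not emulate

The synthetic cohort reproduces the *structure* of the clinical problem:
inter-patient geometric variability, electrode placement variability, an
anisotropic activation sequence, scar-constrained VT with a slow isthmus,
and the two trace modalities. It does not emulate torso conductivity
heterogeneity, Purkinje-mediated endocardial breakthroughs, repolarization
heterogeneity, measurement noise (available as an optional additive
Gaussian flag, default off), fractionated electrograms inside scar, or
functional block. Passing the package's acceptance checks therefore shows
the method works end-to-end under controlled conditions at desk scale —
it does not certify clinical-grade accuracy on real ECGs.

## Numerical choices

* Meshing: structured hexahedra split into 5 tetrahedra with alternating
  parity (even sector counts enforced); degenerate cells dropped; seeded
  jitter only moves interior nodes by ±5% of the edge length.
* Eikonal ties: igraph Dijkstra is deterministic; multi-source solves take
  the per-node minimum of offset single-source solutions.
* UVC lookup ties break to the lowest node index.
* z, rho outside [0,1] at inference are clipped and counted
  (`n_clipped` on the prediction).
* All randomness flows from explicit seeds through an isolated RNG that
  never disturbs the caller's `.Random.seed`; a single global seed derives
  stage seeds via a documented splitting rule (`derive_seed()`).
* Library storage uses RDS plus a plain-text CSV manifest and JSON config
  snapshot — native R serialization keeps the on-disk container
  dependency-free.

## Problem sizes

The evaluation configuration used throughout the package's own acceptance
runs is 5 anatomies at 4 mm target edge length (≈2000 nodes each),
500 paced + 60 VT beats per anatomy, base training ≤150 epochs and
transfer ≤120 epochs with early stopping. At these settings the full
pipeline — libraries, both scenarios, both modalities — completes in well
under half an hour on a single CPU. The 4 mm edge is the coarsest
resolution at which the default scar lobes stay resolvable (≥20 nodes per
lobe); the paced-beat count is a scaled-down stand-in for the ~3000 beats
per model a production run would use, reachable via `library_config()`.

## Known limitations

* LV only: no right ventricle (no RV UVC coordinate), no torso surface.
* One scar morphology (two UVC boxes + corridor); no multi-circuit
  substrates.
* The VT beat is a single systolic activation, not sustained re-entry;
  diastolic corridor activity is summarized by the cycle-length metadata
  only.
* The pseudo-ECG omits torso inhomogeneity, so absolute trace amplitudes
  are not physiologic; per-channel normalization makes the localizer
  scale-free by construction.
* LE is computed in Cartesian mm after nearest-node back-mapping, so it is
  quantized at the mesh edge length.

## A minimal run

```{r}
library(vtlocalizer)

cohort <- make_cohort(5, geometry_params(target_edge_length = 4), 1)
cfg <- library_config(cohort, n_paced_per_anatomy = 500,
                      n_vt_per_anatomy = 60, global_seed = 1)
bundles <- build_bundles(cfg)
pacing <- build_pacing_library(cfg, bundles)
vt <- build_vt_library(cfg, bundles)

s1 <- run_rotating_evaluation(pacing, vt, "seen_pacing_unseen_vt", "ecg",
                              seed = 42)
s1$pooled      # pooled LE over all held-out VT beats
s1$across_models  # mean LE per held-out anatomy, summarized
segment_report(s1$cases)
```
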