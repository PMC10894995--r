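---
title: "Validating volume-conduction head models against sEEG stimulation artifacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating volume-conduction head models against sEEG stimulation artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Under the quasi-static approximation, the electric potential $u$ generated
by a current source density $f$ in a head with conductivity field
$\sigma(x)$ satisfies the Poisson problem
$\nabla\!\cdot(\sigma\nabla u) = f$ with an insulating boundary
($\sigma\,\partial u/\partial n = 0$ on the scalp). Clinical stimulation
mapping injects a brief current pulse between two neighboring depth-electrode
contacts; the passively volume-conducted artifact recorded on every other
intracranial contact is a direct measurement of that potential field, so a
forward model can be tested against it. The study design implemented here
keeps the geometry and the numerical method fixed and varies only the level
of conductivity detail:

* **3C** — scalp 0.43, skull 0.01, everything inside the skull 0.33 S/m;
* **4C** — additionally distinguishes CSF at 1.79 S/m;
* **5C** — additionally splits the brain into gray (0.33) and white
  (0.14) S/m.

The stimulating pair is modeled as a point current dipole at its midpoint,
with moment along the anode–cathode axis times the 3.5 mm contact
separation and unit current; recording contacts are point sensors. The
amplitude left unknown by this convention (stimulation strength, pulse
undersampling) is absorbed by a single scaling factor fitted to the data.

## Analytic oracle

For concentric spherical shells the problem has a semi-analytic solution:
each Legendre degree $n$ contributes radial fields $A r^n + B r^{-(n+1)}$
per shell, with continuity of potential and radial current across
interfaces and zero radial current at the outer surface. Two numerical
choices matter:

* The interface recursion is evaluated in the scaled basis
  $(p, q) = (A r^n, B r^{-(n+1)})$ at the interface radius — the physical
  contributions of the two branches — and the boundary-condition-satisfying
  solution is propagated **inward** from the surface. Building it outward
  instead subtracts exponentially growing basis solutions and hits a
  cancellation floor around $10^{-9}$ relative by degree 200.
* The closed-form infinite-medium dipole term is used at every field point,
  in every shell; the series carries only the induced (reflected) field.
  Without this, a contact radially just above the source converges at the
  multipole rate $(b/r)^n$, which is arbitrarily slow.

Even so, contacts ~1 mm above the innermost interface with a deep-capped
dipole converge at a rate near 0.966 per degree, so the default truncation
is generous (`n_terms` 400 for `shell_model`, 800 with tail tolerance
$10^{-9}$ for the data-generator constructor); degrees cost microseconds.
Truncation failure raises an error carrying the tail estimate rather than
returning an unconverged sum.

## Hexahedral FEM solver

One trilinear hexahedral element per labeled voxel, with nodes at shared
voxel corners. A node touching voxels of two or more tissue labels is moved
`node_shift` × half a voxel (default 0.3, the geometry-adaptation strength)
toward the centroid of its incident voxels carrying the locally-minority
label, smoothing the voxel staircase at interfaces; displacements are
halved iteratively if an element's Jacobian would turn non-positive, and
positivity is verified at all 2×2×2 Gauss points. Stiffness entries
$K_{ij} = \sum_e \sigma_e \int_e \nabla\varphi_i\cdot\nabla\varphi_j$ use
the same quadrature, which is exact for trilinear elements. The 3C/4C/5C
systems share one mesh; only the per-element conductivities change.

**Source model.** Two standard dipole discretizations are provided. Partial integration ($b_i = m\cdot\nabla\varphi_i(x_0)$,
supported on the containing element) is implemented and exposed, but its
accuracy collapses when the dipole lands near an element corner, where
shape-function gradients are discontinuous: on the 50 mm test phantom at
2 mm resolution the worst-case RDM across random dipoles was 0.109. The
St. Venant variant — the minimum-norm monopole distribution on the node
patch around the nearest vertex reproducing zero total current, the exact
dipole moment and zero second moments — cuts that worst case to 0.044
(median 0.016) and is therefore the default of the forward-table
simulation. `source_model = "partial"` restores the alternative.

**Solver.** $K$ is symmetric positive semi-definite with the constant
vector as nullspace. The default solve is Jacobi-preconditioned conjugate
gradients to relative residual $10^{-9}$ (cap $10\sqrt{n} + 1000$
iterations), followed by a zero-mean gauge shift; loads must sum to zero
(compatibility with the insulating boundary), which both source models
satisfy identically. A cached sparse-Cholesky path (`method = "direct"`,
one grounded node) exists for many right-hand sides on small meshes, but on
the phantoms used here CG converges in under a second and is the default.
Element containment uses half-open voxel intervals (a point on a shared
face belongs to the larger-index voxel; the outermost face belongs to the
last voxel), and sensor interpolation inverts the trilinear map by Newton
iteration so that nodal values are reproduced exactly even on shifted
meshes.

**Reciprocity.** The potential table over (stimulation pair × bipolar
channel) can equivalently be computed per channel: solve once with a +1/−1
load at the channel's two contacts and take inner products with each pair's
load vector. Symmetry of $K$ makes the two routes agree to solver
tolerance; the suite asserts $10^{-6}$ relative.

## What the synthetic data emulate — and what they do not

`simulate_recording` plays the role of the clinical acquisition:
stimulation events inject, on every monopolar channel, the analytic
ground-truth potential difference to a white-matter reference, multiplied
by a global gain (default 200, the scale such validations typically fit)
and by a sampled pulse waveform — a 0.3 ms rectangular
pulse through a first-order capacitive high-pass (default corner 80 Hz,
time constant ≈ 2 ms so the filter tail outlasts the pulse), decimated to
1 kHz with the onset 0.4 ms after the trigger sample. The sampled peak is
therefore strictly below the continuous amplitude, exactly the
undersampling the scaling factor compensates. Gaussian noise (default
2 µV) is added; bad channels are replaced by 10 mV white noise to trip the
variance exclusion.

The generator deliberately uses the **analytic** solver, never the FEM
under test, so FEM discretization error remains measurable end-to-end.
Because the analytic solution requires the source inside the innermost
shell, stimulation plans cap the pair-midpoint radius accordingly
(`max_midpoint_radius_mm`); shaft placement likewise keeps contacts inside
the ideal sphere (`inside_radius_mm`), since a voxel phantom's surface
staircase can otherwise poke beyond it.

What passing tests on these data do **not** show about real recordings:
sphere phantoms have no skull holes, no CSF shunting along shafts, no
anisotropy, no tissue-segmentation error; the pulse is monophasic with a
single capacitive pole rather than a full acquisition chain (the 0.1–300 Hz
band-pass is approximated by that pole plus sampling); there is no neural
(evoked) response, no line noise, no amplifier saturation. The synthetic
experiment validates the machinery and its qualitative error structure, not
clinical effect sizes.

## Processing defaults

High-pass: 4th-order Butterworth at 10 Hz applied forward–backward (zero
phase). Epochs −100…+200 ms, baseline −100…−10 ms; both configurable, as
no canonical values exist. Channel exclusion: (a) standard deviation of
the after-peak window (event +5 ms to epoch end) above 10 mV — the stated
criterion mixes a variance with an amplitude unit, so it is implemented
unit-consistently as an SD threshold; (b) contact labeled skull, scalp or
outside; (c) contact in the stimulated pair, a same-shaft neighbor of it,
or within 5 mm of either stimulated contact (the proximity radius is not
specified by the source description; 5 mm is one contact pitch plus
margin). Peaks are the signed largest-magnitude sample within ±1 sample of
the trigger, averaged over a pair's events. The RMS normalizer is computed
over time and the kept bipolar channels of the preprocessed continuous
recording (whether it should be taken before or after per-pair exclusions
is not specified; the static keep-set is used).

## Validation statistics

The scaling factor is the exact L1 minimizer of
$\sum|m_i - s\,x_i|$, i.e. the $|x|$-weighted median of the ratios
$m_i/x_i$ (entries with $x_i = 0$ are excluded from the fit, kept in the
error tables); an L2 variant exists for sensitivity checks. By default one
scale is fitted pooled across all model levels, matching the study design
of a single factor for all datasets — which is why the pooled scale drifts
above the true gain when mismatched levels are pooled, while the
matched-model fit recovers it. When the generator's pulse model is known,
its sampled peak is passed as `sim_gain` so the fitted scale estimates the
gain itself; for real data that factor is unknown and is simply absorbed
into the fitted scale. For gain-recovery experiments the measurement
chain is run without the 10 Hz high-pass: synthetic data have no drift to
remove, and the filter's ~4% peak attenuation would bias the estimate of a
known quantity.

Distances are Euclidean, stimulation-pair midpoint to bipolar-channel
midpoint — the stimulation is modeled at its midpoint and a bipolar channel
has no other natural coordinate. Relative errors are binned in 5 mm steps,
summarized by n/median/quartiles (linear-interpolation quantiles); interior
empty bins are kept, trailing ones dropped. One structural consequence of
the exclusion rules: channels containing a stimulated contact or a
same-shaft neighbor are always excluded, so the closest same-shaft channel
midpoint sits 8.75 mm away and the 0–5 mm bin is populated only by rare
cross-shaft near-crossings; near-field behavior is therefore read from the
nearest populated bin (5–10 mm under the default geometry), where the
median relative error is several times the 35–45 mm value. The
model-misspecification contrasts (skull conductivity ×0.1; relabeling CSF
as brain) are evaluated at zero noise: intracranial potentials are only
weakly sensitive to skull conductivity, and the 2 µV sensor noise would
swamp that deterministic, consistently-signed difference.

## Problem sizes and determinism

The reference experiments use a 50 mm five-shell phantom meshed at 2 mm
(≈66k elements), 6–8 shafts of 10 contacts, 8–10 stimulated pairs with 2
events each, and FEM solves at relative residual $10^{-8}$–$10^{-9}$; the
refinement comparison uses a 25 mm phantom at 2 mm vs 1 mm. A full
pipeline run takes well under a minute on one CPU. Every random step takes
an explicit seed (placement, plan, recording draw their own derived seeds),
RNG state is restored after each call, and a rerun with an identical
configuration reproduces all outputs bit-for-bit, including the serialized
report.

## Known limitations

* Analytic ground truth restricts sources to the innermost shell; pairs in
  outer shells would need a multi-layer source formulation.
* Hexahedral voxel meshes with node shift mitigate but do not remove
  staircase error; very thin shells (around one voxel) degrade accuracy and
  a shell that vanishes entirely raises an error at phantom construction.
* Partial-integration sources are inaccurate near element corners (kept for
  comparison; St. Venant is the default).
* The L1 scale fit weights by simulated amplitude, so near channels
  dominate it; this mirrors the study design rather than a statistical
  optimum.
* No hypothesis testing between model levels is performed, and no inverse
  (source-reconstruction) functionality is included.
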