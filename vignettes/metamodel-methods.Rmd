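---
title: "Methods: surrogate hemodynamics and CoA classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surrogate hemodynamics and CoA classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coameta)
```

## The problem and the modeling idea

Coarctation of the aorta (CoA) narrows the descending thoracic aorta and
reshapes flow throughout the arch: proximal pressure rises, flow is
redirected into the brachiocephalic, left common carotid and left
subclavian arteries, and a pressure gradient appears across the narrowed
segment. Full patient-specific CFD resolves all of this but is expensive.
The package implements the alternative: *metamodels* — regressions from
landmark morphometry (nine diameters) to landmark hemodynamics (velocities
and pressures averaged over small spherical domains) — and logistic
classifiers that decide normal versus CoA from either measured or
metamodel-predicted features.

A note on landmark naming: the spherical domains are the inlet P1, the
four outflow domains (OBCA, OLCCA, OLSCA near the branch origins and O5 in
the distal descending aorta) and interior stations M1–M4. Some textual
descriptions of this layout mention only *three* interior points while the
models use all four M-stations; the package emits all four (M1–M4)
throughout and treats the three-point phrasing as a simplification. A
related ambiguity — whether M3 sits before or after the narrowing — is
resolved literally: the peak-to-peak gradient is always
`gamma = p(M3) - p(M4)`, and the generator concentrates the stenosis loss
between those two stations so the gradient captures it by construction.

## Surrogate model family

Pressures are linear in diameters; velocities are linear in
squared-diameter ratio features. The ratio form comes from continuity:
volumetric flow scales as velocity times squared diameter, so a velocity
at one station relates to diameters elsewhere through terms Di/Dj². The
five canonical responses and their shipped published coefficient sets
(`published_surrogates()`) are:

* `p_P1` = 11.14 + 0.34 D1 − 0.29 DBCA − 0.55 D0 + 0.79 D5
* `p_M2` = 11.2 + 0.45 D2 − 0.27 DBCA − 0.53 D0 + 0.47 D5 (D2 replaces D1
  because M2 sits at the arch transition)
* `v_OBCA` = −0.42 + 0.07 D1/DBCA² − 0.27 D0/DBCA² + 0.1 D4/DBCA² + 0.17 p̂(P1)
* `v_M4` = 1.67 + 0.39 D1/D4² − 0.87 DBCA/D4² − 2.17 DLCCA/D4² + 0.58 D3/D4² − 0.04 p̂(P1)
* `v_O5` = 1.7 + 0.29 D1/D5² − 0.87 DBCA/D5² − 1.25 DLCCA/D5² + 0.75 D3/D5² − 0.06 p̂(P1)

with diameters in mm, pressures in kPa, velocities in m/s (the ~11 kPa
intercepts only make sense on this unit convention, which is why the
package never converts implicitly). The models are *chained*: the inlet
pressure model is evaluated first and its prediction is a regressor of
every velocity model. `fit_surrogates()` refits the same forms by QR-based
least squares, fitting `p_P1` first and injecting its in-sample
predictions, and reports R², the overall-F model p-level and n. One
ambiguity in the printed velocity equations — whether ratio normalization
happens before or after fitting — is resolved by treating each Di/Dj² as a
literal regressor.

## Classifiers

Binary logistic regression with CoA as the positive class,
fitted by iteratively reweighted least squares authored in the package:
convergence when the log-likelihood moves less than 1e-8, a 100-iteration
cap, and explicit detection of (quasi-)separated training data — every
fitted probability collapsing onto its label — in which case the capped
fit is returned with `separated = TRUE` and remains usable for
classification (the decision boundary is well placed even though
coefficient magnitudes are unbounded). Features are z-scored by default,
with the standardization stored in the classifier; this makes coefficient
magnitudes comparable across mm- and kPa-scaled features, which is how the
shipped published coefficient tables are most plausibly scaled. Those
printed tables carry two caveats, both surfaced in the API rather than
guessed away: none documents an intercept (published mode defaults it to 0
and exposes it as configuration), and the metamodel table repeats one
velocity coefficient (−1.05) three times, which looks like a typesetting
artifact and is shipped verbatim with this flag.

Classification is strict: CoA if and only if P(z) > threshold (default
0.5), so a record exactly at the boundary is called normal.

The full protocol (`run_pipeline()`) uses one stratified 80:20 split for
everything: surrogates are fitted on the training records only (leaking
test morphometry into the surrogate fits would flatter the metamodel), the
three classifiers are fitted on the same training half, and all three are
scored on the identical test half. The published hemodynamic classifier
nominally uses {v(OBCA), v(M3), v(O5), p(P1), p(M1)}, but the fitted
pressure surrogates are for P1 and M2 and the velocity surrogates for
OBCA, M4 and O5; a metamodel can only be compared fairly on features it
can predict. The pipeline therefore defaults both the direct and the
metamodel classifier to the predictable quintet
{v_OBCA, v_M4, v_O5, p_P1, p_M2}; the literal published set remains
available via `hemo_features` for standalone use, and an
`all_features = TRUE` ablation runs the direct classifier on all 18
landmark features (typically doing worse — more noise, no more signal).

## The synthetic cohort generator

Real infant cohorts in this area cannot be shared, so evaluation runs on
synthetic cohorts that emulate the *described* class structure, not any
patient's data. Defaults (all in `cohort_config()`, mirrored in
`inst/extdata/default_cohort.yaml`, explicitly marked not
patient-derived):

* **Morphometry.** Truncated-normal diameters per class. CoA shifts D0
  down hard (2.9 ± 0.5 mm vs 7.7 ± 0.85 mm) with visibly smaller spread,
  D3 and D1 down moderately, DBCA up with larger spread, D5 up slightly;
  the remaining diameters barely differ. Within every record D0 is upper-
  truncated at min(D3, D4) — the narrowest descending section cannot
  exceed its neighbours by definition. Draws are rejection-sampled
  (capped at 100 attempts, then an informative error naming the
  parameter).
* **Flow.** Inlet velocity ~ N(0.75, 0.30²) m/s truncated at 0.05 (the
  wide spread stands in for inter-patient size and cardiac-output
  variation). Baseline outlet split BCA 0.16 / LCCA 0.07 / LSCA 0.08 /
  descending 0.69; as stenosis severity S = (D3/D0)⁴ grows, descending
  flow is down-weighted by 1/(1 + 0.2 (S − 1)) and the split renormalized
  — flow blocked distally diverts into the arch branches, which is what
  raises branch velocities in CoA. Outlet velocities then follow from
  continuity, so the squared-diameter balance holds to machine precision
  before noise (a tested invariant).
* **Pressure.** p(P1) = 12.8 kPa + 0.6·Δp, a friction drop of 0.06 kPa
  per station, and a stenosis loss Δp = 0.15 (S − 1) v(P1)² kPa
  concentrated between M3 and M4; 60% of the loss backs up as proximal
  hypertension. The CoA gradient distribution then centres near the
  20 mm Hg surgical threshold (median ≈ 24 mm Hg) with a heavy upper tail
  from the quartic severity term.
* **Noise.** Independent additive Gaussian noise, 0.25 m/s on velocities
  and 0.8 kPa on pressures, applied last; physical-mode velocities are
  floored at zero.

The noise and separation levels were calibrated once, jointly, against the
generator's own contracts — refitting the v(O5) surrogate form on
60-record cohorts should average R² ≈ 0.5–0.6 (it does: 0.61 over 50
seeds, with the model ordering O5 > M4 > OBCA preserved), the
five-diameter classifier should almost always separate the classes
perfectly, and metamodel accuracy should track direct-hemodynamics
accuracy — and then frozen. Problem sizes in the shipped studies (60
records per cohort, 100 classifier seeds, 200 coverage cohorts, 50 R²
seeds) are the package's chosen defaults for a desk-scale study.

A second generator mode, `hemo_model = "equations"`, replaces the five
canonical responses with the published equation forms evaluated on the
drawn diameters plus Gaussian noise. This is the fixture for
identifiability and coverage studies, because there the generating process
lies exactly in the fitted model family; velocities are deliberately *not*
floored at zero in this mode. On noise-free equation-mode cohorts the
chain refit recovers the generating coefficients to ~1e-15. The coverage
study (200 cohorts, 95% CIs per coefficient) conditions the velocity fits
on the generator's *true* chained pressure regressor: parameter recovery
is only well-posed when the design is the generating one, whereas fitting
against the re-estimated p̂(P1) asks a different (errors-in-regressor)
question and visibly attenuates coverage for correlated terms.

**What the generator does not emulate** — and hence what green tests do
not certify about real data: pulsatile waveforms and wave reflection,
3-D jet and recirculation structure, turbulence at the stenosis,
measurement error structure of segmented MSCT surfaces, collateral
circulation (which decouples gradient from severity in real CoA), and any
correlation structure among diameters beyond the D0 ≤ min(D3, D4)
constraint.

## Mesh morphometry: algorithms and numerical choices

* **Slicing.** Plane–mesh intersection collects one chord per crossing
  triangle, keyed by canonical mesh edge so adjacent chords share
  endpoints exactly; chords chain into closed loops, and the loop
  containing the query point is kept. Diameter is the equivalent-circle
  value 2√(area/π) — robust to the mildly elliptic sections of real
  vessels, and exact for the elliptic test fixtures (2√(ab)).
* **Centerline.** Marching cross-section centroids: the inlet plane is
  estimated by PCA of the mesh points nearest the user's inlet hint; each
  station iterates slice → centroid to a fixed point (tolerance 1e-4 mm),
  then advances 1 mm along the running direction (both below anatomical
  scale). Guards reject non-forward or jumping centroids (the failure mode
  near the distal corner), the step shrinks down to 1/64 near the end, and
  both ends are finally extended to the vessel surface along the end
  tangents by ray casting — without this the arc length systematically
  misses a fraction of a millimetre per end, which matters for
  fraction-of-length landmark anchors.
* **Landmarks.** Anatomical definitions are operationalised as
  configurable anchors (`landmark_config()`): D1 literally 10 mm distal to
  the sinotubular junction; D2, D3, D5 at arc-length fractions; D0 and D4
  by scan (≤ 0.5 mm) plus golden-section refinement (0.02 mm interval)
  over the descending range, with a guard that the refined optimum is
  never worse than the scan grid; branch diameters 2 mm distal to the
  branch origin, because "at the origin" is a saddle, not a plane.
* **STL.** Both dialects are read and written natively; vertices are
  merged exactly on read to restore shared edges. Binary STL stores
  float32, so binary round trips are exact only to single precision —
  the ASCII writer keeps full doubles and round-trips to better than
  1e-6 mm.
* **Sphere sampling.** Landmark averages use a cubic grid of spacing
  0.084 mm centred on the 1 mm sphere, chosen once so the strict-interior
  count (895) lands in the 850–900 convention; centring makes the grid
  symmetric, so a linear field averages exactly to its centre value.

## Known limitations

Branch stubs are separate mesh components that interpenetrate the main
tube (fine for section measurement, not for CFD meshing). The marching
centerline assumes a tube-like topology and one distal outlet; it follows
the main vessel past branch ostia only because the containing-loop rule
discards branch sections. The stenosis loss law and flow-redistribution
rule are deliberately simple monotone surrogates, not validated
physiology; severity distributions inherit a heavy tail from the quartic
term. Published-mode classifiers are executable but their decision
boundaries depend on an undocumented intercept and (for the printed
tables) plausible z-scoring of features, so published mode is for model
inspection rather than clinical inference.
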