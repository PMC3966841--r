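---
title: "Methods: phantom construction, segmentation and decay modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom construction, segmentation and decay modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retnathist)
```

## The scientific problem

In an all-cone mouse retina carrying a *Cep290* mutation, cone function
collapses long before cone nuclei disappear — the same structure–function
dissociation seen in patients with severe early-onset *CEP290* retinal
blindness, who keep a residual island of foveal photoreceptor nuclei despite
profound visual loss. Planning a gene-therapy proof-of-concept experiment in
such a model needs a quantitative natural history: how fast the
photoreceptor layer thins, how the dysplastic pseudorosettes are distributed
and decline, and how quickly the cone ERG b-wave decays, so that an
injection age, an assessment age and efficacy/toxicity outcome thresholds
can be chosen before the response disappears into noise.

`retnathist` implements that analysis chain — OCT layer segmentation from
longitudinal reflectivity profiles (LRPs), en-face pseudorosette mapping,
human foveal-island metrics, and exponential ERG decay modelling with a
treatment-window calculator — together with a synthetic-data generator that
emulates the statistical structure of each data type with exact ground
truth, so every stage is testable end to end.

## OCT boundary definitions

All boundaries are located on the 1-D axial reflectivity trace of each
A-scan (the LRP), after averaging repeat frames:

* **RPE**: the *second* hyperreflective band encountered scanning from the
  scleral (deep) end of the profile toward the vitreous, among peaks whose
  topographic prominence reaches a threshold (default 10% of the profile's
  dynamic range). The deepest strong band is choroidal.
* **Total retinal thickness**: vitreoretinal interface (first prominent
  peak from the vitreal end) to the RPE peak.
* **ONL+ (photoreceptor layer)**: from the trough delimited by the peak on
  the sclerad side of the outer plexiform layer to the trough vitreal to
  the RPE band. The S+ scattering band (remnant inner/outer-segment
  signal) lies *inside* ONL+, so exactly one prominent peak between the
  two troughs is normal anatomy.

Numerical choices: profiles are pre-smoothed with a Gaussian of sigma 1.5
pixels for robust band identification, then every boundary is re-centred on
the unsmoothed trace within ±2 pixels (coarse-to-fine); boundaries are
reported at integer pixels (no sub-pixel interpolation — the printed
precision of the thickness statistics does not warrant it); troughs use a
separate prominence threshold (2% of range) because the boundary troughs
are shallow relative to the bands, with an arg-min fallback inside the
flanking-peak interval.

A 0.18 mm zone centred on the optic nerve head (|position| < 0.09 mm) is
always excluded from thickness statistics. "Around the ONH" is read as the
*total* width; the half-width is configurable.

### Pseudorosette exclusion

The study excluded rosette-disrupted regions from thickness profiles
without stating a rule. Two automated modes are provided:

* **lrp mode** (default for meridian line scans, which have no paired
  en-face raster): an A-scan is flagged when two or more prominent peaks
  fall strictly between the ONL+ troughs (one, the S+ band, is expected),
  *or* when a hyperreflective peak at ≥ 75% of the RPE peak height occurs
  vitreal of the S+ band. The second clause is necessary because a bright
  rosette captures the band-identification step itself, so the
  interval-count rule alone cannot flag it.
* **spot-footprint mode** (default when a detected `SpotSet` is supplied):
  positions within 1.5× the effective spot radius of a detected en-face
  spot centroid are excluded.

## The OCT phantom

Each A-scan is rendered as a sum of Gaussian reflectivity bands over a low
baseline (0.10 a.u.): vitreoretinal interface (0.55), inner retina (0.40),
OPL (0.50), S+ (0.45), RPE (0.80, the brightest), and a choroidal band
(0.50) sclerad of the RPE so that the RPE is genuinely the *second* band
from the scleral side. Band depths derive from the thickness geometry: RPE
depth = interface depth + total thickness; the pre-RPE trough sits 18 µm
vitreal of the RPE; the OPL-side trough sits ONL+ µm vitreal of that; the
OPL peak 20 µm vitreal again. Two shallow negative Gaussian dips (depth
0.08, sigma 6 µm) pin the two boundary troughs at their designed depths, so
the rendered minima — and hence the ground truth — sit where the geometry
says, to within one pixel. Ground truth is nevertheless measured on the
*rendered* noise-free profile (arg-min/arg-max near the designed depth),
not copied from the configuration, so generator and segmentation remain
independent routes to the same quantity.

Other phantom features:

* **Curvature**: a smooth sinusoidal depth field (default amplitude 10 µm,
  period 1.6 mm, random phase) shifts whole A-scans, emulating ocular
  curvature; `flatten()` must undo it (to ≤ 1 pixel) before en-face
  integration.
* **Within-eye variation**: ONL+ and total thickness vary along the field
  as smooth random fields (coarse white noise, knot spacing 0.3 mm,
  linearly interpolated) recentred and rescaled so the realised profile
  mean and SD equal the configured values exactly. Extreme thin-eye draws
  are clamped to the geometric floor that keeps band depths ordered.
* **Pseudorosettes**: hyperreflective ellipsoids (reflectivity 0.85 ≈ RPE,
  lateral radius 25 µm, axial semi-axis 28 µm) centred in the ONL and
  extending into the inner retina, rendered by reflectivity replacement
  (`pmax`), not geometric folding. Counts per sector are Poisson with
  configurable densities (defaults: the young-eye hemifield counts 44
  superior / 73 inferior over the 1.5 mm sampled field), positions uniform
  within the sector annulus, centroid pairs closer than 2 radii rejected,
  with bounded retries (an error if the density is infeasible). Exact
  per-sector counts can be forced for count-recovery experiments.
* **Noise**: additive Gaussian reflectivity noise (default SD 0.02 a.u.
  against band amplitudes of 0.4–0.8); repeat frames carry independent
  noise and are averaged on extraction, as the acquisition software does.
* **Scales**: 1.6 µm/pixel axial, 512 axial pixels by default — plausible
  for a small-animal SD-OCT system; the source protocol does not state
  pixel scales, so these are declared defaults, configurable everywhere.

What the phantom does *not* emulate: speckle statistics and the A-scan
point-spread function, vignetting, eye motion, a real ONH (exclusion is
purely positional), rosette-induced geometric folding of the ONL, or
segmentation difficulty of real dysplastic retina. A green recovery test
therefore establishes that the pipeline correctly measures a layered retina
with the configured statistics — not that it would segment real B-scans
unsupervised.

### Variance decomposition

The published profile SDs pool "all data points in the vertical profile"
across eyes, mixing between-eye and along-meridian variance without stating
the split. Cohort simulations decompose the pooled SD into equal parts
(σ/√2 between eyes, σ/√2 within the profile) — e.g. young ONL+ 66.4 ± 7.6 µm
becomes a per-eye mean drawn with SD 5.37 µm plus a within-profile field of
SD 5.37 µm. The old-cohort *total* thickness SD (34.4 µm) is treated
differently: large smooth within-eye swings of that size are unphysical, so
it is placed mostly between eyes (√(34.4² − 10²) between, 10 µm within).
These choices were made once, before any acceptance measurement, and are
not tuned.

## En-face mapping and spot detection

After flattening, backscatter is summed over an axial slab chosen to
envelope the rosette-bearing outer retina — by default from 110 µm vitreal
of the flattened RPE down to just past it (the study's two integration
boundaries are not numerically specified). Spots are segmented by Otsu's
threshold computed outside the ONH disk, floored at median + 6·MAD of the
map: Otsu assumes a bimodal histogram and would otherwise split pure
background noise on a spotless map. Connected components (4-connectivity)
below 4×10⁻⁴ mm² are discarded; centroids are intensity-weighted. Sector
statistics use wedges centred on +90° (superior), −90° (inferior), 0°
(nasal), 180° (temporal), or superior/inferior halves; densities divide by
the sector's share of the annulus between the ONH disk and the field
radius. Touching spots (centroids at exactly twice the radius) can merge
into one component; at the default densities this costs ~2–4% of counts,
within the acceptance tolerances, and is the expected behaviour of a
connected-component counter.

## Foveal-island metrics

* **Foveal ONL average**: mean of five samples at 0, ±0.15 and ±0.3 mm
  eccentricity, linearly interpolated when off-grid. The methods text
  describes the samples "along the vertical meridian" while the scans are
  horizontal; the profile records which meridian it came from and the
  metric is computed on whatever meridian is supplied, without guessing
  the intended one.
* **Island width at half-maximum**: distance between the outermost
  half-maximum crossings on each side of the peak (outermost, so satellite
  bumps cannot shrink the island), linearly interpolated between samples;
  flagged undefined when either side never crosses half-maximum (flat or
  high-baseline profiles, mirroring the patient in whom the metric could
  not be measured).
* **Lower limit of normal**: mean − 2 SD of a normative cohort.
* Off-scale acuity categories are coded HM = 2.3, LP = 2.6, NLP = 2.9
  logMAR for plotting and binning only — they are ordinal labels, not
  measurements, and are excluded from regression by default.

## ERG decay model and the treatment window

Amplitudes decay exponentially, so log10(amplitude) is fitted on age by
ordinary least squares (log base 10 throughout, matching amplitudes quoted
in log µV). Records at or below the noise floor (default 5 µV) are dropped
before fitting (censoring at the floor is available); the published fit's
handling of near-noise responses is unstated, and a fitted rate can differ
from a rounded printed rate for that reason. The 95% prediction-interval
half-width is reported at the design centre, t₀.₉₇₅,ₙ₋₂ · s · √(1 + 1/n) —
the constant-width approximation used when quoting "±0.4 log µV" — with the
exact age-dependent interval available as an option. The implied daily loss
is 100·(1 − 10^slope) percent.

`plan_window()` turns a fit into an experiment design: assessment age =
injection age + delay; expected untreated-eye amplitude from the fit; and
efficacy/toxicity thresholds at 10^(log₁₀(mean) ± 0.3), the normal
interocular asymmetry bound. Thresholds are reported at full precision
(10^1.7 = 50.1 µV, 10^1.1 = 12.6 µV); printed integer thresholds are
rounded presentation, not exact contracts. A warning flags windows whose
expected mean falls below the noise floor (too late to assay).

## Reproducibility

Every stochastic operation takes an explicit seed and restores the caller's
RNG state; identical parameters and seed give byte-identical outputs. The
pipeline derives one sub-seed per stage from the config seed, writes a
provenance sidecar (config hash, seed, package version) next to every
artifact, and re-runs byte-identically. Volumes travel as multi-page TIFF
(uncompressed 64-bit float, one page per B-scan) with a JSON sidecar; the
reader refuses volumes whose page count disagrees with the sidecar.

## Known limitations

* The segmentation presumes the phantom's band ordering; it is not a
  general-purpose human/mouse OCT segmenter and does not handle missing
  bands, pathology other than the modelled rosettes, or vendor formats.
* Histology endpoints are covered only as generic count/thickness
  statistics (`compare_groups` on externally supplied values).
* Detection counts lose a small, density-dependent fraction of planted
  spots to component merging (quantified above).
* The ERG module fits per stimulus; pooling across stimuli, if the source
  analysis did so, would change rate estimates slightly.
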