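---
title: "Methods: choroidal vessel segmentation and Haller/Sattler sublayer mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: choroidal vessel segmentation and Haller/Sattler sublayer mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the measurement model, its assumptions, the
parameters that matter, and the numerical choices made where the design was
genuinely open. Everything quantitative stated here is computed by the test
suite or by `scripts/acceptance.R`; nothing is asserted beyond what those
runs check.

## Coordinate and unit conventions

Volumes are indexed `[z, x, y]`: depth along the A-scan (z, increasing from
the vitreous toward the sclera), fast axis (x), slow axis (y). Depth indices
are 0-based and all depth intervals are half-open `[start, stop)`. A depth
interval of `k` voxels corresponds to `k * axial_sampling_um` micrometres of
optical path and `k * axial_sampling_um / refractive_index` micrometres of
anatomical distance; the default group index is 1.4. Transverse scale is
`mm_per_degree = 0.289` (emmetropic schematic eye) unless configured
otherwise. The instrument's depth sampling calibration is not something the
package can know; `axial_sampling_um` is a run-time input everywhere.

## Boundary detection

The choroid is bounded by the RBC complex above and the choroidal–scleral
interface (CSI) below. Detection runs per B-scan as a dynamic-programming
shortest path over depth: maximize interface evidence minus
`lambda = 2` per voxel of depth jump between neighbouring A-scans (evidence
is normalized to a per-B-scan maximum of 1, so `lambda` is in evidence units
per voxel; `Inf` forces a flat path). Evidence has two terms, both computed
on log intensity — attenuation is multiplicative, so interface contrast is
depth-invariant in the log domain:

* a short-window axial contrast on a transversely smoothed plane (boxcar
  radius `surface_smooth_xy = 7` A-scans/B-scans) that localizes the
  interface: dark-above-bright for the RBC complex, bright-above-dark for
  the CSI;
* a sustained-darkness term on the *transverse brightness envelope* — the
  per-depth maximum over a wide (±14 B-scan) neighbourhood. Below a vessel,
  even a large tube running parallel to the B-scan, bright stroma persists
  somewhere in the neighbourhood; below the CSI nothing is bright anywhere.
  This term is what separates the interface from the anterior envelope of
  the large-vessel layer, which otherwise mimics a boundary.

The DP path is finally re-snapped per A-scan to the strongest local edge
within ±3 voxels, measured without transverse smoothing, which removes the
voxel-scale bias the wide boxcar introduces on curved surfaces. A volume
with no axial contrast yields an all-zero-confidence surface and a log
entry, not an error.

The region is `[ceil(rbc), floor(csi))` per A-scan; whether subvoxel
interface positions or voxel centres should be used is unknowable from the
measurement definition alone, so half-open integer intervals were fixed
once and used consistently on both the measurement and the ground-truth
side.

## Vessel segmentation

* **Denoise** — 3D median filter, radius 1 voxel by default. Radius 0 is the
  identity; note that a radius-1 median erases structures a single voxel
  wide, which is why the noise-free analysis configuration (below) disables
  it.
* **Candidates** — a voxel is a candidate iff it is inside the choroid and
  its intensity is at or below the `candidate_percentile` (default 35) of
  its own 1°×1° tile's choroidal intensities. The per-tile percentile
  adapts to local brightness but *not* to local vascularity: on a noise-free
  two-level volume the threshold jumps from the vessel mode to the stroma
  mode as soon as the percentile exceeds the tile's vessel fraction, turning
  the whole tile into candidates. The default therefore sits below the
  vascularity of any plausible tile (choroidal vascularity indices in the
  literature are ~0.5–0.65; the phantom's tiles span ~0.28–0.6).
* **Cone voting** — every candidate boundary voxel (a candidate with a
  non-candidate 6-neighbour) whose intensity-gradient magnitude reaches the
  60th percentile of boundary gradients casts total weight 1, spread
  uniformly over the voxels of a cone of half-angle `cone_theta_deg = 30°`
  and length `cone_length = 12` voxels opening along the inward gradient
  (bright wall → dark lumen). Votes accumulate in candidates only. The
  exact aperture and weighting of cone-voting vessel detectors vary between
  implementations; these parameters are configuration, not a claim of
  fidelity to any particular instrument pipeline.
* **Cores and caliber recovery** — cores are candidates at or above the
  60th percentile of positive votes; geodesic (6-connected) dilation grows
  them within the candidate mask until stable. Because the adaptive
  threshold clips the partial-volume shell that the median filter blends
  around every vessel, the mask is then grown two further steps into a
  permissive secondary mask (strictly below the 60th tile percentile). The
  strict comparison makes this step inactive on two-level noise-free
  volumes, and the secondary mask excludes the four deepest bins above the
  CSI, where attenuated stroma falls below the permissive threshold as a
  coherent sheet that must not be annexed as vessel.
* **Components** — 26-connectivity labelling (permissive for undulating
  tubes); surface voxels use the 6-neighbour rule so that surface counts
  match the volume/surface ratio analysis; components smaller than
  `min_component_size = 2` voxels are removed — the single-voxel noise rule.

## Sublayer separation

Per tile (1°×1°; 36×36 tiles of 14 B-scans at the default 512-A-scan,
36° geometry), each vessel voxel is assigned a depth bin
`b = (csi − 1) − z`, i.e. voxels above the deepest choroidal voxel of its
A-scan, so profiles are flattened to the scleral boundary. The per-bin
volume/surface voxel ratio is ≥ 1 wherever defined (the surface subset is
contained in the volume) and is undefined where the bin holds no surface
voxels. Profiles are smoothed with a `smooth_w = 5` bin moving average;
isolated undefined bins (speckle fragmentation holes) are bridged when at
least two window values are defined, while longer undefined runs — in
particular the terminal no-vessel run whose position carries the Sattler
inner border — stay undefined.

The border rule follows the valley principle: Haller's layer starts at the
scleral boundary and includes the highest ratio; the first valley anterior
to the maximum marks the Haller/Sattler border; Sattler's layer ends at the
first bin that is undefined or below `noise_floor = 1.05` (isolated plates
and filaments have ratio ≈ 1 and count as noise). A discrete
"value ≤ both neighbours" valley is numerically fragile — per-bin counting
noise produces 0.01-level upticks on near-flat stretches — so the
implementation uses a minimal-prominence valley with these elements, all
verified against hand-traceable profiles in the tests:

* the running minimum must be followed by a rise of at least
  `max(0.25, 15% of the level)` to count as a valley; ties within
  `max(0.1, 5%)` keep the posterior bin, so broad flat valleys resolve to
  their posterior edge;
* if a peak posterior to the global maximum reaches 80% of it with a valley
  between them at ≤ 55% of the posterior peak, the posterior peak is taken
  as the Haller maximum (merged medium-vessel complexes can slightly
  out-ratio a weak Haller tile, but they cannot produce the deep
  intervening valley);
* profiles that level off without a confirming rise (two consecutive steps
  < 0.1 below 20% of the profile height) take the level-off point as "the
  first small ratio";
* the border then walks back to the most posterior bin within half a
  prominence of the stopping level — the border is where the descent
  *reaches* small ratios, not the valley floor itself;
* the inner-border scan starts at the anterior edge of the border valley,
  so a valley that itself dips below the noise floor does not zero out the
  layer above it. A profile that declines to its end without any valley
  yields a zero-thickness Sattler's layer rather than an error (near-zero
  Sattler's layers are a real phenotype and must be representable).

Border indices depend only on the segmented mask, never on absolute
intensities, so they are invariant under uniform intensity rescaling (this
is a tested property). Haller thickness is the border depth and Sattler
thickness the border-to-inner span, both converted to anatomical
micrometres; tile maps are bilinearly upsampled to A-scan resolution for
display and for grid averaging.

## Grid summarisation

The macular grid uses a 1.5 mm central disc (the central submacular field,
CSM), a 3 mm inner ring and a 6 mm outer ring (total macular field), with
quadrants split on the ±45° diagonals and nasal/temporal assignment flipped
by eye laterality. The 1.5 mm central disc replaces the conventional 1 mm
disc because the CSM is defined at 1.5 mm; the 3 mm inner ring is the
standard layout choice. Subfields with more than 50% missing cells are
reported missing. When the mapped field is narrower than 6 mm (as for the
demonstration phantom), the outer disc is capped to the field and the event
is logged; the CSM is never rescaled.

## Repeatability statistics

For repeated measurements the package computes the mean difference with a
t-based 95% CI (small samples), limits of agreement as mean ± 2·SD of the
differences (the small-group rule, giving an LoA width of exactly 4·SD),
the two-way single-measure absolute-agreement ICC with its F-based CI, the
coefficient of repeatability `CR = 1.96 · SD(differences)` with its
relative form `100 · CR / grand mean` (the grand mean of all measurements
entering the differences — the denominator convention is ambiguous in
common usage; dividing by the mean *difference* would be numerically
unstable near perfect agreement), and a one-way repeated-measures ANOVA on
the session factor. All of these match brute-force sums-of-squares and
closed-form oracles to 1e-9 in the tests.

## The synthetic phantom

The phantom emulates what the segmentation relies on, with complete
voxel-level ground truth:

* two smooth boundary surfaces from low-order 2D cosine series (amplitude 6
  voxels by default), mean choroidal thickness 270 µm;
* Haller-class tubes (radii 40–100 µm) whose anterior surfaces cluster at a
  target depth of 140 µm above the interface with 0.5-voxel jitter — the
  anatomical premise of the method is that the large-vessel layer has a
  well-defined anterior limit, and the phantom realizes that limit
  explicitly; Sattler-class tubes (radii 12–30 µm) fill the band above,
  with anterior extents capped at 90 µm above the border (the layer's inner
  envelope) and bottoms resting on the border without penetrating the
  large-vessel zone. The 140/90 µm defaults mirror reported healthy central
  submacular values. Tubes run obliquely (Haller slopes 0.15–0.35 voxels
  per voxel) with mild undulation: posterior-pole vessels radiate rather
  than track the raster axes, and a 100 µm tube lying exactly inside one
  B-scan would be locally indistinguishable from an interface;
* intensity = tissue level × exp(−depth below RBC / τ) × unit-mean gamma
  speckle. Defaults: background 0.2, stroma 1.0, vessel 0.25, τ = 250
  voxels (mild attenuation — deep choroidal penetration is the hallmark of
  1060 nm imaging), speckle shape 25 (≈20% multiplicative noise, the
  "moderate speckle" condition). `τ = Inf` and `shape = Inf` give the
  noise-free piecewise-constant limit with exactly three levels. A 2-voxel
  choriocapillaris band below the RBC complex stays vessel-free.

Ground truth per tile: the Haller/Sattler boundary is the mean over
Haller tubes (those whose centerline crosses the tile — shells grazing from
a neighbouring tile do not count) of each tube's anterior-most rendered
voxel depth; the Sattler inner limit is the anterior envelope of the
Sattler vasculature in the tile. The demonstration geometry is
256×128×128 voxels over a 6°×6° field at 7 µm optical depth sampling
(≈13.5 µm transverse, 5 µm anatomical axial): small enough to analyze in
seconds, fine enough that 12 µm Sattler lumina stay resolvable, and wide
enough that the 1.5 mm CSM disc fits.

What passing phantom tests do **not** show: performance under motion
artifacts, RPE pathology (drusen, atrophy), real speckle statistics and
spatial correlation, vessel branching/tortuosity beyond sinusoidal
undulation, or the cited instrument's actual depth calibration. The phantom
validates the algorithmic chain, not the instrument.

### The noise-free analysis configuration

The noise-free fidelity check runs with `denoise_radius = 0` (there is no
speckle to remove, and a radius-1 median erases single-voxel-wide tubes)
and `candidate_percentile = 25` (a two-level histogram floods any tile
whose vessel fraction is below the percentile; the phantom's minimum tile
vascularity is ≈0.28). These are analysis-configuration choices for a
degenerate input, not changes to the phantom.

## The synthetic repeatability experiment

`run_repeatability_experiment()` draws per-eye anatomy (Haller CSM
thickness ~ N(140, 40) µm truncated to [70, 230]; Sattler ~ N(90, 25) µm
truncated to [45, 150] — between-eye spreads in line with reported healthy
cohorts), renders each eye once per session with fresh speckle and a ≤2
voxel axial positioning jitter (fixed anatomy; session variability in
practice is noise plus positioning inconsistency), analyzes every rendering
with the full pipeline, and feeds CSM and total-field values into the
report. The acceptance configuration uses 10 eyes × 3 sessions at
224×96×96 voxels — a size chosen so the 30 pipeline runs complete in a few
minutes while the CSM disc still spans ~80 A-scans. All seeds derive from
one master seed; identical seeds give identical reports, and sessions
sharing a noise seed agree perfectly (tested).

## Known limitations

* The percentile-based candidate rule has no notion of local vascularity;
  tiles whose vessel fraction is far from the configured percentile are
  thresholded sub-optimally. An adaptive bimodal threshold would remove
  this coupling but is a different contract.
* The valley rule assumes the caliber populations are depth-stratified; in
  tiles where medium-vessel complexes merge across the boundary the border
  is intrinsically ambiguous, and the prominence/re-anchor machinery only
  bounds, not eliminates, the error.
* Sublayer maps are tile-resolution (1°); bilinear upsampling is display
  smoothing, not added information.
* Thickness conversion uses a single group refractive index; no
  axial-length-dependent transverse magnification correction is applied.
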