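# choroidlayers

Automated 3D segmentation of the choroidal vasculature and mapping of
Haller's and Sattler's layer thickness in long-wavelength (1060 nm) optical
coherence tomography volumes.

The choroid — the vascular bed between the retinal pigment
epithelium/Bruch's membrane/choriocapillaris (RBC) complex and the sclera —
is organised into sublayers by vessel caliber: Haller's layer of large
vessels against the sclera, Sattler's layer of medium and small vessels
above it, and the choriocapillaris (below OCT caliber resolution). Sublayer
thickness is of clinical interest in myopia, ageing and age-related macular
degeneration, but manual delineation in 3D volumes is impractical. This
package implements a fully automated measurement chain for researchers
working with volumetric 1060-nm OCT:

1. **Boundary detection** — per-B-scan dynamic programming paths locate the
   RBC complex and the choroidal–scleral interface (CSI); the choroid is the
   half-open depth interval `[rbc, csi)` per A-scan, converted to anatomical
   micrometres via `thickness = voxels × axial_sampling / n`.
2. **Vessel segmentation** — after 3D median denoising, hyporeflective
   vessel candidates are selected by an adaptive per-tile intensity
   percentile; vessel cores are found by *cone voting* (every candidate
   boundary voxel casts probability votes into a 3D cone of half-angle θ
   and length L opening along its inward intensity gradient, so votes
   accumulate at lumen centres without relying on the poorly defined vessel
   wall); cores are grown back to full caliber by geodesic dilation;
   components are labelled with 26-connectivity and single-voxel noise is
   removed.
3. **Sublayer separation** — per 1°×1° tile, segmented vessel voxels are
   binned by depth above the scleral boundary and the ratio

   `ratio(b) = vessel voxels in bin b / vessel surface voxels in bin b`

   is plotted against depth. Large vessels have interiors that outnumber
   their walls (high ratio); small vessels are nearly all wall (ratio ≈ 1).
   Haller's layer runs from the scleral boundary through the ratio maximum
   to the first valley of the smoothed profile; Sattler's layer continues
   until the ratio falls below a noise floor or the vessels end. Borders
   become per-tile thickness maps.
4. **ETDRS-style summarisation** — thickness maps are averaged over the
   nine macular subfields, the 1.5 mm central submacular field (CSM) and the
   6 mm total macular field.
5. **Repeatability statistics** — paired differences with t-based CIs,
   Bland–Altman 95% limits of agreement (mean ± 2·SD of differences),
   two-way single-measure absolute-agreement ICC with F-based CIs,
   absolute and relative coefficients of repeatability (1.96·SD of paired
   differences; percentage of the grand mean), and one-way repeated-measures
   ANOVA.

No clinical volumes ship with the package. Instead a first-class synthetic
phantom generates 1060-nm-like choroid volumes with voxel-level ground truth
(boundary surfaces, vessel tubes in two depth-stratified caliber
populations, depth attenuation, multiplicative gamma speckle), which drives
the whole validation suite end to end.

## Worked example

```r
library(choroidlayers)
cfg <- phantom_config()              # 256 x 128 x 128 voxels, 6 x 6 degrees
ph  <- generate_phantom(cfg, seed = 42)
res <- analyze_volume(ph$volume, cfg)

res$region
#> choroid_region: 128 x 128 A-scans, 16384 defined, depth 53.7 +/- 2.5 voxels
res$vessel_mask
#> vessel_mask: 433143 voxels in 3 components
print(res$summaries$haller)
#> ETDRS subfield thickness (um):
#>   central         144.4 +/- 2.0 (n=9628)
#>   inner_superior  146.4 +/- 1.5 (n=386)
#>   ...
#>   csm             144.4 +/- 2.0 (n=9628)
#>   total           144.2 +/- 2.5 (n=12836)
```

The phantom was generated with a true Haller's layer thickness of 140 µm:
the detected choroid is ~54 voxels (≈270 µm) deep, the vessel mask covers
~0.43 M voxels, and the measured Haller CSM mean of 144 µm agrees with the
per-tile ground truth to a few micrometres. `run_all()` writes the full
artifact set (volume, surfaces, component table, border table, thickness
maps as CSV and PNG, grid summaries, truth tables, run manifest) for a
seeded, byte-reproducible run, and `run_repeatability_experiment()` images a
cohort of synthetic eyes repeatedly to fill the agreement-statistics report.

A command-line front end with `phantom`, `segment`, `all`, `grid` and
`repeat` subcommands is installed under `inst/cli/choroidlayers`.

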