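# ciliaquant

Automatic quantification of primary cilia in multi-channel 3D fluorescence
z-stacks, for labs measuring how ciliary signaling (e.g. optogenetically
controlled cAMP) changes cilium length and protein content. Given a
calibrated stack with a ciliary-marker channel (Arl13B or acetylated
tubulin staining), `ciliaquant` segments, detects and measures every
cilium fully automatically, and ships the companion arithmetic for
ratiometric biosensor recordings (FRET, cADDis, plate-reader Ca²⁺) and
for expression-gated cilia-length analyses.

## Method

For a stack with marker channel $M$:

1. **Threshold** — Renyi-entropy automatic threshold computed on a
   256-bin histogram of the maximum-intensity projection of $M$
   (candidates maximize $H_b^{(\rho)} + H_f^{(\rho)}$ at
   $\rho = \tfrac12, 1, 2$, combined with the published 5-gray-level
   weighting rule), applied once to the full 3D volume; foreground is
   strictly above threshold.
2. **Detection** — 3D connected components (26-connectivity); objects
   below 10 voxels are removed as noise; each remaining object is a
   cilium.
3. **Intensities** — per channel, the arithmetic mean over exactly the
   member voxels (the marker mask serves as the cilia mask in all
   channels).
4. **Length** — the object mask is 3×-upscaled, Gaussian-blurred
   (σ = 3 upscaled pixels ≙ 0.21 µm), re-binarized at half amplitude and
   thinned to a 3D medial-axis skeleton; the length is the longest
   geodesic between skeleton endpoints in calibrated micrometers.

Biosensor traces: $\mathrm{FRET}_{corr} = \mathrm{FRET} - \alpha\,
\mathrm{cerulean} - \beta\,\mathrm{citrine}$ (defaults α = 0.75,
β = 0.02), framewise channel ratios, baseline normalization to the mean
pre-stimulus value, and plate-reader normalization
$(F - F_{base})/(F_{iono} - F_{base})$, optionally per fraction of
reporter-positive cells. Downstream analysis: control-background
subtraction, the strict < 7.5 a.u. expression gate, normalization of
lengths to control cells, the length-vs-expression zero-slope test, and
greedy nearest-centroid tracking for time-lapse recordings.

A synthetic generator (`generate_cilium_field()`) renders curved
tube-shaped cilia with known arc length, radius and channel amplitudes
under configurable blur and noise, so the whole pipeline is testable
without any imaging data.

## Worked example

```r
library(ciliaquant)

spec  <- synthetic_spec(n_cilia = 3, seed = 4)   # 2 channels: marker + cargo
field <- generate_cilium_field(spec)
res   <- run_pipeline(field$stack, pipeline_config())
#> [ciliaquant] threshold = 13.58 (channel 1)
#> [ciliaquant] objects: 5 detected, 3 retained at >= 10 voxels

res$table[, c("id","n_voxels","volume_um3","mean_int_1","mean_int_2","length_um")]
#>  id n_voxels volume_um3 mean_int_1 mean_int_2 length_um
#>   1      102      1.799     53.918     17.235     6.295
#>   3      102      1.799     85.539     19.113     4.835
#>   4      128      2.258     76.659     32.364     6.902
```

Three planted cilia (true arc lengths 5.51, 6.77 and 4.93 µm) come back
as three objects; two sub-10-voxel noise specks were filtered out, as the
log line shows. Measured lengths carry the expected sub-micrometer halo
bias of thresholded sub-resolution tubes, and the cargo-channel means
(`mean_int_2`) order the cilia by their planted cargo amplitudes. The
FRET correction reproduces its defining arithmetic exactly:

```r
fret_bleedthrough_correct(100, 40, 50)   # 100 - 0.75*40 - 0.02*50
#> [1] 69
```

A command-line interface wraps the same functions
(`exec/ciliaquant simulate | segment | quantify | analyze | traces | run`).

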