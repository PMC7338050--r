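---
title: "Quantifying primary cilia in 3D: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying primary cilia in 3D: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliaquant)
```

## The problem

Primary cilia are solitary, antenna-like protrusions of most vertebrate
cells: roughly cylindrical, 2--10 um long and 0.2--0.6 um in diameter —
at or below the resolution limit of confocal microscopy in at least one
dimension. Experiments that manipulate ciliary signaling (for example
optogenetic control of ciliary cAMP) need per-cilium readouts from
multi-channel z-stacks: how long is each cilium, and how much of each
labeled protein does it carry? Manual tracing does not scale to hundreds
of cilia per condition and is observer-dependent, so `ciliaquant`
implements a fully automatic pipeline, plus the trace arithmetic used for
ratiometric cAMP/Ca^2+ biosensor recordings and the downstream gating and
normalization logic of cilia-length experiments.

## The pipeline

One designated channel carries a ciliary marker staining (Arl13B or
acetylated tubulin). The stages are:

1. **Global threshold.** A maximum-intensity projection of the marker
   channel is histogrammed (256 gray levels) and thresholded with the
   Renyi-entropy criterion; the threshold is computed once per stack from
   the projection and applied to every z-slice. Foreground is *strictly
   above* the threshold.
2. **3D object detection.** Foreground voxels are partitioned into
   connected components (default 26-connectivity). Components with fewer
   than 10 voxels are discarded as noise; each surviving component is one
   cilium. Objects touching the stack border are kept but flagged.
3. **Intensity measurement.** For each cilium and each channel, the
   arithmetic mean over exactly the member voxels. The marker mask thus
   serves as the cilia mask for all other channels.
4. **Length measurement.** The object mask is cropped with padding,
   upscaled three-fold by voxel replication, Gaussian-blurred (sigma = 3
   upscaled lateral pixels, i.e. 0.21 um at a 0.21 um pixel),
   re-binarized at half amplitude and thinned to a 3D medial-axis
   skeleton. The cilium length is the longest geodesic between skeleton
   endpoints, summed from Euclidean inter-node distances on the upscaled
   calibration grid; the total skeleton length is reported alongside.

### Renyi-entropy thresholding

For a histogram with bin probabilities $p_i$ and a candidate threshold
$t$, the background/foreground Renyi entropies of order $\rho$ are

$$H_b^{(\rho)}(t) = \frac{1}{1-\rho}\,\ln \sum_{i \le t}
\left(\frac{p_i}{P(t)}\right)^{\rho}, \qquad
H_f^{(\rho)}(t) = \frac{1}{1-\rho}\,\ln \sum_{i > t}
\left(\frac{p_i}{1-P(t)}\right)^{\rho},$$

with the Shannon/Kapur limit at $\rho \to 1$. Three candidate thresholds
maximize $H_b + H_f$ at $\rho = \tfrac12, 1, 2$; the candidates are
sorted and combined with the published weighting rule, in which the
weights depend on whether consecutive sorted candidates lie within 5 gray
levels of each other. Ties within an order break to the lowest bin, so
the procedure is deterministic and depends only on the histogram — never
on pixel positions.

Histograms use 256 bins after min--max scaling to the 0--255 range
(`build_histogram()`), because the reference implementation of this
thresholding family operates on 256-level histograms. For 8-bit data the
scaling is the identity. **Caveat:** for higher-bit-depth data, whether
the original plugin rescales the raw camera range before binning is not
documented; min--max scaling is this package's documented choice and a
potential source of divergence on >8-bit stacks. Because the procedure is
histogram-shape invariant, any affine intensity rescaling of the input
leaves the resulting mask unchanged.

### Skeleton length

Upscaling is nearest-neighbor replication — the subsequent blur provides
all smoothing, so no interpolation kernel needs to be invented. The blur
sigma is specified in upscaled *lateral* pixels; axially the physically
equivalent sigma (`sigma * dx / dz` in upscaled z-pixels) is used, so the
blur is isotropic in micrometers even for the typical 0.4--0.5 um z-step.
Re-binarization at 0.5 of the mask amplitude keeps the mid-surface of the
blurred tube; the 0.5 level is the only choice that recovers a blurred
half-space boundary at its original position (the error-function edge
crosses one half exactly at the boundary).

Thinning removes *simple points* — voxels whose deletion provably
preserves topology, characterized locally in the (26, 6) adjacency pair:
exactly one 26-connected foreground component in the 26-neighborhood and
exactly one 6-connected background component in the 18-neighborhood
touching the center. Curve endpoints (a single foreground neighbor) are
never removed. Deletion runs in six directional subiterations (up, down,
north, south, east, west) with sequential re-checking until stable, which
erodes tubes symmetrically toward their medial axis.

For the length, the skeleton voxels form a graph with edges between
26-adjacent voxels, weighted by Euclidean distance in micrometers. The
primary length is the largest shortest-path distance between endpoint
nodes (degree <= 1); for endpoint-free skeletons (loops) all node pairs
are considered. "Total skeleton length" is the weight of the minimum
spanning forest of this graph: summing *all* edges would double-count the
triangle shortcuts that diagonal adjacency creates at bends. On a
straight unbranched skeleton the two lengths coincide exactly; on curved
chains the geodesic may be marginally shorter than the total because it
takes diagonal shortcuts.

Two properties are exact by construction and pinned by tests: lengths
scale linearly with the calibration, and a collinear chain of $N$ voxels
at spacing $d$ measures $(N-1)d$. One property is only approximate:
because the directional subiterations impose an axis order, thinning a
*thick* mask is not perfectly symmetric under axis permutation — on
synthetic tubes the permuted-axis length differs by up to a few percent.
Thin (already 1-voxel) inputs are exactly invariant.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `min_voxels` | 10 | voxels | objects below this size are noise |
| `connectivity` | 26 | — | 3D adjacency for object detection |
| `upscale_factor` | 3 | — | mask replication factor before blurring |
| `blur_sigma_pixels` | 3 | upscaled px | 0.21 um at a 0.21 um pixel |
| `rebinarize_level` | 0.5 | fraction | mid-surface of the blurred tube |
| `alpha` | 0.75 | — | donor (cerulean) bleed-through fraction |
| `beta` | 0.02 | — | acceptor (citrine) cross-excitation fraction |
| `gate_threshold` | 7.5 | a.u. | strict upper bound on ciliary expression |
| `max_displacement_um` | 2 | um | tracking search radius per frame |

The connectivity default of 26 is a documented assumption: thin diagonal
cilia fragment under 6-connectivity, and 3D flood fill in the reference
ecosystem is 26-connected. The volume filter boundary reads "below 10
voxels is removed", so a 10-voxel object is retained and a 9-voxel object
is not; the expression gate is strict ("< 7.5 a.u."), so 7.5 itself is
excluded. Both boundaries are pinned by tests.

## Biosensor trace corrections

For FRET recordings (cerulean donor, citrine acceptor), the raw
FRET-channel signal contains donor bleed-through and direct acceptor
cross-excitation, removed linearly:

$$\mathrm{FRET}_{corr} = \mathrm{FRET} - \alpha\,\mathrm{cerulean} -
\beta\,\mathrm{citrine},$$

with $\alpha = 0.75$, $\beta = 0.02$ as defaults. An estimator helper
computes these constants from single-fluorophore control recordings as
the least-squares slope through the origin — a simple, reproducible
approximation of correlation-based calibration. Ratio traces
(cerulean/FRET~corr~, cerulean/citrine, mCherry/cpGFP) flag
zero-denominator frames as invalid rather than producing infinities, and
invalid frames stay missing — they are never interpolated. Baseline
normalization divides by the mean over all frames strictly before the
stimulus frame (e.g. 24 frames for stimulation after 120 s at 5-s
intervals) and is idempotent. Plate-reader Ca^2+ responses are anchored as
$(F - F_{baseline})/(F_{ionomycin} - F_{baseline})$, optionally divided
by the fraction of reporter-positive cells.

## Expression gating and length normalization

Cilia-length experiments with transiently expressed constructs must
control for the fact that high ectopic expression itself lengthens
cilia. The analysis module therefore (1) subtracts the mean ciliary
fluorescence of non-transfected control cells ("average" read as the
arithmetic mean), (2) keeps only cilia strictly below the 7.5 a.u. gate,
(3) expresses lengths as percent of the control mean, and (4) fits length
on intensity by ordinary least squares with the standard zero-slope test
to verify independence in the gated regime. Whether the gate is applied
per experiment (after per-experiment background subtraction) or globally
is left to the caller: `gate_params()` takes the background explicitly,
so both workflows are expressible.

## The synthetic generator

`generate_cilium_field()` emulates what the pipeline sees: curved tubes
(arc length 2--8 um, radius 0.1--0.3 um, bounded curvature, lying close
to the imaging plane), rendered at a 0.21 um lateral pixel and 0.4 um
z-step on a dim background; cargo channels share the marker footprint
with per-cilium amplitudes drawn from a configurable range; optional
Gaussian optics (sigma 0.15 um) precede Poisson shot noise and Gaussian
read noise. Ground truth (centerline, exact arc length, radius,
amplitudes, voxel footprint) is recorded *before* blur and noise, so
recovery tolerances absorb both the optics and the algorithm's bias.

What the generator does **not** emulate: a realistic objective PSF
(Gibson--Lanni), cell bodies and extraciliary staining, autofluorescence
structure, photobleaching, and axial anisotropy of the PSF. Passing the
recovery suite therefore demonstrates correctness of the measurement
chain under idealized optics, not performance on difficult real
stacks — on real data, segmentation quality depends on staining contrast
in ways no phantom captures.

Recovery behavior under the default conditions: detected object counts
match planted counts, per-cilium lengths land within
$2r + 10\%$ of truth for ~90% of cilia, and the mean recovered/true
length ratio sits within a few percent of unity (slight *over*estimation:
the threshold halo around a blurred sub-resolution tube extends the mask
tips, which outweighs the endpoint erosion of thinning). Noise-free
fields recover per-channel mean intensities exactly.

## Numerical and I/O choices

- **Axis convention.** Internally always `(time, channel, z, y, x)`,
  1-based in R; physical position of index $i$ is $(i-1) \cdot d$ (voxel
  centers). Degenerate axes are length 1.
- **Calibration precedence.** explicit override > OME-XML > ImageJ-style
  description > TIFF resolution tags > JSON sidecar; absence is an error,
  never a silent pixel-size default, because micrometer lengths are the
  headline output.
- **Sidecar.** The linked TIFF library does not expose description or
  resolution tags on write, so the writer pairs every TIFF with
  `<file>.calibration.json` carrying voxel sizes, axis counts and (for
  float data) the intensity scale. Third-party OME/ImageJ files read
  fine without one.
- **Blur boundary.** Separable convolution with a kernel truncated at
  $4\sigma$ and zero padding; object crops are padded generously before
  upscaling so the truncation never touches the object.
- **Degenerate inputs.** A constant (e.g. all-zero) stack has a
  single-bin histogram and fails at the threshold stage with a
  stage-tagged error; an object too small to survive the blur keeps an
  undefined length (`NA`) but is retained in the table; empty time-lapse
  frames record a track gap instead of failing the run.
- **Determinism.** Everything downstream of the generator is
  deterministic; the generator itself is a pure function of its seed.
  Reruns with the same configuration are bit-identical, and every output
  table embeds the configuration hash and package version.

## Problem sizes in the test suite

The suite validates labeling against a breadth-first-search oracle on one
hundred 16^3 masks, thresholding against an exhaustive-scan oracle on
dozens of seeded histograms, and end-to-end recovery on fifty synthetic
fields of five cilia each (96 x 96 x 14 voxels) — sizes chosen so the
whole suite runs in about a minute while still exercising every stage at
realistic cilium geometry.

## Known limitations

- Touching cilia are merged (no watershed splitting); the paper-scale
  experiments rely on sparse cilia, and the generator enforces
  non-overlap.
- Thick-mask skeletons are not exactly axis-permutation invariant (see
  above), and skeleton endpoints inherit the segmentation halo, giving a
  small positive length bias for sub-resolution tubes.
- Proprietary microscope formats (ND2, LIF, OIB) are out of scope; convert
  to OME-TIFF first.
- Statistical comparisons beyond the zero-slope regression (t-tests,
  Mann--Whitney) are deliberately not re-implemented; the output tables
  feed any statistics tool.
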