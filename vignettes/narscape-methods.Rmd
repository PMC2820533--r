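---
title: "Methods: domain calling from tiling ChIP signal and radial position analysis of FISH loci"
author: "narscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain calling and radial position analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`narscape` implements two linked analyses from nuclear-organization
studies of *Drosophila* cells:

1. **Domain calling.** Nucleoporins such as Nup153 and Megator bind
   chromatin in broad, contiguous stretches rather than sharp peaks.
   The package detects these nucleoporin-associated regions (NARs) from
   tiling-array ChIP signal by a sliding-window density criterion, and
   quantifies how transcriptional activity distributes relative to the
   called domains.
2. **Radial position analysis.** 3D-FISH localizes individual loci
   inside immunostained nuclei.  The package segments the nucleus,
   converts the segmentation into a distance-to-boundary map, and
   summarizes each nucleus by the mean normalized distance of its FISH
   voxels, which is then compared against peripheral and interior
   reference distributions.

Both analyses are driven by a synthetic-data module so that every stage
can be exercised, calibrated and tested without array or microscopy
data.

# The domain-calling model

## Signal chain

Probe intensities (IP and input, replicated) are quantile-normalized,
averaged across replicates **on the linear intensity scale**, and
converted to `log2(IP/input)` per probe.  Averaging linearly before the
log is one of two defensible readings of the usual processing
description; it matches the presentation of mean intensities before
ratios and is the package's fixed choice.

Ratios are smoothed by averaging all probes whose start position lies
within a 500 bp window centred on each probe (inclusive at both edges,
never crossing a chromosome boundary).  A probe is *positive* when its
smoothed ratio exceeds 0.

## Density and threshold

For every probe, the *positive probe density* is the fraction of
positive probes within a 10 kb window centred on the probe start.
Probes whose density strictly exceeds θ = 0.70 ("more than 70%")
qualify, and maximal runs of qualifying probes become domains.  The
domain interval runs from the first qualifying probe start to the last
qualifying probe start plus one probe spacing.

Two deliberate interpretations, both configurable:

* **Extent.** Domains span the run of qualifying *probes*
  (`extent = "probes"`, default).  The union-of-windows alternative
  (`extent = "windows"`) widens each run by half a window per side; it
  changes lengths by ≤ 10 kb and merges near-neighbours.
* **Gaps.** A single non-qualifying probe splits a domain
  (`max_gap_probes = 0`, default), the simplest faithful reading of
  "continuous regions".

The two-stage alternative caller marks seed probes at a stricter
density (default 0.8) and extends them outward while the density stays
above a laxer one (default 0.6; the cited two-stage method's own
parameters are not restated in the source material, so these defaults
are package choices).  Implementation note: "extend outward
probe-by-probe" is computed as maximal above-extend-threshold runs that
contain at least one seed — the two formulations are equivalent and the
latter merges overlapping extensions by construction.

## Why the null is clean

With positive fraction *f* ≤ 0.5 and ~286 probes per 10 kb window, the
binomial tail P(density > 0.7) is below 10⁻¹⁰ per window, so a shuffled
genome produces zero domains with overwhelming probability.  This is
the basis of the randomization acceptance check (10 Mb at *f* = 0.42,
ten shuffle seeds, zero domains).

## Enrichment statistics

Genes are assigned to domains by the **>50% length-overlap rule**
(membership is nowhere defined in the source material; TSS-in-domain
and any-overlap are provided as config alternatives).  Binary labels
(expressed, bound, down-regulated) are tested by two-sided Fisher exact
tests; probe-level signal by Welch's *t*-test (unequal variances — the
robust default where no variant is specified); window-level gene
density (20 kb windows at 1 kb offsets) by Wilcoxon rank-sum.  All
p-values in a batch are corrected with an authored Benjamini–Hochberg
step-up (`bh_fdr()`), which the test suite checks against
`p.adjust(..., "BH")`.  Text output floors tiny p-values at the
conventional `<2.2e-16`; machine output keeps exact values.

# The nucleus model and measurement chain

## Simulated nuclei

Simulated nuclei are voxelized hard spheres: DAPI fills the sphere,
lamin is the one-voxel surface shell, and the FISH signal is a filled
sphere of radius `signal_extent × R` centred at normalized boundary
distance `signal_center` (0 = boundary, 1 = centroid).  Real nuclei are
aspherical; the idealized reference simulations the analysis compares
against are spheres, so spheres are the faithful null here.  Channel
contrast is 180 intensity units (background 20, foreground 200) with
additive Gaussian noise, default SD 10 (≈ 5% of contrast, a
representative confocal signal-to-noise level; the source material
gives no value).  Intensities are clipped at 0.

Reference samples (`simulate_reference()`) add nucleus-to-nucleus
variability: a random signal direction and Gaussian jitter of the
normalized centre position (SD 0.05, truncated to [0, 1]).  These two
dials are the package's "realistic variability" choice, fixed once;
without them every simulated nucleus would give an identical summary
and rank tests against references would be degenerate.

What the generator does **not** emulate: confocal point-spread
functions, anisotropic voxels, chromatic shift, aspherical or touching
nuclei, hybridization background.  A green test therefore establishes
the correctness of the measurement chain on idealized geometry, not
robustness to those effects.

## Segmentation and distance map

The DAPI channel is thresholded by Otsu's criterion, the largest
6-connected component is kept, and holes are filled slice-wise.  The
boundary is cross-checked against the lamin channel: the lamin stain is
thresholded, filled, reduced to a per-slice single-voxel rim, and rim
voxels farther than a tolerance (default 2 voxels; the original
"significant deviation" criterion is not quantified) from the DAPI
surface are flagged.  Nuclei with more than 10% flagged rim are marked
unusable.  Refinement is a QC step: the DAPI geometry is kept, and on
synthetic spheres the DAPI- and lamin-derived radii agree within 2%.

The distance map is a plain 3D Euclidean distance transform of the
inside region with respect to the outside, computed by the separable
lower-envelope algorithm in compiled code.  This *is* the quantity the
measurement defines — distance to the closest point on the nuclear
boundary.  (A "local thickness" map proper would measure the largest
inscribed sphere, a different quantity; the distance transform is the
faithful implementation of the stated measurement.)

## FISH thresholding: a documented deviation

The design default is Otsu on the FISH channel restricted to the mask.
Empirically this fails for very compact spots: when the signal occupies
less than roughly 0.5% of the nucleus, the between-class-variance
criterion is maximized by splitting the background noise rather than
isolating the spot, and essentially the whole nucleus is selected.  For
the default 0.30-extent reference signals (~1–3% of the nuclear volume)
Otsu is reliable and remains the default.  For compact probes the
`"halfmax"` rule — threshold halfway between the in-mask median and the
in-mask maximum — is provided; it is scale-free and exact for
high-contrast spots.  The position-recovery property (below) uses it.

## Summaries and normalization

Per nucleus, the mean of the FISH-voxel distances is computed first and
then divided by the nuclear radius (mean-then-normalize, the stated
order); the radius is the mean surface-voxel-to-centroid distance.
Normalized values are not clamped, so voxelization can push values
slightly above 1 at the exact centre.  Reference distributions can be
pooled per nucleus (default) or per voxel; the acceptance bands for the
simulated references (peripheral median ≤ 30% of the radius, interior
median within 20–60%) are stated for pooled voxel distances.

## Geometry of the position-recovery property

The recovery invariant asks that a signal planted at normalized
position *c* be recovered within ±0.05 through the full pipeline, for
*c* ∈ {0.1, 0.3, 0.5, 0.8}.  This is run with a **compact probe**
(`signal_extent = 0.1`), not the 0.30 reference extent, for a
geometric reason: the per-nucleus summary is a mean over signal voxels,
and for an extended sphere the mean of `R − |x|` is biased toward the
centroid by ≈ a²/(5·r₀) (a = signal radius, r₀ = centre-to-centroid
distance).  At extent 0.30 and c = 0.8 the signal engulfs the centroid
and the bias reaches ≈ 0.09 normalized units — the invariant cannot
hold there for any correct implementation.  A compact probe makes the
bias negligible (≤ 0.01) and isolates what the invariant is about: the
calibration of segmentation + distance transform + normalization.  The
extended-signal behaviour is covered separately by the reference-band
checks.

# Localisation statistics

Each target locus (a set of per-nucleus normalized distances, typically
44–91 nuclei in practice) is compared by two-sided Wilcoxon rank-sum
tests against a peripheral control and an interior control; all
p-values in a batch are BH-corrected together, and calls are made at
α = 0.05 on the q-values:

| vs peripheral ctrl | vs interior ctrl | call |
|---|---|---|
| non-significant | significant | peripheral |
| significant | non-significant | non-peripheral |
| non-significant | non-significant | intermediate |
| significant | significant | ambiguous |

The last two labels are package conventions: the source decision rule
is silent on those cells.  `wilcox.test()`'s standard behaviour (exact
for small untied samples, normal approximation with tie correction
otherwise) is used.

Depletion experiments are tested by Wilcoxon between mock and depleted
samples; a locus is *relocalised* when the test is significant and the
depleted median lies farther from the boundary.  The report includes,
per condition, the proportion of nuclei within the 30% peripheral
distance band.

Reference simulations run through the same voxel pipeline as
measurements (no analytic shortcut), so systematic voxelization biases
cancel in the comparison.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere, including BED/bedGraph
  I/O.
* Window membership (smoothing and density) is by probe start position,
  inclusive at both window edges.
* Strict `>` at the density threshold θ, so a density of exactly 0.70
  does not qualify.
* Fisher tests reject degenerate margins (all genes inside, or constant
  label) rather than returning p = 1 silently.
* Welch's t errors on zero variance on both sides.
* Nuclei whose FISH signal has no voxels inside the mask are excluded
  with a diagnostic rather than contributing a zero.
* The Otsu threshold uses 256 equal-width bins over the observed range;
  the foreground is strictly above the threshold.
* Image stacks are exchanged as plain-text arrays (`write_stack()`):
  the environment has no TIFF codec for R and the format keeps fixtures
  human-readable.  Configs round-trip through JSON for the same reason.

# Known limitations

* The domain caller has no gap tolerance by default and no HMM-style
  segmentation; very noisy profiles fragment.
* Otsu-based FISH spot detection degrades below ~0.5% foreground
  fraction (use `"halfmax"` or a numeric threshold).
* Isotropic voxels are assumed; anisotropic stacks must be resampled
  upstream.
* The synthetic gene model plants expression conditionally on domain
  membership only; no covariation with gene length, density or
  chromatin state beyond that.
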