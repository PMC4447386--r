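---
title: "Sequential histogram fitting: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential histogram fitting: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histonorm)
```

## The model

A stack of serial-section micrographs carries two kinds of histogram
variation. Anatomy changes *slowly*: sections are microns apart, so the
gray-value composition of the tissue drifts smoothly with section index.
Staining and illumination change *irregularly*: each slide is stained and
scanned separately, so its histogram is shifted and compressed by an amount
uncorrelated with its neighbors. Sequential histogram fitting assumes this
decomposition — per-section histogram summary = smooth function of index +
irregular per-section disturbance — and removes the disturbance by
smoothing across the index.

The histogram of section *i* is summarized by landmarks: the dynamic-range
endpoints `L_i1` (darkest steadily occupied gray value) and `L_im` (the
bright-background peak), with the interior `L_i2..L_i,m-1` placed at equal
steps of cumulative frequency between them. Landmarks, not full histograms,
are smoothed: each ordinate's trajectory across the stack is fitted by a
low-order polynomial, the fitted values become the *desired* landmarks, and
a piecewise-linear gray-value map carries each section's landmarks onto its
desired ones. Because the map is monotone and piecewise linear, the
processed histogram is span-by-span an affinely rescaled copy of the
original: cumulative mass between consecutive landmarks is conserved (up to
8-bit binning), which is exactly the sense in which "the shape of the
histogram" survives the correction.

The desired dynamic range is anchored at constant endpoints for every
section (defaults: gray 64 and 228). This is what makes the method
reference-free *and* contrast-normalizing: no section is privileged, and
every processed section spans the same designated band.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `m` | 9 | dynamic-range landmarks per histogram. More landmarks restore histogram shape more finely; fewer are more robust on near-degenerate histograms. |
| `degree` | 3 | polynomial degree of the trajectory fits (3 or 4). Suitable when structure changes slowly; raise to 4 for stacks whose content turns over faster. Requires `N > degree`. |
| `anchors` | (64, 228) | desired gray values of `L'_i1` and `L'_im` (8-bit gray levels). The defaults leave headroom below and above the dynamic range so extrapolated dark/highlight detail is not clipped immediately. |
| `thumbnail_factor` | 8 | block-subsampling factor for histogram computation. Subsampling (not interpolation) keeps the thumbnail histogram an unbiased sample of the full one; transforms always run at full resolution. |
| `eps` | 1e-4 | occupancy threshold (fraction of total mass) for dynamic-range detection. |
| `k` | 3 | window length (bins) for the steady-occupancy rule. |

## Numerical and design choices

**Dynamic-range detection.** "Steadily appeared" is operationalized as the
smallest occupied gray value whose `k`-bin window carries at least
`k * eps` of the total mass. A windowed sum is used rather than requiring
every bin in the window to be occupied, because 8-bit images whose contrast
has been *stretched* (including this package's own output) have comb
histograms — occupied bins alternating with empty ones — on which an
every-bin rule can never fire. On smooth histograms the two rules agree.

**Bright background.** `L_im` is the mode of the top quartile *of the
histogram mass* (the brightest quarter of the pixels). A fixed gray-value
window would miss the background peak whenever staining variation has
pulled it darker; the mass-based quartile follows the peak wherever the
corruption moved it, which is the regime the tool exists for. If the
quartile holds no bin with at least `eps` mass, the brightest bin with
`eps` mass is used instead.

**Desired rows are integer gray values.** After the fitted interior values
are affinely remapped onto the anchor band, rows are repaired to be
strictly increasing with a minimum gap of one gray level — a forward sweep
from the fixed lower anchor, then a backward sweep from the fixed upper
anchor, which guarantees the unit gap exactly (an affine re-scale after the
sweep could shrink gaps below one) — and then rounded half-up. Fractional
landmark targets would make the rounding of the warp phase-dependent and
can merge a heavily-populated bin across a landmark boundary; integer
targets with unit gaps keep the lookup table strictly increasing at every
landmark.

**Warp details.** Scale factors in the outermost dynamic spans are reused
below `L_i1` and above `L_im` (the only extrapolation continuous at the
range ends), results are clipped to [0, 255], and rounding is half-up so
the lookup table is identical across platforms. When desired landmarks
equal the originals the lookup table is exactly the identity, and the
processed stack is bit-identical to the input — the method's fixed point.

**Degenerate sections.** Constant or undetectable-range sections are
excluded from the trajectory fits (a few poorly stained sections therefore
cannot distort the desired histograms) and are warped against a fallback
row spanning [0, 255], with a warning naming them.

**Metrics.** KLD uses natural log with the convention `0 ln(0/q) = 0`.
When a bin has original mass but zero processed mass the raw divergence is
infinite; additive smoothing (`1e-8` per bin, renormalized) is applied to
both distributions *only in that case*, so exact cases (identical inputs,
fully-overlapping supports) are computed without perturbation. CPP uses
truncated neighborhoods at the borders (corner pixels have 3 neighbors),
which keeps the constant-image value exactly zero without padding
artifacts. Stripe variance is the population variance, across sections, of
each section's mean intensity in an orthogonal reslice.

**Baselines.** Classic equalization deliberately includes the background in
its cumulative histogram, reproducing the over-stretching it is known for
on micrographs. Exact equalization implements classical histogram
specification; the reference section is a user parameter (default: middle
of the stack) — automatic reference selection is out of scope.

## What the synthetic generator emulates — and what it does not

`generate_stack()` builds a clean stack of elliptical structures (dark
"tissue" profiles, a few mid-bright "lumen" profiles) on a bright
background (mean gray 230), with per-pixel Gaussian texture noise
(sd 3). Structure radii are modulated by a fixed quadratic in normalized
section index (`0.8 + 0.4 t - 0.3 t^2`), so component mixture weights — and
hence the clean landmark trajectories — drift smoothly, as real anatomy
does through a sectioned volume. Corruption is affine in intensity:
`corrupted = clamp(g_i (clean - 128) + 128 + b_i)` with
`g_i ~ U(0.5, 1.0)` and `b_i ~ U(-40, 10)` drawn independently per section.
These ranges emulate stacks whose staining varies strongly: contrast
compressed up to two-fold and brightness shifted by tens of gray levels,
while keeping the background below saturation so corruption remains
invertible in principle. The default stack is 120 sections of 128 × 128
pixels — small enough that the full pipeline, both baselines, and all
metrics run in seconds, while leaving every histogram comfortably
multi-modal at the default thumbnail factor.

The generator is histogram-faithful, not photorealistic: it produces the
multi-modal histograms with a dominant bright-background mode that the
landmark machinery consumes. It does **not** model spatially varying
shading, stain metachromasia, section folds or tears, registration error,
or texture beyond Gaussian noise. Tests passing on it therefore validate
the histogram pipeline — detection, placement, fitting, warping, metrics —
not robustness to spatial artifacts, which are upstream of this method's
scope (it is a histogram-level correction by construction).

## Known limitations

- The anchors (64, 228) are configuration, not estimation: the package
  does not derive desired endpoints from the data.
- Landmark trajectories are polynomials; stacks whose content changes
  abruptly (lesions, organ boundaries) can be under-fitted at degree 3–4.
  The curve interface is pluggable, but only polynomials are provided.
- The warp is global per section; tile-based local contrast correction is
  a non-goal.
- 8-bit single-channel math throughout; RGB is handled by warping the
  BT.601 luma and rescaling channels by the per-pixel intensity ratio,
  which preserves hue but is this package's choice of recoloring, not a
  colorimetric standard.
- Quantile landmarks crowd wherever a histogram mode holds more mass than
  one equipartition step (e.g. a very dominant background); the unit-gap
  repair keeps the warp monotone there, but shape restoration inside such
  a mode is inherently coarse — more landmarks help.
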