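---
title: "Methods: quantifying protein recruitment to laser-induced strain sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying protein recruitment to laser-induced strain sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scientific setting

Cells repair mechanically damaged actin structures by recruiting dedicated
proteins to the damage site. Two experimental readouts are quantified by this
package:

1. **Live-cell recruitment kinetics.** A stress fiber is cut with a pulsed
   laser while a two-channel time lapse records a fluorescent reporter and an
   F-actin marker. The quantity of interest is the relative fluorescence
   increase of the reporter at the ablation site over time,
   $\Delta F / F_0 = (F(t) - F_0) / F_0$, where $F_0$ is the pre-ablation
   baseline, together with the spatial distribution of the recruitment
   relative to the strained region.
2. **Fixed-tissue gap statistics.** In hair-cell stereocilia, phalloidin line
   scans across actin gaps give an enrichment ratio (reporter intensity in
   the gap over the flanking shaft), and per-organ count tables give the
   percentage of cells with gaps, dead-cell percentages, and stereocilia
   counts.

Real microscopy data for the original experiments are not distributable, so
the package ships a first-class synthetic generator whose defaults mirror the
study's acquisition settings; every analysis step is validated against the
generator's ground truth or independent numerical oracles.

## The recruitment pipeline

`quantify_recruitment()` runs the fixed sequence: split channels →
flat-field → photobleach correction → registration of the reporter →
propagation of shifts to the actin channel → crop around the ablation site →
pre-ablation reference → relative difference → brightest-fraction mask →
trace. The order of the applied corrections follows the order in which the
original analysis describes them.

### Flat-field correction

No calibration image is available, so the package uses a pseudo-flat-field:
the temporal mean image blurred with a Gaussian of scale $\sigma = 10$ µm,
rescaled to unit mean (`estimate_flatfield()`). Two consequences of this
construction drive design choices elsewhere:

* The gain map inevitably contains smooth *specimen* structure (the blurred
  fiber ridge, roughly 7% at default settings), not only instrument shading.
* A multiplicative field common to all frames cancels exactly in the later
  relative difference — but only if it is common *in specimen coordinates*.

Under stage drift the specimen moves while a static gain map does not, which
leaves a drift-proportional residual $g(x+\bar s)/g(x+s_t) - 1$ of order
$10^{-3}$ in the relative difference — the same order as the zero-signal
control bound. The pipeline therefore (a) estimates the gain from the
temporal mean of *all* frames, putting its specimen component at the mean
drift position, and (b) divides each frame by the gain translated to the
frame's estimated drift. The divisor field is then identical for every frame
in specimen coordinates and cancels exactly. A user-supplied calibration
image (a true instrument property) is instead applied statically via
`apply_flatfield()`.

### Photobleach correction

Bleaching is modelled as a global mono-exponential,
$m(t) = A e^{-t/\tau} + c$, fitted by Levenberg–Marquardt to per-frame mean
intensities (`fit_bleach()`), with a frame-ratio fallback when the fit fails.
Each frame is then multiplied by $m(0)/m(t)$ — a single scalar, so spatial
patterns are untouched. Two details matter on drifting data:

* The fit excludes a disc of radius 6 µm around the ablation segment so that
  recruitment and depletion cannot bias the global estimate. A disc fixed in
  camera coordinates would let the bright fiber slide in and out of the kept
  region and imprint a drift trend on the frame means; the exclusion disc is
  therefore translated per frame by the estimated drift (`fit_bleach()`
  accepts a per-frame 3-D exclusion).
* The model is fitted on the *raw* channel — whose frame means are free of
  scene–gain coupling — and applied to the flat-fielded stack. This is valid
  because the correction is a global scalar and the gain map has unit mean.

Registration shifts are estimated *before* the bleach correction is applied;
this is exact, not an approximation, because phase correlation is invariant
to a positive per-frame scalar rescaling of the images.

### Registration

`estimate_shift()` implements phase cross-correlation with matrix-multiply
upsampled-DFT refinement (default precision 1/100 px). Nyquist rows/columns
are zeroed in the normalized cross-power spectrum (their phase is
sign-ambiguous for real images), and sub-pixel translations force the Nyquist
bins of the phase ramp to be real so that shifting a real image stays real.

`register_series()` uses a two-pass reference: pre-ablation frames are first
aligned to frame 1 and averaged, then all frames are registered to that
average. Registering each noisy frame directly against another single noisy
frame whitens the shared noise and biases the correlation peak toward zero
lag; averaging the aligned baseline suppresses the reference noise by
$1/\sqrt{n_\text{pre}}$ and removes that bias. Shifts are re-anchored so
frame 1 has zero shift. The estimated shifts are applied to both channels
with `apply_shifts()` (Fourier translation; exposed border bands are set to
missing rather than wrapped).

### Trace extraction and masking

After cropping a 121-px window (21 µm at 0.173 µm/px) centred on the
ablation segment, the reference image is the mean of the pre-ablation frames
and the per-pixel relative difference is $(F - R)/R$, with a divisor floor of
$10^{-6}\,\mathrm{median}(R)$. Per frame, the mask is the brightest 5% of
valid relative-difference pixels — exactly $k = \mathrm{round}(0.05\,
n_\text{valid})$ pixels, with deterministic tie-breaking (value descending,
then row-major order). The trace is the masked mean of the reporter and, with
the *same reporter-derived mask*, of the actin channel. Plateau values are
the mean over the final third of post-ablation time points.

A subtlety worth stating: the reporter trace of a zero-signal control is
*not* zero-mean. Selecting the top 5% of $\approx$ zero-mean noise and
averaging the selected pixels yields an order-statistics offset of roughly
$2\sigma$ (about +0.04 at 2% noise). This is intrinsic to percentile masking,
not a bug; the unbiased zero-signal check is the masked mean of the *actin*
channel, whose pixels are not selected on their own noise. Package tests
assert the control property on the actin channel and the positivity of the
reporter offset.

### Spatial classification

`spatial_probability()` turns per-frame masks from one or more videos into a
per-pixel occupancy probability over post-ablation time points. The strained
region is modelled as a disc of radius 3.5 µm around the ablation segment
(half the 5 µm cut plus a margin); recruitment is classified
`inside_enriched` when the probability mass inside the disc exceeds twice the
disc's area fraction, `outside_enriched` below half, and `random` otherwise.

## The gap (line-scan and counting) pipeline

`enrichment_ratio()` locates the gap centre as the minimum of the smoothed
phalloidin profile, finds the gap edges as the outermost crossings of 90% of
each flank's outer-quartile median, and reports the mean reporter intensity
inside the gap divided by the mean over the flanks. A profile whose
threshold crossing lands inside the outer flank quartile is rejected as
`open_gap` (the dip is not resolved within the scan). The ratio is invariant
to linear scaling of the reporter by construction; the gap *location* is
additionally invariant to scaling of the phalloidin channel.
`gap_frequency()`, `dead_cell_percent()` and `stereocilia_mean()` pool
counts per organ (not per image) before forming percentages.

## The synthetic generator

`simulate_timelapse()` renders a horizontal stress fiber on a textured
background with: static multiplicative texture at two scales (coarse 1 µm,
10% amplitude; fine speckle 0.14 µm, 5%) giving registration signal;
mono-exponential bleaching; linear stage drift applied by Fourier
translation (so frame means are exactly preserved); cosine-tapered
recruitment with configurable half-time, disc or annular support
(`recruitment_inner_radius`); actin depletion in the ablation zone; and
multiplicative Gaussian noise relative to the local signal. Defaults mirror
the study acquisition: 0.173 µm pixels, 15 pre + 90 post frames at 2 s,
121-px crop. The generator emulates photometry, drift, bleaching, and local
kinetics — not polymerization dynamics, out-of-plane motion, or detector
physics (no Poisson shot noise, no dark current).

`simulate_linescan()` and `simulate_count_study()` provide ground-truth
profiles (Gaussian dip in phalloidin, flat-top enrichment bump in the
reporter) and binomial/Poisson count tables.

All generator randomness flows through an isolated RNG scope, so simulation
never perturbs the caller's random stream, and identical configurations are
bit-identical.

## Numerical and reproducibility choices

* All FFTs use `stats::fft`; Gaussian blurs are FFT-based and exactly
  mean-preserving.
* TIFF output stores float32 with an affine offset/scale recorded in the
  metadata, giving lossless-within-float32 round trips.
* CSV output uses 15 significant digits; reruns of any pipeline with the
  same inputs are byte-identical, and every output file's MD5 checksum is
  recorded in the run report.
* Typical problem sizes: 192–512 px frames, about 100 frames; a full
  default-size video quantification takes a few seconds on one CPU.

## Limitations

* The pseudo-flat-field cannot separate true shading from specimen
  structure; with strong real shading *and* large drift, the
  specimen-coordinate application trades a small shading misalignment for
  exact cancellation of the (dominant) specimen term.
* Registration assumes pure translation; rotation or deformation is out of
  scope.
* The bleach model is a single global exponential per channel; spatially
  varying bleaching is not modelled.
* The reporter-trace selection offset means reporter control traces sit near
  $+2\sigma$, not zero; comparisons between conditions should use the same
  mask fraction.

## A minimal example

```{r, eval = FALSE}
library(strainsite)
sim <- simulate_timelapse(sim_config(seed = 1))
run <- quantify_recruitment(sim$timelapse)
trace_plateau(run$trace, "reporter")
```
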