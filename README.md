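# strainsite

Quantification of protein recruitment to laser-induced strain sites on actin
structures, from two-channel live-cell time lapses and fixed-tissue line
scans.

## Scientific problem

When a stress fiber is locally damaged — for example cut with a pulsed laser —
repair proteins accumulate at the strain site within tens of seconds. The
standard readout is the relative fluorescence change of a reporter at the
site,

    ΔF/F₀ = (F(t) − F₀) / F₀,

where F₀ is the pre-ablation baseline, measured through an adaptive mask of
the brightest pixels near the cut, together with (a) the time course and
plateau of ΔF/F₀, (b) the spatial distribution of the recruitment relative to
the strained region, and (c) the simultaneous F-actin signal read through the
same mask. In fixed hair-cell stereocilia, the analogous readout is the
enrichment ratio of a reporter inside phalloidin-negative actin gaps relative
to the flanking shaft, plus per-organ gap/dead-cell/stereocilia count
statistics.

Raw measurements need flat-field correction, photobleach correction, and
drift registration before ΔF/F₀ is meaningful; each of those corrections can
itself inject a spurious "recruitment" signal of the same order as the noise
floor if it ignores stage drift. This package implements the full chain with
drift-robust corrections, plus a first-class synthetic generator with known
ground truth used to validate every stage.

## What is in the package

- `simulate_timelapse()`, `simulate_linescan()`, `simulate_count_study()` —
  synthetic data with ground truth; defaults mirror the study acquisition
  (0.173 µm/px, 15 pre + 90 post frames at 2 s, 121-px analysis crop).
- `estimate_flatfield()` / `apply_flatfield()` — pseudo-flat-field (blurred
  temporal mean, unit-mean gain) or calibration-based correction.
- `fit_bleach()` / `correct_bleach()` — global mono-exponential bleach model
  with a drift-tracking exclusion region around the ablation site.
- `estimate_shift()` / `register_series()` / `apply_shifts()` — phase
  cross-correlation with upsampled-DFT sub-pixel refinement (1/100 px) and a
  two-pass pre-ablation reference.
- `quantify_recruitment()`, `aggregate_runs()` — full per-video analysis:
  crop, reference, relative difference, brightest-5% masks, reporter and
  actin traces, spatial occupancy-probability maps, strain-region
  classification.
- `enrichment_ratio()`, `gap_frequency()`, `dead_cell_percent()`,
  `stereocilia_mean()` — line-scan and count statistics.
- `run_recruitment_pipeline()`, `run_gap_pipeline()` and the
  `inst/cli/strainsite` script — deterministic end-to-end drivers writing
  CSV/TIFF/JSON with MD5 checksums.

See the vignette (`vignettes/strainsite-methods.Rmd`) for the method details
and design rationale.

## Worked example

```r
library(strainsite)

cfg <- sim_config(
  image_size = c(128L, 128L), crop_size = 81L,
  n_pre_frames = 6L, n_post_frames = 24L,
  drift_per_frame = c(0.4, 0), bleach_tau = 120,
  gaussian_sd = 0.01, recruitment_amplitude = 0.5,
  recruitment_halftime = 6, seed = 9L
)
sim <- simulate_timelapse(cfg)           # truth: plateau 0.5, tau 120 s
run <- quantify_recruitment(sim$timelapse)

trace_plateau(run$trace, "reporter")
#> [1] 0.509
trace_plateau(run$trace, "actin")        # actin depletion at the cut
#> [1] -0.2028
run$bleach$reporter$tau                  # recovered bleach time constant (s)
#> [1] 119.9
tail(run$shifts$dy_px, 1)                # accumulated drift after 29 frames
#> [1] 11.63

ls <- simulate_linescan(fold = 2.0, noise_sd = 2, seed = 1)
enrichment_ratio(ls$profile)$enrichment_ratio
#> [1] 2.005
```

The injected recruitment amplitude 0.5 is recovered as 0.509 despite 11.6 px
of accumulated drift, 1% noise, and bleaching; the bleach time constant
120 s is recovered as 119.9 s; a fold-2.0 gap enrichment is recovered as
2.005 under 2% noise.

## License

MIT (see `LICENSE`).
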