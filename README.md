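# recruitr

Quantification of protein recruitment kinetics at laser-induced DNA damage
stripes, from dual-channel split-view time-lapse fluorescence movies.

When a pulsed laser draws a damage stripe through a cell nucleus,
fluorescently tagged repair factors accumulate there within seconds. With a
split-view emission splitter, two colours are recorded simultaneously on
the two halves of one camera chip, so the relative kinetics of two proteins
can be compared within single cells. `recruitr` is for researchers who
acquire such movies (or want to validate an analysis of them): it turns
TIFF stacks plus ROI definitions into per-cell recruitment curves and
population-level summaries, and ships a synthetic movie generator with
exact ground truth so the whole pipeline is testable without a microscope.

## The quantities it computes

For each cell and channel, with `I_t` the damage-site intensity (median of
the 20 brightest DoG-filtered ROI pixels, "medMax") divided by the
whole-nucleus mean (photobleaching correction), and `I_0` its mean over the
pre-damage frames:

- **RFI** (relative fluorescence intensity): `RFI_t = I_t / I_0` — the fold
  change at the damage site;
- **ΔI**: `I_t − I_0` — the additive excess;
- **FMR** (fraction of maximum recruitment):
  `FMR_t = (RFI_t − 1) / (RFI_max − 1)` — kinetics with the amplitude
  normalized away, 0 at baseline and 1 at the curve maximum;
- **t50**: the time after damage at which FMR first reaches 0.5.

On top of cell records it provides intensity-window quality control,
rank clustering by final FMR, heatmap ordering by windowed mean FMR,
descriptive regressions (initial intensity, nuclear size and cross-channel
against kinetics), mean ± SEM curves, single-cell red/green FMR ratios and
paired t50 scatters — plus split-view channel registration by integer-pixel
cross-correlation.

## A worked example

Simulate one dual-channel movie with known kinetics and push it through the
full pipeline:

```r
library(recruitr)

cfg <- sim_config(shape = c(64L, 96L), n_frames = 150L,
                  nucleus = list(centre = c(47.5, 31.5), semiaxes = c(40, 26)),
                  stripe = rect_roi(18L, 29L, 60L, 4L))
cfg$channels$green$noise_sd <- 17   # pixel SNR 10
cfg$channels$red$noise_sd <- 30
sim <- simulate_movie(cfg, seed = 42)
sim$green
#> Time-lapse movie [green]: 150 frames of 64x96 px, 0.5 s interval (75 s total)

damage <- rect_roi(18L, 25L, 60L, 12L)   # stripe plus an undamaged margin
cell <- analyze_cell("demo", sim$green, sim$red, damage,
                     sim$masks$nucleus$mask)
cell$green$curve
#> Recruitment curve [green]: max RFI 2.16 at 16 s, t50 3 s, final FMR 0.624
cell$red$curve
#> Recruitment curve [red]: max RFI 3.3 at 32 s, t50 4.5 s, final FMR 0.849
```

Reading the output: the green protein roughly doubles its damage-site
signal (max RFI 2.16) and reaches half of its maximal recruitment 3 s
after damage; the red protein has the larger fold change (3.3) but is
slower (t50 4.5 s), and by the last frame the green channel has dissociated
further (final FMR 0.624 vs 0.849). The generator's ground truth for this
seed is t50 = 2.73 s (green) and 4.68 s (red) — the frame-quantized
estimates land within one 0.5 s frame interval.

Population analyses take a list of such records, e.g.
`qc_filter()`, `cluster_by_final_fmr()`, `fmr_ratio()`,
`mean_sem_curves()`. A command-line front-end over the same functions
(`simulate`, `extract`, `analyze` subcommands, YAML/JSON configs,
provenance logs) lives at `inst/cli/recruitr.R`.

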