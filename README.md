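# flatstorm

Quantifying the benefits of flat-field ("top-hat") illumination over
conventional Gaussian illumination in single-molecule localization
microscopy (dSTORM/PALM).

In localization microscopy, photoswitching, photobleaching and photon
emission rates all scale with the local excitation intensity. Under a
Gaussian beam the field center is driven harder than the edges, which (a)
wastes laser power once every pixel must reach a working intensity, and (b)
biases the reconstruction, because the probability that a fluorophore is
ever successfully localized varies across the field. This package is for
microscopists and image analysts who want to quantify both effects — on
synthetic acquisitions with known ground truth, or on their own localization
tables and calibration images.

## What it computes

**Power efficiency.** Model the beam intensity as
I(r) = A·exp(−r²/(2σ²)) with σ in units of the square field's side, and
require I ≥ 1 everywhere on the unit square. The constraint binds at the
corner (r² = 1/2), so the scaled total power is
P(σ) = 2πσ²·exp(1/(4σ²)), minimized at **σ = 1/2** with
**P = (π/2)e ≈ 4.2699**: a threshold-covering Gaussian must deliver at
least ~4.27× the power of a flat-field beam. The 1D analogue has minimum
√(2π)·e½/2 ≈ 2.0664 at σ = 1/2, whose square recovers the 2D value.

**Localization-density bias.** A per-frame Markov blinking simulator
(OFF ↔ ON → BLEACHED, rates ∝ local intensity, Poisson photons,
overlap rejection, precision ∝ psf_sigma/√photons) generates paired
acquisitions of one filament sample under both beams. Localization tables
are persistence-filtered (records within 100 nm of a previous-frame record
removed), binned into 64 × 64 density maps, and divided into a
Gaussian/top-hat ratio map; an undercount factor (edge-region median ratio /
center-region median ratio) > 1 quantifies depletion at the beam center.

**Uniformity QC.** Display ranges (dark level to 1.2 × the 95th
percentile), ROI coefficient of variation, flat-pixel fractions, histograms
and relative-power measurements for TIFF calibration images.

## Worked example

```r
library(flatstorm)

# beam power efficiency
opt <- optimize_sigma(coverage_problem())
opt$sigma_opt   # 0.5
opt$ratio_min   # 4.269867

# paired synthetic experiment: top-hat imaged first, then Gaussian
cfg <- default_pipeline_config()
cfg$structure <- list(n_filaments = 20L, emitters_per_filament = 100L)
cfg$acquisition$n_frames <- 6000L
res <- run_fig5_equivalent(cfg)
nrow(res$table_tophat)    # 8031 filtered records under the top-hat
nrow(res$table_gaussian)  # 2704 under the Gaussian (imaged second)
res$median_ratio          # 0.222  -> below 1: bleaching carry-over
res$bias
#> <bias_report: undercount factor 1.419 (low-I median 0.321 / high-I median 0.226; 79 / 158 bins)>

cfg$simulation$order <- "gaussian_first"
res2 <- run_fig5_equivalent(cfg)
res2$median_ratio                 # 2.268  -> above 1: order reversed
res2$bias$undercount_factor      # 1.611
```

Read the three results together: the overall median of the Gaussian/top-hat
ratio map flips around 1 with the acquisition order (whichever beam is
imaged second sees a partially bleached sample), but the **undercount
factor stays above 1 in both orders** — the beam center recovers
proportionally fewer localizations than the edges whenever the Gaussian
beam is used, which is an illumination effect, not bleaching.

The numbered scripts under `analysis/` run the full study — efficiency
scan, paired simulations for both orders, density/ratio/bias analysis from
the on-disk tables, and uniformity QC on synthetic calibration images —
writing tables under `results/`.

The methods vignette (`vignettes/flatfield-smlm.Rmd`) documents the models,
parameter defaults and units, numerical conventions, and known limitations,
including a reconciliation note on width parametrizations of the efficiency
optimum.

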