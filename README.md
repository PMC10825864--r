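# aieclust

Simulation and quantification of proximity-gated fluorescence readouts of
membrane receptor clustering.

## The problem

Receptors such as HER2 cluster on the cell membrane, and that spatial
organization — not just expression level — carries biological and
therapeutic meaning. An aggregation-induced-emission (AIE) fluorophore
conjugated to an antibody turns this into a plate-scale assay: the dye is
dark unless a second dye-bearing antibody sits within a nanometre-scale
distance window (2.13–6.62 nm), so its widefield intensity reports
receptor *proximity*, while a conventional dye on the same antibody
reports receptor *amount*. Comparing the two channels shows, for
example, whether an anti-HER2 therapeutic disperses clusters while
leaving total receptor content untouched.

`aieclust` is the synthetic counterpart of that experiment, for people
who build or validate such assays and their analysis pipelines. It
provides:

- **Receptor fields** — Thomas cluster processes
  (κ parents/µm², Poisson(µ) offspring, Gaussian scatter σ, hard-core
  separation) and CSR patterns on irregular cell footprints, plus a
  count-conserving disruption model
  p(D, t) = p_max · (1 − e^(−t/τ)) · D^h / (D^h + EC50^h)
  that relocates clustered receptors to uniform positions.
- **Emission and optics** — the binary AIE rule (emissive iff a labeled
  partner lies in the closed window [d_min, d_max]), a
  proximity-insensitive conventional rule, and widefield rendering
  (Gaussian PSF, constant background, Poisson shot noise, Gaussian read
  noise).
- **Quantification** — edge-detection segmentation of the cell area,
  masked mean intensity, SNR = (mean_fg − mean_bg)/sd_bg, Pearson
  colocalization with 2D intensity histograms, dose–response tables
  normalized to untreated controls with Welch-test stars
  (`*` p < 0.05, `**` p < 0.01), hinge-regression onset detection and
  Hill-curve fitting.
- **Reproducibility plumbing** — YAML experiment configs, TIFF/CSV I/O,
  per-stage seed derivation making every well re-simulable in isolation.

## Worked example

Simulate a 24 h treatment plate — six doses in triplicate, six cells per
well, both dye channels — and fit the dose response:

```r
library(aieclust)

dye_antibody_ratio(1015, 749)   # mass-shift / dye-mass arithmetic
#> [1] 1.35
stokes_shift(354, 518)
#> [1] 164

cfg <- experiment_config(times = 24, master_seed = 1)
exp <- run_experiment(cfg)
exp$table
#> Dose-response table (normalized to untreated controls; * p<0.05, ** p<0.01)
#>           dye  dose time n mean_norm sd_norm p_value stars
#>           AIE 0e+00   24 3     1.000   0.016      NA
#>           AIE 1e-02   24 3     0.988   0.021 4.7e-01
#>           AIE 1e-01   24 3     0.903   0.026 9.8e-03    **
#>           AIE 1e+00   24 3     0.550   0.021 1.6e-05    **
#>           AIE 1e+01   24 3     0.338   0.013 8.6e-07    **
#>           AIE 1e+02   24 3     0.316   0.007 1.0e-05    **
#>  conventional 0e+00   24 3     1.000   0.016      NA
#>  conventional 1e-02   24 3     0.999   0.015 9.3e-01
#>  conventional 1e-01   24 3     0.995   0.019 7.5e-01
#>  conventional 1e+00   24 3     0.980   0.015 2.0e-01
#>  conventional 1e+01   24 3     0.973   0.018 1.2e-01
#>  conventional 1e+02   24 3     0.970   0.020 1.2e-01

sub <- exp$table[exp$table$dye == "AIE", ]
fit_hill_decay(sub$dose, sub$mean_norm)
#> <hill_fit> y = 1 - 0.689 * d^1.06 / (d^1.06 + 0.549^1.06)  [ec50 = 0.549]
```

The two channels tell the story: the proximity-gated (AIE) channel loses
two thirds of its signal as clusters disperse with dose, while the
conventional channel stays within noise of 1.0 because the disruption
model conserves receptor count. Note the fitted intensity EC50
(≈ 0.55 µg/mL) sits below the generative disruption EC50 (1 µg/mL): the
AIE signal falls roughly quadratically in the disrupted fraction, a
property of proximity-gated readouts discussed in the methods vignette
(`vignettes/aieclust-methods.Rmd`).

`plot(exp)` draws the per-time dose–response curves;
`write_experiment_csv(exp, "out/")` writes byte-reproducible
`wells.csv`/`doseresponse.csv`; `read_experiment_config()` loads the
annotated YAML schema in `inst/extdata/experiment_config.yaml`.

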