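# fnirsdecode

Decoding motor imagery from continuous-wave fNIRS recordings with fused
wavelet–Hjorth features.

Functional near-infrared spectroscopy (fNIRS) measures cortical
hemodynamics through scalp optodes at two wavelengths. This package
implements a complete decoding pipeline for motor-imagery experiments in
which a participant alternates between rest, **mental drawing (MD)** and
**spatial navigation (SN)**:

1. **Acquisition** — montage modelling (3 sources x 6 detectors over left
   sensorimotor cortex), enumeration of the 18 source–detector channels,
   exclusion of the 4 channels beyond 60 mm, delimited-file I/O and
   event-locked epoching.
2. **Hemodynamics** — conversion of raw intensities to optical density and
   to ΔHbO/ΔHbR (µM) via the modified Beer–Lambert law,
   ΔOD(λ) = [ε_HbO(λ)·ΔHbO + ε_HbR(λ)·ΔHbR]·DPF(λ)·d, solved per channel
   as a 2x2 linear system.
3. **ICA cleaning** — native FastICA (symmetric fixed point, logcosh) with
   pluggable artifact rejection: excess-kurtosis (spikes/shifts) plus
   narrowband spectral concentration (cardiac/respiratory/Mayer waves).
4. **Features** — classical per-epoch moments (mean, variance, skewness,
   kurtosis) and Welch-PSD descriptors (peak frequency/power, FWHM-band
   power), and a fused stream combining Hjorth activity α, Hjorth mobility
   β, trimmed Daubechies level-4 wavelet weights w, symlet smoothing s and
   Hilbert envelopes h:
   `fnew_i = (w_i + α_i + β_i)·f_i` and `fnew1_i = w_i·(h_i + s_i)`.
5. **Classification** — two independent one-vs-rest binary tasks (MD, SN)
   over KNN (k = 10, Euclidean, uniform), LDA, and gradient boosting
   (xgboost; 50 rounds), with seeded stratified k-fold cross-validation,
   run separately on the HbO and HbR streams and on both feature sets.
6. **Rank tests** — Mann–Whitney U (exact by enumeration for small untied
   samples, else tie/continuity-corrected normal approximation) and
   Kruskal–Wallis H validate that feature distributions differ across the
   three activity classes at α = 0.05.
7. **Synthetic sessions** — a seeded generator with known ground truth
   (double-gamma responses of 1 µM in class-specific channels,
   physiological sinusoids, white noise, spike/shift artifacts, forward
   Beer–Lambert emission) exercises every stage end to end.

## Worked example

```r
library(fnirsdecode)

# the bundled probe layout: 18 enumerated channels, 14 within 60 mm
ch <- enumerateChannels(standardMontage())
nChannels(ch)
#> [1] 18
nChannels(filterByDistance(ch, 60))
#> [1] 14

# simulate, preprocess, classify and validate in one call
cfg <- defaultConfig(seed = 1)
cfg$learners <- "gbm_xtreme"
report <- runPipeline(cfg)
print(report)
#> RunReport (12.2 s)
#>  task stream feature_set    learner  accuracy
#>    MD    HbO   classical gbm_xtreme 0.9833333
#>    SN    HbO   classical gbm_xtreme 0.9833333
#>    MD    HbR   classical gbm_xtreme 0.9666667
#>    SN    HbR   classical gbm_xtreme 0.9833333
#>    MD    HbO       fused gbm_xtreme 0.9833333
#>    SN    HbO       fused gbm_xtreme 0.9833333
#>    MD    HbR       fused gbm_xtreme 0.9666667
#>    SN    HbR       fused gbm_xtreme 0.9833333
```

Each `accuracy` is the stratified 5-fold cross-validated accuracy of one
one-vs-rest detector (task) on one hemoglobin stream and feature set; on
the default synthetic benchmark (60 trials, 1 µM responses against
realistic physiological noise) both detectors resolve the imagery tasks at
96–98%. `report$rank_tests` holds the per-feature Kruskal–Wallis and
Mann–Whitney results, and `writeRunReport(report, "out/")` serializes
everything to CSV + JSON.

Stage-level functions are exported too — e.g. `odToHb()`,
`fasticaFit()`/`icaClean()`, `fusedStreams()`, `crossValidate()`,
`mannWhitneyU()`, `kruskalH()` — see the package help and the methods
vignette (`vignettes/decoding-motor-imagery.Rmd`) for the model details
and design decisions.

A thin command-line front end ships at `inst/cli/fnirspipe.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/fnirspipe.R", package="fnirsdecode"))')" \
    simulate --seed 7 --out fixtures/
```

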