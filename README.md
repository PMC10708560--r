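# vitalradar

Contactless vital-sign monitoring with a 24 GHz continuous-wave (CW)
Doppler radar, studied end to end in simulation: the chest wall moves
with respiration (4–12 mm at 0.16–0.33 Hz) and heartbeat (0.2–0.5 mm at
0.83–2 Hz), and that motion phase-modulates the radar's complex baseband
return

&nbsp;&nbsp;&nbsp;&nbsp;*B(t) = A_b s(t) · exp(jβ_r cos(2πF_r t + φ_r)) · exp(jβ_c cos(2πF_c t + φ_c)) + N(t)*,&nbsp;&nbsp;&nbsp;&nbsp;*β = 4πa/λ*.

The package provides

* a **baseband simulator** with calibrated complex Gaussian noise
  (SNR −10…10 dB), validated by constant-modulus and Bessel-line
  (Jacobi–Anger) oracles;
* **labeled dataset builders** — 3000-record rate-regression, 5300-record
  3-state classification (drowsiness / normal / stress), and a
  1500-record generalization set of unseen subjects — plus an
  anti-aliased resample-and-segment preprocessor for external I/Q
  recordings;
* four **temporal network families** (1D-CNN, TCN, Bi-LSTM, CRNN) for
  joint (F_c, F_r) regression and 3-class classification, implemented in
  the package on RcppArmadillo kernels with finite-difference-verified
  backpropagation;
* the **evaluation protocol**: RMSE/MAE/R², the adapted R²\* = 1 −
  SSE/Σy² for blocks sharing one true label, confusion-matrix metrics,
  repeated-training mean ± sd reports, and per-state generalization
  tables.

It is aimed at researchers in radar-based physiological sensing who want
a reproducible, fully synthetic benchmark of temporal architectures
before touching clinical data.

## Worked example

Simulate one subject, check the physics, and estimate the rates without
any learning:

```r
library(vitalradar)

p   <- vital_sign_params(fc_hz = 1.2, fr_hz = 0.25)   # 72 bpm, 15 rpm
rec <- synthesize_baseband(p, radar_config(), snr_db = 5, seed = 1)

estimate_rates_fft(rec)
#> $fr_hz
#> [1] 0.239952
#>
#> $fc_hz
#> [1] 1.19976
```

Both peaks land on the nearest bin of the 0.02 Hz frequency grid of a
50 s record.

Build a desk-scale dataset (records synthesized at 100 Hz, decimated to
10 Hz by the package's anti-aliased resampler, which preserves the
band-limited SNR), train the CRNN classifier, and evaluate:

```r
ds <- build_classification_dataset(8, 7, 7, n_envs = 50, seed = 11)
ds <- decimate_dataset(ds, 10)
ds <- split_dataset(ds, seed = 4)          # 64/16/20, stratified

spec <- model_spec("crnn", "classification", scale = "desk")
fit  <- train(build_model(spec), ds,
              train_config(epochs = 40, lr = 5e-4, seed = 1))
ev   <- evaluate(fit, ds, "test")
ev$metrics$accuracy
#> [1] 0.9818182
ev$metrics$confusion
#>      [,1] [,2] [,3]
#> [1,]   70    0    0
#> [2,]    0   79    1
#> [3,]    1    2   67
```

98.2 % of the 220 held-out records are assigned the correct
physiological state (rows: true drowsiness/normal/stress, columns:
predicted); the published full-scale figure for this model is 99 %.
`reproduce_paper_tables("desk")` runs all four families and writes the
three benchmark tables (regression mean ± sd, classification metrics,
per-state R²\*); `scale = "full"` uses the complete 3000/5300/1500-record
conditions (CPU-hours).

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/vitalradar.R simulate --fc 1.2 --fr 0.25 --snr-db 5 --out rec.csv
Rscript inst/cli/vitalradar.R build-data --task classification --decimate-to 10 --out data/
Rscript inst/cli/vitalradar.R train --family crnn --data data/ --out run/
Rscript inst/cli/vitalradar.R evaluate --run run/ --data data/
```

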