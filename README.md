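# vmdrbf

Hybrid one-step-ahead forecasting of ECG (and other quasi-periodic
physiological) signals in R, for signal-processing researchers and engineers
who need millivolt-accurate next-sample prediction — e.g. to suppress
redundant transmissions from body-worn sensors, where a receiver substitutes
its own prediction whenever the true sample would not differ by more than a
threshold.

## Method

For a series *x*(*n*), the forecaster

1. decomposes *x* into *K* band-limited intrinsic mode functions (IMFs)
   *u_k* with center frequencies *ω_k* by **variational mode decomposition**
   (spectral alternating updates with a Wiener-type mode filter
   1/(1+2αΔω²) and centroid updates of *ω_k*), choosing *K* as the smallest
   mode count whose residual ratio
   R_res = Σ|x−Σ*u_k*| / Σ|x| falls below 1% with no significant further
   decrease;
2. delay-embeds each mode, X_i = (u(i), u(i+τ), …, u(i+(m−1)τ)), with τ from
   the first local minimum of the lagged mutual information (default policy:
   τ = 1 for every mode) and *m* from the false-nearest-neighbour criterion
   ((d_{m+1}−d_m)/d_m ≥ R_T with R_T = 15);
3. trains one **exact-interpolation Gaussian RBF network** per mode (every
   training input becomes a center, σ = spread/(0.8326·√2), output weights
   from one linear solve of H w = y, H_ij = exp(−‖X_i−C_j‖²/2σ²));
4. predicts open-loop one step ahead per mode from true history and **sums**
   the per-mode predictions, reporting RMSE / MAE / MSE on a chronological
   2/3 : 1/3 train/test split.

## Worked example

```r
library(vmdrbf)

s <- synth_ecg(synth_ecg_spec(seed = 42))   # 8 s of 250 Hz synthetic ECG
fit <- hybrid_fit(s, hybrid_config(vmd = vmd_config(K = 10)))
fit
#> <hybrid_model> K = 10 modes, split 1333 train / 667 test, spread = 0.5
#>   m:   2 2 2 2 2 2 2 2 3 3
#>   tau: 1 1 1 1 1 1 1 1 1 1

pred <- hybrid_predict_test(fit)
evaluate_forecast(pred$predictions, pred$actual)
#> <eval_report> n_test = 667
#>   RMSE = 0.00499472  MAE = 0.00364876  MSE = 2.49473e-05
```

The one-step RMSE (0.0050 mV) sits at the fixture's 0.005 mV noise floor —
about 2.8% of the test-segment standard deviation.  Per-mode embedding
dimensions (2–3) are what the FNN criterion selects for narrow-band
oscillators, and a single RBF trained on the raw undecomposed series under
the same embedding machinery is about 2.5 times worse (RMSE 0.0122 mV).
The same pipeline on real recordings reads WFDB format-212
records directly:

```r
s <- read_wfdb_212("100.hea", channel = 1, start = 0, count = 2768)
```

A command-line interface over the same functions ships with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "vmdrbf.R", package = "vmdrbf"))') \
    predict --input signal.csv --k 8 --out pred.csv --report report.json
```

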