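# Shared fixtures, built once per test run and cached: several are expensive
# (full hybrid fits, Lorenz FNN scans) and are examined by more than one file.
.fixture_cache <- new.env(parent = emptyenv())

# seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# Three well-separated tones with 0.5% additive noise: the canonical input
# for the residual-ratio K-selection rule (the noise floor must sit below the
# rule's 1% threshold for the component count to be identifiable).
fx_three_tone <- function() fixture("three_tone", function()
  tone_mixture(c(0.04, 0.15, 0.30), c(1, 0.8, 0.6), 1500,
               noise_sd = 0.005, seed = 7))

fx_three_tone_select <- function() fixture("three_tone_select", function()
  select_num_modes(fx_three_tone(), k_min = 1, k_max = 6))

# Period-40 sine observed with 5% noise: a noiseless exact-period sine is
# lattice-valued (40 distinct values), making binned MI constant up to bin
# geometry; observational noise restores the textbook quarter-period minimum.
fx_noisy_sine <- function() fixture("noisy_sine", function()
  sin(2 * pi * (0:3999) / 40) + with_seed(1, rnorm(4000, 0, 0.05)))

fx_lorenz <- function() fixture("lorenz", function() lorenz63(5000))

fx_lorenz_fnn <- function() fixture("lorenz_fnn", function() {
  lz <- fx_lorenz()
  tau <- select_delay(lz, max_lag = 50)$selected
  list(tau = tau,
       profile = select_embedding_dim(lz, tau = tau, m_max = 5))
})

# The end-to-end study fixture: 8 s of synthetic ECG at 250 Hz, seed 42.
fx_ecg42 <- function() fixture("ecg42", function()
  synth_ecg(synth_ecg_spec(seed = 42)))

fx_hybrid <- function() fixture("hybrid", function() {
  s <- fx_ecg42()
  cfg <- hybrid_config(vmd = vmd_config(K = 10))   # the reference ECG setting
  fit <- suppressWarnings(hybrid_fit(s, cfg))
  pred <- hybrid_predict_test(fit)
  list(signal = s, config = cfg, fit = fit, pred = pred,
       eval = evaluate_forecast(pred$predictions, pred$actual,
                                pred$per_imf, pred$per_imf_actual))
})

fx_baseline <- function() fixture("baseline", function()
  suppressWarnings(raw_rbf_forecast(fx_ecg42(), m = 3)))

# Spread grid spanning the fixture's scale regimes: below the delay-vector
# spacing (0.001), on the optimum plateau (0.5), far above the attractor
# diameter (1000).
fx_sweep <- function() fixture("sweep", function()
  suppressWarnings(spread_sweep(fx_ecg42(), fx_hybrid()$config,
                                c(0.001, 0.5, 1000))))

# Twenty random well-separated tone pairs for the decomposition oracle.
fx_twotone_seeds <- function() fixture("twotone_seeds", function() {
  res <- vector("list", 20)
  with_seed(99, {
    for (s in 1:20) {
      f <- sort(0.03 + 0.44 * stats::runif(2))
      while (diff(f) <= 0.05) f <- sort(0.03 + 0.44 * stats::runif(2))
      x <- tone_mixture(f, c(1, 1), 1000, noise_sd = 0.01, seed = s)
      r <- vmd_decompose(x, vmd_config(K = 2))
      res[[s]] <- list(
        freqs = f, omega = r$omega,
        cors = vapply(1:2, function(k)
          stats::cor(r$modes[k, ], cos(2 * pi * f[k] * 0:999)), numeric(1)))
    }
  })
  res
})
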