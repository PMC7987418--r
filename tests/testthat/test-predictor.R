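test_that("the chronological split follows floor arithmetic", {
  expect_equal(split_series(2768, 2 / 3), c(n_train = 1845L, n_test = 923L))
  expect_equal(split_series(3, 2 / 3), c(n_train = 2L, n_test = 1L))
  for (n in c(10L, 97L, 1234L))
    for (f in c(0.5, 2 / 3, 0.9))
      expect_identical(sum(split_series(n, f)), n)
})

test_that("error metrics match hand evaluation and satisfy rmse^2 = mse", {
  ev0 <- evaluate_forecast(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ev0$rmse, 0); expect_equal(ev0$mae, 0); expect_equal(ev0$mse, 0)
  ev <- evaluate_forecast(c(1, 2, 4), c(1, 2, 3))
  expect_equal(ev$mse, 1 / 3)
  expect_equal(ev$rmse, sqrt(1 / 3))
  expect_equal(ev$mae, 1 / 3)
  expect_identical(ev$rmse^2, ev$mse)
  expect_error(evaluate_forecast(1:3, 1:4), "length")
})

test_that("a constant signal is predicted exactly", {
  fit <- suppressWarnings(
    hybrid_fit(rep(3.7, 300), hybrid_config(vmd = vmd_config(K = 2))))
  pr <- hybrid_predict_test(fit)
  expect_lt(max(abs(pr$predictions - pr$actual)), 1e-9)
})

test_that("two-tone forecasts track each held-out mode almost perfectly", {
  x <- tone_mixture(c(0.05, 0.20), c(1, 1), 900)
  fit <- suppressWarnings(hybrid_fit(x, hybrid_config(vmd = vmd_config(K = 2))))
  pr <- hybrid_predict_test(fit)
  for (k in 1:2)
    expect_gt(cor(pr$per_imf[k, ], pr$per_imf_actual[k, ]), 0.999)
  # the forecast is the sum of the per-mode forecasts, by construction
  expect_equal(pr$predictions, colSums(pr$per_imf), tolerance = 1e-14)
})

test_that("the fitted model has one record per mode and the stated split", {
  h <- fx_hybrid()
  n <- length(fx_ecg42())
  expect_length(h$fit$per_imf, 10L)
  expect_identical(h$fit$split_index, as.integer(floor(2 * n / 3)))
  expect_identical(h$eval$n_test, n - as.integer(floor(2 * n / 3)))
  expect_true(all(vapply(h$fit$per_imf, function(p)
    inherits(p$model, "rbf_model") || p$degenerate, logical(1))))
})

test_that("summed error is bounded by the summed per-mode errors", {
  pr <- fx_hybrid()$pred
  lhs <- sqrt(mean((colSums(pr$per_imf_actual) - colSums(pr$per_imf))^2))
  rhs <- sum(sqrt(rowMeans((pr$per_imf_actual - pr$per_imf)^2)))
  expect_lte(lhs, rhs + 1e-12)
})

test_that("the decomposed pipeline beats the raw-series RBF baseline", {
  h <- fx_hybrid()
  expect_lt(h$eval$rmse, 0.10 * sd(h$pred$actual))
  expect_lt(h$eval$rmse, fx_baseline()$report$rmse)
})

test_that("fit, predict and evaluate are bit-reproducible", {
  s <- synth_ecg(synth_ecg_spec(duration_s = 3, seed = 5))
  cfg <- hybrid_config(vmd = vmd_config(K = 3))
  run <- function() {
    pr <- hybrid_predict_test(suppressWarnings(hybrid_fit(s, cfg)))
    evaluate_forecast(pr$predictions, pr$actual)
  }
  a <- run(); b <- run()
  expect_identical(a$rmse, b$rmse)
  expect_identical(a$mae, b$mae)
})

test_that("a one-spread sweep equals a direct fit at that spread", {
  s <- synth_ecg(synth_ecg_spec(duration_s = 3, seed = 5))
  cfg <- hybrid_config(vmd = vmd_config(K = 3))
  tab <- suppressWarnings(spread_sweep(s, cfg, 0.5))
  expect_identical(nrow(tab), 1L)
  pr <- hybrid_predict_test(suppressWarnings(hybrid_fit(s, cfg)))
  ev <- evaluate_forecast(pr$predictions, pr$actual)
  expect_equal(tab$rmse, ev$rmse, tolerance = 1e-12)
  expect_equal(tab$mae, ev$mae, tolerance = 1e-12)
  expect_equal(attr(tab, "best_spread"), 0.5)
})

test_that("the error curve over spread has a sharp left elbow", {
  tab <- fx_sweep()   # spreads 0.001, 0.5, 1000
  plateau <- tab$rmse[tab$spread == 0.5]
  expect_gt(tab$rmse[tab$spread == 0.001], 10 * plateau)
  # the plateau extends to very wide spreads under a regularised solve
  expect_lt(abs(tab$rmse[tab$spread == 1000] - plateau), 0.5 * plateau)
})

test_that("min-max normalisation leaves the forecast finite and accurate", {
  s <- synth_ecg(synth_ecg_spec(duration_s = 3, seed = 5))
  cfg <- hybrid_config(vmd = vmd_config(K = 3), normalize = TRUE)
  pr <- hybrid_predict_test(suppressWarnings(hybrid_fit(s, cfg)))
  expect_true(all(is.finite(pr$predictions)))
  expect_lt(evaluate_forecast(pr$predictions, pr$actual)$rmse,
            0.2 * sd(pr$actual))
})

test_that("mi-selected delays and fixed dimensions are honoured", {
  s <- synth_ecg(synth_ecg_spec(duration_s = 3, seed = 5))
  cfg <- hybrid_config(vmd = vmd_config(K = 3), delay_policy = "mi_selected",
                       dims_policy = "fixed_list", fixed_dims = c(4, 3, 2))
  fit <- suppressWarnings(hybrid_fit(s, cfg))
  expect_identical(vapply(fit$per_imf, `[[`, integer(1), "m"), c(4L, 3L, 2L))
  expect_true(all(vapply(fit$per_imf, `[[`, integer(1), "tau") >= 1L))
  expect_error(hybrid_config(vmd = vmd_config(K = 3),
                             dims_policy = "fixed_list",
                             fixed_dims = c(2, 2)),
               "per mode")
})
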