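test_that("delay embedding lays out inputs and targets as specified", {
  e <- embed_delay(1:10, m = 3, tau = 2)
  expect_identical(e$M, 6L)
  expect_identical(e$M_usable, 5L)
  expect_equal(e$X[1, ], c(1, 3, 5))
  expect_equal(e$Y[1], 6)
  expect_equal(e$X[6, ], c(6, 8, 10))
  expect_length(e$Y, 5)
  # degenerate embedding: the series and its left shift
  d <- embed_delay(c(4, 2, 7, 1), m = 1, tau = 1)
  expect_equal(drop(d$X), c(4, 2, 7, 1))
  expect_equal(d$Y, c(2, 7, 1))
  expect_error(embed_delay(1:5, m = 3, tau = 3), "short")
})

test_that("the first embedding column plus the tail reproduces the series", {
  x <- with_seed(2, rnorm(200))
  for (ps in list(c(1L, 1L), c(3L, 2L), c(5L, 7L), c(2L, 40L))) {
    e <- embed_delay(x, m = ps[1], tau = ps[2])
    expect_identical(nrow(e$X), length(x) - (ps[1] - 1L) * ps[2])
    tail_len <- (ps[1] - 1L) * ps[2]
    rebuilt <- c(e$X[, 1], if (tail_len) x[(length(x) - tail_len + 1):length(x)])
    expect_identical(rebuilt, x)
  }
})

test_that("histogram MI equals a brute-force double-sum oracle", {
  x <- c(0.3, 1.2, 0.7, 2.5, 1.9, 0.1, 2.2, 0.8, 1.5, 2.8, 0.4, 1.1)
  lag <- 2; nb <- 3
  n <- length(x) - lag
  s <- x[1:n]; q <- x[(1 + lag):length(x)]
  cut_bins <- function(v) pmin(floor((v - min(v)) / (max(v) - min(v)) * nb) + 1, nb)
  si <- cut_bins(s); qi <- cut_bins(q)
  # literal double sum of p(s,q) * log2(p(s,q) / (p(s) p(q)))
  oracle <- 0
  for (i in 1:nb) for (j in 1:nb) {
    psq <- sum(si == i & qi == j) / n
    if (psq > 0)
      oracle <- oracle +
        psq * log2(psq / ((sum(si == i) / n) * (sum(qi == j) / n)))
  }
  expect_equal(mutual_information(x, lag, n_bins = nb), oracle,
               tolerance = 1e-12)
})

test_that("self-pairing MI equals the marginal entropy", {
  x <- with_seed(6, rnorm(500))
  bins <- pmin(floor((x - min(x)) / diff(range(x)) * 16) + 1, 16)
  p <- tabulate(bins, 16) / length(x)
  h <- -sum(p[p > 0] * log2(p[p > 0]))
  expect_equal(mutual_information(x, 0, n_bins = 16), h, tolerance = 1e-12)
})

test_that("independent samples carry almost no mutual information", {
  u <- with_seed(5, runif(10000))
  expect_lt(mutual_information(u, 1, n_bins = 16), 0.05)
})

test_that("MI is symmetric, non-negative and bounded by marginal entropies", {
  ent <- function(v, nb) {
    b <- pmin(floor((v - min(v)) / diff(range(v)) * nb) + 1, nb)
    p <- tabulate(b, nb) / length(v)
    -sum(p[p > 0] * log2(p[p > 0]))
  }
  for (seed in 1:5) {
    x <- with_seed(seed, cumsum(rnorm(300)))
    for (lag in c(1, 3, 9)) {
      mi <- mutual_information(x, lag)
      # reversing the series swaps the roles of the pair members
      expect_equal(mi, mutual_information(rev(x), lag), tolerance = 1e-12)
      expect_gte(mi, -1e-10)
      n <- length(x) - lag
      expect_lte(mi, min(ent(x[1:n], 16), ent(x[(1 + lag):length(x)], 16)) +
                   1e-10)
    }
  }
})

test_that("constant series yields zero MI with a degenerate flag", {
  out <- mutual_information(rep(2, 50), 3)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "degenerate"))
})

test_that("delay selection finds the quarter-period minimum of a sine", {
  p <- select_delay(fx_noisy_sine(), max_lag = 20)
  expect_true(p$selected >= 8 && p$selected <= 12)
  expect_length(p$mi_bits, 20)
  # deterministic: identical on repeat
  expect_identical(p, select_delay(fx_noisy_sine(), max_lag = 20))
})

test_that("a monotone ramp has no MI local minimum", {
  p <- select_delay(as.numeric(1:500), max_lag = 30)
  expect_true(is.na(p$selected))
})

test_that("FNN fractions behave as the attractor dimension dictates", {
  sn <- sin(2 * pi * (0:1999) / 50)
  # a limit cycle embeds in the plane
  expect_lt(fnn_fraction(sn, m = 2, tau = 12, r_threshold = 15), 0.02)
  # one-dimensional projections of noise are almost all false neighbours
  nz <- with_seed(8, rnorm(1500))
  f1 <- fnn_fraction(nz, m = 1, tau = 1)
  expect_gt(f1, 0.8)
  expect_true(f1 >= 0 && f1 <= 1)
  # non-increasing on the deterministic fixture
  fr <- vapply(1:4, function(m) fnn_fraction(sn, m, tau = 12), numeric(1))
  expect_true(all(diff(fr) <= 1e-12))
})

test_that("dimension selection returns 2 for a sine and 3 for Lorenz-63", {
  sel_sine <- select_embedding_dim(sin(2 * pi * (0:1999) / 50), tau = 12,
                                   m_max = 5)
  expect_identical(sel_sine$selected, 2L)
  lf <- fx_lorenz_fnn()
  expect_identical(lf$profile$selected, 3L)
  expect_gt(lf$profile$fractions[2], 0.05)
  expect_lt(lf$profile$fractions[3], 0.05)
})
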