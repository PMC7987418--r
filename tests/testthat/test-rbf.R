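test_that("a one-unit network reproduces its training pair and decays", {
  m <- rbf_train_exact(matrix(1.5), 4.2, spread = 0.3)
  expect_equal(rbf_predict(m, matrix(1.5)), 4.2, tolerance = 1e-12)
  expect_lt(abs(rbf_predict(m, matrix(1.5 + 20 * 0.3))), 1e-10)
})

test_that("the exact design interpolates and matches a direct solve", {
  X <- with_seed(3, matrix(runif(250), 50, 5))
  y <- with_seed(4, rnorm(50))
  m <- rbf_train_exact(X, y, spread = 0.5)
  expect_lt(max(abs(rbf_predict(m, X) - y)), 1e-8)
  # independent oracle: assemble the Gaussian system by hand and solve it
  sigma <- 0.5 / (0.8326 * sqrt(2))
  H <- exp(-as.matrix(dist(X))^2 / (2 * sigma^2))
  expect_equal(m$weights, solve(H, y), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("hidden activation is one half at distance spread", {
  m <- rbf_train_exact(matrix(0), 1, spread = 0.7)
  h <- gauss_design(matrix(0.7), matrix(0), m$sigma)
  expect_equal(drop(h), 0.5, tolerance = 1e-4)
})

test_that("prediction is linear in the weights", {
  m <- rbf_train_exact(matrix(1:4, ncol = 1), c(2, 1, 3, 5), spread = 1)
  q <- matrix(seq(0, 5, by = 0.5))
  p <- rbf_predict(m, q)
  m0 <- m; m0$weights <- rep(0, 4)
  expect_equal(rbf_predict(m0, q), rep(0, nrow(q)))
  m2 <- m; m2$weights <- 2 * m$weights
  expect_equal(rbf_predict(m2, q), 2 * p, tolerance = 1e-12)
})

test_that("a hand-built three-centre model evaluates the Gaussian sum", {
  mod <- structure(list(centers = matrix(c(0, 1, 3), ncol = 1), sigma = 0.8,
                        weights = c(1.5, -2, 0.7), spread = 1, d = 1L),
                   class = "rbf_model")
  x <- 1.2
  hand <- 1.5 * exp(-(x - 0)^2 / (2 * 0.8^2)) -
    2 * exp(-(x - 1)^2 / (2 * 0.8^2)) + 0.7 * exp(-(x - 3)^2 / (2 * 0.8^2))
  expect_equal(rbf_predict(mod, matrix(x)), hand, tolerance = 1e-14)
})

test_that("prediction is invariant to joint permutation of centres/weights", {
  X <- with_seed(9, matrix(rnorm(60), 20, 3))
  y <- with_seed(10, rnorm(20))
  m <- rbf_train_exact(X, y, spread = 1)
  prm <- sample(20)
  mp <- m; mp$centers <- m$centers[prm, ]; mp$weights <- m$weights[prm]
  q <- with_seed(11, matrix(rnorm(15), 5, 3))
  expect_equal(rbf_predict(m, q), rbf_predict(mp, q), tolerance = 1e-12)
})

test_that("narrow spreads vanish off-centre; wide spreads degrade conditioning", {
  X <- with_seed(12, matrix(runif(30), 30, 1))
  y <- with_seed(13, rnorm(30))
  m_narrow <- rbf_train_exact(X, y, spread = 1e-4)
  expect_lt(abs(rbf_predict(m_narrow, matrix(-1))), 1e-10)
  sig <- function(s) s / (0.8326 * sqrt(2))
  k_small <- kappa(gauss_design(X, X, sig(0.05)))
  k_large <- kappa(gauss_design(X, X, sig(5)))
  expect_gt(k_large, 100 * k_small)
})

test_that("models serialise to text and reload bit-exactly", {
  X <- with_seed(14, matrix(rnorm(40), 20, 2))
  y <- with_seed(15, rnorm(20))
  m <- rbf_train_exact(X, y, spread = 0.8)
  f <- withr::local_tempfile(fileext = ".txt")
  write_rbf_model(m, f)
  m2 <- read_rbf_model(f)
  expect_identical(m2$weights, m$weights)
  expect_identical(m2$centers, m$centers)
  expect_identical(m2$sigma, m$sigma)
  q <- with_seed(16, matrix(rnorm(10), 5, 2))
  expect_identical(rbf_predict(m, q), rbf_predict(m2, q))
})

test_that("invalid inputs are rejected", {
  expect_error(rbf_train_exact(matrix(c(1, NA), 2, 1), c(1, 2), 0.5),
               "non-finite")
  m <- rbf_train_exact(matrix(1:3, ncol = 1), c(1, 2, 3), 1)
  expect_error(rbf_predict(m, matrix(1:4, 2, 2)), "dimension")
})
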