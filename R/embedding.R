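#' Delay embedding of a scalar series
#'
#' Builds the phase-space input matrix X and the one-step target vector Y for
#' a series x_1..x_N with embedding dimension `m` and delay `tau` (indices
#' below are 1-based).  Row i of X is `(x_i, x_{i+tau}, ..., x_{i+(m-1)tau})`
#' and its target is the next sample, `Y_i = x_{i+1+(m-1)tau}`.  There are
#' `M = N - (m-1)*tau` delay vectors, of which the last has no observed
#' target; it is retained as the query point for forecasting the next,
#' unobserved sample, so `M_usable = M - 1` supervised pairs are exposed.
#'
#' @param series Numeric vector (an individual IMF, usually).
#' @param m Embedding dimension (positive integer).
#' @param tau Delay in samples (positive integer).
#' @return A list of class `delay_embedding`: `X` (M x m), `Y` (length M - 1,
#'   aligned with the first M - 1 rows of X), `M`, `M_usable`, `m`, `tau`.
#' @examples
#' e <- embed_delay(1:10, m = 3, tau = 2)
#' e$M            # 6
#' e$X[1, ]       # 1 3 5
#' e$Y[1]         # 6
#' @export
embed_delay <- function(series, m, tau) {
  x <- as.numeric(series)
  m <- as.integer(m); tau <- as.integer(tau)
  stopifnot(m >= 1L, tau >= 1L)
  N <- length(x)
  M <- N - (m - 1L) * tau
  if (M < 2L)
    stop(sprintf("series too short to embed: N = %d, m = %d, tau = %d",
                 N, m, tau), call. = FALSE)
  X <- vapply(0:(m - 1L), function(j) x[(1:M) + j * tau], numeric(M))
  X <- matrix(X, nrow = M)
  Y <- x[(1:(M - 1L)) + 1L + (m - 1L) * tau]
  structure(list(X = X, Y = Y, M = M, M_usable = M - 1L, m = m, tau = tau),
            class = "delay_embedding")
}

# Equal-width bin indices over the observed range of v; constant input
# collapses to bin 1 everywhere.
bin_index <- function(v, n_bins) {
  r <- range(v)
  if (r[1] == r[2]) return(rep(1L, length(v)))
  i <- floor((v - r[1]) / (r[2] - r[1]) * n_bins) + 1L
  pmin(as.integer(i), as.integer(n_bins))
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Lagged mutual information of a series
#'
#' Estimates I(S, Q) in bits between S = x_t and its lagged copy
#' Q = x_{t+lag}, using equal-width histograms with `n_bins` bins per axis
#' over each variable's observed range: I = H(S) + H(Q) - H(S, Q) with base-2
#' logs; empty bins contribute zero.  `lag = 0` is allowed (self-pairing) and
#' returns the marginal entropy H(S).
#'
#' @param series Numeric vector; at least 10 pairs must remain after lagging.
#' @param lag Non-negative integer lag in samples.
#' @param n_bins Number of histogram bins per axis (default 16).
#' @return Mutual information in bits.  A constant (zero-range) series returns
#'   0 with attribute `degenerate = TRUE`.
#' @export
mutual_information <- function(series, lag, n_bins = 16L) {
  x <- as.numeric(series)
  lag <- as.integer(lag)
  stopifnot(lag >= 0L, n_bins >= 1L)
  n <- length(x) - lag
  if (n < 10L)
    stop("fewer than 10 lagged pairs available", call. = FALSE)
  s <- x[seq_len(n)]
  q <- x[seq_len(n) + lag]
  if (min(x) == max(x)) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  si <- bin_index(s, n_bins)
  qi <- bin_index(q, n_bins)
  hs <- entropy_bits(tabulate(si, n_bins))
  hq <- entropy_bits(tabulate(qi, n_bins))
  hsq <- entropy_bits(tabulate(si + n_bins * (qi - 1L), n_bins * n_bins))
  hs + hq - hsq
}

#' Select the embedding delay at the first local minimum of mutual information
#'
#' Computes the lagged mutual information for lags `1..max_lag` and selects
#' the smallest lag that is a strict local minimum of the profile (the value
#' at lag 0 is the marginal entropy H(S)).  If the profile has no local
#' minimum within range, `selected` is `NA` and callers should fall back to a
#' default delay (the hybrid predictor uses tau = 1).
#'
#' @param series Numeric vector.
#' @param max_lag Largest lag scanned; must be below half the series length.
#' @param n_bins Histogram bins per axis (default 16).
#' @param min_dip Minimum depth (bits) below both neighbours for a lag to
#'   count as a local minimum.  The default 1e-3 ignores sub-millibit jitter
#'   from histogram-bin geometry (visible e.g. on lattice-valued series such
#'   as exact-period sines or ramps) while leaving genuine minima, whose dips
#'   are orders of magnitude deeper, untouched.
#' @return A list of class `mi_profile`: `lags`, `mi_bits`, `selected`
#'   (integer or `NA`).
#' @export
select_delay <- function(series, max_lag, n_bins = 16L, min_dip = 1e-3) {
  x <- as.numeric(series)
  max_lag <- as.integer(max_lag)
  stopifnot(max_lag >= 1L)
  if (max_lag >= length(x) / 2)
    stop("max_lag must be below half the series length", call. = FALSE)
  mi <- vapply(0:max_lag, mutual_information, numeric(1),
               series = x, n_bins = n_bins)
  sel <- NA_integer_
  for (l in seq_len(max_lag - 1L)) {
    if (mi[l + 1L] < mi[l] - min_dip && mi[l + 1L] < mi[l + 2L] - min_dip) {
      sel <- l
      break
    }
  }
  structure(list(lags = 1:max_lag, mi_bits = mi[-1L], selected = sel),
            class = "mi_profile")
}

#' Fraction of false nearest neighbours at a given embedding dimension
#'
#' For each delay vector of the m-dimensional embedding, finds its Euclidean
#' nearest neighbour among vectors whose time indices differ by more than
#' `theiler` samples, extends both points to dimension m + 1, and declares the
#' pair false when the relative distance growth
#' `(d_{m+1} - d_m) / d_m` reaches `r_threshold`.  Pairs with a zero-distance
#' nearest neighbour are excluded from both counts.  Only points whose
#' (m+1)-dimensional extension exists are considered, so the m- and
#' (m+1)-dimensional point sets are aligned.
#'
#' @param series Numeric vector.
#' @param m Embedding dimension tested.
#' @param tau Delay in samples.
#' @param r_threshold Distance-growth threshold (default 15; the conventional
#'   range is 10--50).
#' @param theiler Temporal exclusion window for neighbour search (default
#'   `tau`).
#' @return Fraction in \[0, 1\] of false pairs among evaluated pairs.
#' @export
fnn_fraction <- function(series, m, tau, r_threshold = 15, theiler = tau) {
  x <- as.numeric(series)
  m <- as.integer(m); tau <- as.integer(tau)
  stopifnot(m >= 1L, tau >= 1L, theiler >= 0L, r_threshold > 0)
  N <- length(x)
  M <- N - m * tau               # points with an (m+1)-dim extension
  if (M < 2L)
    stop("series too short for FNN at this dimension", call. = FALSE)
  E <- vapply(0:(m - 1L), function(j) x[(1:M) + j * tau], numeric(M))
  E <- matrix(E, nrow = M)
  ext <- x[(1:M) + m * tau]
  d2 <- cross_dist2(E, E)
  # Theiler exclusion: ban temporally close neighbours (and self)
  for (i in seq_len(M)) {
    lo <- max(1L, i - theiler)
    hi <- min(M, i + theiler)
    d2[i, lo:hi] <- Inf
  }
  nn <- max.col(-d2, ties.method = "first")
  dm <- sqrt(d2[cbind(seq_len(M), nn)])
  ok <- is.finite(dm) & dm > 0
  if (!any(ok)) return(0)
  growth <- abs(ext - ext[nn])[ok] / dm[ok]
  # (d_{m+1} - d_m)/d_m with d_{m+1}^2 = d_m^2 + growth^2 * d_m^2
  ratio <- sqrt(1 + growth^2) - 1
  mean(ratio >= r_threshold)
}

#' Select the embedding dimension by false nearest neighbours
#'
#' Evaluates [fnn_fraction()] for m = 1..`m_max` and selects the smallest m
#' whose FNN fraction falls below `frac_threshold`; failing that, the smallest
#' m at which the fraction stops changing (absolute change to m + 1 below
#' `plateau_abs`); failing both, `m_max` with a warning.
#'
#' @param series Numeric vector.
#' @param tau Delay in samples.
#' @param m_max Largest dimension scanned (at least 2).
#' @param r_threshold Distance-growth threshold passed to [fnn_fraction()].
#' @param frac_threshold Fraction below which m is accepted (default 0.05).
#' @param plateau_abs Absolute flatness tolerance (default 0.01).
#' @param theiler Temporal exclusion window (default `tau`).
#' @return A list of class `fnn_profile`: `dims`, `fractions`, `selected`,
#'   `warning_flag`.
#' @export
select_embedding_dim <- function(series, tau, m_max = 10L, r_threshold = 15,
                                 frac_threshold = 0.05, plateau_abs = 0.01,
                                 theiler = tau) {
  m_max <- as.integer(m_max)
  stopifnot(m_max >= 2L)
  fr <- vapply(1:m_max, function(m)
    fnn_fraction(series, m, tau, r_threshold, theiler), numeric(1))
  sel <- which(fr < frac_threshold)
  warn <- FALSE
  if (length(sel)) {
    sel <- sel[1L]
  } else {
    flat <- which(abs(diff(fr)) < plateau_abs)
    if (length(flat)) {
      sel <- flat[1L]
    } else {
      sel <- m_max
      warn <- TRUE
      warning("FNN fraction neither small nor flat up to m_max", call. = FALSE)
    }
  }
  structure(list(dims = 1:m_max, fractions = fr, selected = as.integer(sel),
                 warning_flag = warn),
            class = "fnn_profile")
}
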