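#' Construct an evenly sampled scalar signal
#'
#' Container for a single-channel, evenly sampled time series (typically an
#' ECG trace in millivolts).  Most functions in the package accept either an
#' `ecg_signal` or a bare numeric vector.
#'
#' @param samples Numeric vector of amplitudes (mV for ECG data).  All values
#'   must be finite.  A signal of length 1 is rejected; length 0 is permitted
#'   only as the degenerate result of reading an empty window.
#' @param fs Sampling rate in samples/second (optional metadata; must be
#'   positive when given).
#' @param name Text label carried through outputs.
#' @return An object of class `ecg_signal`: a list with elements `samples`,
#'   `fs` and `name`.
#' @examples
#' s <- ecg_signal(sin(2 * pi * 0.01 * 0:499), fs = 250, name = "demo")
#' print(s)
#' @export
ecg_signal <- function(samples, fs = NULL, name = "signal") {
  samples <- as.numeric(samples)
  if (length(samples) == 1L)
    stop("signal must contain at least 2 samples", call. = FALSE)
  if (any(!is.finite(samples)))
    stop("signal contains non-finite samples", call. = FALSE)
  if (!is.null(fs)) {
    fs <- as.numeric(fs)
    if (length(fs) != 1L || !is.finite(fs) || fs <= 0)
      stop("fs must be a single positive number", call. = FALSE)
  }
  structure(list(samples = samples, fs = fs, name = as.character(name)[1L]),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> '%s': %d samples%s\n", x$name, length(x$samples),
              if (!is.null(x$fs)) sprintf(" @ %g Hz (%.2f s)", x$fs,
                                          length(x$samples) / x$fs) else ""))
  if (length(x$samples))
    cat(sprintf("  range [%.4g, %.4g] mV\n",
                min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.ecg_signal <- function(x) length(x$samples)

#' @export
as.numeric.ecg_signal <- function(x, ...) x$samples

# Coerce numeric vector or ecg_signal to a plain sample vector.
signal_samples <- function(x) {
  if (inherits(x, "ecg_signal")) return(x$samples)
  x <- as.numeric(x)
  if (any(!is.finite(x)))
    stop("signal contains non-finite samples", call. = FALSE)
  x
}
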