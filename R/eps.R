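#' Amplitude envelope via the analytic signal
#'
#' Returns the magnitude of the FFT-based analytic signal (the Hilbert
#' construction): the spectrum of the input is one-sided doubled, negative
#' frequencies zeroed, and the inverse transform's modulus taken. For a pure
#' tone sampled well inside the band this is (away from the edges) the
#' tone's amplitude; for an amplitude-modulated carrier it recovers the
#' modulator.
#'
#' @param signal finite numeric vector, length >= 2.
#' @return non-negative numeric vector, same length as the input.
#' @export
#' @examples
#' t <- seq(0, 1, length.out = 128)
#' e <- envelope(2 * cos(2 * pi * 10 * t))
#' range(e[20:100])  # close to 2
envelope <- function(signal) {
  check_signal(signal, min_len = 2)
  n <- length(signal)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  analytic <- fft(fft(signal) * h, inverse = TRUE) / n
  Mod(analytic)
}

#' Two-sided periodogram
#'
#' The raw power-spectral estimate I_N at all N DFT bins:
#' `Mod(fft(y))^2 / N`. Under this 1/N scaling the periodogram conserves
#' energy: the sum over all bins equals `sum(y^2)` (Parseval).
#'
#' @param signal finite numeric vector, length >= 1.
#' @return numeric vector of length `length(signal)`, all values >= 0.
#' @export
periodogram <- function(signal) {
  check_signal(signal, min_len = 1)
  Mod(fft(signal))^2 / length(signal)
}

#' Biased sample autocorrelation at one lag
#'
#' `R(lag) = (1/N) * sum_k y[lag + k] * y[k]` over valid k for
#' `|lag| <= N - 1`, and exactly 0 for `|lag| >= N`. The estimator is
#' biased (always divides by N) and symmetric in the sign of the lag for
#' real input. Together with [periodogram()] it forms a discrete
#' Fourier-transform pair (the Wiener-Khinchin relation).
#'
#' @param signal finite numeric vector.
#' @param lag integer lag (any sign).
#' @return a single number.
#' @export
sample_autocorrelation <- function(signal, lag) {
  check_signal(signal, min_len = 1)
  n <- length(signal)
  lag <- abs(as.integer(lag))
  if (lag >= n) return(0)
  sum(signal[(1 + lag):n] * signal[1:(n - lag)]) / n
}

#' Enveloped-power-spectrum feature vector of one window
#'
#' The feature-extraction pipeline: flatten the selected channels into one
#' sequence, take the amplitude envelope (optional), zero-pad by one sample
#' if the length is odd, compute the periodogram, and keep the one-sided
#' half (bins 0 .. n_padded/2). A 768-sample flattened window (six
#' 128-sample channels) yields 385 spectral values; a 303-sample one
#' (three 101-sample channels) is padded to 304 and yields 153.
#'
#' @param window channels-by-samples matrix, a numeric vector (treated as a
#'   single pre-flattened channel), or a [har_dataset()] window matrix from
#'   [get_window()].
#' @param channel_order 1-based channel indices for [flatten_window()].
#' @param sample_rate sampling rate in Hz, used only to label bin
#'   frequencies.
#' @param use_envelope if `FALSE`, skip the envelope stage and take the
#'   periodogram of the raw flattened signal (sensitivity-check switch).
#' @return an object of class `eps_spectrum`: a list with `power`
#'   (one-sided periodogram, length n_padded/2 + 1), `freqs` (Hz),
#'   `n_original`, and `n_padded`.
#' @export
#' @examples
#' sp <- eps_features(matrix(rnorm(768), nrow = 6))
#' length(sp$power)  # 385
eps_features <- function(window, channel_order = NULL, sample_rate = 50,
                         use_envelope = TRUE) {
  if (is.matrix(window)) {
    ord <- channel_order %||% seq_len(nrow(window))
    y <- flatten_window(window, ord)
  } else {
    y <- as.numeric(window)
  }
  check_signal(y, min_len = 2)
  n0 <- length(y)
  if (use_envelope) y <- envelope(y)
  if (length(y) %% 2 == 1) y <- c(y, 0)
  np <- length(y)
  p <- periodogram(y)
  half <- p[1:(np / 2 + 1)]
  structure(
    list(power = half,
         freqs = seq(0, np / 2) * sample_rate / np,
         n_original = n0,
         n_padded = np),
    class = "eps_spectrum"
  )
}

#' @export
print.eps_spectrum <- function(x, ...) {
  cat(sprintf("<eps_spectrum: %d one-sided bins (0-%g Hz), from %d samples (padded %d)>\n",
              length(x$power), max(x$freqs), x$n_original, x$n_padded))
  invisible(x)
}

#' Extract EPS features for every window of a dataset
#'
#' Applies [eps_features()] to each window and returns the feature matrix
#' as a tibble: one row per window, columns `f0 ... f{d-1}` plus `label`.
#'
#' @param dataset a [har_dataset()].
#' @param channel_order 1-based channel indices for [flatten_window()].
#' @param use_envelope passed to [eps_features()].
#' @return a tibble with `n_windows` rows.
#' @export
eps_transform <- function(dataset, channel_order = NULL, use_envelope = TRUE) {
  flat <- flatten_windows(dataset, channel_order)
  sr <- attr(dataset, "sample_rate") %||% 50
  feats <- t(apply(flat, 1, function(y) {
    eps_features(y, sample_rate = sr, use_envelope = use_envelope)$power
  }))
  colnames(feats) <- paste0("f", seq_len(ncol(feats)) - 1)
  out <- as_tibble(feats)
  out$label <- window_labels(dataset)
  out
}

check_signal <- function(signal, min_len = 1) {
  if (!is.numeric(signal) || length(signal) < min_len) {
    abort(paste0("signal must be numeric with length >= ", min_len))
  }
  if (!all(is.finite(signal))) abort("signal contains non-finite values")
  invisible(signal)
}
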