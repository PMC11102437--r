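#' Power spectral density of a trial (single Hamming window)
#'
#' Per channel, the trial is multiplied by a Hamming window of the trial
#' length, zero-padded to `nfft` points and Fourier transformed; the
#' one-sided periodogram on the `nfft/2 + 1`-point grid spanning
#' `[0, 1/(2 dt)]` is returned. With the default `nfft = 512` a 500-sample
#' trial yields a 257-bin spectrum. This single-window estimator (no Welch
#' averaging) matches how the comparison power features are defined for
#' 500-ms trials; signals longer than `nfft` are rejected.
#'
#' The periodogram is scaled by `1 / (fs * sum(w^2))` with the non-DC,
#' non-Nyquist bins doubled, so that the PSD integrates to approximately
#' the signal variance.
#'
#' @param signal A [trial_signal()] with `L <= nfft`.
#' @param nfft FFT length (default 512).
#' @return An object of class `power_feature`: `psd` (`P x F` nonnegative
#'   matrix), `frequencies` (Hz), `dt`, `channel_ids`.
#' @export
psd_features <- function(signal, nfft = 512) {
  stopifnot(inherits(signal, "trial_signal"))
  L <- n_samples(signal)
  if (L > nfft) {
    stop(sprintf(
      "trial has %d samples but the single-window PSD allows at most nfft = %d",
      L, nfft
    ), call. = FALSE)
  }
  fs <- 1 / signal$dt
  w <- signal::hamming(L)
  padded <- cbind(
    sweep(signal$values, 2L, w, "*"),
    matrix(0, n_channels(signal), nfft - L)
  )
  spec <- t(apply(padded, 1L, stats::fft))
  if (n_channels(signal) == 1L) spec <- matrix(spec, 1L)
  nb <- nfft %/% 2 + 1L
  p <- Mod(spec[, seq_len(nb), drop = FALSE])^2 / (fs * sum(w^2))
  if (nb > 2L) p[, 2:(nb - 1L)] <- 2 * p[, 2:(nb - 1L)]
  freqs <- (seq_len(nb) - 1L) * fs / nfft
  structure(
    list(
      psd = p, frequencies = freqs, dt = signal$dt,
      channel_ids = signal$channel_ids
    ),
    class = "power_feature"
  )
}

#' @export
print.power_feature <- function(x, ...) {
  cat(sprintf(
    "<power_feature> %d channels x %d frequency bins [0, %g] Hz\n",
    nrow(x$psd), ncol(x$psd), max(x$frequencies)
  ))
  invisible(x)
}

#' Band-averaged power per channel
#'
#' Averages the PSD bins whose frequency lies in `[low, high)` — e.g.
#' `c(80, 150)` for the high-gamma band conventionally used in movement
#' decoding.
#'
#' @param psd A [psd_features()] result.
#' @param band Numeric `c(low, high)` in Hz within `[0, Nyquist]`.
#' @return A named numeric vector of length `P`.
#' @export
band_power <- function(psd, band = c(80, 150)) {
  stopifnot(inherits(psd, "power_feature"), length(band) == 2L)
  if (band[1] < 0 || band[2] <= band[1] || band[1] > max(psd$frequencies)) {
    stop("`band` must satisfy 0 <= low < high within the frequency grid",
      call. = FALSE
    )
  }
  keep <- psd$frequencies >= band[1] & psd$frequencies < band[2]
  if (!any(keep)) stop("no PSD bins fall inside `band`", call. = FALSE)
  stats::setNames(rowMeans(psd$psd[, keep, drop = FALSE]), psd$channel_ids)
}

#' Trial-by-channel table of band power features
#'
#' The conventional spectral-power baseline: one row per trial, one column
#' per channel, holding the PSD averaged over `band`.
#'
#' @param x A `trial_set` or list of [trial_signal()]s.
#' @param band Numeric `c(low, high)` in Hz (default high-gamma, 80-150).
#' @param nfft FFT length passed to [psd_features()].
#' @return A tibble `N x P`.
#' @export
power_feature_table <- function(x, band = c(80, 150), nfft = 512) {
  if (inherits(x, "trial_set")) x <- x$trials
  rows <- lapply(x, function(s) band_power(psd_features(s, nfft), band))
  tibble::as_tibble(do.call(rbind, rows))
}
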