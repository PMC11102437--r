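#' Construct a single-trial multichannel signal
#'
#' A `trial_signal` holds one trial's recording as a real matrix with
#' channels in rows and samples in columns, together with the sampling
#' interval. It is the unit every downstream operation (stacking, dynamic
#' mode decomposition, spectral features) consumes.
#'
#' @param values Numeric matrix, `P` channels x `L` samples (finite values).
#' @param dt Sampling interval in seconds (e.g. `0.001` for 1 kHz).
#' @param channel_ids Optional character vector of channel identifiers;
#'   defaults to `"ch1" ... "chP"`.
#'
#' @return An object of class `trial_signal` with fields `values`, `dt`,
#'   and `channel_ids`.
#' @examples
#' x <- trial_signal(matrix(rnorm(4 * 100), 4, 100), dt = 0.001)
#' n_channels(x)
#' @export
trial_signal <- function(values, dt, channel_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (channels x samples)", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 3L) {
    stop("need at least 1 channel and 3 samples", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number (seconds)", call. = FALSE)
  }
  if (is.null(channel_ids)) {
    channel_ids <- paste0("ch", seq_len(nrow(values)))
  }
  if (length(channel_ids) != nrow(values)) {
    stop("`channel_ids` must have one entry per channel", call. = FALSE)
  }
  structure(
    list(values = unname(values), dt = dt, channel_ids = as.character(channel_ids)),
    class = "trial_signal"
  )
}

#' @export
print.trial_signal <- function(x, ...) {
  cat(sprintf(
    "<trial_signal> %d channels x %d samples @ %g Hz (%.3f s)\n",
    n_channels(x), n_samples(x), 1 / x$dt, n_samples(x) * x$dt
  ))
  invisible(x)
}

#' Number of channels / samples of a trial signal
#' @param x A [trial_signal()].
#' @return An integer scalar.
#' @export
n_channels <- function(x) nrow(x$values)

#' @rdname n_channels
#' @export
n_samples <- function(x) ncol(x$values)

#' Nyquist frequency of a trial signal
#' @param x A [trial_signal()].
#' @return Frequency in Hz, `1 / (2 * dt)`.
#' @export
nyquist <- function(x) 1 / (2 * x$dt)

#' Common average reference
#'
#' Re-references a multichannel trial by subtracting, at every time sample,
#' the mean across channels from each channel. This is the standard CAR
#' preprocessing step for ECoG arrays; after the call every column (time
#' sample) sums to zero.
#'
#' @param signal A [trial_signal()] with at least 2 channels.
#' @return A re-referenced [trial_signal()].
#' @export
common_average_reference <- function(signal) {
  stopifnot(inherits(signal, "trial_signal"))
  if (n_channels(signal) < 2L) {
    stop("common average reference needs at least 2 channels", call. = FALSE)
  }
  v <- signal$values
  signal$values <- sweep(v, 2L, colMeans(v), "-")
  signal
}

#' Crop a trial to a time window
#'
#' Retains the samples with `t0 <= t < t1`, where sample `i` (1-based) sits
#' at time `(i - 1) * dt` relative to trial onset. The window is half-open,
#' so cropping a 1 kHz trial to `[0, 0.5)` keeps exactly 500 samples.
#'
#' @param signal A [trial_signal()].
#' @param t0,t1 Window start and end in seconds, `0 <= t0 < t1 <= L * dt`.
#' @return The cropped [trial_signal()].
#' @export
crop_signal <- function(signal, t0, t1) {
  stopifnot(inherits(signal, "trial_signal"))
  L <- n_samples(signal)
  dur <- L * signal$dt
  if (!(t0 >= 0 && t1 > t0 && t1 <= dur + 1e-12)) {
    stop("need 0 <= t0 < t1 <= L * dt", call. = FALSE)
  }
  times <- (seq_len(L) - 1L) * signal$dt
  keep <- times >= t0 - 1e-12 & times < t1 - 1e-12
  if (!any(keep)) stop("empty crop window", call. = FALSE)
  signal$values <- signal$values[, keep, drop = FALSE]
  signal
}
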