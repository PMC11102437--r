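sech <- function(z) 1 / cosh(z)

#' The two-component worked-example signal
#'
#' Generates the canonical demonstration signal: the sum of a 13 Hz sine
#' with amplitude decaying as `0.25^t` and spatial profile `sech(p + 3)`,
#' and an 8 Hz sine growing as `2^t` with profile `sech(p - 3)`, observed
#' on 81 positions `p = -10, -9.75, ..., 10` sampled at 1 kHz for 0.5 s.
#' Hankel-stacked exact DMD at rank 4 recovers both components exactly:
#' conjugate eigenvalue pairs at |f| = 13 Hz (per-second rate 0.25) and
#' |f| = 8 Hz (rate 2).
#'
#' @return A [trial_signal()] with 81 channels x 500 samples, `dt` 0.001 s.
#' @examples
#' d <- exact_dmd(make_two_component_signal(), rank = 4)
#' glance(d)
#' @export
make_two_component_signal <- function() {
  p <- seq(-10, 10, by = 0.25)
  t <- (0:499) / 1000
  v <- outer(p, t, function(pp, tt) {
    sech(pp + 3) * 0.25^tt * sin(2 * pi * 13 * tt) +
      sech(pp - 3) * 2^tt * sin(2 * pi * 8 * tt)
  })
  trial_signal(v, dt = 0.001, channel_ids = sprintf("p%+0.2f", p))
}

#' Specify one spatially weighted oscillator
#'
#' @param frequency Oscillation frequency in Hz (must stay below Nyquist
#'   when the signal is generated).
#' @param growth Per-second amplitude multiplier `r` (`0.25` decays to a
#'   quarter per second, `1` is stationary, `2` doubles); must be positive.
#' @param weights Spatial amplitude profile: either a numeric vector with
#'   one weight per channel or a function of channel position.
#' @param phase Initial phase in radians.
#' @return An `oscillator_spec` list.
#' @export
oscillator_spec <- function(frequency, growth = 1, weights = 1, phase = 0) {
  stopifnot(frequency >= 0, growth > 0)
  structure(
    list(
      frequency = frequency, growth = growth,
      weights = weights, phase = phase
    ),
    class = "oscillator_spec"
  )
}

resolve_weights <- function(w, positions) {
  if (is.function(w)) {
    return(w(positions))
  }
  if (length(w) == 1L) {
    return(rep(w, length(positions)))
  }
  if (length(w) != length(positions)) {
    stop("oscillator weights must match the channel count", call. = FALSE)
  }
  w
}

#' Generate a damped/growing sinusoid mixture with known ground truth
#'
#' Sums spatially weighted oscillators `w_p * r^t * sin(2 pi f t + phase)`
#' over channels and adds white Gaussian noise. The generating `(f, r)`
#' pairs are attached as attribute `"oscillators"` so parameter-recovery
#' tests can compare them with the DMD estimates.
#'
#' @param oscillators List of [oscillator_spec()]s (possibly empty).
#' @param n_channels,n_samples,dt Geometry of the trial.
#' @param noise_sd Standard deviation of the additive white noise, in
#'   signal units.
#' @param seed Optional seed; a fixed seed makes the output bit-identical.
#' @param positions Channel positions for weight functions; defaults to an
#'   even grid on `[-10, 10]`.
#' @return A [trial_signal()] with attribute `oscillators` (a tibble of
#'   `frequency`, `growth`).
#' @export
make_oscillator_signal <- function(oscillators, n_channels, n_samples,
                                   dt = 0.001, noise_sd = 0, seed = NULL,
                                   positions = NULL) {
  stopifnot(n_channels >= 1, n_samples >= 3, dt > 0, noise_sd >= 0)
  if (is.null(positions)) positions <- seq(-10, 10, length.out = n_channels)
  nyq <- 1 / (2 * dt)
  t <- (seq_len(n_samples) - 1L) * dt
  v <- matrix(0, n_channels, n_samples)
  for (osc in oscillators) {
    stopifnot(inherits(osc, "oscillator_spec"))
    if (osc$frequency >= nyq) {
      stop(sprintf(
        "oscillator frequency %g Hz is at or above Nyquist (%g Hz)",
        osc$frequency, nyq
      ), call. = FALSE)
    }
    w <- resolve_weights(osc$weights, positions)
    v <- v + outer(w, osc$growth^t * sin(2 * pi * osc$frequency * t + osc$phase))
  }
  gen <- function() {
    if (noise_sd > 0) {
      v <- v + matrix(stats::rnorm(length(v), sd = noise_sd), nrow(v))
    }
    v
  }
  v <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  out <- trial_signal(v, dt = dt)
  attr(out, "oscillators") <- tibble::tibble(
    frequency = vapply(oscillators, `[[`, numeric(1), "frequency"),
    growth = vapply(oscillators, `[[`, numeric(1), "growth")
  )
  out
}

#' Bundle trials with labels or targets
#'
#' @param trials List of [trial_signal()]s with consistent `P`, `L`, `dt`.
#' @param labels Factor of class labels (classification), or `NULL`.
#' @param targets Numeric `N x D` matrix of continuous targets
#'   (regression), or `NULL`.
#' @param metadata Named list (task name, class descriptions, generator
#'   parameters, ...).
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(trials, labels = NULL, targets = NULL, metadata = list()) {
  stopifnot(is.list(trials), length(trials) >= 1)
  ok <- vapply(trials, inherits, logical(1), "trial_signal")
  if (!all(ok)) stop("all trials must be trial_signal objects", call. = FALSE)
  P <- vapply(trials, n_channels, integer(1))
  L <- vapply(trials, n_samples, integer(1))
  dts <- vapply(trials, function(s) s$dt, numeric(1))
  if (length(unique(P)) != 1L || length(unique(L)) != 1L ||
    length(unique(dts)) != 1L) {
    stop("trials must share P, L and dt", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.factor(labels)
    if (length(labels) != length(trials)) {
      stop("`labels` must have one entry per trial", call. = FALSE)
    }
  }
  if (!is.null(targets)) {
    targets <- as.matrix(targets)
    if (nrow(targets) != length(trials)) {
      stop("`targets` must have one row per trial", call. = FALSE)
    }
  }
  structure(
    list(
      trials = trials, labels = labels, targets = targets,
      metadata = metadata
    ),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf(
    "<trial_set> %d trials, %d channels x %d samples @ %g Hz\n",
    length(x$trials), n_channels(x$trials[[1]]),
    n_samples(x$trials[[1]]), 1 / x$trials[[1]]$dt
  ))
  if (!is.null(x$labels)) print(table(x$labels))
  if (!is.null(x$targets)) {
    cat(sprintf("targets: %d dimension(s)\n", ncol(x$targets))
    )
  }
  invisible(x)
}

#' @export
length.trial_set <- function(x) length(x$trials)

default_class_oscillators <- function(n_classes, positions) {
  centers <- seq(-6, 6, length.out = n_classes)
  lapply(seq_len(n_classes), function(c) {
    list(
      # shared low-frequency background, broad spatial footprint
      oscillator_spec(10, 1, function(p) 0.8 * sech(p / 4)),
      # class-specific high-frequency component on a distinct channel subset
      oscillator_spec(100, 1, local({
        ctr <- centers[c]
        function(p) sech(1.2 * (p - ctr))
      }))
    )
  })
}

#' Generate an ECoG-like multi-class trial set
#'
#' Emulates the structure the sDM method targets: every class shares a
#' low-frequency background oscillation, while a high-frequency (100 Hz)
#' component rides on a class-specific subset of channels (sech-shaped
#' spatial profiles centred at distinct positions). Each trial draws
#' independent uniform phases for every oscillator and white Gaussian
#' noise, so trials of one class share spatial structure but not phase.
#'
#' Defaults — 3 classes x 40 trials, 16 channels, 500 samples at 1 kHz,
#' noise sd 0.2 against unit-amplitude oscillators — give a compact set
#' with class-dependent spatial patterns on oscillatory dynamics plus
#' broadband residual noise.
#'
#' @param n_classes,trials_per_class Class structure. `trials_per_class`
#'   may be a vector (one count per class) for imbalanced designs.
#' @param n_channels,n_samples,dt Trial geometry.
#' @param noise_sd White-noise standard deviation (signal units).
#' @param class_oscillators Optional list (length `n_classes`) of lists of
#'   [oscillator_spec()]s; phases given there are offset by the per-trial
#'   random phase. Supplying identical entries for every class yields a
#'   null set with no class signal.
#' @param seed Seed for reproducibility (default 1).
#' @return A `trial_set` with factor labels `class1 ... classk`.
#' @export
make_trial_set <- function(n_classes = 3, trials_per_class = 40,
                           n_channels = 16, n_samples = 500, dt = 0.001,
                           noise_sd = 0.2, class_oscillators = NULL,
                           seed = 1) {
  stopifnot(n_classes >= 1, all(trials_per_class >= 1))
  counts <- if (length(trials_per_class) == 1L) {
    rep(trials_per_class, n_classes)
  } else {
    stopifnot(length(trials_per_class) == n_classes)
    trials_per_class
  }
  positions <- seq(-10, 10, length.out = n_channels)
  if (is.null(class_oscillators)) {
    class_oscillators <- default_class_oscillators(n_classes, positions)
  }
  stopifnot(length(class_oscillators) == n_classes)
  withr::with_seed(seed, {
    trials <- list()
    labels <- character(0)
    for (c in seq_len(n_classes)) {
      for (i in seq_len(counts[c])) {
        oscs <- lapply(class_oscillators[[c]], function(o) {
          o$phase <- o$phase + stats::runif(1, 0, 2 * pi)
          o
        })
        trials[[length(trials) + 1L]] <- make_oscillator_signal(
          oscs, n_channels, n_samples,
          dt = dt, noise_sd = noise_sd,
          positions = positions
        )
        labels <- c(labels, paste0("class", c))
      }
    }
    trial_set(trials,
      labels = factor(labels),
      metadata = list(
        generator = "make_trial_set", n_classes = n_classes,
        trials_per_class = counts, noise_sd = noise_sd, seed = seed
      )
    )
  })
}

#' Phase-randomized surrogate of a trial
#'
#' Per channel, randomizes the Fourier phases while keeping the amplitude
#' spectrum (conjugate-symmetric construction; DC and Nyquist bins stay
#' real), so each channel's periodogram is preserved exactly while any
#' coherent spatiotemporal structure is destroyed. This is the classic
#' control for dynamics-based features: low-rank DMD reconstructions that
#' are near-exact on the original fail badly on the surrogate.
#'
#' @param signal A [trial_signal()].
#' @param seed Optional seed for the random phases.
#' @return A [trial_signal()] with the same per-channel power spectra.
#' @export
phase_shuffle <- function(signal, seed = NULL) {
  stopifnot(inherits(signal, "trial_signal"))
  shuffle <- function() {
    v <- signal$values
    L <- ncol(v)
    half <- (L - 1L) %/% 2L # bins 2..half+1 get free phases
    out <- v
    for (ch in seq_len(nrow(v))) {
      sp <- stats::fft(v[ch, ])
      if (half >= 1L) {
        th <- stats::runif(half, 0, 2 * pi)
        k <- 2:(half + 1L)
        sp[k] <- Mod(sp[k]) * exp(1i * th)
        sp[L - k + 2L] <- Conj(sp[k])
      }
      out[ch, ] <- Re(stats::fft(sp, inverse = TRUE)) / L
    }
    out
  }
  v <- if (is.null(seed)) shuffle() else withr::with_seed(seed, shuffle())
  trial_signal(v, dt = signal$dt, channel_ids = signal$channel_ids)
}
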