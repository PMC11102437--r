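#' Hankel stacking factor
#'
#' Exact dynamic mode decomposition assumes a tall data matrix (more state
#' dimensions than snapshots). Neural recordings usually have far more
#' samples than channels, so the signal is delay-embedded by stacking `h`
#' time-shifted copies. `compute_h` returns the smallest integer satisfying
#' `h >= (L + 1) / (P + 1)`, i.e. the minimal embedding that makes the
#' stacked matrix at least as tall as it is wide, and never less than 1.
#'
#' @param p Number of channels (`P >= 1`).
#' @param l Number of samples (`L >= 3`).
#' @return A positive integer stacking factor.
#' @examples
#' compute_h(81, 500) # 7
#' @export
compute_h <- function(p, l) {
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p != round(p)) {
    stop("`p` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(l) || length(l) != 1L || l < 3 || l != round(l)) {
    stop("`l` must be an integer >= 3", call. = FALSE)
  }
  max(1L, as.integer(ceiling((l + 1) / (p + 1))))
}

#' Build the Hankel-stacked snapshot matrices
#'
#' Stacks `h` time-shifted copies of the trial, producing the pair of
#' `hP x (L - h)` matrices `X` (snapshots) and `X'` (snapshots advanced by
#' one step). Row-block `s` of `X` holds samples `s ... s + L - h - 1`, so
#' each column of `X` is the delay-embedded state at one time index.
#'
#' @param signal A [trial_signal()].
#' @param h Positive integer stacking factor with `h < L`; defaults to
#'   [compute_h()] on the trial's dimensions.
#' @return A list with elements `x`, `x_prime` (both `hP x (L - h)`), and `h`.
#' @export
stack_signals <- function(signal, h = NULL) {
  stopifnot(inherits(signal, "trial_signal"))
  P <- n_channels(signal)
  L <- n_samples(signal)
  if (is.null(h)) h <- compute_h(P, L)
  if (!is.numeric(h) || length(h) != 1L || h < 1 || h != round(h)) {
    stop("`h` must be a positive integer", call. = FALSE)
  }
  h <- as.integer(h)
  if (h >= L) stop("stacking factor `h` must be smaller than L", call. = FALSE)
  v <- signal$values
  nc <- L - h
  x <- matrix(0, h * P, nc)
  xp <- matrix(0, h * P, nc)
  for (s in seq_len(h)) {
    rows <- ((s - 1L) * P + 1L):(s * P)
    x[rows, ] <- v[, s:(s + nc - 1L), drop = FALSE]
    xp[rows, ] <- v[, (s + 1L):(s + nc), drop = FALSE]
  }
  list(x = x, x_prime = xp, h = h)
}

#' Rank-truncated singular value decomposition
#'
#' Thin SVD keeping at most `rank` components and additionally discarding
#' components whose singular value falls below a relative floor
#' `max(dim(x)) * .Machine$double.eps * s_1` (these would blow up when the
#' singular values are inverted to form the reduced operator).
#'
#' @param x Real matrix.
#' @param rank Maximum number of components to keep; defaults to
#'   `min(dim(x))`.
#' @param floor_factor Multiplier on the machine-epsilon relative floor.
#' @return List with `u`, `d`, `v` (truncated to the effective rank),
#'   `rank` (effective) and `n_above_floor`.
#' @export
truncated_svd <- function(x, rank = NULL, floor_factor = 1) {
  if (!is.matrix(x) || !all(is.finite(x))) {
    stop("`x` must be a finite matrix", call. = FALSE)
  }
  kmax <- min(dim(x))
  if (is.null(rank)) rank <- kmax
  if (rank < 1 || rank > kmax) {
    stop(sprintf("`rank` must be in [1, %d]", kmax), call. = FALSE)
  }
  sv <- svd(x)
  floor <- floor_factor * max(dim(x)) * .Machine$double.eps * sv$d[1]
  n_ok <- sum(sv$d > floor)
  if (n_ok == 0L) {
    stop("matrix is numerically zero: no singular value above the floor",
      call. = FALSE
    )
  }
  k <- min(as.integer(rank), n_ok)
  list(
    u = sv$u[, seq_len(k), drop = FALSE],
    d = sv$d[seq_len(k)],
    v = sv$v[, seq_len(k), drop = FALSE],
    rank = k,
    n_above_floor = n_ok,
    n_components = length(sv$d),
    d_full = sv$d
  )
}

#' Exact dynamic mode decomposition of a trial
#'
#' Estimates the spectral decomposition of the best-fit linear propagator
#' `x(t + dt) = A x(t)` on the Hankel-stacked trial. The stacked snapshot
#' matrix is factored as `X = U S V*`, the operator is projected to the
#' `K`-dimensional subspace (`A_tilde = U* X' V S^-1`), and its
#' eigendecomposition `A_tilde W = W Lambda` yields the dynamic modes
#' `Phi = X' V S^-1 W`. Each eigenvalue `lambda_k` encodes an oscillation
#' frequency `f_k = Arg(lambda_k) / (2 pi dt)` (Hz) and a per-second
#' amplitude multiplier `r_k = |lambda_k|^(1/dt)`. Of the `hP`-dimensional
#' stacked modes, the first `P` coordinates (the first delay block) are
#' exposed as the spatial modes used for feature extraction.
#'
#' Mode amplitudes `b` solve the least-squares initial condition on the
#' stacked state, `b = Phi_stacked^+ x_stacked(0)`. Modes are returned in a
#' canonical deterministic order: ascending `|f_k|`, ties broken by the
#' sign of `f_k` (positive first) then by descending `|b_k|`.
#'
#' @param signal A [trial_signal()].
#' @param rank Number of SVD components `K` to retain (the tunable rank
#'   hyperparameter); defaults to the full numerical rank.
#' @param h Stacking factor; defaults to [compute_h()].
#' @return An object of class `dmd` with fields `modes` (`P x K` complex),
#'   `stacked_modes` (`hP x K`), `eigenvalues`, `frequencies` (Hz),
#'   `rates` (per-second multipliers), `continuous_rates` (`ln(lambda)/dt`),
#'   `amplitudes`, `singular_values` (all values above the floor),
#'   `n_svd_components`, `rank`, `h`, `dt`, `channel_ids`, `initial_state`.
#' @examples
#' s <- make_two_component_signal()
#' d <- exact_dmd(s, rank = 4)
#' tidy(d)
#' @export
exact_dmd <- function(signal, rank = NULL, h = NULL) {
  stopifnot(inherits(signal, "trial_signal"))
  P <- n_channels(signal)
  stk <- stack_signals(signal, h)
  kmax <- min(dim(stk$x))
  if (!is.null(rank) && (rank < 1 || rank > kmax)) {
    stop(sprintf("`rank` must be in [1, %d] for this trial", kmax), call. = FALSE)
  }
  sv <- truncated_svd(stk$x, rank)
  a_tilde <- crossprod(sv$u, stk$x_prime) %*% sv$v %*% diag(1 / sv$d, sv$rank)
  eg <- eigen(a_tilde)
  lam <- as.complex(eg$values)
  phi_stacked <- stk$x_prime %*% sv$v %*% diag(1 / sv$d, sv$rank) %*% eg$vectors

  # dead modes (lambda ~ 0) have no continuous-time representation
  alive <- Mod(lam) > 1e-12 * max(Mod(lam))
  if (!all(alive)) {
    warning(sprintf("dropping %d dead mode(s) with |lambda| ~ 0", sum(!alive)))
    lam <- lam[alive]
    phi_stacked <- phi_stacked[, alive, drop = FALSE]
  }

  dt <- signal$dt
  freq <- Arg(lam) / (2 * pi * dt)
  b <- qr.solve(phi_stacked, stk$x[, 1])

  ord <- order(abs(freq), -sign(freq), -Mod(b))
  lam <- lam[ord]
  freq <- freq[ord]
  b <- b[ord]
  phi_stacked <- phi_stacked[, ord, drop = FALSE]

  structure(
    list(
      modes = phi_stacked[seq_len(P), , drop = FALSE],
      stacked_modes = phi_stacked,
      eigenvalues = lam,
      frequencies = freq,
      rates = Mod(lam)^(1 / dt),
      continuous_rates = log(lam) / dt,
      amplitudes = b,
      singular_values = sv$d_full[seq_len(sv$n_above_floor)],
      n_svd_components = min(dim(stk$x)),
      rank = length(lam),
      h = stk$h,
      dt = dt,
      channel_ids = signal$channel_ids,
      initial_state = stk$x[, 1],
      normalized = FALSE,
      mode_scales = NULL
    ),
    class = "dmd"
  )
}

#' @export
print.dmd <- function(x, ...) {
  cat(sprintf(
    "<dmd> rank %d on %d channels (h = %d, dt = %g s)%s\n",
    x$rank, nrow(x$modes), x$h, x$dt,
    if (isTRUE(x$normalized)) ", L2-normalized modes" else ""
  ))
  print(utils::head(tidy(x), 10))
  invisible(x)
}

#' L2-normalize the spatial dynamic modes
#'
#' Rescales every column of the `P`-row spatial mode matrix to unit
#' Euclidean norm (normalization is applied after truncation to the first
#' `P` coordinates). The per-mode scale factors are recorded in
#' `mode_scales` so the original modes remain recoverable; stacked modes
#' and amplitudes are untouched, so reconstruction still works. Zero-norm
#' modes are dropped with a warning and the rank decremented.
#'
#' @param result A `dmd` object from [exact_dmd()].
#' @return The `dmd` object with unit-norm `modes` and `normalized = TRUE`.
#' @export
normalize_modes <- function(result) {
  stopifnot(inherits(result, "dmd"))
  if (isTRUE(result$normalized)) {
    return(result)
  }
  nrm <- sqrt(colSums(Mod(result$modes)^2))
  keep <- nrm > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-norm mode(s)", sum(!keep)))
    for (f in c(
      "eigenvalues", "frequencies", "rates", "continuous_rates", "amplitudes"
    )) {
      result[[f]] <- result[[f]][keep]
    }
    result$modes <- result$modes[, keep, drop = FALSE]
    result$stacked_modes <- result$stacked_modes[, keep, drop = FALSE]
    result$rank <- sum(keep)
    nrm <- nrm[keep]
  }
  result$modes <- sweep(result$modes, 2L, nrm, "/")
  result$mode_scales <- nrm
  result$normalized <- TRUE
  result
}

#' Reconstruct a signal from its dynamic modes
#'
#' Evaluates the modal superposition
#' `x(t) ~ sum_k phi_k exp(omega_k t) b_k` on the stacked modes and
#' returns the first `P` coordinates, i.e. the reconstructed channel
#' signals at the requested times. For a noiseless signal whose numerical
#' rank is covered by `rank`, the reconstruction matches the original to
#' machine precision.
#'
#' @param result A `dmd` object.
#' @param times Numeric vector of times in seconds (trial onset is 0).
#' @param initial_state Optional `hP` stacked state from which to recompute
#'   the amplitudes; defaults to the amplitudes fitted at decomposition.
#' @return Real matrix `P x length(times)`.
#' @export
reconstruct <- function(result, times, initial_state = NULL) {
  stopifnot(inherits(result, "dmd"), is.numeric(times))
  b <- result$amplitudes
  if (!is.null(initial_state)) {
    if (length(initial_state) != nrow(result$stacked_modes)) {
      stop("`initial_state` must have hP entries", call. = FALSE)
    }
    b <- qr.solve(result$stacked_modes, initial_state)
  }
  growth <- outer(Re(result$continuous_rates), times)
  if (max(growth) > 700) {
    stop("requested times overflow the growing modes (|r|^t too large)",
      call. = FALSE
    )
  }
  P <- nrow(result$modes)
  dyn <- exp(outer(result$continuous_rates, times)) * b
  out <- result$stacked_modes[seq_len(P), , drop = FALSE] %*% dyn
  resid <- max(abs(Im(out)))
  scale <- max(abs(Re(out)), Mod(b), 1e-300)
  if (resid > 1e-6 * scale) {
    warning("reconstruction has a non-negligible imaginary part")
  }
  Re(out)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dynamic mode decomposition
#'
#' @param x A `dmd` object.
#' @param ... Unused.
#' @return A tibble with one row per mode: `mode`, `frequency` (Hz),
#'   `rate` (per-second amplitude multiplier), `amplitude` (`|b_k|`),
#'   `eigenvalue_re`, `eigenvalue_im`.
#' @export
tidy.dmd <- function(x, ...) {
  tibble::tibble(
    mode = seq_len(x$rank),
    frequency = x$frequencies,
    rate = x$rates,
    amplitude = Mod(x$amplitudes),
    eigenvalue_re = Re(x$eigenvalues),
    eigenvalue_im = Im(x$eigenvalues)
  )
}

#' One-row summary of a dynamic mode decomposition
#'
#' @param x A `dmd` object.
#' @param ... Unused.
#' @return A tibble with `rank`, `h`, `n_channels`, `n_nonzero_singular`,
#'   `n_svd_components`, `dt`.
#' @export
glance.dmd <- function(x, ...) {
  tibble::tibble(
    rank = x$rank,
    h = x$h,
    n_channels = nrow(x$modes),
    n_nonzero_singular = length(x$singular_values),
    n_svd_components = x$n_svd_components,
    dt = x$dt
  )
}
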