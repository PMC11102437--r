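#' Grassmann projection kernel between two mode sets
#'
#' Similarity between the subspaces spanned by two matrices of unit-norm
#' dynamic modes: `k_p(Phi_i, Phi_j) = ||Phi_i^dagger Phi_j||_F^2`. The
#' kernel is symmetric, nonnegative, and equals `K` for two identical
#' orthonormal `K`-column matrices.
#'
#' @param modes_i,modes_j Complex (or real) matrices with the channels in
#'   rows; both must share the channel dimension `P`. Columns are expected
#'   to be L2-normalized modes.
#' @return A nonnegative scalar.
#' @export
projection_kernel <- function(modes_i, modes_j) {
  modes_i <- as_mode_matrix(modes_i)
  modes_j <- as_mode_matrix(modes_j)
  if (nrow(modes_i) != nrow(modes_j)) {
    stop("mode matrices must share the channel dimension P", call. = FALSE)
  }
  sum(Mod(Conj(t(modes_i)) %*% modes_j)^2)
}

as_mode_matrix <- function(x) {
  if (inherits(x, "dmd")) {
    if (!isTRUE(x$normalized)) x <- normalize_modes(x)
    return(x$modes)
  }
  if (!is.matrix(x)) stop("expected a dmd object or a mode matrix", call. = FALSE)
  x
}

#' Spatial dynamic-mode (sDM) features of one trial
#'
#' Forms the real symmetric `P x P` matrix `Phi Phi^dagger` from a
#' conjugate-closed set of L2-normalized dynamic modes. This matrix is the
#' explicit feature map of the projection kernel: inner products of
#' vectorized sDM matrices reproduce the kernel exactly. Its diagonal is
#' the per-channel snDM feature vector and its strict upper triangle
#' (row-major) the channel-pair seDM feature vector.
#'
#' For a real signal the dynamic modes come in conjugate pairs, so
#' `Phi Phi^dagger` is real up to numerical noise; an imaginary residue
#' above `imag_tol` (relative to the largest real entry) signals a broken
#' (non-conjugate-closed) mode set and raises an error.
#'
#' @param modes A `dmd` object (L2-normalized automatically) or a `P x K`
#'   complex matrix of unit-norm modes.
#' @param imag_tol Relative tolerance for the imaginary residue.
#' @return An object of class `sdm_feature`: fields `matrix` (`P x P`),
#'   `sndm` (length `P`), `sedm` (length `P(P-1)/2`, row-major upper
#'   triangle), `n_modes`, `channel_ids`, `band` (`NULL` unless built by
#'   [band_filtered_sdm()]).
#' @examples
#' d <- exact_dmd(make_two_component_signal(), rank = 4)
#' f <- sdm_features(d)
#' sum(f$sndm) # trace = number of unit-norm modes
#' @export
sdm_features <- function(modes, imag_tol = 1e-8) {
  channel_ids <- if (inherits(modes, "dmd")) modes$channel_ids else NULL
  phi <- as_mode_matrix(modes)
  new_sdm_feature(phi, channel_ids = channel_ids, imag_tol = imag_tol)
}

new_sdm_feature <- function(phi, channel_ids = NULL, band = NULL,
                            imag_tol = 1e-8) {
  P <- nrow(phi)
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(P))
  if (ncol(phi) == 0L) {
    m <- matrix(0, P, P)
  } else {
    g <- phi %*% Conj(t(phi))
    if (is.complex(g)) {
      scale <- max(abs(Re(g)), 1e-300)
      if (max(abs(Im(g))) > imag_tol * scale) {
        stop(
          "sDM matrix has a non-negligible imaginary part: ",
          "the mode set is not conjugate-closed",
          call. = FALSE
        )
      }
      m <- Re(g)
    } else {
      m <- g
    }
    m <- (m + t(m)) / 2
  }
  dimnames(m) <- list(channel_ids, channel_ids)
  structure(
    list(
      matrix = m,
      sndm = stats::setNames(diag(m), channel_ids),
      sedm = sedm_vector(m, channel_ids),
      n_modes = ncol(phi),
      channel_ids = channel_ids,
      band = band
    ),
    class = "sdm_feature"
  )
}

# strict upper triangle in row-major order: (1,2), (1,3), ..., (2,3), ...
sedm_vector <- function(m, channel_ids) {
  P <- nrow(m)
  if (P < 2L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  idx <- which(upper.tri(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  stats::setNames(
    m[idx],
    paste0(channel_ids[idx[, 1L]], "_", channel_ids[idx[, 2L]])
  )
}

#' @export
print.sdm_feature <- function(x, ...) {
  cat(sprintf(
    "<sdm_feature> %d x %d from %d mode(s)%s\n",
    nrow(x$matrix), ncol(x$matrix), x$n_modes,
    if (!is.null(x$band)) sprintf(" [band %s]", x$band) else ""
  ))
  invisible(x)
}

#' Explicit feature map of the projection kernel
#'
#' Vectorizes (column-major) the sDM matrix `Phi Phi^dagger`. Inner
#' products of these `P^2`-vectors equal [projection_kernel()] values, so
#' a linear model on them is exactly equivalent to a kernel model on the
#' projection-kernel Gram matrix.
#'
#' @inheritParams sdm_features
#' @return A named numeric vector of length `P^2`.
#' @export
feature_map <- function(modes, imag_tol = 1e-8) {
  f <- if (inherits(modes, "sdm_feature")) modes else sdm_features(modes, imag_tol)
  m <- f$matrix
  nm <- outer(f$channel_ids, f$channel_ids, function(a, b) paste0(a, ".", b))
  stats::setNames(as.vector(m), as.vector(nm))
}

#' The eight canonical ECoG frequency bands
#'
#' Delta through high-frequency bands used to group dynamic modes for the
#' frequency-filtered sDM features: 0-1, 1-4, 4-8, 8-13, 13-30, 30-80,
#' 80-150 and 150-500 Hz.
#'
#' @return A tibble with columns `low`, `high` (Hz) and `label`.
#' @export
default_bands <- function() {
  edges <- c(0, 1, 4, 8, 13, 30, 80, 150, 500)
  tibble::tibble(
    low = edges[-length(edges)],
    high = edges[-1],
    label = paste0(edges[-length(edges)], "-", edges[-1], "Hz")
  )
}

validate_bands <- function(bands) {
  bands <- tibble::as_tibble(bands)
  if (!all(c("low", "high") %in% names(bands))) {
    stop("`bands` needs columns `low` and `high` (Hz)", call. = FALSE)
  }
  if (!"label" %in% names(bands)) {
    bands$label <- paste0(bands$low, "-", bands$high, "Hz")
  }
  if (any(bands$high <= bands$low)) stop("bands must have low < high", call. = FALSE)
  o <- order(bands$low)
  bands <- bands[o, ]
  if (nrow(bands) > 1 && any(bands$low[-1] < bands$high[-nrow(bands)])) {
    stop("bands must not overlap", call. = FALSE)
  }
  bands
}

# band index per mode by |f|; half-open [low, high), last band closed
assign_bands <- function(freqs, bands) {
  af <- abs(freqs)
  idx <- rep(NA_integer_, length(af))
  for (i in seq_len(nrow(bands))) {
    inb <- af >= bands$low[i] & af < bands$high[i]
    if (i == nrow(bands)) inb <- inb | af == bands$high[i]
    idx[inb & is.na(idx)] <- i
  }
  idx
}

#' Frequency-filtered sDM features
#'
#' Splits the dynamic modes by the frequency band containing `|f_k|`
#' (conjugate pairs share a band; intervals are half-open `[low, high)`
#' with the final band closed at its upper edge) and builds one sDM
#' feature matrix per band from that band's modes only. A band containing
#' no modes yields an all-zero matrix. Because the bands partition the
#' modes, the band matrices sum to the unfiltered sDM matrix.
#'
#' @param result A `dmd` object (L2-normalized automatically).
#' @param bands A band table as returned by [default_bands()].
#' @param imag_tol Relative tolerance for the imaginary residue.
#' @return A named list of [sdm_features()] objects, one per band.
#' @export
band_filtered_sdm <- function(result, bands = default_bands(), imag_tol = 1e-8) {
  stopifnot(inherits(result, "dmd"))
  if (!isTRUE(result$normalized)) result <- normalize_modes(result)
  bands <- validate_bands(bands)
  idx <- assign_bands(result$frequencies, bands)
  if (anyNA(idx)) {
    warning(sprintf(
      "%d mode(s) fall outside every band and were excluded", sum(is.na(idx))
    ))
  }
  out <- lapply(seq_len(nrow(bands)), function(i) {
    phi <- result$modes[, which(!is.na(idx) & idx == i), drop = FALSE]
    new_sdm_feature(phi,
      channel_ids = result$channel_ids,
      band = bands$label[i], imag_tol = imag_tol
    )
  })
  stats::setNames(out, bands$label)
}

#' Projection-kernel Gram matrix over trials
#'
#' Computes the pairwise projection-kernel similarity between every pair
#' of trials' L2-normalized mode sets. This is the matrix a precomputed-
#' kernel SVM consumes; its entries equal inner products of the trials'
#' explicit sDM feature vectors.
#'
#' @param trial_modes A list of `dmd` objects or `P x K` mode matrices,
#'   all sharing the channel dimension `P`.
#' @param trial_ids Optional identifiers (default `"trial1" ...`).
#' @return An object of class `gram_matrix` with fields `values`
#'   (`N x N` symmetric) and `trial_ids`.
#' @export
gram_matrix <- function(trial_modes, trial_ids = NULL) {
  mats <- lapply(trial_modes, as_mode_matrix)
  n <- length(mats)
  if (n == 0L) stop("no trials", call. = FALSE)
  P <- vapply(mats, nrow, integer(1))
  if (length(unique(P)) != 1L) {
    stop("all trials must share the channel dimension P", call. = FALSE)
  }
  if (is.null(trial_ids)) trial_ids <- paste0("trial", seq_len(n))
  vals <- matrix(0, n, n, dimnames = list(trial_ids, trial_ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      vals[i, j] <- vals[j, i] <- projection_kernel(mats[[i]], mats[[j]])
    }
  }
  structure(list(values = vals, trial_ids = trial_ids), class = "gram_matrix")
}

#' @export
print.gram_matrix <- function(x, ...) {
  cat(sprintf("<gram_matrix> %d x %d trials\n", nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Trial-by-feature table of sDM features
#'
#' Decomposes every trial (at a common rank), L2-normalizes the modes and
#' assembles the requested flavour of sDM features into a tibble with one
#' row per trial — the table the decoding harness consumes. With `bands`
#' supplied, the frequency-filtered variant is produced and each band's
#' columns carry the band label as a prefix.
#'
#' @param x A `trial_set`, a list of [trial_signal()]s, or a list of
#'   precomputed `dmd` objects.
#' @param type One of `"sndm"` (diagonal, `P` columns), `"sedm"` (strict
#'   upper triangle), `"sndm_sedm"` (both), `"sdm"` (full vectorized
#'   feature map, `P^2` columns).
#' @param rank SVD rank for the decomposition (ignored when `x` already
#'   holds `dmd` objects).
#' @param bands Optional band table for frequency-filtered features.
#' @return A tibble, `N` trials x features.
#' @export
sdm_feature_table <- function(x, type = c("sndm", "sedm", "sndm_sedm", "sdm"),
                              rank = NULL, bands = NULL) {
  type <- match.arg(type)
  dmds <- as_dmd_list(x, rank)
  rows <- lapply(dmds, function(d) {
    if (is.null(bands)) {
      sdm_row(sdm_features(d), type)
    } else {
      feats <- band_filtered_sdm(d, bands)
      unlist(lapply(names(feats), function(lb) {
        v <- sdm_row(feats[[lb]], type)
        stats::setNames(v, paste0(lb, ".", names(v)))
      }))
    }
  })
  tibble::as_tibble(do.call(rbind, rows))
}

sdm_row <- function(f, type) {
  switch(type,
    sndm = f$sndm,
    sedm = f$sedm,
    sndm_sedm = c(f$sndm, f$sedm),
    sdm = feature_map(f)
  )
}

as_dmd_list <- function(x, rank = NULL) {
  if (inherits(x, "trial_set")) x <- x$trials
  stopifnot(is.list(x))
  if (all(vapply(x, inherits, logical(1), "dmd"))) {
    return(lapply(x, normalize_modes))
  }
  lapply(x, function(s) normalize_modes(exact_dmd(s, rank = rank)))
}
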