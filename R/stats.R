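#' Trial-to-trial feature reproducibility
#'
#' For every pair of trials sharing a class label, the Pearson correlation
#' between their feature vectors is computed, Fisher z-transformed (with
#' `|r|` clipped just below 1), and averaged over all pairs. High values
#' mean the feature pattern is stable across repetitions of the same
#' condition.
#'
#' @param features Numeric `N x D` matrix / data frame, one feature vector
#'   per trial (`D >= 2`).
#' @param labels Class labels of length `N`; at least one class needs two
#'   or more trials.
#' @return Mean Fisher-z correlation over all within-class trial pairs.
#' @export
reproducibility <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  stopifnot(nrow(features) == length(labels), ncol(features) >= 2)
  zs <- numeric(0)
  n_skipped <- 0L
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) next
    sds <- apply(features[idx, , drop = FALSE], 1L, stats::sd)
    pairs <- utils::combn(seq_along(idx), 2L)
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1L, p]
      j <- pairs[2L, p]
      if (sds[i] == 0 || sds[j] == 0) {
        n_skipped <- n_skipped + 1L
        next
      }
      zs <- c(zs, fisher_z(stats::cor(features[idx[i], ], features[idx[j], ])))
    }
  }
  if (n_skipped > 0L) {
    warning(sprintf("skipped %d pair(s) with zero-variance features", n_skipped))
  }
  if (length(zs) == 0L) {
    stop("no within-class trial pair available", call. = FALSE)
  }
  mean(zs)
}

#' One-way ANOVA F statistic per feature component
#'
#' The classical between-group over within-group mean-square ratio,
#' computed independently for every column of the feature matrix — the
#' selectivity map that highlights which channels (snDM) or channel pairs
#' (seDM) discriminate the conditions. Raw F values are returned with no
#' multiple-testing adjustment (the map is descriptive).
#'
#' @param features Numeric `N x D` matrix / data frame.
#' @param labels Group labels; at least 2 groups with at least 2 samples
#'   each.
#' @return Numeric vector of `D` F statistics (`Inf`, with a warning, for
#'   components with zero within-group variance and distinct means).
#' @export
anova_f_map <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  stopifnot(nrow(features) == length(labels))
  counts <- table(labels)
  if (length(counts) < 2L || any(counts < 2L)) {
    stop("need >= 2 groups with >= 2 samples each", call. = FALSE)
  }
  n <- nrow(features)
  k <- length(counts)
  grand <- colMeans(features)
  ssb <- numeric(ncol(features))
  ssw <- numeric(ncol(features))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    gm <- colMeans(features[idx, , drop = FALSE])
    ssb <- ssb + length(idx) * (gm - grand)^2
    ssw <- ssw + colSums(
      sweep(features[idx, , drop = FALSE], 2L, gm)^2
    )
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- ifelse(msw == 0, ifelse(msb == 0, 0, Inf), msb / msw)
  if (any(is.infinite(f))) {
    warning("some components have zero within-group variance; F = Inf")
  }
  unname(f)
}

#' Correlation profile between snDM features and the PSD
#'
#' For each PSD frequency bin, concatenates the per-channel snDM values
#' over all trials and channels, concatenates the PSD values at that bin
#' the same way, and computes the Pearson correlation (Fisher
#' z-transformed). The resulting profile over frequency shows which
#' spectral band the snDM features resemble most.
#'
#' @param sndm Numeric `N x P` matrix of snDM features (one row per
#'   trial), e.g. from [sdm_feature_table()] with `type = "sndm"`.
#' @param psds List of `N` [psd_features()] objects on a common frequency
#'   grid, in the same trial order.
#' @return A tibble with columns `frequency` (Hz), `r`, and `z`; bins
#'   where either vector is constant are skipped (`NA`) with a warning.
#' @export
feature_psd_correlation <- function(sndm, psds) {
  sndm <- as.matrix(sndm)
  stopifnot(is.list(psds), length(psds) == nrow(sndm))
  ok <- vapply(psds, inherits, logical(1), "power_feature")
  if (!all(ok)) stop("`psds` must be psd_features() results", call. = FALSE)
  freqs <- psds[[1]]$frequencies
  P <- ncol(sndm)
  if (any(vapply(psds, function(p) nrow(p$psd), integer(1)) != P)) {
    stop("PSD channel count must match the snDM columns", call. = FALSE)
  }
  # concatenate trial-major: trial 1 channels 1..P, trial 2, ...
  x <- as.vector(t(sndm))
  psd_mat <- do.call(rbind, lapply(psds, function(p) p$psd)) # (N*P) x F
  if (stats::sd(x) == 0) stop("snDM features are constant", call. = FALSE)
  rs <- vapply(seq_along(freqs), function(b) {
    y <- psd_mat[, b]
    if (stats::sd(y) == 0) {
      return(NA_real_)
    }
    stats::cor(x, y)
  }, numeric(1))
  if (anyNA(rs)) {
    warning(sprintf("skipped %d constant PSD bin(s)", sum(is.na(rs))))
  }
  tibble::tibble(frequency = freqs, r = rs, z = fisher_z(rs))
}
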