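fmt_num <- function(x) sprintf("%.17g", x)

#' Persist a trial set as a plain-text bundle
#'
#' Writes a directory containing `signals.csv` (one row per trial-channel,
#' columns `trial`, `channel`, `s1 ... sL`, values printed with 17
#' significant digits so the round trip is bit-exact), `labels.csv` and/or
#' `targets.csv`, and `meta.json` (sampling interval, channel ids, class
#' names, and any generator metadata) — enough to regenerate the exact
#' `trial_set` anywhere.
#'
#' @param x A [trial_set()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_trialset <- function(x, path) {
  stopifnot(inherits(x, "trial_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  P <- n_channels(x$trials[[1]])
  sig <- do.call(rbind, lapply(x$trials, function(s) s$values))
  tab <- data.frame(
    trial = rep(seq_along(x$trials), each = P),
    channel = rep(x$trials[[1]]$channel_ids, length(x$trials)),
    matrix(apply(sig, 2L, fmt_num), nrow(sig)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(tab)[-(1:2)] <- paste0("s", seq_len(ncol(sig)))
  data.table::fwrite(tab, file.path(path, "signals.csv"), quote = FALSE)
  if (!is.null(x$labels)) {
    data.table::fwrite(
      data.frame(trial = seq_along(x$trials), label = as.character(x$labels)),
      file.path(path, "labels.csv")
    )
  }
  if (!is.null(x$targets)) {
    tg <- data.frame(
      trial = seq_along(x$trials),
      matrix(apply(x$targets, 2L, fmt_num), nrow(x$targets)),
      check.names = FALSE, stringsAsFactors = FALSE
    )
    names(tg)[-1] <- paste0("y", seq_len(ncol(x$targets)))
    data.table::fwrite(tg, file.path(path, "targets.csv"), quote = FALSE)
  }
  meta <- list(
    dt_seconds = x$trials[[1]]$dt,
    n_trials = length(x$trials),
    n_channels = P,
    n_samples = n_samples(x$trials[[1]]),
    channel_ids = x$trials[[1]]$channel_ids,
    class_names = if (!is.null(x$labels)) levels(x$labels) else NULL,
    metadata = x$metadata
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a trial-set bundle written by [write_trialset()]
#'
#' @param path Bundle directory.
#' @return A [trial_set()] with bit-identical signal values.
#' @export
read_trialset <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) {
    stop("not a trial-set bundle: missing meta.json", call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  for (fld in c("dt_seconds", "n_trials", "n_channels", "n_samples")) {
    if (is.null(meta[[fld]])) {
      stop(sprintf("trial-set bundle is missing required field `%s`", fld),
        call. = FALSE
      )
    }
  }
  if (meta$dt_seconds <= 0) {
    stop("field `dt_seconds` must be positive", call. = FALSE)
  }
  sig <- data.table::fread(file.path(path, "signals.csv"), data.table = FALSE)
  if (nrow(sig) != meta$n_trials * meta$n_channels ||
    ncol(sig) != meta$n_samples + 2L) {
    stop("signals.csv shape disagrees with meta.json fields `n_trials`/`n_channels`/`n_samples`",
      call. = FALSE
    )
  }
  vals <- as.matrix(sig[, -(1:2), drop = FALSE])
  trials <- lapply(seq_len(meta$n_trials), function(i) {
    rows <- ((i - 1L) * meta$n_channels + 1L):(i * meta$n_channels)
    trial_signal(vals[rows, , drop = FALSE],
      dt = meta$dt_seconds,
      channel_ids = meta$channel_ids
    )
  })
  labels <- NULL
  lf <- file.path(path, "labels.csv")
  if (file.exists(lf)) {
    labels <- factor(
      data.table::fread(lf, data.table = FALSE)$label,
      levels = meta$class_names
    )
  }
  targets <- NULL
  tf <- file.path(path, "targets.csv")
  if (file.exists(tf)) {
    targets <- as.matrix(
      data.table::fread(tf, data.table = FALSE)[, -1, drop = FALSE]
    )
  }
  md <- meta$metadata
  trial_set(trials,
    labels = labels, targets = targets,
    metadata = if (is.null(md)) list() else as.list(md)
  )
}

#' Single-trial CSV round trip
#'
#' Writes/reads one trial as a headerless numeric CSV with channels in
#' rows and samples in columns (17 significant digits, bit-exact round
#' trip). The sampling interval is not stored in the CSV and must be
#' supplied when reading.
#'
#' @param signal A [trial_signal()].
#' @param file CSV path.
#' @return `write_trial_csv` returns `file` invisibly; `read_trial_csv`
#'   returns a [trial_signal()].
#' @export
write_trial_csv <- function(signal, file) {
  stopifnot(inherits(signal, "trial_signal"))
  ch <- matrix(fmt_num(signal$values), nrow(signal$values))
  utils::write.table(ch, file,
    sep = ",", row.names = FALSE,
    col.names = FALSE, quote = FALSE
  )
  invisible(file)
}

#' @rdname write_trial_csv
#' @param dt Sampling interval in seconds for the trial being read.
#' @param channel_ids Optional channel identifiers.
#' @export
read_trial_csv <- function(file, dt, channel_ids = NULL) {
  v <- as.matrix(data.table::fread(file, header = FALSE, data.table = FALSE))
  trial_signal(unname(v), dt = dt, channel_ids = channel_ids)
}

#' Write a decoding result as structured JSON
#'
#' Serializes the per-fold scores, selected hyperparameters, summary
#' score, model kind and the full CV scheme (including its seed), so the
#' run can be regenerated from the file alone.
#'
#' @param result A `decoding_result`.
#' @param file Output JSON path.
#' @param config Optional configuration list to embed for provenance.
#' @return `file`, invisibly.
#' @export
write_decoding_json <- function(result, file, config = NULL) {
  stopifnot(inherits(result, "decoding_result"))
  out <- list(
    model = result$model,
    metric = result$metric,
    mean_score = result$mean_score,
    scheme = unclass(result$scheme),
    folds = result$scores,
    config = config
  )
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
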