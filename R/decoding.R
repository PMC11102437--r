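#' Nested cross-validation scheme
#'
#' The evaluation protocol: `outer_folds`-fold cross-validation repeated
#' `outer_repeats` times with re-randomized splits; inside every outer
#' training set, hyperparameters are selected by `inner_folds`-fold
#' cross-validation repeated `inner_repeats` times. The defaults (10-fold
#' outer x 10 repeats, 10-fold inner x 10 repeats) match the full
#' protocol; tests and examples use smaller schemes.
#'
#' @param outer_folds,outer_repeats Outer CV geometry.
#' @param inner_folds,inner_repeats Inner (hyperparameter-selection) CV.
#' @param mode `"stratified"` random splits minimizing per-fold class
#'   imbalance, or `"sequential"` contiguous blocks (for time-ordered
#'   regression targets).
#' @param seed Base seed; split seeds are derived deterministically per
#'   repeat index.
#' @return A `cv_scheme` list.
#' @export
cv_scheme <- function(outer_folds = 10, outer_repeats = 10,
                      inner_folds = 10, inner_repeats = 10,
                      mode = c("stratified", "sequential"), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(
    outer_folds >= 2, inner_folds >= 2,
    outer_repeats >= 1, inner_repeats >= 1
  )
  structure(
    list(
      outer_folds = as.integer(outer_folds),
      outer_repeats = as.integer(outer_repeats),
      inner_folds = as.integer(inner_folds),
      inner_repeats = as.integer(inner_repeats),
      mode = mode, seed = as.integer(seed)
    ),
    class = "cv_scheme"
  )
}

#' Build cross-validation fold assignments
#'
#' Stratified mode shuffles each class and deals its trials cyclically
#' into folds, so per-fold class counts differ by at most one; sequential
#' mode cuts the trial order into contiguous blocks (used when targets
#' are time-ordered). Every trial lands in exactly one fold.
#'
#' @param labels Factor of class labels (stratified) or anything of
#'   length `N` (sequential).
#' @param k Number of folds.
#' @param mode `"stratified"` or `"sequential"`.
#' @param seed Seed for the shuffle (ignored for sequential splits).
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(labels, k, mode = c("stratified", "sequential"),
                       seed = 1) {
  mode <- match.arg(mode)
  n <- length(labels)
  if (k > n) stop("more folds than trials", call. = FALSE)
  if (mode == "sequential") {
    return(as.integer(ceiling(seq_len(n) * k / n)))
  }
  labels <- as.factor(labels)
  folds <- integer(n)
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Oversampling indices to balance class counts
#'
#' Returns an index multiset in which every original index appears, and
#' the indices of each minority class are repeated by deterministic
#' cycling until all classes reach the count of the largest class — the
#' standard correction applied to imbalanced training folds before
#' fitting.
#'
#' @param labels Factor (or vector) of class labels; every class needs at
#'   least one sample.
#' @return Integer vector of indices into `labels`.
#' @examples
#' oversample_balance(c("a", "a", "a", "b")) # b's index repeated to 3
#' @export
oversample_balance <- function(labels) {
  labels <- as.factor(labels)
  if (length(labels) == 0L || any(table(labels) == 0L)) {
    stop("every class needs at least one sample", call. = FALSE)
  }
  counts <- table(labels)
  n_max <- max(counts)
  extras <- unlist(lapply(levels(labels), function(cl) {
    idx <- which(labels == cl)
    need <- n_max - length(idx)
    if (need == 0L) {
      return(integer(0))
    }
    rep_len(idx, need)
  }), use.names = FALSE)
  c(seq_along(labels), extras)
}

#' Balanced accuracy
#'
#' Mean over classes of the per-class recall; a constant predictor on `k`
#' balanced classes scores `1/k`, and the metric is insensitive to class
#' imbalance.
#'
#' @param truth Factor (or vector) of true labels; every declared class
#'   level must occur at least once.
#' @param predicted Vector of predicted labels, same length.
#' @return A number in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have the same length", call. = FALSE)
  }
  truth <- as.factor(truth)
  counts <- table(truth)
  if (any(counts == 0L)) {
    stop(
      "class(es) with no truth sample: ",
      paste(names(counts)[counts == 0L], collapse = ", "),
      call. = FALSE
    )
  }
  predicted <- as.character(predicted)
  recalls <- vapply(levels(truth), function(cl) {
    in_cl <- truth == cl
    mean(predicted[in_cl] == cl)
  }, numeric(1))
  mean(recalls)
}

#' Hyperparameter grids of the decoding protocol
#'
#' `default_cost_grid()` is the SVM/logistic cost grid `10^-1 ... 10^8`;
#' `default_lambda_grid()` the ridge penalty grid `10^-8 ... 10^8` (17
#' candidates); `default_rank_grid()` the candidate SVD ranks for the
#' feature pipeline, capped at the maximum available.
#'
#' @return Numeric vector of candidates.
#' @export
default_cost_grid <- function() 10^(-1:8)

#' @rdname default_cost_grid
#' @export
default_lambda_grid <- function() 10^(-8:8)

#' @rdname default_cost_grid
#' @param max_rank Largest admissible rank for the trial geometry.
#' @export
default_rank_grid <- function(max_rank) {
  unique(pmin(c(25, 50, 100, 200, 300, max_rank), max_rank))
}

# ---- model fitting ---------------------------------------------------------

fit_classifier <- function(model, x, y, cost) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) {
    stop("training fold lost all but one class; refusing to fit", call. = FALSE)
  }
  switch(model,
    linear_svm = {
      m <- kernlab::ksvm(x, y,
        type = "C-svc", kernel = "vanilladot",
        kpar = list(), C = cost, scaled = FALSE
      )
      list(predict = function(xnew) as.character(kernlab::predict(m, xnew)))
    },
    kernel_svm = {
      m <- kernlab::ksvm(kernlab::as.kernelMatrix(x), y,
        type = "C-svc", C = cost
      )
      sv <- kernlab::SVindex(m)
      list(predict = function(k_new_train) {
        as.character(kernlab::predict(
          m, kernlab::as.kernelMatrix(k_new_train[, sv, drop = FALSE])
        ))
      })
    },
    l1_logistic = {
      fam <- if (nlevels(y) == 2L) "binomial" else "multinomial"
      m <- glmnet::glmnet(x, y,
        family = fam, alpha = 1,
        lambda = 1 / (nrow(x) * cost), standardize = FALSE
      )
      list(predict = function(xnew) {
        as.character(drop(predict(m, xnew, type = "class")))
      })
    },
    stop("unknown model kind: ", model, call. = FALSE)
  )
}

# feature candidates: named list rank-label -> N x D matrix (or N x N gram)
as_feature_candidates <- function(x, model) {
  is_gram <- function(z) inherits(z, "gram_matrix")
  unwrap <- function(z) {
    if (is_gram(z)) {
      return(z$values)
    }
    as.matrix(z)
  }
  if (!is.list(x) || is.data.frame(x) || is_gram(x)) x <- list(features = x)
  if (is.null(names(x)) || any(names(x) == "")) {
    names(x) <- paste0("candidate", seq_along(x))
  }
  out <- lapply(x, unwrap)
  if (model == "kernel_svm") {
    sq <- vapply(out, function(m) nrow(m) == ncol(m), logical(1))
    if (!all(sq)) {
      stop("kernel_svm needs square Gram matrices as features", call. = FALSE)
    }
  }
  out
}

subset_train <- function(feat, idx, model) {
  if (model == "kernel_svm") feat[idx, idx, drop = FALSE] else feat[idx, , drop = FALSE]
}

subset_test <- function(feat, test_idx, train_idx, model) {
  if (model == "kernel_svm") {
    feat[test_idx, train_idx, drop = FALSE]
  } else {
    feat[test_idx, , drop = FALSE]
  }
}

check_folds_valid <- function(labels, folds) {
  for (f in sort(unique(folds))) {
    tr <- labels[folds != f]
    if (nlevels(droplevels(as.factor(tr))) < nlevels(as.factor(labels))) {
      stop("degenerate split: a class is absent from a training fold",
        call. = FALSE
      )
    }
  }
}

# mean inner-CV balanced accuracy for one (feature, cost) candidate
inner_cv_score <- function(feat, labels, model, cost, scheme, seed_base) {
  scores <- numeric(0)
  for (r in seq_len(scheme$inner_repeats)) {
    folds <- make_folds(labels, scheme$inner_folds,
      mode = "stratified",
      seed = seed_base + r
    )
    for (f in seq_len(scheme$inner_folds)) {
      tr <- which(folds != f)
      te <- which(folds == f)
      if (length(te) == 0L) next
      os <- tr[oversample_balance(labels[tr])]
      fit <- fit_classifier(
        model, subset_train(feat, os, model), labels[os], cost
      )
      pred <- fit$predict(subset_test(feat, te, os, model))
      scores <- c(scores, balanced_accuracy(droplevels(labels[te]), pred))
    }
  }
  mean(scores)
}

#' Nested cross-validated classification
#'
#' The full decoding protocol: for every outer fold, an inner repeated
#' cross-validation over the `(rank, cost)` grid selects the
#' hyperparameters maximizing mean inner balanced accuracy; the model is
#' then refit on the oversampled outer training set with those values and
#' scored on the held-out outer fold. The reported score is the mean
#' balanced accuracy over all outer folds and repeats. Hyperparameter
#' selection never touches outer test trials.
#'
#' @param x Feature input: a numeric matrix / data frame (`N` trials x
#'   features), a [gram_matrix()] (for `model = "kernel_svm"`), or a named
#'   list of either keyed by rank candidate (the rank is then tuned in the
#'   inner loop).
#' @param labels Factor of trial labels.
#' @param model `"linear_svm"` (L2-regularized SVM on explicit features),
#'   `"kernel_svm"` (precomputed projection-kernel Gram), or
#'   `"l1_logistic"` (L1-regularized logistic regression; its `cost` is
#'   mapped to the penalty as `lambda = 1 / (n C)`).
#' @param costs Cost grid (default [default_cost_grid()]).
#' @param scheme A [cv_scheme()].
#' @return A `decoding_result`: tibble of per-fold scores and selections,
#'   `mean_score`, `metric = "balanced_accuracy"`.
#' @export
nested_cv_classify <- function(x, labels,
                               model = c("linear_svm", "kernel_svm", "l1_logistic"),
                               costs = default_cost_grid(),
                               scheme = cv_scheme()) {
  model <- match.arg(model)
  stopifnot(inherits(scheme, "cv_scheme"), length(costs) >= 1)
  labels <- droplevels(as.factor(labels))
  feats <- as_feature_candidates(x, model)
  n <- length(labels)
  if (any(vapply(feats, nrow, integer(1)) != n)) {
    stop("feature rows must match the number of labels", call. = FALSE)
  }
  rows <- list()
  for (rep_i in seq_len(scheme$outer_repeats)) {
    folds <- make_folds(labels, scheme$outer_folds,
      mode = "stratified",
      seed = scheme$seed + 7919L * rep_i
    )
    check_folds_valid(labels, folds)
    for (f in seq_len(scheme$outer_folds)) {
      tr <- which(folds != f)
      te <- which(folds == f)
      if (length(te) == 0L) next
      # joint grid search over rank candidates and costs on the inner CV
      best <- NULL
      for (rk in names(feats)) {
        feat_tr <- subset_train(feats[[rk]], tr, model)
        for (cost in costs) {
          sc <- inner_cv_score(
            feat_tr, droplevels(labels[tr]), model, cost, scheme,
            seed_base = scheme$seed + 104729L * rep_i + 331L * f
          )
          if (is.null(best) || sc > best$score) {
            best <- list(rank = rk, cost = cost, score = sc)
          }
        }
      }
      os <- tr[oversample_balance(labels[tr])]
      fit <- fit_classifier(
        model, subset_train(feats[[best$rank]], os, model), labels[os],
        best$cost
      )
      pred <- fit$predict(subset_test(feats[[best$rank]], te, os, model))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        repeat_ = rep_i, fold = f,
        rank = best$rank, cost = best$cost,
        inner_score = best$score,
        score = balanced_accuracy(droplevels(labels[te]), pred)
      )
    }
  }
  scores <- dplyr::bind_rows(rows)
  new_decoding_result(
    scores = scores, mean_score = mean(scores$score),
    metric = "balanced_accuracy", model = model, scheme = scheme
  )
}

new_decoding_result <- function(scores, mean_score, metric, model, scheme) {
  structure(
    list(
      scores = scores, mean_score = mean_score, metric = metric,
      model = model, scheme = scheme
    ),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "<decoding_result> %s: mean %s = %.4f over %d fold evaluations\n",
    x$model, x$metric, x$mean_score, nrow(x$scores)
  ))
  invisible(x)
}

#' Tidy per-fold decoding scores
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return Tibble with one row per outer fold evaluation (repeat, fold,
#'   selected hyperparameters, score).
#' @export
tidy.decoding_result <- function(x, ...) x$scores

#' One-row decoding summary
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return Tibble with `model`, `metric`, `mean_score`, `sd_score`,
#'   `n_folds`.
#' @export
glance.decoding_result <- function(x, ...) {
  tibble::tibble(
    model = x$model, metric = x$metric, mean_score = x$mean_score,
    sd_score = stats::sd(x$scores$score), n_folds = nrow(x$scores)
  )
}

# ---- ridge regression (closed form via SVD) --------------------------------

# returns a function(xnew) -> n_new x n_lambda prediction matrix;
# features and targets are centered on the training data
ridge_path <- function(x, y, lambdas) {
  x_mean <- colMeans(x)
  y_mean <- mean(y)
  xc <- sweep(x, 2L, x_mean)
  sv <- svd(xc)
  uty <- crossprod(sv$u, y - y_mean)
  betas <- vapply(lambdas, function(lam) {
    drop(sv$v %*% (sv$d / (sv$d^2 + lam) * uty))
  }, numeric(ncol(x)))
  function(xnew) {
    sweep(xnew, 2L, x_mean) %*% betas + y_mean
  }
}

#' Nested cross-validated ridge regression
#'
#' Decodes continuous targets with L2-regularized (ridge) linear
#' regression, the penalty `lambda` selected per target dimension on the
#' inner cross-validation by minimizing mean squared error (jointly with
#' the feature rank when `x` is a list of candidates). Features and
#' targets are mean-centered on each training fold. Accuracy is the
#' Pearson correlation between predicted and true values, Fisher
#' z-transformed, averaged over folds and repeats, then over target
#' dimensions.
#'
#' @param x Feature matrix or named list of candidate matrices (see
#'   [nested_cv_classify()]).
#' @param targets Numeric vector or `N x D` matrix of targets.
#' @param lambdas Penalty grid (default [default_lambda_grid()], 17
#'   candidates `10^-8 ... 10^8`).
#' @param scheme A [cv_scheme()]; `mode = "sequential"` gives contiguous
#'   block splits for time-ordered targets.
#' @return A `decoding_result` with per-fold, per-dimension Fisher-z
#'   correlations and `mean_score` = mean z over dimensions.
#' @export
nested_cv_regress <- function(x, targets, lambdas = default_lambda_grid(),
                              scheme = cv_scheme(mode = "sequential")) {
  stopifnot(inherits(scheme, "cv_scheme"))
  targets <- as.matrix(targets)
  feats <- lapply(as_feature_candidates(x, "ridge"), as.matrix)
  n <- nrow(targets)
  if (any(vapply(feats, nrow, integer(1)) != n)) {
    stop("feature rows must match the number of target rows", call. = FALSE)
  }
  n_dim <- ncol(targets)
  const_dims <- which(apply(targets, 2L, stats::sd) == 0)
  if (length(const_dims) > 0L) {
    warning(sprintf(
      "skipping %d constant target dimension(s)", length(const_dims)
    ))
  }
  dims <- setdiff(seq_len(n_dim), const_dims)
  if (length(dims) == 0L) stop("no usable target dimensions", call. = FALSE)
  rows <- list()
  for (rep_i in seq_len(scheme$outer_repeats)) {
    folds <- make_folds(seq_len(n), scheme$outer_folds,
      mode = scheme$mode, seed = scheme$seed + 7919L * rep_i
    )
    for (f in seq_len(scheme$outer_folds)) {
      tr <- which(folds != f)
      te <- which(folds == f)
      for (d in dims) {
        # inner CV: joint (rank, lambda) selection by MSE
        best <- NULL
        for (rk in names(feats)) {
          xtr <- feats[[rk]][tr, , drop = FALSE]
          ytr <- targets[tr, d]
          mse <- matrix(0, 0, length(lambdas))
          for (ir in seq_len(scheme$inner_repeats)) {
            infolds <- make_folds(seq_along(tr), scheme$inner_folds,
              mode = scheme$mode,
              seed = scheme$seed + 104729L * rep_i + 331L * f + ir
            )
            for (g in seq_len(scheme$inner_folds)) {
              itr <- which(infolds != g)
              ite <- which(infolds == g)
              pred <- ridge_path(
                xtr[itr, , drop = FALSE], ytr[itr], lambdas
              )(xtr[ite, , drop = FALSE])
              mse <- rbind(mse, colMeans((pred - ytr[ite])^2))
            }
          }
          m <- colMeans(mse)
          j <- which.min(m)
          if (is.null(best) || m[j] < best$mse) {
            best <- list(rank = rk, lambda = lambdas[j], mse = m[j])
          }
        }
        pred <- ridge_path(
          feats[[best$rank]][tr, , drop = FALSE], targets[tr, d],
          best$lambda
        )(feats[[best$rank]][te, , drop = FALSE])
        r <- if (stats::sd(pred) == 0 || stats::sd(targets[te, d]) == 0) {
          0
        } else {
          stats::cor(drop(pred), targets[te, d])
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          repeat_ = rep_i, fold = f, dimension = d,
          rank = best$rank, lambda = best$lambda,
          correlation = r, score = fisher_z(r)
        )
      }
    }
  }
  scores <- dplyr::bind_rows(rows)
  per_dim <- tapply(scores$score, scores$dimension, mean)
  new_decoding_result(
    scores = scores, mean_score = mean(per_dim),
    metric = "fisher_z_correlation", model = "ridge", scheme = scheme
  )
}

#' Fisher z-transform of a correlation coefficient
#'
#' `atanh(r)` with `r` clipped to `1 - 1e-12` in magnitude so perfectly
#' correlated pairs stay finite.
#'
#' @param r Correlation value(s).
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  atanh(pmax(pmin(r, 1 - 1e-12), -(1 - 1e-12)))
}
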