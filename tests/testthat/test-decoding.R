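test_that("common average reference removes the channel mean", {
  s <- trial_signal(matrix(c(1, 3, 3, 5, 2, 8), 2), dt = 1)
  car <- common_average_reference(s)
  expect_equal(car$values[, 1], c(-1, 1))
  expect_equal(car$values[, 2], c(-1, 1))
  expect_true(all(abs(colSums(car$values)) <= 1e-12 * max(abs(car$values))))

  # already zero-mean columns are unchanged
  v <- matrix(c(1, -1, 2, -2, 0.5, -0.5), 2)
  expect_equal(common_average_reference(trial_signal(v, 1))$values, v)

  expect_error(
    common_average_reference(trial_signal(matrix(1, 1, 5), 1)),
    "2 channels"
  )
})

test_that("cropping keeps the half-open window", {
  v <- matrix(seq_len(1000), 1)
  s <- trial_signal(v, dt = 0.001)
  expect_equal(n_samples(crop_signal(s, 0, 0.5)), 500L)
  # identity crop
  expect_equal(crop_signal(s, 0, 1)$values, v)
  # [0.1, 0.3) at 1 kHz: 200 samples starting at index 101
  cr <- crop_signal(s, 0.1, 0.3)
  expect_equal(n_samples(cr), 200L)
  expect_equal(cr$values[1, 1], 101)
  expect_error(crop_signal(s, 0.5, 0.5), "t0 < t1")
})

test_that("oversampling cycles minority classes up to the maximum", {
  lab <- factor(rep(c("a", "b", "c"), c(10, 5, 5)))
  idx <- oversample_balance(lab)
  expect_equal(as.vector(table(lab[idx])), c(10, 10, 10))
  expect_true(all(seq_along(lab) %in% idx))

  # already balanced: identity
  bal <- factor(rep(c("a", "b"), each = 4))
  expect_identical(oversample_balance(bal), seq_len(8L))

  # counts (3, 1): the minority index appears 3 times in total
  lab2 <- factor(c("a", "a", "a", "b"))
  idx2 <- oversample_balance(lab2)
  expect_equal(sum(idx2 == 4L), 3L)

  expect_error(oversample_balance(factor(character(0))), "at least one")
})

test_that("balanced accuracy is the mean per-class recall", {
  expect_equal(balanced_accuracy(c("a", "b"), c("a", "b")), 1)
  # constant predictor on 2 balanced classes
  expect_equal(balanced_accuracy(rep(c("a", "b"), 5), rep("a", 10)), 0.5)
  # hand arithmetic: recalls 0.5 and 1
  expect_equal(
    balanced_accuracy(c("A", "A", "B", "B"), c("A", "B", "B", "B")), 0.75
  )
  # a declared class level with no truth sample is an error
  truth <- factor(c("a", "a"), levels = c("a", "b"))
  expect_error(balanced_accuracy(truth, c("a", "a")), "no truth sample")
  expect_error(balanced_accuracy(c("a"), c("a", "b")), "length")
})

test_that("fold construction partitions trials and stratifies classes", {
  lab <- factor(rep(c("a", "b", "c"), c(12, 9, 6)))
  for (seed in 1:4) {
    f <- make_folds(lab, 3, seed = seed)
    expect_length(f, 27)
    expect_setequal(unique(f), 1:3)
    # every trial in exactly one fold; per-class counts differ by <= 1
    for (cl in levels(lab)) {
      counts <- table(f[lab == cl])
      expect_lte(max(counts) - min(counts), 1)
    }
  }
  # sequential folds are contiguous blocks
  fs <- make_folds(seq_len(10), 5, mode = "sequential")
  expect_equal(fs, rep(1:5, each = 2))
  expect_error(make_folds(1:3, 5), "more folds")
})

test_that("hyperparameter grids match the protocol", {
  expect_length(default_cost_grid(), 10)
  expect_equal(range(default_cost_grid()), c(1e-1, 1e8))
  expect_length(default_lambda_grid(), 17)
  expect_equal(range(default_lambda_grid()), c(1e-8, 1e8))
  expect_equal(default_rank_grid(120), c(25, 50, 100, 120))
})

test_that("ridge with huge lambda predicts the training mean", {
  set.seed(8)
  x <- matrix(rnorm(40 * 3), 40)
  y <- rnorm(40, mean = 5)
  pred <- sdmf:::ridge_path(x, y, 1e12)(matrix(rnorm(15), 5))
  expect_equal(drop(pred), rep(mean(y), 5), tolerance = 1e-6)
  # and with lambda = 0 it is ordinary least squares
  pred0 <- sdmf:::ridge_path(x, y, 0)(x)
  ols <- stats::lm.fit(cbind(1, x), y)$fitted.values
  expect_equal(drop(pred0), unname(ols), tolerance = 1e-8)
})

test_that("separable synthetic classes decode above 90% balanced accuracy", {
  ts <- fixture_set()
  feats <- list(
    rank4 = fixture_sndm(4),
    rank16 = fixture_sndm(16)
  )
  res <- nested_cv_classify(
    feats, ts$labels,
    model = "linear_svm", costs = c(1, 100, 1e4),
    scheme = test_scheme()
  )
  expect_gt(res$mean_score, 0.9)
  expect_true(all(res$scores$score >= 0 & res$scores$score <= 1))
  expect_true(all(res$scores$cost %in% c(1, 100, 1e4)))
  expect_true(all(res$scores$rank %in% c("rank4", "rank16")))
  # every trial appears in exactly one outer test fold per repeat
  expect_equal(nrow(res$scores), 5L)
})

test_that("label-permuted decoding sits at chance", {
  ts <- fixture_set()
  perm <- withr::with_seed(99, sample(ts$labels))
  res <- nested_cv_classify(
    fixture_sndm(8), perm,
    model = "linear_svm", costs = c(1, 100),
    scheme = test_scheme()
  )
  expect_gte(res$mean_score, 0.25)
  expect_lte(res$mean_score, 0.42)
})

test_that("kernel and explicit-feature SVM routes predict identical labels", {
  ts <- fixture_set()
  dmds <- fixture_dmds(8)
  psi <- as.matrix(sdm_feature_table(dmds, "sdm"))
  k <- gram_matrix(dmds)$values
  expect_equal(psi %*% t(psi), k, tolerance = 1e-8, ignore_attr = TRUE)

  folds <- make_folds(ts$labels, 5, seed = 13)
  for (cost in c(1, 100)) {
    for (f in 1:5) {
      tr <- which(folds != f)
      te <- which(folds == f)
      lin <- sdmf:::fit_classifier("linear_svm", psi[tr, ], ts$labels[tr], cost)
      ker <- sdmf:::fit_classifier("kernel_svm", k[tr, tr], ts$labels[tr], cost)
      expect_identical(
        lin$predict(psi[te, ]),
        ker$predict(k[te, tr, drop = FALSE])
      )
    }
  }
})

test_that("L1-regularized logistic decoding works on the separable set", {
  ts <- fixture_set()
  res <- nested_cv_classify(
    fixture_sndm(4), ts$labels,
    model = "l1_logistic", costs = c(1, 100),
    scheme = test_scheme()
  )
  expect_gt(res$mean_score, 0.8)
})

test_that("ridge regression recovers a planted linear map and nulls out", {
  x <- as.matrix(fixture_sndm(8))
  n <- nrow(x)
  targets <- withr::with_seed(55, {
    w <- matrix(rnorm(ncol(x) * 2), ncol(x))
    sc <- scale(x %*% w)
    sc + 0.1 * matrix(rnorm(n * 2), n)
  })
  sch <- cv_scheme(
    outer_folds = 5, outer_repeats = 1, inner_folds = 3, inner_repeats = 1,
    mode = "sequential", seed = 3
  )
  res <- nested_cv_regress(x, targets, lambdas = 10^(-4:4), scheme = sch)
  expect_gt(mean(res$scores$correlation), 0.9)
  expect_true(all(res$scores$lambda %in% 10^(-4:4)))

  # targets independent of the signals: mean Fisher-z near 0
  null_t <- withr::with_seed(56, matrix(rnorm(n * 2), n))
  res0 <- nested_cv_regress(x, null_t, lambdas = 10^(-4:4), scheme = sch)
  expect_lt(abs(res0$mean_score), 0.1)

  # constant target dimensions are skipped with a warning
  expect_warning(
    nested_cv_regress(x, cbind(targets[, 1], 1),
      lambdas = 1,
      scheme = sch
    ),
    "constant"
  )
})

test_that("tidy and glance expose decoding results", {
  ts <- fixture_set()
  res <- nested_cv_classify(
    fixture_sndm(4), ts$labels,
    model = "linear_svm",
    costs = 100, scheme = test_scheme()
  )
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("repeat_", "fold", "rank", "cost", "score") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$mean_score, mean(td$score))
  expect_identical(gl$metric, "balanced_accuracy")
})
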