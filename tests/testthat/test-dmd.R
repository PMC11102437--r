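test_that("stacking factor is the minimal tall-matrix embedding", {
  expect_identical(compute_h(81, 500), 7L)
  expect_identical(compute_h(100, 50), 1L)
  expect_identical(compute_h(1, 3), 2L)
  # h is minimal: h - 1 violates the inequality whenever h > 1
  for (pl in list(c(81, 500), c(1, 3), c(4, 100))) {
    h <- compute_h(pl[1], pl[2])
    expect_gte(h, (pl[2] + 1) / (pl[1] + 1))
    if (h > 1) expect_lt(h - 1, (pl[2] + 1) / (pl[1] + 1))
  }
  expect_error(compute_h(0, 10), "positive")
  expect_error(compute_h(3, 2), ">= 3")
})

test_that("stacked snapshot pair has the block-Hankel layout", {
  s <- trial_signal(matrix(c(1, 2, 3, 4), 1), dt = 1)
  stk <- stack_signals(s, h = 2)
  expect_equal(stk$x, matrix(c(1, 2, 2, 3), 2, byrow = TRUE))
  expect_equal(stk$x_prime, matrix(c(2, 3, 3, 4), 2, byrow = TRUE))

  # h = 1 collapses to the unstacked snapshot pair
  v <- matrix(rnorm(3 * 6), 3, 6)
  s2 <- trial_signal(v, dt = 0.1)
  stk1 <- stack_signals(s2, h = 1)
  expect_equal(stk1$x, v[, 1:5])
  expect_equal(stk1$x_prime, v[, 2:6])

  stk_demo <- stack_signals(demo_signal())
  expect_equal(dim(stk_demo$x), c(567L, 493L))
  expect_equal(dim(stk_demo$x_prime), c(567L, 493L))
  # row-block r, column c of X equals sample x_{c + r - 1}
  expect_equal(stk_demo$x[82:162, 5], demo_signal()$values[, 6])

  expect_error(stack_signals(s, h = 4), "smaller than L")
})

test_that("truncated SVD keeps orthonormal factors and drops floor components", {
  set.seed(3)
  u <- qr.Q(qr(matrix(rnorm(36), 6)))[, 1:3]
  v <- qr.Q(qr(matrix(rnorm(25), 5)))[, 1:3]
  x <- u %*% diag(c(5, 2, 1)) %*% t(v)

  sv <- truncated_svd(x, rank = 3)
  expect_equal(crossprod(sv$u), diag(3), tolerance = 1e-10)
  expect_equal(crossprod(sv$v), diag(3), tolerance = 1e-10)
  expect_equal(sv$d, sort(sv$d, decreasing = TRUE))
  expect_equal(sv$d, c(5, 2, 1), tolerance = 1e-10)

  # rank-1 truncation reconstructs a rank-1 matrix exactly
  x1 <- outer(rnorm(6), rnorm(4))
  sv1 <- truncated_svd(x1, rank = 1)
  rec <- sv1$u %*% diag(sv1$d, 1) %*% t(sv1$v)
  expect_lt(norm(x1 - rec, "F") / norm(x1, "F"), 1e-10)

  # near-zero singular values fall below the floor
  sv_fl <- truncated_svd(x1, rank = 4)
  expect_identical(sv_fl$rank, 1L)
  expect_identical(sv_fl$n_above_floor, 1L)

  # matrix with orthonormal columns: all singular values are 1
  svq <- truncated_svd(u, rank = 3)
  expect_equal(svq$d, rep(1, 3), tolerance = 1e-12)

  expect_error(truncated_svd(x, rank = 10), "rank")
  expect_error(truncated_svd(matrix(0, 3, 3)), "numerically zero")
})

test_that("exact DMD matches hand-computable dynamics", {
  # geometric sequence: single eigenvalue 2 (computed by hand: h = 3,
  # X = [1;2;4], X' = [2;4;8], rank-1, A_tilde = 2)
  s <- trial_signal(matrix(c(1, 2, 4, 8), 1), dt = 1)
  d <- exact_dmd(s)
  expect_identical(d$rank, 1L)
  expect_identical(d$h, 3L)
  expect_equal(d$eigenvalues, 2 + 0i, tolerance = 1e-10)
  expect_equal(d$frequencies, 0, tolerance = 1e-10)
  expect_equal(d$rates, 2, tolerance = 1e-10)

  # pure sinusoid: norm-preserving pair e^{+-2 pi i f0 dt}, rate 1
  f0 <- 12
  dt <- 0.005
  t <- (0:99) * dt
  v <- rbind(sin(2 * pi * f0 * t), sin(2 * pi * f0 * t + 1), cos(2 * pi * f0 * t))
  d2 <- exact_dmd(trial_signal(v, dt = dt), rank = 2)
  expect_equal(sort(abs(d2$frequencies)), c(f0, f0), tolerance = 1e-8)
  expect_equal(d2$rates, c(1, 1), tolerance = 1e-8)
  expect_equal(
    sort_complex(d2$eigenvalues),
    sort_complex(exp(c(-1, 1) * 2i * pi * f0 * dt)),
    tolerance = 1e-8
  )

  # constant signal behaves as rank-1 with lambda = 1
  dc <- exact_dmd(trial_signal(matrix(3, 2, 20), dt = 0.01))
  expect_identical(dc$rank, 1L)
  expect_equal(dc$eigenvalues, 1 + 0i, tolerance = 1e-10)
  expect_equal(dc$frequencies, 0, tolerance = 1e-10)
  expect_equal(dc$rates, 1, tolerance = 1e-10)

  expect_error(exact_dmd(s, rank = 100), "rank")
})

test_that("eigenvalues match the dense-propagator oracle on small instances", {
  for (seed in 1:6) {
    withr::with_seed(seed, {
      P <- sample(2:3, 1)
      L <- sample(8:12, 1)
      v <- matrix(rnorm(P * L), P, L)
    })
    s <- trial_signal(v, dt = 0.01)
    d <- exact_dmd(s, h = 1)
    # oracle: dense eigendecomposition of A = X' X^+
    a <- v[, 2:L] %*% pinv_dense(v[, 1:(L - 1)])
    oracle <- as.complex(eigen(a, only.values = TRUE)$values)
    expect_equal(
      sort_complex(d$eigenvalues), sort_complex(oracle),
      tolerance = 1e-8
    )
  }
})

test_that("real input yields conjugate-closed eigenvalues within Nyquist", {
  for (seed in 1:5) {
    d <- random_mode_set(seed, P = 4, L = 60, rank = 6)
    lam <- d$eigenvalues
    tol <- 1e-8 * max(Mod(lam))
    for (z in lam[abs(Im(lam)) > tol]) {
      expect_true(min(Mod(lam - Conj(z))) <= tol)
    }
    expect_true(all(abs(d$frequencies) <= 1 / (2 * d$dt) + 1e-12))
    expect_true(all(d$rates > 0))
    # each non-real mode column has a conjugate partner column
    cplx <- which(abs(Im(d$eigenvalues)) > tol)
    for (k in cplx) {
      partner <- which.min(Mod(d$eigenvalues - Conj(d$eigenvalues[k])))
      diffs <- abs(d$modes[, k] - Conj(d$modes[, partner]))
      expect_lt(max(diffs), 1e-6 * max(Mod(d$modes[, k])))
    }
  }
})

test_that("noiseless damped-sinusoid mixtures recover frequency and rate", {
  specs <- list(
    oscillator_spec(20, 0.5, function(p) sech(p + 2)),
    oscillator_spec(60, 1.5, function(p) sech(p - 2))
  )
  s <- make_oscillator_signal(specs, n_channels = 6, n_samples = 200, dt = 0.001)
  d <- exact_dmd(s, rank = 4)
  expect_equal(sort(unique(round(abs(d$frequencies), 3))), c(20, 60),
    tolerance = 1e-6
  )
  got <- tidy(d) |>
    dplyr::mutate(af = abs(frequency)) |>
    dplyr::distinct(af, rate) |>
    dplyr::arrange(af)
  expect_equal(got$af, c(20, 60), tolerance = 1e-6)
  expect_equal(got$rate, c(0.5, 1.5), tolerance = 1e-6)
})

test_that("reconstruction reproduces the signal and the initial state", {
  s <- demo_signal()
  d <- demo_dmd()
  t <- (0:499) / 1000
  rec <- reconstruct(d, t)
  expect_lt(norm(s$values - rec, "F") / norm(s$values, "F"), 1e-6)

  # t = 0 satisfies the least-squares initial condition
  rec0 <- reconstruct(d, 0)
  expect_equal(drop(rec0), d$initial_state[1:81], tolerance = 1e-8)

  # amplitudes recomputed from a supplied stacked state
  rec0b <- reconstruct(d, 0, initial_state = d$initial_state)
  expect_equal(rec0b, rec0, tolerance = 1e-10)

  # a noiseless low-rank signal at full numerical rank: machine precision
  s2 <- make_oscillator_signal(
    list(oscillator_spec(15, 0.8, function(p) sech(p))),
    n_channels = 5, n_samples = 100, dt = 0.001
  )
  d2 <- exact_dmd(s2)
  rec2 <- reconstruct(d2, (0:99) / 1000)
  expect_lt(norm(s2$values - rec2, "F") / norm(s2$values, "F"), 1e-9)

  # growing modes overflow at absurd horizons
  expect_error(reconstruct(d, 2000), "overflow")
})

test_that("mode normalization yields unit columns and is idempotent", {
  d <- demo_dmd_norm()
  expect_equal(sqrt(colSums(Mod(d$modes)^2)), rep(1, 4), tolerance = 1e-12)
  expect_identical(normalize_modes(d), d)
  # trace of Phi Phi^dagger = number of unit-norm modes
  expect_equal(sum(Re(diag(d$modes %*% Conj(t(d$modes))))), 4,
    tolerance = 1e-8
  )
  # scale factors allow recovering the unnormalized modes
  raw <- demo_dmd()
  expect_equal(
    sweep(d$modes, 2, d$mode_scales, "*"), raw$modes,
    tolerance = 1e-10
  )
})
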