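# Shared fixtures, computed once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

demo_signal <- function() cached("demo_signal", make_two_component_signal())

demo_dmd <- function() {
  cached("demo_dmd", exact_dmd(demo_signal(), rank = 4))
}

demo_dmd_norm <- function() cached("demo_dmd_norm", normalize_modes(demo_dmd()))

# default ECoG-like 3-class set (120 trials, 16 channels, 500 samples)
fixture_set <- function() cached("fixture_set", make_trial_set(seed = 42))

# normalized per-trial decompositions of the fixture set at a given rank
fixture_dmds <- function(rank) {
  cached(paste0("fixture_dmds_", rank), {
    lapply(fixture_set()$trials, function(s) {
      normalize_modes(exact_dmd(s, rank = rank))
    })
  })
}

fixture_sndm <- function(rank = 8) {
  cached(
    paste0("fixture_sndm_", rank),
    sdm_feature_table(fixture_dmds(rank), type = "sndm")
  )
}

# small reduced CV scheme used throughout the tests
test_scheme <- function(seed = 7) {
  cv_scheme(
    outer_folds = 5, outer_repeats = 1, inner_folds = 3, inner_repeats = 1,
    seed = seed
  )
}

# random trial whose modes are conjugate-closed (real signal)
random_mode_set <- function(seed, P = 5, L = 40, rank = 4) {
  withr::with_seed(seed, {
    s <- trial_signal(matrix(rnorm(P * L), P, L), dt = 0.01)
    normalize_modes(exact_dmd(s, rank = rank))
  })
}

# dense Moore-Penrose pseudoinverse (independent of the package's SVD path)
pinv_dense <- function(m, tol = 1e-10) {
  sv <- svd(m)
  keep <- sv$d > tol * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

# sort complex values canonically for multiset comparison
sort_complex <- function(z) z[order(Re(z), Im(z))]

sech <- function(z) 1 / cosh(z)
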