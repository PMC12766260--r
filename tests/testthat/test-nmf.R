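# zone matrix built directly for factorization tests
zm_of <- function(X, mz = seq_len(ncol(X))) {
  structure(list(matrix = X, feature_mz = mz,
                 zone_bounds = data.frame(lo = seq_len(nrow(X)) - 1,
                                          hi = seq_len(nrow(X))),
                 zone_width = 1L, depth_axis = "x", pixel_pitch_um = 150),
            class = "zone_matrix")
}

test_that("zone averages include zeros and match brute force", {
  px <- data.frame(x = 0:3, y = 0L)
  m <- matrix(c(0, 4, 2, 2), 4, 1)
  zm <- zone_average(msi_features(m, 500, px), zone_width = 2)
  expect_equal(as.numeric(zm$matrix), c(2, 2))
  # constant table
  zc <- zone_average(msi_features(matrix(3, 4, 2), c(300, 400), px), 2)
  expect_true(all(zc$matrix == 3))
  # random table vs explicit loop
  t0 <- random_table(35, 4, 7, seed = 6)
  zr <- zone_average(t0, 10)
  d <- t0$pixels$x
  for (f in 1:7) for (z in unique(floor(d / 10))) {
    expect_equal(unname(zr$matrix[z + 1, f]),
                 mean(t0$matrix[floor(d / 10) == z, f]))
  }
})

test_that("maxabs scaling maps every non-zero column onto [0, 1] with max 1", {
  X <- cbind(c(1, 2, 4), c(0, 0, 0), c(5, 1, 2))
  out <- maxabs_scale(zm_of(X))
  expect_equal(out$zm$matrix[, 1], c(0.25, 0.5, 1))
  expect_equal(out$zm$matrix[, 2], c(0, 0, 0))
  expect_equal(out$zero_features, c(FALSE, TRUE, FALSE))
  expect_true(all(apply(out$zm$matrix[, !out$zero_features], 2, max) == 1))
  expect_equal(out$scale, c(4, 1, 5))
})

test_that("an exact rank-3 matrix selects k = 3 with near-zero error", {
  set.seed(99)
  W <- matrix(runif(20 * 3), 20, 3)
  H <- matrix(runif(3 * 50), 3, 50)
  sel <- select_n_components(zm_of(W %*% H), k_max = 6, delta_tol = 0.0015,
                             seed = 1)
  expect_equal(sel$k, 3L)
  expect_lt(sel$error_trace[3], 1e-6)
  expect_true(sel$stabilized)
})

test_that("a rank-1 matrix selects a single component", {
  X <- outer(1:6, c(2, 1, 3))
  sel <- select_n_components(zm_of(X), k_max = 3, delta_tol = 0.0015,
                             seed = 2)
  expect_equal(sel$k, 1L)
  expect_lt(sel$error_trace[1], 1e-10)
})

test_that("the error trace is non-increasing in k on random matrices", {
  for (seed in c(10, 20, 30)) {
    set.seed(seed)
    X <- matrix(rlnorm(15 * 25), 15, 25)
    sel <- suppressWarnings(select_n_components(zm_of(X), k_max = 6,
                                                delta_tol = 1e-6,
                                                seed = seed))
    expect_true(all(diff(sel$error_trace) <= 1e-9))
  }
})

test_that("k_max beyond the matrix rank bound is capped with a warning", {
  X <- matrix(runif(12), 3, 4)
  expect_warning(
    withCallingHandlers(
      sel <- select_n_components(zm_of(X), k_max = 10, seed = 1),
      warning = function(w) {
        if (grepl("never stabilised", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }),
    "capped")
  expect_lte(length(sel$error_trace), 3L)
})

test_that("planted factorizations are recovered to small error", {
  set.seed(12)
  W <- matrix(runif(18 * 4), 18, 4)
  H <- matrix(runif(4 * 30), 4, 30)
  model <- fit_nmf(zm_of(W %*% H), 4, seed = 3)
  expect_lt(model$error_trace[4], 1e-4)
  expect_true(all(model$spatial >= 0))
  expect_true(all(model$contributions >= 0))
})

test_that("k = 1 on a constant matrix reconstructs exactly", {
  model <- fit_nmf(zm_of(matrix(5, 6, 7)), 1, seed = 1)
  expect_lt(model$error_trace[1], 1e-10)
})

test_that("identical seeds give bit-identical factors", {
  set.seed(44)
  X <- matrix(rlnorm(12 * 20), 12, 20)
  m1 <- fit_nmf(zm_of(X), 3, seed = 9)
  m2 <- fit_nmf(zm_of(X), 3, seed = 9)
  expect_identical(m1$spatial, m2$spatial)
  expect_identical(m1$contributions, m2$contributions)
  expect_identical(m1$error_trace, m2$error_trace)
})

test_that("the recorded error matches a recomputation from the factors", {
  set.seed(45)
  X <- matrix(rlnorm(10 * 16), 10, 16)
  model <- fit_nmf(zm_of(X), 3, seed = 5)
  recomputed <- norm(X - model$spatial %*% model$contributions, "F") /
    norm(X, "F")
  expect_equal(recomputed, model$error_trace[3], tolerance = 1e-10)
})

test_that("the model is invariant to pre-scaling of any feature column", {
  set.seed(46)
  X <- matrix(rlnorm(10 * 8), 10, 8)
  X2 <- X; X2[, 3] <- X2[, 3] * 77
  m1 <- fit_nmf(maxabs_scale(zm_of(X))$zm, 2, seed = 6)
  m2 <- fit_nmf(maxabs_scale(zm_of(X2))$zm, 2, seed = 6)
  expect_equal(m1$spatial, m2$spatial, tolerance = 1e-12)
  expect_equal(m1$contributions, m2$contributions, tolerance = 1e-12)
})

test_that("top_features ranks by contribution with low-m/z tie-breaks", {
  model <- structure(list(n_components = 1L,
                          contributions = matrix(c(0.1, 0.9, 0.5), 1),
                          feature_mz = c(300, 400, 500)),
                     class = "fingerprint_model")
  tf <- top_features(model, 1, 2)
  expect_equal(tf$feature, c(2L, 3L))
  expect_equal(nrow(top_features(model, 1, 0)), 0L)
  expect_equal(nrow(top_features(model, 1, 99)), 3L)
  tied <- structure(list(n_components = 1L,
                         contributions = matrix(c(0.5, 0.5, 0.1), 1),
                         feature_mz = c(400, 300, 500)),
                    class = "fingerprint_model")
  expect_equal(top_features(tied, 1, 2)$mz, c(300, 400))
  expect_error(top_features(model, 2, 1), "out of range")
})
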