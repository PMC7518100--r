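test_that("log_prox branches, continuity at the threshold, and parameter guards", {
  expect_identical(log_prox(0.5, lam = 1, a = 0.5), 0)
  # the two branches meet continuously at |y| = lam for any valid (lam, a)
  for (lam in c(0.3, 1, 4)) for (a in c(1e-6, 0.2 / lam, 0.9 / lam)) {
    expect_equal(log_prox(lam, lam, a), 0, tolerance = 1e-9)
    expect_equal(log_prox(lam + 1e-9, lam, a), 0, tolerance = 1e-4)
  }
  expect_error(log_prox(1, lam = 1, a = 1.5), "convexity")
  expect_error(log_prox(1, lam = 1, a = -1), "positive")
  expect_error(log_prox(1, lam = -1, a = 0.5), "positive")
})

test_that("log_prox agrees with grid minimization of the proximal objective", {
  # frozen spot check, computed with oracle_prox_grid(2, 1, 0.4, step = 1e-6)
  expect_equal(log_prox(2.0, lam = 1, a = 0.4), 1.3507810, tolerance = 1e-4)
  set.seed(42)
  for (i in 1:50) {
    lam <- runif(1, 0.2, 2)
    a <- runif(1, 0.05, 0.95) / lam
    y <- runif(1, 0, 4)
    expect_equal(log_prox(y, lam, a), oracle_prox_grid(y, lam, a),
                 tolerance = 1e-4)
  }
})

test_that("log_prox obeys the sandwich, monotonicity and oddness properties", {
  y <- seq(-6, 6, by = 0.01)
  for (lam in c(0.5, 1, 2)) {
    a <- 0.5 / lam
    th <- log_prox(y, lam, a)
    expect_true(all(abs(th) <= abs(y) + 1e-12))
    expect_true(all(abs(th) >= pmax(abs(y) - lam, 0) - 1e-12))
    expect_true(all(diff(th[y >= 0]) >= -1e-12))
    expect_equal(th, -rev(th), tolerance = 1e-12)
  }
})

test_that("log_prox tends to the soft threshold as a -> 0", {
  expect_equal(log_prox(3, lam = 1, a = 1e-8), 2, tolerance = 1e-6)
  y <- seq(-5, 5, by = 0.1)
  expect_equal(log_prox(y, 1, 1e-10), sign(y) * pmax(abs(y) - 1, 0),
               tolerance = 1e-6)
})

test_that("soft_threshold implements the convex baseline", {
  expect_identical(soft_threshold(c(3, 1, 0.2), 1), c(2, 0, 0))
  d <- c(5, 2, 0.5)
  expect_identical(soft_threshold(d, 0), d)
  expect_error(soft_threshold(c(1, NA), 1), "finite")
})

test_that("shrink_spectrum counts surviving values with a floor of 1", {
  pr <- shrinkage_params(lam = 1)
  expect_identical(shrink_spectrum(c(0, 0, 0), pr),
                   list(values = c(0, 0, 0), rank = 1L))
  out <- shrink_spectrum(c(10, 0.5, 0.1), shrinkage_params(1, 0.4))
  expect_identical(out$rank, 1L)
  expect_identical(out$values[2:3], c(0, 0))
  expect_error(shrink_spectrum(c(1, 2), pr), "nonincreasing")
  expect_error(shrink_spectrum(c(2, -1), pr), "nonnegative")
  # rank equals an element-by-element count of positive shrunk values
  set.seed(9)
  for (i in 1:200) {
    delta <- sort(rexp(8, 1 / 2), decreasing = TRUE)
    lam <- runif(1, 0.1, 3)
    pr <- shrinkage_params(lam)
    out <- shrink_spectrum(delta, pr)
    manual <- max(1L, sum(vapply(delta, log_prox, 0, lam = lam, a = pr$a) > 0))
    expect_identical(out$rank, manual)
    expect_false(is.unsorted(rev(out$values)))
  }
})

test_that("shrinkage_params enforces the strict-convexity region", {
  expect_error(shrinkage_params(lam = 2, a = 0.5), "convexity")
  expect_error(shrinkage_params(lam = 0), "positive")
  pr <- shrinkage_params(lam = 2)
  expect_equal(pr$a * pr$lam, 0.5)
})

test_that("estimate_truncation recovers noiseless multilinear ranks", {
  dims <- c(4, 4, 4, 8)
  ranks <- c(2L, 2L, 2L, 1L)
  x <- rand_lowrank_tensor(dims, ranks, seed = 10)
  dmin <- min_mode_sv(x, ranks)
  f <- estimate_truncation(x, shrinkage_params(lam = dmin / 2))
  expect_identical(f$ranks, ranks)
  # threshold above every leading singular value floors all ranks to 1
  dmax <- max(vapply(f$spectra, max, 0))
  f1 <- estimate_truncation(x, shrinkage_params(lam = 2 * dmax))
  expect_identical(f1$ranks, c(1L, 1L, 1L, 1L))
  for (n in 1:4) expect_identical(length(f1$spectra[[n]]), dim(x)[n])
})

test_that("denoise_group is an orthogonal projection", {
  x <- rand_tensor(c(4, 4, 4, 8), seed = 11)
  dmin <- min(vapply(1:4, function(n) min(svd(unfold(x, n))$d), 0))
  # no truncation: projection onto the full space is the identity
  xh <- denoise_group(x, shrinkage_params(lam = dmin / 2))
  expect_lt(sqrt(sum((xh - x)^2)) / sqrt(sum(x^2)), 1e-10)
  # Pythagoras + contractivity for arbitrary thresholds
  for (lam in c(1, 5, 20)) {
    xh <- denoise_group(x, shrinkage_params(lam))
    lhs <- sum(x^2)
    rhs <- sum(xh^2) + sum((x - xh)^2)
    expect_lt(abs(lhs - rhs) / lhs, 1e-8)
    expect_lte(sum(xh^2), sum(x^2) * (1 + 1e-12))
  }
  # noiseless low-rank group is reproduced exactly
  xl <- rand_lowrank_tensor(c(4, 4, 4, 8), c(2, 2, 2, 2), seed = 12)
  lam <- min_mode_sv(xl, c(2, 2, 2, 2)) / 2
  expect_equal(denoise_group(xl, shrinkage_params(lam)), xl, tolerance = 1e-9)
})
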