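test_that("f_update collapses to the data split for an identity blur", {
  n <- 6
  set.seed(31)
  x1 <- matrix(rnorm(n * n), n)
  w1 <- matrix(rnorm(n * n), n)
  zg <- structure(list(horizontal = matrix(0, n, n),
                       vertical = matrix(0, n, n)), class = "gradient_field")
  zc <- structure(setNames(replicate(4, matrix(0, n, n), simplify = FALSE),
                           c("c11", "c12", "c21", "c22")),
                  class = "curvature_field")
  ts <- transfer_set(identity_kernel(), n, c(2, 0, 0))
  f <- f_update(x1, zg, zc, w1, zg, zc, ts)
  expect_equal(f, x1 + w1 / 2, tolerance = 1e-12)
})

test_that("constant split fields produce a constant image", {
  n <- 8
  ones <- matrix(1, n, n)
  cg <- structure(list(horizontal = ones * 0.3, vertical = ones * 0.3),
                  class = "gradient_field")
  cc <- structure(setNames(replicate(4, ones * 0.1, simplify = FALSE),
                           c("c11", "c12", "c21", "c22")),
                  class = "curvature_field")
  ts <- transfer_set(make_gaussian_kernel(3, 1), n, c(1, 1, 1))
  f <- f_update(ones * 2, cg, cc, ones * 0.5, cg, cc, ts)
  expect_lt(diff(range(f)), 1e-12)
})

test_that("FFT image update solves the dense normal equation", {
  set.seed(32)
  n <- 8
  kern <- make_gaussian_kernel(3, 1)
  delta <- c(0.5, 1.2, 0.3)
  ts <- transfer_set(kern, n, delta)
  x1 <- matrix(rnorm(n * n), n); w1 <- matrix(rnorm(n * n), n)
  x2 <- random_gradient_field(n); w2 <- random_gradient_field(n)
  x3 <- random_curvature_field(n); w3 <- random_curvature_field(n)
  f <- f_update(x1, x2, x3, w1, w2, w3, ts)

  H <- dense_operator(function(x) apply_blur(x, kern), n)
  G <- dense_operator(function(x) unclass(forward_diff(x)), n, 2L)
  S <- dense_operator(function(x) unclass(second_order_diff(x)), n, 4L)
  A <- delta[1] * crossprod(H) + delta[2] * crossprod(G) +
    delta[3] * crossprod(S)
  rhs <- delta[1] * t(H) %*% (as.vector(x1) + as.vector(w1) / delta[1]) +
    delta[2] * t(G) %*% (unlist(x2) + unlist(w2) / delta[2]) +
    delta[3] * t(S) %*% (unlist(x3) + unlist(w3) / delta[3])
  resid <- sqrt(sum((A %*% as.vector(f) - rhs)^2)) / sqrt(sum(rhs^2))
  expect_lt(resid, 1e-8)
})

test_that("multiplier update adds delta-weighted residuals", {
  n <- 6
  set.seed(33)
  f <- matrix(runif(n * n), n)
  ts <- transfer_set(make_gaussian_kernel(3, 1), n, c(0.4, 0.7, 0.2))
  exact <- list(f = f, x1 = apply_blur(f, ts), x2 = forward_diff(f),
                x3 = second_order_diff(f),
                w1 = matrix(1, n, n), w2 = random_gradient_field(n),
                w3 = random_curvature_field(n))
  out <- multiplier_update(exact, ts)
  expect_equal(out$w1, exact$w1, tolerance = 1e-12)
  expect_equal(out$w2, exact$w2, tolerance = 1e-12)
  expect_equal(out$w3, exact$w3, tolerance = 1e-12)

  off <- exact
  off$x1 <- exact$x1 + 2        # known residual r = 2
  off$w1 <- matrix(0, n, n)
  out2 <- multiplier_update(off, ts)
  expect_equal(out2$w1, matrix(0.4 * 2, n, n), tolerance = 1e-12)
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(solver_params(lam = 1, eta = 1, delta = c(0, 1, 1)), "delta")
  expect_error(solver_params(lam = 1, eta = 1, delta = c(1, 1, 1), p = 1), "p")
  expect_error(solver_params(lam = -1, eta = 1, delta = c(1, 1, 1)), "lam")
  expect_error(solver_params(lam = 1, eta = -1, delta = c(1, 1, 1)), "eta")
})

test_that("published presets are reproduced exactly", {
  for (mf in c(100, 200, 300, 350)) {
    pd <- default_params("denoise", mf)
    expect_identical(pd$p, 0.1)
    expect_identical(pd$K, 3L)
    expect_identical(pd$n_in, 5L)
    expect_identical(pd$n_out, 50L)
    expect_identical(pd$eps_tol, 1e-3)
    expect_identical(pd$lam, 3 * mf)
    expect_identical(pd$delta, c(5e-3, 3e-2, 2e-4))
  }
  expect_identical(default_params("deblur", 350, "gaussian")$delta,
                   c(0.01, 0.1, 0.01))
  eta_tab <- list(gaussian = c(`350` = 18, `300` = 14, `200` = 6, `100` = 2),
                  motion = c(`350` = 8, `300` = 6, `200` = 4, `100` = 1),
                  custom = c(`350` = 4, `300` = 3, `200` = 2, `100` = 0.2))
  for (bt in names(eta_tab)) {
    for (mf in names(eta_tab[[bt]])) {
      expect_identical(default_params("deblur", as.numeric(mf), bt)$eta,
                       unname(eta_tab[[bt]][mf]))
    }
  }
  # interpolation between printed peaks, flat outside
  expect_equal(default_params("deblur", 250, "gaussian")$eta, 10)
  expect_identical(default_params("deblur", 50, "motion")$eta, 1)
  expect_identical(default_params("deblur", 500, "motion")$eta, 8)
  expect_error(default_params("deblur", 100, "box"))
})

test_that("restoration is deterministic and honours the stopping contract", {
  f <- make_phantom(32, "disks", 7)
  g <- degrade(f, degradation_spec(60, make_gaussian_kernel(5, 1), 7))
  params <- default_params("deblur", 60, "gaussian")
  r1 <- restore(unclass(g), make_gaussian_kernel(5, 1), params)
  r2 <- restore(unclass(g), make_gaussian_kernel(5, 1), params)
  expect_identical(r1$relerr_history, r2$relerr_history)
  expect_false(any(is.na(r1$relerr_history)))
  expect_true(all(is.finite(r1$history$objective)))
  last <- r1$relerr_history[r1$iterations]
  expect_true(last < params$eps_tol || r1$iterations == params$n_out)
  expect_error(restore(matrix(0, 16, 16), identity_kernel(), params), "zero")
})

test_that("a dominant fidelity weight pins the estimate to the observation", {
  set.seed(34)
  g <- matrix(rpois(24 * 24, 50), 24) * 1.0
  params <- solver_params(lam = 1e8, eta = 0.1, delta = c(5, 0.5, 0.1),
                          n_out = 200, eps_tol = 1e-9, max_f = 60)
  res <- restore(g, identity_kernel(), params)
  expect_lt(rel_diff(res$f, g), 1e-2)
})

test_that("row-constant images stay row-constant in the anisotropic limit", {
  n <- 24
  g <- matrix(seq(10, 80, length.out = n), n, n, byrow = TRUE)
  # every row identical (the image varies only along columns); eta = 0, K = 1
  params <- solver_params(lam = 3 * 80, eta = 0, delta = c(5e-3, 3e-2, 2e-4),
                          K = 1, n_out = 20, max_f = 80)
  res <- restore(g, identity_kernel(), params)
  col_spread <- max(apply(res$f, 2, function(cl) diff(range(cl))))
  expect_lt(col_spread, 1e-6)
})

test_that("per-iteration quality logging appears only with ground truth", {
  f <- make_phantom(24, "ramp_blocks", 3)
  g <- degrade(f, degradation_spec(80, identity_kernel(), 3))
  params <- default_params("denoise", 80)
  params$n_out <- 5L
  r0 <- restore(unclass(g), identity_kernel(), params)
  expect_null(r0$history$psnr)
  r1 <- restore(unclass(g), identity_kernel(), params, truth = attr(g, "clean"))
  expect_equal(nrow(r1$history), r1$iterations)
  expect_true(all(c("psnr", "ssim") %in% names(r1$history)))
  expect_true(all(is.finite(r1$history$psnr)))
})
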