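test_that("Sobolev weighting passes DC and attenuates by the closed form", {
  g <- grid2d(32)
  w <- sobolev_weights(g)
  expect_equal(max(w$w), 1)
  expect_equal(w$w[17, 17], 1)  # 0-based (16,16) is the k-space center
  # constant map (delta at k-space center) is unchanged
  ct <- coil_set(g, array(2 + 1i, c(32, 32, 1)), "preconditioned")
  cn <- apply_weighting(ct, w)
  expect_lt(max(abs(cn$values - (2 + 1i))), 1e-12)
  # pure corner frequency attenuated by (1 + a*0.5)^(-b)
  kx <- matrix(0 + 0i, 32, 32); kx[1, 1] <- 1  # khat = (-0.5, -0.5)
  hi <- coil_set(g, array(nlinvpp:::ifft2c(kx), c(32, 32, 1)), "preconditioned")
  out <- apply_weighting(hi, w)
  gain <- sqrt(sum(abs(out$values)^2) / sum(abs(hi$values)^2))
  expect_equal(gain, (1 + 220 * 0.5)^(-16), tolerance = 1e-10)
  # b -> 0 limit: identity
  w0 <- sobolev_weights(g, b = 1e-12)
  set.seed(1)
  x <- coil_set(g, array(rcplx(32 * 32), c(32, 32, 1)), "preconditioned")
  expect_lt(rel_err(apply_weighting(x, w0)$values, x$values), 1e-9)
})

test_that("weighting is linear and the pseudoinverse round-trips smooth maps", {
  g <- grid2d(32)
  w <- sobolev_weights(g)
  set.seed(2)
  a <- array(rcplx(32 * 32 * 2), c(32, 32, 2))
  b <- array(rcplx(32 * 32 * 2), c(32, 32, 2))
  ca <- coil_set(g, a, "preconditioned"); cb <- coil_set(g, b, "preconditioned")
  lin <- apply_weighting(coil_set(g, 2 * a + (1 - 3i) * b, "preconditioned"), w)
  expect_lt(rel_err(lin$values,
                    2 * apply_weighting(ca, w)$values +
                      (1 - 3i) * apply_weighting(cb, w)$values), 1e-12)
  # constant map round trip: error bounded by eps
  const <- coil_set(g, array(1 + 0i, c(32, 32, 1)), "natural")
  rt <- apply_weighting(apply_weighting_pinv(const, w), w)
  expect_lt(rel_err(rt$values, const$values), 2 * w$eps)
  # spectrum confined to w >= 0.1: relative error <= eps / 0.01
  keep <- w$w >= 0.1
  set.seed(4)
  spec <- matrix(rcplx(32 * 32), 32) * keep
  sm <- coil_set(g, array(nlinvpp:::ifft2c(spec), c(32, 32, 1)), "natural")
  rt2 <- apply_weighting(apply_weighting_pinv(sm, w), w)
  expect_lt(rel_err(rt2$values, sm$values), w$eps / 0.01)
})

test_that("forward model masks and reduces to the FFT in the trivial case", {
  g <- grid2d(16)
  w <- sobolev_weights(g)
  pat <- make_pattern(g, 2, 2, 3)
  rho <- complex_image(g, matrix(1 + 0i, 16, 16))
  ct <- coil_set(g, array(1 + 0i, c(16, 16, 1)), "preconditioned")
  y <- forward_model(rho, ct, pat, w)
  expect_true(all(y$values[, , 1][pat$mask == 0] == 0))
  # full mask, c == 1: delta at the k-space center of height sqrt(N)
  yf <- forward_model(rho, ct, make_pattern(g, 1, 1, 0), w)
  expect_equal(abs(yf$values[9, 9, 1]), 16, tolerance = 1e-10)
  expect_lt(sum(abs(yf$values)^2) - abs(yf$values[9, 9, 1])^2, 1e-16)
})

test_that("derivative matches finite differences at second order", {
  g <- grid2d(16)
  w <- sobolev_weights(g)
  pat <- make_pattern(g, 1, 1, 0)
  set.seed(5)
  mk <- function() list(
    rho = complex_image(g, matrix(rcplx(256), 16)),
    ctilde = coil_set(g, array(rcplx(256 * 2), c(16, 16, 2)), "preconditioned"))
  x <- mk(); dx <- mk()
  f0 <- forward_model(x$rho, x$ctilde, pat, w)$values
  dfa <- nlinv_derivative(x, dx, pat, w)$values
  errs <- sapply(c(1e-2, 1e-3), function(h) {
    xh <- list(rho = complex_image(g, x$rho$values + h * dx$rho$values),
               ctilde = coil_set(g, x$ctilde$values + h * dx$ctilde$values,
                                 "preconditioned"))
    fh <- forward_model(xh$rho, xh$ctilde, pat, w)$values
    sqrt(sum(abs(fh - f0 - h * dfa)^2)) / h
  })
  # O(h^2) remainder: error/h shrinks linearly in h
  expect_lt(errs[2] / errs[1], 0.15)
  # dx = 0 maps to 0
  z <- list(rho = complex_image(g, matrix(0 + 0i, 16, 16)),
            ctilde = coil_set(g, array(0 + 0i, c(16, 16, 2)), "preconditioned"))
  expect_true(all(nlinv_derivative(x, z, pat, w)$values == 0))
})

test_that("adjoint identity holds across grid sizes and coil counts", {
  for (n in c(8, 16, 64)) for (nc in c(1, 2, 8)) {
    g <- grid2d(n)
    w <- sobolev_weights(g)
    pat <- make_pattern(g, 2, 1, min(3, n))
    set.seed(n + nc)
    x <- list(rho = complex_image(g, matrix(rcplx(n * n), n)),
              ctilde = coil_set(g, array(rcplx(n * n * nc), c(n, n, nc)),
                                "preconditioned"))
    dx <- list(rho = complex_image(g, matrix(rcplx(n * n), n)),
               ctilde = coil_set(g, array(rcplx(n * n * nc), c(n, n, nc)),
                                 "preconditioned"))
    dy <- kspace_data(g, array(rcplx(n * n * nc), c(n, n, nc)), pat)
    lhs <- sum(nlinv_derivative(x, dx, pat, w)$values * Conj(dy$values))
    adj <- nlinv_adjoint(x, dy, pat, w)
    rhs <- sum(dx$rho$values * Conj(adj$rho$values)) +
      sum(dx$ctilde$values * Conj(adj$ctilde$values))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
    # off-mask residual contributes nothing
    dy0 <- dy
    dy0$values <- dy$values * 0
    off <- nlinv_adjoint(dy = dy0, x = x, pattern = pat, weights = w)
    expect_equal(sum(abs(off$rho$values)), 0)
  }
})

test_that("coil interpolation reproduces band-limited maps on the fine grid", {
  # coils constructed with spectrum confined to the central 8x8 block, so
  # cropping to 32x32 and zero-padding back is lossless
  g <- grid2d(64)
  set.seed(9)
  vals <- array(0 + 0i, c(64, 64, 3))
  for (i in 1:3) {
    k <- matrix(0 + 0i, 64, 64)
    k[30:37, 30:37] <- matrix(rcplx(64), 8)
    vals[, , i] <- nlinvpp:::ifft2c(k)
  }
  coils <- coil_set(g, vals, "natural")
  gs <- grid2d(32)
  cs <- array(0 + 0i, c(32, 32, 3))
  for (i in 1:3) {
    k <- nlinvpp:::fft2c(coils$values[, , i])
    cs[, , i] <- nlinvpp:::ifft2c(k[17:48, 17:48]) * sqrt(32 * 32 / (64 * 64))
  }
  up <- interpolate_coils(coil_set(gs, cs, "natural"), g)
  expect_lt(rel_err(up$values, coils$values), 1e-10)
})
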