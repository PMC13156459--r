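test_that("phase vortex has unit magnitude and the defining values", {
  g <- grid2d(64)
  # place the center exactly on a pixel center
  r0 <- as.vector(pixel_to_position(g, 40, 24))
  th <- phase_vortex(g, r0, 1)
  expect_lt(max(abs(abs(th$values) - 1)), 1e-12)
  # value 1 at r0 + (delta, 0), value i at r0 + (0, delta)
  expect_equal(th$values[44, 25], 1 + 0i, tolerance = 1e-12)
  expect_equal(th$values[41, 28], 0 + 1i, tolerance = 1e-12)
  # winding +-1 around the center, by the brute-force loop oracle
  for (s in c(1, -1)) {
    v <- phase_vortex(g, r0, s)
    cc <- circle_curve(c(40L, 24L), 6, g)
    expect_identical(brute_winding(v$values, cc$points), as.integer(s))
    expect_identical(winding_number(v, cc), as.integer(s))
  }
})

test_that("circle curves are closed, bounded and flagged at the boundary", {
  g <- grid2d(64)
  cc <- circle_curve(c(32L, 32L), 4, g)
  expect_false(cc$clipped)
  expect_gte(nrow(cc$points), 8)
  expect_true(all(abs(cc$points[, 1] - 32) <= 3))
  expect_true(all(abs(cc$points[, 2] - 32) <= 3))
  # no consecutive duplicates (including the wrap-around pair)
  p <- rbind(cc$points, cc$points[1, ])
  expect_true(all(rowSums(abs(diff(p))) > 0))
  # boundary-clipped curve is flagged and yields winding 0
  cb <- circle_curve(c(1L, 32L), 6, g)
  expect_true(cb$clipped)
  expect_identical(winding_number(phase_vortex(g, c(-0.48, 0), 1), cb), 0L)
})

test_that("winding numbers follow the discretized loop-sum definition", {
  g <- grid2d(64)
  r0 <- as.vector(pixel_to_position(g, 32, 32))
  v <- phase_vortex(g, r0, 1)
  enclosing <- circle_curve(c(32L, 32L), 5, g)
  expect_identical(winding_number(v, enclosing), 1L)
  # loop not enclosing the singularity
  away <- circle_curve(c(48L, 48L), 5, g)
  expect_identical(winding_number(v, away), 0L)
  # a zero-valued curve point makes the winding number 0 by convention
  vz <- v$values
  vz[cbind(enclosing$points[1, 1] + 1, enclosing$points[1, 2] + 1)] <- 0
  expect_identical(winding_number(vz, enclosing$points), 0L)
  # constant field: 0; conjugated field: negated
  expect_identical(winding_number(matrix(1 + 1i, 64, 64), enclosing$points), 0L)
  expect_identical(winding_number(Conj(v$values), enclosing$points), -1L)
  # degenerate curve errors
  expect_error(winding_number(v, matrix(c(3L, 3L), 1)), "closed")
})

test_that("vectorized winding maps agree with the per-pixel oracle", {
  g <- grid2d(32)
  coils <- make_coils(g, coil_layout(2, style = "dipole",
                                     dipole_positions = rbind(c(-0.1, 0.1),
                                                              c(0.2, -0.15))))
  cfg <- detect_config(d = 0.15)
  pm <- coil_winding_maps(coils, cfg)
  offs <- nlinvpp:::detection_offsets(g, cfg)
  for (i in 1:2) for (cx in seq(4L, 28L, 4L)) for (cy in seq(4L, 28L, 4L)) {
    pts <- cbind(cx + offs[, 1], cy + offs[, 2])
    expected <- if (any(pts < 0) || any(pts >= 32)) 0L
      else brute_winding(coils$values[, , i], pts)
    expect_identical(as.integer(pm$S[cx + 1, cy + 1, i]), expected)
  }
})

test_that("weighted consensus keeps shared poles and suppresses lone ones", {
  g <- grid2d(64)
  rho <- make_phantom(g)
  coils <- make_coils(g, coil_layout(8))
  r0 <- c(0.08, -0.05)
  # shared conjugate pole: consensus magnitude ~1, detected with + sign
  pp <- plant_artificial_pole(rho, coils, r0, 1)
  pm <- coil_winding_maps(pp$coils)
  expect_equal(max(abs(pm$Sbar)), 1)
  det <- detect_poles(pm)
  expect_equal(det$M, 1L)
  expect_lt(sqrt((det$poles$x - r0[1])^2 + (det$poles$y - r0[2])^2), 0.025)
  expect_equal(det$poles$sign, 1L)
  # pole in one of eight comparable-magnitude coils: bounded by 1/8
  eq <- coil_set(g, array(rep(exp(1i * 0.3), 64 * 64 * 8), c(64, 64, 8)),
                 "natural")
  v <- eq$values
  v[, , 1] <- v[, , 1] * Conj(phase_vortex(g, r0, 1)$values)
  lone <- coil_set(g, v, "natural")
  pml <- coil_winding_maps(lone)
  expect_lte(max(abs(pml$Sbar)), 1 / 8 + 1e-12)
  expect_equal(detect_poles(pml)$M, 0L)
  # all-zero coils: consensus identically zero
  z <- coil_set(g, array(0 + 0i, c(64, 64, 2)), "natural")
  expect_true(all(coil_winding_maps(z)$Sbar == 0))
})

test_that("close same-sign components merge through the closing step", {
  g <- grid2d(64)
  cfg <- detect_config()
  sbar <- matrix(0, 64, 64)
  # two super-threshold blobs 2 pixels apart (< d_closing = 3.2 px)
  sbar[30:31, 32] <- -1; sbar[34:35, 32] <- -1
  pm <- structure(list(grid = g, S = NULL, w = NULL, Sbar = sbar, cfg = cfg),
                  class = "pole_map")
  det <- detect_poles(pm, cfg)
  expect_equal(det$M, 1L)
  expect_equal(det$poles$sign, 1L)
  # far-apart blobs stay distinct
  sbar2 <- matrix(0, 64, 64)
  sbar2[20, 32] <- -1; sbar2[44, 32] <- 1
  pm2 <- structure(list(grid = g, Sbar = sbar2, cfg = cfg), class = "pole_map")
  det2 <- detect_poles(pm2, cfg)
  expect_equal(det2$M, 2L)
  expect_setequal(det2$poles$sign, c(1L, -1L))
})

test_that("global phase selection makes the image overlap real positive", {
  g <- grid2d(32)
  rho <- make_phantom(g)
  # constant-phase field maps to the identity
  const <- complex_image(g, matrix(exp(1i * 0.7), 32, 32))
  out <- global_phase(const, rho)
  expect_lt(max(abs(out$values - 1)), 1e-12)
  # generic vortex: defining post-condition, and idempotence
  th <- phase_vortex(g, c(0.1, 0), 1)
  out2 <- global_phase(th, rho)
  ip <- sum(rho$values * Conj(out2$values * rho$values))
  expect_lt(abs(Im(ip)) / abs(ip), 1e-10)
  expect_gt(Re(ip), 0)
  out3 <- global_phase(out2, rho)
  expect_lt(max(abs(out3$values - out2$values)), 1e-10)
  # zero overlap: warning, unchanged
  z <- complex_image(g, matrix(0 + 0i, 32, 32))
  expect_warning(global_phase(th, z), "zero")
})

test_that("correction fields multiply vortices and stay unit magnitude", {
  g <- grid2d(64)
  rho <- make_phantom(g)
  ps <- structure(list(poles = data.frame(x = c(-0.1, 0.15),
                                          y = c(0.05, -0.1),
                                          sign = c(1L, -1L)), M = 2L),
                  class = "pole_set")
  th <- build_correction(ps, g, rho)
  expect_lt(max(abs(abs(th$values) - 1)), 1e-12)
  # winding -sign around each pole, 0 around a loop enclosing both
  p1 <- as.integer(position_to_pixel(g, -0.1, 0.05))
  p2 <- as.integer(position_to_pixel(g, 0.15, -0.1))
  expect_identical(winding_number(th, circle_curve(p1, 4, g)), -1L)
  expect_identical(winding_number(th, circle_curve(p2, 4, g)), 1L)
  mid <- as.integer(round((p1 + p2) / 2))
  expect_identical(winding_number(th, circle_curve(mid, 28, g)), 0L)
  # M = 0 gives the identity field
  none <- structure(list(poles = data.frame(x = numeric(0), y = numeric(0),
                                            sign = integer(0)), M = 0L),
                    class = "pole_set")
  expect_true(all(build_correction(none, g, rho)$values == 1))
})

test_that("applying a correction removes the planted pole from the coils", {
  g <- grid2d(64)
  w <- sobolev_weights(g)
  rho <- make_phantom(g)
  coils <- make_coils(g, coil_layout(8))
  pp <- plant_artificial_pole(rho, coils, c(0.08, -0.05), 1)
  ct <- apply_weighting_pinv(pp$coils, w)
  det <- detect_poles(coil_winding_maps(apply_weighting(ct, w)))
  expect_equal(det$M, 1L)
  th <- build_correction(det, g, pp$rho)
  corr <- apply_correction(pp$rho, ct, th, w)
  det2 <- detect_poles(coil_winding_maps(apply_weighting(corr$ctilde, w)))
  expect_equal(det2$M, 0L)
  # identity correction: image untouched; coils preserved in the natural
  # domain up to the regularized W+W round trip (the preconditioned
  # variables may differ in the strongly damped high frequencies)
  ident <- complex_image(g, matrix(1 + 0i, 64, 64))
  same <- apply_correction(pp$rho, ct, ident, w)
  expect_identical(same$rho$values, pp$rho$values)
  expect_lt(rel_err(apply_weighting(same$ctilde, w)$values,
                    apply_weighting(ct, w)$values), 0.05)
})

test_that("external coil stacks are corrected with exact product preservation", {
  g <- grid2d(64)
  rho <- make_phantom(g)
  coils <- make_coils(g, coil_layout(6))
  # pole-free stack: identity
  out0 <- correct_external_coils(coils, rho)
  expect_equal(out0$poles$M, 0L)
  expect_identical(out0$coils$values, coils$values)
  # common pole at the same pixel in all coils, conjugate in the image
  r0 <- as.vector(pixel_to_position(g, 40, 28))
  pp <- plant_artificial_pole(rho, coils, r0, 1)
  cfg <- detect_config(external_mode = TRUE)
  pm <- coil_winding_maps(pp$coils, cfg)
  expect_equal(max(abs(pm$Sbar)), 1)
  out <- correct_external_coils(pp$coils, pp$rho, cfg)
  expect_equal(out$poles$M, 1L)
  expect_equal(out$poles$poles$sign, 1L)
  pm2 <- coil_winding_maps(out$coils, cfg)
  expect_equal(detect_poles(pm2, cfg)$M, 0L)
  # pointwise products preserved exactly (no weighting pseudoinverse here)
  before <- product_array(pp$rho, pp$coils)
  after <- product_array(out$combined, out$coils)
  expect_lt(max(abs(after - before)), 1e-12)
})

test_that("repeated correction clears same-sign double poles", {
  g <- grid2d(64)
  rho <- make_phantom(g)
  coils <- make_coils(g, coil_layout(8))
  p1 <- plant_artificial_pole(rho, coils, c(0.05, 0), 1)
  p2 <- plant_artificial_pole(p1$rho, p1$coils, c(0.12, 0), 1)
  w <- sobolev_weights(g)
  ct <- apply_weighting_pinv(p2$coils, w)
  rho_c <- p2$rho
  for (round in 1:2) {
    det <- detect_poles(coil_winding_maps(apply_weighting(ct, w)))
    if (det$M == 0) break
    th <- build_correction(det, g, rho_c)
    corr <- apply_correction(rho_c, ct, th, w)
    rho_c <- corr$rho; ct <- corr$ctilde
  }
  final <- detect_poles(coil_winding_maps(apply_weighting(ct, w)))
  expect_equal(final$M, 0L)
})
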