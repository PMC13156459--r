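# NLINV forward operator, Sobolev weighting and Gauss-Newton linearization.
#
# The coil penalty in the objective is a Sobolev norm, implemented as an
# l2-norm of preconditioned variables ctilde: the natural-domain map is
# c = W ctilde with W the low-pass k-space weighting
#   w(k) = (1 + a |khat|^2)^(-b),   khat in [-0.5, 0.5]^2.
# Penalizing ||ctilde||_2 then penalizes high spatial frequencies of c,
# which is what makes the estimated sensitivities smooth. The inverse
# direction (needed when an externally constructed natural-domain map must
# be pushed into the solver's variables, e.g. after a vortex
# multiplication) uses a regularized pseudoinverse w/(w^2 + eps) so that
# division by the tiny high-frequency weights cannot amplify noise by more
# than 1/(2 sqrt(eps)).

#' Sobolev k-space weights
#'
#' @param grid a \code{\link{grid2d}}
#' @param a curvature parameter of the weight (default 220)
#' @param b decay exponent (default 16)
#' @param eps regularizer of the pseudoinverse (default 1e-6)
#' @return object of class \code{sobolev_weights} with the weight matrix
#'   \code{w} over centered k-space (\code{w(0) = 1}, maximal at DC)
#' @export
sobolev_weights <- function(grid, a = 220, b = 16, eps = 1e-6) {
  kx <- (seq_len(grid$nx) - 1 - floor(grid$nx / 2)) / grid$nx
  ky <- (seq_len(grid$ny) - 1 - floor(grid$ny / 2)) / grid$ny
  k2 <- outer(kx^2, ky^2, `+`)
  structure(list(grid = grid, a = a, b = b, eps = eps,
                 w = (1 + a * k2)^(-b)), class = "sobolev_weights")
}

# internal: act on a bare complex matrix
weight_apply_mat <- function(m, weights) ifft2c(weights$w * fft2c(m))

weight_pinv_mat <- function(m, weights) {
  wp <- weights$w / (weights$w^2 + weights$eps)
  ifft2c(wp * fft2c(m))
}

#' Map preconditioned coils to natural domain
#'
#' Computes \code{c = IFFT(w * FFT(ctilde))} per coil (linear, low-pass).
#'
#' @param ctilde a preconditioned-domain \code{\link{coil_set}}
#' @param weights a \code{\link{sobolev_weights}} on the same grid
#' @return a natural-domain \code{\link{coil_set}}
#' @export
apply_weighting <- function(ctilde, weights) {
  stopifnot_domain(ctilde, "preconditioned")
  if (!same_grid(ctilde$grid, weights$grid)) stop("grid mismatch")
  vals <- ctilde$values
  for (i in seq_len(ctilde$nc)) vals[, , i] <- weight_apply_mat(vals[, , i], weights)
  coil_set(ctilde$grid, vals, "natural")
}

#' Map natural-domain coils to preconditioned domain
#'
#' Regularized pseudoinverse of \code{\link{apply_weighting}}:
#' \code{ctilde = IFFT(w/(w^2 + eps) * FFT(c))}. For maps whose spectrum is
#' confined to frequencies with \code{w >= w0}, the round trip
#' \code{apply_weighting(apply_weighting_pinv(c))} recovers \code{c} with
#' relative error at most \code{eps / w0^2}.
#'
#' @param c a natural-domain \code{\link{coil_set}}
#' @param weights a \code{\link{sobolev_weights}} on the same grid
#' @return a preconditioned-domain \code{\link{coil_set}}
#' @export
apply_weighting_pinv <- function(c, weights) {
  stopifnot_domain(c, "natural")
  if (!same_grid(c$grid, weights$grid)) stop("grid mismatch")
  vals <- c$values
  for (i in seq_len(c$nc)) vals[, , i] <- weight_pinv_mat(vals[, , i], weights)
  coil_set(c$grid, vals, "preconditioned")
}

#' Preconditioned NLINV forward model
#'
#' \eqn{\tilde F(\rho, \tilde c) = P\,F(W\tilde c \odot \rho)}: the masked
#' centered unitary FFT of each coil image.
#'
#' @param rho a \code{\link{complex_image}}
#' @param ctilde a preconditioned \code{\link{coil_set}}
#' @param pattern a \code{\link{sampling_pattern}}
#' @param weights a \code{\link{sobolev_weights}}
#' @return a \code{\link{kspace_data}}
#' @export
forward_model <- function(rho, ctilde, pattern, weights) {
  c_nat <- apply_weighting(ctilde, weights)
  forward_from_natural(rho$values, c_nat$values, pattern)
}

# internal fast paths on bare arrays ----------------------------------------

forward_from_natural <- function(rho_m, c_arr, pattern) {
  nc <- dim(c_arr)[3]
  vals <- array(0 + 0i, dim(c_arr))
  for (i in seq_len(nc)) vals[, , i] <- fft2c(c_arr[, , i] * rho_m) * pattern$mask
  kspace_data(pattern$grid, vals, pattern)
}

# derivative at base point (rho_m, c_arr = W ctilde) applied to
# (drho_m, dct_arr); returns bare k-space array
deriv_arr <- function(rho_m, c_arr, drho_m, dct_arr, pattern, weights) {
  nc <- dim(c_arr)[3]
  out <- array(0 + 0i, dim(c_arr))
  for (i in seq_len(nc)) {
    dci <- weight_apply_mat(dct_arr[, , i], weights)
    out[, , i] <- fft2c(c_arr[, , i] * drho_m + dci * rho_m) * pattern$mask
  }
  out
}

# adjoint of deriv_arr; takes bare k-space array dy_arr
adjoint_arr <- function(rho_m, c_arr, dy_arr, pattern, weights) {
  nc <- dim(c_arr)[3]
  drho <- matrix(0 + 0i, nrow(rho_m), ncol(rho_m))
  dct <- array(0 + 0i, dim(c_arr))
  rho_cj <- Conj(rho_m)
  for (i in seq_len(nc)) {
    q <- ifft2c(dy_arr[, , i] * pattern$mask)
    drho <- drho + Conj(c_arr[, , i]) * q
    dct[, , i] <- weight_apply_mat(rho_cj * q, weights)  # W is self-adjoint
  }
  list(rho = drho, ctilde = dct)
}

#' Gauss-Newton derivative of the forward model
#'
#' Linearization of \eqn{\tilde F} at \code{x = (rho, ctilde)}:
#' \eqn{D\tilde F[dx] = P\,F(c \odot \delta\rho + W\delta\tilde c \odot \rho)}
#' with \eqn{c = W\tilde c}.
#'
#' @param x list with \code{rho} (\code{\link{complex_image}}) and
#'   \code{ctilde} (preconditioned \code{\link{coil_set}})
#' @param dx perturbation, same structure as \code{x}
#' @param pattern a \code{\link{sampling_pattern}}
#' @param weights a \code{\link{sobolev_weights}}
#' @return a \code{\link{kspace_data}}
#' @export
nlinv_derivative <- function(x, dx, pattern, weights) {
  c_nat <- apply_weighting(x$ctilde, weights)
  out <- deriv_arr(x$rho$values, c_nat$values, dx$rho$values,
                   dx$ctilde$values, pattern, weights)
  kspace_data(pattern$grid, out, pattern)
}

#' Adjoint of the Gauss-Newton derivative
#'
#' Exact adjoint under the canonical complex inner product:
#' \eqn{\langle D\tilde F[dx], dy\rangle = \langle dx, D\tilde F^H[dy]\rangle}
#' for all perturbations and k-space residuals.
#'
#' @inheritParams nlinv_derivative
#' @param dy a \code{\link{kspace_data}} residual
#' @return list with \code{rho} (\code{\link{complex_image}}) and
#'   \code{ctilde} (preconditioned \code{\link{coil_set}})
#' @export
nlinv_adjoint <- function(x, dy, pattern, weights) {
  c_nat <- apply_weighting(x$ctilde, weights)
  a <- adjoint_arr(x$rho$values, c_nat$values, dy$values, pattern, weights)
  list(rho = complex_image(pattern$grid, a$rho),
       ctilde = coil_set(pattern$grid, a$ctilde, "preconditioned"))
}

#' Interpolate coil maps to a finer grid
#'
#' Zero-pads the centered k-space of each map. Valid for the smooth
#' sensitivities NLINV estimates: their spectrum is concentrated at the
#' center, so low-resolution estimation followed by k-space zero-padding
#' reproduces the full-resolution maps without phase-interpolation
#' artifacts. Scaling preserves image-domain amplitude.
#'
#' @param coils a natural-domain \code{\link{coil_set}}
#' @param grid target \code{\link{grid2d}} (at least as large per axis)
#' @return a natural-domain \code{\link{coil_set}} on \code{grid}
#' @export
interpolate_coils <- function(coils, grid) {
  stopifnot_domain(coils, "natural")
  g0 <- coils$grid
  if (grid$nx < g0$nx || grid$ny < g0$ny) stop("target grid must be larger")
  out <- array(0 + 0i, c(grid$nx, grid$ny, coils$nc))
  ox <- floor(grid$nx / 2) - floor(g0$nx / 2)
  oy <- floor(grid$ny / 2) - floor(g0$ny / 2)
  sc <- sqrt((grid$nx * grid$ny) / (g0$nx * g0$ny))
  for (i in seq_len(coils$nc)) {
    k <- fft2c(coils$values[, , i])
    pad <- matrix(0 + 0i, grid$nx, grid$ny)
    pad[ox + seq_len(g0$nx), oy + seq_len(g0$ny)] <- k
    out[, , i] <- ifft2c(pad) * sc
  }
  coil_set(grid, out, "natural")
}
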