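# Synthetic k-space generator.
#
# Produces piecewise-constant ellipse phantoms with a smooth polynomial
# phase, smooth ring-array coil maps, coil maps with a genuine phase
# singularity (the transverse field of a magnetic point dipole), planted
# artificial pole pairs (image pole + conjugate coil poles, data-invariant
# by construction), and noisy undersampled Cartesian k-space.

#' Phantom specification
#'
#' A phantom is a sum of ellipse indicator functions with complex
#' amplitudes, multiplied by a smooth unit-magnitude phase
#' \code{exp(1i * poly(x, y))}. The polynomial is quadratic:
#' \code{phase_poly} holds coefficients \code{(1, x, y, x^2, x*y, y^2)}.
#'
#' @param ellipses list of lists with fields \code{center} (length-2, FoV
#'   units), \code{semi_axes} (length-2, FoV units), \code{rotation}
#'   (radians) and \code{amplitude} (complex)
#' @param phase_poly numeric length-6 coefficient vector
#' @return object of class \code{phantom_spec}
#' @export
phantom_spec <- function(ellipses, phase_poly = numeric(6)) {
  if (length(ellipses) < 1L) stop("need at least one ellipse")
  phase_poly <- c(phase_poly, numeric(6))[1:6]
  structure(list(ellipses = ellipses, phase_poly = phase_poly),
            class = "phantom_spec")
}

#' Default brain-like ellipse phantom
#'
#' One large support ellipse plus two internal structures and a gentle
#' quadratic background phase; covers roughly 40% of the FoV.
#'
#' @export
default_phantom_spec <- function() {
  phantom_spec(
    ellipses = list(
      list(center = c(0, 0), semi_axes = c(0.40, 0.34), rotation = 0.2,
           amplitude = 1 + 0i),
      list(center = c(-0.12, 0.06), semi_axes = c(0.12, 0.09),
           rotation = -0.4, amplitude = 0.5 + 0i),
      list(center = c(0.14, -0.10), semi_axes = c(0.09, 0.07),
           rotation = 0.8, amplitude = 0.3 + 0i)),
    phase_poly = c(0.3, 1.2, -0.8, 2.0, 1.0, -1.5))
}

eval_poly2 <- function(coef, x, y) {
  coef[1] + coef[2] * x + coef[3] * y + coef[4] * x^2 + coef[5] * x * y +
    coef[6] * y^2
}

#' Rasterize a phantom
#'
#' Magnitude is the (complex) sum of ellipse indicators evaluated at pixel
#' centers; phase is a smooth single-valued polynomial, so the phantom has
#' no phase singularity anywhere — as the true image in MRI should not,
#' since its phase is a time-integrated local Larmor frequency.
#'
#' @param grid a \code{\link{grid2d}}
#' @param spec a \code{\link{phantom_spec}}
#' @return a \code{\link{complex_image}}
#' @export
make_phantom <- function(grid, spec = default_phantom_spec()) {
  co <- grid_coords(grid)
  acc <- matrix(0 + 0i, grid$nx, grid$ny)
  for (e in spec$ellipses) {
    dx <- co$x - e$center[1]; dy <- co$y - e$center[2]
    cs <- cos(e$rotation); sn <- sin(e$rotation)
    u <- (cs * dx + sn * dy) / e$semi_axes[1]
    v <- (-sn * dx + cs * dy) / e$semi_axes[2]
    acc <- acc + e$amplitude * (u^2 + v^2 <= 1)
  }
  ph <- eval_poly2(spec$phase_poly, co$x, co$y)
  complex_image(grid, acc * exp(1i * ph))
}

#' Coil array layout
#'
#' \code{style = "gaussian_ring"}: \code{nc} coils with Gaussian magnitude
#' lobes centered on a ring just outside the FoV and a smooth low-order
#' polynomial phase — strictly positive magnitude, no singularities.
#' \code{style = "dipole"}: each coil is the transverse field
#' \eqn{B_x - i B_y} of a magnetic point dipole \eqn{m = m\,\hat e_z}
#' offset from the imaging plane, which carries exactly one in-plane phase
#' singularity (azimuthal phase, vanishing amplitude) at the dipole axis.
#'
#' @param nc number of coils (at least 2)
#' @param style \code{"gaussian_ring"} or \code{"dipole"}
#' @param ring_radius radius of the coil-center ring (FoV units)
#' @param sigma Gaussian lobe width (FoV units, gaussian_ring only)
#' @param dipole_positions optional \code{nc x 2} matrix of in-plane dipole
#'   positions (FoV units, dipole only); defaults to a ring of radius 0.25
#' @param z plane offset of the dipoles (FoV units, dipole only)
#' @return object of class \code{coil_layout}
#' @export
coil_layout <- function(nc, style = c("gaussian_ring", "dipole"),
                        ring_radius = 0.55, sigma = 0.35,
                        dipole_positions = NULL, z = 0.15) {
  style <- match.arg(style)
  nc <- as.integer(nc)
  if (nc < 2L) stop("need at least 2 coils")
  if (style == "dipole" && is.null(dipole_positions)) {
    ang <- 2 * pi * (seq_len(nc) - 1) / nc
    dipole_positions <- cbind(0.25 * cos(ang), 0.25 * sin(ang))
  }
  structure(list(nc = nc, style = style, ring_radius = ring_radius,
                 sigma = sigma, dipole_positions = dipole_positions, z = z),
            class = "coil_layout")
}

#' Generate coil sensitivity maps
#'
#' @param grid a \code{\link{grid2d}}
#' @param layout a \code{\link{coil_layout}}
#' @return a natural-domain \code{\link{coil_set}}
#' @export
make_coils <- function(grid, layout) {
  co <- grid_coords(grid)
  vals <- array(0 + 0i, c(grid$nx, grid$ny, layout$nc))
  for (i in seq_len(layout$nc)) {
    if (layout$style == "gaussian_ring") {
      ang <- 2 * pi * (i - 1) / layout$nc
      cx <- layout$ring_radius * cos(ang); cy <- layout$ring_radius * sin(ang)
      mag <- exp(-((co$x - cx)^2 + (co$y - cy)^2) / (2 * layout$sigma^2))
      # smooth per-coil linear+quadratic phase; deterministic in the index
      ph <- eval_poly2(c(0.5 * i, 2.5 * cos(ang), 2.5 * sin(ang),
                         0.8 * cos(2 * ang), 0.5, 0.8 * sin(2 * ang)),
                       co$x, co$y)
      vals[, , i] <- mag * exp(1i * ph)
    } else {
      p <- layout$dipole_positions[i, ]
      dx <- co$x - p[1]; dy <- co$y - p[2]
      r2 <- dx^2 + dy^2 + layout$z^2
      # transverse dipole field on the plane: Bx - i By = 3 m z (X - iY)/|R|^5
      f <- 3 * layout$z * (dx - 1i * dy) / r2^(5 / 2)
      vals[, , i] <- f / max(abs(f))
    }
  }
  coil_set(grid, vals, domain = "natural")
}

#' Plant an artificial phase-pole pair
#'
#' Multiplies the image by a phase vortex of the given sign at \code{r0}
#' and every coil map by the conjugate vortex. Because the vortex has unit
#' magnitude, the observable products \eqn{c_i \odot \rho} — and hence any
#' simulated k-space — are unchanged up to floating-point rounding. This
#' realizes the inherent scaling ambiguity of the joint estimation problem:
#' a spurious image pole compensated by conjugate coil poles.
#'
#' @param rho a \code{\link{complex_image}}
#' @param coils a natural-domain \code{\link{coil_set}}
#' @param r0 length-2 FoV position of the pole
#' @param sign +1 or -1; the winding number the image acquires around
#'   \code{r0} (the coils acquire the opposite winding)
#' @return list with modified \code{rho} and \code{coils}
#' @export
plant_artificial_pole <- function(rho, coils, r0, sign = 1L) {
  stopifnot_domain(coils, "natural")
  if (any(abs(r0) > 0.5)) stop("pole position outside FoV")
  th <- phase_vortex(rho$grid, r0, sign)
  rho2 <- complex_image(rho$grid, rho$values * th$values)
  vals <- coils$values
  for (i in seq_len(coils$nc)) vals[, , i] <- vals[, , i] * Conj(th$values)
  list(rho = rho2, coils = coil_set(coils$grid, vals, "natural"))
}

#' Cartesian undersampling pattern
#'
#' Regular \code{rx x ry} lattice through the k-space center, plus a fully
#' sampled central auto-calibration block of side \code{ac_size}.
#'
#' @param grid a \code{\link{grid2d}}
#' @param rx,ry acceleration factors along kx and ky (1 = fully sampled)
#' @param ac_size side of the central AC block (0 for none)
#' @return a \code{\link{sampling_pattern}}
#' @export
make_pattern <- function(grid, rx = 1L, ry = 1L, ac_size = 0L) {
  stopifnot(rx >= 1, ry >= 1, ac_size <= min(grid$nx, grid$ny))
  cx <- floor(grid$nx / 2); cy <- floor(grid$ny / 2)   # 0-based center
  keep_x <- ((seq_len(grid$nx) - 1 - cx) %% rx) == 0
  keep_y <- ((seq_len(grid$ny) - 1 - cy) %% ry) == 0
  mask <- outer(keep_x, keep_y) * 1
  if (ac_size > 0L) {
    idx <- ac_block_indices(grid, ac_size)
    mask[idx$ix, idx$iy] <- 1
  }
  sampling_pattern(grid, mask, ac_size)
}

# Evaluate a deterministic RNG block without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate multi-coil k-space
#'
#' Computes the centered unitary FFT of each coil image
#' \eqn{c_i \odot \rho}, adds iid complex Gaussian noise (standard
#' deviation \code{noise_sigma} per real/imaginary component; coils are
#' assumed pre-whitened, so noise is iid across coils), and applies the
#' sampling mask. Masked-out entries are exactly zero.
#'
#' @param rho a \code{\link{complex_image}}
#' @param coils a natural-domain \code{\link{coil_set}}
#' @param pattern a \code{\link{sampling_pattern}}
#' @param noise_sigma noise standard deviation per component
#' @param seed integer seed making the noise reproducible
#' @return a \code{\link{kspace_data}}
#' @export
sample_kspace <- function(rho, coils, pattern, noise_sigma = 0, seed = 1L) {
  stopifnot_domain(coils, "natural")
  stopifnot(same_grid(rho$grid, coils$grid), same_grid(rho$grid, pattern$grid),
            noise_sigma >= 0)
  g <- rho$grid
  vals <- array(0 + 0i, c(g$nx, g$ny, coils$nc))
  noise <- if (noise_sigma > 0) {
    with_seed(seed, {
      n <- g$nx * g$ny * coils$nc
      array(complex(real = stats::rnorm(n, sd = noise_sigma),
                    imaginary = stats::rnorm(n, sd = noise_sigma)),
            c(g$nx, g$ny, coils$nc))
    })
  } else NULL
  for (i in seq_len(coils$nc)) {
    y <- fft2c(coils$values[, , i] * rho$values)
    if (!is.null(noise)) y <- y + noise[, , i]
    vals[, , i] <- y * pattern$mask
  }
  kspace_data(g, vals, pattern)
}
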