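# Phase-pole detection and correction.
#
# A phase pole is a point where the phase of a complex field is undefined
# and a closed loop around it accumulates a nonzero multiple of 2*pi of
# phase — equivalently, the field's values along the loop wind around the
# complex origin a nonzero (integer) number of times. Joint image/coil
# estimation is only determined up to a complex scaling field, so the
# solver can converge to a local minimum in which the image carries a
# spurious pole compensated by conjugate poles in every coil map; the
# smoothness penalty then forces the coil amplitude to zero there, leaving
# a "black hole" in the reconstruction.
#
# Detection runs on the coil maps, not the image: a spurious image pole is
# mirrored in all coils, while a genuine coil singularity appears in one
# coil only and comes with vanishing amplitude. Averaging per-coil winding
# maps with weights |c_i|^2 therefore keeps the consensus pole near +-1 and
# suppresses single-coil poles. Correction multiplies a unit-magnitude
# phase vortex onto the image and its conjugate onto the coils, which
# leaves the data consistency untouched and removes the winding.

#' Detection configuration
#'
#' @param d diameter of the winding-number circle, as a fraction of the FoV
#'   (default 0.05, robust for high- and low-resolution detection)
#' @param t consensus threshold on the magnitude of the weighted average
#'   winding map (default 0.5); strict inequality \code{|S| > t}
#' @param d_closing diameter of the disk used for morphological closing of
#'   the detection mask (default \code{d}); merges components closer than
#'   this so a single pole is never corrected twice
#' @param connectivity 8 (default) or 4, for component labeling
#' @param external_mode \code{TRUE} selects the variant for externally
#'   estimated coil stacks whose poles coincide exactly across coils:
#'   winding numbers from the four neighboring pixels (1-pixel circle) and
#'   no closing
#' @return object of class \code{detect_config}
#' @export
detect_config <- function(d = 0.05, t = 0.5, d_closing = d,
                          connectivity = 8L, external_mode = FALSE) {
  stopifnot(d > 0, t > 0, t < 1, connectivity %in% c(4L, 8L))
  structure(list(d = d, t = t, d_closing = d_closing,
                 connectivity = as.integer(connectivity),
                 external_mode = isTRUE(external_mode)),
            class = "detect_config")
}

#' Elementary phase vortex
#'
#' The unit-magnitude field
#' \eqn{\vartheta^{\pm}_{r_0}(r) = ((r-r_0)_x \pm i (r-r_0)_y)/\|r-r_0\|
#' = e^{\pm i\phi(r - r_0)}} with azimuthal phase about \code{r0}. At a
#' pixel coinciding with \code{r0} (distance below 1e-12) the value is set
#' to 1.
#'
#' @param grid a \code{\link{grid2d}}
#' @param r0 length-2 FoV position
#' @param sign +1 or -1, the winding number of the field around \code{r0}
#' @return a \code{\link{complex_image}} with unit magnitude everywhere
#' @export
phase_vortex <- function(grid, r0, sign = 1L) {
  if (any(abs(r0) > 0.5)) stop("vortex center outside FoV")
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  co <- grid_coords(grid)
  dx <- co$x - r0[1]; dy <- co$y - r0[2]
  h <- sqrt(dx^2 + dy^2)
  v <- (dx + 1i * sign * dy) / h
  v[h < 1e-12] <- 1 + 0i
  complex_image(grid, v)
}

#' Discretized circle for winding-number evaluation
#'
#' Approximates a circle of the given pixel diameter around a pixel by
#' \code{N = max(8, ceiling(pi * diameter_px))} angles rounded to the
#' nearest grid point, with consecutive duplicates removed. The point count
#' guarantees per-segment phase steps below \eqn{\pi} for unit-winding
#' vortices at diameters of 2 pixels and above. The curve is closed by
#' convention: the successor of the last point is the first. Curves that
#' would leave the grid are flagged \code{clipped}; winding numbers on
#' clipped curves are reported as 0 (poles closer than half a diameter to
#' the FoV edge are undetectable by construction).
#'
#' @param center_pixel length-2 0-based pixel index
#' @param diameter_px circle diameter in pixels (at least 1)
#' @param grid a \code{\link{grid2d}}
#' @return list with \code{points} (k x 2 matrix of 0-based indices) and
#'   logical \code{clipped}
#' @export
circle_curve <- function(center_pixel, diameter_px, grid) {
  stopifnot(diameter_px >= 1)
  n <- max(8L, ceiling(pi * diameter_px))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  pts <- cbind(round(center_pixel[1] + diameter_px / 2 * cos(ang)),
               round(center_pixel[2] + diameter_px / 2 * sin(ang)))
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) > 1 && all(pts[1, ] == pts[nrow(pts), ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  clipped <- any(pts[, 1] < 0 | pts[, 1] >= grid$nx |
                 pts[, 2] < 0 | pts[, 2] >= grid$ny)
  list(points = pts, clipped = clipped)
}

#' Winding number of a complex field along a closed pixel curve
#'
#' Sums principal-value phase differences
#' \eqn{\mathrm{Arg}\,\exp[i(\phi(r_{j+1}) - \phi(r_j))] \in (-\pi, \pi]}
#' around the loop, divides by \eqn{2\pi} and rounds to the nearest
#' integer. If the field is exactly zero at any curve point the phase is
#' undefined there and the winding number is reported as 0; likewise for
#' curves flagged as clipped at the grid boundary.
#'
#' @param field a \code{\link{complex_image}} or complex matrix
#' @param curve a k x 2 matrix of 0-based pixel indices (closed by
#'   wrap-around), or the list returned by \code{\link{circle_curve}}
#' @return integer winding number
#' @export
winding_number <- function(field, curve) {
  m <- if (inherits(field, "complex_image")) field$values else field
  if (is.list(curve)) {
    if (isTRUE(curve$clipped)) return(0L)
    curve <- curve$points
  }
  if (nrow(curve) > 1 && all(curve[1, ] == curve[nrow(curve), ]))
    curve <- curve[-nrow(curve), , drop = FALSE]
  if (nrow(curve) < 3) stop("curve is not a closed loop (fewer than 3 distinct points)")
  if (any(curve[, 1] < 0 | curve[, 1] >= nrow(m) |
          curve[, 2] < 0 | curve[, 2] >= ncol(m)))
    stop("curve leaves the grid")
  v <- m[cbind(curve[, 1] + 1L, curve[, 2] + 1L)]
  if (any(v == 0)) return(0L)
  vn <- v[c(2:length(v), 1L)]
  as.integer(round(sum(Arg(vn * Conj(v))) / (2 * pi)))
}

# shift a matrix by integer offset o (content moves by -o: result[p] =
# m[p + o]), padding with NA outside the grid
shift_na <- function(m, o) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(NA_complex_, nx, ny)
  sx <- max(1, 1 - o[1]):min(nx, nx - o[1])
  sy <- max(1, 1 - o[2]):min(ny, ny - o[2])
  if (length(sx) > 0 && length(sy) > 0)
    out[sx, sy] <- m[sx + o[1], sy + o[2]]
  out
}

# curve offsets used at every pixel (integer center => rounding commutes
# with translation, so one offset list serves the whole grid)
detection_offsets <- function(grid, cfg) {
  if (cfg$external_mode)
    return(rbind(c(1L, 0L), c(0L, 1L), c(-1L, 0L), c(0L, -1L)))
  circle_curve(c(0L, 0L), cfg$d * grid$nx, grid)$points
}

# winding map of one complex matrix, vectorized over all pixels
winding_map_mat <- function(m, offsets) {
  k <- nrow(offsets)
  shifted <- lapply(seq_len(k), function(j) shift_na(m, offsets[j, ]))
  acc <- matrix(0, nrow(m), ncol(m))
  bad <- matrix(FALSE, nrow(m), ncol(m))
  for (j in seq_len(k)) {
    a <- shifted[[j]]; b <- shifted[[if (j == k) 1L else j + 1L]]
    bad <- bad | is.na(a) | a == 0
    step <- Arg(b * Conj(a))
    step[is.na(step)] <- 0
    acc <- acc + step
  }
  s <- round(acc / (2 * pi))
  s[bad] <- 0
  s
}

#' Per-coil winding maps and their weighted consensus
#'
#' For every pixel of every coil map, computes the winding number on a
#' discretized circle of diameter \code{d * nx} pixels (or on the
#' four-neighbor square in external mode), then forms the weighted average
#' \eqn{\bar S(r) = \sum_i w_i(r) S_i(r) / \sum_i w_i(r)} with weights
#' \eqn{w_i = |c_i|^2}. Genuine coil singularities carry vanishing
#' amplitude, so the weighting suppresses them; only poles shared across
#' coils survive with \eqn{|\bar S| \approx 1}.
#'
#' @param coils a natural-domain \code{\link{coil_set}} with at least 2 coils
#' @param cfg a \code{\link{detect_config}}
#' @return object of class \code{pole_map}: per-coil winding maps \code{S}
#'   (\code{nx x ny x nc}), weights \code{w}, consensus \code{Sbar}
#' @export
coil_winding_maps <- function(coils, cfg = detect_config()) {
  stopifnot_domain(coils, "natural")
  if (coils$nc < 2L) stop("pole detection needs at least 2 coils")
  g <- coils$grid
  offsets <- detection_offsets(g, cfg)
  s <- array(0, c(g$nx, g$ny, coils$nc))
  for (i in seq_len(coils$nc))
    s[, , i] <- winding_map_mat(coils$values[, , i], offsets)
  w <- abs(coils$values)^2
  denom <- apply(w, c(1, 2), sum)
  sbar <- apply(w * s, c(1, 2), sum)
  sbar <- ifelse(denom > 0, sbar / denom, 0)
  structure(list(grid = g, S = s, w = w, Sbar = sbar, cfg = cfg),
            class = "pole_map")
}

# --- binary morphology and labeling on small masks -------------------------

disk_offsets <- function(diameter_px) {
  r <- diameter_px / 2
  ri <- floor(r)
  o <- as.matrix(expand.grid(dx = -ri:ri, dy = -ri:ri))
  o[o[, 1]^2 + o[, 2]^2 <= r^2 + 1e-9, , drop = FALSE]
}

shift_logical <- function(m, o, fill) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(fill, nx, ny)
  sx <- max(1, 1 - o[1]):min(nx, nx - o[1])
  sy <- max(1, 1 - o[2]):min(ny, ny - o[2])
  if (length(sx) > 0 && length(sy) > 0) out[sx, sy] <- m[sx + o[1], sy + o[2]]
  out
}

morph_close <- function(mask, diameter_px) {
  se <- disk_offsets(diameter_px)
  if (nrow(se) <= 1) return(mask)
  dil <- matrix(FALSE, nrow(mask), ncol(mask))
  for (j in seq_len(nrow(se))) dil <- dil | shift_logical(mask, se[j, ], FALSE)
  ero <- matrix(TRUE, nrow(mask), ncol(mask))
  for (j in seq_len(nrow(se))) ero <- ero & shift_logical(dil, se[j, ], FALSE)
  ero
}

label_components <- function(mask, connectivity = 8L) {
  nbr <- if (connectivity == 8L)
    rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
          c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  else rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  todo <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(todo))) {
    p <- todo[r, ]
    if (lab[p[1], p[2]] != 0L) next
    cur <- cur + 1L
    stack <- list(p)
    lab[p[1], p[2]] <- cur
    while (length(stack) > 0) {
      q <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (j in seq_len(nrow(nbr))) {
        a <- q[1] + nbr[j, 1]; b <- q[2] + nbr[j, 2]
        if (a >= 1 && a <= nrow(mask) && b >= 1 && b <= ncol(mask) &&
            mask[a, b] && lab[a, b] == 0L) {
          lab[a, b] <- cur
          stack[[length(stack) + 1L]] <- c(a, b)
        }
      }
    }
  }
  lab
}

#' Extract pole locations from a consensus winding map
#'
#' Thresholds the consensus map at \code{|Sbar| > t}, applies a
#' morphological closing with a disk of diameter \code{d_closing}
#' (skipped in external mode) so that a pole fragmented into nearby
#' components is corrected once rather than twice, labels connected
#' components, and reports the unweighted centroid of each component as
#' the pole location.
#'
#' Sign convention: the returned sign is the winding number of the pole as
#' it appears in the image (the coil maps carry the conjugate, so it is
#' the negated sign of the component mean of \code{Sbar}).
#'
#' @param pm a \code{pole_map} from \code{\link{coil_winding_maps}}
#' @param cfg a \code{\link{detect_config}}
#' @return object of class \code{pole_set}: data frame \code{poles} with
#'   columns \code{x}, \code{y} (FoV units), \code{sign}; count \code{M}
#' @export
detect_poles <- function(pm, cfg = pm$cfg) {
  mask <- abs(pm$Sbar) > cfg$t
  if (!cfg$external_mode && any(mask))
    mask <- morph_close(mask, cfg$d_closing * pm$grid$nx)
  lab <- label_components(mask, cfg$connectivity)
  m <- max(lab)
  if (m == 0)
    return(structure(list(poles = data.frame(x = numeric(0), y = numeric(0),
                                             sign = integer(0)), M = 0L),
                     class = "pole_set"))
  px <- numeric(m); py <- numeric(m); sg <- integer(m)
  for (j in seq_len(m)) {
    idx <- which(lab == j, arr.ind = TRUE)
    cen <- colMeans(idx) - 1  # 0-based fractional pixel
    pos <- pixel_to_position(pm$grid, cen[1], cen[2])
    px[j] <- pos[1]; py[j] <- pos[2]
    sg[j] <- -sign(mean(pm$Sbar[lab == j]))
  }
  keep <- sg != 0
  structure(list(poles = data.frame(x = px[keep], y = py[keep],
                                    sign = as.integer(sg[keep])),
                 M = sum(keep)), class = "pole_set")
}

#' @export
print.pole_set <- function(x, ...) {
  cat(sprintf("<pole_set: %d pole(s)>\n", x$M))
  if (x$M > 0) print(x$poles)
  invisible(x)
}

#' Fix the global phase of a correction field
#'
#' Multiplies the field by the unit complex number that makes the
#' image-power-weighted average of the corrected phase change vanish:
#' afterwards \eqn{\langle\rho, \vartheta\odot\rho\rangle} (inner product
#' conjugate-linear in its second argument) is real and positive, so the
#' correction alters the image phase as little as possible where the
#' signal is strong.
#'
#' @param theta a \code{\link{complex_image}} correction field
#' @param rho a \code{\link{complex_image}}
#' @return the adjusted correction field
#' @export
global_phase <- function(theta, rho) {
  z <- sum(abs(rho$values)^2 * Conj(theta$values))
  if (abs(z) == 0) {
    warning("zero image power overlap; global phase left unchanged")
    return(theta)
  }
  complex_image(theta$grid, theta$values * (z / abs(z)))
}

#' Build a correction field from detected poles
#'
#' Multiplies one elementary vortex per pole — with the winding that
#' cancels the image-domain pole — and applies the global-phase selection
#' (when an image is supplied). With no poles the identity field is
#' returned.
#'
#' @param poles a \code{pole_set} (image-sign convention, as returned by
#'   \code{\link{detect_poles}})
#' @param grid a \code{\link{grid2d}}
#' @param rho optional \code{\link{complex_image}} for the global phase
#' @return a \code{\link{complex_image}} with unit magnitude; multiply it
#'   onto the image and its conjugate onto the coils
#' @export
build_correction <- function(poles, grid, rho = NULL) {
  v <- matrix(1 + 0i, grid$nx, grid$ny)
  if (poles$M > 0) {
    for (j in seq_len(poles$M)) {
      th <- phase_vortex(grid, c(poles$poles$x[j], poles$poles$y[j]),
                         -poles$poles$sign[j])
      v <- v * th$values
    }
  }
  theta <- complex_image(grid, v)
  if (!is.null(rho) && poles$M > 0) theta <- global_phase(theta, rho)
  theta
}

#' Apply a pole correction inside the solver
#'
#' \eqn{\rho \leftarrow \vartheta\odot\rho},
#' \eqn{\tilde c \leftarrow W^{+}(\bar\vartheta \odot W\tilde c)}: the
#' image is multiplied by the vortex product, the coils by its conjugate
#' in the natural domain, and the result is pushed back through the
#' regularized pseudoinverse of the Sobolev weighting. The natural-domain
#' products \eqn{c_i\odot\rho} are preserved up to the bounded
#' pseudoinverse round-trip error.
#'
#' @param rho a \code{\link{complex_image}}
#' @param ctilde a preconditioned \code{\link{coil_set}}
#' @param theta a unit-magnitude \code{\link{complex_image}}
#' @param weights a \code{\link{sobolev_weights}}
#' @return list with corrected \code{rho} and \code{ctilde}
#' @export
apply_correction <- function(rho, ctilde, theta, weights) {
  stopifnot_domain(ctilde, "preconditioned")
  rho2 <- complex_image(rho$grid, rho$values * theta$values)
  c_nat <- apply_weighting(ctilde, weights)
  vals <- c_nat$values
  for (i in seq_len(c_nat$nc)) vals[, , i] <- vals[, , i] * Conj(theta$values)
  ct2 <- apply_weighting_pinv(coil_set(ctilde$grid, vals, "natural"), weights)
  list(rho = rho2, ctilde = ct2)
}

#' Remove phase poles from externally estimated coil maps
#'
#' Variant for coil stacks from auto-calibration methods whose reference
#' phase puts the identical pole in every map at exactly the same pixel:
#' winding numbers use the 1-pixel four-neighbor loop and no closing is
#' applied. Detected vortices are multiplied (conjugated) onto the coils
#' and, if given, onto the combined image, whose pointwise product with the
#' coils is preserved exactly since no weighting pseudoinverse is involved.
#'
#' @param coils a natural-domain \code{\link{coil_set}}
#' @param combined optional \code{\link{complex_image}} (coil-combined image)
#' @param cfg a \code{\link{detect_config}}; \code{external_mode} is forced on
#' @return list with \code{coils}, \code{combined} (or NULL) and the
#'   detected \code{poles}
#' @export
correct_external_coils <- function(coils, combined = NULL,
                                   cfg = detect_config(external_mode = TRUE)) {
  cfg$external_mode <- TRUE
  pm <- coil_winding_maps(coils, cfg)
  poles <- detect_poles(pm, cfg)
  if (poles$M == 0) return(list(coils = coils, combined = combined,
                                poles = poles))
  theta <- build_correction(poles, coils$grid, rho = combined)
  vals <- coils$values
  for (i in seq_len(coils$nc)) vals[, , i] <- vals[, , i] * Conj(theta$values)
  out_combined <- if (!is.null(combined))
    complex_image(combined$grid, combined$values * theta$values) else NULL
  list(coils = coil_set(coils$grid, vals, "natural"),
       combined = out_combined, poles = poles)
}
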