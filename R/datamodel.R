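# Core grid/array types shared by every module, plus CFL file I/O.
#
# Coordinate convention: the field of view (FoV) is the unit square. The
# 0-based pixel (ix, iy) is centered at
#   r = ((ix + 0.5)/nx - 0.5, (iy + 0.5)/ny - 0.5),
# so distances expressed as FoV fractions convert to pixels by multiplying
# by nx (resp. ny). k-space arrays are stored centered (see fft.R).

#' 2D reconstruction grid
#'
#' @param nx,ny pixel counts along x and y; both must be at least 8
#' @return an object of class \code{grid2d}
#' @export
grid2d <- function(nx, ny = nx) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 8L || ny < 8L) stop("grid must be at least 8x8")
  structure(list(nx = nx, ny = ny), class = "grid2d")
}

#' @export
format.grid2d <- function(x, ...) sprintf("<grid2d %dx%d>", x$nx, x$ny)

#' @export
print.grid2d <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

same_grid <- function(a, b) a$nx == b$nx && a$ny == b$ny

#' Pixel/position conversion
#'
#' Maps 0-based pixel indices to FoV-normalized positions in
#' \eqn{[-0.5, 0.5]^2} and back. \code{position_to_pixel} rounds to the
#' nearest pixel center, so \code{position_to_pixel(pixel_to_position(i))}
#' is the identity on indices.
#'
#' @param grid a \code{\link{grid2d}}
#' @param ix,iy 0-based pixel indices (vectors allowed)
#' @return \code{pixel_to_position}: a 2-column matrix of (x, y) positions
#' @export
pixel_to_position <- function(grid, ix, iy) {
  cbind(x = (ix + 0.5) / grid$nx - 0.5, y = (iy + 0.5) / grid$ny - 0.5)
}

#' @rdname pixel_to_position
#' @param x,y FoV-normalized positions
#' @return \code{position_to_pixel}: a 2-column matrix of 0-based (ix, iy)
#' @export
position_to_pixel <- function(grid, x, y) {
  cbind(ix = round((x + 0.5) * grid$nx - 0.5), iy = round((y + 0.5) * grid$ny - 0.5))
}

# Position of every pixel center, as nx x ny matrices (used all over).
grid_coords <- function(grid) {
  px <- (seq_len(grid$nx) - 0.5) / grid$nx - 0.5
  py <- (seq_len(grid$ny) - 0.5) / grid$ny - 0.5
  list(x = matrix(px, grid$nx, grid$ny),
       y = matrix(py, grid$nx, grid$ny, byrow = TRUE))
}

#' Complex-valued image on a grid
#'
#' @param grid a \code{\link{grid2d}}
#' @param values complex matrix of dimension \code{nx x ny}; all finite
#' @return object of class \code{complex_image}
#' @export
complex_image <- function(grid, values) {
  values <- matrix(as.complex(values), grid$nx, grid$ny)
  if (any(!is.finite(values))) stop("image values must be finite")
  structure(list(grid = grid, values = values), class = "complex_image")
}

#' Stack of coil sensitivity maps
#'
#' A set of \code{nc} complex maps sharing one grid. The \code{domain} tag
#' distinguishes natural-domain sensitivities \eqn{c} from the
#' preconditioned variables \eqn{\tilde c} (the Sobolev-weighted k-space
#' representation used inside the solver); operations check the tag so the
#' two are never mixed silently.
#'
#' @param grid a \code{\link{grid2d}}
#' @param values complex array of dimension \code{nx x ny x nc}
#' @param domain \code{"natural"} or \code{"preconditioned"}
#' @return object of class \code{coil_set}
#' @export
coil_set <- function(grid, values, domain = c("natural", "preconditioned")) {
  domain <- match.arg(domain)
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (dim(values)[1] != grid$nx || dim(values)[2] != grid$ny)
    stop("coil array does not match grid")
  storage.mode(values) <- "complex"
  if (any(!is.finite(values))) stop("coil values must be finite")
  structure(list(grid = grid, nc = dim(values)[3], values = values,
                 domain = domain), class = "coil_set")
}

stopifnot_domain <- function(coils, domain) {
  if (!identical(coils$domain, domain))
    stop(sprintf("coil set must be in %s domain (got %s)", domain, coils$domain))
}

#' Cartesian sampling pattern with auto-calibration block
#'
#' @param grid a \code{\link{grid2d}}
#' @param mask 0/1 matrix over centered k-space; must not be all zero
#' @param ac_size side length of the fully sampled central block (0 if none)
#' @return object of class \code{sampling_pattern}
#' @export
sampling_pattern <- function(grid, mask, ac_size = 0L) {
  mask <- matrix(as.numeric(mask != 0), grid$nx, grid$ny)
  if (sum(mask) == 0) stop("sampling mask is empty")
  ac_size <- as.integer(ac_size)
  if (ac_size > 0L) {
    idx <- ac_block_indices(grid, ac_size)
    if (any(mask[idx$ix, idx$iy] != 1))
      stop("central AC block is not fully sampled")
  }
  structure(list(grid = grid, mask = mask, ac_size = ac_size),
            class = "sampling_pattern")
}

# 1-based index ranges of the central ac x ac block, anchored so that the
# zero-frequency pixel (0-based nx/2) sits at 0-based position floor(ac/2)
# within the block (symmetric for odd ac, FFT-convention for even ac).
ac_block_indices <- function(grid, ac) {
  cx <- floor(grid$nx / 2) + 1L; cy <- floor(grid$ny / 2) + 1L
  lo <- floor(ac / 2); hi <- ceiling(ac / 2) - 1L
  list(ix = (cx - lo):(cx + hi), iy = (cy - lo):(cy + hi))
}

#' Multi-coil k-space data
#'
#' @param grid a \code{\link{grid2d}}
#' @param values complex array \code{nx x ny x nc}, centered k-space
#' @param pattern a \code{\link{sampling_pattern}}; values must vanish where
#'   the mask is zero (enforced by masking on construction)
#' @return object of class \code{kspace_data}
#' @export
kspace_data <- function(grid, values, pattern) {
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  storage.mode(values) <- "complex"
  nc <- dim(values)[3]
  for (i in seq_len(nc)) values[, , i] <- values[, , i] * pattern$mask
  structure(list(grid = grid, nc = nc, values = values, pattern = pattern),
            class = "kspace_data")
}

#' Reconstruction configuration
#'
#' Defaults follow the standard NLINV protocol for 2D Cartesian data:
#' twelve Gauss-Newton steps with the regularization parameter decaying
#' exponentially from 1 to \code{alpha_min = 0.001}, k-space data normalized
#' to \eqn{\|y\|_2 = 100}, and (when pole correction is enabled) a single
#' detection pass after eight steps so that four steps remain to refine the
#' corrected estimate.
#'
#' @param newton_steps number of Gauss-Newton steps
#' @param alpha_min floor of the regularization schedule
#' @param alpha_decay per-step decay factor \code{q}; \code{alpha(k) = max(alpha_min, q^k)}
#' @param cg_iters cap on conjugate-gradient iterations per step
#' @param cg_tol relative residual tolerance of the inner CG solve
#' @param data_norm_target target value of \code{norm(y)} after normalization
#' @param pole_correction run phase-pole detection/correction inside the solver
#' @param detect_step Gauss-Newton step index after which detection runs
#' @param detect_every if \code{TRUE}, re-detect after every step from
#'   \code{detect_step} on (for repeated correction of multiple poles)
#' @param detect_params a \code{\link{detect_config}}
#' @return object of class \code{recon_config}
#' @export
recon_config <- function(newton_steps = 12L, alpha_min = 0.001,
                         alpha_decay = 0.5, cg_iters = 50L, cg_tol = 1e-6,
                         data_norm_target = 100, pole_correction = FALSE,
                         detect_step = 8L, detect_every = FALSE,
                         detect_params = detect_config()) {
  stopifnot(alpha_min > 0, alpha_min < 1, alpha_decay > 0, alpha_decay < 1,
            data_norm_target > 0)
  if (isTRUE(pole_correction) && detect_step >= newton_steps)
    stop("detect_step must be smaller than newton_steps so that at least ",
         "one refinement step follows the correction")
  structure(list(newton_steps = as.integer(newton_steps),
                 alpha_min = alpha_min, alpha_decay = alpha_decay,
                 cg_iters = as.integer(cg_iters), cg_tol = cg_tol,
                 data_norm_target = data_norm_target,
                 pole_correction = isTRUE(pole_correction),
                 detect_step = as.integer(detect_step),
                 detect_every = isTRUE(detect_every),
                 detect_params = detect_params), class = "recon_config")
}

#' Read a BART-style CFL file pair
#'
#' Reads \code{<stem>.hdr} (ASCII header whose line after "# Dimensions"
#' holds the array dimensions) and \code{<stem>.cfl} (raw little-endian
#' 32-bit float pairs, interleaved real/imaginary, column-major).
#'
#' @param path_stem path without the \code{.hdr}/\code{.cfl} extension
#' @return complex array with the dimensions declared in the header
#' @export
read_cfl <- function(path_stem) {
  hdr <- paste0(path_stem, ".hdr"); cfl <- paste0(path_stem, ".cfl")
  if (!file.exists(hdr)) stop("missing header file: ", hdr)
  if (!file.exists(cfl)) stop("missing data file: ", cfl)
  lines <- readLines(hdr, warn = FALSE)
  di <- grep("^#\\s*Dimensions", lines)
  if (length(di) == 0 || di[1] == length(lines))
    stop("malformed CFL header (no dimension line): ", hdr)
  dims <- as.integer(strsplit(trimws(lines[di[1] + 1]), "\\s+")[[1]])
  if (any(is.na(dims)) || length(dims) == 0)
    stop("malformed CFL header (unparsable dimensions): ", hdr)
  n <- prod(dims)
  raw <- readBin(cfl, what = "numeric", n = 2L * n + 2L, size = 4L,
                 endian = "little")
  if (length(raw) != 2L * n)
    stop("CFL payload size does not match header dimensions: ", cfl)
  vals <- complex(real = raw[c(TRUE, FALSE)], imaginary = raw[c(FALSE, TRUE)])
  array(vals, dim = dims)
}

#' Write a BART-style CFL file pair
#'
#' @param path_stem path without extension
#' @param values complex (or numeric) array; dimensions are padded with 1s
#'   to at least 5 entries in the header
#' @export
write_cfl <- function(path_stem, values) {
  values <- as.array(values)
  if (any(!is.finite(values))) stop("refusing to write non-finite values")
  dims <- dim(values)
  if (length(dims) < 5L) dims <- c(dims, rep(1L, 5L - length(dims)))
  writeLines(c("# Dimensions", paste(dims, collapse = " ")),
             paste0(path_stem, ".hdr"))
  v <- as.complex(values)
  interleaved <- as.numeric(rbind(Re(v), Im(v)))
  writeBin(interleaved, paste0(path_stem, ".cfl"), size = 4L,
           endian = "little")
  invisible(NULL)
}
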