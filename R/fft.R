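# Centered unitary 2D FFT helpers.
#
# k-space is stored centered: the zero-frequency coefficient sits at 0-based
# pixel (nx/2, ny/2), i.e. R index (nx/2 + 1, ny/2 + 1) for even grids. All
# transforms are unitary so that Parseval holds exactly and the adjoint of
# the forward FFT is its inverse.

circ_shift <- function(x, s) {
  d <- dim(x)
  ix <- ((seq_len(d[1]) - 1 - s[1]) %% d[1]) + 1
  iy <- ((seq_len(d[2]) - 1 - s[2]) %% d[2]) + 1
  x[ix, iy, drop = FALSE]
}

fftshift2 <- function(x) circ_shift(x, c(floor(dim(x)[1] / 2), floor(dim(x)[2] / 2)))

ifftshift2 <- function(x) circ_shift(x, c(-floor(dim(x)[1] / 2), -floor(dim(x)[2] / 2)))

#' Centered unitary 2D FFT
#'
#' Forward transform from image space to centered k-space. Unitary scaling
#' (division by \code{sqrt(nx * ny)}) so that the adjoint equals the inverse
#' and energy is preserved.
#'
#' @param x complex matrix (image-space samples)
#' @return complex matrix of the same shape, zero frequency at the center
#' @keywords internal
fft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

#' @rdname fft2c
#' @keywords internal
ifft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}
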