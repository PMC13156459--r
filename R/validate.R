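# Quantitative quality checks: the point-wise projection test for coil
# maps and a matching score for pole recovery.

#' Coil images from k-space
#'
#' Per-coil centered inverse unitary FFT of the data. Intended for fully
#' sampled data; on undersampled input the zero-filled transform is
#' returned with a warning (it then contains aliasing).
#'
#' @param y a \code{\link{kspace_data}}
#' @return a natural-domain \code{\link{coil_set}} of coil images
#' @export
coil_image <- function(y) {
  if (sum(y$pattern$mask) < y$grid$nx * y$grid$ny)
    warning("k-space is undersampled; coil images are zero-filled transforms")
  vals <- y$values
  for (i in seq_len(y$nc)) vals[, , i] <- ifft2c(y$values[, , i])
  coil_set(y$grid, vals, "natural")
}

#' Point-wise projection test
#'
#' Projects measured coil images onto the pixel-wise one-dimensional
#' subspace spanned by the estimated sensitivities,
#' \eqn{P_c(r) = \|c(r)\|^{-2} c(r) c(r)^H}, and reports the residual
#' \eqn{m - P_c m}. For well-estimated sensitivities the residual is pure
#' measurement noise and carries no image structure; calibration errors
#' (including phase poles) leave visible residual. Where \eqn{\|c(r)\| = 0}
#' the projector is the zero map, so the residual equals \eqn{m} there.
#'
#' @param m a natural-domain \code{\link{coil_set}} of coil images
#'   (e.g. from \code{\link{coil_image}})
#' @param coils a natural-domain \code{\link{coil_set}} of estimated
#'   sensitivities on the same grid
#' @param support optional logical matrix selecting the support for the
#'   scalar summaries; default: pixels where the RSS of \code{m} exceeds
#'   10\% of its maximum
#' @return object of class \code{projection_report}: per-coil
#'   \code{residual} array, \code{rss} residual map, and scalar summaries
#'   \code{mean_rss_support} / \code{mean_rss_background}
#' @export
projection_residual <- function(m, coils, support = NULL) {
  stopifnot_domain(m, "natural"); stopifnot_domain(coils, "natural")
  if (!same_grid(m$grid, coils$grid) || m$nc != coils$nc)
    stop("coil images and sensitivities do not match")
  cn2 <- apply(abs(coils$values)^2, c(1, 2), sum)
  inner <- matrix(0 + 0i, m$grid$nx, m$grid$ny)
  for (i in seq_len(m$nc))
    inner <- inner + Conj(coils$values[, , i]) * m$values[, , i]
  coef <- ifelse(cn2 > 0, inner / ifelse(cn2 > 0, cn2, 1), 0 + 0i)
  residual <- m$values
  for (i in seq_len(m$nc))
    residual[, , i] <- m$values[, , i] - coils$values[, , i] * coef
  rss <- sqrt(apply(abs(residual)^2, c(1, 2), sum))
  if (is.null(support)) {
    mrss <- sqrt(apply(abs(m$values)^2, c(1, 2), sum))
    support <- mrss > 0.1 * max(mrss)
  }
  structure(list(residual = residual, rss = rss, support = support,
                 mean_rss_support = mean(rss[support]),
                 mean_rss_background = if (any(!support))
                   mean(rss[!support]) else 0),
            class = "projection_report")
}

#' Score detected poles against ground truth
#'
#' Greedy matching by increasing distance: a truth/detection pair matches
#' if it is within \code{tol} and has equal sign; each pole matches at most
#' once. Deterministic and invariant to the ordering of either set.
#'
#' @param truth,detected \code{pole_set} objects
#' @param tol matching radius in FoV units
#' @return list with \code{matches}, \code{misses},
#'   \code{false_positives} and \code{mean_location_error}
#' @export
pole_recovery_score <- function(truth, detected, tol) {
  stopifnot(tol > 0)
  nt <- truth$M; nd <- detected$M
  if (nt == 0 || nd == 0)
    return(list(matches = 0L, misses = nt, false_positives = nd,
                mean_location_error = NA_real_))
  pairs <- expand.grid(i = seq_len(nt), j = seq_len(nd))
  pairs$dist <- sqrt((truth$poles$x[pairs$i] - detected$poles$x[pairs$j])^2 +
                     (truth$poles$y[pairs$i] - detected$poles$y[pairs$j])^2)
  ok <- pairs$dist <= tol &
    truth$poles$sign[pairs$i] == detected$poles$sign[pairs$j]
  pairs <- pairs[ok, , drop = FALSE]
  pairs <- pairs[order(pairs$dist), , drop = FALSE]
  used_t <- logical(nt); used_d <- logical(nd)
  errs <- numeric(0)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (!used_t[i] && !used_d[j]) {
      used_t[i] <- TRUE; used_d[j] <- TRUE
      errs <- c(errs, pairs$dist[r])
    }
  }
  list(matches = sum(used_t), misses = sum(!used_t),
       false_positives = sum(!used_d),
       mean_location_error = if (length(errs)) mean(errs) else NA_real_)
}
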