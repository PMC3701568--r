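#' Regularized Heaviside function
#'
#' Smooth arctan-based surrogate for the unit step, used to softly classify
#' pixels as inside (\eqn{\phi > 0}) or outside the evolving contour:
#' \deqn{H_\epsilon(z) = \frac{1}{2}\left(1 + \frac{2}{\pi}\arctan\frac{z}{\epsilon}\right).}
#' Values lie strictly in (0, 1) and \code{heaviside_reg(0) == 0.5}.
#'
#' @param z numeric scalar, vector or matrix (typically a level set field).
#' @param eps positive width of the transition band, in the units of \code{z}.
#' @return object of the same shape as \code{z}.
#' @seealso [dirac_reg()] for its derivative.
#' @export
#' @examples
#' heaviside_reg(0, 1)   # 0.5
#' heaviside_reg(1, 1)   # 0.75
heaviside_reg <- function(z, eps) {
  check_positive(eps, "eps")
  0.5 * (1 + (2 / pi) * atan(z / eps))
}

#' Regularized Dirac delta
#'
#' Derivative of [heaviside_reg()]:
#' \deqn{\delta_\epsilon(z) = \frac{1}{\pi}\,\frac{\epsilon}{\epsilon^2 + z^2},}
#' a strictly positive, even function with global support that peaks at
#' \eqn{1/(\pi\epsilon)} on the zero level set and integrates to 1. It
#' confines (but does not hard-limit) contour forces to a band around the
#' contour.
#'
#' @inheritParams heaviside_reg
#' @return object of the same shape as \code{z}.
#' @export
dirac_reg <- function(z, eps) {
  check_positive(eps, "eps")
  (1 / pi) * eps / (eps^2 + z^2)
}

#' Central-difference gradient
#'
#' First derivatives of a 2D field by central differences in the interior
#' with replicated-edge (Neumann) boundary handling. Rows index y, columns
#' index x.
#'
#' @param field numeric matrix, all values finite.
#' @param spacing length-2 numeric \code{c(dy, dx)}, physical units per pixel.
#' @return list with matrices \code{gy} and \code{gx} of \code{field}'s shape.
#' @export
gradient_c <- function(field, spacing = c(1, 1)) {
  check_field(field)
  n <- nrow(field); m <- ncol(field)
  up    <- field[c(1L, seq_len(n - 1L)), , drop = FALSE]
  down  <- field[c(seq_len(n - 1L) + 1L, n), , drop = FALSE]
  left  <- field[, c(1L, seq_len(m - 1L)), drop = FALSE]
  right <- field[, c(seq_len(m - 1L) + 1L, m), drop = FALSE]
  list(gy = (down - up) / (2 * spacing[1]),
       gx = (right - left) / (2 * spacing[2]))
}

#' Five-point Laplacian
#'
#' \eqn{\Delta f} with replicated-edge boundary handling, consistent with
#' [gradient_c()].
#'
#' @inheritParams gradient_c
#' @return matrix of \code{field}'s shape.
#' @export
laplacian <- function(field, spacing = c(1, 1)) {
  check_field(field)
  n <- nrow(field); m <- ncol(field)
  up    <- field[c(1L, seq_len(n - 1L)), , drop = FALSE]
  down  <- field[c(seq_len(n - 1L) + 1L, n), , drop = FALSE]
  left  <- field[, c(1L, seq_len(m - 1L)), drop = FALSE]
  right <- field[, c(seq_len(m - 1L) + 1L, m), drop = FALSE]
  (up + down - 2 * field) / spacing[1]^2 +
    (left + right - 2 * field) / spacing[2]^2
}

#' Divergence of a 2D vector field
#'
#' @param fy,fx numeric matrices: the y- and x-components.
#' @inheritParams gradient_c
#' @return matrix \code{d(fy)/dy + d(fx)/dx}.
#' @export
divergence <- function(fy, fx, spacing = c(1, 1)) {
  gradient_c(fy, spacing)$gy + gradient_c(fx, spacing)$gx
}

#' Mean curvature of the level sets of a field
#'
#' Computes \eqn{\mathrm{div}(\nabla\phi / |\nabla\phi|)}, which on the zero
#' level set equals the contour's mean curvature (1/r for a circle of radius
#' r). The gradient magnitude is softly guarded as
#' \eqn{\sqrt{|\nabla\phi|^2 + \eta^2}} so flat plateaus contribute zero
#' rather than 0/0.
#'
#' @param phi numeric matrix (level set field).
#' @inheritParams gradient_c
#' @param eta small positive denominator guard.
#' @return matrix of curvature values.
#' @export
curvature_div <- function(phi, spacing = c(1, 1), eta = 1e-10) {
  check_positive(eta, "eta")
  g <- gradient_c(phi, spacing)
  nrm <- sqrt(g$gy^2 + g$gx^2 + eta^2)
  divergence(g$gy / nrm, g$gx / nrm, spacing)
}

#' Distance-regularization flow term
#'
#' Gradient flow of the penalty \eqn{\int \frac{1}{2}(|\nabla\phi| - 1)^2},
#' namely \eqn{\Delta\phi - \mathrm{div}(\nabla\phi/|\nabla\phi|)}. It pulls
#' \eqn{|\nabla\phi|} toward 1 during evolution, which is what removes the
#' need for periodic re-initialization to a signed distance function.
#'
#' @inheritParams curvature_div
#' @return matrix; approximately zero wherever \eqn{|\nabla\phi| \equiv 1}.
#' @export
distance_penalty <- function(phi, spacing = c(1, 1), eta = 1e-10) {
  laplacian(phi, spacing) - curvature_div(phi, spacing, eta)
}

#' Mean deviation of |grad phi| from 1 near the zero level set
#'
#' Regularity diagnostic: mean of \eqn{||\nabla\phi| - 1|} over the pixels
#' within \code{width} pixels of the contour (the band where the level set
#' actually matters).
#'
#' @inheritParams curvature_div
#' @param width band half-width in pixels.
#' @return scalar.
#' @export
band_grad_deviation <- function(phi, width = 5, spacing = c(1, 1)) {
  band <- zero_band(phi > 0, width)
  if (!any(band)) return(NA_real_)
  g <- gradient_c(phi, spacing)
  dev <- abs(sqrt(g$gy^2 + g$gx^2) - 1)
  mean(dev[band])
}

# Pixels within `width` px (chessboard-ish disc) of the mask's boundary.
zero_band <- function(mask, width = 5) {
  bnd <- boundary_mask(mask)
  if (!any(bnd)) return(bnd)
  brush <- EBImage::makeBrush(2L * as.integer(width) + 1L, shape = "disc")
  EBImage::dilate(bnd * 1, brush) > 0.5
}

# ---- internal validation helpers ----

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  invisible(x)
}

check_field <- function(field, min_dim = 3L) {
  if (!is.matrix(field) || !is.numeric(field))
    stop("field must be a numeric matrix", call. = FALSE)
  if (nrow(field) < min_dim || ncol(field) < min_dim)
    stop(sprintf("field must be at least %dx%d", min_dim, min_dim), call. = FALSE)
  if (!all(is.finite(field)))
    stop("field contains non-finite values", call. = FALSE)
  invisible(field)
}
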