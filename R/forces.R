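# The two image-derived driving forces of the ERBLS model: the edge
# detecting function (edf) built from smoothed gradient magnitude, and the
# region detecting function (rdf) built from kernel-weighted local means of
# the intensities inside/outside the contour.

#' Edge detecting function
#'
#' \deqn{edf(I) = \frac{1}{1 + |\nabla (G_{\sigma_g} * I)|}}
#' Values are in (0, 1]: near 0 on strong edges, exactly 1 wherever the
#' smoothed gradient vanishes. In the evolution it modulates the curvature
#' (geodesic length) force so the contour is held at boundaries.
#'
#' @param image numeric matrix of intensities.
#' @param sigma_g positive Gaussian smoothing scale in pixels.
#' @param spacing length-2 \code{c(dy, dx)}.
#' @return object of class \code{edge_map}: list with \code{values}
#'   (matrix in (0,1]) and \code{sigma_g}.
#' @export
compute_edf <- function(image, sigma_g = 3, spacing = c(1, 1)) {
  check_field(image)
  check_positive(sigma_g, "sigma_g")
  smooth <- conv_gauss(image, gaussian_kernel(sigma_g))
  g <- gradient_c(smooth, spacing)
  structure(list(values = 1 / (1 + sqrt(g$gy^2 + g$gx^2)), sigma_g = sigma_g),
            class = "edge_map")
}

#' Pre-compute the contour-independent convolutions
#'
#' Of the four convolutions needed for the local mean fields c1/c2, two
#' involve only the image and the kernel: \eqn{g_\sigma * 1} and
#' \eqn{g_\sigma * I}. They are computed once here, before iteration, so
#' that each evolution step performs exactly two new convolutions (those
#' involving \eqn{H(\phi)}).
#'
#' @param image numeric matrix of intensities.
#' @param kernel a [gaussian_kernel()].
#' @return object of class \code{conv_cache}: list with \code{g_conv_ones},
#'   \code{g_conv_I} and the kernel.
#' @export
build_conv_cache <- function(image, kernel = gaussian_kernel(3)) {
  check_field(image)
  structure(list(
    g_conv_ones = conv_gauss(matrix(1, nrow(image), ncol(image)), kernel),
    g_conv_I    = conv_gauss(image, kernel),
    kernel      = kernel
  ), class = "conv_cache")
}

#' Kernel-weighted local mean intensities inside and outside the contour
#'
#' \deqn{c_1(x) = \frac{(g_\sigma * (I\,H(\phi)))(x)}{(g_\sigma * H(\phi))(x)},
#'       \qquad
#'       c_2(x) = \frac{(g_\sigma * I)(x) - (g_\sigma * (I\,H(\phi)))(x)}
#'                     {(g_\sigma * 1)(x) - (g_\sigma * H(\phi))(x)}}
#' Only the two \eqn{H(\phi)}-dependent convolutions are performed; the
#' others come from the cache. Where a phase is locally (numerically) empty
#' the corresponding mean falls back to that phase's global weighted mean,
#' with a warning.
#'
#' @param image numeric matrix of intensities.
#' @param phi level set field (matrix, same shape).
#' @param cache a [build_conv_cache()] result for this image/kernel.
#' @param eps Heaviside regularization width.
#' @return object of class \code{local_means}: list with matrices \code{c1},
#'   \code{c2} and the \code{kernel}.
#' @export
local_means <- function(image, phi, cache, eps = 1) {
  stopifnot(inherits(cache, "conv_cache"))
  if (!identical(dim(image), dim(phi)))
    stop("`image` and `phi` must have the same shape", call. = FALSE)
  H <- heaviside_reg(phi, eps)
  conv_H  <- conv_gauss(H, cache$kernel)
  conv_IH <- conv_gauss(image * H, cache$kernel)

  den1 <- conv_H
  den2 <- cache$g_conv_ones - conv_H
  num2 <- cache$g_conv_I - conv_IH
  c1 <- conv_IH / pmax(den1, 1e-300)
  c2 <- num2 / pmax(den2, 1e-300)

  bad1 <- den1 < 1e-12
  bad2 <- den2 < 1e-12
  if (any(bad1)) {
    sH <- sum(H)
    c1[bad1] <- if (sH > 1e-12) sum(image * H) / sH else mean(image)
    warning("inside phase locally empty; fell back to global inside mean",
            call. = FALSE)
  }
  if (any(bad2)) {
    sH <- sum(1 - H)
    c2[bad2] <- if (sH > 1e-12) sum(image * (1 - H)) / sH else mean(image)
    warning("outside phase locally empty; fell back to global outside mean",
            call. = FALSE)
  }
  structure(list(c1 = c1, c2 = c2, kernel = cache$kernel),
            class = "local_means")
}

#' Region detecting function
#'
#' Normalized signed-pressure field
#' \deqn{rdf(x) = \frac{I(x) - \tfrac{1}{2}(c_1(x) + c_2(x))}
#'                    {\max_x |\,\cdot\,|}}
#' comparing each pixel's intensity with the midpoint of the local
#' inside/outside mean intensities — the localized form of the signed
#' pressure force, with the global region means replaced by the
#' kernel-weighted local means c1/c2. Its sign selects expansion vs
#' contraction of the contour (positive where the intensity is above the
#' local midpoint, i.e. inside a bright object), and its magnitude —
#' largest deep inside homogeneous phases — sets the local evolution
#' speed. Because c1 and c2 are local, a smooth multiplicative bias field
#' shifts pixel values and midpoint together, which is what makes the
#' model robust to intensity inhomogeneity. The normalization constant is
#' recomputed on every call because c1/c2 evolve with the contour.
#'
#' @param image the intensity matrix the means were computed on.
#' @param means a [local_means()] result.
#' @return object of class \code{region_map}: list with \code{values}
#'   (matrix in [-1, 1]; \code{max(abs(values))} is exactly 1 unless the raw
#'   field is identically zero) and \code{raw} (the un-normalized field).
#' @export
compute_rdf <- function(image, means) {
  stopifnot(inherits(means, "local_means"))
  raw <- image - (means$c1 + means$c2) / 2
  m <- max(abs(raw))
  # a raw field at rounding-noise level (constant image) is identically zero;
  # normalizing it would amplify floating-point dust into O(1) forces
  zero <- m <= 1e-8 * max(abs(image), 1)
  structure(list(values = if (zero) raw * 0 else raw / m, raw = raw),
            class = "region_map")
}
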