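# Seeded phantom generator. Emulates the difficulty regimes the model is
# designed for: piecewise-constant objects degraded by smooth multiplicative
# bias fields (intensity inhomogeneity), Gaussian edge blur, locally erased
# (discontinuous) boundaries, and additive noise — plus a vertebra-like
# phantom (bright ring body with process lobes). Ground-truth masks are
# never degraded. Generation is a pure function of the spec: identical
# specs give bit-identical outputs.

#' Parametric phantom shapes
#'
#' \code{shape_disc}: filled disc. \code{shape_ring}: annulus
#' (\code{r_in <= d <= r_out}). \code{shape_vertebra}: vertebra-like
#' compound — a bright ring body (cortical shell around a darker centre)
#' with three process lobes attached at 30, 150 and 270 degrees.
#'
#' @param center length-2 \code{c(cy, cx)} in pixel coordinates.
#' @param r,r_in,r_out radii in pixels.
#' @return object of class \code{phantom_shape}.
#' @export
shape_disc <- function(center, r) {
  structure(list(type = "disc", center = center, r = r),
            class = "phantom_shape")
}

#' @rdname shape_disc
#' @export
shape_ring <- function(center, r_in, r_out) {
  stopifnot(r_in < r_out)
  structure(list(type = "ring", center = center, r_in = r_in, r_out = r_out),
            class = "phantom_shape")
}

#' @rdname shape_disc
#' @export
shape_vertebra <- function(center, r) {
  structure(list(type = "vertebra", center = center, r = r,
                 r_lobe = 0.45 * r),
            class = "phantom_shape")
}

shape_extent <- function(obj) {
  R <- switch(obj$type,
    disc = obj$r,
    ring = obj$r_out,
    vertebra = obj$r + 2 * obj$r_lobe)
  c(obj$center, R)
}

rasterize_shape <- function(obj, dims) {
  yy <- matrix(seq_len(dims[1]), dims[1], dims[2])
  xx <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  dist2 <- function(c0) sqrt((yy - c0[1])^2 + (xx - c0[2])^2)
  switch(obj$type,
    disc = dist2(obj$center) <= obj$r,
    ring = {
      d <- dist2(obj$center)
      d >= obj$r_in & d <= obj$r_out
    },
    vertebra = {
      d <- dist2(obj$center)
      m <- d >= 0.55 * obj$r & d <= obj$r
      for (ang in c(30, 150, 270) * pi / 180) {
        c_lobe <- obj$center + (obj$r + 0.5 * obj$r_lobe) *
          c(sin(ang), cos(ang))
        m <- m | (dist2(c_lobe) <= obj$r_lobe)
      }
      m
    })
}

#' Phantom specification
#'
#' Degradations are applied to the intensity image in this order: boundary
#' gap, edge blur, multiplicative bias, additive noise. The ground-truth
#' mask is the clean rasterization and is unaffected by all of them.
#'
#' @param shape image dimensions \code{c(H, W)}.
#' @param objects list of [shape_disc()]/[shape_ring()]/[shape_vertebra()].
#' @param fg_level,bg_level object and background intensities (8-bit-like
#'   levels by default so Otsu behaves as on CT-derived images).
#' @param bias_amplitude multiplicative bias amplitude in [0, 1): the bias
#'   field is \code{1 + a * s} with \code{s} a seeded sum of three
#'   low-frequency cosine modes normalized to \code{max|s| = 1}.
#' @param bias_scale wavelength of the bias modes, px.
#' @param blur_sigma Gaussian edge blur, px (0 = none).
#' @param gap fraction of each object's boundary arc, in [0, 1), over which
#'   the sharp edge is replaced by a wide smooth intensity ramp (disc
#'   objects) or erased to background (ring objects) — a locally
#'   undetectable/discontinuous boundary with the far interior and exterior
#'   intensities preserved.
#' @param gap_angle start angle (radians) of the gap arc.
#' @param noise_sigma additive Gaussian noise sd.
#' @param seed integer RNG seed for bias and noise.
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(100, 100), objects,
                         fg_level = 200, bg_level = 50,
                         bias_amplitude = 0, bias_scale = 60,
                         blur_sigma = 0, gap = 0, gap_angle = 0,
                         noise_sigma = 0, seed = 1L) {
  if (fg_level == bg_level)
    stop("`fg_level` and `bg_level` must differ", call. = FALSE)
  if (bias_amplitude < 0 || bias_amplitude >= 1)
    stop("`bias_amplitude` must be in [0, 1)", call. = FALSE)
  if (gap < 0 || gap >= 1) stop("`gap` must be in [0, 1)", call. = FALSE)
  if (inherits(objects, "phantom_shape")) objects <- list(objects)
  for (obj in objects) {
    ext <- shape_extent(obj)
    if (ext[1] - ext[3] < 1 || ext[1] + ext[3] > shape[1] ||
        ext[2] - ext[3] < 1 || ext[2] + ext[3] > shape[2])
      stop("phantom object extends outside the image frame", call. = FALSE)
  }
  structure(list(shape = as.integer(shape), objects = objects,
                 fg_level = fg_level, bg_level = bg_level,
                 bias_amplitude = bias_amplitude, bias_scale = bias_scale,
                 blur_sigma = blur_sigma, gap = gap, gap_angle = gap_angle,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom image and its ground-truth mask
#'
#' @param spec a [phantom_spec()].
#' @return list (class \code{phantom}) with \code{image} (numeric matrix)
#'   and \code{mask} (logical matrix, the undegraded ground truth).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$shape
  mask <- matrix(FALSE, dims[1], dims[2])
  for (obj in spec$objects) mask <- mask | rasterize_shape(obj, dims)
  img <- spec$bg_level + (spec$fg_level - spec$bg_level) * mask

  if (spec$gap > 0) {
    yy <- matrix(seq_len(dims[1]), dims[1], dims[2])
    xx <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
    for (obj in spec$objects) {
      d <- sqrt((yy - obj$center[1])^2 + (xx - obj$center[2])^2)
      theta <- (atan2(yy - obj$center[1], xx - obj$center[2]) -
                  spec$gap_angle) %% (2 * pi)
      sector <- theta < 2 * pi * spec$gap
      if (obj$type == "disc") {
        w <- 0.6 * obj$r
        s <- pmin(1, pmax(0, (obj$r + w - d) / (2 * w)))
        ramp <- spec$bg_level + (spec$fg_level - spec$bg_level) * s
        img[sector] <- ramp[sector]
      } else if (obj$type == "ring") {
        erase <- sector & d >= obj$r_in & d <= obj$r_out
        img[erase] <- spec$bg_level
      }
    }
  }

  if (spec$blur_sigma > 0)
    img <- conv_gauss(img, gaussian_kernel(spec$blur_sigma))

  withr::with_seed(spec$seed, {
    if (spec$bias_amplitude > 0) {
      yy <- matrix(seq_len(dims[1]), dims[1], dims[2])
      xx <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
      ang <- stats::runif(3, 0, pi)
      ph <- stats::runif(3, 0, 2 * pi)
      s <- matrix(0, dims[1], dims[2])
      for (m in 1:3)
        s <- s + cos(2 * pi * (cos(ang[m]) * xx + sin(ang[m]) * yy) /
                       spec$bias_scale + ph[m])
      s <- s / max(abs(s))
      img <- img * (1 + spec$bias_amplitude * s)
    }
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(prod(dims), 0, spec$noise_sigma),
                          dims[1], dims[2])
  })
  structure(list(image = img, mask = mask, spec = spec), class = "phantom")
}

#' Canonical fixture suite
#'
#' The seven named test regimes used throughout the test suite:
#' \code{clean-disc}, \code{bias-disc} (bias amplitude 0.4, noise at
#' contrast/10), \code{blurred-disc}, \code{gap-outline-disc} (20\% of the
#' boundary erased), \code{two-disc}, \code{drifting-disc} (a 9-slice stack
#' whose disc radius drifts 2 px per slice) and \code{vertebra-phantom}.
#'
#' @param seed base RNG seed; each fixture derives its own seed from it.
#' @return named list of 7 fixtures; each has \code{image}+\code{mask},
#'   except \code{drifting-disc} which has lists \code{images}+\code{masks}.
#' @export
fixture_suite <- function(seed = 1L) {
  seed <- as.integer(seed)
  gen <- function(...) generate_phantom(phantom_spec(...))
  out <- list()
  out[["clean-disc"]] <- gen(c(100, 100), shape_disc(c(50, 50), 25),
                             seed = seed)
  out[["bias-disc"]] <- gen(c(100, 100), shape_disc(c(50, 50), 25),
                            bias_amplitude = 0.4, bias_scale = 60,
                            noise_sigma = 15, seed = seed + 1L)
  out[["blurred-disc"]] <- gen(c(100, 100), shape_disc(c(50, 50), 25),
                               blur_sigma = 3, noise_sigma = 5,
                               seed = seed + 2L)
  out[["gap-outline-disc"]] <- gen(c(100, 100), shape_disc(c(50, 50), 25),
                                   gap = 0.2, gap_angle = pi / 4,
                                   seed = seed + 3L)
  out[["two-disc"]] <- gen(c(100, 100),
                           list(shape_disc(c(35, 30), 14),
                                shape_disc(c(65, 68), 16)),
                           noise_sigma = 5, seed = seed + 4L)
  radii <- 18 + 2 * seq_len(9)
  slices <- lapply(seq_along(radii), function(s)
    gen(c(100, 100), shape_disc(c(50, 50), radii[s]),
        bias_amplitude = 0.3, bias_scale = 60, noise_sigma = 10,
        seed = seed + 10L + s))
  out[["drifting-disc"]] <- list(
    images = lapply(slices, `[[`, "image"),
    masks = lapply(slices, `[[`, "mask"))
  out[["vertebra-phantom"]] <- gen(c(128, 128), shape_vertebra(c(64, 64), 32),
                                   bias_amplitude = 0.3, bias_scale = 80,
                                   noise_sigma = 8, seed = seed + 5L)
  out
}
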