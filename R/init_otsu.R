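# Fully automatic initialization: Otsu threshold -> rough foreground
# regions -> binary-step initial level set function. No human input is
# needed anywhere in the pipeline.

#' Otsu threshold
#'
#' Histogram threshold maximizing the between-class variance over an
#' \code{n_bins}-bin histogram spanning \code{[min(image), max(image)]}.
#' Ties are broken toward the smallest qualifying threshold. With 256 bins
#' on 8-bit-range data this reproduces classic integer-image behavior.
#'
#' @param image numeric matrix; must not be constant.
#' @param n_bins number of histogram bins.
#' @return the threshold (scalar, intensity units): pixels strictly above it
#'   form the bright class.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  check_field(image)
  r <- range(image)
  if (r[1] == r[2])
    stop("image is constant; Otsu threshold is undefined", call. = FALSE)
  n_bins <- as.integer(n_bins)
  breaks <- seq(r[1], r[2], length.out = n_bins + 1L)
  bin <- findInterval(image, breaks, all.inside = TRUE)
  counts <- tabulate(bin, n_bins)
  p <- counts / sum(counts)
  mid <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  s0 <- cumsum(p * mid)
  mu <- s0[n_bins]
  t_cand <- seq_len(n_bins - 1L)
  w0t <- w0[t_cand]
  valid <- w0t > 0 & w0t < 1
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mu * w0t[valid] - s0[t_cand][valid])^2 /
    (w0t[valid] * (1 - w0t[valid]))
  t_star <- which.max(bcv)  # first maximum = smallest threshold
  breaks[t_star + 1L]
}

#' Initialization configuration
#'
#' @param c0 positive step height of the initial level set function.
#' @param polarity which intensity class is foreground:
#'   \code{"bright"} (above the threshold; the CT bone convention),
#'   \code{"dark"}, or \code{"auto"} (the class with the higher mean).
#' @param min_region_px connected components of the thresholded foreground
#'   smaller than this many pixels are discarded (thresholded CT maps
#'   contain speckle that slows convergence); set 0 to disable.
#' @return object of class \code{init_config}.
#' @export
init_config <- function(c0 = 2, polarity = c("bright", "dark", "auto"),
                        min_region_px = 20L) {
  check_positive(c0, "c0")
  polarity <- match.arg(polarity)
  if (min_region_px < 0) stop("`min_region_px` must be >= 0", call. = FALSE)
  structure(list(c0 = c0, polarity = polarity,
                 min_region_px = as.integer(min_region_px)),
            class = "init_config")
}

#' Automatic initial level set function
#'
#' Thresholds the image with [otsu_threshold()], selects the foreground
#' class per \code{cfg$polarity}, removes components below
#' \code{cfg$min_region_px}, and returns the binary-step field
#' \eqn{\phi_0 = +c_0} on the foreground and \eqn{-c_0} elsewhere. A step
#' function (not a distance function) is deliberate: the
#' distance-regularization term of the evolution restores the slope, so no
#' distance transform is ever needed.
#'
#' @param image numeric matrix; must not be constant.
#' @param cfg an [init_config()].
#' @return level set field (matrix taking exactly the two values
#'   \code{+c0} and \code{-c0}).
#' @export
init_levelset <- function(image, cfg = init_config()) {
  thr <- otsu_threshold(image)
  bright <- image > thr
  fg <- switch(cfg$polarity,
    bright = bright,
    dark   = !bright,
    auto   = {
      mb <- if (any(bright)) mean(image[bright]) else -Inf
      md <- if (any(!bright)) mean(image[!bright]) else -Inf
      if (mb >= md) bright else !bright
    })
  if (cfg$min_region_px > 0L && any(fg)) {
    lab <- EBImage::bwlabel(fg * 1)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= cfg$min_region_px)
    fg <- matrix(lab %in% keep, nrow(image), ncol(image))
  }
  if (!any(fg))
    stop("empty foreground after thresholding/cleanup; ",
         "try the opposite `polarity` or min_region_px = 0", call. = FALSE)
  ifelse(fg, cfg$c0, -cfg$c0)
}

#' Segment a single image fully automatically
#'
#' Convenience wrapper: [init_levelset()] followed by [evolve()] (or the
#' LBF baseline).
#'
#' @param image intensity matrix.
#' @param params an [erbls_params()] or [lbf_params()] object, matching
#'   \code{model}.
#' @param cfg an [init_config()].
#' @param model \code{"erbls"} (default) or \code{"lbf"}.
#' @param spacing length-2 \code{c(dy, dx)}.
#' @param ... passed on to [evolve()] / [lbf_evolve()].
#' @return a \code{levelset_result}.
#' @export
segment_image <- function(image, params = NULL, cfg = init_config(),
                          model = c("erbls", "lbf"), spacing = c(1, 1),
                          ...) {
  model <- match.arg(model)
  phi0 <- init_levelset(image, cfg)
  if (model == "erbls") {
    if (is.null(params)) params <- erbls_params()
    evolve(image, phi0, params, spacing, ...)
  } else {
    if (is.null(params)) params <- lbf_params()
    lbf_evolve(image, phi0, params, spacing, ...)
  }
}
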