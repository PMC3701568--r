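# Slice-wise volumetric segmentation with slice-to-slice initialization
# propagation: neighboring CT slices have similar contours, so the final
# mask of one slice is a good (and cheap) initial level set for the next.

#' Segment an ordered stack of slices with propagated initialization
#'
#' The seed slice (default: the middle one, so propagation runs outward in
#' both directions and drift is halved) is initialized automatically with
#' [init_levelset()]. Every subsequent slice is initialized as the
#' binary-step field \eqn{+c_0} on the previous slice's final mask and
#' \eqn{-c_0} elsewhere. If a propagated initialization has an empty
#' foreground the slice falls back to Otsu initialization (with a message).
#' Evolution parameters are identical for every slice.
#'
#' @param slices list of intensity matrices (uniform shape), in slice order,
#'   or a 3D array with slices along the third dimension.
#' @param params an [erbls_params()].
#' @param cfg an [init_config()].
#' @param seed_slice index of the slice segmented first.
#' @param spacing length-3 \code{c(dy, dx, dz)} physical units.
#' @param verbose passed to [evolve()].
#' @return object of class \code{volume_result}: list with \code{masks}
#'   (list of logical matrices), \code{results} (list of
#'   \code{erbls_result}), \code{mask3d} (H x W x nslices logical array),
#'   \code{n_iter} (per-slice iteration counts), \code{seed_slice} and
#'   \code{spacing}.
#' @export
segment_stack <- function(slices, params = erbls_params(),
                          cfg = init_config(), seed_slice = NULL,
                          spacing = c(1, 1, 1), verbose = FALSE) {
  if (is.array(slices) && length(dim(slices)) == 3L)
    slices <- lapply(seq_len(dim(slices)[3]), function(k) slices[, , k])
  ns <- length(slices)
  if (ns < 1L) stop("need at least one slice", call. = FALSE)
  dims <- dim(slices[[1]])
  for (s in slices)
    if (!identical(dim(s), dims))
      stop("all slices must share one shape", call. = FALSE)
  if (is.null(seed_slice)) seed_slice <- (ns + 1L) %/% 2L
  seed_slice <- as.integer(seed_slice)
  if (seed_slice < 1L || seed_slice > ns)
    stop("`seed_slice` out of range", call. = FALSE)

  results <- vector("list", ns)
  sp2 <- spacing[1:2]
  run_from_mask <- function(idx, prev_mask) {
    if (!any(prev_mask)) {
      message(sprintf("slice %d: propagated init empty; falling back to Otsu",
                      idx))
      phi0 <- init_levelset(slices[[idx]], cfg)
    } else {
      phi0 <- ifelse(prev_mask, cfg$c0, -cfg$c0)
    }
    evolve(slices[[idx]], phi0, params, sp2, verbose = verbose)
  }

  results[[seed_slice]] <- evolve(slices[[seed_slice]],
                                  init_levelset(slices[[seed_slice]], cfg),
                                  params, sp2, verbose = verbose)
  if (seed_slice < ns)
    for (idx in (seed_slice + 1L):ns)
      results[[idx]] <- run_from_mask(idx, results[[idx - 1L]]$mask)
  if (seed_slice > 1L)
    for (idx in (seed_slice - 1L):1L)
      results[[idx]] <- run_from_mask(idx, results[[idx + 1L]]$mask)

  masks <- lapply(results, `[[`, "mask")
  mask3d <- array(FALSE, c(dims, ns))
  for (k in seq_len(ns)) mask3d[, , k] <- masks[[k]]
  structure(list(masks = masks, results = results, mask3d = mask3d,
                 n_iter = vapply(results, `[[`, integer(1), "n_iter"),
                 seed_slice = seed_slice, spacing = spacing),
            class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("<volume segmentation: %d slices of %dx%d, seed slice %d, mean %.1f iter/slice>\n",
              length(x$masks), dim(x$mask3d)[1], dim(x$mask3d)[2],
              x$seed_slice, mean(x$n_iter)))
  invisible(x)
}
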