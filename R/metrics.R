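# Segmentation accuracy metrics: Dice similarity coefficient and the
# symmetric Hausdorff distance between boundary point sets, both spacing
# aware so HD can be reported in physical units (mm).

#' Dice similarity coefficient
#'
#' \deqn{DSC(A, B) = \frac{2|A \cap B|}{|A| + |B|} \in [0, 1]:}
#' 1 for a perfect match, 0 for disjoint masks. Defined as 1 when both
#' masks are empty (vacuous agreement), which keeps batch evaluation free
#' of NaNs.
#'
#' @param a,b logical (or 0/1) arrays of the same shape, 2D or 3D.
#' @return scalar in [0, 1].
#' @export
dice <- function(a, b) {
  a <- as_binary(a); b <- as_binary(b)
  if (!identical(dim(a), dim(b)))
    stop("masks must have the same shape", call. = FALSE)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Morphological boundary of a binary mask
#'
#' Foreground elements with at least one background face-neighbor
#' (4-connectivity in 2D, 6-connectivity in 3D); positions outside the
#' array count as background, so foreground touching the frame is boundary.
#'
#' @param m logical 2D or 3D array.
#' @return logical array of the same shape.
#' @export
boundary_mask <- function(m) {
  m <- as_binary(m)
  d <- dim(m)
  if (is.null(d)) stop("mask must be a 2D or 3D array", call. = FALSE)
  has_bg <- array(FALSE, d)
  for (ax in seq_along(d)) {
    n <- d[ax]
    fwd <- shift_axis(m, ax, 1L)   # neighbor at +1 along ax, FALSE outside
    bwd <- shift_axis(m, ax, -1L)
    has_bg <- has_bg | !fwd | !bwd
  }
  m & has_bg
}

# Shift logical array by `by` along axis `ax`, filling with FALSE.
shift_axis <- function(m, ax, by) {
  d <- dim(m)
  idx <- seq_len(d[ax]) + by
  pad <- idx < 1L | idx > d[ax]
  idx[pad] <- 1L
  args <- rep(list(quote(expr = )), length(d))
  args[[ax]] <- idx
  out <- do.call(`[`, c(list(m), args, list(drop = FALSE)))
  args[[ax]] <- which(pad)
  if (any(pad)) out <- do.call(`[<-`, c(list(out), args, list(value = FALSE)))
  array(out, d)
}

#' Symmetric Hausdorff distance between mask boundaries
#'
#' \deqn{d_H(A,B) = \max\left(\sup_{a\in A}\inf_{b\in B} d(a,b),\;
#'                             \sup_{b\in B}\inf_{a\in A} d(a,b)\right)}
#' computed between the [boundary_mask()] point sets (element centers),
#' with Euclidean distance scaled by the per-axis \code{spacing}. Zero iff
#' the two boundaries coincide exactly.
#'
#' @param a,b non-empty logical arrays of the same shape.
#' @param spacing per-axis physical units, in the order of the array
#'   dimensions (e.g. \code{c(dy, dx)} or \code{c(dy, dx, dz)}).
#' @return scalar distance in physical units.
#' @export
hausdorff <- function(a, b, spacing = NULL) {
  a <- as_binary(a); b <- as_binary(b)
  if (!identical(dim(a), dim(b)))
    stop("masks must have the same shape", call. = FALSE)
  if (!any(a) || !any(b))
    stop("Hausdorff distance is undefined for empty masks", call. = FALSE)
  if (is.null(spacing)) spacing <- rep(1, length(dim(a)))
  if (length(spacing) != length(dim(a)))
    stop("`spacing` must have one entry per array dimension", call. = FALSE)
  pa <- sweep(which(boundary_mask(a), arr.ind = TRUE), 2, spacing, `*`)
  pb <- sweep(which(boundary_mask(b), arr.ind = TRUE), 2, spacing, `*`)
  max(directed_hd(pa, pb), directed_hd(pb, pa))
}

directed_hd <- function(pa, pb) {
  worst <- 0
  tpb <- t(pb)
  for (i in seq_len(nrow(pa))) {
    d2 <- min(colSums((tpb - pa[i, ])^2))
    if (d2 > worst) worst <- d2
  }
  sqrt(worst)
}

#' Batch evaluation of segmentations against ground truth
#'
#' @param pred,truth lists of masks (or single masks), pairwise comparable.
#' @param spacing per-axis physical units shared by all pairs.
#' @param ids labels for the rows; defaults to list names or indices.
#' @return data.frame with columns \code{id}, \code{dsc}, \code{hd}, plus a
#'   final \code{"mean±sd"} summary row.
#' @export
evaluate_masks <- function(pred, truth, spacing = NULL, ids = NULL) {
  if (!is.list(pred)) pred <- list(pred)
  if (!is.list(truth)) truth <- list(truth)
  if (length(pred) != length(truth))
    stop("`pred` and `truth` must have the same length", call. = FALSE)
  if (is.null(ids)) ids <- if (!is.null(names(pred))) names(pred)
                           else as.character(seq_along(pred))
  dscs <- mapply(dice, pred, truth)
  hds <- mapply(hausdorff, pred, truth, MoreArgs = list(spacing = spacing))
  out <- data.frame(id = ids, dsc = dscs, hd = hds,
                    stringsAsFactors = FALSE, row.names = NULL)
  summ <- data.frame(
    id = sprintf("mean±sd (n=%d)", length(dscs)),
    dsc = mean(dscs), hd = mean(hds), stringsAsFactors = FALSE)
  attr(out, "sd") <- c(dsc = stats::sd(dscs), hd = stats::sd(hds))
  rbind(out, summ)
}

as_binary <- function(m) {
  if (is.logical(m)) return(m)
  v <- unique(as.vector(m))
  if (!all(v %in% c(0, 1)))
    stop("mask must be logical or contain only 0/1", call. = FALSE)
  array(m > 0.5, dim(m))
}
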