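# Small deterministic fields used across tests.

box_phi <- function(dims, rows, cols, c0 = 2) {
  m <- matrix(FALSE, dims[1], dims[2])
  m[rows[1]:rows[2], cols[1]:cols[2]] <- TRUE
  ifelse(m, c0, -c0)
}

circ_phi <- function(dims, cy, cx, r, c0 = 2) {
  yy <- matrix(seq_len(dims[1]), dims[1], dims[2])
  xx <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  ifelse(sqrt((yy - cy)^2 + (xx - cx)^2) <= r, c0, -c0)
}

# signed distance to a circle, positive inside
disc_sdf <- function(dims, cy, cx, r) {
  yy <- matrix(seq_len(dims[1]), dims[1], dims[2])
  xx <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  r - sqrt((yy - cy)^2 + (xx - cx)^2)
}

# piecewise-constant bright disc, no degradation
two_phase <- function(dims = c(40, 40), cy = 20, cx = 20, r = 12,
                      fg = 200, bg = 50) {
  mask <- disc_sdf(dims, cy, cx, r) >= 0
  list(image = bg + (fg - bg) * mask, mask = mask)
}

rand_field <- function(n, m, scale = 1, seed = 1) {
  withr::with_seed(seed, matrix(stats::runif(n * m) * scale, n, m))
}

n_components <- function(mask) max(EBImage::bwlabel(mask * 1))

# are all `changed` pixels within `width` px (chessboard) of mask0's boundary?
within_band <- function(mask0, changed, width = 1) {
  if (!any(changed)) return(TRUE)
  bnd <- boundary_mask(mask0)
  band <- EBImage::dilate(bnd * 1,
                          EBImage::makeBrush(2L * width + 1L, "box")) > 0.5
  all(band[changed])
}
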