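# Independent brute-force oracles. Deliberately written as plain loops with
# their own boundary handling so they share no code path with the package.

# symmetric (edge-repeating) reflection of index i onto 1..n
o_refl <- function(i, n) {
  i <- (i - 1) %% (2 * n)
  ifelse(i < n, i + 1, 2 * n - i)
}

# full 2D convolution with the separable kernel's outer product
oracle_conv <- function(x, kern) {
  K <- outer(kern$k1d, kern$k1d)
  p <- (kern$size - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- 0
    for (a in -p:p) for (b in -p:p)
      s <- s + K[a + p + 1L, b + p + 1L] * x[o_refl(i + a, n), o_refl(j + b, m)]
    out[i, j] <- s
  }
  out
}

# central differences, replicated edges, via clamped indexing
oracle_grad <- function(f, spacing = c(1, 1)) {
  n <- nrow(f); m <- ncol(f)
  gy <- gx <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    gy[i, j] <- (f[min(i + 1L, n), j] - f[max(i - 1L, 1L), j]) / (2 * spacing[1])
    gx[i, j] <- (f[i, min(j + 1L, m)] - f[i, max(j - 1L, 1L)]) / (2 * spacing[2])
  }
  list(gy = gy, gx = gx)
}

oracle_lap <- function(f, spacing = c(1, 1)) {
  n <- nrow(f); m <- ncol(f)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    out[i, j] <-
      (f[min(i + 1L, n), j] + f[max(i - 1L, 1L), j] - 2 * f[i, j]) / spacing[1]^2 +
      (f[i, min(j + 1L, m)] + f[i, max(j - 1L, 1L)] - 2 * f[i, j]) / spacing[2]^2
  out
}

# literal term-by-term transcription of one ERBLS update, all pieces from
# the loop/brute oracles above (assumes healthy local-mean denominators)
oracle_erbls_step <- function(phi, image, params) {
  H <- 0.5 * (1 + (2 / pi) * atan(phi / params$eps))
  kern <- gaussian_kernel(params$sigma, params$kernel_size)
  ones <- matrix(1, nrow(image), ncol(image))
  c_one <- oracle_conv(ones, kern)
  c_img <- oracle_conv(image, kern)
  c_H <- oracle_conv(H, kern)
  c_IH <- oracle_conv(image * H, kern)
  c1 <- c_IH / c_H
  c2 <- (c_img - c_IH) / (c_one - c_H)
  raw <- image - (c1 + c2) / 2
  rdf <- raw / max(abs(raw))

  sm <- oracle_conv(image, gaussian_kernel(params$sigma_g))
  gs <- oracle_grad(sm)
  edf <- 1 / (1 + sqrt(gs$gy^2 + gs$gx^2))

  gp <- oracle_grad(phi)
  nrm <- sqrt(gp$gy^2 + gp$gx^2 + params$eta^2)
  ny <- gp$gy / nrm; nx <- gp$gx / nrm
  edge_div <- oracle_grad(edf * ny)$gy + oracle_grad(edf * nx)$gx
  curv <- oracle_grad(ny)$gy + oracle_grad(nx)$gx
  delta <- (1 / pi) * params$eps / (params$eps^2 + phi^2)

  phi + params$dt * (params$beta * delta * edge_div +
                     params$gamma * rdf * delta +
                     params$mu_reg * (oracle_lap(phi) - curv))
}

# exhaustive between-class-variance search over all n_bins candidate splits
oracle_otsu <- function(image, n_bins = 256L) {
  v <- as.vector(image)
  lo <- min(v); hi <- max(v)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- integer(n_bins)
  for (x in v) {
    b <- 1L
    while (b < n_bins && x >= breaks[b + 1L]) b <- b + 1L
    counts[b] <- counts[b] + 1L
  }
  p <- counts / length(v)
  mid <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  best <- -Inf; t_best <- NA_integer_
  for (t in seq_len(n_bins - 1L)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:t] * mid[1:t]) / w0
    mu1 <- sum(p[(t + 1L):n_bins] * mid[(t + 1L):n_bins]) / w1
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; t_best <- t }   # strict > keeps smallest
  }
  breaks[t_best + 1L]
}

oracle_dice <- function(a, b) {
  n_a <- 0L; n_b <- 0L; n_ab <- 0L
  for (i in seq_along(a)) {
    if (a[i]) n_a <- n_a + 1L
    if (b[i]) n_b <- n_b + 1L
    if (a[i] && b[i]) n_ab <- n_ab + 1L
  }
  if (n_a + n_b == 0L) 1 else 2 * n_ab / (n_a + n_b)
}

# face-neighbor boundary extraction by explicit neighbor loops (2D or 3D)
oracle_boundary_points <- function(m, spacing) {
  d <- dim(m)
  nd <- length(d)
  idx <- which(m, arr.ind = TRUE)
  pts <- NULL
  for (r in seq_len(nrow(idx))) {
    co <- idx[r, ]
    is_b <- FALSE
    for (ax in seq_len(nd)) for (s in c(-1L, 1L)) {
      nb <- co; nb[ax] <- nb[ax] + s
      if (nb[ax] < 1L || nb[ax] > d[ax]) { is_b <- TRUE
      } else {
        v <- if (nd == 2L) m[nb[1], nb[2]] else m[nb[1], nb[2], nb[3]]
        if (!v) is_b <- TRUE
      }
    }
    if (is_b) pts <- rbind(pts, co * spacing)
  }
  pts
}

oracle_hd <- function(a, b, spacing = NULL) {
  if (is.null(spacing)) spacing <- rep(1, length(dim(a)))
  pa <- oracle_boundary_points(a, spacing)
  pb <- oracle_boundary_points(b, spacing)
  dir_hd <- function(p, q) {
    worst <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q))) {
        d2 <- sum((p[i, ] - q[j, ])^2)
        if (d2 < best) best <- d2
      }
      if (best > worst) worst <- best
    }
    sqrt(worst)
  }
  max(dir_hd(pa, pb), dir_hd(pb, pa))
}
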