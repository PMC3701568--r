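# The ERBLS evolution: explicit Euler steps of the gradient flow
#   phi_t = beta * delta(phi) * div(edf * grad(phi)/|grad(phi)|)
#         + gamma * rdf * delta(phi)
#         + mu_reg * (laplacian(phi) - div(grad(phi)/|grad(phi)|))
# with a zero-set-stability stopping rule and no re-initialization ever.

#' ERBLS model parameters
#'
#' @param beta weight of the edge (geodesic curvature) term.
#' @param gamma weight of the region (signed pressure) term.
#' @param eps width of the regularized Heaviside/Dirac, in level-set units.
#' @param sigma scale (px) of the Gaussian kernel defining the local means.
#' @param sigma_g scale (px) of the Gaussian smoothing inside the edge
#'   detecting function. Plays a different role than \code{sigma} and is
#'   therefore configurable separately, though both default to 3.
#' @param kernel_size odd size of the local-mean kernel;
#'   default \code{2*ceiling(2*sigma)+1}.
#' @param dt explicit Euler time increment. Too large a \code{beta*dt} or
#'   \code{mu_reg*dt} destabilizes the explicit scheme; this surfaces as an
#'   evolution error reporting non-finite values.
#' @param mu_reg weight of the distance-regularization flow; the explicit
#'   scheme needs \code{mu_reg * dt < 1/4} to remain stable.
#' @param max_iter iteration cap.
#' @param stop_tol maximum number of changed zero-set (mask) pixels per
#'   iteration still counted as "stable".
#' @param stop_window number of consecutive stable iterations required to
#'   declare convergence.
#' @param eta soft guard added to gradient-magnitude denominators.
#' @return object of class \code{erbls_params}.
#' @export
erbls_params <- function(beta = 5, gamma = 2, eps = 1, sigma = 3,
                         sigma_g = 3, kernel_size = NULL, dt = 1,
                         mu_reg = 0.2, max_iter = 500L, stop_tol = 0L,
                         stop_window = 10L, eta = 1e-10) {
  for (nm in c("beta", "gamma", "eps", "sigma", "sigma_g", "dt", "mu_reg",
               "eta"))
    check_positive(get(nm), nm)
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("`max_iter` must be >= 1", call. = FALSE)
  if (stop_tol < 0) stop("`stop_tol` must be >= 0", call. = FALSE)
  structure(list(beta = beta, gamma = gamma, eps = eps, sigma = sigma,
                 sigma_g = sigma_g, kernel_size = kernel_size, dt = dt,
                 mu_reg = mu_reg, max_iter = max_iter,
                 stop_tol = as.integer(stop_tol),
                 stop_window = as.integer(stop_window), eta = eta),
            class = "erbls_params")
}

region_kernel <- function(params) {
  gaussian_kernel(params$sigma, params$kernel_size)
}

#' One explicit ERBLS evolution step
#'
#' Recomputes the local means and the region detecting function from the
#' current field (the fitting fields are held fixed within the step), then
#' applies one explicit Euler update of the three forces: edge-modulated
#' curvature, region pressure, and distance regularization.
#'
#' @param phi level set field (matrix).
#' @param image intensity matrix, same shape.
#' @param edf an [compute_edf()] result for this image.
#' @param cache a [build_conv_cache()] result for this image and the
#'   region kernel.
#' @param params an [erbls_params()] object.
#' @param spacing length-2 \code{c(dy, dx)}.
#' @return the updated level set field (matrix).
#' @export
erbls_step <- function(phi, image, edf, cache, params = erbls_params(),
                       spacing = c(1, 1)) {
  stopifnot(inherits(edf, "edge_map"), inherits(cache, "conv_cache"))
  means <- local_means(image, phi, cache, eps = params$eps)
  rdf <- compute_rdf(image, means)

  g <- gradient_c(phi, spacing)
  nrm <- sqrt(g$gy^2 + g$gx^2 + params$eta^2)
  ny <- g$gy / nrm
  nx <- g$gx / nrm
  edge_div <- divergence(edf$values * ny, edf$values * nx, spacing)
  curv <- divergence(ny, nx, spacing)
  delta <- dirac_reg(phi, params$eps)

  phi_new <- phi + params$dt * (
    params$beta * delta * edge_div +
    params$gamma * rdf$values * delta +
    params$mu_reg * (laplacian(phi, spacing) - curv)
  )
  if (!all(is.finite(phi_new)))
    stop("non-finite values in phi after evolution step; ",
         "reduce `dt` (or `beta`/`mu_reg`)", call. = FALSE)
  phi_new
}

#' Evolve a level set field to convergence under the ERBLS model
#'
#' Builds the edge map and the contour-independent convolution cache once,
#' then iterates [erbls_step()] until the binary mask \eqn{\{\phi > 0\}} has
#' changed by at most \code{stop_tol} pixels for \code{stop_window}
#' consecutive iterations, or \code{max_iter} is reached. The field is never
#' re-initialized: the distance-regularization term maintains its slope.
#'
#' @param image intensity matrix.
#' @param phi0 initial level set field (e.g. from [init_levelset()]).
#' @param params an [erbls_params()] object.
#' @param spacing length-2 \code{c(dy, dx)}.
#' @param verbose print a progress line every 25 iterations.
#' @param snapshot_every,snapshot_dir if set, dump \code{phi} as a CSV file
#'   every \code{snapshot_every} iterations into \code{snapshot_dir}.
#' @return object of class \code{erbls_result}: list with \code{phi},
#'   logical \code{mask} (\code{phi > 0}), \code{n_iter}, \code{converged},
#'   a per-iteration \code{history} data.frame (columns \code{iter},
#'   \code{zero_change}, \code{grad_dev} = mean abs deviation of
#'   \eqn{|\nabla\phi|} from 1), \code{params} and \code{model = "erbls"}.
#' @export
evolve <- function(image, phi0, params = erbls_params(), spacing = c(1, 1),
                   verbose = FALSE, snapshot_every = NULL,
                   snapshot_dir = NULL) {
  check_field(image)
  if (!identical(dim(image), dim(phi0)))
    stop("`image` and `phi0` must have the same shape", call. = FALSE)
  if (!all(is.finite(phi0))) stop("`phi0` contains non-finite values",
                                  call. = FALSE)
  kernel <- region_kernel(params)
  edf <- compute_edf(image, params$sigma_g, spacing)
  cache <- build_conv_cache(image, kernel)

  phi <- phi0
  mask_prev <- phi > 0
  stable <- 0L
  hist_change <- integer(0)
  hist_dev <- numeric(0)
  n_iter <- 0L
  converged <- FALSE

  for (it in seq_len(params$max_iter)) {
    phi <- tryCatch(
      erbls_step(phi, image, edf, cache, params, spacing),
      error = function(e) stop(sprintf("iteration %d: %s", it,
                                       conditionMessage(e)), call. = FALSE))
    n_iter <- it
    mask <- phi > 0
    change <- sum(mask != mask_prev)
    mask_prev <- mask
    g <- gradient_c(phi, spacing)
    hist_change[it] <- change
    hist_dev[it] <- mean(abs(sqrt(g$gy^2 + g$gx^2) - 1))
    stable <- if (change <= params$stop_tol) stable + 1L else 0L
    if (verbose && it %% 25L == 0L)
      message(sprintf("iter %4d  zero-set change %5d  grad dev %.4f",
                      it, change, hist_dev[it]))
    if (!is.null(snapshot_every) && it %% snapshot_every == 0L) {
      dir.create(snapshot_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(phi,
                         file.path(snapshot_dir, sprintf("phi_%05d.csv", it)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
    if (stable >= params$stop_window) { converged <- TRUE; break }
  }

  structure(list(phi = phi, mask = phi > 0, n_iter = n_iter,
                 converged = converged,
                 history = data.frame(iter = seq_len(n_iter),
                                      zero_change = hist_change,
                                      grad_dev = hist_dev),
                 params = params, model = "erbls"),
            class = c("erbls_result", "levelset_result"))
}

#' @export
print.levelset_result <- function(x, ...) {
  cat(sprintf("<%s segmentation: %dx%d, %d iterations, %s, %d fg px>\n",
              x$model, nrow(x$mask), ncol(x$mask), x$n_iter,
              if (x$converged) "converged" else "NOT converged",
              sum(x$mask)))
  invisible(x)
}

#' Plot a segmentation result
#'
#' Draws the image (if given) in grayscale with the final zero level set
#' overlaid as a contour line.
#'
#' @param x a \code{levelset_result}.
#' @param image optional intensity matrix to use as the backdrop.
#' @param ... passed to [graphics::contour()].
#' @export
plot.levelset_result <- function(x, image = NULL, ...) {
  n <- nrow(x$phi); m <- ncol(x$phi)
  if (!is.null(image)) {
    graphics::image(seq_len(m), seq_len(n), t(image[n:1, , drop = FALSE]),
                    col = grDevices::gray.colors(256, 0, 1), asp = 1,
                    xlab = "x", ylab = "y", useRaster = TRUE)
    graphics::contour(seq_len(m), seq_len(n), t(x$phi[n:1, , drop = FALSE]),
                      levels = 0, add = TRUE, col = "red", lwd = 2,
                      drawlabels = FALSE, ...)
  } else {
    graphics::contour(seq_len(m), seq_len(n), t(x$phi[n:1, , drop = FALSE]),
                      levels = 0, col = "red", lwd = 2, drawlabels = FALSE,
                      asp = 1, ...)
  }
  invisible(x)
}
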