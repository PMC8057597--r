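# Forward degradation model and synthetic fixtures: peak scaling, periodic
# blur, Poisson sampling, named blur kernels and test phantoms.

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Scale an image to a preset peak intensity
#'
#' Multiplies the image by `max_f / max(f)` so its maximum is exactly
#' `max_f` (photons). Lower peaks give relatively stronger Poisson noise.
#'
#' @param f numeric matrix with at least one positive entry.
#' @param max_f target peak, `> 0`.
#' @return Rescaled matrix.
#' @export
scale_to_peak <- function(f, max_f) {
  if (!is.finite(max_f) || max_f <= 0)
    stop("'max_f' must be positive", call. = FALSE)
  m <- max(f)
  if (m <= 0) stop("image must have a positive entry to scale", call. = FALSE)
  f * (max_f / m)
}

#' Degradation specification
#'
#' @param max_f peak photon count of the scaled clean image.
#' @param kernel a [blur_kernel()]; defaults to the identity (pure noise).
#' @param seed integer RNG seed, recorded in output metadata.
#' @return A list of class `degradation_spec`.
#' @export
degradation_spec <- function(max_f, kernel = identity_kernel(), seed = 1L) {
  if (!is.finite(max_f) || max_f <= 0)
    stop("'max_f' must be positive", call. = FALSE)
  stopifnot(inherits(kernel, "blur_kernel"))
  structure(list(max_f = max_f, kernel = kernel, seed = as.integer(seed)),
            class = "degradation_spec")
}

#' Simulate blur and Poisson noise
#'
#' Applies the forward model: scale the clean image to peak `spec$max_f`,
#' blur it by periodic convolution with `spec$kernel`, then draw each pixel
#' independently from a Poisson distribution with that blurred intensity as
#' mean (zero background). Sampling uses R's Mersenne-Twister stream seeded
#' with `spec$seed` (the caller's RNG state is untouched), so the output is
#' reproducible bit for bit.
#'
#' @param f clean image, nonnegative square matrix.
#' @param spec a [degradation_spec()].
#' @return Integer-valued matrix of simulated photon counts, with attributes
#'   `max_f`, `seed` and `clean` (the scaled clean image, for evaluation).
#' @export
degrade <- function(f, spec) {
  check_image(f, arg = "f")
  stopifnot(inherits(spec, "degradation_spec"))
  if (any(f < 0)) stop("clean image must be nonnegative", call. = FALSE)
  scaled <- scale_to_peak(f, spec$max_f)
  mean_img <- apply_blur(scaled, spec$kernel)
  # periodic convolution of a nonnegative image by a nonnegative kernel;
  # clamp FFT round-off at zero so the Poisson mean is valid
  if (any(mean_img < -1e-8 * spec$max_f))
    stop("blurred mean has negative entries", call. = FALSE)
  mean_img <- pmax(mean_img, 0)
  g <- with_seed(spec$seed,
                 matrix(stats::rpois(length(mean_img), mean_img),
                        nrow(mean_img), ncol(mean_img)))
  g <- g * 1.0
  attr(g, "max_f") <- spec$max_f
  attr(g, "seed") <- spec$seed
  attr(g, "clean") <- scaled
  g
}

#' Gaussian blur kernel
#'
#' Isotropic Gaussian sampled at integer offsets from the central element,
#' truncated to `size x size` and normalised to sum 1. Mimics out-of-focus
#' blur; the published protocol uses `size = 9`, `sigma = 1`.
#'
#' @param size odd kernel side length.
#' @param sigma standard deviation in pixels, `> 0`.
#' @return A [blur_kernel()].
#' @export
make_gaussian_kernel <- function(size = 9L, sigma = 1) {
  if (size < 1 || size %% 2 == 0)
    stop("'size' must be odd (no unambiguous centre otherwise)", call. = FALSE)
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  r <- (size - 1) / 2
  off <- seq(-r, r)
  w <- exp(-outer(off^2, off^2, "+") / (2 * sigma^2))
  blur_kernel(w / sum(w))
}

#' Linear motion blur kernel
#'
#' Weights supported on the discretised line segment of the given length
#' through the kernel centre, at `angle_deg` counterclockwise from the
#' horizontal axis. A pixel whose centre projects onto the segment and lies
#' within half a pixel of the line gets weight `1 - d`, `d` its
#' perpendicular distance to the line; weights are normalised to sum 1.
#' For 45 degrees the support lies on the main anti-diagonal.
#'
#' @param length motion length in pixels, `>= 1` (1 gives the identity).
#' @param angle_deg counterclockwise angle in degrees.
#' @return A [blur_kernel()].
#' @export
make_motion_kernel <- function(length = 5, angle_deg = 45) {
  if (!is.finite(length) || length < 1)
    stop("'length' must be at least 1", call. = FALSE)
  if (length == 1) return(identity_kernel())
  theta <- angle_deg * pi / 180
  half <- (length - 1) / 2
  r <- ceiling(half)
  size <- 2L * r + 1L
  # image row index increases downwards; counterclockwise angle means the
  # line rises with x, i.e. the row offset decreases
  ux <- cos(theta); uy <- -sin(theta)
  off <- seq(-r, r)
  w <- matrix(0, size, size)
  for (i in seq_len(size)) {
    for (j in seq_len(size)) {
      dy <- off[i]; dx <- off[j]
      along <- dx * ux + dy * uy
      perp <- abs(dx * uy - dy * ux)
      # half-pixel perpendicular cutoff keeps the support one pixel wide
      # (a gapless Bresenham-like trace at any angle)
      if (abs(along) <= half + 0.5 && perp <= 0.5)
        w[i, j] <- 1 - perp
    }
  }
  blur_kernel(w / sum(w))
}

#' Synthetic test phantoms
#'
#' Deterministic (per seed) clean images in `[0, 1]` exercising the two
#' failure modes the hybrid regulariser targets. `disks` is piecewise
#' constant — randomly placed disks of a few distinct intensities on a flat
#' background — stressing edge preservation and staircase behaviour.
#' `ramp_blocks` abuts smooth linear ramps against flat blocks, stressing
#' over-smoothing: first-order-only priors turn its ramps into staircases.
#'
#' @param n image side, `>= 16`.
#' @param kind `"disks"` or `"ramp_blocks"`.
#' @param seed integer seed controlling placement.
#' @return An `n x n` matrix with values in `[0, 1]`.
#' @export
make_phantom <- function(n, kind = c("disks", "ramp_blocks"), seed = 1L) {
  kind <- match.arg(kind)
  if (n < 16) stop("'n' must be at least 16", call. = FALSE)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  if (kind == "disks") {
    f <- matrix(0.15, n, n)
    levels <- c(0.45, 0.75, 1.0)
    with_seed(seed, {
      for (d in 1:3) {
        cx <- stats::runif(1, 0.2 * n, 0.8 * n)
        cy <- stats::runif(1, 0.2 * n, 0.8 * n)
        rad <- stats::runif(1, 0.1 * n, 0.2 * n)
        f[(rows - cy)^2 + (cols - cx)^2 <= rad^2] <- levels[d]
      }
    })
  } else {
    f <- matrix(0.1, n, n)
    half <- floor(n / 2)
    # left half: horizontal linear ramp from 0.1 to 0.9
    ramp <- 0.1 + 0.8 * (cols - 1) / (n - 1)
    f[, seq_len(half)] <- ramp[, seq_len(half)]
    with_seed(seed, {
      # right half: two flat blocks at seeded levels
      lev <- stats::runif(2, 0.4, 1.0)
      q1 <- half + 1L + floor((n - half) / 8)
      q2 <- n - floor((n - half) / 8)
      mid <- floor((q1 + q2) / 2)
      top <- floor(n / 6); bot <- floor(n / 2.2)
      f[top:bot, q1:mid] <- lev[1]
      f[(n - bot):(n - top), (mid + 1L):q2] <- lev[2]
    })
  }
  f
}
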