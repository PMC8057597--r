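# Image-quality metrics in the exact form used to report results: PSNR from
# the peak intensity, and a single global-statistics SSIM.

#' Peak signal-to-noise ratio
#'
#' `20 * log10(n * max_f / ||f - fhat||_2)` for `n x n` images, which equals
#' `20 * log10(max_f / RMSE)`. Identical images give `Inf`.
#'
#' @param f reference (clean) image.
#' @param fhat estimate, same shape.
#' @param max_f peak intensity the images are scaled to.
#' @return PSNR in dB.
#' @export
psnr <- function(f, fhat, max_f) {
  if (!all(dim(f) == dim(fhat))) stop("image shapes differ", call. = FALSE)
  if (!is.finite(max_f) || max_f <= 0)
    stop("'max_f' must be positive", call. = FALSE)
  err <- sqrt(sum((f - fhat)^2))
  if (err == 0) return(Inf)
  20 * log10(nrow(f) * max_f / err)
}

#' Structural similarity (global form)
#'
#' Evaluates the SSIM formula once over the whole image using global means,
#' variances and covariance (population, 1/n^2, convention) with constants
#' `C1 = max_f^2 / 1e4` and `C2 = 9 * max_f^2 / 1e4`. This is the single
#' global-statistics index used in the reported tables, not the
#' sliding-window local SSIM common elsewhere; set `windowed = TRUE` for a
#' mean-of-local-windows variant (box window) for comparison. The value is
#' 1 for identical images, can be negative for anti-correlated ones, and is
#' never clamped.
#'
#' @inheritParams psnr
#' @param windowed if `TRUE`, average the same formula over all `win x win`
#'   sliding windows instead of using global statistics.
#' @param win window side for the windowed variant.
#' @return SSIM value, `<= 1`.
#' @export
ssim <- function(f, fhat, max_f, windowed = FALSE, win = 8L) {
  if (!all(dim(f) == dim(fhat))) stop("image shapes differ", call. = FALSE)
  if (!is.finite(max_f) || max_f <= 0)
    stop("'max_f' must be positive", call. = FALSE)
  c1 <- max_f^2 / 1e4
  c2 <- 9 * max_f^2 / 1e4
  ssim_stat <- function(mx, my, vx, vy, cxy)
    ((2 * mx * my + c1) * (2 * cxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  if (!windowed) {
    npix <- length(f)
    mx <- mean(f); my <- mean(fhat)
    vx <- sum((f - mx)^2) / npix
    vy <- sum((fhat - my)^2) / npix
    cxy <- sum((f - mx) * (fhat - my)) / npix
    return(ssim_stat(mx, my, vx, vy, cxy))
  }
  n <- nrow(f)
  if (win > n) stop("'win' larger than image", call. = FALSE)
  vals <- numeric(0)
  for (i in seq_len(n - win + 1L)) {
    for (j in seq_len(n - win + 1L)) {
      a <- f[i:(i + win - 1L), j:(j + win - 1L)]
      b <- fhat[i:(i + win - 1L), j:(j + win - 1L)]
      mx <- mean(a); my <- mean(b)
      vals <- c(vals, ssim_stat(mx, my,
                                sum((a - mx)^2) / length(a),
                                sum((b - my)^2) / length(b),
                                sum((a - mx) * (b - my)) / length(a)))
    }
  }
  mean(vals)
}

#' Quality report for a restored image
#'
#' @inheritParams psnr
#' @return A list of class `quality_report` with `psnr`, `ssim` and `max_f`.
#' @export
quality_report <- function(f, fhat, max_f) {
  structure(list(psnr = psnr(f, fhat, max_f),
                 ssim = ssim(f, fhat, max_f), max_f = max_f),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("PSNR %.2f dB, SSIM %.4f (peak %g)\n", x$psnr, x$ssim, x$max_f))
  invisible(x)
}
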