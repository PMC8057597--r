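# Periodic finite-difference operators, their adjoints, TV functionals and
# frequency-domain transfer spectra. All operators assume periodic boundary
# conditions; images are n x n real matrices.

#' @keywords internal
check_image <- function(f, min_n = 2L, arg = "f") {
  if (!is.matrix(f) || !is.numeric(f))
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  if (nrow(f) != ncol(f))
    stop(sprintf("'%s' must be square (got %d x %d)", arg, nrow(f), ncol(f)),
         call. = FALSE)
  if (nrow(f) < min_n)
    stop(sprintf("'%s' must be at least %d x %d", arg, min_n, min_n),
         call. = FALSE)
  invisible(f)
}

# Circular shifts: shift_cols(f, 1)[i, j] == f[i, j + 1] with wraparound.
shift_cols <- function(f, k) {
  n <- ncol(f)
  f[, ((seq_len(n) - 1L + k) %% n) + 1L, drop = FALSE]
}
shift_rows <- function(f, k) {
  n <- nrow(f)
  f[((seq_len(n) - 1L + k) %% n) + 1L, , drop = FALSE]
}

# Single-channel first differences (periodic). d1 acts along columns
# (horizontal direction), d2 along rows (vertical direction).
d1_plus  <- function(f) shift_cols(f, 1L) - f
d2_plus  <- function(f) shift_rows(f, 1L) - f
d1_minus <- function(f) f - shift_cols(f, -1L)
d2_minus <- function(f) f - shift_rows(f, -1L)

# Adjoints under the standard (unweighted) inner product:
# t(D1+) = -D1-, t(D1-) = -D1+, and likewise for rows.
d1_plus_t  <- function(u) shift_cols(u, -1L) - u
d2_plus_t  <- function(u) shift_rows(u, -1L) - u
d1_minus_t <- function(u) u - shift_cols(u, 1L)
d2_minus_t <- function(u) u - shift_rows(u, 1L)

#' Forward first differences of an image
#'
#' Computes the periodic forward-difference gradient: the horizontal channel
#' holds `f[i, j + 1] - f[i, j]` (column `n` wrapping to column 1) and the
#' vertical channel `f[i + 1, j] - f[i, j]` (row wraparound).
#'
#' @param f square numeric matrix (the image).
#' @return A list of class `gradient_field` with matrices `horizontal` and
#'   `vertical`.
#' @examples
#' g <- forward_diff(matrix(1:4, 2, byrow = TRUE))
#' g$horizontal  # each row sums to zero by periodicity
#' @export
forward_diff <- function(f) {
  check_image(f)
  structure(list(horizontal = d1_plus(f), vertical = d2_plus(f)),
            class = "gradient_field")
}

#' Backward first differences of an image
#'
#' @inheritParams forward_diff
#' @return A `gradient_field` list with `horizontal` and `vertical` channels
#'   holding the periodic backward differences.
#' @export
backward_diff <- function(f) {
  check_image(f)
  structure(list(horizontal = d1_minus(f), vertical = d2_minus(f)),
            class = "gradient_field")
}

#' Second-order differences of an image
#'
#' The four channels are compositions of periodic first-order operators:
#' `c11` is the backward-of-forward horizontal difference, `c22` the
#' backward-of-forward vertical difference, and `c12`, `c21` the two mixed
#' forward-forward differences. On a periodic grid `c12` and `c21` coincide;
#' both are kept so the curvature field has the full 4 n^2 dimensionality.
#'
#' @inheritParams forward_diff
#' @return A list of class `curvature_field` with matrices `c11`, `c12`,
#'   `c21`, `c22`.
#' @export
second_order_diff <- function(f) {
  check_image(f)
  g1 <- d1_plus(f)
  g2 <- d2_plus(f)
  structure(list(c11 = d1_minus(g1), c12 = d1_plus(g2),
                 c21 = d2_plus(g1), c22 = d2_minus(g2)),
            class = "curvature_field")
}

#' Adjoint of the forward gradient
#'
#' Exact adjoint of [forward_diff()] under the standard inner product, so
#' that `sum(forward_diff(f)$horizontal * v$horizontal) + ... ==
#' sum(f * adjoint_grad(v))` for any image `f`. Applied to the gradient of
#' `f` it returns the negative periodic Laplacian of `f`.
#'
#' @param v a `gradient_field` (or list with `horizontal`/`vertical`).
#' @return Square numeric matrix.
#' @export
adjoint_grad <- function(v) {
  d1_plus_t(v$horizontal) + d2_plus_t(v$vertical)
}

#' Adjoint of the second-order difference operator
#'
#' @param v a `curvature_field` (or list with `c11`, `c12`, `c21`, `c22`).
#' @return Square numeric matrix, the exact adjoint image of
#'   [second_order_diff()].
#' @export
adjoint_second <- function(v) {
  # t(B A) = t(A) t(B) for each composed channel
  d1_plus_t(d1_minus_t(v$c11)) + d2_plus_t(d1_plus_t(v$c12)) +
    d1_plus_t(d2_plus_t(v$c21)) + d2_plus_t(d2_minus_t(v$c22))
}

#' First- and second-order total variation
#'
#' `tv_value` sums the pixelwise Euclidean norms of the forward gradient;
#' `htv_value` does the same for the four-channel second-difference field.
#'
#' @inheritParams forward_diff
#' @return Nonnegative scalar.
#' @export
tv_value <- function(f) {
  g <- forward_diff(f)
  sum(sqrt(g$horizontal^2 + g$vertical^2))
}

#' @rdname tv_value
#' @export
htv_value <- function(f) {
  s <- second_order_diff(f)
  sum(sqrt(s$c11^2 + s$c12^2 + s$c21^2 + s$c22^2))
}

#' Blur kernel constructor
#'
#' Wraps a small nonnegative matrix of point-spread weights (normalised to
#' sum 1) together with its anchor, the element placed on the pixel being
#' blurred. The anchor defaults to the central element
#' `(ceiling(k1/2), ceiling(k2/2))`.
#'
#' @param weights numeric matrix of kernel weights, all `>= 0`.
#' @param anchor integer `(row, col)` of the kernel centre.
#' @param normalize if `TRUE` (default) rescale weights to sum exactly 1; a
#'   raw sum off by more than 1e-6 triggers a warning.
#' @return An object of class `blur_kernel`.
#' @export
blur_kernel <- function(weights, anchor = NULL, normalize = TRUE) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("kernel weights must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("kernel weights must be finite and nonnegative", call. = FALSE)
  s <- sum(weights)
  if (s <= 0) stop("kernel weights must have positive sum", call. = FALSE)
  if (normalize) {
    if (abs(s - 1) > 1e-6)
      warning(sprintf("kernel weights sum to %.8g; renormalising to 1", s))
    weights <- weights / s
  }
  if (is.null(anchor))
    anchor <- c(ceiling(nrow(weights) / 2), ceiling(ncol(weights) / 2))
  anchor <- as.integer(anchor)
  if (length(anchor) != 2L || any(anchor < 1L) ||
      anchor[1] > nrow(weights) || anchor[2] > ncol(weights))
    stop("anchor must index an element of the kernel", call. = FALSE)
  structure(list(weights = weights, anchor = anchor), class = "blur_kernel")
}

#' @export
print.blur_kernel <- function(x, ...) {
  cat(sprintf("blur_kernel: %d x %d, anchor (%d, %d), sum %.6f\n",
              nrow(x$weights), ncol(x$weights), x$anchor[1], x$anchor[2],
              sum(x$weights)))
  invisible(x)
}

#' Identity (no-blur) kernel
#' @return A 1 x 1 `blur_kernel` acting as the identity operator.
#' @export
identity_kernel <- function() blur_kernel(matrix(1, 1, 1))

#' Transfer spectrum of a periodic convolution kernel
#'
#' Embeds the kernel in an `n x n` grid, circularly shifts its anchor to the
#' grid origin and returns the 2-D DFT — the eigenvalues of the periodic
#' convolution operator (the OTF of the PSF). Applying the operator via
#' `Re(fft(spec * fft(f), inverse = TRUE)) / n^2` equals direct periodic
#' convolution.
#'
#' @param kernel a [blur_kernel()].
#' @param n image side length; the kernel must fit in `n x n`.
#' @return Complex `n x n` matrix.
#' @export
kernel_to_transfer <- function(kernel, n) {
  stopifnot(inherits(kernel, "blur_kernel"))
  k <- kernel$weights
  if (nrow(k) > n || ncol(k) > n)
    stop(sprintf("kernel (%d x %d) larger than image (%d x %d)",
                 nrow(k), ncol(k), n, n), call. = FALSE)
  pad <- matrix(0, n, n)
  pad[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  pad <- shift_rows(shift_cols(pad, kernel$anchor[2] - 1L), kernel$anchor[1] - 1L)
  stats::fft(pad)
}

# Spectrum of a linear shift-invariant operator from its impulse response.
operator_spectrum <- function(op, n) {
  delta <- matrix(0, n, n)
  delta[1, 1] <- 1
  stats::fft(op(delta))
}

# Apply an operator given its spectrum (real part taken: real input/output).
apply_spectrum <- function(spec, f) {
  n <- nrow(f)
  Re(stats::fft(spec * stats::fft(f), inverse = TRUE)) / (n * n)
}

#' Apply a blur kernel to an image by periodic convolution
#'
#' @param f square numeric matrix.
#' @param kernel a [blur_kernel()], or a precomputed [transfer_set()].
#' @return Blurred image, same size as `f`.
#' @export
apply_blur <- function(f, kernel) {
  check_image(f)
  spec <- if (inherits(kernel, "transfer_set")) kernel$h_spec
          else kernel_to_transfer(kernel, nrow(f))
  apply_spectrum(spec, f)
}

#' Precompute the transfer spectra used by the ADMM image update
#'
#' Computes and caches the frequency-domain spectra of the blur kernel, the
#' two first-difference operators and the four second-difference operators on
#' an `n x n` periodic grid, plus the real positive denominator
#' `C = delta1 |F(H)|^2 + delta2 sum |F(grad)|^2 + delta3 sum |F(grad2)|^2`
#' of the FFT-diagonalised normal equation.
#'
#' @param kernel a [blur_kernel()].
#' @param n image side length.
#' @param delta length-3 positive penalty vector `(delta1, delta2, delta3)`.
#' @return An object of class `transfer_set`.
#' @export
transfer_set <- function(kernel, n, delta) {
  if (length(delta) != 3L || any(!is.finite(delta)) || any(delta < 0))
    stop("'delta' must be three finite nonnegative penalties", call. = FALSE)
  h  <- kernel_to_transfer(kernel, n)
  d1 <- operator_spectrum(d1_plus, n)
  d2 <- operator_spectrum(d2_plus, n)
  s11 <- d1 * operator_spectrum(d1_minus, n)   # spectra of compositions multiply
  s12 <- d2 * d1
  s21 <- d1 * d2
  s22 <- d2 * operator_spectrum(d2_minus, n)
  denom <- delta[1] * Mod(h)^2 +
    delta[2] * (Mod(d1)^2 + Mod(d2)^2) +
    delta[3] * (Mod(s11)^2 + Mod(s12)^2 + Mod(s21)^2 + Mod(s22)^2)
  structure(list(h_spec = h, d1_spec = d1, d2_spec = d2,
                 s11_spec = s11, s12_spec = s12, s21_spec = s21,
                 s22_spec = s22, denom = denom, delta = delta, n = n,
                 kernel = kernel),
            class = "transfer_set")
}
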