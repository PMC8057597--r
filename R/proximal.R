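# Per-iteration subproblem solvers: the closed-form Poisson data update, the
# MM solver for the overlapping-group-sparse (OGS) proximal problem, the IRLS
# solver for the lp proximal problem, and the fidelity/regulariser values.

# Zero-padded sliding-window sum: out[r, t] = sum over offsets a, b in
# [off_lo, off_hi] of x[r + a, t + b], out-of-range entries contributing 0.
window_sum <- function(x, off_lo, off_hi) {
  n1 <- nrow(x); n2 <- ncol(x)
  out <- matrix(0, n1, n2)
  for (a in off_lo:off_hi) {
    rs <- seq_len(n1) + a
    ok_r <- rs >= 1L & rs <= n1
    if (!any(ok_r)) next
    for (b in off_lo:off_hi) {
      cs <- seq_len(n2) + b
      ok_c <- cs >= 1L & cs <= n2
      if (!any(ok_c)) next
      out[ok_r, ok_c] <- out[ok_r, ok_c] + x[rs[ok_r], cs[ok_c]]
    }
  }
  out
}

group_offsets <- function(K) {
  m1 <- floor((K - 1) / 2)
  m2 <- floor(K / 2)
  c(-m1, m2)
}

#' MM weights for the overlapping-group-sparse proximal problem
#'
#' Computes, for every pixel, the diagonal entry of the quadratic-majorizer
#' weight matrix: the sum over all K x K groups containing the pixel of the
#' reciprocal group norm. Group windows extend `m1 = floor((K-1)/2)` back and
#' `m2 = floor(K/2)` forward in each direction; indices falling outside the
#' grid contribute zero (zero extension). A small `safeguard` is added inside
#' the inner square root so weights stay finite when a group has zero energy.
#'
#' @param u numeric matrix of current coefficients.
#' @param K group size (window side length), `1 <= K <= min(dim(u))`.
#' @param safeguard small positive scalar added to each group energy.
#' @return Matrix of strictly positive weights, same shape as `u`.
#' @export
group_weights <- function(u, K, safeguard = 1e-12) {
  if (K < 1 || K > min(dim(u)))
    stop("group size K must satisfy 1 <= K <= min(dim(u))", call. = FALSE)
  if (!is.finite(safeguard) || safeguard <= 0)
    stop("'safeguard' must be a small positive number", call. = FALSE)
  off <- group_offsets(K)
  # energy of the group centred at each pixel, then one over its norm,
  # then sum over the (flipped) window of groups containing each pixel
  energy <- window_sum(u * u, off[1], off[2])
  window_sum(1 / sqrt(energy + safeguard), -off[2], -off[1])
}

#' Overlapping-group-sparsity functional
#'
#' `sum over (i, j) of the Euclidean norm of the K x K group centred at
#' (i, j)`, with out-of-range group entries treated as zero. For `K = 1` this
#' is the entrywise absolute sum.
#'
#' @inheritParams group_weights
#' @param v numeric matrix.
#' @return Nonnegative scalar.
#' @export
ogs_value <- function(v, K) {
  if (K < 1 || K > min(dim(v)))
    stop("group size K must satisfy 1 <= K <= min(dim(v))", call. = FALSE)
  off <- group_offsets(K)
  sum(sqrt(window_sum(v * v, off[1], off[2])))
}

#' MM solver for the overlapping-group-sparse proximal problem
#'
#' Approximately minimises `0.5 ||v - v0||^2 + lam_mm * phi_OGS(v)` by
#' majorization-minimization: each inner iteration replaces the group
#' functional with its quadratic majorizer at the current iterate, whose
#' minimiser is the componentwise shrinkage
#' `v <- v0 / (1 + lam_mm * w)` with `w = group_weights(v, K)` (the sum,
#' over the groups containing each pixel, of the reciprocal group norm).
#' The surrogate objective is non-increasing across iterations and every
#' iterate satisfies `|v| <= |v0|` componentwise with matching signs.
#'
#' @param v0 numeric matrix, the proximal centre.
#' @param lam_mm positive regularisation weight.
#' @param K group size.
#' @param n_inner number of MM iterations (fixed count, no tolerance test).
#' @param safeguard passed to [group_weights()].
#' @return Matrix of the same shape as `v0`.
#' @export
ogs_prox <- function(v0, lam_mm, K, n_inner = 5L, safeguard = 1e-12) {
  if (!is.finite(lam_mm) || lam_mm <= 0)
    stop("'lam_mm' must be positive", call. = FALSE)
  if (n_inner < 1) stop("'n_inner' must be at least 1", call. = FALSE)
  v <- v0
  for (k in seq_len(n_inner)) {
    w <- group_weights(v, K, safeguard)
    v <- v0 / (1 + lam_mm * w)
  }
  v
}

#' IRLS solver for the lp proximal problem
#'
#' Approximately minimises `0.5 ||z - z0||^2 + lam_irls * sum |z_i|^p` for
#' `0 < p < 1` by iteratively reweighted least squares on the smoothed
#' penalty `sum (z_i^2 + epsilon)^(p/2)`: each iteration computes weights
#' `omega = lam_irls * p * (z^2 + epsilon)^(p/2 - 1)` and shrinks
#' `z <- z0 / (1 + omega)`. The smoothed objective is non-increasing; the
#' iteration converges to a local minimiser (the problem is nonconvex).
#'
#' @param z0 numeric array (any shape), the proximal centre.
#' @param lam_irls nonnegative penalty weight.
#' @param p exponent in `(0, 1)`.
#' @param epsilon small positive smoothing constant.
#' @param n_irls number of IRLS iterations.
#' @return Array of the same shape as `z0`.
#' @export
lp_prox_irls <- function(z0, lam_irls, p, epsilon = 1e-6, n_irls = 5L) {
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("'p' must lie strictly in (0, 1)", call. = FALSE)
  if (!is.finite(lam_irls) || lam_irls < 0)
    stop("'lam_irls' must be nonnegative", call. = FALSE)
  if (!is.finite(epsilon) || epsilon <= 0)
    stop("'epsilon' must be positive", call. = FALSE)
  z <- z0
  for (k in seq_len(n_irls)) {
    omega <- lam_irls * p * (z * z + epsilon)^(p / 2 - 1)
    z <- z0 / (1 + omega)
  }
  z
}

#' Closed-form Poisson data update
#'
#' Solves the separable x1-subproblem of the ADMM: per pixel, the unique
#' nonnegative root of the optimality condition of
#' `lam * KL(x1 || g) + delta1/2 * ||x1 - Hf + w1/delta1||^2`
#' (background fixed at zero), namely
#' `x1 = 0.5 * (t + sqrt(t^2 + 4 lam g / delta1))` with
#' `t = Hf - (w1 + lam)/delta1`.
#'
#' @param blur_est matrix `Hf`, the current blurred estimate.
#' @param mult matrix `w1` of Lagrange multipliers.
#' @param g observed (photon-count) image, elementwise `>= 0`.
#' @param lam positive fidelity weight.
#' @param delta1 positive penalty parameter.
#' @return Matrix `x1`, nonnegative wherever `g >= 0`.
#' @export
poisson_data_update <- function(blur_est, mult, g, lam, delta1) {
  if (!is.finite(lam) || lam <= 0) stop("'lam' must be positive", call. = FALSE)
  if (!is.finite(delta1) || delta1 <= 0)
    stop("'delta1' must be positive", call. = FALSE)
  if (any(g < 0)) stop("observed image 'g' must be nonnegative", call. = FALSE)
  t0 <- blur_est - (mult + lam) / delta1
  0.5 * (t0 + sqrt(t0 * t0 + 4 * lam * g / delta1))
}

#' Generalised Kullback-Leibler divergence of a blurred estimate from counts
#'
#' `sum of (Hf - g + g * log(g / Hf))` with the convention `0 * log 0 = 0`
#' and natural logarithm (zero background). Infinite (with a warning) when
#' some pixel has `g > 0` but `Hf = 0`.
#'
#' @inheritParams poisson_data_update
#' @return Nonnegative scalar (possibly `Inf`).
#' @export
kl_divergence <- function(blur_est, g) {
  if (any(g < 0)) stop("'g' must be nonnegative", call. = FALSE)
  if (any(blur_est < 0 & g > 0))
    stop("'blur_est' must be nonnegative where g > 0", call. = FALSE)
  pos <- g > 0
  if (any(pos & blur_est == 0)) {
    warning("g > 0 where blurred estimate is 0: KL divergence is infinite")
    return(Inf)
  }
  val <- sum(blur_est) - sum(g)
  val + sum(g[pos] * log(g[pos] / blur_est[pos]))
}

#' Value of the full restoration objective
#'
#' Evaluates `lam * KL(Hf || g) + phi_OGS(grad_h f) + phi_OGS(grad_v f) +
#' eta * sum |second differences|^p` at an image `f`. The lp term is
#' entrywise over all `4 n^2` second-difference entries.
#'
#' @param f current image estimate.
#' @param g observed counts.
#' @param transfer a [transfer_set()] (or [blur_kernel()]) for the blur.
#' @param params a [solver_params()] list (uses `lam`, `eta`, `p`, `K`).
#' @return Scalar objective value.
#' @export
objective_value <- function(f, g, transfer, params) {
  Hf <- apply_blur(f, transfer)
  grd <- forward_diff(f)
  crv <- second_order_diff(f)
  lp <- sum(abs(crv$c11)^params$p) + sum(abs(crv$c12)^params$p) +
    sum(abs(crv$c21)^params$p) + sum(abs(crv$c22)^params$p)
  params$lam * kl_divergence(Hf, g) +
    ogs_value(grd$horizontal, params$K) + ogs_value(grd$vertical, params$K) +
    params$eta * lp
}
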