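# Independent brute-force oracles used across tests. These deliberately use
# plain nested loops and direct definitions, not the package's sliding-window
# or FFT code paths.

# Zero-extended K x K group centred at (i, j) of matrix v, as a vector.
brute_group <- function(v, i, j, K) {
  m1 <- floor((K - 1) / 2)
  m2 <- floor(K / 2)
  out <- numeric(0)
  for (a in (i - m1):(i + m2)) {
    for (b in (j - m1):(j + m2)) {
      out <- c(out, if (a >= 1 && a <= nrow(v) && b >= 1 && b <= ncol(v))
        v[a, b] else 0)
    }
  }
  out
}

# Direct enumeration of the overlapping-group functional.
brute_ogs_value <- function(v, K) {
  tot <- 0
  for (i in seq_len(nrow(v)))
    for (j in seq_len(ncol(v)))
      tot <- tot + sqrt(sum(brute_group(v, i, j, K)^2))
  tot
}

# Quadratic majorizer of the group functional at u, evaluated at v.
brute_majorizer <- function(v, u, K) {
  tot <- 0
  for (i in seq_len(nrow(v))) {
    for (j in seq_len(ncol(v))) {
      nu <- sqrt(sum(brute_group(u, i, j, K)^2))
      nv2 <- sum(brute_group(v, i, j, K)^2)
      tot <- tot + 0.5 * (nv2 / nu + nu)
    }
  }
  tot
}

# High-accuracy solver for the OGS proximal problem
# 0.5 ||v - v0||^2 + lam * phi_OGS(v), by BFGS on the (eps-smoothed)
# objective with an analytic gradient assembled by group enumeration.
oracle_ogs_prox <- function(v0, lam, K, eps = 1e-12) {
  n1 <- nrow(v0); n2 <- ncol(v0)
  energy_at <- function(v, i, j) sum(brute_group(v, i, j, K)^2)
  obj <- function(x) {
    v <- matrix(x, n1, n2)
    tot <- 0
    for (i in seq_len(n1)) for (j in seq_len(n2))
      tot <- tot + sqrt(energy_at(v, i, j) + eps)
    0.5 * sum((v - v0)^2) + lam * tot
  }
  grad <- function(x) {
    v <- matrix(x, n1, n2)
    m1 <- floor((K - 1) / 2); m2 <- floor(K / 2)
    W <- matrix(0, n1, n2)
    for (i in seq_len(n1)) {
      for (j in seq_len(n2)) {
        r <- 1 / sqrt(energy_at(v, i, j) + eps)
        for (a in (i - m1):(i + m2))
          for (b in (j - m1):(j + m2))
            if (a >= 1 && a <= n1 && b >= 1 && b <= n2)
              W[a, b] <- W[a, b] + r
      }
    }
    as.vector(v - v0) + lam * as.vector(v) * as.vector(W)
  }
  fit <- stats::optim(as.vector(v0), obj, grad, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-16))
  matrix(fit$par, n1, n2)
}

# Direct periodic convolution by nested loops (the blur oracle).
brute_periodic_conv <- function(f, kernel) {
  n <- nrow(f)
  w <- kernel$weights
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (a in seq_len(nrow(w))) {
        for (b in seq_len(ncol(w))) {
          oi <- a - kernel$anchor[1]
          oj <- b - kernel$anchor[2]
          s <- s + w[a, b] * f[((i - oi - 1) %% n) + 1, ((j - oj - 1) %% n) + 1]
        }
      }
      out[i, j] <- s
    }
  }
  out
}

# Dense matrix of a linear image operator, by application to basis images.
dense_operator <- function(op, n, out_channels = 1L) {
  N <- n * n
  M <- matrix(0, N * out_channels, N)
  for (l in seq_len(N)) {
    e <- matrix(0, n, n)
    e[l] <- 1
    M[, l] <- unlist(op(e))
  }
  M
}

random_gradient_field <- function(n) {
  structure(list(horizontal = matrix(stats::rnorm(n * n), n),
                 vertical = matrix(stats::rnorm(n * n), n)),
            class = "gradient_field")
}

random_curvature_field <- function(n) {
  structure(stats::setNames(lapply(1:4, function(i)
    matrix(stats::rnorm(n * n), n)), c("c11", "c12", "c21", "c22")),
    class = "curvature_field")
}

rel_diff <- function(a, b) {
  sqrt(sum((unlist(a) - unlist(b))^2)) / sqrt(sum(unlist(b)^2))
}
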