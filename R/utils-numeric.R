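# Shared numerical machinery: fixed quadrature rules and seed splitting.

# Gauss-Legendre nodes/weights on [a, b] via Golub-Welsch (symmetric
# tridiagonal Jacobi matrix).  n is small (<= 200), so eigen() is cheap.
gauss_legendre <- function(n, a = -1, b = 1) {
  if (n == 1L) {
    return(list(nodes = (a + b) / 2, weights = b - a))
  }
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(
    nodes = (b - a) / 2 * x[ord] + (a + b) / 2,
    weights = (b - a) / 2 * w[ord]
  )
}

# Tanh-sinh (double-exponential) rule on (0, 1).  Robust to integrable
# endpoint singularities (log, inverse square root), which arise in the
# angular integral of the planar potential basis.
tanh_sinh <- function(n = 60, tmax = 3.2) {
  t <- seq(-tmax, tmax, length.out = n)
  ht <- t[2] - t[1]
  u <- (pi / 2) * sinh(t)
  x01 <- (tanh(u) + 1) / 2                      # map (-1,1) -> (0,1)
  w <- ht * (pi / 2) * cosh(t) / cosh(u)^2 / 2  # d x01 / d t
  keep <- w > 1e-300 & x01 > 0 & x01 < 1
  list(nodes = x01[keep], weights = w[keep])
}

# Deterministic 32-bit sub-seed derivation so that independent random
# sub-streams (profiles, noise, broken subsets) can be replayed separately.
sub_seed <- function(seed, label, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483629
  s <- (abs(as.numeric(seed)) %% 2147483629)
  as.integer((s * 48271 + h * 16807 + as.numeric(index) * 69621) %% 2147483629)
}

# Evaluate with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

log_space <- function(from, to, n) {
  stopifnot(from > 0, to > 0)
  if (n == 1L) return(sqrt(from * to))
  10^seq(log10(from), log10(to), length.out = n)
}

coord_names <- function(dim) c("x", "y", "z")[seq_len(dim)]

as_coord_matrix <- function(points, dim = NULL) {
  if (is.data.frame(points)) {
    dim <- dim %||% sum(coord_names(3) %in% names(points))
    m <- as.matrix(points[, coord_names(dim), drop = FALSE])
  } else {
    m <- as.matrix(points)
    if (!is.null(dim) && ncol(m) != dim && length(m) == dim) m <- matrix(m, 1)
  }
  storage.mode(m) <- "double"
  m
}

# Pairwise Euclidean distances between the rows of two coordinate matrices.
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
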