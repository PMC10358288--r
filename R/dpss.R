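# Discrete prolate spheroidal (Slepian) tapers.
#
# Uses the symmetric-tridiagonal formulation: the k-th taper is the
# eigenvector of the tridiagonal matrix with diagonal
#   ((n-1-2i)/2)^2 cos(2 pi W),  i = 0..n-1,   W = nw/n
# and off-diagonal i(n-i)/2, belonging to its k-th largest eigenvalue.
# Eigenvalues are located by Sturm-sequence bisection and eigenvectors by
# inverse iteration with tridiagonal (Thomas) solves; the tridiagonal
# eigenvalues are well separated, so the eigenvectors come out orthonormal to
# machine precision. A final modified Gram-Schmidt pass guards the
# orthonormality contract regardless.

taper_cache <- new.env(parent = emptyenv())

#' Slepian (DPSS) tapers
#'
#' Computes the first `k` discrete prolate spheroidal sequences of length `n`
#' with time-bandwidth product `nw`, the taper family whose spectral
#' concentration in the band `[-nw/n, nw/n]` (cycles/sample) is maximal.
#' Tapers are unit-norm, mutually orthogonal, and cached per `(n, nw, k)`.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (default 4).
#' @param k Number of tapers (default `2 * nw - 1`); must satisfy
#'   `k <= 2 * nw - 1` for well-concentrated tapers.
#' @return `n x k` matrix, one taper per column, ordered by decreasing
#'   spectral concentration. Sign convention: symmetric tapers have positive
#'   mean; antisymmetric tapers start with a positive slope.
#' @export
#' @examples
#' h <- dpss_tapers(256, nw = 4, k = 7)
#' round(crossprod(h), 10)[1:3, 1:3]  # identity
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  if (n < 2L) stop("taper length must be at least 2", call. = FALSE)
  if (nw <= 0 || nw >= n / 2) stop("nw must be in (0, n/2)", call. = FALSE)
  if (k < 1L || k > 2 * nw - 1 + 1e-9)
    stop("number of tapers must satisfy 1 <= k <= 2*nw - 1", call. = FALSE)
  k <- as.integer(k)
  key <- sprintf("n%d_nw%g_k%d", n, nw, k)
  if (!is.null(taper_cache[[key]])) return(taper_cache[[key]])

  i <- 0:(n - 1)
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * nw / n)
  e <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  e2 <- e^2

  sturm_count <- function(x) {
    # number of eigenvalues strictly below each shift in x
    q <- d[1] - x
    cnt <- as.integer(q < 0)
    for (ii in 2:n) {
      q <- d[ii] - x - e2[ii - 1] / ifelse(abs(q) < 1e-300, 1e-300, q)
      cnt <- cnt + (q < 0)
    }
    cnt
  }

  rad <- c(e, 0) + c(0, e)
  lo <- rep(min(d - rad), k)
  hi <- rep(max(d + rad), k)
  m <- n - (1:k) + 1L  # ascending rank of the j-th largest eigenvalue
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    ge <- sturm_count(mid) >= m
    hi[ge] <- mid[ge]
    lo[!ge] <- mid[!ge]
    if (max(hi - lo) < 1e-12 * max(abs(hi), 1)) break
  }
  lam <- (lo + hi) / 2

  tapers <- matrix(0, n, k)
  for (j in seq_len(k)) {
    v <- sin((1:n) * pi * j / (n + 1))
    v <- v / sqrt(sum(v^2))
    for (it in 1:4) {
      u <- tridiag_solve(d - lam[j], e, v)
      if (j > 1L)
        u <- u - tapers[, 1:(j - 1), drop = FALSE] %*%
          crossprod(tapers[, 1:(j - 1), drop = FALSE], u)
      v <- as.vector(u) / sqrt(sum(u^2))
    }
    tapers[, j] <- v
  }
  # polish orthonormality (modified Gram-Schmidt)
  for (j in seq_len(k)) {
    v <- tapers[, j]
    if (j > 1L)
      v <- v - tapers[, 1:(j - 1), drop = FALSE] %*%
        crossprod(tapers[, 1:(j - 1), drop = FALSE], v)
    tapers[, j] <- v / sqrt(sum(v^2))
  }
  for (j in seq_len(k)) {
    s <- sum(tapers[, j])
    flip <- if (abs(s) > 1e-8) s < 0 else sum((n - 1 - 2 * i) * tapers[, j]) < 0
    if (flip) tapers[, j] <- -tapers[, j]
  }
  taper_cache[[key]] <- tapers
  tapers
}

# Solve (tridiag(d, e) ) x = b by the Thomas algorithm; d is the diagonal
# (already shifted), e the off-diagonal.
tridiag_solve <- function(dd, e, b) {
  n <- length(dd)
  cp <- numeric(n - 1)
  dp <- numeric(n)
  denom <- if (abs(dd[1]) < 1e-300) 1e-300 else dd[1]
  cp[1] <- e[1] / denom
  dp[1] <- b[1] / denom
  for (ii in 2:n) {
    denom <- dd[ii] - e[ii - 1] * cp[ii - 1]
    if (abs(denom) < 1e-300) denom <- 1e-300
    if (ii < n) cp[ii] <- e[ii] / denom
    dp[ii] <- (b[ii] - e[ii - 1] * dp[ii - 1]) / denom
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (ii in (n - 1):1) x[ii] <- dp[ii] - cp[ii] * x[ii + 1]
  x
}
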