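#' Canonicalize a Gaussian hypothesis pair
#'
#' Reduces an arbitrary pair of Gaussian class-conditionals to the canonical
#' coordinates in which H0 is standard normal and H1 is
#' `N(m, diag(lam))`: the H0 covariance is whitened via its eigenvalue
#' decomposition `Sigma = U D U'`, and the transformed H1 covariance
#' `C = D^{-1/2} U' Theta U D^{-1/2} = V Lam V'` is then diagonalized.  The
#' full transform `A = V' D^{-1/2} U'` maps a raw observation `y` to
#' `x = A (y - mu0)`.  For N = 1 this is simply `m = (mu1 - mu0)/sigma0`,
#' `lam = sigma1^2/sigma0^2`.
#'
#' Eigenvalues are sorted in decreasing order and each eigenvector's sign is
#' fixed by making its largest-magnitude component positive; every reported
#' probability is invariant to these conventions.
#'
#' @param h0,h1 [gaussian_condition()] objects of equal dimension.
#' @param tol tolerance used to flag degenerate coordinates
#'   (`lam == 1` and `m == 0`), which carry no discriminative information.
#' @return an object of class `canonical_pair` with fields `dim`, `m`,
#'   `lam`, `degenerate`, and `transform` (list with matrix `A` and vector
#'   `offset`).
#' @examples
#' h0 <- gaussian_condition(2, 1)
#' h1 <- gaussian_condition(3, 4)
#' canonicalize(h0, h1)   # m = 1, lam = 4
#' @export
canonicalize <- function(h0, h1, tol = 1e-12) {
  stopifnot(inherits(h0, "gaussian_condition"), inherits(h1, "gaussian_condition"))
  if (h0$dim != h1$dim) {
    stop_cellnp("cellnp_dim_mismatch", "h0 and h1 must have the same dimension")
  }
  N <- h0$dim
  e0 <- eigen(symmetrize(h0$cov), symmetric = TRUE)
  if (any(e0$values <= 0)) {
    stop_cellnp("cellnp_not_spd", "H0 covariance is not positive-definite")
  }
  U <- fix_eigvec_signs(e0$vectors)
  W <- diag(1 / sqrt(e0$values), N, N) %*% t(U)   # D^{-1/2} U'
  C <- symmetrize(W %*% h1$cov %*% t(W))
  e1 <- eigen(C, symmetric = TRUE)
  if (any(e1$values <= 0)) {
    stop_cellnp("cellnp_not_spd", "H1 covariance is not positive-definite")
  }
  V <- fix_eigvec_signs(e1$vectors)
  A <- t(V) %*% W
  m <- drop(A %*% (h1$mean - h0$mean))
  lam <- e1$values
  degenerate <- abs(lam - 1) <= tol & abs(m) <= tol
  structure(
    list(dim = N, m = m, lam = lam, degenerate = degenerate,
         transform = list(A = A, offset = h0$mean)),
    class = "canonical_pair"
  )
}

# sign convention: largest-magnitude component of each eigenvector positive
fix_eigvec_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' @export
print.canonical_pair <- function(x, ...) {
  cat(sprintf("Canonical hypothesis pair (N = %d)\n", x$dim))
  cat("  m      :", paste(signif(x$m, 6), collapse = ", "), "\n")
  cat("  lambda :", paste(signif(x$lam, 6), collapse = ", "), "\n")
  if (any(x$degenerate)) {
    cat("  degenerate coordinates:", paste(which(x$degenerate), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Map raw observations to canonical coordinates
#'
#' Applies `x = A (y - mu0)` row-wise.
#'
#' @param y numeric vector (one observation) or matrix (rows = observations).
#' @param pair a `canonical_pair`.
#' @return matrix of canonical observations (rows = observations).
#' @export
to_canonical <- function(y, pair) {
  stopifnot(inherits(pair, "canonical_pair"))
  ym <- if (is.null(dim(y))) matrix(y, ncol = pair$dim) else as.matrix(y)
  if (ncol(ym) != pair$dim) {
    stop_cellnp("cellnp_dim_mismatch", "observation length must equal pair$dim")
  }
  sweep(ym, 2L, pair$transform$offset) %*% t(pair$transform$A)
}

#' Quadratic Neyman-Pearson test statistic
#'
#' Evaluates `Z = sum_i x_i^2 - lam_i^{-1} (x_i - m_i)^2` on canonical
#' observations.  Degenerate coordinates (lam = 1, m = 0) contribute exactly
#' zero.  `Z` is a strictly increasing function of the log-likelihood ratio,
#' so thresholding `Z` realizes the optimal test.
#'
#' @param x numeric vector of length `pair$dim`, or a matrix with that many
#'   columns (one observation per row).
#' @param pair a `canonical_pair`.
#' @return numeric vector of statistic values, one per observation.
#' @examples
#' pair <- canonical_pair_from(m = 1, lam = 4)
#' test_statistic(0, pair)   # -0.25
#' @export
test_statistic <- function(x, pair) {
  stopifnot(inherits(pair, "canonical_pair"))
  if (is.null(dim(x))) {
    if (length(x) != pair$dim && length(x) %% pair$dim != 0) {
      stop_cellnp("cellnp_dim_mismatch", "x must have length/columns equal to pair$dim")
    }
    x <- matrix(x, ncol = pair$dim, byrow = TRUE)
  }
  xm <- as.matrix(x)
  if (ncol(xm) != pair$dim) {
    stop_cellnp("cellnp_dim_mismatch", "x must have length/columns equal to pair$dim")
  }
  keep <- !pair$degenerate
  if (!any(keep)) return(rep(0, nrow(xm)))
  xs <- xm[, keep, drop = FALSE]
  m <- pair$m[keep]
  lam <- pair$lam[keep]
  contrib <- xs^2 - sweep(xs, 2L, m)^2 %*% diag(1 / lam, length(lam), length(lam))
  rowSums(contrib)
}

#' Build a canonical pair directly from (m, lam)
#'
#' Convenience constructor used when the whitened parameters are already
#' known (tests, worked examples): equivalent to canonicalizing
#' `N(0, I)` against `N(m, diag(lam))`.
#'
#' @param m numeric vector of transformed mean separations.
#' @param lam positive numeric vector of variance ratios, same length.
#' @param tol degeneracy tolerance, as in [canonicalize()].
#' @return a `canonical_pair`.
#' @export
canonical_pair_from <- function(m, lam, tol = 1e-12) {
  m <- as.numeric(m); lam <- as.numeric(lam)
  if (length(m) != length(lam) || !length(m)) {
    stop_cellnp("cellnp_dim_mismatch", "m and lam must be equal-length, nonempty")
  }
  if (any(lam <= 0) || any(!is.finite(c(m, lam)))) {
    stop_cellnp("cellnp_invalid_model", "lam must be positive and finite")
  }
  N <- length(m)
  structure(
    list(dim = N, m = m, lam = lam,
         degenerate = abs(lam - 1) <= tol & abs(m) <= tol,
         transform = list(A = diag(N), offset = rep(0, N))),
    class = "canonical_pair"
  )
}

#' One-dimensional decision region in observation space
#'
#' For N = 1 the rejection region `{x : x^2 - (x - m)^2/lam > z_th}` is a
#' quadratic region: two unbounded rays when `lam > 1`, a single ray when
#' `lam = 1`, and a bounded interval (possibly empty) when `lam < 1`.  This
#' exposes the "two disjoint thresholds" geometry of the unequal-variance
#' test as a diagnostic; the operational threshold always lives in Z-space.
#'
#' @param pair a univariate `canonical_pair`.
#' @param z_th threshold on the test statistic.
#' @return a matrix with columns `lower`, `upper`, one row per interval
#'   (zero rows when the region is empty), with an attribute `pfa` giving
#'   the H0 probability of the region (cross-check against
#'   `1 - cdf_test_statistic(z_th, pair, "H0")`).
#' @export
decision_region_1d <- function(pair, z_th) {
  stopifnot(inherits(pair, "canonical_pair"))
  if (pair$dim != 1L) {
    stop_cellnp("cellnp_dim_mismatch", "decision_region_1d requires pair$dim == 1")
  }
  m <- pair$m[1L]; lam <- pair$lam[1L]
  # z(x) = a x^2 + b x + c with a = 1 - 1/lam, b = 2 m / lam, c = -m^2 / lam
  a <- 1 - 1 / lam
  b <- 2 * m / lam
  c0 <- -m^2 / lam - z_th
  intervals <- if (abs(a) < 1e-14) {
    if (abs(b) < 1e-14) {
      # fully degenerate statistic: region is everything or nothing
      if (c0 > 0) matrix(c(-Inf, Inf), 1L) else matrix(numeric(), 0L, 2L)
    } else if (b > 0) {
      matrix(c(-c0 / b, Inf), 1L)
    } else {
      matrix(c(-Inf, -c0 / b), 1L)
    }
  } else {
    disc <- b^2 - 4 * a * (c0)
    if (disc < 0) {
      # no real roots: quadratic has constant sign equal to sign(a)
      if (a > 0) matrix(c(-Inf, Inf), 1L) else matrix(numeric(), 0L, 2L)
    } else if (disc == 0) {
      # double root: boundary point has measure zero
      r0 <- -b / (2 * a)
      if (a > 0) matrix(c(-Inf, r0, r0, Inf), 2L, 2L, byrow = TRUE)
      else matrix(numeric(), 0L, 2L)
    } else {
      r <- sort(c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a)))
      if (a > 0) {
        matrix(c(-Inf, r[1L], r[2L], Inf), 2L, 2L, byrow = TRUE)
      } else {
        matrix(r, 1L, 2L)
      }
    }
  }
  colnames(intervals) <- c("lower", "upper")
  pfa <- if (nrow(intervals)) {
    sum(stats::pnorm(intervals[, "upper"]) - stats::pnorm(intervals[, "lower"]))
  } else 0
  attr(intervals, "pfa") <- pfa
  intervals
}
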