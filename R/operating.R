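#' Solve the detection threshold for a target false alarm probability
#'
#' Finds `z_th` with `P_FA = 1 - F_Z(z_th; H0) = alpha`.  The root is
#' bracketed from the H0 mean +/- 10 SD of `Z` (expanded geometrically if
#' needed) and refined by derivative-free root finding on the monotone CDF.
#'
#' @param pair a `canonical_pair`.
#' @param alpha target false alarm probability in (0, 1).
#' @return threshold `z_th` with `|1 - F_Z(z_th; H0) - alpha| <= 1e-5`.
#' @examples
#' solve_threshold(canonical_pair_from(1, 1), 0.1)  # ~ 2 qnorm(0.9) - 1
#' @export
solve_threshold <- function(pair, alpha) {
  stopifnot(inherits(pair, "canonical_pair"))
  if (!is_prob(alpha)) {
    stop_cellnp("cellnp_domain_error", "alpha must lie strictly in (0, 1)")
  }
  mo <- test_statistic_moments(pair, "H0")
  sd0 <- sqrt(mo$var)
  f <- function(z) cdf_test_statistic(z, pair, "H0") - (1 - alpha)
  lo <- mo$mean - 10 * sd0
  hi <- mo$mean + 10 * sd0
  for (k in 1:40) {
    if (f(lo) < 0) break
    lo <- mo$mean - (10 + 2^k) * sd0
  }
  for (k in 1:40) {
    if (f(hi) > 0) break
    hi <- mo$mean + (10 + 2^k) * sd0
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-9 * max(1, sd0))$root
}

#' Detection probability at a threshold
#'
#' `P_D = 1 - F_Z(z_th; H1)`, nonincreasing in `z_th`.
#'
#' @param pair a `canonical_pair`.
#' @param z_th threshold on the test statistic.
#' @return probability in `[0, 1]`.
#' @export
detection_probability <- function(pair, z_th) {
  stopifnot(inherits(pair, "canonical_pair"))
  1 - cdf_test_statistic(z_th, pair, "H1")
}

#' Optimal operating point for a Gaussian hypothesis pair
#'
#' Composition canonicalize -> solve_threshold -> detection_probability:
#' the Neyman-Pearson operating point at false alarm level `alpha`.
#'
#' @param h0,h1 [gaussian_condition()] models (H0 = low stimulus,
#'   H1 = high stimulus).
#' @param alpha target false alarm probability in (0, 1).
#' @return object of class `operating_point`: list with `z_th`, `pfa`,
#'   `pd`, `pm` (= 1 - pd), and the `canonical_pair` used.
#' @examples
#' op <- operating_point(gaussian_condition(0, 1), gaussian_condition(1, 1), 0.1)
#' op$pd   # ~ 0.389
#' @export
operating_point <- function(h0, h1, alpha) {
  pair <- canonicalize(h0, h1)
  op_from_pair(pair, alpha)
}

op_from_pair <- function(pair, alpha) {
  z_th <- solve_threshold(pair, alpha)
  pfa <- 1 - cdf_test_statistic(z_th, pair, "H0")
  pd <- detection_probability(pair, z_th)
  structure(list(z_th = z_th, pfa = pfa, pd = pd, pm = 1 - pd, pair = pair),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("NP operating point (N = %d): z_th = %.6g, P_FA = %.6f, P_D = %.6f, P_M = %.6f\n",
              x$pair$dim, x$z_th, x$pfa, x$pd, x$pm))
  invisible(x)
}

#' Receiver operating characteristic curve
#'
#' Detection probability across a grid of false alarm levels.  For the
#' likelihood-ratio test the curve is nondecreasing, concave, and lies on
#' or above the chance diagonal.
#'
#' @param h0,h1 [gaussian_condition()] models.
#' @param pfa_grid strictly increasing false alarm probabilities in (0, 1).
#' @return data.frame of class `roc_curve` with columns `pfa`, `pd`, and
#'   attributes `model_dim`, `m`, `lam`.
#' @export
roc_curve <- function(h0, h1, pfa_grid = seq(0.01, 0.99, by = 0.01)) {
  pfa_grid <- as.numeric(pfa_grid)
  if (any(pfa_grid <= 0) || any(pfa_grid >= 1) ||
      is.unsorted(pfa_grid, strictly = TRUE)) {
    stop_cellnp("cellnp_domain_error",
                "pfa_grid must be strictly increasing inside (0, 1)")
  }
  pair <- canonicalize(h0, h1)
  pd <- vapply(pfa_grid, function(a) {
    detection_probability(pair, solve_threshold(pair, a))
  }, numeric(1))
  out <- data.frame(pfa = pfa_grid, pd = pd)
  class(out) <- c("roc_curve", "data.frame")
  attr(out, "model_dim") <- pair$dim
  attr(out, "m") <- pair$m
  attr(out, "lam") <- pair$lam
  out
}

#' Smallest false alarm probability achieving a target detection rate
#'
#' Inverts the ROC: finds the threshold with
#' `P_D(z_th) = target_pd` on the monotone CDF under H1, and reports the
#' corresponding `P_FA` -- the smallest false alarm probability with
#' `P_D >= target_pd` for the optimal test.
#'
#' @param h0,h1 [gaussian_condition()] models.
#' @param target_pd target detection probability in (0, 1).
#' @return false alarm probability (with attribute `z_th`).
#' @export
pfa_at_pd <- function(h0, h1, target_pd) {
  if (!is_prob(target_pd)) {
    stop_cellnp("cellnp_domain_error", "target_pd must lie strictly in (0, 1)")
  }
  pair <- canonicalize(h0, h1)
  mo <- test_statistic_moments(pair, "H1")
  sd1 <- sqrt(mo$var)
  f <- function(z) cdf_test_statistic(z, pair, "H1") - (1 - target_pd)
  lo <- mo$mean - 10 * sd1
  hi <- mo$mean + 10 * sd1
  for (k in 1:40) {
    if (f(lo) < 0) break
    lo <- mo$mean - (10 + 2^k) * sd1
  }
  for (k in 1:40) {
    if (f(hi) > 0) break
    hi <- mo$mean + (10 + 2^k) * sd1
  }
  z_th <- stats::uniroot(f, c(lo, hi), tol = 1e-9 * max(1, sd1))$root
  out <- 1 - cdf_test_statistic(z_th, pair, "H0")
  attr(out, "z_th") <- z_th
  out
}

#' Export an ROC curve or operating point
#'
#' ROC curves go to CSV (columns `pfa`, `pd`); operating points to JSON
#' including the canonical parameters of the hypothesis pair.
#'
#' @param x a `roc_curve` or `operating_point`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_detection_result <- function(x, path) {
  if (inherits(x, "roc_curve")) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  } else if (inherits(x, "operating_point")) {
    jsonlite::write_json(
      list(dim = x$pair$dim, m = x$pair$m, lam = x$pair$lam,
           z_th = x$z_th, pfa = x$pfa, pd = x$pd, pm = x$pm),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    stop_cellnp("cellnp_domain_error", "x must be a roc_curve or operating_point")
  }
  invisible(path)
}
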