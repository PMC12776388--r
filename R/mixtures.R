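#' Mixture class-conditional model for heterogeneous populations
#'
#' A finite Gaussian mixture describing a population in which each cell
#' belongs to one genotype (component) with a fixed probability -- e.g. a
#' fraction `beta` of knockout cells and `1 - beta` wild type.  Mixing is at
#' the component level: a cell is entirely WT or entirely KO across all time
#' points of its observation vector.
#'
#' @param components list of [gaussian_condition()] objects of equal
#'   dimension (a single `gaussian_condition` is wrapped automatically).
#' @param weights nonnegative weights summing to 1 (tolerance 1e-12).
#' @return object of class `mixture_condition` with fields `dim`,
#'   `components`, `weights`.
#' @examples
#' wt <- gaussian_condition(0, 1); ko <- gaussian_condition(1, 1.5)
#' mixture_condition(list(wt, ko), c(0.7, 0.3))
#' @export
mixture_condition <- function(components, weights = NULL) {
  if (inherits(components, "gaussian_condition")) components <- list(components)
  if (!length(components) ||
      !all(vapply(components, inherits, logical(1), "gaussian_condition"))) {
    stop_cellnp("cellnp_invalid_model",
                "components must be gaussian_condition objects")
  }
  if (is.null(weights)) weights <- rep(1 / length(components), length(components))
  weights <- as.numeric(weights)
  if (length(weights) != length(components) || any(weights < 0)) {
    stop_cellnp("cellnp_invalid_model", "weights must be nonnegative, one per component")
  }
  if (abs(sum(weights) - 1) > 1e-12) {
    stop_cellnp("cellnp_weight_error",
                sprintf("weights must sum to 1 (got %.15g)", sum(weights)))
  }
  dims <- vapply(components, `[[`, numeric(1), "dim")
  if (length(unique(dims)) != 1L) {
    stop_cellnp("cellnp_dim_mismatch", "all components must share one dimension")
  }
  structure(list(dim = dims[1L], components = components, weights = weights),
            class = "mixture_condition")
}

as_mixture <- function(x) {
  if (inherits(x, "mixture_condition")) x else mixture_condition(x, 1)
}

#' @export
print.mixture_condition <- function(x, ...) {
  cat(sprintf("Mixture condition (N = %d, %d components; weights %s)\n",
              x$dim, length(x$components),
              paste(signif(x$weights, 4), collapse = ", ")))
  invisible(x)
}

# log density of a multivariate normal at rows of y (n x N)
log_dmvnorm <- function(y, mean, cov) {
  N <- length(mean)
  ch <- chol(cov)
  centered <- sweep(y, 2L, mean)
  solved <- backsolve(ch, t(centered), transpose = TRUE)
  -0.5 * colSums(solved^2) - sum(log(diag(ch))) - 0.5 * N * log(2 * pi)
}

log_mixture_density <- function(y, mix) {
  live <- which(mix$weights > 0)
  ll <- vapply(live, function(k) {
    log(mix$weights[k]) +
      log_dmvnorm(y, mix$components[[k]]$mean, mix$components[[k]]$cov)
  }, numeric(nrow(y)))
  ll <- matrix(ll, nrow = nrow(y))
  mx <- do.call(pmax, as.data.frame(ll))
  mx + log(rowSums(exp(ll - mx)))
}

#' Log-likelihood ratio for mixture hypotheses
#'
#' `ln p(y; H1) - ln p(y; H0)` with mixture densities, computed with
#' log-sum-exp stabilization.  This is the statistic thresholded by the
#' Neyman-Pearson test when the class-conditionals are mixtures (no scalar
#' quadratic reduction exists).
#'
#' @param y numeric vector (one observation) or matrix (rows = cells).
#' @param h0,h1 `mixture_condition` (or `gaussian_condition`) models.
#' @return numeric vector of log-likelihood ratios.
#' @export
log_likelihood_ratio <- function(y, h0, h1) {
  h0 <- as_mixture(h0); h1 <- as_mixture(h1)
  if (h0$dim != h1$dim) {
    stop_cellnp("cellnp_dim_mismatch", "h0 and h1 must share a dimension")
  }
  ym <- if (is.null(dim(y))) matrix(y, ncol = h0$dim) else as.matrix(y)
  if (ncol(ym) != h0$dim) {
    stop_cellnp("cellnp_dim_mismatch", "observation length must equal model dim")
  }
  log_mixture_density(ym, h1) - log_mixture_density(ym, h0)
}

#' Quadrature grid for mixture error probabilities
#'
#' A per-dimension regular grid covering every component mean +/- `k`
#' standard deviations under both hypotheses; the mass outside the grid is
#' bounded by the Gaussian tail at `k` SD and reported as an error bar.
#'
#' @param h0,h1 mixture (or Gaussian) models, dimension 1 or 2.
#' @param k half-width of the coverage in component SDs (default 8).
#' @param points grid points per dimension (defaults: 4001 for N = 1,
#'   801 for N = 2).
#' @return object of class `grid_spec` with fields `dim`, `lo`, `hi`,
#'   `points`, `k`.
#' @export
mixture_grid <- function(h0, h1, k = 8, points = NULL) {
  h0 <- as_mixture(h0); h1 <- as_mixture(h1)
  N <- h0$dim
  if (!N %in% c(1L, 2L)) {
    stop_cellnp("cellnp_unsupported_dimension",
                "quadrature grids support N in {1, 2}; use the Monte Carlo oracle beyond")
  }
  comps <- c(h0$components, h1$components)
  lo <- rep(Inf, N); hi <- rep(-Inf, N)
  for (cm in comps) {
    s <- sqrt(diag(cm$cov))
    lo <- pmin(lo, cm$mean - k * s)
    hi <- pmax(hi, cm$mean + k * s)
  }
  if (is.null(points)) points <- if (N == 1L) 4001L else 801L
  points <- as.integer(points)
  if (points < 3L) stop_cellnp("cellnp_domain_error", "points must be >= 3")
  structure(list(dim = N, lo = lo, hi = hi, points = points, k = k),
            class = "grid_spec")
}

# precompute quadrature nodes, trapezoid masses under both hypotheses, and
# the LLR field aggregated by distinct LLR values; everything downstream is
# thresholding this object.  P0/P1 hold the probability of {LLR > v} with
# boundary nodes half-weighted (the trapezoid-consistent choice, O(h^2));
# S0/S1 hold the strict-inequality step function used for atom fallbacks.
mixture_quadrature <- function(h0, h1, grid) {
  h0 <- as_mixture(h0); h1 <- as_mixture(h1)
  N <- grid$dim
  axes <- lapply(seq_len(N), function(d) seq(grid$lo[d], grid$hi[d], length.out = grid$points))
  wts <- lapply(seq_len(N), function(d) {
    step <- (grid$hi[d] - grid$lo[d]) / (grid$points - 1L)
    w <- rep(step, grid$points); w[c(1L, grid$points)] <- step / 2
    w
  })
  if (N == 1L) {
    nodes <- matrix(axes[[1L]], ncol = 1L)
    w <- wts[[1L]]
  } else {
    nodes <- as.matrix(expand.grid(axes[[1L]], axes[[2L]], KEEP.OUT.ATTRS = FALSE))
    # expand.grid varies the first axis fastest, matching as.vector(outer())
    w <- as.vector(wts[[1L]] %o% wts[[2L]])
  }
  l0 <- log_mixture_density(nodes, h0)
  l1 <- log_mixture_density(nodes, h1)
  q0 <- exp(l0) * w
  q1 <- exp(l1) * w
  llr <- l1 - l0
  tail0 <- max(0, 1 - sum(q0)); tail1 <- max(0, 1 - sum(q1))
  ord <- order(llr)
  llr_s <- llr[ord]
  grp <- cumsum(c(TRUE, diff(llr_s) != 0))
  vs <- llr_s[!duplicated(grp)]
  g0 <- as.vector(rowsum(q0[ord], grp))
  g1 <- as.vector(rowsum(q1[ord], grp))
  incl0 <- rev(cumsum(rev(g0)))   # mass with llr >= v
  incl1 <- rev(cumsum(rev(g1)))
  s0 <- incl0 - g0                # strict: llr > v
  s1 <- incl1 - g1
  list(vs = vs,
       P0 = s0 + g0 / 2, P1 = s1 + g1 / 2,
       S0 = s0, S1 = s1, I0 = incl0, I1 = incl1,
       err = max(tail0, tail1, N * 2 * stats::pnorm(-grid$k)))
}

# piecewise-linear, monotone nonincreasing interpolant of P(llr > lg)
interp_prob <- function(vs, P, lg) {
  n <- length(vs)
  if (lg > vs[n]) return(0)
  if (lg < vs[1]) return(1)
  j <- findInterval(lg, vs)
  if (vs[j] == lg || j == n) return(P[j])
  w <- (lg - vs[j]) / (vs[j + 1] - vs[j])
  (1 - w) * P[j] + w * P[j + 1]
}

errs_at <- function(quad, log_gamma, boundary = c("interp", "strict")) {
  boundary <- match.arg(boundary)
  if (boundary == "interp") {
    c(pfa = interp_prob(quad$vs, quad$P0, log_gamma),
      pd = interp_prob(quad$vs, quad$P1, log_gamma))
  } else {
    n <- length(quad$vs)
    j <- findInterval(log_gamma, quad$vs)
    if (j == 0L) c(pfa = 1, pd = 1)
    else if (quad$vs[j] == log_gamma) c(pfa = quad$S0[j], pd = quad$S1[j])
    else if (j == n) c(pfa = 0, pd = 0)
    else c(pfa = quad$I0[j + 1L], pd = quad$I1[j + 1L])
  }
}

#' Error probabilities of a mixture likelihood-ratio test
#'
#' False alarm and detection probabilities of the region
#' `{y : LLR(y) > log_gamma}` computed by deterministic trapezoid
#' quadrature over the grid.  Grid cells on the region boundary are
#' half-weighted and the threshold map is linearly interpolated between
#' distinct LLR node values, which keeps the boundary error at second
#' order in the grid spacing.
#'
#' @param h0,h1 mixture (or Gaussian) models, N in {1, 2}.
#' @param log_gamma threshold on the log-likelihood ratio.
#' @param grid a [mixture_grid()]; defaults to the models' standard grid.
#' @return list with `pfa`, `pd`, and `err` (tail + normalization budget).
#' @export
mixture_error_probs <- function(h0, h1, log_gamma, grid = NULL) {
  if (is.null(grid)) grid <- mixture_grid(h0, h1)
  quad <- mixture_quadrature(h0, h1, grid)
  e <- errs_at(quad, log_gamma)
  list(pfa = unname(e["pfa"]), pd = unname(e["pd"]), err = quad$err)
}

solve_gamma <- function(quad, target, which = c("pfa", "pd")) {
  which <- match.arg(which)
  lo <- quad$vs[1] - 1
  hi <- quad$vs[length(quad$vs)] + 1
  # value(lg) is nonincreasing in lg for both pfa and pd
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    v <- errs_at(quad, mid)[[which]]
    if (v > target) lo <- mid else hi <- mid
    if (hi - lo < 1e-13 * max(1, abs(hi))) break
  }
  (lo + hi) / 2
}

#' Mixture threshold for a target false alarm probability
#'
#' Bisects the monotone map `log_gamma -> P_FA` for the smallest rejection
#' region with `P_FA <= alpha`.  When an LLR atom makes `alpha` exactly
#' unattainable the conservative (smaller-region) point is returned and
#' flagged (`atom = TRUE`); randomized tests are out of scope.
#'
#' @param h0,h1 mixture (or Gaussian) models.
#' @param alpha target false alarm probability in (0, 1).
#' @param grid optional [mixture_grid()].
#' @return object of class `mixture_operating_point`: list with
#'   `log_gamma`, `pfa`, `pd`, `err`, `atom`.
#' @export
mixture_solve_threshold <- function(h0, h1, alpha, grid = NULL) {
  if (!is_prob(alpha)) {
    stop_cellnp("cellnp_domain_error", "alpha must lie strictly in (0, 1)")
  }
  if (is.null(grid)) grid <- mixture_grid(h0, h1)
  quad <- mixture_quadrature(h0, h1, grid)
  lg <- solve_gamma(quad, alpha, "pfa")
  e <- errs_at(quad, lg)
  atom <- abs(e[["pfa"]] - alpha) > 1e-4
  if (atom) {
    # LLR atom: fall back to the conservative strict-inequality point
    j <- which(quad$S0 <= alpha)[1L]
    lg <- quad$vs[j]
    e <- c(pfa = quad$S0[j], pd = quad$S1[j])
  }
  structure(list(log_gamma = lg, pfa = unname(e["pfa"]), pd = unname(e["pd"]),
                 err = quad$err, atom = atom),
            class = "mixture_operating_point")
}

#' @export
print.mixture_operating_point <- function(x, ...) {
  cat(sprintf("Mixture NP operating point: log_gamma = %.6g, P_FA = %.6f, P_D = %.6f%s\n",
              x$log_gamma, x$pfa, x$pd,
              if (isTRUE(x$atom)) " [LLR atom: conservative point]" else ""))
  invisible(x)
}

mixture_pfa_at_pd_quad <- function(quad, target_pd) {
  lg <- solve_gamma(quad, target_pd, "pd")
  e <- errs_at(quad, lg)
  if (abs(e[["pd"]] - target_pd) <= 1e-4) return(e)
  # LLR atom: include the whole atom (smallest pfa with pd >= target among
  # nonrandomized tests)
  ok <- which(quad$I1 >= target_pd)
  if (!length(ok)) return(c(pfa = 1, pd = 1))
  j <- max(ok)
  c(pfa = quad$I0[j], pd = quad$I1[j])
}

build_beta_mixtures <- function(wt_h0, ko_h0, wt_h1, ko_h1, beta) {
  list(
    h0 = mixture_condition(list(wt_h0, ko_h0), c(1 - beta, beta)),
    h1 = mixture_condition(list(wt_h1, ko_h1), c(1 - beta, beta))
  )
}

#' Detection probability across knockout fractions
#'
#' For each `beta` builds the mixture hypotheses
#' `H0 = (1-beta) WT + beta KO` at the low dose and
#' `H1 = (1-beta) WT + beta KO` at the high dose (same composition under
#' both hypotheses) and reports `P_D` at fixed false alarm level `alpha`.
#'
#' @param wt_h0,ko_h0,wt_h1,ko_h1 [gaussian_condition()] models of one
#'   shared dimension: genotype-specific conditionals at the low (H0) and
#'   high (H1) dose.
#' @param beta_grid knockout fractions in `[0, 1]`.
#' @param alpha false alarm level in (0, 1).
#' @param grid optional shared [mixture_grid()].
#' @return data.frame with columns `beta`, `pfa`, `pd`.
#' @export
beta_sweep_pd <- function(wt_h0, ko_h0, wt_h1, ko_h1, beta_grid, alpha,
                          grid = NULL) {
  beta_grid <- as.numeric(beta_grid)
  if (any(beta_grid < 0 | beta_grid > 1)) {
    stop_cellnp("cellnp_domain_error", "beta_grid must lie in [0, 1]")
  }
  if (is.null(grid)) {
    grid <- mixture_grid(mixture_condition(list(wt_h0, ko_h0), c(0.5, 0.5)),
                         mixture_condition(list(wt_h1, ko_h1), c(0.5, 0.5)))
  }
  rows <- lapply(beta_grid, function(beta) {
    mx <- build_beta_mixtures(wt_h0, ko_h0, wt_h1, ko_h1, beta)
    op <- mixture_solve_threshold(mx$h0, mx$h1, alpha, grid)
    data.frame(beta = beta, pfa = op$pfa, pd = op$pd)
  })
  do.call(rbind, rows)
}

#' False alarm probability across knockout fractions at fixed detection
#'
#' For each `beta`, the smallest `P_FA` whose optimal mixture test achieves
#' `P_D >= target_pd`, by bisection over the log-likelihood-ratio threshold.
#'
#' @inheritParams beta_sweep_pd
#' @param target_pd target detection probability in (0, 1).
#' @return data.frame with columns `beta`, `pfa`, `pd`.
#' @export
beta_sweep_pfa <- function(wt_h0, ko_h0, wt_h1, ko_h1, beta_grid, target_pd,
                           grid = NULL) {
  beta_grid <- as.numeric(beta_grid)
  if (any(beta_grid < 0 | beta_grid > 1)) {
    stop_cellnp("cellnp_domain_error", "beta_grid must lie in [0, 1]")
  }
  if (!is_prob(target_pd)) {
    stop_cellnp("cellnp_domain_error", "target_pd must lie strictly in (0, 1)")
  }
  if (is.null(grid)) {
    grid <- mixture_grid(mixture_condition(list(wt_h0, ko_h0), c(0.5, 0.5)),
                         mixture_condition(list(wt_h1, ko_h1), c(0.5, 0.5)))
  }
  rows <- lapply(beta_grid, function(beta) {
    mx <- build_beta_mixtures(wt_h0, ko_h0, wt_h1, ko_h1, beta)
    quad <- mixture_quadrature(mx$h0, mx$h1, grid)
    e <- mixture_pfa_at_pd_quad(quad, target_pd)
    data.frame(beta = beta, pfa = e[["pfa"]], pd = e[["pd"]])
  })
  do.call(rbind, rows)
}

#' Export a beta-sweep table as CSV
#'
#' Columns `beta`, `variant`, `pfa`, `pd`, `alpha_or_target`.
#'
#' @param sweep data.frame as produced by [cmd_mixture_sweep()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(sweep, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
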