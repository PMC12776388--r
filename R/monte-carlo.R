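# Simulation-based estimators of every probability the analytic pipeline
# produces; used as an independent verification oracle in tests and as the
# fallback for dimensions the quadrature grids do not support.

mc_estimate <- function(value, n, seed) {
  structure(list(value = value, se = sqrt(value * (1 - value) / n),
                 n = n, seed = seed),
            class = "mc_estimate")
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf("MC estimate: %.6f (SE %.2g, n = %g, seed = %d)\n",
              x$value, x$se, x$n, x$seed))
  invisible(x)
}

#' Draw observations from a Gaussian or mixture condition
#'
#' Reproducible sampler: identical `(n, seed)` give bit-identical draws
#' (Mersenne-Twister, inversion normals, fixed per-operation stream).
#'
#' @param model a [gaussian_condition()] or [mixture_condition()].
#' @param n number of draws.
#' @param seed integer seed.
#' @return `n x dim` matrix; for mixtures, the component index of each draw
#'   is attached as attribute `component`.
#' @export
sample_condition <- function(model, n, seed) {
  if (!is_count(n)) stop_cellnp("cellnp_domain_error", "n must be a positive count")
  local_rng(derive_seed(seed, "sample_condition"), {
    if (inherits(model, "gaussian_condition")) {
      sample_gaussian(model, n)
    } else if (inherits(model, "mixture_condition")) {
      comp <- sample.int(length(model$weights), n, replace = TRUE,
                         prob = model$weights)
      out <- matrix(NA_real_, n, model$dim)
      for (k in seq_along(model$components)) {
        idx <- which(comp == k)
        if (length(idx)) out[idx, ] <- sample_gaussian(model$components[[k]], length(idx))
      }
      attr(out, "component") <- comp
      out
    } else {
      stop_cellnp("cellnp_invalid_model", "model must be gaussian or mixture condition")
    }
  })
}

sample_gaussian <- function(model, n) {
  ch <- chol(model$cov)
  sweep(matrix(stats::rnorm(n * model$dim), n, model$dim) %*% ch,
        2L, model$mean, "+")
}

# canonical-coordinate draws of X under either hypothesis
sample_canonical <- function(pair, hypothesis, n) {
  X <- matrix(stats::rnorm(n * pair$dim), n, pair$dim)
  if (hypothesis == "H1") {
    X <- sweep(X %*% diag(sqrt(pair$lam), pair$dim, pair$dim), 2L, pair$m, "+")
  }
  X
}

#' Monte Carlo operating point
#'
#' Empirical false alarm and detection frequencies of the rejection region,
#' specified either as `z_th` on the canonical quadratic statistic (Gaussian
#' hypothesis pairs) or as `log_gamma` on the log-likelihood ratio (any pair
#' of Gaussian/mixture models, any dimension).
#'
#' @param h0,h1 condition models.
#' @param z_th threshold on the canonical statistic (Gaussian pairs only).
#' @param log_gamma threshold on the LLR; give exactly one of
#'   `z_th`/`log_gamma`.
#' @param n draws per hypothesis.
#' @param seed integer seed.
#' @return list with `pfa` and `pd`, each an `mc_estimate`.
#' @export
mc_operating_point <- function(h0, h1, z_th = NULL, log_gamma = NULL,
                               n = 1e6, seed = 1L) {
  if (is.null(z_th) == is.null(log_gamma)) {
    stop_cellnp("cellnp_domain_error", "give exactly one of z_th or log_gamma")
  }
  if (!is.null(z_th)) {
    if (!inherits(h0, "gaussian_condition") || !inherits(h1, "gaussian_condition")) {
      stop_cellnp("cellnp_domain_error",
                  "z_th thresholds apply to Gaussian hypothesis pairs")
    }
    pair <- canonicalize(h0, h1)
    reject <- function(y) test_statistic(to_canonical(y, pair), pair) > z_th
  } else {
    reject <- function(y) log_likelihood_ratio(y, h0, h1) > log_gamma
  }
  y0 <- sample_condition(h0, n, derive_seed(seed, "mc_op_h0"))
  y1 <- sample_condition(h1, n, derive_seed(seed, "mc_op_h1"))
  list(pfa = mc_estimate(mean(reject(y0)), n, seed),
       pd = mc_estimate(mean(reject(y1)), n, seed))
}

#' Monte Carlo CDF of the test statistic
#'
#' Empirical fraction of simulated `Z` values at or below `z`.
#'
#' @param pair a `canonical_pair`.
#' @param z evaluation point (vectorized).
#' @param hypothesis `"H0"` or `"H1"`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return an `mc_estimate` (for scalar `z`) or list thereof.
#' @export
mc_cdf <- function(pair, z, hypothesis = c("H0", "H1"), n = 1e6, seed = 1L) {
  stopifnot(inherits(pair, "canonical_pair"))
  hypothesis <- match.arg(hypothesis)
  if (all(pair$degenerate)) {
    stop_cellnp("cellnp_degenerate_statistic", "degenerate pair: Z == 0")
  }
  Z <- local_rng(derive_seed(seed, paste0("mc_cdf_", hypothesis)), {
    test_statistic(sample_canonical(pair, hypothesis, n), pair)
  })
  ests <- lapply(as.numeric(z), function(zi) mc_estimate(mean(Z <= zi), n, seed))
  if (length(ests) == 1L) ests[[1L]] else ests
}

#' Monte Carlo characteristic function of the test statistic
#'
#' Sample mean of `exp(j omega Z)`; real and imaginary parts carry their
#' own standard errors (each bounded by `1/sqrt(n)`).
#'
#' @inheritParams mc_cdf
#' @param omega real frequency (scalar).
#' @return list with `value` (complex), `se_re`, `se_im`, `n`, `seed`.
#' @export
mc_char_fn <- function(pair, omega, hypothesis = c("H0", "H1"), n = 1e6, seed = 1L) {
  stopifnot(inherits(pair, "canonical_pair"))
  hypothesis <- match.arg(hypothesis)
  Z <- local_rng(derive_seed(seed, paste0("mc_cf_", hypothesis)), {
    test_statistic(sample_canonical(pair, hypothesis, n), pair)
  })
  re <- cos(omega * Z); im <- sin(omega * Z)
  list(value = complex(real = mean(re), imaginary = mean(im)),
       se_re = stats::sd(re) / sqrt(n), se_im = stats::sd(im) / sqrt(n),
       n = n, seed = seed)
}
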