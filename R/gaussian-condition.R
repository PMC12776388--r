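#' Gaussian class-conditional model for one hypothesis
#'
#' A multivariate Gaussian describing log-responses of one condition
#' (cell type, dose, set of time points).  Used as the class-conditional
#' density under a hypothesis in the Neyman-Pearson test.
#'
#' @param mean numeric vector of length N (means of the log responses).
#' @param cov symmetric positive-definite N x N covariance matrix (a scalar
#'   variance is accepted for N = 1).
#' @param n optional number of observations the model was fitted from.
#' @param estimator covariance estimator label recorded in metadata
#'   (default "unbiased", i.e. the n - 1 divisor).
#' @return an object of class `gaussian_condition` with fields `dim`, `mean`,
#'   `cov`, `n`, `estimator`, `log_scale`.
#' @examples
#' gaussian_condition(c(0, 0), diag(2))
#' @export
gaussian_condition <- function(mean, cov, n = NA_integer_, estimator = "unbiased") {
  mean <- as.numeric(mean)
  if (length(mean) < 1L || anyNA(mean) || any(!is.finite(mean))) {
    stop_cellnp("cellnp_invalid_model", "mean must be a finite numeric vector")
  }
  if (is.null(dim(cov))) cov <- matrix(as.numeric(cov), length(mean), length(mean))
  cov <- as.matrix(cov)
  N <- length(mean)
  if (!all(dim(cov) == c(N, N))) {
    stop_cellnp("cellnp_invalid_model", "cov must be an N x N matrix matching mean")
  }
  if (any(!is.finite(cov))) {
    stop_cellnp("cellnp_invalid_model", "cov must be finite")
  }
  if (max(abs(cov - t(cov))) > 1e-10 * max(1, max(abs(cov)))) {
    stop_cellnp("cellnp_invalid_model", "cov must be symmetric (tolerance 1e-10)")
  }
  cov <- symmetrize(cov)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop_cellnp("cellnp_not_spd", "cov must be positive-definite (all eigenvalues > 0)")
  }
  structure(
    list(dim = N, mean = mean, cov = cov, n = n,
         estimator = estimator, log_scale = TRUE),
    class = "gaussian_condition"
  )
}

#' @export
print.gaussian_condition <- function(x, ...) {
  cat(sprintf("Gaussian condition (N = %d)\n", x$dim))
  cat("  mean:", paste(signif(x$mean, 6), collapse = ", "), "\n")
  cat("  cov :\n")
  print(signif(x$cov, 6))
  if (!is.na(x$n)) cat(sprintf("  fitted from n = %d (%s estimator)\n", x$n, x$estimator))
  invisible(x)
}

#' Serialize / read a Gaussian condition as JSON
#'
#' The JSON layout is `{dim, mean, cov, n, estimator, log_scale}` with the
#' covariance stored row-wise as a list of rows.
#'
#' @param model a `gaussian_condition`.
#' @param path file path.
#' @return `write_gaussian_json` returns `path` invisibly;
#'   `read_gaussian_json` returns a `gaussian_condition`.
#' @export
write_gaussian_json <- function(model, path) {
  stopifnot(inherits(model, "gaussian_condition"))
  payload <- list(
    dim = model$dim, mean = model$mean,
    cov = apply(model$cov, 1L, identity, simplify = FALSE),
    n = model$n, estimator = model$estimator, log_scale = model$log_scale
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gaussian_json
#' @export
read_gaussian_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cov <- payload$cov
  if (is.list(cov)) cov <- do.call(rbind, cov)
  gaussian_condition(payload$mean, matrix(as.numeric(cov), payload$dim, payload$dim),
                     n = payload$n %||% NA_integer_,
                     estimator = payload$estimator %||% "unbiased")
}
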