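# Synthetic single-cell response generator.
#
# The measured dataset this package was designed around (nuclear NF-kB in
# WT and A20-deficient fibroblasts across a TNF dose panel) is not publicly
# deposited, so the generator emulates its statistical structure: lognormal
# responses whose log-means rise with dose along a saturating Hill curve,
# roughly dose-independent log-SDs, late-time attenuation in WT (negative
# feedback), an upward shift and weaker late attenuation in the knockout,
# and optional cross-time correlation of the paired measurements.

#' Scenario configuration for the synthetic generator
#'
#' @param doses TNF dose panel in ng/mL.
#' @param times measurement times in minutes.
#' @param params data.frame with one row per (cell_type, time): columns
#'   `cell_type`, `time`, `b` (baseline log-mean at dose 0), `A` (log-mean
#'   amplitude, must be > 0 so means increase with dose), `K`
#'   (half-saturation dose, ng/mL), `h` (Hill exponent), `log_sd`
#'   (dose-independent SD of log responses).
#' @param rho cross-time correlation of log responses, |rho| < 1.
#' @param n_per_condition cells per (cell_type, dose).
#' @param seed integer seed for [generate_dataset()].
#' @return validated object of class `scenario_config`.
#' @export
scenario_config <- function(doses, times, params, rho = 0.3,
                            n_per_condition = 1000L, seed = 20250101L) {
  doses <- as.numeric(doses); times <- as.numeric(times)
  if (any(doses < 0) || anyNA(doses)) {
    stop_cellnp("cellnp_config_error", "doses must be nonnegative")
  }
  if (any(times <= 0) || is.unsorted(times, strictly = TRUE)) {
    stop_cellnp("cellnp_config_error", "times must be positive and strictly increasing")
  }
  need <- c("cell_type", "time", "b", "A", "K", "h", "log_sd")
  if (!all(need %in% names(params))) {
    stop_cellnp("cellnp_config_error",
                sprintf("params needs columns: %s", paste(need, collapse = ", ")))
  }
  if (any(params$K <= 0) || any(params$h <= 0) || any(params$log_sd <= 0) ||
      any(params$A <= 0)) {
    stop_cellnp("cellnp_config_error",
                "params must satisfy K > 0, h > 0, log_sd > 0, A > 0 (field at fault: check K/h/log_sd/A)")
  }
  if (!is.numeric(rho) || length(rho) != 1L || abs(rho) >= 1) {
    stop_cellnp("cellnp_config_error", "rho must satisfy |rho| < 1 (field: rho)")
  }
  combos <- expand.grid(cell_type = unique(params$cell_type), time = times,
                        stringsAsFactors = FALSE)
  key <- paste(params$cell_type, params$time)
  if (!all(paste(combos$cell_type, combos$time) %in% key)) {
    stop_cellnp("cellnp_config_error", "params must cover every (cell_type, time)")
  }
  if (!is_count(n_per_condition)) {
    stop_cellnp("cellnp_config_error", "n_per_condition must be a positive count")
  }
  structure(list(doses = doses, times = times,
                 cell_types = unique(params$cell_type),
                 params = as.data.frame(params), rho = rho,
                 n_per_condition = as.integer(n_per_condition),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Default synthetic scenario
#'
#' Calibration (arbitrary, implementer-chosen; see the package vignette):
#' dose panel 0.0021, 0.0052, 0.013, 0.2, 0.51, 1.3, 50 ng/mL; times 30 and
#' 240 min; Hill-type log-mean dose responses with WT separation exceeding
#' KO separation and 30-min separation exceeding 4-h separation
#' (WT: A = 1.5 at 30 min, 0.8 at 4 h on baseline b = 4.0; KO: A = 0.9 and
#' 0.6 on the shifted baseline b = 4.4, i.e. the knockout sits higher but
#' discriminates doses less at both times, and attenuates less over time --
#' the near-linear pathway without its negative feedback); log-SD 0.5
#' everywhere; cross-time correlation 0.3; 1000 cells per condition.
#'
#' @return a [scenario_config()].
#' @export
default_scenario <- function() {
  params <- data.frame(
    cell_type = c("WT", "WT", "KO", "KO"),
    time = c(30, 240, 30, 240),
    b = c(4.0, 4.0, 4.4, 4.4),
    A = c(1.5, 0.8, 0.9, 0.6),
    K = 0.05, h = 1, log_sd = 0.5,
    stringsAsFactors = FALSE
  )
  scenario_config(doses = c(0.0021, 0.0052, 0.013, 0.2, 0.51, 1.3, 50),
                  times = c(30, 240), params = params,
                  rho = 0.3, n_per_condition = 1000L, seed = 20250101L)
}

#' Exact generating-model parameters for one condition
#'
#' The log-mean per time point follows
#' `b + A d^h / (K^h + d^h)` and the log-covariance is
#' `[[s1^2, rho s1 s2], [rho s1 s2, s2^2]]` (restricted to the requested
#' times) -- the ground truth that [fit_gaussian()] should recover from
#' generated data up to sampling error.
#'
#' @param config a [scenario_config()].
#' @param cell_type,dose condition identifiers.
#' @param times time points (defaults to all configured times).
#' @return a [gaussian_condition()] holding the exact log-scale parameters.
#' @export
condition_truth <- function(config, cell_type, dose, times = config$times) {
  stopifnot(inherits(config, "scenario_config"))
  if (!cell_type %in% config$cell_types) {
    stop_cellnp("cellnp_config_error", sprintf("unknown cell_type %s", cell_type))
  }
  if (dose < 0) stop_cellnp("cellnp_domain_error", "dose must be nonnegative")
  rows <- lapply(times, function(t) {
    r <- config$params[config$params$cell_type == cell_type & config$params$time == t, ]
    if (nrow(r) != 1L) {
      stop_cellnp("cellnp_config_error", sprintf("unknown time %g for %s", t, cell_type))
    }
    r
  })
  mu <- vapply(rows, function(r) {
    hill <- if (dose == 0) 0 else dose^r$h / (r$K^r$h + dose^r$h)
    r$b + r$A * hill
  }, numeric(1))
  s <- vapply(rows, `[[`, numeric(1), "log_sd")
  N <- length(times)
  cov <- diag(s^2, N, N)
  if (N > 1L) {
    for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
      cov[i, j] <- cov[j, i] <- config$rho * s[i] * s[j]
    }
  }
  gaussian_condition(mu, cov)
}

#' Generate a synthetic wide-layout response table
#'
#' For every (cell_type, dose) draws `n_per_condition` cells from the
#' condition's exact lognormal law (correlated across time points) and
#' returns a raw-scale wide table.  Deterministic given `config$seed`.
#'
#' @param config a [scenario_config()].
#' @return a raw-scale wide `response_table`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  local_rng(derive_seed(config$seed, "generate_dataset"), {
    blocks <- list()
    for (ct in config$cell_types) {
      for (di in seq_along(config$doses)) {
        d <- config$doses[di]
        truth <- condition_truth(config, ct, d)
        logresp <- sample_gaussian(truth, config$n_per_condition)
        blk <- data.frame(
          cell_id = sprintf("%s_d%02d_%05d", ct, di, seq_len(config$n_per_condition)),
          cell_type = ct, dose = d, stringsAsFactors = FALSE
        )
        for (ti in seq_along(config$times)) {
          blk[[paste0("response_", config$times[ti])]] <- exp(logresp[, ti])
        }
        blocks[[length(blocks) + 1L]] <- blk
      }
    }
    new_response_table(do.call(rbind, blocks), "wide", times = config$times,
                       log_scale = FALSE)
  })
}

#' Generate a mixed-genotype population at one dose
#'
#' Each cell is independently knockout with probability `beta`, then drawn
#' from its genotype's condition; the genotype label is retained in an
#' auxiliary `genotype` column for validation while `cell_type` is set to
#' `"MIX"`.
#'
#' @param config a [scenario_config()] (must contain cell types WT and KO).
#' @param beta knockout fraction in `[0, 1]`.
#' @param dose TNF dose in ng/mL.
#' @param n number of cells.
#' @param seed integer seed.
#' @return a raw-scale wide `response_table` with a `genotype` column.
#' @export
generate_mixed_population <- function(config, beta, dose, n, seed) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.numeric(beta) || beta < 0 || beta > 1) {
    stop_cellnp("cellnp_domain_error", "beta must lie in [0, 1]")
  }
  if (!is_count(n)) stop_cellnp("cellnp_domain_error", "n must be a positive count")
  local_rng(derive_seed(seed, "generate_mixed_population"), {
    genotype <- ifelse(stats::runif(n) < beta, "KO", "WT")
    out <- matrix(NA_real_, n, length(config$times))
    for (ct in c("WT", "KO")) {
      idx <- which(genotype == ct)
      if (length(idx)) {
        truth <- condition_truth(config, ct, dose)
        out[idx, ] <- exp(sample_gaussian(truth, length(idx)))
      }
    }
    df <- data.frame(cell_id = sprintf("MIX_%06d", seq_len(n)),
                     cell_type = "MIX", dose = dose, stringsAsFactors = FALSE)
    for (ti in seq_along(config$times)) {
      df[[paste0("response_", config$times[ti])]] <- out[, ti]
    }
    df$genotype <- genotype
    new_response_table(df, "wide", times = config$times, log_scale = FALSE)
  })
}

#' Read / write a scenario configuration (YAML)
#'
#' Full round trip of every field; doses and times are stored as lists,
#' params as a column map.
#'
#' @param config a [scenario_config()].
#' @param path YAML file path.
#' @return `write_scenario` returns `path` invisibly; `read_scenario`
#'   returns a `scenario_config`.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  payload <- list(doses = config$doses, times = config$times,
                  params = as.list(config$params), rho = config$rho,
                  n_per_condition = config$n_per_condition, seed = config$seed)
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  payload <- yaml::read_yaml(path)
  scenario_config(doses = unlist(payload$doses), times = unlist(payload$times),
                  params = as.data.frame(payload$params,
                                         stringsAsFactors = FALSE),
                  rho = payload$rho,
                  n_per_condition = payload$n_per_condition,
                  seed = payload$seed)
}
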