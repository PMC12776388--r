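#' Column-name schema for single-cell response tables
#'
#' Maps the canonical fields (cell id, cell type, dose, time, response) to
#' the column headers used in a CSV file, so arbitrary headers are supported.
#' In wide layout the per-time response columns are named
#' `<response>_<time>` (e.g. `nfkb_au_30`, `nfkb_au_240`).
#'
#' @param cell_id,cell_type,dose,time,response column names in the file.
#' @return a named list of class `response_schema`.
#' @export
response_schema <- function(cell_id = "cell_id", cell_type = "cell_type",
                            dose = "tnf_ng_ml", time = "time_min",
                            response = "nfkb_au") {
  structure(list(cell_id = cell_id, cell_type = cell_type, dose = dose,
                 time = time, response = response),
            class = "response_schema")
}

new_response_table <- function(df, layout, times = NULL, log_scale = FALSE) {
  structure(df, layout = layout, times = times, log_scale = log_scale,
            class = c("response_table", "data.frame"))
}

#' @export
print.response_table <- function(x, ...) {
  cat(sprintf("Single-cell response table: %d rows, %s layout, %s scale\n",
              nrow(x), attr(x, "layout"),
              if (isTRUE(attr(x, "log_scale"))) "log" else "raw"))
  if (identical(attr(x, "layout"), "wide")) {
    cat("  time points:", paste(attr(x, "times"), collapse = ", "), "min\n")
  }
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

response_cols <- function(table) {
  if (identical(attr(table, "layout"), "wide")) {
    paste0("response_", attr(table, "times"))
  } else {
    "response"
  }
}

#' Read a single-cell response table from CSV
#'
#' Long layout expects one measurement per row (columns for cell id, cell
#' type, dose, time, response).  Wide layout expects one row per cell with
#' one response column per time point, named `<response>_<time>` as declared
#' by the schema; an optional `genotype` column (from mixed-population
#' simulations) is carried along when present.
#'
#' @param path CSV file (comma-separated, UTF-8, header row required).
#' @param schema a [response_schema()] mapping canonical fields to headers.
#' @param layout `"long"` or `"wide"`.
#' @param strict if `TRUE`, nonpositive responses are a parse error naming
#'   the offending data rows; otherwise they are kept and dealt with at
#'   [log_transform()] time.
#' @return a `response_table` (data.frame with canonical column names and
#'   `layout`/`times`/`log_scale` attributes).
#' @export
read_response_table <- function(path, schema = response_schema(),
                                layout = c("long", "wide"), strict = FALSE) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    stop_cellnp("cellnp_io_error", sprintf("file not found: %s", path))
  }
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c(schema$cell_id, schema$cell_type, schema$dose)
  if (layout == "long") need <- c(need, schema$time, schema$response)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop_cellnp("cellnp_schema_error",
                sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  df <- data.frame(
    cell_id = as.character(raw[[schema$cell_id]]),
    cell_type = as.character(raw[[schema$cell_type]]),
    dose = as.numeric(raw[[schema$dose]]),
    stringsAsFactors = FALSE
  )
  parse_numeric <- function(col, label) {
    x <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(x) & !is.na(col))
    if (length(bad)) {
      stop_cellnp("cellnp_parse_error",
                  sprintf("non-numeric %s at data row(s) %s (file line(s) %s)",
                          label, paste(bad, collapse = ", "),
                          paste(bad + 1L, collapse = ", ")))
    }
    x
  }
  times <- NULL
  if (layout == "long") {
    df$time <- parse_numeric(raw[[schema$time]], schema$time)
    df$response <- parse_numeric(raw[[schema$response]], schema$response)
    resp_cols <- "response"
  } else {
    wide_names <- grep(paste0("^", schema$response, "_"), names(raw), value = TRUE)
    if (!length(wide_names)) {
      stop_cellnp("cellnp_schema_error",
                  sprintf("wide layout needs columns named %s_<time>", schema$response))
    }
    times <- as.numeric(sub(paste0("^", schema$response, "_"), "", wide_names))
    ord <- order(times)
    times <- times[ord]
    wide_names <- wide_names[ord]
    for (i in seq_along(times)) {
      df[[paste0("response_", times[i])]] <-
        parse_numeric(raw[[wide_names[i]]], wide_names[i])
    }
    if (anyDuplicated(df$cell_id)) {
      stop_cellnp("cellnp_parse_error",
                  "wide layout requires each cell_id to appear exactly once")
    }
    resp_cols <- paste0("response_", times)
  }
  if ("genotype" %in% names(raw)) df$genotype <- as.character(raw$genotype)
  if (strict) {
    bad <- which(rowSums(as.matrix(df[resp_cols]) <= 0 |
                         is.na(as.matrix(df[resp_cols]))) > 0)
    if (length(bad)) {
      stop_cellnp("cellnp_parse_error",
                  sprintf("nonpositive/missing response at data row(s): %s",
                          paste(utils::head(bad, 20L), collapse = ", ")))
    }
  }
  new_response_table(df, layout, times = times, log_scale = FALSE)
}

#' Write a response table to CSV
#'
#' Numeric values are written with 17 significant digits so a
#' write-then-read round trip reproduces the table exactly.
#'
#' @param table a `response_table`.
#' @param path output CSV path.
#' @param schema column-name mapping used for the header row.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(table, path, schema = response_schema()) {
  stopifnot(inherits(table, "response_table"))
  df <- as.data.frame(table)
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL,
                    stats::setNames(list(df$cell_id, df$cell_type),
                                    c(schema$cell_id, schema$cell_type)))
  fmt <- function(x) sprintf("%.17g", x)
  out[[schema$dose]] <- fmt(df$dose)
  if (identical(attr(table, "layout"), "long")) {
    out[[schema$time]] <- fmt(df$time)
    out[[schema$response]] <- fmt(df$response)
  } else {
    for (t in attr(table, "times")) {
      out[[paste0(schema$response, "_", t)]] <- fmt(df[[paste0("response_", t)]])
    }
  }
  if ("genotype" %in% names(df)) out$genotype <- df$genotype
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Natural-log transform of the responses
#'
#' Replaces every response by its natural logarithm and flags the table as
#' log-scale.  Nonpositive responses cannot be log-transformed; the policy
#' is configurable: `"drop"` removes the affected cells with a warning
#' stating the count (immunocytochemistry backgrounds can produce zeros),
#' `"error"` aborts listing the offending cell ids.
#'
#' @param table a raw-scale `response_table`.
#' @param nonpositive `"drop"` (default) or `"error"`.
#' @return a log-scale `response_table`.
#' @export
log_transform <- function(table, nonpositive = c("drop", "error")) {
  stopifnot(inherits(table, "response_table"))
  nonpositive <- match.arg(nonpositive)
  if (isTRUE(attr(table, "log_scale"))) {
    stop_cellnp("cellnp_domain_error", "table is already log-scale")
  }
  cols <- response_cols(table)
  resp <- as.matrix(as.data.frame(table)[cols])
  bad <- which(rowSums(resp <= 0 | is.na(resp)) > 0)
  if (length(bad)) {
    if (nonpositive == "error") {
      stop_cellnp("cellnp_domain_error",
                  sprintf("nonpositive response for cell_id(s): %s",
                          paste(utils::head(table$cell_id[bad], 20L), collapse = ", ")))
    }
    warning(sprintf("log_transform: dropped %d cell(s) with nonpositive responses",
                    length(bad)), call. = FALSE)
    table <- table[-bad, , drop = FALSE]
  }
  df <- as.data.frame(table)
  for (cl in cols) df[[cl]] <- log(df[[cl]])
  new_response_table(df, attr(table, "layout"), times = attr(table, "times"),
                     log_scale = TRUE)
}

#' @export
`[.response_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    out <- new_response_table(as.data.frame(out), attr(x, "layout"),
                              times = attr(x, "times"),
                              log_scale = attr(x, "log_scale"))
  }
  out
}

#' Condition key: one hypothesis condition
#'
#' Identifies the cells entering one class-conditional model: a cell type, a
#' dose, and the ordered time points forming the observation vector.
#'
#' @param cell_type label, e.g. `"WT"` or `"KO"`.
#' @param dose dose in ng/mL (nonnegative).
#' @param times strictly increasing vector of measurement times (minutes).
#' @return an object of class `condition_key`.
#' @export
condition_key <- function(cell_type, dose, times) {
  times <- as.numeric(times)
  if (length(times) < 1L || any(!is.finite(times)) || any(times <= 0) ||
      is.unsorted(times, strictly = TRUE)) {
    stop_cellnp("cellnp_domain_error", "times must be strictly increasing and positive")
  }
  if (!is.numeric(dose) || length(dose) != 1L || dose < 0) {
    stop_cellnp("cellnp_domain_error", "dose must be a nonnegative scalar")
  }
  structure(list(cell_type = as.character(cell_type), dose = dose, times = times),
            class = "condition_key")
}

same_dose <- function(x, dose) abs(x - dose) <= 1e-8 * pmax(1, abs(dose))

#' Observation matrix for one condition
#'
#' Selects the cells matching a condition key and returns the N-column
#' observation matrix (rows = cells, columns ordered as `key$times`).
#' Multi-time observations (N > 1) require a wide-layout table, i.e.
#' explicitly paired per-cell measurements.
#'
#' @param table a log-scale `response_table`.
#' @param key a [condition_key()].
#' @return numeric matrix, one row per matching cell.
#' @export
select_condition <- function(table, key) {
  stopifnot(inherits(table, "response_table"), inherits(key, "condition_key"))
  if (!isTRUE(attr(table, "log_scale"))) {
    stop_cellnp("cellnp_domain_error", "select_condition requires a log-scale table")
  }
  N <- length(key$times)
  df <- as.data.frame(table)
  if (identical(attr(table, "layout"), "wide")) {
    have <- attr(table, "times")
    missing_t <- setdiff(key$times, have)
    if (length(missing_t)) {
      stop_cellnp("cellnp_selection_error",
                  sprintf("time point(s) %s not present in wide table",
                          paste(missing_t, collapse = ", ")))
    }
    keep <- df$cell_type == key$cell_type & same_dose(df$dose, key$dose)
    obs <- as.matrix(df[keep, paste0("response_", key$times), drop = FALSE])
  } else {
    if (N > 1L) {
      stop_cellnp("cellnp_pairing_error",
                  "N > 1 requires a wide-layout table with per-cell pairing")
    }
    keep <- df$cell_type == key$cell_type & same_dose(df$dose, key$dose) &
      df$time == key$times
    obs <- matrix(df$response[keep], ncol = 1L)
  }
  if (nrow(obs) == 0L) {
    stop_cellnp("cellnp_selection_error",
                sprintf("no cells match (%s, %g ng/mL, times %s)",
                        key$cell_type, key$dose, paste(key$times, collapse = ",")))
  }
  colnames(obs) <- paste0("t", key$times)
  obs
}

#' Fit a Gaussian class-conditional model
#'
#' Column-wise sample means and the unbiased (n - 1 divisor) sample
#' covariance of an observation matrix of log responses.
#'
#' @param observations numeric matrix (rows = cells) or vector (N = 1).
#' @param cond_cap condition-number cap above which the covariance is
#'   declared numerically singular.
#' @return a [gaussian_condition()].
#' @export
fit_gaussian <- function(observations, cond_cap = 1e12) {
  obs <- if (is.null(dim(observations))) matrix(observations, ncol = 1L)
         else as.matrix(observations)
  if (any(!is.finite(obs))) {
    stop_cellnp("cellnp_domain_error", "observations must be finite")
  }
  N <- ncol(obs)
  n <- nrow(obs)
  if (n < N + 2L) {
    stop_cellnp("cellnp_insufficient_data",
                sprintf("need at least N + 2 = %d observations, got %d", N + 2L, n))
  }
  mu <- colMeans(obs)
  S <- symmetrize(stats::cov(obs))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > cond_cap) {
    stop_cellnp("cellnp_degenerate_covariance",
                sprintf("sample covariance is singular or ill-conditioned (kappa = %.3g)",
                        max(ev) / max(min(ev), .Machine$double.xmin)))
  }
  gaussian_condition(mu, S, n = n, estimator = "unbiased")
}

#' Per-condition dynamic-range summary
#'
#' Mean and standard deviation of log responses for every
#' (cell type, dose, time) present in the table -- the summary behind
#' dose-response "dynamic range" plots.  Values match [fit_gaussian()] on
#' the corresponding selections.
#'
#' @param table a log-scale `response_table`.
#' @return data.frame with columns `cell_type`, `dose`, `time`, `n`,
#'   `mean`, `sd`, ordered by cell type, time, dose.
#' @export
dynamic_range_summary <- function(table) {
  stopifnot(inherits(table, "response_table"))
  if (!isTRUE(attr(table, "log_scale"))) {
    stop_cellnp("cellnp_domain_error", "dynamic_range_summary requires a log-scale table")
  }
  df <- as.data.frame(table)
  if (nrow(df) == 0L) {
    return(data.frame(cell_type = character(), dose = numeric(),
                      time = numeric(), n = integer(),
                      mean = numeric(), sd = numeric()))
  }
  if (identical(attr(table, "layout"), "wide")) {
    times <- attr(table, "times")
    long <- do.call(rbind, lapply(times, function(t) {
      data.frame(cell_type = df$cell_type, dose = df$dose, time = t,
                 response = df[[paste0("response_", t)]],
                 stringsAsFactors = FALSE)
    }))
  } else {
    long <- df[c("cell_type", "dose", "time", "response")]
  }
  if (nrow(long) == 0L) {
    return(data.frame(cell_type = character(), dose = numeric(),
                      time = numeric(), n = integer(),
                      mean = numeric(), sd = numeric()))
  }
  agg <- stats::aggregate(response ~ cell_type + dose + time, data = long,
                          FUN = function(x) c(n = length(x), mean = mean(x),
                                              sd = stats::sd(x)))
  out <- data.frame(cell_type = agg$cell_type, dose = agg$dose, time = agg$time,
                    n = as.integer(agg$response[, "n"]),
                    mean = agg$response[, "mean"], sd = agg$response[, "sd"],
                    stringsAsFactors = FALSE)
  out[order(out$cell_type, out$time, out$dose), , drop = FALSE]
}
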