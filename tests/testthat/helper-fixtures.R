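# shared fixture builders; everything is generated in code at test time

# random symmetric positive-definite matrix with moderate conditioning
random_spd <- function(N) {
  A <- matrix(stats::rnorm(N * N), N)
  crossprod(A) + diag(0.5, N)
}

# random nondegenerate Gaussian hypothesis pair of dimension N
random_pair_models <- function(N) {
  list(h0 = gaussian_condition(stats::rnorm(N), random_spd(N)),
       h1 = gaussian_condition(stats::rnorm(N, sd = 1.5), random_spd(N)))
}

# equal-variance closed form: P_D at false alarm alpha for effect size meff
gaussian_pd <- function(alpha, meff) {
  1 - stats::pnorm(stats::qnorm(1 - alpha) - meff)
}

# tiny long-layout CSV on disk; returns the path
write_long_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("cell_id,cell_type,tnf_ng_ml,time_min,nfkb_au", lines), path)
  path
}

# wide response_table built directly from a matrix of raw responses
wide_table_from <- function(resp, cell_type = "WT", dose = 0.2,
                            times = c(30, 240)) {
  df <- data.frame(cell_id = sprintf("c%04d", seq_len(nrow(resp))),
                   cell_type = cell_type, dose = dose,
                   stringsAsFactors = FALSE)
  for (i in seq_along(times)) df[[paste0("response_", times[i])]] <- resp[, i]
  cellnp:::new_response_table(df, "wide", times = times, log_scale = FALSE)
}

# fast scenario for pipeline tests: fewer cells, fewer doses
small_scenario <- function(n = 400L, seed = 42L) {
  cfg <- default_scenario()
  cfg$n_per_condition <- as.integer(n)
  cfg$seed <- as.integer(seed)
  cfg
}
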