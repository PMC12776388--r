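test_that("CSV read-back preserves records and maps schema columns", {
  path <- write_long_csv(c("c1,WT,0.2,30,5.5",
                           "c2,WT,0.2,30,6.25",
                           "c3,KO,50,240,12.125"))
  tab <- read_response_table(path)
  expect_s3_class(tab, "response_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$response, c(5.5, 6.25, 12.125))
  expect_equal(tab$cell_type, c("WT", "WT", "KO"))

  # arbitrary headers through a schema mapping
  alt <- tempfile(fileext = ".csv")
  writeLines(c("id,genotype_label,dose_ngml,t,value", "x,WT,1,30,2.5"), alt)
  tab2 <- read_response_table(alt, response_schema("id", "genotype_label",
                                                   "dose_ngml", "t", "value"))
  expect_equal(tab2$response, 2.5)
})

test_that("schema and parse errors are reported with context", {
  path <- write_long_csv("c1,WT,0.2,30,5.5")
  expect_error(read_response_table(path, response_schema(dose = "absent")),
               class = "cellnp_schema_error")
  bad <- write_long_csv(c("c1,WT,0.2,30,5.5", "c2,WT,0.2,30,oops"))
  expect_error(read_response_table(bad), "row\\(s\\) 2", class = "cellnp_parse_error")
  neg <- write_long_csv(c("c1,WT,0.2,30,5.5", "c2,WT,0.2,30,-1"))
  expect_error(read_response_table(neg, strict = TRUE), "2",
               class = "cellnp_parse_error")
  expect_silent(tab <- read_response_table(neg))  # lenient keeps the row
  expect_equal(nrow(tab), 2L)
})

test_that("write-then-read round trips both layouts exactly", {
  path <- write_long_csv(c("c1,WT,0.0052,30,5.512986",
                           "c2,KO,50,240,0.1234567890123456"))
  tab <- read_response_table(path)
  out <- tempfile(fileext = ".csv")
  write_response_table(tab, out)
  back <- read_response_table(out)
  expect_identical(as.data.frame(back), as.data.frame(tab))

  wide <- wide_table_from(matrix(c(exp(1), pi, 2.5, 1 / 3), 2, 2))
  out2 <- tempfile(fileext = ".csv")
  write_response_table(wide, out2)
  back2 <- read_response_table(out2, layout = "wide")
  expect_equal(as.data.frame(back2), as.data.frame(wide), tolerance = 0)
  expect_equal(attr(back2, "times"), c(30, 240))
})

test_that("log_transform computes natural logs and applies the nonpositive policy", {
  path <- write_long_csv(c("c1,WT,0.2,30,1.0",
                           sprintf("c2,WT,0.2,30,%.10f", exp(2)),
                           "c3,WT,0.2,30,0"))
  tab <- read_response_table(path)
  expect_warning(lt <- log_transform(tab), "1 cell")
  expect_equal(nrow(lt), 2L)
  expect_equal(lt$response, c(0, 2), tolerance = 1e-9)
  expect_true(attr(lt, "log_scale"))
  expect_error(log_transform(tab, nonpositive = "error"), "c3",
               class = "cellnp_domain_error")
  expect_error(log_transform(log_transform(tab[1:2, ])),
               class = "cellnp_domain_error")
})

test_that("select_condition returns the matching observation matrix", {
  resp <- matrix(exp(seq(0.1, 1, length.out = 10)), 5, 2)
  lt <- log_transform(wide_table_from(resp))
  full <- select_condition(lt, condition_key("WT", 0.2, c(30, 240)))
  expect_equal(dim(full), c(5L, 2L))
  one <- select_condition(lt, condition_key("WT", 0.2, 30))
  expect_equal(dim(one), c(5L, 1L))
  expect_equal(one[, 1], full[, 1])
  expect_error(select_condition(lt, condition_key("WT", 99, 30)),
               class = "cellnp_selection_error")
  # pairing: N > 1 impossible on long layout
  longp <- write_long_csv(c("c1,WT,0.2,30,5", "c1,WT,0.2,240,6"))
  longt <- log_transform(read_response_table(longp))
  expect_error(select_condition(longt, condition_key("WT", 0.2, c(30, 240))),
               class = "cellnp_pairing_error")
  # raw-scale tables are refused
  expect_error(select_condition(wide_table_from(resp),
                                condition_key("WT", 0.2, 30)),
               class = "cellnp_domain_error")
})

test_that("fit_gaussian matches hand-computed moments and guards degeneracy", {
  f1 <- fit_gaussian(c(0, 2, 1))
  expect_equal(f1$mean, 1)
  expect_equal(f1$cov[1, 1], var(c(0, 2, 1)))
  f1b <- fit_gaussian(c(0, 2, 0, 2))
  expect_equal(f1b$mean, 1)
  expect_equal(f1b$cov[1, 1], 4 / 3)  # unbiased divisor n - 1 = 3

  obs <- rbind(c(0, 0), c(2, 2), c(0, 2), c(2, 0))
  f2 <- fit_gaussian(obs)
  expect_equal(f2$mean, c(0, 0) + 1)
  expect_equal(f2$cov, matrix(c(4 / 3, 0, 0, 4 / 3), 2))
  expect_equal(f2$estimator, "unbiased")

  expect_error(fit_gaussian(matrix(1:4, 2, 2)), class = "cellnp_insufficient_data")
  dup <- cbind(rnorm(10), 0)
  dup[, 2] <- dup[, 1]  # duplicated column -> singular covariance
  expect_error(fit_gaussian(dup), class = "cellnp_degenerate_covariance")
})

test_that("large-sample fit recovers generator parameters", {
  set.seed(11)
  model <- gaussian_condition(4.0, 0.25)
  draws <- sample_condition(model, 50000L, seed = 7L)
  fit <- fit_gaussian(draws)
  expect_lt(abs(fit$mean - 4.0), 0.01)  # 4 * 0.5/sqrt(5e4) ~ 0.009
  expect_lt(abs(sqrt(fit$cov[1, 1]) - 0.5), 0.01)
})

test_that("gaussian_condition JSON serialization round trips", {
  m <- gaussian_condition(c(1.5, -0.25), matrix(c(2, 0.3, 0.3, 1), 2), n = 123L)
  path <- tempfile(fileext = ".json")
  write_gaussian_json(m, path)
  back <- read_gaussian_json(path)
  expect_equal(back$mean, m$mean)
  expect_equal(back$cov, m$cov)
  expect_equal(back$n, 123L)
})

test_that("dynamic_range_summary agrees with fit_gaussian and orders by dose", {
  cfg <- small_scenario(n = 200L)
  lt <- log_transform(generate_dataset(cfg))
  drs <- dynamic_range_summary(lt)
  expect_equal(nrow(drs), 2L * length(cfg$doses) * length(cfg$times))
  row <- drs[drs$cell_type == "WT" & drs$dose == 0.2 & drs$time == 30, ]
  fit <- fit_gaussian(select_condition(lt, condition_key("WT", 0.2, 30)))
  expect_equal(row$mean, fit$mean)
  expect_equal(row$sd, sqrt(fit$cov[1, 1]))
  # generator dose response is strictly monotone in truth; fitted means track
  # it up to sampling noise (4 SE of a difference of two condition means)
  for (ct in c("WT", "KO")) for (t in cfg$times) {
    truth <- vapply(sort(cfg$doses), function(d) {
      condition_truth(cfg, ct, d, t)$mean
    }, numeric(1))
    expect_true(all(diff(truth) > 0))
    sub <- drs[drs$cell_type == ct & drs$time == t, ]
    sub <- sub[order(sub$dose), ]
    slack <- 4 * sqrt(2) * max(sub$sd) / sqrt(min(sub$n))
    expect_true(all(diff(sub$mean) > -slack))
  }
  # empty selection yields empty summary
  empty <- lt[0, ]
  expect_equal(nrow(dynamic_range_summary(empty)), 0L)
})
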