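test_that("canonicalize reproduces the univariate standardization", {
  pair <- canonicalize(gaussian_condition(2, 1), gaussian_condition(3, 4))
  expect_equal(pair$m, 1)
  expect_equal(pair$lam, 4)

  # identical hypotheses: fully degenerate
  h <- gaussian_condition(c(1, 2), matrix(c(2, 0.5, 0.5, 1), 2))
  same <- canonicalize(h, h)
  expect_equal(same$m, c(0, 0), tolerance = 1e-10)
  expect_equal(same$lam, c(1, 1), tolerance = 1e-10)
  expect_true(all(same$degenerate))

  # equal identity covariances: whitening is the identity up to rotation
  pr <- canonicalize(gaussian_condition(c(0, 0), diag(2)),
                     gaussian_condition(c(1, 0), diag(2)))
  expect_equal(pr$lam, c(1, 1))
  expect_equal(sqrt(sum(pr$m^2)), 1)

  expect_error(canonicalize(gaussian_condition(0, 1), h),
               class = "cellnp_dim_mismatch")
})

test_that("canonical transform maps H0 to N(0, I) and H1 to N(m, diag(lam))", {
  set.seed(31)
  for (N in c(2L, 3L)) {
    mods <- random_pair_models(N)
    pair <- canonicalize(mods$h0, mods$h1)
    A <- pair$transform$A
    expect_equal(A %*% mods$h0$cov %*% t(A), diag(N), tolerance = 1e-8)
    T1 <- A %*% mods$h1$cov %*% t(A)
    expect_equal(T1, diag(pair$lam, N), tolerance = 1e-8)
    expect_equal(drop(A %*% (mods$h1$mean - mods$h0$mean)), pair$m,
                 tolerance = 1e-10)
  }
})

test_that("test_statistic evaluates the quadratic form", {
  expect_equal(test_statistic(0, canonical_pair_from(1, 4)), -0.25)
  pair11 <- canonical_pair_from(c(1, 1), c(1, 1))
  expect_equal(test_statistic(c(1, 1), pair11), 2)  # x = m, lam = 1 -> sum m^2
  expect_equal(test_statistic(c(1, -1), pair11), (1 - 0) + (1 - 4))
  expect_error(test_statistic(c(1, 2, 3), pair11), class = "cellnp_dim_mismatch")
  # degenerate coordinates contribute exactly zero
  deg <- canonical_pair_from(c(1, 0), c(4, 1))
  expect_equal(test_statistic(c(0.3, 123), deg),
               test_statistic(0.3, canonical_pair_from(1, 4)))
})

test_that("char_fn matches closed forms and satisfies CF identities", {
  # m = 0, lam = 4, H0: CF of (3/4) chi2_1
  pair <- canonical_pair_from(0, 4)
  w <- c(0.1, 0.7, 2.3)
  expect_equal(char_fn(w, pair, "H0"), (1 - 1.5i * w)^(-1 / 2), tolerance = 1e-12)
  # lam = 1, m = 1: Z Gaussian N(-1, 4) under H0
  pg <- canonical_pair_from(1, 1)
  expect_equal(char_fn(0.5, pg, "H0"), exp(-0.5) * complex(real = cos(0.5),
                                                           imaginary = -sin(0.5)),
               tolerance = 1e-12)
  set.seed(5)
  for (rep in 1:5) {
    N <- sample(1:3, 1)
    pr <- canonical_pair_from(rnorm(N), exp(rnorm(N, sd = 0.7)))
    for (hyp in c("H0", "H1")) {
      ws <- seq(-3, 3, by = 0.5)
      phi <- char_fn(ws, pr, hyp)
      expect_equal(char_fn(0, pr, hyp), 1 + 0i)
      expect_true(all(Mod(phi) <= 1 + 1e-12))
      expect_equal(char_fn(-ws, pr, hyp), Conj(phi), tolerance = 1e-12)
    }
  }
})

test_that("Gil-Pelaez inversion matches the Gaussian closed form when all lam = 1", {
  pair <- canonical_pair_from(1, 1)
  expect_equal(cdf_test_statistic(0, pair, "H0"), pnorm(0.5), tolerance = 1e-6)
  expect_equal(cdf_test_statistic(-1, pair, "H0"), 0.5, tolerance = 1e-6)
  zs <- seq(-7, 5, length.out = 25)
  expect_equal(cdf_test_statistic(zs, pair, "H0"), pnorm(zs, -1, 2),
               tolerance = 1e-6)
  expect_equal(cdf_test_statistic(zs, pair, "H1"), pnorm(zs, 1, 2),
               tolerance = 1e-6)
  p2 <- canonical_pair_from(c(0.8, -0.6), c(1, 1))
  mu <- c(-1, 1) * sum(c(0.8, -0.6)^2)
  sd2 <- 2 * sqrt(sum(c(0.8, -0.6)^2))
  expect_equal(cdf_test_statistic(zs, p2, "H0"), pnorm(zs, mu[1], sd2),
               tolerance = 1e-6)
  expect_equal(cdf_test_statistic(zs, p2, "H1"), pnorm(zs, mu[2], sd2),
               tolerance = 1e-6)
})

test_that("Gil-Pelaez inversion matches the scaled-chi-square closed form when m = 0", {
  for (lam in c(4, 0.25, 2.2)) {
    pair <- canonical_pair_from(0, lam)
    a0 <- (lam - 1) / lam
    zq <- a0 * qchisq(seq(0.025, 0.975, length.out = 20), df = 1)
    ref <- if (a0 > 0) pchisq(zq / a0, 1) else 1 - pchisq(zq / a0, 1)
    expect_equal(cdf_test_statistic(zq, pair, "H0"), ref, tolerance = 1e-6)
    a1 <- lam - 1
    zq1 <- a1 * qchisq(seq(0.025, 0.975, length.out = 20), df = 1)
    ref1 <- if (a1 > 0) pchisq(zq1 / a1, 1) else 1 - pchisq(zq1 / a1, 1)
    expect_equal(cdf_test_statistic(zq1, pair, "H1"), ref1, tolerance = 1e-6)
  }
  # chi-square median check from the support boundary
  pair4 <- canonical_pair_from(0, 4)
  expect_equal(cdf_test_statistic(0, pair4, "H0"), 0, tolerance = 1e-6)
  expect_equal(cdf_test_statistic(0.75 * qchisq(0.5, 1), pair4, "H0"), 0.5,
               tolerance = 1e-6)
})

test_that("inversion matches the noncentral chi-square closed form (m != 0, lam != 1)", {
  for (cse in list(c(1.3, 2.5), c(0.8, 0.4), c(-0.9, 5))) {
    m <- cse[1]; lam <- cse[2]
    pair <- canonical_pair_from(m, lam)
    a <- (lam - 1) / lam; b <- 2 * m / lam
    d2 <- (b / (2 * a))^2; shift <- -m^2 / lam - a * d2
    zq <- a * qchisq(seq(0.01, 0.99, length.out = 15), 1, ncp = d2) + shift
    ref <- if (a > 0) pchisq((zq - shift) / a, 1, ncp = d2)
           else 1 - pchisq((zq - shift) / a, 1, ncp = d2)
    expect_equal(cdf_test_statistic(zq, pair, "H0"), ref, tolerance = 1e-6)
  }
})

test_that("cdf_test_statistic is monotone and errors on degenerate pairs", {
  pair <- canonical_pair_from(c(0.5, -0.3), c(2, 0.7))
  zs <- seq(-8, 8, length.out = 41)
  for (hyp in c("H0", "H1")) {
    F <- cdf_test_statistic(zs, pair, hyp)
    expect_true(all(diff(F) >= -1e-9))
    expect_true(all(F >= 0 & F <= 1))
  }
  h <- gaussian_condition(1, 2)
  expect_error(cdf_test_statistic(0, canonicalize(h, h), "H0"),
               class = "cellnp_degenerate_statistic")
})

test_that("solve_threshold and detection_probability reproduce Gaussian closed forms", {
  pair <- canonical_pair_from(1, 1)
  z01 <- solve_threshold(pair, 0.1)
  expect_equal(z01, 2 * qnorm(0.9) - 1, tolerance = 1e-5)
  expect_equal(solve_threshold(pair, 0.5), -1, tolerance = 1e-5)
  expect_gt(solve_threshold(pair, 0.001), solve_threshold(pair, 0.999))
  expect_equal(detection_probability(pair, z01), 1 - pnorm(qnorm(0.9) - 1),
               tolerance = 1e-5)
  expect_equal(detection_probability(pair, -1e3), 1, tolerance = 1e-6)
  expect_error(solve_threshold(pair, 1.2), class = "cellnp_domain_error")

  p2 <- canonical_pair_from(c(1, 1), c(1, 1))
  op2 <- operating_point(gaussian_condition(c(0, 0), diag(2)),
                         gaussian_condition(c(1, 1), diag(2)), 0.1)
  expect_equal(op2$pd, 1 - pnorm(qnorm(0.9) - sqrt(2)), tolerance = 1e-5)
  expect_equal(op2$pfa, 0.1, tolerance = 1e-5)
  expect_equal(op2$pm, 1 - op2$pd)
})

test_that("operating_point composes the pipeline and rejects identical hypotheses", {
  op <- operating_point(gaussian_condition(0, 1), gaussian_condition(1, 1), 0.1)
  expect_equal(op$pd, gaussian_pd(0.1, 1), tolerance = 1e-5)
  h <- gaussian_condition(c(0, 1), diag(2))
  expect_error(operating_point(h, h, 0.1), class = "cellnp_degenerate_statistic")
})

test_that("roc_curve passes LRT sanity: above diagonal, monotone, correct endpoints", {
  set.seed(91)
  grid <- seq(0.02, 0.98, by = 0.04)
  mods <- random_pair_models(2L)
  roc <- roc_curve(mods$h0, mods$h1, grid)
  expect_true(all(roc$pd >= roc$pfa - 1e-4))
  expect_true(all(diff(roc$pd) >= -1e-6))
  # concavity on the grid (LRT ROCs are concave)
  sec <- diff(roc$pd) / diff(roc$pfa)
  expect_true(all(diff(sec) <= 1e-3))
  # closed-form spot check
  roc1 <- roc_curve(gaussian_condition(0, 1), gaussian_condition(1, 1),
                    c(0.1, 0.5))
  expect_equal(roc1$pd, c(gaussian_pd(0.1, 1), pnorm(1)), tolerance = 1e-5)
  expect_error(roc_curve(mods$h0, mods$h1, c(0.5, 0.2)),
               class = "cellnp_domain_error")
})

test_that("pfa_at_pd inverts the ROC", {
  h0 <- gaussian_condition(0, 1); h1 <- gaussian_condition(1, 1)
  a <- pfa_at_pd(h0, h1, pnorm(1))
  expect_equal(as.numeric(a), 0.5, tolerance = 1e-4)
  a2 <- pfa_at_pd(h0, h1, gaussian_pd(0.1, 1))
  expect_equal(as.numeric(a2), 0.1, tolerance = 1e-4)
  # huge separation: tiny pfa suffices
  a3 <- pfa_at_pd(gaussian_condition(0, 1), gaussian_condition(12, 1), 0.9)
  expect_lt(as.numeric(a3), 1e-6)
})

test_that("decision_region_1d exposes the quadratic rejection geometry", {
  ray <- decision_region_1d(canonical_pair_from(1, 1), -1)
  expect_equal(nrow(ray), 1L)
  expect_equal(unname(ray[1, "lower"]), 0, tolerance = 1e-12)
  expect_equal(unname(ray[1, "upper"]), Inf)

  two <- decision_region_1d(canonical_pair_from(0, 4), 0)
  expect_equal(nrow(two), 2L)
  expect_equal(unname(two[1, "upper"]), 0, tolerance = 1e-9)
  expect_equal(unname(two[2, "lower"]), 0, tolerance = 1e-9)

  none <- decision_region_1d(canonical_pair_from(0, 0.25), 0)
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "pfa"), 0)

  # region measure under H0 equals P_FA from the CDF route
  pair <- canonical_pair_from(0.7, 3)
  z <- solve_threshold(pair, 0.2)
  reg <- decision_region_1d(pair, z)
  expect_equal(attr(reg, "pfa"), 0.2, tolerance = 1e-4)
  expect_error(decision_region_1d(canonical_pair_from(c(1, 1), c(1, 1)), 0),
               class = "cellnp_dim_mismatch")
})

test_that("operating points are invariant to affine reparameterization", {
  set.seed(17)
  mods <- random_pair_models(2L)
  base <- operating_point(mods$h0, mods$h1, 0.1)
  for (rep in 1:4) {
    A <- matrix(rnorm(4), 2); while (abs(det(A)) < 0.1) A <- matrix(rnorm(4), 2)
    b <- rnorm(2)
    t0 <- gaussian_condition(drop(A %*% mods$h0$mean) + b, A %*% mods$h0$cov %*% t(A))
    t1 <- gaussian_condition(drop(A %*% mods$h1$mean) + b, A %*% mods$h1$cov %*% t(A))
    op <- operating_point(t0, t1, 0.1)
    expect_equal(op$pfa, base$pfa, tolerance = 1e-6)
    expect_equal(op$pd, base$pd, tolerance = 1e-6)
  }
})

test_that("appending a degenerate coordinate changes no probability", {
  set.seed(23)
  mods <- random_pair_models(2L)
  base <- operating_point(mods$h0, mods$h1, 0.1)
  pad <- function(m) {
    gaussian_condition(c(m$mean, 0.7), rbind(cbind(m$cov, 0), c(0, 0, 1.3)))
  }
  # same third coordinate under both hypotheses -> lam = 1, m = 0 there
  op <- operating_point(pad(mods$h0), pad(mods$h1), 0.1)
  expect_equal(op$pfa, base$pfa, tolerance = 1e-6)
  expect_equal(op$pd, base$pd, tolerance = 1e-6)
})

test_that("bivariate ROC dominates each marginal ROC (NP optimality on full data)", {
  set.seed(57)
  mods <- random_pair_models(2L)
  grid <- seq(0.05, 0.95, by = 0.09)
  roc2 <- roc_curve(mods$h0, mods$h1, grid)
  for (d in 1:2) {
    m0 <- gaussian_condition(mods$h0$mean[d], mods$h0$cov[d, d])
    m1 <- gaussian_condition(mods$h1$mean[d], mods$h1$cov[d, d])
    roc1 <- roc_curve(m0, m1, grid)
    expect_true(all(roc2$pd >= roc1$pd - 1e-4))
  }
})
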