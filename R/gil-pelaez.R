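# Gil-Pelaez inversion of the test-statistic characteristic function.
#
# Under either hypothesis the statistic decomposes over canonical
# coordinates into independent quadratics in a standard normal W:
#   Z_i = a_i W^2 + b_i W + kappa_i
# with (H0) a = (lam-1)/lam, b = 2m/lam,       kappa = -m^2/lam
#      (H1) a =  lam-1,      b = 2m sqrt(lam), kappa =  m^2.
# Writing the CF modulus/phase directly in terms of (a, b^2) avoids the
# catastrophic cancellation of the usual noncentral-chi-square form
# (delta^2 = b^2/(4a^2) blows up as a -> 0):
#   psi(u)  = sum_i [ atan(2 a_i u)/2 - a_i b_i^2 u^3 / (1 + 4 a_i^2 u^2) ]
#             + (sum_i kappa_i - z) u
#   lnrho(u)= sum_i [ log(1 + 4 a_i^2 u^2)/4 + b_i^2 u^2 / (2 (1 + 4 a_i^2 u^2)) ]
# and the Gil-Pelaez integrand is g(u) = sin(psi) exp(-lnrho)/u with the
# analytic limit g(0+) = E[Z] - z.  F(z) = 1/2 - (1/pi) Int_0^inf g(u) du.
#
# The integral is computed by chunked adaptive quadrature with phase-based
# chunking; when the envelope decays only polynomially (no coordinate with a
# dominating Gaussian term) the oscillatory tail is summed over exact
# half-wave cells with Euler (iterated-averaging) acceleration, or, when the
# asymptotic phase slope vanishes, by a 1/u substitution of the monotone tail.

z_components <- function(pair, hypothesis) {
  keep <- !pair$degenerate
  lam <- pair$lam[keep]
  m <- pair$m[keep]
  if (hypothesis == "H0") {
    a <- (lam - 1) / lam
    b <- 2 * m / lam
    kap <- -m^2 / lam
  } else {
    a <- lam - 1
    b <- 2 * m * sqrt(lam)
    kap <- m^2
  }
  b2 <- b^2
  ksum <- sum(kap)
  # drop coordinates whose random contribution is negligible relative to the
  # statistic's overall scale (their kappa shift is kept in ksum)
  sd_i <- sqrt(2 * a^2 + b2)
  scale <- if (length(sd_i)) max(sd_i) else 0
  live <- if (is.finite(scale) && scale > 0) sd_i > 1e-7 * scale else rep(FALSE, length(a))
  a <- a[live]; b2 <- b2[live]
  list(
    a = a, b2 = b2, ksum = ksum,
    EZ = sum(a) + ksum,
    VZ = sum(2 * a^2 + b2),
    n_comp = length(a)
  )
}

gp_eval_phase <- function(u, comp, z) {
  psi <- (comp$ksum - z) * u
  lrho <- numeric(length(u))
  for (i in seq_along(comp$a)) {
    a <- comp$a[i]; b2 <- comp$b2[i]
    au2 <- 4 * a^2 * u^2
    q <- 1 + au2
    psi <- psi + 0.5 * atan(2 * a * u) - a * b2 * u^3 / q
    lrho <- lrho + 0.25 * log1p(au2) + b2 * u^2 / (2 * q)
  }
  list(psi = psi, lrho = lrho)
}

gp_integrand <- function(u, comp, z) {
  out <- numeric(length(u))
  pos <- u > 0
  if (any(pos)) {
    ev <- gp_eval_phase(u[pos], comp, z)
    out[pos] <- sin(ev$psi) * exp(-ev$lrho) / u[pos]
  }
  out[!pos] <- comp$EZ - z
  out
}

# chunk boundaries over [lo, hi] such that the phase advances by at most
# ~2.5 rad per chunk and no chunk hides an aliased oscillation
gp_breaks <- function(comp, z, lo, hi, max_rounds = 14L, max_chunks = 6000L) {
  knots <- unlist(lapply(comp$a[comp$a != 0], function(a) 1 / (2 * abs(a)) * c(0.25, 1, 4)))
  seed <- sort(unique(c(
    seq(lo, hi, length.out = 33L),
    if (hi / max(lo, hi * 1e-9) > 50) exp(seq(log(max(lo, hi * 1e-7)), log(hi), length.out = 33L)),
    knots[knots > lo & knots < hi]
  )))
  br <- unique(pmin(pmax(seed, lo), hi))
  psi_of <- function(u) gp_eval_phase(u, comp, z)$psi
  for (round in seq_len(max_rounds)) {
    p <- psi_of(br)
    mid <- (br[-1] + br[-length(br)]) / 2
    pm <- psi_of(mid)
    dphi <- abs(p[-1] - p[-length(p)])
    curve <- abs(pm - (p[-1] + p[-length(p)]) / 2)
    split <- which(dphi > 2.5 | curve > 0.5)
    if (!length(split) || length(br) > max_chunks) break
    br <- sort(unique(c(br, mid[split])))
  }
  br
}

gp_quad_chunks <- function(comp, z, breaks) {
  f <- function(u) gp_integrand(u, comp, z)
  total <- 0
  for (i in seq_len(length(breaks) - 1L)) {
    r <- stats::integrate(f, breaks[i], breaks[i + 1L],
                          rel.tol = 1e-10, abs.tol = 1e-13,
                          subdivisions = 400L, stop.on.error = FALSE)
    total <- total + r$value
  }
  total
}

# adaptive integral of one (possibly very wide) cell; log-substitution keeps
# the quadrature well-conditioned when the cell spans decades in u
gp_cell_integral <- function(comp, z, lo, hi) {
  if (hi / lo > 10) {
    f <- function(v) {
      u <- exp(v)
      gp_integrand(u, comp, z) * u
    }
    r <- stats::integrate(f, log(lo), log(hi), rel.tol = 1e-10, abs.tol = 1e-14,
                          subdivisions = 600L, stop.on.error = FALSE)
  } else {
    r <- stats::integrate(function(u) gp_integrand(u, comp, z), lo, hi,
                          rel.tol = 1e-10, abs.tol = 1e-14,
                          subdivisions = 400L, stop.on.error = FALSE)
  }
  r$value
}

# Euler transformation via iterated averaging of the tail partial sums
euler_accelerate <- function(terms) {
  S <- cumsum(terms)
  v <- utils::tail(S, 48L)
  while (length(v) > 1L) v <- (v[-1L] + v[-length(v)]) / 2
  v
}

gp_integral <- function(comp, z) {
  s_inf <- comp$ksum - z -
    sum(ifelse(comp$a != 0, comp$b2 / (4 * comp$a), 0))
  gaussish <- comp$b2 >= 1440 * comp$a^2 & comp$b2 > 0
  if (any(gaussish)) {
    # some coordinate's Gaussian term dominates: envelope <= exp(-b2 u^2/4)
    # well before the chi-square flattening kicks in; truncation error < 1e-15
    U <- sqrt(90 / max(comp$b2[gaussish]))
    return(gp_quad_chunks(comp, z, gp_breaks(comp, z, 0, U)))
  }
  # polynomial envelope: burn-in + oscillatory tail
  amin <- min(abs(comp$a))
  Rc <- sum(1 / (4 * abs(comp$a)) + comp$b2 / (16 * abs(comp$a)^3))
  if (abs(s_inf) > 1e-15) {
    U_A <- max(5 / amin, sqrt(2 * Rc / abs(s_inf)))
  } else {
    U_A <- 50 / amin
  }
  I_A <- gp_quad_chunks(comp, z, gp_breaks(comp, z, 0, U_A))
  if (abs(s_inf) <= 1e-15) {
    # no asymptotic oscillation: map the monotone tail to (0, 1]
    f <- function(t) {
      u <- U_A / t
      gp_integrand(u, comp, z) * U_A / t^2
    }
    r <- stats::integrate(f, 0, 1, rel.tol = 1e-9, abs.tol = 1e-12,
                          subdivisions = 600L, stop.on.error = FALSE)
    return(I_A + r$value)
  }
  # half-wave cells at psi = k*pi beyond U_A (psi' has the sign of s_inf there)
  psi_of <- function(u) gp_eval_phase(u, comp, z)$psi
  dir <- sign(s_inf)
  psiA <- psi_of(U_A)
  target <- if (dir > 0) (floor(psiA / pi) + 1) * pi else (ceiling(psiA / pi) - 1) * pi
  u_cur <- U_A
  period <- pi / abs(s_inf)
  terms <- numeric(0)
  kmax <- 100L
  for (k in seq_len(kmax)) {
    step <- 2.2 * period
    u_hi <- u_cur + step
    tries <- 0L
    while (sign(psi_of(u_hi) - target) == sign(psiA - target) && tries < 30L) {
      u_hi <- u_cur + (u_hi - u_cur) * 2
      tries <- tries + 1L
    }
    root <- tryCatch(
      stats::uniroot(function(u) psi_of(u) - target, c(u_cur, u_hi),
                     tol = 1e-10 * max(1, u_cur))$root,
      error = function(e) NA_real_)
    if (!is.finite(root)) break
    terms[k] <- gp_cell_integral(comp, z, u_cur, root)
    u_cur <- root
    psiA <- target
    target <- target + dir * pi
    if (abs(terms[k]) < 1e-14 && k > 4L) break
  }
  I_A + if (length(terms)) euler_accelerate(terms) else 0
}

#' CDF of the test statistic by Gil-Pelaez inversion
#'
#' Numerically inverts the closed-form characteristic function of the
#' quadratic test statistic to obtain `F_Z(z; H)`:
#' \deqn{F_Z(z) = \frac12 - \frac1\pi \int_0^\infty
#'   \frac{\mathrm{Im}[e^{-j\omega z}\varphi_Z(\omega)]}{\omega}\, d\omega.}
#' The integrand's finite limit at `omega -> 0` (`E[Z;H] - z`) is used
#' analytically; the oscillatory tail is handled as described in the
#' package vignette.  Contracted absolute error is 1e-4; in practice the
#' inversion agrees with available closed forms to ~1e-8.
#'
#' @param z numeric vector of evaluation points.
#' @param pair a `canonical_pair` with at least one non-degenerate
#'   coordinate.
#' @param hypothesis `"H0"` or `"H1"`.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @examples
#' pair <- canonical_pair_from(m = 1, lam = 1)
#' cdf_test_statistic(0, pair, "H0")   # Phi(0.5), since Z ~ N(-1, 4) under H0
#' @export
cdf_test_statistic <- function(z, pair, hypothesis = c("H0", "H1")) {
  stopifnot(inherits(pair, "canonical_pair"))
  hypothesis <- match.arg(hypothesis)
  if (all(pair$degenerate)) {
    stop_cellnp("cellnp_degenerate_statistic",
                "all coordinates are degenerate: Z == 0 and no test exists")
  }
  comp <- z_components(pair, hypothesis)
  if (comp$n_comp == 0L) {
    stop_cellnp("cellnp_degenerate_statistic",
                "test statistic is numerically degenerate for this pair")
  }
  vapply(as.numeric(z), function(zi) {
    val <- 0.5 - gp_integral(comp, zi) / pi
    min(max(val, 0), 1)
  }, numeric(1))
}

# moments of Z used for bracketing; exported for reuse in oracles/tests
#' Mean and variance of the test statistic
#'
#' `E[Z; H0] = sum(1 - (1 + m^2)/lam)`, `E[Z; H1] = sum(lam + m^2 - 1)`,
#' with matching closed-form variances; used to bracket threshold searches.
#'
#' @inheritParams cdf_test_statistic
#' @return list with elements `mean` and `var`.
#' @export
test_statistic_moments <- function(pair, hypothesis = c("H0", "H1")) {
  stopifnot(inherits(pair, "canonical_pair"))
  hypothesis <- match.arg(hypothesis)
  comp <- z_components(pair, hypothesis)
  list(mean = comp$EZ, var = comp$VZ)
}
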