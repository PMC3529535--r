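test_that("pdf evaluates the Stacy density and respects the support", {
  expect_equal(gg_pdf(1, gg_params(1, 1, 1)), exp(-1))
  # symbolic evaluation of p x^{p nu - 1}/(a^{p nu} Gamma(nu)) e^{-(x/a)^p}
  expect_equal(gg_pdf(0.5, gg_params(1, 1, 2)), 2 * 0.5 * exp(-0.25))
  expect_identical(gg_pdf(c(-1, 0), gg_params(2, 3, 0.7)), c(0, 0))
  expect_error(gg_params(-1, 1, 1), "invalid")
  expect_error(gg_params(1, 0, 1), "invalid")
})

test_that("pdf integrates to one across a shape grid", {
  for (nu in c(0.3, 1, 2, 5)) for (p in c(0.3, 1, 2, 5)) {
    pr <- gg_params(1.3, nu, p)
    expect_equal(quad_gg(function(t) gg_pdf(t, pr), pr), 1,
                 tolerance = 1e-8)
  }
})

test_that("cdf matches quadrature of the pdf and has CDF shape", {
  expect_equal(gg_cdf(1, gg_params(1, 1, 3)), 1 - exp(-1))
  expect_identical(gg_cdf(c(-2, 0), gg_params(1, 1, 1)), c(0, 0))
  pr <- gg_params(1, 2, 1)
  expect_equal(gg_cdf(2, pr),
               quad_gg(function(t) gg_pdf(t, pr), pr, hi = 2),
               tolerance = 1e-9)
  x <- seq(0.01, 20, length.out = 200)
  expect_true(all(diff(gg_cdf(x, gg_params(0.8, 0.5, 2))) >= 0))
  expect_equal(gg_cdf(1e8, gg_params(1, 2, 1)), 1)
})

test_that("sampling is reproducible and matches the moment formula", {
  expect_identical(gg_sample(100, gg_params(1, 2, 1.5), seed = 5),
                   gg_sample(100, gg_params(1, 2, 1.5), seed = 5))
  pr <- gg_params(2, 1.5, 0.8)
  x <- gg_sample(1e5, pr, seed = 7)
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - gg_raw_moment(1, pr)), 3 * se)
  x1 <- gg_sample(1e5, gg_params(1, 1, 1), seed = 3)
  expect_lt(abs(mean(x1) - 1), 3 * stats::sd(x1) / sqrt(1e5))
})

test_that("raw moments agree with quadrature and respect existence", {
  expect_equal(gg_raw_moment(1, gg_params(1, 1, 1)), 1)
  expect_equal(gg_raw_moment(2, gg_params(1, 1, 2)), 1)
  pr <- gg_params(2, 1.5, 0.8)
  expect_equal(gg_raw_moment(3, pr),
               quad_gg(function(t) t^3 * gg_pdf(t, pr), pr),
               tolerance = 1e-7)
  expect_error(gg_raw_moment(-2, gg_params(1, 1, 1)), "does not exist")
})

test_that("Lawless conversion is exact and matches the defining map", {
  lw <- to_lawless(gg_params(1, 1, 1))
  expect_equal(c(lw$mu, lw$sigma, lw$k), c(0, 1, 1))
  lw2 <- to_lawless(gg_params(1, 4, 0.5))
  expect_equal(lw2$mu, 2 * log(4))
  expect_equal(lw2$sigma, 1)
  expect_equal(lw2$k, 4)
  pr <- gg_params(2, 0.7, 3.1)
  rt <- from_lawless(to_lawless(pr))
  expect_equal(c(rt$a, rt$nu, rt$p), c(2, 0.7, 3.1), tolerance = 1e-12)
})

test_that("special-case families reproduce their native densities", {
  x <- seq(0.05, 6, length.out = 80)
  expect_equal(gg_pdf(x, special_case_to_gg("exponential", rate = 1)),
               stats::dexp(x), tolerance = 1e-12)
  expect_equal(gg_pdf(x, special_case_to_gg("weibull", scale = 1.3,
                                            shape = 2.2)),
               stats::dweibull(x, shape = 2.2, scale = 1.3),
               tolerance = 1e-12)
  expect_equal(gg_pdf(x, special_case_to_gg("gamma", shape = 2.5,
                                            scale = 0.7)),
               stats::dgamma(x, shape = 2.5, scale = 0.7),
               tolerance = 1e-12)
  # Rayleigh(sigma): r/sigma^2 exp(-r^2 / 2 sigma^2)
  ray <- function(r, s) r / s^2 * exp(-r^2 / (2 * s^2))
  expect_equal(gg_pdf(x, special_case_to_gg("rayleigh", sigma = 1)),
               ray(x, 1), tolerance = 1e-12)
  expect_equal(gg_pdf(1, special_case_to_gg("rayleigh", sigma = 1)),
               exp(-0.5))
  # Nakagami with m = 1 collapses onto the Rayleigh with sigma^2 = Omega
  expect_equal(gg_pdf(x, special_case_to_gg("nakagami", m = 1, omega = 1.7)),
               gg_pdf(x, special_case_to_gg("rayleigh", sigma = sqrt(1.7))),
               tolerance = 1e-12)
  # generic Nakagami against its closed form (E{R^2} = 2 Omega convention)
  nak <- function(r, m, om)
    2 * m^m * r^(2 * m - 1) / (gamma(m) * (2 * om)^m) *
      exp(-(m / (2 * om)) * r^2)
  expect_equal(gg_pdf(x, special_case_to_gg("nakagami", m = 2.5,
                                            omega = 1.2)),
               nak(x, 2.5, 1.2), tolerance = 1e-12)
})

test_that("scaling closure: kX ~ GG(ka, nu, p)", {
  pr <- gg_params(1, 2, 1.5)
  x <- 3.7 * gg_sample(1e4, pr, seed = 11)
  ks <- ks_statistic(x, gg_params(3.7, 2, 1.5))
  # 1% KS critical value for n = 1e4
  expect_lt(ks, 1.63 / sqrt(1e4))
})

test_that("power closure: X^p is Gamma distributed", {
  pr <- gg_params(1.4, 2, 1.5)
  x <- gg_sample(1e4, pr, seed = 12)
  y <- x^pr$p
  ks <- suppressWarnings(stats::ks.test(y, "pgamma", shape = pr$nu,
                                        scale = pr$a^pr$p))
  expect_gt(ks$p.value, 0.01)
})

test_that("log transform of GG(1, nu, 1) has the log-Gamma density", {
  nu <- 2.3
  z <- seq(-4, 3, length.out = 60)
  f_direct <- exp(nu * z - exp(z)) / gamma(nu)
  f_jacobian <- gg_pdf(exp(z), gg_params(1, nu, 1)) * exp(z)
  expect_equal(f_jacobian, f_direct, tolerance = 1e-12)
})

test_that("shape equation solver stays in its bracket and matches bisection", {
  # A = Euler-Mascheroni: log(1) - digamma(1) = gamma, so nu = 1
  expect_equal(solve_shape_nu(-digamma(1)), 1, tolerance = 1e-9)
  for (A in exp(seq(log(0.01), log(10), length.out = 25))) {
    nu <- solve_shape_nu(A)
    expect_gt(nu, 1 / (2 * A))
    expect_lt(nu, 1 / A)
    expect_lt(abs(log(nu) - digamma(nu) - A), 1e-10)
    expect_equal(nu, bisect_shape_nu(A), tolerance = 1e-8)
  }
  expect_error(solve_shape_nu(0), "degenerate")
  expect_error(solve_shape_nu(-1), "degenerate")
})

test_that("parameter JSON round-trips both parametrizations", {
  pr <- gg_params(2.5, 0.9, 1.7)
  rt <- params_from_json(params_to_json(pr))
  expect_equal(unclass(rt), unclass(pr))
  lw <- to_lawless(pr)
  rt2 <- params_from_json(params_to_json(lw))
  expect_equal(unclass(rt2), unclass(lw))
})
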