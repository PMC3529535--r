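test_that("E-step applies Bayes with conserved responsibilities", {
  x <- gg_sample(200, gg_params(1, 2, 1), seed = 101)
  m1 <- gg_mixture(1, list(gg_params(1, 2, 1)))
  es1 <- e_step(x, m1)
  expect_true(all(es1$gamma == 1))
  twin <- gg_mixture(c(0.5, 0.5), list(gg_params(1, 2, 1),
                                       gg_params(1, 2, 1)))
  es2 <- e_step(x, twin)
  expect_equal(as.vector(es2$gamma), rep(0.5, 2 * length(x)))
  # direct Bayes oracle on hand-picked points, well-separated components
  comps <- list(gg_params(1, 2, 1), gg_params(10, 2, 1))
  mm <- gg_mixture(c(0.3, 0.7), comps)
  pts <- c(0.2, 0.5, 1, 2, 5, 8, 12, 20, 40, 80)
  es3 <- e_step(pts, mm)
  direct <- 0.3 * gg_pdf(pts, comps[[1]]) /
    (0.3 * gg_pdf(pts, comps[[1]]) + 0.7 * gg_pdf(pts, comps[[2]]))
  expect_equal(es3$gamma[, 1], direct, tolerance = 1e-12)
  expect_equal(rowSums(es3$gamma), rep(1, length(pts)), tolerance = 1e-12)
  expect_equal(es3$loglik, sum(log(0.3 * gg_pdf(pts, comps[[1]]) +
                                   0.7 * gg_pdf(pts, comps[[2]]))),
               tolerance = 1e-10)
})

test_that("weight update averages responsibilities and conserves mass", {
  g <- matrix(1 / 3, 30, 3)
  expect_equal(update_weights(g), rep(1 / 3, 3))
  onehot <- cbind(c(rep(1, 30), rep(0, 70)), c(rep(0, 30), rep(1, 70)))
  expect_equal(update_weights(onehot), c(0.3, 0.7))
  set.seed(5)
  r <- matrix(stats::runif(200), 50, 4)
  r <- r / rowSums(r)
  expect_equal(sum(update_weights(r)), 1)
})

test_that("M-steps with unit responsibilities reduce to the single-GG ML", {
  x <- gg_sample(4000, gg_params(1, 2, 1.5), seed = 111)
  fp <- fit_ml_proposed(x)
  m0 <- gg_mixture(1, list(gg_params(exp(mean(log(x))), 1, 1)))
  resp <- matrix(1, length(x), 1)
  up1 <- m_step_ggmm1(x, resp, m0)[[1]]
  expect_equal(up1$a, fp$params$a, tolerance = 1e-5)
  expect_equal(up1$nu, fp$params$nu, tolerance = 1e-5)
  expect_equal(up1$p, fp$params$p, tolerance = 1e-5)
  up2 <- m_step_ggmm2(x, resp, m0)[[1]]
  expect_equal(up2$p, fp$params$p, tolerance = 1e-5)
  expect_equal(loglik_gg(x, up2), fp$loglik, tolerance = 1e-7)
})

test_that("GGMM2 scale equation root satisfies its contract", {
  x <- gg_sample(3000, gg_params(1, 1.5, 2), seed = 112)
  lx <- log(x)
  w <- rep(1, length(x))
  fc <- speckleGG:::fit_component_ggmm2(lx, w, 1, 100, 1e-8)
  resid <- speckleGG:::lawless_S(lx, fc$sigma * sqrt(fc$k), w = w)$ratio -
    mean(lx) - fc$sigma / sqrt(fc$k)
  expect_lt(abs(resid), 1e-10)
  expect_gt(fc$sigma, 0)
  expect_lt(fc$sigma, fc$sigma_hi)
})

test_that("one EM step from the truth does not decrease the likelihood", {
  set.seed(115)
  x <- c(gg_sample(4000, gg_params(1, 2, 1)),
         gg_sample(6000, gg_params(8, 2, 1)))
  truth <- gg_mixture(c(0.4, 0.6), list(gg_params(1, 2, 1),
                                        gg_params(8, 2, 1)))
  es <- e_step(x, truth)
  model <- truth
  model$weights <- update_weights(es$gamma)
  model$components <- m_step_ggmm1(x, es$gamma, model)
  expect_gte(e_step(x, model)$loglik, es$loglik - 1e-8)
})

test_that("EM recovers a two-component mixture with monotone likelihood", {
  set.seed(120)
  x <- c(gg_sample(4000, gg_params(1, 2, 1)),
         gg_sample(6000, gg_params(8, 2, 1)))
  m <- fit_mixture(x, 2, "ggmm1", seed = 2, max_iter = 300)
  expect_true(all(diff(m$loglik_trace) > -1e-8))
  expect_lt(abs(m$weights[1] - 0.4), 0.05)
  means <- vapply(m$components, gg_mean, 0)
  expect_lt(abs(means[1] - gg_mean(gg_params(1, 2, 1))) /
              gg_mean(gg_params(1, 2, 1)), 0.07)
  expect_lt(abs(means[2] - gg_mean(gg_params(8, 2, 1))) /
              gg_mean(gg_params(8, 2, 1)), 0.07)
  # components reported in increasing mean order
  expect_true(diff(means) > 0)
})

test_that("J = 1 mixtures equal the single-component estimator", {
  x <- gg_sample(3000, gg_params(1, 2, 1.5), seed = 121)
  fp <- fit_ml_proposed(x)
  for (meth in c("ggmm1", "ggmm2")) {
    m <- fit_mixture(x, 1, meth)
    expect_lt(abs(m$loglik - fp$loglik), 1e-6 * length(x))
    grid <- seq(0.05, 5, length.out = 50)
    expect_equal(gg_pdf(grid, m$components[[1]]), gg_pdf(grid, fp$params),
                 tolerance = 1e-5)
  }
})

test_that("constrained mixtures pin their shape parameters", {
  set.seed(122)
  x <- c(gg_sample(2000, gg_params(1, 2, 1)),
         gg_sample(3000, gg_params(6, 2, 1)))
  gmm <- fit_mixture(x, 2, "gmm", seed = 3, max_iter = 40)
  expect_true(all(vapply(gmm$components, function(p) p$p, 0) == 1))
  nmm <- fit_mixture(x, 2, "nmm", seed = 3, max_iter = 40)
  expect_true(all(vapply(nmm$components, function(p) p$p, 0) == 2))
  rmm <- fit_mixture(x, 2, "rmm", seed = 3, max_iter = 40)
  expect_true(all(vapply(rmm$components, function(p) p$p, 0) == 2))
  expect_true(all(vapply(rmm$components, function(p) p$nu, 0) == 1))
  # every EM variant is monotone
  for (m in list(gmm, nmm, rmm))
    expect_true(all(diff(m$loglik_trace) > -1e-8))
  # free model can only do better in likelihood than its special cases
  gg2 <- fit_mixture(x, 2, "ggmm1", seed = 3, max_iter = 40)
  expect_gte(gg2$loglik, gmm$loglik - 1e-6 * length(x))
})

test_that("mixture JSON serialization round-trips", {
  m <- gg_mixture(c(0.25, 0.75), list(gg_params(1, 2, 1),
                                      gg_params(5, 1, 2)))
  rt <- model_from_json(model_to_json(m))
  expect_equal(rt$weights, m$weights)
  expect_equal(unclass(rt$components[[2]]), unclass(m$components[[2]]))
})
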