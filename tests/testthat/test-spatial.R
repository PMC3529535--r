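test_that("posterior maps are Bayes-consistent and conserve probability", {
  # well-separated components: means differing 10x
  tr <- two_region_image(par1 = gg_params(1, 2, 2),
                         par2 = gg_params(10, 2, 2), seed = 401)
  model <- gg_mixture(c(0.5, 0.5), list(gg_params(1, 2, 2),
                                        gg_params(10, 2, 2)))
  pm <- posterior_map(tr$image, model)
  expect_equal(max(abs(apply(pm$prob, c(1, 2), sum) - 1)), 0,
               tolerance = 1e-12)
  # region-mean posterior of the correct class
  expect_gt(mean(pm$prob[, 1:24, 1]), 0.9)
  expect_gt(mean(pm$prob[, 25:48, 2]), 0.9)
  # single class: certainty everywhere
  pm1 <- posterior_map(tr$image, gg_mixture(1, list(gg_params(1, 2, 1))))
  expect_true(all(pm1$prob == 1))
  # zero pixels are floored and flagged
  img0 <- tr$image
  img0[1, 1] <- 0
  pm0 <- posterior_map(img0, model)
  expect_true(pm0$floored[1, 1])
  expect_false(any(is.na(pm0$prob)))
})

test_that("structure tensors are PSD, vanish on flat maps, and orient edges", {
  flat <- array(0.5, c(16, 16, 2))
  st <- structure_tensors(flat, 1.5)
  expect_true(all(st$lambda1 == 0) && all(st$lambda2 == 0))
  # vertical edge (step along x): dominant eigenvector horizontal
  step <- array(0, c(32, 32, 2))
  step[, 17:32, 1] <- 1
  step[, , 2] <- 1 - step[, , 1]
  st2 <- structure_tensors(step, 1.5)
  mid <- 16:17
  expect_gt(min(abs(st2$v1x[16, mid, 1])), 0.99)
  expect_lt(max(abs(st2$v1y[16, mid, 1])), 0.1)
  # PSD: lambda1 >= lambda2 >= 0 everywhere
  expect_true(all(st2$lambda1 >= st2$lambda2))
  expect_true(all(st2$lambda2 >= 0))
  # symmetry of the tensor is structural: t12 enters both off-diagonals
  expect_error(structure_tensors(step, -1), "positive")
})

test_that("POSRAD reduces to conservative isotropic diffusion on flat maps", {
  set.seed(410)
  u0 <- matrix(stats::runif(32 * 32, 0, 100), 32, 32)
  flat <- array(0.5, c(32, 32, 2))
  expect_identical(posrad_filter(u0, flat, n_iter = 0), u0)
  u40 <- posrad_filter(u0, flat, n_iter = 40)
  expect_lt(abs(sum(u40) - sum(u0)) / sum(u0), 1e-6)
  expect_lt(stats::var(as.vector(u40)), stats::var(as.vector(u0)))
  # independent 5-point explicit heat-equation oracle
  heat <- u0
  for (it in 1:40) {
    up <- heat[c(1, 1:31), ]; dn <- heat[c(2:32, 32), ]
    lf <- heat[, c(1, 1:31)]; rt <- heat[, c(2:32, 32)]
    heat <- heat + 0.2 * (up + dn + lf + rt - 4 * heat)
  }
  expect_equal(u40, heat, tolerance = 1e-10)
  expect_error(posrad_filter(u0, flat, dt = 0.5), "stability")
})

test_that("POSRAD preserves probability edges better than isotropic blur", {
  tr <- two_region_image(H = 40, W = 40, seed = 411)
  model <- gg_mixture(c(0.5, 0.5), list(gg_params(1, 2, 1),
                                        gg_params(8, 2, 1)))
  pm <- posterior_map(tr$image, model)
  aniso <- posrad_filter(tr$image, pm, n_iter = 30)
  flat <- array(0.5, c(40, 40, 2))
  iso <- posrad_filter(tr$image, flat, n_iter = 30)
  gap <- function(u) abs(mean(u[, 1:20]) - mean(u[, 21:40]))
  # the cross-edge contrast survives the anisotropic filter better
  expect_gt(gap(aniso), gap(iso))
  # both smooth within regions
  expect_lt(stats::var(as.vector(aniso[5:36, 3:18])),
            stats::var(as.vector(tr$image[5:36, 3:18])))
})

test_that("LBP reduces to the input without pairwise term and keeps symmetry", {
  set.seed(420)
  p <- array(stats::runif(10 * 10 * 3), c(10, 10, 3))
  p <- p / array(apply(p, c(1, 2), sum), dim(p))
  out <- lbp_coherence(p, n_iter = 5, pair_weight = 0)
  expect_equal(out$prob, p, tolerance = 1e-9)
  u <- array(1 / 3, c(8, 8, 3))
  outu <- lbp_coherence(u, n_iter = 10)
  expect_equal(outu$prob, u, tolerance = 1e-9)
  expect_equal(max(abs(apply(out$prob, c(1, 2), sum) - 1)), 0,
               tolerance = 1e-12)
})

test_that("min-sum labeling attains the exhaustive energy minimum on 4x4", {
  set.seed(421)
  p <- array(stats::runif(4 * 4 * 2), c(4, 4, 2))
  p <- p / array(apply(p, c(1, 2), sum), dim(p))
  lab <- classify_max_posterior(lbp_coherence(p, n_iter = 30))
  # vectorized independent oracle over all 2^16 labelings of the
  # energy: unary -log p at each pixel plus, for every directed neighbor
  # pair (i, k), -log p at pixel k of pixel i's label
  lp <- log(pmax(p, 1e-12))
  cost1 <- -lp[, , 1]; cost2 <- -lp[, , 2]     # per-pixel unary costs
  nb <- function(m, dr, dc) {                  # neighbor sum with 0 pad
    out <- matrix(0, 4, 4)
    rs <- (1:4) + dr; cs <- (1:4) + dc
    vr <- rs >= 1 & rs <= 4; vc <- cs >= 1 & cs <= 4
    out[vr, vc] <- m[rs[vr], cs[vc]]
    out
  }
  nsum <- function(m) nb(m, 1, 0) + nb(m, -1, 0) + nb(m, 0, 1) +
    nb(m, 0, -1)
  node1 <- cost1 + nsum(cost1)                 # total cost if label 1
  node2 <- cost2 + nsum(cost2)
  all_lab <- t(sapply(0:(2^16 - 1),
                      function(m) as.integer(intToBits(m))[1:16]))
  energies <- all_lab %*% as.vector(node2) +
    (1 - all_lab) %*% as.vector(node1)
  e_min <- min(energies)
  expect_equal(lbp_energy(lab, p), e_min, tolerance = 1e-9)
  # and lbp_energy itself agrees with the oracle on arbitrary labelings
  for (m in c(0, 77, 4097, 65535)) {
    l <- matrix(as.integer(intToBits(m))[1:16] + 1L, 4, 4)
    expect_equal(lbp_energy(l, p), energies[m + 1], tolerance = 1e-9)
  }
})

test_that("LBP removes isolated salt-and-pepper labels on a two-region map", {
  set.seed(422)
  truth <- matrix(1L, 24, 24)
  truth[, 13:24] <- 2L
  conf <- ifelse(stats::runif(24 * 24) < 0.12, 0.25, 0.9)
  prob <- array(0, c(24, 24, 2))
  prob[, , 1] <- ifelse(truth == 1, conf, 1 - conf)
  prob[, , 2] <- 1 - prob[, , 1]
  pre <- classify_max_posterior(prob)
  post <- classify_max_posterior(lbp_coherence(prob, n_iter = 30))
  expect_lt(count_isolated(post), count_isolated(pre))
  expect_gt(mean(post == truth), mean(pre == truth))
})

test_that("max-posterior classification is exact, tie-stable and scale-free", {
  onehot <- array(0, c(3, 3, 2))
  onehot[, , 1][c(1, 5, 9)] <- 1
  onehot[, , 2] <- 1 - onehot[, , 1]
  lab <- classify_max_posterior(onehot)
  expect_identical(lab, matrix(c(1L, 2L, 2L, 2L, 1L, 2L, 2L, 2L, 1L), 3))
  # ties go to the lower-mean (first) class
  tie <- array(0.5, c(2, 2, 2))
  expect_true(all(classify_max_posterior(tie) == 1L))
  # rescaling probabilities per pixel cannot change the argmax
  set.seed(430)
  p <- array(stats::runif(5 * 5 * 3), c(5, 5, 3))
  scaled <- p * array(stats::runif(25, 0.5, 2)[rep(1:25, 3)], dim(p))
  expect_identical(classify_max_posterior(p),
                   classify_max_posterior(scaled))
})
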