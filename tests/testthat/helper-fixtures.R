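# Shared fixtures and small independent oracles used across the suite.

# adaptive-quadrature integral of the GG pdf over (lo, hi), split at the
# median to cope with densities that are unbounded at the origin
quad_gg <- function(f, params, lo = 0, hi = Inf, rel.tol = 1e-10) {
  m <- gg_quantile(0.5, params)
  if (lo >= m || hi <= m)
    return(stats::integrate(f, lo, hi, rel.tol = rel.tol)$value)
  stats::integrate(f, lo, m, rel.tol = rel.tol)$value +
    stats::integrate(f, m, hi, rel.tol = rel.tol)$value
}

# dense bisection oracle for log(nu) - digamma(nu) = A, independent of
# the package's Brent path
bisect_shape_nu <- function(A, lo = 1e-8, hi = 1e8, iters = 200) {
  f <- function(nu) log(nu) - digamma(nu) - A
  for (i in seq_len(iters)) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# count label pixels whose 4-neighbors all disagree with them
count_isolated <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  n <- 0L
  for (r in seq_len(H)) for (c in seq_len(W)) {
    nb <- c(if (r > 1) lab[r - 1, c], if (r < H) lab[r + 1, c],
            if (c > 1) lab[r, c - 1], if (c < W) lab[r, c + 1])
    if (all(nb != lab[r, c])) n <- n + 1L
  }
  n
}

# relative error of a fit against true parameters
rel_err <- function(fit_params, true_params) {
  c(a = abs(fit_params$a - true_params$a) / true_params$a,
    nu = abs(fit_params$nu - true_params$nu) / true_params$nu,
    p = abs(fit_params$p - true_params$p) / true_params$p)
}

# two-region test image: left half from one GG component, right half
# from another; returns image, truth labels and the pooled samples
two_region_image <- function(H = 48, W = 48, par1 = gg_params(1, 2, 1),
                             par2 = gg_params(8, 2, 1), seed = 42) {
  set.seed(seed)
  img <- matrix(0, H, W)
  w1 <- floor(W / 2)
  img[, seq_len(w1)] <- gg_sample(H * w1, par1)
  img[, (w1 + 1):W] <- gg_sample(H * (W - w1), par2)
  truth <- matrix(1L, H, W)
  truth[, (w1 + 1):W] <- 2L
  list(image = img, truth = truth)
}
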