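# Goodness-of-fit: histogram Kullback-Leibler divergence, the
# Kolmogorov-Smirnov statistic, and the multi-family comparison harness.

model_cdf_fun <- function(model) {
  if (inherits(model, "gg_params")) function(x) gg_cdf(x, model)
  else if (inherits(model, "gg_mixture")) function(x) mixture_cdf(x, model)
  else if (is.function(model)) model
  else stop("model must be gg_params, gg_mixture, or a CDF function",
            call. = FALSE)
}

#' Histogram-based Kullback-Leibler divergence
#'
#' \deqn{D_{KL} = \sum_i p_n(i) \log\frac{p_n(i)}{f_X(i)}} over occupied
#' histogram bins, where \eqn{p_n} are the empirical bin probabilities on
#' equal-width bins spanning \eqn{[\min x, \max x]} and \eqn{f_X} the
#' model bin probabilities (CDF differences). A model probability of zero
#' on an occupied bin yields \code{Inf}, reported explicitly rather than
#' floored.
#'
#' @param samples Positive numeric vector.
#' @param model A [gg_params()], a \code{"gg_mixture"}, or a CDF function.
#' @param n_bins Number of histogram bins (default 150).
#' @return Non-negative divergence in nats (possibly \code{Inf}).
#' @export
kl_divergence <- function(samples, model, n_bins = 150) {
  x <- check_samples(samples)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  F <- model_cdf_fun(model)
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  cnt <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins),
                  nbins = n_bins)
  p_n <- cnt / length(x)
  f_x <- diff(F(edges))
  occ <- p_n > 0
  if (any(f_x[occ] <= 0)) return(Inf)
  sum(p_n[occ] * (log(p_n[occ]) - log(f_x[occ])))
}

#' Kolmogorov-Smirnov statistic against a fitted model
#'
#' The sup-norm distance between the empirical CDF and the model CDF,
#' evaluated exactly at the sorted sample points:
#' \eqn{D_{KS} = \max_i \max(|i/n - F(x_{(i)})|, |(i-1)/n - F(x_{(i)})|)}.
#'
#' @param samples Positive numeric vector.
#' @param model A [gg_params()], a \code{"gg_mixture"}, or a CDF function.
#' @return The statistic, in \eqn{[0, 1]}.
#' @export
ks_statistic <- function(samples, model) {
  x <- sort(check_samples(samples))
  F <- model_cdf_fun(model)
  n <- length(x)
  Fx <- F(x)
  max(pmax(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx)))
}

#' Welch's unequal-variance t-test
#'
#' Closed-form two-sided Welch t-test with the Welch-Satterthwaite
#' degrees of freedom; used to compare replicate lists of goodness-of-fit
#' scores between candidate distributions.
#'
#' @param x,y Numeric vectors.
#' @return List with \code{statistic}, \code{df}, \code{p_value}.
#' @export
welch_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x) / nx; vy <- stats::var(y) / ny
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  list(statistic = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df))
}

fit_family_ml <- function(x, family) {
  lx <- log(x)
  w1 <- rep(1, length(x))
  switch(family,
    exponential = gg_params(mean(x), 1, 1),
    rayleigh    = gg_params(sqrt(mean(x^2)), 1, 2),
    gamma       = fit_component_constrained(lx, w1, "p_fixed_1")$params,
    nakagami    = fit_component_constrained(lx, w1, "p_fixed_2")$params,
    weibull     = {                 # nu = 1, profile over p
      negw <- function(logp) {
        p <- exp(logp)
        log_a <- (logsumexp(p * lx) - log(length(x))) / p
        -(length(x) * log(p) - length(x) * p * log_a + (p - 1) * sum(lx) -
            exp(logsumexp(p * (lx - log_a))))
      }
      o <- stats::optimize(negw, c(log(0.05), log(50)), tol = 1e-10)
      p <- exp(o$minimum)
      gg_params(exp((logsumexp(p * lx) - log(length(x))) / p), 1, p)
    },
    gg          = fit_ml_proposed(x)$params,
    normal      = {
      m <- mean(x); s <- stats::sd(x)
      structure(list(mean = m, sd = s), class = "normal_params")
    },
    stop("unknown family '", family, "'", call. = FALSE))
}

#' Fit and rank candidate envelope distributions
#'
#' Fits each requested family by maximum likelihood (the nested families
#' via their constrained GG profiles, the Normal directly), then scores
#' each fit by the Kolmogorov-Smirnov statistic and the histogram KL
#' divergence. Reports are sorted by \eqn{D_{KS}}.
#'
#' @param samples Positive numeric vector.
#' @param families Character vector among \code{"exponential"},
#'   \code{"rayleigh"}, \code{"weibull"}, \code{"normal"},
#'   \code{"nakagami"}, \code{"gamma"}, \code{"gg"} (at least 2).
#' @param n_bins Histogram bins for the KL divergence.
#' @return A data frame with one row per family: \code{family},
#'   \code{d_ks}, \code{d_kl}, \code{n_bins}, \code{n}, \code{ok} (FALSE
#'   when that family's fit failed; failures are recorded, not fatal).
#'   The fitted parameter objects are attached as attribute
#'   \code{"fits"}.
#' @export
compare_families <- function(samples,
                             families = c("exponential", "rayleigh",
                                          "weibull", "normal", "nakagami",
                                          "gamma", "gg"),
                             n_bins = 150) {
  x <- check_samples(samples)
  if (length(families) < 2) stop("need at least 2 families", call. = FALSE)
  fits <- list()
  rows <- lapply(families, function(fam) {
    fit <- tryCatch(fit_family_ml(x, fam), error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(family = fam, d_ks = NA_real_, d_kl = NA_real_,
                        n_bins = n_bins, n = length(x), ok = FALSE))
    fits[[fam]] <<- fit
    F <- if (inherits(fit, "normal_params"))
      function(q) stats::pnorm(q, fit$mean, fit$sd)
    else function(q) gg_cdf(q, fit)
    data.frame(family = fam,
               d_ks = ks_statistic(x, F),
               d_kl = kl_divergence(x, F, n_bins = n_bins),
               n_bins = n_bins, n = length(x), ok = TRUE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$d_ks), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
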