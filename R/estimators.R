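# Single-component Generalized Gamma estimators: Stacy moments, the
# chi-squared grid heuristic, the iterative log-scale (Lawless) ML, and
# the profile-likelihood ML that the mixture machinery builds on.

new_gg_fit <- function(params, method, loglik, iterations, converged,
                       diagnostics = list()) {
  structure(list(params = params, method = method, loglik = loglik,
                 iterations = iterations, converged = converged,
                 diagnostics = diagnostics),
            class = "gg_fit")
}

#' @export
print.gg_fit <- function(x, ...) {
  cat(sprintf("GG fit (%s): a = %.6g, nu = %.6g, p = %.6g\n",
              x$method, x$params$a, x$params$nu, x$params$p))
  cat(sprintf("  log-likelihood = %.6f, iterations = %d, converged = %s\n",
              x$loglik, x$iterations, x$converged))
  invisible(x)
}

check_samples <- function(x) {
  if (!is.numeric(x) || length(x) == 0)
    stop("samples must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all samples must be finite and strictly positive ",
         "(GG support is (0, Inf))", call. = FALSE)
  invisible(as.numeric(x))
}

#' Log-likelihood of a Generalized Gamma sample
#'
#' \deqn{\mathcal{LL} = n\log p - np\nu\log a - n\log\Gamma(\nu)
#'   + (p\nu - 1)\sum_i \log x_i - \sum_i (x_i/a)^p.}
#'
#' @param samples Positive numeric vector.
#' @param params A [gg_params()] object.
#' @return The log-likelihood (scalar).
#' @export
loglik_gg <- function(samples, params) {
  x <- check_samples(samples)
  stopifnot(inherits(params, "gg_params"))
  a <- params$a; nu <- params$nu; p <- params$p
  n <- length(x)
  lx <- log(x)
  n * log(p) - n * p * nu * log(a) - n * lgamma(nu) +
    (p * nu - 1) * sum(lx) - sum(exp(p * (lx - log(a))))
}

#' Score-equation residuals at a parameter point
#'
#' Residuals of the three ML stationarity equations for the GG
#' log-likelihood (derivatives with respect to \eqn{a}, \eqn{\nu}, \eqn{p},
#' scaled to sample-sum form). All three vanish at a maximum-likelihood
#' point; they serve as a self-consistency diagnostic for every estimator.
#'
#' @param samples Positive numeric vector.
#' @param params A [gg_params()] object.
#' @return Named numeric vector \code{c(a = ..., nu = ..., p = ...)}.
#' @export
score_residuals <- function(samples, params) {
  x <- check_samples(samples)
  stopifnot(inherits(params, "gg_params"))
  a <- params$a; nu <- params$nu; p <- params$p
  n <- length(x)
  lr <- log(x) - log(a)          # log(x_i / a)
  z <- exp(p * lr)               # (x_i / a)^p
  c(a  = sum(z) - n * nu,
    nu = p * sum(lr) - n * digamma(nu),
    p  = n / p + nu * sum(lr) - sum(z * lr))
}

# Profile step: for a fixed power p, the ML estimates of (a, nu) of the
# Gamma-distributed transform Y = X^p are available from one well-behaved
# scalar equation. Returns the profiled parameters and the GG
# log-likelihood at (a(p), nu(p), p). All in log-space for stability.
profile_given_p <- function(lx, p) {
  n <- length(lx)
  ly <- p * lx
  m <- mean(ly)
  u <- ly - m
  # A = log(mean(y)) - mean(log y) suffers catastrophic cancellation for
  # small p (A ~ p^2 var(log x)/2); the expm1/log1p route preserves it
  A <- if (max(abs(u)) < 1) log1p(mean(expm1(u)))
       else logsumexp(u) - log(n)
  log_mean_y <- m + A
  nu <- solve_shape_nu(A)
  log_a <- (log_mean_y - log(nu)) / p
  ll <- n * log(p) - n * p * nu * log_a - n * lgamma(nu) +
    (p * nu - 1) * sum(lx) - exp(logsumexp(p * (lx - log_a)))
  list(log_a = log_a, nu = nu, A = A, loglik = ll)
}

#' Profile-likelihood maximum-likelihood fit of the Generalized Gamma
#'
#' The power transform \eqn{Y = X^{p_0}} is Gamma distributed exactly when
#' \eqn{p_0 = p}, and the Gamma ML sub-problem in \eqn{(a, \nu)} reduces to
#' one well-behaved scalar equation, \eqn{\log\nu - \Psi(\nu) = A(p)} with
#' \eqn{A(p) = \log\bar{y} - \overline{\log y} > 0}, solved by Brent's
#' method inside its guaranteed bracket \eqn{(1/(2A), 1/A)}, after which
#' \eqn{\hat a^p = \sum y_i / (n\hat\nu)}. The outer search over \eqn{p}
#' maximizes the resulting profiled GG log-likelihood by Nelder-Mead on
#' \eqn{\log p} (positivity enforced by the parametrization), with
#' restarts from \eqn{p \in \{0.5, 2\}} if the simplex fails, followed by
#' a short golden-section polish around the best point. The search is
#' confined to \eqn{p \in [10^{-3}, 10^3]}: outside that range the GG is
#' numerically indistinguishable from its lognormal limit
#' (\eqn{p \to 0}, \eqn{\nu \to \infty}), which heavily discretized data
#' can favor without an interior maximum.
#'
#' @param samples Positive numeric vector, at least 3 values, not all equal.
#' @param max_iter Maximum Nelder-Mead iterations for the outer search.
#' @param tol Relative convergence tolerance of the outer search.
#' @param p_init Initial value for the power shape \eqn{p}.
#' @return A \code{"gg_fit"} object; \code{diagnostics$score} holds the
#'   score-equation residuals at the solution.
#' @export
fit_ml_proposed <- function(samples, max_iter = 100, tol = 1e-8, p_init = 1) {
  x <- check_samples(samples)
  if (length(x) < 3) stop("need at least 3 samples", call. = FALSE)
  if (max(x) == min(x))
    stop("degenerate data: all samples are equal", call. = FALSE)
  lx <- log(x)
  # the power search is confined to p in [1e-3, 1e3]: outside, the GG is
  # numerically indistinguishable from its lognormal limit (p -> 0 with
  # nu -> infinity) and the profiled equations lose their conditioning
  lim <- log(1e3)
  negprof <- function(logp) {
    if (abs(logp) > lim) return(Inf)
    tryCatch({
      prof <- profile_given_p(lx, exp(logp))
      # reject scales that cannot be represented in linear space
      if (abs(prof$log_a) > 700 || !is.finite(prof$loglik)) Inf
      else -prof$loglik
    }, error = function(e) Inf)
  }

  run_nm <- function(start) {
    suppressWarnings(stats::optim(log(start), negprof, method = "Nelder-Mead",
                                  control = list(maxit = max_iter,
                                                 reltol = tol)))
  }
  fit <- run_nm(p_init)
  iters <- fit$counts[["function"]]
  if (!is.finite(fit$value) || fit$convergence > 1) {
    for (ps in c(0.5, 2)) {
      alt <- run_nm(ps)
      iters <- iters + alt$counts[["function"]]
      if (is.finite(alt$value) && alt$value < fit$value) fit <- alt
    }
  }
  # golden-section polish of the 1-D profile around the simplex solution
  # (suppressed warnings: the objective is Inf by design off-domain)
  pol <- suppressWarnings(
    stats::optimize(negprof,
                    interval = c(max(fit$par - 0.2, -lim + 1e-9),
                                 min(fit$par + 0.2, lim - 1e-9)),
                    tol = 1e-10))
  logp <- if (pol$objective < fit$value) pol$minimum else fit$par

  p <- exp(logp)
  prof <- profile_given_p(lx, p)
  params <- gg_params(exp(prof$log_a), prof$nu, p)
  new_gg_fit(params, "proposed", prof$loglik, iterations = iters,
             converged = fit$convergence == 0 || pol$objective < fit$value,
             diagnostics = list(score = score_residuals(x, params),
                                A = prof$A))
}

#' Stacy moments estimator of the Generalized Gamma
#'
#' Matches the first three central moments of the log-data
#' \eqn{y_i = \log x_i}: the shape \eqn{\hat\nu} solves
#' \eqn{-|g_y| = \Psi^{(2)}(\hat\nu)/(\Psi^{(1)}(\hat\nu))^{3/2}} (sample
#' log-skewness against the log-Gamma skewness), then
#' \eqn{\hat p = -\mathrm{sign}(g_y)\sqrt{\Psi^{(1)}(\hat\nu)}/S_y} and
#' \eqn{\hat a = \exp(\bar y - \Psi^{(0)}(\hat\nu)/\hat p)}.
#'
#' The method can land outside the parameter space: the log-Gamma skewness
#' magnitude is confined to \eqn{(0, 2)}, and a positive sample skewness
#' implies a negative \eqn{\hat p}. Both cases raise a condition of class
#' \code{"gg_out_of_space"}.
#'
#' @param samples Positive numeric vector, at least 3 values.
#' @return A \code{"gg_fit"} object.
#' @export
fit_stacy_moments <- function(samples) {
  x <- check_samples(samples)
  n <- length(x)
  if (n < 3) stop("need at least 3 samples for the skewness", call. = FALSE)
  y <- log(x)
  y_bar <- mean(y)
  m2 <- mean((y - y_bar)^2)
  m3 <- mean((y - y_bar)^3)
  if (m2 <= 0)
    stop("degenerate data: zero variance of log-samples", call. = FALSE)
  g_y <- m3 / m2^1.5

  fail <- function(msg) {
    cond <- structure(class = c("gg_out_of_space", "error", "condition"),
                      list(message = msg, call = sys.call(-1)))
    stop(cond)
  }
  if (g_y >= 0)
    fail(paste0("moment estimate outside parameter space: non-negative ",
                "log-skewness (", format(g_y), ") implies p <= 0"))
  if (abs(g_y) >= 2)
    fail(paste0("moment estimate outside parameter space: |log-skewness| = ",
                format(abs(g_y)), " exceeds the attainable range (0, 2)"))

  # -psigamma(nu,2)/psigamma(nu,1)^1.5 decreases from 2 (nu -> 0) to 0
  h <- function(nu) -psigamma(nu, 2) / psigamma(nu, 1)^1.5 - abs(g_y)
  hi <- 1
  while (h(hi) > 0) hi <- hi * 2
  lo <- hi / 2
  while (h(lo) < 0) { lo <- lo / 2; if (lo < 1e-12) break }
  nu <- stats::uniroot(h, lower = lo, upper = hi, tol = 1e-12)$root

  p <- sqrt(psigamma(nu, 1) / m2)          # -sign(g_y) = +1 here
  a <- exp(y_bar - digamma(nu) / p)
  params <- gg_params(a, nu, p)
  new_gg_fit(params, "stacy", loglik_gg(x, params), iterations = 0L,
             converged = TRUE,
             diagnostics = list(g_y = g_y, S_y2 = m2,
                                score = score_residuals(x, params)))
}

#' Chi-squared grid heuristic fit (Gomes-style)
#'
#' For each candidate power \eqn{p} on a grid, the transform
#' \eqn{Y = X^p} is fitted as a Gamma distribution by moments
#' (\eqn{\hat\nu = \bar y^2 / S_y^2}, scale \eqn{= S_y^2/\bar y}), and a
#' chi-squared goodness-of-fit statistic is computed on bins that are
#' equiprobable under the candidate fit; bins whose expected count falls
#' below 5 are merged by coarsening the binning. The grid point with the
#' smallest chi-squared statistic (best fit) wins.
#'
#' @param samples Positive numeric vector.
#' @param p_grid Candidate powers; default a 150-point geometric grid on
#'   \eqn{[0.1, 10]}.
#' @param n_bins Number of chi-squared bins (default 150).
#' @return A \code{"gg_fit"} object; \code{diagnostics} holds the winning
#'   chi-squared statistic and p-value.
#' @export
fit_gomes <- function(samples, p_grid = NULL, n_bins = 150) {
  x <- check_samples(samples)
  n <- length(x)
  if (is.null(p_grid))
    p_grid <- exp(seq(log(0.1), log(10), length.out = 150))
  if (any(p_grid <= 0)) stop("p_grid must be positive", call. = FALSE)
  if (n_bins < 5) stop("n_bins must be at least 5", call. = FALSE)

  # expected counts are n/n_bins under equiprobable binning; merging
  # low-expectation bins amounts to coarsening until E >= 5
  nb <- min(n_bins, max(5L, floor(n / 5)))
  lx <- log(x)
  best <- NULL
  for (p in p_grid) {
    y <- exp(p * lx)
    m <- mean(y); v <- stats::var(y)
    if (!is.finite(m) || !is.finite(v) || v <= 0) next
    shape <- m^2 / v
    scale <- v / m
    edges <- stats::qgamma((1:(nb - 1)) / nb, shape = shape, scale = scale)
    if (any(diff(edges) <= 0)) next
    obs <- tabulate(findInterval(y, edges) + 1L, nbins = nb)
    expd <- n / nb
    stat <- sum((obs - expd)^2 / expd)
    if (is.null(best) || stat < best$stat)
      best <- list(stat = stat, p = p, shape = shape, scale = scale)
  }
  if (is.null(best))
    stop("chi-squared grid fit failed on every candidate p", call. = FALSE)
  params <- gg_params(best$scale^(1 / best$p), best$shape, best$p)
  df <- nb - 1L - 2L
  new_gg_fit(params, "gomes", loglik_gg(x, params),
             iterations = length(p_grid), converged = TRUE,
             diagnostics = list(chisq = best$stat,
                                p_value = stats::pchisq(best$stat, df,
                                                        lower.tail = FALSE),
                                n_bins = nb,
                                score = score_residuals(x, params)))
}

# Weighted/unweighted exponential log-moment ratio S1/S0 and log(S0),
# computed with the max shift so that sigma -> 0 never overflows.
lawless_S <- function(y, sc, w = NULL) {
  # sc = sigma * sqrt(k)
  u <- (y - max(y)) / sc
  e <- exp(u)
  if (!is.null(w)) e <- w * e
  s0 <- sum(e)
  list(ratio = sum(y * e) / s0,
       log_S0 = max(y) / sc + log(s0 / if (is.null(w)) length(y) else sum(w)))
}

#' Iterative log-scale (Lawless) maximum-likelihood fit
#'
#' Works on \eqn{Y = \log X} in the Lawless parametrization
#' \eqn{(\mu, \sigma, k)}. Each cycle solves, in turn,
#' \itemize{
#'   \item the shape equation
#'     \eqn{\log k - \Psi(k) - L/\sqrt{k} = 0} with
#'     \eqn{L = (\mu - \bar y)/\sigma \ge 0}, whose root is bracketed in
#'     \eqn{(1/(4L^2), 1/L^2)};
#'   \item the scale equation
#'     \eqn{R(\sigma) = S_1/S_0 - \bar y - \sigma/\sqrt{k} = 0} with
#'     \eqn{S_j = \frac{1}{n}\sum_i y_i^j e^{y_i/(\sigma\sqrt{k})}},
#'     monotone decreasing with root in
#'     \eqn{(0, \sqrt{k}\,(y_{\max} - \bar y))};
#'   \item the location update \eqn{\mu = \sigma\sqrt{k}\log S_0},
#' }
#' until the log-likelihood change falls below \code{tol}.
#'
#' @param samples Positive numeric vector.
#' @param init Optional [gg_params()] initial guess; default is the Stacy
#'   moments estimate, falling back to a Gamma (\eqn{p = 1}) profile fit
#'   when the moments land outside the parameter space.
#' @param max_iter Maximum outer iterations (default 100).
#' @param tol Absolute log-likelihood convergence tolerance (default 1e-8).
#' @return A \code{"gg_fit"} object (parameters converted back to the
#'   Stacy form). \code{converged = FALSE} flags exhaustion of
#'   \code{max_iter}; the last iterate is still returned.
#' @details The plain alternation between the shape and scale equations is
#'   a linearly convergent fixed-point map; each outer iteration here
#'   applies the cycle twice and then an Aitken \eqn{\Delta^2}
#'   extrapolation on \eqn{(\log k, \log\sigma)}, which restores fast
#'   convergence without changing the equations being solved (the
#'   extrapolated point is only kept when it remains in the parameter
#'   domain and the subsequent cycle succeeds).
#' @export
fit_noufaily <- function(samples, init = NULL, max_iter = 100, tol = 1e-8) {
  x <- check_samples(samples)
  if (length(x) < 3) stop("need at least 3 samples", call. = FALSE)
  if (max(x) == min(x))
    stop("degenerate data: all samples are equal", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  y <- log(x)
  y_bar <- mean(y)
  y_max <- max(y)

  if (is.null(init)) {
    init <- tryCatch(fit_stacy_moments(x)$params, error = function(e) {
      prof <- profile_given_p(y, 1)
      gg_params(exp(prof$log_a), prof$nu, 1)
    })
  }
  stopifnot(inherits(init, "gg_params"))
  lw <- to_lawless(init)

  # one cycle of the iteration: location update, shape equation, scale
  # equation, in the order of the original scheme; state = c(k, sigma)
  cycle <- function(st) {
    k <- st[1]; sigma <- st[2]
    mu <- sigma * sqrt(k) * lawless_S(y, sigma * sqrt(k))$log_S0
    L <- max((mu - y_bar) / sigma, .Machine$double.eps)
    g <- function(kk) log(kk) - digamma(kk) - L / sqrt(kk)
    lo <- 0.99 / (4 * L^2)
    hi <- min(1.01 / L^2, 1e9)
    k <- if (g(lo) > 0 && g(hi) < 0)
      stats::uniroot(g, lower = lo, upper = hi, tol = 1e-12)$root
    else min(max(1 / L^2, lo), hi)
    R <- function(s) lawless_S(y, s * sqrt(k))$ratio - y_bar - s / sqrt(k)
    sigma <- stats::uniroot(R, lower = 1e-12,
                            upper = sqrt(k) * (y_max - y_bar) * 1.01,
                            tol = 1e-12)$root
    c(k, sigma)
  }
  ll_at <- function(st) {
    k <- st[1]; sigma <- st[2]
    mu <- sigma * sqrt(k) * lawless_S(y, sigma * sqrt(k))$log_S0
    loglik_gg(x, from_lawless(lawless_params(mu, sigma, k)))
  }

  st <- c(lw$k, lw$sigma)
  ll_old <- ll_at(st)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    st1 <- cycle(st)
    st2 <- cycle(st1)
    l0 <- log(st); l1 <- log(st1); l2 <- log(st2)
    den <- l2 - 2 * l1 + l0
    acc <- ifelse(abs(den) > 1e-14, l0 - (l1 - l0)^2 / den, l2)
    stA <- exp(acc)
    st <- st2
    ll <- ll_at(st2)
    # accept the extrapolated state only when it improves the likelihood
    if (all(is.finite(stA)) && all(stA > 0)) {
      stC <- tryCatch(cycle(stA), error = function(e) NULL)
      if (!is.null(stC)) {
        llC <- ll_at(stC)
        if (is.finite(llC) && llC >= ll) {
          st <- stC
          ll <- llC
        }
      }
    }
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      ll_old <- ll
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  k <- st[1]; sigma <- st[2]
  mu <- sigma * sqrt(k) * lawless_S(y, sigma * sqrt(k))$log_S0
  params <- from_lawless(lawless_params(mu, sigma, k))
  new_gg_fit(params, "noufaily", ll_old, iterations = iter,
             converged = converged,
             diagnostics = list(score = score_residuals(x, params)))
}

#' Fit a single Generalized Gamma by any of the implemented estimators
#'
#' Convenience dispatcher used by the command-line interface.
#'
#' @param samples Positive numeric vector.
#' @param method One of \code{"proposed"}, \code{"stacy"}, \code{"gomes"},
#'   \code{"noufaily"}.
#' @param ... Passed to the selected estimator.
#' @return A \code{"gg_fit"} object.
#' @export
fit_gg <- function(samples, method = c("proposed", "stacy", "gomes",
                                       "noufaily"), ...) {
  method <- match.arg(method)
  switch(method,
         proposed = fit_ml_proposed(samples, ...),
         stacy    = fit_stacy_moments(samples),
         gomes    = fit_gomes(samples, ...),
         noufaily = fit_noufaily(samples, ...))
}
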