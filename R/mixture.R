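# EM fitting of Generalized Gamma mixture models. Two M-step variants:
# GGMM1 (Nelder-Mead over each component's power shape, profiled a and nu)
# and GGMM2 (iterative Lawless shape/scale equations). Constrained
# variants pin p (Gamma, Nakagami) and additionally nu (Rayleigh).

new_gg_mixture <- function(weights, components, method, constraint,
                           loglik = NA_real_, loglik_trace = numeric(0),
                           iterations = 0L, converged = FALSE,
                           responsibilities = NULL) {
  stopifnot(length(weights) == length(components),
            all(vapply(components, inherits, TRUE, "gg_params")))
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0))
    stop("mixture weights must be non-negative and sum to 1", call. = FALSE)
  structure(list(J = length(weights), weights = as.numeric(weights),
                 components = components, method = method,
                 constraint = constraint, loglik = loglik,
                 loglik_trace = loglik_trace, iterations = iterations,
                 converged = converged,
                 responsibilities = responsibilities),
            class = "gg_mixture")
}

#' Construct a Generalized Gamma mixture model object
#'
#' @param weights Numeric vector of mixing proportions (sum to 1).
#' @param components List of [gg_params()] objects, one per component.
#' @param method Label of the fitting method (free-form for hand-built
#'   models).
#' @param constraint One of \code{"free"}, \code{"p_fixed_1"},
#'   \code{"p_fixed_2"}, \code{"p2_nu1"}.
#' @return A \code{"gg_mixture"} object.
#' @export
gg_mixture <- function(weights, components, method = "manual",
                       constraint = "free") {
  new_gg_mixture(weights, components, method, constraint)
}

#' @export
print.gg_mixture <- function(x, ...) {
  cat(sprintf("GG mixture (%s, %d components, constraint = %s)\n",
              x$method, x$J, x$constraint))
  for (j in seq_len(x$J))
    cat(sprintf("  [%d] pi = %.4f  a = %.5g  nu = %.5g  p = %.5g\n", j,
                x$weights[j], x$components[[j]]$a, x$components[[j]]$nu,
                x$components[[j]]$p))
  if (is.finite(x$loglik))
    cat(sprintf("  log-likelihood = %.4f after %d iterations (converged: %s)\n",
                x$loglik, x$iterations, x$converged))
  invisible(x)
}

#' Mixture density and distribution function
#'
#' @param x Evaluation points.
#' @param model A \code{"gg_mixture"} object.
#' @param log Return log-density?
#' @return Numeric vector.
#' @export
mixture_pdf <- function(x, model, log = FALSE) {
  stopifnot(inherits(model, "gg_mixture"))
  lm <- vapply(seq_len(model$J), function(j)
    log(model$weights[j]) + gg_pdf(x, model$components[[j]], log = TRUE),
    numeric(length(x)))
  lm <- matrix(lm, nrow = length(x))
  out <- apply(lm, 1L, logsumexp)
  if (log) out else exp(out)
}

#' @rdname mixture_pdf
#' @export
mixture_cdf <- function(x, model) {
  stopifnot(inherits(model, "gg_mixture"))
  out <- numeric(length(x))
  for (j in seq_len(model$J))
    out <- out + model$weights[j] * gg_cdf(x, model$components[[j]])
  out
}

#' Expectation step: responsibilities and data log-likelihood
#'
#' Computes the posterior membership probabilities
#' \eqn{\gamma_{ij} = \pi_j f(x_i \mid \Theta_j) / \sum_l \pi_l
#' f(x_i \mid \Theta_l)} (Bayes) in log-space with a log-sum-exp guard, so
#' no row can become NaN even when all densities underflow.
#'
#' @param samples Positive numeric vector of length N.
#' @param model A \code{"gg_mixture"} object.
#' @return List with \code{gamma} (N x J matrix, rows summing to 1) and
#'   \code{loglik} (the data log-likelihood
#'   \eqn{\sum_i \log \sum_j \pi_j f(x_i|\Theta_j)}).
#' @export
e_step <- function(samples, model) {
  x <- check_samples(samples)
  stopifnot(inherits(model, "gg_mixture"))
  J <- model$J
  lm <- matrix(0, length(x), J)
  for (j in seq_len(J))
    lm[, j] <- log(model$weights[j]) +
      gg_pdf(x, model$components[[j]], log = TRUE)
  m <- apply(lm, 1L, max)
  # all-underflow rows: fall back to uniform responsibilities
  bad <- !is.finite(m)
  if (any(bad)) lm[bad, ] <- 0
  m <- pmax(m, -.Machine$double.xmax)
  w <- exp(lm - m)
  rs <- rowSums(w)
  list(gamma = w / rs,
       loglik = sum(ifelse(bad, -745, m + log(rs))))
}

#' Maximization step for the mixing weights
#'
#' \eqn{\hat\pi_j = N^{-1}\sum_i \gamma_{ij}} (the Lagrange-multiplier
#' solution under \eqn{\sum_j \pi_j = 1}).
#'
#' @param resp N x J responsibility matrix (rows summing to 1).
#' @return Weight vector of length J.
#' @export
update_weights <- function(resp) {
  resp <- as.matrix(resp)
  w <- colMeans(resp)
  if (any(colSums(resp) < 2))
    warning("component collapse: a component received responsibility mass ",
            "below 2 samples", call. = FALSE)
  w / sum(w)
}

# gamma-weighted profile of (a, nu) at a fixed power p, on log-samples lx
# with weights w. A_j = log(sum(w x^p)/sum(w)) - sum(w log x^p)/sum(w).
# sigma_min floors the component's log-scale width 1/(p sqrt(nu)):
# narrower components are indistinguishable from intensity-quantization
# atoms, the degenerate likelihood spikes of continuous mixtures on
# discretized data. The floored step is a constrained M-step (the
# weighted likelihood is unimodal in nu, so the constrained maximum sits
# on the boundary) and EM monotonicity is preserved.
weighted_profile_given_p <- function(lx, w, p, sigma_min = 0) {
  sw <- sum(w)
  lw <- log(w)
  keep <- is.finite(lw)
  ly <- p * lx
  m <- sum(w * ly) / sw
  u <- ly - m
  # cancellation-safe weighted A (see profile_given_p)
  A <- if (max(abs(u[keep])) < 1) log1p(sum(w[keep] * expm1(u[keep])) / sw)
       else logsumexp((u + lw)[keep]) - log(sw)
  log_mean_y <- m + A
  nu <- solve_shape_nu(A)
  if (sigma_min > 0) nu <- min(nu, 1 / (p * sigma_min)^2)
  log_a <- (log_mean_y - log(nu)) / p
  wll <- sw * log(p) - sw * p * nu * log_a - sw * lgamma(nu) +
    (p * nu - 1) * sum(w * lx) - exp(logsumexp((p * (lx - log_a) + lw)[keep]))
  list(log_a = log_a, nu = nu, A = A, wll = wll)
}

# single-component weighted fits used by the M-steps ------------------

fit_component_ggmm1 <- function(lx, w, p_init, max_iter, tol,
                                sigma_min = 0) {
  # the power shape is kept inside [0.05, 100]: below, the component is a
  # lognormal-limit shape whose Stacy scale leaves double range; above,
  # it describes nothing an envelope image can express
  negw <- function(logp) {
    if (logp < log(0.05) || logp > log(100)) return(Inf)
    tryCatch({
      prof <- weighted_profile_given_p(lx, w, exp(logp), sigma_min)
      # reject scales that cannot be represented in linear space
      if (abs(prof$log_a) > 700 || !is.finite(prof$wll)) Inf else -prof$wll
    }, error = function(e) Inf)
  }
  fit <- suppressWarnings(stats::optim(log(min(max(p_init, 0.051), 99)),
                                       negw, method = "Nelder-Mead",
                                       control = list(maxit = max_iter,
                                                      reltol = tol)))
  pol <- suppressWarnings(
    stats::optimize(negw,
                    interval = c(max(fit$par - 0.2, log(0.05) + 1e-9),
                                 min(fit$par + 0.2, log(100) - 1e-9)),
                    tol = 1e-10))
  logp <- if (pol$objective < fit$value) pol$minimum else fit$par
  p <- exp(logp)
  prof <- weighted_profile_given_p(lx, w, p, sigma_min)
  list(params = gg_params(exp(prof$log_a), prof$nu, p), wll = prof$wll)
}

fit_component_ggmm2 <- function(lx, w, p_init, max_iter, tol,
                                sigma_min = 0) {
  y <- lx                       # Lawless works on log-samples
  sw <- sum(w)
  y_bar_w <- sum(w * y) / sw
  y_max <- max(y[w > 0])

  # one cycle of the Lawless alternation: p -> k (weighted shape
  # equation) -> sigma (weighted scale equation) -> p = 1/(sigma sqrt(k))
  cycle_full <- function(p) {
    A <- weighted_profile_given_p(lx, w, p)$A
    k <- solve_shape_nu(A)
    if (sigma_min > 0) k <- min(k, 1 / (p * sigma_min)^2)
    R <- function(s) {
      lawless_S(y, s * sqrt(k), w = w)$ratio - y_bar_w - s / sqrt(k)
    }
    s_hi <- sqrt(k) * (y_max - y_bar_w)
    sigma <- stats::uniroot(R, lower = 1e-12, upper = s_hi * 1.01,
                            tol = 1e-12)$root
    if (sigma_min > 0) sigma <- max(sigma, sigma_min)
    list(p = min(max(1 / (sigma * sqrt(k)), 0.05), 100), k = k,
         sigma = sigma, sigma_hi = s_hi)
  }
  cycle <- function(p) cycle_full(p)$p

  # the alternation converges linearly (and can drift very slowly far
  # from the optimum); Aitken extrapolation on log p accelerates it, and
  # a candidate step is only accepted when it does not decrease the
  # weighted log-likelihood, which also guards against extrapolating to
  # a spurious quasi-stationary region
  wll_at <- function(p) weighted_profile_given_p(lx, w, p, sigma_min)$wll
  p <- p_init
  wll_old <- wll_at(p)
  for (it in seq_len(max_iter)) {
    p1 <- cycle(p)
    p2 <- cycle(p1)
    den <- log(p2) - 2 * log(p1) + log(p)
    pA <- if (abs(den) > 1e-14) exp(log(p) - (log(p1) - log(p))^2 / den)
          else p2
    p_new <- p2
    wll_new <- wll_at(p2)
    if (is.finite(pA) && pA > 0) {
      pC <- tryCatch(cycle(pA), error = function(e) NA_real_)
      if (is.finite(pC) && pC > 0) {
        wll_C <- wll_at(pC)
        if (is.finite(wll_C) && wll_C >= wll_new) {
          p_new <- pC
          wll_new <- wll_C
        }
      }
    }
    p <- p_new
    if (is.finite(wll_old) && abs(wll_new - wll_old) < tol) break
    wll_old <- wll_new
  }
  # final cycle so the returned sigma is an exact root of the scale
  # equation for the returned k
  fin <- cycle_full(p)
  k <- fin$k; sigma <- fin$sigma
  mu <- sigma * sqrt(k) * lawless_S(y, sigma * sqrt(k), w = w)$log_S0
  params <- tryCatch(from_lawless(lawless_params(mu, sigma, k)),
                     error = function(e)
                       stop("component collapse in M-step", call. = FALSE))
  list(params = params,
       wll = weighted_profile_given_p(lx, w, params$p, sigma_min)$wll,
       sigma = sigma, k = k, sigma_hi = fin$sigma_hi)
}

fit_component_constrained <- function(lx, w, constraint, sigma_min = 0) {
  if (constraint == "p2_nu1") {          # Rayleigh: a^2 = sum(w x^2)/sum(w)
    lw <- log(w); keep <- is.finite(lw)
    log_a <- 0.5 * (logsumexp((2 * lx + lw)[keep]) - log(sum(w)))
    params <- gg_params(exp(log_a), 1, 2)
    prof_wll <- {
      sw <- sum(w)
      sw * log(2) - sw * 2 * log_a + 1 * sum(w * lx) -
        exp(logsumexp((2 * (lx - log_a) + lw)[keep]))
    }
    return(list(params = params, wll = prof_wll))
  }
  p <- if (constraint == "p_fixed_1") 1 else 2
  prof <- weighted_profile_given_p(lx, w, p, sigma_min)
  list(params = gg_params(exp(prof$log_a), prof$nu, p), wll = prof$wll)
}

#' Maximization step for the component parameters (GGMM1 variant)
#'
#' For each component j, maximizes the responsibility-weighted expected
#' log-likelihood over \eqn{p_j} by Nelder-Mead, with \eqn{\hat a_j} and
#' \eqn{\hat\nu_j} profiled out exactly: \eqn{\hat\nu_j} solves the
#' weighted shape equation \eqn{\log\nu - \Psi(\nu) = A_j} (Brent inside
#' the bracket \eqn{(1/(2A_j), 1/A_j)}) and
#' \eqn{\hat a_j^{p_j} = \sum_i\gamma_{ij}x_i^{p_j} / (\nu_j\sum_i\gamma_{ij})}.
#'
#' @param samples Positive numeric vector.
#' @param resp N x J responsibility matrix.
#' @param model Current \code{"gg_mixture"} (supplies warm starts and the
#'   constraint).
#' @param max_iter,tol Inner Nelder-Mead budget and tolerance.
#' @param sigma_min Component log-scale width floor, as in
#'   [fit_mixture()].
#' @return List of updated [gg_params()], one per component.
#' @export
m_step_ggmm1 <- function(samples, resp, model, max_iter = 100, tol = 1e-8,
                         sigma_min = 0) {
  x <- check_samples(samples)
  lx <- log(x)
  lapply(seq_len(model$J), function(j) {
    w <- resp[, j]
    if (sum(w) < 2) stop("component collapse in M-step", call. = FALSE)
    if (model$constraint != "free")
      fit_component_constrained(lx, w, model$constraint, sigma_min)$params
    else
      fit_component_ggmm1(lx, w, model$components[[j]]$p, max_iter,
                          tol, sigma_min)$params
  })
}

#' Maximization step for the component parameters (GGMM2 variant)
#'
#' Works in the Lawless parametrization: from the current \eqn{p_j},
#' \eqn{k_j} is obtained from the weighted shape equation, then
#' \eqn{\sigma_j} from the weighted scale equation
#' \eqn{\tilde S_1/\tilde S_0 - \bar y_w - \sigma/\sqrt{k} = 0}
#' (root bracketed in \eqn{(0, \sqrt{k}(y_{\max} - \bar y_w))}), the two
#' alternated until the weighted log-likelihood change falls below
#' \code{tol}; finally \eqn{\mu_j = \sigma_j\sqrt{k_j}\log\tilde S_0}.
#'
#' @inheritParams m_step_ggmm1
#' @return List of updated [gg_params()], one per component.
#' @export
m_step_ggmm2 <- function(samples, resp, model, max_iter = 100, tol = 1e-8,
                         sigma_min = 0) {
  x <- check_samples(samples)
  lx <- log(x)
  lapply(seq_len(model$J), function(j) {
    w <- resp[, j]
    if (sum(w) < 2) stop("component collapse in M-step", call. = FALSE)
    if (model$constraint != "free")
      fit_component_constrained(lx, w, model$constraint, sigma_min)$params
    else
      fit_component_ggmm2(lx, w, model$components[[j]]$p, max_iter,
                          tol, sigma_min)$params
  })
}

mixture_constraint <- function(method) {
  switch(method,
         ggmm1 = "free", ggmm2 = "free",
         gmm = "p_fixed_1", nmm = "p_fixed_2", rmm = "p2_nu1")
}

init_mixture <- function(x, J, method, jitter = 0) {
  constraint <- mixture_constraint(method)
  xs <- sort(x)
  n <- length(xs)
  groups <- if (J == 1L) list(xs)
    else split(xs, cut(seq_len(n), J, labels = FALSE))
  comps <- lapply(groups, function(g) {
    lx <- log(g)
    w <- rep(1, length(g))
    pr <- tryCatch({
      if (constraint == "free") {
        f <- fit_ml_proposed(g)
        f$params
      } else {
        fit_component_constrained(lx, w, constraint)$params
      }
    }, error = function(e)
      gg_params(exp(mean(lx)), 1, if (constraint == "p_fixed_2" ||
                                      constraint == "p2_nu1") 2 else 1))
    if (jitter > 0) {
      j_a <- exp(stats::runif(1, -jitter, jitter))
      j_nu <- exp(stats::runif(1, -jitter, jitter))
      j_p <- exp(stats::runif(1, -jitter, jitter))
      pr <- switch(constraint,
                   free = gg_params(pr$a * j_a, pr$nu * j_nu, pr$p * j_p),
                   p_fixed_1 = gg_params(pr$a * j_a, pr$nu * j_nu, 1),
                   p_fixed_2 = gg_params(pr$a * j_a, pr$nu * j_nu, 2),
                   p2_nu1 = gg_params(pr$a * j_a, 1, 2))
    }
    pr
  })
  new_gg_mixture(rep(1 / J, J), comps, method, constraint)
}

sort_mixture <- function(model, gamma = NULL) {
  means <- vapply(model$components, gg_mean, 0)
  nus <- vapply(model$components, function(p) p$nu, 0)
  ord <- order(means, nus)
  model$weights <- model$weights[ord]
  model$components <- model$components[ord]
  if (!is.null(gamma)) model$responsibilities <- gamma[, ord, drop = FALSE]
  model
}

#' Fit a J-component mixture of Generalized Gamma distributions by EM
#'
#' Alternates the expectation step ([e_step()]) with the weight update
#' ([update_weights()]) and one of the M-step variants until the data
#' log-likelihood changes by less than \code{tol} or \code{max_iter}
#' iterations elapse. Methods:
#' \describe{
#'   \item{ggmm1}{free GG components, Nelder-Mead over each \eqn{p_j}}
#'   \item{ggmm2}{free GG components, iterative Lawless shape/scale
#'     equations}
#'   \item{gmm}{Gamma mixture: \eqn{p_j} pinned at 1}
#'   \item{nmm}{Nakagami mixture: \eqn{p_j} pinned at 2}
#'   \item{rmm}{Rayleigh mixture: \eqn{p_j = 2}, \eqn{\nu_j = 1}}
#' }
#' Initialization splits the sorted samples into J quantile groups, fits
#' each singly, and starts from equal weights. A component whose
#' responsibility mass drops below 2 samples triggers a seeded jittered
#' re-initialization (up to 3 retries). Components are reported sorted by
#' increasing mean \eqn{a\Gamma(\nu + 1/p)/\Gamma(\nu)} (ties broken by
#' \eqn{\nu}).
#'
#' @param samples Positive numeric vector.
#' @param J Number of components, \eqn{\ge 1}.
#' @param method One of \code{"ggmm1"}, \code{"ggmm2"}, \code{"gmm"},
#'   \code{"nmm"}, \code{"rmm"}.
#' @param init Optional \code{"gg_mixture"} starting model.
#' @param max_iter Maximum EM iterations (default 100).
#' @param tol Absolute data log-likelihood tolerance (default 1e-8).
#' @param seed Optional integer seed (controls restart jitter).
#' @param sigma_min Floor on each component's log-scale width
#'   \eqn{1/(p_j\sqrt{\nu_j})} (default 0.01). Components narrower than
#'   this are indistinguishable from the intensity-quantization atoms of
#'   8-bit image data, the degenerate likelihood spikes of continuous
#'   mixtures on discretized samples; the floor turns the M-step into a
#'   constrained maximization and keeps EM monotone. Set to 0 to disable.
#' @return A converged \code{"gg_mixture"} with \code{loglik_trace},
#'   \code{responsibilities} (N x J), and convergence metadata.
#' @export
fit_mixture <- function(samples, J, method = c("ggmm1", "ggmm2", "gmm",
                                               "nmm", "rmm"),
                        init = NULL, max_iter = 100, tol = 1e-8,
                        seed = NULL, sigma_min = 0.01) {
  method <- match.arg(method)
  x <- check_samples(samples)
  if (J < 1) stop("J must be >= 1", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  constraint <- mixture_constraint(method)

  # a one-component mixture is exactly a single-component fit
  if (J == 1L) {
    comp <- switch(method,
      ggmm1 = fit_ml_proposed(x, max_iter = max_iter, tol = tol)$params,
      ggmm2 = fit_component_ggmm2(log(x), rep(1, length(x)), 1,
                                  max_iter, tol, sigma_min)$params,
      fit_component_constrained(log(x), rep(1, length(x)),
                                constraint)$params)
    model <- new_gg_mixture(1, list(comp), method, constraint)
    es <- e_step(x, model)
    model$loglik <- es$loglik
    model$loglik_trace <- es$loglik
    model$iterations <- 1L
    model$converged <- TRUE
    model$responsibilities <- es$gamma
    return(model)
  }

  run_em <- function(model) {
    trace <- numeric(0)
    es <- e_step(x, model)
    ll_old <- es$loglik
    trace <- c(trace, ll_old)
    converged <- FALSE
    iter <- 0L
    for (iter in seq_len(max_iter)) {
      if (any(colSums(es$gamma) < 2)) stop("component collapse",
                                           call. = FALSE)
      model$weights <- suppressWarnings(update_weights(es$gamma))
      model$components <- if (method == "ggmm2")
        m_step_ggmm2(x, es$gamma, model, tol = tol, sigma_min = sigma_min)
      else
        m_step_ggmm1(x, es$gamma, model, tol = tol, sigma_min = sigma_min)
      es <- e_step(x, model)
      trace <- c(trace, es$loglik)
      if (abs(es$loglik - ll_old) < tol) {
        converged <- TRUE
        ll_old <- es$loglik
        break
      }
      ll_old <- es$loglik
    }
    model$loglik <- ll_old
    model$loglik_trace <- trace
    model$iterations <- iter
    model$converged <- converged
    sort_mixture(model, es$gamma)
  }

  attempts <- if (is.null(init)) 4L else 1L
  last_err <- NULL
  for (att in seq_len(attempts)) {
    model0 <- if (!is.null(init)) init
      else init_mixture(x, J, method, jitter = if (att == 1L) 0 else 0.25)
    res <- tryCatch(run_em(model0), error = function(e) e)
    if (!inherits(res, "error")) return(res)
    last_err <- res
  }
  stop("EM failed after re-initialization retries: ",
       conditionMessage(last_err), call. = FALSE)
}

#' Serialize a mixture model to/from JSON
#'
#' Format: \code{{"weights":[...], "components":[{"a":..,"nu":..,"p":..},...],
#' "method":.., "loglik":..}}.
#'
#' @param model A \code{"gg_mixture"} object.
#' @param json JSON string or file path.
#' @return \code{model_to_json}: JSON string; \code{model_from_json}: a
#'   \code{"gg_mixture"}.
#' @export
model_to_json <- function(model) {
  stopifnot(inherits(model, "gg_mixture"))
  jsonlite::toJSON(list(
    weights = model$weights,
    components = lapply(model$components, unclass),
    method = model$method,
    constraint = model$constraint,
    loglik = model$loglik), auto_unbox = TRUE, digits = NA)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  comps <- lapply(obj$components, function(cc) gg_params(cc$a, cc$nu, cc$p))
  m <- new_gg_mixture(obj$weights, comps,
                      method = obj$method %||% "manual",
                      constraint = obj$constraint %||% "free")
  m$loglik <- obj$loglik %||% NA_real_
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
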