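# Posterior tissue-probability maps and their applications: structure
# tensors, probability-driven oriented anisotropic diffusion (POSRAD),
# loopy-belief-propagation spatial coherence, and max-posterior labels.

# mirror (Neumann) index vector of length n shifted by d
mirror_idx <- function(n, d) {
  i <- seq_len(n) + d
  i[i < 1] <- 2 - i[i < 1]
  i[i > n] <- 2 * n - i[i > n]
  i
}

# separable Gaussian convolution with mirror boundaries
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  tmp <- matrix(0, H, W)
  for (d in -r:r) tmp <- tmp + k[d + r + 1] * m[mirror_idx(H, d), ]
  out <- matrix(0, H, W)
  for (d in -r:r) out <- out + k[d + r + 1] * tmp[, mirror_idx(W, d)]
  out
}

# central-difference gradients with mirror boundaries; rows = y, cols = x
grad_xy <- function(m) {
  H <- nrow(m); W <- ncol(m)
  list(gx = (m[, mirror_idx(W, 1)] - m[, mirror_idx(W, -1)]) / 2,
       gy = (m[mirror_idx(H, 1), ] - m[mirror_idx(H, -1), ]) / 2)
}

#' Per-pixel posterior tissue-class probabilities
#'
#' Applies Bayes' rule with the mixture weights and component densities
#' at every pixel. Pixels with value 0 (outside the GG support, e.g.
#' outside the scan fan) are floored to the smallest positive observed
#' intensity before density evaluation and flagged.
#'
#' @param image Numeric matrix of intensities.
#' @param model A \code{"gg_mixture"} with components sorted by mean (as
#'   returned by [fit_mixture()]).
#' @return A \code{"posterior_map"}: \code{prob} (height x width x J
#'   array, slices summing to 1 per pixel), \code{floored} (logical
#'   matrix of adjusted pixels), \code{model}.
#' @export
posterior_map <- function(image, model) {
  stopifnot(is.matrix(image), inherits(model, "gg_mixture"))
  v <- as.vector(image)
  floored <- v <= 0
  if (all(floored)) stop("image has no positive pixels", call. = FALSE)
  v[floored] <- min(v[!floored])
  es <- e_step(v, model)
  prob <- array(es$gamma, dim = c(nrow(image), ncol(image), model$J))
  structure(list(prob = prob,
                 floored = matrix(floored, nrow(image), ncol(image)),
                 model = model),
            class = "posterior_map")
}

as_prob_array <- function(pmap) {
  if (inherits(pmap, "posterior_map")) pmap$prob
  else if (is.array(pmap) && length(dim(pmap)) == 3) pmap
  else stop("expected a posterior_map or a H x W x J array", call. = FALSE)
}

#' Structure tensors of the class-probability maps
#'
#' For each class j,
#' \eqn{T_j = G_\sigma * (\nabla_\sigma p_j \, \nabla_\sigma p_j^T)}: the
#' Gaussian-smoothed outer product of the Gaussian-smoothed probability
#' gradient. A single scale \eqn{\sigma} is shared by the gradient
#' smoothing and the tensor smoothing.
#'
#' @param pmap A [posterior_map()] or probability array.
#' @param sigma Gaussian scale in pixels (> 0).
#' @return A \code{"structure_tensor_field"}: arrays \code{t11},
#'   \code{t12}, \code{t22}, eigenvalues \code{lambda1 >= lambda2 >= 0},
#'   leading eigenvectors \code{v1x}, \code{v1y}, and the smoothed
#'   gradients \code{gx}, \code{gy} (all height x width x J).
#' @export
structure_tensors <- function(pmap, sigma = 1.5) {
  prob <- as_prob_array(pmap)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  H <- dim(prob)[1]; W <- dim(prob)[2]; J <- dim(prob)[3]
  z <- array(0, c(H, W, J))
  out <- list(t11 = z, t12 = z, t22 = z, lambda1 = z, lambda2 = z,
              v1x = z, v1y = z, gx = z, gy = z, sigma = sigma)
  for (j in seq_len(J)) {
    g <- grad_xy(gaussian_blur(prob[, , j], sigma))
    out$gx[, , j] <- g$gx; out$gy[, , j] <- g$gy
    t11 <- gaussian_blur(g$gx * g$gx, sigma)
    t12 <- gaussian_blur(g$gx * g$gy, sigma)
    t22 <- gaussian_blur(g$gy * g$gy, sigma)
    tr2 <- (t11 + t22) / 2
    disc <- sqrt(pmax((t11 - t22)^2 / 4 + t12^2, 0))
    l1 <- tr2 + disc; l2 <- pmax(tr2 - disc, 0)
    # leading eigenvector; for (near-)isotropic tensors default to e_x
    vx <- t12; vy <- l1 - t11
    deg <- abs(vx) + abs(vy) < 1e-30
    vx[deg] <- 1; vy[deg] <- 0
    nrm <- sqrt(vx^2 + vy^2)
    out$t11[, , j] <- t11; out$t12[, , j] <- t12; out$t22[, , j] <- t22
    out$lambda1[, , j] <- l1; out$lambda2[, , j] <- l2
    out$v1x[, , j] <- vx / nrm; out$v1y[, , j] <- vy / nrm
  }
  class(out) <- "structure_tensor_field"
  out
}

#' Probability-driven oriented speckle-reducing anisotropic diffusion
#'
#' Builds a per-pixel diffusion tensor from the structure tensors of the
#' class-posterior maps: at each pixel the class
#' \eqn{\hat j = \arg\max_j \lambda_1^j} (the most probable boundary
#' orientation) supplies the eigenbasis \eqn{(e_1, e_2)}, and the
#' diffusivities are
#' \eqn{\lambda_1 = 1 - \|\nabla_{e_1,\sigma} p_{\hat j}\|^2}
#' (clamped to \eqn{[0,1]}) across the boundary and \eqn{\lambda_2 = 1}
#' along it. Where the probability field is flat the tensor is the
#' identity and the iteration reduces to isotropic (heat) diffusion. The
#' PDE \eqn{\partial u/\partial t = \mathrm{div}(D\nabla u)} is advanced
#' by an explicit finite-volume scheme with zero-flux (Neumann)
#' boundaries, which conserves the total intensity exactly.
#'
#' @param image Numeric matrix to filter.
#' @param pmap A [posterior_map()] or probability array for the same
#'   image.
#' @param sigma Gaussian scale of the structure tensors (default 1.5 px).
#' @param n_iter Number of explicit iterations (default 40); 0 returns
#'   the input unchanged.
#' @param dt Time step; must satisfy the 2-D explicit stability bound
#'   \code{dt <= 0.25} (default 0.2).
#' @return The filtered image matrix.
#' @export
posrad_filter <- function(image, pmap, sigma = 1.5, n_iter = 40, dt = 0.2) {
  stopifnot(is.matrix(image))
  prob <- as_prob_array(pmap)
  if (n_iter < 0) stop("n_iter must be >= 0", call. = FALSE)
  if (dt <= 0 || dt > 0.25)
    stop("dt must lie in (0, 0.25] for explicit stability", call. = FALSE)
  if (n_iter == 0) return(image)
  H <- nrow(image); W <- ncol(image)
  st <- structure_tensors(prob, sigma)
  J <- dim(prob)[3]

  # class with maximal lambda1 per pixel
  jhat <- apply(st$lambda1, c(1, 2), which.max)
  pick <- function(arr) {
    m <- matrix(0, H, W)
    for (j in seq_len(J)) {
      sel <- jhat == j
      m[sel] <- arr[, , j][sel]
    }
    m
  }
  e1x <- pick(st$v1x); e1y <- pick(st$v1y)
  dp <- pick(st$gx) * e1x + pick(st$gy) * e1y   # directional derivative
  l1 <- pmin(pmax(1 - dp^2, 0), 1)
  # D = l1 e1 e1' + e2 e2', with e2 = (-e1y, e1x)
  d11 <- l1 * e1x^2 + e1y^2
  d12 <- l1 * e1x * e1y - e1y * e1x
  d22 <- l1 * e1y^2 + e1x^2

  u <- image
  for (it in seq_len(n_iter)) {
    g <- grad_xy(u)
    # horizontal interface fluxes between columns x and x+1
    fx <- (d11[, -W] + d11[, -1]) / 2 * (u[, -1] - u[, -W]) +
      (d12[, -W] + d12[, -1]) / 2 * (g$gy[, -W] + g$gy[, -1]) / 2
    # vertical interface fluxes between rows y and y+1
    fy <- (d22[-H, ] + d22[-1, ]) / 2 * (u[-1, ] - u[-H, ]) +
      (d12[-H, ] + d12[-1, ]) / 2 * (g$gx[-H, ] + g$gx[-1, ]) / 2
    div <- matrix(0, H, W)
    div[, -W] <- div[, -W] + fx
    div[, -1] <- div[, -1] - fx
    div[-H, ] <- div[-H, ] + fy
    div[-1, ] <- div[-1, ] - fy
    u <- u + dt * div
  }
  u
}

floor_log <- function(p, eps = 1e-12) log(pmax(p, eps))

#' Energy of a labeling under the spatial-coherence model
#'
#' \eqn{V(Z) = \sum_i V_1(Z_i) + \sum_i\sum_{k\in\eta(i)} V_2(Z_i, Z_k)}
#' on the 4-connected grid, with unary cost
#' \eqn{V_1(Z_i) = -\log p(Z_i = j \mid x_i, \Theta)} and, by default, the
#' data-driven pairwise cost
#' \eqn{V_2(Z_i, Z_k) = -\log p(Z_k = Z_i \mid x_k, \Theta)} (each
#' neighbor is charged the negative log-posterior, at its own pixel, of
#' the center's label). \code{pairwise = "potts"} substitutes a standard
#' Potts penalty \eqn{w\,[Z_i \ne Z_k]}.
#'
#' @param labels Integer matrix of class labels (1..J).
#' @param pmap A [posterior_map()] or probability array.
#' @param pairwise \code{"data"} (default) or \code{"potts"}.
#' @param potts_weight Potts penalty weight.
#' @param pair_weight Multiplier on the pairwise term (0 removes it).
#' @return The scalar energy.
#' @export
lbp_energy <- function(labels, pmap, pairwise = c("data", "potts"),
                       potts_weight = 1, pair_weight = 1) {
  pairwise <- match.arg(pairwise)
  prob <- as_prob_array(pmap)
  H <- dim(prob)[1]; W <- dim(prob)[2]; J <- dim(prob)[3]
  stopifnot(all(dim(labels) == c(H, W)), all(labels %in% seq_len(J)))
  lp <- array(floor_log(prob), c(H, W, J))
  idx <- cbind(as.vector(row(labels)), as.vector(col(labels)),
               as.vector(labels))
  e <- -sum(lp[idx])
  pair <- function(zi, pk_row, pk_col) {
    if (pairwise == "data")
      -lp[cbind(pk_row, pk_col, zi)]
    else
      potts_weight * (zi != labels[cbind(pk_row, pk_col)])
  }
  # neighbors: for each pixel i, sum over its 4-neighborhood
  for (sh in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
    ri <- seq_len(H); ci <- seq_len(W)
    rk <- ri + sh[1]; ck <- ci + sh[2]
    vr <- rk >= 1 & rk <= H; vc <- ck >= 1 & ck <= W
    ii <- expand.grid(r = ri[vr], c = ci[vc])
    kk <- data.frame(r = ii$r + sh[1], c = ii$c + sh[2])
    zi <- labels[cbind(ii$r, ii$c)]
    e <- e + pair_weight * sum(pair(zi, kk$r, kk$c))
  }
  e
}

#' Spatially coherent posteriors by loopy belief propagation
#'
#' Min-sum message passing on the 4-connected pixel grid with the energy
#' of [lbp_energy()]. Messages are updated synchronously with damping
#' (0.5 by default) for a fixed iteration budget; convergence is not
#' guaranteed on a cyclic graph, so the message change at the last sweep
#' is reported rather than enforced. Beliefs are renormalized to per-pixel
#' probabilities.
#'
#' @param pmap A [posterior_map()] or probability array.
#' @param n_iter Number of synchronous sweeps (default 30).
#' @param pairwise,potts_weight,pair_weight As in [lbp_energy()];
#'   \code{pair_weight = 0} reduces the output to the input posteriors.
#' @param damping Message damping factor in \eqn{[0, 1)} (default 0.5).
#' @return A \code{"posterior_map"} whose \code{prob} holds the beliefs;
#'   attribute \code{"message_delta"} carries the final maximum message
#'   change.
#' @export
lbp_coherence <- function(pmap, n_iter = 30, pairwise = c("data", "potts"),
                          potts_weight = 1, pair_weight = 1,
                          damping = 0.5) {
  pairwise <- match.arg(pairwise)
  prob <- as_prob_array(pmap)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  H <- dim(prob)[1]; W <- dim(prob)[2]; J <- dim(prob)[3]
  V1 <- -array(floor_log(prob), c(H, W, J))

  # msg[[d]][r, c, z] = message INTO pixel (r, c) from its neighbor at
  # offset offs[[d]]; pixels whose neighbor falls outside the grid keep 0
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  opp <- c(2L, 1L, 4L, 3L)
  msg <- rep(list(array(0, c(H, W, J))), 4)
  from_neighbor <- function(a, off) {
    # receiver (r, c) reads the value computed at (r + off1, c + off2)
    out <- array(0, dim(a))
    rs <- seq_len(H) + off[1]; cs <- seq_len(W) + off[2]
    vr <- rs >= 1 & rs <= H; vc <- cs >= 1 & cs <= W
    out[vr, vc, ] <- a[rs[vr], cs[vc], , drop = FALSE]
    out
  }
  delta <- Inf
  for (it in seq_len(n_iter)) {
    total_in <- msg[[1]] + msg[[2]] + msg[[3]] + msg[[4]]
    newmsg <- msg
    for (d in seq_along(offs)) {
      # at every pixel (acting as the sender k):
      # base_k(z_k) = V1_k(z_k) + sum of msgs into k except the one from
      # the receiver (which sits at offset -off, i.e. direction opp[d])
      base_k <- V1 + total_in - msg[[opp[d]]]
      mn <- apply(base_k, c(1, 2), min)
      raw_at_k <- if (pairwise == "data") {
        # pairwise term depends only on z_i, evaluated at pixel k:
        # m(z_i) = pair_weight * V1_k(z_i) + min_z base_k(z)
        pair_weight * V1 + array(mn, c(H, W, J))
      } else {
        # Potts: the energy sums over directed pairs, so each undirected
        # edge carries 2w; m(z_i) = min(base_k(z_i), min_z base_k(z) + 2w)
        pmin(base_k, array(mn + 2 * pair_weight * potts_weight,
                           c(H, W, J)))
      }
      # normalize (min-subtract) at the sender, then route to receivers
      raw_at_k <- raw_at_k -
        array(apply(raw_at_k, c(1, 2), min), c(H, W, J))
      newmsg[[d]] <- damping * msg[[d]] +
        (1 - damping) * from_neighbor(raw_at_k, offs[[d]])
    }
    delta <- max(vapply(1:4, function(d) max(abs(newmsg[[d]] - msg[[d]])),
                        0))
    msg <- newmsg
  }
  beliefs <- V1 + msg[[1]] + msg[[2]] + msg[[3]] + msg[[4]]
  b <- exp(-(beliefs - array(apply(beliefs, c(1, 2), min), c(H, W, J))))
  b <- b / array(apply(b, c(1, 2), sum), c(H, W, J))
  out <- structure(list(prob = b,
                        floored = if (inherits(pmap, "posterior_map"))
                          pmap$floored else NULL,
                        model = if (inherits(pmap, "posterior_map"))
                          pmap$model else NULL),
                   class = "posterior_map")
  attr(out, "message_delta") <- delta
  out
}

#' Maximum-posterior (or maximum-belief) classification
#'
#' Assigns each pixel the class with the highest probability; ties are
#' broken toward the lower class index, i.e. the component with the
#' smaller mean (components are sorted by mean).
#'
#' @param pmap A [posterior_map()] or probability array.
#' @return Integer matrix of class labels (1..J).
#' @export
classify_max_posterior <- function(pmap) {
  prob <- as_prob_array(pmap)
  apply(prob, c(1, 2), which.max)
}
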