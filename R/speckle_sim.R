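# Synthetic data: GG estimator-validation experiments and B-mode speckle
# phantoms built from the random-walk scatterer model with a polar (fan)
# acquisition geometry and linear interpolation to the Cartesian grid.

#' Polar scan geometry for the phantom simulator
#'
#' Describes a fan of sample sites: the probe apex sits above the image,
#' the fan opens symmetrically about the vertical, and sites are uniform
#' in angle and radius. The fan is sized automatically so every sample
#' site lies inside the image.
#'
#' @param n_angular Number of angular samples (default 50).
#' @param n_radial Number of radial samples (default 100).
#' @param width,height Image size in pixels (default 128 x 128).
#' @param apex_offset Apex height above the top edge, as a fraction of the
#'   image height (default 0.25). Larger values flatten the fan.
#' @return A \code{"scan_geometry"} object with the apex position, the
#'   angular aperture and the radial range.
#' @export
scan_geometry <- function(n_angular = 50, n_radial = 100,
                          width = 128, height = 128, apex_offset = 0.25) {
  if (n_angular < 2 || n_radial < 2)
    stop("need at least 2 angular and 2 radial samples", call. = FALSE)
  cx <- (1 + width) / 2
  cy <- -apex_offset * height
  # inscribe the fan: aperture limited by the bottom corners, radii by
  # the top and bottom edges, so every sample site lies inside the image
  th_max <- atan2(width - cx, height - cy)
  r_min <- (1 - cy) / cos(th_max)
  r_max <- height - cy
  structure(list(n_angular = as.integer(n_angular),
                 n_radial = as.integer(n_radial),
                 width = as.integer(width), height = as.integer(height),
                 apex = c(x = cx, y = cy),
                 theta = seq(-th_max, th_max, length.out = n_angular),
                 r = seq(r_min, r_max, length.out = n_radial)),
            class = "scan_geometry")
}

#' Scatterer configuration for the speckle model
#'
#' @param n_scatterers Effective scatterers per resolution cell (a single
#'   count, or a matrix matching the image to vary it spatially).
#' @param amp_sigma Standard deviation of the zero-mean Normal scatterer
#'   amplitudes (default 8, in image intensity units).
#' @param seed Optional integer seed controlling the rendered speckle.
#' @return A \code{"speckle_config"} object.
#' @export
speckle_config <- function(n_scatterers = 20, amp_sigma = 8, seed = NULL) {
  if (any(n_scatterers < 1)) stop("n_scatterers must be >= 1", call. = FALSE)
  if (amp_sigma <= 0) stop("amp_sigma must be positive", call. = FALSE)
  structure(list(n_scatterers = n_scatterers, amp_sigma = amp_sigma,
                 seed = seed), class = "speckle_config")
}

#' Draw speckle envelope values from the random-walk scatterer model
#'
#' Each envelope value is the modulus of a complex phasor sum: a
#' deterministic (specular) component equal to the local echogenicity on
#' the real axis, plus \code{N} scatterer phasors with Normal amplitudes
#' and phases uniform on \eqn{[0, 2\pi]}. The carrier frequency drops out
#' of the envelope under the quadrature decomposition, so it is not
#' simulated. With zero echogenicity and many scatterers the output is
#' Rayleigh (fully formed speckle); a dominant specular component yields
#' a Rician envelope (fully resolved speckle).
#'
#' @param echogenicity Specular amplitude(s); vector of length M.
#' @param N Scatterer count(s); scalar or vector of length M.
#' @param amp_sigma Scatterer amplitude standard deviation.
#' @return Numeric vector of M non-negative envelope values (one
#'   independent phasor sum per element, drawn from the current RNG
#'   stream).
#' @export
speckle_envelope <- function(echogenicity, N, amp_sigma) {
  M <- length(echogenicity)
  N <- as.integer(rep_len(N, M))
  if (any(N < 1)) stop("N must be >= 1", call. = FALSE)
  if (amp_sigma <= 0) stop("amp_sigma must be positive", call. = FALSE)
  total <- sum(N)
  alpha <- stats::rnorm(total, 0, amp_sigma)
  phi <- stats::runif(total, 0, 2 * pi)
  idx <- rep.int(seq_len(M), N)
  re <- echogenicity + as.vector(rowsum(alpha * cos(phi), idx))
  im <- as.vector(rowsum(alpha * sin(phi), idx))
  sqrt(re^2 + im^2)
}

#' Render a synthetic B-mode speckle phantom
#'
#' Builds a scene (echogenicity map and scatterer-density map), corrupts
#' each polar sample site with [speckle_envelope()], and rearranges the
#' fan into Cartesian coordinates by bilinear interpolation on the
#' structured \eqn{(r, \theta)} grid. Pixels outside the fan are set to 0
#' and flagged in the mask.
#'
#' Scene kinds:
#' \describe{
#'   \item{gradient}{echogenicity ramps linearly 0 to 255 left to right
#'     (increasingly echolucent tissue with a growing specular component);
#'     constant scatterer count from \code{config}.}
#'   \item{density}{homogeneous zero echogenicity (no deterministic
#'     component); scatterer count decreases linearly 256 to 1 left to
#'     right, sweeping fully formed to partially formed speckle.}
#'   \item{custom}{user scene: pass \code{echo_map} and optionally
#'     \code{density_map} matrices of size height x width.}
#' }
#'
#' @param kind One of \code{"gradient"}, \code{"density"}, \code{"custom"}.
#' @param geometry A [scan_geometry()] object.
#' @param config A [speckle_config()] object.
#' @param echo_map,density_map Scene matrices for \code{kind = "custom"}.
#' @return A \code{"speckle_phantom"} object: \code{image} (height x
#'   width, 8-bit range, 0 outside the fan), \code{raw} (unclipped
#'   interpolated envelope), \code{mask} (TRUE inside the fan),
#'   \code{echo_map}, \code{density_map}, \code{clip_fraction} (fraction
#'   of in-fan pixels clipped at 255), the polar sample values, and the
#'   inputs.
#' @export
render_phantom <- function(kind = c("gradient", "density", "custom"),
                           geometry = scan_geometry(),
                           config = speckle_config(),
                           echo_map = NULL, density_map = NULL) {
  kind <- match.arg(kind)
  W <- geometry$width; H <- geometry$height
  ramp <- matrix(rep(seq(0, 255, length.out = W), each = H), H, W)
  if (kind == "gradient") {
    echo_map <- ramp
    density_map <- matrix(config$n_scatterers[1], H, W)
  } else if (kind == "density") {
    echo_map <- matrix(0, H, W)
    density_map <- matrix(rep(round(seq(256, 1, length.out = W)), each = H),
                          H, W)
  } else {
    if (is.null(echo_map)) stop("custom phantom needs echo_map", call. = FALSE)
    if (is.null(density_map)) density_map <- matrix(config$n_scatterers[1],
                                                    H, W)
    stopifnot(all(dim(echo_map) == c(H, W)),
              all(dim(density_map) == c(H, W)))
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  # polar sample sites (theta varies fastest)
  th <- rep(geometry$theta, times = geometry$n_radial)
  rr <- rep(geometry$r, each = geometry$n_angular)
  sx <- geometry$apex["x"] + rr * sin(th)
  sy <- geometry$apex["y"] + rr * cos(th)
  px <- pmin(pmax(round(sx), 1), W)
  py <- pmin(pmax(round(sy), 1), H)
  site <- cbind(py, px)
  env <- speckle_envelope(echo_map[site], density_map[site],
                          config$amp_sigma)
  samp <- matrix(env, geometry$n_angular, geometry$n_radial)

  # Cartesian rearrangement: bilinear interpolation on the (theta, r) grid
  gx <- matrix(rep(seq_len(W), each = H), H, W)
  gy <- matrix(rep(seq_len(H), times = W), H, W)
  dx <- gx - geometry$apex["x"]; dy <- gy - geometry$apex["y"]
  pr <- sqrt(dx^2 + dy^2)
  pth <- atan2(dx, dy)
  fi <- (pth - geometry$theta[1]) / diff(geometry$theta[1:2]) + 1
  fj <- (pr - geometry$r[1]) / diff(geometry$r[1:2]) + 1
  mask <- fi >= 1 & fi <= geometry$n_angular & fj >= 1 &
    fj <= geometry$n_radial
  raw <- matrix(0, H, W)
  i0 <- pmin(floor(fi[mask]), geometry$n_angular - 1L)
  j0 <- pmin(floor(fj[mask]), geometry$n_radial - 1L)
  wi <- fi[mask] - i0; wj <- fj[mask] - j0
  raw[mask] <-
    samp[cbind(i0, j0)] * (1 - wi) * (1 - wj) +
    samp[cbind(i0 + 1L, j0)] * wi * (1 - wj) +
    samp[cbind(i0, j0 + 1L)] * (1 - wi) * wj +
    samp[cbind(i0 + 1L, j0 + 1L)] * wi * wj
  img <- pmin(pmax(raw, 0), 255)
  clip <- sum(raw[mask] > 255) / sum(mask)

  structure(list(image = round(img), raw = raw, mask = mask,
                 echo_map = echo_map, density_map = density_map,
                 polar_samples = samp, clip_fraction = clip,
                 kind = kind, geometry = geometry, config = config),
            class = "speckle_phantom")
}

#' @export
print.speckle_phantom <- function(x, ...) {
  cat(sprintf("Speckle phantom ('%s', %dx%d, %dx%d polar samples)\n",
              x$kind, x$geometry$height, x$geometry$width,
              x$geometry$n_angular, x$geometry$n_radial))
  cat(sprintf("  in-fan pixels: %d, clipped fraction: %.4f\n",
              sum(x$mask), x$clip_fraction))
  invisible(x)
}

#' Positive in-fan pixel intensities of a phantom (or plain image)
#'
#' Convenience accessor used before density fitting: returns the in-fan
#' pixel values, flooring zeros to the smallest positive observed
#' intensity (values of exactly 0 lie outside the GG support).
#'
#' @param x A \code{"speckle_phantom"} or a numeric matrix.
#' @param dither If \code{TRUE}, integer-valued (quantized) intensities
#'   are dequantized with uniform jitter on \eqn{(-0.5, 0.5)} from the
#'   current RNG stream. Recommended when fitting continuous densities to
#'   8-bit data: quantization atoms are exactly the degenerate spikes a
#'   continuous mixture likelihood can exploit. Default \code{FALSE}.
#' @return Positive numeric vector.
#' @export
phantom_samples <- function(x, dither = FALSE) {
  v <- if (inherits(x, "speckle_phantom")) x$image[x$mask] else as.vector(x)
  pos <- v[v > 0]
  if (length(pos) == 0) stop("no positive intensities", call. = FALSE)
  v[v <= 0] <- min(pos)
  if (dither && all(v == round(v))) {
    v <- v + stats::runif(length(v), -0.5, 0.5)
    v[v <= 0.5] <- 0.5
  }
  v
}

#' Replicated synthetic experiments for estimator validation
#'
#' Each replicate draws shape parameters \eqn{\nu, p} independently from
#' a uniform distribution on \code{param_range} (scale fixed at
#' \eqn{a = 1}, which only rescales the data) and generates
#' \code{n_samples} GG draws via the Gamma-power construction.
#'
#' @param n_reps Number of replicates.
#' @param n_samples Sample size per replicate.
#' @param param_range Range of the uniform law for \eqn{\nu} and \eqn{p}
#'   (default \code{c(0.3, 5)}; smaller shapes produce densities that are
#'   unbounded at the origin or have unrealistically heavy tails for
#'   envelope data).
#' @param seed Optional integer seed.
#' @return List of replicates, each a list with \code{params} (the true
#'   [gg_params()]) and \code{sample}.
#' @export
simulate_gg_experiment <- function(n_reps, n_samples,
                                   param_range = c(0.3, 5), seed = NULL) {
  if (n_reps < 1 || n_samples < 1)
    stop("n_reps and n_samples must be >= 1", call. = FALSE)
  if (length(param_range) != 2 || any(param_range <= 0) ||
      diff(param_range) < 0)
    stop("invalid param_range", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_reps), function(i) {
    nu <- stats::runif(1, param_range[1], param_range[2])
    p <- stats::runif(1, param_range[1], param_range[2])
    pr <- gg_params(1, nu, p)
    list(params = pr, sample = gg_sample(n_samples, pr))
  })
}
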