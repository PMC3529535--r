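# Small I/O helpers shared by the command-line interface: sample lists,
# 8-bit grayscale images (PNG / text PGM / TIFF), and fit reports.

#' Read and write whitespace-delimited sample vectors
#'
#' @param path File with positive reals separated by whitespace/newlines.
#' @param x Numeric vector to write (one value per line).
#' @return \code{read_samples}: numeric vector.
#' @export
read_samples <- function(path) {
  x <- scan(path, what = numeric(), quiet = TRUE)
  check_samples(x)
  x
}

#' @rdname read_samples
#' @export
write_samples <- function(x, path) {
  writeLines(format(x, digits = 17, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' Read a grayscale image as an intensity matrix
#'
#' PNG (via the png package), TIFF (via the tiff package, if installed)
#' and ASCII PGM (P2) are supported; color inputs are averaged to gray.
#' PNG/TIFF intensities in \eqn{[0,1]} are rescaled to \eqn{[0,255]}.
#'
#' @param path Image file path.
#' @return Numeric matrix (rows = image rows).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3])], c(1, 2),
                                        mean)
    return(a * 255)
  }
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    a <- tiff::readTIFF(path)
    if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3])], c(1, 2),
                                        mean)
    return(a * 255)
  }
  if (ext == "pgm") {
    txt <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
    if (txt[1] != "P2") stop("only ASCII (P2) PGM supported", call. = FALSE)
    w <- as.integer(txt[2]); h <- as.integer(txt[3])
    vals <- as.numeric(txt[-(1:4)])
    return(matrix(vals, h, w, byrow = TRUE))
  }
  stop("unsupported image format: ", ext, call. = FALSE)
}

#' Write an intensity matrix as an 8-bit grayscale image
#'
#' @param img Numeric matrix; values are clipped to \eqn{[0, 255]}.
#' @param path Output path; format chosen by extension (\code{.png} or
#'   ASCII \code{.pgm}).
#' @return The path, invisibly.
#' @export
write_image <- function(img, path) {
  v <- pmin(pmax(img, 0), 255)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(v / 255, path)
  } else if (ext == "pgm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
    apply(round(v), 1, function(r) writeLines(paste(r, collapse = " "), con))
  } else stop("unsupported image format: ", ext, call. = FALSE)
  invisible(path)
}

#' Serialize a single-distribution fit to JSON
#'
#' @param fit A \code{"gg_fit"} object.
#' @return JSON string with the parameters, method, log-likelihood,
#'   iteration count, convergence flag and score residuals.
#' @export
fit_to_json <- function(fit) {
  stopifnot(inherits(fit, "gg_fit"))
  jsonlite::toJSON(list(
    params = unclass(fit$params),
    method = fit$method,
    loglik = fit$loglik,
    iterations = fit$iterations,
    converged = fit$converged,
    score_residuals = as.list(fit$diagnostics$score)),
    auto_unbox = TRUE, digits = NA)
}
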