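# Truncated Gaussian window and windowed (local) convolution.
#
# Every local statistic in this model is a Gaussian-weighted integral over a
# circular neighbourhood O_y = {x : |x - y| <= r}.  The weight is a truncated
# Gaussian: w(d) = exp(-|d|^2 / (2 sigma^2)) / a for |d| <= r and 0 beyond,
# with a chosen so the mask sums to 1.  All window integrals in the updates
# are realised as discrete convolutions with this mask.

#' Build a truncated Gaussian kernel mask
#'
#' Constructs the `(2*radius+1) x (2*radius+1)` weighting mask that defines the
#' local neighbourhood used by all windowed statistics.  Entries at Euclidean
#' distance `d <= radius` from the centre equal `exp(-d^2 / (2*sigma^2)) / a`;
#' entries beyond the circular truncation radius are exactly zero even though
#' the square mask contains them.  The normaliser `a` makes the mask sum to 1.
#'
#' @param sigma Standard deviation of the Gaussian, in pixels (default 4, the
#'   value used for all experiments in the underlying model).
#' @param radius Truncation radius `r` of the circular neighbourhood, in
#'   pixels (default 15).
#' @return An object of class `kernel_mask`: a list with elements `weights`
#'   (the normalised mask), `radius`, `sigma` and `normalizer` (the constant
#'   `a`).
#' @examples
#' k <- gaussian_kernel(sigma = 2, radius = 5)
#' sum(k$weights)  # 1
#' @export
gaussian_kernel <- function(sigma = 4, radius = 15) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius < 1 || radius != round(radius))
    stop("`radius` must be a single positive integer", call. = FALSE)
  radius <- as.integer(radius)
  d2 <- outer((-radius:radius)^2, (-radius:radius)^2, "+")
  w <- exp(-d2 / (2 * sigma^2))
  w[d2 > radius^2] <- 0  # circular truncation: |d| <= r
  a <- sum(w)
  structure(
    list(weights = w / a, radius = radius, sigma = sigma, normalizer = a,
         .fft_cache = new.env(parent = emptyenv())),
    class = "kernel_mask"
  )
}

#' @export
print.kernel_mask <- function(x, ...) {
  cat(sprintf("Truncated Gaussian kernel: %dx%d, sigma = %g, radius = %d, sum = %g\n",
              nrow(x$weights), ncol(x$weights), x$sigma, x$radius, sum(x$weights)))
  invisible(x)
}

#' Windowed convolution with a kernel mask
#'
#' Computes `out[y] = sum_x kernel[x - y] * field[x]` for every pixel `y`,
#' i.e. the discrete realisation of the Gaussian-window integrals that appear
#' in all local statistics.  The image is zero-padded, so near the boundary
#' the window silently loses the part that falls outside the domain; all
#' ratio-form updates divide two such convolutions, which renormalises the
#' effective window there.
#'
#' @param field A numeric matrix, finite everywhere.
#' @param kernel A [gaussian_kernel()] mask.  Must not exceed the field in
#'   either dimension.
#' @return A numeric matrix of the same dimensions as `field`.
#' @export
kern_convolve <- function(field, kernel) {
  stopifnot(inherits(kernel, "kernel_mask"))
  if (!is.matrix(field) || !is.numeric(field))
    stop("`field` must be a numeric matrix", call. = FALSE)
  r <- kernel$radius
  k <- 2L * r + 1L
  nr <- nrow(field); nc <- ncol(field)
  if (k > nr || k > nc)
    stop("kernel is larger than the image in at least one dimension", call. = FALSE)
  pr <- nr + 2L * r
  pc <- nc + 2L * r
  key <- paste0(pr, "x", pc)
  kf <- kernel$.fft_cache[[key]]
  if (is.null(kf)) {
    km <- matrix(0, pr, pc)
    km[1:k, 1:k] <- kernel$weights
    kf <- stats::fft(km)
    assign(key, kf, envir = kernel$.fft_cache)
  }
  fp <- matrix(0, pr, pc)
  fp[1:nr, 1:nc] <- field
  conv <- Re(stats::fft(stats::fft(fp) * kf, inverse = TRUE)) / (pr * pc)
  conv[(r + 1L):(r + nr), (r + 1L):(r + nc), drop = FALSE]
}
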