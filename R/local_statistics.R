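# Closed-form coordinate-descent updates of the statistical variables and the
# per-region evidence fields that drive the contour.
#
# All quantities are Gaussian-window integrals.  The double integrals over
# window centres y and member pixels x are expanded into single convolutions
# against the window mask: for a symmetric kernel,
#   sum_y w(x - y) f(y) = kern_convolve(f)(x),
# so e.g. the numerator of the constant update
#   sum_x sum_y w(x - y) (J(x) - b(y)) M_i(x)
# becomes sum_x M_i(x) [ J(x) * conv(mask)(x) - conv(b * mask)(x) ].
# Equivalence with the literal double loops is a tested property.
#
# `mask` is the validity mask from the log transform (1 = usable pixel);
# masked pixels contribute to no window sum, on either index.

as_mask <- function(mask, like) {
  if (is.null(mask)) return(matrix(1, nrow(like), ncol(like)))
  if (is.logical(mask)) mask <- mask * 1.0
  stopifnot(identical(dim(mask), dim(like)))
  mask
}

#' Update the region constants
#'
#' Closed-form minimiser of the data energy with respect to the region
#' constants `c_i`: the window-weighted mean of `J(x) - b(y)` over the pixels
#' belonging to region i,
#' `c_i = [sum_{x,y} w(x-y) (J(x) - b(y)) M_i(x)] / [sum_{x,y} w(x-y) M_i(x)]`.
#'
#' @param J Log-intensity matrix.
#' @param bias Log-domain bias field matrix.
#' @param memberships List of N membership matrices in `[0, 1]`.
#' @param kernel A [gaussian_kernel()] mask.
#' @param mask Optional validity mask (logical or 0/1 matrix); `NULL` means
#'   all pixels valid.
#' @param prev Previous constants, kept (with a warning) for any region whose
#'   weighted mass vanishes.
#' @return Numeric vector of N constants (log-intensity units).
#' @export
update_region_constants <- function(J, bias, memberships, kernel,
                                    mask = NULL, prev = NULL) {
  mask <- as_mask(mask, J)
  W <- kern_convolve(mask, kernel)
  Bc <- kern_convolve(bias * mask, kernel)
  n <- length(memberships)
  cs <- numeric(n)
  for (i in seq_len(n)) {
    mi <- memberships[[i]] * mask
    den <- sum(mi * W)
    if (den <= .Machine$double.eps) {
      if (is.null(prev))
        stop("region ", i, " has no weighted mass and no previous constant",
             call. = FALSE)
      warning("region ", i, " collapsed; keeping previous constant",
              call. = FALSE)
      cs[i] <- prev[i]
    } else {
      cs[i] <- sum(mi * (J * W - Bc)) / den
    }
  }
  cs
}

#' Update the region standard deviations
#'
#' Closed-form minimiser with respect to `sigma_i`: the square root of the
#' window-weighted mean squared residual `(J(x) - b(y) - c_i)^2` over region
#' i, floored at `sigma_floor` so later divisions by `sigma_i^2` stay finite
#' on noise-free regions.
#'
#' @inheritParams update_region_constants
#' @param constants Freshly updated region constants.
#' @param sigma_floor Lower bound for each standard deviation (default 1e-3
#'   log-intensity units).
#' @return Numeric vector of N standard deviations.
#' @export
update_region_stddevs <- function(J, bias, constants, memberships, kernel,
                                  mask = NULL, sigma_floor = 1e-3, prev = NULL) {
  mask <- as_mask(mask, J)
  W <- kern_convolve(mask, kernel)
  Bc <- kern_convolve(bias * mask, kernel)
  B2c <- kern_convolve(bias^2 * mask, kernel)
  n <- length(memberships)
  s <- numeric(n)
  for (i in seq_len(n)) {
    mi <- memberships[[i]] * mask
    den <- sum(mi * W)
    if (den <= .Machine$double.eps) {
      if (is.null(prev))
        stop("region ", i, " has no weighted mass and no previous stddev",
             call. = FALSE)
      warning("region ", i, " collapsed; keeping previous stddev",
              call. = FALSE)
      s[i] <- prev[i]
    } else {
      res <- J - constants[i]
      v <- sum(mi * (res^2 * W - 2 * res * Bc + B2c)) / den
      s[i] <- max(sqrt(max(v, 0)), sigma_floor)
    }
  }
  s
}

#' Update the bias field
#'
#' Pointwise closed-form minimiser with respect to the log-domain bias:
#' `b(y) = [sum_i conv(w, (J - c_i) M_i / sigma_i^2)](y) /
#'         [sum_i conv(w, M_i / sigma_i^2)](y)`.
#' Pixels whose window carries no weighted mass keep their previous value.
#'
#' @inheritParams update_region_stddevs
#' @param stddevs Region standard deviations (already floored).
#' @param prev Previous bias field matrix, used where the denominator
#'   vanishes (and for masked-out regions far from any valid pixel).
#' @return The updated bias field matrix.
#' @export
update_bias_field <- function(J, constants, stddevs, memberships, kernel,
                              mask = NULL, prev = NULL) {
  mask <- as_mask(mask, J)
  if (is.null(prev)) prev <- matrix(0, nrow(J), ncol(J))
  num_f <- matrix(0, nrow(J), ncol(J))
  den_f <- matrix(0, nrow(J), ncol(J))
  for (i in seq_along(memberships)) {
    w_i <- memberships[[i]] * mask / stddevs[i]^2
    num_f <- num_f + (J - constants[i]) * w_i
    den_f <- den_f + w_i
  }
  num <- kern_convolve(num_f, kernel)
  den <- kern_convolve(den_f, kernel)
  ok <- den > .Machine$double.eps
  if (!all(ok))
    warning("bias denominator vanished at ", sum(!ok),
            " pixel(s); keeping previous values", call. = FALSE)
  b <- prev
  b[ok] <- num[ok] / den[ok]
  b
}

#' Update the spatial prior maps
#'
#' Constrained minimiser with respect to the priors under the pointwise
#' simplex constraint: `p_i(y) = conv(w, M_i)(y) / sum_j conv(w, M_j)(y)`,
#' i.e. the window-smoothed membership fractions.  Each prior is floored at
#' `prior_floor` (then renormalised) so its logarithm stays finite.
#'
#' @inheritParams update_region_constants
#' @param prior_floor Lower bound applied to each prior before renormalising.
#' @return A list of N prior matrices summing to 1 at every pixel.
#' @export
update_priors <- function(memberships, kernel, mask = NULL,
                          prior_floor = 1e-6) {
  mask <- as_mask(mask, memberships[[1]])
  n <- length(memberships)
  conv_m <- lapply(memberships, function(m) kern_convolve(m * mask, kernel))
  den <- Reduce(`+`, conv_m)
  ok <- den > .Machine$double.eps
  p <- lapply(conv_m, function(cm) {
    out <- matrix(1 / n, nrow(cm), ncol(cm))
    out[ok] <- cm[ok] / den[ok]
    pmax(out, prior_floor)
  })
  tot <- Reduce(`+`, p)
  lapply(p, function(pi) pi / tot)
}

#' Per-region evidence fields
#'
#' The window-integrated MAP cost of assigning pixel x to region i:
#' `e_i(x) = int w(x - y) [ -log p_i(y) + log(sqrt(2*pi)*sigma_i)
#'                          + (J(x) - b(y) - c_i)^2 / (2*sigma_i^2) ] dy`,
#' expanded into convolutions of `-log p_i`, `b`, and `b^2` so no per-pixel
#' inner loop is needed.  The contour moves toward regions with lower
#' evidence cost.  Values on masked-out pixels are set to zero so they exert
#' no force.
#'
#' @inheritParams update_bias_field
#' @param bias Log-domain bias field.
#' @param priors List of N prior matrices (floored away from zero).
#' @return A list of N evidence matrices.
#' @export
compute_evidence_fields <- function(J, bias, constants, stddevs, priors,
                                    kernel, mask = NULL) {
  mask <- as_mask(mask, J)
  W <- kern_convolve(mask, kernel)
  Bc <- kern_convolve(bias * mask, kernel)
  B2c <- kern_convolve(bias^2 * mask, kernel)
  e <- vector("list", length(constants))
  for (i in seq_along(constants)) {
    Li <- kern_convolve(-log(priors[[i]]) * mask, kernel)
    res <- J - constants[i]
    ei <- Li + log(sqrt(2 * pi) * stddevs[i]) * W +
      (res^2 * W - 2 * res * Bc + B2c) / (2 * stddevs[i]^2)
    ei <- ei * mask
    if (!all(is.finite(ei))) {
      bad <- which(!is.finite(ei), arr.ind = TRUE)[1, ]
      stop("non-finite evidence for region ", i, " at pixel (",
           bad[1], ", ", bad[2], ")", call. = FALSE)
    }
    e[[i]] <- ei
  }
  e
}

#' Gauge normalisation of the bias/constant pair
#'
#' The energy is invariant under `b -> b + kappa`, `c_i -> c_i - kappa`; for
#' reporting, the bias is shifted to zero mean over the valid mask and the
#' constants are shifted oppositely.
#'
#' @param bias Log-domain bias field.
#' @param constants Region constants.
#' @param mask Optional validity mask.
#' @return List with `bias` (zero-mean over the mask) and `constants`.
#' @export
gauge_normalize <- function(bias, constants, mask = NULL) {
  mask <- as_mask(mask, bias)
  kappa <- sum(bias * mask) / sum(mask)
  list(bias = bias - kappa, constants = constants + kappa)
}
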