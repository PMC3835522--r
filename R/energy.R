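# Evaluation of the full objective.  Used for monitoring, monotonicity tests
# and optimality checks, not in the iteration hot path.
#
# total F = data energy E + nu * sum_j length(phi_j) + mu * sum_j reg(phi_j)

#' Data energy
#'
#' The window-integrated MAP cost summed over all window centres:
#' `E = sum_y sum_i int w(x - y) [ -log p_i(y) + log(sqrt(2*pi)*sigma_i)
#'      + (J(x) - b(y) - c_i)^2 / (2*sigma_i^2) ] M_i(x) dx`,
#' discretised with unit pixel area and evaluated with smoothed memberships.
#' The x-integrals are expanded into convolutions of `M_i`, `M_i * J` and
#' `M_i * J^2`.
#'
#' @param J Log-intensity matrix.
#' @param memberships List of N smoothed membership matrices.
#' @param constants,stddevs Region constants and standard deviations.
#' @param bias Log-domain bias field.
#' @param priors List of N prior matrices (floored away from zero).
#' @param kernel A [gaussian_kernel()] mask.
#' @param mask Optional validity mask.
#' @return The scalar data energy.
#' @export
data_energy <- function(J, memberships, constants, stddevs, bias, priors,
                        kernel, mask = NULL) {
  mask <- as_mask(mask, J)
  E <- 0
  for (i in seq_along(memberships)) {
    mi <- memberships[[i]] * mask
    A <- kern_convolve(mi, kernel)            # sum_x w(x-y) M_i(x)
    G <- kern_convolve(mi * J, kernel)        # sum_x w(x-y) M_i(x) J(x)
    Q <- kern_convolve(mi * J^2, kernel)      # sum_x w(x-y) M_i(x) J(x)^2
    ctr <- bias + constants[i]
    term <- (-log(priors[[i]]) + log(sqrt(2 * pi) * stddevs[i])) * A +
      (Q - 2 * ctr * G + ctr^2 * A) / (2 * stddevs[i]^2)
    E <- E + sum(term * mask)
  }
  if (!is.finite(E)) stop("data energy is non-finite", call. = FALSE)
  E
}

#' Contour length term
#'
#' Discrete `sum_x delta_eps(phi) * |grad phi|`, the length of the zero level
#' set measured through the smoothed delta.
#'
#' @param phi Level-set function matrix.
#' @param eps Heaviside/delta smoothing width.
#' @return Nonnegative scalar.
#' @export
length_term <- function(phi, eps = 1) {
  sum(delta_eps(phi, eps) * grad_magnitude(phi))
}

#' Signed-distance deviation penalty
#'
#' Discrete `sum_x (|grad phi| - 1)^2 / 2`; zero when `phi` is an exact
#' signed distance function.
#'
#' @param phi Level-set function matrix.
#' @return Nonnegative scalar.
#' @export
distance_regularizer <- function(phi) {
  sum(0.5 * (grad_magnitude(phi) - 1)^2)
}

#' Full energy breakdown
#'
#' @inheritParams data_energy
#' @param state A [level_set_state()]; memberships are recomputed from it.
#' @param params An [evolution_params()] supplying the weights `nu` and `mu`.
#' @return A list with `data`, per-function `length` and `regularizer`
#'   vectors, and `total = data + nu * sum(length) + mu * sum(regularizer)`.
#' @export
energy_breakdown <- function(J, state, constants, stddevs, bias, priors,
                             kernel, params, mask = NULL) {
  m <- compute_memberships(state)
  E <- data_energy(J, m, constants, stddevs, bias, priors, kernel, mask)
  L <- vapply(state$phi, length_term, numeric(1), eps = state$eps)
  R <- vapply(state$phi, distance_regularizer, numeric(1))
  list(data = E, length = L, regularizer = R,
       total = E + params$nu * sum(L) + params$mu * sum(R))
}
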