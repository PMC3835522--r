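# Level-set representation of the partition, membership functions, and the
# explicit gradient-flow evolution.
#
# Two-phase: one function phi with Omega_1 = {phi > 0}, Omega_2 = {phi < 0}.
# Multiphase: two functions (phi_1, phi_2) encode 3 or 4 regions via products
# of smoothed Heaviside factors.

#' Smoothed Heaviside function
#'
#' `H_eps(x) = 1/2 * (1 + (2/pi) * atan(x / eps))`, a differentiable surrogate
#' for the unit step used to turn the sign of a level-set function into a soft
#' region indicator.
#'
#' @param x Numeric vector, matrix or array.
#' @param eps Smoothing width (default 1).
#' @return Values in (0, 1), same shape as `x`.
#' @export
heaviside_eps <- function(x, eps = 1) {
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("`eps` must be a single positive number", call. = FALSE)
  0.5 * (1 + (2 / pi) * atan(x / eps))
}

#' Smoothed Dirac delta
#'
#' `delta_eps(x) = (1/pi) * eps / (eps^2 + x^2)`, the derivative of
#' [heaviside_eps()].  It concentrates the contour forces in a band around the
#' zero level set.
#'
#' @inheritParams heaviside_eps
#' @return Positive values, same shape as `x`.
#' @export
delta_eps <- function(x, eps = 1) {
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("`eps` must be a single positive number", call. = FALSE)
  (eps / pi) / (eps^2 + x^2)
}

#' Evolution parameters
#'
#' Bundles the gradient-flow parameters.  Defaults are the values the model
#' was designed with: time step `dt = 0.1`, distance-regulariser weight
#' `mu = 1`, length weight `nu = 0.001 * 255^2` (scaled for 8-bit images),
#' at most 500 iterations, and convergence declared when the hard label map
#' is unchanged for `stable_iters` consecutive iterations.
#'
#' @param dt Explicit Euler time step.
#' @param mu Weight of the signed-distance regulariser (keeps `|grad phi|`
#'   near 1 without reinitialisation).
#' @param nu Weight of the contour length penalty.
#' @param max_iter Maximum number of outer iterations.
#' @param stable_iters Consecutive iterations with an unchanged label map
#'   required to declare convergence.
#' @return An object of class `evolution_params`.
#' @export
evolution_params <- function(dt = 0.1, mu = 1.0, nu = 0.001 * 255^2,
                             max_iter = 500L, stable_iters = 10L) {
  stopifnot(dt > 0, mu >= 0, nu >= 0, max_iter >= 1, stable_iters >= 1)
  structure(list(dt = dt, mu = mu, nu = nu,
                 max_iter = as.integer(max_iter),
                 stable_iters = as.integer(stable_iters)),
            class = "evolution_params")
}

#' Level-set state
#'
#' @param phi A numeric matrix (two-phase) or a list of one or two numeric
#'   matrices.
#' @param n_phases Number of regions N (2, 3 or 4).
#' @param eps Heaviside smoothing width.
#' @return An object of class `level_set_state` with elements `phi` (list of
#'   matrices), `n_phases`, `n_functions`, `eps`.
#' @export
level_set_state <- function(phi, n_phases = 2L, eps = 1) {
  if (is.matrix(phi)) phi <- list(phi)
  if (!is.list(phi) || !all(vapply(phi, is.matrix, logical(1))))
    stop("`phi` must be a matrix or a list of matrices", call. = FALSE)
  n_phases <- as.integer(n_phases)
  n_fun <- length(phi)
  ok <- (n_phases == 2L && n_fun == 1L) || (n_phases %in% c(3L, 4L) && n_fun == 2L)
  if (!ok)
    stop("unsupported combination: N = ", n_phases, " regions with ",
         n_fun, " level-set function(s)", call. = FALSE)
  if (!all(vapply(phi, function(p) all(is.finite(p)), logical(1))))
    stop("level-set functions must be finite", call. = FALSE)
  d <- dim(phi[[1]])
  if (n_fun > 1L && !identical(dim(phi[[2]]), d))
    stop("all level-set functions must share dimensions", call. = FALSE)
  structure(list(phi = phi, n_phases = n_phases, n_functions = n_fun, eps = eps),
            class = "level_set_state")
}

#' Initialise level-set functions as binary steps
#'
#' Each function is set to `-c0` inside its seed region and `+c0` outside, the
#' standard binary-step initialisation that needs no signed-distance
#' computation.
#'
#' @param shape Integer vector `(rows, cols)`.
#' @param seeds A single seed spec, or a list of one spec per level-set
#'   function.  A seed spec is a list with `type = "rect"` (`rows = c(r1, r2)`,
#'   `cols = c(c1, c2)`, inclusive), `type = "disc"` (`center = c(row, col)`,
#'   `radius`), or `type = "multi"` (`shapes` = list of the above, unioned).
#' @param c0 Magnitude of the binary step (default 2).
#' @param n_phases Number of regions (2, 3 or 4); 3 and 4 use two functions.
#' @param eps Heaviside smoothing width.
#' @return A [level_set_state()].
#' @export
initialize_level_set <- function(shape, seeds, c0 = 2, n_phases = 2L, eps = 1) {
  if (!is.numeric(c0) || length(c0) != 1L || c0 <= 0)
    stop("`c0` must be a single positive number", call. = FALSE)
  n_fun <- if (n_phases == 2L) 1L else 2L
  if (!is.null(seeds$type)) seeds <- list(seeds)
  if (length(seeds) != n_fun)
    stop("need ", n_fun, " seed region(s) for N = ", n_phases, call. = FALSE)
  phi <- lapply(seeds, function(s) {
    inside <- seed_mask(shape, s)
    if (!any(inside))
      stop("seed region is empty or outside the image", call. = FALSE)
    p <- matrix(c0, shape[1], shape[2])
    p[inside] <- -c0
    p
  })
  level_set_state(phi, n_phases = n_phases, eps = eps)
}

# Rasterise a seed spec to a logical matrix.
seed_mask <- function(shape, s) {
  nr <- shape[1]; nc <- shape[2]
  m <- matrix(FALSE, nr, nc)
  if (identical(s$type, "rect")) {
    r <- round(s$rows); cc <- round(s$cols)
    if (r[1] < 1 || r[2] > nr || cc[1] < 1 || cc[2] > nc || r[1] > r[2] || cc[1] > cc[2])
      stop("rectangular seed out of bounds", call. = FALSE)
    m[r[1]:r[2], cc[1]:cc[2]] <- TRUE
  } else if (identical(s$type, "disc")) {
    if (s$radius <= 0) stop("disc seed needs positive radius", call. = FALSE)
    d2 <- outer((seq_len(nr) - s$center[1])^2, (seq_len(nc) - s$center[2])^2, "+")
    m <- d2 <= s$radius^2
    if (s$center[1] - s$radius < 0.5 || s$center[1] + s$radius > nr + 0.5 ||
        s$center[2] - s$radius < 0.5 || s$center[2] + s$radius > nc + 0.5)
      stop("disc seed out of bounds", call. = FALSE)
  } else if (identical(s$type, "multi")) {
    for (sub in s$shapes) m <- m | seed_mask(shape, sub)
  } else stop("unknown seed type: ", s$type, call. = FALSE)
  m
}

#' Region membership functions
#'
#' Turns the level-set state into N soft region indicators that form a
#' partition of unity: for N = 2, `(H(phi), 1 - H(phi))`; for N = 3,
#' `(H1*H2, H1*(1-H2), 1-H1)`; for N = 4 the four products of `H1/(1-H1)`
#' with `H2/(1-H2)`.
#'
#' @param state A [level_set_state()].
#' @param smooth If `TRUE` (default) use the smoothed Heaviside; if `FALSE`
#'   use the exact step `phi > 0`, as used for hard labelling.
#' @return A list of N numeric matrices summing to 1 at every pixel.
#' @export
compute_memberships <- function(state, smooth = TRUE) {
  stopifnot(inherits(state, "level_set_state"))
  H <- if (smooth) function(p) heaviside_eps(p, state$eps)
       else function(p) (p > 0) * 1.0
  N <- state$n_phases
  if (N == 2L) {
    h <- H(state$phi[[1]])
    list(h, 1 - h)
  } else {
    h1 <- H(state$phi[[1]]); h2 <- H(state$phi[[2]])
    if (N == 3L) list(h1 * h2, h1 * (1 - h2), 1 - h1)
    else list(h1 * h2, h1 * (1 - h2), (1 - h1) * h2, (1 - h1) * (1 - h2))
  }
}

# Analytic derivatives dM_i/dphi_j of the membership products; a list indexed
# [[j]][[i]].  Used by the multiphase gradient flow.
membership_derivatives <- function(state) {
  N <- state$n_phases
  e <- state$eps
  if (N == 2L) {
    d1 <- delta_eps(state$phi[[1]], e)
    return(list(list(d1, -d1)))
  }
  h1 <- heaviside_eps(state$phi[[1]], e); d1 <- delta_eps(state$phi[[1]], e)
  h2 <- heaviside_eps(state$phi[[2]], e); d2 <- delta_eps(state$phi[[2]], e)
  if (N == 3L) {
    list(
      list(d1 * h2, d1 * (1 - h2), -d1),
      list(h1 * d2, -h1 * d2, 0 * h1)
    )
  } else {
    list(
      list(d1 * h2, d1 * (1 - h2), -d1 * h2, -d1 * (1 - h2)),
      list(h1 * d2, -h1 * d2, (1 - h1) * d2, -(1 - h1) * d2)
    )
  }
}

#' Hard region labels from a level-set state
#'
#' Argmax over the exact (non-smoothed) memberships; ties break toward the
#' lowest region index.
#'
#' @param state A [level_set_state()].
#' @return An integer matrix with values in `1..N`.
#' @export
hard_labels <- function(state) {
  m <- compute_memberships(state, smooth = FALSE)
  lab <- matrix(1L, nrow(m[[1]]), ncol(m[[1]]))
  best <- m[[1]]
  for (i in seq_along(m)[-1]) {
    better <- m[[i]] > best
    lab[better] <- i
    best[better] <- m[[i]][better]
  }
  lab
}

# --- finite differences (replicate boundary) --------------------------------

shift_rows <- function(m, by) {
  n <- nrow(m)
  idx <- pmin(pmax(seq_len(n) + by, 1L), n)
  m[idx, , drop = FALSE]
}
shift_cols <- function(m, by) {
  n <- ncol(m)
  idx <- pmin(pmax(seq_len(n) + by, 1L), n)
  m[, idx, drop = FALSE]
}

# Central differences along rows and columns with replicated edges.
grad_central <- function(m) {
  list(dr = (shift_rows(m, 1L) - shift_rows(m, -1L)) / 2,
       dc = (shift_cols(m, 1L) - shift_cols(m, -1L)) / 2)
}

grad_magnitude <- function(m) {
  g <- grad_central(m)
  sqrt(g$dr^2 + g$dc^2)
}

#' Mean curvature of a level-set function
#'
#' `div(grad(phi) / |grad(phi)|)` by central differences with replicated
#' edges; a small guard `eta` is added to the gradient-magnitude denominator
#' because the expression is singular where the gradient vanishes.
#'
#' @param phi Numeric matrix.
#' @param eta Guard added to `|grad phi|` (default 1e-10).
#' @return Numeric matrix of curvature values.
#' @export
curvature <- function(phi, eta = 1e-10) {
  g <- grad_central(phi)
  mag <- sqrt(g$dr^2 + g$dc^2) + eta
  nr <- g$dr / mag
  nc <- g$dc / mag
  (shift_rows(nr, 1L) - shift_rows(nr, -1L)) / 2 +
    (shift_cols(nc, 1L) - shift_cols(nc, -1L)) / 2
}

# 5-point Laplacian, replicate boundary.
laplacian5 <- function(m) {
  shift_rows(m, 1L) + shift_rows(m, -1L) +
    shift_cols(m, 1L) + shift_cols(m, -1L) - 4 * m
}

#' One explicit Euler step of the two-phase gradient flow
#'
#' Advances `phi` by
#' `dt * ( -delta_eps(phi) * (e1 - e2) + nu * delta_eps(phi) * curvature(phi)
#'         + mu * (laplacian(phi) - curvature(phi)) )`.
#' The first term moves the contour toward lower per-region evidence cost, the
#' second shortens it, the third keeps `phi` close to a signed distance
#' function.
#'
#' @param state A two-phase [level_set_state()].
#' @param e_fields List of two evidence matrices from
#'   [compute_evidence_fields()].
#' @param params An [evolution_params()].
#' @param iteration Optional iteration index, used only in error messages.
#' @return The updated `level_set_state`.
#' @export
evolve_two_phase <- function(state, e_fields, params, iteration = NA_integer_) {
  stopifnot(inherits(state, "level_set_state"), state$n_functions == 1L,
            state$n_phases == 2L, length(e_fields) == 2L)
  phi <- state$phi[[1]]
  dlt <- delta_eps(phi, state$eps)
  kap <- curvature(phi)
  dphi <- -dlt * (e_fields[[1]] - e_fields[[2]]) +
    params$nu * dlt * kap +
    params$mu * (laplacian5(phi) - kap)
  phi <- phi + params$dt * dphi
  if (!all(is.finite(phi)))
    stop("level-set evolution produced non-finite values",
         if (!is.na(iteration)) paste0(" at iteration ", iteration),
         call. = FALSE)
  state$phi[[1]] <- phi
  state
}

#' One explicit Euler step of the multiphase gradient flow
#'
#' Each function `phi_j` is advanced by
#' `dt * ( -sum_i dM_i/dphi_j * e_i + nu * delta_eps(phi_j) * curvature(phi_j)
#'         + mu * (laplacian(phi_j) - curvature(phi_j)) )`,
#' with `dM_i/dphi_j` the analytic derivatives of the membership products.
#'
#' @param state A multiphase [level_set_state()] (N = 3 or 4, two functions).
#' @param e_fields List of N evidence matrices.
#' @param params An [evolution_params()].
#' @param iteration Optional iteration index for error messages.
#' @return The updated `level_set_state`.
#' @export
evolve_multiphase <- function(state, e_fields, params, iteration = NA_integer_) {
  stopifnot(inherits(state, "level_set_state"), state$n_functions == 2L,
            length(e_fields) == state$n_phases)
  dM <- membership_derivatives(state)
  for (j in 1:2) {
    phi <- state$phi[[j]]
    data_term <- 0
    for (i in seq_len(state$n_phases))
      data_term <- data_term + dM[[j]][[i]] * e_fields[[i]]
    kap <- curvature(phi)
    dphi <- -data_term +
      params$nu * delta_eps(phi, state$eps) * kap +
      params$mu * (laplacian5(phi) - kap)
    phi <- phi + params$dt * dphi
    if (!all(is.finite(phi)))
      stop("level-set evolution produced non-finite values in phi_", j,
           if (!is.na(iteration)) paste0(" at iteration ", iteration),
           call. = FALSE)
    state$phi[[j]] <- phi
  }
  state
}
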