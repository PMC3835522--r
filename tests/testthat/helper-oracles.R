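# Independent brute-force implementations of every windowed quantity, written
# as literal double/quadruple loops over pixel pairs.  They share nothing with
# the convolution-based implementations they check.

# out[y] = sum_x w[x - y] * field[x]
oracle_convolve <- function(field, kernel) {
  r <- kernel$radius
  nr <- nrow(field); nc <- ncol(field)
  out <- matrix(0, nr, nc)
  w <- kernel$weights
  for (y1 in 1:nr) for (y2 in 1:nc) {
    s <- 0
    for (x1 in max(1, y1 - r):min(nr, y1 + r))
      for (x2 in max(1, y2 - r):min(nc, y2 + r))
        s <- s + w[x1 - y1 + r + 1, x2 - y2 + r + 1] * field[x1, x2]
    out[y1, y2] <- s
  }
  out
}

# c_i = sum_{x,y} w(x-y) (J(x) - b(y)) M_i(x) / sum_{x,y} w(x-y) M_i(x),
# restricted to the valid mask on both indices.
oracle_constants <- function(J, bias, memberships, kernel, mask) {
  r <- kernel$radius; w <- kernel$weights
  nr <- nrow(J); nc <- ncol(J)
  vapply(memberships, function(M) {
    num <- 0; den <- 0
    for (x1 in 1:nr) for (x2 in 1:nc) {
      if (mask[x1, x2] == 0) next
      for (y1 in max(1, x1 - r):min(nr, x1 + r))
        for (y2 in max(1, x2 - r):min(nc, x2 + r)) {
          if (mask[y1, y2] == 0) next
          wt <- w[x1 - y1 + r + 1, x2 - y2 + r + 1] * M[x1, x2]
          num <- num + wt * (J[x1, x2] - bias[y1, y2])
          den <- den + wt
        }
    }
    num / den
  }, numeric(1))
}

oracle_stddevs <- function(J, bias, constants, memberships, kernel, mask,
                           sigma_floor = 1e-3) {
  r <- kernel$radius; w <- kernel$weights
  nr <- nrow(J); nc <- ncol(J)
  out <- numeric(length(memberships))
  for (i in seq_along(memberships)) {
    M <- memberships[[i]]
    num <- 0; den <- 0
    for (x1 in 1:nr) for (x2 in 1:nc) {
      if (mask[x1, x2] == 0) next
      for (y1 in max(1, x1 - r):min(nr, x1 + r))
        for (y2 in max(1, x2 - r):min(nc, x2 + r)) {
          if (mask[y1, y2] == 0) next
          wt <- w[x1 - y1 + r + 1, x2 - y2 + r + 1] * M[x1, x2]
          num <- num + wt * (J[x1, x2] - bias[y1, y2] - constants[i])^2
          den <- den + wt
        }
    }
    out[i] <- max(sqrt(num / den), sigma_floor)
  }
  out
}

oracle_bias <- function(J, constants, stddevs, memberships, kernel, mask) {
  r <- kernel$radius; w <- kernel$weights
  nr <- nrow(J); nc <- ncol(J)
  out <- matrix(0, nr, nc)
  for (y1 in 1:nr) for (y2 in 1:nc) {
    num <- 0; den <- 0
    for (x1 in max(1, y1 - r):min(nr, y1 + r))
      for (x2 in max(1, y2 - r):min(nc, y2 + r)) {
        if (mask[x1, x2] == 0) next
        wt <- w[x1 - y1 + r + 1, x2 - y2 + r + 1]
        for (i in seq_along(memberships)) {
          mi <- memberships[[i]][x1, x2] / stddevs[i]^2
          num <- num + wt * (J[x1, x2] - constants[i]) * mi
          den <- den + wt * mi
        }
      }
    out[y1, y2] <- num / den
  }
  out
}

oracle_priors <- function(memberships, kernel, mask) {
  conv <- lapply(memberships, function(M) oracle_convolve(M * mask, kernel))
  den <- Reduce(`+`, conv)
  lapply(conv, function(cm) cm / den)
}

# e_i(x) = sum_y w(x-y) [ -log p_i(y) + log(sqrt(2 pi) sigma_i)
#                         + (J(x) - b(y) - c_i)^2 / (2 sigma_i^2) ]
oracle_evidence <- function(J, bias, constants, stddevs, priors, kernel, mask) {
  r <- kernel$radius; w <- kernel$weights
  nr <- nrow(J); nc <- ncol(J)
  lapply(seq_along(constants), function(i) {
    out <- matrix(0, nr, nc)
    for (x1 in 1:nr) for (x2 in 1:nc) {
      if (mask[x1, x2] == 0) next
      s <- 0
      for (y1 in max(1, x1 - r):min(nr, x1 + r))
        for (y2 in max(1, x2 - r):min(nc, x2 + r)) {
          if (mask[y1, y2] == 0) next
          wt <- w[x1 - y1 + r + 1, x2 - y2 + r + 1]
          s <- s + wt * (-log(priors[[i]][y1, y2]) +
                           log(sqrt(2 * pi) * stddevs[i]) +
                           (J[x1, x2] - bias[y1, y2] - constants[i])^2 /
                             (2 * stddevs[i]^2))
        }
      out[x1, x2] <- s
    }
    out
  })
}

# Literal quadruple-loop data energy.
oracle_energy <- function(J, memberships, constants, stddevs, bias, priors,
                          kernel, mask) {
  r <- kernel$radius; w <- kernel$weights
  nr <- nrow(J); nc <- ncol(J)
  E <- 0
  for (y1 in 1:nr) for (y2 in 1:nc) {
    if (mask[y1, y2] == 0) next
    for (x1 in max(1, y1 - r):min(nr, y1 + r))
      for (x2 in max(1, y2 - r):min(nc, y2 + r)) {
        if (mask[x1, x2] == 0) next
        wt <- w[x1 - y1 + r + 1, x2 - y2 + r + 1]
        for (i in seq_along(constants)) {
          E <- E + wt * memberships[[i]][x1, x2] *
            (-log(priors[[i]][y1, y2]) + log(sqrt(2 * pi) * stddevs[i]) +
               (J[x1, x2] - bias[y1, y2] - constants[i])^2 /
                 (2 * stddevs[i]^2))
        }
      }
  }
  E
}

# A small random test instance shared by the oracle-equivalence tests.
random_instance <- function(n = 16, n_regions = 2, seed = 42, with_mask = FALSE) {
  set.seed(seed)
  J <- matrix(rnorm(n * n, mean = 4, sd = 0.5), n, n)
  bias <- matrix(rnorm(n * n, sd = 0.1), n, n)
  raw <- lapply(seq_len(n_regions), function(i) matrix(runif(n * n), n, n))
  tot <- Reduce(`+`, raw)
  memberships <- lapply(raw, function(m) m / tot)
  praw <- lapply(seq_len(n_regions), function(i) matrix(runif(n * n, 0.05, 1), n, n))
  ptot <- Reduce(`+`, praw)
  priors <- lapply(praw, function(p) p / ptot)
  mask <- if (with_mask) {
    m <- matrix(1, n, n); m[sample(n * n, floor(n * n / 10))] <- 0; m
  } else matrix(1, n, n)
  constants <- seq(3.5, 4.5, length.out = n_regions)
  stddevs <- seq(0.3, 0.5, length.out = n_regions)
  list(J = J, bias = bias, memberships = memberships, priors = priors,
       mask = mask, constants = constants, stddevs = stddevs,
       kernel = gaussian_kernel(sigma = 2, radius = 4))
}
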