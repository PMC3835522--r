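test_that("smoothed Heaviside and delta match their analytic anchors", {
  expect_equal(heaviside_eps(0, 1), 0.5)
  expect_equal(heaviside_eps(1, 1), 0.75)   # arctan(1) = pi/4
  x <- seq(-5, 5, by = 0.37)
  expect_equal(heaviside_eps(x, 1.3) + heaviside_eps(-x, 1.3), rep(1, length(x)))

  expect_equal(delta_eps(0, 1), 1 / pi)
  expect_equal(delta_eps(0, 0.5), 1 / (pi * 0.5))
  expect_equal(delta_eps(x, 2), delta_eps(-x, 2))

  # delta integrates to ~1 over a wide interval (quadrature oracle)
  eps <- 0.8
  xs <- seq(-100 * eps, 100 * eps, length.out = 200001)
  integral <- sum(delta_eps(xs, eps)) * (xs[2] - xs[1])
  expect_lt(abs(integral - 1), 0.01)
})

test_that("memberships form a partition of unity for N = 2, 3, 4", {
  set.seed(4)
  phi1 <- matrix(rnorm(100, sd = 3), 10, 10)
  phi2 <- matrix(rnorm(100, sd = 3), 10, 10)
  for (N in c(2L, 3L, 4L)) {
    st <- level_set_state(if (N == 2) list(phi1) else list(phi1, phi2),
                          n_phases = N)
    m <- compute_memberships(st)
    expect_length(m, N)
    expect_true(all(vapply(m, function(x) all(x >= 0 & x <= 1), logical(1))))
    expect_equal(Reduce(`+`, m), matrix(1, 10, 10), tolerance = 1e-12)
  }

  # known values
  stp <- level_set_state(list(matrix(10, 4, 4)), n_phases = 2)
  mp <- compute_memberships(stp)
  expect_equal(mp[[1]][1, 1], 0.5 * (1 + (2 / pi) * atan(10)), tolerance = 1e-12)
  st3 <- level_set_state(list(matrix(0, 4, 4), matrix(0, 4, 4)), n_phases = 3)
  m3 <- compute_memberships(st3)
  expect_equal(vapply(m3, function(x) x[1, 1], numeric(1)), c(0.25, 0.25, 0.5))

  expect_error(level_set_state(list(phi1), n_phases = 3), "unsupported")
  expect_error(level_set_state(list(phi1, phi2), n_phases = 2), "unsupported")
})

test_that("membership derivatives sum to zero over regions", {
  set.seed(8)
  for (N in c(3L, 4L)) {
    st <- level_set_state(list(matrix(rnorm(64), 8, 8),
                               matrix(rnorm(64), 8, 8)), n_phases = N)
    dM <- lsbias:::membership_derivatives(st)
    for (j in 1:2)
      expect_equal(Reduce(`+`, dM[[j]]), matrix(0, 8, 8), tolerance = 1e-12)
  }
})

test_that("curvature matches the analytic value for circles and planes", {
  n <- 101
  ctr <- 51
  d <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  for (R in c(15, 25)) {
    phi <- d - R   # signed distance to a circle of radius R
    kap <- curvature(phi)
    ring <- abs(phi) < 0.5
    expect_lt(max(abs(kap[ring] - 1 / R)) / (1 / R), 0.10)
    # sign flip is odd
    expect_equal(curvature(-phi), -kap, tolerance = 1e-12)
  }
  # planar level sets are flat
  plane <- outer(1:n, 1:n, function(i, j) 0.3 * i + 0.7 * j)
  expect_equal(max(abs(curvature(plane)[10:90, 10:90])), 0, tolerance = 1e-10)
})

test_that("binary-step initialisation takes the stated values", {
  st <- initialize_level_set(c(64, 64),
                             list(type = "rect", rows = c(23, 42), cols = c(23, 42)),
                             c0 = 2)
  phi <- st$phi[[1]]
  expect_setequal(unique(as.vector(phi)), c(-2, 2))
  expect_equal(sum(phi == -2), 400)

  # seed covering everything
  st2 <- initialize_level_set(c(32, 32),
                              list(type = "rect", rows = c(1, 32), cols = c(1, 32)))
  expect_true(all(st2$phi[[1]] == -2))

  # two disjoint disc seeds for two functions
  st3 <- initialize_level_set(c(64, 64),
                              list(list(type = "disc", center = c(20, 20), radius = 8),
                                   list(type = "disc", center = c(44, 44), radius = 8)),
                              n_phases = 4)
  for (j in 1:2) expect_setequal(unique(as.vector(st3$phi[[j]])), c(-2, 2))

  expect_error(initialize_level_set(c(32, 32),
                                    list(type = "disc", center = c(2, 2), radius = 8)),
               "out of bounds")
  expect_error(initialize_level_set(c(32, 32),
                                    list(type = "rect", rows = c(10, 5), cols = c(1, 5))),
               "out of bounds")
})

test_that("two-phase evolution is stationary and signed as expected", {
  params <- evolution_params()
  n <- 32
  # straight-line signed distance, equal evidence: nothing moves
  phi <- matrix(rep(1:n - n / 2 - 0.5, each = n), n, n)  # |grad| = 1, straight
  st <- level_set_state(phi, n_phases = 2)
  e <- list(matrix(1, n, n), matrix(1, n, n))
  st1 <- evolve_two_phase(st, e, params)
  expect_equal(st1$phi[[1]][5:(n - 5), 5:(n - 5)],
               phi[5:(n - 5), 5:(n - 5)], tolerance = 1e-12)

  # lower cost for region 1 near the front raises phi there
  params0 <- evolution_params(nu = 0, mu = 0)
  e2 <- list(matrix(0, n, n), matrix(2, n, n))
  st2 <- evolve_two_phase(st, e2, params0)
  front <- abs(phi) < 0.6
  expect_true(all(st2$phi[[1]][front] > phi[front]))

  # with nu = mu = 0 a single step is exactly -dt * delta * (e1 - e2)
  set.seed(12)
  phir <- matrix(rnorm(64), 8, 8)
  str <- level_set_state(phir, n_phases = 2)
  er <- list(matrix(rnorm(64), 8, 8), matrix(rnorm(64), 8, 8))
  out <- evolve_two_phase(str, er, params0)
  expect_equal(out$phi[[1]],
               phir - 0.1 * delta_eps(phir, 1) * (er[[1]] - er[[2]]),
               tolerance = 1e-15)
})

test_that("one explicit Euler step matches a direct right-hand-side oracle", {
  set.seed(13)
  n <- 8
  params <- evolution_params(dt = 0.1, mu = 1, nu = 65.025)
  rhs_oracle <- function(phi, e1, e2, nu, mu, eps = 1, eta = 1e-10) {
    # independent, index-by-index finite differences with replicated edges
    at <- function(m, i, j) m[min(max(i, 1), nrow(m)), min(max(j, 1), ncol(m))]
    out <- matrix(0, nrow(phi), ncol(phi))
    for (i in 1:nrow(phi)) for (j in 1:ncol(phi)) {
      gr <- function(m, i, j) c((at(m, i + 1, j) - at(m, i - 1, j)) / 2,
                                (at(m, i, j + 1) - at(m, i, j - 1)) / 2)
      # normalised gradient field for the divergence
      nx <- matrix(0, nrow(phi), ncol(phi)); ny <- nx
      for (a in 1:nrow(phi)) for (b in 1:ncol(phi)) {
        g <- gr(phi, a, b); mag <- sqrt(sum(g^2)) + eta
        nx[a, b] <- g[1] / mag; ny[a, b] <- g[2] / mag
      }
      kap <- (at(nx, i + 1, j) - at(nx, i - 1, j)) / 2 +
        (at(ny, i, j + 1) - at(ny, i, j - 1)) / 2
      lap <- at(phi, i + 1, j) + at(phi, i - 1, j) +
        at(phi, i, j + 1) + at(phi, i, j - 1) - 4 * at(phi, i, j)
      dlt <- (1 / pi) * eps / (eps^2 + phi[i, j]^2)
      out[i, j] <- -dlt * (e1[i, j] - e2[i, j]) + nu * dlt * kap +
        mu * (lap - kap)
    }
    out
  }
  phi <- matrix(rnorm(n * n, sd = 2), n, n)
  e1 <- matrix(rnorm(n * n), n, n); e2 <- matrix(rnorm(n * n), n, n)
  st <- level_set_state(phi, n_phases = 2)
  stepped <- evolve_two_phase(st, list(e1, e2), params)
  expect_equal(stepped$phi[[1]],
               phi + 0.1 * rhs_oracle(phi, e1, e2, params$nu, params$mu),
               tolerance = 1e-12)
})

test_that("multiphase evolution respects the partition-derivative identity", {
  set.seed(14)
  n <- 8
  params <- evolution_params(dt = 0.1, mu = 1, nu = 65.025)
  phi1 <- matrix(rnorm(n * n, sd = 2), n, n)
  phi2 <- matrix(rnorm(n * n, sd = 2), n, n)
  st <- level_set_state(list(phi1, phi2), n_phases = 4)

  # equal evidence in all regions: the data term vanishes, so the update
  # must equal the pure nu/mu geometric flow
  e_const <- replicate(4, matrix(3.7, n, n), simplify = FALSE)
  out <- evolve_multiphase(st, e_const, params)
  geo <- function(phi) {
    kap <- curvature(phi)
    phi + 0.1 * (params$nu * delta_eps(phi, 1) * kap +
                   params$mu * (lsbias:::laplacian5(phi) - kap))
  }
  expect_equal(out$phi[[1]], geo(phi1), tolerance = 1e-12)
  expect_equal(out$phi[[2]], geo(phi2), tolerance = 1e-12)

  # direct RHS oracle for the data term of phi1 (N = 3)
  st3 <- level_set_state(list(phi1, phi2), n_phases = 3)
  e <- replicate(3, matrix(rnorm(n * n), n, n), simplify = FALSE)
  params0 <- evolution_params(nu = 0, mu = 0)
  out3 <- evolve_multiphase(st3, e, params0)
  h2 <- heaviside_eps(phi2, 1); d1 <- delta_eps(phi1, 1)
  data1 <- d1 * h2 * e[[1]] + d1 * (1 - h2) * e[[2]] - d1 * e[[3]]
  expect_equal(out3$phi[[1]], phi1 - 0.1 * data1, tolerance = 1e-12)

  # N = 3: when region 3 is much cheaper, phi1 decreases near its zero set
  e3 <- list(matrix(5, n, n), matrix(5, n, n), matrix(-5, n, n))
  out_s <- evolve_multiphase(st3, e3, params0)
  band <- abs(phi1) < 1
  expect_true(all(out_s$phi[[1]][band] < phi1[band]))
})

test_that("the distance regulariser drives the gradient magnitude toward 1", {
  # pure mu flow from a binary step: the median |grad phi| near the zero set
  # approaches 1 (slowly, since the flow only acts where gradients exist)
  st <- initialize_level_set(c(64, 64),
                             list(type = "disc", center = c(32, 32), radius = 14))
  params <- evolution_params(nu = 0)
  e0 <- list(matrix(0, 64, 64), matrix(0, 64, 64))
  r0 <- distance_regularizer(st$phi[[1]])
  for (i in 1:400) st <- evolve_two_phase(st, e0, params)
  r1 <- distance_regularizer(st$phi[[1]])
  expect_lt(r1, r0)
  band <- abs(st$phi[[1]]) < 3
  med <- stats::median(lsbias:::grad_magnitude(st$phi[[1]])[band])
  expect_gt(med, 0.8)
  expect_lt(med, 1.2)
})
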