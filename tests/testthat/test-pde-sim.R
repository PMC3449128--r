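test_that("Neumann eigenmodes carry the closed-form eigenvalues on intervals and rectangles", {
  g <- grid_spec(pi, 41)
  modes <- neumann_laplacian_modes(g, 3)
  expect_equal(modes[[1]]$mu, 0)
  expect_true(all(modes[[1]]$phi == 1))
  expect_equal(modes[[2]]$mu, 1)
  expect_equal(modes[[2]]$phi, cos(g$coords[[1]]))

  g2 <- grid_spec(c(pi, 2 * pi), c(13, 17))
  m2 <- neumann_laplacian_modes(g2, 4)
  expect_equal(vapply(m2, `[[`, numeric(1), "mu"), c(0, 0.25, 1, 1))

  expect_error(neumann_laplacian_modes(g, 0), class = "fbr_invalid_input")
  expect_error(neumann_laplacian_modes(g, 1000), class = "fbr_invalid_input")
  expect_error(grid_spec(pi, 5), class = "fbr_invalid_input")
  expect_error(grid_spec(-1, 20), class = "fbr_invalid_input")
})

test_that("discrete Neumann Laplacian eigenvalues converge at second order", {
  err_at <- function(n) {
    g <- grid_spec(pi, n)
    L <- as.matrix(fbrstab:::.grid_laplacian(g))
    ev <- sort(eigen(-L, only.values = TRUE)$values)
    abs(ev[2] - 1) # first nonconstant interval mode has mu = 1
  }
  e1 <- err_at(21); e2 <- err_at(41)
  ratio <- e1 / e2
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("the linearized simulator is exactly zero on zero data and tracks modal rates", {
  p <- default_params()
  co <- linear_coefficients(p, interior_equilibrium(p))
  g <- grid_spec(pi, 61)
  zero <- matrix(0, 5, 61)
  sol0 <- simulate_linearized(co, p, zero, g, t_end = 1, n_out = 5)
  expect_true(all(sol0$fields == 0))

  # eigenvector of the discrete mode-1 matrix: pure exponential at its rate
  h <- g$h[1]
  mu_h <- (4 / h^2) * sin(h / 2)^2
  ev <- eigen(-modal_matrix(co, p, mu_h))
  i <- which(abs(Im(ev$values)) < 1e-12)[1]
  rate_h <- Re(ev$values[i])
  v <- Re(ev$vectors[, i])
  init <- outer(v, cos(g$coords[[1]]))
  sol <- simulate_linearized(co, p, init, g, t_end = 3, n_out = 31)
  fit <- growth_rate_estimate(sol)
  expect_equal(fit$rate, rate_h, tolerance = 1e-5)
  expect_gt(fit$r_squared, 1 - 1e-10)
  # continuum modal prediction for the same branch within 5%
  cont <- modal_eigenvalues(co, p, 1)$sigma
  rate_cont <- Re(cont[which.min(abs(Re(cont) - rate_h))])
  expect_lt(abs(fit$rate - rate_cont) / abs(rate_cont), 0.05)
})

test_that("the modal-rate discretization error shrinks at second order", {
  p <- default_params()
  co <- linear_coefficients(p, interior_equilibrium(p))
  rate_err <- function(n) {
    g <- grid_spec(pi, n)
    h <- g$h[1]
    mu_h <- (4 / h^2) * sin(h / 2)^2
    ev <- eigen(-modal_matrix(co, p, mu_h))
    # track the debris branch, whose eigenvalue is exactly -b11 - Dd*mu
    i <- which.min(Mod(ev$values - (-co$b11 - p$Dd * mu_h)))
    init <- outer(Re(ev$vectors[, i]), cos(g$coords[[1]]))
    sol <- simulate_linearized(co, p, init, g, t_end = 3, n_out = 31,
                               rtol = 1e-10, atol = 1e-12)
    sig1_cont <- -co$b11 - p$Dd * 1 # continuum rate of the same branch
    abs(growth_rate_estimate(sol)$rate - sig1_cont)
  }
  e1 <- rate_err(21); e2 <- rate_err(41)
  expect_gt(e1 / e2, 3)
  expect_lt(e1 / e2, 5)
})

test_that("spatially uniform data reduces the nonlinear PDE to the reaction ODE", {
  p <- default_params()
  eq <- interior_equilibrium(p)
  g <- grid_spec(1, 21)

  # at the uniform equilibrium the solution is constant in space and time
  s_eq <- equilibrium_state(eq)
  sol_eq <- simulate_full(p, outer(s_eq, rep(1, 21)), g, t_end = 4, n_out = 9)
  dev <- max(abs(sweep(sol_eq$fields, 2, s_eq)))
  expect_lt(dev, 1e-6)

  # off-equilibrium uniform data tracks the ODE integrator pointwise
  s0 <- s_eq * c(1.2, 0.8, 1.1, 1.15, 0.9)
  sol <- simulate_full(p, outer(s0, rep(1, 21)), g, t_end = 5, n_out = 21)
  tr <- integrate_reactions(s0, p, 5, n_out = 21)
  expect_lt(max(abs(sol$fields[, , 11] - as.matrix(tr[, -1]))), 1e-6)
})

test_that("small perturbations of a reaction-stable equilibrium decay in L2", {
  p <- default_params()
  eq <- interior_equilibrium(p)
  g <- grid_spec(pi, 41)
  set.seed(42)
  base <- outer(equilibrium_state(eq), rep(1, 41))
  wob <- outer(rep(1, 5), cos(g$coords[[1]])) * 0.02 +
    matrix(stats::rnorm(5 * 41, sd = 0.002), 5, 41)
  sol <- simulate_full(p, pmax(base + wob, 0), g, t_end = 25, n_out = 26)
  dev_norm <- function(i) {
    sqrt(sum((sol$fields[i, , ] - base)^2 %*% fbrstab:::.grid_weights(g)))
  }
  expect_lt(dev_norm(26), 0.1 * dev_norm(1))
})

test_that("growth-rate estimation is exact on synthetic exponentials and validates input", {
  t <- seq(0, 10, length.out = 50)
  syn <- list(times = t, l2_norms = exp(-0.5 * t))
  fit <- growth_rate_estimate(syn)
  expect_equal(fit$rate, -0.5, tolerance = 1e-12)

  flat <- list(times = t, l2_norms = rep(2, 50))
  expect_equal(growth_rate_estimate(flat)$rate, 0, tolerance = 1e-12)

  bad <- list(times = t, l2_norms = c(rep(1, 49), 0))
  expect_error(growth_rate_estimate(bad), class = "fbr_invalid_input")
  expect_error(growth_rate_estimate(syn, window = c(0, 0.1)),
               class = "fbr_invalid_input")
})

test_that("the blow-up cap truncates a growing run and flags it", {
  cx <- counterexample_params(regime = "unstable")
  g <- grid_spec(pi, 41)
  init <- outer(rep(1, 5), cos(g$coords[[1]]))
  # the integrator legitimately complains while the norm explodes
  sol <- suppressWarnings(
    simulate_linearized(cx$coefficients, cx$params, init, g,
                        t_end = 80, n_out = 81, cap = 100))
  expect_true(sol$blowup)
  expect_lt(length(sol$times), 81)
  expect_true(all(sol$l2_norms <= 100 * sol$l2_norms[1]))
})

test_that("2D linearized runs decay at the tensor-mode rate", {
  p <- default_params()
  co <- linear_coefficients(p, interior_equilibrium(p))
  g <- grid_spec(c(pi, 2 * pi), c(17, 21))
  mode <- neumann_laplacian_modes(g, 2)[[2]] # (0,1): mu = 0.25
  ev <- eigen(-modal_matrix(co, p, mode$mu))
  i <- which(abs(Im(ev$values)) < 1e-12)[1]
  init <- outer(Re(ev$vectors[, i]), as.numeric(mode$phi))
  sol <- simulate_linearized(co, p, init, g, t_end = 2, n_out = 21)
  fit <- growth_rate_estimate(sol)
  expect_equal(fit$rate, Re(ev$values[i]), tolerance = 0.02)
})
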