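test_that("the modal matrix reduces to the reaction matrix at mu = 0 and places the chemotaxis entries", {
  p <- default_params()
  co <- linear_coefficients(p, interior_equilibrium(p))
  expect_equal(modal_matrix(co, p, 0), reaction_matrix(co))
  mu <- 1.7
  M <- modal_matrix(co, p, mu)
  expect_equal(M["m", "c"], -(co$chim * mu - co$b42))
  expect_equal(M["f", "c"], -(co$chif * mu - co$b32))
  expect_equal(M["e", "c"], -co$chie2 * mu)
  expect_equal(M["e", "f"], -(co$chie1 * mu - co$b53))
  expect_equal(M["d", "d"], co$b11 + p$Dd * mu)
  expect_error(modal_matrix(co, p, -0.1), class = "fbr_invalid_input")
})

test_that("the characteristic polynomial factors into the 3-block and the two damped scalars", {
  # arbitrary coefficients, including nonzero b44 and b14
  co <- linear_coefficient_set(b11 = 0.9, b14 = 0.3, b21 = -0.8, b22 = 1.4,
                               b24 = -0.5, b32 = -0.2, b33 = 0.7, b34 = -0.4,
                               b42 = -1.1, b44 = 0.25, b53 = -0.15, b55 = 0.6,
                               chif = 0.2, chim = 0.35, chie1 = 0.1, chie2 = 0.05)
  p <- list(Dd = 0.4, Dc = 1.2, Df = 0.9, Dm = 0.7, De = 1.5)
  mu <- 2.3
  M <- modal_matrix(co, p, mu)
  for (s in c(-1.1, 0.4, 2.2)) {
    lhs <- det(M + s * diag(5))
    B1 <- matrix(c(
      s + p$Dd * mu + co$b11, 0, co$b14,
      co$b21, s + p$Dc * mu + co$b22, co$b24,
      0, -(co$chim * mu - co$b42), s + p$Dm * mu + co$b44), 3, 3, byrow = TRUE)
    rhs <- (s + p$De * mu + co$b55) * (s + p$Df * mu + co$b33) * det(B1)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("closed-form modal eigenvalues match the dense eigensolver over mu grids", {
  sets <- random_param_sets(40, branch = "both", seed0 = 4000L)
  mu_grid <- default_mu_grid(L = pi, n = 20)
  for (p in sets) {
    co <- linear_coefficients(p, interior_equilibrium(p))
    for (mu in mu_grid) {
      cf <- modal_eigenvalues(co, p, mu)
      num <- eigen(-modal_matrix(co, p, mu), only.values = TRUE)$values
      expect_lt(spectrum_match_error(cf$sigma, num), 1e-9)
    }
  }
})

test_that("reaction stability forces every mode to be damped (epsilon stays negative)", {
  sets <- random_param_sets(30, branch = "Eq14", seed0 = 4100L)
  for (p in sets) {
    co <- linear_coefficients(p, interior_equilibrium(p))
    expect_gt(co$b24, 0)
    scan <- pde_stability_report(co, p, default_mu_grid(L = pi, n = 30))
    expect_identical(scan$ode$classification, "asymptotically_stable")
    expect_true(scan$stable)
    expect_true(all(scan$table$epsilon[scan$table$mu > 0] < 0))
    expect_true(all(scan$table$cond_damping))
  }
})

test_that("with zero mobilities the modal spectrum replicates the reaction spectrum at every mu", {
  pu <- default_params("unstable_b24")
  co <- linear_coefficients(pu, interior_equilibrium(pu))
  co$chim <- 0
  p0 <- list(Dd = 0, Dc = 0, Df = 0, Dm = 0, De = 0)
  sig0 <- ode_eigenvalues(co)
  for (mu in c(0, 1, 10)) {
    cf <- modal_eigenvalues(co, p0, mu)
    expect_lt(spectrum_match_error(cf$sigma, sig0), 1e-12)
  }
  scan <- pde_stability_report(co, p0, c(0, 1, 10))
  expect_false(scan$stable)
  expect_identical(scan$ode$classification, "unstable")
})

test_that("diffusive damping of sigma1, sigma4, sigma5 is exactly affine in mu", {
  p <- default_params()
  co <- linear_coefficients(p, interior_equilibrium(p))
  s0 <- modal_eigenvalues(co, p, 0)$sigma
  s1 <- modal_eigenvalues(co, p, 1)$sigma
  s2 <- modal_eigenvalues(co, p, 2)$sigma
  expect_equal(unname(Re(s1 - s0)[c(1, 4, 5)]), -c(p$Dd, p$Df, p$De))
  expect_equal(unname(Re(s2 - s1)[c(1, 4, 5)]), -c(p$Dd, p$Df, p$De))
})

test_that("the mobility threshold marks the marginal boundary of the unstable mode", {
  # shrink the mobilities so the unstable reaction mode survives at mu = 1
  pu <- model_params(Dm = 0.05, Dc = 0.05, base = default_params("unstable_b24"))
  co <- linear_coefficients(pu, interior_equilibrium(pu))
  mu <- 1
  thr <- diffusion_stabilization_threshold(co, pu, mu)
  expect_false(thr$damped)
  expect_identical(thr$damped, thr$epsilon < 0)

  # placing chim exactly on the bound makes epsilon vanish -> sigma3 = 0
  co_b <- co; co_b$chim <- thr$chim_max
  cf <- modal_eigenvalues(co_b, pu, mu)
  expect_lt(abs(cf$epsilon), 1e-10)
  expect_lt(abs(max(Re(cf$sigma[c("sigma2", "sigma3")]))), 1e-8)

  # increasing macrophage mobility tenfold beyond the bound damps the pair
  pu10 <- pu; pu10$Dm <- 10 * max(pu$Dm, thr$Dm_min)
  cf10 <- modal_eigenvalues(co, pu10, mu)
  expect_lt(max(Re(cf10$sigma[c("sigma2", "sigma3")])), 0)

  # pushing chim above the bound re-creates a growing root
  co_hi <- co; co_hi$chim <- thr$chim_max + 1
  cf_hi <- modal_eigenvalues(co_hi, pu, mu)
  expect_gt(cf_hi$epsilon, 0)
  expect_gt(max(Re(cf_hi$sigma)), 0)

  expect_error(diffusion_stabilization_threshold(co, pu, 0),
               class = "fbr_invalid_input")
  co_pos <- co; co_pos$b24 <- 0.5
  expect_error(diffusion_stabilization_threshold(co_pos, pu, 1),
               class = "fbr_invalid_input")
})

test_that("mu grids are validated", {
  p <- default_params()
  co <- linear_coefficients(p, interior_equilibrium(p))
  g <- default_mu_grid(L = pi, n = 60)
  expect_length(g, 60)
  expect_identical(g[1], 0)
  expect_true(all(diff(g) > 0))
  expect_error(pde_stability_report(co, p, numeric(0)), class = "fbr_invalid_input")
  expect_error(pde_stability_report(co, p, c(1, 2)), class = "fbr_invalid_input")
  expect_error(pde_stability_report(co, p, c(0, -1)), class = "fbr_invalid_input")
})
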