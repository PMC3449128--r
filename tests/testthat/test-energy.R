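test_that("Poincare constants follow the zero-mean Neumann closed forms", {
  expect_equal(poincare_constant(domain_spec("interval", pi)), 1)
  expect_equal(poincare_constant(domain_spec("interval", 2 * pi)), 0.25)
  expect_equal(poincare_constant(domain_spec("rectangle", c(pi, 2 * pi))), 0.25)
  expect_equal(poincare_constant(domain_spec("interval", 1, Cp = 3)), 3)
  expect_error(domain_spec("interval", -1), class = "fbr_invalid_input")
  expect_error(domain_spec("rectangle", pi), class = "fbr_invalid_input")
})

test_that("the rectangle constant matches the discrete Neumann Laplacian spectrum", {
  g <- grid_spec(c(pi, 2 * pi), c(17, 25))
  L <- as.matrix(fbrstab:::.grid_laplacian(g))
  ev <- sort(eigen(-L, only.values = TRUE)$values)
  # smallest nonzero discrete eigenvalue -> continuum constant, O(h^2)
  expect_equal(ev[2], 0.25, tolerance = 5e-3)
  expect_lt(abs(ev[1]), 1e-10)
})

test_that("each printed condition agrees with an independent PSD oracle for its quadratic form", {
  sets <- random_param_sets(60, branch = "both", seed0 = 5000L)
  dom <- domain_spec("interval", pi)
  for (p in sets) {
    rep <- energy_conditions_report(p, d = dom)
    for (cd in rep$conditions) {
      if (!cd$applicable) next
      lam_min <- form_min_eigenvalue(cd$a, cd$cross, cd$c)
      scale <- max(1, abs(cd$a), abs(cd$c))
      if (abs(lam_min) > 1e-10 * scale) {
        expect_identical(cd$holds, lam_min > 0,
                         label = sprintf("condition %d (%s)", cd$id, cd$form))
      }
      expect_identical(cd$holds, cd$psd)
    }
  }
})

test_that("large diffusivities make all eight conditions hold, even for reaction-unstable kinetics", {
  for (regime in c("stable", "unstable_b24")) {
    p <- default_params(regime)
    big <- model_params(Dd = 1000, Dc = 1000, Df = 1000, Dm = 1000, De = 1000,
                        base = p)
    rep <- energy_conditions_report(big, d = domain_spec("interval", pi))
    expect_identical(rep$overall, "asymptotically-stable")
    expect_true(all(vapply(rep$conditions, function(cd) cd$strict, logical(1))))
  }
})

test_that("chemotaxis just above the gradient-form bound breaks exactly that condition", {
  cx <- counterexample_params(regime = "stable",
                              chi_m = 1.01 * counterexample_params(regime = "stable")$thresholds$chim_stable_max)
  c5 <- cx$conditions$conditions$condition5
  expect_false(c5$holds)
  expect_lt(c5$margin, 0)
  # the neighbouring gradient conditions are untouched
  expect_true(cx$conditions$conditions$condition6$holds)
  expect_true(cx$conditions$conditions$condition8$holds)
})

test_that("condition 3 is reported not-applicable when its well-posedness check fails", {
  cx <- counterexample_params(regime = "stable", free = list(a0 = 5))
  c3 <- cx$conditions$conditions$condition3
  expect_false(c3$applicable)
  expect_match(c3$note, "well-posedness")
  expect_identical(cx$conditions$overall, "inconclusive")
})

test_that("the auxiliary constant equals the squared equilibrium root term", {
  p <- default_params()
  eq <- interior_equilibrium(p)
  rep <- energy_conditions_report(p, eq, domain_spec("interval", pi))
  expect_equal(rep$A_value, eq$L1^2, tolerance = 1e-12)
  expect_equal(sqrt(rep$A_value), rep$coefficients$b33, tolerance = 1e-12)
})

test_that("the Lyapunov functional evaluates constants exactly and rejects mismatched grids", {
  g <- grid_spec(1, 11)
  zero <- rep(0, 11)
  expect_identical(
    lyapunov_functional(list(d = zero, c = zero, f = zero, m = zero, e = zero),
                        0.4, g), 0)
  expect_equal(
    lyapunov_functional(list(d = rep(1, 11), c = zero, f = zero, m = zero,
                             e = zero), 0.4, g), 0.5)
  expect_error(
    lyapunov_functional(list(d = rep(1, 7), c = zero, f = zero, m = zero,
                             e = zero), 0.4, g),
    class = "fbr_invalid_input")
})

test_that("the energy is nonincreasing along a zero-mean run when all conditions hold", {
  p <- default_params()
  dom <- domain_spec("interval", pi)
  rep <- energy_conditions_report(p, d = dom)
  expect_identical(rep$overall, "asymptotically-stable")

  g <- grid_spec(pi, 61)
  co <- linear_coefficients(p, interior_equilibrium(p))
  phi <- neumann_laplacian_modes(g, 3)
  init <- outer(c(1, -0.5, 0.8, 0.6, -0.7), phi[[2]]$phi) +
    outer(c(0.3, 0.2, -0.4, 0.1, 0.5), phi[[3]]$phi)
  sol <- simulate_linearized(co, p, init, g, t_end = 6, n_out = 61)
  en <- lyapunov_series(sol, p$lambda1)
  expect_true(all(diff(en) <= 1e-8 * en[1]))
  expect_lt(en[61], 0.05 * en[1])
  # zero-mean data stays zero-mean under the no-flux walls
  expect_lt(max(abs(sol$means)), 1e-8 * max(abs(init)))
})

test_that("the counter-example construction realizes both sides of the dichotomy", {
  un <- counterexample_params(regime = "unstable")
  expect_gt(max(Re(un$modal$sigma)), 0)
  expect_gt(un$thresholds$epsilon, 0)
  expect_identical(un$predicted_sign, 1)
  # the reaction system itself is unstable (b24 < 0): the decay below is
  # genuinely conditional on the spatial structure
  ode_un <- ode_stability_report(un$coefficients)
  expect_lt(un$coefficients$b24, 0)
  expect_identical(ode_un$classification, "unstable")

  st <- counterexample_params(regime = "stable")
  expect_lt(max(Re(st$modal$sigma)), 0)
  expect_lt(st$thresholds$epsilon, 0)
  expect_identical(st$conditions$overall, "asymptotically-stable")
  expect_lt(st$coefficients$b24, 0)
  # printed construction identities
  expect_equal(st$coefficients$b22, 0.8 * 1)
  expect_equal(st$coefficients$b24, -sqrt(1 / 20))
  expect_gte(-st$coefficients$b42, st$a0)
})
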