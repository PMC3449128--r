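# Energy-method (Lyapunov) stability machinery ---------------------------

#' Domain specification
#'
#' Interval or rectangle with its Poincare constant for zero-mean Neumann
#' data, i.e. the constant in `Cp*Int(u^2) <= Int(|grad u|^2) + (Int u)^2`.
#' For an interval of length `L` the sharp constant is `(pi/L)^2`; for a
#' rectangle it is the minimum over the two axes. A user override is
#' allowed (e.g. a non-sharp constant for a different geometry).
#'
#' @param kind `"interval"` or `"rectangle"`.
#' @param lengths positive lengths (1 for interval, 2 for rectangle).
#' @param Cp optional override of the Poincare constant.
#' @return an `fbr_domain`: list with `kind`, `lengths`, `Cp`.
#' @export
#' @examples
#' domain_spec("interval", pi)$Cp # 1
domain_spec <- function(kind = c("interval", "rectangle"), lengths, Cp = NULL) {
  kind <- match.arg(kind)
  lengths <- as.numeric(lengths)
  n_expected <- if (kind == "interval") 1L else 2L
  if (length(lengths) != n_expected || any(!is.finite(lengths)) || any(lengths <= 0)) {
    .stop_fbr(sprintf("%s requires %d strictly positive length(s)", kind, n_expected),
              "fbr_invalid_input")
  }
  if (is.null(Cp)) {
    Cp <- min((pi / lengths)^2)
  } else if (!.is_scalar_number(Cp) || Cp <= 0) {
    .stop_fbr("Cp override must be a positive number", "fbr_invalid_input")
  }
  structure(list(kind = kind, lengths = lengths, Cp = Cp), class = "fbr_domain")
}

#' Poincare constant of a domain
#'
#' @param d an `fbr_domain`.
#' @return the constant `Cp > 0`.
#' @export
poincare_constant <- function(d) {
  if (!inherits(d, "fbr_domain")) {
    .stop_fbr("d must be an fbr_domain (see domain_spec())", "fbr_invalid_input")
  }
  d$Cp
}

# One 2x2 quadratic form a*x^2 + b*x*y + c*y^2 evaluated two ways:
# the printed-inequality route sqrt(a*c) >= |b|/2 and the discriminant
# route b^2 <= 4*a*c. Both are carried in the report and must agree.
.form_condition <- function(id, form, a, cross, c_) {
  lhs <- if (a >= 0 && c_ >= 0) sqrt(a * c_) else NA_real_
  margin <- if (is.na(lhs)) -Inf else lhs - abs(cross) / 2
  holds <- a >= 0 && c_ >= 0 && !is.na(lhs) && lhs >= abs(cross) / 2
  psd <- a >= 0 && c_ >= 0 && cross^2 <= 4 * a * c_
  list(id = id, form = form, a = a, cross = cross, c = c_,
       holds = holds, margin = margin, strict = holds && margin > 0,
       psd = psd, applicable = TRUE, note = NULL)
}

# Core evaluation from a coefficient-level description. `m2_extra` is the
# a11*me - a0 surplus entering the m^2 coefficient of B(c,m).
.energy_conditions_core <- function(co, diff, Cp, m2_extra) {
  Dd <- diff$Dd; Dc <- diff$Dc; Df <- diff$Df; Dm <- diff$Dm; De <- diff$De
  conds <- list(
    .form_condition(1L, "B(c,d)", Dc * Cp / 6 + co$b22, co$b21, co$b11 + Dd * Cp),
    .form_condition(2L, "B(f,m)", Df * Cp / 4 + co$b33, co$b34, Dm * Cp / 3),
    .form_condition(3L, "B(c,m)", Dc * Cp / 6 + co$b22, co$b24, Dm * Cp / 3 + m2_extra),
    .form_condition(4L, "B(c,f)", Dc * Cp / 6, co$b32, Df * Cp / 4),
    .form_condition(5L, "B(grad c, grad m)", Dc / 6, -co$chim, Dm / 3),
    .form_condition(6L, "B(grad c, grad f)", Dc / 6, -co$chif, Df / 4),
    .form_condition(7L, "B(grad f, grad e)", Df / 4, -co$chie1, De / 2),
    .form_condition(8L, "B(grad c, grad e)", Dc / 6, -co$chie2, De / 2)
  )
  # Condition 3 well-posedness: the m^2 coefficient itself must be >= 0.
  if (Dm * Cp / 3 + m2_extra < 0) {
    conds[[3]]$applicable <- FALSE
    conds[[3]]$holds <- FALSE
    conds[[3]]$strict <- FALSE
    conds[[3]]$note <- sprintf(
      "not applicable: Dm*Cp/3 + (a11*me - a0) = %g < 0 (well-posedness fails)",
      Dm * Cp / 3 + m2_extra)
  }
  # The two routes are algebraically equivalent; a disagreement beyond
  # rounding would mean a coding defect in one of them.
  for (cd in conds) {
    if (cd$applicable && cd$holds != cd$psd && abs(cd$margin) > 1e-12 * max(1, abs(cd$a), abs(cd$c))) {
      .stop_fbr(sprintf(
        "internal inconsistency in condition %d (%s): inequality route says %s, discriminant route says %s",
        cd$id, cd$form, cd$holds, cd$psd), "fbr_internal_error")
    }
  }
  applicable <- vapply(conds, function(x) x$applicable, logical(1))
  holds <- vapply(conds, function(x) x$holds, logical(1))
  strict <- vapply(conds, function(x) x$strict, logical(1))
  overall <- if (!all(applicable)) {
    "inconclusive"
  } else if (all(strict)) {
    "asymptotically-stable"
  } else if (all(holds)) {
    "Lyapunov-stable"
  } else {
    "inconclusive"
  }
  names(conds) <- paste0("condition", 1:8)
  list(conditions = conds, overall = overall, Cp = Cp)
}

#' Sufficient energy-method stability conditions
#'
#' Evaluates the eight sufficient conditions under which the energy
#' estimate closes for zero-mean perturbations: each condition demands
#' positive semidefiniteness of one 2x2 quadratic form that splits the
#' diffusive dissipation (via the Poincare constant for the reaction-level
#' forms, directly for the gradient-level forms) against one off-diagonal
#' reaction or chemotaxis coupling. The quadratic coefficient of `d^2` in
#' the chemoattractant/debris form is `b11 + Dd*Cp` (the term the estimate
#' actually produces); the alternate flattened reading `f0 + Dd*Cp` is
#' recorded in the report for cross-reference. Condition 3 requires a
#' well-posedness check (`Dm*Cp/3 + a11*me - a0 >= 0`); when it fails the
#' condition is reported as not applicable rather than false by fiat.
#'
#' Each condition is evaluated twice -- as the printed inequality
#' `sqrt(a*c) >= |cross|/2` and as the discriminant test
#' `cross^2 <= 4*a*c` -- and the two must agree.
#'
#' All eight holding with strict margins certifies asymptotic stability of
#' zero-mean perturbations; holding non-strictly certifies Lyapunov
#' stability.
#'
#' @param p an `fbr_params` object.
#' @param eq an `fbr_equilibrium` (defaults to `interior_equilibrium(p)`).
#' @param d an `fbr_domain`.
#' @return an `fbr_condition_report`: per-condition entries (`holds`,
#'   `margin`, `strict`, `psd`, `applicable`), `overall` verdict, the
#'   auxiliary constant `A_value` (square of the equilibrium root term
#'   `L1`, so that `b33 = sqrt(A)`), `Cp`, and `alternate_condition1`.
#' @export
energy_conditions_report <- function(p, eq = interior_equilibrium(p), d) {
  co <- linear_coefficients(p, eq)
  core <- .energy_conditions_core(co, p, poincare_constant(d),
                                  m2_extra = p$a11 * eq$me - p$a0)
  alt1 <- .form_condition(1L, "B(c,d) [printed d^2 coefficient]",
                          p$Dc * core$Cp / 6 + co$b22, co$b21,
                          p$f0 + p$Dd * core$Cp)
  structure(c(core, list(A_value = eq$L1^2, alternate_condition1 = alt1,
                         coefficients = co)),
            class = "fbr_condition_report")
}

#' @export
print.fbr_condition_report <- function(x, ...) {
  cat("<fbr_condition_report> overall:", x$overall,
      sprintf(" (Cp = %g)\n", x$Cp))
  for (cd in x$conditions) {
    cat(sprintf("  %d %-18s holds: %-5s margin: % .4g%s\n", cd$id, cd$form,
                cd$holds, cd$margin,
                if (!cd$applicable) paste0("  [", cd$note, "]") else ""))
  }
  invisible(x)
}

#' Lyapunov functional of a perturbation snapshot
#'
#' The weighted energy
#' `(1/2) * [ Int d^2 + lambda1 * Int (c^2 + f^2 + m^2 + e^2) ]`
#' whose monotone decay along solutions certifies stability. Integrals use
#' the trapezoidal rule on the uniform grid (matching the second-order
#' spatial discretization of the simulator).
#'
#' @param fields list with components `d, c, f, m, e`, each a vector (1D)
#'   or matrix (2D) on the nodes of `g`.
#' @param lambda1 classical macrophage fraction weighting the non-debris
#'   fields.
#' @param g an `fbr_grid`.
#' @return scalar energy value.
#' @export
lyapunov_functional <- function(fields, lambda1, g) {
  need <- c("d", "c", "f", "m", "e")
  if (!all(need %in% names(fields))) {
    .stop_fbr("fields must have components d, c, f, m, e", "fbr_invalid_input")
  }
  w <- .grid_weights(g)
  for (nm in need) {
    if (length(fields[[nm]]) != length(w)) {
      .stop_fbr(sprintf("field '%s' does not match the grid (%d values, %d nodes)",
                        nm, length(fields[[nm]]), length(w)), "fbr_invalid_input")
    }
  }
  quad <- function(u) sum(w * as.numeric(u)^2)
  0.5 * (quad(fields$d) +
           lambda1 * (quad(fields$c) + quad(fields$f) + quad(fields$m) + quad(fields$e)))
}

#' Lyapunov energy along a simulated solution
#'
#' @param sol an `fbr_field_solution`.
#' @param lambda1 weighting fraction, see [lyapunov_functional()].
#' @return numeric vector, one energy value per output time.
#' @export
lyapunov_series <- function(sol, lambda1) {
  vapply(seq_along(sol$times), function(i) {
    lyapunov_functional(list(
      d = sol$fields[i, 1, ], c = sol$fields[i, 2, ], f = sol$fields[i, 3, ],
      m = sol$fields[i, 4, ], e = sol$fields[i, 5, ]), lambda1, sol$grid)
  }, numeric(1))
}

#' Chemotaxis counter-example construction
#'
#' Coefficient-level construction on the interval `[0, pi]` (Poincare
#' constant 1, first nonconstant Neumann mode `cos x`, `mu = 1`) showing
#' that PDE behavior is genuinely conditional on the mobilities when the
#' reaction system is unstable: fix `b22 = (4/5)*Dc`,
#' `b24 = -sqrt(Dc*Dm/20) < 0` (so the reaction system is unstable through
#' `sigma3 > 0`), keep the remaining couplings at mild documented defaults
#' with `a11*me >= a0`, and choose the macrophage chemotaxis sensitivity
#' `chim` on one side of two derived thresholds:
#' below `chim_stable_max = sqrt(2*Dc*Dm)/3` every energy condition holds
#' and the `cos x` mode decays; above
#' `chim_growth_min = b42 + (9/5)*sqrt(20*Dc*Dm)` the modal quantity `eps`
#' at `mu = 1` turns positive and the mode grows without bound.
#'
#' @param Dc,Dm chemoattractant and macrophage diffusivities (> 0).
#' @param regime `"stable"` or `"unstable"`.
#' @param chi_m optional explicit sensitivity overriding the default
#'   placement (0.5x the stable bound, or the growth threshold plus a 50%
#'   margin of `max(1, |threshold|)`).
#' @param free named list overriding the remaining free coefficients
#'   (`b11, b21, b32, b33, b34, b42, b55, chif, chie1, chie2, a0,
#'   Dd, Df, De`).
#' @return an `fbr_counterexample`: list with `regime`, `chi_m`,
#'   `coefficients` (`fbr_lincoef`), `params` (diffusivities), `domain`,
#'   `mu`, `thresholds`, `modal` (spectrum at `mu = 1`), `predicted_sign`
#'   of the dominant modal real part, `conditions` (energy report at
#'   coefficient level), and `a0`.
#' @export
counterexample_params <- function(Dc = 1, Dm = 1,
                                  regime = c("stable", "unstable"),
                                  chi_m = NULL, free = list()) {
  regime <- match.arg(regime)
  if (!.is_scalar_number(Dc) || Dc <= 0 || !.is_scalar_number(Dm) || Dm <= 0) {
    .stop_fbr("Dc and Dm must be strictly positive", "fbr_invalid_input")
  }
  fr <- utils::modifyList(list(
    b11 = 1, b21 = -1, b32 = -0.1, b33 = 1, b34 = -0.1, b42 = -1, b55 = 1,
    chif = 0.1, chie1 = 0.1, chie2 = 0.1, a0 = 0.5, Dd = 1, Df = 1, De = 1
  ), free)
  b22 <- 0.8 * Dc
  b24 <- -sqrt(Dc * Dm / 20)
  chim_stable_max <- 2 * sqrt((Dc / 6) * (Dm / 3))       # Condition 5 boundary
  chim_growth_min <- fr$b42 + (9 / 5) * sqrt(20 * Dc * Dm) # eps > 0 at mu = 1
  if (is.null(chi_m)) {
    chi_m <- switch(regime,
      stable = 0.5 * chim_stable_max,
      unstable = chim_growth_min + 0.5 * max(1, abs(chim_growth_min))
    )
  }
  co <- linear_coefficient_set(
    b11 = fr$b11, b21 = fr$b21, b22 = b22, b24 = b24, b32 = fr$b32,
    b33 = fr$b33, b34 = fr$b34, b42 = fr$b42, b55 = fr$b55,
    chif = fr$chif, chim = chi_m, chie1 = fr$chie1, chie2 = fr$chie2
  )
  pars <- list(Dd = fr$Dd, Dc = Dc, Df = fr$Df, Dm = Dm, De = fr$De)
  dom <- domain_spec("interval", pi, Cp = 1)
  modal <- modal_eigenvalues(co, pars, 1)
  conds <- .energy_conditions_core(co, pars, Cp = 1,
                                   m2_extra = -co$b42 - fr$a0)
  structure(list(
    regime = regime, chi_m = chi_m, coefficients = co, params = pars,
    domain = dom, mu = 1,
    thresholds = list(chim_stable_max = chim_stable_max,
                      chim_growth_min = chim_growth_min,
                      epsilon = modal$epsilon),
    modal = modal,
    predicted_sign = sign(max(Re(modal$sigma))),
    conditions = conds, a0 = fr$a0
  ), class = "fbr_counterexample")
}

#' @export
print.fbr_counterexample <- function(x, ...) {
  cat("<fbr_counterexample> regime:", x$regime,
      sprintf(" chi_m = %.4g (stable bound %.4g, growth threshold %.4g)\n",
              x$chi_m, x$thresholds$chim_stable_max, x$thresholds$chim_growth_min))
  cat(sprintf("  mode mu = 1: max Re sigma = %.4g (eps = %.4g); energy verdict: %s\n",
              max(Re(x$modal$sigma)), x$thresholds$epsilon, x$conditions$overall))
  invisible(x)
}
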