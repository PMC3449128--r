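# Linearized reaction system ---------------------------------------------

.fbr_b_names <- c("b11", "b14", "b21", "b22", "b24", "b32", "b33", "b34",
                  "b42", "b44", "b53", "b55")
.fbr_chi_names <- c("chif", "chim", "chie1", "chie2")

#' Linearized coefficients at a state
#'
#' Jacobian entries `b_ij` of the reaction system and the linearized
#' chemotaxis coefficients, evaluated at a given (usually equilibrium)
#' state. Sign convention: the coefficients are stored exactly as they
#' appear in the linearized system written as `u' = -B u`, so eigenvalues
#' of `-B` are the growth rates. At the interior equilibrium,
#' `b44 = a0 - a11*ce`, `b14 = -(f0_tilde*lambda3 - f0*lambda1*de)` and
#' `b53 = -a16*(1 - ee/E0)` all vanish identically.
#'
#' Chemotaxis coefficients: `chif = fe*chi0`, `chim = chi1*me`,
#' `chie1 = Bcoef*Df*ee/F0`, `chie2 = Bcoef*chij*ee*fe/F0`.
#'
#' @param p an `fbr_params` object.
#' @param eq an `fbr_equilibrium` (or any list with fields
#'   `de, ce, fe, me, ee` for off-equilibrium linearization).
#' @return an `fbr_lincoef`: named list of the `b` and `chi` coefficients,
#'   carrying `lambda1` along for the energy machinery.
#' @export
linear_coefficients <- function(p, eq) {
  structure(list(
    b11 = p$f0 * p$lambda1 * eq$me,
    b14 = -(p$f0_tilde * p$lambda3 - p$f0 * p$lambda1 * eq$de),
    b21 = -p$f1,
    b22 = p$f3 * p$lambda2 * eq$me + p$f4,
    b24 = -(p$f2 * p$lambda3 - p$f3 * p$lambda2 * eq$ce),
    b32 = -p$a12 * eq$fe,
    b33 = -(p$a2 * (1 - 2 * eq$fe / p$F0) + p$a12 * eq$ce - p$a3),
    b34 = -p$a1 * p$lambda1,
    b42 = -p$a11 * eq$me,
    b44 = p$a0 - p$a11 * eq$ce,
    b53 = -p$a16 * (1 - eq$ee / p$E0),
    b55 = p$a16 * eq$fe / p$E0,
    chif = eq$fe * p$chi0,
    chim = p$chi1 * eq$me,
    chie1 = p$Bcoef * p$Df * eq$ee / p$F0,
    chie2 = p$Bcoef * p$chij * eq$ee * eq$fe / p$F0,
    lambda1 = p$lambda1
  ), class = "fbr_lincoef")
}

#' Assemble a coefficient set directly
#'
#' Builds an `fbr_lincoef` from explicitly given entries (defaults 0),
#' bypassing any kinetic parameter set. Used for coefficient-level
#' constructions such as the chemotaxis counter-example.
#'
#' @param ... named entries among
#'   `b11, b14, b21, b22, b24, b32, b33, b34, b42, b44, b53, b55`,
#'   `chif, chim, chie1, chie2`, `lambda1`.
#' @return an `fbr_lincoef`.
#' @export
linear_coefficient_set <- function(...) {
  co <- stats::setNames(
    as.list(rep(0, length(.fbr_b_names) + length(.fbr_chi_names) + 1L)),
    c(.fbr_b_names, .fbr_chi_names, "lambda1"))
  co$lambda1 <- 1
  dots <- list(...)
  unknown <- setdiff(names(dots), names(co))
  if (length(unknown)) {
    .stop_fbr(paste0("unknown coefficient(s): ", paste(unknown, collapse = ", ")),
              "fbr_invalid_input")
  }
  co[names(dots)] <- dots
  structure(co, class = "fbr_lincoef")
}

#' Reaction matrix B
#'
#' The 5x5 matrix of the linearized reaction system `u' = -B u`, rows and
#' columns in the order `(d, c, f, m, e)`.
#'
#' @param co an `fbr_lincoef`.
#' @return 5x5 numeric matrix with dimnames `d, c, f, m, e`.
#' @export
reaction_matrix <- function(co) {
  B <- matrix(0, 5, 5, dimnames = list(c("d", "c", "f", "m", "e"),
                                       c("d", "c", "f", "m", "e")))
  B["d", "d"] <- co$b11; B["d", "m"] <- co$b14
  B["c", "d"] <- co$b21; B["c", "c"] <- co$b22; B["c", "m"] <- co$b24
  B["f", "c"] <- co$b32; B["f", "f"] <- co$b33; B["f", "m"] <- co$b34
  B["m", "c"] <- co$b42; B["m", "m"] <- co$b44
  B["e", "f"] <- co$b53; B["e", "e"] <- co$b55
  B
}

.coef_scale <- function(co) {
  max(1, abs(unlist(co[.fbr_b_names])))
}

#' Closed-form eigenvalues of the reaction system
#'
#' With the equilibrium identities `b44 = b14 = 0`, the spectrum of `-B`
#' factors into a 3-block (debris/chemoattractant/macrophage) and a
#' triangular 2-block, giving
#' `sigma1 = -b11`,
#' `sigma2,3 = (-b22 -/+ sqrt(b22^2 + 4 b42 b24)) / 2`,
#' `sigma4 = -b33`, `sigma5 = -b55`.
#' When the identities do not hold (off-equilibrium coefficients) the
#' function warns and falls back to a dense numeric eigensolve of `-B`.
#'
#' @param co an `fbr_lincoef`.
#' @param force_numeric always use the numeric eigensolver.
#' @return named complex 5-vector `sigma1..sigma5`, with attribute
#'   `method` (`"closed_form"` or `"numeric"`).
#' @export
ode_eigenvalues <- function(co, force_numeric = FALSE) {
  off <- max(abs(co$b44), abs(co$b14))
  if (force_numeric || off > 1e-8 * .coef_scale(co)) {
    if (!force_numeric) {
      warning("b44 and b14 are not zero (coefficients not at the interior ",
              "equilibrium); using the numeric eigensolver", call. = FALSE)
    }
    ev <- eigen(-reaction_matrix(co), only.values = TRUE)$values
    ev <- as.complex(ev[order(-Re(ev), -Im(ev))])
    return(structure(stats::setNames(ev, paste0("sigma", 1:5)), method = "numeric"))
  }
  disc <- sqrt(as.complex(co$b22^2 + 4 * co$b42 * co$b24))
  sig <- c(sigma1 = as.complex(-co$b11),
           sigma2 = (-co$b22 - disc) / 2,
           sigma3 = (-co$b22 + disc) / 2,
           sigma4 = as.complex(-co$b33),
           sigma5 = as.complex(-co$b55))
  structure(sig, method = "closed_form")
}

#' Stability classification of the reaction system
#'
#' Classifies the interior equilibrium from the closed-form spectrum and
#' reports the two parameter conditions with their margins: `b33 > 0`
#' (fibroblast logistic growth plus chemoattractant-driven proliferation
#' overcome by fibroblast death; automatic at the interior equilibrium,
#' where `b33` equals the square-root term `L1 > 0`) and `b24 > 0`
#' (regulatory macrophage clearance of the chemoattractant outweighing
#' inflammatory production; the binding condition).
#'
#' @param co an `fbr_lincoef`.
#' @param tol tolerance on the maximal real part: below `-tol` is
#'   asymptotically stable, within `[-tol, tol]` marginal, above unstable.
#' @return an `fbr_stability` report: eigenvalues, `max_re`,
#'   `classification`, named `conditions` with margins, `interpretation`.
#' @export
ode_stability_report <- function(co, tol = 1e-10) {
  sig <- ode_eigenvalues(co)
  max_re <- max(Re(sig))
  classification <- if (max_re < -tol) {
    "asymptotically_stable"
  } else if (max_re <= tol) {
    "marginal"
  } else {
    "unstable"
  }
  structure(list(
    eigenvalues = sig,
    max_re = max_re,
    classification = classification,
    tol = tol,
    conditions = list(
      b33_positive = list(holds = co$b33 > 0, margin = co$b33),
      b24_positive = list(holds = co$b24 > 0, margin = co$b24)
    ),
    interpretation = if (co$b24 > 0) {
      "regulatory macrophages dominate the inflammatory phenotype (b24 > 0): the chemoattractant-macrophage loop is damped"
    } else {
      "inflammatory macrophages dominate the regulatory phenotype (b24 <= 0): the chemoattractant-macrophage loop amplifies perturbations"
    }
  ), class = "fbr_stability")
}

# Serialize a stability report to a JSON-ready list (eigenvalues as
# (re, im) pairs).
.stability_to_list <- function(rep) {
  list(
    eigenvalues = lapply(seq_along(rep$eigenvalues), function(i) {
      list(re = Re(rep$eigenvalues[i]), im = Im(rep$eigenvalues[i]))
    }),
    max_re = rep$max_re,
    classification = rep$classification,
    conditions = rep$conditions,
    interpretation = rep$interpretation
  )
}

#' @export
print.fbr_stability <- function(x, ...) {
  cat("<fbr_stability>", x$classification, sprintf("(max Re sigma = %.6g)\n", x$max_re))
  print(x$eigenvalues)
  cat(" ", x$interpretation, "\n")
  invisible(x)
}

#' @export
print.fbr_lincoef <- function(x, ...) {
  cat("<fbr_lincoef> linearized coefficients (dynamics u' = -B u)\n")
  print(unlist(x[c(.fbr_b_names, .fbr_chi_names)]))
  invisible(x)
}
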