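# Model parameters -------------------------------------------------------

.fbr_param_names <- c(
  "Dd", "Dc", "Df", "Dm", "De",
  "chi0", "chi1", "chij", "Bcoef",
  "f0", "f0_tilde", "f1", "f2", "f3", "f4",
  "a0", "a1", "a2", "a3", "a11", "a12", "a16",
  "lambda1", "lambda2", "lambda3",
  "F0", "M0", "E0"
)

# Default kinetic ledger. The model prints no fitted rates, so these are
# documented fixtures: "stable" sits on the regulatory-dominated existence
# branch (f2*l3*a11 < f3*a0*l2 and f4*f0*l1*a0 < a11*f1*f0t*l3), which makes
# the interior equilibrium asymptotically stable for the reaction system;
# "unstable_b24" sits on the inflammatory-dominated branch, where b24 < 0
# and one reaction eigenvalue is positive.
.fbr_stable_defaults <- list(
  Dd = 1, Dc = 1, Df = 1, Dm = 1, De = 1,
  chi0 = 0.1, chi1 = 0.1, chij = 0.1, Bcoef = 0.5,
  f0 = 1, f0_tilde = 1, f1 = 1, f2 = 0.4, f3 = 2, f4 = 0.2,
  a0 = 0.5, a1 = 0.5, a2 = 1, a3 = 0.5, a11 = 1, a12 = 0.2, a16 = 0.5,
  lambda1 = 0.4, lambda2 = 0.4, lambda3 = 0.2,
  F0 = 1, M0 = 2, E0 = 1
)

.fbr_unstable_defaults <- utils::modifyList(.fbr_stable_defaults, list(
  f0_tilde = 0.5, f1 = 0.2, f2 = 2, f3 = 0.4, f4 = 1.5,
  lambda1 = 0.3, lambda2 = 0.2, lambda3 = 0.5
))

#' Construct a model parameter set
#'
#' Bundles every rate constant of the foreign-body reaction model: diffusion
#' coefficients `Dd`, `Dc`, `Df`, `Dm`, `De` (length^2/time) for debris,
#' chemoattractant, fibroblasts, macrophages and ECM; chemotaxis
#' sensitivities `chi0` (fibroblasts), `chi1` (macrophages) and `chij`
#' together with the ECM flux scale `Bcoef`; debris/chemoattractant kinetics
#' `f0`, `f0_tilde`, `f1`, `f2`, `f3`, `f4`; fibroblast/macrophage/ECM
#' kinetics `a0`, `a1`, `a2`, `a3`, `a11`, `a12`, `a16`; macrophage
#' phenotype fractions `lambda1` (classical), `lambda2` (regulatory),
#' `lambda3` (inflammatory); and saturation thresholds `F0`, `M0`, `E0`.
#' All coefficients are assumed positive and each `lambda` lies in (0, 1).
#'
#' Unspecified fields are taken from the packaged default ledger (see
#' [default_params()]). The constructor does not reject invalid values;
#' use [validate_params()] for that.
#'
#' @param ... named numeric scalars overriding individual fields.
#' @param base parameter list to start from (defaults to the stable ledger).
#' @return an object of class `fbr_params` (a named list).
#' @seealso [default_params()], [validate_params()]
#' @export
#' @examples
#' p <- model_params(lambda1 = 0.5, lambda2 = 0.3, lambda3 = 0.2)
#' p$lambda1
model_params <- function(..., base = NULL) {
  p <- if (is.null(base)) .fbr_stable_defaults else unclass(base)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots)))) {
      .stop_fbr("all arguments to model_params() must be named", "fbr_invalid_input")
    }
    unknown <- setdiff(names(dots), .fbr_param_names)
    if (length(unknown)) {
      .stop_fbr(paste0("unknown parameter field(s): ", paste(unknown, collapse = ", ")),
                "fbr_invalid_input")
    }
    p[names(dots)] <- dots
  }
  p <- p[.fbr_param_names]
  structure(p, class = "fbr_params")
}

#' Packaged default parameter ledgers
#'
#' Two documented fixture regimes: `"stable"` places the macrophage
#' phenotype mix on the regulatory-dominated existence branch, so the
#' interior equilibrium is asymptotically stable for the reaction system;
#' `"unstable_b24"` places it on the inflammatory-dominated branch, where
#' the cross coefficient b24 is negative and one reaction eigenvalue is
#' positive. Neither set is a claim about measured biology.
#'
#' @param regime which fixture to return.
#' @return an `fbr_params` object.
#' @export
default_params <- function(regime = c("stable", "unstable_b24")) {
  regime <- match.arg(regime)
  base <- switch(regime,
    stable = .fbr_stable_defaults,
    unstable_b24 = .fbr_unstable_defaults
  )
  structure(base[.fbr_param_names], class = "fbr_params")
}

#' Validate a parameter set
#'
#' Checks structural admissibility (every coefficient a positive finite
#' scalar, each phenotype fraction strictly inside (0, 1)) and, when the
#' interior equilibrium exists, whether the below-threshold regime assumed
#' by the analysis holds (`fe <= F0`, `me <= M0`, so the Heaviside gates are
#' identically 1 near the equilibrium). Violations of positivity are
#' errors; a phenotype sum different from 1, a missing interior equilibrium
#' or a threshold-regime violation are reported as warnings. The input is
#' never modified and no condition is raised.
#'
#' @param p an `fbr_params` object.
#' @return an `fbr_validation` report: list with character vectors `errors`
#'   and `warnings` and logical `valid`.
#' @export
validate_params <- function(p) {
  errors <- character()
  warnings <- character()
  for (nm in .fbr_param_names) {
    v <- p[[nm]]
    if (is.null(v) || !.is_scalar_number(v)) {
      errors <- c(errors, sprintf("field '%s' must be a finite numeric scalar", nm))
    } else if (v <= 0) {
      errors <- c(errors, sprintf("field '%s' must be strictly positive (got %g)", nm, v))
    }
  }
  lam_names <- c("lambda1", "lambda2", "lambda3")
  lam_ok <- vapply(lam_names, function(nm) .is_scalar_number(p[[nm]]), logical(1))
  for (nm in lam_names[lam_ok]) {
    if (p[[nm]] >= 1) {
      errors <- c(errors, sprintf("phenotype fraction '%s' must lie in (0, 1)", nm))
    }
  }
  if (all(lam_ok)) {
    lam_sum <- p$lambda1 + p$lambda2 + p$lambda3
    if (is.finite(lam_sum) && abs(lam_sum - 1) > 1e-8) {
      warnings <- c(warnings, sprintf(
        "phenotype fractions sum to %g, not 1 (the model does not require this, but it is the usual convention)",
        lam_sum))
    }
  }
  if (!length(errors)) {
    eq <- tryCatch(interior_equilibrium(p), error = function(e) NULL)
    if (is.null(eq)) {
      warnings <- c(warnings,
        "existence condition for the interior equilibrium fails (me <= 0)")
    } else {
      if (eq$fe > p$F0) {
        warnings <- c(warnings, sprintf(
          "threshold regime violated: equilibrium fe = %g exceeds F0 = %g", eq$fe, p$F0))
      }
      if (eq$me > p$M0) {
        warnings <- c(warnings, sprintf(
          "threshold regime violated: equilibrium me = %g exceeds M0 = %g", eq$me, p$M0))
      }
    }
  }
  structure(
    list(errors = errors, warnings = warnings, valid = length(errors) == 0L),
    class = "fbr_validation"
  )
}

#' @export
print.fbr_params <- function(x, ...) {
  cat("<fbr_params> foreign-body reaction model parameters\n")
  v <- unlist(x)
  print(v)
  invisible(x)
}

#' @export
print.fbr_validation <- function(x, ...) {
  cat("<fbr_validation>", if (x$valid) "valid" else "INVALID", "\n")
  if (length(x$errors)) cat(paste0("  error:   ", x$errors, collapse = "\n"), "\n")
  if (length(x$warnings)) cat(paste0("  warning: ", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}
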