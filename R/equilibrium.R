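# Interior (inflammatory) equilibrium ------------------------------------

#' Closed-form interior equilibrium
#'
#' The unique spatially uniform steady state with all five components
#' strictly positive (the "inflammatory" equilibrium), in closed form:
#' \deqn{d_e = \tilde f_0 \lambda_3 / (f_0 \lambda_1), \quad
#'       c_e = a_0 / a_{11}, \quad e_e = E_0,}
#' \deqn{m_e = \frac{f_4 f_0 \lambda_1 a_0 - a_{11} f_1 \tilde f_0 \lambda_3}
#'                  {f_0 \lambda_1 (f_2 \lambda_3 a_{11} - f_3 a_0 \lambda_2)},}
#' \deqn{f_e = \frac{F_0}{2 a_2}\left[(a_2 - a_3 + a_{12} a_0/a_{11}) + L_1\right],
#'       \quad
#'       L_1 = \sqrt{(a_2 - a_3 + a_{12} a_0/a_{11})^2
#'                   + 4 (a_2/F_0) a_1 \lambda_1 m_e}.}
#' Only the "+" root of the fibroblast quadratic is taken; it is the
#' positive one whenever `me > 0`. Existence requires `me > 0`, i.e. the
#' two factors of the macrophage quotient share a sign (see
#' [existence_report()]); otherwise a classed error
#' (`fbr_no_equilibrium`) naming the failing inequality is thrown.
#'
#' @param p an `fbr_params` object.
#' @return an `fbr_equilibrium`: list with fields `de, ce, fe, me, ee` and
#'   the auxiliary square-root term `L1`.
#' @export
#' @examples
#' eq <- interior_equilibrium(default_params())
#' max(abs(reaction_rhs(equilibrium_state(eq), default_params()))) # ~ 0
interior_equilibrium <- function(p) {
  ce <- p$a0 / p$a11
  de <- p$f0_tilde * p$lambda3 / (p$f0 * p$lambda1)
  num <- p$f4 * p$f0 * p$lambda1 * p$a0 - p$a11 * p$f1 * p$f0_tilde * p$lambda3
  den <- p$f0 * p$lambda1 * (p$f2 * p$lambda3 * p$a11 - p$f3 * p$a0 * p$lambda2)
  me <- num / den
  if (!is.finite(me) || me <= 0) {
    .stop_fbr(sprintf(
      paste0("no interior equilibrium: me = %g <= 0; the factors ",
             "(f2*lambda3*a11 - f3*a0*lambda2) = %g and ",
             "(f4*f0*lambda1*a0 - a11*f1*f0_tilde*lambda3) = %g must share a sign"),
      me, den / (p$f0 * p$lambda1), num), "fbr_no_equilibrium")
  }
  alpha <- p$a2 - p$a3 + p$a12 * ce
  L1 <- sqrt(alpha^2 + 4 * (p$a2 / p$F0) * p$a1 * p$lambda1 * me)
  fe <- (p$F0 / (2 * p$a2)) * (alpha + L1)
  structure(list(de = de, ce = ce, fe = fe, me = me, ee = p$E0, L1 = L1),
            class = "fbr_equilibrium")
}

#' Equilibrium as a state vector
#'
#' @param eq an `fbr_equilibrium`.
#' @return named numeric 5-vector `(D, C, F, M, E)`.
#' @export
equilibrium_state <- function(eq) {
  c(D = eq$de, C = eq$ce, F = eq$fe, M = eq$me, E = eq$ee)
}

#' Existence report for the interior equilibrium
#'
#' The equilibrium exists iff the macrophage component is positive, which
#' happens on exactly one of two sign branches:
#' `"Eq13"` (inflammatory-dominated): `f2*lambda3*a11 > f3*a0*lambda2` and
#' `f4*f0*lambda1*a0 > a11*f1*f0_tilde*lambda3`; `"Eq14"`
#' (regulatory/classical-dominated): both inequalities reversed. On the
#' `"Eq13"` branch the cross coefficient `b24` of the linearization is
#' negative and the reaction system is unstable; on `"Eq14"` it is positive
#' and the reaction system is asymptotically stable.
#'
#' @param p an `fbr_params` object.
#' @return an `fbr_existence`: list with `exists`, `branch` (one of
#'   `"Eq13"`, `"Eq14"`, `"none"`), `me_value`, and `regime_flags`
#'   (logical `fe_le_F0`, `me_le_M0`, `NA` when the equilibrium is absent).
#' @export
existence_report <- function(p) {
  g1 <- p$f2 * p$lambda3 * p$a11 - p$f3 * p$a0 * p$lambda2
  g2 <- p$f4 * p$f0 * p$lambda1 * p$a0 - p$a11 * p$f1 * p$f0_tilde * p$lambda3
  me <- g2 / (p$f0 * p$lambda1 * g1)
  exists <- is.finite(me) && me > 0
  branch <- if (g1 > 0 && g2 > 0) "Eq13" else if (g1 < 0 && g2 < 0) "Eq14" else "none"
  flags <- c(fe_le_F0 = NA, me_le_M0 = NA)
  if (exists) {
    eq <- interior_equilibrium(p)
    flags <- c(fe_le_F0 = eq$fe <= p$F0, me_le_M0 = eq$me <= p$M0)
  }
  structure(list(exists = exists, branch = branch,
                 me_value = if (is.finite(me)) me else NA_real_,
                 regime_flags = flags),
            class = "fbr_existence")
}

#' Scan the macrophage phenotype simplex for equilibrium existence
#'
#' Evaluates [existence_report()] on a barycentric grid over
#' `(lambda1, lambda2, lambda3)` with the remaining parameters held fixed,
#' mapping the region where the inflammatory equilibrium exists
#' (`me > 0`) and which sign branch produces it.
#'
#' @param p an `fbr_params` object supplying all non-phenotype parameters.
#' @param resolution number of subdivisions of the simplex edge (interior
#'   points only); ignored when `lambdas` is given.
#' @param lambdas optional matrix-like with 3 columns of positive weights;
#'   each row is normalized to sum to 1 before evaluation.
#' @return data frame with columns
#'   `lambda1, lambda2, lambda3, exists, branch, me`.
#' @export
phenotype_region_scan <- function(p, resolution = 30, lambdas = NULL) {
  if (is.null(lambdas)) {
    if (!.is_scalar_number(resolution) || resolution < 3) {
      .stop_fbr("resolution must be at least 3", "fbr_invalid_input")
    }
    r <- as.integer(resolution)
    ij <- expand.grid(i = seq_len(r - 1L), j = seq_len(r - 1L))
    ij <- ij[ij$i + ij$j < r, , drop = FALSE]
    lambdas <- cbind(ij$i / r, ij$j / r, (r - ij$i - ij$j) / r)
  } else {
    lambdas <- as.matrix(lambdas)
    if (ncol(lambdas) != 3L || nrow(lambdas) == 0L) {
      .stop_fbr("lambdas must be a non-empty matrix with 3 columns",
                "fbr_invalid_input")
    }
    if (any(lambdas <= 0)) {
      .stop_fbr("all phenotype weights must be strictly positive",
                "fbr_invalid_input")
    }
    lambdas <- lambdas / rowSums(lambdas)
  }
  res <- lapply(seq_len(nrow(lambdas)), function(k) {
    pk <- model_params(lambda1 = lambdas[k, 1], lambda2 = lambdas[k, 2],
                       lambda3 = lambdas[k, 3], base = p)
    ex <- existence_report(pk)
    data.frame(lambda1 = lambdas[k, 1], lambda2 = lambdas[k, 2],
               lambda3 = lambdas[k, 3], exists = ex$exists,
               branch = ex$branch, me = ex$me_value)
  })
  do.call(rbind, res)
}

#' @export
print.fbr_equilibrium <- function(x, ...) {
  cat("<fbr_equilibrium> interior (inflammatory) equilibrium\n")
  print(c(de = x$de, ce = x$ce, fe = x$fe, me = x$me, ee = x$ee, L1 = x$L1))
  invisible(x)
}

#' @export
print.fbr_existence <- function(x, ...) {
  cat("<fbr_existence> exists:", x$exists, " branch:", x$branch,
      " me:", format(x$me_value), "\n")
  invisible(x)
}
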