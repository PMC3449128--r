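# Reaction kinetics (spatially uniform part of the model) ----------------

#' Heaviside gate
#'
#' Sharp convention `H(0) = 1` (the analysis assumes the below-threshold
#' regime where the gates are identically 1, so the convention only matters
#' exactly at the saturation boundary). A logistic surrogate of configurable
#' steepness is available for integrator robustness near the threshold.
#'
#' @param x numeric vector.
#' @param smooth use the logistic surrogate `1/(1 + exp(-k x))`?
#' @param steepness logistic steepness `k` (only used when `smooth`).
#' @return numeric vector in \[0, 1\].
#' @export
heaviside <- function(x, smooth = FALSE, steepness = 50) {
  if (smooth) 1 / (1 + exp(-steepness * x)) else as.numeric(x >= 0)
}

# Vectorized reaction rates; shared by reaction_rhs() and the nonlinear
# PDE simulator so the uniform-field reduction is exact by construction.
.reaction_rates <- function(D, C, F, M, E, p, smooth = FALSE, steepness = 50) {
  Hf <- heaviside(p$F0 - F, smooth = smooth, steepness = steepness)
  Hm <- heaviside(p$M0 - M, smooth = smooth, steepness = steepness)
  list(
    D = -p$f0 * p$lambda1 * M * D + p$f0_tilde * p$lambda3 * M,
    C = p$f1 * D + p$f2 * p$lambda3 * M - p$f3 * p$lambda2 * M * C - p$f4 * C,
    F = p$a1 * p$lambda1 * M + p$a2 * F * (1 - F / p$F0) - p$a3 * F +
      p$a12 * C * F * Hf,
    M = -p$a0 * M + p$a11 * C * M * Hm,
    E = p$a16 * F * (1 - E / p$E0)
  )
}

.as_state <- function(state) {
  if (is.list(state)) state <- unlist(state)
  if (length(state) != 5L) {
    .stop_fbr("a state vector has exactly 5 components (D, C, F, M, E)",
              "fbr_invalid_input")
  }
  if (!is.null(names(state)) && all(c("D", "C", "F", "M", "E") %in% names(state))) {
    state <- state[c("D", "C", "F", "M", "E")]
  }
  stats::setNames(as.numeric(state), c("D", "C", "F", "M", "E"))
}

#' Reaction right-hand side
#'
#' Rates of change of the spatially uniform system: debris is digested by
#' classical macrophages and replenished by inflammatory ones; the
#' chemoattractant is produced by debris and inflammatory macrophages and
#' cleared by regulatory macrophages and first-order decay; fibroblasts
#' follow gated logistic growth plus macrophage-driven recruitment and
#' chemoattractant-driven proliferation; macrophages balance apoptosis
#' against gated chemoattractant-driven proliferation; ECM is secreted by
#' fibroblasts up to its saturation.
#'
#' @param state numeric 5-vector `(D, C, F, M, E)` (names optional).
#' @param p an `fbr_params` object.
#' @param smooth,steepness Heaviside convention, see [heaviside()].
#' @return named numeric 5-vector of rates.
#' @export
#' @examples
#' p <- default_params()
#' reaction_rhs(c(0, 0, 0, 0, 0), p) # the origin is a steady state
reaction_rhs <- function(state, p, smooth = FALSE, steepness = 50) {
  s <- .as_state(state)
  if (!all(is.finite(s))) {
    .stop_fbr("state vector must be finite", "fbr_invalid_input")
  }
  r <- .reaction_rates(s[["D"]], s[["C"]], s[["F"]], s[["M"]], s[["E"]], p,
    smooth = smooth, steepness = steepness)
  c(D = r$D, C = r$C, F = r$F, M = r$M, E = r$E)
}

#' Integrate the reaction system
#'
#' Solves the spatially uniform system by stiff integration (method of
#' choice from \pkg{deSolve}). A trajectory started exactly at the interior
#' equilibrium stays there; one started nearby converges to it exactly when
#' the reaction spectrum has negative real parts.
#'
#' @param s0 initial state, numeric 5-vector `(D, C, F, M, E)`.
#' @param p an `fbr_params` object.
#' @param t_end final time (> 0), arbitrary model time units.
#' @param n_out number of equally spaced output times (including 0).
#' @param method \pkg{deSolve} integration method.
#' @param rtol,atol integrator tolerances.
#' @param smooth,steepness Heaviside convention, see [heaviside()].
#' @return an `fbr_trajectory`: data frame with columns `t, D, C, F, M, E`.
#' @export
integrate_reactions <- function(s0, p, t_end, n_out = 201, method = "lsoda",
                                rtol = 1e-8, atol = 1e-10,
                                smooth = FALSE, steepness = 50) {
  if (!.is_scalar_number(t_end) || t_end <= 0) {
    .stop_fbr("t_end must be a positive number", "fbr_invalid_input")
  }
  s0 <- .as_state(s0)
  times <- seq(0, t_end, length.out = n_out)
  rhs <- function(t, y, parms) {
    list(unname(reaction_rhs(y, p, smooth = smooth, steepness = steepness)))
  }
  out <- deSolve::ode(y = unname(s0), times = times, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (nrow(out) < length(times) || any(!is.finite(out))) {
    diag <- attr(out, "istate")
    .stop_fbr(sprintf(
      "reaction integrator failed after t = %g (returned %d of %d steps; istate[1] = %s)",
      max(out[, 1]), nrow(out), length(times),
      if (is.null(diag)) "NA" else diag[1]), "fbr_integrator_failure")
  }
  traj <- as.data.frame(out)
  names(traj) <- c("t", "D", "C", "F", "M", "E")
  class(traj) <- c("fbr_trajectory", "data.frame")
  attr(traj, "params") <- p
  traj
}

#' Write a trajectory to CSV
#'
#' Header `t,D,C,F,M,E`, one row per output time.
#'
#' @param traj an `fbr_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("t", "D", "C", "F", "M", "E")],
                   path, row.names = FALSE)
  invisible(path)
}
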