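# Modal (per-Fourier-mode) stability of the linearized PDE system --------

#' Modal matrix M(mu)
#'
#' For a Neumann Laplacian eigenvalue `mu >= 0`, the perturbation component
#' along the corresponding eigenfunction evolves as `u' = -M(mu) u`, where
#' `M(mu)` adds diffusive damping `D*mu` to the diagonal of the reaction
#' matrix and replaces the chemotactic cross couplings by `-(chi*mu - b)`
#' terms. At `mu = 0` it reduces to the reaction matrix `B`.
#'
#' @param co an `fbr_lincoef`.
#' @param p a parameter set (any list carrying `Dd, Dc, Df, Dm, De`).
#' @param mu Neumann Laplacian eigenvalue, `mu >= 0`.
#' @return 5x5 numeric matrix (rows/cols `d, c, f, m, e`).
#' @export
modal_matrix <- function(co, p, mu) {
  if (!.is_scalar_number(mu) || mu < 0) {
    .stop_fbr("mu must be a nonnegative number", "fbr_invalid_input")
  }
  M <- reaction_matrix(co)
  M["d", "d"] <- M["d", "d"] + p$Dd * mu
  M["c", "c"] <- M["c", "c"] + p$Dc * mu
  M["f", "f"] <- M["f", "f"] + p$Df * mu
  M["m", "m"] <- M["m", "m"] + p$Dm * mu
  M["e", "e"] <- M["e", "e"] + p$De * mu
  M["f", "c"] <- -(co$chif * mu - co$b32)
  M["m", "c"] <- -(co$chim * mu - co$b42)
  M["e", "c"] <- -co$chie2 * mu
  M["e", "f"] <- -(co$chie1 * mu - co$b53)
  M
}

#' Closed-form modal eigenvalues
#'
#' With the equilibrium identities `b44 = b14 = 0`, the spectrum of
#' `-M(mu)` is
#' `sigma1 = -b11 - Dd*mu`,
#' `sigma2,3 = (-(b22 + Dc*mu + Dm*mu) -/+ sqrt((b22 + Dc*mu + Dm*mu)^2 + 4*eps)) / 2`,
#' `sigma4 = -b33 - Df*mu`, `sigma5 = -b55 - De*mu`, where
#' `eps = (b42 - chim*mu)*b24 - Dm*mu*(b22 + Dc*mu)`.
#' Both quadratic roots are always returned. When the equilibrium
#' identities fail the function warns and falls back to a numeric
#' eigensolve (still reporting `eps`).
#'
#' @inheritParams modal_matrix
#' @param force_numeric always use the numeric eigensolver.
#' @return list with `sigma` (named complex 5-vector), `epsilon`, `mu`,
#'   and `method`.
#' @export
modal_eigenvalues <- function(co, p, mu, force_numeric = FALSE) {
  if (!.is_scalar_number(mu) || mu < 0) {
    .stop_fbr("mu must be a nonnegative number", "fbr_invalid_input")
  }
  eps <- (co$b42 - co$chim * mu) * co$b24 - p$Dm * mu * (co$b22 + p$Dc * mu)
  off <- max(abs(co$b44), abs(co$b14))
  if (force_numeric || off > 1e-8 * .coef_scale(co)) {
    if (!force_numeric) {
      warning("b44 and b14 are not zero; using the numeric modal eigensolver",
              call. = FALSE)
    }
    ev <- eigen(-modal_matrix(co, p, mu), only.values = TRUE)$values
    ev <- as.complex(ev[order(-Re(ev), -Im(ev))])
    return(list(sigma = stats::setNames(ev, paste0("sigma", 1:5)),
                epsilon = eps, mu = mu, method = "numeric"))
  }
  q <- co$b22 + p$Dc * mu + p$Dm * mu
  disc <- sqrt(as.complex(q^2 + 4 * eps))
  sig <- c(sigma1 = as.complex(-co$b11 - p$Dd * mu),
           sigma2 = (-q - disc) / 2,
           sigma3 = (-q + disc) / 2,
           sigma4 = as.complex(-co$b33 - p$Df * mu),
           sigma5 = as.complex(-co$b55 - p$De * mu))
  list(sigma = sig, epsilon = eps, mu = mu, method = "closed_form")
}

#' Default mu grid
#'
#' 0 plus logarithmically spaced points up to `mu_max = (10*pi/L)^2`,
#' covering roughly the first ten Neumann interval modes and the large-mu
#' diffusion-dominated regime.
#'
#' @param L domain length.
#' @param n number of grid points (including 0).
#' @param mu_max override the upper end.
#' @return nonnegative numeric vector of length `n`, starting at 0.
#' @export
default_mu_grid <- function(L = pi, n = 60, mu_max = (10 * pi / L)^2) {
  c(0, exp(seq(log(mu_max / 1e4), log(mu_max), length.out = n - 1L)))
}

#' Modal stability scan over a mu grid
#'
#' Evaluates the closed-form modal spectrum at every `mu`, together with
#' the two reduced stability conditions (`b22 + Dc*mu + Dm*mu > 0` and
#' `eps < 0`) and the maximal real part. The overall verdict is
#' "PDE-stable on the grid" iff the maximal real part is negative at every
#' `mu`. The scan also instantiates the main theorem: when the reaction
#' (mu = 0) report is asymptotically stable, every mode must be damped;
#' a violation raises an error, since it would contradict the closed-form
#' argument (a bug, not a parameter regime).
#'
#' @param co an `fbr_lincoef`.
#' @param p parameter set carrying the five diffusion coefficients.
#' @param mu_grid nonnegative grid of Laplacian eigenvalues; must include 0.
#' @param tol classification tolerance on real parts.
#' @return an `fbr_modal_spectrum`: list with `table` (data frame:
#'   `mu, re_sigma_1..5, im_sigma_1..5, epsilon, max_re, cond_damping,
#'   cond_epsilon`), `stable`, and the mu = 0 `ode` stability report.
#' @export
pde_stability_report <- function(co, p, mu_grid = default_mu_grid(), tol = 1e-10) {
  mu_grid <- as.numeric(mu_grid)
  if (!length(mu_grid)) .stop_fbr("mu_grid is empty", "fbr_invalid_input")
  if (any(!is.finite(mu_grid)) || any(mu_grid < 0)) {
    .stop_fbr("mu_grid must be finite and nonnegative", "fbr_invalid_input")
  }
  if (!any(mu_grid == 0)) {
    .stop_fbr("mu_grid must include 0 (the spatially uniform mode)",
              "fbr_invalid_input")
  }
  rows <- lapply(mu_grid, function(mu) {
    me <- modal_eigenvalues(co, p, mu)
    s <- me$sigma
    out <- c(mu = mu, stats::setNames(Re(s), paste0("re_sigma_", 1:5)),
             stats::setNames(Im(s), paste0("im_sigma_", 1:5)),
             epsilon = me$epsilon, max_re = max(Re(s)))
    out
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab$cond_damping <- co$b22 + p$Dc * tab$mu + p$Dm * tab$mu > 0
  tab$cond_epsilon <- tab$epsilon < 0
  ode <- ode_stability_report(co, tol = tol)
  stable <- all(tab$max_re < 0)
  if (ode$classification == "asymptotically_stable" && any(tab$max_re > tol)) {
    .stop_fbr(paste0(
      "internal inconsistency: the reaction system is asymptotically stable ",
      "but a spatial mode appears to grow (max Re sigma = ",
      format(max(tab$max_re)), " at mu = ",
      format(tab$mu[which.max(tab$max_re)]),
      "); this contradicts the closed-form modal spectrum"),
      "fbr_theorem_violation")
  }
  structure(list(table = tab, stable = stable, ode = ode, tol = tol),
            class = "fbr_modal_spectrum")
}

#' Mobility bounds that damp an unstable mode
#'
#' In the reaction-unstable regime (`b24 < 0`) a mode `mu > 0` is damped
#' exactly when `eps < 0`, i.e.
#' `Dm*mu*(b22 + Dc*mu) > (b42 - chim*mu)*b24`. Solved for the chemotaxis
#' sensitivity this gives the exact upper bound
#' `chim < (Dm*mu*(b22 + Dc*mu) - b42*b24) / (-mu*b24)` and, for the
#' macrophage mobility, the lower bound
#' `Dm > (b42 - chim*mu)*b24 / (mu*(b22 + Dc*mu))`. A cruder printed
#' sufficient form, `Dm*Dc > (b42 - chim*mu)*b24/mu`, is reported alongside
#' for cross-reference; the `eps`-based condition is the primary one.
#'
#' @param co an `fbr_lincoef` with `b24 < 0`.
#' @param p parameter set carrying `Dc, Dm` (and the rest of the
#'   diffusivities for the eigenvalue check).
#' @param mu mode, strictly positive (the condition is vacuous at `mu = 0`).
#' @return list with `epsilon`, `damped` (eps < 0 at the supplied
#'   mobilities), `chim_max`, `Dm_min`, and `printed_form`
#'   (list `lhs`, `rhs`, `holds`).
#' @export
diffusion_stabilization_threshold <- function(co, p, mu) {
  if (!.is_scalar_number(mu) || mu <= 0) {
    .stop_fbr("mu must be strictly positive (the condition is vacuous at mu = 0)",
              "fbr_invalid_input")
  }
  if (co$b24 >= 0) {
    .stop_fbr("b24 >= 0: the reaction system is not unstable through this mode; no stabilization threshold applies",
              "fbr_invalid_input")
  }
  eps <- (co$b42 - co$chim * mu) * co$b24 - p$Dm * mu * (co$b22 + p$Dc * mu)
  chim_max <- (p$Dm * mu * (co$b22 + p$Dc * mu) - co$b42 * co$b24) / (-mu * co$b24)
  Dm_min <- (co$b42 - co$chim * mu) * co$b24 / (mu * (co$b22 + p$Dc * mu))
  list(
    epsilon = eps,
    damped = eps < 0,
    chim_max = chim_max,
    Dm_min = Dm_min,
    printed_form = list(
      lhs = p$Dm * p$Dc,
      rhs = (co$b42 - co$chim * mu) * co$b24 / mu,
      holds = p$Dm * p$Dc > (co$b42 - co$chim * mu) * co$b24 / mu
    )
  )
}

#' @export
print.fbr_modal_spectrum <- function(x, ...) {
  cat("<fbr_modal_spectrum>", nrow(x$table), "mu values;",
      if (x$stable) "PDE-stable on grid" else "unstable mode on grid", "\n")
  cat("  reaction (mu = 0) classification:", x$ode$classification, "\n")
  cat(sprintf("  max Re sigma over grid: %.6g at mu = %.6g\n",
              max(x$table$max_re), x$table$mu[which.max(x$table$max_re)]))
  invisible(x)
}
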