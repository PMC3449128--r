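# Method-of-lines simulator on intervals/rectangles with Neumann walls ---

#' Uniform simulation grid
#'
#' Node-centered uniform grid on an interval or rectangle. Neumann
#' boundaries are realized by mirror ghost nodes, equivalently by
#' zero-flux faces of the conservative stencil; both views give the same
#' second-order operator.
#'
#' @param extents domain length(s): one number (interval) or two
#'   (rectangle).
#' @param n_points nodes per axis (scalar recycled), at least 8.
#' @return an `fbr_grid`: list with `dimension`, `extents`, `n`, `h`
#'   (spacings) and `coords` (node coordinates per axis).
#' @export
grid_spec <- function(extents, n_points = 101) {
  extents <- as.numeric(extents)
  dim <- length(extents)
  if (!dim %in% 1:2 || any(!is.finite(extents)) || any(extents <= 0)) {
    .stop_fbr("extents must be 1 or 2 strictly positive lengths",
              "fbr_invalid_input")
  }
  n <- as.integer(rep_len(n_points, dim))
  if (any(n < 8L)) .stop_fbr("need at least 8 nodes per axis", "fbr_invalid_input")
  h <- extents / (n - 1L)
  coords <- lapply(seq_len(dim), function(k) seq(0, extents[k], length.out = n[k]))
  structure(list(dimension = dim, extents = extents, n = n, h = h,
                 coords = coords), class = "fbr_grid")
}

.grid_npoints <- function(g) prod(g$n)

.grid_weights <- function(g) {
  w <- .trapz_weights(g$n[1], g$h[1])
  if (g$dimension == 2L) w <- as.numeric(outer(w, .trapz_weights(g$n[2], g$h[2])))
  w
}

# 1D Neumann Laplacian (mirror ghosts), sparse, n x n.
.laplacian_matrix_1d <- function(n, h) {
  main <- rep(-2, n)
  upper <- rep(1, n - 1L); lower <- rep(1, n - 1L)
  upper[1L] <- 2; lower[n - 1L] <- 2
  Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
                     diagonals = list(lower, main, upper)) / h^2
}

.grid_laplacian <- function(g) {
  Lx <- .laplacian_matrix_1d(g$n[1], g$h[1])
  if (g$dimension == 1L) return(Lx)
  Ly <- .laplacian_matrix_1d(g$n[2], g$h[2])
  Matrix::kronecker(Matrix::Diagonal(g$n[2]), Lx) +
    Matrix::kronecker(Ly, Matrix::Diagonal(g$n[1]))
}

#' Neumann Laplacian eigenmodes
#'
#' Continuum eigenpairs of `-Laplacian` with zero normal derivative,
#' sampled on the grid: on an interval of length `L`,
#' `mu_n = (n*pi/L)^2` with eigenfunction `cos(n*pi*x/L)` (`n = 0` is the
#' constant ground mode); on a rectangle, tensor products ordered by
#' increasing eigenvalue. The discrete operator's eigenvalues converge to
#' these at second order in the spacing.
#'
#' @param g an `fbr_grid`.
#' @param k number of modes requested (`k >= 1`, at most the number of
#'   resolvable modes, i.e. nodes per axis).
#' @return list of `k` modes, each a list with `mu`, `phi` (vector or
#'   matrix of node values) and `index` (per-axis mode numbers).
#' @export
neumann_laplacian_modes <- function(g, k) {
  if (!.is_scalar_number(k) || k < 1) .stop_fbr("k must be >= 1", "fbr_invalid_input")
  k <- as.integer(k)
  if (g$dimension == 1L) {
    if (k > g$n[1]) {
      .stop_fbr(sprintf("k = %d exceeds the %d resolvable interval modes", k, g$n[1]),
                "fbr_invalid_input")
    }
    x <- g$coords[[1]]; L <- g$extents[1]
    return(lapply(seq_len(k) - 1L, function(n) {
      list(mu = (n * pi / L)^2, phi = cos(n * pi * x / L), index = n)
    }))
  }
  if (k > prod(g$n)) {
    .stop_fbr("k exceeds the number of resolvable rectangle modes", "fbr_invalid_input")
  }
  nn <- expand.grid(nx = 0:(min(g$n[1], k) - 1L), ny = 0:(min(g$n[2], k) - 1L))
  mus <- (nn$nx * pi / g$extents[1])^2 + (nn$ny * pi / g$extents[2])^2
  ord <- order(mus, nn$nx, nn$ny)[seq_len(k)]
  lapply(ord, function(i) {
    phix <- cos(nn$nx[i] * pi * g$coords[[1]] / g$extents[1])
    phiy <- cos(nn$ny[i] * pi * g$coords[[2]] / g$extents[2])
    list(mu = mus[i], phi = outer(phix, phiy), index = c(nn$nx[i], nn$ny[i]))
  })
}

# Normalize initial data to a 5 x N matrix in (d, c, f, m, e) row order.
.init_matrix <- function(init, g, names5) {
  N <- .grid_npoints(g)
  if (is.list(init)) {
    if (!all(names5 %in% names(init))) {
      .stop_fbr(paste0("init must have components ", paste(names5, collapse = ", ")),
                "fbr_invalid_input")
    }
    init <- do.call(rbind, lapply(init[names5], as.numeric))
  }
  init <- as.matrix(init)
  if (nrow(init) != 5L || ncol(init) != N) {
    .stop_fbr(sprintf("init must be 5 x %d (fields x grid nodes)", N),
              "fbr_invalid_input")
  }
  if (any(!is.finite(init))) .stop_fbr("init must be finite", "fbr_invalid_input")
  rownames(init) <- names5
  init
}

.field_solution <- function(out, g, names5, cap_norm = Inf) {
  times <- out[, 1]
  vals <- out[, -1, drop = FALSE]
  N <- .grid_npoints(g)
  w <- .grid_weights(g)
  nt <- nrow(vals)
  fields <- array(NA_real_, dim = c(nt, 5L, N),
                  dimnames = list(NULL, names5, NULL))
  l2 <- numeric(nt); means <- matrix(NA_real_, nt, 5L, dimnames = list(NULL, names5))
  vol <- sum(w)
  for (i in seq_len(nt)) {
    m <- matrix(vals[i, ], nrow = 5L, byrow = TRUE)
    fields[i, , ] <- m
    l2[i] <- sqrt(sum(m^2 %*% w))
    means[i, ] <- as.numeric(m %*% w) / vol
  }
  ok <- is.finite(l2) & l2 <= cap_norm
  blowup <- !all(ok)
  if (blowup) {
    keep <- seq_len(max(1L, which(!ok)[1] - 1L))
    times <- times[keep]; fields <- fields[keep, , , drop = FALSE]
    l2 <- l2[keep]; means <- means[keep, , drop = FALSE]
  }
  structure(list(times = times, fields = fields, l2_norms = l2, means = means,
                 grid = g, blowup = blowup),
            class = "fbr_field_solution")
}

#' Simulate the linearized system
#'
#' Method-of-lines integration of the constant-coefficient perturbation
#' system: diffusion and the chemotactic cross-Laplacian terms are
#' discretized with the same second-order mirror-ghost stencil, the
#' reaction coupling is `-B`. Initial data proportional to a Neumann
#' eigenmode stays proportional to it, with the five modal amplitudes
#' evolving under `-M(mu)` for the discrete eigenvalue of that mode.
#'
#' @param co an `fbr_lincoef`.
#' @param p parameter set carrying the diffusivities `Dd..De`.
#' @param init perturbation initial data: list with `d, c, f, m, e` or a
#'   `5 x N` matrix (rows in that order; 2D fields flattened column-major).
#' @param g an `fbr_grid`.
#' @param t_end final time.
#' @param n_out output times (equally spaced, including 0).
#' @param method \pkg{deSolve} method (`"lsodes"` suits the sparse
#'   operator).
#' @param rtol,atol integrator tolerances.
#' @param cap blow-up guard: output is truncated (and flagged) once the
#'   solution L2 norm exceeds `cap` times the initial norm.
#' @return an `fbr_field_solution`: `times`, `fields` (time x field x
#'   node array), `l2_norms` (aggregate perturbation L2 norm per time),
#'   `means` (spatial means per field), `grid`, `blowup`.
#' @export
simulate_linearized <- function(co, p, init, g, t_end, n_out = 101,
                                method = "lsodes", rtol = 1e-8, atol = 1e-10,
                                cap = 1e8) {
  names5 <- c("d", "c", "f", "m", "e")
  u0 <- .init_matrix(init, g, names5)
  N <- .grid_npoints(g)
  Lap <- .grid_laplacian(g)
  X <- diag(c(p$Dd, p$Dc, p$Df, p$Dm, p$De))
  X[3, 2] <- -co$chif
  X[4, 2] <- -co$chim
  X[5, 2] <- -co$chie2
  X[5, 3] <- -co$chie1
  A <- Matrix::kronecker(X, Lap) +
    Matrix::kronecker(-reaction_matrix(co), Matrix::Diagonal(N))
  y0 <- as.numeric(t(u0))  # blocks d, c, f, m, e
  times <- seq(0, t_end, length.out = n_out)
  rhs <- function(t, y, parms) list(as.numeric(A %*% y))
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  w <- .grid_weights(g)
  norm0 <- sqrt(sum(u0^2 %*% w))
  sol <- .field_solution(out, g, names5,
                         cap_norm = if (norm0 > 0) cap * norm0 else Inf)
  if (nrow(sol$fields) < n_out && !sol$blowup) {
    .stop_fbr("linearized integrator returned an incomplete solution",
              "fbr_integrator_failure")
  }
  sol
}

# divergence of q * grad(pot) on a 1D node grid with zero-flux walls.
.div_flux_1d <- function(q, pot, h, upwind = FALSE) {
  n <- length(q)
  vel <- diff(pot) / h
  qf <- if (upwind) ifelse(vel > 0, q[-n], q[-1L]) else (q[-n] + q[-1L]) / 2
  flux <- qf * vel
  w <- .trapz_weights(n, h)
  (c(flux, 0) - c(0, flux)) / w
}

.lap_1d <- function(u, h) .div_flux_1d(rep(1, length(u)), u, h)

# 2D versions operate on matrices, axis by axis.
.div_flux_2d <- function(q, pot, h, upwind = FALSE) {
  out <- matrix(0, nrow(q), ncol(q))
  for (j in seq_len(ncol(q))) {
    out[, j] <- out[, j] + .div_flux_1d(q[, j], pot[, j], h[1], upwind)
  }
  for (i in seq_len(nrow(q))) {
    out[i, ] <- out[i, ] + .div_flux_1d(q[i, ], pot[i, ], h[2], upwind)
  }
  out
}

.div_flux <- function(q, pot, g, upwind = FALSE) {
  if (g$dimension == 1L) {
    .div_flux_1d(as.numeric(q), as.numeric(pot), g$h[1], upwind)
  } else {
    as.numeric(.div_flux_2d(matrix(q, g$n[1], g$n[2]),
                            matrix(pot, g$n[1], g$n[2]), g$h, upwind))
  }
}

.lap_field <- function(u, g) {
  if (g$dimension == 1L) {
    .lap_1d(as.numeric(u), g$h[1])
  } else {
    as.numeric(.div_flux_2d(matrix(1, g$n[1], g$n[2]),
                            matrix(u, g$n[1], g$n[2]), g$h))
  }
}

#' Simulate the full nonlinear system
#'
#' Method-of-lines integration of the five nonlinear equations including
#' the fibroblast and macrophage chemotaxis fluxes and the composite ECM
#' flux. Chemotactic fluxes use a conservative face form with
#' interface-averaged carrier density (optionally upwinded), which
#' preserves the no-flux walls discretely; diffusion uses the same
#' conservative stencil. Spatially uniform initial data reproduces the
#' reaction ODE trajectory exactly (the spatial terms vanish on uniform
#' fields).
#'
#' @param p an `fbr_params` object.
#' @param init initial fields: list with `D, C, F, M, E` or a `5 x N`
#'   matrix (rows in that order).
#' @param g an `fbr_grid`.
#' @param t_end final time.
#' @param n_out number of output times.
#' @param method \pkg{deSolve} method.
#' @param rtol,atol integrator tolerances.
#' @param smooth,steepness Heaviside convention, see [heaviside()].
#' @param upwind upwind the chemotactic carrier (recommended for strongly
#'   advection-dominated runs).
#' @param cap blow-up guard, as in [simulate_linearized()].
#' @return an `fbr_field_solution` (fields named `D, C, F, M, E`).
#' @export
simulate_full <- function(p, init, g, t_end, n_out = 101, method = "lsoda",
                          rtol = 1e-8, atol = 1e-10, smooth = FALSE,
                          steepness = 50, upwind = FALSE, cap = 1e8) {
  names5 <- c("D", "C", "F", "M", "E")
  u0 <- .init_matrix(init, g, names5)
  if (any(u0 < 0)) .stop_fbr("init must be componentwise nonnegative",
                             "fbr_invalid_input")
  N <- .grid_npoints(g)
  idx <- lapply(0:4, function(k) k * N + seq_len(N))
  rhs <- function(t, y, parms) {
    D <- y[idx[[1]]]; C <- y[idx[[2]]]; F <- y[idx[[3]]]
    M <- y[idx[[4]]]; E <- y[idx[[5]]]
    r <- .reaction_rates(D, C, F, M, E, p, smooth = smooth, steepness = steepness)
    Hf <- heaviside(p$F0 - F, smooth = smooth, steepness = steepness)
    Hm <- heaviside(p$M0 - M, smooth = smooth, steepness = steepness)
    dD <- p$Dd * .lap_field(D, g) + r$D
    dC <- p$Dc * .lap_field(C, g) + r$C
    dF <- p$Df * .lap_field(F, g) - p$chi0 * .div_flux(F, C, g, upwind) + r$F
    dM <- p$Dm * .lap_field(M, g) - p$chi1 * .div_flux(M * Hm, C, g, upwind) + r$M
    dE <- p$De * .lap_field(E, g) -
      (p$Bcoef * p$Df / p$F0) * .div_flux(E, F, g, upwind) -
      (p$Bcoef * p$chij / p$F0) * .div_flux(E * F * Hf, C, g, upwind) + r$E
    list(c(dD, dC, dF, dM, dE))
  }
  times <- seq(0, t_end, length.out = n_out)
  y0 <- as.numeric(t(u0))
  out <- suppressWarnings(
    deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                 method = method, rtol = rtol, atol = atol))
  w <- .grid_weights(g)
  norm0 <- sqrt(sum(u0^2 %*% w))
  sol <- .field_solution(out, g, names5,
                         cap_norm = if (norm0 > 0) cap * norm0 else Inf)
  if (nrow(sol$fields) < 2L) {
    .stop_fbr("nonlinear integrator failed immediately (possible blow-up); see diagnostics",
              "fbr_integrator_failure")
  }
  sol
}

#' Estimate an exponential growth/decay rate
#'
#' Least-squares slope of `log(L2 norm)` against time over a window,
#' with fit diagnostics. Matches the dominant modal real part when the
#' solution has settled onto a single real mode.
#'
#' @param sol an `fbr_field_solution`.
#' @param window length-2 time window `c(t0, t1)` (default: full range).
#' @return list with `rate`, `se`, `r_squared`, `n`.
#' @export
growth_rate_estimate <- function(sol, window = range(sol$times)) {
  keep <- sol$times >= window[1] & sol$times <= window[2]
  t <- sol$times[keep]; l2 <- sol$l2_norms[keep]
  if (length(t) < 3L) .stop_fbr("window contains fewer than 3 samples",
                                "fbr_invalid_input")
  if (any(l2 <= 0)) .stop_fbr("L2 norms must be strictly positive on the window",
                              "fbr_invalid_input")
  fit <- stats::lm(log(l2) ~ t)
  # summary.lm warns on numerically perfect fits; that case is fine here
  sm <- suppressWarnings(summary(fit))
  list(rate = unname(stats::coef(fit)[2]),
       se = sm$coefficients[2, 2],
       r_squared = sm$r.squared,
       n = length(t))
}

#' Time series of norms and means as a data frame
#'
#' Columns `t, l2, mean_d, mean_c, mean_f, mean_m, mean_e` (lower-case
#' names regardless of whether the run was linearized or nonlinear).
#'
#' @param sol an `fbr_field_solution`.
#' @return data frame.
#' @export
norms_series <- function(sol) {
  m <- sol$means
  colnames(m) <- paste0("mean_", c("d", "c", "f", "m", "e"))
  cbind(data.frame(t = sol$times, l2 = sol$l2_norms), as.data.frame(m))
}

#' @export
print.fbr_field_solution <- function(x, ...) {
  cat("<fbr_field_solution>", length(x$times), "times x",
      dim(x$fields)[3], "nodes;",
      if (x$blowup) "TRUNCATED at blow-up cap" else "complete", "\n")
  cat(sprintf("  L2 norm: %.4g -> %.4g\n", x$l2_norms[1],
              x$l2_norms[length(x$l2_norms)]))
  invisible(x)
}
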