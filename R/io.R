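# Configuration I/O, fixture generation, task dispatch -------------------

.config_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) return("yaml")
  if (ext == "json") return("json")
  .stop_fbr(sprintf("unrecognized config extension '.%s' (use .yaml/.yml/.json)", ext),
            "fbr_config_error")
}

#' Read a parameter config file
#'
#' Flat key-value file (YAML or JSON, auto-detected from the extension)
#' with keys matching the `fbr_params` field names; a `schema` key and any
#' non-parameter keys are ignored for the parameter set itself.
#'
#' @param path config file path.
#' @return an `fbr_params`.
#' @export
read_params_config <- function(path) {
  if (!file.exists(path)) .stop_fbr(paste0("config not found: ", path), "fbr_config_error")
  fmt <- .config_format(path)
  raw <- tryCatch(
    switch(fmt,
      yaml = yaml::read_yaml(path),
      json = jsonlite::read_json(path, simplifyVector = TRUE)),
    error = function(e) .stop_fbr(paste0("unreadable config: ", conditionMessage(e)),
                                  "fbr_config_error"))
  if (!is.list(raw)) .stop_fbr("config must be a key-value mapping", "fbr_config_error")
  keys <- intersect(names(raw), .fbr_param_names)
  if (!length(keys)) .stop_fbr("config contains no recognised parameter keys",
                               "fbr_config_error")
  do.call(model_params, lapply(raw[keys], as.numeric))
}

#' Write a parameter config file
#'
#' @param p an `fbr_params`.
#' @param path output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_params_config <- function(p, path) {
  fmt <- .config_format(path)
  payload <- c(list(schema = "fbr-params/1"), unclass(p))
  switch(fmt,
    yaml = yaml::write_yaml(payload, path, precision = 17L),
    json = jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                                pretty = TRUE))
  invisible(path)
}

# Run a sampler under a local, seed-determined RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Sample a parameter set in a named dynamical regime
#'
#' Rejection-samples positive parameter sets (rates log-uniform, phenotype
#' fractions uniform on the simplex) until the defining inequalities of
#' the requested regime hold, then places the saturation thresholds `F0`
#' and `M0` above the implied equilibrium so the below-threshold analysis
#' applies. Deterministic given `seed`; the caller's RNG state is left
#' untouched.
#'
#' Regimes: `"existence_eq13"` / `"existence_eq14"` (the two existence sign
#' branches), `"ode_stable"` (regulatory-dominated branch, reaction system
#' asymptotically stable), `"ode_unstable_b24"` (inflammatory-dominated
#' branch, `b24 < 0` so one reaction eigenvalue is positive), and
#' `"counterexample"` (an `ode_unstable_b24` set with the `mu = 1` mobility
#' thresholds attached as attribute `"thresholds"`).
#'
#' @param regime regime name.
#' @param seed integer seed.
#' @param max_tries rejection budget.
#' @return an `fbr_params` passing [validate_params()] (warnings allowed).
#' @export
generate_fixture_params <- function(regime = c("existence_eq13", "existence_eq14",
                                               "ode_stable", "ode_unstable_b24",
                                               "counterexample"),
                                    seed = 1L, max_tries = 20000L) {
  regime <- match.arg(regime)
  target_branch <- switch(regime,
    existence_eq13 = "Eq13", ode_unstable_b24 = "Eq13", counterexample = "Eq13",
    existence_eq14 = "Eq14", ode_stable = "Eq14")
  .with_seed(seed, {
    for (try in seq_len(max_tries)) {
      lam <- -log(stats::runif(3)); lam <- lam / sum(lam)
      r <- function(n = 1L) 10^stats::runif(n, -1, 0.5)
      p <- model_params(
        Dd = r(), Dc = r(), Df = r(), Dm = r(), De = r(),
        chi0 = r() / 5, chi1 = r() / 5, chij = r() / 5, Bcoef = r(),
        f0 = r(), f0_tilde = r(), f1 = r(), f2 = r(), f3 = r(), f4 = r(),
        a0 = r(), a1 = r(), a2 = r(), a3 = r(), a11 = r(), a12 = r() / 5,
        a16 = r(),
        lambda1 = lam[1], lambda2 = lam[2], lambda3 = lam[3],
        F0 = 1, M0 = 1, E0 = r())
      ex <- existence_report(p)
      if (!ex$exists || ex$branch != target_branch) next
      # place thresholds above the equilibrium: fe <= F0 iff
      # F0 >= a1*lambda1*me/(a3 - a12*ce), needing a3 > a12*ce
      ce <- p$a0 / p$a11
      gap <- p$a3 - p$a12 * ce
      if (gap <= 0) next
      p$F0 <- 1.25 * p$a1 * p$lambda1 * ex$me_value / gap
      p$M0 <- 1.5 * ex$me_value
      rep <- ode_stability_report(linear_coefficients(p, interior_equilibrium(p)))
      ok <- switch(regime,
        ode_stable = rep$classification == "asymptotically_stable",
        ode_unstable_b24 = ,
        counterexample = rep$classification == "unstable" &&
          rep$conditions$b24_positive$margin < 0,
        TRUE)
      if (!ok) next
      if (regime == "counterexample") {
        co <- linear_coefficients(p, interior_equilibrium(p))
        attr(p, "thresholds") <- diffusion_stabilization_threshold(co, p, mu = 1)
      }
      attr(p, "regime") <- regime
      attr(p, "seed") <- seed
      return(p)
    }
    .stop_fbr(sprintf("could not sample regime '%s' in %d tries; relax the bounds",
                      regime, max_tries), "fbr_sampling_error")
  })
}

# -- task dispatch --------------------------------------------------------

.read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) .stop_fbr(paste0("config not found: ", config),
                                        "fbr_config_error")
    fmt <- .config_format(config)
    config <- tryCatch(
      switch(fmt,
        yaml = yaml::read_yaml(config),
        json = jsonlite::read_json(config, simplifyVector = TRUE)),
      error = function(e) .stop_fbr(paste0("unreadable config: ", conditionMessage(e)),
                                    "fbr_config_error"))
  }
  if (!is.list(config) || is.null(config$task)) {
    .stop_fbr("run config must be a list with a 'task' field", "fbr_config_error")
  }
  config
}

.config_params <- function(cfg) {
  if (is.null(cfg$params)) return(default_params())
  if (is.character(cfg$params)) return(read_params_config(cfg$params))
  keys <- intersect(names(cfg$params), .fbr_param_names)
  do.call(model_params, lapply(cfg$params[keys], as.numeric))
}

.write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  path
}

#' Run a named analysis task
#'
#' Dispatches a run configuration (a list, or a path to a YAML/JSON file)
#' to one of the analysis chains and writes its artifacts plus a run log
#' (package version, seed, config echo) into the output directory. Tasks:
#' `"equilibrium"`, `"ode-stability"`, `"modal-spectrum"`, `"energy-check"`,
#' `"simulate"` (linearized or full, per `config$model`),
#' `"counterexample"`, `"sweep"` (phenotype region scan).
#'
#' Config fields (all optional unless a task needs them): `params` (inline
#' list or file path; packaged defaults otherwise), `seed`, `domain`
#' (`kind`, `lengths`), `grid` (`extents`, `n_points`), `t_end`, `model`
#' (`"linearized"`/`"full"`), `mode` (initial eigenmode index),
#' `amplitude`, `resolution`, `Dc`, `Dm`, `out`.
#'
#' @param config list or path.
#' @param out_dir output directory (overrides `config$out`; default
#'   `tempdir()` subdirectory).
#' @return invisibly, list with `status = 0` and `artifacts` (paths).
#' @export
run_cli <- function(config, out_dir = NULL) {
  cfg <- .read_run_config(config)
  task <- cfg$task
  known <- c("equilibrium", "ode-stability", "modal-spectrum", "energy-check",
             "simulate", "counterexample", "sweep")
  if (!task %in% known) {
    .stop_fbr(sprintf("unknown task '%s' (known: %s)", task,
                      paste(known, collapse = ", ")), "fbr_unknown_task")
  }
  out_dir <- out_dir %||% cfg$out %||% file.path(tempdir(), paste0("fbr-", task))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  p <- .config_params(cfg)
  artifacts <- character()

  if (task == "equilibrium") {
    eq <- interior_equilibrium(p)
    ex <- existence_report(p)
    artifacts <- .write_json_artifact(list(
      equilibrium = eq[c("de", "ce", "fe", "me", "ee", "L1")],
      existence = list(exists = ex$exists, branch = ex$branch,
                       me_value = ex$me_value,
                       regime_flags = as.list(ex$regime_flags))),
      file.path(out_dir, "equilibrium.json"))
  } else if (task == "ode-stability") {
    co <- linear_coefficients(p, interior_equilibrium(p))
    rep <- ode_stability_report(co)
    artifacts <- .write_json_artifact(
      c(.stability_to_list(rep), list(coefficients = unclass(co))),
      file.path(out_dir, "ode_stability.json"))
  } else if (task == "modal-spectrum") {
    L <- (cfg$domain$lengths %||% pi)[1]
    co <- linear_coefficients(p, interior_equilibrium(p))
    scan <- pde_stability_report(co, p, default_mu_grid(L = L))
    path <- file.path(out_dir, "modal_spectrum.csv")
    utils::write.csv(scan$table, path, row.names = FALSE)
    verdict <- .write_json_artifact(list(
      stable = scan$stable, ode_classification = scan$ode$classification),
      file.path(out_dir, "modal_verdict.json"))
    artifacts <- c(path, verdict)
  } else if (task == "energy-check") {
    dom <- domain_spec(cfg$domain$kind %||% "interval",
                       cfg$domain$lengths %||% pi,
                       Cp = cfg$domain$Cp)
    rep <- energy_conditions_report(p, d = dom)
    artifacts <- .write_json_artifact(list(
      overall = rep$overall, Cp = rep$Cp, A_value = rep$A_value,
      conditions = lapply(rep$conditions, function(cd) {
        cd["note"] <- list(cd$note %||% "")
        cd
      })),
      file.path(out_dir, "energy_conditions.json"))
  } else if (task == "simulate") {
    g <- grid_spec(cfg$grid$extents %||% pi,
                   cfg$grid$n_points %||% 101)
    t_end <- cfg$t_end %||% 10
    model <- cfg$model %||% "linearized"
    mode_k <- as.integer(cfg$mode %||% 1L)
    amp <- cfg$amplitude %||% 1e-2
    eq <- interior_equilibrium(p)
    phi <- neumann_laplacian_modes(g, mode_k + 1L)[[mode_k + 1L]]$phi
    if (model == "linearized") {
      co <- linear_coefficients(p, eq)
      init <- matrix(rep(amp * as.numeric(phi), each = 5), nrow = 5)
      sol <- simulate_linearized(co, p, init, g, t_end)
      lam <- p$lambda1
    } else if (model == "full") {
      base <- equilibrium_state(eq)
      init <- pmax(outer(base, rep(1, .grid_npoints(g))) +
                     amp * outer(rep(1, 5), as.numeric(phi)), 0)
      sol <- simulate_full(p, init, g, t_end)
      lam <- p$lambda1
    } else {
      .stop_fbr("config$model must be 'linearized' or 'full'", "fbr_config_error")
    }
    path <- file.path(out_dir, "norms.csv")
    utils::write.csv(norms_series(sol), path, row.names = FALSE)
    artifacts <- path
  } else if (task == "counterexample") {
    Dc <- cfg$Dc %||% 1; Dm <- cfg$Dm %||% 1
    both <- lapply(c(stable = "stable", unstable = "unstable"), function(rg) {
      cx <- counterexample_params(Dc = Dc, Dm = Dm, regime = rg)
      list(regime = rg, chi_m = cx$chi_m,
           thresholds = cx$thresholds[c("chim_stable_max", "chim_growth_min")],
           epsilon = cx$thresholds$epsilon,
           max_re_sigma_mu1 = max(Re(cx$modal$sigma)),
           energy_verdict = cx$conditions$overall,
           derived_b = cx$coefficients[.fbr_b_names],
           chemotaxis = cx$coefficients[.fbr_chi_names],
           diffusion = cx$params)
    })
    artifacts <- .write_json_artifact(both, file.path(out_dir, "counterexample.json"))
  } else if (task == "sweep") {
    scan <- phenotype_region_scan(p, resolution = cfg$resolution %||% 30)
    path <- file.path(out_dir, "phenotype_region.csv")
    utils::write.csv(scan, path, row.names = FALSE)
    artifacts <- path
  }

  log_path <- file.path(out_dir, "run_log.json")
  .write_json_artifact(list(
    package = "fbrstab",
    version = as.character(utils::packageVersion("fbrstab")),
    task = task, seed = seed, config = cfg,
    artifacts = basename(artifacts)), log_path)
  invisible(list(status = 0L, artifacts = c(artifacts, log_path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
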