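#' Construct a scenario
#'
#' A scenario bundles everything a run needs: parameters, input schedule,
#' initial state, solver configuration and a seed, so a serialized scenario
#' reproduces its outputs exactly.
#'
#' @param name Scenario name.
#' @param params Parameter vector.
#' @param schedule An [input_schedule()].
#' @param x0 Initial state.
#' @param cfg A [sim_config()].
#' @param analysis Optional analysis-specific configuration list.
#' @param seed Integer seed for any stochastic stage.
#' @return A `scenario` object.
#' @export
scenario <- function(name, params = default_parameters(),
                     schedule = input_schedule(0.01, 7),
                     x0 = default_initial_state(),
                     cfg = sim_config(), analysis = list(), seed = 1) {
  viol <- validate_params(params)
  if (length(viol)) stop("invalid scenario parameters: ",
                         paste(viol, collapse = "; "))
  structure(list(name = name, params = params, schedule = schedule,
                 x0 = x0, cfg = cfg, analysis = analysis,
                 seed = as.integer(seed)),
            class = "scenario")
}

#' Canonical exposure scenarios
#'
#' The named presets used throughout the analysis, all starting from the
#' canonical baseline state:
#' \describe{
#'   \item{persistent}{continuous input at the canonical level 0.02
#'     (cutoff beyond the horizon).}
#'   \item{persistent_low}{continuous input at 0.01, the level of the
#'     bifurcation analyses.}
#'   \item{finite_7d}{input 0.01 for 7 days, then none; 70-day horizon.}
#'   \item{finite_14d}{input at the persistent level 0.02 for 14 days
#'     (brief exposure before the latent takeoff: fully reversible).}
#'   \item{finite_70d_retrial}{input 0.02 for 70 days (long enough to cross
#'     the takeoff threshold, pushing the state into the chronic basin) plus
#'     a re-exposure pulse on [140, 210] that no longer changes the
#'     outcome; 280-day horizon.}
#'   \item{high_clearance}{continuous input 0.01 with `d_v1 = 100`, the
#'     efficient-clearance regime of the basin analyses.}
#' }
#'
#' "Persistent" input is encoded as a cutoff beyond the simulation horizon
#' rather than a special infinite flag.
#'
#' @return Named list of `scenario` objects.
#' @export
canonical_scenarios <- function() {
  x0 <- default_initial_state()
  p <- default_parameters()
  horizon <- function(t1) sim_config(t_span = c(0, t1))
  list(
    persistent = scenario("persistent", p,
                          input_schedule(0.02, 1e6), x0, horizon(200)),
    persistent_low = scenario("persistent_low", p,
                              input_schedule(0.01, 1e6), x0, horizon(200)),
    finite_7d = scenario("finite_7d", p, input_schedule(0.01, 7), x0,
                         horizon(70)),
    finite_14d = scenario("finite_14d", p, input_schedule(0.02, 14), x0,
                          horizon(70)),
    finite_70d_retrial = scenario(
      "finite_70d_retrial", p,
      input_schedule(0.02, 70, extra = list(c(140, 210, 0.02))), x0,
      horizon(280)),
    high_clearance = scenario("high_clearance",
                              modify_parameters(p, d_v1 = 100),
                              input_schedule(0.01, 1e6), x0, horizon(200))
  )
}

#' Sample perturbed parameter sets
#'
#' Draws `n` copies of a base parameter set with only the named parameters
#' perturbed, either log-uniformly over a span of decades centred on the
#' base value (`mode = "log_uniform"`) or multiplicatively within a
#' relative fraction (`mode = "relative"`). Half-saturation constants and
#' Hill coefficients characterize the model's dynamical structure and are
#' never sampled unless `allow_shape = TRUE` is set explicitly.
#'
#' @param base Base parameter vector.
#' @param which Character vector of parameter names to perturb.
#' @param mode `"log_uniform"` or `"relative"`.
#' @param spread Decades of total span (log_uniform) or relative half-width
#'   (relative).
#' @param n Number of sampled sets (>= 1).
#' @param seed RNG seed (restored on exit).
#' @param allow_shape Permit sampling of `k_*` / `n_*` parameters.
#' @return List of `n` parameter vectors.
#' @export
sample_parameters <- function(base, which, mode = c("relative", "log_uniform"),
                              spread = 0.3, n = 1, seed = 1,
                              allow_shape = FALSE) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  bad <- setdiff(which, names(base))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  shape <- which[grepl("^(k_|n_)", which)]
  if (length(shape) && !allow_shape) {
    stop("refusing to sample half-saturation/Hill parameters (",
         paste(shape, collapse = ", "), ") without allow_shape = TRUE")
  }
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      p <- base
      for (nm in which) {
        p[[nm]] <- if (mode == "log_uniform") {
          p[[nm]] * 10^stats::runif(1, -spread / 2, spread / 2)
        } else {
          p[[nm]] * stats::runif(1, 1 - spread, 1 + spread)
        }
      }
      p
    })
  })
}

#' Serialize / restore a scenario
#'
#' Scenarios round-trip losslessly through JSON.
#'
#' @param sc A `scenario`.
#' @param path JSON file path.
#' @return `path` (write) or the restored `scenario` (read).
#' @export
write_scenario <- function(sc, path) {
  jsonlite::write_json(list(
    name = sc$name, params = as.list(sc$params),
    schedule = list(phi = sc$schedule$phi, T_end = sc$schedule$T_end,
                    extra = sc$schedule$extra),
    x0 = as.list(sc$x0), cfg = unclass(sc$cfg),
    analysis = sc$analysis, seed = sc$seed
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- NULL
  if (length(s$schedule$extra)) {
    ex <- s$schedule$extra
    extra <- if (is.matrix(ex)) {
      lapply(seq_len(nrow(ex)), function(i) as.numeric(ex[i, ]))
    } else lapply(ex, as.numeric)
  }
  scenario(
    name = s$name, params = unlist(s$params),
    schedule = input_schedule(s$schedule$phi, s$schedule$T_end, extra),
    x0 = unlist(s$x0),
    cfg = sim_config(t_span = s$cfg$t_span, rel_tol = s$cfg$rel_tol,
                     abs_tol = s$cfg$abs_tol,
                     max_step = if (is.null(s$cfg$max_step)) Inf else s$cfg$max_step,
                     dense_grid = s$cfg$dense_grid),
    analysis = as.list(s$analysis), seed = s$seed
  )
}

#' Run an analysis stage end-to-end and write its outputs
#'
#' Dispatches a scenario to one of the pipeline stages and writes tidy CSV
#' outputs plus a JSON manifest (scenario echo, stage, wall time) under
#' `out_dir`. Stages: `simulate`, `equilibria`, `sweep`, `scan2d`,
#' `basins`, `durations`, `subsystems`. Stage-specific options are read
#' from `sc$analysis` (see the analysis drivers for worked examples).
#'
#' @param sc A `scenario` (or path to a serialized one).
#' @param stage Stage name.
#' @param out_dir Output directory (created if needed).
#' @return Named list of written file paths, invisibly.
#' @export
run_pipeline <- function(sc, stage = c("simulate", "equilibria", "sweep",
                                       "scan2d", "basins", "durations",
                                       "subsystems"),
                         out_dir = ".") {
  stage <- match.arg(stage)
  if (is.character(sc)) sc <- read_scenario(sc)
  stopifnot(inherits(sc, "scenario"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  an <- sc$analysis
  paths <- list()
  out <- function(f) file.path(out_dir, f)

  if (stage == "simulate") {
    traj <- simulate_model(sc$x0, sc$params, sc$schedule, sc$cfg)
    paths$trajectory <- write_trajectory(traj, out("trajectory.csv"))
  } else if (stage == "equilibria") {
    es <- find_equilibria(sc$params, sc$schedule$phi,
                          n_starts = an$n_starts %||% 200, seed = sc$seed)
    paths$equilibria <- write_equilibria(es, out("equilibria.csv"))
  } else if (stage == "sweep") {
    br <- sweep_parameter(an$param %||% "d_v1",
                          an$values %||% 10^seq(-2, 2, length.out = 25),
                          sc$params, sc$schedule$phi,
                          n_starts = an$n_starts %||% 200, seed = sc$seed)
    paths$branches <- write_branches(br, out("branches.csv"))
  } else if (stage == "scan2d") {
    cm <- two_parameter_count_scan(
      an$p1 %||% "a_v0", an$p1_grid %||% 10^seq(-1 + log10(2.5), 1 + log10(2.5), length.out = 15),
      an$p2 %||% "d_v1", an$p2_grid %||% 10^seq(-1 + log10(0.24), 1 + log10(0.24), length.out = 15),
      sc$params, sc$schedule$phi,
      n_starts = an$n_starts %||% 200, seed = sc$seed)
    paths$count_map <- write_count_map(cm, out("count_map.csv"))
  } else if (stage == "basins") {
    bm <- basin_scan(an$I0_grid %||% seq(0, 2, length.out = 21),
                     an$C0_grid %||% seq(0, 2, length.out = 21),
                     p = sc$params, alpha_level = sc$schedule$phi)
    paths$basins <- write_basin_map(bm, out("basin_map.csv"))
  } else if (stage == "durations") {
    tab <- sensitivity_experiment(
      an$focal_param %||% "k_v0",
      an$focal_values %||% 10^seq(-2, 1, length.out = 13),
      n_reps = an$n_reps %||% 10, p_base = sc$params, sched = sc$schedule,
      cfg = an$duration_cfg %||% duration_config(), x0 = sc$x0,
      seed = sc$seed)
    paths$durations <- out("durations.csv")
    utils::write.csv(tab, paths$durations, row.names = FALSE)
  } else if (stage == "subsystems") {
    specs <- enumerate_subsystems(
      clamp_source = an$clamp_source %||% baseline_clamp_state(sc$params),
      focal_grid = an$focal_grid %||% 10^seq(-2, 2, length.out = 25))
    results <- lapply(specs, detect_bistability, p = sc$params,
                      alpha_level = sc$schedule$phi,
                      n_starts = an$n_starts %||% 100, seed = sc$seed)
    paths$subsystems <- write_subsystem_results(results,
                                                out("subsystems.csv"))
    paths$frequency <- out("bistability_frequency.csv")
    utils::write.csv(membership_frequency(results), paths$frequency,
                     row.names = FALSE)
  }

  manifest <- list(
    stage = stage,
    scenario = list(name = sc$name, params = as.list(sc$params),
                    schedule = list(phi = sc$schedule$phi,
                                    T_end = sc$schedule$T_end,
                                    extra = sc$schedule$extra),
                    x0 = as.list(sc$x0), cfg = unclass(sc$cfg),
                    analysis = an, seed = sc$seed),
    outputs = lapply(paths, basename),
    wall_time_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    package_version = tryCatch(
      as.character(utils::packageVersion("virimmune")),
      error = function(e) NA_character_)
  )
  jsonlite::write_json(manifest, out(paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
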