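#' Simulation configuration
#'
#' @param t_span Length-2 numeric `(t0, t1)` in days, `t0 < t1`.
#' @param rel_tol,abs_tol Solver tolerances (defaults 1e-8 / 1e-10; branch
#'   and basin classification is tolerance-sensitive, so defaults are tight).
#' @param max_step Maximum solver step in days (`Inf` leaves it to the solver).
#' @param dense_grid Output resolution, points per day.
#' @return A `sim_config` list.
#' @export
sim_config <- function(t_span = c(0, 70), rel_tol = 1e-8, abs_tol = 1e-10,
                       max_step = Inf, dense_grid = 10) {
  stopifnot(length(t_span) == 2, t_span[1] < t_span[2],
            rel_tol > 0, abs_tol > 0, dense_grid > 0)
  structure(list(t_span = as.numeric(t_span), rel_tol = rel_tol,
                 abs_tol = abs_tol, max_step = max_step,
                 dense_grid = dense_grid),
            class = "sim_config")
}

# deSolve adapter: constant input level on one smooth piece.
.desolve_func <- function(t, y, parms) {
  list(unname(rhs(t, pmax(y, 0), parms$p, parms$alpha)))
}
.desolve_jac <- function(t, y, parms) {
  jacobian(pmax(y, 0), parms$p, parms$alpha)
}

#' Simulate the virus-immune model
#'
#' Integrates the model with a stiff implicit solver (deSolve's `lsoda` with
#' the analytic Jacobian supplied). Integration is restarted at every jump of
#' the input schedule so no step straddles a discontinuity; small negative
#' undershoot (below `-abs_tol`, a purely numerical artifact of an
#' inward-pointing field) is clipped to zero and counted.
#'
#' @param x0 Nonnegative initial state `(V, I, C, H, S, IL6)`.
#' @param p Parameter vector.
#' @param sched An [input_schedule()] (or constant level).
#' @param cfg A [sim_config()].
#' @return A `trajectory` object: list with `times`, `states` (matrix, one
#'   row per time), `schedule`, `params`, `n_clipped`.
#' @export
simulate_model <- function(x0, p, sched, cfg = sim_config()) {
  stopifnot(length(x0) == 6, all(is.finite(x0)), all(x0 >= 0))
  viol <- validate_params(p)
  if (length(viol)) stop("invalid parameters: ", paste(viol, collapse = "; "))
  if (!inherits(sched, "input_schedule")) sched <- input_schedule(sched, Inf)

  t0 <- cfg$t_span[1]; t1 <- cfg$t_span[2]
  br <- schedule_breaks(sched)
  cuts <- sort(unique(c(t0, br[br > t0 & br < t1], t1)))
  grid <- seq(t0, t1, by = 1 / cfg$dense_grid)
  if (grid[length(grid)] < t1) grid <- c(grid, t1)

  x <- unname(as.numeric(x0))
  times_out <- numeric(0)
  states_out <- NULL
  n_clipped <- 0L
  for (i in seq_len(length(cuts) - 1)) {
    a <- cuts[i]; b <- cuts[i + 1]
    # alpha is evaluated just inside the piece so each segment is autonomous
    alpha <- input_rate(min(a + (b - a) * 1e-9, b), sched)
    seg_times <- sort(unique(c(a, grid[grid > a & grid < b], b)))
    sol <- deSolve::ode(
      y = x, times = seg_times, func = .desolve_func,
      parms = list(p = p, alpha = alpha),
      jacfunc = .desolve_jac, jactype = "fullusr",
      method = "lsoda", rtol = cfg$rel_tol, atol = cfg$abs_tol,
      hmax = if (is.finite(cfg$max_step)) cfg$max_step else NULL
    )
    if (attr(sol, "istate")[1] < 0) {
      stop("simulate_model: solver failure; last accepted time ",
           max(sol[, 1]))
    }
    seg_states <- sol[, -1, drop = FALSE]
    n_clipped <- n_clipped + sum(seg_states < -cfg$abs_tol)
    seg_states[seg_states < 0] <- 0
    keep <- if (i == 1) seq_len(nrow(sol)) else -1L  # drop duplicated cut row
    times_out <- c(times_out, sol[keep, 1])
    states_out <- rbind(states_out, seg_states[keep, , drop = FALSE])
    x <- seg_states[nrow(seg_states), ]
  }
  colnames(states_out) <- state_names()
  states_out[1, ] <- unname(as.numeric(x0))
  structure(list(times = times_out, states = states_out, schedule = sched,
                 params = p, config = cfg, n_clipped = n_clipped),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times), " time points over [",
      x$times[1], ", ", x$times[length(x$times)], "] days\n", sep = "")
  cat("  final state:",
      paste(sprintf("%s=%.4g", state_names(), x$states[nrow(x$states), ]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Integrate to a steady state under constant input
#'
#' Runs the model under a constant input level and reports the terminal
#' state together with a convergence verdict: converged means the residual
#' max-norm of the vector field fell below `conv_tol` *and* the state varied
#' by less than `conv_tol` (max-norm) over a trailing window. `t_conv` is
#' the earliest grid time from which both held through the end of the run.
#'
#' @param x0 Initial state.
#' @param p Parameter vector.
#' @param alpha_level Constant input level (>= 0).
#' @param cfg A [sim_config()].
#' @param conv_tol Convergence tolerance (max-norm), default 1e-7.
#' @param window Trailing window length in days, default 10.
#' @return List `(state, converged, t_conv, trajectory)`.
#' @export
steady_state_by_integration <- function(x0, p, alpha_level = 0,
                                        cfg = sim_config(t_span = c(0, 500), dense_grid = 2),
                                        conv_tol = 1e-7, window = 10) {
  traj <- simulate_model(x0, p, input_schedule(alpha_level, Inf), cfg)
  tt <- traj$times; st <- traj$states
  n <- length(tt)
  res <- vapply(seq_len(n), function(i) {
    max(abs(rhs(tt[i], st[i, ], p, alpha_level)))
  }, numeric(1))
  ok <- res < conv_tol
  # earliest time from which both the residual and the deviation from the
  # terminal state stay below conv_tol (suffix maxima, computed backwards)
  t_conv <- NA_real_
  if (ok[n]) {
    final <- st[n, ]
    row_dev <- apply(abs(sweep(st, 2, final)), 1, max)
    suffix_bad <- rev(cummax(rev(pmax(row_dev, res)))) >= conv_tol
    if (!suffix_bad[n]) {
      i0 <- if (any(suffix_bad)) max(which(suffix_bad)) + 1L else 1L
      if (tt[n] - tt[i0] >= window || i0 == 1L) t_conv <- tt[i0]
    }
  }
  converged <- ok[n] && !is.na(t_conv)
  list(state = st[n, ], converged = converged,
       t_conv = if (converged) t_conv else NA_real_, trajectory = traj)
}

#' Recovery time of selected components
#'
#' Earliest time at or after the input cutoff from which every selected
#' component stays within a relative tolerance of its baseline value for the
#' remainder of the trajectory. Near-zero baselines are handled with an
#' absolute floor: the allowed deviation for component `j` is
#' `max(frac_tol * |baseline_j|, abs_floor)`.
#'
#' @param traj A `trajectory` extending beyond the schedule cutoff.
#' @param baseline Reference state the components must return to (e.g. the
#'   post-input steady state).
#' @param components Character subset of [state_names()] to monitor.
#' @param frac_tol Relative tolerance (default 0.1, i.e. within 10%).
#' @param abs_floor Absolute floor for near-zero baselines (default 1e-3).
#' @return Recovery time in days, or `NA` if some component never settles.
#' @export
recovery_time <- function(traj, baseline,
                          components = c("V", "I", "C", "IL6"),
                          frac_tol = 0.1, abs_floor = 1e-3) {
  stopifnot(inherits(traj, "trajectory"))
  T_cut <- traj$schedule$T_end
  if (max(traj$times) <= T_cut) stop("trajectory does not extend beyond the input cutoff")
  idx <- match(components, state_names())
  stopifnot(!anyNA(idx))
  base <- as.numeric(baseline)[idx]
  tol <- pmax(frac_tol * abs(base), abs_floor)
  sel <- traj$times >= T_cut
  tt <- traj$times[sel]
  dev <- sweep(traj$states[sel, idx, drop = FALSE], 2, base)
  inside <- rowSums(abs(dev) > rep(tol, each = nrow(dev))) == 0
  if (!inside[length(inside)]) return(NA_real_)
  # last excursion outside the band determines recovery
  out_idx <- which(!inside)
  if (length(out_idx) == 0) return(tt[1])
  tt[max(out_idx) + 1]
}

#' Export / import a trajectory as tidy CSV with a JSON sidecar
#'
#' The CSV holds columns `time, V, I, C, H, S, IL6`; the sidecar
#' (`<path>.json`) records parameters, schedule and solver configuration so
#' the run is reproducible from its files alone.
#'
#' @param traj A `trajectory`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(
    params = as.list(traj$params),
    schedule = list(phi = traj$schedule$phi, T_end = traj$schedule$T_end,
                    extra = traj$schedule$extra),
    config = unclass(traj$config),
    n_clipped = traj$n_clipped
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sched <- input_schedule(meta$schedule$phi, meta$schedule$T_end,
                          extra = if (length(meta$schedule$extra)) {
                            lapply(seq_len(nrow(meta$schedule$extra)),
                                   function(i) as.numeric(meta$schedule$extra[i, ]))
                          })
  cfg <- do.call(sim_config, meta$config[c("t_span", "rel_tol", "abs_tol",
                                           "max_step", "dense_grid")])
  structure(list(times = df$time,
                 states = as.matrix(df[, state_names()]),
                 schedule = sched,
                 params = unlist(meta$params),
                 config = cfg,
                 n_clipped = meta$n_clipped),
            class = "trajectory")
}
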