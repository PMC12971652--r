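#' Duration-indicator configuration
#'
#' Thresholds and debouncing for the infectious-duration (viral load above
#' `theta_V`) and illness-duration (IL-6 above `theta_IL6`) indicators.
#' The default thresholds sit at a few percent of the canonical peak scale;
#' they are echoed into every result so no conclusion is implicit in them.
#'
#' @param theta_V Infectiousness threshold on V (> 0), default 0.05.
#' @param theta_IL6 Inflammation threshold on IL-6 (> 0), default 0.02.
#' @param min_duration Debounce window in days: a crossing only counts when
#'   sustained at least this long (default 0.1).
#' @param smooth_window Moving-average window in days applied before
#'   crossing detection, or `NULL` (default) for none — solver output is
#'   already smooth.
#' @param t_end Observation horizon in days (episodes still open at `t_end`
#'   are censored), default 70.
#' @return A `duration_config` list.
#' @export
duration_config <- function(theta_V = 0.05, theta_IL6 = 0.02,
                            min_duration = 0.1, smooth_window = NULL,
                            t_end = 70) {
  stopifnot(theta_V > 0, theta_IL6 > 0, min_duration >= 0)
  structure(list(theta_V = theta_V, theta_IL6 = theta_IL6,
                 min_duration = min_duration, smooth_window = smooth_window,
                 t_end = t_end),
            class = "duration_config")
}

# linear interpolation of the time where the series crosses theta between
# samples i and i+1
.cross_time <- function(times, values, i, theta) {
  t1 <- times[i]; t2 <- times[i + 1]
  v1 <- values[i]; v2 <- values[i + 1]
  if (v2 == v1) return(t2)
  t1 + (theta - v1) / (v2 - v1) * (t2 - t1)
}

#' First sustained threshold crossing of a series
#'
#' Finds the onset time (earliest time the series reaches or exceeds
#' `theta`, sustained for at least the debounce window) and the offset time
#' (earliest later time it falls below `theta`, again sustained). Crossing
#' times are located by linear interpolation between samples; optional
#' moving-average smoothing is applied first. An episode still above
#' threshold at the end of the series is censored (no offset).
#'
#' @param times Increasing sample times.
#' @param values Series values at `times`.
#' @param theta Threshold (> 0).
#' @param cfg A [duration_config()] (supplies debounce and smoothing).
#' @return List `(t_on, t_off, censored)`; `t_on`/`t_off` are `NA` when the
#'   respective crossing never happens.
#' @export
first_crossing_window <- function(times, values, theta,
                                  cfg = duration_config()) {
  if (length(times) == 0) stop("first_crossing_window: empty series")
  stopifnot(length(times) == length(values), !is.unsorted(times))
  if (!is.null(cfg$smooth_window) && cfg$smooth_window > 0) {
    # centered moving average over ~smooth_window days
    step <- stats::median(diff(times))
    k <- max(1L, round(cfg$smooth_window / step / 2))
    n <- length(values)
    values <- vapply(seq_len(n), function(i) {
      mean(values[max(1, i - k):min(n, i + k)])
    }, numeric(1))
  }
  above <- values >= theta
  n <- length(times)

  # runs of constant above/below state; a run's time length is measured from
  # entering it to leaving it, and a run reaching the series end always
  # passes the debounce (its true length is unknowable)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  run_len <- function(k) {
    if (ends[k] == n) Inf else times[ends[k] + 1] - times[starts[k]]
  }
  sustained <- vapply(seq_along(r$values),
                      function(k) run_len(k) >= cfg$min_duration, logical(1))

  on_run <- which(r$values & sustained)
  if (!length(on_run)) {
    return(list(t_on = NA_real_, t_off = NA_real_, censored = FALSE))
  }
  on_run <- on_run[1]
  i_on <- starts[on_run]
  t_on <- if (i_on == 1) times[1] else .cross_time(times, values, i_on - 1, theta)

  off_run <- which(!r$values & sustained & seq_along(r$values) > on_run)
  if (!length(off_run)) {
    return(list(t_on = t_on, t_off = NA_real_, censored = TRUE))
  }
  i_off <- starts[off_run[1]]
  t_off <- .cross_time(times, values, i_off - 1, theta)
  list(t_on = t_on, t_off = t_off, censored = FALSE)
}

#' Infectious and illness durations of a trajectory
#'
#' Applies [first_crossing_window()] to the viral-load and IL-6 series of a
#' trajectory: the infectious duration is the time V spends at or above
#' `theta_V` from first onset to first sustained offset, the illness
#' duration likewise for IL-6 against `theta_IL6`. A threshold never
#' reached gives duration 0 with both times absent; an episode still open
#' at the horizon is censored (duration measured to `t_end`).
#'
#' @param traj A `trajectory` spanning `[0, t_end]`.
#' @param cfg A [duration_config()].
#' @return A `duration_result`: `t_on_V`, `t_off_V`, `D_infec`, `t_on_IL6`,
#'   `t_off_IL6`, `D_ill`, `censored_V`, `censored_IL6`, `config`.
#' @export
durations_for <- function(traj, cfg = duration_config()) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- traj$times <= cfg$t_end + 1e-12
  tt <- traj$times[sel]
  if (max(tt) < cfg$t_end - 1e-9) {
    stop("durations_for: trajectory ends before t_end")
  }
  one <- function(comp, theta) {
    cr <- first_crossing_window(tt, traj$states[sel, comp], theta, cfg)
    D <- if (is.na(cr$t_on)) 0
         else if (cr$censored) cfg$t_end - cr$t_on
         else cr$t_off - cr$t_on
    c(cr, list(D = D))
  }
  v <- one("V", cfg$theta_V)
  il <- one("IL6", cfg$theta_IL6)
  structure(list(t_on_V = v$t_on, t_off_V = v$t_off, D_infec = v$D,
                 t_on_IL6 = il$t_on, t_off_IL6 = il$t_off, D_ill = il$D,
                 censored_V = v$censored, censored_IL6 = il$censored,
                 config = cfg),
            class = "duration_result")
}

#' Duration sensitivity under multi-parameter perturbation
#'
#' For each value of a focal parameter (varied across orders of magnitude)
#' and each replicate, every non-focal rate parameter (`a_*`, `d_*` and
#' `delta`) is multiplied by an independent draw from
#' `Uniform(1 - perturb_frac, 1 + perturb_frac)`; half-saturation constants
#' and Hill coefficients are never perturbed. One finite-exposure
#' simulation and one duration evaluation are run per cell.
#'
#' @param focal_param Name of the focal parameter.
#' @param focal_values Positive (log-spaced) grid for the focal parameter.
#' @param n_reps Replicates per focal value (>= 1).
#' @param perturb_frac Relative perturbation half-width, default 0.3.
#' @param p_base Base parameter vector.
#' @param sched Input schedule of the scenario (default 7-day exposure at
#'   0.01).
#' @param cfg A [duration_config()]; the simulation horizon is `cfg$t_end`.
#' @param sim_cfg Solver configuration (defaults to `[0, t_end]`).
#' @param x0 Initial state.
#' @param seed RNG seed (restored on exit).
#' @return Tidy data.frame: `focal_param`, `focal_value`, `replicate`,
#'   `seed`, `D_infec`, `D_ill`, `censored_V`, `censored_IL6`. Failed
#'   integrations yield `NA` rows rather than aborting the experiment.
#' @export
sensitivity_experiment <- function(focal_param, focal_values, n_reps = 10,
                                   perturb_frac = 0.3,
                                   p_base = default_parameters(),
                                   sched = input_schedule(0.01, 7),
                                   cfg = duration_config(),
                                   sim_cfg = NULL,
                                   x0 = default_initial_state(),
                                   seed = 1) {
  stopifnot(all(focal_values > 0), n_reps >= 1)
  if (!focal_param %in% names(p_base)) stop("unknown parameter: ", focal_param)
  if (is.null(sim_cfg)) sim_cfg <- sim_config(t_span = c(0, cfg$t_end))
  rate_names <- names(p_base)[grepl("^(a_|d_)", names(p_base)) |
                                names(p_base) == "delta"]
  rate_names <- setdiff(rate_names, focal_param)
  cells <- expand.grid(replicate = seq_len(n_reps),
                       focal_value = focal_values)
  factors <- with_seed(seed, {
    matrix(stats::runif(nrow(cells) * length(rate_names),
                        1 - perturb_frac, 1 + perturb_frac),
           nrow = nrow(cells))
  })
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    pv <- p_base
    pv[rate_names] <- pv[rate_names] * factors[k, ]
    pv[[focal_param]] <- cells$focal_value[k]
    res <- tryCatch({
      traj <- simulate_model(x0, pv, sched, sim_cfg)
      durations_for(traj, cfg)
    }, error = function(e) NULL)
    data.frame(
      focal_param = focal_param, focal_value = cells$focal_value[k],
      replicate = cells$replicate[k], seed = seed,
      D_infec = if (is.null(res)) NA_real_ else res$D_infec,
      D_ill = if (is.null(res)) NA_real_ else res$D_ill,
      censored_V = if (is.null(res)) NA else res$censored_V,
      censored_IL6 = if (is.null(res)) NA else res$censored_IL6)
  })
  do.call(rbind, rows)
}
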