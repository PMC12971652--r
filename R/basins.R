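#' Outcome classes of the long-run immune state
#'
#' With viral clearance efficient (high `d_v1`) the virus converges near
#' zero and the long-run outcome is summarized by whether cellular immunity
#' and IL-6 settle high or low: `LOW_IL6_LOW_C` (homeostasis restored),
#' `HIGH_IL6_LOW_C` (inflammation without cellular engagement) and
#' `HIGH_IL6_HIGH_C` (sustained immune activation / chronic inflammation).
#' The fourth combination is not expected dynamically and is reported as
#' `ANOMALY_LOW_IL6_HIGH_C` if ever observed.
#'
#' @param final A converged steady state.
#' @param thresholds List with `C` and `IL6` high/low separators (see
#'   [calibrate_thresholds()]).
#' @return Character label with attribute `borderline` (TRUE when either
#'   value lies within 1e-6 of its threshold).
#' @export
classify_outcome <- function(final, thresholds) {
  Cv <- final[[3]]; IL <- final[[6]]
  hiC <- Cv >= thresholds$C
  hiIL <- IL >= thresholds$IL6
  label <- if (!hiIL && !hiC) "LOW_IL6_LOW_C"
           else if (hiIL && !hiC) "HIGH_IL6_LOW_C"
           else if (hiIL && hiC) "HIGH_IL6_HIGH_C"
           else "ANOMALY_LOW_IL6_HIGH_C"
  borderline <- abs(Cv - thresholds$C) < 1e-6 || abs(IL - thresholds$IL6) < 1e-6
  structure(label, borderline = borderline)
}

#' Self-calibrating high/low thresholds
#'
#' Places the C and IL-6 separators at the midpoint between the lowest and
#' highest stable-equilibrium values of each variable found by the census at
#' the scenario's parameters, so "high" and "low" always refer to the
#' branches that actually coexist there. When the census finds a single
#' stable level the midpoint between zero and that level is used.
#'
#' @param p Parameter vector of the scenario.
#' @param alpha_level Constant input level.
#' @param n_starts,seed Census configuration.
#' @return List `(C, IL6)` of thresholds.
#' @export
calibrate_thresholds <- function(p, alpha_level, n_starts = 200, seed = 1) {
  es <- find_equilibria(p, alpha_level, n_starts = n_starts, seed = seed)
  st <- Filter(function(r) r$stability == "stable", es$records)
  if (!length(st)) stop("calibrate_thresholds: no stable equilibrium found")
  mid <- function(v) {
    if (max(v) - min(v) > 1e-6) (min(v) + max(v)) / 2 else max(v) / 2
  }
  list(C = mid(vapply(st, function(r) r$state[["C"]], numeric(1))),
       IL6 = mid(vapply(st, function(r) r$state[["IL6"]], numeric(1))))
}

#' Scan initial conditions in the (I0, C0) plane
#'
#' Integrates the model to steady state from every node of an initial-
#' condition grid (innate immunity on one axis, cellular immunity on the
#' other, all other components at their supplied defaults) and classifies
#' each long-run outcome. Intended for the efficient-clearance regime
#' (e.g. `d_v1 = 100`) where the virus converges near zero and outcomes
#' differ in the immune variables.
#'
#' @param I0_grid,C0_grid Numeric grids of initial innate / cellular levels.
#' @param other_x0 Defaults for the remaining components (V, H, S, IL6 taken
#'   from it; default [default_initial_state()]).
#' @param p Parameter vector (caller sets `d_v1` high for the scenario).
#' @param alpha_level Constant input level (default 0.01).
#' @param cfg [sim_config()] for the per-node integration.
#' @param thresholds Outcome thresholds; `NULL` (default) self-calibrates
#'   via [calibrate_thresholds()].
#' @param conv_tol Convergence tolerance for the per-node steady state.
#' @return A `basin_map`: grids, `labels` matrix (rows = I0, cols = C0),
#'   `final_states` array, `thresholds`, `n_nonconverged` (non-converged
#'   nodes are labelled `"NONCONVERGED"`; if they exceed 5% of nodes a
#'   warning is recorded in the metadata).
#' @export
basin_scan <- function(I0_grid, C0_grid, other_x0 = default_initial_state(),
                       p = modify_parameters(default_parameters(), d_v1 = 100),
                       alpha_level = 0.01,
                       cfg = sim_config(t_span = c(0, 400), rel_tol = 1e-8,
                                        abs_tol = 1e-10, dense_grid = 1),
                       thresholds = NULL, conv_tol = 1e-6) {
  if (is.null(thresholds)) thresholds <- calibrate_thresholds(p, alpha_level)
  nI <- length(I0_grid); nC <- length(C0_grid)
  labels <- matrix(NA_character_, nI, nC)
  finals <- array(NA_real_, c(nI, nC, 6),
                  dimnames = list(NULL, NULL, state_names()))
  n_bad <- 0L
  for (i in seq_len(nI)) {
    for (j in seq_len(nC)) {
      x0 <- other_x0
      x0[["I"]] <- I0_grid[i]; x0[["C"]] <- C0_grid[j]
      ss <- steady_state_by_integration(x0, p, alpha_level, cfg,
                                        conv_tol = conv_tol)
      finals[i, j, ] <- ss$state
      if (!ss$converged) {
        labels[i, j] <- "NONCONVERGED"
        n_bad <- n_bad + 1L
      } else {
        labels[i, j] <- as.character(classify_outcome(ss$state, thresholds))
      }
    }
  }
  warn <- if (n_bad > 0.05 * nI * nC) {
    sprintf("%d of %d nodes (> 5%%) did not converge", n_bad, nI * nC)
  }
  structure(list(I0_grid = I0_grid, C0_grid = C0_grid, labels = labels,
                 final_states = finals, thresholds = thresholds,
                 alpha_level = alpha_level, params = p,
                 n_nonconverged = n_bad, warning = warn),
            class = "basin_map")
}

# separable Gaussian smoothing of a matrix on its index grid; bandwidth in
# grid cells. Kernel renormalized at the edges.
.gauss_smooth2d <- function(m, bandwidth) {
  if (bandwidth <= 0) return(m)
  r <- ceiling(3 * bandwidth)
  w <- stats::dnorm(-r:r, sd = bandwidth)
  sm1 <- function(x) {  # smooth columns of a matrix along rows
    n <- nrow(x)
    out <- x * 0
    for (i in seq_len(n)) {
      lo <- max(1, i - r); hi <- min(n, i + r)
      ww <- w[(lo - i + r + 1):(hi - i + r + 1)]
      out[i, ] <- colSums(x[lo:hi, , drop = FALSE] * ww) / sum(ww)
    }
    out
  }
  t(sm1(t(sm1(m))))
}

#' Outcome probability density over the initial-condition plane
#'
#' Replicates a basin scan with multiplicative jitter on the initial (I0,
#' C0) of every node, computes the per-class occurrence frequency at each
#' node, and smooths each class surface with a separable Gaussian kernel
#' (class probabilities renormalized to sum to one at every node). Far from
#' basin boundaries the density is degenerate (one class at probability 1);
#' near boundaries the jitter mixes classes and probabilities become
#' fractional.
#'
#' @param I0_grid,C0_grid Grids as in [basin_scan()].
#' @param n_replicates Number of jittered replicates (>= 2, default 50).
#' @param jitter_frac Multiplicative jitter half-width (default 0.02,
#'   i.e. uniform within 2% of each initial value).
#' @param bandwidth Gaussian bandwidth in grid cells (default 1).
#' @param seed RNG seed (restored on exit).
#' @param other_x0,p,alpha_level,cfg,thresholds,conv_tol As in [basin_scan()];
#'   thresholds are calibrated once for all replicates when `NULL`.
#' @return A `density_map`: grids, named list `density` of per-class
#'   probability matrices, `classes`, `n_replicates`, `jitter_frac`,
#'   `bandwidth`, `seed`.
#' @export
outcome_density <- function(I0_grid, C0_grid, n_replicates = 50,
                            jitter_frac = 0.02, bandwidth = 1, seed = 1,
                            other_x0 = default_initial_state(),
                            p = modify_parameters(default_parameters(),
                                                  d_v1 = 100),
                            alpha_level = 0.01,
                            cfg = sim_config(t_span = c(0, 400),
                                             dense_grid = 1),
                            thresholds = NULL, conv_tol = 1e-6) {
  stopifnot(n_replicates >= 2)
  if (is.null(thresholds)) thresholds <- calibrate_thresholds(p, alpha_level)
  classes <- c("LOW_IL6_LOW_C", "HIGH_IL6_LOW_C", "HIGH_IL6_HIGH_C",
               "ANOMALY_LOW_IL6_HIGH_C")
  nI <- length(I0_grid); nC <- length(C0_grid)
  tally <- lapply(classes, function(cl) matrix(0, nI, nC))
  names(tally) <- classes
  n_eff <- matrix(0, nI, nC)
  jit <- with_seed(seed, {
    array(stats::runif(n_replicates * nI * nC * 2,
                       1 - jitter_frac, 1 + jitter_frac),
          c(n_replicates, nI * nC, 2))
  })
  for (r in seq_len(n_replicates)) {
    # jittered node positions; scan evaluates each jittered point directly
    bm <- .basin_scan_points(
      I0 = rep(I0_grid, times = nC) * jit[r, , 1],
      C0 = rep(C0_grid, each = nI) * jit[r, , 2],
      other_x0 = other_x0, p = p, alpha_level = alpha_level, cfg = cfg,
      thresholds = thresholds, conv_tol = conv_tol)
    lab <- matrix(bm, nI, nC)
    for (cl in classes) tally[[cl]] <- tally[[cl]] + (lab == cl)
    n_eff <- n_eff + (lab != "NONCONVERGED")
  }
  dens <- lapply(tally, function(m) m / pmax(n_eff, 1))
  dens <- lapply(dens, .gauss_smooth2d, bandwidth = bandwidth)
  tot <- Reduce(`+`, dens)
  dens <- lapply(dens, function(m) ifelse(tot > 0, m / tot, 0))
  structure(list(I0_grid = I0_grid, C0_grid = C0_grid, density = dens,
                 classes = classes, n_replicates = n_replicates,
                 jitter_frac = jitter_frac, bandwidth = bandwidth,
                 seed = seed),
            class = "density_map")
}

# classify a vector of (I0, C0) points; returns character labels
.basin_scan_points <- function(I0, C0, other_x0 = default_initial_state(),
                               p = modify_parameters(default_parameters(),
                                                     d_v1 = 100),
                               alpha_level = 0.01,
                               cfg = sim_config(t_span = c(0, 400),
                                                dense_grid = 1),
                               thresholds = NULL, conv_tol = 1e-6) {
  if (is.null(thresholds)) thresholds <- calibrate_thresholds(p, alpha_level)
  vapply(seq_along(I0), function(k) {
    x0 <- other_x0
    x0[["I"]] <- I0[k]; x0[["C"]] <- C0[k]
    ss <- steady_state_by_integration(x0, p, alpha_level, cfg,
                                      conv_tol = conv_tol)
    if (!ss$converged) "NONCONVERGED"
    else as.character(classify_outcome(ss$state, thresholds))
  }, character(1))
}

#' Export a basin map as tidy CSV
#'
#' Columns: `I0, C0, label`, then the six final-state components.
#' @param bm A `basin_map`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_basin_map <- function(bm, path) {
  grid <- expand.grid(i = seq_along(bm$I0_grid), j = seq_along(bm$C0_grid))
  df <- data.frame(
    I0 = bm$I0_grid[grid$i], C0 = bm$C0_grid[grid$j],
    label = bm$labels[cbind(grid$i, grid$j)]
  )
  for (k in 1:6) {
    df[[state_names()[k]]] <- bm$final_states[cbind(grid$i, grid$j, k)]
  }
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(thresholds = bm$thresholds, alpha_level = bm$alpha_level,
         n_nonconverged = bm$n_nonconverged,
         warning = if (is.null(bm$warning)) NA else bm$warning),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
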