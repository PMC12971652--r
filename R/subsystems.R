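#' Baseline clamp state for subsystem analysis
#'
#' The long-run state of the full model started from the canonical baseline
#' with no viral input, used as the level at which excluded variables are
#' clamped in subsystem analysis.
#'
#' @param p Parameter vector.
#' @param alpha_level Input level (default 0, the resting condition).
#' @return Named six-component state vector.
#' @export
baseline_clamp_state <- function(p = default_parameters(), alpha_level = 0) {
  ss <- steady_state_by_integration(default_initial_state(), p, alpha_level)
  if (!ss$converged) warning("baseline did not fully converge; using terminal state")
  ss$state
}

# default focal parameter policy: d_v1 when V is active, otherwise the
# self-/primary activation strength of the highest-priority active variable
.default_focal <- function(active) {
  pri <- c(V = "d_v1", I = "a_I1", C = "a_C2", H = "a_H0", S = "a_S0",
           IL6 = "a_IL0")
  pri[[state_names()[which(active)[1]]]]
}

#' Enumerate all variable-subset subsystems
#'
#' Builds the 63 non-empty subsets of the six state variables. Each
#' subsystem keeps its member variables dynamic and clamps the excluded
#' ones at the supplied levels; each is assigned a focal parameter by the
#' policy (default: `d_v1` whenever V is a member, otherwise the
#' self-activation strength of the highest-priority member — I: `a_I1`,
#' C: `a_C2`, H: `a_H0`, S: `a_S0`, IL6: `a_IL0`).
#'
#' @param clamp_source Six-component state supplying clamp values
#'   (default [baseline_clamp_state()] of the canonical parameters).
#' @param focal_policy Function `active_mask -> parameter name`, default as
#'   above.
#' @param focal_grid Focal-parameter grid applied to every spec (default 25
#'   log-spaced values over `[1e-2, 1e2]`).
#' @return List of 63 `subsystem_spec` objects (fields `active`,
#'   `clamp_values`, `focal_param`, `focal_grid`, `mask` as a 6-char 0/1
#'   string in V, I, C, H, S, IL6 order).
#' @export
enumerate_subsystems <- function(clamp_source = NULL,
                                 focal_policy = .default_focal,
                                 focal_grid = 10^seq(-2, 2, length.out = 25)) {
  if (is.null(clamp_source)) clamp_source <- baseline_clamp_state()
  stopifnot(length(clamp_source) == 6, all(clamp_source >= 0))
  specs <- list()
  for (code in 1:63) {
    active <- as.logical(bitwAnd(code, 2^(0:5)))
    names(active) <- state_names()
    specs[[code]] <- structure(
      list(active = active,
           clamp_values = stats::setNames(as.numeric(clamp_source),
                                          state_names()),
           focal_param = focal_policy(active),
           focal_grid = focal_grid,
           mask = paste(as.integer(active), collapse = "")),
      class = "subsystem_spec")
  }
  specs
}

#' Vector field of a subsystem
#'
#' Restriction of the full model field to a subsystem's active variables:
#' inactive variables are replaced by their clamp values wherever they
#' appear, and only the active components' derivatives are evaluated and
#' returned. The all-active spec reproduces the full field exactly.
#'
#' @param spec A `subsystem_spec`.
#' @param p Parameter vector.
#' @param alpha_level Constant input level (enters only if V is active).
#' @return Function mapping a vector over the active variables to their
#'   rates of change.
#' @export
reduced_rhs <- function(spec, p, alpha_level = 0) {
  active <- spec$active
  clamp <- spec$clamp_values
  function(x_active) {
    full <- clamp
    full[active] <- x_active
    unname(rhs(0, full, p, alpha_level))[active]
  }
}

# Jacobian of the reduced field: the active-row/active-column submatrix of
# the full Jacobian at the embedded state (clamped entries are constants).
reduced_jacobian <- function(spec, p, alpha_level = 0) {
  active <- spec$active
  clamp <- spec$clamp_values
  function(x_active) {
    full <- clamp
    full[active] <- x_active
    jacobian(full, p, alpha_level)[active, active, drop = FALSE]
  }
}

#' Test a subsystem for bistability under its focal-parameter sweep
#'
#' Runs the multistart equilibrium census on the reduced system at every
#' value of the subsystem's focal grid and reports whether any value supports at
#' least two stable equilibria. The witness records the first such focal
#' value and the two stable states (embedded back into full coordinates).
#'
#' @param spec A `subsystem_spec`.
#' @param p Base parameter vector.
#' @param alpha_level Constant input level.
#' @param n_starts Multistart count per focal value (default 100; reduced
#'   systems have at most six dimensions).
#' @param seed RNG seed for the census starts.
#' @param margin Stability margin on eigenvalue real parts.
#' @return A `subsystem_result`: `spec`, `bistable`, `max_stable_count`,
#'   `witness` (`NULL` unless bistable).
#' @export
detect_bistability <- function(spec, p = default_parameters(),
                               alpha_level = 0.01, n_starts = 100, seed = 1,
                               margin = 1e-7) {
  active <- spec$active
  nd <- sum(active)
  box <- matrix(rep(c(1e-4, 10), nd), nrow = 2)
  extra <- rbind(unname(default_initial_state())[active], rep(0, nd))
  max_stable <- 0L
  witness <- NULL
  for (v in spec$focal_grid) {
    pv <- modify_parameters(p, stats::setNames(v, spec$focal_param))
    fF <- reduced_rhs(spec, pv, alpha_level)
    fJ <- reduced_jacobian(spec, pv, alpha_level)
    fn <- function(x) list(F = fF(x), J = fJ(x))
    roots <- census_roots(fn, box, n_starts, seed, extra_starts = extra)
    if (!length(roots)) next
    stable <- Filter(function(x) {
      all(Re(eigen(fJ(x), only.values = TRUE)$values) < -margin)
    }, roots)
    if (length(stable) > max_stable) {
      max_stable <- length(stable)
      if (length(stable) >= 2 && is.null(witness)) {
        embed <- function(xa) {
          full <- spec$clamp_values; full[active] <- xa; full
        }
        witness <- list(focal_value = v,
                        states = lapply(stable[1:2], embed))
      }
    }
  }
  structure(list(spec = spec, bistable = max_stable >= 2,
                 max_stable_count = max_stable, witness = witness),
            class = "subsystem_result")
}

#' Bistability frequency by variable membership
#'
#' Cross-tabulates the 63 subsystem verdicts by variable: for each of the
#' six variables, Group 1 is the 32 subsystems containing it and Group 2
#' the 31 excluding it, each split into bistable / not bistable.
#'
#' @param results List of exactly 63 `subsystem_result`s, one per spec
#'   (duplicate or missing masks are an error).
#' @return data.frame with one row per variable: `variable`,
#'   `group1_total`, `group1_bistable`, `group2_total`, `group2_bistable`.
#' @export
membership_frequency <- function(results) {
  masks <- vapply(results, function(r) r$spec$mask, character(1))
  if (length(masks) != 63 || anyDuplicated(masks) ||
      "000000" %in% masks) {
    stop("membership_frequency: need exactly the 63 distinct non-empty masks")
  }
  bist <- vapply(results, `[[`, logical(1), "bistable")
  act <- t(vapply(results, function(r) r$spec$active, logical(6)))
  df <- do.call(rbind, lapply(seq_len(6), function(j) {
    data.frame(variable = state_names()[j],
               group1_total = sum(act[, j]),
               group1_bistable = sum(bist[act[, j]]),
               group2_total = sum(!act[, j]),
               group2_bistable = sum(bist[!act[, j]]))
  }))
  df
}

#' Export subsystem results as CSV
#'
#' One row per subsystem: the 0/1 membership mask (V, I, C, H, S, IL6
#' order), focal parameter, bistability flag and maximum stable count.
#'
#' @param results List of `subsystem_result`s.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_subsystem_results <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(mask = r$spec$mask, focal_param = r$spec$focal_param,
               bistable = r$bistable,
               max_stable_count = r$max_stable_count)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
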