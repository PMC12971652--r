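# distance used for branch linking: Euclidean, scaled by branch magnitude
.link_dist <- function(a, b) sqrt(sum((a - b)^2)) / (1 + sqrt(sum(a^2)))

#' Sweep one parameter and trace equilibrium branches
#'
#' Runs the multistart equilibrium census at every grid value and links
#' roots across adjacent values by nearest-neighbour matching in state
#' space (grid census + linking rather than pseudo-arclength continuation:
#' the outputs of interest are branch diagrams and counts). Unmatched roots
#' open new branches; branches whose root disappears are closed and emit a
#' `fold` event bracketed by the adjacent grid values. A stability flip
#' along a branch emits a `fold` event when the leading eigenvalue is real
#' at the flip and a `hopf` event when it belongs to a complex pair.
#'
#' @param param_name Name of the swept parameter (a [default_parameters()] field).
#' @param values Monotone numeric grid of parameter values.
#' @param p Base parameter vector (the swept entry is overwritten).
#' @param alpha_level Constant input level.
#' @param n_starts,seed,start_box Census configuration per [find_equilibria()].
#' @param link_tol Maximum scaled state distance for linking roots across
#'   adjacent grid values (continuation step bound), default 0.5.
#' @return List of `branch` objects: each has `param_name`, `points`
#'   (data.frame: value, V..IL6, stability, leading_real, im_leading) and
#'   `events` (data.frame: type, lower, upper).
#' @export
sweep_parameter <- function(param_name, values, p, alpha_level = 0.01,
                            n_starts = 200, seed = 1, start_box = NULL,
                            link_tol = 0.5) {
  if (!param_name %in% names(p)) stop("unknown parameter: ", param_name)
  stopifnot(length(values) >= 1, !is.unsorted(values) || !is.unsorted(rev(values)))

  censuses <- lapply(values, function(v) {
    find_equilibria(modify_parameters(p, stats::setNames(v, param_name)),
                    alpha_level, n_starts = n_starts, seed = seed,
                    start_box = start_box)
  })

  new_point <- function(v, r) {
    lead <- r$eigenvalues[which.max(Re(r$eigenvalues))]
    data.frame(value = v, t(r$state), stability = r$stability,
               leading_real = r$leading_real, im_leading = abs(Im(lead)))
  }
  branches <- list()   # each: list(points=df, last_state, open)
  for (gi in seq_along(values)) {
    recs <- censuses[[gi]]$records
    open_idx <- which(vapply(branches, `[[`, logical(1), "open"))
    used_rec <- rep(FALSE, length(recs))
    # greedy nearest-neighbour matching
    if (length(open_idx) && length(recs)) {
      dm <- outer(open_idx, seq_along(recs),
                  Vectorize(function(bi, ri) {
                    .link_dist(branches[[bi]]$last_state, recs[[ri]]$state)
                  }))
      while (TRUE) {
        m <- which(dm == min(dm), arr.ind = TRUE)[1, , drop = TRUE]
        if (!is.finite(dm[m[1], m[2]]) || dm[m[1], m[2]] > link_tol) break
        bi <- open_idx[m[1]]; ri <- m[2]
        r <- recs[[ri]]
        br <- branches[[bi]]
        prev <- br$points[nrow(br$points), ]
        pt <- new_point(values[gi], r)
        # stability flip => bracketed event
        if (prev$stability != pt$stability) {
          complex_pair <- max(prev$im_leading, pt$im_leading) > 1e-7
          br$events <- rbind(br$events, data.frame(
            type = if (complex_pair) "hopf" else "fold",
            lower = min(prev$value, pt$value),
            upper = max(prev$value, pt$value)))
        }
        br$points <- rbind(br$points, pt)
        br$last_state <- r$state
        branches[[bi]] <- br
        dm[m[1], ] <- Inf; dm[, m[2]] <- Inf
        used_rec[ri] <- TRUE
      }
    }
    # close unmatched branches (root disappeared): fold candidate
    for (bi in open_idx) {
      last_v <- branches[[bi]]$points$value[nrow(branches[[bi]]$points)]
      if (last_v != values[gi]) {
        branches[[bi]]$open <- FALSE
        branches[[bi]]$events <- rbind(branches[[bi]]$events, data.frame(
          type = "fold", lower = min(last_v, values[gi]),
          upper = max(last_v, values[gi])))
      }
    }
    # unmatched roots open new branches
    for (ri in which(!used_rec)) {
      branches[[length(branches) + 1]] <- list(
        points = new_point(values[gi], recs[[ri]]),
        events = data.frame(type = character(0), lower = numeric(0),
                            upper = numeric(0)),
        last_state = recs[[ri]]$state, open = TRUE)
    }
  }
  lapply(branches, function(b) {
    structure(list(param_name = param_name, points = b$points,
                   events = b$events), class = "branch")
  })
}

# Follow the equilibrium of `branch` to parameter value v by Newton from the
# nearest recorded branch state; NULL when the root is lost.
.follow_root <- function(branch, v, p, alpha_level) {
  pts <- branch$points
  i <- which.min(abs(pts$value - v))
  x0 <- as.numeric(pts[i, state_names()])
  pv <- modify_parameters(p, stats::setNames(v, branch$param_name))
  fn <- function(x) list(F = unname(rhs(0, x, pv, alpha_level)),
                         J = jacobian(x, pv, alpha_level))
  sol <- newton_root(x0, fn, tol = 1e-11)
  if (!sol$converged || any(sol$x < -1e-9)) return(NULL)
  list(state = pmax(sol$x, 0), params = pv)
}

#' Refine a fold/exchange event by bisection
#'
#' Bisects the event's parameter bracket, following the branch root by
#' Newton continuation and tracking the sign of the leading real eigenvalue.
#' If the root is lost during bisection (the branch terminates inside the
#' bracket) the last valid bracket is reported with `root_lost = TRUE`.
#'
#' @param branch A `branch` from [sweep_parameter()].
#' @param event One row of `branch$events` (type `fold` or `exchange`).
#' @param p,alpha_level Model context of the sweep.
#' @param tol Parameter tolerance of the returned crossing.
#' @return List `(value, bracket, root_lost)`.
#' @export
refine_fold <- function(branch, event, p, alpha_level = 0.01, tol = 1e-6) {
  stopifnot(event$type %in% c("fold", "exchange"))
  lo <- event$lower; hi <- event$upper
  sgn_at <- function(v) {
    r <- .follow_root(branch, v, p, alpha_level)
    if (is.null(r)) return(NA_real_)
    sign(max(Re(eigen(jacobian(r$state, r$params, alpha_level),
                      only.values = TRUE)$values)))
  }
  s_lo <- sgn_at(lo); s_hi <- sgn_at(hi)
  root_lost <- is.na(s_lo) || is.na(s_hi)
  if (!root_lost && s_lo == s_hi) root_lost <- TRUE  # flip not visible on this root
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    s_mid <- sgn_at(mid)
    if (is.na(s_mid)) { root_lost <- TRUE; break }
    if (root_lost) {  # disappearance fold: shrink toward the side that exists
      if (is.na(s_lo)) lo <- mid else hi <- mid
      next
    }
    if (s_mid == s_lo) lo <- mid else hi <- mid
  }
  list(value = (lo + hi) / 2, bracket = c(lo, hi), root_lost = root_lost)
}

# sustained-oscillation test on a trajectory component: >= 3 post-transient
# peaks whose heights have coefficient of variation < cv_tol
.sustained_oscillation <- function(times, x, cv_tol = 0.05) {
  keep <- times >= (times[1] + (times[length(times)] - times[1]) / 2)
  x <- x[keep]
  n <- length(x)
  if (n < 5) return(list(oscillating = FALSE, amplitude = 0))
  pk <- which(diff(sign(diff(x))) == -2) + 1
  if (length(pk) < 3) return(list(oscillating = FALSE, amplitude = 0))
  h <- x[pk]
  amp <- (max(x) - min(x)) / 2
  if (amp < 1e-8) return(list(oscillating = FALSE, amplitude = amp))
  cv <- stats::sd(h) / max(mean(h), 1e-12)
  list(oscillating = cv < cv_tol, amplitude = amp)
}

#' Detect and verify Hopf candidates along a branch
#'
#' Flags sign changes of the real part of the leading complex-conjugate
#' eigenvalue pair (nonzero imaginary part) between consecutive branch
#' points. Each candidate is verified by simulating just past the crossing,
#' started near the equilibrium, and testing for sustained oscillation
#' (at least three post-transient peaks with coefficient of variation of
#' peak heights below 0.05); the observed amplitude is recorded so
#' supercritical (amplitude growing from ~0) versus subcritical (jump)
#' signatures can be judged by the caller, not assumed.
#'
#' @param branch A `branch`.
#' @param p,alpha_level Model context of the sweep.
#' @param verify Run the simulation check (default TRUE).
#' @param t_verify Horizon of the verification run, days.
#' @return data.frame of candidates: `lower`, `upper`, `verified`, `amplitude`.
#' @export
detect_hopf <- function(branch, p, alpha_level = 0.01, verify = TRUE,
                        t_verify = 400) {
  pts <- branch$points
  out <- data.frame(lower = numeric(0), upper = numeric(0),
                    verified = logical(0), amplitude = numeric(0))
  if (nrow(pts) < 2) return(out)
  # real part of the leading member of a complex pair, per point
  cplx_re <- function(i) {
    pv <- modify_parameters(p, stats::setNames(pts$value[i], branch$param_name))
    ev <- eigen(jacobian(as.numeric(pts[i, state_names()]), pv, alpha_level),
                only.values = TRUE)$values
    ev <- ev[abs(Im(ev)) > 1e-7]
    if (!length(ev)) return(NA_real_)
    max(Re(ev))
  }
  res <- vapply(seq_len(nrow(pts)), cplx_re, numeric(1))
  for (i in seq_len(nrow(pts) - 1)) {
    if (is.na(res[i]) || is.na(res[i + 1])) next
    if (sign(res[i]) * sign(res[i + 1]) < 0) {
      # simulate just past the crossing (the unstable-focus side)
      past <- if (res[i + 1] > 0) i + 1 else i
      verified <- FALSE; amp <- NA_real_
      if (verify) {
        pv <- modify_parameters(
          p, stats::setNames(pts$value[past], branch$param_name))
        x0 <- pmax(as.numeric(pts[past, state_names()]) * 1.01 + 1e-4, 0)
        traj <- simulate_model(x0, pv, input_schedule(alpha_level, Inf),
                               sim_config(t_span = c(0, t_verify),
                                          dense_grid = 10))
        osc <- .sustained_oscillation(traj$times, traj$states[, "V"])
        if (!osc$oscillating) {
          osc <- .sustained_oscillation(traj$times, traj$states[, "C"])
        }
        verified <- osc$oscillating; amp <- osc$amplitude
      }
      out <- rbind(out, data.frame(
        lower = min(pts$value[i], pts$value[i + 1]),
        upper = max(pts$value[i], pts$value[i + 1]),
        verified = verified, amplitude = amp))
    }
  }
  out
}

#' Two-parameter steady-state count scan
#'
#' Runs the full multistart census at every node of a log-spaced grid over
#' two parameters and records both the total number of equilibria and the
#' number of stable ones (the two counts answer different questions about
#' the steady-state landscape, so both are first-class outputs).
#'
#' @param p1_name,p2_name Parameter names.
#' @param p1_grid,p2_grid Positive (log-spaced) value grids.
#' @param p Base parameter vector.
#' @param alpha_level Constant input level.
#' @param n_starts,seed,start_box Census configuration.
#' @param progress Print a progress line per grid row.
#' @return A `count_map`: list with the grids, `counts` and `stable_counts`
#'   matrices (rows = `p1_grid`, cols = `p2_grid`) and census metadata.
#' @export
two_parameter_count_scan <- function(p1_name, p1_grid, p2_name, p2_grid, p,
                                     alpha_level = 0.01, n_starts = 200,
                                     seed = 1, start_box = NULL,
                                     progress = FALSE) {
  stopifnot(all(p1_grid > 0), all(p2_grid > 0))
  counts <- matrix(NA_integer_, length(p1_grid), length(p2_grid))
  stable <- counts
  for (i in seq_along(p1_grid)) {
    for (j in seq_along(p2_grid)) {
      pv <- modify_parameters(p, stats::setNames(p1_grid[i], p1_name))
      pv <- modify_parameters(pv, stats::setNames(p2_grid[j], p2_name))
      es <- find_equilibria(pv, alpha_level, n_starts = n_starts,
                            seed = seed, start_box = start_box)
      counts[i, j] <- length(es$records)
      stable[i, j] <- count_stable(es)
    }
    if (progress) {
      message(sprintf("scan row %d/%d (%s = %.3g) done",
                      i, length(p1_grid), p1_name, p1_grid[i]))
    }
  }
  structure(list(p1_name = p1_name, p2_name = p2_name,
                 p1_grid = p1_grid, p2_grid = p2_grid,
                 counts = counts, stable_counts = stable,
                 alpha_level = alpha_level,
                 census_meta = list(n_starts = n_starts, seed = seed)),
            class = "count_map")
}

#' Export branches or a count map as tidy CSV
#'
#' @param branches List of `branch` objects from [sweep_parameter()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_branches <- function(branches, path) {
  rows <- do.call(rbind, lapply(seq_along(branches), function(i) {
    cbind(branch = i, param = branches[[i]]$param_name, branches[[i]]$points)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_branches
#' @param cm A `count_map`.
#' @export
write_count_map <- function(cm, path) {
  grid <- expand.grid(p1 = cm$p1_grid, p2 = cm$p2_grid)
  df <- data.frame(grid$p1, grid$p2,
                   count = as.vector(cm$counts),
                   stable_count = as.vector(cm$stable_counts))
  names(df)[1:2] <- c(cm$p1_name, cm$p2_name)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    c(cm$census_meta, list(alpha_level = cm$alpha_level)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
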