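# Run expr with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Damped Newton with backtracking line search and projection onto the
# nonnegative orthant. `fn(x)` must return list(F = residual vector,
# J = Jacobian matrix). Returns list(x, fval, converged).
newton_root <- function(x0, fn, tol = 1e-11, max_iter = 60) {
  x <- pmax(x0, 0)
  ev <- tryCatch(fn(x), error = function(e) NULL)
  if (is.null(ev) || any(!is.finite(ev$F))) {
    return(list(x = x, fval = Inf, converged = FALSE))
  }
  fnorm <- max(abs(ev$F))
  for (it in seq_len(max_iter)) {
    if (fnorm < tol) break
    dx <- tryCatch(solve(ev$J, -ev$F), error = function(e) NULL)
    if (is.null(dx) || any(!is.finite(dx))) {
      return(list(x = x, fval = fnorm, converged = FALSE))
    }
    s <- 1
    improved <- FALSE
    for (ls in 1:12) {
      x_new <- pmax(x + s * dx, 0)
      ev_new <- tryCatch(fn(x_new), error = function(e) NULL)
      if (!is.null(ev_new) && all(is.finite(ev_new$F))) {
        fnew <- max(abs(ev_new$F))
        if (fnew < fnorm) {
          x <- x_new; ev <- ev_new; fnorm <- fnew; improved <- TRUE
          break
        }
      }
      s <- s / 2
    }
    if (!improved) break
  }
  list(x = x, fval = fnorm, converged = fnorm < tol)
}

# Dimension-agnostic multistart root census: damped Newton from log-uniform
# starts in `box` (2 x d matrix of positive ranges) plus `extra_starts`
# (matrix, one start per row). Converged roots with components below -1e-9
# are discarded, |x| < 1e-12 clamped to 0, and the set deduplicated at
# relative tolerance 1e-6 (absolute floor 1e-9). Returns a list of root
# vectors. RNG state is restored.
census_roots <- function(fn, box, n_starts, seed, extra_starts = NULL,
                         resid_tol = 1e-10) {
  nd <- ncol(box)
  lo <- log10(box[1, ]); hi <- log10(box[2, ])
  starts <- with_seed(seed, {
    m <- matrix(stats::runif(n_starts * nd), ncol = nd)
    10^sweep(sweep(m, 2, hi - lo, `*`), 2, lo, `+`)
  })
  if (!is.null(extra_starts)) starts <- rbind(extra_starts, starts)
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    sol <- newton_root(starts[i, ], fn, tol = resid_tol)
    if (!sol$converged) next
    x <- sol$x
    if (any(x < -1e-9)) next
    x[abs(x) < 1e-12] <- 0
    dup <- FALSE
    for (r in roots) {
      if (.states_equal(r, x)) { dup <- TRUE; break }
    }
    if (!dup) roots[[length(roots) + 1]] <- x
  }
  roots
}

# componentwise duplicate test at relative tolerance with absolute floor
.states_equal <- function(a, b, rel_tol = 1e-6, abs_floor = 1e-9) {
  all(abs(a - b) <= pmax(rel_tol * pmax(abs(a), abs(b)), abs_floor))
}

#' Classify the stability of an equilibrium
#'
#' Evaluates the eigenvalues of the analytic Jacobian at a supplied
#' equilibrium and applies the margin rule: stable when all real parts are
#' below `-margin`, unstable when any exceeds `+margin`, marginal otherwise.
#' A near-Hopf configuration (a complex pair with `|Re| < margin` and
#' `|Im| > margin`) is flagged.
#'
#' @param state Equilibrium state (residual of [rhs()] must be below
#'   `resid_tol`, otherwise an error naming the residual is thrown).
#' @param p Parameter vector.
#' @param alpha_level Constant input level.
#' @param margin Stability margin on real parts, default 1e-7.
#' @param resid_tol Maximum accepted residual, default 1e-8.
#' @return An `equilibrium_record`: list with `state`, `residual`,
#'   `eigenvalues`, `stability`, `leading_real`, `near_hopf`.
#' @export
classify_stability <- function(state, p, alpha_level = 0, margin = 1e-7,
                               resid_tol = 1e-8) {
  resid <- max(abs(rhs(0, state, p, alpha_level)))
  if (resid > resid_tol) {
    stop(sprintf("classify_stability: not an equilibrium (residual %.3e > %.1e)",
                 resid, resid_tol))
  }
  ev <- eigen(jacobian(state, p, alpha_level), only.values = TRUE)$values
  re <- Re(ev)
  stability <- if (all(re < -margin)) "stable"
               else if (any(re > margin)) "unstable"
               else "marginal"
  near_hopf <- any(abs(re) < margin & abs(Im(ev)) > margin)
  structure(list(state = stats::setNames(as.numeric(state), state_names()),
                 residual = resid, eigenvalues = ev, stability = stability,
                 leading_real = max(re), near_hopf = near_hopf),
            class = "equilibrium_record")
}

#' Multistart Newton census of equilibria
#'
#' Finds the equilibria of the model at a fixed parameter set and constant
#' input level by damped Newton iteration (backtracking line search,
#' projection onto the nonnegative orthant) from `n_starts` log-uniform
#' random starts plus the origin and the canonical baseline state. Converged
#' roots (residual < `resid_tol`) with any component below -1e-9 are
#' discarded, components of magnitude below 1e-12 are clamped to zero, and
#' the set is deduplicated componentwise at relative tolerance 1e-6
#' (absolute floor 1e-9). Each survivor is stability-classified.
#'
#' @param p Parameter vector.
#' @param alpha_level Constant input level (>= 0).
#' @param n_starts Number of random starts (>= 1).
#' @param start_box 2 x 6 matrix of per-variable (lower, upper) sampling
#'   ranges; starts are log-uniform within. Default `[1e-4, 10]` for every
#'   variable, covering the canonical scales and the near-zero branch.
#' @param seed Integer seed for the start sample (RNG state is restored).
#' @param resid_tol Residual acceptance threshold, default 1e-10.
#' @param margin Stability margin passed to [classify_stability()].
#' @return An `equilibrium_set`: list with `records` (each an
#'   `equilibrium_record`), `alpha_level`, `n_starts`, `seed`, `params`.
#' @export
find_equilibria <- function(p, alpha_level = 0, n_starts = 200,
                            start_box = NULL, seed = 1,
                            resid_tol = 1e-10, margin = 1e-7) {
  stopifnot(n_starts >= 1)
  if (is.null(start_box)) {
    start_box <- matrix(rep(c(1e-4, 10), 6), nrow = 2)
  }
  stopifnot(nrow(start_box) == 2, all(start_box > 0))
  fn <- function(x) list(F = unname(rhs(0, x, p, alpha_level)),
                         J = jacobian(x, p, alpha_level))
  extra <- rbind(unname(default_initial_state()), rep(0, ncol(start_box)))
  roots <- census_roots(fn, start_box, n_starts, seed,
                        extra_starts = extra, resid_tol = resid_tol)
  records <- lapply(roots, function(x) {
    classify_stability(x, p, alpha_level, margin = margin,
                       resid_tol = max(resid_tol, 1e-9) * 10)
  })
  structure(list(records = records, alpha_level = alpha_level,
                 n_starts = n_starts, seed = seed, params = p),
            class = "equilibrium_set")
}

#' Number of stable equilibria in a census
#' @param set An `equilibrium_set`.
#' @return Integer count of records classified stable.
#' @export
count_stable <- function(set) {
  sum(vapply(set$records, function(r) r$stability == "stable", logical(1)))
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat("<equilibrium_set> ", length(x$records), " equilibria (",
      count_stable(x), " stable) at alpha = ", x$alpha_level,
      ", n_starts = ", x$n_starts, ", seed = ", x$seed, "\n", sep = "")
  for (r in x$records) {
    cat(sprintf("  [%s] leading Re(lambda) = %+.3e  state = (%s)\n",
                r$stability, r$leading_real,
                paste(sprintf("%.4g", r$state), collapse = ", ")))
  }
  invisible(x)
}

#' Export an equilibrium census as CSV (+ JSON sidecar)
#'
#' One row per record: the six state columns, residual, leading real part and
#' stability class; the sidecar records parameters, input level, n_starts and
#' seed so the census is auditable.
#'
#' @param set An `equilibrium_set`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_equilibria <- function(set, path) {
  states <- do.call(rbind, lapply(set$records, function(r) r$state))
  df <- data.frame(
    if (is.null(states)) matrix(numeric(0), 0, 6,
                                dimnames = list(NULL, state_names()))
    else states,
    residual = vapply(set$records, `[[`, numeric(1), "residual"),
    leading_real = vapply(set$records, `[[`, numeric(1), "leading_real"),
    stability = vapply(set$records, `[[`, character(1), "stability"),
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(params = as.list(set$params), alpha_level = set$alpha_level,
         n_starts = set$n_starts, seed = set$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
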