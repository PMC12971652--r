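#' Hill activation function
#'
#' The saturating response \eqn{x^n / (k^n + x^n)} used for every
#' cross-module activation, clearance and suppression term of the model.
#' Vectorized over `x`.
#'
#' @param x Nonnegative input level(s).
#' @param k Half-saturation constant (> 0): `hill(k, k, n)` is exactly 1/2.
#' @param n Hill coefficient (> 0), the steepness of the response.
#' @return Value(s) in `[0, 1]`, nondecreasing in `x`.
#' @export
#' @examples
#' hill(0.4, 0.2, 3)   # 0.064 / 0.072
hill <- function(x, k, n) {
  if (any(!is.finite(x)) || any(x < 0)) stop("hill: x must be finite and >= 0")
  if (!is.finite(k) || k <= 0) stop("hill: k must be > 0")
  if (!is.finite(n) || n <= 0) stop("hill: n must be > 0")
  xn <- x^n
  xn / (k^n + xn)
}

# d/dx of hill(x; k, n): n k^n x^(n-1) / (k^n + x^n)^2.
# Internal; assumes validated inputs and n >= 1 so the limit at x = 0 exists
# (0 for n > 1, 1/k for n = 1).
dhill <- function(x, k, n) {
  kn <- k^n
  if (x == 0) {
    if (n > 1) return(0)
    return(1 / k)  # n == 1
  }
  n * kn * x^(n - 1) / (kn + x^n)^2
}

#' Construct an exogenous viral input schedule
#'
#' The input rate \eqn{\alpha(t)} equals `phi` on `[0, T]`, zero afterwards,
#' except inside optional pulse intervals (re-exposure episodes), where it
#' takes the interval's own level.
#'
#' @param phi Input level (>= 0) on the primary exposure window.
#' @param T_end Cutoff time of the primary window, days (>= 0; use a value
#'   beyond the simulation horizon for persistent exposure).
#' @param extra Optional list of pulses, each `c(start, end, level)`; pulses
#'   must be non-overlapping, lie at or after `T_end`, and have `start < end`.
#' @return An object of class `input_schedule`.
#' @export
#' @examples
#' input_schedule(0.01, 7)
#' input_schedule(0.01, 70, extra = list(c(140, 210, 0.01)))
input_schedule <- function(phi, T_end, extra = NULL) {
  stopifnot(is.finite(phi), phi >= 0, !is.na(T_end), T_end >= 0)
  if (!is.null(extra)) {
    extra <- lapply(extra, function(iv) {
      stopifnot(length(iv) == 3, iv[1] < iv[2], iv[3] >= 0, iv[1] >= T_end)
      as.numeric(iv)
    })
    starts <- vapply(extra, `[`, numeric(1), 1)
    ends <- vapply(extra, `[`, numeric(1), 2)
    o <- order(starts)
    extra <- extra[o]
    if (length(extra) > 1 && any(starts[o][-1] < ends[o][-length(o)])) {
      stop("input_schedule: pulse intervals overlap")
    }
  }
  structure(list(phi = phi, T_end = T_end, extra = extra),
            class = "input_schedule")
}

#' Evaluate the input rate at a time point
#'
#' @param t Time in days (>= 0).
#' @param sched An [input_schedule()].
#' @return The input level \eqn{\alpha(t)}.
#' @export
input_rate <- function(t, sched) {
  if (any(t < 0)) stop("input_rate: t must be >= 0")
  vapply(t, function(ti) {
    if (ti <= sched$T_end) return(sched$phi)
    if (!is.null(sched$extra)) {
      for (iv in sched$extra) {
        if (ti >= iv[1] && ti <= iv[2]) return(iv[3])
      }
    }
    0
  }, numeric(1))
}

# Times at which alpha(t) jumps; integration is restarted at each.
schedule_breaks <- function(sched) {
  br <- sched$T_end
  if (!is.null(sched$extra)) {
    br <- c(br, unlist(lapply(sched$extra, function(iv) iv[1:2])))
  }
  sort(unique(br))
}

#' Right-hand side of the virus-immune network model
#'
#' The six coupled rates of change: viral load with exogenous input,
#' saturating self-replication, three immune clearance routes and natural
#' decay; innate immunity with viral activation, self-amplification,
#' suppression and decay; cellular immunity with dual-condition (innate AND
#' virus) initiation, self-amplification, suppression and decay; humoral
#' immunity activated by the cellular and innate arms; immune suppression
#' with basal generation `delta`, activation by C and I and down-regulation
#' by IL-6; and IL-6 driven by C and V.
#'
#' @param t Time in days (only the input schedule depends on it).
#' @param x Nonnegative state vector `(V, I, C, H, S, IL6)`.
#' @param p Parameter vector (see [default_parameters()]).
#' @param sched An [input_schedule()], or a single nonnegative number taken
#'   as a constant input level.
#' @return Numeric vector of the six derivatives, named as the state.
#' @export
rhs <- function(t, x, p, sched) {
  if (any(!is.finite(x))) stop("rhs: non-finite state")
  alpha <- if (inherits(sched, "input_schedule")) input_rate(t, sched) else sched
  V <- x[[1]]; I <- x[[2]]; C <- x[[3]]; H <- x[[4]]; S <- x[[5]]; IL6 <- x[[6]]
  hl <- function(z, k, n) { zn <- z^n; zn / (k^n + zn) }
  dV <- alpha + p[["a_v0"]] * hl(V, p[["k_v0"]], p[["n_v0"]]) -
    (p[["d_v1"]] * hl(C, p[["k_v1"]], p[["n_v1"]]) +
     p[["d_v2"]] * hl(I, p[["k_v2"]], p[["n_v2"]]) +
     p[["d_v3"]] * hl(H, p[["k_v3"]], p[["n_v3"]])) * V -
    p[["d_v4"]] * V
  dI <- p[["a_I0"]] * hl(V, p[["k_I0"]], p[["n_I0"]]) +
    p[["a_I1"]] * hl(I, p[["k_I1"]], p[["n_I1"]]) -
    p[["d_I2"]] * hl(S, p[["k_I2"]], p[["n_I2"]]) * I -
    p[["d_I3"]] * I
  dC <- p[["a_C0"]] * hl(I, p[["k_C0"]], p[["n_C0"]]) * hl(V, p[["k_C1"]], p[["n_C1"]]) +
    p[["a_C2"]] * hl(C, p[["k_C2"]], p[["n_C2"]]) -
    p[["d_C3"]] * hl(S, p[["k_C3"]], p[["n_C3"]]) * C -
    p[["d_C4"]] * C
  dH <- p[["a_H0"]] * hl(C, p[["k_H0"]], p[["n_H0"]]) +
    p[["a_H1"]] * hl(I, p[["k_H1"]], p[["n_H1"]]) -
    p[["d_H2"]] * hl(S, p[["k_H2"]], p[["n_H2"]]) * H -
    p[["d_H3"]] * H
  dS <- p[["delta"]] +
    p[["a_S0"]] * hl(C, p[["k_S0"]], p[["n_S0"]]) +
    p[["a_S1"]] * hl(I, p[["k_S1"]], p[["n_S1"]]) -
    p[["d_S2"]] * hl(IL6, p[["k_S2"]], p[["n_S2"]]) * S -
    p[["d_S3"]] * S
  dIL <- p[["a_IL0"]] * hl(C, p[["k_IL0"]], p[["n_IL0"]]) +
    p[["a_IL1"]] * hl(V, p[["k_IL1"]], p[["n_IL1"]]) -
    p[["d_IL2"]] * IL6
  c(V = dV, I = dI, C = dC, H = dH, S = dS, IL6 = dIL)
}

#' Analytic Jacobian of the autonomous vector field
#'
#' Partial derivatives of [rhs()] with the exogenous input held at a constant
#' level (the input is piecewise constant, so on each piece the system is
#' autonomous and this is the Jacobian the stability analysis needs).
#'
#' @param x Nonnegative state vector.
#' @param p Parameter vector; all Hill coefficients must be >= 1 so the
#'   derivative of the Hill terms is defined at the orthant boundary.
#' @param alpha_level Constant input level (enters no derivative; accepted so
#'   call sites document the regime under analysis).
#' @return 6 x 6 numeric matrix, rows = equations, columns = state variables.
#' @export
jacobian <- function(x, p, alpha_level = 0) {
  if (any(!is.finite(x)) || any(x < 0)) stop("jacobian: state must be finite and >= 0")
  nn <- names(p)[startsWith(names(p), "n_")]
  if (any(p[nn] < 1)) stop("jacobian: Hill coefficients < 1 are not supported")
  V <- x[[1]]; I <- x[[2]]; C <- x[[3]]; H <- x[[4]]; S <- x[[5]]; IL6 <- x[[6]]
  hl <- function(z, k, n) { zn <- z^n; zn / (k^n + zn) }
  J <- matrix(0, 6, 6, dimnames = list(state_names(), state_names()))
  # dV/dt
  J[1, 1] <- p[["a_v0"]] * dhill(V, p[["k_v0"]], p[["n_v0"]]) -
    (p[["d_v1"]] * hl(C, p[["k_v1"]], p[["n_v1"]]) +
     p[["d_v2"]] * hl(I, p[["k_v2"]], p[["n_v2"]]) +
     p[["d_v3"]] * hl(H, p[["k_v3"]], p[["n_v3"]])) - p[["d_v4"]]
  J[1, 2] <- -p[["d_v2"]] * dhill(I, p[["k_v2"]], p[["n_v2"]]) * V
  J[1, 3] <- -p[["d_v1"]] * dhill(C, p[["k_v1"]], p[["n_v1"]]) * V
  J[1, 4] <- -p[["d_v3"]] * dhill(H, p[["k_v3"]], p[["n_v3"]]) * V
  # dI/dt
  J[2, 1] <- p[["a_I0"]] * dhill(V, p[["k_I0"]], p[["n_I0"]])
  J[2, 2] <- p[["a_I1"]] * dhill(I, p[["k_I1"]], p[["n_I1"]]) -
    p[["d_I2"]] * hl(S, p[["k_I2"]], p[["n_I2"]]) - p[["d_I3"]]
  J[2, 5] <- -p[["d_I2"]] * dhill(S, p[["k_I2"]], p[["n_I2"]]) * I
  # dC/dt
  J[3, 1] <- p[["a_C0"]] * hl(I, p[["k_C0"]], p[["n_C0"]]) *
    dhill(V, p[["k_C1"]], p[["n_C1"]])
  J[3, 2] <- p[["a_C0"]] * dhill(I, p[["k_C0"]], p[["n_C0"]]) *
    hl(V, p[["k_C1"]], p[["n_C1"]])
  J[3, 3] <- p[["a_C2"]] * dhill(C, p[["k_C2"]], p[["n_C2"]]) -
    p[["d_C3"]] * hl(S, p[["k_C3"]], p[["n_C3"]]) - p[["d_C4"]]
  J[3, 5] <- -p[["d_C3"]] * dhill(S, p[["k_C3"]], p[["n_C3"]]) * C
  # dH/dt
  J[4, 2] <- p[["a_H1"]] * dhill(I, p[["k_H1"]], p[["n_H1"]])
  J[4, 3] <- p[["a_H0"]] * dhill(C, p[["k_H0"]], p[["n_H0"]])
  J[4, 4] <- -p[["d_H2"]] * hl(S, p[["k_H2"]], p[["n_H2"]]) - p[["d_H3"]]
  J[4, 5] <- -p[["d_H2"]] * dhill(S, p[["k_H2"]], p[["n_H2"]]) * H
  # dS/dt
  J[5, 2] <- p[["a_S1"]] * dhill(I, p[["k_S1"]], p[["n_S1"]])
  J[5, 3] <- p[["a_S0"]] * dhill(C, p[["k_S0"]], p[["n_S0"]])
  J[5, 5] <- -p[["d_S2"]] * hl(IL6, p[["k_S2"]], p[["n_S2"]]) - p[["d_S3"]]
  J[5, 6] <- -p[["d_S2"]] * dhill(IL6, p[["k_S2"]], p[["n_S2"]]) * S
  # dIL6/dt
  J[6, 1] <- p[["a_IL1"]] * dhill(V, p[["k_IL1"]], p[["n_IL1"]])
  J[6, 3] <- p[["a_IL0"]] * dhill(C, p[["k_IL0"]], p[["n_IL0"]])
  J[6, 6] <- -p[["d_IL2"]]
  J
}
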