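# shared fixtures: everything is generated in code at test time

table1 <- default_parameters()
x0_canonical <- default_initial_state()

# central finite-difference Jacobian, the independent oracle for the
# analytic one
fd_jacobian <- function(x, p, alpha, h = 1e-6) {
  stopifnot(all(x > h))  # interior states only: keep the stencil central
  J <- matrix(0, 6, 6)
  for (j in 1:6) {
    e <- rep(0, 6); e[j] <- h
    J[, j] <- (rhs(0, x + e, p, alpha) - rhs(0, x - e, p, alpha)) / (2 * h)
  }
  J
}

# random interior states, reproducible
random_states <- function(n, lo = 0.05, hi = 2, seed = 42) {
  with_seed <- get("with_seed", envir = asNamespace("virimmune"))
  with_seed(seed, matrix(stats::runif(6 * n, lo, hi), ncol = 6))
}

max_state_dist <- function(a, b) max(abs(as.numeric(a) - as.numeric(b)))
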