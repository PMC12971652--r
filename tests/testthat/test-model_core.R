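test_that("hill function: zero, half-saturation, hand-computed value, domain errors", {
  expect_equal(hill(0, 0.2, 3), 0)
  expect_equal(hill(0.4, 0.2, 3), 0.064 / 0.072)
  # half-saturation identity over randomized (k, n)
  set.seed(7)
  for (i in 1:25) {
    k <- runif(1, 1e-3, 10); n <- runif(1, 1, 6)
    expect_equal(hill(k, k, n), 0.5)
  }
  expect_error(hill(-0.1, 0.2, 3), "x must be")
  expect_error(hill(0.1, 0, 3), "k must be")
  expect_error(hill(0.1, 0.2, -1), "n must be")
})

test_that("hill is nondecreasing and bounded in [0, 1] for random parameters", {
  set.seed(11)
  for (i in 1:20) {
    k <- runif(1, 0.01, 5); n <- runif(1, 1, 5)
    x <- sort(runif(50, 0, 10))
    y <- hill(x, k, n)
    expect_true(all(diff(y) >= 0))
    expect_true(all(y >= 0 & y <= 1))
  }
})

test_that("input_rate follows the piecewise schedule including re-exposure pulses", {
  expect_equal(input_rate(3, input_schedule(0.01, 7)), 0.01)
  expect_equal(input_rate(7.5, input_schedule(0.01, 7)), 0)
  sched <- input_schedule(0.01, 70, extra = list(c(140, 210, 0.01)))
  expect_equal(input_rate(150, sched), 0.01)
  expect_equal(input_rate(100, sched), 0)
  expect_equal(input_rate(250, sched), 0)
  expect_error(input_rate(-1, sched), "t must be")
  expect_error(input_schedule(0.01, 70, extra = list(c(210, 140, 0.01))))
  # overlapping pulses rejected
  expect_error(input_schedule(0.01, 7,
                              extra = list(c(10, 20, 0.1), c(15, 25, 0.1))),
               "overlap")
})

test_that("rhs at the origin: only basal immune suppression is generated", {
  r0 <- rhs(0, rep(0, 6), table1, 0)
  expect_equal(unname(r0), c(0, 0, 0, 0, 2e-4, 0))
  r1 <- rhs(0, rep(0, 6), table1, input_schedule(0.02, 7))
  expect_equal(unname(r1), c(0.02, 0, 0, 0, 2e-4, 0))
})

test_that("rhs at the canonical state matches an independent term-by-term evaluation", {
  # independent oracle: each Eq. term rebuilt from scratch with plain arithmetic
  h <- function(x, k, n) x^n / (k^n + x^n)
  x <- c(V = 0, I = 0.3, C = 1.2, H = 0.4, S = 0.25, IL6 = 0.005)
  p <- table1
  expected <- c(
    0 + p[["a_v0"]] * h(0, 0.2, 3) - 0,
    p[["a_I0"]] * h(0, 0.025, 3) + p[["a_I1"]] * h(0.3, 0.1, 3) -
      p[["d_I2"]] * h(0.25, 3, 3) * 0.3 - p[["d_I3"]] * 0.3,
    p[["a_C0"]] * h(0.3, 0.05, 3) * h(0, 0.05, 3) +
      p[["a_C2"]] * h(1.2, 0.4, 3) -
      p[["d_C3"]] * h(0.25, 3, 3) * 1.2 - p[["d_C4"]] * 1.2,
    p[["a_H0"]] * h(1.2, 0.05, 3) + p[["a_H1"]] * h(0.3, 0.05, 3) -
      p[["d_H2"]] * h(0.25, 0.4, 3) * 0.4 - p[["d_H3"]] * 0.4,
    p[["delta"]] + p[["a_S0"]] * h(1.2, 0.08, 3) + p[["a_S1"]] * h(0.3, 0.08, 3) -
      p[["d_S2"]] * h(0.005, 0.1, 3) * 0.25 - p[["d_S3"]] * 0.25,
    p[["a_IL0"]] * h(1.2, 0.5, 3) + p[["a_IL1"]] * h(0, 0.025, 3) -
      p[["d_IL2"]] * 0.005
  )
  expect_equal(unname(rhs(0, x, p, 0)), expected, tolerance = 1e-12)
  expect_error(rhs(0, c(NA, 0, 0, 0, 0, 0), p, 0), "non-finite")
})

test_that("analytic Jacobian agrees with central finite differences on 100 random states", {
  states <- random_states(100)
  for (i in seq_len(nrow(states))) {
    x <- states[i, ]
    J <- jacobian(x, table1, 0.01)
    Jfd <- fd_jacobian(x, table1, 0.01)
    expect_lt(max(abs(J - Jfd)) / max(abs(Jfd)), 1e-6)
  }
})

test_that("Jacobian structural entries: absent couplings are zero, IL-6 self-decay is -d_IL2", {
  states <- random_states(10, seed = 5)
  for (i in seq_len(nrow(states))) {
    J <- jacobian(states[i, ], table1, 0)
    expect_identical(J["S", "H"], 0)     # H absent from the S equation
    expect_identical(J["IL6", "IL6"], -3)
    expect_identical(J["V", "IL6"], 0)
    expect_identical(J["IL6", "I"], 0)
  }
  p_bad <- table1; p_bad[["n_v0"]] <- 0.5
  expect_error(jacobian(rep(0.1, 6), p_bad), "Hill coefficients")
})

test_that("vector field never points out of the nonnegative orthant", {
  set.seed(23)
  for (i in 1:50) {
    x <- runif(6, 0, 3)
    zero_idx <- sample(1:6, sample(1:3, 1))
    x[zero_idx] <- 0
    r <- rhs(0, x, table1, runif(1, 0, 0.02))
    expect_true(all(r[zero_idx] >= 0))
  }
})

test_that("rhs is locally Lipschitz: difference quotients stay bounded on a compact box", {
  set.seed(31)
  q <- replicate(200, {
    a <- runif(6, 0, 4); b <- a + runif(6, 1e-4, 1e-2)
    max(abs(rhs(0, b, table1, 0.01) - rhs(0, a, table1, 0.01))) /
      max(abs(b - a))
  })
  expect_true(all(is.finite(q)))
  expect_lt(max(q), 1e3)
})

test_that("validate_params reports named violations and accepts the canonical set", {
  expect_length(validate_params(table1), 0)
  p <- table1; p[["k_v0"]] <- 0
  expect_match(validate_params(p), "k_v0", all = FALSE)
  p <- table1; p[["n_v1"]] <- -1
  expect_match(validate_params(p), "n_v1", all = FALSE)
  p <- table1; p[["d_v4"]] <- 0
  expect_match(validate_params(p), "d_v4", all = FALSE)
  p <- table1[-3]
  expect_match(validate_params(p), "missing", all = FALSE)
})

test_that("parameter files override Table-1 defaults and reject unknown keys", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(d_v1 = 100, a_v0 = 1), f, auto_unbox = TRUE)
  p <- read_parameter_file(f)
  expect_equal(p[["d_v1"]], 100)
  expect_equal(p[["a_v0"]], 1)
  expect_equal(p[["k_v0"]], 0.2)  # untouched default
  jsonlite::write_json(list(not_a_param = 1), f, auto_unbox = TRUE)
  expect_error(read_parameter_file(f), "unknown parameter key")
  jsonlite::write_json(list(k_v0 = -1), f, auto_unbox = TRUE)
  expect_error(read_parameter_file(f), "invalid")
})
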