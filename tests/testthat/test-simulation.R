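test_that("a stable equilibrium is a fixed point of the integrator", {
  es <- find_equilibria(table1, 0, n_starts = 120, seed = 1)
  stable <- Filter(function(r) r$stability == "stable", es$records)
  expect_gt(length(stable), 0)
  x_star <- stable[[1]]$state
  traj <- simulate_model(x_star, table1, input_schedule(0, 1e6),
                         sim_config(t_span = c(0, 100), dense_grid = 1))
  expect_lt(max(abs(sweep(traj$states, 2, x_star))), 1e-6)
})

test_that("finite 7-day exposure: V rises during input and decays toward zero after", {
  sc <- canonical_scenarios()$finite_7d
  traj <- simulate_model(sc$x0, sc$params, sc$schedule, sc$cfg)
  expect_equal(traj$states[1, ], unname(sc$x0), ignore_attr = TRUE)
  v <- traj$states[, "V"]
  during <- traj$times <= 7
  expect_true(all(diff(v[during]) >= -1e-12))
  expect_lt(v[length(v)], 1e-6)
  expect_true(all(diff(traj$times) > 0))
  expect_true(all(traj$states >= 0))
})

test_that("halving the relative tolerance barely moves the final state", {
  sc <- canonical_scenarios()$finite_7d
  f1 <- simulate_model(sc$x0, sc$params, sc$schedule,
                       sim_config(t_span = c(0, 70), rel_tol = 1e-8))
  f2 <- simulate_model(sc$x0, sc$params, sc$schedule,
                       sim_config(t_span = c(0, 70), rel_tol = 5e-9))
  expect_lt(max_state_dist(f1$states[nrow(f1$states), ],
                           f2$states[nrow(f2$states), ]), 10 * 1e-8)
})

test_that("long runs respect the closed-form boundedness caps", {
  phi <- 0.01
  caps <- c(
    V = (phi + table1[["a_v0"]]) / table1[["d_v4"]],
    I = (table1[["a_I0"]] + table1[["a_I1"]]) / table1[["d_I3"]],
    C = (table1[["a_C0"]] + table1[["a_C2"]]) / table1[["d_C4"]],
    H = (table1[["a_H0"]] + table1[["a_H1"]]) / table1[["d_H3"]],
    S = (table1[["delta"]] + table1[["a_S0"]] + table1[["a_S1"]]) / table1[["d_S3"]],
    IL6 = (table1[["a_IL0"]] + table1[["a_IL1"]]) / table1[["d_IL2"]]
  )
  expect_equal(unname(caps[["V"]]), 5.02)
  set.seed(17)
  for (i in 1:4) {
    x0 <- runif(6, 0, 2)
    traj <- simulate_model(x0, table1, input_schedule(phi, 1e6),
                           sim_config(t_span = c(0, 300), dense_grid = 1))
    # trajectories may overshoot transiently from a high start but settle
    # under the caps; assert on the trailing half
    tail_states <- traj$states[traj$times > 150, ]
    expect_true(all(sweep(tail_states, 2, caps) <= 1e-8))
  }
})

test_that("brief input is reversible, 70-day input commits to the chronic basin", {
  scs <- canonical_scenarios()
  # classify outcomes against the censused attractors at alpha = 0
  es <- find_equilibria(table1, 0, n_starts = 150, seed = 9)
  stable_states <- lapply(Filter(function(r) r$stability == "stable",
                                 es$records), `[[`, "state")
  nearest <- function(x) {
    which.min(vapply(stable_states, function(s) max(abs(s - x)), numeric(1)))
  }
  baseline <- steady_state_by_integration(x0_canonical, table1, 0)$state

  t14 <- simulate_model(scs$finite_14d$x0, table1, scs$finite_14d$schedule,
                        scs$finite_14d$cfg)
  fin14 <- t14$states[nrow(t14$states), ]
  expect_identical(nearest(fin14), nearest(baseline))

  t70 <- simulate_model(scs$finite_70d_retrial$x0, table1,
                        scs$finite_70d_retrial$schedule,
                        scs$finite_70d_retrial$cfg)
  fin70 <- t70$states[nrow(t70$states), ]
  expect_false(nearest(fin70) == nearest(baseline))
  expect_gt(fin70[["V"]], 1)  # chronic high-virus state
  # re-exposure during [140, 210] did not change the attained attractor
  pre_pulse <- t70$states[which.min(abs(t70$times - 139)), ]
  expect_identical(nearest(pre_pulse), nearest(fin70))
})

test_that("steady_state_by_integration converges and agrees with Newton refinement", {
  ss <- steady_state_by_integration(x0_canonical, table1, 0)
  expect_true(ss$converged)
  expect_false(is.na(ss$t_conv))
  # polish the terminal state by Newton and compare
  newton_root <- get("newton_root", envir = asNamespace("virimmune"))
  fn <- function(x) list(F = unname(rhs(0, x, table1, 0)),
                         J = jacobian(x, table1, 0))
  pol <- newton_root(as.numeric(ss$state), fn, tol = 1e-12)
  expect_true(pol$converged)
  expect_lt(max(abs(pol$x - as.numeric(ss$state))), 1e-8)
  # starting at the steady state converges immediately
  ss2 <- steady_state_by_integration(ss$state, table1, 0,
                                     sim_config(t_span = c(0, 50), dense_grid = 2))
  expect_true(ss2$converged)
  expect_equal(ss2$t_conv, 0)
})

test_that("recovery_time: identity at baseline, canonical scenario, and slow components", {
  sc <- canonical_scenarios()$finite_7d
  traj <- simulate_model(sc$x0, sc$params, sc$schedule, sc$cfg)
  final <- traj$states[nrow(traj$states), ]
  # identical-to-baseline trajectory recovers at the cutoff
  flat <- traj
  flat$states <- matrix(rep(final, each = length(flat$times)),
                        ncol = 6, dimnames = list(NULL, state_names()))
  class(flat) <- "trajectory"
  expect_equal(recovery_time(flat, final), 7)
  # fast components recover within ~5 days of cutoff
  rt <- recovery_time(traj, final, c("V", "I", "C", "IL6"), 0.1)
  expect_false(is.na(rt))
  expect_lt(rt, 12.5)
  # humoral immunity settles above its pre-exposure level: recovery is
  # defined against the post-input steady state, not the initial state
  expect_gt(final[["H"]], sc$x0[["H"]])
  rt_init <- recovery_time(traj, sc$x0, c("V", "I", "C", "IL6", "H", "S"),
                           0.001, 1e-6)
  expect_true(is.na(rt_init))
})

test_that("trajectories round-trip through CSV + JSON sidecar", {
  sc <- canonical_scenarios()$finite_7d
  traj <- simulate_model(sc$x0, sc$params, sc$schedule,
                         sim_config(t_span = c(0, 20)))
  f <- tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  back <- read_trajectory(f)
  expect_equal(back$times, traj$times)
  expect_equal(back$states, traj$states, ignore_attr = TRUE)
  expect_equal(back$params, traj$params)
  expect_equal(back$schedule$phi, traj$schedule$phi)
  expect_equal(back$schedule$T_end, traj$schedule$T_end)
})
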