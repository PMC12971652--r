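clamp <- c(V = 0, I = 0.3, C = 1.2, H = 0.4, S = 0.25, IL6 = 0.005)

test_that("subsystem enumeration yields the 63 distinct non-empty masks", {
  specs <- enumerate_subsystems(clamp)
  expect_length(specs, 63)
  masks <- vapply(specs, function(s) s$mask, character(1))
  expect_identical(anyDuplicated(masks), 0L)
  expect_false("000000" %in% masks)
  # each variable appears in exactly 2^5 = 32 subsystems
  act <- t(vapply(specs, function(s) s$active, logical(6)))
  expect_identical(unname(colSums(act)), rep(32, 6))
})

test_that("the focal-parameter policy follows variable priority", {
  specs <- enumerate_subsystems(clamp)
  for (s in specs) {
    expected <- if (s$active[["V"]]) "d_v1"
    else if (s$active[["I"]]) "a_I1"
    else if (s$active[["C"]]) "a_C2"
    else if (s$active[["H"]]) "a_H0"
    else if (s$active[["S"]]) "a_S0"
    else "a_IL0"
    expect_identical(s$focal_param, expected)
  }
})

test_that("the all-active reduced field reproduces the full model exactly", {
  specs <- enumerate_subsystems(clamp)
  full <- specs[[63]]
  expect_true(all(full$active))
  f <- reduced_rhs(full, table1, 0.01)
  states <- random_states(100, seed = 12)
  for (i in seq_len(nrow(states))) {
    expect_identical(f(states[i, ]), unname(rhs(0, states[i, ], table1, 0.01)))
  }
})

test_that("the V-only subsystem reduces to the closed-form scalar field", {
  spec <- enumerate_subsystems(stats::setNames(rep(0, 6), state_names()))[[1]]
  expect_identical(unname(spec$active), c(TRUE, rep(FALSE, 5)))
  f <- reduced_rhs(spec, table1, 0.01)
  for (v in c(0, 0.05, 0.3, 2)) {
    expected <- 0.01 + table1[["a_v0"]] * hill(v, 0.2, 3) - table1[["d_v4"]] * v
    out <- f(v)
    expect_length(out, 1)   # clamped derivatives are never returned
    expect_equal(out, expected, tolerance = 1e-14)
  }
})

test_that("a pure-decay scalar subsystem is monostable, never bistable", {
  p <- table1
  p[grepl("^a_", names(p))] <- 0
  specs <- enumerate_subsystems(stats::setNames(rep(0, 6), state_names()),
                                focal_grid = 10^seq(-1, 1, length.out = 5))
  il6_only <- Filter(function(s) s$mask == "000001", specs)[[1]]
  res <- detect_bistability(il6_only, p, alpha_level = 0, n_starts = 30,
                            seed = 1)
  expect_false(res$bistable)
  expect_lte(res$max_stable_count, 1L)
})

test_that("the full-model subsystem census matches find_equilibria exactly", {
  specs <- enumerate_subsystems(clamp, focal_grid = 0.24)
  full <- specs[[63]]
  res <- detect_bistability(full, table1, alpha_level = 0.01, n_starts = 120,
                            seed = 1)
  es <- find_equilibria(table1, 0.01, n_starts = 120, seed = 1)
  expect_identical(res$max_stable_count, count_stable(es))
  expect_true(res$bistable)
  # witness states are genuine stable fixed points of the full dynamics
  for (w in res$witness$states) {
    traj <- simulate_model(w, table1, input_schedule(0.01, 1e6),
                           sim_config(t_span = c(0, 150), dense_grid = 0.5))
    expect_lt(max(abs(traj$states[nrow(traj$states), ] - w)), 1e-6)
  }
})

test_that("bistability verdicts are invariant to the multistart seed", {
  specs <- enumerate_subsystems(clamp,
                                focal_grid = 10^seq(-1, 1, length.out = 5))
  vic <- Filter(function(s) s$mask == "111000", specs)[[1]]  # V, I, C
  r1 <- detect_bistability(vic, table1, 0.01, n_starts = 60, seed = 1)
  r2 <- detect_bistability(vic, table1, 0.01, n_starts = 60, seed = 99)
  expect_identical(r1$bistable, r2$bistable)
  expect_identical(r1$max_stable_count, r2$max_stable_count)
})

test_that("membership frequency table has the 32/31 group structure", {
  specs <- enumerate_subsystems(clamp, focal_grid = 1)
  fake <- lapply(specs, function(s) {
    structure(list(spec = s, bistable = s$active[["V"]],
                   max_stable_count = ifelse(s$active[["V"]], 2L, 1L),
                   witness = NULL), class = "subsystem_result")
  })
  ft <- membership_frequency(fake)
  expect_identical(ft$group1_total, rep(32L, 6))
  expect_identical(ft$group2_total, rep(31L, 6))
  expect_identical(ft$group1_bistable[ft$variable == "V"], 32L)
  expect_identical(ft$group2_bistable[ft$variable == "V"], 0L)
  # every subsystem is counted once per variable
  expect_identical(sum(ft$group1_bistable + ft$group2_bistable),
                   6L * sum(vapply(fake, `[[`, logical(1), "bistable")))
  expect_error(membership_frequency(fake[-1]), "63")
  expect_error(membership_frequency(c(fake[-1], fake[2])), "63")
})
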