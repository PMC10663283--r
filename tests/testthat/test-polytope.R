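test_that("moment polytopes carry the model rows with box bounds", {
  m <- synth_model()
  W <- build_task_wrenches(task_spec(), m)$wrenches
  p <- build_moment_polytope(m, W[1, ])
  expect_equal(ncol(p$eq_mat), 7L)
  expect_equal(nrow(p$eq_mat), 4L)
  expect_equal(nrow(p$ineq_mat), 0L)
  expect_equal(p$lower, rep(0, 7))
  expect_equal(p$upper, rep(1, 7))
  expect_equal(drop(p$eq_rhs), unname(W[1, ]))
})

test_that("the stacked trajectory polytope has the expected structure", {
  m <- synth_model()
  seqs <- build_task_wrenches(task_spec(), m)
  spec <- build_trajectory_polytope(m, seqs, 0.12)
  expect_equal(ncol(spec$eq_mat), 49L)
  expect_equal(nrow(spec$eq_mat), 28L)          # 4 wrench rows x 7 slices
  expect_equal(nrow(spec$ineq_mat), 84L)        # 2 x 7 muscles x 6 pairs
  # time-major, muscle-minor variable order
  expect_equal(spec$var_labels$label[1:8],
               c(paste0("m", 1:7, "@t0"), "m1@t1"))
  # each Lipschitz row touches one muscle at two consecutive slices
  expect_true(all(rowSums(spec$ineq_mat != 0) == 2L))
  expect_true(all(spec$ineq_rhs == 0.12))
})

test_that("rate-limit nesting: tighter-delta samples satisfy looser systems", {
  m <- synth_model()
  seqs <- build_task_wrenches(task_spec(), m)
  tight <- build_trajectory_polytope(m, seqs, 0.1)
  loose <- build_trajectory_polytope(m, seqs, 0.3)
  st <- hit_and_run(tight, chain_config(100L, 300L, 5L, rng_seed = 21))
  audit <- audit_samples(st, loose)
  expect_true(audit$pass)
})

test_that("a vacuous rate limit admits any sequence of moment-feasible slices", {
  toy <- make_planar_toy()
  seqs <- build_task_wrenches(toy$task, toy$model)
  spec <- build_trajectory_polytope(toy$model, seqs, 1)
  # glue together independent single-moment samples; delta = 1 cannot bind
  mp <- build_moment_polytope(toy$model, 1)
  sl <- lapply(1:7, function(t)
    hit_and_run(mp, chain_config(50L, 100L, 2L, rng_seed = t))$samples)
  X <- do.call(cbind, sl)
  st <- sample_store(X, spec$var_labels)
  expect_true(audit_samples(st, spec)$pass)
})

test_that("zero rate limit collapses all slices to one shared activation", {
  toy <- make_planar_toy()
  seqs <- build_task_wrenches(toy$task, toy$model)
  spec <- build_trajectory_polytope(toy$model, seqs, 0)
  st <- hit_and_run(spec, chain_config(200L, 200L, 2L, rng_seed = 5))
  ts <- reshape_to_trajectories(st)
  sp <- activation_speeds(ts)
  expect_lt(max(abs(sp$tensor)), 1e-9)
  # each shared activation is feasible for every wrench in the sequence
  mp <- build_moment_polytope(toy$model, 1)
  first <- sample_store(ts$tensor[, 1, ], mp$var_labels)
  expect_true(audit_samples(first, mp)$pass)
})

test_that("infeasible stacked systems report the first failing prefix", {
  # two muscles, one wrench component, a jump the rate limit cannot bridge
  m <- h_matrix(matrix(c(1, 1), 1, 2), wrench_names = "fx")
  W <- matrix(c(0.2, 1.8, 0.2), 3, 1, dimnames = list(NULL, "fx"))
  seqs <- structure(list(wrenches = W,
                         task = task_spec(magnitude = 1, arc_degrees = 0,
                                          n_steps = 3)),
                    class = "wrench_sequence")
  expect_error(build_trajectory_polytope(m, seqs, 0.1),
               "first infeasible prefix has 2 slices")
})

test_that("seed constraints pin the first (and clamped last) slice", {
  m <- synth_model()
  seqs <- build_task_wrenches(task_spec(), m)
  spec <- build_trajectory_polytope(m, seqs, 0.25)
  st <- hit_and_run(spec, chain_config(50L, 300L, 5L, rng_seed = 31))
  seed_act <- as.numeric(reshape_to_trajectories(st)$tensor[1, 1, ])

  sp_seeded <- add_seed_constraint(spec, seed_point(seed_act))
  st_s <- hit_and_run(sp_seeded, chain_config(40L, 300L, 5L, rng_seed = 32))
  ts_s <- reshape_to_trajectories(st_s)
  for (i in seq_len(40)) {
    expect_equal(as.numeric(ts_s$tensor[i, 1, ]), seed_act, tolerance = 1e-9)
  }
  # seeded samples satisfy the unseeded system (containment)
  expect_true(audit_samples(st_s, spec)$pass)

  sp_cl <- add_seed_constraint(spec, seed_point(seed_act, clamp = TRUE))
  st_c <- hit_and_run(sp_cl, chain_config(40L, 300L, 5L, rng_seed = 33))
  ts_c <- reshape_to_trajectories(st_c)
  T <- dim(ts_c$tensor)[2]
  for (i in seq_len(40)) {
    expect_equal(as.numeric(ts_c$tensor[i, 1, ]), seed_act, tolerance = 1e-9)
    expect_equal(as.numeric(ts_c$tensor[i, T, ]), seed_act, tolerance = 1e-9)
  }
})

test_that("bad seeds raise errors that distinguish the failure mode", {
  m <- synth_model()
  seqs <- build_task_wrenches(task_spec(), m)
  spec <- build_trajectory_polytope(m, seqs, 0.25)
  expect_error(seed_point(c(1.1, rep(0.5, 6))), "\\[0, 1\\]")
  expect_error(add_seed_constraint(spec, rep(0.5, 7)),
               "not feasible for the first moment")
  expect_error(add_seed_constraint(spec, rep(0.5, 3)), "does not match")
})

test_that("polytopes export as labeled plain text", {
  toy <- make_planar_toy()
  seqs <- build_task_wrenches(toy$task, toy$model)
  spec <- build_trajectory_polytope(toy$model, seqs, 0.5)
  path <- withr::local_tempfile(fileext = ".txt")
  export_polytope_text(spec, path)
  lines <- readLines(path)
  expect_true(any(grepl("^wrench\\[t0", lines)))
  expect_true(any(grepl("lipschitz\\[m1,t0->t1\\]", lines)))
})
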