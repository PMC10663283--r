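test_that("stores reshape into trajectories by label, not position", {
  m <- synth_model()
  seqs <- build_task_wrenches(task_spec(), m)
  spec <- build_trajectory_polytope(m, seqs, 0.5)
  st <- hit_and_run(spec, chain_config(10L, 200L, 2L, rng_seed = 41))
  ts <- reshape_to_trajectories(st)
  expect_equal(dim(ts$tensor), c(10L, 7L, 7L))
  expect_equal(ts$tensor[3, 2, 5], unname(st$samples[3, "m5@t1"]))

  # permuting the store's columns must not change the tensor
  perm <- sample(ncol(st$samples))
  st_p <- sample_store(st$samples[, perm], st$var_labels[perm, ],
                       st$provenance)
  ts_p <- reshape_to_trajectories(st_p)
  expect_equal(ts_p$tensor, ts$tensor)

  # an incomplete grid is refused with the missing labels named
  st_m <- sample_store(st$samples[, -1], st$var_labels[-1, ], st$provenance)
  expect_error(reshape_to_trajectories(st_m), "missing: m1@t0")
})

test_that("differentiation and maxima follow their definitions", {
  const <- manual_trajectories(rep(list(matrix(0.4, 2, 3)), 4))
  expect_true(all(activation_speeds(const)$tensor == 0))
  expect_true(all(max_abs_speed(const) == 0))

  ramp <- manual_trajectories(lapply(0:6, function(t) matrix(0.1 * t, 1, 2)))
  expect_true(all(abs(activation_speeds(ramp)$tensor - 0.1) < 1e-12))

  two <- manual_trajectories(list(matrix(0.2, 1, 1), matrix(0.32, 1, 1)))
  expect_equal(as.numeric(activation_speeds(two)$tensor), 0.12)

  # activation path (0, 0.1, 0.4, 0.2) has speeds (0.1, 0.3, -0.2)
  tr <- manual_trajectories(lapply(c(0, 0.1, 0.4, 0.2), function(v)
    matrix(v, 1, 1)))
  expect_equal(as.numeric(max_abs_speed(tr)), 0.3)
})

test_that("the rate filter keeps exactly the compliant trajectories", {
  # five trajectories with known maximal speeds 0.05 0.10 0.12 0.20 0.50
  mk <- function(v) c(0.2, 0.2 + v, 0.2)
  slices <- lapply(1:3, function(t)
    matrix(sapply(c(0.05, 0.10, 0.12, 0.20, 0.50), mk)[t, ], 5, 1))
  ts <- manual_trajectories(slices)
  expect_equal(n_trajectories(filter_by_delta(ts, 0.12)), 3L)
  expect_equal(n_trajectories(filter_by_delta(ts, 1)), 5L)
  expect_equal(n_trajectories(filter_by_delta(ts, 0)), 0L)
})

test_that("seed selection is deterministic and returns feasible first slices", {
  m <- synth_model()
  seqs <- build_task_wrenches(task_spec(), m)
  spec <- build_trajectory_polytope(m, seqs, 0.25)
  st <- hit_and_run(spec, chain_config(60L, 300L, 3L, rng_seed = 51))
  ts <- reshape_to_trajectories(st)
  s1 <- select_seeds(ts, 5L, rng_seed = 99)
  s2 <- select_seeds(ts, 5L, rng_seed = 99)
  expect_identical(lapply(s1, `[[`, "activation"),
                   lapply(s2, `[[`, "activation"))
  expect_error(select_seeds(ts, 100L, rng_seed = 1), "100")
  all_seeds <- select_seeds(ts, n_trajectories(ts), rng_seed = 7)
  expect_equal(length(all_seeds), n_trajectories(ts))
  # every seed reproduces the first wrench
  mp <- build_moment_polytope(m, seqs$wrenches[1, ])
  for (s in s1) {
    expect_lt(max(abs(m$values %*% s$activation - seqs$wrenches[1, ])), 1e-6)
  }
})

test_that("per-timestep PCA recovers planar structure with a fixed sign convention", {
  # slice data on an exact 2-plane in 4-D
  set.seed(2)
  zz <- matrix(runif(400), 200, 2)
  base <- cbind(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5))
  slice <- 0.1 + 0.4 * (zz %*% t(base))
  ts <- manual_trajectories(list(slice, slice))
  models <- fit_pc_per_timestep(ts)
  expect_equal(length(models), 2L)
  expect_equal(sum(models[[1]]$explained), 1, tolerance = 1e-10)
  # duplicated data give the identical model
  models2 <- fit_pc_per_timestep(ts)
  expect_identical(models[[1]]$loadings, models2[[1]]$loadings)
  # deterministic sign: dominant loading entry positive
  for (j in 1:2) {
    L <- models[[1]]$loadings[, j]
    expect_gt(L[which.max(abs(L))], 0)
  }

  # toy segment slice: the single informative direction is (1,-1)/sqrt(2)
  toy <- make_planar_toy()
  p <- build_moment_polytope(toy$model, 1)
  st <- hit_and_run(p, chain_config(300L, 300L, 2L, rng_seed = 61))
  tst <- manual_trajectories(list(st$samples, st$samples))
  mt <- fit_pc_per_timestep(tst)
  expect_equal(abs(sum(mt[[1]]$loadings[, 1] * c(1, -1) / sqrt(2))), 1,
               tolerance = 1e-8)
  expect_true(mt[[1]]$rank_deficient)
})

test_that("projection uses the unseeded chart and preserves in-plane distances", {
  m <- synth_model()
  seqs <- build_task_wrenches(task_spec(), m)
  spec <- build_trajectory_polytope(m, seqs, 0.5)
  st <- hit_and_run(spec, chain_config(80L, 300L, 3L, rng_seed = 71))
  ts <- reshape_to_trajectories(st)
  models <- fit_pc_per_timestep(ts)
  pr <- project_timestep(ts, models, 2L)
  expect_equal(dim(pr), c(80L, 2L))
  # the centering vector itself projects to the origin
  ctr <- models[[2]]$center
  one <- trajectory_set(array(rep(ctr, each = 7), c(1, 7, length(ctr))),
                        ts$muscles, ts$times)
  expect_equal(as.numeric(project_timestep(one, models, 2L)), c(0, 0),
               tolerance = 1e-10)
  # orthonormal loadings: distances within the plane are preserved
  L <- models[[2]]$loadings
  v <- (ts$tensor[1, 2, ] - ts$tensor[2, 2, ])
  in_plane <- L %*% crossprod(L, v)
  expect_equal(sqrt(sum((pr[1, ] - pr[2, ])^2)), sqrt(sum(in_plane^2)),
               tolerance = 1e-10)
  expect_error(project_timestep(ts, models, 9L), "outside")
})

test_that("hull areas and reduction ratios follow plane geometry", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(as.numeric(hull_area(sq)), 1)
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(as.numeric(hull_area(tri)), 0.5)
  col <- cbind(1:5, 2 * (1:5))
  expect_equal(as.numeric(hull_area(col)), 0)
  expect_true(attr(hull_area(col), "degenerate"))
  expect_true(attr(hull_area(tri[1:2, ]), "degenerate"))

  expect_equal(seeded_reduction_ratio(tri, sq), 0.5)
  expect_equal(seeded_reduction_ratio(sq, sq), 1)
  expect_error(seeded_reduction_ratio(tri, col), "degenerate unseeded")

  # ratio is invariant to rigid rotation of the PC plane
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expect_equal(seeded_reduction_ratio(tri %*% t(R), sq %*% t(R)),
               0.5, tolerance = 1e-12)
  # and to the loading sign convention
  expect_equal(seeded_reduction_ratio(tri %*% diag(c(-1, 1)),
                                      sq %*% diag(c(-1, 1))), 0.5)
})

test_that("occupancy summaries match hand-computed quartiles", {
  vals <- c(0.1, 0.2, 0.3, 0.4)
  slices <- lapply(1:2, function(t) matrix(vals, 4, 1))
  ts <- manual_trajectories(slices)
  occ <- occupancy_summary(ts)
  act <- occ[occ$quantity == "activation", ]
  expect_equal(act$min, 0.1)
  expect_equal(act$q25, as.numeric(quantile(rep(vals, 2), 0.25)))
  expect_equal(act$median, 0.25)
  expect_equal(act$max, 0.4)
  sp <- occ[occ$quantity == "speed", ]
  expect_true(all(sp[, c("min", "q25", "median", "q75", "max")] == 0))

  const <- manual_trajectories(rep(list(matrix(0.4, 3, 2)), 3))
  occ2 <- occupancy_summary(const)
  expect_true(all(occ2$max[occ2$quantity == "activation"] ==
                    occ2$min[occ2$quantity == "activation"]))
})
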