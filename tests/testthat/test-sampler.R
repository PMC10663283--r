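test_that("interior points sit at symmetric centers", {
  sq <- cube_spec(2L)
  ip <- find_interior_point(sq)
  expect_equal(as.numeric(ip), c(0.5, 0.5), tolerance = 1e-4)

  toy <- make_planar_toy()
  p <- build_moment_polytope(toy$model, 1)
  ip2 <- find_interior_point(p)
  expect_equal(as.numeric(ip2), c(0.5, 0.5), tolerance = 1e-6)
  expect_gt(attr(ip2, "margin"), 0)
})

test_that("contradictory equalities raise an infeasibility error", {
  vl <- data.frame(muscle = c("m1", "m2"), time = 0L,
                   label = c("m1@t0", "m2@t0"))
  bad <- polytope_spec(eq_mat = rbind(c(1, 1), c(1, 1)), eq_rhs = c(1, 1.5),
                       lower = c(0, 0), upper = c(1, 1), var_labels = vl)
  expect_error(find_interior_point(bad), class = "actspace_infeasible")
})

test_that("charts span the equality null space orthonormally", {
  toy <- make_planar_toy()
  p <- build_moment_polytope(toy$model, 1)
  ch <- build_chart(p)
  expect_equal(ch$dim, 1L)
  b <- ch$basis[, 1]
  expect_equal(abs(sum(b * c(1, -1) / sqrt(2))), 1, tolerance = 1e-12)
  expect_equal(crossprod(ch$basis), diag(1), tolerance = 1e-12,
               ignore_attr = TRUE)
  # points in the chart satisfy the equalities identically
  for (z in c(-0.3, 0.1, 0.6)) {
    x <- ch$anchor + ch$basis %*% z
    expect_lt(abs(sum(x) - 1), 1e-10)
  }

  m <- synth_model()
  seqs <- build_task_wrenches(task_spec(), m)
  spec <- build_trajectory_polytope(m, seqs, 0.12)
  ch49 <- build_chart(spec)
  expect_equal(ch49$dim, 49L - 28L)
})

test_that("a full-rank equality system gives a zero-dimensional chart", {
  vl <- data.frame(muscle = c("m1", "m2"), time = 0L,
                   label = c("m1@t0", "m2@t0"))
  pin <- polytope_spec(eq_mat = diag(2), eq_rhs = c(0.3, 0.7),
                       lower = c(0, 0), upper = c(1, 1), var_labels = vl)
  err <- tryCatch(find_interior_point(pin), error = function(e) e)
  expect_s3_class(err, "actspace_degenerate")
  expect_equal(as.numeric(err$point), c(0.3, 0.7), tolerance = 1e-12)
  expect_warning(st <- hit_and_run(pin, chain_config(5L, 0L, 1L, 1L)),
                 "unique feasible point")
  expect_equal(unname(st$samples),
               matrix(rep(c(0.3, 0.7), each = 5), 5, 2), tolerance = 1e-12)
})

test_that("chord extents recover closed-form geometry", {
  sq <- cube_spec(2L)
  ch <- build_chart(sq, anchor = c(0.5, 0.5))
  ext <- chord_extent(c(0, 0) + 0, c(1, 0), ch)
  # chart coordinates are centered on the anchor
  expect_equal(unname(ext), c(-0.5, 0.5), tolerance = 1e-12)
  ext2 <- chord_extent(c(0, 0), c(1, 1) / sqrt(2), ch)
  expect_equal(unname(ext2), c(-sqrt(0.5), sqrt(0.5)), tolerance = 1e-12)

  # toy segment: from the point at a1 = 0.25 the chord reaches both endpoints
  toy <- make_planar_toy()
  p <- build_moment_polytope(toy$model, 1)
  chs <- build_chart(p, anchor = c(0.25, 0.75))
  ext3 <- chord_extent(0, 1, chs)
  expect_equal(sort(abs(unname(ext3))), sort(c(0.25, 0.75) * sqrt(2)),
               tolerance = 1e-12)
})

test_that("hit-and-run reproduces uniform moments on analytic fixtures", {
  toy <- make_planar_toy()
  p <- build_moment_polytope(toy$model, 1)
  st <- hit_and_run(p, chain_config(20000L, 1000L, 5L, rng_seed = 3))
  a1 <- st$samples[, 1]
  expect_lt(abs(mean(a1) - 0.5), 0.02)
  expect_lt(abs(var(a1) - 1 / 12) / (1 / 12), 0.15)

  cube <- cube_spec(3L)
  stc <- hit_and_run(cube, chain_config(20000L, 500L, 2L, rng_seed = 4))
  for (j in 1:3) expect_lt(abs(mean(stc$samples[, j]) - 0.5), 0.02)
})

test_that("hit-and-run matches analytic cell masses on the triangle", {
  tri <- triangle_spec()
  st <- hit_and_run(tri, chain_config(20000L, 1000L, 10L, rng_seed = 8))
  X <- st$samples
  ix <- pmin(floor(X[, 1] * 4), 3)
  iy <- pmin(floor(X[, 2] * 4), 3)
  cell <- ix + 4 * iy
  # analytic bin masses on the 4x4 grid: full cells below the diagonal,
  # half cells on it, zero above
  mass <- sapply(0:15, function(c) {
    i <- c %% 4; j <- c %/% 4
    if (i + j <= 2) 1 / 16 else if (i + j == 3) 1 / 32 else 0
  })
  mass <- mass / sum(mass)
  keep <- mass > 0
  counts <- tabulate(cell + 1, nbins = 16)
  expect_equal(sum(counts[!keep]), 0)
  pval <- suppressWarnings(
    stats::chisq.test(counts[keep], p = mass[keep])$p.value)
  expect_gt(pval, 0.01)
})

test_that("the rejection oracle is exact and agrees with hit-and-run", {
  toy <- make_planar_toy()
  p <- build_moment_polytope(toy$model, 1)
  hr <- hit_and_run(p, chain_config(5000L, 1000L, 5L, rng_seed = 11))
  or <- rejection_oracle(p, 5000L, rng_seed = 12)
  ks <- suppressWarnings(stats::ks.test(hr$samples[, 1], or$samples[, 1]))
  expect_gt(ks$p.value, 0.01)

  # oracle hull recovers the triangle area within 5% at n = 20,000
  tri <- triangle_spec()
  ot <- rejection_oracle(tri, 20000L, rng_seed = 13)
  area <- as.numeric(hull_area(ot$samples))
  expect_lt(abs(area - 0.5) / 0.5, 0.05)

  # reproducibility: identical seeds give identical stores
  or2 <- rejection_oracle(tri, 100L, rng_seed = 14)
  or3 <- rejection_oracle(tri, 100L, rng_seed = 14)
  expect_identical(or2$samples, or3$samples)
})

test_that("the oracle refuses high-dimensional charts", {
  m <- synth_model()
  seqs <- build_task_wrenches(task_spec(), m)
  spec <- build_trajectory_polytope(m, seqs, 0.5)
  expect_error(rejection_oracle(spec, 10L, rng_seed = 1), "dimension <= 4")
})

test_that("hit-and-run chains are reproducible and fully audited", {
  m <- synth_model()
  seqs <- build_task_wrenches(task_spec(), m)
  spec <- build_trajectory_polytope(m, seqs, 0.25)
  cc <- chain_config(200L, 300L, 3L, rng_seed = 77)
  s1 <- hit_and_run(spec, cc)
  s2 <- hit_and_run(spec, cc)
  expect_identical(s1$samples, s2$samples)
  a <- audit_samples(s1, spec)
  expect_true(a$pass)
  expect_lt(a$max_eq_residual, 1e-6)
  expect_lt(a$max_bound_violation, 1e-9)
  expect_lt(a$max_ineq_violation, 1e-9)
})

test_that("slice marginals under a vacuous rate limit match single-moment sampling", {
  toy <- make_planar_toy()
  seqs <- build_task_wrenches(toy$task, toy$model)
  spec <- build_trajectory_polytope(toy$model, seqs, 1)
  st <- hit_and_run(spec, chain_config(400L, 1000L, 5L, rng_seed = 19))
  ts <- reshape_to_trajectories(st)
  mp <- build_moment_polytope(toy$model, 1)
  direct <- hit_and_run(mp, chain_config(400L, 1000L, 5L, rng_seed = 20))
  for (t in c(1L, 4L)) {
    p <- energy_perm_test(ts$tensor[, t, 1], direct$samples[, 1],
                          n_perm = 199, seed = t)
    expect_gt(p, 0.01)
  }
})
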