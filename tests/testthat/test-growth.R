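# growth_loop: connection placement, growth, shrinkage, foundation update,
# the simulation step and run

test_that("place_connections respects range, topology, angle and rest-length rules", {
  p <- sim_params()
  # far apart: nothing
  expect_identical(nrow(place_connections(parallel_chains(3), p)$pairs), 0L)
  # close parallel chains: perpendicular pairs rest exactly at th_sub
  cs <- place_connections(parallel_chains(0.5), p)
  expect_gt(nrow(cs$pairs), 0)
  expect_true(all(cs$rest_len <= p$th_sub + 1e-12))
  n <- 11
  perp <- cs$pairs[, 2] - cs$pairs[, 1] == n
  expect_true(any(perp))
  expect_equal(unique(cs$rest_len[perp]), p$th_sub)
  # a single 3-vertex chain: neighbours and neighbours-of-neighbours excluded
  chain3 <- tissue_mesh(pos = rbind(c(0, 0), c(0.4, 0), c(0.8, 0)),
                        edges = rbind(c(1L, 2L), c(2L, 3L)),
                        fixed = c(TRUE, FALSE, TRUE))
  expect_identical(nrow(place_connections(chain3, p)$pairs), 0L)
  # visibility: a wall between two chains blocks connections across it
  m <- parallel_chains(1.0)
  blocker <- tissue_mesh(pos = rbind(m$pos, c(-0.1, 0.5), c(10.1, 0.5)),
                         edges = rbind(m$edges, c(23L, 24L)),
                         fixed = c(m$fixed, TRUE, TRUE))
  cs2 <- place_connections(blocker, p)
  across <- abs(blocker$pos[cs2$pairs[, 1], 2] - blocker$pos[cs2$pairs[, 2], 2]) > 0.9
  expect_identical(sum(across), 0L)
})

test_that("rest lengths compound exactly as (1 + dt*g_b)^n", {
  p <- sim_params()
  m <- small_nest(4, params = p)
  r0 <- m$rest_len
  m1 <- grow_rest_lengths(m, p)
  expect_identical(m1$rest_len, r0 * 1.005)
  mn <- m
  for (i in 1:100) mn <- grow_rest_lengths(mn, p)
  expect_equal(mn$rest_len, r0 * 1.005^100, tolerance = 1e-12)
  expect_equal(1.005^100, 1.6467, tolerance = 1e-4)
  p0 <- default_params(g_b = 0)
  expect_identical(grow_rest_lengths(m, p0)$rest_len, r0)
})

test_that("shrink_domain scales only the shrink axis, about the template centre", {
  p <- sim_params()
  m <- small_nest(4, params = p)
  s <- shrink_domain(m, p)
  expect_identical(s$pos[, 2], m$pos[, 2])               # y bit-identical
  expect_equal(diff(range(s$pos[, 1])) / diff(range(m$pos[, 1])), 0.997)
  expect_equal(s$foundation[, 1],
               mean(range(m$pos[m$fixed, 1])) +
                 (m$foundation[, 1] - mean(range(m$pos[m$fixed, 1]))) * 0.997)
  expect_identical(shrink_domain(m, default_params(g_axis = 0))$pos, m$pos)
  expect_error(shrink_domain(m, default_params(g_axis = -300)), "g_axis")
})

test_that("update_foundation closes exactly dt_foundation of the gap", {
  p <- sim_params()
  m <- small_nest(1, params = p)
  m$foundation <- m$foundation + 1       # 1 um gap everywhere (sqrt(2) in 2D)
  u <- update_foundation(m, p)
  expect_equal(m$pos - u$foundation, (m$pos - m$foundation) * (1 - 0.01))
  u1 <- update_foundation(m, default_params(dt_foundation = 1))
  expect_identical(u1$foundation, m$pos)
  u0 <- update_foundation(m, default_params(dt_foundation = 0))
  expect_identical(u0$foundation, m$foundation)
})

test_that("simulation_step is a fixpoint without growth or shrinkage", {
  p <- default_params(g_b = 0, g_axis = 0)
  m <- small_nest(4, params = p)
  st <- simulation_step(m, p)
  expect_equal(st$mesh$pos, m$pos, tolerance = 1e-12)
  expect_identical(st$mesh$rest_len, m$rest_len)
  expect_identical(st$mesh$foundation, m$foundation)
})

test_that("simulation_step runs the full pipeline and logs sane quantities", {
  p <- sim_params()
  m <- small_nest(4, params = p)
  st <- simulation_step(m, p)
  expect_true(is.finite(st$log$energy))
  expect_gte(st$log$n_connections, 0)
  expect_true(st$log$converged)
  # subdivision inside the step conserves total boundary rest length
  expect_equal(sum(st$mesh$rest_len), sum(m$rest_len) * 1.005, tolerance = 1e-9)
  # and all face loops are still simple polygons
  expect_true(all(mesh_stats(st$mesh)$simple))
})

test_that("run_simulation: 0 steps returns the input; same seed is bit-identical", {
  p <- sim_params()
  m <- small_nest(4, params = p)
  r0 <- run_simulation(m, p, steps = 0, snapshot_every = 0)
  expect_identical(r0$mesh$pos, m$pos)
  expect_identical(nrow(r0$log), 0L)
  ra <- run_simulation(small_nest(4, params = p), p, steps = 5, snapshot_every = 0)
  rb <- run_simulation(small_nest(4, params = p), p, steps = 5, snapshot_every = 0)
  expect_identical(ra$log, rb$log)
  expect_identical(ra$mesh$pos, rb$mesh$pos)
})
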