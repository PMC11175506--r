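# mechanics: force laws, energies, gradient consistency, equilibrium solving

test_that("edge_force follows the linear stretch law", {
  expect_identical(edge_force(2, 1, 0.2), 0.2)   # doubled length, table stiffness
  expect_identical(edge_force(1, 1, 0.2), 0)
  expect_equal(edge_force(0.5, 1, 0.2), -0.1)
  expect_error(edge_force(1, 0, 0.2), "l_rest")
})

test_that("bending torque is linear and zero at rest", {
  expect_identical(bending_torque(pi, pi, 5e-4), 0)
  expect_equal(bending_torque(pi / 2, pi, 0.001), -0.001 * pi / 2)
})

test_that("a straight chain vertex at rest exerts no force", {
  p <- default_params(k_foundation = 0)
  m <- tissue_mesh(pos = rbind(c(0, 0), c(1, 0), c(2, 0)),
                   edges = rbind(c(1L, 2L), c(2L, 3L)),
                   fixed = c(TRUE, FALSE, TRUE))
  r <- mesh_forces(m, NULL, p)
  expect_true(all(abs(r$forces) < 1e-15))
})

test_that("foundation force is Hookean in displacement and antisymmetric", {
  expect_equal(foundation_force(c(0, 0), c(0, 0), 0.1), c(0, 0))
  f <- foundation_force(c(1, 0), c(0, 0), 0.1)
  expect_equal(sqrt(sum(f^2)), 0.1)          # unit displacement, table stiffness
  expect_equal(f, c(-0.1, 0))                # pointing toward the anchor
  expect_equal(foundation_force(c(0, 0), c(1, 0), 0.1),
               -foundation_force(c(1, 0), c(0, 0), 0.1))
})

test_that("connections resist only compression", {
  expect_identical(connection_force(1.2, 1, 0.1), 0)
  expect_identical(connection_force(1, 1, 0.1), 0)
  expect_equal(connection_force(0.5, 1, 0.1), -0.05)  # repulsive, magnitude 0.05
})

test_that("forces are the exact negative gradient of the total energy", {
  p <- default_params(junction_bending = TRUE)
  for (seed in 1:3) {
    set.seed(seed)
    m <- small_nest(2, side = 4, seed = seed, params = p)
    m$pos <- m$pos + matrix(rnorm(length(m$pos), sd = 0.08), ncol = 2)
    m <- epibuckle:::ensure_angles(m, p)
    conn <- place_connections(m, p)
    ana <- epibuckle:::energy_grad(m, conn, p)$grad
    num <- numeric_gradient(m, conn, p)
    scale <- max(abs(num), 1e-8)
    expect_lt(max(abs(ana - num)) / scale, 1e-6)
  }
})

test_that("total_energy is zero at rest and counts a stretched edge", {
  p <- default_params(k_foundation = 0)
  m <- small_nest(4, params = p)
  expect_lt(as.numeric(total_energy(m, NULL, p)), 1e-15)
  one <- tissue_mesh(pos = rbind(c(0, 0), c(2, 0)), edges = rbind(c(1L, 2L)),
                     rest_len = 1, fixed = c(TRUE, TRUE))
  e <- total_energy(one, NULL, p)
  expect_equal(as.numeric(e), 0.5 * p$k_b * 1 * (2 / 1 - 1)^2)
  expect_equal(unname(attr(e, "parts")["bending"]), 0)
})

test_that("solve_equilibrium: 1-D closed form, symmetry, and monotone energy", {
  p <- default_params(k_foundation = 0)
  # single free vertex on one stretched spring -> ends at distance l_rest
  b <- tissue_mesh(pos = rbind(c(0, 0), c(2, 0)), edges = rbind(c(1L, 2L)),
                   rest_len = 1, fixed = c(TRUE, FALSE))
  s <- solve_equilibrium(b, NULL, p, tol = 1e-9)
  expect_equal(unname(s$mesh$pos[2, ]), c(1, 0), tolerance = 1e-6)
  expect_true(s$report$converged)

  # symmetric 3-spring star: free centre ends at the centroid
  th <- 2 * pi * (0:2) / 3
  star <- tissue_mesh(pos = rbind(cbind(cos(th), sin(th)), c(0.3, 0.1)),
                      edges = cbind(1:3, 4L), rest_len = rep(0.2, 3),
                      fixed = c(TRUE, TRUE, TRUE, FALSE))
  s2 <- solve_equilibrium(star, NULL, p, tol = 1e-9)
  expect_equal(unname(s2$mesh$pos[4, ]), c(0, 0), tolerance = 1e-6)

  # energy trace is non-increasing across every accepted outer step
  set.seed(9)
  m <- small_nest(4, params = p)
  m$pos[!m$fixed, ] <- m$pos[!m$fixed, ] + matrix(rnorm(2 * sum(!m$fixed), sd = 0.1),
                                                  ncol = 2)
  s3 <- solve_equilibrium(m, NULL, p)
  expect_true(all(diff(s3$report$energy_trace) <= 1e-12))
})

test_that("internal stretch and bending forces obey Newton's third law", {
  # free-floating wavy chain, no foundation: zero net force
  p <- default_params(k_foundation = 0)
  x <- seq(0, 5, by = 0.5)
  m <- tissue_mesh(pos = cbind(x, 0.3 * sin(x)),
                   edges = cbind(seq_along(x)[-length(x)], seq_along(x)[-1]),
                   rest_len = rep(0.4, length(x) - 1),
                   fixed = rep(FALSE, length(x)))
  m$rest_angle[] <- pi
  r <- mesh_forces(m, NULL, p)
  expect_lt(max(abs(colSums(r$forces))), 1e-12)
  # and zero net torque about the origin
  tq <- sum(m$pos[, 1] * r$forces[, 2] - m$pos[, 2] * r$forces[, 1])
  expect_lt(abs(tq), 1e-12)
})

test_that("non-convergence is flagged, not fatal", {
  p <- default_params(k_foundation = 0)
  b <- tissue_mesh(pos = rbind(c(0, 0), c(2, 0)), edges = rbind(c(1L, 2L)),
                   rest_len = 1, fixed = c(TRUE, FALSE))
  expect_warning(s <- solve_equilibrium(b, NULL, p, tol = 1e-14, max_iter = 2),
                 "residual")
  expect_false(s$report$converged)
})
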