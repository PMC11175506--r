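# experiments: ablation recoil, beam buckling scans (fast cases; the full
# published-scale scans run in test-acceptance.R)

test_that("ablate validates its edge selection", {
  m <- small_nest(4, params = sim_params())
  expect_error(ablate(m, c(1L, 3L)), "contiguous")
  expect_error(ablate(m, 10^6L), "range")
})

test_that("cutting an unstressed network produces no recoil", {
  p <- sim_params()
  m <- small_nest(4, side = 10, seed = 2, params = p)
  # pick an interior wall: a free chain vertex and one of its edges
  deg <- tabulate(c(m$edges[, 1], m$edges[, 2]), nbins = nrow(m$pos))
  v <- which(!m$fixed & deg == 2)[1]
  eid <- which(m$edges[, 1] == v | m$edges[, 2] == v)[1]
  res <- ablate(m, eid, p, n_relax_steps = 5)
  junction_len <- sum(m$rest_len)  / length(m$faces)  # generous scale
  expect_lt(max(abs(res$series$opening)), 0.01 * junction_len)
})

test_that("a uniformly pre-tensed network opens monotonically to a plateau", {
  p <- default_params(k_foundation = 0.02)
  m <- small_nest(4, side = 10, seed = 2, params = p)
  m$rest_len <- 0.8 * m$rest_len          # uniform pre-tension
  deg <- tabulate(c(m$edges[, 1], m$edges[, 2]), nbins = nrow(m$pos))
  v <- which(!m$fixed & deg == 2)[3]
  eid <- which(m$edges[, 1] == v | m$edges[, 2] == v)[1]
  res <- ablate(m, eid, p, n_relax_steps = 12, relax_maxit = 10)
  op <- res$series$opening
  expect_gt(tail(op, 1), 0.05)                        # measurable recoil
  expect_true(all(diff(op) > -1e-8))                  # monotone growth
  expect_lt(abs(op[13] - op[12]), 0.02 * tail(op, 1)) # plateau reached
})

test_that("plastic foundation reset stabilises buckled junctions against cutting", {
  # stiff axial springs so the stored energy is bending, as in a beam cartoon
  p <- default_params(k_foundation = 0.05, k_b = 2,
                      k_b_tension = 2, k_b_compression = 2)
  beam <- make_beam(16, 0.25, p)
  r <- beam_response(beam, 0.05, p, seed_amplitude = 1e-3, perturbation = "noise")
  expect_gt(r$amplitude, 10 * 1e-3)
  # rebuild the buckled state with anchors consistent with the compression
  comp <- beam
  cen <- mean(range(comp$pos[, 1]))
  comp$pos[, 1] <- cen + (comp$pos[, 1] - cen) * (1 - 0.05)
  comp$foundation[, 1] <- cen + (comp$foundation[, 1] - cen) * (1 - 0.05)
  buck <- comp
  buck$pos <- as.matrix(r$profile)
  mid <- which.min(abs(buck$pos[, 1] - cen))
  eid <- which(buck$edges[, 1] == mid)[1]
  # (a) foundation never reset (anchors on the straight pre-buckling line):
  #     halves straighten after the cut
  res_a <- ablate(buck, eid, p, n_relax_steps = 8)
  # (b) plastic limit: anchors fully reset to the buckled positions first
  buck_b <- buck
  buck_b$foundation <- buck_b$pos
  res_b <- ablate(buck_b, eid, p, n_relax_steps = 8)
  d_straight <- function(s) {
    mean(c(tail(s$straightness_a, 1) - s$straightness_a[1],
           tail(s$straightness_b, 1) - s$straightness_b[1]))
  }
  s0 <- mean(unlist(res_b$series[1, c("straightness_a", "straightness_b")]))
  expect_gt(d_straight(res_a$series), 0)
  expect_lt(abs(d_straight(res_b$series)) / s0, 0.05)
  expect_gt(d_straight(res_a$series), 5 * abs(d_straight(res_b$series)))
})

test_that("a compressed beam below critical load stays straight, above it buckles", {
  p <- default_params(k_foundation = 0)
  beam <- make_beam(16, 1, p)
  # theory for this discretisation: eps_c = pi^2 k_bend a / (k_b L^2)
  eps_c <- pi^2 * p$k_bend * 1 / (p$k_b * 16^2)
  below <- beam_response(beam, 0.5 * eps_c, p, seed_amplitude = 1e-3)
  above <- beam_response(beam, 3 * eps_c, p, seed_amplitude = 1e-3)
  expect_lt(below$amplitude, 10 * 1e-3)
  expect_gt(above$amplitude, 10 * 1e-3)
  expect_gt(above$load, 0)
})

test_that("doubling the beam length divides the critical load by about 4", {
  sc <- euler_buckling_scan(lengths = c(12, 24),
                            strain_schedule = 10^seq(-5.5, -2.5, length.out = 25))
  expect_false(any(sc$table$failed))
  expect_equal(sc$table$critical_load[1] / sc$table$critical_load[2], 4,
               tolerance = 0.5)
})

test_that("foundation stiffness selects the buckling mode", {
  p <- sim_params()
  # Euler limit: no foundation, half-sine seed -> single half-wave (mode 1)
  beam <- make_beam(16, 0.25, default_params(k_foundation = 0))
  r0 <- beam_response(beam, 0.01, default_params(k_foundation = 0),
                      seed_amplitude = 1e-3, perturbation = "halfsine")
  free <- which(!beam$fixed)
  dw0 <- epibuckle:::dominant_wavelength(r0$profile$x[free], r0$profile$y[free])
  expect_identical(dw0$mode, 1L)
  # default foundation: several undulations on a single junction (mode >= 2)
  pf <- sim_params()   # k_foundation = 0.1
  beam2 <- make_beam(16, 0.125, pf)
  r1 <- beam_response(beam2, 0.12, pf, seed_amplitude = 1e-3, perturbation = "noise")
  free2 <- which(!beam2$fixed)
  dw1 <- epibuckle:::dominant_wavelength(r1$profile$x[free2], r1$profile$y[free2])
  expect_gte(dw1$mode, 2L)
})
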