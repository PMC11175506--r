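# morphometrics: polygon stats, straightness, fluctuation RMS, morphospace

test_that("polygon_stats matches closed forms and scaling laws", {
  # unit square
  sq <- polygon_stats(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(sq$area, 1)
  expect_equal(sq$perimeter, 4)
  expect_equal(sq$circularity, pi / 4)
  # finely discretised circle: circularity 1 within 1e-4
  circ <- polygon_stats(regular_polygon(2048))
  expect_lt(abs(circ$circularity - 1), 1e-4)
  # uniform scaling: area x s^2, perimeter x s, circularity invariant
  poly <- random_simple_polygon(17, seed = 11)
  a <- polygon_stats(poly)
  b <- polygon_stats(poly * 3.7)
  expect_equal(b$area, a$area * 3.7^2)
  expect_equal(b$perimeter, a$perimeter * 3.7)
  expect_equal(b$circularity, a$circularity)
  # self-intersecting loop flagged with NaN circularity
  bow <- polygon_stats(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1)))
  expect_false(bow$simple)
  expect_true(is.nan(bow$circularity))
  expect_error(polygon_stats(rbind(c(0, 0), c(1, 1))), "3")
})

test_that("circularity never exceeds 1 on random simple polygons", {
  for (seed in 1:25) {
    poly <- random_simple_polygon(sample(5:40, 1), seed = seed)
    st <- polygon_stats(poly)
    expect_true(st$simple)
    expect_lte(st$circularity, 1 + 1e-12)
  }
})

test_that("junction_straightness matches closed forms", {
  expect_identical(junction_straightness(rbind(c(0, 0), c(3, 4))), 1)
  th <- seq(0, pi, length.out = 3000)
  expect_equal(junction_straightness(cbind(cos(th), sin(th))), 2 / pi,
               tolerance = 1e-6)
  loop <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 0))
  expect_identical(junction_straightness(loop), 0)
  expect_error(junction_straightness(rbind(c(1, 1), c(1, 1))), "zero arc")
  # straightness <= 1, with equality iff collinear in order
  for (seed in 1:10) {
    set.seed(seed)
    pl <- cbind(cumsum(runif(8)), cumsum(rnorm(8)))
    expect_lte(junction_straightness(pl), 1)
  }
})

test_that("fluctuation RMS: exact cases and drift cancellation", {
  # static vertices
  static <- make_trajectories(5, 10, jitter_sigma = 0, seed = 1)$trajectories
  expect_equal(vertex_fluctuation_rms(static)$rms, 0)
  # pure rigid translation cancels exactly under drift correction
  drift <- make_trajectories(5, 10, jitter_sigma = 0,
                             drift_per_frame = c(0.3, -0.1), seed = 1)$trajectories
  expect_equal(vertex_fluctuation_rms(drift, drift_correct = TRUE)$rms, 0)
  expect_gt(vertex_fluctuation_rms(drift, drift_correct = FALSE)$rms, 0)
  # ragged series error
  bad <- drift[-1, ]
  expect_error(vertex_fluctuation_rms(bad), "ragged")
})

test_that("fluctuation RMS estimates sigma*sqrt(2) and matches a brute-force oracle", {
  tr <- make_trajectories(10, 1000, jitter_sigma = 0.07, seed = 3)$trajectories
  r <- vertex_fluctuation_rms(tr, drift_correct = FALSE)
  expect_equal(r$rms, 0.07 * sqrt(2), tolerance = 0.03)
  # brute-force recomputation (independent loops)
  ids <- unique(tr$vertex_id)
  acc <- c()
  for (v in ids) {
    sub <- tr[tr$vertex_id == v, ]
    acc <- c(acc, (sub$x - mean(sub$x))^2 + (sub$y - mean(sub$y))^2)
  }
  expect_equal(r$rms, sqrt(mean(acc)), tolerance = 1e-12)
  # two populations: RMS ratio ~ sigma ratio
  t2 <- make_trajectories(10, 500, jitter_sigma = 0.7, seed = 4)$trajectories
  r2 <- vertex_fluctuation_rms(t2, drift_correct = FALSE)
  expect_equal(r2$rms / r$rms, 10, tolerance = 0.5)
})

test_that("morphospace summary is deterministic and order-invariant", {
  set.seed(7)
  a <- data.frame(area = runif(30, 50, 100), perimeter = runif(30, 30, 40))
  b <- data.frame(area = runif(30, 200, 300), perimeter = runif(30, 80, 100))
  st <- rbind(a, b)
  st$circularity <- 4 * pi * st$area / st$perimeter^2
  g <- rep(c("young", "old"), each = 30)
  ms <- morphospace_summary(st, g)
  # single cell: its own values as median
  one <- morphospace_summary(st[1, , drop = FALSE])
  expect_equal(one$summary$median[one$summary$variable == "area"], st$area[1])
  # permuting rows leaves the output identical
  perm <- sample(nrow(st))
  ms2 <- morphospace_summary(st[perm, ], g[perm])
  expect_identical(ms$summary, ms2$summary)
  expect_identical(ms$bins_pa, ms2$bins_pa)
  # two disjoint populations occupy disjoint bins
  occ <- ms$bins_pa[ms$bins_pa$count > 0, ]
  key <- paste(occ$bin_x, occ$bin_y)
  expect_length(intersect(key[occ$group == "young"], key[occ$group == "old"]), 0)
  expect_error(morphospace_summary(st[0, ]), "empty")
})

test_that("label-image statistics agree with the source polygons", {
  nest <- small_nest(4, side = 8, seed = 6)
  lab <- render_label_image(nest, pixel_size = 0.05)
  st_img <- label_stats(lab, pixel_size = 0.05)
  st_msh <- mesh_stats(nest)
  expect_identical(nrow(st_img), nrow(st_msh))
  expect_equal(st_img$area, st_msh$area, tolerance = 0.03)
  expect_equal(st_img$circularity, st_msh$circularity, tolerance = 0.03)
})
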