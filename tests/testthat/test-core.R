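# core: parameter container, mesh validation, serialization

test_that("sim_params defaults reproduce the published parameter table exactly", {
  p <- sim_params()
  expect_identical(p$th_sub, 1)
  expect_identical(p$k_b, 0.2)
  expect_identical(p$k_bend, 0.0005)
  expect_identical(p$k_connect, 0.1)
  expect_identical(abs(p$g_axis), 0.6)
  expect_identical(p$shrink_axis, "x")
  expect_identical(p$g_b, 1.0)
  expect_identical(p$dt, 0.005)
  expect_identical(p$k_foundation, 0.1)
  expect_identical(p$dt_foundation, 0.01)
})

test_that("sim_params rejects invalid values", {
  expect_error(sim_params(th_sub = 0), "th_sub")
  expect_error(sim_params(dt = -1), "dt")
  expect_error(sim_params(dt_foundation = 1.5), "dt_foundation")
  expect_error(sim_params(length_factor = 0.5), "length_factor")
  expect_error(sim_params(k_b = -1), "stiffness")
})

test_that("params round-trip through JSON and unknown fields error", {
  path <- withr::local_tempfile(fileext = ".json")
  p <- sim_params(k_bend = 0.002, seed = 7L)
  write_params(p, path)
  q <- read_params(path)
  expect_equal(q[names(q)], p[names(p)])
  writeLines('{"not_a_field": 1}', path)
  expect_error(read_params(path), "unknown config field")
})

test_that("validate_mesh returns no violations for a fresh cell grid", {
  m <- small_nest(16, side = 16, seed = 0)
  expect_identical(validate_mesh(m), character(0))
})

test_that("validate_mesh names the offending entity and never raises", {
  m <- small_nest(4)
  m$rest_len[3] <- 0
  v <- validate_mesh(m)
  expect_length(v, 1)
  expect_match(v, "edge #3")

  # self-intersecting face (bow-tie), oracle: segment-pair crossing
  bow <- tissue_mesh(pos = rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1)),
                     edges = rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L)),
                     faces = list(1:4), fixed = rep(TRUE, 4))
  v <- validate_mesh(bow)
  expect_true(any(grepl("face 1 is self-intersecting", v)))

  # missing foundation anchor
  m2 <- small_nest(4)
  m2$foundation[which(!m2$fixed)[1], 1] <- NA
  expect_true(any(grepl("foundation", validate_mesh(m2))))
})

test_that("mesh write/read round trip is lossless, including an empty mesh", {
  path <- withr::local_tempfile(fileext = ".txt")
  m <- small_nest(4, seed = 5)
  write_mesh(m, path)
  m2 <- read_mesh(path)
  expect_identical(m2$pos, unname(m$pos))
  expect_identical(m2$foundation, unname(m$foundation))
  expect_identical(m2$edges, unname(m$edges))
  expect_identical(m2$rest_len, unname(m$rest_len))
  expect_identical(m2$rest_angle, unname(m$rest_angle))
  expect_identical(m2$fixed, unname(m$fixed))
  expect_identical(lapply(m2$faces, as.integer), lapply(m$faces, as.integer))

  empty <- tissue_mesh(pos = matrix(numeric(0), ncol = 2),
                       edges = matrix(integer(0), ncol = 2))
  write_mesh(empty, path)
  e2 <- read_mesh(path)
  expect_identical(nrow(e2$pos), 0L)
  expect_identical(nrow(e2$edges), 0L)
  expect_identical(length(e2$faces), 0L)
})

test_that("malformed mesh files produce parse errors naming line and field", {
  path <- withr::local_tempfile(fileext = ".txt")
  m <- small_nest(1)
  write_mesh(m, path)
  lines <- readLines(path)
  # remove the rest_length column from the EDGES header
  k <- grep("^i j rest_length$", lines)
  lines[k] <- "i j"
  writeLines(lines, path)
  expect_error(read_mesh(path), "rest_length")
  expect_error(read_mesh(path), "line")
  writeLines("not a mesh", path)
  expect_error(read_mesh(path), "line 1")
  expect_error(read_mesh(file.path(tempdir(), "nope.txt")), "not found")
})
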