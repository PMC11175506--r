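#' Tissue mesh: spring-chain representation of cell boundaries
#'
#' A `tissue_mesh` holds the state of the 2-D junction network: vertex
#' positions, elastic-foundation anchor positions, boundary edges with rest
#' lengths, per-vertex rest angles, ordered cell faces and a fixed-vertex mask
#' (Dirichlet template boundary).
#'
#' @param pos n x 2 numeric matrix of vertex positions (um).
#' @param edges m x 2 integer matrix of boundary springs (vertex index pairs).
#' @param rest_len Length-m rest lengths; defaults to current edge lengths.
#' @param faces List of integer vertex loops, one per cell, wound
#'   counter-clockwise.
#' @param fixed Logical length-n mask of vertices with prescribed positions.
#' @param foundation n x 2 anchor positions; defaults to `pos`.
#' @param rest_angle Length-n rest angles (radians); defaults to `2*pi/n_i`
#'   where `n_i` is the number of boundary neighbours of vertex i (`NA` for
#'   vertices with fewer than 2 neighbours).
#' @return An object of class `tissue_mesh`.
#' @export
tissue_mesh <- function(pos, edges, rest_len = NULL, faces = list(),
                        fixed = NULL, foundation = NULL, rest_angle = NULL) {
  pos <- matrix(as.numeric(pos), ncol = 2)
  n <- nrow(pos)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (is.null(fixed)) fixed <- rep(FALSE, n)
  if (is.null(foundation)) foundation <- pos
  foundation <- matrix(as.numeric(foundation), ncol = 2)
  m <- list(pos = pos, foundation = foundation, fixed = as.logical(fixed),
            edges = edges, rest_len = NULL, faces = faces,
            rest_angle = NULL, angles = NULL)
  class(m) <- "tissue_mesh"
  m$rest_len <- if (is.null(rest_len)) edge_lengths(m) else as.numeric(rest_len)
  deg <- vertex_degree(m)
  m$rest_angle <- if (is.null(rest_angle)) {
    ifelse(deg >= 2, 2 * pi / deg, NA_real_)
  } else as.numeric(rest_angle)
  # faces stored counter-clockwise
  m$faces <- lapply(faces, function(f) {
    f <- as.integer(f)
    if (length(f) >= 3 && polygon_area_signed(pos[f, , drop = FALSE]) < 0) rev(f) else f
  })
  m
}

#' @export
print.tissue_mesh <- function(x, ...) {
  cat(sprintf("<tissue_mesh> %d vertices (%d fixed), %d edges, %d faces\n",
              nrow(x$pos), sum(x$fixed), nrow(x$edges), length(x$faces)))
  invisible(x)
}

#' Current edge lengths
#' @param mesh A `tissue_mesh`.
#' @param pos Optional alternative position matrix.
#' @return Numeric vector of Euclidean edge lengths.
#' @export
edge_lengths <- function(mesh, pos = mesh$pos) {
  d <- pos[mesh$edges[, 1], , drop = FALSE] - pos[mesh$edges[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

vertex_degree <- function(mesh) {
  tabulate(c(mesh$edges[, 1], mesh$edges[, 2]), nbins = nrow(mesh$pos))
}

# Adjacency list: neighbours of each vertex along boundary edges.
adjacency_list <- function(mesh) {
  n <- nrow(mesh$pos)
  out <- vector("list", n)
  if (nrow(mesh$edges) == 0) return(lapply(out, function(x) integer(0)))
  i <- c(mesh$edges[, 1], mesh$edges[, 2])
  j <- c(mesh$edges[, 2], mesh$edges[, 1])
  sp <- split(j, factor(i, levels = seq_len(n)))
  lapply(sp, as.integer)
}

# Angular-spring table: one row per spring, columns (i, j, k) meaning the
# angle at j measured counter-clockwise from ray j->i to ray j->k, with rest
# angle `rest`. At free 2-neighbour vertices there is one spring (rest pi by
# the 2*pi/n rule). With junction_bending, free vertices of degree >= 3 get
# one spring per incident wedge (neighbours sorted by azimuth), rest
# 2*pi/degree. No spring is centred on a fixed vertex: the template frame is
# a rigid Dirichlet boundary and exerts no bending moment of its own.
build_angle_table <- function(mesh, junction_bending = FALSE) {
  adj <- adjacency_list(mesh)
  deg <- lengths(adj)
  rows_i <- integer(0); rows_j <- integer(0); rows_k <- integer(0); rest <- numeric(0)
  chain <- which(deg == 2 & !mesh$fixed)
  if (length(chain)) {
    ni <- vapply(adj[chain], `[`, integer(1), 1L)
    nk <- vapply(adj[chain], `[`, integer(1), 2L)
    rows_i <- c(rows_i, ni); rows_j <- c(rows_j, chain); rows_k <- c(rows_k, nk)
    rest <- c(rest, mesh$rest_angle[chain])
  }
  if (junction_bending) {
    for (v in which(deg >= 3 & !mesh$fixed)) {
      nb <- adj[[v]]
      az <- atan2(mesh$pos[nb, 2] - mesh$pos[v, 2], mesh$pos[nb, 1] - mesh$pos[v, 1])
      nb <- nb[order(az)]
      d <- length(nb)
      nxt <- nb[c(2:d, 1)]
      rows_i <- c(rows_i, nb); rows_j <- c(rows_j, rep.int(v, d)); rows_k <- c(rows_k, nxt)
      rest <- c(rest, rep.int(2 * pi / d, d))
    }
  }
  list(triples = cbind(i = rows_i, j = rows_j, k = rows_k), rest = rest)
}

ensure_angles <- function(mesh, params) {
  jb <- isTRUE(params$junction_bending)
  if (is.null(mesh$angles) || !identical(attr(mesh$angles, "junction_bending"), jb)) {
    mesh$angles <- build_angle_table(mesh, jb)
    attr(mesh$angles, "junction_bending") <- jb
  }
  mesh
}

#' Validate a tissue mesh
#'
#' Checks the structural invariants of a `tissue_mesh` and returns a
#' character vector describing every violation (empty when the mesh is
#' well formed). Validation never raises.
#'
#' Invariants checked: every edge has a positive rest length; every face is a
#' simple closed polygon with at least 3 vertices; every non-fixed vertex has
#' a finite foundation anchor; non-fixed vertices have 2 (interior) or 3
#' (junction) boundary neighbours; edge indices are in range.
#'
#' @param mesh A `tissue_mesh`.
#' @return Character vector of violation descriptions, each naming the
#'   offending entity.
#' @export
validate_mesh <- function(mesh) {
  v <- character(0)
  n <- nrow(mesh$pos)
  e <- mesh$edges
  if (nrow(e)) {
    oob <- which(e[, 1] < 1 | e[, 1] > n | e[, 2] < 1 | e[, 2] > n)
    for (k in oob) v <- c(v, sprintf("edge #%d has out-of-range vertex index", k))
    bad <- which(!(mesh$rest_len > 0))
    for (k in bad)
      v <- c(v, sprintf("edge #%d (%d-%d) has non-positive rest length %g",
                        k, e[k, 1], e[k, 2], mesh$rest_len[k]))
  }
  if (length(mesh$rest_len) != nrow(e))
    v <- c(v, "rest_len length does not match the number of edges")
  if (nrow(mesh$foundation) != n) {
    v <- c(v, "foundation matrix does not have one row per vertex")
  } else if (n > 0) {
    bad <- which(!mesh$fixed & !is.finite(rowSums(mesh$foundation)))
    for (k in bad) v <- c(v, sprintf("non-fixed vertex %d lacks a finite foundation position", k))
  }
  for (fi in seq_along(mesh$faces)) {
    f <- mesh$faces[[fi]]
    if (length(f) < 3) {
      v <- c(v, sprintf("face %d has fewer than 3 vertices", fi))
    } else if (!polygon_is_simple(mesh$pos[f, , drop = FALSE])) {
      v <- c(v, sprintf("face %d is self-intersecting", fi))
    }
  }
  if (n > 0 && nrow(e)) {
    deg <- vertex_degree(mesh)
    bad <- which(!mesh$fixed & (deg < 2 | deg > 3))
    for (k in bad)
      v <- c(v, sprintf("non-fixed vertex %d has %d boundary neighbours (expected 2 or 3)",
                        k, deg[k]))
  }
  v
}

#' Read and write the plain-text mesh format
#'
#' The format is a diffable sectioned text file:
#' \preformatted{
#' EPIBUCKLE-MESH 1
#' VERTICES <n>
#' x y fixed fx fy
#' <n rows>
#' EDGES <m>
#' i j rest_length
#' <m rows>
#' ANGLES <n>
#' i rest_angle
#' <n rows>
#' FACES <f>
#' <f rows: v1 v2 ... vk>
#' }
#' Coordinates are written with 17 significant digits so a write/read round
#' trip is lossless.
#'
#' @param mesh A `tissue_mesh`.
#' @param path File path.
#' @return `read_mesh` returns a `tissue_mesh`; `write_mesh` returns `path`
#'   invisibly.
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$pos)
  fmt <- function(x) sprintf("%.17g", x)
  writeLines("EPIBUCKLE-MESH 1", con)
  writeLines(sprintf("VERTICES %d", n), con)
  writeLines("x y fixed fx fy", con)
  if (n) writeLines(paste(fmt(mesh$pos[, 1]), fmt(mesh$pos[, 2]),
                          as.integer(mesh$fixed),
                          fmt(mesh$foundation[, 1]), fmt(mesh$foundation[, 2])), con)
  m <- nrow(mesh$edges)
  writeLines(sprintf("EDGES %d", m), con)
  writeLines("i j rest_length", con)
  if (m) writeLines(paste(mesh$edges[, 1], mesh$edges[, 2], fmt(mesh$rest_len)), con)
  writeLines(sprintf("ANGLES %d", n), con)
  writeLines("i rest_angle", con)
  if (n) writeLines(paste(seq_len(n), fmt(mesh$rest_angle)), con)
  writeLines(sprintf("FACES %d", length(mesh$faces)), con)
  for (f in mesh$faces) writeLines(paste(f, collapse = " "), con)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  ln <- 0L
  nextline <- function() {
    ln <<- ln + 1L
    if (ln > length(lines)) stop("unexpected end of mesh file at line ", ln, call. = FALSE)
    lines[[ln]]
  }
  hdr <- nextline()
  if (!startsWith(hdr, "EPIBUCKLE-MESH"))
    stop("line 1: not an epibuckle mesh file", call. = FALSE)
  expect_section <- function(name) {
    l <- nextline()
    parts <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(parts) != 2 || parts[1] != name || is.na(suppressWarnings(as.integer(parts[2]))))
      stop(sprintf("line %d: expected '%s <count>', got '%s'", ln, name, l), call. = FALSE)
    as.integer(parts[2])
  }
  read_rows <- function(count, ncols, section, colnames_line) {
    hdr <- nextline()
    got <- strsplit(trimws(hdr), "\\s+")[[1]]
    want <- strsplit(colnames_line, " ")[[1]]
    if (!identical(got, want))
      stop(sprintf("line %d: %s section missing column(s): expected '%s'",
                   ln, section, colnames_line), call. = FALSE)
    out <- matrix(NA_real_, nrow = count, ncol = ncols)
    for (r in seq_len(count)) {
      parts <- suppressWarnings(as.numeric(strsplit(trimws(nextline()), "\\s+")[[1]]))
      if (length(parts) != ncols || anyNA(parts))
        stop(sprintf("line %d: %s row %d: expected %d numeric fields",
                     ln, section, r, ncols), call. = FALSE)
      out[r, ] <- parts
    }
    out
  }
  n <- expect_section("VERTICES")
  vr <- read_rows(n, 5, "VERTICES", "x y fixed fx fy")
  m <- expect_section("EDGES")
  er <- read_rows(m, 3, "EDGES", "i j rest_length")
  na <- expect_section("ANGLES")
  if (na != n) stop(sprintf("line %d: ANGLES count %d != vertex count %d", ln, na, n), call. = FALSE)
  ar <- read_rows(n, 2, "ANGLES", "i rest_angle")
  nf <- expect_section("FACES")
  faces <- vector("list", nf)
  for (r in seq_len(nf)) {
    parts <- suppressWarnings(as.integer(strsplit(trimws(nextline()), "\\s+")[[1]]))
    if (!length(parts) || anyNA(parts))
      stop(sprintf("line %d: FACES row %d: expected integer vertex ids", ln, r), call. = FALSE)
    faces[[r]] <- parts
  }
  rest_angle <- rep(NA_real_, n)
  if (n) rest_angle[as.integer(ar[, 1])] <- ar[, 2]
  tissue_mesh(
    pos = vr[, 1:2, drop = FALSE],
    edges = if (m) er[, 1:2, drop = FALSE] else matrix(integer(0), ncol = 2),
    rest_len = if (m) er[, 3] else numeric(0),
    faces = faces,
    fixed = if (n) vr[, 3] != 0 else logical(0),
    foundation = vr[, 4:5, drop = FALSE],
    rest_angle = rest_angle
  )
}
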