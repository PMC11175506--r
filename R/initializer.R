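# Construction of the initial polygonal cell nest and its unstressed rest state.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build an initial polygonal cell nest by successive shortest-wall division
#'
#' Starting from a single rectangular cell, the largest cell is repeatedly
#' divided by the shortest wall passing through its centroid (candidate
#' orientations scanned at 1 degree resolution with a small seed-controlled
#' jitter; ties broken by the lowest angle) until `n_cells` faces tile the
#' rectangle. Each new wall is "pinched": its attachment points are displaced
#' toward each other along the wall by `pinch_fraction` of the wall length,
#' shortening the new wall and kinking the parent boundary, as freshly divided
#' cells do. Attachment points on the fixed outer rectangle are not displaced,
#' so the faces always tile the full rectangle exactly.
#'
#' @param width,height Template dimensions (um).
#' @param n_cells Number of cells to create (>= 1).
#' @param pinch_fraction Fraction of the wall length by which each attachment
#'   point is pulled inward, in `[0, 0.5)`.
#' @param seed Integer seed for the orientation jitter.
#' @return A `tissue_mesh` whose outer-rectangle vertices are fixed. Rest
#'   lengths/angles are set from the current geometry (see
#'   [init_rest_state()], which is still run after [subdivide_long_edges()]
#'   in the standard pipeline).
#' @export
make_cell_grid <- function(width, height, n_cells, pinch_fraction = 0.1, seed = 1L) {
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (pinch_fraction < 0 || pinch_fraction >= 0.5)
    stop("pinch_fraction must lie in [0, 0.5)", call. = FALSE)
  verts <- matrix(c(0, 0, width, 0, width, height, 0, height),
                  ncol = 2, byrow = TRUE)
  faces <- list(c(1L, 2L, 3L, 4L))
  eps <- 1e-9

  on_outer <- function(p) {
    abs(p[1]) < eps || abs(p[1] - width) < eps ||
      abs(p[2]) < eps || abs(p[2] - height) < eps
  }

  # insert pt on segment (a, b) of every face containing it; returns id and
  # whether an existing vertex was reused
  insert_point <- function(a, b, pt) {
    if (sqrt(sum((verts[a, ] - pt)^2)) < 1e-7) return(list(id = a, reused = TRUE))
    if (sqrt(sum((verts[b, ] - pt)^2)) < 1e-7) return(list(id = b, reused = TRUE))
    verts <<- rbind(verts, pt)
    id <- nrow(verts)
    for (fi in seq_along(faces)) {
      f <- faces[[fi]]
      k <- length(f)
      nxt <- c(f[-1], f[1])
      hit <- which((f == a & nxt == b) | (f == b & nxt == a))
      if (length(hit)) {
        h <- hit[1]
        faces[[fi]] <<- append(f, id, after = h)
      }
    }
    list(id = id, reused = FALSE)
  }

  chord_at <- function(loop, cen, phi) {
    d <- c(cos(phi), sin(phi))
    k <- length(loop)
    p <- verts[loop, , drop = FALSE]
    q <- verts[c(loop[-1], loop[1]), , drop = FALSE]
    ex <- q[, 1] - p[, 1]; ey <- q[, 2] - p[, 2]
    den <- d[1] * (-ey) - d[2] * (-ex)
    rx <- p[, 1] - cen[1]; ry <- p[, 2] - cen[2]
    t <- (rx * (-ey) - ry * (-ex)) / den
    u <- (d[1] * ry - d[2] * rx) / den
    ok <- is.finite(t) & is.finite(u) & u >= -1e-12 & u < 1 - 1e-12
    tn <- t[ok & t < -1e-9]; tp <- t[ok & t > 1e-9]
    if (!length(tn) || !length(tp)) return(NULL)
    t1 <- max(tn); t2 <- min(tp)
    s1 <- which(ok & t == t1)[1]; s2 <- which(ok & t == t2)[1]
    list(len = t2 - t1,
         p1 = cen + t1 * d, seg1 = s1,
         p2 = cen + t2 * d, seg2 = s2)
  }

  with_seed(seed, {
    while (length(faces) < n_cells) {
      areas <- vapply(faces, function(f) abs(polygon_area_signed(verts[f, , drop = FALSE])),
                      numeric(1))
      fi <- which.max(areas)
      loop <- faces[[fi]]
      cen <- polygon_centroid(verts[loop, , drop = FALSE])
      jitter <- stats::runif(1, -0.5, 0.5) * pi / 180
      best <- NULL; best_len <- Inf
      for (deg in 0:179) {
        ch <- chord_at(loop, cen, deg * pi / 180 + jitter)
        if (!is.null(ch) && ch$len < best_len - 1e-12) {
          best <- ch; best_len <- ch$len
        }
      }
      if (is.null(best)) stop("no dividing wall found for face ", fi, call. = FALSE)
      k <- length(loop)
      nxt <- c(loop[-1], loop[1])
      a1 <- loop[best$seg1]; b1 <- nxt[best$seg1]
      a2 <- loop[best$seg2]; b2 <- nxt[best$seg2]
      r1 <- insert_point(a1, b1, best$p1)
      r2 <- insert_point(a2, b2, best$p2)
      if (r1$id == r2$id) stop("degenerate dividing wall in face ", fi, call. = FALSE)
      # pinch: pull attachment points toward each other along the wall
      wall <- verts[r2$id, ] - verts[r1$id, ]
      wl <- sqrt(sum(wall^2))
      if (pinch_fraction > 0 && wl > 0) {
        u <- wall / wl
        if (!r1$reused && !on_outer(verts[r1$id, ]))
          verts[r1$id, ] <- verts[r1$id, ] + pinch_fraction * wl * u
        if (!r2$reused && !on_outer(verts[r2$id, ]))
          verts[r2$id, ] <- verts[r2$id, ] - pinch_fraction * wl * u
      }
      # split the dividing face along the new wall
      f <- faces[[fi]]
      i1 <- match(r1$id, f); i2 <- match(r2$id, f)
      if (is.na(i1) || is.na(i2)) stop("internal error: wall endpoint missing from face loop")
      cyc <- function(from, to) {
        if (from <= to) f[from:to] else c(f[from:length(f)], f[1:to])
      }
      loop1 <- cyc(i1, i2); loop2 <- cyc(i2, i1)
      if (length(loop1) < 3 || length(loop2) < 3)
        stop("degenerate division of face ", fi, call. = FALSE)
      faces[[fi]] <- loop1
      faces[[length(faces) + 1]] <- loop2
    }
  })

  # collect unique edges from the face loops
  ekeys <- character(0); ei <- integer(0); ej <- integer(0)
  for (f in faces) {
    nxt <- c(f[-1], f[1])
    for (s in seq_along(f)) {
      a <- min(f[s], nxt[s]); b <- max(f[s], nxt[s])
      key <- paste(a, b)
      if (!(key %in% ekeys)) {
        ekeys <- c(ekeys, key); ei <- c(ei, a); ej <- c(ej, b)
      }
    }
  }
  fixed <- vapply(seq_len(nrow(verts)), function(i) on_outer(verts[i, ]), logical(1))
  tissue_mesh(pos = verts, edges = cbind(ei, ej), faces = faces, fixed = fixed)
}

#' Subdivide boundary segments longer than a threshold
#'
#' Every edge whose current length or rest length exceeds `th_sub` is split
#' at its midpoint; the parent's rest length is halved onto the two children,
#' the new 2-neighbour vertex receives rest angle `pi` (the `2*pi/n` rule)
#' and a foundation anchor at its creation position, and faces are updated
#' consistently. Passes repeat until every edge is at most `th_sub` by both
#' measures, so a second application is a no-op.
#'
#' The rest length is the material coordinate that growth inflates, so
#' triggering on it keeps the discretisation uniform in material length even
#' when the wall is deeply compressed (current lengths well below `th_sub`).
#' Without this, the buckling wavelength falls to the lattice scale in the
#' jammed regime and hairpin folds can self-cross inside the
#' neighbour-of-neighbour exclusion zone of the penalty connections.
#'
#' @param mesh A `tissue_mesh`.
#' @param th_sub Length threshold (um).
#' @return The subdivided `tissue_mesh`.
#' @export
subdivide_long_edges <- function(mesh, th_sub) {
  stopifnot(th_sub > 0)
  repeat {
    len <- pmax(edge_lengths(mesh), mesh$rest_len)
    long <- which(len > th_sub * (1 + 1e-12))
    if (!length(long)) break
    n0 <- nrow(mesh$pos)
    li <- mesh$edges[long, 1]; lj <- mesh$edges[long, 2]
    mid <- (mesh$pos[li, , drop = FALSE] + mesh$pos[lj, , drop = FALSE]) / 2
    ids <- n0 + seq_along(long)
    key <- paste(pmin(li, lj), pmax(li, lj))
    mid_of <- stats::setNames(ids, key)
    mesh$pos <- rbind(mesh$pos, mid)
    mesh$foundation <- rbind(mesh$foundation, mid)
    mesh$fixed <- c(mesh$fixed, mesh$fixed[li] & mesh$fixed[lj])
    mesh$rest_angle <- c(mesh$rest_angle, rep(pi, length(long)))
    half <- mesh$rest_len[long] / 2
    keep <- setdiff(seq_len(nrow(mesh$edges)), long)
    mesh$edges <- rbind(mesh$edges[keep, , drop = FALSE],
                        cbind(li, ids), cbind(ids, lj))
    mesh$rest_len <- c(mesh$rest_len[keep], half, half)
    mesh$faces <- lapply(mesh$faces, function(f) {
      nxt <- c(f[-1], f[1])
      kf <- paste(pmin(f, nxt), pmax(f, nxt))
      ins <- mid_of[kf]
      hit <- !is.na(ins)
      if (!any(hit)) return(f)
      out <- integer(0)
      for (s in seq_along(f)) {
        out <- c(out, f[s])
        if (hit[s]) out <- c(out, as.integer(ins[s]))
      }
      out
    })
    mesh$angles <- NULL
  }
  mesh
}

#' Initialise the unstressed rest state
#'
#' Sets every edge's rest length to its current length, every vertex's rest
#' angle to `2*pi/n` (`pi` for 2-neighbour chain vertices, `2*pi/3` at
#' tri-junctions), and moves every foundation anchor to the vertex's current
#' position. With the default bending configuration the resulting mesh has
#' exactly zero elastic energy and is at mechanical equilibrium.
#'
#' @param mesh A `tissue_mesh`.
#' @param params A `sim_params` (controls the bending configuration cache).
#' @return The initialised `tissue_mesh`.
#' @export
init_rest_state <- function(mesh, params = sim_params()) {
  deg <- vertex_degree(mesh)
  bad <- which(!mesh$fixed & deg < 2)
  if (length(bad))
    stop("structural error: non-fixed vertex ", bad[1], " has ", deg[bad[1]],
         " boundary neighbour(s)", call. = FALSE)
  mesh$rest_len <- edge_lengths(mesh)
  mesh$rest_angle <- ifelse(deg >= 2, 2 * pi / deg, NA_real_)
  mesh$foundation <- mesh$pos
  mesh$angles <- NULL
  ensure_angles(mesh, params)
}
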