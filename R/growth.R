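# The simulation loop: connection placement -> growth & domain shrinkage ->
# equilibrium -> subdivision -> plastic foundation update.

#' Place transient compression-only penalty connections
#'
#' Connects vertex pairs that are (i) within `length_factor * th_sub` of each
#' other, (ii) at least 3 boundary edges apart topologically (no neighbours or
#' neighbours-of-neighbours), (iii) mutually visible (the connecting segment
#' properly crosses no boundary edge), and (iv) sufficiently transverse to the
#' local boundary: the angle `alpha` between the connection and the boundary
#' tangent (minimum over the boundary edges incident to either endpoint) must
#' exceed `angle_threshold`. Rest lengths are set on the tangent circle of
#' diameter `th_sub`: `rest = th_sub * sin(alpha)`, so a perpendicular
#' connection rests at `th_sub` and grazing ones at ~0. Connections are
#' regenerated every simulation iteration and never persist.
#'
#' @param mesh A `tissue_mesh`.
#' @param params A `sim_params`.
#' @return A `connection_set`: list with `pairs` (c x 2 integer), `rest_len`
#'   and scalar `stiffness`.
#' @export
place_connections <- function(mesh, params = sim_params()) {
  empty <- structure(list(pairs = matrix(integer(0), ncol = 2),
                          rest_len = numeric(0),
                          stiffness = params$k_connect),
                     class = "connection_set")
  n <- nrow(mesh$pos)
  if (n < 2 || nrow(mesh$edges) == 0) return(empty)
  r <- params$length_factor * params$th_sub
  pos <- mesh$pos

  # --- candidate pairs within r via sparse cell-incidence algebra ---------
  origin <- c(min(pos[, 1]), min(pos[, 2])) - r
  gk <- grid_keys(pos, origin, r)
  nx <- max(gk$ix) + 2L
  cell_id <- gk$ix + nx * gk$iy + 1L
  cells <- sort(unique(cell_id))
  cidx <- match(cell_id, cells)
  V <- Matrix::sparseMatrix(i = seq_len(n), j = cidx, x = 1,
                            dims = c(n, length(cells)))
  all_off <- c(-nx - 1L, -nx, -nx + 1L, -1L, 0L, 1L, nx - 1L, nx, nx + 1L)
  nb_i <- integer(0); nb_j <- integer(0)
  for (oi in all_off) {
    m <- match(cells + oi, cells)
    hit <- which(!is.na(m))
    nb_i <- c(nb_i, hit); nb_j <- c(nb_j, m[hit])
  }
  C <- Matrix::sparseMatrix(i = nb_i, j = nb_j, x = 1,
                            dims = c(length(cells), length(cells)))
  P <- Matrix::tril(V %*% C %*% Matrix::t(V), k = -1L)
  S <- methods::as(P, "TsparseMatrix")
  ci <- S@j + 1L; cj <- S@i + 1L              # ci < cj
  if (!length(ci)) return(empty)
  d2 <- (pos[ci, 1] - pos[cj, 1])^2 + (pos[ci, 2] - pos[cj, 2])^2
  keep <- d2 <= r^2 & d2 > 0
  ci <- ci[keep]; cj <- cj[keep]
  if (!length(ci)) return(empty)

  # --- exclude pairs at topological distance <= 2 -----------------------
  A <- Matrix::sparseMatrix(i = c(mesh$edges[, 1], mesh$edges[, 2]),
                            j = c(mesh$edges[, 2], mesh$edges[, 1]),
                            x = 1, dims = c(n, n))
  near <- (A + A %*% A)[cbind(ci, cj)] > 0
  ci <- ci[!near]; cj <- cj[!near]
  if (!length(ci)) return(empty)

  # --- visibility: no proper crossing with any boundary edge ------------
  E <- mesh$edges
  # bin each edge into every grid cell its bounding box covers (edges can be
  # longer than a cell)
  ex1 <- pmin(pos[E[, 1], 1], pos[E[, 2], 1]); ex2 <- pmax(pos[E[, 1], 1], pos[E[, 2], 1])
  ey1 <- pmin(pos[E[, 1], 2], pos[E[, 2], 2]); ey2 <- pmax(pos[E[, 1], 2], pos[E[, 2], 2])
  bx1 <- as.integer(floor((ex1 - origin[1]) / r)); bx2 <- as.integer(floor((ex2 - origin[1]) / r))
  by1 <- as.integer(floor((ey1 - origin[2]) / r)); by2 <- as.integer(floor((ey2 - origin[2]) / r))
  nxc <- bx2 - bx1 + 1L; nyc <- by2 - by1 + 1L
  cnts <- nxc * nyc
  eix <- rep(seq_len(nrow(E)), cnts)
  off <- sequence(cnts) - 1L
  ecell <- (bx1[eix] + off %% nxc[eix]) + nx * (by1[eix] + off %/% nxc[eix]) + 1L
  eord <- order(ecell)
  eback <- eix[eord]   # edge id for each binned entry
  ecs <- ecell[eord]
  ucell <- unique(ecs)
  first <- match(ucell, ecs)
  cnt <- diff(c(first, length(ecs) + 1L))
  # a connection is at most length_factor*th_sub = one cell long, so the 3x3
  # neighbourhood of its first endpoint's cell covers the whole segment
  pair_cell <- cell_id[ci]
  pid_l <- vector("list", length(all_off))
  eid_l <- vector("list", length(all_off))
  for (t in seq_along(all_off)) {
    g <- match(pair_cell + all_off[t], ucell)
    hit <- which(!is.na(g))
    if (!length(hit)) next
    gh <- g[hit]
    reps <- cnt[gh]
    pid_l[[t]] <- rep.int(hit, reps)
    eid_l[[t]] <- eback[sequence(reps, from = first[gh])]
  }
  pair_id <- unlist(pid_l, use.names = FALSE)
  edge_id <- unlist(eid_l, use.names = FALSE)
  if (length(pair_id)) {
    # cheap bbox-overlap prefilter before the exact crossing test
    sx1 <- pmin(pos[ci, 1], pos[cj, 1]); sx2 <- pmax(pos[ci, 1], pos[cj, 1])
    sy1 <- pmin(pos[ci, 2], pos[cj, 2]); sy2 <- pmax(pos[ci, 2], pos[cj, 2])
    keep2 <- ex1[edge_id] <= sx2[pair_id] & ex2[edge_id] >= sx1[pair_id] &
      ey1[edge_id] <= sy2[pair_id] & ey2[edge_id] >= sy1[pair_id]
    pair_id <- pair_id[keep2]; edge_id <- edge_id[keep2]
    pi1 <- ci[pair_id]; pi2 <- cj[pair_id]
    ee1 <- E[edge_id, 1]; ee2 <- E[edge_id, 2]
    sh <- pi1 == ee1 | pi1 == ee2 | pi2 == ee1 | pi2 == ee2
    pair_id <- pair_id[!sh]; edge_id <- edge_id[!sh]
    if (length(pair_id)) {
      crossing <- segments_cross_xy(
        pos[ci[pair_id], 1], pos[ci[pair_id], 2],
        pos[cj[pair_id], 1], pos[cj[pair_id], 2],
        pos[E[edge_id, 1], 1], pos[E[edge_id, 1], 2],
        pos[E[edge_id, 2], 1], pos[E[edge_id, 2], 2]
      )
      blocked <- unique(pair_id[crossing])
      if (length(blocked)) {
        ci <- ci[-blocked]; cj <- cj[-blocked]
      }
    }
  }
  if (!length(ci)) return(empty)

  # --- angle to the local boundary tangent (vectorised over neighbours) --
  deg <- tabulate(c(E[, 1], E[, 2]), nbins = n)
  maxdeg <- max(deg)
  nbr <- matrix(NA_integer_, n, maxdeg)
  slot <- integer(n)
  for (k in seq_len(nrow(E))) {
    a <- E[k, 1]; b <- E[k, 2]
    slot[a] <- slot[a] + 1L; nbr[a, slot[a]] <- b
    slot[b] <- slot[b] + 1L; nbr[b, slot[b]] <- a
  }
  segx <- pos[cj, 1] - pos[ci, 1]; segy <- pos[cj, 2] - pos[ci, 2]
  segl <- sqrt(segx^2 + segy^2)
  sinmin <- rep(1, length(ci))
  for (side in list(ci, cj)) {
    for (d in seq_len(maxdeg)) {
      nb <- nbr[side, d]
      ok <- !is.na(nb)
      if (!any(ok)) next
      evx <- pos[nb[ok], 1] - pos[side[ok], 1]
      evy <- pos[nb[ok], 2] - pos[side[ok], 2]
      el <- sqrt(evx^2 + evy^2)
      s <- abs(segx[ok] * evy - segy[ok] * evx) / (segl[ok] * el)
      sinmin[ok] <- pmin(sinmin[ok], pmin(1, s))
    }
  }
  alpha <- asin(sinmin)
  keep <- alpha > params$angle_threshold
  structure(list(pairs = cbind(ci[keep], cj[keep]),
                 rest_len = params$th_sub * sin(alpha[keep]),
                 stiffness = params$k_connect),
            class = "connection_set")
}

#' @export
print.connection_set <- function(x, ...) {
  cat(sprintf("<connection_set> %d compression-only pairs, k = %g\n",
              nrow(x$pairs), x$stiffness))
  invisible(x)
}

#' Grow boundary rest lengths by one time step
#'
#' Multiplies every boundary rest length by `(1 + dt * g_b)`, the discrete
#' form of exponential junction growth. Connection rest lengths are untouched
#' (connections are regenerated each iteration anyway).
#'
#' @param mesh A `tissue_mesh`.
#' @param params A `sim_params`.
#' @return The grown `tissue_mesh`.
#' @export
grow_rest_lengths <- function(mesh, params = sim_params()) {
  mesh$rest_len <- mesh$rest_len * (1 + params$dt * params$g_b)
  mesh
}

#' Shrink the simulation domain by one time step
#'
#' Scales all vertex positions (fixed ones included) and all foundation
#' anchors by `(1 + g_axis * dt)` along `shrink_axis`, about the centre of the
#' template frame (the bounding box of the fixed vertices); the other axis is
#' untouched.
#'
#' @param mesh A `tissue_mesh`.
#' @param params A `sim_params`.
#' @return The rescaled `tissue_mesh`.
#' @export
shrink_domain <- function(mesh, params = sim_params()) {
  s <- 1 + params$g_axis * params$dt
  if (abs(params$g_axis * params$dt) >= 1)
    stop("|g_axis * dt| must be < 1", call. = FALSE)
  if (s == 1 || nrow(mesh$pos) == 0) return(mesh)
  ax <- if (params$shrink_axis == "x") 1L else 2L
  ref <- if (any(mesh$fixed)) mesh$pos[mesh$fixed, ax] else mesh$pos[, ax]
  cen <- (min(ref) + max(ref)) / 2
  mesh$pos[, ax] <- cen + (mesh$pos[, ax] - cen) * s
  mesh$foundation[, ax] <- cen + (mesh$foundation[, ax] - cen) * s
  mesh
}

#' Plastic update of the elastic foundation
#'
#' Moves every foundation anchor toward its vertex's current position:
#' `P_foundation <- P_foundation + (P_current - P_foundation) * dt_foundation`.
#' This is the slow stress-dissipating plasticity that stabilises buckled
#' junctions.
#'
#' @param mesh A `tissue_mesh`.
#' @param params A `sim_params`.
#' @return The updated `tissue_mesh`.
#' @export
update_foundation <- function(mesh, params = sim_params()) {
  f <- params$dt_foundation
  mesh$foundation <- mesh$foundation + (mesh$pos - mesh$foundation) * f
  mesh
}

#' One iteration of the simulation loop
#'
#' Executes, in order: [place_connections()], [grow_rest_lengths()] +
#' [shrink_domain()], [solve_equilibrium()], [subdivide_long_edges()],
#' [update_foundation()].
#'
#' @param mesh A `tissue_mesh`.
#' @param params A `sim_params`.
#' @return List with the updated `mesh`, the `connections` used, the solver
#'   `report`, and `log`: a one-row data frame (energy, residual,
#'   n_connections, mean_circularity, template_width, converged).
#' @export
simulation_step <- function(mesh, params = sim_params()) {
  conn <- place_connections(mesh, params)
  mesh <- grow_rest_lengths(mesh, params)
  mesh <- shrink_domain(mesh, params)
  sol <- solve_equilibrium(mesh, conn, params)
  mesh <- sol$mesh
  mesh <- subdivide_long_edges(mesh, params$th_sub)
  mesh <- update_foundation(mesh, params)
  circ <- if (length(mesh$faces)) {
    st <- mesh_stats(mesh, check_simple = FALSE)
    mean(st$circularity, na.rm = TRUE)
  } else NA_real_
  ax <- if (params$shrink_axis == "x") 1L else 2L
  ref <- if (any(mesh$fixed)) mesh$pos[mesh$fixed, ax] else mesh$pos[, ax]
  log <- data.frame(
    energy = sol$report$energy,
    residual = sol$report$residual,
    n_connections = nrow(conn$pairs),
    mean_circularity = circ,
    template_width = diff(range(ref)),
    converged = sol$report$converged
  )
  list(mesh = mesh, connections = conn, report = sol$report, log = log)
}

#' Run a full growth-and-buckling simulation
#'
#' Repeats [simulation_step()] for `steps` iterations. Template shrinkage is
#' switched off once the template width along the shrink axis falls to
#' `shrink_stop_frac` of its initial value; junction growth continues
#' throughout. The run is deterministic: given the same initial mesh and
#' parameters the log is bit-identical.
#'
#' The default of 150 steps spans the observed morphological transition: at
#' the default rates it grows the junctional rest length about 2.1-fold
#' (measured junctional material grows ~1.7-fold over the transition) and
#' takes mean cell circularity from ~0.8 to ~0.2, the published endpoint.
#' Much longer runs push the model far outside this regime (500 steps grow
#' junctions 12-fold) where the compression-only penalty springs are
#' eventually overwhelmed and walls begin to interpenetrate.
#'
#' @param mesh Initial `tissue_mesh`; if `NULL`, a default 16-cell nest is
#'   built with [make_cell_grid()] (55 x 55 um template, seed from `params`),
#'   subdivided and rest-initialised.
#' @param params A `sim_params`.
#' @param steps Number of iterations (0 returns the initial mesh only).
#' @param snapshot_every Snapshot cadence (also snapshots the final state).
#' @param out_dir Optional directory: per-step CSV log, snapshot mesh files
#'   and final-state morphometrics are written there.
#' @param shrink_stop_frac Stop-shrinking threshold (fraction of initial
#'   template width).
#' @return List with `mesh` (final), `log` (per-step data frame), `snapshots`
#'   (named list of meshes, including step 0), and `initial_width`.
#' @export
run_simulation <- function(mesh = NULL, params = sim_params(), steps = 150,
                           snapshot_every = 50, out_dir = NULL,
                           shrink_stop_frac = 0.4) {
  if (is.null(mesh)) {
    mesh <- make_cell_grid(55, 55, 16, seed = params$seed)
    mesh <- subdivide_long_edges(mesh, params$th_sub)
    mesh <- init_rest_state(mesh, params)
  }
  ax <- if (params$shrink_axis == "x") 1L else 2L
  ref <- if (any(mesh$fixed)) mesh$pos[mesh$fixed, ax] else mesh$pos[, ax]
  w0 <- diff(range(ref))
  snapshots <- list("0" = mesh)
  logs <- vector("list", steps)
  p <- params
  for (s in seq_len(steps)) {
    ref <- if (any(mesh$fixed)) mesh$pos[mesh$fixed, ax] else mesh$pos[, ax]
    if (diff(range(ref)) <= shrink_stop_frac * w0) p$g_axis <- 0
    st <- simulation_step(mesh, p)
    mesh <- st$mesh
    logs[[s]] <- cbind(step = s, st$log)
    if (snapshot_every > 0 && (s %% snapshot_every == 0 || s == steps))
      snapshots[[as.character(s)]] <- mesh
  }
  log <- if (steps) do.call(rbind, logs) else
    data.frame(step = integer(0), energy = numeric(0), residual = numeric(0),
               n_connections = integer(0), mean_circularity = numeric(0),
               template_width = numeric(0), converged = logical(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(log, file.path(out_dir, "run_log.csv"), row.names = FALSE)
    for (nm in names(snapshots))
      write_mesh(snapshots[[nm]], file.path(out_dir, sprintf("snapshot_%s.txt", nm)))
    if (length(mesh$faces))
      utils::write.csv(mesh_stats(mesh), file.path(out_dir, "final_stats.csv"),
                       row.names = FALSE)
  }
  list(mesh = mesh, log = log, snapshots = snapshots, initial_width = w0)
}
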