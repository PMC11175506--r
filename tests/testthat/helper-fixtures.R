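# Shared fixtures and oracles, all built in code.

default_params <- function(...) {
  p <- sim_params()
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}

# small rest-initialised nest
small_nest <- function(n_cells = 4, side = 10, seed = 2, params = sim_params()) {
  m <- make_cell_grid(side, side, n_cells, seed = seed)
  m <- subdivide_long_edges(m, params$th_sub)
  init_rest_state(m, params)
}

# two parallel horizontal chains at a vertical gap, ends fixed
parallel_chains <- function(gap, len = 10, spacing = 1) {
  x <- seq(0, len, by = spacing)
  n <- length(x)
  pos <- rbind(cbind(x, 0), cbind(x, gap))
  edges <- rbind(cbind(1:(n - 1), 2:n), cbind(n + 1:(n - 1), n + 2:n))
  tissue_mesh(pos, edges, fixed = rep(c(TRUE, rep(FALSE, n - 2), TRUE), 2))
}

# central-difference gradient of the total energy (the independent oracle
# for the force laws)
numeric_gradient <- function(mesh, connections, params, h = 1e-6) {
  mesh <- epibuckle:::ensure_angles(mesh, params)
  G <- matrix(0, nrow(mesh$pos), 2)
  for (v in seq_len(nrow(mesh$pos))) {
    for (cc in 1:2) {
      mp <- mesh; mp$pos[v, cc] <- mp$pos[v, cc] + h
      mm <- mesh; mm$pos[v, cc] <- mm$pos[v, cc] - h
      ep <- epibuckle:::energy_grad(mp, connections, params, want_grad = FALSE)$energy
      em <- epibuckle:::energy_grad(mm, connections, params, want_grad = FALSE)$energy
      G[v, cc] <- (ep - em) / (2 * h)
    }
  }
  G
}

# random star-shaped (hence simple) polygon
random_simple_polygon <- function(k, seed) {
  set.seed(seed)
  th <- sort(runif(k, 0, 2 * pi))
  r <- runif(k, 0.2, 1)
  cbind(r * cos(th), r * sin(th))
}

# proper boundary-crossing count over all non-adjacent edge pairs
count_boundary_crossings <- function(mesh) {
  E <- mesh$edges
  pos <- mesh$pos
  cr <- 0L
  for (k in seq_len(nrow(E) - 1)) {
    js <- (k + 1):nrow(E)
    shared <- E[js, 1] %in% E[k, ] | E[js, 2] %in% E[k, ]
    js <- js[!shared]
    if (!length(js)) next
    hit <- epibuckle:::segments_cross(
      pos[rep(E[k, 1], length(js)), , drop = FALSE],
      pos[rep(E[k, 2], length(js)), , drop = FALSE],
      pos[E[js, 1], , drop = FALSE], pos[E[js, 2], , drop = FALSE]
    )
    cr <- cr + sum(hit)
  }
  cr
}
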