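# Force laws and quasi-static equilibrium solving.
#
# Energies (forces are exact negative gradients):
#   stretch     E = 1/2 k l_rest (l/l_rest - 1)^2        per edge
#   bending     E = 1/2 k_bend wrap(theta - theta_rest)^2 per angular spring
#   foundation  E = 1/2 k_foundation |P - P_f|^2          per free vertex
#   connection  stretch form with k_connect, active only when l < l_rest

#' Axial spring force of a boundary segment
#'
#' Linear spring in strain: `F = k * (l / l_rest - 1)`. Positive values are
#' tension (the spring pulls its endpoints together), negative compression.
#'
#' @param l Current length (um). Vectorised.
#' @param l_rest Rest length (um), must be positive.
#' @param k Spring stiffness.
#' @return Signed axial force in model force units.
#' @examples
#' edge_force(2, 1, 0.2)  # 0.2
#' @export
edge_force <- function(l, l_rest, k) {
  if (any(l_rest <= 0)) stop("l_rest must be > 0", call. = FALSE)
  k * (l / l_rest - 1)
}

#' Restoring torque of an angular spring
#'
#' @param theta Current angle at the vertex (radians).
#' @param theta_rest Rest angle (radians).
#' @param k_bend Angular stiffness.
#' @return Torque `k_bend * (theta - theta_rest)`.
#' @export
bending_torque <- function(theta, theta_rest, k_bend) {
  k_bend * (theta - theta_rest)
}

#' Elastic-foundation restoring force
#'
#' Hookean in the displacement: `F = k_foundation * (P_foundation - P_current)`,
#' pointing from the vertex toward its anchor. (The stretch law of
#' [edge_force()] is undefined at zero rest length, so the foundation uses the
#' displacement form with unit reference length.)
#'
#' @param p_current,p_foundation Positions, either length-2 vectors or
#'   matching n x 2 matrices.
#' @param k_foundation Foundation stiffness.
#' @return Force vector(s), same shape as the inputs.
#' @export
foundation_force <- function(p_current, p_foundation, k_foundation) {
  k_foundation * (p_foundation - p_current)
}

#' Compression-only connection force
#'
#' Penalty springs across cells resist only compression: for `l < rest_length`
#' the stretch law applies with stiffness `k_connect` (negative = repulsive);
#' for `l >= rest_length` the force is exactly zero.
#'
#' @param l Current pair distance (um). Vectorised.
#' @param rest_length Connection rest length (um).
#' @param k_connect Connection stiffness.
#' @return Signed axial force (0 when slack).
#' @export
connection_force <- function(l, rest_length, k_connect) {
  ifelse(l < rest_length, k_connect * (l / rest_length - 1), 0)
}

# accumulate `w` onto a length-n vector by integer index
acc_index <- function(n, idx, w) {
  out <- numeric(n)
  if (length(idx)) {
    s <- rowsum(w, idx)
    out[as.integer(rownames(s))] <- s
  }
  out
}

# Total elastic energy and its gradient at positions `pos`.
# Returns list(energy, grad [n x 2], parts).
energy_grad <- function(mesh, connections = NULL, params = sim_params(),
                        pos = mesh$pos, want_grad = TRUE) {
  n <- nrow(pos)
  G <- if (want_grad) matrix(0, n, 2) else NULL
  e_stretch <- e_bend <- e_found <- e_conn <- 0

  if (nrow(mesh$edges)) {
    i <- mesh$edges[, 1]; j <- mesh$edges[, 2]
    dx <- pos[i, 1] - pos[j, 1]; dy <- pos[i, 2] - pos[j, 2]
    l <- sqrt(dx^2 + dy^2)
    lr <- mesh$rest_len
    strain <- l / lr - 1
    kv <- ifelse(strain >= 0, params$k_b_tension, params$k_b_compression)
    e_stretch <- sum(0.5 * kv * lr * strain^2)
    if (want_grad) {
      f <- kv * strain / pmax(l, 1e-300)  # dE/dl / l
      ij <- c(i, j)
      G[, 1] <- G[, 1] + acc_index(n, ij, c(f * dx, -f * dx))
      G[, 2] <- G[, 2] + acc_index(n, ij, c(f * dy, -f * dy))
    }
  }

  ang <- mesh$angles
  if (!is.null(ang) && nrow(ang$triples) && params$k_bend > 0) {
    ti <- ang$triples[, 1]; tj <- ang$triples[, 2]; tk <- ang$triples[, 3]
    vix <- pos[ti, 1] - pos[tj, 1]; viy <- pos[ti, 2] - pos[tj, 2]
    vkx <- pos[tk, 1] - pos[tj, 1]; vky <- pos[tk, 2] - pos[tj, 2]
    theta <- (atan2(vky, vkx) - atan2(viy, vix)) %% (2 * pi)
    d <- theta - ang$rest
    d <- atan2(sin(d), cos(d))  # wrap deviation to (-pi, pi]
    e_bend <- sum(0.5 * params$k_bend * d^2)
    if (want_grad) {
      li2 <- vix^2 + viy^2; lk2 <- vkx^2 + vky^2
      # d theta / dK = perp(vk)/|vk|^2 ; d theta / dI = -perp(vi)/|vi|^2
      gkx <- -vky / lk2; gky <- vkx / lk2
      gix <- viy / li2; giy <- -vix / li2
      w <- params$k_bend * d
      tik <- c(tk, ti, tj)
      G[, 1] <- G[, 1] + acc_index(n, tik, c(w * gkx, w * gix, -w * (gkx + gix)))
      G[, 2] <- G[, 2] + acc_index(n, tik, c(w * gky, w * giy, -w * (gky + giy)))
    }
  }

  if (params$k_foundation > 0) {
    free <- !mesh$fixed
    if (any(free)) {
      dxy <- pos[free, , drop = FALSE] - mesh$foundation[free, , drop = FALSE]
      e_found <- 0.5 * params$k_foundation * sum(dxy^2)
      if (want_grad) G[free, ] <- G[free, ] + params$k_foundation * dxy
    }
  }

  if (!is.null(connections) && nrow(connections$pairs)) {
    i <- connections$pairs[, 1]; j <- connections$pairs[, 2]
    dx <- pos[i, 1] - pos[j, 1]; dy <- pos[i, 2] - pos[j, 2]
    l <- sqrt(dx^2 + dy^2)
    lr <- connections$rest_len
    act <- l < lr
    if (any(act)) {
      strain <- l[act] / lr[act] - 1
      e_conn <- sum(0.5 * connections$stiffness * lr[act] * strain^2)
      if (want_grad) {
        f <- connections$stiffness * strain / pmax(l[act], 1e-300)
        ia <- i[act]; ja <- j[act]
        gx <- f * dx[act]; gy <- f * dy[act]
        G[, 1] <- G[, 1] + acc_index(n, ia, gx) - acc_index(n, ja, gx)
        G[, 2] <- G[, 2] + acc_index(n, ia, gy) - acc_index(n, ja, gy)
      }
    }
  }

  list(energy = e_stretch + e_bend + e_found + e_conn,
       grad = G,
       parts = c(stretch = e_stretch, bending = e_bend,
                 foundation = e_found, connection = e_conn))
}

#' Total elastic energy of a mesh
#'
#' Sum of stretch, bending, foundation and active connection energies; all
#' force laws in the package are exact negative gradients of this quantity.
#'
#' @param mesh A `tissue_mesh`.
#' @param connections Optional `connection_set` from [place_connections()].
#' @param params A `sim_params`.
#' @return Scalar energy with a `parts` attribute (named energy breakdown).
#' @export
total_energy <- function(mesh, connections = NULL, params = sim_params()) {
  mesh <- ensure_angles(mesh, params)
  eg <- energy_grad(mesh, connections, params, want_grad = FALSE)
  structure(eg$energy, parts = eg$parts)
}

#' Per-vertex forces and equilibrium residual
#'
#' @inheritParams total_energy
#' @return A `force_report`: list with `forces` (n x 2, reported for fixed
#'   vertices too but never applied to them), `energy`, `parts` and
#'   `residual` (max force magnitude over non-fixed vertices).
#' @export
mesh_forces <- function(mesh, connections = NULL, params = sim_params()) {
  mesh <- ensure_angles(mesh, params)
  eg <- energy_grad(mesh, connections, params)
  forces <- -eg$grad
  free <- !mesh$fixed
  residual <- if (any(free)) max(sqrt(rowSums(forces[free, , drop = FALSE]^2))) else 0
  structure(list(forces = forces, energy = eg$energy, parts = eg$parts,
                 residual = residual),
            class = "force_report")
}

#' @export
print.force_report <- function(x, ...) {
  cat(sprintf("<force_report> energy %.6g, residual %.3g\n", x$energy, x$residual))
  invisible(x)
}

#' Relax a mesh to mechanical equilibrium
#'
#' Moves the non-fixed vertices until the residual force drops below
#' `tol` or the iteration budget is exhausted. Two modes:
#' \describe{
#'   \item{`"prox"`}{Backward-Euler steps of the overdamped dynamics
#'     `x' = F` (unit drag): each outer step solves
#'     `x_{k+1} = argmin E(x) + |x - x_k|^2 / (2 h)` with an adaptive step
#'     `h`; total energy is non-increasing across every accepted step.}
#'   \item{`"direct"`}{Chunked quasi-Newton minimisation of the energy
#'     itself (the infinite-step limit), used by the physics scans where
#'     residual forces of order 1e-11 must be resolved.}
#' }
#'
#' @param mesh A `tissue_mesh`.
#' @param connections Optional `connection_set` (held fixed during the solve).
#' @param params A `sim_params` supplying defaults for `tol`, `max_iter` and
#'   the inner solver precision.
#' @param method `"prox"` or `"direct"`.
#' @param tol Residual threshold (max force on a free vertex); `0` relaxes
#'   until the minimiser makes no further progress.
#' @param max_iter Cap on inner minimisation iterations.
#' @param factr Inner L-BFGS-B precision control.
#' @return List with `mesh` (relaxed), and `report`: a `force_report` plus
#'   `converged`, `iterations` and the per-outer-step `energy_trace`.
#' @export
solve_equilibrium <- function(mesh, connections = NULL, params = sim_params(),
                              method = c("prox", "direct"),
                              tol = params$solver_tol,
                              max_iter = params$solver_max_iter,
                              factr = params$solver_factr) {
  method <- match.arg(method)
  mesh <- ensure_angles(mesh, params)
  free <- which(!mesh$fixed)
  nf <- length(free)
  report0 <- mesh_forces(mesh, connections, params)
  if (nf == 0 || report0$residual < tol) {
    report0$converged <- TRUE
    report0$iterations <- 0L
    report0$energy_trace <- report0$energy
    return(list(mesh = mesh, report = report0))
  }

  pos <- mesh$pos
  pack <- function(p) as.vector(p[free, ])
  unpack <- function(x) {
    p <- pos
    p[free, ] <- matrix(x, nf, 2)
    p
  }

  iter_used <- 0L
  trace <- report0$energy
  h <- 1

  objective <- function(x0, hh) {
    list(
      fn = function(x) {
        p <- unpack(x)
        e <- energy_grad(mesh, connections, params, pos = p, want_grad = FALSE)$energy
        if (is.finite(hh)) e <- e + sum((x - x0)^2) / (2 * hh)
        e
      },
      gr = function(x) {
        p <- unpack(x)
        g <- energy_grad(mesh, connections, params, pos = p)$grad
        gv <- as.vector(g[free, ])
        if (is.finite(hh)) gv <- gv + (x - x0) / hh
        gv
      }
    )
  }

  x <- pack(pos)
  repeat {
    hh <- if (method == "prox") h else Inf
    obj <- objective(x, hh)
    chunk <- min(500L, max_iter - iter_used)
    fit <- stats::optim(x, obj$fn, obj$gr, method = "L-BFGS-B",
                        control = list(maxit = chunk, factr = factr,
                                       pgtol = if (tol > 0) tol / 2 else 0))
    iter_used <- iter_used + max(1L, fit$counts[["function"]])
    x_new <- fit$par
    pos_new <- unpack(x_new)
    eg <- energy_grad(mesh, connections, params, pos = pos_new)
    res <- max(sqrt(rowSums(eg$grad[free, , drop = FALSE]^2)))
    # inner optimiser met its own factr/pgtol criterion: no further progress
    # is possible at this precision (in direct mode the subproblem IS the
    # energy, so this is a global stall; in prox mode only once h is large)
    stalled <- fit$convergence == 0 && (method == "direct" || h >= 1e8)
    progressed <- eg$energy < trace[length(trace)] - 1e-300 ||
      sum((x_new - x)^2) > 0
    x <- x_new
    pos <- pos_new
    trace <- c(trace, eg$energy)
    if (method == "prox") h <- min(h * 4, 1e8)
    if (res < tol || iter_used >= max_iter || !progressed || stalled) {
      mesh$pos <- pos
      rep <- mesh_forces(mesh, connections, params)
      rep$converged <- rep$residual < tol || (tol <= 0 && (!progressed || stalled))
      rep$iterations <- iter_used
      rep$energy_trace <- trace
      if (!rep$converged && tol > 0 && iter_used >= max_iter)
        warning(sprintf("equilibrium solve stopped at residual %.3g (tol %.3g) after %d iterations",
                        rep$residual, tol, iter_used), call. = FALSE)
      return(list(mesh = mesh, report = rep))
    }
  }
}
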