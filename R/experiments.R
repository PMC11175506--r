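# In-silico physics experiments: ablation recoil, Euler critical-load scaling,
# foundation (Winkler) buckling-mode selection.

#' Build a straight spring-chain beam
#'
#' A single chain of vertices along x with both endpoints fixed (pinned: no
#' angular spring acts at a chain end), rest state initialised to the straight
#' configuration, foundation anchors at the initial positions.
#'
#' @param length Beam length (um).
#' @param spacing Segment length (um); the discretisation scale.
#' @param params A `sim_params` (for the bending-configuration cache).
#' @return A `tissue_mesh` with no faces.
#' @export
make_beam <- function(length, spacing = 1, params = sim_params()) {
  x <- seq(0, length, by = spacing)
  if (abs(x[length(x)] - length) > 1e-9) x <- c(x, length)
  n <- length(x)
  pos <- cbind(x, 0)
  edges <- cbind(seq_len(n - 1), 2:n)
  fixed <- c(TRUE, rep(FALSE, n - 2), TRUE)
  m <- tissue_mesh(pos, edges, fixed = fixed)
  m$rest_len <- edge_lengths(m)
  m$foundation <- m$pos
  ensure_angles(m, params)
}

# Dense modified-Newton relaxation for small chains. Near a buckling
# threshold the transverse (soft) mode sits many orders of magnitude below
# the axial stiffness, which defeats quasi-Newton line searches at machine
# precision; an explicit eigendecomposition of the Hessian handles the
# conditioning and walks off the straight-state saddle along its negative
# curvature direction. Hessian by central differences of the analytic
# gradient; energy is kept non-increasing by backtracking.
newton_relax <- function(mesh, params, gtol = 1e-12, max_iter = 60, h_fd = 1e-6) {
  mesh <- ensure_angles(mesh, params)
  free <- which(!mesh$fixed)
  nf <- length(free)
  pos <- mesh$pos
  grad_at <- function(p) {
    g <- energy_grad(mesh, NULL, params, pos = p)$grad
    as.vector(g[free, ])
  }
  energy_at <- function(p) energy_grad(mesh, NULL, params, pos = p,
                                       want_grad = FALSE)$energy
  set_x <- function(p, x) { p[free, ] <- matrix(x, nf, 2); p }
  x <- as.vector(pos[free, ])
  e <- energy_at(pos)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    p <- set_x(pos, x)
    g <- grad_at(p)
    H <- matrix(0, 2 * nf, 2 * nf)
    for (k in seq_len(2 * nf)) {
      xp <- x; xp[k] <- xp[k] + h_fd
      xm <- x; xm[k] <- xm[k] - h_fd
      H[, k] <- (grad_at(set_x(pos, xp)) - grad_at(set_x(pos, xm))) / (2 * h_fd)
    }
    H <- (H + t(H)) / 2
    eg <- eigen(H, symmetric = TRUE)
    lam <- eg$values
    lmax <- max(abs(lam))
    if (max(abs(g)) < gtol && min(lam) > -1e-9 * lmax) { converged <- TRUE; break }
    gl <- drop(crossprod(eg$vectors, g))
    if (max(abs(g)) < gtol && min(lam) <= -1e-9 * lmax) {
      # on a saddle: line-search along the most negative curvature direction
      v <- eg$vectors[, which.min(lam)]
      f1 <- function(a) energy_at(set_x(pos, x + a * v))
      opt <- stats::optimize(f1, interval = c(-2, 2))
      if (opt$objective < e) { x <- x + opt$minimum * v; e <- opt$objective }
      next
    }
    # saddle-free Newton step: descend along negative-curvature directions too
    d <- -drop(eg$vectors %*% (gl / pmax(abs(lam), 1e-8 * lmax)))
    a <- 1
    repeat {
      e_new <- energy_at(set_x(pos, x + a * d))
      if (e_new <= e || a < 1e-8) break
      a <- a / 2
    }
    if (e_new > e) break   # no downhill progress possible
    x <- x + a * d
    e <- e_new
  }
  mesh$pos <- set_x(pos, x)
  list(mesh = mesh, converged = converged, energy = e)
}

#' Deflection response of a pinned beam under end-to-end compression
#'
#' Moves both pinned ends symmetrically inward to impose a compressive strain,
#' seeds a small transverse perturbation, relaxes to equilibrium with a
#' high-precision direct solve, and reports the resulting transverse
#' amplitude and the measured axial load.
#'
#' @param beam A beam from [make_beam()] (or any 2-fixed-end chain).
#' @param strain End-to-end compressive strain (0 = uncompressed).
#' @param params A `sim_params` (k_foundation = 0 reproduces the Euler case).
#' @param seed_amplitude Amplitude (um) of the symmetry-breaking seed.
#' @param perturbation `"halfsine"` (seeds mode 1) or `"noise"` (broadband,
#'   deterministic under `params$seed`).
#' @param max_iter Inner iteration budget for the relaxation.
#' @param newton_polish Finish with the dense modified-Newton relaxer. Needed
#'   when no foundation is present: near the Euler threshold the soft
#'   transverse mode sits far below the axial stiffness and quasi-Newton
#'   line searches stall at machine precision. With a foundation the
#'   transverse stiffness scale is healthy and the polish is unnecessary.
#' @return List with `amplitude` (max |transverse deflection| over free
#'   vertices), `load` (mean axial compressive force, positive in
#'   compression), `profile` (data frame x, y over all vertices) and
#'   `converged`.
#' @export
beam_response <- function(beam, strain, params = sim_params(),
                          seed_amplitude = 1e-3,
                          perturbation = c("halfsine", "noise"),
                          max_iter = 20000,
                          newton_polish = params$k_foundation == 0) {
  perturbation <- match.arg(perturbation)
  m <- beam
  L <- diff(range(m$pos[, 1]))
  x0 <- min(m$pos[, 1])
  # scale every x toward the centre so the ends move symmetrically inward
  cen <- x0 + L / 2
  m$pos[, 1] <- cen + (m$pos[, 1] - cen) * (1 - strain)
  if (params$k_foundation > 0)
    m$foundation[, 1] <- cen + (m$foundation[, 1] - cen) * (1 - strain)
  free <- which(!m$fixed)
  s <- (beam$pos[free, 1] - x0) / L
  m$pos[free, 2] <- m$pos[free, 2] + switch(
    perturbation,
    halfsine = seed_amplitude * sin(pi * s),
    noise = with_seed(params$seed, seed_amplitude * stats::rnorm(length(free)))
  )
  # pre-relax with the quasi-Newton solver, then optionally polish (and
  # escape the straight-state saddle) with the dense Newton relaxer
  sol <- solve_equilibrium(m, NULL, params, method = "direct",
                           tol = 0, max_iter = max_iter, factr = 1)
  rm <- sol$mesh
  converged <- sol$report$converged
  if (newton_polish) {
    nr <- newton_relax(rm, params)
    rm <- nr$mesh
    converged <- nr$converged
  }
  amp <- max(abs(rm$pos[free, 2]))
  lens <- edge_lengths(rm)
  fax <- edge_force(lens, rm$rest_len, params$k_b)
  list(amplitude = amp,
       load = -mean(fax),
       profile = data.frame(x = rm$pos[, 1], y = rm$pos[, 2]),
       converged = converged)
}

#' Critical-load scaling of pinned spring-chain beams (Euler scan)
#'
#' For each beam length, ramps the end-to-end compressive strain along
#' `strain_schedule` (ascending), relaxing from a straight-plus-seed state at
#' every level, and detects buckling as the first level whose relaxed
#' transverse deflection exceeds `detection_factor` times the seed amplitude.
#' The bracket is then refined by bisection and the critical load is the
#' measured axial force at the smallest buckled strain. A slender elastic
#' beam obeys `P_c = pi^2 B / L^2`, so the fitted log-log slope of load
#' against length is -2.
#'
#' @param lengths Beam lengths (um), at least 4 spanning a >= 4-fold range
#'   for a meaningful fit.
#' @param params A `sim_params`; `k_foundation` is forced to 0.
#' @param spacing Beam discretisation (um).
#' @param seed_amplitude Transverse seed amplitude (um).
#' @param detection_factor Buckling-onset criterion: deflection exceeds
#'   `detection_factor * seed_amplitude`.
#' @param strain_schedule Ascending compressive strains to scan.
#' @param n_bisect Bisection refinements of the onset bracket.
#' @return List with `table` (length, critical_strain, critical_load,
#'   amplitude, failed), `exponent` (fitted log-log slope) and `fit` (the lm).
#' @export
euler_buckling_scan <- function(lengths = c(8, 16, 32, 64),
                                params = sim_params(),
                                spacing = params$th_sub,
                                seed_amplitude = 1e-3,
                                detection_factor = 10,
                                strain_schedule = 10^seq(-6, -1.7, length.out = 40),
                                n_bisect = 8) {
  params$k_foundation <- 0
  noise_floor <- detection_factor * seed_amplitude
  rows <- lapply(lengths, function(L) {
    beam <- make_beam(L, spacing, params)
    probe <- function(eps) beam_response(beam, eps, params, seed_amplitude, "halfsine")
    lo <- 0; hi <- NA; hit <- NULL
    for (eps in strain_schedule) {
      r <- probe(eps)
      if (r$amplitude > noise_floor) { hi <- eps; hit <- r; break }
      lo <- eps
    }
    if (is.na(hi))
      return(data.frame(length = L, critical_strain = NA_real_,
                        critical_load = NA_real_, amplitude = NA_real_,
                        failed = TRUE))
    for (b in seq_len(n_bisect)) {
      mid <- sqrt(max(lo, hi / 64) * hi)  # geometric bisection
      r <- probe(mid)
      if (r$amplitude > noise_floor) { hi <- mid; hit <- r } else lo <- mid
    }
    data.frame(length = L, critical_strain = hi, critical_load = hit$load,
               amplitude = hit$amplitude, failed = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- !tab$failed
  fit <- if (sum(ok) >= 2)
    stats::lm(log(critical_load) ~ log(length), data = tab[ok, ]) else NULL
  list(table = tab,
       exponent = if (!is.null(fit)) unname(stats::coef(fit)[2]) else NA_real_,
       fit = fit)
}

# Dominant wavelength of a transverse deflection profile: FFT magnitude peak
# with parabolic interpolation; mode number from interior sign changes.
dominant_wavelength <- function(x, y) {
  o <- order(x)
  y <- y[o]
  span <- diff(range(x))
  yd <- y - mean(y)
  sp <- Mod(stats::fft(yd))
  nh <- floor(length(y) / 2)
  if (nh < 2) return(list(wavelength = NA_real_, mode = NA_integer_))
  mags <- sp[2:(nh + 1)]              # bins 1..nh (cycles per span)
  m <- which.max(mags)
  delta <- 0
  if (m > 1 && m < length(mags)) {
    a <- mags[m - 1]; b <- mags[m]; c <- mags[m + 1]
    den <- a - 2 * b + c
    if (den != 0) delta <- 0.5 * (a - c) / den
  }
  # mode number = interior crossings of the straight baseline (y = 0) + 1,
  # ignoring wiggles below 2% of the peak deflection
  sgn <- sign(y[abs(y) > 0.02 * max(abs(y))])
  crossings <- sum(diff(sgn) != 0)
  list(wavelength = span / (m + delta), mode = crossings + 1L)
}

#' Buckling-mode selection on an elastic foundation (Winkler scan)
#'
#' A beam coupled to an elastic foundation buckles at the wavelength
#' `lambda = 2*pi*(B/k)^(1/4)` (B = bending modulus per unit length, k =
#' foundation stiffness per unit length), so the log-log slope of the
#' dominant wavelength against `k_foundation` is -1/4: stiff foundations
#' preclude low-mode buckling. For each stiffness the onset strain is located
#' by an ascending ramp, the beam is relaxed at `overstrain` times the onset,
#' and the dominant wavelength is read from the spectrum of the transverse
#' deflection.
#'
#' The default beam is discretised at 0.5 um with `k_bend = 0.01` and
#' `k_b = 2` so that the selected wavelength spans at least ~6 lattice
#' spacings over the whole 2-decade stiffness range (the nest defaults put
#' the wavelength below the lattice resolution).
#'
#' @param k_foundation_values Foundation stiffnesses, >= 4 values spanning
#'   two or more decades.
#' @param beam_length Beam length (um), >= 32 subdivision thresholds.
#' @param spacing Beam discretisation (um).
#' @param params Base `sim_params`; `k_bend`/`k_b` below override it.
#' @param k_bend,k_b Scan-specific stiffnesses (see above).
#' @param seed_amplitude Broadband seed amplitude (um).
#' @param overstrain Multiple of the detected onset strain at which the
#'   post-buckling spectrum is measured.
#' @param strain_schedule Ascending strains used to locate the onset.
#' @return List with `table` (k_foundation, onset_strain, wavelength, mode,
#'   failed), `exponent` (fitted log-log slope of wavelength vs stiffness)
#'   and `fit`.
#' @export
foundation_mode_scan <- function(k_foundation_values = 10^seq(-3.5, -1.5, length.out = 5),
                                 beam_length = 64,
                                 spacing = 0.5,
                                 params = sim_params(),
                                 k_bend = 0.01,
                                 k_b = 2,
                                 seed_amplitude = 1e-3,
                                 overstrain = 1.3,
                                 strain_schedule = 10^seq(-4, -0.6, length.out = 25)) {
  base <- params
  base$k_bend <- k_bend
  base$k_b <- base$k_b_tension <- base$k_b_compression <- k_b
  base$dt_foundation <- 0
  noise_floor <- 10 * seed_amplitude
  rows <- lapply(k_foundation_values, function(kf) {
    p <- base
    p$k_foundation <- kf
    beam <- make_beam(beam_length, spacing, p)
    onset <- NA
    for (eps in strain_schedule) {
      r <- beam_response(beam, eps, p, seed_amplitude, "noise")
      if (r$amplitude > noise_floor) { onset <- eps; break }
    }
    if (is.na(onset))
      return(data.frame(k_foundation = kf, onset_strain = NA_real_,
                        wavelength = NA_real_, mode = NA_integer_, failed = TRUE))
    r <- beam_response(beam, min(overstrain * onset, 0.45), p,
                       seed_amplitude, "noise")
    free <- which(!beam$fixed)
    dw <- dominant_wavelength(r$profile$x[free], r$profile$y[free])
    data.frame(k_foundation = kf, onset_strain = onset,
               wavelength = dw$wavelength, mode = dw$mode, failed = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- !tab$failed & is.finite(tab$wavelength)
  fit <- if (sum(ok) >= 2)
    stats::lm(log(wavelength) ~ log(k_foundation), data = tab[ok, ]) else NULL
  list(table = tab,
       exponent = if (!is.null(fit)) unname(stats::coef(fit)[2]) else NA_real_,
       fit = fit)
}

#' In-silico laser ablation
#'
#' Removes a contiguous run of boundary edges (and the angular springs that
#' couple across them), then relaxes the mesh with no growth, foundation
#' anchors frozen, recording per relaxation step the gap between the two cut
#' ends and the straightness of the two severed half-junctions (the chains
#' from each cut end to the next junction or fixed vertex).
#'
#' @param mesh A `tissue_mesh`.
#' @param edge_ids Indices into `mesh$edges` forming a contiguous path.
#' @param params A `sim_params`.
#' @param n_relax_steps Number of recorded relaxation steps.
#' @param relax_maxit Inner iterations per recorded step.
#' @return List with `series` (data frame: step, gap, opening,
#'   straightness_a, straightness_b, energy), `mesh` (final state), and
#'   `ends` (the two cut-end vertex ids).
#' @export
ablate <- function(mesh, edge_ids, params = sim_params(),
                   n_relax_steps = 20, relax_maxit = 80) {
  edge_ids <- as.integer(edge_ids)
  if (!length(edge_ids) || any(edge_ids < 1 | edge_ids > nrow(mesh$edges)))
    stop("edge_ids out of range", call. = FALSE)
  sub <- mesh$edges[edge_ids, , drop = FALSE]
  cnt <- table(c(sub[, 1], sub[, 2]))
  endpoints <- as.integer(names(cnt)[cnt == 1])
  if (length(endpoints) != 2 || any(cnt > 2))
    stop("edge_ids must form a single contiguous path", call. = FALSE)
  # connectivity of the path itself
  if (nrow(sub) > 1) {
    reach <- endpoints[1]
    rem <- seq_len(nrow(sub))
    repeat {
      hit <- rem[sub[rem, 1] %in% reach | sub[rem, 2] %in% reach]
      if (!length(hit)) break
      reach <- unique(c(reach, sub[hit, ]))
      rem <- setdiff(rem, hit)
    }
    if (length(rem)) stop("edge_ids must form a single contiguous path", call. = FALSE)
  }

  cut <- mesh
  keep <- setdiff(seq_len(nrow(mesh$edges)), edge_ids)
  cut$edges <- mesh$edges[keep, , drop = FALSE]
  cut$rest_len <- mesh$rest_len[keep]
  cut$faces <- list()   # faces are opened by the cut; drop them
  cut$angles <- NULL
  cut <- ensure_angles(cut, params)

  adj <- adjacency_list(cut)
  half_chain <- function(v) {
    chain <- v
    prev <- -1L
    while (length(adj[[v]]) >= 1) {
      nb <- setdiff(adj[[v]], prev)
      if (length(nb) != 1) break           # junction or dead end
      prev <- v; v <- nb[1]
      chain <- c(chain, v)
      if (cut$fixed[v] || length(adj[[v]]) != 2) break
    }
    chain
  }
  chain_a <- half_chain(endpoints[1])
  chain_b <- half_chain(endpoints[2])
  straight <- function(ch) {
    if (length(ch) < 2) return(NA_real_)
    junction_straightness(cut$pos[ch, , drop = FALSE])
  }
  gap0 <- sqrt(sum((cut$pos[endpoints[1], ] - cut$pos[endpoints[2], ])^2))
  rows <- vector("list", n_relax_steps + 1)
  rows[[1]] <- data.frame(step = 0, gap = gap0, opening = 0,
                          straightness_a = straight(chain_a),
                          straightness_b = straight(chain_b),
                          energy = as.numeric(total_energy(cut, NULL, params)))
  for (s in seq_len(n_relax_steps)) {
    sol <- solve_equilibrium(cut, NULL, params, method = "direct",
                             tol = 0, max_iter = relax_maxit, factr = 10)
    cut <- sol$mesh
    gap <- sqrt(sum((cut$pos[endpoints[1], ] - cut$pos[endpoints[2], ])^2))
    rows[[s + 1]] <- data.frame(step = s, gap = gap, opening = gap - gap0,
                                straightness_a = straight(chain_a),
                                straightness_b = straight(chain_b),
                                energy = sol$report$energy)
  }
  list(series = do.call(rbind, rows), mesh = cut, ends = endpoints)
}
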