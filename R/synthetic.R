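# Deterministic synthetic-data generators with known ground truth. Every
# generator returns its ground truth alongside the artifact (and the CLI
# writes it as a JSON sidecar), so analysis-on-synthetic closes the loop.

#' Rasterise a mesh into an integer label image
#'
#' Pixels are labelled by the id of the face containing their centre
#' (0 = outside). Pixel centres sit at `(col - 0.5) * pixel_size,
#' (row - 0.5) * pixel_size` relative to the mesh bounding-box origin.
#'
#' @param mesh A `tissue_mesh` with simple polygonal faces.
#' @param pixel_size Pixel edge length (um).
#' @param shape Optional `c(ny, nx)`; default covers the mesh bounding box.
#' @param pad Background margin (um) added around the mesh bounding box.
#' @return Integer matrix (rows = y) with attributes `pixel_size` and
#'   `origin` (the mesh coordinates of the image corner).
#' @export
render_label_image <- function(mesh, pixel_size = 0.1, shape = NULL, pad = 0) {
  stopifnot(pixel_size > 0, length(mesh$faces) > 0, pad >= 0)
  origin <- c(min(mesh$pos[, 1]), min(mesh$pos[, 2])) - pad
  ext <- c(max(mesh$pos[, 1]), max(mesh$pos[, 2])) + pad - origin
  if (is.null(shape)) shape <- ceiling(rev(ext) / pixel_size) + 1L
  ny <- shape[1]; nx <- shape[2]
  cx <- origin[1] + (seq_len(nx) - 0.5) * pixel_size
  cy <- origin[2] + (seq_len(ny) - 0.5) * pixel_size
  pts <- cbind(rep(cx, each = ny), rep(cy, times = nx))
  lab <- matrix(0L, ny, nx)
  for (fi in seq_along(mesh$faces)) {
    poly <- mesh$pos[mesh$faces[[fi]], , drop = FALSE]
    bb <- apply(poly, 2, range)
    cand <- which(pts[, 1] >= bb[1, 1] & pts[, 1] <= bb[2, 1] &
                    pts[, 2] >= bb[1, 2] & pts[, 2] <= bb[2, 2])
    if (!length(cand)) next
    inside <- points_in_polygon(pts[cand, , drop = FALSE], poly)
    lab[cand[inside]] <- fi
  }
  attr(lab, "pixel_size") <- pixel_size
  attr(lab, "origin") <- origin
  lab
}

#' Synthetic membrane z-stack with two axial intensity peaks
#'
#' Emulates a basolateral-membrane z-stack: at every xy pixel the axial
#' profile is the sum of two unit-amplitude Gaussians whose centres are
#' separated by the local value of `thickness_field` and centred in the
#' stack, plus additive Gaussian noise of s.d. `1/snr` (none when
#' `snr = Inf`). Deterministic under `seed`.
#'
#' @param thickness_field Matrix of ground-truth thicknesses (um).
#' @param z_spacing Plane spacing (um).
#' @param peak_width Gaussian width of each membrane peak (um).
#' @param snr Peak amplitude over noise s.d.; `Inf` = noiseless.
#' @param seed Integer seed.
#' @param z_margin Stack padding beyond the outermost peak (um).
#' @return List with `stack` (ny x nx x nz), `ground_truth` (list with the
#'   generator settings and the thickness field).
#' @export
make_membrane_zstack <- function(thickness_field, z_spacing = 1,
                                 peak_width = 1, snr = Inf, seed = 1L,
                                 z_margin = 4) {
  tf <- as.matrix(thickness_field)
  if (any(!is.finite(tf)) || any(tf <= 0))
    stop("thickness values must be positive and finite", call. = FALSE)
  zmax <- max(tf) + 2 * z_margin
  nz <- max(8L, ceiling(zmax / z_spacing) + 1L)
  ny <- nrow(tf); nx <- ncol(tf)
  z <- (seq_len(nz) - 0.5) * z_spacing
  mid <- nz * z_spacing / 2
  stack <- array(0, c(ny, nx, nz))
  for (iy in seq_len(ny)) {
    c1 <- mid - tf[iy, ] / 2
    c2 <- mid + tf[iy, ] / 2
    prof <- exp(-outer(c1, z, function(c, zz) (zz - c)^2) / (2 * peak_width^2)) +
      exp(-outer(c2, z, function(c, zz) (zz - c)^2) / (2 * peak_width^2))
    stack[iy, , ] <- prof
  }
  if (is.finite(snr))
    stack <- stack + with_seed(seed, array(stats::rnorm(length(stack), sd = 1 / snr),
                                           dim(stack)))
  list(stack = stack,
       ground_truth = list(kind = "membrane_zstack", thickness = tf,
                           z_spacing = z_spacing, peak_width = peak_width,
                           snr = snr, seed = seed))
}

#' Synthetic vertex trajectories: common drift plus jitter
#'
#' Each vertex starts at a random position in a 10 x 10 um field and moves
#' with a shared rigid per-frame drift plus i.i.d. Gaussian jitter of
#' per-coordinate s.d. `jitter_sigma`, emulating tracked junction vertices.
#'
#' @param n_vertices Number of vertices.
#' @param T Number of frames (>= 2).
#' @param jitter_sigma Per-coordinate jitter s.d. (um).
#' @param drift_per_frame Length-2 rigid drift per frame (um).
#' @param seed Integer seed.
#' @return List with `trajectories` (data frame: vertex_id, t, x, y) and
#'   `ground_truth`.
#' @export
make_trajectories <- function(n_vertices = 10, T = 30, jitter_sigma = 0.07,
                              drift_per_frame = c(0, 0), seed = 1L) {
  if (T < 2) stop("T must be >= 2", call. = FALSE)
  with_seed(seed, {
    base <- matrix(stats::runif(n_vertices * 2, 0, 10), n_vertices, 2)
    jit <- array(stats::rnorm(T * n_vertices * 2, sd = jitter_sigma),
                 c(T, n_vertices, 2))
    drift <- outer(seq_len(T) - 1, drift_per_frame)
    df <- do.call(rbind, lapply(seq_len(n_vertices), function(v) {
      data.frame(vertex_id = v, t = seq_len(T),
                 x = base[v, 1] + drift[, 1] + jit[, v, 1],
                 y = base[v, 2] + drift[, 2] + jit[, v, 2])
    }))
    list(trajectories = df,
         ground_truth = list(kind = "trajectories", jitter_sigma = jitter_sigma,
                             drift_per_frame = drift_per_frame,
                             n_vertices = n_vertices, T = T, seed = seed))
  })
}

#' Synthetic junction/cytosol intensity image with a set enrichment ratio
#'
#' Renders the mesh to labels, builds a junction mask (pixels within one
#' pixel of any boundary edge) and a cytosol mask (cell interior minus the
#' junction band), then paints `background` outside, a cytosol level inside
#' and `ratio` times the cytosol level (above background) on the junction
#' band, plus Gaussian noise at the stated SNR.
#'
#' @param mesh A `tissue_mesh`.
#' @param ratio Ground-truth junction/cytosol enrichment ratio.
#' @param background Background intensity level.
#' @param cytosol_level Cytosol intensity above background.
#' @param snr Cytosol level over noise s.d.; `Inf` = noiseless.
#' @param pixel_size Pixel edge length (um).
#' @param seed Integer seed.
#' @return List with `image`, `junction_mask`, `cytosol_mask`, `labels`,
#'   `ground_truth`.
#' @export
make_enrichment_image <- function(mesh, ratio = 1.5, background = 10,
                                  cytosol_level = 100, snr = Inf,
                                  pixel_size = 0.2, seed = 1L) {
  # pad with a background ring so the background estimator has support
  lab <- render_label_image(mesh, pixel_size, pad = 10 * pixel_size)
  origin <- attr(lab, "origin")
  ny <- nrow(lab); nx <- ncol(lab)
  cx <- origin[1] + (seq_len(nx) - 0.5) * pixel_size
  cy <- origin[2] + (seq_len(ny) - 0.5) * pixel_size
  jm <- matrix(FALSE, ny, nx)
  E <- mesh$edges
  for (k in seq_len(nrow(E))) {
    a <- mesh$pos[E[k, 1], ]; b <- mesh$pos[E[k, 2], ]
    pad <- 1.5 * pixel_size
    ix <- which(cx >= min(a[1], b[1]) - pad & cx <= max(a[1], b[1]) + pad)
    iy <- which(cy >= min(a[2], b[2]) - pad & cy <= max(a[2], b[2]) + pad)
    if (!length(ix) || !length(iy)) next
    px <- rep(cx[ix], each = length(iy)); py <- rep(cy[iy], times = length(ix))
    ab <- b - a
    len2 <- sum(ab^2)
    t <- pmin(1, pmax(0, ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2))
    d2 <- (px - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2
    hit <- d2 <= pixel_size^2
    if (any(hit)) {
      sub <- jm[iy, ix]
      sub[hit] <- TRUE
      jm[iy, ix] <- sub
    }
  }
  cm <- lab > 0 & !jm
  img <- matrix(background, ny, nx)
  img[cm] <- background + cytosol_level
  img[jm] <- background + ratio * cytosol_level
  if (is.finite(snr))
    img <- img + with_seed(seed, matrix(stats::rnorm(length(img),
                                                     sd = cytosol_level / snr), ny, nx))
  list(image = img, junction_mask = jm, cytosol_mask = cm, labels = lab,
       ground_truth = list(kind = "enrichment_image", ratio = ratio,
                           background = background, cytosol_level = cytosol_level,
                           snr = snr, pixel_size = pixel_size, seed = seed))
}

#' Default synthetic cell nest
#'
#' A ~15-cell polygonal nest at realistic scale (cell areas in the
#' 120-200 um^2 range), subdivided and rest-initialised: the standard
#' fixture for the simulation and imaging pipelines.
#'
#' @param n_cells Number of cells.
#' @param seed Integer seed.
#' @param params A `sim_params`.
#' @return A `tissue_mesh`.
#' @export
make_nest <- function(n_cells = 15, seed = 1L, params = sim_params()) {
  side <- sqrt(n_cells * 160)   # ~160 um^2 per cell
  m <- make_cell_grid(side, side, n_cells, seed = seed)
  m <- subdivide_long_edges(m, params$th_sub)
  init_rest_state(m, params)
}

#' Write a generator's ground truth as a JSON sidecar
#'
#' @param ground_truth Ground-truth list from a generator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}
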