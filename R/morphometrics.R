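# Shape statistics: area, perimeter, circularity, junction straightness,
# vertex fluctuation RMS, morphospace tables.

#' Polygon shape statistics
#'
#' Area by the surveyor's formula, perimeter as summed segment lengths, and
#' circularity `4 * pi * A / P^2` (1 for a circle, decreasing as the outline
#' becomes convoluted). Self-intersecting loops are flagged and get `NaN`
#' circularity.
#'
#' @param xy Ordered loop of 2-D points (>= 3 rows; a repeated closing point
#'   is dropped). Units are pixels or um.
#' @param scale Length per coordinate unit (e.g. pixel size in um); areas
#'   scale with `scale^2`.
#' @param check_simple Run the O(k^2) self-intersection test (skip for cheap
#'   logging of large loops; the loop is then assumed simple).
#' @return One-row data frame: `area`, `perimeter`, `circularity`, `simple`.
#' @examples
#' polygon_stats(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # unit square, pi/4
#' @export
polygon_stats <- function(xy, scale = 1, check_simple = TRUE) {
  xy <- as.matrix(xy)
  if (nrow(xy) >= 2 && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  if (nrow(xy) < 3) stop("polygon needs at least 3 distinct points", call. = FALSE)
  a <- abs(polygon_area_signed(xy)) * scale^2
  p <- polygon_perimeter(xy) * scale
  simple <- if (check_simple) polygon_is_simple(xy) else NA
  circ <- if (!isFALSE(simple) && p > 0) 4 * pi * a / p^2 else NaN
  data.frame(area = a, perimeter = p, circularity = circ, simple = simple)
}

#' Per-cell shape statistics of a mesh
#'
#' @param mesh A `tissue_mesh`.
#' @param scale Length per coordinate unit.
#' @inheritParams polygon_stats
#' @return Data frame with one row per face: `cell_id`, `area`, `perimeter`,
#'   `circularity`, `simple`.
#' @export
mesh_stats <- function(mesh, scale = 1, check_simple = TRUE) {
  if (!length(mesh$faces))
    return(data.frame(cell_id = integer(0), area = numeric(0),
                      perimeter = numeric(0), circularity = numeric(0),
                      simple = logical(0)))
  out <- do.call(rbind, lapply(mesh$faces, function(f)
    polygon_stats(mesh$pos[f, , drop = FALSE], scale, check_simple)))
  cbind(cell_id = seq_along(mesh$faces), out)
}

#' Junction straightness
#'
#' Ratio of the end-to-end distance of an open polyline over its curvilinear
#' (arc) length; 1 for a straight junction, 0 for a closed loop.
#'
#' @param xy Ordered polyline points (>= 2 rows).
#' @return Straightness in `[0, 1]`.
#' @examples
#' th <- seq(0, pi, length.out = 400)
#' junction_straightness(cbind(cos(th), sin(th)))  # semicircle, 2/pi
#' @export
junction_straightness <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2) stop("polyline needs at least 2 points", call. = FALSE)
  arc <- sum(sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2)))
  if (arc == 0) stop("polyline has zero arc length", call. = FALSE)
  sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2)) / arc
}

#' Root-mean-square vertex fluctuation
#'
#' Pools squared displacements of every vertex from its own time-mean
#' position over all frames and vertices, then takes the square root; the
#' magnitude RMS over both coordinates, so i.i.d. jitter of per-coordinate
#' s.d. `sigma` gives `sigma * sqrt(2)` for long series. With
#' `drift_correct`, the frame-wise displacement of the centre of mass of all
#' vertices is subtracted first, which removes any rigid common translation
#' exactly.
#'
#' @param traj Either a data frame with columns `vertex_id`, `t`, `x`, `y`
#'   (all series the same length), or a `T x n x 2` array.
#' @param drift_correct Subtract the common centre-of-mass drift first.
#' @return List with `rms` (scalar, um) and `per_vertex` (named vector).
#' @export
vertex_fluctuation_rms <- function(traj, drift_correct = TRUE) {
  if (is.data.frame(traj)) {
    need <- c("vertex_id", "t", "x", "y")
    if (!all(need %in% names(traj)))
      stop("trajectory data frame needs columns vertex_id, t, x, y", call. = FALSE)
    ids <- sort(unique(traj$vertex_id))
    ts <- sort(unique(traj$t))
    cnt <- table(traj$vertex_id)
    if (length(unique(cnt)) != 1 || nrow(traj) != length(ids) * length(ts))
      stop("ragged trajectories: all vertices need the same time points", call. = FALSE)
    arr <- array(NA_real_, c(length(ts), length(ids), 2),
                 dimnames = list(NULL, ids, c("x", "y")))
    o <- order(traj$vertex_id, traj$t)
    arr[, , 1] <- matrix(traj$x[o], length(ts), length(ids))
    arr[, , 2] <- matrix(traj$y[o], length(ts), length(ids))
  } else {
    arr <- traj
    if (length(dim(arr)) != 3 || dim(arr)[3] != 2)
      stop("trajectory array must be T x n x 2", call. = FALSE)
  }
  if (dim(arr)[1] < 2) stop("need at least 2 time points", call. = FALSE)
  if (anyNA(arr)) stop("trajectories contain missing values", call. = FALSE)
  if (drift_correct) {
    com <- apply(arr, c(1, 3), mean)          # T x 2
    com <- sweep(com, 2, com[1, ])            # displacement since first frame
    arr[, , 1] <- arr[, , 1] - com[, 1]
    arr[, , 2] <- arr[, , 2] - com[, 2]
  }
  mx <- colMeans(arr[, , 1, drop = FALSE][, , 1])
  my <- colMeans(arr[, , 2, drop = FALSE][, , 1])
  d2 <- sweep(arr[, , 1], 2, mx)^2 + sweep(arr[, , 2], 2, my)^2
  per_vertex <- sqrt(colMeans(d2))
  list(rms = sqrt(mean(d2)), per_vertex = per_vertex)
}

#' Morphospace summary table
#'
#' Per-group medians and quartiles of area, perimeter and circularity, plus
#' deterministic 2-D bin counts in the perimeter-area and circularity-area
#' planes. Bin edges are declared in the result (defaults: 10 equal-width
#' bins over the pooled range) so the binning is reproducible; the output is
#' invariant to input row order.
#'
#' @param stats Data frame with columns `area`, `perimeter`, `circularity`
#'   (e.g. from [mesh_stats()]).
#' @param group Optional grouping labels (recycled to `nrow(stats)`).
#' @param n_bins Number of bins per axis when breaks are not supplied.
#' @param area_breaks,perimeter_breaks,circularity_breaks Optional explicit
#'   bin edges.
#' @return List with `summary` (per-group quartile table), `bins_pa` and
#'   `bins_ca` (long-format bin counts per group) and `breaks`.
#' @export
morphospace_summary <- function(stats, group = NULL, n_bins = 10,
                                area_breaks = NULL, perimeter_breaks = NULL,
                                circularity_breaks = NULL) {
  if (!nrow(stats)) stop("empty input", call. = FALSE)
  if (is.null(group)) group <- rep("all", nrow(stats))
  group <- factor(rep_len(group, nrow(stats)))
  mk_breaks <- function(x, br) {
    if (!is.null(br)) return(br)
    r <- range(x, finite = TRUE)
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = n_bins + 1)
  }
  br_a <- mk_breaks(stats$area, area_breaks)
  br_p <- mk_breaks(stats$perimeter, perimeter_breaks)
  br_c <- mk_breaks(stats$circularity, circularity_breaks)
  qrow <- function(x) {
    if (!length(x) || all(is.na(x)))
      return(c(q25 = NaN, median = NaN, q75 = NaN))
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    c(q25 = q[1], median = q[2], q75 = q[3])
  }
  sm <- do.call(rbind, lapply(levels(group), function(g) {
    sub <- stats[group == g, , drop = FALSE]
    if (!nrow(sub)) message("morphospace_summary: empty group '", g, "'")
    do.call(rbind, lapply(c("area", "perimeter", "circularity"), function(v) {
      data.frame(group = g, variable = v, n = sum(!is.na(sub[[v]])),
                 t(qrow(sub[[v]])))
    }))
  }))
  bin2d <- function(x, y, brx, bry) {
    bx <- cut(x, brx, include.lowest = TRUE)
    by <- cut(y, bry, include.lowest = TRUE)
    do.call(rbind, lapply(levels(group), function(g) {
      tb <- table(bx[group == g], by[group == g])
      df <- as.data.frame(tb, stringsAsFactors = FALSE)
      names(df) <- c("bin_x", "bin_y", "count")
      cbind(group = g, df)
    }))
  }
  list(summary = sm,
       bins_pa = bin2d(stats$perimeter, stats$area, br_p, br_a),
       bins_ca = bin2d(stats$circularity, stats$area, br_c, br_a),
       breaks = list(area = br_a, perimeter = br_p, circularity = br_c))
}

#' Shape statistics from an integer label image
#'
#' Extracts each labelled region's outline at the 0.5 level with marching
#' squares and runs [polygon_stats()] on it. Intended for segmentation label
#' images (0 = background).
#'
#' @param labels Integer matrix (rows = y, columns = x).
#' @param pixel_size Pixel edge length in um.
#' @return Data frame with one row per label.
#' @export
label_stats <- function(labels, pixel_size) {
  stopifnot(pixel_size > 0)
  ids <- sort(setdiff(unique(as.vector(labels)), 0))
  out <- lapply(ids, function(id) {
    cont <- label_contour(labels, id)
    if (is.null(cont)) return(NULL)
    cbind(cell_id = id, polygon_stats(cont, scale = pixel_size))
  })
  do.call(rbind, out)
}

# Longest marching-squares contour of one label, in pixel-centre coordinates
# (x = column - 0.5, y = row - 0.5). Returns NULL if the label is absent.
label_contour <- function(labels, id) {
  mask <- matrix(0, nrow(labels) + 2, ncol(labels) + 2)
  mask[2:(nrow(labels) + 1), 2:(ncol(labels) + 1)] <- (labels == id) * 1
  if (!any(mask > 0)) return(NULL)
  # contourLines treats z[i, j] with x ~ rows; feed transposed so x = columns
  cl <- grDevices::contourLines(x = seq_len(ncol(mask)) - 1.5,
                                y = seq_len(nrow(mask)) - 1.5,
                                z = t(mask), levels = 0.5)
  if (!length(cl)) return(NULL)
  best <- which.max(vapply(cl, function(c) length(c$x), numeric(1)))
  xy <- cbind(cl[[best]]$x, cl[[best]]$y)
  if (nrow(xy) >= 2 && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  xy
}
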