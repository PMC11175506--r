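# Intensity-based quantifications: junctional enrichment and double-Gaussian
# membrane thickness mapping.

#' Junctional enrichment ratio
#'
#' Ratio of the mean background-normalised intensity over the junction mask to
#' the same over the cytosol mask. The background is the median of the pixels
#' outside both masks and is subtracted before the ratio, so the result is
#' invariant under global multiplicative rescaling of the image. (A low
#' quantile such as the 5th percentile would be biased below the true
#' background by ~1.64 noise s.d. under Gaussian noise — enough to break the
#' 5% recovery contract at SNR 10 — whereas the median is unbiased for
#' symmetric noise and equally robust to bright contamination outside the
#' masks.) If the background-subtracted cytosol mean is degenerate (within
#' machine precision of zero, e.g. a perfectly uniform image where the
#' background equals the signal), the ratio of raw means is returned instead.
#'
#' @param image Numeric intensity matrix.
#' @param junction_mask,cytosol_mask Logical matrices, same shape as `image`,
#'   disjoint and non-empty.
#' @return Dimensionless enrichment ratio.
#' @export
junctional_enrichment <- function(image, junction_mask, cytosol_mask) {
  if (!all(dim(image) == dim(junction_mask)) || !all(dim(image) == dim(cytosol_mask)))
    stop("masks must match the image shape", call. = FALSE)
  junction_mask <- junction_mask != 0
  cytosol_mask <- cytosol_mask != 0
  if (!any(junction_mask) || !any(cytosol_mask))
    stop("masks must be non-empty", call. = FALSE)
  if (any(junction_mask & cytosol_mask))
    stop("junction and cytosol masks overlap", call. = FALSE)
  outside <- !(junction_mask | cytosol_mask)
  bg <- if (any(outside)) stats::median(image[outside]) else 0
  mj <- mean(image[junction_mask])
  mc <- mean(image[cytosol_mask])
  denom <- mc - bg
  scale <- max(abs(mj), abs(mc), 1e-300)
  if (abs(denom) <= 1e-12 * scale) return(mj / mc)
  (mj - bg) / denom
}

# Double-Gaussian fit of one axial profile. Returns c1, c2 (plane units),
# widths, amplitudes, offset, rss; or NULL when no two seeds are found.
fit_double_gaussian <- function(y) {
  nz <- length(y)
  z <- seq_len(nz)
  ys <- stats::filter(y, rep(1 / 3, 3), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  ys <- as.numeric(ys)
  loc <- which(diff(sign(diff(ys))) < 0) + 1
  loc <- loc[order(ys[loc], decreasing = TRUE)]
  if (length(loc) < 2) return(NULL)
  c1 <- min(loc[1:2]); c2 <- max(loc[1:2])
  off0 <- min(y)
  a0 <- c(max(y[c1] - off0, 1e-6), max(y[c2] - off0, 1e-6))
  p0 <- c(A1 = a0[1], c1 = c1, s1 = 1, A2 = a0[2], c2 = c2, s2 = 1, b = off0)
  lower <- c(0, 1, 0.3, 0, 1, 0.3, -Inf)
  upper <- c(Inf, nz, nz / 2, Inf, nz, nz / 2, Inf)
  model <- function(p) {
    p[1] * exp(-(z - p[2])^2 / (2 * p[3]^2)) +
      p[4] * exp(-(z - p[5])^2 / (2 * p[6]^2)) + p[7]
  }
  obj <- function(p) sum((model(p) - y)^2)
  fit <- try(stats::optim(p0, obj, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  p <- fit$par
  list(c1 = min(p[2], p[5]), c2 = max(p[2], p[5]),
       s = c(p[3], p[6]), A = c(p[1], p[4]), b = p[7], rss = fit$value)
}

#' Per-pixel membrane thickness from a two-peak z-stack
#'
#' For every xy pixel the axial intensity profile is fitted to a double
#' Gaussian (two amplitudes, centres, widths and a common offset, seeded at
#' the two largest local maxima of the smoothed profile); the thickness is
#' the distance between the two fitted centres times `z_spacing`. The
#' estimate is invariant under global intensity scaling and additive offsets.
#' Degenerate fits are set to `NaN` and counted: fewer than two local maxima,
#' peak separation below 1.5x the mean fitted width (merged peaks), or peak
#' amplitude below 2x the residual noise.
#'
#' @param stack Numeric array `ny x nx x nz` (>= 8 z-planes).
#' @param z_spacing Plane spacing (um), > 0.
#' @return List with `map` (ny x nx thickness matrix, um), `mean` (over valid
#'   pixels; `NaN` with `valid = FALSE` if fewer than 5% of pixels fit),
#'   `valid` flag, `n_failed` and `fraction_valid`.
#' @export
thickness_map <- function(stack, z_spacing) {
  if (length(dim(stack)) != 3) stop("stack must be a ny x nx x nz array", call. = FALSE)
  if (dim(stack)[3] < 8) stop("stack needs at least 8 z-planes", call. = FALSE)
  if (!(z_spacing > 0)) stop("z_spacing must be > 0", call. = FALSE)
  ny <- dim(stack)[1]; nx <- dim(stack)[2]
  map <- matrix(NaN, ny, nx)
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      f <- fit_double_gaussian(stack[iy, ix, ])
      if (is.null(f)) next
      sep <- f$c2 - f$c1
      resid_sd <- sqrt(f$rss / dim(stack)[3])
      if (sep < 1.5 * mean(f$s)) next            # merged peaks
      if (min(f$A) < 2 * resid_sd) next           # amplitude below noise
      map[iy, ix] <- sep * z_spacing
    }
  }
  n_ok <- sum(is.finite(map))
  frac <- n_ok / length(map)
  valid <- frac >= 0.05
  list(map = map,
       mean = if (valid) mean(map[is.finite(map)]) else NaN,
       valid = valid,
       n_failed = length(map) - n_ok,
       fraction_valid = frac)
}
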