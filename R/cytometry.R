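#' Label-free cell and nucleus segmentation
#'
#' Segments cells from a non-negative signal image (absorption, optical
#' density or mass): the smoothed signal is thresholded with the triangle
#' method (robust when the background class dominates and the foreground
#' spans faint cytoplasm to dense nuclei, where Otsu tends to cut inside
#' the foreground), holes are filled, touching cells are split by watershed
#' on the distance map, and small objects are dropped. The nucleus mask is
#' obtained by Otsu thresholding of the nucleus signal (nucleic-acid
#' channel if supplied, otherwise the high-signal core of the cell channel)
#' restricted to the cell mask, where the two-class assumption does hold;
#' nucleus pixels inherit their cell's label. Deterministic.
#'
#' @param signal Non-negative matrix (>= 64 px per side); cells bright.
#' @param nucleus_signal Optional matrix highlighting nuclei (defaults to
#'   `signal`).
#' @param smooth_sigma Gaussian pre-smoothing sigma, px.
#' @param min_area_px Minimum cell area, px.
#' @param watershed_tol Watershed tolerance (distance-map units).
#' @return List with `cells` and `nuclei` integer label matrices (same
#'   labels for a nucleus and its cell) and `n_cells`.
#' @export
segment_cells <- function(signal, nucleus_signal = NULL, smooth_sigma = 2,
                          min_area_px = 50, watershed_tol = 1) {
  if (nrow(signal) < 64 || ncol(signal) < 64)
    stop("validation error: image must be >= 64 px per side")
  if (is.null(nucleus_signal)) nucleus_signal <- signal
  rng <- range(signal)
  if (rng[2] == rng[1])
    return(list(cells = matrix(0L, nrow(signal), ncol(signal)),
                nuclei = matrix(0L, nrow(signal), ncol(signal)),
                n_cells = 0L))
  s01 <- (signal - rng[1]) / (rng[2] - rng[1])
  sm <- EBImage::gblur(EBImage::Image(s01), sigma = smooth_sigma)
  # estimate the threshold on the smoothed histogram (stable), apply it to
  # the raw image (boundary-faithful), and clean speckle by opening
  thr <- thresh_triangle(EBImage::imageData(sm))
  mask <- EBImage::opening(EBImage::Image(s01 > thr),
                           EBImage::makeBrush(3L, "disc"))
  mask <- EBImage::fillHull(mask)
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = watershed_tol)
  lab <- EBImage::imageData(labels)
  # drop small objects, relabel compactly
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  lab[lab > 0] <- remap[lab[lab > 0]]
  n_cells <- length(keep)
  if (n_cells == 0)
    return(list(cells = matrix(0L, nrow(signal), ncol(signal)),
                nuclei = matrix(0L, nrow(signal), ncol(signal)),
                n_cells = 0L))

  nuc <- matrix(0L, nrow(signal), ncol(signal))
  nr <- range(nucleus_signal)
  if (nr[2] > nr[1]) {
    n01 <- (nucleus_signal - nr[1]) / (nr[2] - nr[1])
    nsm <- EBImage::imageData(EBImage::gblur(EBImage::Image(n01),
                                             sigma = smooth_sigma / 2))
    inside <- lab > 0
    nthr <- EBImage::otsu(EBImage::Image(nsm * inside), range = c(0, 1))
    nmask <- nsm > nthr & inside
    nuc[nmask] <- lab[nmask]
  }
  list(cells = matrix(as.integer(lab), nrow(signal), ncol(signal)),
       nuclei = nuc, n_cells = as.integer(n_cells))
}

#' Per-cell morphometric features
#'
#' Computes, for every labelled cell: area and nuclear area (um^2),
#' nuclear-to-cell area ratio, nuclear roundness (isoperimetric quotient
#' `4*pi*A / P^2`, perimeter measured as the traced boundary-contour length
#' summed over nuclear components, clamped to 1), and the centroid. Cells
#' without nucleus pixels or whose nucleus leaks outside the cell are
#' flagged.
#'
#' @param labels A [segment_cells()] result (or list with `cells`,
#'   `nuclei`).
#' @param pixel_size Pixel size, um.
#' @return data.frame with one row per cell: `cell_id`, `area_um2`,
#'   `nuclear_area_um2`, `nc_ratio`, `nuclear_roundness`, `centroid_x`,
#'   `centroid_y` (px), `flagged`.
#' @export
cell_features <- function(labels, pixel_size = 1) {
  lab <- labels$cells; nuc <- labels$nuclei
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0)
    return(data.frame(cell_id = integer(0), area_um2 = numeric(0),
                      nuclear_area_um2 = numeric(0), nc_ratio = numeric(0),
                      nuclear_roundness = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      flagged = logical(0)))
  px2 <- pixel_size^2
  rows <- lapply(ids, function(id) {
    cmask <- lab == id
    nmask <- nuc == id
    area <- sum(cmask) * px2
    narea <- sum(nmask) * px2
    idx <- which(cmask, arr.ind = TRUE)
    cx <- mean(idx[, 2]); cy <- mean(idx[, 1])
    flagged <- narea == 0 || any(nmask & !cmask)
    roundness <- NA_real_
    if (narea > 0) {
      P <- mask_perimeter(nmask) * pixel_size
      roundness <- min(4 * pi * narea / P^2, 1)
    }
    data.frame(cell_id = id, area_um2 = area, nuclear_area_um2 = narea,
               nc_ratio = if (area > 0) narea / area else NA_real_,
               nuclear_roundness = roundness,
               centroid_x = cx, centroid_y = cy, flagged = flagged)
  })
  do.call(rbind, rows)
}

# Triangle threshold (Zack): on the image histogram, draw a line from the
# modal (background) bin to the farthest-populated bin and take the bin
# whose histogram point lies farthest below the line.
thresh_triangle <- function(x, n_bins = 256) {
  h <- tabulate(pmin(pmax(floor(x * (n_bins - 1)) + 1L, 1L), n_bins),
                n_bins)
  pk <- which.max(h)
  last <- max(which(h > 0))
  if (last <= pk) return(0.5)
  bx <- seq.int(pk, last)
  # distance of (bin, count) points below the peak-to-end chord
  fy <- h[pk] + (h[last] - h[pk]) * (bx - pk) / (last - pk)
  best <- bx[which.max(fy - h[bx])]
  (best - 1) / (n_bins - 1)
}

# Boundary-contour length of a binary mask: sum of traced contour polygon
# lengths over connected components (EBImage::ocontour; closed polygons).
mask_perimeter <- function(mask) {
  lb <- EBImage::bwlabel(EBImage::Image(mask * 1))
  oc <- EBImage::ocontour(lb)
  sum(vapply(oc, function(pts) {
    if (nrow(pts) < 2) return(4)  # single pixel
    d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), ])^2))
    sum(d)
  }, numeric(1)))
}
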