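#' Brenner gradient sharpness metric
#'
#' Sum over pixels of the squared finite differences at a fixed offset in
#' both directions, normalized by the pixel count:
#' `sum((I(x+s, y) - I(x, y))^2 + (I(x, y+s) - I(x, y))^2) / N`.
#' Zero iff the image is constant; invariant to additive offsets; scales
#' with the square of a multiplicative gain.
#'
#' @param image Non-negative real matrix, >= 8 px per side.
#' @param spacing Finite-difference offset in pixels (default 2, the classic
#'   Brenner form).
#' @return Scalar score >= 0.
#' @export
brenner <- function(image, spacing = 2L) {
  ny <- nrow(image); nx <- ncol(image)
  if (ny < 8 || nx < 8) stop("validation error: image must be >= 8 px")
  if (spacing >= nx || spacing >= ny)
    stop("validation error: spacing must be smaller than the image")
  dx <- image[, (spacing + 1):nx] - image[, 1:(nx - spacing)]
  dy <- image[(spacing + 1):ny, ] - image[1:(ny - spacing), ]
  (sum(dx^2) + sum(dy^2)) / (ny * nx)
}

#' Autofocus by axial back-propagation sweep
#'
#' Back-propagates the field over a grid of candidate distances and scores
#' the refocused intensity with the Brenner metric; the best distance is the
#' argmax with parabolic sub-step refinement. The sweep back-propagates with
#' negative distances, so `z` is the distance from the field's plane back
#' toward the sample: a field recorded after propagating a sample by `d`
#' refocuses at `z = d`.
#'
#' @param field A [complex_field()].
#' @param z_min,z_max Search range, um (`z_min < z_max`).
#' @param z_step Search step, um (> 0).
#' @param spacing Brenner spacing.
#' @param on Score on `"amplitude"` (default) or `"intensity"`. Amplitude
#'   scoring is markedly more robust for specimens with phase structure,
#'   whose defocused intensity develops caustic texture that out-scores the
#'   true focal plane.
#' @return List with `z_best` (um), `z` (grid), `score` (Brenner curve).
#' @export
autofocus_field <- function(field, z_min, z_max, z_step, spacing = 2L,
                            on = c("amplitude", "intensity")) {
  on <- match.arg(on)
  if (z_step <= 0) stop("validation error: z_step must be > 0")
  if (z_min >= z_max) stop("validation error: empty z range")
  zs <- seq(z_min, z_max, by = z_step)
  score <- vapply(zs, function(z) {
    f <- propagate(field, -z)
    img <- if (on == "intensity") Mod(f$values)^2 else Mod(f$values)
    brenner(img, spacing)
  }, numeric(1))
  k <- which.max(score)
  z_best <- zs[k]
  if (k > 1 && k < length(zs)) {
    cm <- score[k - 1]; c0 <- score[k]; cp <- score[k + 1]
    den <- cm - 2 * c0 + cp
    if (den < 0) z_best <- zs[k] + 0.5 * (cm - cp) / den * z_step
  }
  list(z_best = z_best, z = zs, score = score)
}

#' Tile-wise topographic height map
#'
#' Runs [autofocus_field()] on overlapping tiles of the field and assembles
#' the per-tile best refocus distance into a map. Tiles whose refocused
#' dynamic range is below a floor (empty background) are marked invalid and
#' filled from the nearest valid tile; the validity mask is returned. `z` is
#' reported relative to the field's plane (the coded surface); converting it
#' to a display height is a presentation choice (`height = z_ref - z`).
#'
#' @param field A [complex_field()].
#' @param tile_px Tile size in px (>= 32).
#' @param overlap_px Tile overlap in px.
#' @param z_min,z_max,z_step Search parameters, um.
#' @param range_floor Minimum in-focus amplitude dynamic range (max - min,
#'   relative to the tile median) for a tile to count as valid.
#' @return An object of class `height_map`: list with `z_values` (tile
#'   matrix, um), `valid` (logical matrix), `tile_centers_px`, `z`, `scores`
#'   (per-tile Brenner curves), `tile_px`, `z_range`, `z_step`.
#' @export
height_map <- function(field, tile_px = 64L, overlap_px = 16L,
                       z_min, z_max, z_step, range_floor = 0.1) {
  if (tile_px < 32) stop("validation error: tile size must be >= 32 px")
  g <- field$grid
  step <- tile_px - overlap_px
  y0 <- seq(1, max(1, g$ny - tile_px + 1), by = step)
  x0 <- seq(1, max(1, g$nx - tile_px + 1), by = step)
  zs <- seq(z_min, z_max, by = z_step)
  nty <- length(y0); ntx <- length(x0)
  # refocus the full field once per z (keeps every tile's diffraction
  # context), then score tiles on the refocused intensity
  surf <- array(NA_real_, c(nty, ntx, length(zs)))
  rng <- array(NA_real_, c(nty, ntx, length(zs)))
  for (k in seq_along(zs)) {
    amp <- Mod(propagate(field, -zs[k])$values)
    for (iy in seq_len(nty)) for (ix in seq_len(ntx)) {
      ys <- y0[iy]:(min(y0[iy] + tile_px - 1, g$ny))
      xs <- x0[ix]:(min(x0[ix] + tile_px - 1, g$nx))
      if (length(ys) < 32 || length(xs) < 32) next
      surf[iy, ix, k] <- brenner(amp[ys, xs])
      a <- amp[ys, xs]
      med <- stats::median(a)
      rng[iy, ix, k] <- if (med > 0) (max(a) - min(a)) / med else 0
    }
  }
  zvals <- matrix(NA_real_, nty, ntx)
  valid <- matrix(FALSE, nty, ntx)
  scores <- vector("list", nty * ntx)
  centers <- array(NA_real_, c(nty, ntx, 2))
  # near-empty tiles score far below tiles with real structure; gate on
  # the field-wide strongest tile so leakage from neighbours cannot
  # masquerade as content
  score_floor <- 0.1 * max(surf, na.rm = TRUE)
  for (iy in seq_len(nty)) for (ix in seq_len(ntx)) {
    sc <- surf[iy, ix, ]
    if (all(is.na(sc))) next
    k <- which.max(sc)
    zb <- zs[k]
    if (k > 1 && k < length(zs)) {
      den <- sc[k - 1] - 2 * sc[k] + sc[k + 1]
      if (!is.na(den) && den < 0)
        zb <- zs[k] + 0.5 * (sc[k - 1] - sc[k + 1]) / den * z_step
    }
    zvals[iy, ix] <- zb
    scores[[(iy - 1) * ntx + ix]] <- sc
    # a tile is trustworthy if, at its own best focus, it shows real
    # structure (amplitude dynamic range above the floor) and its score
    # curve is peaked rather than flat
    valid[iy, ix] <- rng[iy, ix, k] > range_floor &&
      max(sc, na.rm = TRUE) > 1.3 * stats::median(sc, na.rm = TRUE) &&
      max(sc, na.rm = TRUE) >= score_floor
    centers[iy, ix, ] <- c(y0[iy] + tile_px / 2, x0[ix] + tile_px / 2)
  }
  if (!any(valid)) stop("height map error: all tiles invalid")
  # nearest-valid fill
  vi <- which(valid, arr.ind = TRUE)
  for (iy in seq_along(y0)) for (ix in seq_along(x0)) {
    if (!valid[iy, ix]) {
      dd <- (vi[, 1] - iy)^2 + (vi[, 2] - ix)^2
      nb <- vi[which.min(dd), ]
      zvals[iy, ix] <- zvals[nb[1], nb[2]]
    }
  }
  structure(list(z_values = zvals, valid = valid,
                 tile_centers_px = centers,
                 z_range = c(z_min, z_max), z_step = z_step,
                 tile_px = tile_px, scores = scores),
            class = "height_map")
}
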