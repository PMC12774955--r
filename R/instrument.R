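#' System geometry of the lensless coded-surface imager
#'
#' Distances are in um. `d1` is the sample-to-coded-surface distance
#' (millimeter-scale working range), `d2` the fixed coded-surface-to-pixel
#' separation, `a` the virtual-state perturbation factor applied to `d2` in
#' the virtual forward path, and `source_distance` the source-to-sample
#' distance of the folded illumination path, which sets the geometric blur
#' scale of an extended emitter: a source-plane offset maps to a
#' detector-plane shift of `offset * (d1 + d2) / source_distance`.
#'
#' @param d1 Sample to coded surface, um (working range 200-2000).
#' @param d2 Coded surface to pixel array, um (default 840).
#' @param a Virtual-state propagation-distance perturbation factor
#'   (default 1.1; must differ from 1 when a virtual state is in use).
#' @param source_distance Source to sample, um (default 2e5).
#' @return An object of class `system_geometry`.
#' @export
system_geometry <- function(d1, d2 = 840, a = 1.1, source_distance = 2e5) {
  if (d1 <= 0 || d2 <= 0) stop("validation error: distances must be positive")
  if (a <= 0) stop("validation error: a must be positive")
  if (source_distance <= 0) stop("validation error: source_distance must be positive")
  structure(list(d1 = d1, d2 = d2, a = a, source_distance = source_distance),
            class = "system_geometry")
}

#' Jittered-grid scan plan
#'
#' Generates `n_side^2` lateral shift positions visited in serpentine
#' (boustrophedon) order. Every move between consecutive positions has a
#' length drawn uniformly in `[step_min, step_max]` um and a randomly
#' jittered heading (with mild mean reversion toward the row baseline so the
#' pattern stays grid-like), so consecutive nearest-neighbour spacing is
#' inside the configured interval by construction. With
#' `step_min == step_max` the jitter vanishes and the plan is an exact
#' rectangular serpentine grid. Positions are returned relative to the first
#' position and are bit-reproducible for a fixed seed.
#'
#' @param n_side Positions per side (>= 2).
#' @param step_min,step_max Step bounds in um (0 < step_min <= step_max).
#' @param seed Integer RNG seed.
#' @return An object of class `scan_plan`: list with `positions` (n x 2
#'   matrix, columns x, y in um), `n_side`, `step_min`, `step_max`, `seed`.
#' @export
make_scan_plan <- function(n_side, step_min, step_max, seed = 1L) {
  if (n_side < 2) stop("validation error: n_side must be >= 2")
  if (step_min <= 0) stop("validation error: step_min must be > 0")
  if (step_max < step_min) stop("validation error: step_max < step_min")
  # heading jitter amplitude, radians; zero when the step range is a point
  theta <- 0.5 * (step_max - step_min) / (step_max + step_min) * (pi / 2)
  pos <- with_seed(seed, {
    out <- matrix(0, n_side^2, 2)
    cur <- c(0, 0)
    k <- 2L
    for (r in seq_len(n_side)) {
      y_row <- cur[2]
      dir <- if (r %% 2 == 1) 1 else -1
      for (m in seq_len(n_side - 1)) {
        L <- stats::runif(1, step_min, step_max)
        revert <- if (theta > 0)
          max(-theta / 2, min(theta / 2, -0.5 * (cur[2] - y_row) / L)) else 0
        ang <- stats::runif(1, -theta, theta) + revert
        cur <- cur + L * c(dir * cos(ang), sin(ang))
        out[k, ] <- cur
        k <- k + 1L
      }
      if (r < n_side) {
        L <- stats::runif(1, step_min, step_max)
        ang <- pi / 2 + stats::runif(1, -theta, theta)
        cur <- cur + L * c(cos(ang), sin(ang))
        out[k, ] <- cur
        k <- k + 1L
      }
    }
    out
  })
  pos <- sweep(pos, 2, pos[1, ])
  structure(list(positions = pos, n_side = as.integer(n_side),
                 step_min = step_min, step_max = step_max,
                 seed = as.integer(seed)),
            class = "scan_plan")
}

#' Random coded surface
#'
#' Builds a complex transmission map with spatially correlated random
#' amplitude and phase (low-pass-filtered white noise). The correlation
#' length is set by `feature_size`; amplitudes span `amp_range` and phases
#' span `phase_range` radians (centered on zero). Deterministic per seed.
#'
#' @param grid A [pty_grid()].
#' @param seed Integer RNG seed.
#' @param feature_size Correlation length in um (>= pitch).
#' @param amp_range Length-2 amplitude interval inside \[0, 1\].
#' @param phase_range Total phase span in radians (default 2*pi).
#' @param label `"object_path"` or `"virtual_path"`.
#' @return An object of class `coded_surface`: list with `grid`, `values`,
#'   `label`.
#' @export
make_coded_surface <- function(grid, seed = 1L, feature_size = 4 * grid$pitch,
                               amp_range = c(0.3, 1), phase_range = 2 * pi,
                               label = c("object_path", "virtual_path")) {
  stopifnot(inherits(grid, "pty_grid"))
  label <- match.arg(label)
  if (feature_size < grid$pitch)
    stop("validation error: feature_size must be >= pitch")
  if (amp_range[1] < 0 || amp_range[2] > 1 || amp_range[1] > amp_range[2])
    stop("validation error: amp_range must lie inside [0, 1]")
  if (phase_range < 0) stop("validation error: phase_range must be >= 0")
  fields <- with_seed(seed, {
    list(a = smooth_noise(grid$ny, grid$nx, feature_size / grid$pitch),
         p = smooth_noise(grid$ny, grid$nx, feature_size / grid$pitch))
  })
  amp <- rescale01(fields$a) * diff(amp_range) + amp_range[1]
  pha <- (rescale01(fields$p) - 0.5) * phase_range
  structure(list(grid = grid, values = amp * exp(1i * pha), label = label),
            class = "coded_surface")
}

# Gaussian-correlated unit noise field: white noise filtered so its
# autocorrelation FWHM is ~ feature_px pixels.
smooth_noise <- function(ny, nx, feature_px) {
  w <- matrix(stats::rnorm(ny * nx), ny, nx)
  if (feature_px <= 1) return(w)
  # filter sigma chosen so the filtered field's autocorrelation (Gaussian,
  # sigma * sqrt(2)) has FWHM = feature_px
  sig <- feature_px / (2 * sqrt(2 * log(2)) * sqrt(2))
  fg <- freq_grids(ny, nx, 1)
  Hf <- exp(-2 * pi^2 * sig^2 * (fg$fx^2 + fg$fy^2))
  Re(ifft2u(fft2u(w + 0i) * Hf))
}

rescale01 <- function(x) {
  r <- range(x)
  if (r[2] == r[1]) return(matrix(0.5, nrow(x), ncol(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Partially coherent source model
#'
#' Represents an extended, finite-bandwidth emitter as a weighted set of
#' mutually incoherent point-source states plus a sampled Gaussian spectrum.
#' A point shape with one spatial state and one spectral sample is the fully
#' coherent (laser-diode) model. For a disc emitter the states sample the
#' disc with equal weights: one central state plus a symmetric ring at the
#' equal-area median radius, so the weighted centroid is at the origin.
#'
#' @param shape `"point"`, `"disc"`, or a non-negative matrix mask giving the
#'   emitter intensity profile (sampled at `mask_pitch` um/pixel).
#' @param radius Disc radius in um (required for `"disc"`).
#' @param n_states Number of spatial states (>= 1).
#' @param bandwidth_fwhm Spectral FWHM in nm (0 for monochromatic).
#' @param n_spectral Number of spectral samples (>= 1).
#' @param center_wavelength Center wavelength in nm.
#' @param mask_pitch Sampling pitch of a matrix `shape`, um/pixel.
#' @param seed RNG seed (used only for mask sampling).
#' @return An object of class `source_model`: list with `states` (n x 3
#'   matrix: offset_x, offset_y um, weight) and `spectrum` (k x 2 matrix:
#'   wavelength nm, weight); both weight sets sum to 1.
#' @export
make_source_model <- function(shape = "point", radius = NULL, n_states = 1L,
                              bandwidth_fwhm = 0, n_spectral = 1L,
                              center_wavelength = 405, mask_pitch = 1,
                              seed = 1L) {
  if (n_states < 1 || n_spectral < 1)
    stop("validation error: n_states and n_spectral must be >= 1")
  if (is.matrix(shape)) {
    if (any(shape < 0)) stop("validation error: mask must be non-negative")
    idx <- which(shape > 0, arr.ind = TRUE)
    if (nrow(idx) == 0) stop("validation error: empty mask")
    k <- min(n_states, nrow(idx))
    pick <- with_seed(seed,
      sample.int(nrow(idx), k, prob = shape[idx]))
    ctr <- c(mean(range(idx[, 2])), mean(range(idx[, 1])))
    states <- cbind((idx[pick, 2] - ctr[1]) * mask_pitch,
                    (idx[pick, 1] - ctr[2]) * mask_pitch,
                    shape[idx[pick, , drop = FALSE]])
  } else if (identical(shape, "point") || n_states == 1L) {
    states <- matrix(c(0, 0, 1), 1, 3)
  } else if (identical(shape, "disc")) {
    if (is.null(radius) || radius <= 0)
      stop("validation error: disc shape requires a positive radius")
    nring <- n_states - 1L
    th <- 2 * pi * seq_len(nring) / nring
    rr <- radius / sqrt(2)  # equal-area median radius
    states <- rbind(c(0, 0, 1),
                    cbind(rr * cos(th), rr * sin(th), 1))
  } else stop("validation error: unknown source shape")
  states[, 3] <- states[, 3] / sum(states[, 3])
  colnames(states) <- c("offset_x", "offset_y", "weight")

  if (n_spectral == 1L || bandwidth_fwhm <= 0) {
    spectrum <- matrix(c(center_wavelength, 1), 1, 2)
  } else {
    off <- seq(-bandwidth_fwhm, bandwidth_fwhm, length.out = n_spectral)
    w <- stats::dnorm(off, sd = bandwidth_fwhm / (2 * sqrt(2 * log(2))))
    spectrum <- cbind(center_wavelength + off, w / sum(w))
  }
  colnames(spectrum) <- c("wavelength", "weight")
  structure(list(states = states, spectrum = spectrum),
            class = "source_model")
}

# Detector-plane shift (um) of each source state: shadow magnification of
# the emitter offset through the d1 + d2 lever arm.
source_detector_offsets <- function(source, geometry) {
  scale <- (geometry$d1 + geometry$d2) / geometry$source_distance
  source$states[, 1:2, drop = FALSE] * scale
}
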