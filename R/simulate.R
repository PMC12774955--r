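#' Synthetic cell phantom
#'
#' Generates a ground-truth phantom emulating a smear of unstained cells:
#' elliptical cells with protein-rich cytoplasm and nucleic-acid-rich nuclei,
#' smooth (cosine-tapered) edges, per-cell random topographic height, and a
#' background/cytoplasm/nucleus label map. Amounts are areal molar densities
#' (mol/um^2) — the product concentration x path length of the Beer-Lambert
#' law, which is the only identifiable combination. Defaults give peak
#' optical densities of roughly 0.2-0.8 at the deep-UV wavelengths under the
#' default extinction table, in line with unstained single cells.
#'
#' `kind = "mononuclear"` produces round cells with one large round nucleus
#' (high nuclear-to-cell area ratio); `kind = "polymorphonuclear"` produces
#' cells with a three-lobed nucleus (low roundness, lower area ratio);
#' `"generic"` mixes sizes freely.
#'
#' @param grid A [pty_grid()].
#' @param n_cells Number of cells (>= 0; 0 gives an empty phantom).
#' @param seed RNG seed.
#' @param pro_range,nuc_range Peak areal-density ranges, mol/um^2, for
#'   cytoplasmic protein and nuclear nucleic acid. The defaults give, under
#'   [default_extinction_table()], nuclear nucleic-acid optical densities of
#'   ~0.3-0.7 at 266 nm (~6 pg of nucleic acid in a 10 um nucleus, the
#'   diploid-genome scale) and protein optical densities of ~0.1-0.2 at
#'   280 nm.
#' @param height_range Cell height range, um.
#' @param radius_range Cell radius range, um.
#' @param dn Refractive-index contrast used for the phase map.
#' @param kind Cell morphology class (see Details).
#' @param margin_px Border kept free of cells, px.
#' @return An object of class `phantom`: list with `grid`, `n_pro`, `n_nuc`
#'   (mol/um^2 matrices), `height` (um), `dn`, `labels` (0 background,
#'   1 cytoplasm, 2 nucleus), `cell_id` (per-pixel owning cell, 0 outside).
#' @export
make_cell_phantom <- function(grid, n_cells, seed = 1L,
                              pro_range = c(2e-17, 5e-17),
                              nuc_range = c(4e-16, 9e-16),
                              height_range = c(0.5, 3),
                              radius_range = NULL,
                              dn = 0.1,
                              kind = c("generic", "mononuclear",
                                       "polymorphonuclear"),
                              margin_px = 12L) {
  stopifnot(inherits(grid, "pty_grid"))
  kind <- match.arg(kind)
  if (n_cells < 0) stop("validation error: n_cells must be >= 0")
  ny <- grid$ny; nx <- grid$nx; p <- grid$pitch
  if (is.null(radius_range))
    radius_range <- c(9, 14) * p
  ph <- list(grid = grid,
             n_pro = matrix(0, ny, nx), n_nuc = matrix(0, ny, nx),
             height = matrix(0, ny, nx), dn = dn,
             labels = matrix(0L, ny, nx), cell_id = matrix(0L, ny, nx))
  class(ph) <- "phantom"
  if (n_cells == 0) return(ph)

  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  ys <- matrix(rep(seq_len(ny), nx), ny, nx)

  ph <- with_seed(seed, {
    centers <- matrix(NA_real_, 0, 2)
    placed <- 0L
    tries <- 0L
    radii <- numeric(0)
    while (placed < n_cells) {
      tries <- tries + 1L
      if (tries > 200L * n_cells)
        stop("placement error: could not place cells without overlap; ",
             "grid too small for n_cells")
      r_um <- stats::runif(1, radius_range[1], radius_range[2])
      # if placement keeps failing (crowded grid), progressively favour
      # smaller cells instead of giving up; deterministic, and inactive
      # for grids where the first draws fit
      if (tries > 50L)
        r_um <- max(0.6 * radius_range[1],
                    r_um * 0.97^(tries - 50L))
      r_px <- r_um / p
      cx <- stats::runif(1, margin_px + r_px, nx - margin_px - r_px)
      cy <- stats::runif(1, margin_px + r_px, ny - margin_px - r_px)
      if (cx < margin_px + r_px || cy < margin_px + r_px) next
      ok <- TRUE
      if (placed > 0) {
        dmin <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
        ok <- all(dmin > (radii + r_px) + 2)
      }
      if (!ok) next
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, r_px)
      placed <- placed + 1L
    }

    for (ci in seq_len(n_cells)) {
      cx <- centers[ci, 1]; cy <- centers[ci, 2]; r_px <- radii[ci]
      ecc <- if (kind == "generic") stats::runif(1, 0.75, 1) else
        stats::runif(1, 0.9, 1)
      ang <- stats::runif(1, 0, pi)
      ca <- cos(ang); sa <- sin(ang)
      u <- (xs - cx) * ca + (ys - cy) * sa
      v <- -(xs - cx) * sa + (ys - cy) * ca
      rr <- sqrt((u / r_px)^2 + (v / (r_px * ecc))^2)
      edge <- 2 / r_px  # taper width in normalized radius
      cellw <- taper(rr, 1, edge)
      inside <- cellw > 0.5

      # nucleus mask / weight
      if (kind == "polymorphonuclear") {
        nw <- matrix(0, ny, nx)
        lob_r <- 0.30 * r_px
        off <- 0.42 * r_px
        for (lo in 0:2) {
          la <- ang + 2 * pi * lo / 3 + stats::runif(1, -0.2, 0.2)
          lx <- cx + off * cos(la); ly <- cy + off * sin(la)
          rl <- sqrt((xs - lx)^2 + (ys - ly)^2) / lob_r
          nw <- pmax(nw, taper(rl, 1, 2 / lob_r))
        }
        nw <- nw * cellw
      } else {
        nfrac <- if (kind == "mononuclear") stats::runif(1, 0.62, 0.72) else
          stats::runif(1, 0.4, 0.55)
        nr <- nfrac * r_px
        ox <- stats::runif(1, -0.1, 0.1) * r_px
        oy <- stats::runif(1, -0.1, 0.1) * r_px
        rn <- sqrt((xs - cx - ox)^2 + (ys - cy - oy)^2) / nr
        nw <- taper(rn, 1, 2 / nr) * cellw
      }
      nmask <- nw > 0.5

      amp_pro <- stats::runif(1, pro_range[1], pro_range[2])
      amp_nuc <- stats::runif(1, nuc_range[1], nuc_range[2])
      h <- stats::runif(1, height_range[1], height_range[2])
      # protein fills the whole cell (cytoplasm + nucleoproteins at reduced
      # level inside the nucleus); nucleic acid is nuclear
      ph$n_pro <- ph$n_pro + amp_pro * cellw * (1 - 0.4 * nw)
      ph$n_nuc <- ph$n_nuc + amp_nuc * nw
      ph$height <- pmax(ph$height, h * cellw)
      ph$labels[inside] <- 1L
      ph$labels[nmask] <- 2L
      ph$cell_id[inside | nmask] <- ci
    }
    ph
  })
  ph$n_pro[ph$labels == 0L] <- 0
  ph$n_nuc[ph$labels == 0L] <- 0
  ph
}

# Smooth edge taper: 1 well inside rr < r0, 0 outside, cosine roll-off of
# width w in the same (normalized) units.
taper <- function(rr, r0, w) {
  t <- (r0 + w / 2 - rr) / w
  pmin(pmax(t, 0), 1)^2 * (3 - 2 * pmin(pmax(t, 0), 1))
}

#' Complex exit field of a phantom
#'
#' Applies the Beer-Lambert law on intensity: the amplitude transmission is
#' `10^(-OD/2)` with `OD = eps_pro * n_pro + eps_nuc * n_nuc` when the
#' wavelength is present in the extinction table, and 1 otherwise (phase-only
#' imaging, e.g. 405 nm). The phase is `2*pi * dn * height / lambda`.
#'
#' @param phantom A [make_cell_phantom()] phantom.
#' @param wavelength Wavelength in nm.
#' @param eps An [extinction_table()] (may be NULL for phase-only).
#' @return A [complex_field()] at the sample plane (wavelength taken from
#'   `wavelength`, grid geometry from the phantom).
#' @export
sample_exit_field <- function(phantom, wavelength, eps = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  if (any(phantom$n_pro < 0) || any(phantom$n_nuc < 0))
    stop("validation error: negative areal amounts")
  g <- phantom$grid
  grid <- pty_grid(g$nx, g$ny, g$pitch, wavelength)
  if (!is.null(eps) && wavelength %in% eps$wavelengths) {
    od <- eps_at(eps, wavelength, "pro") * phantom$n_pro +
      eps_at(eps, wavelength, "nuc") * phantom$n_nuc
    amp <- 10^(-od / 2)
  } else {
    amp <- matrix(1, g$ny, g$nx)
  }
  phase <- 2 * pi * phantom$dn * phantom$height / (wavelength * 1e-3)
  complex_field(amp * exp(1i * phase), grid, plane = "sample")
}

#' Simulate a diffraction dataset
#'
#' Exact forward model of the coded-surface lensless imager. For each scan
#' position the exit field is propagated to the coded-surface plane (d1),
#' shifted by the (true) scan position, masked by the coded surface,
#' propagated to the detector (d2), and its intensity recorded. Partial
#' coherence is an incoherent sum: spectral samples re-evaluate the
#' propagation phases at each sampled wavelength, and each spatial source
#' state shifts the detector-plane field by its geometric shadow offset
#' `offset * (d1 + d2) / source_distance` before squaring.
#'
#' Optional artifacts emulate real system errors: `ghost` adds a weak
#' delayed coherent copy of the detector field (sensor-stack double bounce,
#' amplitude `ghost_r`, extra path `ghost_delta`), `shot`/`read` add scaled
#' Poisson and Gaussian noise, and `position_jitter` perturbs the true
#' positions while recording the nominal ones.
#'
#' @param phantom A [make_cell_phantom()] phantom.
#' @param cs A [make_coded_surface()] coded surface on the detector grid.
#' @param geometry A [system_geometry()].
#' @param scan A [make_scan_plan()] scan plan.
#' @param source A [make_source_model()] (default: coherent point source).
#' @param eps [extinction_table()] or NULL.
#' @param wavelength Center wavelength in nm (default: the coded-surface
#'   grid's wavelength).
#' @param background_level Mean illumination intensity on empty pixels.
#' @param artifacts Character vector, subset of
#'   `c("ghost", "shot", "read", "position_jitter")`.
#' @param ghost_r,ghost_delta Ghost amplitude and extra path (um; default
#'   `2 * d2`).
#' @param photon_budget Counts/pixel at background for shot noise.
#' @param read_sigma Read-noise standard deviation (intensity units).
#' @param jitter_px Position jitter half-width in pixels.
#' @param seed RNG seed for noise and jitter.
#' @return An object of class `diffraction_dataset`: list with `frames`
#'   (list of intensity matrices), `scan` (nominal), `true_positions`,
#'   `geometry`, `source`, `wavelength`, `background_level`, `pitch`,
#'   `clipped_fraction`.
#' @export
simulate_dataset <- function(phantom, cs, geometry, scan,
                             source = make_source_model(),
                             eps = NULL, wavelength = NULL,
                             background_level = 1,
                             artifacts = character(0),
                             ghost_r = 0.1, ghost_delta = NULL,
                             photon_budget = 1e4, read_sigma = 1e-3,
                             jitter_px = 2, seed = 1L) {
  stopifnot(inherits(phantom, "phantom"), inherits(cs, "coded_surface"),
            inherits(geometry, "system_geometry"),
            inherits(scan, "scan_plan"), inherits(source, "source_model"))
  g <- phantom$grid
  if (cs$grid$nx != g$nx || cs$grid$ny != g$ny)
    stop("validation error: coded-surface grid mismatch")
  bad <- setdiff(artifacts, c("ghost", "shot", "read", "position_jitter"))
  if (length(bad)) stop("validation error: unknown artifacts: ",
                        paste(bad, collapse = ", "))
  if (is.null(wavelength)) wavelength <- cs$grid$wavelength
  if (is.null(ghost_delta)) ghost_delta <- 2 * geometry$d2
  pitch <- g$pitch
  n_frames <- nrow(scan$positions)

  true_pos <- scan$positions
  if ("position_jitter" %in% artifacts) {
    true_pos <- true_pos + with_seed(seed + 1L,
      matrix(stats::runif(2 * n_frames, -jitter_px, jitter_px),
             n_frames, 2)) * pitch
  }

  # spectral samples: offsets applied around the requested center wavelength
  lam_offsets <- source$spectrum[, 1] - stats::weighted.mean(
    source$spectrum[, 1], source$spectrum[, 2])
  det_off <- source_detector_offsets(source, geometry) / pitch  # px

  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) frames[[i]] <- matrix(0, g$ny, g$nx)

  exit0 <- sample_exit_field(phantom, wavelength, eps)
  for (k in seq_len(nrow(source$spectrum))) {
    lam_k <- wavelength + lam_offsets[k]
    w_k <- source$spectrum[k, 2]
    gk <- pty_grid(g$nx, g$ny, pitch, lam_k)
    exit_k <- complex_field(exit0$values, gk, plane = "sample")
    at_cs <- propagate(exit_k, geometry$d1, plane = "coded_surface")
    at_cs_hat <- fft2u(at_cs$values)
    H2 <- as_transfer(g$ny, g$nx, pitch, lam_k, geometry$d2)
    Hg <- if ("ghost" %in% artifacts)
      as_transfer(g$ny, g$nx, pitch, lam_k, ghost_delta) else NULL
    for (i in seq_len(n_frames)) {
      sx <- -true_pos[i, 1] / pitch
      sy <- -true_pos[i, 2] / pitch
      shifted <- ifft2u(at_cs_hat * shift_ramp(g$ny, g$nx, sy, sx))
      det_hat <- fft2u(shifted * cs$values) * H2
      if (!is.null(Hg)) det_hat <- det_hat + ghost_r * det_hat * Hg
      for (s in seq_len(nrow(source$states))) {
        w_s <- source$states[s, 3]
        if (det_off[s, 1] == 0 && det_off[s, 2] == 0) {
          psi <- ifft2u(det_hat)
        } else {
          psi <- ifft2u(det_hat *
            shift_ramp(g$ny, g$nx, det_off[s, 2], det_off[s, 1]))
        }
        frames[[i]] <- frames[[i]] + w_k * w_s * Mod(psi)^2
      }
    }
  }

  for (i in seq_len(n_frames))
    frames[[i]] <- frames[[i]] * background_level

  clipped <- 0
  if (any(c("shot", "read") %in% artifacts)) {
    frames <- with_seed(seed + 2L, {
      for (i in seq_len(n_frames)) {
        f <- frames[[i]]
        if ("shot" %in% artifacts)
          f <- matrix(stats::rpois(length(f), f * photon_budget) /
                        photon_budget, nrow(f), ncol(f))
        if ("read" %in% artifacts)
          f <- f + matrix(stats::rnorm(length(f), sd = read_sigma),
                          nrow(f), ncol(f))
        clipped <- clipped + mean(f < 0)
        f[f < 0] <- 0
        frames[[i]] <- f
      }
      frames
    })
    clipped <- clipped / n_frames
  }

  structure(list(frames = frames, scan = scan, true_positions = true_pos,
                 geometry = geometry, source = source,
                 wavelength = wavelength,
                 background_level = background_level, pitch = pitch,
                 grid = pty_grid(g$nx, g$ny, pitch, wavelength),
                 clipped_fraction = clipped),
            class = "diffraction_dataset")
}

#' @export
print.diffraction_dataset <- function(x, ...) {
  cat(sprintf(
    "<diffraction_dataset: %d frames of %d x %d px, %g nm, pitch %g um>\n",
    length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
    x$wavelength, x$pitch))
  invisible(x)
}
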