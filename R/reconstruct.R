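#' Reconstruction options
#'
#' @param n_iter Total iterations (epochs) over the dataset.
#' @param use_virtual Enable the virtual error-bin state.
#' @param a Virtual-path propagation perturbation factor (must differ from 1
#'   when `use_virtual` is TRUE; default 1.1).
#' @param n_modes_used Number of source states included in the forward model
#'   (NULL = all states of the supplied source model).
#' @param multires_levels 1 = single resolution, 2 = half-resolution warm
#'   start (30% of iterations) then full resolution (default 2).
#' @param update_step Relaxation of the regularized inverse-modulation
#'   update, in (0, 1]; larger is more aggressive (default 0.9).
#' @param refine_positions_every Refine scan positions every k iterations
#'   (0 = never).
#' @param seed RNG seed (frame ordering, virtual-state initialization).
#' @return An object of class `recon_options`.
#' @export
recon_options <- function(n_iter = 100, use_virtual = FALSE, a = 1.1,
                          n_modes_used = NULL, multires_levels = 2,
                          update_step = 0.9, refine_positions_every = 0,
                          seed = 1L) {
  if (n_iter < 1) stop("validation error: n_iter must be >= 1")
  if (use_virtual && a == 1)
    stop("validation error: a must differ from 1 when use_virtual is TRUE")
  if (update_step <= 0 || update_step > 1)
    stop("validation error: update_step must be in (0, 1]")
  if (!multires_levels %in% c(1, 2))
    stop("validation error: multires_levels must be 1 or 2")
  structure(list(n_iter = as.integer(n_iter), use_virtual = use_virtual,
                 a = a, n_modes_used = n_modes_used,
                 multires_levels = as.integer(multires_levels),
                 update_step = update_step,
                 refine_positions_every = as.integer(refine_positions_every),
                 seed = as.integer(seed)),
            class = "recon_options")
}

# Internal: assemble the per-run context (transfer functions, source
# offsets) for one resolution level.
recon_context <- function(ny, nx, pitch, wavelength, geometry, source,
                          use_virtual, a, n_modes_used = NULL) {
  states <- source$states
  if (!is.null(n_modes_used) && n_modes_used < nrow(states)) {
    states <- states[seq_len(n_modes_used), , drop = FALSE]
    states[, 3] <- states[, 3] / sum(states[, 3])
  }
  off <- states[, 1:2, drop = FALSE] *
    (geometry$d1 + geometry$d2) / geometry$source_distance / pitch
  list(
    H2 = as_transfer(ny, nx, pitch, wavelength, geometry$d2),
    Hv = if (use_virtual)
      as_transfer(ny, nx, pitch, wavelength, geometry$d2 * a) else NULL,
    weights = states[, 3],
    det_off = off,
    ny = ny, nx = nx, pitch = pitch
  )
}

# Forward model for one frame: returns detector-plane state wavefields for
# the object path (and virtual path), intermediate fields needed by the
# update, and the model intensity.
forward_frame <- function(E, Ev, cs_vals, csv_vals, pos_px, ctx) {
  ramp_m <- shift_ramp(ctx$ny, ctx$nx, -pos_px[2], -pos_px[1])
  phi <- ifft2u(fft2u(E) * ramp_m)
  exit <- phi * cs_vals
  psi_hat <- fft2u(exit) * ctx$H2
  K <- length(ctx$weights)
  states <- vector("list", K)
  for (s in seq_len(K)) {
    states[[s]] <- if (ctx$det_off[s, 1] == 0 && ctx$det_off[s, 2] == 0)
      ifft2u(psi_hat)
    else
      ifft2u(psi_hat * shift_ramp(ctx$ny, ctx$nx,
                                  ctx$det_off[s, 2], ctx$det_off[s, 1]))
  }
  model <- Reduce(`+`, Map(function(ps, w) w * Mod(ps)^2,
                           states, as.list(ctx$weights)))
  out <- list(phi = phi, exit = exit, psi_hat = psi_hat, states = states,
              ramp_m = ramp_m, model = model)
  if (!is.null(ctx$Hv)) {
    phiv <- ifft2u(fft2u(Ev) * ramp_m)
    exitv <- phiv * csv_vals
    psiv_hat <- fft2u(exitv) * ctx$Hv
    statesv <- vector("list", K)
    for (s in seq_len(K)) {
      statesv[[s]] <- if (ctx$det_off[s, 1] == 0 && ctx$det_off[s, 2] == 0)
        ifft2u(psiv_hat)
      else
        ifft2u(psiv_hat * shift_ramp(ctx$ny, ctx$nx,
                                     ctx$det_off[s, 2], ctx$det_off[s, 1]))
    }
    out$phiv <- phiv; out$exitv <- exitv; out$psiv_hat <- psiv_hat
    out$statesv <- statesv
    out$model <- out$model + Reduce(`+`, Map(function(ps, w) w * Mod(ps)^2,
                                             statesv, as.list(ctx$weights)))
  }
  out
}

#' Forward model states for one frame
#'
#' Evaluates the mixed-state forward model of a reconstruction state at one
#' scan position: the object field is shifted to the position, masked by the
#' coded surface and propagated to the detector; the virtual field (if
#' active) follows the same path with its own coded surface and the
#' perturbed distance `d2 * a`. The model intensity is the weighted
#' incoherent sum over all source states of both paths.
#'
#' @param state A `recon_state` (see [reconstruct()]).
#' @param position_index Frame index (1-based).
#' @return List with `states_object`, `states_virtual` (lists of complex
#'   detector wavefields, one per source state) and `model_intensity`.
#' @export
forward_states <- function(state, position_index) {
  n <- nrow(state$positions)
  if (position_index < 1 || position_index > n)
    stop("validation error: position index out of range")
  ctx <- recon_context(nrow(state$E), ncol(state$E), state$pitch,
                       state$wavelength, state$geometry, state$source,
                       use_virtual = !is.null(state$E_virtual) &&
                         state$use_virtual,
                       a = state$a, n_modes_used = state$n_modes_used)
  pos_px <- state$positions[position_index, ] / state$pitch
  fw <- forward_frame(state$E, state$E_virtual, state$CS, state$CS_virtual,
                      pos_px, ctx)
  list(states_object = fw$states,
       states_virtual = if (is.null(fw$statesv)) list() else fw$statesv,
       model_intensity = fw$model)
}

#' Intensity projection for an incoherent mixture
#'
#' Scales every state wavefield by `sqrt(measured / model)` pixel-wise
#' (shared-magnitude projection), so the updated incoherent mixture
#' reproduces the measured intensity exactly while per-state intensity
#' ratios are preserved. Where the model intensity is below the floor
#' (`1e-12 x` frame mean), each state is replaced by
#' `sqrt(measured / K) * phase(state)`.
#'
#' @param states List of complex detector wavefields (all paths pooled).
#' @param measured Non-negative measured intensity frame.
#' @param weights Per-state weights of the incoherent sum (same length).
#'   Defaults to 1 for every state (plain intensity summation).
#' @return List of updated state wavefields.
#' @export
project_intensity <- function(states, measured, weights = NULL) {
  if (any(measured < 0)) stop("validation error: negative measurement")
  K <- length(states)
  if (is.null(weights)) weights <- rep(1, K)
  model <- Reduce(`+`, Map(function(ps, w) w * Mod(ps)^2,
                           states, as.list(weights)))
  floorv <- 1e-12 * mean(measured)
  fac <- sqrt(measured / pmax(model, floorv))
  low <- model < floorv
  out <- lapply(seq_len(K), function(s) {
    ps <- states[[s]] * fac
    if (any(low)) {
      ph <- states[[s]][low]
      ph <- ifelse(Mod(ph) > 0, ph / Mod(ph), 1 + 0i)
      ps[low] <- sqrt(measured[low] / (K * weights[s])) * ph
    }
    ps
  })
  out
}

#' Iterative mixed-state ptychographic reconstruction
#'
#' Reconstructs the object wavefield at the coded-surface plane (and, when
#' enabled, a virtual error-bin wavefield) from a stack of diffraction
#' intensities. Each epoch visits the frames in a seeded random order; for
#' every frame the forward model is evaluated, the measured intensity is
#' enforced by shared-magnitude projection, and each path's corrected exit
#' field drives a regularized inverse-modulation (rPIE-style) update of its
#' field, with the denominator mixing `|CS|^2` and its maximum according to
#' `update_step`. Source states are shifted replicas of the master field
#' with fixed geometric offsets, so there is a single unknown object field.
#' With `multires_levels = 2` the first 30% of iterations run at half
#' resolution and the fields are then Fourier-upsampled.
#'
#' The coded surface is treated as known and fixed; the virtual path uses
#' the same coded surface and the perturbed propagation distance `d2 * a`.
#' The virtual field is initialized to small seeded complex noise so that
#' only model-inconsistent signal accumulates in it.
#'
#' @param dataset A [simulate_dataset()] result (or equivalent structure).
#' @param cs The known [make_coded_surface()] coded surface.
#' @param geometry A [system_geometry()] (default: the dataset's).
#' @param source A [make_source_model()] for the reconstruction (default:
#'   the dataset's).
#' @param opts A [recon_options()].
#' @return An object of class `recon_state`: list with `E`, `E_virtual`,
#'   `CS`, `CS_virtual`, `positions` (um, refined), `history` (per-epoch
#'   data-fidelity error), plus the geometry/source/wavelength context
#'   needed to re-evaluate the forward model.
#' @export
reconstruct <- function(dataset, cs, geometry = NULL, source = NULL,
                        opts = recon_options()) {
  stopifnot(inherits(dataset, "diffraction_dataset"),
            inherits(cs, "coded_surface"), inherits(opts, "recon_options"))
  if (is.null(geometry)) geometry <- dataset$geometry
  if (is.null(source)) source <- dataset$source
  if (opts$use_virtual && geometry$a != opts$a) geometry$a <- opts$a
  ny <- nrow(dataset$frames[[1]]); nx <- ncol(dataset$frames[[1]])
  if (cs$grid$ny != ny || cs$grid$nx != nx)
    stop("validation error: coded-surface grid mismatch")
  pitch <- dataset$pitch
  lam <- dataset$wavelength
  n_frames <- length(dataset$frames)
  bg <- dataset$background_level

  # iteration split across resolution levels
  if (opts$multires_levels == 2 && ny %% 2 == 0 && nx %% 2 == 0 &&
      opts$n_iter >= 10) {
    iters <- c(max(1L, round(0.3 * opts$n_iter)),
               opts$n_iter - max(1L, round(0.3 * opts$n_iter)))
    levels <- c(0.5, 1)
  } else {
    iters <- opts$n_iter
    levels <- 1
  }

  E <- NULL; Ev <- NULL
  history <- numeric(0)
  positions <- dataset$scan$positions
  epoch_seed <- opts$seed

  for (li in seq_along(levels)) {
    fct <- levels[li]
    if (fct != 1) {
      frames <- lapply(dataset$frames, bin2)
      csv <- resample(complex_field(cs$values, cs$grid), fct)$values
      lny <- ny / 2; lnx <- nx / 2; lpitch <- pitch * 2
    } else {
      frames <- dataset$frames
      csv <- cs$values
      lny <- ny; lnx <- nx; lpitch <- pitch
    }
    if (is.null(E)) {
      E <- matrix(sqrt(bg) + 0i, lny, lnx)
      Ev <- if (opts$use_virtual)
        with_seed(opts$seed + 7L,
                  matrix(complex(real = stats::rnorm(lny * lnx),
                                 imaginary = stats::rnorm(lny * lnx)),
                         lny, lnx) * 1e-3 * sqrt(bg))
      else NULL
    } else if (fct == 1 && nrow(E) != ny) {
      gE <- pty_grid(lnx / 2, lny / 2, pitch * 2, lam)
      # carry only the amplitude of the warm start: the binned low-res
      # problem is not exactly consistent with the data, and the phase
      # configuration it settles on (vortices included) can trap the
      # full-resolution refinement, while amplitude-only warm starts
      # converge as fast as the flat initialization
      E <- Mod(resample(complex_field(E, gE), 2)$values) + 0i
      if (!is.null(Ev))
        Ev <- with_seed(opts$seed + 8L,
                        matrix(complex(real = stats::rnorm(lny * lnx),
                                       imaginary = stats::rnorm(lny * lnx)),
                               lny, lnx) * 1e-3 * sqrt(bg))
    }
    ctx <- recon_context(lny, lnx, lpitch, lam, geometry, source,
                         use_virtual = opts$use_virtual, a = opts$a,
                         n_modes_used = opts$n_modes_used)
    gamma <- 1 - opts$update_step
    csmax2 <- max(Mod(csv)^2)
    denom <- (1 - gamma) * Mod(csv)^2 + gamma * csmax2

    for (it in seq_len(iters[li])) {
      order_i <- with_seed(epoch_seed, sample.int(n_frames))
      epoch_seed <- epoch_seed + 1L
      err_acc <- 0
      for (i in order_i) {
        pos_px <- positions[i, ] / lpitch
        fw <- forward_frame(E, Ev, csv, csv, pos_px, ctx)
        meas <- frames[[i]]
        err_acc <- err_acc +
          sum((sqrt(pmax(fw$model, 0)) - sqrt(meas))^2) / sum(meas)
        allstates <- c(fw$states, fw$statesv)
        w2 <- c(ctx$weights, if (!is.null(fw$statesv)) ctx$weights)
        upd <- project_intensity(allstates, meas, weights = w2)
        # recombine corrected states into corrected path spectra
        K <- length(ctx$weights)
        # in-band residual: back-propagate the *difference* of corrected and
        # model detector spectra, so out-of-band exit content (invisible to
        # the band-limited measurement) is left untouched and the truth is
        # an exact fixed point
        psi_hat2 <- accumulate_states(upd[seq_len(K)], ctx)
        dexit <- ifft2u((psi_hat2 - fw$psi_hat) * Conj(ctx$H2))
        phi2 <- fw$phi + Conj(csv) * dexit / denom
        E <- ifft2u(fft2u(phi2) * Conj(fw$ramp_m))
        if (!is.null(fw$statesv)) {
          psiv_hat2 <- accumulate_states(upd[K + seq_len(K)], ctx)
          dexitv <- ifft2u((psiv_hat2 - fw$psiv_hat) * Conj(ctx$Hv))
          phiv2 <- fw$phiv + Conj(csv) * dexitv / denom
          Ev <- ifft2u(fft2u(phiv2) * Conj(fw$ramp_m))
        }
      }
      history <- c(history, err_acc / n_frames)
      if (any(!is.finite(Re(E))))
        stop("reconstruction diverged: non-finite object field at iteration ",
             length(history))
      if (opts$refine_positions_every > 0 && li == length(levels) &&
          it >= 2 && it %% opts$refine_positions_every == 0) {
        st <- make_state(E, Ev, csv, csv, positions, history, geometry,
                         source, lam, lpitch, bg, opts)
        positions <- refine_positions(st, dataset, frames_override = frames,
                                      pitch_override = lpitch)$positions
      }
    }
  }

  make_state(E, Ev, cs$values, cs$values, positions, history, geometry,
             source, lam, pitch, bg, opts)
}

make_state <- function(E, Ev, csv, csvv, positions, history, geometry,
                       source, wavelength, pitch, background, opts) {
  structure(list(E = E, E_virtual = Ev, CS = csv, CS_virtual = csvv,
                 positions = positions, history = history,
                 geometry = geometry, source = source,
                 wavelength = wavelength, pitch = pitch,
                 background_level = background,
                 use_virtual = opts$use_virtual, a = opts$a,
                 n_modes_used = opts$n_modes_used),
            class = "recon_state")
}

# Weighted recombination of corrected per-source-state detector fields back
# into a single path spectrum (inverse of the per-state shifts).
accumulate_states <- function(states, ctx) {
  K <- length(states)
  acc <- matrix(0 + 0i, ctx$ny, ctx$nx)
  for (s in seq_len(K)) {
    sh <- fft2u(states[[s]])
    if (ctx$det_off[s, 1] != 0 || ctx$det_off[s, 2] != 0)
      sh <- sh * shift_ramp(ctx$ny, ctx$nx,
                            -ctx$det_off[s, 2], -ctx$det_off[s, 1])
    acc <- acc + ctx$weights[s] * sh
  }
  acc / sum(ctx$weights)
}

#' @export
print.recon_state <- function(x, ...) {
  cat(sprintf(
    "<recon_state: %d x %d px, %g nm, %d positions, %d epochs, err %.3g>\n",
    nrow(x$E), ncol(x$E), x$wavelength, nrow(x$positions),
    length(x$history),
    if (length(x$history)) utils::tail(x$history, 1) else NA))
  invisible(x)
}

# 2x2 mean binning of an intensity frame.
bin2 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  0.25 * (m[seq(1, ny, 2), seq(1, nx, 2)] + m[seq(2, ny, 2), seq(1, nx, 2)] +
          m[seq(1, ny, 2), seq(2, nx, 2)] + m[seq(2, ny, 2), seq(2, nx, 2)])
}

#' Post-measurement scan-position refinement
#'
#' For each frame, compares the object-plane patch implied by the measured
#' intensity (intensity-projected, back-propagated, coded-surface-
#' demodulated) with the current model patch, locates the cross-correlation
#' peak with sub-pixel quadratic interpolation, and corrects the stored
#' position, bounded to 1 px per call for stability. A single-frame dataset
#' is left untouched (positions are defined only up to a global offset).
#' Frames whose correlation is degenerate (flat) are left unchanged with a
#' warning.
#'
#' @param state A `recon_state`.
#' @param dataset The measured [simulate_dataset()] dataset.
#' @param frames_override,pitch_override Internal (multi-resolution) use.
#' @return The state with updated `positions`.
#' @export
refine_positions <- function(state, dataset, frames_override = NULL,
                             pitch_override = NULL) {
  frames <- if (is.null(frames_override)) dataset$frames else frames_override
  pitch <- if (is.null(pitch_override)) state$pitch else pitch_override
  n <- length(frames)
  if (n < 2) return(state)
  ny <- nrow(state$E); nx <- ncol(state$E)
  ctx <- recon_context(ny, nx, pitch, state$wavelength, state$geometry,
                       state$source, use_virtual = state$use_virtual,
                       a = state$a, n_modes_used = state$n_modes_used)
  eps_d <- 1e-3 * max(Mod(state$CS)^2)
  dem <- Conj(state$CS) / (Mod(state$CS)^2 + eps_d)
  positions <- state$positions
  for (i in seq_len(n)) {
    pos_px <- positions[i, ] / pitch
    fw <- forward_frame(state$E, state$E_virtual, state$CS, state$CS_virtual,
                        pos_px, ctx)
    upd <- project_intensity(c(fw$states, fw$statesv), frames[[i]],
                             weights = c(ctx$weights,
                                         if (!is.null(fw$statesv))
                                           ctx$weights))
    K <- length(ctx$weights)
    psi_hat2 <- accumulate_states(upd[seq_len(K)], ctx)
    oest <- Mod(ifft2u(psi_hat2 * Conj(ctx$H2)) * dem)
    ocur <- Mod(fw$phi)
    a1 <- oest - mean(oest); b1 <- ocur - mean(ocur)
    if (stats::sd(a1) == 0 || stats::sd(b1) == 0) {
      warning("flat frame ", i, ": position left unchanged")
      next
    }
    cc <- Re(stats::fft(stats::fft(a1) * Conj(stats::fft(b1)),
                        inverse = TRUE))
    d <- corr_peak_subpx(cc)
    # oest is the model patch shifted by the (negated) position error; move
    # the stored position opposite to the found displacement
    d <- pmax(pmin(d, 1), -1)
    positions[i, ] <- positions[i, ] + c(-d[2], -d[1]) * pitch
  }
  state$positions <- positions
  state
}

# Integer + quadratic sub-pixel peak of a circular cross-correlation
# surface; returns c(dy, dx). Ties break at the lowest linear index.
corr_peak_subpx <- function(cc) {
  ny <- nrow(cc); nx <- ncol(cc)
  pk <- which(cc == max(cc))[1]
  py <- (pk - 1) %% ny + 1
  px <- (pk - 1) %/% ny + 1
  sub <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) 0 else 0.5 * (cm - cp) / den
  }
  wy <- function(j) (j - 1) %% ny + 1
  wx <- function(j) (j - 1) %% nx + 1
  oy <- sub(cc[wy(py - 1 + ny), px], cc[py, px], cc[wy(py + 1), px])
  ox <- sub(cc[py, wx(px - 1 + nx)], cc[py, px], cc[py, wx(px + 1)])
  dy <- py - 1 + oy; dx <- px - 1 + ox
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  c(dy, dx)
}

#' Data-fidelity error of a reconstruction
#'
#' Mean over frames of `sum((sqrt(model) - sqrt(measured))^2) /
#' sum(measured)`; zero iff the model intensities equal the measurements,
#' and 1 for an all-zero model against any positive measurement.
#'
#' @param state A `recon_state`.
#' @param dataset The measured dataset.
#' @return Scalar error.
#' @export
recon_error <- function(state, dataset) {
  n <- length(dataset$frames)
  errs <- vapply(seq_len(n), function(i) {
    fw <- forward_states(state, i)
    meas <- dataset$frames[[i]]
    sum((sqrt(pmax(fw$model_intensity, 0)) - sqrt(meas))^2) / sum(meas)
  }, numeric(1))
  mean(errs)
}
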