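#' Molar extinction-coefficient table
#'
#' Holds decadic molar extinction coefficients for protein and nucleic acid
#' at the two deep-UV wavelengths, in units consistent with areal molar
#' densities: per (mol/um^2), i.e. a conventional molar coefficient in
#' M^-1 cm^-1 multiplied by 1e11. Also carries the molar masses used to
#' convert unmixed amounts into mass maps. The 2x2 wavelength-by-species
#' matrix must be nonsingular; its condition number is stored.
#'
#' @param eps Named 2x2 matrix: rows are wavelengths (nm, as rownames),
#'   columns `pro` and `nuc`.
#' @param molar_mass Named vector with entries `pro` and `nuc` (g/mol).
#' @return An object of class `extinction_table`.
#' @export
extinction_table <- function(eps, molar_mass) {
  if (!is.matrix(eps) || any(dim(eps) != 2) ||
      !all(colnames(eps) == c("pro", "nuc")))
    stop("validation error: eps must be a 2x2 matrix with columns pro, nuc")
  if (any(eps <= 0)) stop("validation error: all extinction entries must be > 0")
  if (!all(c("pro", "nuc") %in% names(molar_mass)) || any(molar_mass <= 0))
    stop("validation error: molar_mass needs positive pro and nuc entries")
  d <- det(eps)
  if (abs(d) < 1e-12 * max(abs(eps))^2)
    stop("singular-system error: extinction matrix is singular")
  structure(list(eps = eps,
                 wavelengths = as.numeric(rownames(eps)),
                 molar_mass = molar_mass,
                 condition = kappa(eps, exact = TRUE)),
            class = "extinction_table")
}

eps_at <- function(eps, wavelength, species) {
  i <- match(wavelength, eps$wavelengths)
  if (is.na(i)) stop("wavelength ", wavelength, " nm not in extinction table")
  eps$eps[i, species]
}

#' Default extinction table
#'
#' A clearly synthetic default for simulation and testing, built from
#' standard literature-scale constants: a BSA-like protein (66.5 kDa,
#' eps280 ~ 44,000 M^-1 cm^-1, lower at 266 nm) and an average nucleotide
#' (330 g/mol, eps peak near 260 nm, ~ half at 280 nm). Values are converted
#' to per-(mol/um^2) units (x 1e11). Quantitative work on real data should
#' supply a user table instead.
#'
#' @return An [extinction_table()].
#' @export
default_extinction_table <- function() {
  eps <- matrix(c(30000, 43824,   # pro at 266, 280 (M^-1 cm^-1)
                  7400,  3700),   # nuc at 266, 280
                nrow = 2, dimnames = list(c("266", "280"), c("pro", "nuc")))
  extinction_table(eps * 1e11, c(pro = 66500, nuc = 330))
}

#' Sub-pixel image registration by phase cross-correlation
#'
#' Estimates the translation between two equally shaped real images with
#' normalized phase cross-correlation, refined to sub-pixel precision by a
#' matrix-multiply discrete Fourier transform evaluated on an upsampled
#' neighbourhood of the coarse peak. The returned shift `(sx, sy)` is such
#' that shifting `moving` by `+shift` aligns it to `ref`; the aligned image
#' (Fourier-shifted) is returned alongside.
#'
#' @param ref,moving Real matrices of identical shape.
#' @param upsample Upsampling factor for the sub-pixel refinement
#'   (default 100).
#' @return List with `shift` (c(sx, sy), pixels) and `aligned` (moving
#'   resampled onto ref).
#' @export
register_pair <- function(ref, moving, upsample = 100) {
  if (!all(dim(ref) == dim(moving))) stop("validation error: shape mismatch")
  if (all(ref == 0) || all(moving == 0))
    stop("registration error: all-zero image has no signal")
  ny <- nrow(ref); nx <- ncol(ref)
  F1 <- stats::fft(ref); F2 <- stats::fft(moving)
  R <- F1 * Conj(F2)
  R <- R / pmax(Mod(R), .Machine$double.eps)
  cc <- Re(stats::fft(R, inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  dy <- as.numeric(pk[1]) - 1; dx <- as.numeric(pk[2]) - 1
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  if (upsample > 1) {
    # refine in a 1.5 px neighbourhood with a matrix-multiply DFT
    half <- ceiling(1.5 * upsample / 2)
    off_y <- dy - half / upsample; off_x <- dx - half / upsample
    ky <- fft_freq(ny) # cycles/px
    kx <- fft_freq(nx)
    ey <- exp(2i * pi * outer((off_y + seq_len(2 * half + 1) / upsample -
                                 1 / upsample), ky))
    ex <- exp(2i * pi * outer(kx, (off_x + seq_len(2 * half + 1) / upsample -
                                     1 / upsample)))
    cc_up <- Mod(ey %*% R %*% ex)
    pk2 <- which(cc_up == max(cc_up), arr.ind = TRUE)[1, ]
    dy <- off_y + (as.numeric(pk2[1]) - 1) / upsample
    dx <- off_x + (as.numeric(pk2[2]) - 1) / upsample
  }
  shift <- c(sx = dx, sy = dy)
  aligned <- Re(fourier_shift(moving + 0i, shift[["sy"]], shift[["sx"]]))
  list(shift = shift, aligned = aligned)
}

#' Optical density
#'
#' Decadic absorbance `OD = log10(I_background) - log10(I_sample)` per
#' pixel. The sample intensity is floored at a configurable fraction of the
#' background before the logarithm so empty or noisy pixels cannot produce
#' infinities.
#'
#' @param i_sample Intensity image.
#' @param i_background Intensity image of the same shape, or a positive
#'   scalar.
#' @param floor_frac Sample floor as a fraction of background
#'   (default 1e-6).
#' @return OD matrix.
#' @export
optical_density <- function(i_sample, i_background, floor_frac = 1e-6) {
  if (any(i_background <= 0))
    stop("validation error: background intensity must be positive")
  if (length(i_background) == 1)
    i_background <- matrix(i_background, nrow(i_sample), ncol(i_sample))
  s <- pmax(i_sample, floor_frac * i_background)
  log10(i_background) - log10(s)
}

#' Two-wavelength Beer-Lambert unmixing
#'
#' Solves, per pixel, the 2x2 linear system expressing each optical density
#' as the extinction-weighted sum of protein and nucleic-acid areal
#' densities, via the closed-form determinant expressions. Negative results
#' (noise) are reported and clipped to zero.
#'
#' @param od266,od280 Optical-density maps at 266 and 280 nm.
#' @param eps An [extinction_table()].
#' @return List with `n_pro`, `n_nuc` (mol/um^2, clipped at 0),
#'   `negatives_clipped_fraction`.
#' @export
unmix_amounts <- function(od266, od280, eps) {
  stopifnot(inherits(eps, "extinction_table"))
  ep266 <- eps_at(eps, 266, "pro"); en266 <- eps_at(eps, 266, "nuc")
  ep280 <- eps_at(eps, 280, "pro"); en280 <- eps_at(eps, 280, "nuc")
  D <- ep266 * en280 - ep280 * en266
  if (abs(D) < 1e-12 * max(abs(eps$eps))^2)
    stop("singular-system error: extinction matrix is singular")
  n_pro <- (od266 * en280 - od280 * en266) / D
  n_nuc <- (od266 * ep280 - od280 * ep266) / (ep280 * en266 - ep266 * en280)
  neg <- (mean(n_pro < 0) + mean(n_nuc < 0)) / 2
  n_pro[n_pro < 0] <- 0
  n_nuc[n_nuc < 0] <- 0
  list(n_pro = n_pro, n_nuc = n_nuc, negatives_clipped_fraction = neg)
}

#' Areal amounts to per-pixel masses
#'
#' `m = n * pixel_size^2 * molar_mass`, converted from grams to femtograms.
#'
#' @param n_pro,n_nuc Areal molar densities (mol/um^2).
#' @param pixel_size Pixel size at the sample, um.
#' @param eps An [extinction_table()] (supplies the molar masses).
#' @return List with `m_pro`, `m_nuc` in fg/px.
#' @export
amounts_to_mass <- function(n_pro, n_nuc, pixel_size, eps) {
  if (pixel_size <= 0) stop("validation error: pixel_size must be > 0")
  area <- pixel_size^2
  list(m_pro = n_pro * area * eps$molar_mass[["pro"]] * 1e15,
       m_nuc = n_nuc * area * eps$molar_mass[["nuc"]] * 1e15)
}

#' Differential deep-UV mass-recovery pipeline
#'
#' Chains the full quantitative path from two reconstructed amplitude images
#' to registered, unmixed, mass-calibrated maps: intensities are squared
#' amplitudes; the background is the median intensity over the stated empty
#' region of interest; the 280-nm image is registered onto the 266-nm image
#' by phase cross-correlation; optical densities are unmixed with the
#' extinction table and converted to femtograms per pixel.
#'
#' @param amp266,amp280 Reconstructed amplitude images on a common grid.
#' @param background_roi Logical mask (same shape) marking empty pixels, or
#'   a list `list(rows =, cols =)` of index ranges.
#' @param eps An [extinction_table()].
#' @param pixel_size Pixel size, um.
#' @param upsample Registration upsampling (default 20).
#' @return An object of class `mass_maps`: list with `od266`, `od280`,
#'   `n_pro`, `n_nuc`, `m_pro`, `m_nuc` (fg/px), `shift` (registration,
#'   px), `negatives_clipped_fraction`, `background` (the two medians).
#' @export
duv_mass_pipeline <- function(amp266, amp280, background_roi, eps,
                              pixel_size, upsample = 20) {
  if (!all(dim(amp266) == dim(amp280)))
    stop("validation error: reconstructions must share one grid")
  roi <- if (is.logical(background_roi)) background_roi else {
    m <- matrix(FALSE, nrow(amp266), ncol(amp266))
    m[background_roi$rows, background_roi$cols] <- TRUE
    m
  }
  if (!any(roi)) stop("validation error: empty background ROI")
  i266 <- Mod(amp266)^2
  i280 <- Mod(amp280)^2
  reg <- register_pair(i266, i280, upsample = upsample)
  i280r <- pmax(reg$aligned, 0)
  bg266 <- stats::median(i266[roi])
  bg280 <- stats::median(i280r[roi])
  od266 <- optical_density(i266, bg266)
  od280 <- optical_density(i280r, bg280)
  un <- unmix_amounts(od266, od280, eps)
  m <- amounts_to_mass(un$n_pro, un$n_nuc, pixel_size, eps)
  structure(list(od266 = od266, od280 = od280,
                 n_pro = un$n_pro, n_nuc = un$n_nuc,
                 m_pro = m$m_pro, m_nuc = m$m_nuc,
                 shift = reg$shift,
                 negatives_clipped_fraction = un$negatives_clipped_fraction,
                 background = c(bg266 = bg266, bg280 = bg280)),
            class = "mass_maps")
}
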