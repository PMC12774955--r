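#' Virtual-stain palette
#'
#' Color constants for the two deterministic renderers. For the
#' fluorescence mode, `fluor_nuc` / `fluor_pro` are non-negative RGB
#' emission vectors (nucleic acid in blue tones, protein in purple). For the
#' H&E-like mode, `he_nuc` / `he_pro` are unit-normalized RGB optical-
#' density vectors (hematoxylin-like for nucleic acid, eosin-like for
#' protein; the classic stain-separation directions) scaled by per-species
#' strengths, and `he_green` is the constant green background term that
#' makes the empty background white.
#'
#' @param fluor_nuc,fluor_pro Emission RGB vectors in \[0, 1\].
#' @param he_nuc,he_pro Optical-density RGB direction vectors (non-negative).
#' @param he_strength_nuc,he_strength_pro OD strengths at the normalization
#'   mass scale.
#' @param he_green Constant green additive term.
#' @param gamma Display gamma applied at the end of each render.
#' @return An object of class `stain_palette`.
#' @export
stain_palette <- function(fluor_nuc = c(0.10, 0.25, 1.00),
                          fluor_pro = c(0.60, 0.15, 0.80),
                          he_nuc = c(0.650, 0.704, 0.286),
                          he_pro = c(0.070, 0.990, 0.110),
                          he_strength_nuc = 1.2,
                          he_strength_pro = 0.8,
                          he_green = 0.08,
                          gamma = 1) {
  chk <- function(v, nm) {
    if (length(v) != 3 || any(v < 0)) stop("validation error: ", nm,
                                           " must be a non-negative RGB triple")
    v
  }
  structure(list(fluor_nuc = chk(fluor_nuc, "fluor_nuc"),
                 fluor_pro = chk(fluor_pro, "fluor_pro"),
                 he_nuc = chk(he_nuc, "he_nuc") / sqrt(sum(he_nuc^2)),
                 he_pro = chk(he_pro, "he_pro") / sqrt(sum(he_pro^2)),
                 he_strength_nuc = he_strength_nuc,
                 he_strength_pro = he_strength_pro,
                 he_green = he_green, gamma = gamma),
            class = "stain_palette")
}

mass_scale <- function(m, scale) {
  if (!is.null(scale)) return(scale)
  pos <- m[m > 0]
  if (length(pos) == 0) return(1)
  as.numeric(stats::quantile(pos, 0.95))
}

#' Virtual fluorescence rendering
#'
#' Dark-background render mimicking fluorescence microscopy: each species'
#' mass is mapped through a saturating linear response
#' `min(mass / scale, 1)` (scale defaults to the species' 95th positive mass
#' percentile) and emitted along its palette color vector; channels are the
#' clipped sum. Intensity is monotone in mass and exactly linear below
#' saturation; the render is a pure function of its inputs.
#'
#' @param mass A `mass_maps` object (or any list with `m_nuc`, `m_pro`).
#' @param palette A [stain_palette()].
#' @param scale_nuc,scale_pro Optional fixed normalization scales (fg/px).
#' @return ny x nx x 3 array in \[0, 1\].
#' @export
render_fluorescence <- function(mass, palette = stain_palette(),
                                scale_nuc = NULL, scale_pro = NULL) {
  if (any(mass$m_nuc < 0) || any(mass$m_pro < 0))
    stop("validation error: negative mass")
  vn <- pmin(mass$m_nuc / mass_scale(mass$m_nuc, scale_nuc), 1)
  vp <- pmin(mass$m_pro / mass_scale(mass$m_pro, scale_pro), 1)
  out <- array(0, c(nrow(vn), ncol(vn), 3))
  for (c in 1:3)
    out[, , c] <- pmin(vn * palette$fluor_nuc[c] + vp * palette$fluor_pro[c],
                       1)
  if (palette$gamma != 1) out <- out^(1 / palette$gamma)
  out
}

#' H&E-like virtual staining
#'
#' Optical-density color mixing on a white background: per channel,
#' `RGB = 10^-(m_nuc' * v_nuc + m_pro' * v_pro)` with masses normalized by
#' their scale and weighted by the palette strengths, then the constant
#' green background term is added and the result clipped to \[0, 1\]. Zero
#' mass gives a white pixel; nucleic acid pulls toward hematoxylin blue,
#' protein toward eosin pink; before the green term every channel is
#' non-increasing in each mass.
#'
#' @inheritParams render_fluorescence
#' @return ny x nx x 3 array in \[0, 1\].
#' @export
render_he <- function(mass, palette = stain_palette(),
                      scale_nuc = NULL, scale_pro = NULL) {
  if (any(mass$m_nuc < 0) || any(mass$m_pro < 0))
    stop("validation error: negative mass")
  mn <- mass$m_nuc / mass_scale(mass$m_nuc, scale_nuc) *
    palette$he_strength_nuc
  mp <- mass$m_pro / mass_scale(mass$m_pro, scale_pro) *
    palette$he_strength_pro
  out <- array(0, c(nrow(mn), ncol(mn), 3))
  for (c in 1:3) {
    od <- mn * palette$he_nuc[c] + mp * palette$he_pro[c]
    ch <- 10^(-od)
    if (c == 2) ch <- ch + palette$he_green
    out[, , c] <- pmin(pmax(ch, 0), 1)
  }
  if (palette$gamma != 1) out <- out^(1 / palette$gamma)
  out
}

#' Michelson contrast of a region of interest
#'
#' `(max - min) / (max + min)` computed after clipping the ROI to its 1st
#' and 99th percentiles (robust to isolated hot pixels). In \[0, 1\],
#' invariant to multiplicative gain; a constant ROI returns 0. The metric
#' definition (percentile-clipped Michelson) is this package's declared
#' convention for method comparisons.
#'
#' @param image Real matrix.
#' @param roi Optional list `list(rows =, cols =)`; default is the whole
#'   image. The ROI must be at least 16 px per side.
#' @return Scalar contrast in \[0, 1\].
#' @export
contrast_metric <- function(image, roi = NULL) {
  v <- if (is.null(roi)) image else {
    if (length(roi$rows) < 16 || length(roi$cols) < 16)
      stop("validation error: ROI must be >= 16 px per side")
    image[roi$rows, roi$cols]
  }
  if (is.null(roi) && (nrow(image) < 16 || ncol(image) < 16))
    stop("validation error: ROI must be >= 16 px per side")
  q <- stats::quantile(v, c(0.01, 0.99))
  v <- pmin(pmax(v, q[1]), q[2])
  mx <- max(v); mn <- min(v)
  if (mx + mn == 0 || mx == mn) return(0)
  (mx - mn) / (mx + mn)
}
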