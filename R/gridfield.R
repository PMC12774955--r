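#' Physical sampling grid
#'
#' A `pty_grid` describes the sampling of a 2-D complex wavefield: pixel
#' counts, sampling pitch and the wavelength the field is defined at.
#' Pixel (1,1) is the array's top-left corner; the physical origin is at the
#' grid center; spatial frequencies are expressed in cycles/um.
#'
#' @param nx,ny Pixel counts (>= 8).
#' @param pitch Sampling interval in um/pixel (> 0).
#' @param wavelength Wavelength in nm (> 0).
#' @return An object of class `pty_grid`.
#' @export
pty_grid <- function(nx, ny = nx, pitch, wavelength) {
  if (nx < 8 || ny < 8) stop("invalid grid: nx and ny must be >= 8 pixels")
  if (pitch <= 0) stop("invalid grid: pitch must be > 0")
  if (wavelength <= 0) stop("invalid grid: wavelength must be > 0")
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny),
         pitch = pitch, wavelength = wavelength),
    class = "pty_grid"
  )
}

#' @export
print.pty_grid <- function(x, ...) {
  cat(sprintf("<pty_grid %d x %d px, pitch %.4g um, wavelength %.4g nm>\n",
              x$nx, x$ny, x$pitch, x$wavelength))
  invisible(x)
}

#' Complex wavefield on a physical grid
#'
#' @param values Complex (or real, promoted) matrix of shape (ny, nx).
#' @param grid A [pty_grid()].
#' @param plane Plane label: one of `"sample"`, `"coded_surface"`,
#'   `"detector"`.
#' @return An object of class `complex_field` with elements `values`, `grid`,
#'   `plane`.
#' @export
complex_field <- function(values, grid, plane = c("sample", "coded_surface",
                                                  "detector")) {
  plane <- match.arg(plane)
  stopifnot(inherits(grid, "pty_grid"))
  if (!is.matrix(values)) stop("values must be a matrix")
  if (is.numeric(values)) values <- values + 0i
  if (nrow(values) != grid$ny || ncol(values) != grid$nx)
    stop("values shape must equal (ny, nx) of the grid")
  if (any(!is.finite(Re(values))) || any(!is.finite(Im(values))))
    stop("validation error: field values must be finite")
  structure(list(values = values, grid = grid, plane = plane),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field at '%s' plane, %d x %d px, energy %.4g>\n",
              x$plane, x$grid$ny, x$grid$nx, field_energy(x)))
  invisible(x)
}

#' Total field energy
#'
#' Sum of squared moduli of the field samples.
#' @param field A [complex_field()].
#' @return Scalar energy.
#' @export
field_energy <- function(field) sum(Mod(field$values)^2)

# Angular-spectrum transfer function on an (ny, nx) frequency grid.
# Exact scalar free-space kernel exp(i 2 pi d sqrt(1/lambda^2 - fx^2 - fy^2));
# evanescent components are zeroed. With band_limit = TRUE the Matsushima-
# style local frequency limit suppresses the aliased replicas that the
# periodic transfer-function sampling would otherwise fold in at long
# distances.
as_transfer <- function(ny, nx, pitch, wavelength_nm, distance,
                        method = c("angular_spectrum", "fresnel"),
                        band_limit = TRUE) {
  method <- match.arg(method)
  lam <- wavelength_nm * 1e-3  # um
  fg <- freq_grids(ny, nx, pitch)
  f2 <- fg$fx^2 + fg$fy^2
  if (method == "angular_spectrum") {
    arg <- 1 / lam^2 - f2
    kz <- sqrt(pmax(arg, 0))
    H <- exp(2i * pi * distance * kz)
    H[arg < 0] <- 0 + 0i
  } else {
    H <- exp(2i * pi * distance / lam) *
      exp(-1i * pi * lam * distance * f2)
  }
  if (band_limit && distance != 0) {
    dfx <- 1 / (nx * pitch)
    dfy <- 1 / (ny * pitch)
    flx <- 1 / (lam * sqrt((2 * distance * dfx)^2 + 1))
    fly <- 1 / (lam * sqrt((2 * distance * dfy)^2 + 1))
    H[abs(fg$fx) > flx | abs(fg$fy) > fly] <- 0 + 0i
  }
  H
}

#' Free-space propagation of a complex field
#'
#' Propagates a wavefield over a signed axial distance with the band-limited
#' angular-spectrum method (exact scalar transfer function, evanescent
#' components zeroed). Positive distances propagate away from the source;
#' negative distances back-propagate. `propagate(f, 0)` is the identity, and
#' propagation is unitary on the band-limited support, so
#' `propagate(propagate(f, d), -d)` returns `f` to round-off.
#'
#' @param field A [complex_field()].
#' @param distance Signed propagation distance in um.
#' @param method `"angular_spectrum"` (default) or `"fresnel"` for the
#'   paraxial transfer function (useful for cross-checks in the Fresnel
#'   regime where both agree).
#' @param band_limit Zero the transfer function beyond the local frequency
#'   limit (default TRUE).
#' @param plane Optional plane label for the returned field (defaults to the
#'   input's label).
#' @return A [complex_field()] on the same grid.
#' @export
propagate <- function(field, distance, method = c("angular_spectrum",
                                                  "fresnel"),
                      band_limit = TRUE, plane = NULL) {
  stopifnot(inherits(field, "complex_field"))
  method <- match.arg(method)
  g <- field$grid
  if (distance == 0) {
    out <- field
    if (!is.null(plane)) out$plane <- plane
    return(out)
  }
  H <- as_transfer(g$ny, g$nx, g$pitch, g$wavelength, distance,
                   method = method, band_limit = band_limit)
  vals <- ifft2u(fft2u(field$values) * H)
  complex_field(vals, g, plane = if (is.null(plane)) field$plane else plane)
}

#' Propagate a field to a list of axial planes
#'
#' @param field A [complex_field()].
#' @param distances Non-empty numeric vector of signed distances in um.
#' @param ... Passed to [propagate()].
#' @return List of [complex_field()], one per distance, order preserved.
#' @export
refocus_sweep <- function(field, distances, ...) {
  if (length(distances) == 0) stop("validation error: empty distance list")
  lapply(distances, function(d) propagate(field, d, ...))
}

#' Fourier-domain resampling of a field
#'
#' Crops or zero-pads the centered spectrum so the physical extent of the
#' field is preserved while the pixel count is scaled by `factor`; the pitch
#' rescales accordingly. Values (not summed energy) are preserved: a constant
#' field stays at the same amplitude, and a band-limited field whose support
#' lies inside the reduced band survives a factor-1/2 then factor-2 round
#' trip exactly.
#'
#' @param field A [complex_field()].
#' @param factor Positive resampling factor; the new pixel counts are
#'   `round(n * factor)` and must be >= 8.
#' @return A [complex_field()] on the rescaled grid.
#' @export
resample <- function(field, factor) {
  stopifnot(inherits(field, "complex_field"))
  if (factor <= 0) stop("validation error: factor must be positive")
  g <- field$grid
  nx2 <- as.integer(round(g$nx * factor))
  ny2 <- as.integer(round(g$ny * factor))
  if (nx2 < 8 || ny2 < 8)
    stop("validation error: resampled grid would be below 8 px")
  if (nx2 == g$nx && ny2 == g$ny) return(field)
  spec <- fftshift2(fft2u(field$values))
  out <- matrix(0 + 0i, ny2, nx2)
  # centered crop/pad index ranges
  cy <- floor(g$ny / 2) + 1L; cx <- floor(g$nx / 2) + 1L
  cy2 <- floor(ny2 / 2) + 1L; cx2 <- floor(nx2 / 2) + 1L
  hy <- min(cy - 1L, cy2 - 1L); hx <- min(cx - 1L, cx2 - 1L)
  ty <- min(g$ny - cy, ny2 - cy2); tx <- min(g$nx - cx, nx2 - cx2)
  out[(cy2 - hy):(cy2 + ty), (cx2 - hx):(cx2 + tx)] <-
    spec[(cy - hy):(cy + ty), (cx - hx):(cx + tx)]
  # sqrt(N2/N1) preserves sample values (not summed energy) across the
  # pixel-count change; physical energy sum(|v|^2) * pitch^2 is preserved
  # for in-band content.
  vals <- ifft2u(ifftshift2(out)) * sqrt((ny2 * nx2) / (g$ny * g$nx))
  grid2 <- pty_grid(nx2, ny2, pitch = g$pitch * g$nx / nx2,
                    wavelength = g$wavelength)
  complex_field(vals, grid2, plane = field$plane)
}
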