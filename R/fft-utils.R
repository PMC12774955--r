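# Internal Fourier helpers shared by the propagation, simulation and
# reconstruction code. All transforms are unitary (norm-preserving) so that
# energy bookkeeping is direct: sum(|x|^2) == sum(|fft2u(x)|^2).

fft2u <- function(x) stats::fft(x) / sqrt(length(x))

ifft2u <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

# Discrete sample frequencies in cycles per physical unit, fft ordering.
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

# Frequency-coordinate matrices for an ny x nx array (rows = y, cols = x),
# in cycles/um when pitch is in um.
freq_grids <- function(ny, nx, pitch) {
  fx <- fft_freq(nx, pitch)
  fy <- fft_freq(ny, pitch)
  list(
    fx = matrix(fx, nrow = ny, ncol = nx, byrow = TRUE),
    fy = matrix(fy, nrow = ny, ncol = nx)
  )
}

# Linear phase ramp implementing the Fourier shift theorem: multiplying a
# spectrum by shift_ramp(ny, nx, sy, sx) and inverse-transforming shifts the
# image content by (+sy, +sx) pixels (circularly, exact for band-limited data).
shift_ramp <- function(ny, nx, sy, sx) {
  fy <- fft_freq(ny)
  fx <- fft_freq(nx)
  py <- exp(-2i * pi * sy * fy)
  px <- exp(-2i * pi * sx * fx)
  outer(py, px)
}

# Circular sub-pixel shift of a complex or real matrix by (sy, sx) pixels.
fourier_shift <- function(x, sy, sx) {
  if (sy == 0 && sx == 0) return(x)
  out <- ifft2u(fft2u(x) * shift_ramp(nrow(x), ncol(x), sy, sx))
  if (is.complex(x)) out else Re(out)
}

fftshift2 <- function(x) {
  ny <- nrow(x); nx <- ncol(x)
  x[c(seq.int(floor(ny / 2) + 1L, ny), seq.int(1L, floor(ny / 2))),
    c(seq.int(floor(nx / 2) + 1L, nx), seq.int(1L, floor(nx / 2)))]
}

ifftshift2 <- function(x) {
  ny <- nrow(x); nx <- ncol(x)
  x[c(seq.int(ny - floor(ny / 2) + 1L, ny), seq.int(1L, ny - floor(ny / 2))),
    c(seq.int(nx - floor(nx / 2) + 1L, nx), seq.int(1L, nx - floor(nx / 2)))]
}

# Run code under a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Normalized root-mean-square error
#'
#' RMS of the (complex) difference normalized by the RMS of the reference.
#'
#' @param x Estimate (matrix or vector, real or complex).
#' @param ref Reference of the same shape.
#' @return Scalar NRMSE.
#' @export
nrmse <- function(x, ref) {
  sqrt(mean(Mod(x - ref)^2)) / sqrt(mean(Mod(ref)^2))
}
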