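# Shared fixture builders and independent oracles. Everything is generated
# in code at test time; no stored binary data.

# Independent free-space propagation oracle: direct O(N^4) diffraction sum.
# The forward/inverse DFTs are explicit matrix products (no fft()) and the
# band-limited angular-spectrum transfer function is re-derived from the
# physics, so this path shares no code with the implementation under test.
direct_diffraction_sum <- function(vals, pitch, lam_nm, d) {
  n <- nrow(vals)
  lam <- lam_nm * 1e-3
  k <- c(seq.int(0, ceiling(n / 2) - 1), seq.int(-floor(n / 2), -1)) /
    (n * pitch)
  W <- exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  A <- W %*% vals %*% W
  FX <- matrix(k, n, n, byrow = TRUE)
  FY <- matrix(k, n, n)
  arg <- 1 / lam^2 - FX^2 - FY^2
  H <- ifelse(arg > 0, exp(2i * pi * d * sqrt(pmax(arg, 0))), 0 + 0i)
  fl <- 1 / (lam * sqrt((2 * d / (n * pitch))^2 + 1))
  H[abs(FX) > fl | abs(FY) > fl] <- 0
  Wi <- Conj(W)
  (Wi %*% (A * H) %*% Wi) / n^2
}

# Random band-limited complex field on an n x n grid (spectral support
# inside a disc of radius frac * Nyquist).
band_limited_field <- function(n, pitch, lam_nm, frac = 0.3, seed = 1) {
  set.seed(seed)
  v <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n)
  k <- c(seq.int(0, ceiling(n / 2) - 1), seq.int(-floor(n / 2), -1))
  KX <- matrix(k, n, n, byrow = TRUE)
  KY <- matrix(k, n, n)
  msk <- (KX^2 + KY^2) < (frac * n / 2)^2
  vals <- stats::fft(stats::fft(v) * msk, inverse = TRUE) / n^2
  complex_field(vals, pty_grid(n, n, pitch, lam_nm))
}

# Small standard simulation: phantom + coded surface + coherent noiseless
# dataset, cached per options so repeated tests don't re-simulate.
small_sim <- local({
  cache <- list()
  function(n = 64, n_cells = 2, n_side = 4, d1 = 800, dn = 0.1,
           seed = 5, artifacts = character(0), source = NULL, ...) {
    key <- paste(n, n_cells, n_side, d1, dn, seed,
                 paste(artifacts, collapse = "+"),
                 if (is.null(source)) "pt" else "src", sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    eps <- default_extinction_table()
    g <- pty_grid(n, n, 1.85, 266)
    ph <- make_cell_phantom(g, n_cells, seed = seed, dn = dn,
                            margin_px = 10L)
    cs <- make_coded_surface(g, seed = 100)
    geom <- system_geometry(d1 = d1)
    scan <- make_scan_plan(n_side, 4, 7, seed = 11)
    src <- if (is.null(source)) make_source_model() else source
    ds <- simulate_dataset(ph, cs, geom, scan, src, eps = eps, seed = 1,
                           artifacts = artifacts, ...)
    out <- list(phantom = ph, cs = cs, geometry = geom, scan = scan,
                dataset = ds, eps = eps, grid = g,
                exit = sample_exit_field(ph, 266, eps))
    cache[[key]] <<- out
    out
  }
})
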