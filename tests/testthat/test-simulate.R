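test_that("cell phantoms honour counts, ranges and the background contract", {
  g <- pty_grid(96, 96, 1.85, 266)
  ph0 <- make_cell_phantom(g, 0)
  expect_true(all(ph0$n_pro == 0) && all(ph0$n_nuc == 0))
  ph <- make_cell_phantom(pty_grid(192, 192, 1.85, 266), 5, seed = 3)
  # exactly 5 connected nuclear components (independent labelling oracle)
  lab <- EBImage::bwlabel(EBImage::Image((ph$labels == 2) * 1))
  expect_equal(max(lab), 5)
  # amounts in range on non-background pixels, zero outside
  expect_true(all(ph$n_pro[ph$labels == 0] == 0))
  expect_true(all(ph$n_nuc[ph$labels == 0] == 0))
  expect_lte(max(ph$n_nuc), 9e-16 * (1 + 1e-12))
  expect_identical(ph$n_pro,
                   make_cell_phantom(pty_grid(192, 192, 1.85, 266), 5,
                                     seed = 3)$n_pro)
})

test_that("exit fields implement the Beer-Lambert law on intensity", {
  eps <- default_extinction_table()
  g <- pty_grid(64, 64, 1.85, 266)
  ph0 <- make_cell_phantom(g, 0)
  f0 <- sample_exit_field(ph0, 266, eps)
  expect_equal(max(Mod(f0$values - 1)), 0)
  # decadic OD 1 -> intensity transmission 0.1
  ph1 <- make_cell_phantom(g, 0)
  ph1$n_pro[30, 30] <- 1 / codedpty:::eps_at(eps, 266, "pro")
  ph1$labels[30, 30] <- 1L
  f1 <- sample_exit_field(ph1, 266, eps)
  expect_equal(Mod(f1$values[30, 30])^2, 0.1, tolerance = 1e-12)
  # forward/inverse OD identity over a full phantom
  sim <- small_sim()
  od <- -log10(Mod(sim$exit$values)^2)
  od_true <- codedpty:::eps_at(sim$eps, 266, "pro") * sim$phantom$n_pro +
    codedpty:::eps_at(sim$eps, 266, "nuc") * sim$phantom$n_nuc
  expect_lt(max(abs(od - od_true)), 1e-12)
  # phase map at 405 nm
  f405 <- sample_exit_field(sim$phantom, 405, sim$eps)
  expect_equal(max(abs(Mod(f405$values) - 1)), 0)
  expect_lt(max(Mod(f405$values -
                      exp(1i * 2 * pi * 0.1 * sim$phantom$height / 0.405))),
            1e-9)
})

test_that("the forward simulator conserves energy and is deterministic", {
  eps <- default_extinction_table()
  g <- pty_grid(64, 64, 1.85, 266)
  geom <- system_geometry(d1 = 800)
  scan <- make_scan_plan(3, 4, 7, seed = 2)
  # empty phantom + transparent surface -> uniform frames at background
  ph0 <- make_cell_phantom(g, 0)
  cs0 <- make_coded_surface(g, seed = 1, amp_range = c(1, 1),
                            phase_range = 0)
  ds0 <- simulate_dataset(ph0, cs0, geom, scan, eps = eps,
                          background_level = 2.5)
  expect_lt(max(abs(unlist(ds0$frames) - 2.5)), 1e-9)
  # per-frame total intensity identical for a phase-only coded surface
  # (128 px grid: the propagation operator is exactly unitary there, no
  # band-limit clipping at these distances)
  g128 <- pty_grid(128, 128, 1.85, 266)
  ph <- make_cell_phantom(g128, 3, seed = 5)
  csp <- make_coded_surface(g128, seed = 3, amp_range = c(1, 1))
  dsp <- simulate_dataset(ph, csp, system_geometry(d1 = 800),
                          make_scan_plan(2, 4, 7, seed = 2), eps = eps)
  sums <- vapply(dsp$frames, sum, 0)
  expect_lt(diff(range(sums)) / mean(sums), 1e-9)
  # determinism
  sim <- small_sim()
  ds2 <- simulate_dataset(sim$phantom, sim$cs, sim$geometry, sim$scan,
                          eps = sim$eps, seed = 1)
  expect_identical(ds2$frames, sim$dataset$frames)
})

test_that("incoherent summation is linear in per-state intensities", {
  eps <- default_extinction_table()
  g <- pty_grid(64, 64, 1.85, 266)
  ph <- make_cell_phantom(g, 2, seed = 5, margin_px = 10)
  cs <- make_coded_surface(g, seed = 3)
  geom <- system_geometry(d1 = 800)
  scan <- make_scan_plan(2, 4, 7, seed = 2)
  src <- make_source_model("disc", radius = 300, n_states = 3,
                           center_wavelength = 266)
  full <- simulate_dataset(ph, cs, geom, scan, src, eps = eps)
  acc <- matrix(0, 64, 64)
  for (s in 1:3) {
    one <- src
    one$states <- src$states[s, , drop = FALSE]
    one$states[, 3] <- 1
    d1 <- simulate_dataset(ph, cs, geom, scan, one, eps = eps)
    acc <- acc + src$states[s, 3] * d1$frames[[2]]
  }
  expect_equal(full$frames[[2]], acc, tolerance = 1e-12)
})

test_that("simulating at a shift equals simulating a pre-shifted phantom at zero", {
  eps <- default_extinction_table()
  g <- pty_grid(64, 64, 1.85, 266)
  ph <- make_cell_phantom(g, 2, seed = 5, margin_px = 10)
  cs <- make_coded_surface(g, seed = 3)
  geom <- system_geometry(d1 = 800)
  # single-position plans at (0,0) and at a 2-px shift
  mk <- function(pos) {
    sp <- make_scan_plan(2, 2, 2, seed = 1)
    sp$positions <- rbind(pos, pos + c(2, 0), pos + c(2, 2), pos + c(0, 2))
    sp
  }
  ds_a <- simulate_dataset(ph, cs, geom, mk(c(3.7, 0)), eps = eps)
  # the same frame computed by pre-shifting the coded-surface-plane field
  # by -2 px (Fourier shift theorem) and running the zero-shift path
  exit <- sample_exit_field(ph, 266, eps)
  at_cs <- propagate(exit, 800)
  pre <- codedpty:::fourier_shift(at_cs$values, 0, -3.7 / 1.85)
  det <- propagate(complex_field(pre * cs$values, g), 840)
  expect_equal(ds_a$frames[[1]], Mod(det$values)^2, tolerance = 1e-6)
})

test_that("noise artifacts keep frames non-negative and report clipping", {
  sim <- small_sim()
  ds <- simulate_dataset(sim$phantom, sim$cs, sim$geometry, sim$scan,
                         eps = sim$eps, seed = 7,
                         artifacts = c("shot", "read"), read_sigma = 0.05)
  expect_true(all(unlist(ds$frames) >= 0))
  expect_gt(ds$clipped_fraction, 0)
  expect_error(simulate_dataset(sim$phantom, sim$cs, sim$geometry, sim$scan,
                                eps = sim$eps, artifacts = "nope"),
               "unknown artifacts")
})
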