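test_that("scan plans are jittered serpentine grids with bounded steps", {
  # zero jitter: exact square corners
  sp <- make_scan_plan(2, 2, 2, seed = 3)
  expect_equal(sp$positions,
               rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)),
               tolerance = 1e-12)
  # dataset-scale plan: 400 positions
  sp400 <- make_scan_plan(20, 1, 3, seed = 1)
  expect_equal(nrow(sp400$positions), 400L)
  # consecutive spacing within the configured interval
  d <- sqrt(rowSums(diff(sp400$positions)^2))
  expect_true(all(d >= 1 - 1e-9 & d <= 3 + 1e-9))
  # determinism / seed sensitivity
  expect_identical(sp400$positions, make_scan_plan(20, 1, 3, seed = 1)$positions)
  expect_false(identical(sp400$positions,
                         make_scan_plan(20, 1, 3, seed = 2)$positions))
  expect_error(make_scan_plan(5, 0, 3), "step_min")
  expect_error(make_scan_plan(1, 1, 3), "n_side")
})

test_that("coded surfaces have the requested amplitude span and correlation length", {
  g <- pty_grid(128, 128, 1.85, 266)
  # identity modulator
  cs0 <- make_coded_surface(g, seed = 1, amp_range = c(1, 1), phase_range = 0)
  expect_equal(max(Mod(cs0$values - 1)), 0)
  cs <- make_coded_surface(g, seed = 2, feature_size = 4 * g$pitch,
                           amp_range = c(0.3, 1))
  amp <- Mod(cs$values)
  expect_lt(abs(min(amp) - 0.3), 0.02 * 0.7)
  expect_lt(abs(max(amp) - 1.0), 0.02 * 0.7)
  # autocorrelation FWHM ~ 4 px
  a <- amp - mean(amp)
  ac <- Re(stats::fft(Mod(stats::fft(a))^2, inverse = TRUE))
  prof <- ac[1, ] / ac[1, 1]
  j <- which(prof[1:20] < 0.5)[1]              # first lag below half max
  cross <- (j - 2) + (prof[j - 1] - 0.5) / (prof[j - 1] - prof[j])
  fwhm <- 2 * cross                            # symmetric autocorrelation
  expect_lt(abs(fwhm - 4), 1)
  expect_identical(cs$values, make_coded_surface(g, seed = 2,
                                                 feature_size = 4 * g$pitch,
                                                 amp_range = c(0.3, 1))$values)
  expect_error(make_coded_surface(g, amp_range = c(-0.1, 1)), "amp_range")
  expect_error(make_coded_surface(g, feature_size = 0.1), "feature_size")
})

test_that("source models are normalized, centered and cover the band", {
  pt <- make_source_model("point")
  expect_equal(unname(pt$states), matrix(c(0, 0, 1), 1, 3))
  disc <- make_source_model("disc", radius = 150, n_states = 5,
                            center_wavelength = 266)
  expect_equal(sum(disc$states[, 3]), 1)
  centroid <- colSums(disc$states[, 1:2] * disc$states[, 3])
  expect_lt(max(abs(centroid)), 150 / 100)
  expect_true(all(sqrt(rowSums(disc$states[, 1:2]^2)) <= 150))
  spec <- make_source_model("point", bandwidth_fwhm = 10, n_spectral = 5,
                            center_wavelength = 266)$spectrum
  expect_equal(sum(spec[, 2]), 1)
  expect_equal(spec[, 2], rev(spec[, 2]))
  expect_equal(mean(range(spec[, 1])), 266)
  expect_error(make_source_model("disc", radius = -1, n_states = 3),
               "radius")
})

test_that("the geometric source-blur rule maps emitter offsets to detector shifts", {
  geom <- system_geometry(d1 = 2160, d2 = 840, source_distance = 200000)
  src <- make_source_model("disc", radius = 100 * sqrt(2), n_states = 2)
  off <- codedpty:::source_detector_offsets(src, geom)
  # ring state at radius 100 um, lever arm 3 mm / 200 mm -> 1.5 um
  expect_equal(max(sqrt(rowSums(off^2))), 1.5, tolerance = 1e-9)
})

test_that("geometry validation enforces positive distances", {
  expect_error(system_geometry(d1 = -5), "positive")
  expect_error(system_geometry(d1 = 800, a = 0), "a must be")
})
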