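test_that("phase cross-correlation registration is exact to the stated precision", {
  set.seed(4)
  base <- matrix(rnorm(128^2), 128)
  k <- c(0:63, -64:-1)
  lp <- exp(-0.01 * (matrix(k, 128, 128, byrow = TRUE)^2 +
                       matrix(k, 128, 128)^2))
  img <- Re(stats::fft(stats::fft(base) * lp, inverse = TRUE)) / 128^2
  expect_equal(register_pair(img, img)$shift, c(sx = 0, sy = 0))
  mv_i <- Re(codedpty:::fourier_shift(img + 0i, -5, 3))
  expect_equal(register_pair(mv_i, img, upsample = 1)$shift,
               c(sx = 3, sy = -5))
  mv_s <- Re(codedpty:::fourier_shift(img + 0i, -0.70, 0.30))
  r <- register_pair(mv_s, img, upsample = 100)
  expect_lt(max(abs(r$shift - c(0.30, -0.70))), 0.05)
  expect_lt(max(abs(r$aligned - mv_s)), 1e-6)
  expect_error(register_pair(matrix(0, 8, 8), matrix(0, 8, 8)), "signal")
})

test_that("optical density follows the decadic definition with flooring", {
  i_bg <- matrix(2, 16, 16)
  expect_equal(optical_density(i_bg, i_bg), matrix(0, 16, 16))
  expect_equal(optical_density(0.1 * i_bg, i_bg), matrix(1, 16, 16),
               tolerance = 1e-12)
  # zero sample intensity is floored, not infinite
  od <- optical_density(matrix(0, 16, 16), i_bg, floor_frac = 1e-6)
  expect_true(all(is.finite(od)))
  expect_equal(od[1, 1], 6)
  expect_error(optical_density(i_bg, -i_bg), "background")
})

test_that("two-wavelength unmixing inverts the forward mixing exactly", {
  eps <- default_extinction_table()
  # one-species limit
  n_pro <- matrix(runif(64, 0, 5e-16), 8, 8)
  od266 <- codedpty:::eps_at(eps, 266, "pro") * n_pro
  od280 <- codedpty:::eps_at(eps, 280, "pro") * n_pro
  un <- unmix_amounts(od266, od280, eps)
  expect_equal(un$n_pro, n_pro, tolerance = 1e-12)
  expect_equal(max(un$n_nuc), 0)
  # property: forward then inverse is exact for random positive tables
  set.seed(11)
  for (i in 1:25) {
    e <- matrix(runif(4, 0.5, 50), 2,
                dimnames = list(c("266", "280"), c("pro", "nuc")))
    if (abs(det(e)) < 1e-3 * max(e)^2) next
    tab <- extinction_table(e, c(pro = 5e4, nuc = 330))
    np <- matrix(runif(16, 0, 2), 4, 4)
    nn <- matrix(runif(16, 0, 2), 4, 4)
    o1 <- e["266", "pro"] * np + e["266", "nuc"] * nn
    o2 <- e["280", "pro"] * np + e["280", "nuc"] * nn
    u <- unmix_amounts(o1, o2, tab)
    expect_lt(max(abs(u$n_pro - np)) / max(np), 1e-12)
    expect_lt(max(abs(u$n_nuc - nn)) / max(nn), 1e-12)
  }
  # proportional columns -> singular
  es <- matrix(c(2, 4, 1, 2), 2,
               dimnames = list(c("266", "280"), c("pro", "nuc")))
  expect_error(extinction_table(es, c(pro = 5e4, nuc = 330)), "singular")
})

test_that("mass conversion is dimensionally correct", {
  eps <- default_extinction_table()
  z <- matrix(0, 4, 4)
  expect_equal(amounts_to_mass(z, z, 1.85, eps)$m_pro, z)
  n <- matrix(0, 4, 4); n[2, 2] <- 1e-21
  # independent unit oracle: mol/um^2 * um^2 * g/mol = g; 1 g = 1e15 fg
  m2 <- amounts_to_mass(n, z, 2, eps)$m_pro[2, 2]
  expect_equal(m2, 1e-21 * 4 * 66500 * 1e15, tolerance = 1e-12)
  # doubling the pixel size quadruples per-pixel mass
  m1 <- amounts_to_mass(n, z, 1, eps)$m_pro[2, 2]
  expect_equal(m2 / m1, 4, tolerance = 1e-12)
})

test_that("the mass pipeline is exact on exit fields and symmetric under swap", {
  eps <- default_extinction_table()
  g <- pty_grid(128, 128, 1.85, 266)
  ph <- make_cell_phantom(g, 3, seed = 5)
  a266 <- Mod(sample_exit_field(ph, 266, eps)$values)
  a280 <- Mod(sample_exit_field(ph, 280, eps)$values)
  roi <- list(rows = c(1:8, 121:128), cols = 1:128)
  mm <- duv_mass_pipeline(a266, a280, roi, eps, 1.85)
  tm <- amounts_to_mass(ph$n_pro, ph$n_nuc, 1.85, eps)
  for (id in sort(unique(ph$cell_id[ph$cell_id > 0]))) {
    px <- ph$cell_id == id
    expect_lt(abs(sum(mm$m_pro[px]) - sum(tm$m_pro[px])) / sum(tm$m_pro[px]),
              1e-9)
    expect_lt(abs(sum(mm$m_nuc[px]) - sum(tm$m_nuc[px])) / sum(tm$m_nuc[px]),
              1e-9)
  }
  # zero-absorption phantom: both mass maps at the noise floor
  ph0 <- make_cell_phantom(g, 0)
  a0 <- Mod(sample_exit_field(ph0, 266, eps)$values)
  mm0 <- duv_mass_pipeline(a0, a0, roi, eps, 1.85)
  expect_lt(max(mm0$m_pro, mm0$m_nuc), 1e-9 * max(tm$m_pro))
  # swapping wavelengths with a symmetric table swaps the species roles
  es <- matrix(c(10, 3, 3, 10), 2,
               dimnames = list(c("266", "280"), c("pro", "nuc")))
  tab <- extinction_table(es, c(pro = 1, nuc = 1))
  np <- matrix(0, 16, 16); np[8, 8] <- 0.5
  o266 <- es["266", "pro"] * np; o280 <- es["280", "pro"] * np
  u_fwd <- unmix_amounts(o266, o280, tab)
  u_swp <- unmix_amounts(o280, o266, tab)
  expect_equal(u_swp$n_nuc, u_fwd$n_pro, tolerance = 1e-12)
  expect_error(duv_mass_pipeline(a266, a280, matrix(FALSE, 128, 128),
                                 eps, 1.85), "ROI")
})

test_that("registration and unmixing commute with a common translation", {
  eps <- default_extinction_table()
  g <- pty_grid(96, 96, 1.85, 266)
  ph <- make_cell_phantom(g, 2, seed = 9, margin_px = 20)
  a266 <- Mod(sample_exit_field(ph, 266, eps)$values)
  a280 <- Mod(sample_exit_field(ph, 280, eps)$values)
  roi <- list(rows = 1:8, cols = 1:96)
  base <- duv_mass_pipeline(a266, a280, roi, eps, 1.85)
  sh <- function(m) Re(codedpty:::fourier_shift(m + 0i, 0, 5))
  shifted <- duv_mass_pipeline(sh(a266), sh(a280), roi, eps, 1.85)
  expect_equal(shifted$m_nuc, sh(base$m_nuc), tolerance = 1e-6)
})
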