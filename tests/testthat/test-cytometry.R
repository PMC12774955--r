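test_that("segmentation handles empty images and recovers phantom cells", {
  expect_equal(segment_cells(matrix(0, 64, 64))$n_cells, 0L)
  g <- pty_grid(192, 192, 1.85, 266)
  ph <- make_cell_phantom(g, 10, seed = 3)
  eps <- default_extinction_table()
  od <- codedpty:::eps_at(eps, 266, "pro") * ph$n_pro +
    codedpty:::eps_at(eps, 266, "nuc") * ph$n_nuc
  seg <- segment_cells(od, ph$n_nuc)
  expect_equal(seg$n_cells, 10L)
  ious <- vapply(1:10, function(id) {
    tm <- ph$cell_id == id
    ov <- table(seg$cells[tm])
    ov <- ov[names(ov) != "0"]
    if (!length(ov)) return(0)
    pm <- seg$cells == as.integer(names(ov)[which.max(ov)])
    sum(pm & tm) / sum(pm | tm)
  }, 0)
  expect_true(all(ious > 0.8))
})

test_that("touching cells with distinct nuclei are split by the watershed", {
  img <- matrix(0, 96, 96)
  xs <- matrix(rep(1:96, each = 96), 96); ys <- t(xs)
  # two overlapping discs with separated cores
  img[(xs - 38)^2 + (ys - 48)^2 < 16^2] <- 0.6
  img[(xs - 60)^2 + (ys - 48)^2 < 16^2] <- pmax(
    img[(xs - 60)^2 + (ys - 48)^2 < 16^2], 0.6)
  nuc <- matrix(0, 96, 96)
  nuc[(xs - 38)^2 + (ys - 48)^2 < 7^2] <- 1
  nuc[(xs - 60)^2 + (ys - 48)^2 < 7^2] <- 1
  seg <- segment_cells(img + nuc, nuc, smooth_sigma = 1)
  expect_equal(seg$n_cells, 2L)
})

test_that("cell features match analytic disc and square fixtures", {
  lab <- matrix(0L, 128, 128)
  xs <- matrix(rep(1:128, each = 128), 128); ys <- t(xs)
  lab[(xs - 64)^2 + (ys - 64)^2 <= 40^2] <- 1L
  nuc <- matrix(0L, 128, 128)
  nuc[(xs - 64)^2 + (ys - 64)^2 <= 20^2] <- 1L
  f <- cell_features(list(cells = lab, nuclei = nuc), pixel_size = 1)
  expect_equal(f$nc_ratio, 0.25, tolerance = 0.02 / 0.25)
  expect_gte(f$nuclear_roundness, 0.85)
  expect_lte(f$nuclear_roundness, 1)
  # square nucleus: isoperimetric quotient pi/4
  nsq <- matrix(0L, 128, 128)
  nsq[44:84, 44:84] <- 1L
  fsq <- cell_features(list(cells = lab, nuclei = nsq * lab), pixel_size = 1)
  expect_equal(fsq$nuclear_roundness, pi / 4, tolerance = 0.05 / (pi / 4))
  # empty label map
  e <- cell_features(list(cells = matrix(0L, 8, 8),
                          nuclei = matrix(0L, 8, 8)))
  expect_equal(nrow(e), 0)
})

test_that("features are invariant to translation and 90-degree rotation", {
  g <- pty_grid(128, 128, 1.85, 266)
  ph <- make_cell_phantom(g, 3, seed = 8)
  sig <- ph$n_pro + ph$n_nuc
  f0 <- cell_features(segment_cells(sig, ph$n_nuc), 1.85)
  sh <- function(m) rbind(m[118:128, ], m[1:117, ])
  f1 <- cell_features(segment_cells(sh(sig), sh(ph$n_nuc)), 1.85)
  f2 <- cell_features(segment_cells(t(sig), t(ph$n_nuc)), 1.85)
  key <- function(f) f[order(f$area_um2), c("area_um2", "nc_ratio",
                                            "nuclear_roundness")]
  expect_equal(key(f1), key(f0), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(key(f2)$nuclear_roundness, key(f0)$nuclear_roundness,
               tolerance = 0.02)
})

test_that("mononuclear-like and polymorphonuclear-like populations separate", {
  g <- pty_grid(192, 192, 1.85, 266)
  eps <- default_extinction_table()
  od_img <- function(ph) codedpty:::eps_at(eps, 266, "pro") * ph$n_pro +
    codedpty:::eps_at(eps, 266, "nuc") * ph$n_nuc
  fm <- cell_features(local({
    ph <- make_cell_phantom(g, 8, seed = 21, kind = "mononuclear")
    segment_cells(od_img(ph), ph$n_nuc)
  }), 1.85)
  fp <- cell_features(local({
    ph <- make_cell_phantom(g, 8, seed = 22, kind = "polymorphonuclear")
    segment_cells(od_img(ph), ph$n_nuc)
  }), 1.85)
  expect_gte(nrow(fm), 6)
  expect_gte(nrow(fp), 6)
  # zero overlap in the (nc_ratio, roundness) plane: the roundness axis
  # alone separates the populations
  expect_gt(min(fm$nuclear_roundness), max(fp$nuclear_roundness))
})
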