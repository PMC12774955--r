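test_that("intensity projection scales incoherent mixtures exactly", {
  m <- matrix(2.0, 8, 8)
  # fixed point: model == measured
  s <- list(matrix(sqrt(2) + 0i, 8, 8))
  upd <- project_intensity(s, m)
  expect_equal(upd[[1]], s[[1]], tolerance = 1e-12)
  # single state |psi|^2 = 4, measured 9 -> |psi'| = 3, phase kept
  s1 <- list(matrix(2i, 8, 8))
  upd1 <- project_intensity(s1, matrix(9, 8, 8))
  expect_equal(upd1[[1]], matrix(3i, 8, 8), tolerance = 1e-12)
  # two states 1 and 3, measured 8 -> 2 and 6 (ratios kept, sum matches)
  s2 <- list(matrix(1 + 0i, 8, 8), matrix(sqrt(3) + 0i, 8, 8))
  upd2 <- project_intensity(s2, matrix(8, 8, 8))
  expect_equal(Mod(upd2[[1]])^2, matrix(2, 8, 8), tolerance = 1e-12)
  expect_equal(Mod(upd2[[2]])^2, matrix(6, 8, 8), tolerance = 1e-12)
  # the updated mixture always reproduces the measurement exactly
  set.seed(1)
  s3 <- lapply(1:3, function(i)
    matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8))
  meas <- matrix(runif(64, 0.1, 4), 8, 8)
  upd3 <- project_intensity(s3, meas)
  expect_equal(Reduce(`+`, lapply(upd3, function(p) Mod(p)^2)), meas,
               tolerance = 1e-10)
  expect_error(project_intensity(s3, -meas), "negative")
})

test_that("forward model degenerate identities hold", {
  sim <- small_sim()
  ds <- sim$dataset
  truthE <- propagate(sim$exit, 800)$values
  opts <- list(use_virtual = TRUE, a = 1.1, n_modes_used = NULL)
  # virtual field of zeros adds nothing
  st0 <- codedpty:::make_state(truthE, matrix(0 + 0i, 64, 64), sim$cs$values,
                               sim$cs$values, sim$scan$positions, numeric(0),
                               sim$geometry, ds$source, 266, 1.85, 1, opts)
  fw0 <- forward_states(st0, 1)
  expect_equal(fw0$model_intensity, ds$frames[[1]], tolerance = 1e-9)
  # a = 1 with shared CS and E_virtual = E duplicates the object path
  opts1 <- list(use_virtual = TRUE, a = 1, n_modes_used = NULL)
  st1 <- codedpty:::make_state(truthE, truthE, sim$cs$values, sim$cs$values,
                               sim$scan$positions, numeric(0), sim$geometry,
                               ds$source, 266, 1.85, 1, opts1)
  fw1 <- forward_states(st1, 1)
  expect_equal(fw1$model_intensity, 2 * ds$frames[[1]], tolerance = 1e-9)
  expect_error(forward_states(st0, 99), "index")
})

test_that("recon_error is zero at the truth and one for a dark model", {
  sim <- small_sim()
  truthE <- propagate(sim$exit, 800)$values
  opts <- list(use_virtual = FALSE, a = 1.1, n_modes_used = NULL)
  st <- codedpty:::make_state(truthE, NULL, sim$cs$values, sim$cs$values,
                              sim$scan$positions, numeric(0), sim$geometry,
                              sim$dataset$source, 266, 1.85, 1, opts)
  expect_lt(recon_error(st, sim$dataset), 1e-20)
  st_dark <- st
  st_dark$E <- matrix(0 + 0i, 64, 64)
  expect_equal(recon_error(st_dark, sim$dataset), 1, tolerance = 1e-12)
  # the truth is an exact fixed point of the projection step
  fw <- forward_states(st, 1)
  upd <- project_intensity(fw$states_object, sim$dataset$frames[[1]])
  expect_lt(max(Mod(upd[[1]] - fw$states_object[[1]])), 1e-10)
})

test_that("the noiseless coherent benchmark converges to the phantom", {
  sim <- small_sim()
  st <- reconstruct(sim$dataset, sim$cs,
                    opts = recon_options(n_iter = 30, multires_levels = 1,
                                         seed = 2))
  fld <- propagate(recon_field(st), -800, plane = "sample")
  expect_lt(nrmse(Mod(fld$values), Mod(sim$exit$values)), 1e-6)
  # error history decreases after the early iterations
  h <- st$history
  expect_true(all(diff(h[5:length(h)]) <= 1e-12))
  # determinism: same options, same seed -> bit-identical state
  st2 <- reconstruct(sim$dataset, sim$cs,
                     opts = recon_options(n_iter = 30, multires_levels = 1,
                                          seed = 2))
  expect_identical(st$E, st2$E)
})

test_that("the multi-resolution schedule reaches the same solution", {
  sim <- small_sim()
  st <- reconstruct(sim$dataset, sim$cs,
                    opts = recon_options(n_iter = 40, multires_levels = 2,
                                         seed = 2))
  fld <- propagate(recon_field(st), -800, plane = "sample")
  expect_lt(nrmse(Mod(fld$values), Mod(sim$exit$values)), 1e-4)
})

test_that("position refinement is a fixed point at the truth and recovers jitter", {
  sim <- small_sim()
  st <- reconstruct(sim$dataset, sim$cs,
                    opts = recon_options(n_iter = 15, multires_levels = 1,
                                         seed = 2))
  st_ref <- refine_positions(st, sim$dataset)
  expect_lt(max(abs(st_ref$positions - sim$scan$positions)) / 1.85, 0.05)
  # jittered acquisition: nominal recorded, true perturbed by up to 2 px
  dsj <- simulate_dataset(sim$phantom, sim$cs, sim$geometry, sim$scan,
                          eps = sim$eps, seed = 3,
                          artifacts = "position_jitter", jitter_px = 2)
  stj <- reconstruct(dsj, sim$cs,
                     opts = recon_options(n_iter = 30, multires_levels = 1,
                                          refine_positions_every = 2,
                                          seed = 2))
  resid <- stj$positions - dsj$true_positions
  resid <- sweep(resid, 2, colMeans(resid))  # global offset is a gauge
  expect_lt(sqrt(mean(resid^2)) / 1.85, 0.3)
  # single-frame dataset: positions pinned
  ds1 <- sim$dataset
  ds1$frames <- ds1$frames[1]
  st1 <- st
  st1$positions <- matrix(0, 1, 2)
  expect_identical(refine_positions(st1, ds1)$positions, st1$positions)
})

test_that("reconstruction options validate their invariants", {
  expect_error(recon_options(n_iter = 0), "n_iter")
  expect_error(recon_options(use_virtual = TRUE, a = 1), "a must differ")
  expect_error(recon_options(update_step = 0), "update_step")
})
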