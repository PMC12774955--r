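#' Validated run configuration
#'
#' Builds and schema-validates the single configuration block driving the
#' command-line pipeline: geometry, scan, source, phantom, reconstruction
#' options and output settings. Unknown keys are rejected, as is a virtual
#' state with `a = 1`. The input may be a named list or a path to a
#' YAML/JSON file.
#'
#' @param config Named list, or path to a YAML or JSON file.
#' @return An object of class `run_config` (validated, defaults filled in).
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  defaults <- list(
    wavelengths_nm = c(266, 280, 405),
    d1_um = 800, d2_um = 840, a = 1.1, source_distance_um = 2e5,
    pitch_um = 1.85,
    grid_px = 128L,
    background_level = 1,
    scan = list(n_side = 6L, step_min_um = 4, step_max_um = 7, seed = 11L),
    source = list(shape = "point", n_states = 1L, radius_um = 150,
                  bandwidth_fwhm_nm = 0, n_spectral = 1L),
    phantom = list(n_cells = 3L, seed = 5L),
    recon = list(n_iter = 60L, use_virtual = FALSE, multires_levels = 2L,
                 update_step = 0.9, refine_positions_every = 0L),
    artifacts = character(0),
    seed = 1L
  )
  check_keys <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop("validation error: unknown config key(s) in ", where, ": ",
           paste(bad, collapse = ", "))
  }
  check_keys(config, names(defaults), "config")
  for (blk in c("scan", "source", "phantom", "recon"))
    if (!is.null(config[[blk]]))
      check_keys(config[[blk]], names(defaults[[blk]]), blk)
  merged <- utils::modifyList(defaults, config)
  if (isTRUE(merged$recon$use_virtual) && merged$a == 1)
    stop("validation error: a must differ from 1 when use_virtual is TRUE")
  if (merged$pitch_um <= 0)
    stop("validation error: pitch_um must be positive")
  if (merged$grid_px < 64)
    stop("validation error: grid_px must be >= 64")
  structure(merged, class = "run_config")
}

config_objects <- function(cfg, wavelength) {
  grid <- pty_grid(cfg$grid_px, cfg$grid_px, cfg$pitch_um, wavelength)
  geometry <- system_geometry(d1 = cfg$d1_um, d2 = cfg$d2_um, a = cfg$a,
                              source_distance = cfg$source_distance_um)
  scan <- make_scan_plan(cfg$scan$n_side, cfg$scan$step_min_um,
                         cfg$scan$step_max_um, seed = cfg$scan$seed)
  source <- make_source_model(shape = cfg$source$shape,
                              radius = cfg$source$radius_um,
                              n_states = cfg$source$n_states,
                              bandwidth_fwhm = cfg$source$bandwidth_fwhm_nm,
                              n_spectral = cfg$source$n_spectral,
                              center_wavelength = wavelength,
                              seed = cfg$seed)
  cs <- make_coded_surface(grid, seed = cfg$seed + 100L)
  list(grid = grid, geometry = geometry, scan = scan, source = source,
       cs = cs)
}

#' Object field of a reconstruction as a complex field
#'
#' @param state A `recon_state` from [reconstruct()].
#' @param which `"object"` or `"virtual"`.
#' @return A [complex_field()] at the coded-surface plane.
#' @export
recon_field <- function(state, which = c("object", "virtual")) {
  which <- match.arg(which)
  v <- if (which == "object") state$E else state$E_virtual
  if (is.null(v)) stop("no virtual field in this state")
  complex_field(v, pty_grid(ncol(v), nrow(v), state$pitch,
                            state$wavelength),
                plane = "coded_surface")
}

#' Simulate and write the demo datasets
#'
#' Generates the phantom and one diffraction dataset per configured
#' wavelength, writing each dataset (TIFF + JSON sidecar), the phantom
#' ground truth and a manifest with all seeds to `outdir`.
#'
#' @param config A [run_config()] (or anything accepted by it).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
cmd_simulate <- function(config = list(), outdir) {
  cfg <- run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  eps <- default_extinction_table()
  grid0 <- pty_grid(cfg$grid_px, cfg$grid_px, cfg$pitch_um,
                    cfg$wavelengths_nm[1])
  phantom <- make_cell_phantom(grid0, cfg$phantom$n_cells,
                               seed = cfg$phantom$seed)
  ph_path <- file.path(outdir, "phantom.tiff")
  ph_enc <- write_pages(list(phantom$n_pro, phantom$n_nuc, phantom$height),
                        ph_path)
  jsonlite::write_json(
    list(pages = c("n_pro_mol_per_um2", "n_nuc_mol_per_um2", "height_um"),
         encoding = ph_enc),
    paste0(ph_path, ".json"), auto_unbox = TRUE, digits = NA)
  files <- character(0)
  for (wl in cfg$wavelengths_nm) {
    obj <- config_objects(cfg, wl)
    ds <- simulate_dataset(phantom, obj$cs, obj$geometry, obj$scan,
                           obj$source, eps = eps, wavelength = wl,
                           background_level = cfg$background_level,
                           artifacts = cfg$artifacts, seed = cfg$seed)
    f <- file.path(outdir, sprintf("dataset_%dnm.tiff", as.integer(wl)))
    write_dataset(ds, f)
    files <- c(files, f)
  }
  manifest <- list(package_version = as.character(
                     utils::packageVersion("codedpty")),
                   config = unclass(cfg),
                   config_hash = config_hash(cfg),
                   datasets = files,
                   n_frames = nrow(obj$scan$positions))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' End-to-end demonstration pipeline
#'
#' Chains the full method on simulated data: phantom generation, forward
#' simulation at the two deep-UV wavelengths and 405 nm, reconstruction,
#' digital refocus check, differential mass recovery, virtual staining,
#' and cytometry. Writes recovered amplitude/phase TIFFs, mass maps, H&E
#' and fluorescence PNG renders, a per-cell feature CSV and a JSON metrics
#' report (amplitude NRMSE against ground truth, per-cell mass-recovery
#' errors, autofocus error), and returns the report.
#'
#' @param config A [run_config()] (or anything accepted by it).
#' @param outdir Output directory.
#' @return The report list, invisibly.
#' @export
cmd_full_demo <- function(config = list(), outdir) {
  cfg <- run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  eps <- default_extinction_table()
  t0 <- Sys.time()
  grid0 <- pty_grid(cfg$grid_px, cfg$grid_px, cfg$pitch_um, 266)
  phantom <- make_cell_phantom(grid0, cfg$phantom$n_cells,
                               seed = cfg$phantom$seed)
  opts <- recon_options(n_iter = cfg$recon$n_iter,
                        use_virtual = cfg$recon$use_virtual, a = cfg$a,
                        multires_levels = cfg$recon$multires_levels,
                        update_step = cfg$recon$update_step,
                        refine_positions_every =
                          cfg$recon$refine_positions_every,
                        seed = cfg$seed)
  stages <- list()
  recons <- list()
  amp_nrmse <- list()
  for (wl in c(266, 280)) {
    ts <- Sys.time()
    obj <- config_objects(cfg, wl)
    ds <- simulate_dataset(phantom, obj$cs, obj$geometry, obj$scan,
                           obj$source, eps = eps, wavelength = wl,
                           background_level = cfg$background_level,
                           artifacts = cfg$artifacts, seed = cfg$seed)
    st <- reconstruct(ds, obj$cs, opts = opts)
    fld <- propagate(recon_field(st), -cfg$d1_um, plane = "sample")
    export_amp_phase(fld,
                     file.path(outdir, sprintf("amp_%dnm.tiff", wl)),
                     file.path(outdir, sprintf("phase_%dnm.tiff", wl)))
    truth <- sample_exit_field(phantom, wl, eps)
    amp_nrmse[[as.character(wl)]] <-
      nrmse(Mod(fld$values),
            Mod(truth$values) * sqrt(cfg$background_level))
    recons[[as.character(wl)]] <- fld
    stages[[sprintf("recon_%dnm_s", wl)]] <-
      as.numeric(difftime(Sys.time(), ts, units = "secs"))
  }

  # refocus check: re-propagate the recovered sample field forward and ask
  # the autofocus to find its way back
  ts <- Sys.time()
  af <- autofocus_field(propagate(recons[["266"]], cfg$d1_um,
                                  plane = "coded_surface"),
                        z_min = max(cfg$d1_um - 300, 50),
                        z_max = cfg$d1_um + 300, z_step = 20)
  focus_error_um <- abs(af$z_best - cfg$d1_um)
  stages$autofocus_s <- as.numeric(difftime(Sys.time(), ts, units = "secs"))

  # mass recovery
  m <- cfg$grid_px
  roi <- list(rows = c(1:8, (m - 7):m), cols = 1:m)
  mass <- duv_mass_pipeline(Mod(recons[["266"]]$values),
                            Mod(recons[["280"]]$values),
                            roi, eps, cfg$pitch_um)
  truth_mass <- amounts_to_mass(phantom$n_pro, phantom$n_nuc, cfg$pitch_um,
                                eps)
  cell_err <- per_cell_mass_errors(mass, truth_mass, phantom)
  mm_path <- file.path(outdir, "mass_maps_fg.tiff")
  mm_enc <- write_pages(list(mass$m_pro, mass$m_nuc), mm_path)
  jsonlite::write_json(
    list(pages = c("m_pro_fg_per_px", "m_nuc_fg_per_px"),
         units = "fg/px", encoding = mm_enc),
    paste0(mm_path, ".json"), auto_unbox = TRUE, digits = NA)

  # staining + cytometry
  pal <- stain_palette()
  write_render(render_fluorescence(mass, pal),
               file.path(outdir, "virtual_fluorescence.png"))
  write_render(render_he(mass, pal), file.path(outdir, "virtual_he.png"))
  seg <- segment_cells(mass$od266, mass$m_nuc)
  feats <- cell_features(seg, pixel_size = cfg$pitch_um)
  utils::write.csv(feats, file.path(outdir, "cell_features.csv"),
                   row.names = FALSE)

  report <- list(
    package_version = as.character(utils::packageVersion("codedpty")),
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    amplitude_nrmse = amp_nrmse,
    focus_error_um = focus_error_um,
    mass_recovery = cell_err,
    registration_shift_px = as.list(mass$shift),
    n_cells_segmented = seg$n_cells,
    stage_seconds = stages,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

# Integrated per-cell masses (fg) for recovered vs ground-truth maps, and
# their relative errors.
per_cell_mass_errors <- function(mass, truth_mass, phantom) {
  ids <- sort(unique(phantom$cell_id[phantom$cell_id > 0]))
  per <- lapply(ids, function(id) {
    px <- phantom$cell_id == id
    tp <- sum(truth_mass$m_pro[px]); tn <- sum(truth_mass$m_nuc[px])
    rp <- sum(mass$m_pro[px]); rn <- sum(mass$m_nuc[px])
    list(cell_id = id,
         true_pro_fg = tp, recovered_pro_fg = rp,
         true_nuc_fg = tn, recovered_nuc_fg = rn,
         rel_err_pro = abs(rp - tp) / tp,
         rel_err_nuc = abs(rn - tn) / tn)
  })
  list(per_cell = per,
       max_rel_err_pro = max(vapply(per, `[[`, 1, "rel_err_pro")),
       max_rel_err_nuc = max(vapply(per, `[[`, 1, "rel_err_nuc")))
}
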