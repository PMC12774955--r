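# On-disk containers: multi-page 32-bit float TIFF for array payloads with a
# JSON sidecar for metadata. TIFF payloads are affinely normalized to [0, 1]
# per page (the tiff writer clamps outside that range); the sidecar records
# each page's offset and scale so reads are exact up to float-32 rounding.
# Complex fields are stored as two pages (real, imaginary).

norm_page <- function(m) {
  lo <- min(m); hi <- max(m)
  sc <- if (hi > lo) hi - lo else 1
  list(page = matrix(as.numeric((m - lo) / sc), nrow(m)),
       offset = lo, scale = sc)
}

denorm_page <- function(page, offset, scale) page * scale + offset

write_pages <- function(mats, path) {
  np <- lapply(mats, norm_page)
  tiff::writeTIFF(lapply(np, `[[`, "page"), path, bits.per.sample = 32,
                  reduce = FALSE)
  list(offset = vapply(np, `[[`, 0, "offset"),
       scale = vapply(np, `[[`, 0, "scale"))
}

read_pages <- function(path, enc) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  Map(function(p, o, s) denorm_page(p, o, s), pages,
      as.list(enc$offset), as.list(enc$scale))
}

#' Write / read a complex field
#'
#' Stores the field as a two-page 32-bit float TIFF (real, imaginary) plus a
#' JSON sidecar with the grid, plane and page-scaling metadata.
#'
#' @param field A [complex_field()].
#' @param path Output TIFF path; the sidecar is `path` + `.json`.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  enc <- write_pages(list(Re(field$values), Im(field$values)), path)
  meta <- list(nx = field$grid$nx, ny = field$grid$ny,
               pitch_um = field$grid$pitch,
               wavelength_nm = field$grid$wavelength, plane = field$plane,
               encoding = enc)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- read_pages(path, meta$encoding)
  grid <- pty_grid(meta$nx, meta$ny, meta$pitch_um, meta$wavelength_nm)
  complex_field(pages[[1]] + 1i * pages[[2]], grid, plane = meta$plane)
}

#' Export amplitude and phase of a field as TIFF
#'
#' Each output is a single-page 32-bit float TIFF with a JSON sidecar
#' recording the affine page scaling.
#'
#' @param field A [complex_field()].
#' @param amp_path,phase_path Output paths (either may be NULL).
#' @return Invisibly NULL.
#' @export
export_amp_phase <- function(field, amp_path = NULL, phase_path = NULL) {
  if (!is.null(amp_path)) {
    enc <- write_pages(list(Mod(field$values)), amp_path)
    jsonlite::write_json(list(content = "amplitude", encoding = enc),
                         paste0(amp_path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(phase_path)) {
    enc <- write_pages(list(Arg(field$values)), phase_path)
    jsonlite::write_json(list(content = "phase_rad", encoding = enc),
                         paste0(phase_path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(NULL)
}

#' Write / read a diffraction dataset
#'
#' Frames go to a multi-page 32-bit float TIFF; the scan plan, geometry,
#' source model and acquisition metadata go to a JSON sidecar, from which
#' the dataset is fully reconstructible.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param path Output TIFF path; the sidecar is `path` + `.json`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  enc <- write_pages(dataset$frames, path)
  meta <- list(
    wavelength_nm = dataset$wavelength,
    pitch_um = dataset$pitch,
    background_level = dataset$background_level,
    clipped_fraction = dataset$clipped_fraction,
    encoding = enc,
    geometry = unclass(dataset$geometry),
    scan = list(positions = dataset$scan$positions,
                n_side = dataset$scan$n_side,
                step_min = dataset$scan$step_min,
                step_max = dataset$scan$step_max,
                seed = dataset$scan$seed),
    true_positions = dataset$true_positions,
    source = list(states = dataset$source$states,
                  spectrum = dataset$source$spectrum)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- read_pages(path, meta$encoding)
  geom <- do.call(system_geometry, meta$geometry)
  scan <- structure(list(positions = as.matrix(meta$scan$positions),
                         n_side = meta$scan$n_side,
                         step_min = meta$scan$step_min,
                         step_max = meta$scan$step_max,
                         seed = meta$scan$seed),
                    class = "scan_plan")
  states <- as.matrix(meta$source$states)
  colnames(states) <- c("offset_x", "offset_y", "weight")
  spectrum <- as.matrix(meta$source$spectrum)
  colnames(spectrum) <- c("wavelength", "weight")
  src <- structure(list(states = states, spectrum = spectrum),
                   class = "source_model")
  ny <- nrow(frames[[1]]); nx <- ncol(frames[[1]])
  structure(list(frames = frames, scan = scan,
                 true_positions = as.matrix(meta$true_positions),
                 geometry = geom, source = src,
                 wavelength = meta$wavelength_nm, pitch = meta$pitch_um,
                 background_level = meta$background_level,
                 grid = pty_grid(nx, ny, meta$pitch_um, meta$wavelength_nm),
                 clipped_fraction = meta$clipped_fraction),
            class = "diffraction_dataset")
}

#' Write an RGB render to PNG
#'
#' @param rgb ny x nx x 3 array in \[0, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_render <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}
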