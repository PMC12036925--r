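#' Read and write quantitative maps as NIfTI-1
#'
#' Arrays and [quantitative_map()]s are stored as NIfTI volumes with the voxel
#' spacing in `pixdim`; masked voxels are written as `NaN`.
#'
#' @param map A [quantitative_map()] or numeric array.
#' @param path Output `.nii`/`.nii.gz` path.
#' @param spacing Voxel spacing in mm.
#' @return `path` (write) or a numeric array (read), invisibly for write.
#' @export
write_map_nifti <- function(map, path, spacing = c(1, 1, 5)) {
  vals <- if (inherits(map, "quantitative_map")) {
    v <- map$values; v[!map$mask] <- NA_real_; v
  } else map
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_map_nifti
#' @export
read_map_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)  # singleton slice
  arr
}

#' Write an acquisition series to NIfTI plus a metadata CSV
#'
#' Complex series are written as a magnitude/phase file pair; real series as
#' a single 4D volume. The per-volume metadata table is written alongside as
#' CSV so the series can be reconstructed.
#'
#' @param series An [acquisition_series()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The directory, invisibly.
#' @export
write_acquisition_series <- function(series, dir, prefix = series$modality) {
  stopifnot(inherits(series, "acquisition_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(suffix) file.path(dir, paste0(prefix, suffix))
  if (is.complex(series$data)) {
    write_map_nifti(Mod(series$data), p("_mag.nii.gz"), series$spacing)
    write_map_nifti(Arg(series$data), p("_phase.nii.gz"), series$spacing)
  } else {
    write_map_nifti(series$data, p(".nii.gz"), series$spacing)
  }
  readr::write_csv(series$meta, p("_meta.csv"))
  invisible(dir)
}

#' @rdname write_acquisition_series
#' @param modality Modality string of the series to read back.
#' @export
read_acquisition_series <- function(dir, prefix, modality = prefix) {
  p <- function(suffix) file.path(dir, paste0(prefix, suffix))
  meta <- readr::read_csv(p("_meta.csv"), show_col_types = FALSE)
  if (file.exists(p("_mag.nii.gz"))) {
    mag <- read_map_nifti(p("_mag.nii.gz"))
    ph <- read_map_nifti(p("_phase.nii.gz"))
    dat <- array(complex(modulus = mag, argument = ph), dim(mag))
  } else {
    dat <- read_map_nifti(p(".nii.gz"))
  }
  acquisition_series(dat, meta, modality)
}

#' Write a muscle label map (NIfTI + muscle table CSV)
#'
#' @param labelmap A [muscle_label_map()].
#' @param path Output NIfTI path; the muscle table goes to `<path>.csv`.
#' @param spacing Voxel spacing (mm).
#' @return `path`, invisibly.
#' @export
write_labelmap_nifti <- function(labelmap, path, spacing = c(1, 1, 5)) {
  stopifnot(inherits(labelmap, "muscle_label_map"))
  write_map_nifti(labelmap$labels, path, spacing)
  readr::write_csv(labelmap$muscles, paste0(path, ".csv"))
  invisible(path)
}

#' @rdname write_labelmap_nifti
#' @export
read_labelmap_nifti <- function(path) {
  labels <- round(read_map_nifti(path))
  storage.mode(labels) <- "integer"
  muscle_label_map(labels, readr::read_csv(paste0(path, ".csv"),
                                           show_col_types = FALSE))
}

#' Read and write single-voxel spectra
#'
#' JSON carries `ppm`, `real`, `imag`, `f0_mhz`; CSV the columns `ppm`,
#' `real`, `imag`.
#'
#' @param spec An [mrs_spectrum()].
#' @param path `.json` or `.csv` file path.
#' @return `path` (write) or an [mrs_spectrum()] (read).
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "mrs_spectrum"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(ppm = spec$ppm, real = Re(spec$signal),
                              imag = Im(spec$signal), f0_mhz = spec$f0_mhz),
                         path, digits = NA)
  } else {
    readr::write_csv(tibble::tibble(ppm = spec$ppm, real = Re(spec$signal),
                                    imag = Im(spec$signal)), path)
  }
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  if (grepl("\\.json$", path)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    mrs_spectrum(x$ppm, complex(real = x$real, imaginary = x$imag),
                 f0_mhz = x$f0_mhz %||% PROTON_MHZ_3T)
  } else {
    x <- readr::read_csv(path, show_col_types = FALSE)
    mrs_spectrum(x$ppm, complex(real = x$real, imaginary = x$imag))
  }
}

#' Serialize a phantom's ground truth next to its images
#'
#' Writes the per-muscle truth table (CSV), the scalar configuration echo
#' (JSON, including the seed) and the realized truth maps (NIfTI).
#'
#' @param truth A [phantom_ground_truth()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "phantom_ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- truth$config
  readr::write_csv(truth$truth, file.path(dir, "muscle_truth.csv"))
  jsonlite::write_json(
    list(nx = cfg$nx, ny = cfg$ny, nz = cfg$nz, spacing = cfg$spacing,
         b1_range = cfg$b1_range, psi_amp_hz = cfg$psi_amp_hz,
         sigma = cfg$sigma, seed = cfg$seed,
         dixon_te_ms = cfg$dixon_te_ms, mse_te_ms = cfg$mse_te_ms,
         dti_bval = cfg$dti_bval, dti_shifts_ms = cfg$dti_shifts_ms,
         olefinic_scale = cfg$olefinic_scale),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  sp <- cfg$spacing
  lm <- truth$labels; storage.mode(lm) <- "double"
  write_map_nifti(lm, file.path(dir, "labels.nii.gz"), sp)
  for (nm in c("ff", "t2w", "t1w", "b1", "psi"))
    write_map_nifti(truth[[nm]], file.path(dir, paste0(nm, ".nii.gz")), sp)
  invisible(dir)
}
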