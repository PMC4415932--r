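## NIfTI / JSON / CSV persistence. Volumes follow the x = right-left,
## y = anterior-posterior (increasing toward posterior), z = feet-head axis
## convention; voxel sizes are carried in the NIfTI pixdim.

nifti_with_pixdim <- function(arr, voxel_size) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size[seq_len(min(3, length(dim(arr))))]
  img
}

## plain numeric array, shorn of RNifti header attributes
read_nifti_array <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  array(as.numeric(arr), dim(arr))
}

#' Write / read a multi-echo complex image as NIfTI
#'
#' The complex 4D signal is stored as a real/imaginary pair of 4D NIfTI
#' files plus a JSON sidecar holding the acquisition protocol and the fat
#' spectrum used.
#'
#' @param image a `multiecho_image`.
#' @param prefix file path prefix; writes `<prefix>_real.nii.gz`,
#'   `<prefix>_imag.nii.gz`, `<prefix>.json`.
#' @return `write_multiecho` returns the written paths invisibly;
#'   `read_multiecho` returns the `multiecho_image`.
#' @export
write_multiecho <- function(image, prefix) {
  stopifnot(inherits(image, "multiecho_image"))
  vs <- image$protocol$voxel_size
  paths <- c(real = paste0(prefix, "_real.nii.gz"),
             imag = paste0(prefix, "_imag.nii.gz"),
             json = paste0(prefix, ".json"))
  RNifti::writeNifti(nifti_with_pixdim(Re(image$signal), vs), paths["real"])
  RNifti::writeNifti(nifti_with_pixdim(Im(image$signal), vs), paths["imag"])
  side <- list(protocol = unclass(image$protocol),
               fat_spectrum = unclass(image$spectrum),
               axes = "x=right-left, y=anterior-posterior(+), z=feet-head")
  jsonlite::write_json(side, paths["json"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_multiecho
#' @export
read_multiecho <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  pr <- side$protocol
  protocol <- acquisition_protocol(pr$field_strength, pr$n_echoes, pr$te_first,
                                   pr$delta_te, pr$voxel_size, pr$grid_shape,
                                   pr$flip_angle, pr$tr)
  spectrum <- fat_spectrum(side$fat_spectrum$frequencies_hz,
                           side$fat_spectrum$amplitudes,
                           side$fat_spectrum$reference_field)
  re <- read_nifti_array(paste0(prefix, "_real.nii.gz"))
  im <- read_nifti_array(paste0(prefix, "_imag.nii.gz"))
  structure(list(signal = array(complex(real = re, imaginary = im), dim(re)),
                 protocol = protocol, spectrum = spectrum),
            class = "multiecho_image")
}

#' Write / read quantitative maps as NIfTI
#'
#' One file per map (`water`, `fat`, `ff`, `r2s`, `fieldmap`, `residual`);
#' FF is stored as a fraction in `[0, 1]`. A JSON sidecar carries the voxel
#' size, the reconstruction options and the fat spectrum.
#'
#' @param maps a `quantitative_maps` object.
#' @param prefix file path prefix.
#' @return Written paths invisibly / the `quantitative_maps`.
#' @export
write_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "quantitative_maps"))
  nm <- c("water", "fat", "ff", "r2s", "fieldmap", "residual")
  paths <- c(stats::setNames(paste0(prefix, "_", nm, ".nii.gz"), nm),
             json = paste0(prefix, ".json"))
  for (k in nm)
    RNifti::writeNifti(nifti_with_pixdim(maps[[k]], maps$voxel_size), paths[[k]])
  RNifti::writeNifti(nifti_with_pixdim(array(as.integer(maps$degenerate),
                                             dim(maps$ff)), maps$voxel_size),
                     paste0(prefix, "_degenerate.nii.gz"), datatype = "uint8")
  side <- list(voxel_size = maps$voxel_size, options = unclass(maps$options),
               fat_spectrum = unclass(maps$spectrum))
  jsonlite::write_json(side, paths[["json"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_maps
#' @export
read_maps <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  out <- list()
  for (k in c("water", "fat", "ff", "r2s", "fieldmap", "residual"))
    out[[k]] <- read_nifti_array(paste0(prefix, "_", k, ".nii.gz"))
  out$degenerate <- array(as.array(
    RNifti::readNifti(paste0(prefix, "_degenerate.nii.gz"))) > 0, dim(out$ff))
  out$voxel_size <- as.numeric(side$voxel_size)
  op <- side$options
  out$options <- recon_options(op$mu, op$psi_step, op$psi_range, op$r2s_max,
                               op$r2s_step, op$r2s_stride, op$n_scales,
                               op$icm_sweeps, op$icm_window_hz,
                               op$magnitude_discrimination,
                               op$fieldmap_r_set %||% c(0, 25, 50, 100),
                               op$psi_refine %||% TRUE)
  out$spectrum <- fat_spectrum(side$fat_spectrum$frequencies_hz,
                               side$fat_spectrum$amplitudes,
                               side$fat_spectrum$reference_field)
  class(out) <- "quantitative_maps"
  out
}

#' Write / read a VOI mask as uint8 NIfTI
#'
#' @param mask a `voi_mask` (or logical array).
#' @param path output `.nii.gz` path.
#' @param voxel_size voxel size in mm.
#' @return The path invisibly / the `voi_mask` (provenance and state are
#'   restored from the JSON sidecar when present).
#' @export
write_mask <- function(mask, path, voxel_size = c(1, 1, 2)) {
  arr <- array(as.integer(as.logical(mask)), dim(mask))
  RNifti::writeNifti(nifti_with_pixdim(arr, voxel_size), path, datatype = "uint8")
  if (inherits(mask, "voi_mask")) {
    jsonlite::write_json(list(provenance = attr(mask, "provenance"),
                              state = attr(mask, "state")),
                         paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  else list(provenance = "crude_manual", state = NA_character_)
  voi_mask(array(arr > 0, dim(arr)), meta$provenance,
           meta$state %||% NA_character_)
}

#' Write / read a rigid transform as JSON
#'
#' @param t a [rigid_transform()].
#' @param path output `.json` path.
#' @return The path invisibly / the `rigid_transform`.
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  jsonlite::write_json(unclass(t), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$rotation, x$translation,
                  x$fixed_state %||% NA_character_,
                  x$moving_state %||% NA_character_)
}

#' Write / read VOI measurements as CSV
#'
#' @param measurements data.frame of per-subject per-state VOI summaries.
#' @param path output `.csv` path.
#' @return The path invisibly / the measurements data.frame (with `mode`
#'   attribute inferred from the states present).
#' @export
write_measurements <- function(measurements, path) {
  write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  attr(m, "mode") <- if (all(m$state %in% PROCEDURE_STATES))
    "procedure_study" else "cooling_reheating"
  m
}
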