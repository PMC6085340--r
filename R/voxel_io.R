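#' Write / read a label volume with a self-describing header
#'
#' The native exchange format is a flat binary of one byte per voxel
#' (column-major, x fastest) alongside a JSON header recording the grid
#' shape, voxel size, origin, label legend, landmarks and geometry, so no
#' external imaging dependency is required. If `path` ends in `.nii` or
#' `.nii.gz` and the RNifti package is installed, a NIfTI volume is written
#' or read instead (landmarks and geometry then travel in a sidecar JSON).
#'
#' @param model A [voxel_model()].
#' @param path Output path; `<path>.json` holds the header for the flat
#'   binary format.
#' @return `path` (write) or a [voxel_model()] (read). The optics table is
#'   not serialized with the volume; supply it on read.
#' @export
write_voxel_model <- function(model, path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      abort("writing NIfTI requires the RNifti package")
    }
    img <- RNifti::asNifti(model$labels, pixdim = rep(model$voxel_size, 3))
    RNifti::writeNifti(img, path)
  } else {
    writeBin(as.raw(as.integer(model$labels)), path)
  }
  hdr <- list(shape = dim(model$labels), voxel_size_mm = model$voxel_size,
              origin_mm = model$origin, legend = tissue_classes(),
              wavelengths_nm = model$wavelengths,
              landmarks_mm = model$landmarks, geometry = model$geometry)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @param optics Optical property table to attach on read.
#' @rdname write_voxel_model
#' @export
read_voxel_model <- function(path, optics = default_tissue_optics()) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  shape <- as.integer(hdr$shape)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      abort("reading NIfTI requires the RNifti package")
    }
    lab <- array(as.integer(RNifti::readNifti(path)), dim = shape)
  } else {
    lab <- array(as.integer(readBin(path, "raw", n = prod(shape))),
                 dim = shape)
  }
  landmarks <- purrr::map(hdr$landmarks_mm, as.numeric)
  geometry <- hdr$geometry
  geometry$type <- as.character(geometry$type)
  voxel_model(lab, hdr$voxel_size_mm, origin = as.numeric(hdr$origin_mm),
              wavelengths = as.numeric(hdr$wavelengths_nm),
              landmarks = landmarks, optics = optics, geometry = geometry)
}

#' Write a scalar voxel field as flat binary + JSON header
#'
#' Used for sensitivity volumes and maximum-sensitivity maps: float64 flat
#' binary (column-major) with a JSON sidecar describing shape and voxel size.
#'
#' @param values 3-D numeric array.
#' @param voxel_size Voxel edge, mm.
#' @param path Output path.
#' @param meta Optional named list merged into the JSON header.
#' @return `path`, invisibly.
#' @export
write_voxel_field <- function(values, voxel_size, path, meta = list()) {
  writeBin(as.numeric(values), path, size = 8)
  hdr <- c(list(shape = dim(values), voxel_size_mm = voxel_size,
                dtype = "float64"), meta)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_voxel_field
#' @export
read_voxel_field <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  shape <- as.integer(hdr$shape)
  array(readBin(path, "double", n = prod(shape), size = 8), dim = shape)
}
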