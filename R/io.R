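# NIfTI input/output with a JSON sidecar.
#
# Volumes and masks travel as .nii/.nii.gz files; the sidecar (same path
# with the .nii/.nii.gz extension replaced by .json) carries what the
# NIfTI-1 header cannot represent losslessly or at all: the unit tag, the
# structure role/label, the physical origin, and a float64 copy of the
# spacing (NIfTI stores pixdim as float32).  Sidecar values win over the
# header on read, which makes the write/read round trip bit-exact.

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write an image volume to NIfTI (+ JSON sidecar)
#'
#' @param vol an `image_volume`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("`path` must end in .nii or .nii.gz")
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(
    list(kind = "volume", unit = vol$unit,
         spacing_mm = vol$spacing, origin_mm = vol$origin),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image volume from NIfTI (+ JSON sidecar)
#'
#' @param path path to a `.nii`/`.nii.gz` file written by [write_volume()]
#'   (or any 3D NIfTI; without a sidecar the unit must be supplied).
#' @param unit unit tag override; required when no sidecar is present.
#' @return an `image_volume`.
#' @export
read_volume <- function(path, unit = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("NIfTI payload is not 3D: ", path)
  data <- array(as.numeric(img), dim(img))  # strip niftiImage attributes
  if (!all(is.finite(data)))
    stop("volume contains non-finite voxels: ", path)
  spacing <- as.numeric(RNifti::pixdim(img))[1:3]
  origin <- c(0, 0, 0)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$spacing_mm)) spacing <- as.numeric(meta$spacing_mm)
    if (!is.null(meta$origin_mm)) origin <- as.numeric(meta$origin_mm)
    if (is.null(unit) && !is.null(meta$unit)) unit <- meta$unit
  }
  if (is.null(unit))
    stop("no unit tag: supply `unit=` or provide a JSON sidecar")
  image_volume(data, spacing, origin, unit = unit)
}

#' Write a structure mask to NIfTI (+ JSON sidecar)
#'
#' The payload is written as 0/1; role and label go to the sidecar.
#'
#' @param mask a `structure_mask`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "structure_mask"))
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("`path` must end in .nii or .nii.gz")
  img <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  jsonlite::write_json(
    list(kind = "mask", role = mask$role, label = mask$label,
         spacing_mm = mask$spacing, origin_mm = mask$origin),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a structure mask from NIfTI (+ JSON sidecar)
#'
#' Without a sidecar the role is taken from `role=`, or inferred from a
#' `<case>_<ROLE>.nii.gz` filename convention, else `"OTHER"`.
#'
#' @param path path to a `.nii`/`.nii.gz` mask file (0/1 payload).
#' @param role optional role override.
#' @return a `structure_mask`.
#' @export
read_mask <- function(path, role = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("NIfTI payload is not 3D: ", path)
  data <- array(as.numeric(img), dim(img))
  if (anyNA(data) || !all(data %in% c(0, 1)))
    stop("mask payload must be binary 0/1: ", path)
  spacing <- as.numeric(RNifti::pixdim(img))[1:3]
  origin <- c(0, 0, 0)
  label <- ""
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$spacing_mm)) spacing <- as.numeric(meta$spacing_mm)
    if (!is.null(meta$origin_mm)) origin <- as.numeric(meta$origin_mm)
    if (is.null(role) && !is.null(meta$role)) role <- meta$role
    if (!is.null(meta$label)) label <- meta$label
  }
  if (is.null(role)) {
    stem <- sub("\\.nii(\\.gz)?$", "", basename(path))
    suffix <- toupper(sub(".*_", "", stem))
    role <- if (suffix %in% MASK_ROLES) suffix else "OTHER"
  }
  structure_mask(array(data != 0, dim(data)), spacing, origin,
                 role = role, label = label)
}
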