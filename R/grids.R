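#' @useDynLib aminopet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"

VOLUME_UNITS <- c("SUV", "activity_kBq_per_mL", "Gy", "arbitrary")

MASK_ROLES <- c("GTV", "BTV", "CTV", "PTV", "BASAL_GANGLIA", "BARRIER",
                "RECURRENCE", "BRAIN", "OTHER")

#' Create a 3D image volume on a regular voxel grid
#'
#' An `image_volume` is a 3D scalar field with anisotropic voxel spacing in
#' mm, a physical origin (the center of voxel \[1,1,1\]) and an explicit
#' unit tag.  All geometric computations in the package use physical mm
#' derived from the spacing; voxel values represent the field at the voxel
#' center.
#'
#' @param data 3D numeric array; all values must be finite.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin numeric length-3, physical coordinate (mm) of the center
#'   of the first voxel.
#' @param unit one of `"SUV"`, `"activity_kBq_per_mL"`, `"Gy"`,
#'   `"arbitrary"`.  Operations that require a particular unit reject
#'   volumes tagged otherwise.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         unit = "arbitrary") {
  unit <- match.arg(unit, VOLUME_UNITS)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("image volume contains non-finite voxel values")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  structure(list(data = data, spacing = spacing, origin = origin,
                 unit = unit),
            class = "image_volume")
}

#' Create a binary structure mask on a voxel grid
#'
#' @param data 3D logical (or 0/1 numeric) array.
#' @param spacing,origin grid geometry, as in [image_volume()].
#' @param role structure role, one of `"GTV"`, `"BTV"`, `"CTV"`, `"PTV"`,
#'   `"BASAL_GANGLIA"`, `"BARRIER"`, `"RECURRENCE"`, `"BRAIN"`, `"OTHER"`.
#' @param label free-text label.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                           role = "OTHER", label = "") {
  role <- match.arg(role, MASK_ROLES)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (is.numeric(data)) {
    if (any(is.na(data)) || !all(data %in% c(0, 1)))
      stop("numeric mask payload must contain only 0 and 1")
    data <- array(data != 0, dim(data))
  }
  if (!is.logical(data) || anyNA(data))
    stop("`data` must be logical without NAs")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  structure(list(data = data, spacing = spacing, origin = origin,
                 role = role, label = label),
            class = "structure_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s  dims %s  spacing %s mm  range [%.4g, %.4g]\n",
              x$unit, paste(dim(x$data), collapse = "x"),
              paste(x$spacing, collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> %s%s  dims %s  spacing %s mm  %d voxels (%.3f cc)\n",
              x$role, if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              paste(dim(x$data), collapse = "x"),
              paste(x$spacing, collapse = "x"),
              sum(x$data), mask_volume_cc(x)))
  invisible(x)
}

#' Test whether two gridded objects share a grid
#'
#' Two volumes/masks are considered co-registered iff their array shape,
#' spacing and origin match exactly.  The package never resamples: mixed
#' geometries are rejected so that silent misalignment cannot occur.
#'
#' @param a,b `image_volume` or `structure_mask` objects.
#' @return `TRUE` or `FALSE`.
#' @export
same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    identical(a$spacing, b$spacing) &&
    identical(a$origin, b$origin)
}

assert_coregistered <- function(...) {
  objs <- list(...)
  ref <- objs[[1]]
  for (o in objs[-1]) {
    if (!same_grid(ref, o))
      stop("inputs are not co-registered (shape, spacing and origin must match exactly)")
  }
  invisible(TRUE)
}

#' Physical volume of a mask in cubic centimeters
#'
#' `count(TRUE) * dx*dy*dz / 1000`, i.e. voxel-counting volume on the
#' mask's own grid.
#'
#' @param mask a `structure_mask`.
#' @return volume in cm^3.
#' @export
mask_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$data) * prod(mask$spacing) / 1000
}

#' Voxelwise boolean algebra on co-registered masks
#'
#' @param a,b co-registered `structure_mask` objects.
#' @param op `"and"`, `"or"` or `"minus"` (set difference a \ b).
#' @param role role of the result (default `"OTHER"`).
#' @param label label of the result.
#' @return a `structure_mask` on the common grid.
#' @export
mask_op <- function(a, b, op = c("and", "or", "minus"), role = "OTHER",
                    label = "") {
  op <- match.arg(op)
  stopifnot(inherits(a, "structure_mask"), inherits(b, "structure_mask"))
  assert_coregistered(a, b)
  d <- switch(op,
              and   = a$data & b$data,
              or    = a$data | b$data,
              minus = a$data & !b$data)
  structure_mask(d, a$spacing, a$origin, role = role, label = label)
}

#' @rdname mask_op
#' @export
mask_and <- function(a, b, role = "OTHER", label = "")
  mask_op(a, b, "and", role, label)

#' @rdname mask_op
#' @export
mask_or <- function(a, b, role = "OTHER", label = "")
  mask_op(a, b, "or", role, label)

#' @rdname mask_op
#' @export
mask_minus <- function(a, b, role = "OTHER", label = "")
  mask_op(a, b, "minus", role, label)

# physical coordinates (mm) of voxel centers along each axis
grid_axes_mm <- function(x) {
  d <- dim(x$data)
  lapply(1:3, function(ax) x$origin[ax] + (seq_len(d[ax]) - 1) * x$spacing[ax])
}

# squared physical distance of every voxel center from `center_mm`,
# returned as a 3D array on the grid of `x`
grid_dist2_mm <- function(x, center_mm) {
  ax <- grid_axes_mm(x)
  dx2 <- (ax[[1]] - center_mm[1])^2
  dy2 <- (ax[[2]] - center_mm[2])^2
  dz2 <- (ax[[3]] - center_mm[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+")
}

#' Euclidean distance map to a mask (mm)
#'
#' Exact Euclidean distance transform: for every voxel center, the distance
#' in physical mm to the nearest voxel center belonging to the mask.
#' Anisotropic spacing is honoured.
#'
#' @param mask a non-empty `structure_mask`.
#' @return an `image_volume` (unit `"arbitrary"`) of distances in mm;
#'   zero inside the mask.
#' @export
distance_map_mm <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  if (!any(mask$data)) stop("distance map of an empty mask is undefined")
  d <- .cpp_edt(mask$data, dim(mask$data), mask$spacing)
  image_volume(d, mask$spacing, mask$origin, unit = "arbitrary")
}
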