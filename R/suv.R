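# SUV quantification: body-weight SUV, physical decay correction and
# spherical-ROI statistics.

#' Acquisition metadata for SUV computation
#'
#' @param injected_activity_MBq injected activity in MBq, calibrated at
#'   injection time.
#' @param patient_weight_kg patient weight in kg.
#' @param t_injection,t_acquisition injection/acquisition times, either
#'   `POSIXct` or ISO-8601 strings (`"2020-01-01T10:00:00"`); acquisition
#'   must not precede injection.
#' @param half_life_min isotope physical half-life in minutes; the default
#'   109.77 is fluorine-18.
#' @return an object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(injected_activity_MBq, patient_weight_kg,
                             t_injection, t_acquisition,
                             half_life_min = 109.77) {
  parse_ts <- function(x) {
    if (inherits(x, "POSIXct")) return(x)
    out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    if (is.na(out)) out <- as.POSIXct(x, tz = "UTC")
    if (is.na(out)) stop("cannot parse timestamp: ", x)
    out
  }
  if (!is.numeric(injected_activity_MBq) || injected_activity_MBq <= 0)
    stop("injected activity must be positive")
  if (!is.numeric(patient_weight_kg) || patient_weight_kg <= 0)
    stop("patient weight must be positive")
  if (!is.numeric(half_life_min) || half_life_min <= 0)
    stop("half-life must be positive")
  ti <- parse_ts(t_injection)
  ta <- parse_ts(t_acquisition)
  if (ta < ti) stop("acquisition time precedes injection time")
  structure(list(injected_activity_MBq = injected_activity_MBq,
                 patient_weight_kg = patient_weight_kg,
                 t_injection = ti, t_acquisition = ta,
                 half_life_min = half_life_min),
            class = "acquisition_meta")
}

#' Read acquisition metadata from a JSON sidecar
#'
#' Expects keys `injected_activity_MBq`, `patient_weight_kg`,
#' `t_injection`, `t_acquisition` and optionally `half_life_min`.
#'
#' @param path path to a JSON file.
#' @return an `acquisition_meta`.
#' @export
read_acquisition_meta <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  acquisition_meta(m$injected_activity_MBq, m$patient_weight_kg,
                   m$t_injection, m$t_acquisition,
                   half_life_min = if (is.null(m$half_life_min)) 109.77
                                   else m$half_life_min)
}

#' Radioactive decay correction factor
#'
#' `2^(dt_min / half_life_min)`: the multiplicative factor that corrects a
#' signal measured `dt_min` minutes *after* a reference time back to that
#' reference.  Negative `dt_min` decays a reference-time value forward.
#'
#' @param dt_min elapsed time in minutes (may be negative).
#' @param half_life_min physical half-life in minutes.
#' @return the multiplicative factor; `decay_factor(0, .) == 1`.
#' @export
decay_factor <- function(dt_min, half_life_min = 109.77) {
  if (!is.numeric(half_life_min) || half_life_min <= 0)
    stop("half-life must be positive")
  if (any(!is.finite(dt_min))) stop("dt_min must be finite")
  2^(dt_min / half_life_min)
}

#' Injected activity decay-corrected to acquisition time
#'
#' @param meta an `acquisition_meta`.
#' @return activity in MBq at acquisition time.
#' @export
activity_at_acquisition_MBq <- function(meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  dt_min <- as.numeric(difftime(meta$t_acquisition, meta$t_injection,
                                units = "mins"))
  meta$injected_activity_MBq / decay_factor(dt_min, meta$half_life_min)
}

#' Standardized uptake value by the body-weight method
#'
#' `SUV(v) = c(v) / (A_acq / (weight_kg * 1000 mL))` with the tissue
#' density taken as 1 g/mL, `c` the activity concentration in kBq/mL and
#' `A_acq` the injected activity decay-corrected to acquisition time (in
#' kBq).  Equivalently `SUV = c * weight_kg / A_acq_MBq`.
#'
#' @param activity an `image_volume` tagged `"activity_kBq_per_mL"`.
#' @param meta an `acquisition_meta`.
#' @return an `image_volume` tagged `"SUV"` on the same grid.
#' @export
compute_suv <- function(activity, meta) {
  stopifnot(inherits(activity, "image_volume"),
            inherits(meta, "acquisition_meta"))
  if (activity$unit != "activity_kBq_per_mL")
    stop("compute_suv needs an activity volume in kBq/mL, got unit '",
         activity$unit, "'")
  a_acq <- activity_at_acquisition_MBq(meta)
  suv <- activity$data * meta$patient_weight_kg / a_acq
  image_volume(suv, activity$spacing, activity$origin, unit = "SUV")
}

#' Spherical region of interest on a voxel grid
#'
#' A voxel belongs to the ROI iff its center lies within `diameter_mm / 2`
#' of `center_mm` in physical mm (boundary inclusive).  The clinical
#' default is the 1-cm sphere used for tumor and contralateral
#' white-matter reference readings.
#'
#' @param grid an `image_volume` or `structure_mask` supplying the grid.
#' @param center_mm sphere center, physical mm.
#' @param diameter_mm sphere diameter in mm (default 10).
#' @param role role of the resulting mask.
#' @return a `structure_mask`; error if no voxel center falls inside.
#' @export
place_sphere_roi <- function(grid, center_mm, diameter_mm = 10,
                             role = "OTHER") {
  stopifnot(diameter_mm > 0)
  d2 <- grid_dist2_mm(grid, center_mm)
  inside <- d2 <= (diameter_mm / 2)^2
  if (!any(inside))
    stop("sphere ROI contains no voxel centers (wholly outside the grid?)")
  structure_mask(inside, grid$spacing, grid$origin, role = role,
                 label = sprintf("sphere d=%gmm", diameter_mm))
}

#' Intensity statistics over an ROI
#'
#' @param suv an `image_volume` (any unit).
#' @param roi a non-empty co-registered `structure_mask`.
#' @return a list with `mean`, `max`, `voxel_count` and `center_mm` (the
#'   centroid of the ROI voxel centers).
#' @export
roi_stats <- function(suv, roi) {
  stopifnot(inherits(suv, "image_volume"), inherits(roi, "structure_mask"))
  assert_coregistered(suv, roi)
  if (!any(roi$data)) stop("ROI is empty")
  vals <- suv$data[roi$data]
  ax <- grid_axes_mm(roi)
  idx <- which(roi$data, arr.ind = TRUE)
  center <- c(mean(ax[[1]][idx[, 1]]), mean(ax[[2]][idx[, 2]]),
              mean(ax[[3]][idx[, 3]]))
  list(mean = mean(vals), max = max(vals), voxel_count = length(vals),
       center_mm = center)
}
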