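# Biological target volume segmentation by tumor-to-normal threshold.

#' Tumor-to-normal uptake threshold
#'
#' The BTV is the set of brain voxels whose SUV is at least
#' `ratio * normal_reference`, where the normal reference is the mean SUV
#' of a contralateral white-matter ROI (centrum semiovale level).  The
#' study ratios for FDOPA high-grade glioma delineation are 1.7 and 2.0.
#'
#' @param ratio positive T/N ratio.
#' @param normal_reference positive normal-tissue reference SUV.
#' @return an object of class `tn_threshold`.
#' @export
tn_threshold <- function(ratio, normal_reference) {
  if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) ||
      ratio <= 0)
    stop("`ratio` must be a positive number")
  if (!is.numeric(normal_reference) || length(normal_reference) != 1L ||
      !is.finite(normal_reference) || normal_reference <= 0)
    stop("`normal_reference` must be a positive SUV")
  structure(list(ratio = ratio, normal_reference = normal_reference),
            class = "tn_threshold")
}

#' Segment the biological target volume by T/N thresholding
#'
#' `BTV = { v in brain : SUV(v) >= ratio * normal_reference } \ exclusions`.
#' The comparison is inclusive (>=) so that tie voxels are handled
#' deterministically.  Exclusion masks implement the anatomical correction
#' for physiologically avid structures (for FDOPA, the basal ganglia).
#'
#' @param suv an `image_volume` tagged `"SUV"`.
#' @param thr a [tn_threshold()].
#' @param brain a non-empty co-registered brain `structure_mask`.
#' @param exclusions list of co-registered `structure_mask`s removed from
#'   the result.
#' @return a `structure_mask` with role `"BTV"` and label `"BTV<ratio>"`.
#' @export
segment_btv <- function(suv, thr, brain, exclusions = list()) {
  stopifnot(inherits(suv, "image_volume"), inherits(thr, "tn_threshold"),
            inherits(brain, "structure_mask"))
  if (suv$unit != "SUV")
    stop("segment_btv needs an SUV volume, got unit '", suv$unit, "'")
  if (!any(brain$data)) stop("brain mask is empty")
  do.call(assert_coregistered, c(list(suv, brain), exclusions))
  cutoff <- thr$ratio * thr$normal_reference
  sel <- brain$data & (suv$data >= cutoff)
  for (ex in exclusions) sel <- sel & !ex$data
  structure_mask(sel, suv$spacing, suv$origin, role = "BTV",
                 label = sprintf("BTV%.4g", thr$ratio))
}

#' Connected-component filtering of a mask
#'
#' Components are 26-connected.  `policy = "all"` is the identity,
#' `"largest"` keeps the component with the most voxels (ties broken by
#' first encounter in column-major order), `"touching_seed"` keeps the
#' component containing the voxel nearest to `seed_mm`.
#'
#' @param mask a `structure_mask`.
#' @param policy `"all"`, `"largest"` or `"touching_seed"`.
#' @param seed_mm physical point (mm) for `"touching_seed"`.
#' @return a filtered `structure_mask` with the same role/label.
#' @export
keep_components <- function(mask, policy = c("all", "largest",
                                             "touching_seed"),
                            seed_mm = NULL) {
  policy <- match.arg(policy)
  stopifnot(inherits(mask, "structure_mask"))
  if (policy == "all") return(mask)
  if (!any(mask$data)) stop("mask is empty; no components to keep")
  lab <- .cpp_label26(mask$data, dim(mask$data))
  if (policy == "largest") {
    counts <- tabulate(lab[lab > 0])
    keep <- which.max(counts)  # ties: smallest label = first encountered
  } else {
    if (is.null(seed_mm)) stop("`seed_mm` required for policy 'touching_seed'")
    d <- dim(mask$data)
    vox <- round((seed_mm - mask$origin) / mask$spacing) + 1
    if (any(vox < 1) || any(vox > d))
      stop("seed point lies outside the grid")
    keep <- lab[vox[1], vox[2], vox[3]]
    if (keep == 0)
      stop("seed point does not touch any component")
  }
  structure_mask(array(lab == keep, dim(mask$data)), mask$spacing,
                 mask$origin, role = mask$role, label = mask$label)
}

#' Component labels of a mask (26-connectivity)
#'
#' @param mask a `structure_mask`.
#' @return integer array, 0 = background, components numbered from 1.
#' @export
label_components <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  .cpp_label26(mask$data, dim(mask$data))
}
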