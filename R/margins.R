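# CTV/PTV construction by Euclidean margin expansion with anatomical
# barriers.

#' Margin policy for target-volume construction
#'
#' European-guideline glioblastoma margins: CTV = GTV + 20 mm clipped to
#' anatomical barriers, PTV = CTV + 3-5 mm (default 3, the lower end of
#' the recommended band).
#'
#' @param ctv_margin_mm GTV-to-CTV margin in mm (>= 0).
#' @param ptv_margin_mm CTV-to-PTV margin in mm (>= 0).
#' @param barriers list of `structure_mask`s excluded from the CTV
#'   (falx, tentorium, bone... supplied by the caller).
#' @param bound outer bound `structure_mask` (typically the brain /
#'   external contour); `NULL` means the whole grid.
#' @return an object of class `margin_policy`.
#' @export
margin_policy <- function(ctv_margin_mm = 20, ptv_margin_mm = 3,
                          barriers = list(), bound = NULL) {
  if (ctv_margin_mm < 0 || ptv_margin_mm < 0)
    stop("margins must be non-negative")
  structure(list(ctv_margin_mm = ctv_margin_mm,
                 ptv_margin_mm = ptv_margin_mm,
                 barriers = barriers, bound = bound),
            class = "margin_policy")
}

#' Expand a mask by a physical margin
#'
#' Euclidean-distance expansion: the result contains every voxel of
#' `bound`, outside all `barriers`, whose center lies within `margin_mm`
#' (inclusive) of the nearest voxel center of `mask`.  Distances are
#' physical mm via an exact distance transform, so anisotropic grids are
#' handled correctly.  Barrier voxels are removed from the candidate set;
#' regions beyond a barrier are not shadowed (no geodesic reachability).
#'
#' @param mask a non-empty `structure_mask`.
#' @param margin_mm margin in mm (>= 0); 0 returns `mask` clipped to
#'   `bound` minus barriers.
#' @param barriers list of co-registered `structure_mask`s.
#' @param bound co-registered `structure_mask` or `NULL` (whole grid).
#' @param role role of the result.
#' @return an expanded `structure_mask`.
#' @export
expand_margin <- function(mask, margin_mm, barriers = list(), bound = NULL,
                          role = "OTHER") {
  stopifnot(inherits(mask, "structure_mask"))
  if (margin_mm < 0) stop("margin must be non-negative")
  if (!any(mask$data)) stop("cannot expand an empty mask")
  others <- c(barriers, if (!is.null(bound)) list(bound))
  do.call(assert_coregistered, c(list(mask), others))
  d <- .cpp_edt(mask$data, dim(mask$data), mask$spacing)
  sel <- d <= margin_mm
  if (!is.null(bound)) sel <- sel & bound$data
  for (b in barriers) sel <- sel & !b$data
  structure_mask(sel, mask$spacing, mask$origin, role = role)
}

#' Build CTV and PTV from a GTV
#'
#' `CTV = expand(GTV, ctv_margin, barriers, bound)`;
#' `PTV = expand(CTV, ptv_margin, barriers = none, bound)`.  The setup
#' margin ignores barriers (setup uncertainty does not respect anatomy);
#' both stay within the bound.
#'
#' @param gtv a non-empty `structure_mask` (role GTV).
#' @param policy a [margin_policy()].
#' @return a list with elements `ctv` and `ptv`.
#' @export
build_targets <- function(gtv, policy = margin_policy()) {
  stopifnot(inherits(gtv, "structure_mask"), inherits(policy, "margin_policy"))
  if (!any(gtv$data)) stop("GTV is empty")
  ctv <- expand_margin(gtv, policy$ctv_margin_mm, barriers = policy$barriers,
                       bound = policy$bound, role = "CTV")
  ptv <- expand_margin(ctv, policy$ptv_margin_mm, barriers = list(),
                       bound = policy$bound, role = "PTV")
  list(ctv = ctv, ptv = ptv)
}
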