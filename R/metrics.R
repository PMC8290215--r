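# Concordance and coverage metrics between target volumes.

# logical array shifted by one voxel along `axis` in direction `dir`
# (+1/-1), padding with FALSE
shift_bool <- function(a, axis, dir) {
  d <- dim(a)
  out <- array(FALSE, d)
  n <- d[axis]
  if (n < 2) return(out)
  src <- vector("list", 3)
  dst <- vector("list", 3)
  for (ax in 1:3) {
    src[[ax]] <- seq_len(d[ax])
    dst[[ax]] <- seq_len(d[ax])
  }
  if (dir > 0) {
    dst[[axis]] <- 2:n
    src[[axis]] <- 1:(n - 1)
  } else {
    dst[[axis]] <- 1:(n - 1)
    src[[axis]] <- 2:n
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Surface voxels of a mask
#'
#' A mask voxel is a surface voxel iff at least one of its six
#' face-neighbours lies outside the mask; neighbours beyond the grid
#' boundary count as outside.
#'
#' @param mask a non-empty `structure_mask`.
#' @return a `structure_mask` of the surface voxels (role preserved).
#' @export
surface_voxels <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  m <- mask$data
  if (!any(m)) stop("surface of an empty mask is undefined")
  all_in <- shift_bool(m, 1, +1) & shift_bool(m, 1, -1) &
            shift_bool(m, 2, +1) & shift_bool(m, 2, -1) &
            shift_bool(m, 3, +1) & shift_bool(m, 3, -1)
  structure_mask(m & !all_in, mask$spacing, mask$origin,
                 role = mask$role, label = mask$label)
}

# distances (mm) from the voxels of `from` (logical array) to the nearest
# surface voxel of `target_surface` (structure_mask), via the exact EDT
dist_to_surface <- function(from_logical, target_surface) {
  d <- .cpp_edt(target_surface$data, dim(target_surface$data),
                target_surface$spacing)
  d[from_logical]
}

#' Directed percentile Hausdorff distance (HD95)
#'
#' For each surface voxel of `source`, the Euclidean distance (mm) to the
#' nearest surface voxel of `target`; the statistic is the `percentile`-th
#' percentile of these distances, with linear interpolation between order
#' statistics.  Directed: `hd95_directed(a, b)` generally differs from
#' `hd95_directed(b, a)`.
#'
#' @param source,target non-empty co-registered `structure_mask`s.
#' @param percentile percentile in (0, 100]; default 95.
#' @return distance in mm.
#' @export
hd95_directed <- function(source, target, percentile = 95) {
  stopifnot(inherits(source, "structure_mask"),
            inherits(target, "structure_mask"))
  assert_coregistered(source, target)
  if (!any(source$data) || !any(target$data))
    stop("hd95 requires two non-empty masks")
  src_surf <- surface_voxels(source)
  tgt_surf <- surface_voxels(target)
  dd <- dist_to_surface(src_surf$data, tgt_surf)
  stats::quantile(dd, percentile / 100, type = 7, names = FALSE)
}

#' Supplementary-volume distances from GTV to BTV
#'
#' The supplementary volume is `btv \ gtv` — PET-avid tissue outside the
#' MRI-defined target.  For each of its voxels the distance (mm) to the
#' nearest GTV surface voxel is computed; the max and mean summarize how
#' far the PET volume extends beyond the GTV.  If the supplementary
#' volume is empty both distances are 0.
#'
#' @param gtv non-empty `structure_mask`.
#' @param btv co-registered `structure_mask`.
#' @return named numeric `c(max_mm=, mean_mm=)`.
#' @export
svc_distances <- function(gtv, btv) {
  stopifnot(inherits(gtv, "structure_mask"), inherits(btv, "structure_mask"))
  assert_coregistered(gtv, btv)
  if (!any(gtv$data)) stop("GTV is empty")
  svc <- btv$data & !gtv$data
  if (!any(svc)) return(c(max_mm = 0, mean_mm = 0))
  dd <- dist_to_surface(svc, surface_voxels(gtv))
  c(max_mm = max(dd), mean_mm = mean(dd))
}

#' Within/outside volume decomposition of BTV against GTV
#'
#' @param btv,gtv co-registered `structure_mask`s.
#' @return list with `total_cc`, `within_cc`, `outside_cc` and
#'   `outside_fraction` (0 when the BTV is empty).  Volumes are voxel
#'   counting, so `within_cc + outside_cc == total_cc` exactly.
#' @export
overlap_decomposition <- function(btv, gtv) {
  stopifnot(inherits(btv, "structure_mask"), inherits(gtv, "structure_mask"))
  assert_coregistered(btv, gtv)
  vox_cc <- prod(btv$spacing) / 1000
  n_total <- sum(btv$data)
  n_within <- sum(btv$data & gtv$data)
  n_outside <- n_total - n_within
  within_cc <- n_within * vox_cc
  outside_cc <- n_outside * vox_cc
  # total as the sum of the parts, so conservation holds to the bit
  list(total_cc = within_cc + outside_cc,
       within_cc = within_cc,
       outside_cc = outside_cc,
       outside_fraction = if (n_total == 0) 0 else n_outside / n_total)
}

#' Isodose coverage of a structure
#'
#' Fraction of the structure's voxels receiving at least
#' `iso_fraction * prescription_Gy` (inclusive comparison).  The clinical
#' convention assessed here is coverage by the 95% isodose of a 60 Gy
#' prescription, i.e. the 57 Gy level.
#'
#' @param dose an `image_volume` tagged `"Gy"`.
#' @param mask non-empty co-registered `structure_mask`.
#' @param prescription_Gy prescribed dose in Gy (> 0).
#' @param iso_fraction isodose level as a fraction of prescription.
#' @return list with `covered_fraction`, `iso_level_Gy`, `prescription_Gy`.
#' @export
dose_coverage <- function(dose, mask, prescription_Gy, iso_fraction = 0.95) {
  stopifnot(inherits(dose, "image_volume"), inherits(mask, "structure_mask"))
  if (dose$unit != "Gy")
    stop("dose_coverage needs a dose volume in Gy, got unit '", dose$unit, "'")
  assert_coregistered(dose, mask)
  if (prescription_Gy <= 0) stop("prescription must be positive")
  if (!any(mask$data)) stop("structure mask is empty")
  iso <- iso_fraction * prescription_Gy
  list(covered_fraction = mean(dose$data[mask$data] >= iso),
       iso_level_Gy = iso, prescription_Gy = prescription_Gy)
}

#' Recurrence location relative to reference structures
#'
#' For each reference structure, the fraction of the recurrence volume
#' lying outside it.
#'
#' @param rec non-empty recurrence `structure_mask`.
#' @param references named list of co-registered `structure_mask`s
#'   (e.g. `list(GTV=, BTV1.7=, BTV2.0=, PTV=)`).
#' @return named numeric vector of outside fractions in \[0, 1\].
#' @export
recurrence_analysis <- function(rec, references) {
  stopifnot(inherits(rec, "structure_mask"), is.list(references))
  if (!any(rec$data)) stop("recurrence mask is empty")
  n_rec <- sum(rec$data)
  vapply(references, function(ref) {
    assert_coregistered(rec, ref)
    sum(rec$data & !ref$data) / n_rec
  }, numeric(1))
}

#' Full concordance report between a GTV and a BTV
#'
#' Bundles the directed HD95 (GTV to BTV), the supplementary-volume
#' distances and the within/outside decomposition.
#'
#' @param gtv,btv non-empty co-registered `structure_mask`s.
#' @return list with `hd95_mm`, `svc_max_mm`, `svc_mean_mm`, `total_cc`,
#'   `within_cc`, `outside_cc`, `outside_fraction`.
#' @export
concordance_report <- function(gtv, btv) {
  dec <- overlap_decomposition(btv, gtv)
  svc <- svc_distances(gtv, btv)
  hd <- if (any(btv$data)) hd95_directed(gtv, btv) else NA_real_
  c(list(hd95_mm = hd,
         svc_max_mm = unname(svc["max_mm"]),
         svc_mean_mm = unname(svc["mean_mm"])),
    dec)
}

#' Dice similarity coefficient of two masks
#'
#' @param a,b co-registered `structure_mask`s.
#' @return `2|A&B| / (|A|+|B|)`; 1 when both are empty.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "structure_mask"), inherits(b, "structure_mask"))
  assert_coregistered(a, b)
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0) return(1)
  2 * sum(a$data & b$data) / (na + nb)
}
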