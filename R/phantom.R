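# Digital brain phantom: a co-registered synthetic patient (SUV volume,
# structure masks, dose grid, optional recurrence) with closed-form
# ground truth for every downstream metric.
#
# All uptake regions are radially symmetric analytic profiles, so the
# iso-contour of any T/N ratio -- hence the true BTV mask and its volume
# -- is known exactly.  That closed form is what parameter-recovery tests
# compare the pipeline against.

#' Specification of the digital brain phantom
#'
#' The phantom is a brain-shaped ellipsoid of uniform white-matter uptake
#' (SUV `background_suv`), high-uptake basal-ganglia blobs, and a tumor
#' whose tracer-avid (infiltration) extent exceeds its contrast-enhancement
#' (GTV) extent — the mismatch the concordance metrics quantify.  An
#' optional PSF smoothing and multiplicative noise stage emulates scanner
#' resolution and statistical noise; a geometric dose field covers the PTV
#' built from the GTV.
#'
#' @param shape grid dimensions (voxels).
#' @param spacing_mm voxel spacing in mm.
#' @param brain_semiaxes_mm ellipsoid semi-axes of the brain (mm).
#' @param background_suv uniform white-matter SUV; also the ground-truth
#'   normal reference, so `peak_tn_ratio` is the tumor-center T/N ratio.
#' @param basal_ganglia list of `list(offset_mm=, radius_mm=, tn=)` blobs,
#'   offsets relative to the brain center; `tn` their uptake ratio.
#' @param tumor list with `offset_mm` (from brain center),
#'   `enhancement_radius_mm` (the MRI/GTV extent),
#'   `infiltration_radius_mm` (the PET-avid extent, must be >=
#'   enhancement), `peak_tn_ratio` (> 1) and `profile` (`"step"`,
#'   `"radial_linear"` or `"radial_gaussian"`).
#' @param noise_sigma_fraction multiplicative Gaussian noise SD as a
#'   fraction of local signal (0 = noiseless).
#' @param psf_fwhm_mm Gaussian PSF FWHM in mm (0 = no smoothing).
#' @param prescription_Gy prescribed dose.
#' @param dose_falloff_mm linear dose falloff distance outside the PTV.
#' @param ctv_margin_mm,ptv_margin_mm margins used for the phantom's
#'   CTV/PTV.
#' @param recurrence optional `list(radius_mm=, designed_outside_fraction=,
#'   vs=)` with `vs` one of the generated mask roles (`"GTV"`, `"PTV"`,
#'   `"CTV"`, `"BRAIN"`).
#' @param seed integer RNG seed for the noise stage.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128, 128),
                         spacing_mm = c(2, 2, 2),
                         brain_semiaxes_mm = c(70, 85, 60),
                         background_suv = 1.0,
                         basal_ganglia = list(
                           list(offset_mm = c(-22, 18, 2), radius_mm = 11,
                                tn = 2.2),
                           list(offset_mm = c(22, 18, 2), radius_mm = 11,
                                tn = 2.2)),
                         tumor = list(offset_mm = c(40, -20, 5),
                                      enhancement_radius_mm = 9,
                                      infiltration_radius_mm = 20,
                                      peak_tn_ratio = 3.0,
                                      profile = "radial_linear"),
                         noise_sigma_fraction = 0.05,
                         psf_fwhm_mm = 4,
                         prescription_Gy = 60,
                         dose_falloff_mm = 20,
                         ctv_margin_mm = 20,
                         ptv_margin_mm = 3,
                         recurrence = NULL,
                         seed = 1L) {
  tumor$profile <- match.arg(tumor$profile,
                             c("step", "radial_linear", "radial_gaussian"))
  if (tumor$infiltration_radius_mm < tumor$enhancement_radius_mm)
    stop("infiltration radius must be >= enhancement radius")
  if (tumor$peak_tn_ratio <= 1)
    stop("peak T/N ratio must exceed 1")
  if (noise_sigma_fraction < 0 || psf_fwhm_mm < 0)
    stop("noise and PSF parameters must be non-negative")
  if (background_suv <= 0) stop("background SUV must be positive")
  structure(list(shape = as.integer(shape), spacing_mm = as.numeric(spacing_mm),
                 brain_semiaxes_mm = brain_semiaxes_mm,
                 background_suv = background_suv,
                 basal_ganglia = basal_ganglia, tumor = tumor,
                 noise_sigma_fraction = noise_sigma_fraction,
                 psf_fwhm_mm = psf_fwhm_mm,
                 prescription_Gy = prescription_Gy,
                 dose_falloff_mm = dose_falloff_mm,
                 ctv_margin_mm = ctv_margin_mm, ptv_margin_mm = ptv_margin_mm,
                 recurrence = recurrence, seed = as.integer(seed)),
            class = "phantom_spec")
}

# brain center in physical mm (grid origin fixed at 0)
phantom_brain_center <- function(spec) {
  spec$spacing_mm * (spec$shape - 1) / 2
}

#' Tumor center of a phantom in physical mm
#' @param spec a `phantom_spec`.
#' @return length-3 numeric.
#' @export
phantom_tumor_center <- function(spec) {
  phantom_brain_center(spec) + spec$tumor$offset_mm
}

# T/N profile value at radius r (vectorized)
tn_profile <- function(spec, r) {
  peak <- spec$tumor$peak_tn_ratio
  rinf <- spec$tumor$infiltration_radius_mm
  switch(spec$tumor$profile,
    step = ifelse(r <= rinf, peak, 1),
    radial_linear = ifelse(r <= rinf, peak - (peak - 1) * r / rinf, 1),
    radial_gaussian = {
      sigma <- rinf / 3
      1 + (peak - 1) * exp(-r^2 / (2 * sigma^2))
    })
}

#' Analytic iso-contour radius of the phantom tumor profile
#'
#' Radius (mm) at which the tumor's T/N profile equals `ratio`; the true
#' BTV at that threshold is the ball of this radius around the tumor
#' center.  For the linear profile of peak `p` and infiltration radius
#' `R`, the radius at ratio `t` is `R (p - t) / (p - 1)`.
#'
#' @param spec a `phantom_spec`.
#' @param ratio T/N ratio in (1, peak\].
#' @return radius in mm.
#' @export
tn_iso_radius <- function(spec, ratio) {
  peak <- spec$tumor$peak_tn_ratio
  rinf <- spec$tumor$infiltration_radius_mm
  if (ratio <= 1 || ratio > peak)
    stop("ratio must lie in (1, peak_tn_ratio]")
  switch(spec$tumor$profile,
    step = rinf,
    radial_linear = rinf * (peak - ratio) / (peak - 1),
    radial_gaussian = {
      sigma <- rinf / 3
      sigma * sqrt(2 * log((peak - 1) / (ratio - 1)))
    })
}

#' Analytic true-BTV volume of the phantom at a T/N ratio
#' @param spec a `phantom_spec`.
#' @param ratio T/N ratio in (1, peak\].
#' @return ball volume `(4/3) pi r^3 / 1000` in cm^3.
#' @export
true_btv_cc <- function(spec, ratio) {
  r <- tn_iso_radius(spec, ratio)
  4 / 3 * pi * r^3 / 1000
}

sphere_mask <- function(template, center_mm, radius_mm, role = "OTHER",
                        label = "") {
  d2 <- grid_dist2_mm(template, center_mm)
  structure_mask(d2 <= radius_mm^2, template$spacing, template$origin,
                 role = role, label = label)
}

#' Voxelized ground-truth BTV mask of a phantom at a T/N ratio
#'
#' The analytic iso-contour region `{ r <= tn_iso_radius(spec, ratio) }`
#' sampled at voxel centers (boundary inclusive, matching the inclusive
#' threshold of [segment_btv()]).
#'
#' @param spec a `phantom_spec`.
#' @param ratio T/N ratio in (1, peak\].
#' @return a `structure_mask` with role `"BTV"`.
#' @export
true_btv_mask <- function(spec, ratio) {
  template <- phantom_template(spec)
  sphere_mask(template, phantom_tumor_center(spec), tn_iso_radius(spec, ratio),
              role = "BTV", label = sprintf("true BTV%.4g", ratio))
}

# zero-filled image on the phantom grid (origin 0)
phantom_template <- function(spec) {
  image_volume(array(0, spec$shape), spec$spacing_mm, c(0, 0, 0),
               unit = "arbitrary")
}

#' Generate the digital patient
#'
#' Builds, on one co-registered grid: the SUV volume (tumor and
#' basal-ganglia uptake over uniform brain background, optionally PSF
#' smoothed then degraded with seeded multiplicative noise), the BRAIN /
#' GTV / BASAL_GANGLIA / CTV / PTV masks, the dose grid (prescription
#' inside the PTV with linear falloff outside), the optional recurrence
#' mask, and a ground-truth record.  Deterministic given the spec
#' (including its seed); changing only the seed changes only the noise.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `suv` (`image_volume`, SUV), `dose`
#'   (`image_volume`, Gy), `masks` (named list: `brain`, `gtv`,
#'   `basal_ganglia`, `ctv`, `ptv`, optionally `recurrence`), `truth`
#'   (bookkeeping: volumes, centers, achieved recurrence fraction) and
#'   `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  template <- phantom_template(spec)
  bc <- phantom_brain_center(spec)
  ax <- grid_axes_mm(template)
  ex2 <- outer(outer(((ax[[1]] - bc[1]) / spec$brain_semiaxes_mm[1])^2,
                     ((ax[[2]] - bc[2]) / spec$brain_semiaxes_mm[2])^2, "+"),
               ((ax[[3]] - bc[3]) / spec$brain_semiaxes_mm[3])^2, "+")
  brain <- structure_mask(ex2 <= 1, spec$spacing_mm, c(0, 0, 0),
                          role = "BRAIN")

  tc <- phantom_tumor_center(spec)
  tumor_r <- sqrt(grid_dist2_mm(template, tc))
  if (any(tumor_r <= spec$tumor$infiltration_radius_mm & !brain$data))
    stop("tumor infiltration region extends outside the brain")

  suv <- array(0, spec$shape)
  suv[brain$data] <- spec$background_suv
  tn <- tn_profile(spec, tumor_r)
  suv <- pmax(suv, ifelse(brain$data, spec$background_suv * tn, 0))

  bg_mask <- array(FALSE, spec$shape)
  for (b in spec$basal_ganglia) {
    m <- sphere_mask(template, bc + b$offset_mm, b$radius_mm)
    bg_mask <- bg_mask | m$data
    suv[m$data] <- pmax(suv[m$data], spec$background_suv * b$tn)
  }
  basal_ganglia <- structure_mask(bg_mask, spec$spacing_mm, c(0, 0, 0),
                                  role = "BASAL_GANGLIA")

  if (spec$psf_fwhm_mm > 0)
    suv <- .cpp_gauss_blur(suv, dim(suv), spec$spacing_mm, spec$psf_fwhm_mm)
  if (spec$noise_sigma_fraction > 0) {
    suv <- with_seed(spec$seed, {
      noise <- array(stats::rnorm(length(suv), 0, spec$noise_sigma_fraction),
                     dim(suv))
      pmax(suv * (1 + noise), 0)
    })
  }
  suv_vol <- image_volume(suv, spec$spacing_mm, c(0, 0, 0), unit = "SUV")

  gtv <- sphere_mask(template, tc, spec$tumor$enhancement_radius_mm,
                     role = "GTV")
  targets <- build_targets(gtv, margin_policy(spec$ctv_margin_mm,
                                              spec$ptv_margin_mm,
                                              bound = brain))

  d_out <- .cpp_edt(targets$ptv$data, dim(suv), spec$spacing_mm)
  dose_arr <- spec$prescription_Gy * pmax(1 - d_out / spec$dose_falloff_mm, 0)
  dim(dose_arr) <- spec$shape
  dose <- image_volume(dose_arr, spec$spacing_mm, c(0, 0, 0), unit = "Gy")

  masks <- list(brain = brain, gtv = gtv, basal_ganglia = basal_ganglia,
                ctv = targets$ctv, ptv = targets$ptv)
  truth <- list(brain_cc = mask_volume_cc(brain),
                gtv_cc = mask_volume_cc(gtv),
                tumor_center_mm = tc,
                brain_center_mm = bc,
                normal_reference = spec$background_suv)

  if (!is.null(spec$recurrence)) {
    rc <- spec$recurrence
    ref <- masks[[tolower(rc$vs)]]
    if (is.null(ref)) stop("unknown recurrence reference role: ", rc$vs)
    rec <- make_recurrence(ref, rc$designed_outside_fraction,
                           radius_mm = rc$radius_mm)
    masks$recurrence <- rec
    truth$recurrence_designed_outside_fraction <- rc$designed_outside_fraction
    truth$recurrence_achieved_outside_fraction <-
      attr(rec, "achieved_outside_fraction")
    truth$recurrence_vs <- rc$vs
  }

  list(suv = suv_vol, dose = dose, masks = masks, truth = truth, spec = spec)
}

#' Construct a recurrence blob with a designed outside fraction
#'
#' Places a spherical blob so that the fraction of its voxels lying
#' outside `reference` matches `designed_outside_fraction` as closely as
#' the voxelization allows (the achieved fraction, recorded in the
#' `"achieved_outside_fraction"` attribute, is within one voxel of the
#' design for feasible geometries).  The center is found by bisection
#' along a ray from the deepest interior point of the reference to a
#' fully-exterior point; the default ray direction is slightly oblique to
#' the grid axes to avoid whole planes of voxels crossing the boundary at
#' once.
#'
#' @param reference non-empty `structure_mask` the fraction is measured
#'   against.
#' @param designed_outside_fraction target fraction in \[0, 1\].
#' @param radius_mm blob radius in mm.
#' @param direction ray direction (need not be normalized).
#' @return a `structure_mask` with role `"RECURRENCE"` and attribute
#'   `achieved_outside_fraction`.
#' @export
make_recurrence <- function(reference, designed_outside_fraction,
                            radius_mm = 8,
                            direction = c(1, 0.137, 0.071)) {
  stopifnot(inherits(reference, "structure_mask"))
  f_target <- designed_outside_fraction
  if (f_target < 0 || f_target > 1)
    stop("designed outside fraction must be in [0, 1]")
  if (!any(reference$data)) stop("reference mask is empty")
  sp <- reference$spacing
  dims <- dim(reference$data)
  ax <- grid_axes_mm(reference)
  u <- direction / sqrt(sum(direction^2))

  # deepest interior point: argmax of distance-to-complement
  comp <- structure_mask(!reference$data, sp, reference$origin)
  depth <- if (any(comp$data))
    .cpp_edt(comp$data, dims, sp) else
    array(Inf, dims)  # reference fills the grid
  i_in <- arrayInd(which.max(depth), dims)
  p_in <- c(ax[[1]][i_in[1]], ax[[2]][i_in[2]], ax[[3]][i_in[3]])
  if (f_target == 0 && max(depth) < radius_mm)
    stop("infeasible: reference too thin to contain the blob")

  # fraction of blob voxels outside the reference for a given center
  frac_at <- function(center) {
    lo <- pmax(1, floor((center - radius_mm - reference$origin) / sp) + 1)
    hi <- pmin(dims, ceiling((center + radius_mm - reference$origin) / sp) + 1)
    if (any(lo > hi)) return(c(frac = NA, total = 0))
    xs <- ax[[1]][lo[1]:hi[1]]; ys <- ax[[2]][lo[2]:hi[2]]
    zs <- ax[[3]][lo[3]:hi[3]]
    d2 <- outer(outer((xs - center[1])^2, (ys - center[2])^2, "+"),
                (zs - center[3])^2, "+")
    inside <- d2 <= radius_mm^2
    total <- sum(inside)
    if (total == 0) return(c(frac = NA, total = 0))
    ref_sub <- reference$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    c(frac = sum(inside & !ref_sub) / total, total = total)
  }

  # march outward to a fully exterior center within the grid
  dist_ref <- .cpp_edt(reference$data, dims, sp)
  grid_lo <- reference$origin
  grid_hi <- reference$origin + (dims - 1) * sp
  step <- min(sp) / 2
  p_out <- NULL
  for (t in seq(0, sum((grid_hi - grid_lo) * abs(u)) + radius_mm, by = step)) {
    p <- p_in + t * u
    if (any(p < grid_lo + radius_mm) || any(p > grid_hi - radius_mm)) break
    vox <- pmin(dims, pmax(1, round((p - reference$origin) / sp) + 1))
    if (dist_ref[vox[1], vox[2], vox[3]] > radius_mm + max(sp) * 2) {
      p_out <- p
      break
    }
  }
  if (is.null(p_out)) {
    if (f_target > 0.5)
      stop("infeasible: no fully exterior blob position inside the grid")
    p_out <- p_in + min((grid_hi - grid_lo)) / 2 * u  # partial exterior is enough
  }

  best <- NULL
  tries <- list(u,
                c(u[1], u[2] + 0.09, u[3] - 0.053),
                c(u[1] - 0.071, u[2], u[3] + 0.113),
                c(u[1] + 0.057, u[2] - 0.111, u[3]))
  for (uu in tries) {
    uu <- uu / sqrt(sum(uu^2))
    ray_out <- p_in + sqrt(sum((p_out - p_in)^2)) * uu
    lo_t <- 0; hi_t <- 1
    f_lo <- frac_at(p_in)["frac"]
    for (iter in 1:60) {
      mid <- (lo_t + hi_t) / 2
      fm <- frac_at(p_in + mid * (ray_out - p_in))["frac"]
      if (is.na(fm)) { hi_t <- mid; next }
      if (fm < f_target) lo_t <- mid else hi_t <- mid
    }
    for (t in c(lo_t, hi_t, (lo_t + hi_t) / 2)) {
      ctr <- p_in + t * (ray_out - p_in)
      fa <- frac_at(ctr)
      if (fa["total"] == 0 || is.na(fa["frac"])) next
      err <- abs(fa["frac"] - f_target)
      if (is.null(best) || err < best$err)
        best <- list(center = ctr, err = err, frac = fa["frac"],
                     total = fa["total"])
    }
    if (!is.null(best) && best$err <= 1 / best$total + 1e-12) break
  }
  if (is.null(best))
    stop("infeasible recurrence geometry")
  rec <- sphere_mask(image_volume(array(0, dims), sp, reference$origin),
                     best$center, radius_mm, role = "RECURRENCE")
  achieved <- sum(rec$data & !reference$data) / sum(rec$data)
  attr(rec, "achieved_outside_fraction") <- achieved
  rec
}
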