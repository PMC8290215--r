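# Per-case pipeline orchestration and cohort aggregation.

#' Run the full per-case analysis
#'
#' Composes the pipeline for one case: BTV segmentation at each T/N
#' threshold, CTV/PTV construction, GTV-BTV concordance (HD95,
#' supplementary-volume distances, within/outside decomposition), dose
#' coverage, and recurrence-overlap fractions.  Deterministic given its
#' inputs.
#'
#' @param case_id case identifier.
#' @param suv `image_volume` tagged `"SUV"`.
#' @param gtv non-empty GTV `structure_mask`.
#' @param brain non-empty brain `structure_mask`.
#' @param normal_reference positive normal-tissue reference SUV (e.g. the
#'   mean of a contralateral white-matter sphere ROI via [roi_stats()]).
#' @param thresholds numeric vector of T/N ratios (default `c(1.7, 2)`).
#' @param exclusions list of masks excluded from segmentation (basal
#'   ganglia correction).
#' @param policy a [margin_policy()]; default 20 mm CTV / 3 mm PTV bounded
#'   by `brain`.
#' @param dose optional `image_volume` tagged `"Gy"`.
#' @param prescription_Gy prescription for coverage assessment.
#' @param iso_fraction isodose level as fraction of prescription.
#' @param recurrence optional recurrence `structure_mask`; outside
#'   fractions are reported against GTV, PTV and each BTV.
#' @return an object of class `case_result`: list with `case_id`,
#'   `gtv_cc`, `thresholds` (data.frame, one row per T/N ratio),
#'   `recurrence` (named vector or `NULL`), and the constructed `ctv` /
#'   `ptv` masks.
#' @export
run_case <- function(case_id, suv, gtv, brain, normal_reference,
                     thresholds = c(1.7, 2.0), exclusions = list(),
                     policy = NULL, dose = NULL, prescription_Gy = 60,
                     iso_fraction = 0.95, recurrence = NULL) {
  if (is.null(policy))
    policy <- margin_policy(bound = brain)
  if (!any(gtv$data)) stop("case ", case_id, ": GTV is empty")
  targets <- build_targets(gtv, policy)

  btvs <- lapply(thresholds, function(ratio)
    segment_btv(suv, tn_threshold(ratio, normal_reference), brain,
                exclusions = exclusions))
  names(btvs) <- sprintf("BTV%.4g", thresholds)

  rows <- lapply(seq_along(thresholds), function(i) {
    ratio <- thresholds[i]
    btv <- btvs[[i]]
    dec <- overlap_decomposition(btv, gtv)
    if (any(btv$data)) {
      hd <- hd95_directed(gtv, btv)
      svc <- svc_distances(gtv, btv)
      cov <- if (!is.null(dose))
        dose_coverage(dose, btv, prescription_Gy, iso_fraction)$covered_fraction
      else NA_real_
    } else {
      hd <- NA_real_
      svc <- c(max_mm = 0, mean_mm = 0)
      cov <- NA_real_
    }
    data.frame(case_id = case_id, threshold = ratio,
               gtv_cc = mask_volume_cc(gtv),
               btv_cc = dec$total_cc, within_cc = dec$within_cc,
               outside_cc = dec$outside_cc,
               outside_fraction = dec$outside_fraction,
               hd95_mm = hd, svc_max_mm = unname(svc["max_mm"]),
               svc_mean_mm = unname(svc["mean_mm"]),
               covered_fraction = cov)
  })
  tab <- do.call(rbind, rows)

  rec <- NULL
  if (!is.null(recurrence)) {
    refs <- c(list(GTV = gtv, PTV = targets$ptv), btvs)
    rec <- recurrence_analysis(recurrence, refs)
  }

  structure(list(case_id = case_id, gtv_cc = mask_volume_cc(gtv),
                 thresholds = tab, recurrence = rec,
                 ctv = targets$ctv, ptv = targets$ptv),
            class = "case_result")
}

#' Run the pipeline on a generated phantom
#'
#' Convenience wrapper: generates the phantom, derives the normal
#' reference from a 1-cm contralateral white-matter sphere ROI (the tumor
#' center mirrored through the mid-sagittal plane), excludes the basal
#' ganglia dilated by the PSF FWHM (so spill-out from smoothing cannot
#' masquerade as tumor), and runs [run_case()] with the phantom's dose and
#' recurrence.
#'
#' @param spec a [phantom_spec()].
#' @param case_id case identifier.
#' @param thresholds T/N ratios.
#' @return a `case_result` with the generated `phantom` attached.
#' @export
run_phantom_case <- function(spec, case_id = "phantom",
                             thresholds = c(1.7, 2.0)) {
  ph <- generate_phantom(spec)
  bc <- ph$truth$brain_center_mm
  tc <- ph$truth$tumor_center_mm
  roi_center <- c(2 * bc[1] - tc[1], tc[2], tc[3])
  roi <- place_sphere_roi(ph$suv, roi_center, diameter_mm = 10)
  normal_ref <- roi_stats(ph$suv, roi)$mean
  excl_margin <- max(spec$psf_fwhm_mm, min(spec$spacing_mm))
  exclusions <- list(expand_margin(ph$masks$basal_ganglia, excl_margin))
  res <- run_case(case_id, ph$suv, ph$masks$gtv, ph$masks$brain, normal_ref,
                  thresholds = thresholds, exclusions = exclusions,
                  policy = margin_policy(spec$ctv_margin_mm,
                                         spec$ptv_margin_mm,
                                         bound = ph$masks$brain),
                  dose = ph$dose, prescription_Gy = spec$prescription_Gy,
                  recurrence = ph$masks$recurrence)
  res$normal_reference <- normal_ref
  res$phantom <- ph
  res
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf("<case_result> %s  GTV %.2f cc\n", x$case_id, x$gtv_cc))
  print(x$thresholds[, setdiff(names(x$thresholds), "case_id")],
        row.names = FALSE)
  if (!is.null(x$recurrence)) {
    cat("recurrence outside fractions:\n")
    print(round(x$recurrence, 4))
  }
  invisible(x)
}

#' Per-case table of a set of case results
#'
#' @param results list of `case_result` objects (or a single one).
#' @return data.frame, one row per case x threshold.
#' @export
case_table <- function(results) {
  if (inherits(results, "case_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) r$thresholds))
}

#' Cohort summary: mean / min / max per metric
#'
#' Arithmetic mean and range of every numeric metric, per T/N threshold,
#' across cases.  `NA` metrics (e.g. HD95 of an empty BTV) are dropped
#' from that metric's summary; `n` records the contributing cases.
#'
#' @param results list of `case_result`s or a data.frame from
#'   [case_table()].
#' @return data.frame with columns `threshold`, `metric`, `mean`, `min`,
#'   `max`, `n`.
#' @export
summarize_cohort <- function(results) {
  tab <- if (is.data.frame(results)) results else case_table(results)
  if (is.null(tab) || nrow(tab) == 0) stop("no cases to summarize")
  metrics <- setdiff(names(tab), c("case_id", "threshold"))
  out <- list()
  for (th in sort(unique(tab$threshold))) {
    sub <- tab[tab$threshold == th, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]
      v <- v[!is.na(v)]
      if (length(v) == 0) next
      out[[length(out) + 1]] <- data.frame(
        threshold = th, metric = m, mean = mean(v), min = min(v),
        max = max(v), n = length(v))
    }
  }
  do.call(rbind, out)
}

#' Write per-case results to CSV
#'
#' @param results list of `case_result`s or a [case_table()] data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_case_csv <- function(results, path) {
  tab <- if (is.data.frame(results)) results else case_table(results)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-case results CSV
#'
#' @param path CSV path written by [write_case_csv()].
#' @return data.frame as produced by [case_table()].
#' @export
read_case_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
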