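#' Thresholds for RT-qPCR sample and assay quality control
#'
#' @param reference_median_cq_max Pass a sample only when the median Cq of
#'   its detected reference miRs is at or below this many cycles (default
#'   20). High reference Cq means too little intact miRNA for reliable
#'   quantification.
#' @param haemolysis_score_max Exclude a sample when its haemolysis score
#'   strictly exceeds this value in log2 (Cq) units (default 6.0).
#' @param haemolysis_marker Assay id of the erythrocyte-enriched marker
#'   (default `"hsa-miR-451"`).
#' @param haemolysis_denominator Either `"panel_median"` (score = per-sample
#'   median Cq of the full quantified panel minus the marker's Cq; robust,
#'   the default) or `"miR-23a"` (the classic marker-pair delta,
#'   `Cq(miR-23a) - Cq(miR-451)`).
#' @param mir23a_id Assay id of the haemolysis-insensitive comparator used
#'   by the marker-pair mode.
#' @param efficiency_min_pct,efficiency_max_pct Acceptable amplification
#'   efficiency window in percent (defaults 90 and 110).
#' @param min_r2 Minimum r-squared of the standard-curve fit for an assay
#'   to count as linearly amplified (default 0.99).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(reference_median_cq_max = 20,
                          haemolysis_score_max = 6.0,
                          haemolysis_marker = "hsa-miR-451",
                          haemolysis_denominator = c("panel_median", "miR-23a"),
                          mir23a_id = "hsa-miR-23a",
                          efficiency_min_pct = 90,
                          efficiency_max_pct = 110,
                          min_r2 = 0.99) {
  haemolysis_denominator <- match.arg(haemolysis_denominator)
  vals <- c(reference_median_cq_max, haemolysis_score_max,
            efficiency_min_pct, efficiency_max_pct, min_r2)
  if (any(!is.finite(vals))) stop("all thresholds must be finite")
  if (efficiency_min_pct >= efficiency_max_pct) {
    stop("efficiency_min_pct must be below efficiency_max_pct")
  }
  structure(list(reference_median_cq_max = reference_median_cq_max,
                 haemolysis_score_max = haemolysis_score_max,
                 haemolysis_marker = haemolysis_marker,
                 haemolysis_denominator = haemolysis_denominator,
                 mir23a_id = mir23a_id,
                 efficiency_min_pct = efficiency_min_pct,
                 efficiency_max_pct = efficiency_max_pct,
                 min_r2 = min_r2),
            class = "qc_thresholds")
}

#' Reference-expression quality control
#'
#' Computes, per sample, the median Cq over the detected reference assays.
#' A sample passes when this median is at or below
#' `reference_median_cq_max` cycles; a sample whose reference assays are
#' all undetected fails. The cutoff direction follows the exclusion
#' rationale "too low expression": low overall miR content shows up as a
#' *high* reference Cq.
#'
#' @param cq A [cq_table()] containing at least one reference assay.
#' @param thresholds A [qc_thresholds()].
#' @return `data.frame(sample_id, reference_median_cq, pass)`.
#' @export
reference_expression_qc <- function(cq, thresholds = qc_thresholds()) {
  stopifnot(inherits(cq, "cq_table"))
  refs <- assays_with_role(cq, "reference")
  if (length(refs) == 0) {
    stop("no reference assays in table; check the assay role map")
  }
  med <- apply(cq$cq[, refs, drop = FALSE], 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else stats::median(v)
  })
  data.frame(sample_id = sample_ids(cq),
             reference_median_cq = unname(med),
             pass = !is.na(med) & med <= thresholds$reference_median_cq_max,
             row.names = NULL)
}

#' Per-sample haemolysis score
#'
#' Red blood cell lysis releases erythrocyte-enriched miR-451 into plasma,
#' lowering its Cq relative to the rest of the panel. In the default
#' `panel_median` mode the score is the per-sample median of all detected
#' panel Cq values minus the marker's Cq (log2 units: one unit = one PCR
#' cycle = roughly a 2-fold excess of miR-451); in `miR-23a` mode it is the
#' classic `Cq(miR-23a) - Cq(miR-451)` delta. Samples scoring strictly
#' above `haemolysis_score_max` are marked for exclusion; samples whose
#' marker is undetected get an undefined score and are flagged for manual
#' review, not auto-excluded.
#'
#' @inheritParams reference_expression_qc
#' @return `data.frame(sample_id, haemolysis_score, exclude, needs_review)`.
#' @export
haemolysis_score <- function(cq, thresholds = qc_thresholds()) {
  stopifnot(inherits(cq, "cq_table"))
  marker <- thresholds$haemolysis_marker
  if (!marker %in% assay_ids(cq)) {
    stop("haemolysis marker '", marker, "' not in table")
  }
  marker_cq <- cq$cq[, marker]
  denom <- if (thresholds$haemolysis_denominator == "panel_median") {
    apply(cq$cq, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else stats::median(v)
    })
  } else {
    if (!thresholds$mir23a_id %in% assay_ids(cq)) {
      stop("comparator '", thresholds$mir23a_id, "' not in table")
    }
    cq$cq[, thresholds$mir23a_id]
  }
  score <- denom - marker_cq
  data.frame(sample_id = sample_ids(cq),
             haemolysis_score = unname(score),
             exclude = !is.na(score) & score > thresholds$haemolysis_score_max,
             needs_review = is.na(score),
             row.names = NULL)
}

#' Amplification efficiency from a dilution series
#'
#' Fits the least-squares line of Cq against log10 relative input and
#' converts the slope to percent efficiency,
#' `E = (10^(-1/slope) - 1) * 100` (a slope of -3.3219 is 100%). An assay
#' passes when the slope is negative, the efficiency falls inside the
#' configured window and the fit's r-squared meets `min_r2`.
#'
#' @param series `data.frame(log10_dilution, cq)` with at least 3 points
#'   spanning at least 2 log10 units (see [generate_dilution_series()]).
#' @param thresholds A [qc_thresholds()].
#' @return A list with `efficiency_pct`, `r2`, `slope`, `pass` and
#'   `reasons` (character vector, empty when passing).
#' @export
assay_efficiency <- function(series, thresholds = qc_thresholds()) {
  series <- as.data.frame(series)
  stopifnot(all(c("log10_dilution", "cq") %in% names(series)))
  series <- series[stats::complete.cases(series), , drop = FALSE]
  if (nrow(series) < 3) {
    stop("insufficient series: need at least 3 dilution points")
  }
  span <- diff(range(series$log10_dilution))
  if (span == 0) stop("insufficient series: dilutions have zero variance")
  if (span < 2) {
    stop("insufficient series: dilutions must span at least 2 log10 units")
  }
  fit <- stats::lm(cq ~ log10_dilution, data = series)
  slope <- unname(stats::coef(fit)[2])
  # noiseless curves fit perfectly; the summary warning is not informative
  r2 <- suppressWarnings(summary(fit)$r.squared)
  reasons <- character()
  if (slope >= 0) {
    reasons <- c(reasons, "non_negative_slope")
    efficiency <- NA_real_
  } else {
    efficiency <- (10^(-1 / slope) - 1) * 100
    if (efficiency < thresholds$efficiency_min_pct ||
        efficiency > thresholds$efficiency_max_pct) {
      reasons <- c(reasons, "efficiency_out_of_range")
    }
  }
  if (is.na(r2) || r2 < thresholds$min_r2) {
    reasons <- c(reasons, "poor_linearity")
  }
  list(efficiency_pct = efficiency, r2 = r2, slope = slope,
       pass = length(reasons) == 0, reasons = reasons)
}

#' Apply per-sample quality control and filter the Cq table
#'
#' Evaluates the reference-expression gate and the haemolysis score
#' independently on every sample (each sample's panel median is computed
#' within that sample, so one sample's verdict never depends on another's),
#' accumulates exclusion reasons, and returns the table restricted to the
#' passing samples in their original order.
#'
#' @inheritParams reference_expression_qc
#' @return A list with `report` (a `qc_report` data frame:
#'   `sample_id, reference_median_cq, haemolysis_score, excluded,
#'   needs_review, reasons`) and `filtered` (the passing-sample
#'   [cq_table()]).
#' @export
apply_sample_qc <- function(cq, thresholds = qc_thresholds()) {
  ref <- reference_expression_qc(cq, thresholds)
  haem <- haemolysis_score(cq, thresholds)
  reasons <- Map(function(ref_ok, haem_bad) {
    c(if (!ref_ok) "low_reference_expression",
      if (haem_bad) "haemolysis")
  }, ref$pass, haem$exclude)
  excluded <- lengths(reasons) > 0
  report <- data.frame(sample_id = ref$sample_id,
                       reference_median_cq = ref$reference_median_cq,
                       haemolysis_score = haem$haemolysis_score,
                       excluded = excluded,
                       needs_review = haem$needs_review,
                       row.names = NULL)
  report$reasons <- unname(reasons)
  class(report) <- c("qc_report", "data.frame")
  keep <- report$sample_id[!report$excluded]
  filtered <- cq_table(cq$cq[keep, , drop = FALSE], cq$roles)
  list(report = report, filtered = filtered)
}
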