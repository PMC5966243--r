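#' Parameters for discovery-phase microarray processing
#'
#' @param present_sd_multiplier A spot is "present" when its intensity
#'   strictly exceeds `background_mean + multiplier * background_sd`
#'   (default 2).
#' @param normalization_target Global normalization target: the median of
#'   all background-subtracted signal is scaled to this value (default 25).
#' @param detection_group_fraction Minimum fraction of pooled groups in
#'   which a miR must be present to be retained (default 0.20; compared
#'   exactly, `>=`, no pre-rounding).
#' @param assay_number_range Inclusive miR-number range for which validated
#'   single-assay chemistry is expected (default `c(1, 700)`).
#' @param floor_negative_to_zero Floor background-subtracted values at zero
#'   (default `TRUE`).
#' @param median_over_present_only Compute the normalization median over
#'   present spots only instead of all spots (default `FALSE`: the global
#'   median is taken over every background-subtracted value).
#' @return A list of class `microarray_params`.
#' @export
microarray_params <- function(present_sd_multiplier = 2,
                              normalization_target = 25,
                              detection_group_fraction = 0.20,
                              assay_number_range = c(1, 700),
                              floor_negative_to_zero = TRUE,
                              median_over_present_only = FALSE) {
  if (present_sd_multiplier < 0) stop("present_sd_multiplier must be >= 0")
  if (detection_group_fraction <= 0 || detection_group_fraction > 1) {
    stop("detection_group_fraction must lie in (0, 1]")
  }
  if (normalization_target <= 0) stop("normalization_target must be positive")
  structure(list(present_sd_multiplier = present_sd_multiplier,
                 normalization_target = normalization_target,
                 detection_group_fraction = detection_group_fraction,
                 assay_number_range = assay_number_range,
                 floor_negative_to_zero = floor_negative_to_zero,
                 median_over_present_only = median_over_present_only),
            class = "microarray_params")
}

#' Present/absent calls against the chip background
#'
#' A spot is called present when its raw intensity strictly exceeds the
#' chip's background mean plus `present_sd_multiplier` background standard
#' deviations; boundary spots are absent (conservative).
#'
#' @param panel An [intensity_panel()].
#' @param params A [microarray_params()].
#' @return Logical matrix (miRs x groups).
#' @export
present_call <- function(panel, params = microarray_params()) {
  stopifnot(inherits(panel, "intensity_panel"))
  threshold <- panel$background_mean +
    params$present_sd_multiplier * panel$background_sd
  sweep(panel$intensity, 2, threshold, FUN = ">")
}

#' Background subtraction and global median normalization
#'
#' Subtracts each chip's background mean from its intensities (flooring
#' negative values at zero by default), then rescales all values by
#' `normalization_target / median(subtracted values)` so that the global
#' median of the output equals the target (25 by default).
#'
#' @inheritParams present_call
#' @return Normalized intensity matrix (miRs x groups) with attribute
#'   `normalization_factor`.
#' @export
background_subtract_normalize <- function(panel, params = microarray_params()) {
  stopifnot(inherits(panel, "intensity_panel"))
  sub <- sweep(panel$intensity, 2, panel$background_mean)
  if (params$floor_negative_to_zero) sub <- pmax(sub, 0)
  med_values <- if (params$median_over_present_only) {
    sub[present_call(panel, params)]
  } else {
    sub
  }
  med <- stats::median(med_values)
  if (!is.finite(med) || med <= 0) {
    stop("degenerate panel: median of background-subtracted data is not positive")
  }
  factor <- params$normalization_target / med
  out <- sub * factor
  attr(out, "normalization_factor") <- factor
  out
}

#' Filter miRs by detection across pooled groups
#'
#' Retains a miR when it is present in at least
#' `detection_group_fraction` of the groups (exact fraction comparison).
#'
#' @param present Logical matrix from [present_call()].
#' @param params A [microarray_params()].
#' @return Character vector of retained miR ids.
#' @export
filter_by_detection <- function(present, params = microarray_params()) {
  frac <- rowSums(present) / ncol(present)
  rownames(present)[frac >= params$detection_group_fraction]
}

#' Filter miRs by assay-number range
#'
#' Keeps miRs whose numeric miR designation (parsed from names like
#' `hsa-miR-652-5p`) falls within the configured inclusive range, for which
#' validated single-assay RT-qPCR chemistry is expected to exist. Ids
#' without a parseable miR number (e.g. the let-7 family) are retained and
#' flagged in the `unparsed` attribute.
#'
#' @param mir_ids Character vector of miR ids.
#' @param params A [microarray_params()].
#' @return Retained ids, with attribute `unparsed` listing the flagged ones.
#' @export
filter_by_assay_range <- function(mir_ids, params = microarray_params()) {
  num <- parse_mir_number(mir_ids)
  lo <- params$assay_number_range[1]; hi <- params$assay_number_range[2]
  keep <- is.na(num) | (num >= lo & num <= hi)
  out <- mir_ids[keep]
  attr(out, "unparsed") <- mir_ids[is.na(num)]
  out
}

parse_mir_number <- function(ids) {
  m <- regmatches(ids, regexpr("mir-?[0-9]+", ids, ignore.case = TRUE))
  num <- rep(NA_integer_, length(ids))
  has <- grepl("mir-?[0-9]+", ids, ignore.case = TRUE)
  num[has] <- as.integer(gsub("[^0-9]", "", m))
  num
}

#' Select candidate miRs from the discovery panel
#'
#' Two selection arms plus a literature list, de-duplicated:
#' \describe{
#'   \item{benign vs malignant}{per-miR two-sided Mann-Whitney test on the
#'     normalized pooled-group signal; selected when `p < p_threshold`.
#'     Disabled with a warning when either side has fewer than 2 pools.}
#'   \item{BRCA1-benign vs wildtype-benign}{mean-signal ratio
#'     (BRCA1-benign / wildtype-benign) at least `brca1_fold_threshold`;
#'     the top `n_brca1` by ratio are selected.}
#' }
#'
#' @param norm Normalized intensity matrix (miRs x groups), e.g. from
#'   [background_subtract_normalize()].
#' @param groups `data.frame(group_id, class, brca1)` with `class` in
#'   benign/malignant and `brca1` logical, one row per pooled group.
#' @param p_threshold Mann-Whitney selection threshold (default 0.05).
#' @param brca1_fold_threshold Minimum mean-signal ratio (default 2).
#' @param n_brca1 Number of fold-rule candidates to keep (default 4).
#' @param literature Character vector of literature-based miR ids to add.
#' @param params A [stats_params()] (controls the exact-test cutoff).
#' @return `data.frame(mir_id, source, statistic, p_raw)`; `statistic` is
#'   the U value (test arm) or the mean ratio (fold arm), `p_raw` is `NA`
#'   for non-test sources.
#' @export
select_candidates <- function(norm, groups, p_threshold = 0.05,
                              brca1_fold_threshold = 2, n_brca1 = 4,
                              literature = character(),
                              params = stats_params()) {
  groups <- as.data.frame(groups)
  stopifnot(all(c("group_id", "class", "brca1") %in% names(groups)))
  missing_groups <- setdiff(groups$group_id, colnames(norm))
  if (length(missing_groups) > 0) {
    stop("groups not in matrix: ", paste(missing_groups, collapse = ", "))
  }
  benign <- groups$group_id[groups$class == "benign"]
  malignant <- groups$group_id[groups$class == "malignant"]
  out <- list()

  if (length(benign) < 2 || length(malignant) < 2) {
    warning("fewer than 2 pools per arm; Mann-Whitney selection arm disabled")
  } else {
    res <- apply(norm, 1, function(v) {
      mw <- mann_whitney(v[benign], v[malignant], params = params)
      c(u = mw$u, p = mw$p)
    })
    sel <- which(res["p", ] < p_threshold)
    if (length(sel) > 0) {
      out$test <- data.frame(mir_id = rownames(norm)[sel],
                             source = "benign_vs_malignant",
                             statistic = res["u", sel],
                             p_raw = res["p", sel],
                             row.names = NULL)
    }
  }

  brca1_benign <- groups$group_id[groups$class == "benign" & groups$brca1]
  wt_benign <- groups$group_id[groups$class == "benign" & !groups$brca1]
  if (length(brca1_benign) >= 1 && length(wt_benign) >= 1) {
    num <- rowMeans(norm[, brca1_benign, drop = FALSE])
    den <- rowMeans(norm[, wt_benign, drop = FALSE])
    ratio <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, NA_real_))
    hit <- which(!is.na(ratio) & ratio >= brca1_fold_threshold)
    if (length(hit) > 0) {
      hit <- hit[order(-ratio[hit])][seq_len(min(n_brca1, length(hit)))]
      out$brca1 <- data.frame(mir_id = rownames(norm)[hit],
                              source = "brca1_benign_vs_wildtype",
                              statistic = ratio[hit],
                              p_raw = NA_real_, row.names = NULL)
    }
  }

  if (length(literature) > 0) {
    out$literature <- data.frame(mir_id = literature, source = "literature",
                                 statistic = NA_real_, p_raw = NA_real_)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(mir_id = character(), source = character(),
                      statistic = numeric(), p_raw = numeric())
  }
  res[!duplicated(res$mir_id), , drop = FALSE]
}
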