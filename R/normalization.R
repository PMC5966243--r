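#' geNorm reference-stability M-values
#'
#' For every pair of assays `(j, k)` the pairwise variation
#' `V_jk = sd_samples(expr_j - expr_k)` is computed on the log2 scale (for
#' RT-qPCR data, raw Cq values are already log2-abundance up to sign, so
#' they can be passed directly); an assay's M-value is the mean of its
#' pairwise variations. The iterative variant then repeatedly eliminates
#' the currently least stable (highest-M) assay and re-computes until two
#' remain; the stability ranking is the reverse elimination order. Because
#' the statistic only ever sees differences between assay columns, it is
#' invariant to per-sample global shifts (e.g. input amount) and to
#' per-assay constant offsets.
#'
#' @param expr Complete numeric matrix, samples in rows, assays in columns
#'   (log2 scale). At least 3 assays and 2 samples; missing values are an
#'   error (drop or impute incomplete assays first).
#' @return A `stability_result` data frame with one row per assay:
#'   `assay_id`, `m_value` (full-panel M), `ranking` (1 = most stable).
#'   The elimination order is attached as attribute `elimination_order`.
#' @export
genorm_m_values <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) stop("'expr' must be a numeric matrix")
  if (ncol(expr) < 3) stop("geNorm needs at least 3 assays")
  if (nrow(expr) < 2) stop("geNorm needs at least 2 samples")
  if (anyNA(expr)) {
    stop("matrix contains missing values; drop or impute incomplete assays first")
  }
  if (is.null(colnames(expr))) colnames(expr) <- paste0("assay", seq_len(ncol(expr)))

  m_full <- pairwise_m(expr)

  remaining <- seq_len(ncol(expr))
  eliminated <- integer()
  while (length(remaining) > 2) {
    m <- pairwise_m(expr[, remaining, drop = FALSE])
    # ties: drop the later column, keeping input order stable
    worst <- max(which(m == max(m)))
    eliminated <- c(eliminated, remaining[worst])
    remaining <- remaining[-worst]
  }
  order_idx <- c(remaining, rev(eliminated))  # most stable first
  ranking <- integer(ncol(expr))
  ranking[order_idx] <- seq_along(order_idx)

  out <- data.frame(assay_id = colnames(expr), m_value = unname(m_full),
                    ranking = ranking, row.names = NULL)
  class(out) <- c("stability_result", "data.frame")
  attr(out, "elimination_order") <- colnames(expr)[eliminated]
  out
}

pairwise_m <- function(expr) {
  k <- ncol(expr)
  v <- matrix(0, k, k)
  for (j in seq_len(k - 1)) {
    for (l in seq(j + 1, k)) {
      v[j, l] <- v[l, j] <- stats::sd(expr[, j] - expr[, l])
    }
  }
  rowSums(v) / (k - 1)
}

#' Group-aware stability score (variance share)
#'
#' A model-light analogue of NormFinder's inter/intra-group decomposition:
#' per assay, the one-way between-group sum of squares divided by the total
#' sum of squares. Values near 0 mean the assay's level is unrelated to the
#' grouping (stable across groups); values near 1 mean almost all of its
#' variance is between groups. Constant assays score 0.
#'
#' @param expr Numeric matrix, samples x assays.
#' @param groups Group labels, one per sample. Groups with fewer than 2
#'   samples are excluded with a warning.
#' @return Named numeric vector of per-assay scores in `[0, 1]`.
#' @export
intergroup_variance_share <- function(expr, groups) {
  groups <- as.factor(groups)
  if (length(groups) != nrow(expr)) stop("one group label per sample required")
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("excluding group(s) with < 2 samples: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    expr <- expr[keep, , drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups with >= 2 samples")
  apply(expr, 2, function(v) {
    grand <- mean(v)
    total <- sum((v - grand)^2)
    if (total == 0) return(0)
    means <- tapply(v, groups, mean)
    n_g <- tabulate(groups)
    sum(n_g * (means[levels(groups)] - grand)^2) / total
  })
}

#' Normalizer specification for median delta-Cq normalization
#'
#' @param normalizer_set Assay ids whose per-sample median Cq serves as the
#'   reference value; `NULL` (default) uses every assay in the table, i.e.
#'   the full quantified panel.
#' @param min_detected_fraction Minimum fraction of the normalizer set that
#'   must be detected in a sample for it to be normalized (default 0.5;
#'   samples below are flagged and dropped).
#' @return A list of class `normalization_spec`.
#' @export
normalization_spec <- function(normalizer_set = NULL,
                               min_detected_fraction = 0.5) {
  if (!is.null(normalizer_set) && length(normalizer_set) == 0) {
    stop("normalizer_set must be non-empty (or NULL for the full panel)")
  }
  structure(list(normalizer_set = normalizer_set,
                 min_detected_fraction = min_detected_fraction),
            class = "normalization_spec")
}

#' Median-of-panel delta-Cq normalization
#'
#' Converts Cq values to log2-scale relative expression against the
#' sample's own panel: `value[s, m] = median(detected Cq[s, normalizer
#' set]) - Cq[s, m]`. Positive values mean the miR is more abundant than
#' the panel midpoint (one unit = one PCR cycle = 2-fold); an undetected
#' target stays missing. Samples with fewer than half of the normalizer
#' set detected are flagged and dropped from the output. For a sample with
#' the full normalizer set detected, the median of its output values over
#' that set is 0 by construction.
#'
#' @param cq A [cq_table()].
#' @param spec A [normalization_spec()].
#' @return An object of class `rel_expr`: list with `value` (samples x
#'   miRs matrix), `normalizer` (description string), `roles` (assay
#'   roles) and `dropped_samples`.
#' @export
median_normalize <- function(cq, spec = normalization_spec()) {
  stopifnot(inherits(cq, "cq_table"))
  set <- spec$normalizer_set
  if (is.null(set)) set <- assay_ids(cq)
  missing_assays <- setdiff(set, assay_ids(cq))
  if (length(missing_assays) > 0) {
    stop("normalizer assays not in table: ",
         paste(missing_assays, collapse = ", "))
  }
  sub <- cq$cq[, set, drop = FALSE]
  n_det <- rowSums(!is.na(sub))
  ok <- n_det >= spec$min_detected_fraction * length(set)
  dropped <- sample_ids(cq)[!ok]
  if (length(dropped) > 0) {
    warning("dropping sample(s) with under-detected normalizer panel: ",
            paste(dropped, collapse = ", "))
  }
  med <- apply(sub[ok, , drop = FALSE], 1, stats::median, na.rm = TRUE)
  value <- med - cq$cq[ok, , drop = FALSE]
  structure(list(value = value,
                 normalizer = sprintf("median of %d-assay panel", length(set)),
                 normalizer_set = set,
                 roles = cq$roles,
                 dropped_samples = dropped),
            class = "rel_expr")
}

#' @export
print.rel_expr <- function(x, ...) {
  cat(sprintf("rel_expr: %d samples x %d miRs, normalizer: %s\n",
              nrow(x$value), ncol(x$value), x$normalizer))
  invisible(x)
}

#' Linear fold change between two sample groups
#'
#' `FC = 2^(center_A(value) - center_B(value))` per miR on the log2
#' relative-expression scale; `FC > 1` means higher in group A. The mean
#' center corresponds to a ratio of geometric means on the linear scale;
#' a median option is provided. Requires at least one detected value per
#' arm per miR (otherwise that miR's FC is `NA`).
#'
#' @param rel A `rel_expr` object from [median_normalize()].
#' @param group_a,group_b Non-overlapping character vectors of sample ids.
#' @param center `"mean"` (default) or `"median"`.
#' @return Named numeric vector of per-miR linear fold changes (A vs B).
#' @export
fold_change <- function(rel, group_a, group_b, center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(inherits(rel, "rel_expr"))
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both contrast arms must be non-empty")
  }
  missing_s <- setdiff(c(group_a, group_b), rownames(rel$value))
  if (length(missing_s) > 0) {
    stop("samples not in matrix: ", paste(missing_s, collapse = ", "))
  }
  cfun <- if (center == "mean") mean else stats::median
  a <- rel$value[group_a, , drop = FALSE]
  b <- rel$value[group_b, , drop = FALSE]
  ca <- apply(a, 2, function(v) if (all(is.na(v))) NA_real_ else cfun(v, na.rm = TRUE))
  cb <- apply(b, 2, function(v) if (all(is.na(v))) NA_real_ else cfun(v, na.rm = TRUE))
  2^(ca - cb)
}
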