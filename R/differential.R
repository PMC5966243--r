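#' Parameters for differential testing
#'
#' @param fdr_q Benjamini-Hochberg false-discovery-rate level (default
#'   0.10, i.e. a 10% FDR cutoff).
#' @param alpha Two-sided raw significance level (default 0.05).
#' @param two_sided Use two-sided p-values (default `TRUE`).
#' @param exact_max_n Largest per-arm size for which the exact Mann-Whitney
#'   null distribution is used (default 10); larger arms, or any ties, use
#'   the tie-corrected normal approximation with continuity correction.
#' @return A list of class `stats_params`.
#' @export
stats_params <- function(fdr_q = 0.10, alpha = 0.05, two_sided = TRUE,
                         exact_max_n = 10) {
  if (fdr_q <= 0 || fdr_q >= 1) stop("fdr_q must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(fdr_q = fdr_q, alpha = alpha, two_sided = two_sided,
                 exact_max_n = exact_max_n),
            class = "stats_params")
}

#' Mann-Whitney U test
#'
#' Rank-based two-group test. The U statistic counts pairs with
#' `a_i > b_j`, ties counting one half. P-values are exact (permutation
#' null) when both arms are at most `exact_max_n` and tie-free, and
#' otherwise use the normal approximation with tie-corrected variance and
#' continuity correction.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param params A [stats_params()].
#' @return List with `u` and `p`.
#' @export
mann_whitney <- function(a, b, params = stats_params()) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) {
    stop("both arms must be non-empty")
  }
  r <- rank(c(a, b))
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) <= params$exact_max_n &&
    length(b) <= params$exact_max_n
  alt <- if (params$two_sided) "two.sided" else "greater"
  p <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alt, exact = exact,
                       correct = TRUE)$p.value)
  list(u = unname(u), p = min(p, 1))
}

#' Benjamini-Hochberg FDR step-up procedure
#'
#' Sorts the p-values ascending, forms rank critical values
#' `i * q / m`, finds the largest rank `k` whose p-value is at or below
#' its critical value, and rejects ranks `1..k`. Adjusted p-values are
#' the usual step-up-monotone `min(1, min_{j >= i} p_(j) * m / j)`.
#' All outputs are returned in input order.
#'
#' @param p_values Numeric vector of raw p-values in `(0, 1]`.
#' @param params A [stats_params()] (supplies `fdr_q`).
#' @return List with `adjusted`, `critical` and `reject`, each aligned to
#'   the input.
#' @export
bh_fdr <- function(p_values, params = stats_params()) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(p_values)
  q <- params$fdr_q
  o <- order(p_values)
  crit_sorted <- seq_len(m) * q / m
  below <- which(p_values[o] <= crit_sorted)
  k <- if (length(below) == 0) 0 else max(below)
  reject_sorted <- seq_len(m) <= k
  adjusted <- stats::p.adjust(p_values, method = "BH")
  critical <- reject <- numeric(m)
  critical[o] <- crit_sorted
  reject <- logical(m)
  reject[o] <- reject_sorted
  list(adjusted = adjusted, critical = critical, reject = reject)
}

#' Run a differential-expression contrast
#'
#' For each candidate miR: linear fold change (arm A vs arm B), Mann-
#' Whitney U and raw p-value, then Benjamini-Hochberg adjustment across
#' the family of miRs tested in this contrast. Named contrasts resolve
#' their arms from the sample metadata:
#' \describe{
#'   \item{`malignant_vs_benign`}{malignant vs benign samples}
#'   \item{`metastatic_vs_nonmetastatic`}{within malignant samples}
#'   \item{`brca1_benign_vs_wildtype`}{benign BRCA1 carriers vs benign
#'     wildtype}
#' }
#' A list `list(a = ids, b = ids)` gives a custom contrast. Both arms must
#' contain at least 2 samples present in the expression matrix.
#'
#' @param rel A `rel_expr` from [median_normalize()].
#' @param meta A `sample_metadata` data frame.
#' @param contrast Contrast name (above) or a two-element list of sample
#'   ids.
#' @param params A [stats_params()].
#' @param mirs miR ids to test; default: the candidate-role assays of the
#'   panel (falling back to all columns when roles are absent).
#' @return A `differential_result` data frame: `mir_id, fold_change,
#'   u_statistic, p_raw, p_bh_adjusted, bh_critical, significant_raw,
#'   significant_fdr`.
#' @export
run_contrast <- function(rel, meta, contrast, params = stats_params(),
                         mirs = NULL) {
  stopifnot(inherits(rel, "rel_expr"))
  present <- rownames(rel$value)
  arms <- resolve_contrast(contrast, meta, present)
  if (length(arms$a) < 2 || length(arms$b) < 2) {
    stop("contrast arms must each contain at least 2 samples (got ",
         length(arms$a), " and ", length(arms$b), ")")
  }
  if (is.null(mirs)) {
    mirs <- if (!is.null(rel$roles)) {
      names(rel$roles)[rel$roles == "candidate"]
    } else {
      colnames(rel$value)
    }
  }
  mirs <- intersect(mirs, colnames(rel$value))
  usable <- vapply(mirs, function(m) {
    any(!is.na(rel$value[arms$a, m])) && any(!is.na(rel$value[arms$b, m]))
  }, logical(1))
  if (any(!usable)) {
    warning("skipping miR(s) with an all-missing arm: ",
            paste(mirs[!usable], collapse = ", "))
    mirs <- mirs[usable]
  }
  if (length(mirs) == 0) stop("no testable miRs in contrast")

  fc <- fold_change(rel, arms$a, arms$b)[mirs]
  tests <- lapply(mirs, function(m) {
    mann_whitney(rel$value[arms$a, m], rel$value[arms$b, m], params = params)
  })
  p_raw <- vapply(tests, `[[`, numeric(1), "p")
  u <- vapply(tests, `[[`, numeric(1), "u")
  bh <- bh_fdr(p_raw, params = params)
  out <- data.frame(mir_id = mirs,
                    fold_change = unname(fc),
                    u_statistic = u,
                    p_raw = p_raw,
                    p_bh_adjusted = bh$adjusted,
                    bh_critical = bh$critical,
                    significant_raw = p_raw < params$alpha,
                    significant_fdr = bh$reject,
                    row.names = NULL)
  class(out) <- c("differential_result", "data.frame")
  attr(out, "contrast") <- if (is.character(contrast)) contrast else "custom"
  attr(out, "n_a") <- length(arms$a)
  attr(out, "n_b") <- length(arms$b)
  out
}

resolve_contrast <- function(contrast, meta, present) {
  if (is.list(contrast)) {
    stopifnot(length(contrast) == 2)
    return(list(a = intersect(contrast[[1]], present),
                b = intersect(contrast[[2]], present)))
  }
  meta <- meta[meta$sample_id %in% present, , drop = FALSE]
  switch(contrast,
    malignant_vs_benign = list(
      a = meta$sample_id[meta$group == "malignant"],
      b = meta$sample_id[meta$group == "benign"]),
    metastatic_vs_nonmetastatic = list(
      a = meta$sample_id[meta$group == "malignant" & meta$metastatic],
      b = meta$sample_id[meta$group == "malignant" & !meta$metastatic]),
    brca1_benign_vs_wildtype = list(
      a = meta$sample_id[meta$group == "benign" & meta$brca1_carrier],
      b = meta$sample_id[meta$group == "benign" & !meta$brca1_carrier]),
    stop("unknown contrast '", contrast, "'")
  )
}

#' Spearman rank correlation
#'
#' Rank-based correlation with average ranks for ties; two-sided p-value,
#' exact for n at most 8 without ties, approximate otherwise. Constant
#' input leaves rho undefined (`NA`, with a warning).
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return List with `rho` and `p`.
#' @export
spearman_correlation <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors with at least 3 complete pairs")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = !ties && length(x) <= 8))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Exact tests for 2 x c contingency tables
#'
#' Fisher's exact test for 2x2 tables and the Freeman-Halton extension for
#' 2x3 and 2x4 tables: the exact conditional p-value obtained by
#' enumerating all tables with the observed margins and summing the
#' probabilities of those no more probable than the observed table.
#'
#' @param table Matrix of non-negative integer counts with 2 rows and 2-4
#'   columns.
#' @return The exact two-sided p-value.
#' @export
categorical_tests <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2 || !ncol(table) %in% 2:4) {
    stop("unsupported shape: need a 2x2, 2x3 or 2x4 table")
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  stats::fisher.test(table)$p.value
}
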