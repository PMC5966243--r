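#' Pipeline configuration
#'
#' Bundles the per-stage parameter objects and the global seed that drives
#' every stochastic stage (each stage derives its own substream from it,
#' so changing one stage's settings does not perturb another's draws).
#'
#' @param seed Global integer seed.
#' @param validation A [synthetic_config()] for the validation cohort
#'   (individual RT-qPCR samples).
#' @param discovery Optional [synthetic_config()] for the discovery cohort
#'   (pooled microarray samples); `NULL` skips the discovery stage.
#' @param qc A [qc_thresholds()].
#' @param microarray A [microarray_params()].
#' @param normalization A [normalization_spec()].
#' @param stats A [stats_params()].
#' @param clustering A [clustering_params()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            validation = NULL,
                            discovery = NULL,
                            qc = qc_thresholds(),
                            microarray = microarray_params(),
                            normalization = normalization_spec(),
                            stats = stats_params(),
                            clustering = clustering_params()) {
  if (is.null(validation)) {
    validation <- synthetic_config(seed = derive_seed(seed, 1),
                                   cohort = "validation",
                                   fold_changes = default_fold_changes())
  }
  structure(list(seed = seed, validation = validation, discovery = discovery,
                 qc = qc, microarray = microarray,
                 normalization = normalization, stats = stats,
                 clustering = clustering),
            class = "pipeline_config")
}

# derived per-stage substream seeds, kept below 2^31
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% 2147483647)
}

#' Default discovery-cohort configuration
#'
#' Mirrors the smaller pooled discovery design: 10 benign (3 BRCA1
#' carriers) and 19 malignant samples (6 metastatic, 2 BRCA1 carriers).
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [synthetic_config()].
#' @return A [synthetic_config()].
#' @export
discovery_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, cohort = "discovery",
                   n_benign = 10, n_malignant = 19, n_metastatic = 6,
                   n_brca1_benign = 3, n_brca1_malignant = 2,
                   fold_changes = default_fold_changes())
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}

#' Run the full analysis pipeline on synthetic cohorts
#'
#' Stage order: simulate cohorts, discovery-phase microarray processing
#' (pooling, present-calls, background subtraction and normalization,
#' detection and assay-range filters, candidate selection, Ward
#' clustering of the pooled groups), validation-phase sample QC,
#' median delta-Cq normalization, differential contrasts (malignant vs
#' benign, metastatic vs non-metastatic, BRCA1-benign vs wildtype when
#' arm sizes allow, Spearman age correlations), and a reproducibility
#' manifest with conserved sample accounting at every stage. Identical
#' config (including seed) reproduces every output byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all stage outputs are
#'   written there (TSV/JSON/Newick).
#' @return A list with `manifest`, `metadata`, `qc`, `rel`, `contrasts`,
#'   `age_correlation`, and (when a discovery config is present)
#'   `discovery` (pooled table, panel, normalized matrix, candidates,
#'   dendrogram).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("plasmamir")),
                   stages = list())

  # --- validation cohort simulation ------------------------------------
  sim <- generate_cohort(config$validation)
  meta <- sim$metadata
  manifest$stages$simulate <- list(
    samples_in = 0L, samples_out = nrow(meta), excluded = 0L)

  # --- discovery phase -------------------------------------------------
  discovery <- NULL
  if (!is.null(config$discovery)) {
    dsim <- generate_cohort(config$discovery)
    dqc <- apply_sample_qc(dsim$cq, config$qc)
    dmeta <- dsim$metadata[dsim$metadata$sample_id %in%
                             sample_ids(dqc$filtered), , drop = FALSE]
    pools <- assign_pools(dmeta, pool_size = config$discovery$pool_size)
    pooled <- pool_samples(dqc$filtered, pools)
    panel <- generate_microarray_panel(config$discovery, pooled)
    present <- present_call(panel, config$microarray)
    norm <- background_subtract_normalize(panel, config$microarray)
    detected <- filter_by_detection(present, config$microarray)
    retained <- filter_by_assay_range(detected, config$microarray)
    norm_kept <- norm[retained, , drop = FALSE]

    pool_class <- data.frame(
      group_id = names(pools),
      class = ifelse(grepl("benign", names(pools)), "benign", "malignant"),
      brca1 = grepl("brca1", names(pools)))
    candidates <- select_candidates(norm_kept, pool_class,
                                    params = config$stats)

    drel <- median_normalize(pooled, config$normalization)
    cand_cols <- intersect(names(drel$roles)[drel$roles == "candidate"],
                           colnames(drel$value))
    prof <- drel$value[, cand_cols, drop = FALSE]
    prof <- prof[, colSums(is.na(prof)) == 0, drop = FALSE]
    dend <- ward_cluster(distance_matrix(prof), config$clustering)

    discovery <- list(metadata = dsim$metadata, qc = dqc, pools = pools,
                      pooled = pooled, panel = panel, present = present,
                      normalized = norm, retained_mirs = retained,
                      candidates = candidates, rel = drel, dendrogram = dend)
    manifest$stages$discovery_qc <- stage_counts(nrow(dsim$metadata),
                                                 nrow(dmeta), dqc$report)
    manifest$stages$microarray_filter <- list(
      mirs_in = nrow(panel$intensity),
      mirs_out = length(retained),
      excluded = nrow(panel$intensity) - length(retained))
  }

  # --- validation sample QC -------------------------------------------
  qc <- apply_sample_qc(sim$cq, config$qc)
  meta_kept <- meta[meta$sample_id %in% sample_ids(qc$filtered), , drop = FALSE]
  manifest$stages$sample_qc <- stage_counts(nrow(meta),
                                            nrow(meta_kept), qc$report)

  # --- normalization ---------------------------------------------------
  rel <- median_normalize(qc$filtered, config$normalization)
  manifest$stages$normalization <- list(
    samples_in = nrow(qc$filtered$cq),
    samples_out = nrow(rel$value),
    excluded = length(rel$dropped_samples))

  # --- contrasts -------------------------------------------------------
  contrasts <- list()
  for (name in c("malignant_vs_benign", "metastatic_vs_nonmetastatic",
                 "brca1_benign_vs_wildtype")) {
    contrasts[[name]] <- tryCatch(
      run_contrast(rel, meta_kept, name, params = config$stats),
      error = function(e) {
        warning("contrast '", name, "' skipped: ", conditionMessage(e))
        NULL
      })
  }

  cand_cols <- intersect(names(rel$roles)[rel$roles == "candidate"],
                         colnames(rel$value))
  ages <- meta_kept$age[match(rownames(rel$value), meta_kept$sample_id)]
  age_correlation <- do.call(rbind, lapply(cand_cols, function(m) {
    sc <- spearman_correlation(ages, rel$value[, m])
    data.frame(mir_id = m, rho = sc$rho, p = sc$p)
  }))

  manifest$stages$differential <- list(
    contrasts_run = names(Filter(Negate(is.null), contrasts)),
    n_candidate_mirs = length(cand_cols))

  result <- list(manifest = manifest, metadata = meta, qc = qc, rel = rel,
                 contrasts = contrasts, age_correlation = age_correlation,
                 discovery = discovery)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

stage_counts <- function(n_in, n_out, report) {
  tally <- table(unlist(report$reasons))
  list(samples_in = n_in, samples_out = n_out, excluded = n_in - n_out,
       exclusion_reasons = as.list(tally))
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_sample_metadata(result$metadata, p("metadata.tsv"))
  write_report(qc_report_serializable(result$qc$report), p("qc_report.json"))
  write_cq_table(result$qc$filtered, p("cq_filtered.tsv"))
  rel_df <- cbind(sample_id = rownames(result$rel$value),
                  as.data.frame(result$rel$value, check.names = FALSE))
  utils::write.table(rel_df, p("relative_expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (name in names(result$contrasts)) {
    if (!is.null(result$contrasts[[name]])) {
      write_report(as.data.frame(result$contrasts[[name]]),
                   p(paste0("contrast_", name, ".json")))
    }
  }
  write_report(result$age_correlation, p("age_correlation.json"))
  if (!is.null(result$discovery)) {
    write_report(result$discovery$candidates, p("discovery_candidates.json"))
    writeLines(to_newick(result$discovery$dendrogram),
               p("discovery_dendrogram.nwk"))
  }
  write_report(result$manifest, p("manifest.json"))
  invisible(out_dir)
}

qc_report_serializable <- function(report) {
  df <- as.data.frame(report)
  df$reasons <- vapply(df$reasons, paste, character(1), collapse = ";")
  df
}

#' Baseline characteristics of a cohort
#'
#' Counts and percentages per clinical stratum (diagnosis group with
#' metastasis split, BRCA1 carriership, familial risk, T and N stage,
#' receptor and TNBC status among the breast-cancer cases) plus the age
#' median and interquartile range. Percentages are exact in the `pct`
#' column; the `label` column renders them rounded to the nearest integer
#' (the style used for baseline tables), with the metastatic share of the
#' breast-cancer cases also available at one decimal via `pct`. Empty
#' strata render as `0 (0%)` without division errors.
#'
#' @param meta A `sample_metadata` data frame.
#' @return A list with `strata` (data frame: `section, level, n,
#'   denominator, pct, label`) and `age` (median and IQR).
#' @export
summarize_cohort <- function(meta) {
  n <- nrow(meta)
  rows <- list()
  add <- function(section, level, count, denom) {
    pct <- if (denom > 0) 100 * count / denom else 0
    rows[[length(rows) + 1]] <<- data.frame(
      section = section, level = level, n = count, denominator = denom,
      pct = pct, label = sprintf("%d (%.0f%%)", count, pct))
  }
  mal <- meta$group == "malignant"
  add("classification", "benign", sum(!mal), n)
  add("classification", "non_metastatic_bc", sum(mal & !meta$metastatic), n)
  add("classification", "metastatic_bc", sum(mal & meta$metastatic), n)
  add("brca1", "carrier", sum(meta$brca1_carrier), n)
  add("familial", "familial", sum(meta$familial), n)
  n_mal <- sum(mal)
  add("breast_cancer", "metastatic", sum(mal & meta$metastatic), n_mal)
  for (ts in .t_stages) add("t_stage", ts, sum(mal & meta$t_stage == ts), n_mal)
  for (ns in .n_stages) add("n_stage", ns, sum(mal & meta$n_stage == ns), n_mal)
  for (col in c("er_positive", "pr_positive", "her2_positive", "tnbc")) {
    for (lv in .tri_states) {
      add(col, lv, sum(mal & meta[[col]] == lv), n_mal)
    }
  }
  strata <- do.call(rbind, rows)
  age <- list(median = stats::median(meta$age, na.rm = TRUE),
              iqr = unname(stats::quantile(meta$age, c(0.25, 0.75),
                                           na.rm = TRUE)))
  list(strata = strata, age = age)
}
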