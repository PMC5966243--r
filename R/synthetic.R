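#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the seeded generator that emulates the data
#' structure of a two-phase plasma circulating-miR study: a validation
#' cohort of individual samples quantified by RT-qPCR on a 25-assay panel
#' (5 stable reference miRs, 2 haemolysis markers, 18 candidates), and a
#' discovery cohort whose samples are pooled 2-3 at a time before
#' microarray profiling.
#'
#' The Cq model is
#' `cq[s, m] = baseline_cq[m] + sample_effect[s] - log2(FC[m, stratum(s)]) + noise`,
#' so an injected linear fold change is exact on the linear (2^-Cq) scale.
#' Reference miRs never receive group effects. Haemolysis-contaminated
#' samples have the erythrocyte marker miR-451 shifted *down* by
#' `haemolysis_shift` cycles (more template, earlier amplification);
#' low-RNA-yield samples have every assay shifted *up* by
#' `low_input_shift` cycles so that they fail the reference-expression
#' quality gate. The contaminated and low-yield sample sets are drawn
#' disjoint so exclusion tallies add.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param cohort `"validation"` or `"discovery"` (label written to metadata).
#' @param n_benign,n_malignant,n_metastatic Stratum sizes; metastatic
#'   samples are a subset of the malignant ones.
#' @param n_brca1_benign,n_brca1_malignant Number of BRCA1-mutation carriers
#'   within each diagnosis group.
#' @param n_reference_mirs,n_candidate_mirs Panel composition (defaults 5
#'   and 18; the two haemolysis markers are always added).
#' @param baseline_cq Optional named numeric vector of per-assay baseline
#'   Cq values. When `NULL`, candidate baselines are drawn uniformly from
#'   `[22, 32]`, reference baselines from `[15, 18]` (abundant, so clean
#'   samples clear the 20-cycle reference cutoff), and the haemolysis
#'   markers sit at fixed moderate abundances (miR-451 at 26, miR-23a at
#'   25 cycles).
#' @param sample_effect_sd Between-sample global shift SD, cycles (default
#'   0.8; RNA yield / input variation removed later by normalization).
#' @param noise_sd Per-reaction technical noise SD, cycles (default 0.3).
#' @param fold_changes `data.frame(mir_id, contrast, fc)` of injected linear
#'   fold changes; `contrast` is one of `"malignant"`, `"metastatic"`,
#'   `"brca1_benign"`, `"brca1_malignant"`. Effects accumulate (a metastatic
#'   sample receives the malignant and metastatic effects). `NULL` injects
#'   nothing.
#' @param haemolysis_fraction Proportion of samples contaminated by red
#'   blood cell lysis (rounded to a count).
#' @param haemolysis_shift Cycles subtracted from miR-451 in contaminated
#'   samples (default 8).
#' @param mir23a_shift Cycles subtracted from miR-23a in contaminated
#'   samples (default 0; miR-23a is only mildly haemolysis-sensitive).
#' @param low_input_fraction Proportion of samples with poor RNA yield.
#' @param low_input_shift Cycles added to every assay of a low-yield sample
#'   (default 8, pushing the reference median past the 20-cycle gate).
#' @param familial_fraction Proportion of non-carrier samples annotated as
#'   familial breast cancer risk (default 0.25).
#' @param pool_size Target discovery pool size, 2 or 3 (default 3).
#' @param background_mean,background_sd Microarray chip background model.
#' @param absent_fraction Fraction of panel miRs emitted at background level
#'   on the microarray (below the present-call threshold).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             cohort = c("validation", "discovery"),
                             n_benign = 30, n_malignant = 49, n_metastatic = 8,
                             n_brca1_benign = 1, n_brca1_malignant = 2,
                             n_reference_mirs = 5, n_candidate_mirs = 18,
                             baseline_cq = NULL,
                             sample_effect_sd = 0.8, noise_sd = 0.3,
                             fold_changes = NULL,
                             haemolysis_fraction = 0, haemolysis_shift = 8,
                             mir23a_shift = 0,
                             low_input_fraction = 0, low_input_shift = 8,
                             familial_fraction = 0.25,
                             pool_size = 3,
                             background_mean = 100, background_sd = 10,
                             absent_fraction = 0.1) {
  cohort <- match.arg(cohort)
  counts <- c(n_benign = n_benign, n_malignant = n_malignant,
              n_metastatic = n_metastatic, n_brca1_benign = n_brca1_benign,
              n_brca1_malignant = n_brca1_malignant,
              n_reference_mirs = n_reference_mirs,
              n_candidate_mirs = n_candidate_mirs)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("all counts must be non-negative integers")
  }
  if (n_metastatic > n_malignant) stop("n_metastatic cannot exceed n_malignant")
  if (n_brca1_benign > n_benign) stop("n_brca1_benign cannot exceed n_benign")
  if (n_brca1_malignant > n_malignant) {
    stop("n_brca1_malignant cannot exceed n_malignant")
  }
  for (frac in c(haemolysis_fraction, low_input_fraction, familial_fraction,
                 absent_fraction)) {
    if (frac < 0 || frac > 1) stop("fractions must lie in [0, 1]")
  }
  if (!is.null(fold_changes)) {
    fold_changes <- as.data.frame(fold_changes)
    if (!all(c("mir_id", "contrast", "fc") %in% names(fold_changes))) {
      stop("'fold_changes' needs columns mir_id, contrast, fc")
    }
    if (any(fold_changes$fc <= 0)) stop("fold changes must be positive")
    ok <- fold_changes$contrast %in%
      c("malignant", "metastatic", "brca1_benign", "brca1_malignant")
    if (!all(ok)) {
      stop("unknown fold-change contrast: ",
           paste(unique(fold_changes$contrast[!ok]), collapse = ", "))
    }
  }
  if (!pool_size %in% c(2, 3)) stop("pool_size must be 2 or 3")
  if (noise_sd < 0 || sample_effect_sd < 0) stop("SDs must be non-negative")
  structure(list(seed = seed, cohort = cohort,
                 n_benign = n_benign, n_malignant = n_malignant,
                 n_metastatic = n_metastatic,
                 n_brca1_benign = n_brca1_benign,
                 n_brca1_malignant = n_brca1_malignant,
                 n_reference_mirs = n_reference_mirs,
                 n_candidate_mirs = n_candidate_mirs,
                 baseline_cq = baseline_cq,
                 sample_effect_sd = sample_effect_sd, noise_sd = noise_sd,
                 fold_changes = fold_changes,
                 haemolysis_fraction = haemolysis_fraction,
                 haemolysis_shift = haemolysis_shift,
                 mir23a_shift = mir23a_shift,
                 low_input_fraction = low_input_fraction,
                 low_input_shift = low_input_shift,
                 familial_fraction = familial_fraction,
                 pool_size = pool_size,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 absent_fraction = absent_fraction),
            class = "synthetic_config")
}

#' Default fold changes emulating the validated biomarker effects
#'
#' The effect sizes injected by default when simulating a "positive" cohort:
#' miR-652-5p up 1.26-fold and let-7b up 1.53-fold in malignant vs benign
#' plasma; eight metastasis-associated shifts; and the two BRCA1-benign
#' effects (miR-185-5p up 2.16-fold, miR-675-5p down to 0.25).
#'
#' @return A `data.frame(mir_id, contrast, fc)`.
#' @export
default_fold_changes <- function() {
  rbind(
    data.frame(mir_id = c("hsa-miR-652-5p", "hsa-let-7b"),
               contrast = "malignant", fc = c(1.26, 1.53)),
    data.frame(mir_id = c("hsa-miR-18b-5p", "hsa-miR-21-5p", "hsa-miR-29b",
                          "hsa-miR-135-3p", "hsa-miR-202-3p",
                          "hsa-miR-382-3p", "hsa-miR-675-5p",
                          "hsa-miR-195-5p"),
               contrast = "metastatic",
               fc = c(0.52, 0.50, 0.71, 1.89, 0.48, 0.09, 1.36, 1.02)),
    data.frame(mir_id = c("hsa-miR-185-5p", "hsa-miR-675-5p"),
               contrast = "brca1_benign", fc = c(2.16, 0.25))
  )
}

.haemolysis_marker_id <- "hsa-miR-451"
.mir23a_id <- "hsa-miR-23a"

default_candidate_ids <- function(n) {
  named <- c("hsa-miR-18b-5p", "hsa-miR-21-5p", "hsa-miR-29b",
             "hsa-miR-135-3p", "hsa-miR-185-5p", "hsa-miR-195-5p",
             "hsa-miR-202-3p", "hsa-miR-382-3p", "hsa-miR-652-5p",
             "hsa-miR-675-5p", "hsa-let-7b")
  if (n <= length(named)) return(named[seq_len(n)])
  c(named, sprintf("cand-miR-%03d", seq_len(n - length(named))))
}

panel_assay_ids <- function(config) {
  refs <- sprintf("ref-miR-%d", seq_len(config$n_reference_mirs))
  cands <- default_candidate_ids(config$n_candidate_mirs)
  list(reference = refs,
       haemolysis = c(.haemolysis_marker_id, .mir23a_id),
       candidate = cands)
}

panel_roles <- function(config) {
  ids <- panel_assay_ids(config)
  stats::setNames(
    c(rep("reference", length(ids$reference)),
      rep("haemolysis_marker", length(ids$haemolysis)),
      rep("candidate", length(ids$candidate))),
    c(ids$reference, ids$haemolysis, ids$candidate))
}

draw_baselines <- function(config) {
  if (!is.null(config$baseline_cq)) return(config$baseline_cq)
  ids <- panel_assay_ids(config)
  ref_base <- stats::setNames(stats::runif(length(ids$reference), 15, 18),
                              ids$reference)
  cand_base <- stats::setNames(stats::runif(length(ids$candidate), 22, 32),
                               ids$candidate)
  # in clean plasma both haemolysis markers are typical mid-abundance
  # members of the panel (which is exactly why a median-normalized miR-451
  # score detects haemolysis): anchor their baselines at the panel's
  # central baseline. Because the markers never receive group effects,
  # they also pin the per-sample panel median, keeping the normalization
  # reference group-stable.
  mid <- stats::median(c(ref_base, cand_base))
  c(ref_base,
    stats::setNames(c(mid, mid), ids$haemolysis),
    cand_base)
}

#' Generate a synthetic plasma-miR cohort
#'
#' Draws sample metadata (diagnosis group, metastasis, BRCA1/familial
#' status, age, T/N stage, receptor status) and an RT-qPCR Cq table under
#' the additive Cq model described in [synthetic_config()]. Identical
#' configurations (including the seed) yield identical output.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `metadata` (a `sample_metadata` data frame)
#'   and `cq` (a [cq_table()]). The ids of contaminated and low-yield
#'   samples are attached to `cq` as attributes `haemolysed` and
#'   `low_input`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  meta <- draw_metadata(config)
  roles <- panel_roles(config)
  baseline <- draw_baselines(config)
  baseline <- baseline[names(roles)]
  n <- nrow(meta)
  m <- length(roles)

  sample_effect <- stats::rnorm(n, 0, config$sample_effect_sd)
  noise <- matrix(stats::rnorm(n * m, 0, config$noise_sd), n, m)
  cq <- matrix(rep(baseline, each = n), n, m) + sample_effect + noise
  dimnames(cq) <- list(meta$sample_id, names(roles))

  cq <- apply_fold_changes(cq, meta, roles, config$fold_changes)

  # low-yield samples first, contamination drawn from the remainder
  n_low <- round(config$low_input_fraction * n)
  low_ids <- if (n_low > 0) sample(meta$sample_id, n_low) else character()
  if (n_low > 0) cq[low_ids, ] <- cq[low_ids, ] + config$low_input_shift
  n_haem <- round(config$haemolysis_fraction * n)
  pool_from <- setdiff(meta$sample_id, low_ids)
  haem_ids <- if (n_haem > 0) sample(pool_from, n_haem) else character()
  if (n_haem > 0) {
    cq[haem_ids, .haemolysis_marker_id] <-
      cq[haem_ids, .haemolysis_marker_id] - config$haemolysis_shift
    cq[haem_ids, .mir23a_id] <- cq[haem_ids, .mir23a_id] - config$mir23a_shift
  }

  cq[cq > 40] <- NA  # beyond the 40-cycle detection limit
  cq[cq < 0] <- 0
  tab <- cq_table(cq, roles)
  attr(tab, "haemolysed") <- haem_ids
  attr(tab, "low_input") <- low_ids
  # expose the realized baselines so a second cohort measuring the same
  # assays (e.g. discovery vs validation) can share them
  attr(tab, "baseline_cq") <- baseline
  list(metadata = meta, cq = tab)
}

draw_metadata <- function(config) {
  nb <- config$n_benign; nm <- config$n_malignant
  prefix <- if (config$cohort == "validation") "V" else "D"
  ids <- c(sprintf("%s-B%03d", prefix, seq_len(nb)),
           sprintf("%s-M%03d", prefix, seq_len(nm)))
  group <- c(rep("benign", nb), rep("malignant", nm))
  metastatic <- c(rep(FALSE, nb),
                  rep(c(TRUE, FALSE), c(config$n_metastatic,
                                        nm - config$n_metastatic)))
  brca1 <- c(rep(c(TRUE, FALSE), c(config$n_brca1_benign,
                                   nb - config$n_brca1_benign)),
             rep(c(TRUE, FALSE), c(config$n_brca1_malignant,
                                   nm - config$n_brca1_malignant)))
  n <- nb + nm
  familial <- brca1 | (stats::runif(n) < config$familial_fraction)
  age <- round(pmin(pmax(stats::rnorm(n, 55, 9), 25), 85), 1)

  t_stage <- rep("unknown", n)
  n_stage <- rep("unknown", n)
  er <- pr <- her2 <- tnbc <- rep("unknown", n)
  mal <- group == "malignant"
  t_stage[mal] <- sample(c("T1", "T2", "T3"), sum(mal), replace = TRUE,
                         prob = c(0.57, 0.39, 0.04))
  n_stage[mal] <- sample(c("N0", "N1", "N2", "N3"), sum(mal), replace = TRUE,
                         prob = c(0.51, 0.33, 0.08, 0.08))
  er[mal] <- sample(c("pos", "neg"), sum(mal), TRUE, prob = c(0.82, 0.18))
  pr[mal] <- sample(c("pos", "neg"), sum(mal), TRUE, prob = c(0.70, 0.30))
  her2[mal] <- sample(c("pos", "neg"), sum(mal), TRUE, prob = c(0.20, 0.80))
  tnbc[mal] <- ifelse(er[mal] == "neg" & pr[mal] == "neg" & her2[mal] == "neg",
                      "pos", "neg")
  validate_sample_metadata(data.frame(
    sample_id = ids, cohort = config$cohort, group = group,
    metastatic = metastatic, brca1_carrier = brca1, familial = familial,
    age = age, t_stage = t_stage, n_stage = n_stage,
    er_positive = er, pr_positive = pr, her2_positive = her2, tnbc = tnbc,
    stringsAsFactors = FALSE))
}

apply_fold_changes <- function(cq, meta, roles, fold_changes) {
  if (is.null(fold_changes) || nrow(fold_changes) == 0) return(cq)
  strata <- list(
    malignant = meta$group == "malignant",
    metastatic = meta$metastatic,
    brca1_benign = meta$brca1_carrier & meta$group == "benign",
    brca1_malignant = meta$brca1_carrier & meta$group == "malignant")
  for (i in seq_len(nrow(fold_changes))) {
    mir <- fold_changes$mir_id[i]
    if (!mir %in% colnames(cq)) {
      stop("fold change names unknown assay '", mir, "'")
    }
    if (roles[[mir]] == "reference") {
      stop("reference miRs carry no group effect (", mir, ")")
    }
    rows <- strata[[fold_changes$contrast[i]]]
    cq[rows, mir] <- cq[rows, mir] - log2(fold_changes$fc[i])
  }
  cq
}

#' Pool samples on the linear abundance scale
#'
#' Plasma pooling mixes molecules, not cycles: the pooled Cq is the Cq of
#' the mean linear-scale abundance of the members,
#' `cq_pool = -log2(mean(2^-cq_member))`. Members whose reaction did not
#' amplify are excluded from the mean; a pool whose members are all
#' undetected is undetected.
#'
#' @param cq A [cq_table()] of individual samples.
#' @param groups Named list mapping pooled group id to member sample ids
#'   (typically 2-3 members, mirroring the pooled discovery design).
#' @return A [cq_table()] with one row per pooled group.
#' @export
pool_samples <- function(cq, groups) {
  stopifnot(inherits(cq, "cq_table"))
  if (length(groups) == 0) stop("no pools given")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("'groups' must be a named list (group id -> member sample ids)")
  }
  sizes <- lengths(groups)
  if (any(sizes == 0)) {
    stop("empty pool(s): ", paste(names(groups)[sizes == 0], collapse = ", "))
  }
  unknown <- setdiff(unlist(groups), sample_ids(cq))
  if (length(unknown) > 0) {
    stop("pool member(s) not in Cq table: ", paste(unknown, collapse = ", "))
  }
  if (any(sizes > 3)) {
    warning("pool(s) larger than 3 members: ",
            paste(names(groups)[sizes > 3], collapse = ", "))
  }
  pooled <- t(vapply(groups, function(members) {
    apply(cq$cq[members, , drop = FALSE], 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else -log2(mean(2^(-v)))
    })
  }, numeric(ncol(cq$cq))))
  dimnames(pooled) <- list(names(groups), assay_ids(cq))
  out <- cq_table(pooled, cq$roles)
  attr(out, "pool_members") <- groups
  out
}

#' Assign discovery samples to pools of similar clinical characteristics
#'
#' Chunks samples into pools of at most `pool_size` (never fewer than 2
#' where the stratum allows) within strata defined by diagnosis group,
#' BRCA1 carriership and metastasis, mimicking a pooled discovery design.
#' Deterministic: pools follow metadata order within each stratum.
#'
#' @param meta A `sample_metadata` data frame.
#' @param pool_size Maximum pool size (2 or 3).
#' @return Named list of member sample-id vectors, suitable for
#'   [pool_samples()].
#' @export
assign_pools <- function(meta, pool_size = 3) {
  if (!pool_size %in% c(2, 3)) stop("pool_size must be 2 or 3")
  stratum <- paste0(ifelse(meta$group == "benign", "benign", "malignant"),
                    ifelse(meta$brca1_carrier, "-brca1", ""),
                    ifelse(meta$metastatic, "-met", ""))
  pools <- list()
  for (s in unique(stratum)) {
    ids <- meta$sample_id[stratum == s]
    k <- max(1, ceiling(length(ids) / pool_size))
    # spread members as evenly as possible (sizes differ by at most 1),
    # so no pool exceeds pool_size and singleton tails only occur when
    # the stratum itself is a singleton
    sizes <- rep(length(ids) %/% k, k)
    extra <- length(ids) %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    chunks <- split(ids, rep(seq_len(k), times = sizes))
    names(chunks) <- sprintf("pool-%s-%d", s, seq_along(chunks))
    pools <- c(pools, chunks)
  }
  pools
}

#' Simulate a microarray panel from pooled Cq profiles
#'
#' Converts pooled Cq values to chip intensities proportional to linear
#' abundance (`2^(40 - cq)`, i.e. one cycle = one doubling of signal) on
#' top of an additive Gaussian chip background, and forces a configured
#' fraction of miRs down to pure background so that downstream
#' present-calls have something to reject. Deterministic for a fixed
#' config seed.
#'
#' @param config A [synthetic_config()] (supplies seed, background model
#'   and `absent_fraction`).
#' @param pooled A pooled [cq_table()] (see [pool_samples()]).
#' @return An [intensity_panel()] (miRs x pooled groups).
#' @export
generate_microarray_panel <- function(config, pooled) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(pooled, "cq_table"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + 1L)

  cqm <- t(pooled$cq)  # miRs x groups
  signal <- 2^(40 - cqm)
  signal[is.na(signal)] <- 0
  n_absent <- round(config$absent_fraction * nrow(signal))
  absent <- if (n_absent > 0) sample(rownames(signal), n_absent) else character()
  signal[absent, ] <- 0
  bg <- matrix(stats::rnorm(length(signal), config$background_mean,
                            config$background_sd),
               nrow(signal), ncol(signal))
  intensity <- pmax(signal + bg, 0)
  dimnames(intensity) <- dimnames(cqm)
  panel <- intensity_panel(intensity,
                           background_mean = config$background_mean,
                           background_sd = config$background_sd)
  attr(panel, "absent_mirs") <- absent
  panel
}

#' Simulate an assay-efficiency dilution series
#'
#' A serial dilution of a control sample amplified at a given PCR
#' efficiency produces Cq values on the line
#' `cq = start_cq + slope * log10(relative input)` with
#' `slope = -1 / log10(1 + efficiency_pct / 100)`; at 100% efficiency the
#' slope is -3.3219 Cq per 10-fold dilution.
#'
#' @param efficiency_pct True amplification efficiency in percent (> 0).
#' @param points Number of dilution points (>= 3).
#' @param start_cq Cq of the undiluted control.
#' @param dilution_step Fold-dilution between consecutive points (default 10).
#' @param noise_sd Optional Gaussian Cq noise (default 0, noiseless).
#' @param seed Optional seed used when `noise_sd > 0`.
#' @return `data.frame(log10_dilution, cq)` with `log10_dilution = 0` for
#'   the undiluted point and negative values for dilutions.
#' @export
generate_dilution_series <- function(efficiency_pct, points = 5,
                                     start_cq = 20, dilution_step = 10,
                                     noise_sd = 0, seed = NULL) {
  if (efficiency_pct <= 0) stop("efficiency must be positive")
  if (points < 3) stop("a dilution series needs at least 3 points")
  slope <- -1 / log10(1 + efficiency_pct / 100)
  log10_dilution <- -(seq_len(points) - 1) * log10(dilution_step)
  cq <- start_cq + slope * log10_dilution
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    cq <- cq + stats::rnorm(points, 0, noise_sd)
  }
  data.frame(log10_dilution = log10_dilution, cq = cq)
}
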