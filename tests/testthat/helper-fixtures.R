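# Small in-code fixtures shared across test files.

# A Cq matrix with named samples/assays and a matching role map.
make_cq <- function(values, sample_names = NULL, assay_roles = NULL) {
  m <- as.matrix(values)
  if (!is.null(sample_names)) rownames(m) <- sample_names
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%d", seq_len(nrow(m)))
  if (is.null(assay_roles)) {
    assay_roles <- stats::setNames(rep("candidate", ncol(m)),
                                   sprintf("a%d", seq_len(ncol(m))))
  }
  colnames(m) <- names(assay_roles)
  cq_table(m, assay_roles)
}

# A QC-style panel: n_ref reference assays, the two haemolysis markers and
# filler candidates, every assay at `level` cycles except where overridden.
make_qc_panel <- function(n_samples = 1, level = 20, n_ref = 5, n_cand = 18,
                          overrides = list()) {
  roles <- stats::setNames(
    c(rep("reference", n_ref), rep("haemolysis_marker", 2),
      rep("candidate", n_cand)),
    c(sprintf("ref-miR-%d", seq_len(n_ref)), "hsa-miR-451", "hsa-miR-23a",
      sprintf("cand-miR-%03d", seq_len(n_cand))))
  m <- matrix(level, n_samples, length(roles),
              dimnames = list(sprintf("s%d", seq_len(n_samples)),
                              names(roles)))
  for (s in names(overrides)) {
    for (a in names(overrides[[s]])) {
      m[s, a] <- overrides[[s]][[a]]
    }
  }
  cq_table(m, roles)
}

minimal_meta_row <- function(sample_id = "s1", cohort = "validation",
                             group = "malignant", metastatic = FALSE,
                             brca1_carrier = FALSE, familial = FALSE,
                             age = 50, t_stage = "T1", n_stage = "N0",
                             er_positive = "pos", pr_positive = "pos",
                             her2_positive = "neg", tnbc = "neg") {
  data.frame(sample_id = sample_id, cohort = cohort, group = group,
             metastatic = metastatic, brca1_carrier = brca1_carrier,
             familial = familial, age = age, t_stage = t_stage,
             n_stage = n_stage, er_positive = er_positive,
             pr_positive = pr_positive, her2_positive = her2_positive,
             tnbc = tnbc, stringsAsFactors = FALSE)
}
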