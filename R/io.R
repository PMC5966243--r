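#' Quantification-cycle (Cq) table
#'
#' Container for an RT-qPCR Cq matrix (samples in rows, assays in columns)
#' together with the role of each assay in the panel. Undetected reactions
#' (no amplification within 40 PCR cycles) are stored as `NA`, never as 40:
#' 40 cycles is the detection limit of the run, and imputing it would bias
#' the per-sample panel medians that downstream normalization relies on.
#'
#' @param cq Numeric matrix with sample ids as row names and assay ids as
#'   column names. Non-missing values must lie in `[0, 40]`; `NA` means
#'   undetected.
#' @param roles Named character vector mapping every assay id to one of
#'   `"reference"`, `"haemolysis_marker"`, `"candidate"`.
#' @param impute_undetected Optional numeric; when supplied (e.g. 40),
#'   `NA` cells are replaced by this value on construction. Off by default.
#' @return An object of class `cq_table`: a list with elements `cq`
#'   (the validated matrix) and `roles`.
#' @examples
#' m <- matrix(c(20, 21, 22, 23), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("a1", "a2")))
#' cq_table(m, c(a1 = "reference", a2 = "candidate"))
#' @export
cq_table <- function(cq, roles, impute_undetected = NULL) {
  if (!is.matrix(cq) || !is.numeric(cq)) {
    stop("'cq' must be a numeric matrix")
  }
  if (is.null(rownames(cq)) || is.null(colnames(cq))) {
    stop("'cq' must carry sample ids as rownames and assay ids as colnames")
  }
  if (anyDuplicated(rownames(cq))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(cq)[duplicated(rownames(cq))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(cq))) {
    stop("duplicate assay ids: ",
         paste(unique(colnames(cq)[duplicated(colnames(cq))]), collapse = ", "))
  }
  roles <- validate_assay_roles(roles, colnames(cq))
  bad <- which(!is.na(cq) & (cq < 0 | cq > 40), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("Cq value %g outside [0, 40] at sample '%s', assay '%s'",
                 cq[i, j], rownames(cq)[i], colnames(cq)[j]))
  }
  if (!is.null(impute_undetected)) {
    cq[is.na(cq)] <- impute_undetected
  }
  structure(list(cq = cq, roles = roles), class = "cq_table")
}

validate_assay_roles <- function(roles, assay_ids) {
  allowed <- c("reference", "haemolysis_marker", "candidate")
  if (is.null(names(roles)) || any(names(roles) == "")) {
    stop("'roles' must be a fully named character vector (assay id -> role)")
  }
  if (!all(roles %in% allowed)) {
    stop("assay roles must be one of: ", paste(allowed, collapse = ", "))
  }
  missing_roles <- setdiff(assay_ids, names(roles))
  if (length(missing_roles) > 0) {
    stop("no role assigned for assays: ", paste(missing_roles, collapse = ", "))
  }
  roles[assay_ids]
}

#' @export
print.cq_table <- function(x, ...) {
  cat(sprintf("cq_table: %d samples x %d assays (%d reference, %d haemolysis marker, %d candidate)\n",
              nrow(x$cq), ncol(x$cq),
              sum(x$roles == "reference"),
              sum(x$roles == "haemolysis_marker"),
              sum(x$roles == "candidate")))
  cat(sprintf("undetected cells: %d\n", sum(is.na(x$cq))))
  invisible(x)
}

#' @rdname cq_table
#' @param x A `cq_table`.
#' @export
sample_ids <- function(x) rownames(x$cq)

#' @rdname cq_table
#' @export
assay_ids <- function(x) colnames(x$cq)

#' @rdname cq_table
#' @param role Assay role to select.
#' @export
assays_with_role <- function(x, role) names(x$roles)[x$roles == role]

#' Microarray intensity panel
#'
#' Raw microarray signal for a set of miRs over pooled discovery groups,
#' together with per-chip (per-group) background statistics used for
#' present/absent calls and background subtraction.
#'
#' @param intensity Non-negative numeric matrix, miRs in rows (row names =
#'   miR ids), pooled groups in columns (column names = group ids).
#' @param background_mean Numeric vector of per-group background means
#'   (recycled if length 1).
#' @param background_sd Numeric vector of per-group background standard
#'   deviations, all `>= 0` (recycled if length 1).
#' @return An object of class `intensity_panel`.
#' @export
intensity_panel <- function(intensity, background_mean, background_sd) {
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    stop("'intensity' must be a numeric matrix")
  }
  if (is.null(rownames(intensity)) || is.null(colnames(intensity))) {
    stop("'intensity' must carry miR ids as rownames and group ids as colnames")
  }
  if (any(intensity < 0, na.rm = TRUE)) stop("intensities must be non-negative")
  g <- ncol(intensity)
  background_mean <- rep_len(as.numeric(background_mean), g)
  background_sd <- rep_len(as.numeric(background_sd), g)
  if (any(background_mean < 0)) stop("background means must be non-negative")
  if (any(background_sd < 0)) stop("background standard deviations must be non-negative")
  names(background_mean) <- names(background_sd) <- colnames(intensity)
  structure(list(intensity = intensity,
                 background_mean = background_mean,
                 background_sd = background_sd),
            class = "intensity_panel")
}

#' @export
print.intensity_panel <- function(x, ...) {
  cat(sprintf("intensity_panel: %d miRs x %d groups\n",
              nrow(x$intensity), ncol(x$intensity)))
  invisible(x)
}

#' Read a Cq matrix from delimited text
#'
#' Expects assay ids in the first row and sample ids in the first column.
#' The separator is sniffed from the header line (tab by default, comma
#' accepted). Empty cells or the sentinel (default `"ND"`) mark reactions
#' that did not amplify within 40 cycles and are stored as missing.
#'
#' @param path Path to a TSV/CSV file.
#' @param roles Named character vector of assay roles (see [cq_table()]).
#' @param undetected Sentinel string meaning "not detected". Default `"ND"`.
#' @param impute_undetected Passed to [cq_table()].
#' @return A validated [cq_table()].
#' @export
read_cq_table <- function(path, roles, undetected = "ND",
                          impute_undetected = NULL) {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2) stop("Cq table needs at least one assay column")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  vals[vals %in% c("", undetected, "NA")] <- NA
  m <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                               dimnames = list(ids, colnames(vals))))
  not_num <- !is.na(vals) & is.na(m)
  if (any(not_num)) {
    idx <- which(not_num, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric Cq value '%s' at sample '%s', assay '%s'",
                 vals[idx[1], idx[2]], ids[idx[1]], colnames(vals)[idx[2]]))
  }
  cq_table(m, roles, impute_undetected = impute_undetected)
}

#' Write a Cq table as tab-separated text
#'
#' @param x A [cq_table()].
#' @param path Output path.
#' @param undetected Sentinel written for missing cells.
#' @export
write_cq_table <- function(x, path, undetected = "ND") {
  m <- x$cq
  out <- cbind(sample_id = rownames(m),
               as.data.frame(m, check.names = FALSE))
  for (j in seq(2, ncol(out))) {
    v <- format(out[[j]], trim = TRUE, digits = 15)
    v[is.na(out[[j]])] <- undetected
    out[[j]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

.tri_states <- c("pos", "neg", "unknown")
.t_stages <- c("T1", "T2", "T3", "unknown")
.n_stages <- c("N0", "N1", "N2", "N3", "unknown")

#' Read and validate sample metadata
#'
#' Reads a delimited table of per-sample clinical annotation: cohort
#' (discovery/validation), diagnosis group (benign/malignant), metastasis
#' flag, BRCA1 carrier and familial-risk status, age, tumour (T) and nodal
#' (N) stage, and ER/PR/HER2/TNBC receptor status. Unknown categories are
#' preserved as `"unknown"`. Enforced invariants: metastatic samples must be
#' malignant; a TNBC-positive sample must be ER-, PR- and HER2-negative;
#' sample ids must be unique within a cohort; ages must be positive.
#'
#' @param path Path to a TSV/CSV file whose header matches the fields above.
#' @return A `data.frame` of validated records, one row per sample, in input
#'   order, with class `sample_metadata` prepended.
#' @export
read_sample_metadata <- function(path) {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  validate_sample_metadata(df)
}

#' @rdname read_sample_metadata
#' @param df A data frame of raw records.
#' @export
validate_sample_metadata <- function(df) {
  required <- c("sample_id", "cohort", "group", "metastatic", "brca1_carrier",
                "familial", "age", "t_stage", "n_stage", "er_positive",
                "pr_positive", "her2_positive", "tnbc")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df$cohort <- match_enum(df$cohort, c("discovery", "validation"), "cohort")
  df$group <- match_enum(df$group, c("benign", "malignant"), "group")
  df$metastatic <- parse_flag(df$metastatic, "metastatic")
  df$brca1_carrier <- parse_flag(df$brca1_carrier, "brca1_carrier")
  df$familial <- parse_flag(df$familial, "familial")
  df$age <- as.numeric(df$age)
  df$t_stage <- match_enum(df$t_stage, .t_stages, "t_stage")
  df$n_stage <- match_enum(df$n_stage, .n_stages, "n_stage")
  for (col in c("er_positive", "pr_positive", "her2_positive", "tnbc")) {
    df[[col]] <- match_enum(df[[col]], .tri_states, col)
  }
  if (any(!is.na(df$age) & df$age <= 0)) {
    stop("ages must be positive")
  }
  for (co in unique(df$cohort)) {
    ids <- df$sample_id[df$cohort == co]
    if (anyDuplicated(ids)) {
      stop("duplicate sample ids within cohort '", co, "': ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
  }
  bad <- df$metastatic & df$group != "malignant"
  if (any(bad)) {
    stop("metastatic flag set on non-malignant sample(s): ",
         paste(df$sample_id[bad], collapse = ", "))
  }
  tn <- df$tnbc == "pos"
  bad_tn <- tn & !(df$er_positive == "neg" & df$pr_positive == "neg" &
                     df$her2_positive == "neg")
  if (any(bad_tn)) {
    stop("TNBC-positive sample(s) with a non-negative receptor: ",
         paste(df$sample_id[bad_tn], collapse = ", "))
  }
  class(df) <- c("sample_metadata", "data.frame")
  df
}

match_enum <- function(x, levels, field) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "unknown"
  ok <- x %in% c(levels, "unknown")
  if (!all(ok)) {
    stop(sprintf("invalid value(s) for '%s': %s (allowed: %s)", field,
                 paste(unique(x[!ok]), collapse = ", "),
                 paste(levels, collapse = ", ")))
  }
  if (!"unknown" %in% levels && any(x == "unknown")) {
    stop(sprintf("'%s' does not admit unknown values", field))
  }
  x
}

parse_flag <- function(x, field) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "yes", "1", "t")] <- TRUE
  out[x %in% c("false", "no", "0", "f")] <- FALSE
  if (anyNA(out)) {
    stop(sprintf("invalid boolean value(s) for '%s': %s", field,
                 paste(unique(x[is.na(out)]), collapse = ", ")))
  }
  out
}

#' Write sample metadata as tab-separated text
#'
#' @param meta A metadata data frame (see [read_sample_metadata()]).
#' @param path Output path.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an analysis result as JSON
#'
#' Serializes any pipeline result (QC reports, differential-expression
#' tables, manifests) to JSON at full numeric precision so that reading it
#' back reproduces the object. Data frames become arrays of row objects in
#' input order; an empty result set becomes a valid empty JSON array.
#'
#' @param report A serializable result object (data frame, list, vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path Path to a JSON file.
#' @return The deserialized object (data frames simplified from row arrays).
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}
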