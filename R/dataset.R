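#' Construct a cohort dataset
#'
#' The universal pipeline container: a samples x features measurement matrix
#' together with the subject covariate table and the feature descriptor
#' table. Rows of `measurements` correspond to rows of `subjects` (one row
#' per subject per timepoint) and columns to rows of `features`.
#'
#' @param measurements numeric matrix, samples x features
#' @param subjects data.frame as from [generate_subjects()]
#' @param features data.frame as from [generate_panel()]
#' @param normalized whether measurements are within-cohort z-scores
#' @param viral_load optional per-(subject, timepoint) viral-load table
#' @return object of class `cohort_dataset`
#' @export
cohort_dataset <- function(measurements, subjects, features,
                           normalized = FALSE, viral_load = NULL) {
  measurements <- as.matrix(measurements)
  if (nrow(measurements) != nrow(subjects)) {
    stop("measurement rows (", nrow(measurements), ") != subjects (",
         nrow(subjects), ")", call. = FALSE)
  }
  if (ncol(measurements) != nrow(features)) {
    stop("measurement columns (", ncol(measurements), ") != features (",
         nrow(features), ")", call. = FALSE)
  }
  rownames(measurements) <- sample_ids(subjects)
  colnames(measurements) <- features$feature_id
  structure(list(measurements = measurements, subjects = subjects,
                 features = features, normalized = isTRUE(normalized),
                 viral_load = viral_load),
            class = "cohort_dataset")
}

# One id per matrix row; timepoint-qualified for longitudinal samples.
sample_ids <- function(subjects) {
  ifelse(subjects$timepoint == "none", subjects$subject_id,
         paste(subjects$subject_id, subjects$timepoint, sep = "."))
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("cohort_dataset:", nrow(x$measurements), "samples x",
      ncol(x$measurements), "features\n")
  cat("  cohorts:", paste(sprintf("%s (%d)", names(table(x$subjects$cohort)),
                                  table(x$subjects$cohort)), collapse = ", "), "\n")
  cat("  normalized:", x$normalized, "\n")
  if (!is.null(x$viral_load)) cat("  viral-load table:", nrow(x$viral_load), "rows\n")
  invisible(x)
}

#' Subset a cohort dataset by sample and/or feature
#'
#' @param dataset a `cohort_dataset`
#' @param samples logical/integer index over samples, or NULL for all
#' @param features logical/integer index over features, or NULL for all
#' @export
subset_dataset <- function(dataset, samples = NULL, features = NULL) {
  s <- if (is.null(samples)) seq_len(nrow(dataset$measurements)) else samples
  f <- if (is.null(features)) seq_len(ncol(dataset$measurements)) else features
  cohort_dataset(dataset$measurements[s, f, drop = FALSE],
                 dataset$subjects[s, , drop = FALSE],
                 dataset$features[f, , drop = FALSE],
                 normalized = dataset$normalized,
                 viral_load = dataset$viral_load)
}

#' Write a cohort dataset as TSV tables
#'
#' Writes subjects.tsv, features.tsv, matrix.tsv (and viral_load.tsv when
#' present) under `dir`. Missing values are written as empty fields.
#'
#' @param dataset a `cohort_dataset`
#' @param dir output directory (created if absent)
#' @return invisibly, the vector of files written
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(subjects = file.path(dir, "subjects.tsv"),
             features = file.path(dir, "features.tsv"),
             matrix = file.path(dir, "matrix.tsv"))
  write_tsv(dataset$subjects, files["subjects"])
  write_tsv(dataset$features, files["features"])
  mat <- data.frame(sample_id = rownames(dataset$measurements),
                    dataset$measurements, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(mat, files["matrix"])
  if (!is.null(dataset$viral_load)) {
    files["viral_load"] <- file.path(dir, "viral_load.tsv")
    write_tsv(dataset$viral_load, files["viral_load"])
  }
  invisible(files)
}

#' Read a cohort dataset written by [write_dataset()]
#' @param dir directory containing subjects.tsv, features.tsv, matrix.tsv
#' @param normalized whether the stored matrix is already normalized
#' @return a `cohort_dataset`
#' @export
read_dataset <- function(dir, normalized = FALSE) {
  subjects <- read_tsv(file.path(dir, "subjects.tsv"))
  features <- read_tsv(file.path(dir, "features.tsv"))
  for (col in c("stimulus", "analyte", "subset", "signaling_param",
                "cell_type", "pathway")) {
    if (col %in% names(features)) features[[col]][is.na(features[[col]])] <- "none"
  }
  mat <- read_tsv(file.path(dir, "matrix.tsv"))
  m <- as.matrix(mat[, -1, drop = FALSE])
  rownames(m) <- mat[[1]]
  vl_path <- file.path(dir, "viral_load.tsv")
  vl <- if (file.exists(vl_path)) read_tsv(vl_path) else NULL
  cohort_dataset(m, subjects, features, normalized = normalized, viral_load = vl)
}
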