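#' Stimulation response from raw intensities
#'
#' Default cytometry convention: `asinh(x / cofactor)` transform (cofactor 5
#' for mass cytometry) of stimulated and unstimulated intensities, response
#' = transformed difference. A raw-ratio mode is available; values already
#' on the transformed scale can be flagged through.
#'
#' @param stim,unstim raw (non-negative) intensities, or transformed values
#'   when `already_transformed`
#' @param cofactor arcsinh cofactor
#' @param transform "arcsinh" difference or raw "ratio"
#' @param already_transformed skip the transform
#' @return numeric response values
#' @export
stimulation_response <- function(stim, unstim, cofactor = 5,
                                 transform = c("arcsinh", "ratio"),
                                 already_transformed = FALSE) {
  transform <- match.arg(transform)
  if (already_transformed) return(stim - unstim)
  if (any(stim < 0, na.rm = TRUE) || any(unstim < 0, na.rm = TRUE)) {
    config_error("raw intensities must be non-negative")
  }
  if (transform == "ratio") return(stim / unstim)
  asinh(stim / cofactor) - asinh(unstim / cofactor)
}

#' Trajectory summary: mean and SEM per (cell type, timepoint)
#'
#' When a young-control reference is supplied (named vector of means and
#' SDs per cell type, or a data.frame with cell_type, mean, sd), reference
#' normalized values `z = (x - mean_young) / sd_young` are summarized
#' instead. Points with a single subject carry an NA SEM and are flagged.
#'
#' @param responses data.frame with subject_id, timepoint, cell_type, value
#' @param reference optional data.frame (cell_type, mean, sd)
#' @return data.frame with cell_type, timepoint, n, mean, sem, ci_lo, ci_hi,
#'   flagged
#' @export
trajectory_summary <- function(responses, reference = NULL) {
  stopifnot(all(c("subject_id", "timepoint", "cell_type", "value") %in%
                  names(responses)))
  if (!is.null(reference)) {
    idx <- match(responses$cell_type, reference$cell_type)
    if (anyNA(idx)) config_error("reference missing cell type(s)")
    responses$value <- (responses$value - reference$mean[idx]) /
      reference$sd[idx]
  }
  groups <- split(responses,
                  list(responses$cell_type, responses$timepoint), drop = TRUE)
  out <- lapply(groups, function(gr) {
    n <- sum(!is.na(gr$value))
    mu <- mean(gr$value, na.rm = TRUE)
    sem <- if (n >= 2) stats::sd(gr$value, na.rm = TRUE) / sqrt(n) else NA_real_
    data.frame(cell_type = gr$cell_type[1], timepoint = gr$timepoint[1],
               n = n, mean = mu, sem = sem,
               ci_lo = mu - 1.96 * sem, ci_hi = mu + 1.96 * sem,
               flagged = n < 2, row.names = NULL, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$cell_type, res$timepoint), , drop = FALSE]
}

#' Nonparametric group comparisons
#'
#' Kruskal-Wallis across independent groups, or Wilcoxon matched-pairs
#' signed-rank between paired pre/post measurements (zero differences
#' dropped; exact distribution for n <= 25 without ties). A degenerate
#' paired comparison (no nonzero differences) reports p = 1, flagged.
#'
#' @param data data.frame of observations
#' @param value column holding the measurement
#' @param group column holding group labels (Kruskal-Wallis), or the
#'   timepoint column for paired tests
#' @param test "kruskal_wallis" or "wilcoxon_signed_rank"
#' @param subject column identifying subjects (paired test)
#' @param pre,post group labels compared by the paired test
#' @param label comparison label carried into the result
#' @return one-row data.frame: label, test, statistic, p, flagged
#' @export
group_comparisons <- function(data, value = "value", group = "group",
                              test = c("kruskal_wallis",
                                       "wilcoxon_signed_rank"),
                              subject = "subject_id", pre = "pre",
                              post = "post", label = NULL) {
  test <- match.arg(test)
  if (test == "kruskal_wallis") {
    kt <- stats::kruskal.test(data[[value]], factor(data[[group]]))
    lab <- if (is.null(label))
      paste(levels(factor(data[[group]])), collapse = " vs ") else label
    return(data.frame(label = lab, test = test,
                      statistic = unname(kt$statistic), p = kt$p.value,
                      flagged = FALSE, stringsAsFactors = FALSE))
  }
  pre_df <- data[data[[group]] == pre, ]
  post_df <- data[data[[group]] == post, ]
  ids <- union(pre_df[[subject]], post_df[[subject]])
  missing <- ids[!(ids %in% pre_df[[subject]]) | !(ids %in% post_df[[subject]])]
  if (length(missing)) {
    config_error("unmatched pair(s) for subject(s): ",
                 paste(utils::head(missing, 5), collapse = ", "))
  }
  x <- post_df[[value]][match(ids, post_df[[subject]])]
  y <- pre_df[[value]][match(ids, pre_df[[subject]])]
  lab <- if (is.null(label)) paste(pre, "vs", post) else label
  diffs <- x - y
  if (all(diffs == 0, na.rm = TRUE)) {
    return(data.frame(label = lab, test = test, statistic = NA_real_, p = 1,
                      flagged = TRUE, stringsAsFactors = FALSE))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
  data.frame(label = lab, test = test, statistic = unname(wt$statistic),
             p = wt$p.value, flagged = FALSE, stringsAsFactors = FALSE)
}
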