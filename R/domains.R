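pretty_cell <- function(cell_type) {
  map <- c("CD4 T" = "CD4+ T cells", "CD8 T" = "CD8+ T cells",
           "gd T" = "\u03b3\u03b4 T cells", "B" = "B cells", "NK" = "NK cells",
           "Monocytes" = "monocytes", "DC" = "DCs")
  out <- map[cell_type]
  out[is.na(out)] <- cell_type[is.na(out)]
  unname(out)
}

pretty_stimulus <- function(stimulus) {
  map <- c(IFNa = "IFN-\u03b1", IFNg = "IFN-\u03b3", IL2 = "IL-2", IL6 = "IL-6",
           IL7 = "IL-7", IL10 = "IL-10", IL21 = "IL-21", BCR = "BCR")
  out <- map[stimulus]
  out[is.na(out)] <- stimulus[is.na(out)]
  unname(out)
}

# T cell subsets counted as memory/naive skewing rather than plain frequency
memory_subsets <- function() {
  c("naive", "central memory", "effector memory", "TEMRA", "memory")
}

#' Assign each feature to a functional domain
#'
#' Deterministic rules: memory/naive T cell frequencies map to
#' "T cell memory skewing"; other cell frequencies to "<cell type> frequency";
#' baseline signaling to "Baseline signaling in <cell type>"; stimulation
#' responses to "Sensitivity to <stimulus> in <cell type>"; serum analytes to
#' "Systemic <analyte>". Every feature maps to exactly one domain.
#'
#' @param features feature descriptor data.frame from [generate_panel()]
#' @return character vector of domain labels, one per feature
#' @export
assign_domain <- function(features) {
  n <- nrow(features)
  domain <- character(n)
  for (i in seq_len(n)) {
    f <- features[i, ]
    domain[i] <- switch(
      f$modality,
      cell_frequency = {
        if (f$cell_type %in% c("CD4 T", "CD8 T") &&
            f$subset %in% memory_subsets()) {
          "T cell memory skewing"
        } else {
          paste(pretty_cell(f$cell_type), "frequency")
        }
      },
      baseline_signaling = paste("Baseline signaling in",
                                 pretty_cell(f$cell_type)),
      stim_response = paste("Sensitivity to", pretty_stimulus(f$stimulus),
                            "in", pretty_cell(f$cell_type)),
      serum_protein = paste("Systemic", f$analyte),
      config_error("feature '", f$feature_id, "' has unknown modality '",
                   f$modality, "'"))
    if (f$modality %in% c("baseline_signaling", "stim_response") &&
        (is.na(f$signaling_param) || f$signaling_param == "none")) {
      config_error("signaling feature '", f$feature_id,
                   "' lacks a signaling parameter")
    }
  }
  domain
}

#' Cross-cohort overlap of significant domains
#'
#' Partitions three domain sets into the seven disjoint Venn regions.
#'
#' @param sets named list of three character vectors (one per driver)
#' @return list with `regions` (data.frame: region, count, members) and
#'   `total` (number of unique domains)
#' @export
domain_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) == 3)
  nm <- names(sets)
  if (is.null(nm) || any(nm == "")) nm <- c("A", "B", "C")
  a <- unique(sets[[1]]); b <- unique(sets[[2]]); c_ <- unique(sets[[3]])
  all3 <- intersect(intersect(a, b), c_)
  ab <- setdiff(intersect(a, b), all3)
  ac <- setdiff(intersect(a, c_), all3)
  bc <- setdiff(intersect(b, c_), all3)
  only_a <- setdiff(a, union(b, c_))
  only_b <- setdiff(b, union(a, c_))
  only_c <- setdiff(c_, union(a, b))
  regions <- list(only_a, only_b, only_c, ab, ac, bc, all3)
  names(regions) <- c(paste0(nm, "_only"),
                      paste(nm[1], nm[2], sep = "_"),
                      paste(nm[1], nm[3], sep = "_"),
                      paste(nm[2], nm[3], sep = "_"),
                      paste(nm, collapse = "_"))
  df <- data.frame(
    region = names(regions),
    count = vapply(regions, length, integer(1)),
    members = vapply(regions, function(x) paste(sort(x), collapse = "; "),
                     character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(regions = df, total = length(unique(c(a, b, c_))))
}

#' Significant domain sets per driver from regression results
#'
#' @param regression results from [cohort_regression()]
#' @param domains_map data.frame (feature_id, domain)
#' @param driver_cohorts named map from driver to the cohort testing it
#' @return named list of domain sets
#' @export
significant_domains <- function(regression, domains_map,
                                driver_cohorts = c(age = "aging", hiv = "hiv",
                                                   hcv = "hcv")) {
  out <- list()
  for (d in names(driver_cohorts)) {
    sig <- regression[regression$covariate == d &
                        regression$cohort == driver_cohorts[[d]] &
                        regression$significant, , drop = FALSE]
    out[[d]] <- unique(domains_map$domain[match(sig$feature_id,
                                                domains_map$feature_id)])
  }
  out
}

#' Effect-size table for domains shared across drivers
#'
#' One row per (feature, driver) for every significant feature whose domain
#' lies in the shared set, carrying the signed regression coefficient
#' (negative = dampening effect of the driver, positive = boosting).
#'
#' @param regression results from [cohort_regression()]
#' @param domains_map data.frame (feature_id, domain)
#' @param shared_domains character vector of domain labels
#' @param driver_cohorts named map from driver to the cohort testing it
#' @return data.frame with domain, feature_id, driver, beta
#' @export
shared_effect_table <- function(regression, domains_map, shared_domains,
                                driver_cohorts = c(age = "aging", hiv = "hiv",
                                                   hcv = "hcv")) {
  unknown <- setdiff(shared_domains, domains_map$domain)
  if (length(unknown)) {
    config_error("unknown domain name(s): ", paste(unknown, collapse = ", "))
  }
  rows <- list()
  for (d in names(driver_cohorts)) {
    sig <- regression[regression$covariate == d &
                        regression$cohort == driver_cohorts[[d]] &
                        regression$significant, , drop = FALSE]
    if (!nrow(sig)) next
    dom <- domains_map$domain[match(sig$feature_id, domains_map$feature_id)]
    keep <- dom %in% shared_domains
    if (!any(keep)) next
    rows[[d]] <- data.frame(domain = dom[keep],
                            feature_id = sig$feature_id[keep],
                            driver = d, beta = sig$beta[keep],
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(domain = character(), feature_id = character(),
                      driver = character(), beta = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
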