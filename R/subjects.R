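#' Default cohort configuration
#'
#' Three cohorts: an aging cohort of 60 older (61-90 y) cases and 29 young
#' (22-33 y) controls, an HIV cohort of 24 infected (26-78 y) and 45
#' uninfected (25-78 y) individuals, and an HCV cohort of 14 infected
#' (29-71 y) and 11 uninfected (18-74 y) individuals.
#'
#' @param female_prop probability a subject is female
#' @param cmv_prev CMV seropositivity prevalence
#' @return nested list consumed by [generate_subjects()]
#' @export
default_cohort_config <- function(female_prop = 0.5, cmv_prev = 0.5) {
  list(
    cohorts = list(
      aging = list(case = list(n = 60, age = c(61, 90)),
                   control = list(n = 29, age = c(22, 33))),
      hiv   = list(case = list(n = 24, age = c(26, 78)),
                   control = list(n = 45, age = c(25, 78))),
      hcv   = list(case = list(n = 14, age = c(29, 71)),
                   control = list(n = 11, age = c(18, 74)))),
    female_prop = female_prop,
    cmv_prev = cmv_prev)
}

#' Generate synthetic subjects for the three cohorts
#'
#' Ages are drawn uniformly (integer years) within each group's configured
#' range; sex and CMV serostatus are Bernoulli at the configured prevalences.
#' HIV status is 1 only for HIV-cohort cases and HCV status 1 only for
#' HCV-cohort cases.
#'
#' @param config as returned by [default_cohort_config()]
#' @param seed integer seed; identical config + seed gives identical output
#' @return data.frame with columns subject_id, cohort, group, age, sex, cmv,
#'   hiv, hcv, timepoint
#' @export
generate_subjects <- function(config = default_cohort_config(), seed = 1) {
  stopifnot(is.list(config), !is.null(config$cohorts))
  config$female_prop <- config$female_prop %||% 0.5
  config$cmv_prev <- config$cmv_prev %||% 0.5
  for (co in names(config$cohorts)) {
    for (gr in names(config$cohorts[[co]])) {
      g <- config$cohorts[[co]][[gr]]
      if (is.null(g$n) || g$n < 0) {
        config_error("negative or missing size for ", co, "/", gr)
      }
      if (g$n > 0 && (length(g$age) != 2 || g$age[1] > g$age[2])) {
        config_error("invalid age range for ", co, "/", gr)
      }
    }
  }
  with_seed(seed, {
    rows <- list()
    for (co in names(config$cohorts)) {
      for (gr in names(config$cohorts[[co]])) {
        g <- config$cohorts[[co]][[gr]]
        if (g$n == 0) next
        is_case <- gr == "case"
        rows[[paste(co, gr)]] <- data.frame(
          subject_id = sprintf("%s_%s_%03d", co, substr(gr, 1, 4), seq_len(g$n)),
          cohort = co, group = gr,
          age = sample(seq(g$age[1], g$age[2]), g$n, replace = TRUE),
          sex = ifelse(stats::runif(g$n) < config$female_prop, "F", "M"),
          cmv = as.integer(stats::runif(g$n) < config$cmv_prev),
          hiv = as.integer(co == "hiv" & is_case),
          hcv = as.integer(co == "hcv" & is_case),
          timepoint = "none", stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) {
      return(data.frame(subject_id = character(), cohort = character(),
                        group = character(), age = integer(), sex = character(),
                        cmv = integer(), hiv = integer(), hcv = integer(),
                        timepoint = character(), stringsAsFactors = FALSE))
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}
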