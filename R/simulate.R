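#' @title Synthetic measurement generator
#' @description Simulates cross-sectional cohort measurements with planted
#'   linear driver effects and planted correlation-block structure, and
#'   longitudinal treatment-course measurements for the HCV cohort.
#' @name simulate
NULL

# Driver design columns used by the generator and by the regression stage:
# age enters as the within-cohort z-score (so planted age effects are in
# within-cohort SD units per SD of age), hiv/hcv as 0/1 indicators.
driver_columns <- function(subjects) {
  age_z <- stats::ave(as.numeric(subjects$age), subjects$cohort,
                      FUN = function(a) {
                        s <- stats::sd(a)
                        if (!is.finite(s) || s == 0) rep(0, length(a))
                        else (a - mean(a)) / s
                      })
  list(age = age_z, sex = as.numeric(subjects$sex == "F"),
       cmv = as.numeric(subjects$cmv), hiv = as.numeric(subjects$hiv),
       hcv = as.numeric(subjects$hcv))
}

#' Default planted driver effects
#'
#' Plants effects (in within-cohort SD units) that emulate the shared
#' signatures of chronic inflammation: memory T cell accumulation with naive
#' loss, elevated baseline STAT signaling, dampened sensitivity to IFN-alpha
#' (negative betas), plus driver-specific frequency and serum-protein shifts.
#' All three drivers hit the same nine functional domains so that the
#' cross-cohort overlap stage has a non-trivial shared region.
#'
#' @param panel feature panel from [generate_panel()]
#' @param beta effect magnitude in SD units
#' @return data.frame with columns feature_id, driver, beta
#' @export
default_effects <- function(panel = generate_panel(), beta = 1) {
  plant <- function(ids, driver, b) {
    ids <- intersect(ids, panel$feature_id)
    if (!length(ids)) return(NULL)
    data.frame(feature_id = ids, driver = driver, beta = b,
               stringsAsFactors = FALSE)
  }
  mem <- c("freq_CD4T_centralmemory", "freq_CD4T_effectormemory",
           "freq_CD8T_centralmemory", "freq_CD8T_effectormemory")
  nai <- c("freq_CD4T_naive", "freq_CD8T_naive")
  base_stat <- c("bs_pSTAT1_CD4T", "bs_pSTAT3_CD4T", "bs_pSTAT1_CD8T",
                 "bs_pSTAT3_CD8T", "bs_pSTAT1_Monocytes", "bs_pSTAT3_Monocytes")
  ifn_sens <- c("sr_IFNa_pSTAT1_CD4T", "sr_IFNa_pSTAT1_CD8T",
                "sr_IFNa_pSTAT1_B", "sr_IFNa_pSTAT1_Monocytes")
  shared <- function(driver) rbind(
    plant(mem, driver, beta), plant(nai, driver, -beta),
    plant(base_stat, driver, beta), plant(ifn_sens, driver, -beta),
    plant("serum_TNF-a", driver, beta))
  out <- rbind(
    shared("age"),
    plant(c("freq_NK_total", "freq_Monocytes_total"), "age", beta),
    plant(c("serum_IL-12p70", "serum_IL-18", "serum_IL-1b", "serum_IL-8",
            "serum_MIP-1b", "serum_SCF", "serum_IL-12p40"), "age", beta),
    plant("freq_gdT_total", "age", -beta),
    shared("hiv"),
    plant(c("freq_CD4T_total", "freq_CD4T_CD28", "freq_CD8T_CD28"), "hiv", -beta),
    shared("hcv"),
    plant(c("sr_IFNa_pSTAT1_NK", "sr_IFNa_pSTAT1_DC", "sr_IFNa_pSTAT1_gdT"),
          "hcv", -beta),
    # global baseline elevation of phosphorylated hubs across cell types
    plant(panel$feature_id[panel$modality == "baseline_signaling" &
                             panel$signaling_param %in%
                             c("pSTAT1", "pSTAT3", "pSTAT5", "pCREB", "pS6")],
          "hcv", beta),
    plant(c("bs_pSTAT4_Monocytes", "bs_pERK12_B", "bs_pERK12_Monocytes",
            "bs_pERK12_NK"), "hcv", -beta),
    plant(c("serum_IL-1RA", "serum_IP-10", "serum_RANTES", "serum_Resistin",
            "serum_VCAM-1", "serum_VEGF", "serum_VEGFD", "serum_IL-12p40"),
          "hcv", beta),
    plant(c("serum_EGF", "freq_gdT_total", "freq_CD4T_CD28", "freq_CD8T_CD28"),
          "hcv", -beta))
  out <- out[!duplicated(out[c("feature_id", "driver")]), ]
  rownames(out) <- NULL
  out
}

#' Default planted correlation-community structure
#'
#' Assigns the 84 baseline signaling nodes to four latent blocks reflecting
#' the coordinated pathway activity the network stage should recover:
#' pathogen-sensing/antiviral (IkBa, pIRF7), the STAT5-Akt axis, MAPK
#' (pERK1/2, pMAPKAPK2, pp38), and a joint proliferation/ STAT block
#' (pCREB, pS6, pSTAT1, pSTAT3, pSTAT4). Within-block loading `lambda`
#' gives expected within-block Pearson correlation lambda^2.
#'
#' @param panel feature panel
#' @param lambda factor loading in [0, 1]
#' @return data.frame with columns feature_id, block, lambda
#' @export
default_community_spec <- function(panel = generate_panel(), lambda = 0.8) {
  sig <- panel[panel$modality == "baseline_signaling", ]
  if (nrow(sig) == 0) {
    return(data.frame(feature_id = character(), block = character(),
                      lambda = numeric(), stringsAsFactors = FALSE))
  }
  block_of <- c(IkBa = "PSAV", pIRF7 = "PSAV",
                pSTAT5 = "STAT5-Akt", pAkt = "STAT5-Akt",
                pERK12 = "MAPK", pMAPKAPK2 = "MAPK", pp38 = "MAPK",
                pCREB = "PSD-STAT", pS6 = "PSD-STAT", pSTAT1 = "PSD-STAT",
                pSTAT3 = "PSD-STAT", pSTAT4 = "PSD-STAT")
  data.frame(feature_id = sig$feature_id,
             block = unname(block_of[sig$signaling_param]),
             lambda = lambda, stringsAsFactors = FALSE)
}

#' Simulate cross-sectional cohort measurements
#'
#' Each feature value is the sum of planted driver effects, an optional
#' shared latent block factor scaled by its loading, and Gaussian noise:
#' `y = sum(beta * driver) + lambda * f_block + sqrt(1 - lambda^2) * e`,
#' with `e ~ N(0, noise_sd^2)`. With `noise_sd = 1` every feature has unit
#' variance (before planted effects) and within-block pairwise correlation
#' `lambda^2`.
#'
#' @param subjects subject table from [generate_subjects()]
#' @param panel feature panel from [generate_panel()]
#' @param effects planted effects (feature_id, driver, beta) or NULL
#' @param community_spec block assignment (feature_id, block, lambda) or NULL
#' @param noise_sd Gaussian noise SD
#' @param seed integer seed
#' @return a [cohort_dataset()]
#' @export
simulate_measurements <- function(subjects, panel, effects = NULL,
                                  community_spec = NULL, noise_sd = 1,
                                  seed = 1) {
  n <- nrow(subjects); m <- nrow(panel)
  if (!is.null(community_spec) && nrow(community_spec)) {
    if (any(community_spec$lambda < 0 | community_spec$lambda > 1)) {
      config_error("community loading lambda must lie in [0, 1]")
    }
    bad <- setdiff(community_spec$feature_id, panel$feature_id)
    if (length(bad)) config_error("community_spec names unknown features: ",
                                  paste(utils::head(bad, 3), collapse = ", "))
  }
  if (!is.null(effects) && nrow(effects)) {
    bad <- setdiff(effects$feature_id, panel$feature_id)
    if (length(bad)) config_error("effects name unknown features: ",
                                  paste(utils::head(bad, 3), collapse = ", "))
    stopifnot(all(is.finite(effects$beta)),
              all(effects$driver %in% c("age", "hiv", "hcv")))
  }
  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * m, sd = noise_sd), n, m)
    if (!is.null(community_spec) && nrow(community_spec) && n > 0) {
      blocks <- unique(community_spec$block)
      fac <- matrix(stats::rnorm(n * length(blocks)), n, length(blocks),
                    dimnames = list(NULL, blocks))
      idx <- match(community_spec$feature_id, panel$feature_id)
      for (r in seq_along(idx)) {
        lam <- community_spec$lambda[r]
        Y[, idx[r]] <- lam * fac[, community_spec$block[r]] +
          sqrt(1 - lam^2) * Y[, idx[r]]
      }
    }
    if (!is.null(effects) && nrow(effects) && n > 0) {
      drv <- driver_columns(subjects)
      idx <- match(effects$feature_id, panel$feature_id)
      for (r in seq_along(idx)) {
        Y[, idx[r]] <- Y[, idx[r]] + effects$beta[r] * drv[[effects$driver[r]]]
      }
    }
    cohort_dataset(Y, subjects, panel)
  })
}

#' Treatment timepoint grid (weeks since treatment start)
#' @export
timepoint_weeks <- function() {
  c(pre = 0, wk1 = 1, wk2 = 2, wk4 = 4, wk8 = 8, wk12 = 12, post = 52)
}

#' Default features planted to improve after treatment
#'
#' Thirteen features: the pSTAT1 response to IFN-alpha in each of the seven
#' lineages, baseline IkBa in monocytes, the pSTAT1 response to IFN-gamma in
#' DCs, and four serum analytes (PAI-1, EGF, IP-10, IL-1RA).
#'
#' @param panel feature panel
#' @export
default_improved_features <- function(panel = generate_panel()) {
  ids <- c(paste0("sr_IFNa_pSTAT1_",
                  gsub(" ", "", default_cell_types())),
           "bs_IkBa_Monocytes", "sr_IFNg_pSTAT1_DC",
           "serum_PAI-1", "serum_EGF", "serum_IP-10", "serum_IL-1RA")
  intersect(ids, panel$feature_id)
}

#' Default longitudinal simulation settings
#'
#' Viral load decays exponentially from `vl0` at `decay_rate` per week and
#' is floored at the assay detection limit. DC stimulation responses receive
#' a transient pulse at week 2; the planted improved set shifts by
#' `improve_delta` SD at the post-treatment timepoint. `mid_lambda_scale`
#' attenuates the correlation-block loadings at on-treatment timepoints,
#' emulating the transient loss of network coordination during therapy.
#'
#' @param panel feature panel
#' @param lambda block loading for the baseline-signaling community structure
#' @return list of longitudinal settings
#' @export
default_longitudinal_spec <- function(panel = generate_panel(), lambda = 0.8) {
  list(vl0 = 1e6, decay_rate = 2, detection_limit = 15,
       pulse_features = "DC", pulse_amplitude = 1.0,
       improve_features = default_improved_features(panel),
       improve_delta = 1.5,
       community_spec = default_community_spec(panel, lambda = lambda),
       global_lambda = 0.4, mid_lambda_scale = 0.7,
       subject_sd = sqrt(0.5), noise_sd = sqrt(0.5))
}

#' Simulate the longitudinal HCV treatment course
#'
#' Generates the complete subject x timepoint panel over the grid
#' pre, wk1, wk2, wk4, wk8, wk12, post for the HCV-infected subjects, with
#' a subject-level random intercept (pairing pre/post observations), the
#' planted correlation-block structure on the baseline-signaling nodes, a
#' transient week-2 stimulation-response pulse in the configured lineages,
#' a planted post-treatment improvement in a small feature subset, and an
#' exponentially decaying viral-load table floored at the detection limit.
#' Baseline-signaling nodes additionally share a weak global coherence
#' factor (loading `global_lambda`), giving positive node-level median
#' correlations as in coordinated immune-signaling data; both block and
#' global loadings are attenuated by `mid_lambda_scale` while on treatment,
#' emulating the transient loss of network coordination during therapy.
#'
#' @param subjects subject table containing HCV-cohort cases
#' @param panel feature panel
#' @param spec settings from [default_longitudinal_spec()]
#' @param seed integer seed
#' @return a [cohort_dataset()] with one row per subject per timepoint and a
#'   `viral_load` table
#' @export
simulate_longitudinal_hcv <- function(subjects, panel,
                                      spec = default_longitudinal_spec(panel),
                                      seed = 1) {
  cases <- subjects[subjects$cohort == "hcv" & subjects$group == "case", ]
  if (nrow(cases) == 0) config_error("no HCV-cohort case subjects supplied")
  stopifnot(spec$vl0 > 0, spec$decay_rate > 0)
  bad <- setdiff(spec$improve_features, panel$feature_id)
  if (length(bad)) config_error("improve_features outside panel: ",
                                paste(utils::head(bad, 3), collapse = ", "))
  tps <- names(timepoint_weeks())
  wk <- timepoint_weeks()
  n <- nrow(cases); m <- nrow(panel); tn <- length(tps)
  long_subjects <- cases[rep(seq_len(n), times = tn), ]
  long_subjects$timepoint <- rep(tps, each = n)
  # infected at pre and on-treatment timepoints, cleared at post
  long_subjects$hcv <- as.integer(long_subjects$timepoint != "post")
  rownames(long_subjects) <- NULL

  cs <- spec$community_spec
  block_features <- if (is.null(cs)) character() else cs$feature_id
  is_block <- panel$feature_id %in% block_features
  pulse_idx <- which(panel$modality == "stim_response" &
                       panel$signaling_param == "pSTAT1" &
                       panel$stimulus == "IFNa" &
                       panel$cell_type %in% spec$pulse_features)
  improve_idx <- match(spec$improve_features, panel$feature_id)
  on_treatment <- c("wk1", "wk2", "wk4", "wk8", "wk12")

  with_seed(seed, {
    # subject-level intercepts for non-block features (pair pre/post samples)
    u <- matrix(stats::rnorm(n * m, sd = spec$subject_sd), n, m)
    u[, is_block] <- 0
    Y <- matrix(0, n * tn, m)
    for (t in seq_along(tps)) {
      rows <- (t - 1) * n + seq_len(n)
      eps <- matrix(stats::rnorm(n * m), n, m)
      Yt <- u + spec$noise_sd * eps
      if (!is.null(cs) && nrow(cs)) {
        lam_scale <- if (tps[t] %in% on_treatment) spec$mid_lambda_scale else 1
        lam_g <- (spec$global_lambda %||% 0) * lam_scale
        blocks <- unique(cs$block)
        fac <- matrix(stats::rnorm(n * length(blocks)), n, length(blocks),
                      dimnames = list(NULL, blocks))
        glob <- stats::rnorm(n)
        idx <- match(cs$feature_id, panel$feature_id)
        for (r in seq_along(idx)) {
          lam <- cs$lambda[r] * lam_scale
          if (lam^2 + lam_g^2 > 1) {
            config_error("block and global loadings exceed unit variance")
          }
          Yt[, idx[r]] <- lam * fac[, cs$block[r]] + lam_g * glob +
            sqrt(1 - lam^2 - lam_g^2) * stats::rnorm(n)
        }
      }
      if (tps[t] == "wk2" && length(pulse_idx)) {
        Yt[, pulse_idx] <- Yt[, pulse_idx] + spec$pulse_amplitude
      }
      if (tps[t] == "post" && length(improve_idx)) {
        Yt[, improve_idx] <- Yt[, improve_idx] + spec$improve_delta
      }
      Y[rows, ] <- Yt
    }
    vl <- data.frame(
      subject_id = rep(cases$subject_id, times = tn),
      timepoint = rep(tps, each = n),
      week = rep(unname(wk), each = n),
      viral_load = pmax(spec$vl0 * exp(-spec$decay_rate * rep(unname(wk), each = n)),
                        spec$detection_limit),
      stringsAsFactors = FALSE)
    cohort_dataset(Y, long_subjects, panel, viral_load = vl)
  })
}
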