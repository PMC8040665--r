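#' @title Immune feature panels
#' @description Constructors for the feature panel used throughout the
#'   pipeline: per-lineage phospho-signaling parameters at baseline and after
#'   ex vivo stimulation, cell-subset frequencies, and serum analytes.
#' @name panel
NULL

#' The seven PBMC lineages profiled by the phospho panel
#' @export
default_cell_types <- function() {
  c("CD4 T", "CD8 T", "gd T", "B", "NK", "Monocytes", "DC")
}

#' The twelve signaling parameters of the phospho panel
#' @export
default_signaling_params <- function() {
  c("pCREB", "pAkt", "pS6",                 # proliferation/survival/differentiation
    "IkBa", "pIRF7",                        # pathogen sensing / antiviral
    "pERK12", "pMAPKAPK2", "pp38",          # MAPK
    "pSTAT1", "pSTAT3", "pSTAT4", "pSTAT5") # STAT
}

#' Map signaling parameters to their pathway
#'
#' PSD = proliferation/survival/differentiation, PSAV = pathogen
#' sensing/antiviral, MAPK and STAT as usually defined.
#'
#' @param param character vector of signaling parameter names
#' @return character vector of pathway labels (PSD, PSAV, MAPK, STAT)
#' @export
signaling_pathway <- function(param) {
  map <- c(pCREB = "PSD", pAkt = "PSD", pS6 = "PSD",
           IkBa = "PSAV", pIRF7 = "PSAV",
           pERK12 = "MAPK", pMAPKAPK2 = "MAPK", pp38 = "MAPK",
           pSTAT1 = "STAT", pSTAT3 = "STAT", pSTAT4 = "STAT", pSTAT5 = "STAT")
  unknown <- setdiff(unique(param[!is.na(param) & param != "none"]), names(map))
  if (length(unknown) > 0) {
    config_error("unknown signaling parameter(s): ", paste(unknown, collapse = ", "))
  }
  out <- unname(map[param])
  out[is.na(param) | param == "none"] <- "none"
  out
}

default_stimuli <- function() c("IFNa", "IFNg")

# 63 serum analytes (Luminex-style panel): cytokines, chemokines, growth
# factors and the extra systemic proteins measured in the treatment cohort.
default_serum_analytes <- function() {
  c("IL-1b", "IL-1RA", "IL-2", "IL-4", "IL-5", "IL-6", "IL-7", "IL-8",
    "IL-10", "IL-12p40", "IL-12p70", "IL-13", "IL-15", "IL-17A", "IL-17F",
    "IL-18", "IL-21", "IL-22", "IL-23", "IL-27", "IL-31", "IFN-a", "IFN-b",
    "IFN-g", "TNF-a", "TNF-b", "GM-CSF", "G-CSF", "M-CSF", "EGF", "FGF-2",
    "HGF", "VEGF", "VEGFD", "PDGF-BB", "SCF", "TGF-a", "TGF-b", "LIF",
    "IP-10", "MCP-1", "MCP-3", "MIG", "MIP-1a", "MIP-1b", "RANTES",
    "Eotaxin", "GRO-a", "SDF-1a", "Fractalkine", "Leptin", "Resistin",
    "PAI-1", "ICAM-1", "VCAM-1", "CD40L", "FasL", "TRAIL", "NGF", "BDNF",
    "Amphiregulin", "Betacellulin", "ENA-78")
}

# Cell-subset frequency features: 42 subsets across the seven lineages.
default_freq_subsets <- function() {
  data.frame(
    cell_type = c(
      rep("CD4 T", 8), rep("CD8 T", 8), rep("B", 6), rep("NK", 5),
      rep("Monocytes", 5), rep("DC", 4), rep("gd T", 4), rep("CD4 T", 1),
      rep("CD8 T", 1)),
    subset = c(
      c("naive", "central memory", "effector memory", "TEMRA",
        "CD28+", "CD27+", "Treg", "total"),
      c("naive", "central memory", "effector memory", "TEMRA",
        "CD28+", "CD27+", "PD1+", "total"),
      c("naive", "memory", "transitional", "plasmablast", "IgD+CD27-", "total"),
      c("CD56bright", "CD56dim", "CD16+", "NKG2C+", "total"),
      c("classical", "intermediate", "nonclassical", "CD86+", "total"),
      c("mDC", "pDC", "CD86+", "total"),
      c("Vd1", "Vd2", "CD27+", "total"),
      "PD1+", "HLADR+"),
    stringsAsFactors = FALSE)
}

#' Generate the immune feature panel
#'
#' Enumerates the full cross product of cell types and signaling parameters
#' at baseline and per stimulus, plus cell-subset frequency and serum-protein
#' features. With defaults this yields 357 features: 84 baseline signaling
#' (12 parameters x 7 lineages), 168 stimulation responses (2 stimuli x 84),
#' 42 subset frequencies, and 63 serum analytes.
#'
#' @param cell_types lineage names (default the seven PBMC lineages)
#' @param signaling_params phospho-parameter names (default the twelve hubs)
#' @param stimuli stimuli for response features; empty vector for none
#' @param analytes serum analyte names; empty vector for none
#' @param freq_subsets data.frame with columns cell_type, subset; NULL for none
#' @param include_baseline include the baseline signaling block
#' @return data.frame of feature descriptors with columns feature_id,
#'   modality, cell_type, signaling_param, stimulus, analyte, subset, pathway
#' @export
generate_panel <- function(cell_types = default_cell_types(),
                           signaling_params = default_signaling_params(),
                           stimuli = default_stimuli(),
                           analytes = default_serum_analytes(),
                           freq_subsets = default_freq_subsets(),
                           include_baseline = TRUE) {
  signaling_pathway(signaling_params)  # validates parameter names
  blocks <- list()
  blank <- function(n) rep("none", n)
  if (include_baseline && length(cell_types) && length(signaling_params)) {
    g <- expand.grid(signaling_param = signaling_params, cell_type = cell_types,
                     stringsAsFactors = FALSE)
    blocks$baseline <- data.frame(
      feature_id = paste("bs", g$signaling_param, gsub(" ", "", g$cell_type), sep = "_"),
      modality = "baseline_signaling", cell_type = g$cell_type,
      signaling_param = g$signaling_param, stimulus = blank(nrow(g)),
      analyte = blank(nrow(g)), subset = blank(nrow(g)),
      stringsAsFactors = FALSE)
  }
  if (length(stimuli) && length(cell_types) && length(signaling_params)) {
    g <- expand.grid(signaling_param = signaling_params, cell_type = cell_types,
                     stimulus = stimuli, stringsAsFactors = FALSE)
    blocks$response <- data.frame(
      feature_id = paste("sr", g$stimulus, g$signaling_param,
                         gsub(" ", "", g$cell_type), sep = "_"),
      modality = "stim_response", cell_type = g$cell_type,
      signaling_param = g$signaling_param, stimulus = g$stimulus,
      analyte = blank(nrow(g)), subset = blank(nrow(g)),
      stringsAsFactors = FALSE)
  }
  if (!is.null(freq_subsets) && nrow(freq_subsets)) {
    bad <- setdiff(unique(freq_subsets$cell_type), cell_types)
    if (length(bad)) config_error("freq subsets name unknown cell types: ",
                                  paste(bad, collapse = ", "))
    blocks$freq <- data.frame(
      feature_id = paste("freq", gsub(" ", "", freq_subsets$cell_type),
                         gsub("[ +]", "", freq_subsets$subset), sep = "_"),
      modality = "cell_frequency", cell_type = freq_subsets$cell_type,
      signaling_param = blank(nrow(freq_subsets)),
      stimulus = blank(nrow(freq_subsets)), analyte = blank(nrow(freq_subsets)),
      subset = freq_subsets$subset, stringsAsFactors = FALSE)
  }
  if (length(analytes)) {
    blocks$serum <- data.frame(
      feature_id = paste("serum", gsub("[ /]", "", analytes), sep = "_"),
      modality = "serum_protein", cell_type = blank(length(analytes)),
      signaling_param = blank(length(analytes)),
      stimulus = blank(length(analytes)), analyte = analytes,
      subset = blank(length(analytes)), stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, c(blocks, list(make.row.names = FALSE)))
  if (is.null(panel)) {
    panel <- data.frame(feature_id = character(), modality = character(),
                        cell_type = character(), signaling_param = character(),
                        stimulus = character(), analyte = character(),
                        subset = character(), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(panel$feature_id)) {
    config_error("duplicate feature_id in panel: ",
                 paste(unique(panel$feature_id[duplicated(panel$feature_id)]),
                       collapse = ", "))
  }
  panel$pathway <- signaling_pathway(panel$signaling_param)
  panel
}
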