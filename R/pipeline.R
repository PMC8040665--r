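#' Default pipeline configuration
#'
#' Stage parameters default to the study-scale analysis settings: 1000
#' regression permutations with FDR < 0.2 selection, SAM FDR < 0.01 with
#' 1000 sign-flip permutations, |rho| >= 0.5 network edges with top-20%
#' hub/bottleneck rules and 10000 robustness permutations, and a gap-statistic
#' scan up to k = 10 with 100 reference datasets.
#'
#' @param seed master seed; all stage randomness is derived from it
#' @return nested configuration list
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(noise_sd = 1, lambda = 0.8, beta = 1),
    regress = list(n_perm = 1000, fdr = 0.2,
                   drivers = c("age", "sex", "cmv", "hiv", "hcv")),
    cluster = list(kmax = 10, B = 100, metric = "euclidean",
                   linkage = "average"),
    sam = list(n_perm = 1000, fdr = 0.01, pre = "pre", post = "post"),
    network = list(threshold = 0.5, n_perm = 10000,
                   timepoints = c(pre = "pre", mid = "wk4", post = "post"),
                   resolution = 1.0, n_restarts = 10, top_frac = 0.2),
    kinetics = list(stimulus = "IFNa", param = "pSTAT1"))
}

stage_simulate <- function(config, outdir) {
  seed <- config$seed
  sim <- config$simulate
  subjects <- generate_subjects(seed = derive_seed(seed, "simulate", "subjects"))
  panel <- generate_panel()
  if (nrow(panel) == 0) config_error("empty feature panel")
  effects <- default_effects(panel, beta = sim$beta)
  community <- default_community_spec(panel, lambda = sim$lambda)
  cross <- simulate_measurements(subjects, panel, effects, community,
                                 noise_sd = sim$noise_sd,
                                 seed = derive_seed(seed, "simulate", "cross"))
  lspec <- default_longitudinal_spec(panel, lambda = sim$lambda)
  long <- simulate_longitudinal_hcv(subjects, panel, lspec,
                                    seed = derive_seed(seed, "simulate", "long"))
  f1 <- write_dataset(cross, file.path(outdir, "cross_sectional"))
  f2 <- write_dataset(long, file.path(outdir, "longitudinal"))
  truth <- file.path(outdir, "truth.tsv")
  write_tsv(effects, truth)
  improved <- file.path(outdir, "truth_improved.tsv")
  write_tsv(data.frame(feature_id = lspec$improve_features), improved)
  c(f1, f2, truth = truth, improved = improved)
}

stage_regress <- function(config, outdir) {
  cross <- read_dataset(file.path(outdir, "cross_sectional"))
  rg <- config$regress
  res <- cohort_regression(cross, drivers = rg$drivers, n_perm = rg$n_perm,
                           fdr_threshold = rg$fdr,
                           seed = derive_seed(config$seed, "regress"))
  path <- file.path(outdir, "regression_results.tsv")
  write_tsv(res, path)
  c(regression = path)
}

stage_domains <- function(config, outdir) {
  features <- read_tsv(file.path(outdir, "cross_sectional", "features.tsv"))
  for (col in names(features)) features[[col]][is.na(features[[col]])] <- "none"
  res <- read_tsv(file.path(outdir, "regression_results.tsv"))
  domains_map <- data.frame(feature_id = features$feature_id,
                            domain = assign_domain(features),
                            stringsAsFactors = FALSE)
  sig <- significant_domains(res, domains_map)
  ov <- domain_overlap(sig)
  shared <- strsplit(ov$regions$members[ov$regions$region == "age_hiv_hcv"],
                     "; ")[[1]]
  shared <- shared[shared != ""]
  eff <- shared_effect_table(res, domains_map, shared)
  paths <- c(domains = file.path(outdir, "domains.tsv"),
             overlap = file.path(outdir, "overlap.tsv"),
             shared = file.path(outdir, "shared_effects.tsv"))
  write_tsv(domains_map, paths["domains"])
  write_tsv(ov$regions, paths["overlap"])
  write_tsv(eff, paths["shared"])
  paths
}

stage_cluster <- function(config, outdir) {
  cross <- read_dataset(file.path(outdir, "cross_sectional"))
  cl <- config$cluster
  hcv_rows <- cross$subjects$cohort == "hcv"
  sig_cols <- cross$features$modality == "baseline_signaling"
  ds <- subset_dataset(cross, hcv_rows, sig_cols)
  ds <- znormalize_within_cohort(ds)
  mat <- ds$measurements
  tree <- hierarchical_cluster(mat, metric = cl$metric, linkage = cl$linkage)
  kmax <- min(cl$kmax, nrow(mat) - 1)
  gap <- gap_statistic(mat, kmax = kmax, B = cl$B,
                       seed = derive_seed(config$seed, "cluster"),
                       metric = cl$metric, linkage = cl$linkage)
  chosen <- attr(gap, "chosen_k")
  k_enrich <- max(chosen, 2)
  labels <- tree$labels_at_k(k_enrich)
  enr <- hypergeom_enrichment(ds$subjects$group, labels)
  clusters <- data.frame(sample_id = rownames(mat),
                         group = ds$subjects$group, cluster = labels,
                         stringsAsFactors = FALSE)
  gap_df <- as.data.frame(gap)
  gap_df$chosen_k <- chosen
  paths <- c(clusters = file.path(outdir, "clusters.tsv"),
             gap = file.path(outdir, "gap.tsv"),
             enrichment = file.path(outdir, "cluster_enrichment.tsv"))
  write_tsv(clusters, paths["clusters"])
  write_tsv(gap_df, paths["gap"])
  write_tsv(enr, paths["enrichment"])
  paths
}

stage_sam <- function(config, outdir) {
  long <- read_dataset(file.path(outdir, "longitudinal"))
  sm <- config$sam
  diffs <- paired_differences(long, pre = sm$pre, post = sm$post)
  sam <- signflip_fdr(diffs, n_perm = sm$n_perm, fdr_threshold = sm$fdr,
                      seed = derive_seed(config$seed, "sam"))
  paths <- c(sam = file.path(outdir, "sam_results.tsv"),
             fdr = file.path(outdir, "sam_fdr.tsv"))
  write_tsv(sam$stats, paths["sam"])
  write_tsv(sam$fdr_table, paths["fdr"])
  paths
}

stage_network <- function(config, outdir) {
  long <- read_dataset(file.path(outdir, "longitudinal"))
  nw <- config$network
  sig_cols <- long$features$modality == "baseline_signaling"
  features <- long$features[sig_cols, , drop = FALSE]
  networks <- list()
  corrs <- list()
  node_rows <- list()
  enrich_rows <- list()
  paths <- character()
  for (nm in names(nw$timepoints)) {
    tp <- nw$timepoints[[nm]]
    rows <- long$subjects$timepoint == tp
    mat <- long$measurements[rows, sig_cols, drop = FALSE]
    rho <- spearman_matrix(mat)
    corrs[[nm]] <- rho
    net <- build_network(rho, threshold = nw$threshold, timepoint = tp)
    net <- node_centralities(net)
    net <- classify_roles(net, frac = nw$top_frac)
    net <- detect_communities(net, resolution = nw$resolution,
                              n_restarts = nw$n_restarts,
                              seed = derive_seed(config$seed, "network", nm))
    networks[[nm]] <- net
    ann <- data.frame(node = features$feature_id,
                      cell_type = features$cell_type,
                      signaling_param = features$signaling_param,
                      pathway = features$pathway, stringsAsFactors = FALSE)
    gml <- file.path(outdir, paste0("network_", nm, ".graphml"))
    write_network_graphml(net, gml, annotations = ann)
    paths[paste0("graphml_", nm)] <- gml
    nd <- net$nodes
    nd$timepoint <- nm
    nd$modularity <- net$modularity
    node_rows[[nm]] <- nd
    for (cat_col in c("signaling_param", "pathway")) {
      for (subset_name in c("hub", "bottleneck")) {
        mask <- net$nodes[[subset_name]]
        if (!any(mask)) next
        er <- category_enrichment(net, ann[[cat_col]], mask)
        er$timepoint <- nm
        er$node_subset <- subset_name
        er$category_type <- cat_col
        enrich_rows[[paste(nm, cat_col, subset_name)]] <- er
      }
    }
  }
  rob <- robustness_test(corrs, n_perm = nw$n_perm,
                         seed = derive_seed(config$seed, "network", "robust"))
  topo <- topology_over_time(networks)
  paths["nodes"] <- file.path(outdir, "network_nodes.tsv")
  paths["enrichment"] <- file.path(outdir, "network_enrichment.tsv")
  paths["robustness"] <- file.path(outdir, "robustness.tsv")
  paths["topology"] <- file.path(outdir, "network_topology.tsv")
  paths["topo_tests"] <- file.path(outdir, "network_topology_tests.tsv")
  write_tsv(do.call(rbind, c(node_rows, list(make.row.names = FALSE))),
            paths["nodes"])
  write_tsv(do.call(rbind, c(enrich_rows, list(make.row.names = FALSE))),
            paths["enrichment"])
  write_tsv(rob$per_node, paths["robustness"])
  write_tsv(topo$summary, paths["topology"])
  write_tsv(topo$tests, paths["topo_tests"])
  paths
}

stage_kinetics <- function(config, outdir) {
  long <- read_dataset(file.path(outdir, "longitudinal"))
  cross <- read_dataset(file.path(outdir, "cross_sectional"))
  kn <- config$kinetics
  resp_cols <- long$features$modality == "stim_response" &
    long$features$stimulus == kn$stimulus &
    long$features$signaling_param == kn$param
  feat <- long$features[resp_cols, , drop = FALSE]
  mat <- long$measurements[, resp_cols, drop = FALSE]
  responses <- data.frame(
    subject_id = rep(long$subjects$subject_id, times = ncol(mat)),
    timepoint = rep(long$subjects$timepoint, times = ncol(mat)),
    cell_type = rep(feat$cell_type, each = nrow(mat)),
    value = as.vector(mat), stringsAsFactors = FALSE)
  # young controls from the aging cohort as the reference population
  young_rows <- cross$subjects$cohort == "aging" &
    cross$subjects$group == "control"
  cross_cols <- match(feat$feature_id, cross$features$feature_id)
  young_mat <- cross$measurements[young_rows, cross_cols, drop = FALSE]
  reference <- data.frame(cell_type = feat$cell_type,
                          mean = colMeans(young_mat),
                          sd = apply(young_mat, 2, stats::sd),
                          stringsAsFactors = FALSE)
  traj <- trajectory_summary(responses)
  traj_ref <- trajectory_summary(responses, reference = reference)
  traj$scale <- "response"
  traj_ref$scale <- "young_reference_z"
  tests <- list()
  for (ct in unique(feat$cell_type)) {
    sub <- responses[responses$cell_type == ct &
                       responses$timepoint %in% c("pre", "post"), ]
    tests[[paste(ct, "paired")]] <- cbind(
      cell_type = ct,
      group_comparisons(sub, value = "value", group = "timepoint",
                        test = "wilcoxon_signed_rank",
                        label = paste0(ct, ": pre vs post")))
    # cross-cohort comparison at baseline (Kruskal-Wallis)
    ccol <- cross_cols[feat$cell_type == ct]
    kw <- data.frame(value = cross$measurements[, ccol],
                     group = paste(cross$subjects$cohort,
                                   cross$subjects$group, sep = "_"),
                     stringsAsFactors = FALSE)
    tests[[paste(ct, "kw")]] <- cbind(
      cell_type = ct,
      group_comparisons(kw, value = "value", group = "group",
                        test = "kruskal_wallis",
                        label = paste0(ct, ": across cohorts")))
  }
  paths <- c(trajectories = file.path(outdir, "trajectories.tsv"),
             tests = file.path(outdir, "group_tests.tsv"))
  write_tsv(rbind(traj, traj_ref), paths["trajectories"])
  write_tsv(do.call(rbind, c(tests, list(make.row.names = FALSE))),
            paths["tests"])
  paths
}

#' Run the full analysis pipeline
#'
#' Executes simulate, regress, domains, cluster, sam, network and kinetics
#' in order. Every stage reads its inputs from files under `outdir` written
#' by earlier stages, so any stage can be re-run standalone with identical
#' results. All randomness derives from the master seed through per-stage
#' substreams. A run manifest (config hash, seed, per-stage outputs and
#' wall-clock) is written as run_manifest.json.
#'
#' @param config configuration list from [default_config()]
#' @param outdir output directory
#' @param stages character vector of stages to run (default all)
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(config = default_config(), outdir,
                         stages = c("simulate", "regress", "domains",
                                    "cluster", "sam", "network", "kinetics")) {
  stopifnot(!missing(outdir))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  all_stages <- list(simulate = stage_simulate, regress = stage_regress,
                     domains = stage_domains, cluster = stage_cluster,
                     sam = stage_sam, network = stage_network,
                     kinetics = stage_kinetics)
  unknown <- setdiff(stages, names(all_stages))
  if (length(unknown)) config_error("unknown stage(s): ",
                                    paste(unknown, collapse = ", "))
  if (!("simulate" %in% stages) &&
      !dir.exists(file.path(outdir, "cross_sectional"))) {
    config_error("input tables missing and no simulate stage requested")
  }
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  manifest <- list(config_hash = cfg_hash, seed = config$seed,
                   package_version = as.character(utils::packageVersion("immunosig")),
                   stages = list())
  for (st in intersect(names(all_stages), stages)) {
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(all_stages[[st]](config, outdir),
                      error = function(e) {
                        stop("stage '", st, "' failed: ", conditionMessage(e),
                             call. = FALSE)
                      })
    manifest$stages[[st]] <- list(
      outputs = unname(files),
      seconds = round(proc.time()[["elapsed"]] - t0, 2))
  }
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
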