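#' Spearman correlation matrix over signaling nodes
#'
#' Rank-based correlation with average ranks for ties, pairwise complete
#' observations. Constant node features get missing correlations (and will
#' be isolated in the thresholded network).
#'
#' @param mat subjects x nodes numeric matrix
#' @param min_subjects minimum number of rows required
#' @return symmetric correlation matrix with unit diagonal
#' @export
spearman_matrix <- function(mat, min_subjects = 4) {
  mat <- as.matrix(mat)
  if (nrow(mat) < min_subjects) {
    config_error("need >= ", min_subjects, " subjects for correlation")
  }
  constant <- apply(mat, 2, function(x) stats::sd(x, na.rm = TRUE) == 0)
  if (any(constant, na.rm = TRUE)) {
    message("constant node feature(s) isolated: ",
            paste(utils::head(colnames(mat)[which(constant)], 5), collapse = ", "))
  }
  rho <- suppressWarnings(
    stats::cor(mat, method = "spearman", use = "pairwise.complete.obs"))
  diag(rho) <- 1
  rho
}

#' Build a thresholded signaling network
#'
#' Undirected edge (i, j) iff `|rho_ij| >= threshold`, carrying the signed
#' correlation as weight. Node degree is the incident-edge count and node
#' strength the sum of |rho| over incident edges.
#'
#' @param corr symmetric correlation matrix
#' @param threshold edge threshold in (0, 1]
#' @param timepoint optional label stored on the network
#' @return object of class `signaling_network` with `graph` (igraph),
#'   `nodes` (metrics data.frame), `corr`, `threshold`, `timepoint`
#' @export
build_network <- function(corr, threshold = 0.5, timepoint = NA_character_) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    config_error("threshold must lie in (0, 1]")
  }
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) ||
      !isTRUE(all.equal(corr, t(corr), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    config_error("correlation matrix must be symmetric")
  }
  if (is.null(rownames(corr))) {
    rownames(corr) <- colnames(corr) <- paste0("node", seq_len(nrow(corr)))
  }
  adj <- abs(corr) >= threshold
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = nrow(corr), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rownames(corr))
  if (nrow(idx)) {
    g <- igraph::add_edges(g, rbind(idx[, 1], idx[, 2]))
    igraph::E(g)$rho <- corr[idx]
    igraph::E(g)$weight <- abs(corr[idx])
  }
  nodes <- data.frame(
    node = rownames(corr),
    degree = as.numeric(igraph::degree(g)),
    strength = if (nrow(idx)) {
      as.numeric(igraph::strength(g, weights = abs(igraph::E(g)$rho)))
    } else 0,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(graph = g, nodes = nodes, corr = corr,
                 threshold = threshold, timepoint = timepoint),
            class = "signaling_network")
}

#' @export
print.signaling_network <- function(x, ...) {
  cat("signaling_network", if (!is.na(x$timepoint)) paste0("[", x$timepoint, "]"),
      ":", nrow(x$nodes), "nodes,", igraph::ecount(x$graph),
      "edges (|rho| >=", x$threshold, ")\n")
  invisible(x)
}

#' Betweenness and eccentricity per node
#'
#' Betweenness counts unordered source-target pairs whose shortest paths
#' pass through the node, with fractional credit shared among multiple
#' shortest paths; eccentricity is the maximum geodesic distance within the
#' node's connected component. Shortest paths are unweighted by default; the
#' optional weighted mode uses `1 - |rho|` edge lengths.
#'
#' @param network a `signaling_network`
#' @param weighted use 1 - |rho| edge distances instead of hop counts
#' @return the network with `betweenness` and `eccentricity` node columns
#' @export
node_centralities <- function(network, weighted = FALSE) {
  g <- network$graph
  if (igraph::ecount(g) > 0 && "weight" %in% igraph::edge_attr_names(g)) {
    # geodesics are hop counts by default; weighted mode uses 1 - |rho|
    igraph::E(g)$weight <- if (weighted) 1 - abs(igraph::E(g)$rho) else 1
  }
  btw <- igraph::betweenness(g, directed = FALSE)
  ecc <- rep(0, igraph::vcount(g))
  comp <- igraph::components(g)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    if (length(members) < 2) next
    sub <- igraph::induced_subgraph(g, members)
    ecc[members] <- igraph::eccentricity(sub)
  }
  network$nodes$betweenness <- as.numeric(btw)
  network$nodes$eccentricity <- as.numeric(ecc)
  network
}

# top ceiling(frac * N) nodes by a metric, boundary ties included;
# an all-equal metric classifies nobody
top_fraction <- function(values, frac = 0.2) {
  n <- length(values)
  if (length(unique(values)) < 2) return(rep(FALSE, n))
  k <- ceiling(frac * n)
  cutoff <- sort(values, decreasing = TRUE)[k]
  values >= cutoff
}

#' Hub / bottleneck role classification
#'
#' Hubs are the top 20% of nodes by degree and bottlenecks the top 20% by
#' betweenness centrality (boundary ties all included). Roles cross-classify
#' as H-B, H-NB, NH-B, NH-NB.
#'
#' @param network a `signaling_network` with centralities computed
#' @param frac top fraction defining hubs and bottlenecks
#' @return the network with logical `hub`, `bottleneck` and character `role`
#'   node columns
#' @export
classify_roles <- function(network, frac = 0.2) {
  if (nrow(network$nodes) == 0) config_error("empty network")
  if (is.null(network$nodes$betweenness)) {
    network <- node_centralities(network)
  }
  hub <- top_fraction(network$nodes$degree, frac)
  bott <- top_fraction(network$nodes$betweenness, frac)
  network$nodes$hub <- hub
  network$nodes$bottleneck <- bott
  network$nodes$role <- ifelse(hub & bott, "H-B",
                               ifelse(hub, "H-NB",
                                      ifelse(bott, "NH-B", "NH-NB")))
  network
}

#' Louvain community detection with restarts
#'
#' Modularity maximization on |rho| edge weights; the best partition over
#' `n_restarts` random vertex orders is kept. An edgeless network puts every
#' node in its own community with Q = 0.
#'
#' @param network a `signaling_network`
#' @param resolution Louvain resolution parameter
#' @param n_restarts random restarts
#' @param seed integer seed
#' @return the network with a `community` node column plus `modularity` and
#'   `community_composition` elements
#' @export
detect_communities <- function(network, resolution = 1.0, n_restarts = 10,
                               seed = 1) {
  g <- network$graph
  nv <- igraph::vcount(g)
  if (igraph::ecount(g) == 0) {
    network$nodes$community <- seq_len(nv)
    network$modularity <- 0
  } else {
    w <- abs(igraph::E(g)$rho)
    n_neg <- sum(igraph::E(g)$rho < 0)
    if (n_neg > 0) {
      message(n_neg, " negative edge(s) enter modularity via |rho|")
    }
    best_q <- -Inf
    best_members <- NULL
    with_seed(seed, {
      for (r in seq_len(n_restarts)) {
        perm <- sample.int(nv)
        gp <- igraph::permute(g, perm)
        cl <- igraph::cluster_louvain(gp, weights = abs(igraph::E(gp)$rho),
                                      resolution = resolution)
        mem <- igraph::membership(cl)[perm]  # back to original order
        q <- igraph::modularity(g, mem, weights = w)
        if (q > best_q + 1e-12) {
          best_q <- q
          best_members <- mem
        }
      }
    })
    # stable labels: communities numbered by first appearance
    network$nodes$community <- match(best_members, unique(best_members))
    network$modularity <- best_q
  }
  sizes <- table(network$nodes$community)
  network$community_composition <- data.frame(
    community = as.integer(names(sizes)),
    size = as.integer(sizes),
    composition_pct = 100 * as.integer(sizes) / nv,
    row.names = NULL, stringsAsFactors = FALSE)
  network
}

#' Category enrichment of a node subset
#'
#' Upper-tail hypergeometric enrichment of node categories (signaling
#' parameter or pathway labels) within hubs, bottlenecks, or a community,
#' against the full node universe.
#'
#' @param network a `signaling_network`
#' @param categories character vector of category labels, one per node
#' @param subset logical/character selection of nodes (names or mask)
#' @return data.frame as from [hypergeom_enrichment()] restricted to the
#'   subset "cluster"
#' @export
category_enrichment <- function(network, categories, subset) {
  nodes <- network$nodes$node
  if (length(categories) != length(nodes)) {
    config_error("categories must cover all ", length(nodes), " nodes")
  }
  if (is.character(subset)) {
    if (!all(subset %in% nodes)) config_error("subset not contained in nodes")
    mask <- nodes %in% subset
  } else {
    mask <- as.logical(subset)
  }
  if (!any(mask)) config_error("empty node subset")
  res <- hypergeom_enrichment(categories, ifelse(mask, "subset", "rest"))
  res[res$cluster == "subset", , drop = FALSE]
}

#' Cross-timepoint robustness of node coordination
#'
#' For each node v and timepoint t, `m_t(v)` is the median correlation of v
#' with all other nodes. For each timepoint pair the observed change is
#' `delta_obs(v) = |m_t1(v) - m_t2(v)|`; the null permutes the
#' node-to-median assignment independently within each timepoint `n_perm`
#' times, and `p(v)` is the proportion of null changes at least as large as
#' the observed one.
#'
#' @param corr_list named list (by timepoint) of correlation matrices over
#'   the same nodes
#' @param n_perm number of permutations (study-scale default 10000)
#' @param seed integer seed
#' @return list of class `robustness_report`: `per_node` data.frame (pair,
#'   node, m_t1, m_t2, delta_obs, p), `fraction_significant` at p < 0.05
#' @export
robustness_test <- function(corr_list, n_perm = 10000, seed = 1) {
  if (length(corr_list) < 2) config_error("need >= 2 timepoints")
  nodesets <- lapply(corr_list, rownames)
  if (!all(vapply(nodesets, identical, TRUE, nodesets[[1]]))) {
    config_error("mismatched node sets across timepoints")
  }
  nodes <- nodesets[[1]]
  nn <- length(nodes)
  med <- vapply(corr_list, function(cm) {
    diag(cm) <- NA
    apply(cm, 1, stats::median, na.rm = TRUE)
  }, numeric(nn))
  tps <- names(corr_list)
  pairs <- utils::combn(tps, 2, simplify = FALSE)
  rows <- list()
  with_seed(seed, {
    for (pr in pairs) {
      m1 <- med[, pr[1]]; m2 <- med[, pr[2]]
      delta_obs <- abs(m1 - m2)
      exceed <- integer(nn)
      for (b in seq_len(n_perm)) {
        dn <- abs(m1[sample.int(nn)] - m2[sample.int(nn)])
        exceed <- exceed + (dn >= delta_obs)
      }
      rows[[paste(pr, collapse = "_vs_")]] <- data.frame(
        pair = paste(pr, collapse = "_vs_"), node = nodes,
        m_t1 = m1, m_t2 = m2, delta_obs = delta_obs,
        p = exceed / n_perm, row.names = NULL, stringsAsFactors = FALSE)
    }
  })
  per_node <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(list(per_node = per_node, n_perm = n_perm,
                 fraction_significant = mean(per_node$p < 0.05)),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("robustness_report:", length(unique(x$per_node$node)), "nodes,",
      length(unique(x$per_node$pair)), "timepoint pair(s),",
      x$n_perm, "permutations\n")
  cat("  fraction of node changes significant at p < 0.05:",
      round(100 * x$fraction_significant, 1), "%\n")
  invisible(x)
}

#' Topology summaries across timepoints
#'
#' Median and IQR of degree, strength, betweenness and eccentricity per
#' timepoint, plus pairwise Wilcoxon rank-sum comparisons between
#' timepoints for each metric. Single-node networks yield no tests.
#'
#' @param networks named list of `signaling_network`s (with centralities)
#' @return list with `summary` and `tests` data.frames
#' @export
topology_over_time <- function(networks) {
  if (length(networks) < 2) config_error("need >= 2 timepoints")
  metrics <- c("degree", "strength", "betweenness", "eccentricity")
  networks <- lapply(networks, function(nw) {
    if (is.null(nw$nodes$betweenness)) node_centralities(nw) else nw
  })
  summ <- list(); tests <- list()
  for (tp in names(networks)) {
    nd <- networks[[tp]]$nodes
    for (mt in metrics) {
      v <- nd[[mt]]
      summ[[paste(tp, mt)]] <- data.frame(
        timepoint = tp, metric = mt, median = stats::median(v),
        q1 = unname(stats::quantile(v, 0.25)),
        q3 = unname(stats::quantile(v, 0.75)),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  tps <- names(networks)
  if (nrow(networks[[1]]$nodes) > 1) {
    for (pr in utils::combn(tps, 2, simplify = FALSE)) {
      for (mt in metrics) {
        v1 <- networks[[pr[1]]]$nodes[[mt]]
        v2 <- networks[[pr[2]]]$nodes[[mt]]
        p <- if (stats::sd(c(v1, v2)) == 0) 1 else
          suppressWarnings(stats::wilcox.test(v1, v2)$p.value)
        tests[[paste(pr[1], pr[2], mt)]] <- data.frame(
          t1 = pr[1], t2 = pr[2], metric = mt, p = p,
          row.names = NULL, stringsAsFactors = FALSE)
      }
    }
  }
  list(summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
       tests = if (length(tests))
         do.call(rbind, c(tests, list(make.row.names = FALSE)))
       else data.frame(t1 = character(), t2 = character(),
                       metric = character(), p = numeric()))
}

#' Export a signaling network as GraphML
#'
#' Node attributes (degree, strength, betweenness, eccentricity, role,
#' community and any supplied annotation) and the signed edge correlation
#' are carried on the graph.
#'
#' @param network a `signaling_network`
#' @param file output path (.graphml)
#' @param annotations optional data.frame of extra node columns (must
#'   include `node`)
#' @export
write_network_graphml <- function(network, file, annotations = NULL) {
  g <- network$graph
  nd <- network$nodes
  if (!is.null(annotations)) {
    nd <- merge(nd, annotations, by = "node", sort = FALSE)
    nd <- nd[match(network$nodes$node, nd$node), , drop = FALSE]
  }
  for (col in setdiff(names(nd), "node")) {
    g <- igraph::set_vertex_attr(g, col, value = nd[[col]])
  }
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}
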