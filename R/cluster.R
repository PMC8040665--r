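#' Agglomerative hierarchical clustering
#'
#' Thin, validated wrapper around [stats::hclust()] on a
#' [stats::dist()] matrix, returning a tree that can be cut at any k.
#'
#' @param mat numeric matrix, rows are the objects to cluster
#' @param metric distance metric for [stats::dist()]
#' @param linkage agglomeration method for [stats::hclust()]
#' @return object of class `cluster_tree` with elements `hclust`, `metric`,
#'   `linkage`, and `labels_at_k(k)`
#' @export
hierarchical_cluster <- function(mat, metric = "euclidean",
                                 linkage = "average") {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) config_error("need at least 2 rows to cluster")
  d <- stats::dist(mat, method = metric)
  if (anyNA(d)) {
    dm <- as.matrix(d)
    bad <- rownames(dm)[unique(which(is.na(dm), arr.ind = TRUE)[, 1])]
    if (is.null(bad)) bad <- unique(which(is.na(dm), arr.ind = TRUE)[, 1])
    stop("non-finite distances involving row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, metric = metric, linkage = linkage,
                 labels_at_k = function(k) stats::cutree(hc, k = k)),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("cluster_tree:", length(x$hclust$order), "objects,",
      x$linkage, "linkage,", x$metric, "distance\n")
  invisible(x)
}

# Pooled within-cluster dispersion W_k = sum_r D_r / (2 n_r), with D_r the
# sum of pairwise squared Euclidean distances inside cluster r. Equivalent
# to the total within-cluster sum of squares about cluster centroids.
within_dispersion <- function(mat, labels) {
  w <- 0
  for (cl in unique(labels)) {
    rows <- mat[labels == cl, , drop = FALSE]
    if (nrow(rows) < 2) next
    w <- w + sum(stats::dist(rows)^2) / nrow(rows)
  }
  w
}

#' Gap statistic for the number of clusters
#'
#' Compares log within-cluster dispersion against its expectation under B
#' reference datasets drawn uniformly over each feature's observed range.
#' `Gap(k) = E*[log W_k] - log W_k`; the chosen k is the smallest k with
#' `Gap(k) >= Gap(k+1) - s_{k+1}`, where `s_k` is the reference SD times
#' `sqrt(1 + 1/B)`. Clustering of both the data and the references uses the
#' same hierarchical tree cut (metric/linkage as supplied).
#'
#' @param mat numeric matrix of objects x features
#' @param kmax largest number of clusters to consider (must be < nrow)
#' @param B number of reference datasets
#' @param seed integer seed for the reference draws
#' @param metric,linkage passed to [hierarchical_cluster()]
#' @param reference "uniform" draws over feature ranges; "pca" rotates to
#'   principal axes first (Tibshirani's method b)
#' @return object of class `gap_curve`: data.frame with k, logW, ElogW, gap,
#'   s, plus attribute `chosen_k`
#' @export
gap_statistic <- function(mat, kmax, B = 100, seed = 1,
                          metric = "euclidean", linkage = "average",
                          reference = c("uniform", "pca")) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (kmax < 1 || kmax >= n) config_error("kmax must satisfy 1 <= kmax < n")
  if (B < 10) config_error("need B >= 10 reference datasets")
  reference <- match.arg(reference)
  logW_at <- function(x) {
    tree <- hierarchical_cluster(x, metric, linkage)
    vapply(seq_len(kmax), function(k) {
      log(max(within_dispersion(x, tree$labels_at_k(k)), .Machine$double.xmin))
    }, numeric(1))
  }
  logW <- logW_at(mat)
  if (reference == "pca") {
    ctr <- scale(mat, center = TRUE, scale = FALSE)
    v <- svd(ctr, nu = 0)$v
    box <- ctr %*% v
  } else {
    box <- mat
  }
  lo <- apply(box, 2, min); hi <- apply(box, 2, max)
  ref_logW <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      ref <- sapply(seq_along(lo), function(j) stats::runif(n, lo[j], hi[j]))
      if (reference == "pca") ref <- ref %*% t(v)
      logW_at(ref)
    }, numeric(kmax))
  })
  ElogW <- rowMeans(ref_logW)
  s <- apply(ref_logW, 1, stats::sd) * sqrt(1 + 1 / B)
  gap <- ElogW - logW
  chosen <- kmax
  for (k in seq_len(kmax - 1)) {
    if (gap[k] >= gap[k + 1] - s[k + 1]) { chosen <- k; break }
  }
  out <- data.frame(k = seq_len(kmax), logW = logW, ElogW = ElogW,
                    gap = gap, s = s)
  attr(out, "chosen_k") <- chosen
  class(out) <- c("gap_curve", class(out))
  out
}

#' @export
print.gap_curve <- function(x, ...) {
  cat("gap_curve (chosen k =", attr(x, "chosen_k"), ")\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Upper-tail hypergeometric enrichment of categories within clusters
#'
#' For each (cluster, category) pair with overlap k, cluster size n,
#' category size K and universe size N, reports the exact probability of
#' drawing at least k category members in n draws without replacement:
#' `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`.
#'
#' @param labels category label per object (the universe)
#' @param clusters cluster assignment per object (same length)
#' @return data.frame with cluster, category, N, K, n, k, p
#' @export
hypergeom_enrichment <- function(labels, clusters) {
  if (length(labels) != length(clusters)) {
    config_error("labels and clusters must cover the same universe")
  }
  N <- length(labels)
  out <- list()
  for (cl in sort(unique(clusters))) {
    in_cl <- clusters == cl
    n <- sum(in_cl)
    for (cat in sort(unique(labels))) {
      K <- sum(labels == cat)
      k <- sum(in_cl & labels == cat)
      out[[paste(cl, cat)]] <- data.frame(
        cluster = cl, category = cat, N = N, K = K, n = n, k = k,
        p = hyper_upper_tail(k, K, N, n),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# P(X >= k) for X ~ Hypergeometric(N, K, n); exact via stats::phyper.
hyper_upper_tail <- function(k, K, N, n) {
  if (K > N || n > N) config_error("category or cluster larger than universe")
  if (k > min(K, n)) config_error("overlap k exceeds min(K, n)")
  if (k <= 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
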