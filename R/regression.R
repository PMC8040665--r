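#' Standard-score normalize measurements within each cohort
#'
#' Each feature is centered and scaled to unit sample SD within each cohort.
#' Features with zero variance in any cohort are excluded from the returned
#' matrix (and recorded in `$excluded_features`) rather than propagating
#' NaN. The raw matrix is retained in `$raw`. Idempotent: an already
#' normalized dataset is returned unchanged.
#'
#' @param dataset a [cohort_dataset()]
#' @return a normalized `cohort_dataset`
#' @export
znormalize_within_cohort <- function(dataset) {
  if (dataset$normalized) return(dataset)
  Y <- dataset$measurements
  cohorts <- unique(dataset$subjects$cohort)
  excluded <- character()
  for (co in cohorts) {
    rows <- which(dataset$subjects$cohort == co)
    if (length(rows) < 2) {
      config_error("cohort '", co, "' has fewer than 2 subjects")
    }
    mu <- colMeans(Y[rows, , drop = FALSE], na.rm = TRUE)
    sdv <- apply(Y[rows, , drop = FALSE], 2, stats::sd, na.rm = TRUE)
    zero <- !is.finite(sdv) | sdv == 0
    excluded <- union(excluded, colnames(Y)[zero])
    sdv[zero] <- 1
    Y[rows, ] <- sweep(sweep(Y[rows, , drop = FALSE], 2, mu), 2, sdv, "/")
  }
  if (length(excluded)) {
    message("excluding ", length(excluded),
            " zero-variance feature(s): ",
            paste(utils::head(excluded, 5), collapse = ", "))
  }
  keep <- !(colnames(Y) %in% excluded)
  out <- cohort_dataset(Y[, keep, drop = FALSE], dataset$subjects,
                        dataset$features[keep, , drop = FALSE],
                        normalized = TRUE, viral_load = dataset$viral_load)
  out$raw <- dataset$measurements
  out$excluded_features <- excluded
  out
}

#' Ordinary least squares by the normal equations
#'
#' Fits `y ~ intercept + covariates` after dropping covariates that are
#' constant over the (complete-case) subjects. A rank-deficient design after
#' that drop is an error naming the collinear columns.
#'
#' @param y numeric response vector
#' @param covariates data.frame or matrix of design columns (no intercept)
#' @return list with `beta` (named, starting with intercept), `residuals`,
#'   `fitted`, `dropped` (constant columns removed)
#' @export
ols_fit <- function(y, covariates) {
  X0 <- as.matrix(covariates)
  if (is.null(colnames(X0))) colnames(X0) <- paste0("x", seq_len(ncol(X0)))
  ok <- stats::complete.cases(y, X0)
  y <- y[ok]; X0 <- X0[ok, , drop = FALSE]
  keep <- apply(X0, 2, function(v) length(unique(v)) > 1)
  dropped <- colnames(X0)[!keep]
  X <- cbind(intercept = 1, X0[, keep, drop = FALSE])
  if (length(y) <= ncol(X)) {
    stop("too few subjects (", length(y), ") for ", ncol(X) - 1,
         " non-constant covariates", call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  list(beta = beta, residuals = y - fitted, fitted = fitted, dropped = dropped)
}

# Coefficient matrix (p x m) for design X and response matrix Y.
coef_matrix <- function(X, Y) solve(crossprod(X), crossprod(X, Y))

#' Permutation p-values for regression coefficients
#'
#' Fits the full linear model `y ~ age + sex + cmv + hiv + hcv` (age as the
#' within-cohort z-score; covariates constant within a cohort are dropped)
#' per cohort and per feature, then permutes each driver covariate column
#' across subjects `n_perm` times, refits the full model, and reports
#' `p = #(|beta_perm| >= |beta_obs|) / n_perm`. The same permutation stream
#' serves all features of a (cohort, covariate) pass, which lets a single
#' normal-equations solve per permutation cover the whole feature panel.
#' The add-one-smoothed value `(b + 1) / (B + 1)` is reported alongside.
#'
#' @param dataset a normalized [cohort_dataset()] (normalized if not)
#' @param drivers covariates to test (those constant in a cohort are skipped)
#' @param n_perm number of permutations (study-scale default 1000)
#' @param seed integer seed; streams are derived per (cohort, covariate)
#' @param scheme "covariate" permutes the covariate column; "freedman_lane"
#'   permutes reduced-model residuals
#' @return data.frame with cohort, feature_id, covariate, beta, perm_p,
#'   perm_p_smooth, n_perm
#' @export
permutation_pvalues <- function(dataset,
                                drivers = c("age", "sex", "cmv", "hiv", "hcv"),
                                n_perm = 1000, seed = 1,
                                scheme = c("covariate", "freedman_lane")) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) config_error("n_perm must be >= 1")
  dataset <- znormalize_within_cohort(dataset)
  out <- list()
  for (co in unique(dataset$subjects$cohort)) {
    rows <- which(dataset$subjects$cohort == co)
    sub <- dataset$subjects[rows, , drop = FALSE]
    Y <- dataset$measurements[rows, , drop = FALSE]
    drv <- driver_columns(sub)
    varying <- names(drv)[vapply(drv, function(v) length(unique(v)) > 1, TRUE)]
    X <- cbind(intercept = 1,
               do.call(cbind, drv[varying]))
    colnames(X) <- c("intercept", varying)
    for (d in intersect(drivers, varying)) {
      res <- perm_pvalues_one(Y, X, d, n_perm,
                              derive_seed(seed, "perm", co, d), scheme)
      out[[paste(co, d)]] <- data.frame(
        cohort = co, feature_id = colnames(Y), covariate = d,
        beta = res$beta, perm_p = res$p, perm_p_smooth = res$p_smooth,
        n_perm = n_perm, row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Permutation p-values for one driver column in one cohort.
# Fast path assumes complete data; features with missing values are handled
# per feature with complete cases under the same permutation indices.
perm_pvalues_one <- function(Y, X, driver, n_perm, seed, scheme) {
  n <- nrow(X)
  d <- match(driver, colnames(X))
  if (length(unique(X[, d])) < 2) config_error("driver '", driver,
                                               "' is constant in this cohort")
  has_na <- apply(Y, 2, anyNA)
  beta_obs <- rep(NA_real_, ncol(Y))
  exceed <- rep(0L, ncol(Y))
  perms <- with_seed(seed, replicate(n_perm, sample.int(n)))
  cc_cols <- which(!has_na)
  if (length(cc_cols)) {
    Yc <- Y[, cc_cols, drop = FALSE]
    beta_obs[cc_cols] <- coef_matrix(X, Yc)[d, ]
    if (scheme == "covariate") {
      for (b in seq_len(n_perm)) {
        Xb <- X
        Xb[, d] <- X[perms[, b], d]
        bp <- coef_matrix(Xb, Yc)[d, ]
        exceed[cc_cols] <- exceed[cc_cols] +
          (abs(bp) >= abs(beta_obs[cc_cols]))
      }
    } else {
      Xr <- X[, -d, drop = FALSE]
      Cr <- coef_matrix(Xr, Yc)
      fit_r <- Xr %*% Cr
      res_r <- Yc - fit_r
      P <- solve(crossprod(X), t(X))[d, , drop = FALSE]
      for (b in seq_len(n_perm)) {
        bp <- drop(P %*% (fit_r + res_r[perms[, b], , drop = FALSE]))
        exceed[cc_cols] <- exceed[cc_cols] +
          (abs(bp) >= abs(beta_obs[cc_cols]))
      }
    }
  }
  for (j in which(has_na)) {
    ok <- !is.na(Y[, j])
    if (sum(ok) <= ncol(X)) next
    fit <- ols_fit(Y[ok, j], X[ok, -1, drop = FALSE])
    if (!(driver %in% names(fit$beta))) next
    beta_obs[j] <- fit$beta[driver]
    for (b in seq_len(n_perm)) {
      Xb <- X
      Xb[, d] <- X[perms[, b], d]
      bp <- coef_matrix(Xb[ok, , drop = FALSE], Y[ok, j, drop = FALSE])[d, ]
      exceed[j] <- exceed[j] + (abs(bp) >= abs(beta_obs[j]))
    }
  }
  list(beta = beta_obs, p = exceed / n_perm,
       p_smooth = (exceed + 1) / (n_perm + 1))
}

#' Storey q-values with FDR-threshold selection
#'
#' Estimates pi0 from a lambda grid (0.05 to 0.95 by 0.05) with spline
#' smoothing when at least 50 p-values are supplied; with fewer, pi0 is
#' fixed at 1, which reduces the procedure to Benjamini-Hochberg step-up.
#' q-values are monotone non-decreasing in p.
#'
#' @param p vector of p-values in [0, 1]
#' @param fdr_threshold features with q below this are called significant
#' @param pi0 optionally force the null proportion
#' @return data.frame with p, q, significant; `pi0` as an attribute
#' @export
qvalue_select <- function(p, fdr_threshold = 0.2, pi0 = NULL) {
  if (length(p) < 1) config_error("need at least one p-value")
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    config_error("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 50) {
      pi0 <- 1
    } else {
      lam <- seq(0.05, 0.95, by = 0.05)
      pi0_lam <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lam, pi0_lam, df = 3)
      pi0 <- stats::predict(fit, x = max(lam))$y
      pi0 <- min(max(pi0, 0), 1)
      if (pi0 <= 0) pi0 <- min(1, 2 * mean(p))  # all-signal degenerate case
      if (pi0 <= 0) pi0 <- 1 / m
    }
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  q <- numeric(m)
  q[o] <- q_sorted
  out <- data.frame(p = p, q = q, significant = q < fdr_threshold)
  attr(out, "pi0") <- pi0
  out
}

#' Per-cohort regression feature selection
#'
#' The full pipeline regression stage: z-normalize within cohort, compute
#' permutation p-values for every requested driver that varies within each
#' cohort, then q-values per (cohort, covariate) with significance at the
#' FDR threshold.
#'
#' @inheritParams permutation_pvalues
#' @param fdr_threshold q-value cutoff for significance (default 0.2)
#' @return data.frame with cohort, feature_id, covariate, beta, perm_p,
#'   perm_p_smooth, n_perm, q, significant
#' @export
cohort_regression <- function(dataset,
                              drivers = c("age", "sex", "cmv", "hiv", "hcv"),
                              n_perm = 1000, fdr_threshold = 0.2, seed = 1,
                              scheme = "covariate") {
  res <- permutation_pvalues(dataset, drivers, n_perm, seed, scheme)
  res$q <- NA_real_
  res$significant <- NA
  for (key in unique(paste(res$cohort, res$covariate))) {
    idx <- paste(res$cohort, res$covariate) == key
    qs <- qvalue_select(res$perm_p[idx], fdr_threshold)
    res$q[idx] <- qs$q
    res$significant[idx] <- qs$significant
  }
  res
}
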