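#' Agglomerative clustering with silhouette curve
#'
#' Hierarchically clusters individuals on their (inverse-rank-normalized)
#' cytokine responses with Euclidean distance and Ward linkage, cuts the
#' tree at each k in \code{k_range}, and records the average silhouette
#' width per k.
#'
#' @param X numeric matrix, individuals x traits (normalize first, e.g.
#'   with \code{\link{inverse_rank_normalize}} per column).
#' @param k_range candidate cluster numbers (default 2:15).
#' @param linkage hclust method (default "ward.D2"; "average" is used for
#'   correlation-heatmap reordering).
#' @return list of class \code{cluster_curve}: \code{labels} (matrix,
#'   individuals x k), \code{silhouette} (named per k), \code{best_k}
#'   (silhouette argmax).
#' @export
cluster_and_silhouette <- function(X, k_range = 2:15, linkage = "ward.D2") {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= max(k_range)) stop("need more individuals than clusters", call. = FALSE)
  d <- stats::dist(X)
  if (all(d == 0)) stop("all points identical; silhouette undefined", call. = FALSE)
  hc <- stats::hclust(d, method = linkage)
  sil <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  labels <- matrix(NA_integer_, nrow = n, ncol = length(k_range),
                   dimnames = list(rownames(X), k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    cl <- stats::cutree(hc, k = k)
    labels[, i] <- cl
    s <- cluster::silhouette(cl, d)
    sil[i] <- if (is.matrix(s)) mean(s[, "sil_width"]) else NA_real_
  }
  structure(list(labels = labels, silhouette = sil,
                 best_k = k_range[which.max(sil)]),
            class = "cluster_curve")
}

# pooled within-cluster dispersion W_k = sum_r (1/(2 n_r)) sum_{i,i' in r} d_ii'^2
# (equals the within-cluster sum of squares about the centroids)
.wk_dispersion <- function(X, labels) {
  sum(vapply(unique(labels), function(g) {
    Xg <- X[labels == g, , drop = FALSE]
    sum(sweep(Xg, 2, colMeans(Xg), "-")^2)
  }, numeric(1)))
}

#' Gap statistic for cluster-number selection
#'
#' For each k, compares log within-cluster dispersion of the data against
#' its expectation under B Monte Carlo reference datasets whose features
#' are sampled independently from a uniform distribution spanning each
#' observed feature's range. The same normalization applied to the data is
#' applied to every reference draw. Reports gap_k, the standard error
#' s_k = sd_B(log W_ref) * sqrt(1 + 1/B), and the 1-SE selection
#' k* = smallest k with gap_k >= gap_{k+1} - s_{k+1}.
#'
#' @param X numeric matrix (raw scale; see \code{normalize}).
#' @param k_range candidate k values, should include 1 (default 1:15).
#' @param B number of reference datasets (default 100).
#' @param seed integer seed.
#' @param linkage hclust linkage (default "ward.D2").
#' @param normalize function applied column-wise to the data and to every
#'   reference draw before clustering (default
#'   \code{\link{inverse_rank_normalize}}; use \code{identity} to skip).
#' @return list of class \code{gap_curve}: \code{gap}, \code{s}, \code{W},
#'   \code{k_range}, \code{k_star}.
#' @export
gap_statistic <- function(X, k_range = 1:15, B = 100L, seed = 1L,
                          linkage = "ward.D2",
                          normalize = inverse_rank_normalize) {
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= max(k_range)) stop("need more individuals than clusters", call. = FALSE)
  rng <- apply(X, 2, range)
  norm_cols <- function(M) apply(M, 2, normalize)

  cluster_w <- function(M) {
    labels_k <- if (max(k_range) > 1) {
      hc <- stats::hclust(stats::dist(M), method = linkage)
      stats::cutree(hc, k = k_range[k_range > 1])
    }
    vapply(seq_along(k_range), function(i) {
      k <- k_range[i]
      lab <- if (k == 1) rep(1L, n)
             else if (is.matrix(labels_k)) labels_k[, as.character(k)]
             else labels_k
      .wk_dispersion(M, lab)
    }, numeric(1))
  }

  W_obs <- cluster_w(norm_cols(X))
  logW_ref <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      R <- vapply(seq_len(ncol(X)), function(j)
        stats::runif(n, rng[1, j], rng[2, j]), numeric(n))
      log(cluster_w(norm_cols(R)))
    }, numeric(length(k_range)))
  })
  if (is.null(dim(logW_ref))) logW_ref <- matrix(logW_ref, nrow = 1)
  gap <- rowMeans(logW_ref) - log(W_obs)
  s <- apply(logW_ref, 1, stats::sd) * sqrt(1 + 1 / B)
  k_star <- NA_integer_
  for (i in seq_along(k_range)[-length(k_range)]) {
    if (gap[i] >= gap[i + 1] - s[i + 1]) { k_star <- k_range[i]; break }
  }
  if (is.na(k_star)) k_star <- k_range[length(k_range)]
  structure(list(gap = stats::setNames(gap, k_range),
                 s = stats::setNames(s, k_range),
                 W = stats::setNames(W_obs, k_range),
                 k_range = k_range, k_star = k_star),
            class = "gap_curve")
}

#' Statistical characterization of clusters
#'
#' Compares every covariate between clusters: Mann-Whitney U (two-sided
#' Wilcoxon rank-sum) for continuous variables, chi-square without
#' continuity correction for categorical ones; with more than two clusters
#' the continuous test becomes Kruskal-Wallis. P-values are Bonferroni
#' adjusted across all tested variables.
#'
#' @param labels integer cluster labels per individual.
#' @param covariate_table data.frame of covariates (columns with <= 5
#'   distinct values are treated as categorical).
#' @return data.frame: variable, type, statistic, p, p_bonferroni.
#' @export
characterize_clusters <- function(labels, covariate_table) {
  ks <- sort(unique(labels))
  sizes <- table(labels)
  if (any(sizes < 2)) {
    warning("cluster with fewer than 2 members; tests skipped")
    return(data.frame(variable = character(0), type = character(0),
                      statistic = numeric(0), p = numeric(0),
                      p_bonferroni = numeric(0)))
  }
  vars <- setdiff(names(covariate_table), "individual_id")
  rows <- lapply(vars, function(v) {
    x <- covariate_table[[v]]
    ok <- !is.na(x)
    categorical <- !is.numeric(x) || length(unique(x[ok])) <= 5
    if (categorical) {
      tab <- table(x[ok], labels[ok])
      tst <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(variable = v, type = "categorical",
                 statistic = unname(tst$statistic), p = tst$p.value)
    } else if (length(ks) == 2) {
      tst <- suppressWarnings(
        stats::wilcox.test(x[ok & labels == ks[1]], x[ok & labels == ks[2]],
                           exact = TRUE))
      data.frame(variable = v, type = "continuous",
                 statistic = unname(tst$statistic), p = tst$p.value)
    } else {
      tst <- stats::kruskal.test(x[ok], factor(labels[ok]))
      data.frame(variable = v, type = "continuous",
                 statistic = unname(tst$statistic), p = tst$p.value)
    }
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out
}
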