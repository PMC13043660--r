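#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks on ties; two-sided p from t = rho * sqrt((n-2)/(1-rho^2))
#' with n-2 degrees of freedom. Constant inputs give a missing result with
#' a warning.
#'
#' @param predictions,observations paired numeric vectors (NA pairs dropped).
#' @return list with \code{rho}, \code{p}, \code{n}.
#' @export
spearman_eval <- function(predictions, observations) {
  ok <- !is.na(predictions) & !is.na(observations)
  x <- predictions[ok]; y <- observations[ok]
  n <- length(x)
  if (n < 3) {
    warning("fewer than 3 paired values; Spearman undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector; Spearman undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Friedman test with Conover post-hoc comparisons
#'
#' Compares model variants (rows) across traits (columns) on within-trait
#' ranks. The omnibus Friedman chi-square uses average ranks on ties with
#' the standard tie correction; pairwise Conover t statistics follow, with
#' Holm step-down adjustment at level alpha. Models that cannot be
#' distinguished (no rejected pairwise test connecting them) are grouped by
#' connected components, the convention of critical-difference diagrams.
#'
#' @param perf numeric matrix, models x traits; higher is better. Columns
#'   containing missing entries are dropped with a warning.
#' @param alpha significance level for the post-hoc grouping.
#' @return list: \code{friedman_chisq}, \code{friedman_p}, \code{avg_rank}
#'   (per model; rank 1 = best), \code{pairwise} (data.frame with raw and
#'   Holm-adjusted p), \code{groups} (integer group id per model).
#' @export
friedman_conover <- function(perf, alpha = 0.05) {
  perf <- as.matrix(perf)
  k <- nrow(perf); n <- ncol(perf)
  if (k < 3 || n < 2) stop("need >= 3 models and >= 2 traits", call. = FALSE)
  bad <- colSums(is.na(perf)) > 0
  if (any(bad)) {
    warning(sum(bad), " trait column(s) with missing entries dropped")
    perf <- perf[, !bad, drop = FALSE]
    n <- ncol(perf)
    if (n < 2) stop("too few complete trait columns", call. = FALSE)
  }
  if (is.null(rownames(perf))) rownames(perf) <- paste0("model", seq_len(k))
  # rank within each trait column, best (largest) performance = rank 1
  R <- apply(perf, 2, function(col) rank(-col, ties.method = "average"))
  Rsum <- rowSums(R)
  avg_rank <- Rsum / n
  # tie-corrected Friedman statistic
  A <- sum(R^2)
  C <- n * k * (k + 1)^2 / 4
  denom <- A - C
  if (denom <= 0) {
    chisq <- 0; p_f <- 1
    groups <- rep(1L, k)
    return(list(friedman_chisq = 0, friedman_p = 1,
                avg_rank = stats::setNames(avg_rank, rownames(perf)),
                pairwise = NULL,
                groups = stats::setNames(groups, rownames(perf))))
  }
  B <- sum(Rsum^2) / n
  chisq <- (k - 1) * n * (B - C) / denom
  p_f <- stats::pchisq(chisq, df = k - 1, lower.tail = FALSE)

  # Conover pairwise t statistics on rank sums
  df2 <- (n - 1) * (k - 1)
  s2 <- (A - B) / df2
  pairs <- utils::combn(k, 2)
  tstat <- abs(Rsum[pairs[1, ]] - Rsum[pairs[2, ]]) /
    sqrt(max(s2, .Machine$double.eps) * 2 * n)
  p_raw <- 2 * stats::pt(-tstat, df2)
  p_adj <- stats::p.adjust(p_raw, method = "holm")
  pairwise <- data.frame(model_a = rownames(perf)[pairs[1, ]],
                         model_b = rownames(perf)[pairs[2, ]],
                         t = tstat, p = p_raw, p_holm = p_adj,
                         stringsAsFactors = FALSE)

  # connected components over edges of NON-rejected pairs
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in which(p_adj >= alpha)) {
    a <- find(pairs[1, e]); b <- find(pairs[2, e])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(k), find, integer(1))
  groups <- match(roots, unique(roots))
  list(friedman_chisq = chisq, friedman_p = p_f,
       avg_rank = stats::setNames(avg_rank, rownames(perf)),
       pairwise = pairwise,
       groups = stats::setNames(groups, rownames(perf)))
}

#' Permutation feature importance
#'
#' For each feature, the test-set column is permuted (seeded), the model
#' re-predicts, and the importance is the baseline Spearman correlation
#' minus the mean correlation over \code{n_perm} permutations. Categories
#' aggregate member features by summing their scores; by convention all
#' selected genetic markers map to a single "SNPs" category.
#'
#' @param model a fitted \code{ml_model}.
#' @param test_X numeric test feature matrix (named columns).
#' @param test_y observed test targets.
#' @param category_map named character vector feature -> category; NULL
#'   makes every feature its own category.
#' @param n_perm number of permutations per feature (default 50).
#' @param seed integer seed.
#' @param joint_blocks if TRUE, all members of each category are permuted
#'   jointly (one score per category) instead of summing per-feature
#'   scores; off by default.
#' @return list of class \code{importance_report}: \code{baseline_rho},
#'   \code{per_feature}, \code{per_category} (named numeric vectors).
#' @export
permutation_importance <- function(model, test_X, test_y, category_map = NULL,
                                   n_perm = 50L, seed = 1L,
                                   joint_blocks = FALSE) {
  test_X <- as.matrix(test_X)
  n <- nrow(test_X)
  if (n < 2) stop("test set must contain at least 2 rows", call. = FALSE)
  feats <- colnames(test_X)
  if (is.null(category_map))
    category_map <- stats::setNames(feats, feats)
  baseline <- spearman_eval(predict(model, test_X), test_y)$rho
  if (is.na(baseline)) {
    empty <- stats::setNames(rep(NA_real_, length(feats)), feats)
    return(structure(list(baseline_rho = NA_real_, per_feature = empty,
                          per_category = tapply(empty, category_map[feats], sum)),
                     class = "importance_report"))
  }
  # each column group is scored from n_perm permuted copies of the test set;
  # groups are batched into large stacked matrices so one predict() call
  # covers many (group, permutation) pairs, which keeps per-call overhead low
  score_groups <- function(groups) {
    out <- rep(NA_real_, length(groups))
    block_rows <- n * n_perm
    per_chunk <- max(1L, floor(2e5 / block_rows))
    for (start in seq(1, length(groups), by = per_chunk)) {
      gs <- groups[start:min(start + per_chunk - 1L, length(groups))]
      big <- test_X[rep(seq_len(n), n_perm * length(gs)), , drop = FALSE]
      for (gi in seq_along(gs)) {
        for (r in seq_len(n_perm)) {
          rows <- (gi - 1L) * block_rows + (r - 1L) * n + seq_len(n)
          perm <- sample.int(n)
          big[rows, gs[[gi]]] <- test_X[perm, gs[[gi]], drop = FALSE]
        }
      }
      pred <- predict(model, big)
      for (gi in seq_along(gs)) {
        rhos <- vapply(seq_len(n_perm), function(r) {
          pr <- pred[(gi - 1L) * block_rows + (r - 1L) * n + seq_len(n)]
          suppressWarnings(spearman_eval(pr, test_y)$rho)
        }, numeric(1))
        out[start + gi - 1L] <- baseline - mean(rhos, na.rm = TRUE)
      }
    }
    out
  }
  withr::with_seed(seed, {
    if (joint_blocks) {
      cats <- unique(category_map[feats])
      per_category <- stats::setNames(
        score_groups(lapply(cats, function(cg)
          which(category_map[feats] == cg))), cats)
      per_feature <- NULL
    } else {
      varying <- which(apply(test_X, 2, stats::sd) > 0)
      per_feature <- stats::setNames(rep(0, length(feats)), feats)
      # constant columns keep importance 0: permutation is the identity
      per_feature[varying] <- score_groups(as.list(varying))
      per_category <- tapply(per_feature, category_map[feats], sum)
      per_category <- stats::setNames(as.numeric(per_category),
                                      names(per_category))
    }
    structure(list(baseline_rho = baseline, per_feature = per_feature,
                   per_category = per_category),
              class = "importance_report")
  })
}

#' Paired data-leakage experiment
#'
#' Runs the benchmark twice with identical folds, seeds and model: once
#' with genetic feature selection restricted to the training split
#' (TRAIN_ONLY) and once with selection on the entire cohort including the
#' test folds (FULL_COHORT, the data-leaking scenario). Reports the
#' per-fold paired difference in test Spearman and in the aggregated SNPs
#' importance category.
#'
#' @inheritParams run_benchmark
#' @param model_kind single model kind for both arms.
#' @return list: \code{train_only}, \code{full_cohort} (benchmark reports),
#'   \code{delta_rho} (per fold), \code{delta_snp_importance} (per fold),
#'   \code{mean_delta_rho}, \code{mean_delta_snp_importance}.
#' @export
leakage_experiment <- function(cohort, trait, fold_plan, model_kind = "rf",
                               params = clump_params(), importance = TRUE,
                               n_perm = 50L, importance_folds = NULL,
                               seed = 1L) {
  arms <- lapply(c("TRAIN_ONLY", "FULL_COHORT"), function(mode)
    run_benchmark(cohort, trait, model_kinds = model_kind,
                  feature_sets = "combined", leakage_mode = mode,
                  fold_plan = fold_plan, params = params,
                  importance = importance, n_perm = n_perm,
                  importance_folds = importance_folds, seed = seed))
  names(arms) <- c("train_only", "full_cohort")
  r_to <- arms$train_only$results
  r_fc <- arms$full_cohort$results
  zero_na <- function(x) ifelse(is.na(x), 0, x)
  delta_rho <- zero_na(r_fc$rho) - zero_na(r_to$rho)
  snp_imp <- function(report) vapply(seq_len(fold_plan$k), function(f) {
    rep_f <- report$importance[[paste(f, model_kind, "combined", sep = ".")]]
    if (is.null(rep_f) || !"SNPs" %in% names(rep_f$per_category)) return(NA_real_)
    rep_f$per_category[["SNPs"]]
  }, numeric(1))
  d_imp <- if (importance) snp_imp(arms$full_cohort) - snp_imp(arms$train_only)
           else rep(NA_real_, fold_plan$k)
  list(train_only = arms$train_only, full_cohort = arms$full_cohort,
       delta_rho = delta_rho, delta_snp_importance = d_imp,
       mean_delta_rho = mean(delta_rho),
       mean_delta_snp_importance = mean(d_imp, na.rm = TRUE))
}

#' Cross-cohort validation
#'
#' Trains one model on the full first cohort (genetic feature selection and
#' scaling parameters estimated there only) and evaluates Spearman
#' correlation of its predictions in a second cohort. Genetic features use
#' the intersection of variants present in both cohorts; if no selected
#' variant is shared the model proceeds on covariates alone with a warning.
#'
#' @param train_cohort,test_cohort \code{sim_cohort}-like objects.
#' @param trait cytokine column (name or index), present in both cohorts.
#' @param model_kind learner kind.
#' @param configuration hyperparameter configuration (default:
#'   \code{default_config(model_kind)}).
#' @param params a \code{\link{clump_params}} for feature selection.
#' @param covariate_columns covariates shared by the cohorts.
#' @param seed integer seed.
#' @return list: \code{rho}, \code{p}, \code{predictions} (data.frame with
#'   individual_id, predicted and observed log2 values).
#' @export
cross_cohort_validate <- function(train_cohort, test_cohort, trait = 1L,
                                  model_kind = "rf", configuration = NULL,
                                  params = clump_params(),
                                  covariate_columns = c(
                                    "bmi", "age", "sex", "cmv", "s1", "s2",
                                    "neutrophils", "lymphocytes", "monocytes",
                                    "basophils", "eosinophils"),
                                  seed = 1L) {
  if (is.null(configuration)) configuration <- default_config(model_kind)
  y_tr <- train_cohort$cytokines[, trait]
  y_te <- test_cohort$cytokines[, trait]
  cov_tr <- .covariate_features(train_cohort$covariates, covariate_columns)
  cov_te <- .covariate_features(test_cohort$covariates, covariate_columns)
  cc_tr <- !is.na(y_tr) & stats::complete.cases(cov_tr)
  cc_te <- !is.na(y_te) & stats::complete.cases(cov_te)

  adj_cols <- intersect(colnames(cov_tr),
                        c("age", "bmi", "sex", "s1", "s2", "neutrophils",
                          "monocytes", "lymphocytes", "eosinophils",
                          "basophils"))
  adj <- residualize(y_tr[cc_tr], cov_tr[cc_tr, adj_cols, drop = FALSE])
  adj <- inverse_rank_normalize(adj)
  G_tr <- genotype_matrix(train_cohort$genotypes$dosages[cc_tr, , drop = FALSE],
                          train_cohort$genotypes$variants)
  ss <- suppressWarnings(run_univariate_gwas(G_tr, adj))
  cl <- clump(ss, G_tr, params)
  shared <- intersect(cl$index$ID, test_cohort$genotypes$variants$id)
  if (!length(shared) && nrow(cl$index))
    warning("no selected variant shared between cohorts; using covariates only")

  snp_tr <- train_cohort$genotypes$dosages[cc_tr, shared, drop = FALSE]
  snp_te <- test_cohort$genotypes$dosages[cc_te, shared, drop = FALSE]
  X_tr <- cbind(snp_tr, cov_tr[cc_tr, , drop = FALSE])
  X_te <- cbind(snp_te, cov_te[cc_te, , drop = FALSE])
  scaler <- suppressWarnings(fit_scaler(X_tr))
  X_trs <- apply_scaler(X_tr, scaler)
  X_tes <- apply_scaler(X_te, scaler)
  y_scaler <- fit_scaler(matrix(y_tr[cc_tr], dimnames = list(NULL, "y")))
  y_trs <- as.numeric(apply_scaler(matrix(y_tr[cc_tr], ncol = 1,
                                          dimnames = list(NULL, "y")), y_scaler))
  model <- fit_model(model_kind, configuration, X_trs, y_trs, seed = seed)
  pred <- predict(model, X_tes)
  ev <- spearman_eval(pred, y_te[cc_te])
  list(rho = ev$rho, p = ev$p,
       predictions = data.frame(
         individual_id = test_cohort$covariates$individual_id[cc_te],
         predicted_log2 = pred * y_scaler$sd[["y"]] + y_scaler$mean[["y"]],
         observed_log2 = y_te[cc_te], stringsAsFactors = FALSE),
       n_shared_variants = length(shared))
}
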