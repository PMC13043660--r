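#' Clumping parameters
#'
#' Defaults follow the C+T protocol: primary index threshold p1 = 1e-5,
#' secondary membership threshold p2 = 1e-2, LD threshold r^2 > 0.5,
#' 250 kb window.
#'
#' @param p1 primary p-value threshold for index variants.
#' @param p2 secondary threshold for clump membership.
#' @param r2_min LD threshold (clump membership requires r^2 > r2_min).
#' @param window_kb half-window in kilobases around the index variant.
#' @return list of class \code{clump_params}.
#' @export
clump_params <- function(p1 = 1e-5, p2 = 1e-2, r2_min = 0.5, window_kb = 250) {
  if (p1 > p2) stop("p1 must be <= p2", call. = FALSE)
  if (r2_min <= 0 || r2_min > 1) stop("r2_min must lie in (0,1]", call. = FALSE)
  if (window_kb <= 0) stop("window_kb must be positive", call. = FALSE)
  structure(list(p1 = p1, p2 = p2, r2_min = r2_min, window_kb = window_kb),
            class = "clump_params")
}

#' LD clumping of GWAS summary statistics
#'
#' Greedy clumping by ascending p-value: each variant with p < p1 not yet
#' assigned to a clump becomes an index variant; all unassigned variants
#' with p < p2 on the same chromosome, within the window, and with
#' dosage r^2 > r2_min against the index (computed in the LD source
#' cohort) join its clump. Ties on p are broken by (chrom, pos, ID).
#'
#' @param sumstats data.frame with CHR, POS, ID, A1, BETA, P columns.
#' @param ld_source a \code{genotype_matrix} supplying dosages for r^2;
#'   must contain every index candidate.
#' @param params a \code{\link{clump_params}}.
#' @return list of class \code{clump_result}: \code{index} (sumstats rows
#'   of the index variants, in selection order) and \code{members} (named
#'   list: index ID -> IDs of clumped variants).
#' @export
clump <- function(sumstats, ld_source, params = clump_params()) {
  stopifnot(inherits(ld_source, "genotype_matrix"))
  ss <- sumstats[!is.na(sumstats$P), , drop = FALSE]
  ss <- ss[order(ss$P, ss$CHR, ss$POS, ss$ID), , drop = FALSE]
  cand <- which(ss$P < params$p1)
  if (!length(cand))
    return(structure(list(index = ss[0, , drop = FALSE],
                          members = list()), class = "clump_result"))
  if (!all(ss$ID[cand] %in% colnames(ld_source$dosages)))
    stop("LD source lacks genotypes for index candidate(s): ",
         paste(utils::head(setdiff(ss$ID[cand], colnames(ld_source$dosages)), 5),
               collapse = ", "), call. = FALSE)
  assigned <- rep(FALSE, nrow(ss))
  index_rows <- integer(0)
  members <- list()
  window_bp <- params$window_kb * 1000
  for (i in cand) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    index_rows <- c(index_rows, i)
    near <- which(!assigned & ss$P < params$p2 & ss$CHR == ss$CHR[i] &
                    abs(ss$POS - ss$POS[i]) <= window_bp)
    near <- near[ss$ID[near] %in% colnames(ld_source$dosages)]
    if (length(near)) {
      g_index <- ld_source$dosages[, ss$ID[i]]
      r2 <- vapply(near, function(j) {
        r <- suppressWarnings(stats::cor(g_index, ld_source$dosages[, ss$ID[j]],
                                         use = "pairwise.complete.obs"))
        if (is.na(r)) 0 else r^2
      }, numeric(1))
      hits <- near[r2 > params$r2_min]
      assigned[hits] <- TRUE
      members[[ss$ID[i]]] <- ss$ID[hits]
    } else {
      members[[ss$ID[i]]] <- character(0)
    }
  }
  structure(list(index = ss[index_rows, , drop = FALSE], members = members),
            class = "clump_result")
}

#' C+T polygenic score model from a clump result
#'
#' Index variants carry their training-GWAS effect sizes; clumped members
#' are discarded (standard C+T).
#'
#' @param clump_result a \code{\link{clump}} result.
#' @return data.frame of class \code{ct_score_model}: variant_key,
#'   effect_allele, beta.
#' @export
ct_score_model <- function(clump_result) {
  stopifnot(inherits(clump_result, "clump_result"))
  idx <- clump_result$index
  structure(data.frame(variant_key = idx$ID, effect_allele = idx$A1,
                       beta = idx$BETA, stringsAsFactors = FALSE),
            class = c("ct_score_model", "data.frame"))
}

# Align weight records with a genotype panel and return the effect-allele
# dosage matrix. Matching rule: effect_allele == ALT -> dosage;
# == REF -> 2 - dosage; otherwise the variant is skipped (strand flips are
# never guessed). Missing dosages are replaced by the variant's mean dosage
# in the scored cohort. Shared by ct_score() and apply_pgs().
.effect_allele_dosages <- function(genotypes, variant_key, effect_allele) {
  vr <- genotypes$variants
  keys <- vr$id
  pos_keys <- paste0(vr$chrom, ":", vr$pos)
  hit <- match(variant_key, keys)
  hit[is.na(hit)] <- match(variant_key[is.na(hit)], pos_keys)
  matched <- flipped <- rep(FALSE, length(variant_key))
  D <- matrix(NA_real_, nrow = nrow(genotypes$dosages), ncol = length(variant_key))
  for (k in seq_along(variant_key)) {
    j <- hit[k]
    if (is.na(j)) next
    d <- genotypes$dosages[, j]
    mean_d <- mean(d, na.rm = TRUE)
    if (is.nan(mean_d)) next
    d[is.na(d)] <- mean_d
    if (effect_allele[k] == vr$alt[j]) {
      D[, k] <- d; matched[k] <- TRUE
    } else if (effect_allele[k] == vr$ref[j]) {
      D[, k] <- 2 - d; flipped[k] <- TRUE
    }
  }
  used <- matched | flipped
  list(dosages = D[, used, drop = FALSE],
       used = used,
       counts = c(matched = sum(matched), flipped = sum(flipped),
                  skipped = sum(!used)))
}

#' Score individuals with a C+T model
#'
#' score_i = sum over index variants of beta x effect-allele dosage_i.
#' Allele matching follows the shared rule: effect allele equal to ALT uses
#' the dosage, equal to REF uses 2 - dosage, anything else is skipped with
#' a warning. Missing dosages contribute the variant's mean dosage.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param model a \code{\link{ct_score_model}}.
#' @return numeric score per individual.
#' @export
ct_score <- function(genotypes, model) {
  stopifnot(inherits(model, "ct_score_model"))
  al <- .effect_allele_dosages(genotypes, model$variant_key, model$effect_allele)
  if (!ncol(al$dosages)) stop("no matchable variants in the score model",
                              call. = FALSE)
  if (al$counts["skipped"] > 0)
    warning(al$counts["skipped"], " variant(s) skipped (allele mismatch or absent)")
  as.numeric(al$dosages %*% model$beta[al$used])
}

#' Random cross-validation fold plan
#'
#' Partitions n individuals into k disjoint folds whose sizes differ by at
#' most one, deterministically given the seed.
#'
#' @param n number of individuals.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of class \code{fold_plan}: \code{assignment} (integer in
#'   1..k per individual), \code{k}, \code{seed}.
#' @export
make_folds <- function(n, k = 5L, seed = 1L) {
  if (n < k) stop("n must be >= k", call. = FALSE)
  assignment <- withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  structure(list(assignment = assignment, k = as.integer(k),
                 seed = as.integer(seed)), class = "fold_plan")
}

#' Random hyperparameter search with internal cross-validation
#'
#' Samples up to \code{n_configs} configurations from the model's grid
#' (all of them when the grid is no larger) and evaluates each by mean
#' test-fold Spearman correlation under an internal k-fold cross-validation
#' applied only to the training data. Configurations whose fit fails are
#' skipped with a warning.
#'
#' @param model_kind model kind (see \code{\link{hyper_grid}}).
#' @param X,y training features and target (complete cases).
#' @param n_configs maximum number of sampled configurations (default 25).
#' @param inner_k internal folds (default 5).
#' @param seed integer seed for sampling and folds.
#' @return list: \code{best} configuration, \code{scores} per evaluated
#'   configuration.
#' @export
random_search <- function(model_kind, X, y, n_configs = 25L, inner_k = 5L,
                          seed = 1L) {
  grid <- hyper_grid(model_kind)
  picks <- if (length(grid) <= n_configs) seq_along(grid)
           else withr::with_seed(seed, sample.int(length(grid), n_configs))
  plan <- make_folds(nrow(X), inner_k, seed = seed + 1L)
  scores <- rep(NA_real_, length(picks))
  for (ci in seq_along(picks)) {
    cfg <- grid[[picks[ci]]]
    rhos <- rep(NA_real_, inner_k)
    ok <- TRUE
    for (f in seq_len(inner_k)) {
      te <- plan$assignment == f
      if (sum(!te) < 2 || sum(te) < 3) next
      pred <- tryCatch(
        fit_predict(model_kind, cfg,
                    list(X = X[!te, , drop = FALSE], y = y[!te]),
                    list(X = X[te, , drop = FALSE]),
                    seed = seed + 100L + f),
        error = function(e) { ok <<- FALSE; NULL })
      if (!ok) break
      rhos[f] <- spearman_eval(pred, y[te])$rho
    }
    if (!ok) { warning("configuration skipped: fit failed"); next }
    scores[ci] <- mean(rhos, na.rm = TRUE)
  }
  if (all(is.na(scores))) stop("every configuration failed", call. = FALSE)
  best_i <- which.max(ifelse(is.nan(scores), -Inf, scores))
  list(best = grid[[picks[best_i]]], scores = scores,
       configs = grid[picks])
}

# covariate feature columns used by the prediction models (seasonality is
# encoded as s1/s2 before use)
.benchmark_covariates <- c("age", "bmi", "sex", "cmv", "s1", "s2",
                           "neutrophils", "monocytes", "lymphocytes",
                           "eosinophils", "basophils", "oestradiol",
                           "progesterone", "testosterone")

.covariate_features <- function(covariates,
                                columns = .benchmark_covariates) {
  s <- encode_seasonality(covariates$doy)
  tab <- cbind(covariates, s1 = s$s1, s2 = s$s2)
  as.matrix(tab[, columns, drop = FALSE])
}

#' Benchmark prediction models under a leakage mode
#'
#' Runs the full fold pipeline for one cytokine trait: per outer fold a
#' univariate GWAS on the residualized, inverse-rank-normalized trait of
#' the selection cohort (the training split under \code{"TRAIN_ONLY"}; all
#' individuals under \code{"FULL_COHORT"}, the data-leaking scenario),
#' LD clumping in the same selection cohort, feature assembly (selected
#' variant dosages alone for \code{"genetic"}, plus z-scored biological and
#' environmental covariates for \code{"combined"}; scaling parameters are
#' always estimated on the training split only), optional random
#' hyperparameter search, model fitting, and test-fold Spearman evaluation.
#'
#' When a fold's training GWAS yields no variant below p1 the genetic
#' feature set is empty: C+T emits a missing result and learners fall back
#' to intercept-only predictions (Spearman recorded as missing).
#'
#' @param cohort a \code{sim_cohort} (or list with \code{genotypes},
#'   \code{covariates}, \code{cytokines}).
#' @param trait column name or index of the cytokine panel.
#' @param model_kinds character vector of model kinds.
#' @param feature_sets subset of c("genetic", "combined").
#' @param leakage_mode "TRAIN_ONLY" or "FULL_COHORT".
#' @param fold_plan a \code{\link{make_folds}} plan.
#' @param params a \code{\link{clump_params}}; the defaults follow the
#'   C+T protocol, desk-scale runs may widen p1.
#' @param search run \code{\link{random_search}} per fold (default FALSE:
#'   use \code{\link{default_config}}).
#' @param n_configs configurations sampled when \code{search} is TRUE.
#' @param importance compute permutation feature importance per fold
#'   (learner models only).
#' @param n_perm permutations for the importance scores.
#' @param importance_folds folds on which importance is evaluated
#'   (default: all); restricting it bounds the forest-prediction cost of
#'   large replicated experiments.
#' @param seed integer seed.
#' @return object of class \code{benchmark_report}: \code{results}
#'   (data.frame: fold, model, feature_set, rho, p, n_test, n_selected),
#'   \code{importance} (per fold x model x feature set category scores),
#'   \code{audit} (individual IDs touched per stage and fold), \code{seed}.
#' @export
run_benchmark <- function(cohort, trait = 1L,
                          model_kinds = c("ct", "ridge", "rf"),
                          feature_sets = c("genetic", "combined"),
                          leakage_mode = c("TRAIN_ONLY", "FULL_COHORT"),
                          fold_plan, params = clump_params(),
                          search = FALSE, n_configs = 25L,
                          importance = FALSE, n_perm = 50L,
                          importance_folds = NULL, seed = 1L) {
  if (is.null(importance_folds)) importance_folds <- seq_len(fold_plan$k)
  leakage_mode <- match.arg(leakage_mode)
  feature_sets <- match.arg(feature_sets, several.ok = TRUE)
  y_all <- cohort$cytokines[, trait]
  cov_feat <- .covariate_features(cohort$covariates)
  complete <- !is.na(y_all) & stats::complete.cases(cov_feat)
  if (sum(complete) < 20) stop("fewer than 20 complete cases", call. = FALSE)
  G <- cohort$genotypes
  idx_all <- which(complete)
  ids <- cohort$covariates$individual_id
  assignment <- fold_plan$assignment[idx_all]

  res <- list(); imp <- list(); audit <- list()
  adj_covars <- c("age", "bmi", "sex", "s1", "s2", "neutrophils", "monocytes",
                  "lymphocytes", "eosinophils", "basophils")

  for (f in seq_len(fold_plan$k)) {
    te <- idx_all[assignment == f]
    tr <- idx_all[assignment != f]
    sel <- if (leakage_mode == "TRAIN_ONLY") tr else idx_all
    audit[[f]] <- list(selection_ids = ids[sel], train_ids = ids[tr],
                       test_ids = ids[te])

    # GWAS-based genetic feature selection in the selection cohort
    adj <- residualize(y_all[sel], cov_feat[sel, adj_covars, drop = FALSE])
    adj <- inverse_rank_normalize(adj)
    sel_geno <- genotype_matrix(G$dosages[sel, , drop = FALSE], G$variants)
    ss <- suppressWarnings(run_univariate_gwas(sel_geno, adj))
    cl <- clump(ss, sel_geno, params)
    snp_ids <- cl$index$ID
    ctm <- ct_score_model(cl)

    y_scaler <- fit_scaler(matrix(y_all[tr], dimnames = list(NULL, "y")))
    y_tr <- as.numeric(apply_scaler(matrix(y_all[tr], ncol = 1,
                                           dimnames = list(NULL, "y")), y_scaler))

    for (fs in feature_sets) {
      snp_X <- if (length(snp_ids))
        G$dosages[, snp_ids, drop = FALSE] else matrix(0, length(y_all), 0)
      X_full <- if (fs == "genetic") snp_X else cbind(snp_X, cov_feat)
      feat_scaler <- if (ncol(X_full))
        suppressWarnings(fit_scaler(X_full[tr, , drop = FALSE])) else NULL
      X_tr <- if (ncol(X_full)) apply_scaler(X_full[tr, , drop = FALSE], feat_scaler)
              else X_full[tr, , drop = FALSE]
      X_te <- if (ncol(X_full)) apply_scaler(X_full[te, , drop = FALSE], feat_scaler)
              else X_full[te, , drop = FALSE]

      for (mk in model_kinds) {
        rho <- p <- NA_real_
        model <- NULL
        if (mk == "ct") {
          if (fs != "genetic") next
          if (length(snp_ids)) {
            sc <- ct_score(genotype_matrix(G$dosages[te, , drop = FALSE],
                                           G$variants), ctm)
            ev <- spearman_eval(sc, y_all[te])
            rho <- ev$rho; p <- ev$p
          }
        } else if (ncol(X_tr) == 0) {
          # empty feature set: intercept-only fallback, Spearman undefined
        } else {
          cfg <- if (search)
            random_search(mk, X_tr, y_tr, n_configs = n_configs,
                          seed = seed + 13L * f)$best
          else default_config(mk)
          model <- fit_model(mk, cfg, X_tr, y_tr, seed = seed + 29L * f)
          pred <- predict(model, X_te)
          ev <- spearman_eval(pred, y_all[te])
          rho <- ev$rho; p <- ev$p
        }
        res[[length(res) + 1L]] <- data.frame(
          fold = f, model = mk, feature_set = fs, rho = rho, p = p,
          n_test = length(te), n_selected = length(snp_ids),
          stringsAsFactors = FALSE)
        if (importance && f %in% importance_folds && !is.null(model)) {
          cat_map <- .benchmark_category_map(colnames(X_tr), snp_ids)
          imp[[paste(f, mk, fs, sep = ".")]] <- permutation_importance(
            model, X_te, y_all[te], category_map = cat_map,
            n_perm = n_perm, seed = seed + 97L * f)
        }
      }
    }
  }
  structure(list(results = do.call(rbind, res), importance = imp,
                 audit = audit, seed = seed, leakage_mode = leakage_mode),
            class = "benchmark_report")
}

# feature -> category map: all selected variants aggregate to "SNPs",
# the two seasonal encodings to "seasonality", others are singletons
.benchmark_category_map <- function(feature_names, snp_ids) {
  cat <- feature_names
  cat[feature_names %in% snp_ids] <- "SNPs"
  cat[feature_names %in% c("s1", "s2")] <- "seasonality"
  stats::setNames(cat, feature_names)
}

#' Mean test-set Spearman per model and feature set
#'
#' Folds with missing correlations (degenerate predictions or empty
#' genetic feature sets) contribute zero rank skill to the mean.
#'
#' @param report a \code{benchmark_report}.
#' @return data.frame: model, feature_set, mean_rho, n_folds, n_missing.
#' @export
summarize_benchmark <- function(report) {
  r <- report$results
  agg <- stats::aggregate(rho ~ model + feature_set, data = transform(
    r, rho = ifelse(is.na(rho), 0, rho)), FUN = mean)
  names(agg)[names(agg) == "rho"] <- "mean_rho"
  miss <- stats::aggregate(cbind(n_missing = is.na(r$rho)) ~ model + feature_set,
                           data = r, FUN = sum)
  out <- merge(agg, miss, by = c("model", "feature_set"))
  out$n_folds <- max(r$fold)
  out
}
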