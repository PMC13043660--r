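#' Apply polygenic-score weights to a cohort
#'
#' score_i = sum over matchable variants of effect_weight x effect-allele
#' dosage_i, with the shared allele-matching rule (effect allele equal to
#' ALT uses the dosage, equal to REF uses 2 - dosage, anything else is
#' skipped and logged; strand flips are never guessed). Missing dosages
#' contribute the variant's mean dosage in the scored cohort.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param weights data.frame from \code{\link{read_pgs_weights}} (columns
#'   variant_key, effect_allele, effect_weight).
#' @return list of class \code{pgs_profile}: \code{score} (per individual),
#'   \code{counts} (matched / flipped / skipped; they sum to the weight-file
#'   variant count).
#' @export
apply_pgs <- function(genotypes, weights) {
  al <- .effect_allele_dosages(genotypes, weights$variant_key,
                               weights$effect_allele)
  if (!ncol(al$dosages)) {
    unmatched <- utils::head(weights$variant_key[!al$used], 10)
    stop("no matchable variants; first unmatched keys: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  structure(list(score = as.numeric(al$dosages %*%
                                      weights$effect_weight[al$used]),
                 counts = al$counts),
            class = "pgs_profile")
}

#' Permutation test of PGS-cytokine association
#'
#' Observed Spearman correlation between a polygenic score and a cytokine
#' response, tested against a null built by randomly permuting the cytokine
#' vector \code{n_perm} times. The two-sided empirical p-value is
#' (1 + #\{|rho_perm| >= |rho_obs|\}) / (n_perm + 1), never exactly zero.
#'
#' @param score numeric PGS per individual.
#' @param trait numeric cytokine response per individual.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return list: \code{rho}, \code{p_perm}, \code{significant} (at 0.05),
#'   \code{null_rho} (the permuted correlations).
#' @export
pgs_association_permutation <- function(score, trait, n_perm = 1000L,
                                        seed = 1L) {
  ok <- !is.na(score) & !is.na(trait)
  x <- score[ok]; y <- trait[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant or too-short input; association undefined")
    return(list(rho = NA_real_, p_perm = NA_real_, significant = NA,
                null_rho = numeric(0)))
  }
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  null_rho <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i)
    stats::cor(rx, sample(ry)), numeric(1)))
  p <- (1 + sum(abs(null_rho) >= abs(rho_obs))) / (n_perm + 1)
  list(rho = rho_obs, p_perm = p, significant = p < 0.05,
       null_rho = null_rho)
}

#' Append polygenic scores as prediction features
#'
#' Adds one standardized column per PGS profile to a feature table, aligned
#' on individual_id; downstream benchmarking and permutation-importance
#' machinery applies unchanged.
#'
#' @param profiles named list of \code{pgs_profile} objects (or numeric
#'   vectors), each aligned with \code{ids}.
#' @param cohort_features data.frame or matrix of existing features with
#'   rownames (or an \code{individual_id} column) identifying individuals.
#' @param ids individual IDs aligned with each profile's scores.
#' @return the feature table with standardized PGS columns appended.
#' @export
pgs_as_features <- function(profiles, cohort_features, ids) {
  X <- as.matrix(cohort_features)
  feat_ids <- if (!is.null(rownames(X))) rownames(X) else ids
  if (!length(profiles)) return(X)
  out <- X
  for (nm in names(profiles)) {
    sc <- profiles[[nm]]
    if (inherits(sc, "pgs_profile")) sc <- sc$score
    if (length(sc) != length(ids))
      stop("profile ", nm, " is not aligned with ids", call. = FALSE)
    m <- match(feat_ids, ids)
    if (any(is.na(m)))
      stop("individuals missing from profiles: ",
           paste(utils::head(feat_ids[is.na(m)], 10), collapse = ", "),
           call. = FALSE)
    v <- sc[m]
    out <- cbind(out, (v - mean(v)) / stats::sd(v))
    colnames(out)[ncol(out)] <- nm
  }
  out
}
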