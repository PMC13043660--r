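#' Seasonal encoding of sample collection dates
#'
#' Maps a day of year onto the unit circle with two periodic functions,
#' s1 = sin(2*pi*doy/365) and s2 = cos(2*pi*doy/365), so that one full
#' revolution corresponds to a one-year cycle. Day 366 (leap day) is mapped
#' to 365 before encoding.
#'
#' @param doy day-of-year, numeric vector with values in [1, 366].
#' @return data.frame with columns \code{s1}, \code{s2}, \code{doy}.
#' @export
encode_seasonality <- function(doy) {
  if (any(!is.finite(doy)) || any(doy < 1 | doy > 366))
    stop("doy must lie in [1, 366]", call. = FALSE)
  doy <- ifelse(doy > 365, 365, doy)
  ang <- 2 * pi * doy / 365
  data.frame(s1 = sin(ang), s2 = cos(ang), doy = doy)
}

#' Minor allele frequency from dosages
#'
#' @param dosages numeric vector in [0,2]; NA = missing genotype.
#' @return MAF = min(p, 1-p) with p the alt-allele frequency
#'   mean(dosage)/2 over non-missing entries.
#' @export
compute_maf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) stop("all dosages missing", call. = FALSE)
  p <- mean(d) / 2
  min(p, 1 - p)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the heterozygote count: given the sample size
#' and minor-allele count, the two-sided p-value is the sum of the
#' probabilities of all attainable heterozygote counts whose conditional
#' probability under HWE does not exceed that of the observed count.
#' Probabilities are computed on the log scale for numerical stability.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major hom, het, minor hom).
#' @return two-sided exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("at least one genotype required", call. = FALSE)
  n_minor <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_minor == 0) return(1)
  # attainable heterozygote counts share the parity of the minor-allele count
  het <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  hom_minor <- (n_minor - het) / 2
  hom_major <- n - het - hom_minor
  logp <- lgamma(n + 1) - lgamma(hom_major + 1) - lgamma(het + 1) -
    lgamma(hom_minor + 1) + het * log(2) +
    lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) - lgamma(2 * n + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[het == n_Aa]
  min(1, sum(prob[prob <= obs * (1 + 1e-10)]))
}

#' Variant quality control
#'
#' Removes variants with call rate <= 1 - \code{call_rate_max_missing}
#' (default: missingness >= 5\%), minor allele frequency below
#' \code{maf_min} (strict <), or exact Hardy-Weinberg p-value below
#' \code{hwe_p_min}. Dosages are rounded to the nearest genotype for the
#' HWE genotype counts. A variant failing several filters is counted once
#' per criterion but removed once.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param call_rate_max_missing missingness fraction at/above which a
#'   variant is removed (0.05 realizes "call rate <= 0.95 removed").
#' @param maf_min MAF threshold; variants with MAF < maf_min are removed.
#' @param hwe_p_min HWE exact p threshold; variants with p < hwe_p_min are
#'   removed.
#' @return list with the filtered \code{genotypes} and a \code{report}
#'   (counts removed per criterion and totals).
#' @export
apply_variant_qc <- function(genotypes, call_rate_max_missing = 0.05,
                             maf_min = 0.05, hwe_p_min = 0.001) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  dos <- genotypes$dosages
  m <- ncol(dos)
  miss_frac <- colMeans(is.na(dos))
  fail_call <- miss_frac >= call_rate_max_missing
  maf <- apply(dos, 2, function(d)
    if (all(is.na(d))) 0 else compute_maf(d))
  fail_maf <- maf < maf_min
  hwe_p <- apply(dos, 2, function(d) {
    d <- round(d[!is.na(d)])
    if (!length(d)) return(1)
    hwe_exact_test(sum(d == 0), sum(d == 1), sum(d == 2))
  })
  fail_hwe <- hwe_p < hwe_p_min
  keep <- !(fail_call | fail_maf | fail_hwe)
  if (!any(keep)) warning("variant QC removed every variant")
  report <- list(n_input = m, n_retained = sum(keep),
                 n_fail_call_rate = sum(fail_call),
                 n_fail_maf = sum(fail_maf),
                 n_fail_hwe = sum(fail_hwe))
  list(genotypes = genotype_matrix(dos[, keep, drop = FALSE],
                                   genotypes$variants[keep, , drop = FALSE]),
       report = report)
}

#' Principal components of the dosage matrix
#'
#' Missing dosages are mean-imputed per variant, columns are standardized
#' (zero-variance variants dropped), and the first k principal-component
#' scores are returned, ordered by decreasing explained variance. Used as
#' ancestry covariates in association models.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param k number of components (default 3).
#' @return matrix n x k of scores, columns PC1..PCk, with the proportion of
#'   variance explained attached as attribute \code{"explained"}.
#' @export
genotype_pca <- function(genotypes, k = 3L) {
  dos <- genotypes$dosages
  for (j in seq_len(ncol(dos))) {
    nas <- is.na(dos[, j])
    if (any(nas)) dos[nas, j] <- mean(dos[, j], na.rm = TRUE)
  }
  sds <- apply(dos, 2, stats::sd)
  dos <- dos[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(dos, center = TRUE, scale. = TRUE)
  if (k > ncol(pc$x)) stop("k exceeds the rank of the dosage matrix", call. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  attr(scores, "explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  scores
}

#' Inverse rank normalization
#'
#' Maps values through their ranks to standard-normal quantiles,
#' y_i = qnorm((r_i - 3/8) / (n + 1/4)) (Blom offset), with average ranks
#' for ties. Missing entries are passed through untouched.
#'
#' @param values numeric vector with at least 3 non-missing values.
#' @return normalized vector of the same length.
#' @export
inverse_rank_normalize <- function(values) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 3) stop("need >= 3 non-missing values", call. = FALSE)
  if (length(unique(x)) < 2) stop("constant vector cannot be rank-normalized",
                                  call. = FALSE)
  r <- rank(x, ties.method = "average")
  n <- length(x)
  out <- values
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Regress covariates out of a trait
#'
#' Ordinary least squares of the trait on an intercept plus the covariate
#' matrix; returns the residuals. Constant covariate columns are dropped
#' first; remaining rank deficiency is an error naming the collinear
#' columns. Rows with any missing value are excluded (residual NA there).
#'
#' @param trait numeric vector.
#' @param covariate_matrix numeric matrix or data.frame, rows aligned with
#'   the trait.
#' @return residual vector, same length as the trait (NA on incomplete rows).
#' @export
residualize <- function(trait, covariate_matrix) {
  X <- as.matrix(covariate_matrix)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  cc <- stats::complete.cases(X) & !is.na(trait)
  Xc <- X[cc, , drop = FALSE]
  keep <- apply(Xc, 2, function(v) stats::sd(v) > 0)
  Xc <- Xc[, keep, drop = FALSE]
  Xd <- cbind(`(Intercept)` = 1, Xc)
  qr_x <- qr(Xd)
  if (qr_x$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qr_x$pivot[(qr_x$rank + 1):ncol(Xd)]]
    stop("covariate matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- rep(NA_real_, length(trait))
  res[cc] <- stats::lm.fit(Xd, trait[cc])$residuals
  res
}

#' Train-set scaler (z-scoring)
#'
#' \code{fit_scaler} estimates per-variable mean and standard deviation on a
#' training subset; \code{apply_scaler} applies those parameters to any
#' table (in particular the test set, which must never contribute to the
#' scaling parameters). Zero-variance variables are dropped with a warning.
#'
#' @param train_table numeric matrix or data.frame.
#' @return \code{fit_scaler}: list of class \code{scaler_params} with
#'   \code{mean}, \code{sd}, \code{vars}.
#' @export
fit_scaler <- function(train_table) {
  X <- as.matrix(train_table)
  if (!nrow(X)) stop("empty training table", call. = FALSE)
  mu <- colMeans(X, na.rm = TRUE)
  sdv <- apply(X, 2, stats::sd, na.rm = TRUE)
  drop <- !is.finite(sdv) | sdv == 0
  if (any(drop))
    warning("dropping zero-variance variables: ",
            paste(colnames(X)[drop], collapse = ", "))
  structure(list(mean = mu[!drop], sd = sdv[!drop],
                 vars = colnames(X)[!drop]),
            class = "scaler_params")
}

#' @rdname fit_scaler
#' @param table table to transform.
#' @param params a \code{scaler_params} from \code{fit_scaler}.
#' @export
apply_scaler <- function(table, params) {
  stopifnot(inherits(params, "scaler_params"))
  X <- as.matrix(table)[, params$vars, drop = FALSE]
  sweep(sweep(X, 2, params$mean, "-"), 2, params$sd, "/")
}
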