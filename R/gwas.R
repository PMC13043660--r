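#' Univariate GWAS by per-variant linear regression
#'
#' Simple linear regression of an adjusted trait (already residualized on
#' covariates and inverse-rank normalized by the caller) on each variant's
#' dosage, one variant at a time, with complete cases per variant. The
#' two-sided p-value comes from the t distribution with n-2 degrees of
#' freedom. Monomorphic variants (or variants with fewer than 3 complete
#' cases) yield missing results with a warning.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param adjusted_trait numeric vector aligned with the genotype rows.
#' @return data.frame of summary statistics: CHR, POS, ID, A1 (the ALT /
#'   dosage-counted allele), BETA, SE, STAT, P, N.
#' @export
run_univariate_gwas <- function(genotypes, adjusted_trait) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  G <- genotypes$dosages
  y <- as.numeric(adjusted_trait)
  if (length(y) != nrow(G)) stop("trait length mismatch", call. = FALSE)
  m <- ncol(G)
  beta <- se <- tstat <- p <- rep(NA_real_, m)
  nn <- integer(m)
  y_ok <- !is.na(y)
  g_na <- colSums(is.na(G)) > 0

  fit_one <- function(g, yv) {
    n <- length(g)
    sxx <- sum((g - mean(g))^2)
    if (n < 3 || sxx == 0) return(c(NA, NA, NA, NA, n))
    sxy <- sum((g - mean(g)) * (yv - mean(yv)))
    syy <- sum((yv - mean(yv))^2)
    b <- sxy / sxx
    rss <- syy - b * sxy
    s <- sqrt(max(rss, 0) / ((n - 2) * sxx))
    if (s == 0) return(c(b, 0, Inf * sign(b), 0, n))
    t <- b / s
    c(b, s, t, 2 * stats::pt(-abs(t), n - 2), n)
  }

  # fast path: variants with no missing dosage share the same complete cases
  simple <- which(!g_na)
  if (length(simple)) {
    Gs <- G[y_ok, simple, drop = FALSE]
    yv <- y[y_ok]
    n <- length(yv)
    gm <- colMeans(Gs)
    Gc <- sweep(Gs, 2, gm, "-")
    yc <- yv - mean(yv)
    sxx <- colSums(Gc^2)
    sxy <- as.numeric(crossprod(Gc, yc))
    syy <- sum(yc^2)
    ok <- sxx > 0 & n >= 3
    b <- ifelse(ok, sxy / sxx, NA_real_)
    rss <- pmax(syy - b * sxy, 0)
    s <- ifelse(ok, sqrt(rss / ((n - 2) * sxx)), NA_real_)
    t <- ifelse(ok & s > 0, b / s, ifelse(ok & s == 0, Inf * sign(b), NA_real_))
    pv <- ifelse(ok, ifelse(is.finite(t), 2 * stats::pt(-abs(t), n - 2), 0),
                 NA_real_)
    beta[simple] <- b; se[simple] <- s; tstat[simple] <- t; p[simple] <- pv
    nn[simple] <- n
  }
  for (j in which(g_na)) {
    cc <- y_ok & !is.na(G[, j])
    r <- fit_one(G[cc, j], y[cc])
    beta[j] <- r[1]; se[j] <- r[2]; tstat[j] <- r[3]; p[j] <- r[4]
    nn[j] <- r[5]
  }
  n_mono <- sum(is.na(beta))
  if (n_mono) warning(n_mono, " variant(s) monomorphic or underpowered; results missing")
  data.frame(CHR = genotypes$variants$chrom, POS = genotypes$variants$pos,
             ID = genotypes$variants$id, A1 = genotypes$variants$alt,
             BETA = beta, SE = se, STAT = tstat, P = p, N = nn,
             stringsAsFactors = FALSE)
}

#' Build a cytokine network around a central trait
#'
#' The network entering the multivariate test is the central cytokine plus
#' every trait whose absolute Pearson correlation with it (on pairwise
#' complete observations) exceeds the threshold.
#'
#' @param trait_matrix numeric matrix, individuals x traits (named columns).
#' @param central name of the central trait.
#' @param threshold correlation threshold (default 0.2, strict >).
#' @return list of class \code{cytokine_network}: \code{central},
#'   \code{members}, \code{correlations}.
#' @export
build_cytokine_network <- function(trait_matrix, central, threshold = 0.2) {
  if (!central %in% colnames(trait_matrix))
    stop("central trait not found: ", central, call. = FALSE)
  r <- suppressWarnings(
    stats::cor(trait_matrix, trait_matrix[, central],
               use = "pairwise.complete.obs")[, 1])
  members <- union(central, colnames(trait_matrix)[!is.na(r) & abs(r) > threshold])
  structure(list(central = central, members = members, correlations = r),
            class = "cytokine_network")
}

#' Multivariate (canonical-correlation) GWAS
#'
#' For each variant, tests the association between the dosage vector and the
#' linear combination of the network's adjusted cytokine responses that
#' maximizes their correlation. For a single variant against q traits the
#' squared canonical correlation rho^2 equals the R^2 of the least-squares
#' regression of the dosage on the traits; the test statistic is Wilks'
#' lambda = 1 - rho^2, transformed to an F statistic
#' F = ((n-q-1)/q) * rho^2/(1-rho^2) with (q, n-q-1) degrees of freedom
#' (exact in this rank-1 case). Canonical loadings are the regression
#' coefficient vector scaled to unit norm, sign fixed so the
#' largest-magnitude loading is positive.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param network_trait_matrix numeric matrix of the adjusted member traits.
#' @return data.frame: CHR, POS, ID, A1, RHO, WILKS, F, P, N, LOADINGS
#'   (semicolon-joined).
#' @export
run_multivariate_gwas <- function(genotypes, network_trait_matrix) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  Y <- as.matrix(network_trait_matrix)
  q <- ncol(Y)
  if (q < 1) stop("need at least one member trait", call. = FALSE)
  G <- genotypes$dosages
  m <- ncol(G)
  rho <- f <- p <- rep(NA_real_, m)
  nn <- integer(m)
  loadings <- character(m)
  for (j in seq_len(m)) {
    cc <- stats::complete.cases(Y) & !is.na(G[, j])
    n <- sum(cc)
    nn[j] <- n
    if (q >= n - 1) stop("too few complete cases for ", q, " traits", call. = FALSE)
    g <- G[cc, j]
    if (stats::sd(g) == 0 || n < q + 2) next
    fit <- stats::lm.fit(cbind(1, Y[cc, , drop = FALSE]), g)
    res <- fit$residuals
    tss <- sum((g - mean(g))^2)
    r2 <- max(0, min(1, 1 - sum(res^2) / tss))
    co <- fit$coefficients[-1]
    co[is.na(co)] <- 0
    nrm <- sqrt(sum(co^2))
    if (nrm > 0) {
      co <- co / nrm
      if (co[which.max(abs(co))] < 0) co <- -co
    }
    rho[j] <- sqrt(r2)
    fj <- ((n - q - 1) / q) * (r2 / (1 - r2))
    f[j] <- fj
    p[j] <- stats::pf(fj, q, n - q - 1, lower.tail = FALSE)
    loadings[j] <- paste(formatC(co, format = "g", digits = 8), collapse = ";")
  }
  data.frame(CHR = genotypes$variants$chrom, POS = genotypes$variants$pos,
             ID = genotypes$variants$id, A1 = genotypes$variants$alt,
             RHO = rho, WILKS = 1 - rho^2, F = f, P = p, N = nn,
             LOADINGS = loadings, stringsAsFactors = FALSE)
}

#' Identify lead SNPs
#'
#' Greedy selection: repeatedly take the smallest remaining p-value below
#' the genome-wide significance threshold, report the variant as a lead
#' SNP, and mask all variants within +/- window_bp on the same chromosome.
#' Ties on p are broken by (chrom, pos, ID) ascending.
#'
#' @param sumstats data.frame with CHR, POS, ID, P columns.
#' @param window_bp half-window in base pairs (default 500000).
#' @param threshold significance threshold (default 5e-8).
#' @return subset of \code{sumstats} rows that are lead SNPs (possibly empty).
#' @export
find_lead_snps <- function(sumstats, window_bp = 500000, threshold = 5e-8) {
  ss <- sumstats[!is.na(sumstats$P) & sumstats$P < threshold, , drop = FALSE]
  ss <- ss[order(ss$P, ss$CHR, ss$POS, ss$ID), , drop = FALSE]
  leads <- integer(0)
  masked <- rep(FALSE, nrow(ss))
  for (i in seq_len(nrow(ss))) {
    if (masked[i]) next
    leads <- c(leads, i)
    masked <- masked | (ss$CHR == ss$CHR[i] & abs(ss$POS - ss$POS[i]) <= window_bp)
  }
  ss[leads, , drop = FALSE]
}

#' Genomic inflation factor
#'
#' lambda_GC = median of the chi-square(1 df) quantiles of the p-values
#' divided by the null median of chi-square(1). Values near 1 indicate
#' well-calibrated association tests.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return lambda_GC.
#' @export
genomic_inflation <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (length(p) < 100) stop("need >= 100 p-values", call. = FALSE)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}
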