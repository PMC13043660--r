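#' Simulation configuration for synthetic stimulated-cytokine cohorts
#'
#' Defines the generative model of a synthetic cohort: LD-block genotype
#' structure (haplotype pools per block), covariate distributions, and a
#' cytokine trait whose variance is partitioned between planted SNP effects,
#' environmental/biological effects (seasonality, monocyte counts, age, CMV
#' serostatus, sex, hormones) and Gaussian noise on the log2 scale.
#'
#' Three archetypes anchor the variance partition:
#' \describe{
#'   \item{TCR_LIKE}{genetics-dominant: a few moderate SNP effects
#'     (default 5 causal variants, h2 = 0.25) and no seasonal or monocyte
#'     effect, as observed for adaptive (T-cell receptor) stimulations.}
#'   \item{TLR_LIKE}{environment-dominant: many tiny SNP effects
#'     (default 20 causal, h2 = 0.05) with strong seasonality and monocyte
#'     effects, as observed for innate (Toll-like receptor) stimulations.}
#'   \item{NULL}{pure noise; every planted effect is zero.}
#' }
#'
#' @param n_individuals cohort size.
#' @param n_blocks number of independent LD blocks.
#' @param block_size variants per block.
#' @param haplotype_pool_size distinct haplotypes per block (>= 2).
#' @param maf_range allele-frequency range, within (0, 0.5].
#' @param archetype one of "TCR_LIKE", "TLR_LIKE", "NULL".
#' @param n_causal number of causal variants (each in a distinct block).
#' @param h2_genetic fraction of trait variance from planted SNPs.
#' @param env_effects named list of standardized effect sizes with entries
#'   \code{a}, \code{b} (seasonal sin/cos amplitudes), \code{monocytes},
#'   \code{age}, \code{cmv}, \code{sex}, \code{hormone}.
#' @param noise_sd residual standard deviation on the log2 scale; by default
#'   chosen so the total variance is approximately 1.
#' @param missing_rate MCAR missingness rate applied to the cytokine panel.
#' @param n_traits number of cytokine traits to generate.
#' @param seed integer seed; all randomness derives from it.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_individuals,
                       n_blocks = 50L,
                       block_size = 40L,
                       haplotype_pool_size = 8L,
                       maf_range = c(0.05, 0.5),
                       archetype = c("TCR_LIKE", "TLR_LIKE", "NULL"),
                       n_causal = NULL,
                       h2_genetic = NULL,
                       env_effects = NULL,
                       noise_sd = NULL,
                       missing_rate = 0,
                       n_traits = 1L,
                       seed = 1L) {
  archetype <- match.arg(archetype)
  if (n_individuals < 0 || n_blocks <= 0 || block_size <= 0)
    stop("invalid config: non-positive dimensions", call. = FALSE)
  if (haplotype_pool_size < 2)
    stop("invalid config: haplotype_pool_size must be >= 2", call. = FALSE)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("invalid config: maf_range must lie within (0, 0.5]", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1)
    stop("invalid config: missing_rate must be in [0,1]", call. = FALSE)

  defaults <- switch(archetype,
    TCR_LIKE = list(n_causal = 5L, h2 = 0.25,
                    env = list(a = 0, b = 0, monocytes = 0,
                               age = 0.1, cmv = 0.2, sex = 0.1, hormone = 0)),
    TLR_LIKE = list(n_causal = 20L, h2 = 0.05,
                    env = list(a = 0.4, b = 0.25, monocytes = 0.4,
                               age = 0.1, cmv = 0.1, sex = 0.05, hormone = 0)),
    "NULL"   = list(n_causal = 0L, h2 = 0,
                    env = list(a = 0, b = 0, monocytes = 0,
                               age = 0, cmv = 0, sex = 0, hormone = 0)))
  if (is.null(n_causal)) n_causal <- defaults$n_causal
  if (is.null(h2_genetic)) h2_genetic <- defaults$h2
  env <- defaults$env
  if (!is.null(env_effects)) {
    bad <- setdiff(names(env_effects), names(env))
    if (length(bad)) stop("unknown env_effects: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    env[names(env_effects)] <- env_effects
  }
  if (n_causal > n_blocks * block_size)
    stop("invalid config: n_causal exceeds the variant panel", call. = FALSE)
  if (n_causal > n_blocks)
    stop("invalid config: n_causal must not exceed n_blocks (one causal variant per block)",
         call. = FALSE)
  if (h2_genetic > 0 && n_causal == 0)
    stop("invalid config: h2_genetic > 0 requires n_causal > 0", call. = FALSE)

  env_var <- .env_variance(env)
  if (h2_genetic + env_var > 1)
    stop("invalid config: h2_genetic + environmental variance exceeds 1",
         call. = FALSE)
  if (is.null(noise_sd))
    noise_sd <- sqrt(max(1 - h2_genetic - env_var, 0.05))
  if (noise_sd <= 0) stop("invalid config: noise_sd must be positive", call. = FALSE)

  structure(list(n_individuals = as.integer(n_individuals),
                 n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size),
                 haplotype_pool_size = as.integer(haplotype_pool_size),
                 maf_range = maf_range, archetype = archetype,
                 n_causal = as.integer(n_causal), h2_genetic = h2_genetic,
                 env_effects = env, noise_sd = noise_sd,
                 missing_rate = missing_rate, n_traits = as.integer(n_traits),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# theoretical variance contribution of the environmental terms:
# s1, s2 have variance ~ 1/2 over a uniform year; standardized continuous
# covariates have variance 1; sex is Bernoulli(0.5), CMV Bernoulli(0.35)
.env_variance <- function(env) {
  env$a^2 * 0.5 + env$b^2 * 0.5 + env$monocytes^2 + env$age^2 +
    env$hormone^2 + env$cmv^2 * 0.35 * 0.65 + env$sex^2 * 0.25
}

# deterministic sub-seed for (stage, cohort); keeps results < 2^31
.child_seed <- function(seed, stage, cohort_id = 0L) {
  as.integer((abs(as.numeric(seed)) %% 65011) * 33029 +
               stage * 7919 + cohort_id * 104729) %% 2147483629L
}

#' Simulate LD-block genotype dosages
#'
#' Each block carries a pool of \code{haplotype_pool_size} haplotypes whose
#' allele frequencies are drawn uniformly from \code{maf_range}; every
#' individual receives the sum of two haplotypes drawn independently (with
#' replacement) from the pool, so within-block variants are in strong LD
#' while blocks are statistically independent. Positions are laid out so a
#' block spans < 250 kb and consecutive blocks are > 1 Mb apart.
#'
#' The haplotype pools depend only on \code{config$seed}; the individual
#' draws additionally depend on \code{cohort_id}, so two cohorts share the
#' same variant panel and LD structure but contain different individuals.
#'
#' @param config a \code{\link{sim_config}}.
#' @param cohort_id integer distinguishing cohorts drawn from the same pools.
#' @return a \code{genotype_matrix}: list with \code{dosages}
#'   (individuals x variants, values in \{0,1,2\}) and \code{variants}
#'   (data.frame: chrom, pos, id, ref, alt).
#' @export
simulate_genotypes <- function(config, cohort_id = 1L) {
  stopifnot(inherits(config, "sim_config"))
  H <- config$haplotype_pool_size
  B <- config$n_blocks
  L <- config$block_size
  n <- config$n_individuals

  pools <- .build_pools(config)$pools

  dos <- withr::with_seed(.child_seed(config$seed, 2L, cohort_id), {
    blocks <- lapply(pools, function(hap) {
      i1 <- sample.int(H, n, replace = TRUE)
      i2 <- sample.int(H, n, replace = TRUE)
      hap[i1, , drop = FALSE] + hap[i2, , drop = FALSE]
    })
    do.call(cbind, blocks)
  })

  # at most 100 blocks per chromosome keeps positions within integer range
  spacing <- max(1L, floor(249000 / L))
  chrom_of_block <- (seq_len(B) - 1L) %/% 100L + 1L
  block_slot <- (seq_len(B) - 1L) %% 100L
  pos <- unlist(lapply(seq_len(B), function(b)
    block_slot[b] * 2000000L + 1L + (seq_len(L) - 1L) * spacing))
  ids <- sprintf("rs%d", seq_len(B * L))
  variants <- data.frame(chrom = as.character(rep(chrom_of_block, each = L)),
                         pos = as.integer(pos), id = ids,
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  dimnames(dos) <- list(sprintf("ind_%04d", seq_len(n)), ids)
  genotype_matrix(dos, variants)
}

#' Construct a genotype_matrix container
#'
#' @param dosages numeric matrix, individuals x variants, entries in [0,2]
#'   (NA allowed for missing genotypes).
#' @param variants data.frame with columns chrom, pos, id, ref, alt.
#' @return an object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(dosages, variants) {
  stopifnot(is.matrix(dosages), ncol(dosages) == nrow(variants),
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(variants)))
  if (any(variants$pos < 1)) stop("variant pos must be >= 1", call. = FALSE)
  if (any(variants$ref == variants$alt)) stop("ref == alt", call. = FALSE)
  rng <- range(dosages, na.rm = TRUE)
  if (nrow(dosages) > 0 && is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("dosages must lie in [0, 2]", call. = FALSE)
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Simulate biological and environmental covariates
#'
#' Emits age (uniform integers 20-60), sex (binary), BMI (truncated normal,
#' mean 23.5, sd 2.5, bounds 17-32), day-of-year of sample collection
#' (uniform 1-365), five blood immune cell counts and three sex hormones
#' (log-normal; hormone location parameters depend on sex), and CMV
#' serostatus (binary, prevalence 0.35).
#'
#' @inheritParams simulate_genotypes
#' @return data.frame keyed by \code{individual_id}.
#' @export
simulate_covariates <- function(config, cohort_id = 1L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  cols <- c("individual_id", "age", "sex", "bmi", "doy",
            "neutrophils", "monocytes", "lymphocytes", "eosinophils",
            "basophils", "oestradiol", "progesterone", "testosterone", "cmv")
  if (n == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    out$individual_id <- character(0)
    return(out)
  }
  withr::with_seed(.child_seed(config$seed, 3L, cohort_id), {
    age <- sample(20:60, n, replace = TRUE)
    sex <- stats::rbinom(n, 1L, 0.5)
    bmi <- stats::rnorm(n, 23.5, 2.5)
    out_of_bounds <- which(bmi < 17 | bmi > 32)
    while (length(out_of_bounds)) {
      bmi[out_of_bounds] <- stats::rnorm(length(out_of_bounds), 23.5, 2.5)
      out_of_bounds <- which(bmi < 17 | bmi > 32)
    }
    doy <- sample(1:365, n, replace = TRUE)
    cells <- vapply(.cell_meanlog, function(m)
      stats::rlnorm(n, meanlog = m, sdlog = 0.35), numeric(n))
    # hormone location depends on sex: testosterone higher in males,
    # oestradiol/progesterone higher in females
    oestradiol <- stats::rlnorm(n, meanlog = ifelse(sex == 0, 4.6, 3.3), sdlog = 0.5)
    progesterone <- stats::rlnorm(n, meanlog = ifelse(sex == 0, 1.0, -0.7), sdlog = 0.6)
    testosterone <- stats::rlnorm(n, meanlog = ifelse(sex == 1, 1.6, 0.1), sdlog = 0.4)
    cmv <- stats::rbinom(n, 1L, 0.35)
    data.frame(individual_id = sprintf("ind_%04d", seq_len(n)),
               age = age, sex = sex, bmi = bmi, doy = doy,
               neutrophils = cells[, 1], monocytes = cells[, 2],
               lymphocytes = cells[, 3], eosinophils = cells[, 4],
               basophils = cells[, 5],
               oestradiol = oestradiol, progesterone = progesterone,
               testosterone = testosterone, cmv = cmv,
               stringsAsFactors = FALSE)
  })
}

.cell_meanlog <- c(neutrophils = 1.5, monocytes = -0.7, lymphocytes = 0.6,
                   eosinophils = -1.6, basophils = -3.0)

#' Simulate log2-scale cytokine responses with recorded ground truth
#'
#' The trait is generated on the log2 scale as
#' intercept + sum(beta_j g_j) + gamma_age age_std + gamma_cmv CMV +
#' a s1 + b s2 + gamma_mono monocytes_std + gamma_sex sex + noise,
#' where s1/s2 are the seasonal sine/cosine encodings of the collection day.
#' Causal variants are placed in distinct LD blocks and their effect sizes
#' are scaled analytically (using the known pool allele frequencies) so the
#' planted-SNP variance fraction equals \code{h2_genetic}. Continuous
#' covariates enter standardized by their theoretical moments so the same
#' coefficients apply identically in any cohort drawn from the configuration.
#'
#' @param genotypes a \code{genotype_matrix} from \code{\link{simulate_genotypes}}.
#' @param covariates data.frame from \code{\link{simulate_covariates}}.
#' @param config the same \code{\link{sim_config}}.
#' @param cohort_id cohort stream for the noise draw; the planted
#'   coefficients themselves are cohort-independent.
#' @param intercept_shift constant added to the log2 trait (models, e.g., a
#'   stimulus-concentration difference between cohorts).
#' @return list with \code{panel} (matrix n x n_traits, log2 pg/ml) and
#'   \code{truth} (per-trait list of planted coefficients and theoretical
#'   variance fractions).
#' @export
simulate_cytokines <- function(genotypes, covariates, config,
                               cohort_id = 1L, intercept_shift = 0) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(covariates)
  env <- config$env_effects
  s <- encode_seasonality(covariates$doy)
  age_std <- (covariates$age - 40) / sqrt((41^2 - 1) / 12)
  mono_std <- (log(covariates$monocytes) - .cell_meanlog[["monocytes"]]) / 0.35
  horm_std <- (log(covariates$testosterone) -
                 ifelse(covariates$sex == 1, 1.6, 0.1)) / 0.4

  pool_freq <- .pool_allele_freq(config)
  panel <- matrix(NA_real_, nrow = n, ncol = config$n_traits,
                  dimnames = list(covariates$individual_id,
                                  sprintf("cytokine_%d", seq_len(config$n_traits))))
  truth <- vector("list", config$n_traits)
  intercept <- 5

  for (t in seq_len(config$n_traits)) {
    causal_ids <- character(0)
    beta <- numeric(0)
    if (config$n_causal > 0) {
      withr::with_seed(.child_seed(config$seed, 10L + t), {
        blocks <- sample.int(config$n_blocks, config$n_causal)
        within <- sample.int(config$block_size, config$n_causal, replace = TRUE)
        idx <- (blocks - 1L) * config$block_size + within
        causal_ids <- genotypes$variants$id[idx]
        raw <- stats::rnorm(config$n_causal)
        p <- pool_freq[idx]
        denom <- sum(raw^2 * 2 * p * (1 - p))
        if (denom <= 0)
          stop("invalid config: requested h2 unattainable with the drawn MAFs",
               call. = FALSE)
        beta <- raw * sqrt(config$h2_genetic / denom)
      })
    }
    gcomp <- if (length(causal_ids))
      as.numeric(genotypes$dosages[, causal_ids, drop = FALSE] %*% beta)
    else rep(0, n)
    envcomp <- env$age * age_std + env$cmv * covariates$cmv +
      env$a * s$s1 + env$b * s$s2 + env$monocytes * mono_std +
      env$sex * covariates$sex + env$hormone * horm_std
    eps <- withr::with_seed(.child_seed(config$seed, 20L + t, cohort_id),
                            stats::rnorm(n, 0, config$noise_sd))
    y <- intercept + intercept_shift + gcomp + envcomp + eps
    panel[, t] <- y

    total <- config$h2_genetic + .env_variance(env) + config$noise_sd^2
    truth[[t]] <- list(
      causal_variant_ids = causal_ids,
      causal_betas = beta,
      env_betas = env,
      intercept = intercept + intercept_shift,
      realized_variance_fractions = list(
        genetic = config$h2_genetic / total,
        environment = .env_variance(env) / total,
        noise = config$noise_sd^2 / total))
  }
  list(panel = panel, truth = truth)
}

# haplotype pools per block; every variant is guaranteed polymorphic in the
# pool (allele count clamped to [1, H-1]), so its marginal allele frequency
# is exactly n_ones/H
.build_pools <- function(config) {
  H <- config$haplotype_pool_size
  L <- config$block_size
  withr::with_seed(.child_seed(config$seed, 1L), {
    freq <- numeric(0)
    pools <- lapply(seq_len(config$n_blocks), function(b) {
      p <- stats::runif(L, config$maf_range[1], config$maf_range[2])
      n_ones <- pmin(pmax(round(H * p), 1L), H - 1L)
      hap <- matrix(0L, nrow = H, ncol = L)
      for (j in seq_len(L)) hap[sample.int(H, n_ones[j]), j] <- 1L
      attr(hap, "freq") <- n_ones / H
      hap
    })
    list(pools = pools,
         freq = unlist(lapply(pools, attr, "freq")))
  })
}

.pool_allele_freq <- function(config) .build_pools(config)$freq

#' Mask cytokine panel entries completely at random
#'
#' @param panel numeric matrix of cytokine responses.
#' @param rate probability in [0,1] that each entry is masked.
#' @param seed integer seed.
#' @return the panel with masked entries set to NA; the logical mask is
#'   attached as attribute \code{"miss_mask"}.
#' @export
inject_missingness <- function(panel, rate, seed = 1L) {
  if (rate < 0 || rate > 1) stop("rate must be in [0,1]", call. = FALSE)
  mask <- withr::with_seed(seed, matrix(stats::runif(length(panel)) < rate,
                                        nrow = nrow(panel)))
  out <- panel
  out[mask] <- NA_real_
  attr(out, "miss_mask") <- mask
  out
}

#' Simulate a complete cohort (genotypes, covariates, cytokines)
#'
#' @inheritParams simulate_genotypes
#' @param intercept_shift constant log2 shift of the cytokine traits.
#' @return object of class \code{sim_cohort}: list with \code{genotypes},
#'   \code{covariates}, \code{cytokines} (log2 matrix), \code{truth},
#'   \code{config}.
#' @export
simulate_cohort <- function(config, cohort_id = 1L, intercept_shift = 0) {
  g <- simulate_genotypes(config, cohort_id)
  cov <- simulate_covariates(config, cohort_id)
  cy <- simulate_cytokines(g, cov, config, cohort_id, intercept_shift)
  panel <- cy$panel
  if (config$missing_rate > 0)
    panel <- inject_missingness(panel, config$missing_rate,
                                .child_seed(config$seed, 90L, cohort_id))
  structure(list(genotypes = g, covariates = cov, cytokines = panel,
                 truth = cy$truth, config = config),
            class = "sim_cohort")
}

#' Simulate a replication cohort sharing the training cohort's ground truth
#'
#' Draws new individuals from the same haplotype pools and covariate
#' distributions, applies the identical planted coefficients, and adds a
#' constant intercept shift on the log2 scale (emulating, e.g., a different
#' stimulus concentration between cohorts). Because downstream evaluation is
#' rank-based, the shift does not affect Spearman correlations.
#'
#' @inheritParams simulate_cohort
#' @export
simulate_replication_cohort <- function(config, intercept_shift = 0,
                                        cohort_id = 2L) {
  simulate_cohort(config, cohort_id = cohort_id,
                  intercept_shift = intercept_shift)
}
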