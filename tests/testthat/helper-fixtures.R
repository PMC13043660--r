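# shared fixture builders; everything is generated in code at test time

small_cohort <- local({
  cache <- new.env()
  function(archetype = "NULL", n = 200, seed = 5, ...) {
    key <- paste(archetype, n, seed, ...)
    if (is.null(cache[[key]])) {
      cfg <- sim_config(n, n_blocks = 10, block_size = 20,
                        archetype = archetype, seed = seed, ...)
      cache[[key]] <- simulate_cohort(cfg)
    }
    cache[[key]]
  }
})

# random sumstats table + matching genotype panel for clumping tests
random_clump_instance <- function(seed, max_variants = 50, n_ind = 60) {
  set.seed(seed)
  m <- sample(5:max_variants, 1)
  chrom <- sample(c("1", "2"), m, replace = TRUE)
  pos <- sample.int(2e6, m)
  ids <- paste0("v", seq_len(m))
  # blocky LD: consecutive variants share a latent genotype with high prob.
  g <- matrix(NA_real_, n_ind, m)
  base <- rbinom(n_ind, 2, runif(1, 0.1, 0.5))
  for (j in seq_len(m)) {
    if (j == 1 || runif(1) < 0.4) base <- rbinom(n_ind, 2, runif(1, 0.1, 0.5))
    flip <- runif(n_ind) < 0.1
    g[, j] <- ifelse(flip, rbinom(n_ind, 2, 0.3), base)
  }
  colnames(g) <- ids
  ss <- data.frame(CHR = chrom, POS = pos, ID = ids, A1 = "G",
                   BETA = rnorm(m), SE = 1,
                   P = 10^runif(m, -9, 0), N = n_ind,
                   stringsAsFactors = FALSE)
  gm <- genotype_matrix(g, data.frame(chrom = chrom, pos = pos, id = ids,
                                      ref = "A", alt = "G",
                                      stringsAsFactors = FALSE))
  list(sumstats = ss, genotypes = gm)
}

# exhaustive reference clumping: no sorting tricks, literal restatement of
# the greedy rule with full scans
clump_oracle <- function(ss, gm, params) {
  ss <- ss[!is.na(ss$P), , drop = FALSE]
  assigned <- rep(FALSE, nrow(ss))
  index_ids <- character(0)
  repeat {
    cand <- which(!assigned & ss$P < params$p1)
    if (!length(cand)) break
    ord <- cand[order(ss$P[cand], ss$CHR[cand], ss$POS[cand], ss$ID[cand])]
    i <- ord[1]
    assigned[i] <- TRUE
    index_ids <- c(index_ids, ss$ID[i])
    for (j in seq_len(nrow(ss))) {
      if (assigned[j] || is.na(ss$P[j]) || ss$P[j] >= params$p2) next
      if (ss$CHR[j] != ss$CHR[i]) next
      if (abs(ss$POS[j] - ss$POS[i]) > params$window_kb * 1000) next
      if (!(ss$ID[j] %in% colnames(gm$dosages))) next
      r <- suppressWarnings(stats::cor(gm$dosages[, ss$ID[i]],
                                       gm$dosages[, ss$ID[j]]))
      if (!is.na(r) && r^2 > params$r2_min) assigned[j] <- TRUE
    }
  }
  index_ids
}

# full-enumeration HWE oracle: direct evaluation of the conditional
# distribution of the heterozygote count via choose() products
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_minor <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  probs <- vapply(hets, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    exp(lchoose(n, hom_major) + lchoose(n - hom_major, h) + h * log(2) -
          (lchoose(2 * n, n_minor)))
  }, numeric(1))
  probs <- probs / sum(probs)
  obs <- probs[hets == n_Aa]
  min(1, sum(probs[probs <= obs * (1 + 1e-10)]))
}
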