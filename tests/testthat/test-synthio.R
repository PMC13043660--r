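test_that("genotype simulation has the declared shape, codomain and LD structure", {
  cfg <- sim_config(100, n_blocks = 10, block_size = 20, archetype = "NULL",
                    seed = 1)
  g <- simulate_genotypes(cfg)
  expect_equal(dim(g$dosages), c(100, 200))
  expect_true(all(g$dosages %in% c(0, 1, 2)))
  expect_equal(nrow(g$variants), 200)

  # block span < 250 kb, consecutive blocks > 1 Mb apart
  pos_by_block <- split(g$variants$pos, rep(1:10, each = 20))
  spans <- vapply(pos_by_block, function(p) diff(range(p)), numeric(1))
  expect_true(all(spans < 250000))
  gaps <- vapply(1:9, function(b)
    min(pos_by_block[[b + 1]]) - max(pos_by_block[[b]]), numeric(1))
  expect_true(all(gaps > 1e6))

  # pool of 2 haplotypes: every within-block pair is in perfect LD
  cfg2 <- sim_config(200, n_blocks = 2, block_size = 5,
                     haplotype_pool_size = 2, archetype = "NULL", seed = 2)
  g2 <- simulate_genotypes(cfg2)
  block1 <- g2$dosages[, 1:5]
  r2 <- cor(block1)^2
  expect_true(all(abs(r2 - 1) < 1e-12))
})

test_that("cross-block dosages are independent (mean r^2 near 1/n)", {
  cfg <- sim_config(2000, n_blocks = 10, block_size = 10,
                    archetype = "NULL", seed = 3)
  g <- simulate_genotypes(cfg)
  r <- cor(g$dosages)
  block_of <- rep(1:10, each = 10)
  cross <- r[outer(block_of, block_of, "!=")]^2
  expect_lt(mean(cross), 0.05)
})

test_that("simulation is deterministic and invalid configs error", {
  cfg <- sim_config(50, n_blocks = 6, block_size = 6, archetype = "TCR_LIKE",
                    seed = 9)
  expect_identical(simulate_cohort(cfg)$cytokines, simulate_cohort(cfg)$cytokines)
  expect_error(sim_config(-1, archetype = "NULL"), "non-positive")
  expect_error(sim_config(10, haplotype_pool_size = 1, archetype = "NULL"),
               "haplotype_pool_size")
  expect_error(sim_config(10, maf_range = c(0, 0.6), archetype = "NULL"),
               "maf_range")
  expect_error(sim_config(10, archetype = "NULL", h2_genetic = 0.3,
                          n_causal = 0), "n_causal")
  expect_error(sim_config(10, archetype = "TCR_LIKE", h2_genetic = 0.9,
                          env_effects = list(a = 1)), "exceeds 1")
})

test_that("covariate tables have the full schema and calibrated distributions", {
  cfg0 <- sim_config(0, archetype = "NULL", seed = 1)
  empty <- simulate_covariates(cfg0)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("individual_id", "age", "sex", "bmi", "doy", "monocytes",
                    "oestradiol", "testosterone", "cmv") %in% names(empty)))

  cfg <- sim_config(10000, archetype = "NULL", seed = 4)
  cov <- simulate_covariates(cfg)
  expect_identical(cov, simulate_covariates(cfg))
  expect_true(all(cov$age >= 20 & cov$age <= 60))
  expect_true(all(cov$bmi >= 17 & cov$bmi <= 32))
  expect_true(all(cov$doy >= 1 & cov$doy <= 365))
  se <- sqrt(0.35 * 0.65 / 10000)
  expect_lt(abs(mean(cov$cmv) - 0.35), 3 * se)
})

test_that("NULL-archetype traits are pure noise", {
  co <- small_cohort("NULL", n = 1000, seed = 11)
  y <- co$cytokines[, 1]
  lim <- 4 / sqrt(1000)
  for (v in c("age", "sex", "bmi", "monocytes", "cmv"))
    expect_lt(abs(cor(y, co$covariates[[v]])), lim)
  expect_lt(abs(cor(y, co$genotypes$dosages[, 7])), lim)
})

test_that("TCR-like planted heritability is recovered by OLS on the causal set", {
  cfg <- sim_config(5000, n_blocks = 10, block_size = 20,
                    archetype = "TCR_LIKE", seed = 13)
  co <- simulate_cohort(cfg)
  tr <- co$truth[[1]]
  g <- co$genotypes$dosages[, tr$causal_variant_ids, drop = FALSE]
  r2 <- summary(lm(co$cytokines[, 1] ~ g))$r.squared
  # R^2 is the genetic share of total variance (~0.25 of ~1)
  expect_lt(abs(r2 * var(co$cytokines[, 1]) - 0.25), 0.05)
})

test_that("seasonal amplitude is recovered from solstice-quarter contrast", {
  cfg <- sim_config(6000, n_blocks = 2, block_size = 5, archetype = "TLR_LIKE",
                    env_effects = list(a = 1, b = 0, monocytes = 0, age = 0,
                                       cmv = 0, sex = 0, hormone = 0),
                    n_causal = 0, h2_genetic = 0, noise_sd = 0.3, seed = 15)
  co <- simulate_cohort(cfg)
  y <- co$cytokines[, 1]
  doy <- co$covariates$doy
  # quarters centered on the s1 extrema (doy ~ 91 and ~ 274)
  q_up <- doy > 91 - 45 & doy < 91 + 46
  q_dn <- doy > 274 - 45 & doy < 274 + 46
  observed <- mean(y[q_up]) - mean(y[q_dn])
  # analytic mean of sin over a quarter centered on the extremum:
  # (1/(pi/2)) * int_{-pi/4}^{pi/4} cos(t) dt = 2*sqrt(2)/pi per side
  expected <- 2 * (2 * sqrt(2) / pi)
  expect_lt(abs(observed - expected), 0.1)
})

test_that("variance bookkeeping matches the recorded truth at large n", {
  for (arch in c("TCR_LIKE", "TLR_LIKE")) {
    cfg <- sim_config(5000, n_blocks = 25, block_size = 10, archetype = arch,
                      seed = 17)
    co <- simulate_cohort(cfg)
    tr <- co$truth[[1]]
    y <- co$cytokines[, 1]
    g <- co$genotypes$dosages[, tr$causal_variant_ids, drop = FALSE]
    gen_var <- if (ncol(g)) var(as.numeric(g %*% tr$causal_betas)) else 0
    expect_lt(abs(gen_var / var(y) -
                    tr$realized_variance_fractions$genetic), 0.05)
  }
})

test_that("MCAR missingness injection is calibrated and records its mask", {
  panel <- matrix(rnorm(1000 * 11), 1000, 11)
  expect_identical(inject_missingness(panel, 0, seed = 1)[, ], panel)
  expect_true(all(is.na(inject_missingness(panel, 1, seed = 1))))
  m <- inject_missingness(panel, 0.2, seed = 2)
  frac <- mean(is.na(m))
  se <- sqrt(0.2 * 0.8 / length(panel))
  expect_lt(abs(frac - 0.2), 3 * se)
  expect_identical(is.na(m)[, ], attr(m, "miss_mask"))
  expect_error(inject_missingness(panel, 1.2), "rate")
})

test_that("replication cohorts share truth and shift only the intercept", {
  cfg <- sim_config(500, n_blocks = 8, block_size = 10,
                    archetype = "TCR_LIKE", seed = 19)
  r0 <- simulate_replication_cohort(cfg, 0)
  r2 <- simulate_replication_cohort(cfg, 2)
  expect_identical(r0$truth[[1]]$causal_betas,
                   simulate_cohort(cfg)$truth[[1]]$causal_betas)
  # monotone shift: exact rank identity and +2 difference everywhere
  expect_equal(unname(r2$cytokines - r0$cytokines),
               matrix(2, 500, 1), tolerance = 1e-12)
  expect_equal(cor(r0$cytokines[, 1], r2$cytokines[, 1], method = "spearman"), 1)
  # mean shifted by 2 within a t-interval of the unshifted generator mean
  tt <- t.test(r2$cytokines[, 1], r0$cytokines[, 1])
  expect_lt(abs(diff(range(tt$estimate)) - 2), 1e-9)
})
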