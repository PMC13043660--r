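test_that("univariate regression matches the closed-form OLS oracle", {
  set.seed(51)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    g <- rbinom(n, 2, runif(1, 0.1, 0.5))
    if (sd(g) == 0) g[1] <- g[1] + 1
    y <- rnorm(n)
    gm <- genotype_matrix(matrix(g, ncol = 1),
                          data.frame(chrom = "1", pos = 100, id = "v",
                                     ref = "A", alt = "G"))
    ss <- run_univariate_gwas(gm, y)
    # independent oracle: R's QR-based lm fit
    sm <- summary(lm(y ~ g))$coefficients
    expect_lt(abs(ss$BETA - sm[2, 1]), 1e-10)
    expect_lt(abs(ss$SE - sm[2, 2]), 1e-10)
    expect_lt(abs(ss$P - sm[2, 4]), 1e-10)
    expect_lt(abs(ss$STAT - ss$BETA / ss$SE), 1e-8)
  }
})

test_that("perfect association and monomorphic variants are handled", {
  set.seed(53)
  g <- rbinom(50, 2, 0.4)
  gm <- genotype_matrix(cbind(v1 = g, v2 = rep(1, 50)),
                        data.frame(chrom = "1", pos = c(1, 2), id = c("v1", "v2"),
                                   ref = "A", alt = "G"))
  expect_warning(ss <- run_univariate_gwas(gm, g - mean(g)), "monomorphic")
  expect_equal(ss$BETA[1], 1, tolerance = 1e-12)
  expect_lt(ss$P[1], 1e-100)
  expect_true(is.na(ss$BETA[2]))
})

test_that("a planted variant reaches genome-wide significance with high power", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 2000
    g <- rbinom(n, 2, 0.3)
    b <- sqrt(0.05 / (2 * 0.3 * 0.7))
    y <- b * g + rnorm(n, 0, sqrt(0.95))
    gm <- genotype_matrix(matrix(g, ncol = 1, dimnames = list(NULL, "v")),
                          data.frame(chrom = "1", pos = 1, id = "v",
                                     ref = "A", alt = "G"))
    if (run_univariate_gwas(gm, y)$P < 5e-8) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("cytokine networks apply the absolute-correlation threshold", {
  set.seed(55)
  n <- 500
  central <- rnorm(n)
  mk <- function(r) r * central + sqrt(1 - r^2) * rnorm(n)
  # large n keeps the sample correlations close to the targets
  Y <- cbind(c0 = central, t1 = mk(0.25), t2 = mk(0.19), t3 = mk(-0.3))
  net <- build_cytokine_network(Y, "c0")
  expect_true(all(c("c0", "t1", "t3") %in% net$members))
  expect_false("t2" %in% net$members)
  expect_equal(build_cytokine_network(Y, "c0", threshold = 1)$members, "c0")
  expect_setequal(build_cytokine_network(Y, "c0", threshold = 0)$members,
                  colnames(Y))
  expect_error(build_cytokine_network(Y, "nope"), "central")
})

test_that("multivariate test matches the canonical-correlation oracle", {
  set.seed(57)
  n <- 200; q <- 3
  Y <- matrix(rnorm(n * q), n, q)
  g <- rbinom(n, 2, 0.4) + 0.3 * Y[, 1]
  g <- pmin(pmax(g, 0), 2)
  gm <- genotype_matrix(matrix(g, ncol = 1, dimnames = list(NULL, "v")),
                        data.frame(chrom = "1", pos = 1, id = "v",
                                   ref = "A", alt = "G"))
  mv <- run_multivariate_gwas(gm, Y)
  # independent oracle: stats::cancor eigen decomposition
  cc <- cancor(matrix(g, ncol = 1), Y)
  expect_lt(abs(mv$RHO - cc$cor[1]), 1e-10)
  expect_lt(abs(mv$WILKS - (1 - cc$cor[1]^2)), 1e-10)
  # invariance under invertible re-mixing of the member traits
  A <- matrix(c(2, 0.5, -1, 0, 1, 3, 1, 0, 1), 3, 3)
  mv2 <- run_multivariate_gwas(gm, Y %*% A)
  expect_lt(abs(mv$P - mv2$P), 1e-8)
  # loadings have unit norm with the largest-magnitude element positive
  lo <- as.numeric(strsplit(mv$LOADINGS, ";")[[1]])
  expect_equal(sum(lo^2), 1, tolerance = 1e-6)
  expect_gt(lo[which.max(abs(lo))], 0)
})

test_that("q = 1 multivariate test reduces to the univariate regression", {
  co <- small_cohort("NULL", n = 150, seed = 59)
  g10 <- genotype_matrix(co$genotypes$dosages[, 1:10],
                         co$genotypes$variants[1:10, ])
  y <- co$cytokines[, 1]
  uni <- suppressWarnings(run_univariate_gwas(g10, y))
  mv <- run_multivariate_gwas(g10, matrix(y, ncol = 1))
  expect_lt(max(abs(mv$P - uni$P), na.rm = TRUE), 1e-8)
})

test_that("lead SNP selection is greedy over 500 kb windows", {
  ss <- data.frame(CHR = "1", POS = c(1e6, 1.1e6, 1.7e6),
                   ID = c("a", "b", "c"), P = c(1e-9, 1e-8, 2e-9),
                   stringsAsFactors = FALSE)
  leads <- find_lead_snps(ss)
  # a (smallest p) masks b at 100 kb; c at 700 kb survives
  expect_equal(sort(leads$ID), c("a", "c"))
  # 600 kb apart -> both lead
  ss2 <- data.frame(CHR = "1", POS = c(1e6, 1.6e6), ID = c("a", "b"),
                    P = c(1e-9, 1e-8), stringsAsFactors = FALSE)
  expect_equal(nrow(find_lead_snps(ss2)), 2)
  expect_equal(nrow(find_lead_snps(transform(ss2, P = 1e-4))), 0)
  # row-order invariance
  shuffled <- ss[c(3, 1, 2), ]
  expect_equal(sort(find_lead_snps(shuffled)$ID), sort(leads$ID))
})

test_that("genomic inflation is calibrated", {
  expect_equal(genomic_inflation(rep(0.5, 200)), 1, tolerance = 1e-12)
  set.seed(61)
  p <- runif(1e5)
  expect_lt(abs(genomic_inflation(p) - 1), 0.02)
  expect_gt(genomic_inflation(p / 2), 1)
  expect_error(genomic_inflation(runif(50)), "100")
  expect_error(genomic_inflation(c(rep(0.5, 100), 0)), "0, 1")
})

test_that("GWAS p-values match cor.test on individual variants", {
  cfg <- sim_config(150, n_blocks = 10, block_size = 4,
                    archetype = "NULL", seed = 63)
  co <- simulate_cohort(cfg)
  y <- co$cytokines[, 1]
  ss <- suppressWarnings(run_univariate_gwas(co$genotypes, y))
  for (j in c(1, 17, 33)) {
    ct <- cor.test(co$genotypes$dosages[, j], y)
    expect_equal(ss$P[j], ct$p.value, tolerance = 1e-10)
  }
})
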