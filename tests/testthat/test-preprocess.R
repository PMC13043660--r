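test_that("seasonal encoding lies on the unit circle and matches the formula", {
  s <- encode_seasonality(c(365, 365 / 4, 182, 1))
  expect_equal(s$s1[1], sin(2 * pi), tolerance = 1e-12)
  expect_equal(s$s2[1], cos(2 * pi), tolerance = 1e-12)
  expect_equal(s$s1[2], 1, tolerance = 1e-12)
  expect_equal(s$s2[2], 0, tolerance = 1e-12)
  # mid-year is nearly antipodal to the year boundary
  expect_lt(abs(s$s2[3] + 1), 0.01)
  all_days <- encode_seasonality(1:365)
  expect_equal(all_days$s1^2 + all_days$s2^2, rep(1, 365), tolerance = 1e-12)
  # leap day mapped onto day 365
  expect_equal(encode_seasonality(366)$s1, encode_seasonality(365)$s1)
  expect_error(encode_seasonality(0), "doy")
  expect_error(encode_seasonality(367), "doy")
})

test_that("minor allele frequency is the folded mean-dosage frequency", {
  expect_equal(compute_maf(c(0, 1, 2, 2)), 0.375)
  expect_equal(compute_maf(rep(0, 10)), 0)
  expect_error(compute_maf(c(NA_real_, NA_real_)), "missing")
  set.seed(1)
  d <- rbinom(10000, 2, 0.3)
  se <- sqrt(0.3 * 0.7 / (2 * 10000))
  expect_lt(abs(compute_maf(d) - 0.3), 3 * se)
})

test_that("HWE exact test agrees with the enumeration oracle", {
  expect_equal(hwe_exact_test(0, 2, 0), 1.0)
  expect_equal(hwe_exact_test(100, 0, 0), 1.0)
  set.seed(42)
  for (i in 1:200) {
    n <- sample(1:200, 1)
    n_aa <- sample(0:n, 1)
    n_Aa <- if (n > n_aa) sample(0:(n - n_aa), 1) else 0
    n_AA <- n - n_aa - n_Aa
    expect_lt(abs(hwe_exact_test(n_AA, n_Aa, n_aa) -
                    hwe_oracle(n_AA, n_Aa, n_aa)), 1e-12)
  }
  expect_error(hwe_exact_test(-1, 2, 0), "non-negative")
})

test_that("variant QC applies the three filters with correct boundaries", {
  set.seed(7)
  n <- 200
  mk <- function(p) rbinom(n, 2, p)
  dos <- cbind(
    ok1 = mk(0.3),
    low_call = replace(mk(0.3), 1:12, NA),          # 6% missing -> removed
    boundary_call = replace(mk(0.3), 1:9, NA),      # 4.5% missing -> retained
    rare = rbinom(n, 2, 0.01),                      # MAF < 0.05 -> removed
    boundary_maf = rep(c(0, 1), c(180, 20)),        # MAF exactly 0.05 -> kept
    hwe_bad = rep(c(0, 2), each = n / 2),           # no hets -> HWE fail
    ok2 = mk(0.4))
  vr <- data.frame(chrom = "1", pos = 1:7 * 1000, id = colnames(dos),
                   ref = "A", alt = "G", stringsAsFactors = FALSE)
  g <- genotype_matrix(dos, vr)
  qc <- apply_variant_qc(g)
  kept <- qc$genotypes$variants$id
  expect_true(all(c("ok1", "ok2", "boundary_call", "boundary_maf") %in% kept))
  expect_false("low_call" %in% kept)
  expect_false("rare" %in% kept)
  expect_false("hwe_bad" %in% kept)
  expect_equal(qc$report$n_fail_call_rate, 1)
  expect_gte(qc$report$n_fail_maf, 1)
  expect_gte(qc$report$n_fail_hwe, 1)
  expect_equal(qc$report$n_retained, length(kept))
})

test_that("genotype PCA is orthogonal, ordered, and consistent for duplicates", {
  co <- small_cohort("NULL", n = 100, seed = 23)
  g <- co$genotypes
  g$dosages[5, ] <- g$dosages[4, ]  # duplicate individual
  pc <- genotype_pca(g, k = 3)
  expect_equal(pc[4, ], pc[5, ], tolerance = 1e-10)
  expect_lt(abs(cor(pc[, 1], pc[, 2])), 1e-10)
  expl <- attr(pc, "explained")
  expect_true(all(diff(expl) <= 1e-12))
  expect_error(genotype_pca(g, k = 1000), "rank")
})

test_that("inverse rank normalization follows the Blom formula", {
  expect_equal(inverse_rank_normalize(c(3, 1, 2))[3], 0)
  x <- sort(rnorm(25))
  expect_equal(inverse_rank_normalize(x),
               qnorm(((1:25) - 3 / 8) / (25 + 1 / 4)), tolerance = 1e-12)
  y <- c(5, 1, 1, 9)
  out <- inverse_rank_normalize(y)
  expect_equal(out[2], out[3])
  withna <- inverse_rank_normalize(c(2, NA, 1, 3))
  expect_true(is.na(withna[2]))
  expect_error(inverse_rank_normalize(rep(1, 5)), "constant")
})

test_that("residualization matches the normal-equations oracle and is idempotent", {
  set.seed(31)
  n <- 200; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  res <- residualize(y, X)
  # independent oracle: solve the normal equations directly
  Xd <- cbind(1, X)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  expect_equal(res, as.numeric(y - Xd %*% beta), tolerance = 1e-10)
  expect_true(all(abs(t(Xd) %*% res) < 1e-8 * n))
  expect_equal(residualize(res, X), res, tolerance = 1e-10)
  # trait equal to a covariate vanishes
  expect_equal(residualize(X[, 1], X), rep(0, n), tolerance = 1e-10)
  expect_error(residualize(y, cbind(X, X[, 1])), "collinear")
})

test_that("scaler parameters come from the training set only", {
  set.seed(37)
  train <- matrix(rnorm(50 * 3, mean = 2), 50, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  sc <- fit_scaler(train)
  z <- apply_scaler(train, sc)
  expect_equal(unname(colMeans(z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(apply_scaler(rbind(sc$mean), sc))[1, ], rep(0, 3),
               tolerance = 1e-12)
  shifted <- apply_scaler(train + 5, sc)
  expect_equal(unname(colMeans(shifted)), unname(5 / sc$sd), tolerance = 1e-12)
  expect_warning(fit_scaler(cbind(train, const = 1)), "zero-variance")
})
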