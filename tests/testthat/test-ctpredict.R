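test_that("clumping reproduces the hand-traced greedy example", {
  ss <- data.frame(CHR = "1", POS = c(1e6, 1.05e6, 1.5e6, 1.06e6),
                   ID = c("v1", "v2", "v3", "v4"), A1 = "G", BETA = 1,
                   SE = 1, P = c(1e-9, 1e-6, 1e-6, 1e-3), N = 50,
                   stringsAsFactors = FALSE)
  set.seed(2)
  base <- rbinom(50, 2, 0.3)
  g <- cbind(v1 = base, v2 = base, v3 = rbinom(50, 2, 0.3), v4 = base)
  gm <- genotype_matrix(g, data.frame(chrom = "1", pos = ss$POS, id = ss$ID,
                                      ref = "A", alt = "G",
                                      stringsAsFactors = FALSE))
  cl <- clump(ss, gm, clump_params())
  expect_equal(cl$index$ID, c("v1", "v3"))
  expect_setequal(cl$members[["v1"]], c("v2", "v4"))
  # nothing below p1 -> empty result
  empty <- clump(transform(ss, P = 1e-3), gm, clump_params())
  expect_equal(nrow(empty$index), 0)
  # missing index genotypes -> error
  gm2 <- genotype_matrix(g[, 2:4], gm$variants[2:4, ])
  expect_error(clump(ss, gm2, clump_params()), "LD source")
})

test_that("clumping matches the exhaustive reference on random instances", {
  params <- clump_params(p1 = 1e-4, p2 = 1e-2)
  for (s in 1:60) {
    inst <- random_clump_instance(s)
    got <- clump(inst$sumstats, inst$genotypes, params)$index$ID
    want <- clump_oracle(inst$sumstats, inst$genotypes, params)
    expect_identical(got, want)
  }
})

test_that("C+T scores are linear sums of effect-allele dosages", {
  g <- cbind(v1 = c(0, 1, 2), v2 = c(2, 1, 0))
  gm <- genotype_matrix(g, data.frame(chrom = "1", pos = c(1, 2),
                                      id = c("v1", "v2"), ref = "A", alt = "G",
                                      stringsAsFactors = FALSE))
  m <- structure(data.frame(variant_key = "v1", effect_allele = "G",
                            beta = 0.5, stringsAsFactors = FALSE),
                 class = c("ct_score_model", "data.frame"))
  expect_equal(ct_score(gm, m), c(0, 0.5, 1.0))
  # REF as effect allele flips the dosage: hand computation
  m2 <- structure(data.frame(variant_key = c("v1", "v2"),
                             effect_allele = c("G", "A"),
                             beta = c(1, 2), stringsAsFactors = FALSE),
                  class = c("ct_score_model", "data.frame"))
  hand <- g[, "v1"] * 1 + (2 - g[, "v2"]) * 2
  expect_equal(ct_score(gm, m2), hand)
  # zero betas and linear scaling
  m3 <- m2; m3$beta <- 0
  expect_equal(ct_score(gm, m3), c(0, 0, 0))
  m4 <- m2; m4$beta <- 3 * m2$beta
  expect_equal(ct_score(gm, m4), 3 * ct_score(gm, m2))
  # unmatched alleles are skipped; nothing matchable is an error
  m5 <- m2; m5$effect_allele <- c("T", "A")
  expect_warning(s5 <- ct_score(gm, m5), "skipped")
  expect_equal(s5, (2 - g[, "v2"]) * 2)
  m6 <- m2; m6$effect_allele <- "T"
  expect_error(suppressWarnings(ct_score(gm, m6)), "matchable")
  # missing dosage contributes the variant's mean dosage
  gm$dosages[2, "v1"] <- NA
  expect_equal(ct_score(gm, m)[2], 0.5 * mean(c(0, 2)))
})

test_that("fold plans partition the cohort with near-equal sizes", {
  plan <- make_folds(10, 5, seed = 1)
  expect_equal(as.integer(table(plan$assignment)), rep(2L, 5))
  plan2 <- make_folds(403, 5, seed = 2)
  expect_equal(sort(as.integer(table(plan2$assignment))), c(80L, 80L, 81L, 81L, 81L))
  expect_equal(sort(unique(plan2$assignment)), 1:5)
  expect_identical(plan2$assignment, make_folds(403, 5, seed = 2)$assignment)
  expect_error(make_folds(3, 5), ">= k")
})

test_that("random search is seeded, exhaustive on small grids, and finds signal", {
  set.seed(71)
  X <- matrix(rnorm(150 * 10), 150, 10,
              dimnames = list(NULL, paste0("x", 1:10)))
  y <- as.numeric(X %*% rnorm(10) + rnorm(150, 0.5))
  expect_identical(random_search("ols", X, y, seed = 3)$best, list())
  r1 <- random_search("rf", X, y, n_configs = 3, seed = 4)
  r2 <- random_search("rf", X, y, n_configs = 3, seed = 4)
  expect_identical(r1$best, r2$best)
  # heavy penalty destroys a planted linear fit
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    Xs <- matrix(rnorm(150 * 10), 150, 10)
    ys <- as.numeric(Xs %*% rnorm(10) + rnorm(150, 0, 0.5))
    best <- suppressWarnings(random_search("en", Xs, ys, seed = s))$best
    if (best$alpha < 1000) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("learners satisfy the fit_predict contract", {
  set.seed(73)
  X <- matrix(rnorm(80 * 4), 80, 4, dimnames = list(NULL, paste0("x", 1:4)))
  beta <- c(1, -2, 0.5, 0)
  y <- as.numeric(X %*% beta)
  tr <- list(X = X[1:60, ], y = y[1:60])
  te <- list(X = X[61:80, ])
  # noiseless linear target, n > p: OLS interpolates
  expect_equal(fit_predict("ols", list(), tr, te), y[61:80], tolerance = 1e-6)
  # constant target: near-constant predictions, Spearman undefined
  tr0 <- list(X = X[1:60, ], y = rep(2, 60))
  p0 <- fit_predict("rf", default_config("rf"), tr0, te, seed = 1)
  expect_warning(ev <- spearman_eval(p0, y[61:80]), "constant")
  expect_true(is.na(ev$rho))
  # p > n tolerated
  Xw <- matrix(rnorm(20 * 50), 20, 50)
  yw <- rnorm(20)
  for (mk in c("ols", "ridge", "en")) {
    p <- fit_predict(mk, default_config(mk),
                     list(X = Xw[1:15, ], y = yw[1:15]),
                     list(X = Xw[16:20, ]))
    expect_true(all(is.finite(p)))
  }
  expect_error(fit_predict("ols", list(), list(X = X[1:5, ] * NA, y = y[1:5]),
                           te), "non-finite")
})

test_that("every learner kind trains on a planted signal and is deterministic", {
  set.seed(75)
  X <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- as.numeric(X %*% c(1, -1, 0.5, 0, 0) + rnorm(200, 0, 0.3))
  tr <- list(X = X[1:150, ], y = y[1:150]); te <- list(X = X[151:200, ])
  for (mk in c("ols", "ridge", "en", "rf", "gbt", "ann")) {
    p1 <- fit_predict(mk, default_config(mk), tr, te, seed = 4)
    p2 <- fit_predict(mk, default_config(mk), tr, te, seed = 4)
    expect_identical(p1, p2)
    expect_gt(spearman_eval(p1, y[151:200])$rho, 0.5)
  }
})

test_that("benchmark reports are reproducible and leak-free in TRAIN_ONLY mode", {
  co <- small_cohort("TCR_LIKE", n = 150, seed = 77)
  plan <- make_folds(150, 5, seed = 7)
  args <- list(co, 1, model_kinds = c("ct", "ridge"),
               feature_sets = c("genetic", "combined"),
               leakage_mode = "TRAIN_ONLY", fold_plan = plan,
               params = clump_params(p1 = 1e-2, p2 = 1e-2), seed = 7)
  b1 <- do.call(run_benchmark, args)
  b2 <- do.call(run_benchmark, args)
  expect_identical(b1$results, b2$results)
  # audit: the selection stage never touches test-fold individuals
  for (f in seq_len(plan$k))
    expect_length(intersect(b1$audit[[f]]$selection_ids,
                            b1$audit[[f]]$test_ids), 0)
  # C+T evaluation equals the Spearman of the raw score (z-scoring monotone)
  r <- b1$results
  expect_true(all(c("ct", "ridge") %in% r$model))
  expect_true(all(is.na(r$rho) | (r$rho >= -1 & r$rho <= 1)))
})

test_that("sampled configurations always lie inside the printed grids", {
  for (mk in c("ridge", "en", "rf", "gbt", "ann")) {
    grid <- hyper_grid(mk)
    flat <- unique(unlist(lapply(grid, names)))
    for (cfg in grid[seq(1, length(grid), length.out = min(10, length(grid)))]) {
      expect_setequal(names(cfg), flat)
    }
  }
  expect_equal(length(hyper_grid("ridge")), 8)
  expect_equal(length(hyper_grid("en")), 40)
  expect_equal(length(hyper_grid("rf")), 54)
  expect_equal(length(hyper_grid("gbt")), 81)
})
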