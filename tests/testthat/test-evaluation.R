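test_that("NRMSE follows the definition with unbiased variance", {
  comp <- matrix(c(1, 3, 5, 7), 2)
  imp <- matrix(c(2, 2, 5, 7), 2)
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  # true (1,3), imputed (2,2): mse 1, sample var 2
  expect_equal(nrmse(comp, imp, mask), sqrt(0.5), tolerance = 1e-12)
  # perfect imputation
  expect_identical(nrmse(comp, comp, mask), 0)
  # scale invariance
  expect_equal(nrmse(3.7 * comp, 3.7 * imp, mask), nrmse(comp, imp, mask),
               tolerance = 1e-12)
})

test_that("NRMSE matches the loop-based oracle on random instances", {
  for (s in 1:5) {
    x <- small_positive_matrix(7, 5, seed = s)
    mask <- random_mcar_mask(7, 5, 6, seed = s + 50)
    xm <- x
    xm[mask] <- NA
    imp <- impute_constant(xm, "mean")
    expect_equal(nrmse(x, imp, mask), nrmse_oracle(x, imp$values, mask),
                 tolerance = 1e-12)
  }
})

test_that("NRMSE rejects degenerate inputs", {
  comp <- matrix(1:4, 2)
  expect_error(nrmse(comp, comp, matrix(FALSE, 2, 2)), "2 masked cells")
  one <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2)
  expect_error(nrmse(comp, comp, one), "2 masked cells")
  expect_error(nrmse(comp, comp, matrix(TRUE, 2, 1)), "shape")
  const <- matrix(c(2, 2, 2, 2), 2)
  expect_error(nrmse(const, const + 1, matrix(c(TRUE, TRUE, FALSE, FALSE), 2)),
               "constant")
})

test_that("per-feature NRMSE averages the feature-wise ratios", {
  x <- small_positive_matrix(8, 4, seed = 9)
  mask <- matrix(FALSE, 8, 4)
  mask[1:3, 1] <- TRUE
  mask[2:5, 3] <- TRUE
  xm <- x
  xm[mask] <- NA
  imp <- impute_constant(xm, "mean")$values
  by_hand <- mean(c(
    sqrt(mean((x[1:3, 1] - imp[1:3, 1])^2) / var(x[1:3, 1])),
    sqrt(mean((x[2:5, 3] - imp[2:5, 3])^2) / var(x[2:5, 3]))))
  expect_equal(nrmse(x, imp, mask, per_feature = TRUE), by_hand,
               tolerance = 1e-12)
})

test_that("a trial scores all methods on one shared mask", {
  x <- generate_complete_matrix(datagen_config(
    n_samples = 20, n_features = 15, latent_rank = 3, seed = 61))
  spec <- missingness_spec("MCAR", 0.1)
  cfg <- imputer_config(knn_k = 4, rf_ntree = 15, pca_components = 2)
  rec <- run_single_trial(x, spec, config = cfg, seed = 62,
                          dataset_id = "d1", permutation = 3L)
  expect_identical(nrow(rec), 9L)
  expect_setequal(rec$method, imputation_methods())
  expect_true(all(rec$permutation == 3L & rec$dataset_id == "d1" &
                    rec$mechanism == "MCAR" & rec$rate == 0.1))
  expect_true(all(rec$ok))
  expect_true(all(rec$nrmse >= 0))

  # the ZERO record must equal a direct independent recomputation
  masked <- simulate_missingness(x, spec,
                                 seed = lcimpute:::derive_seed(62, "mask"))
  zero_direct <- nrmse_oracle(x, impute_constant(masked, "zero")$values,
                              masked$mask)
  expect_equal(rec$nrmse[rec$method == "ZERO"], zero_direct, tolerance = 1e-12)

  # reruns with the same seed reproduce the records exactly
  rec2 <- run_single_trial(x, spec, config = cfg, seed = 62,
                           dataset_id = "d1", permutation = 3L)
  expect_identical(rec$nrmse, rec2$nrmse)
})

test_that("imputer failures yield flagged records, not aborts", {
  x <- small_positive_matrix(6, 5, seed = 70)
  rec <- run_single_trial(x, missingness_spec("MCAR", 0.1),
                          methods = c("MEAN", "SVD"),
                          config = imputer_config(pca_components = 5),
                          seed = 71)
  expect_identical(nrow(rec), 2L)
  svd_row <- rec[rec$method == "SVD", ]
  expect_false(svd_row$ok)
  expect_true(is.na(svd_row$nrmse))
  expect_match(svd_row$note, "pca_components")
  expect_true(rec$ok[rec$method == "MEAN"])
  expect_message(s <- summarize_benchmark(rec), "excluding 1 flagged")
  expect_setequal(s$method, "MEAN")
})

test_that("a reduced benchmark produces the full record grid deterministically", {
  cfg <- benchmark_config(
    n_permutations = 5, n_features_per_trial = 10,
    mechanisms = c("MCAR", "MNAR"), rates = 0.1,
    methods = c("ZERO", "MEAN", "MIN"),
    datasets = list(datagen_config(n_samples = 20, n_features = 14, seed = 80)),
    master_seed = 81)
  rec <- run_benchmark(cfg)
  expect_identical(nrow(rec), 5L * 2L * 1L * 3L)
  keep <- setdiff(names(rec), "runtime_s")   # wall-clock diagnostic
  expect_identical(rec[keep], run_benchmark(cfg)[keep])
  # every trial holds one mask: records of a trial share the same seed
  by_trial <- split(rec, list(rec$permutation, rec$mechanism))
  expect_true(all(vapply(by_trial, function(d) length(unique(d$seed)) == 1L,
                         logical(1))))
})

test_that("datasets too small for the requested subset are skipped with a warning", {
  cfg <- benchmark_config(
    n_permutations = 1, n_features_per_trial = 50,
    mechanisms = "MCAR", rates = 0.1, methods = "MEAN",
    datasets = list(datagen_config(n_samples = 15, n_features = 10, seed = 1)),
    master_seed = 3)
  expect_warning(expect_error(run_benchmark(cfg), "no benchmark records"),
                 "skipped")
})

test_that("summaries aggregate by method, mechanism and rate with a pooled row", {
  set.seed(90)
  grid <- expand.grid(permutation = 1:4, mechanism = c("MCAR", "MAR"),
                      rate = c(0.1, 0.3), method = c("ZERO", "RF"),
                      stringsAsFactors = FALSE)
  grid$dataset_id <- "d"
  grid$nrmse <- runif(nrow(grid))
  grid$seed <- 1L
  grid$runtime_s <- 0
  grid$ok <- TRUE
  grid$note <- ""
  s <- summarize_benchmark(grid)
  expect_identical(nrow(s), 2L * 2L * 2L + 2L * 2L)  # per-rate + pooled
  # independent recomputation of one cell
  sel <- grid$method == "RF" & grid$mechanism == "MAR" & grid$rate == 0.3
  row <- s[s$method == "RF" & s$mechanism == "MAR" & s$rate == "0.3", ]
  expect_equal(row$mean_nrmse, mean(grid$nrmse[sel]), tolerance = 1e-12)
  expect_equal(row$sd_nrmse, sd(grid$nrmse[sel]), tolerance = 1e-12)
  expect_identical(row$n_reps, sum(sel))
  pooled <- s[s$method == "RF" & s$mechanism == "MAR" & s$rate == "all", ]
  sel_pool <- grid$method == "RF" & grid$mechanism == "MAR"
  expect_equal(pooled$mean_nrmse, mean(grid$nrmse[sel_pool]), tolerance = 1e-12)
  expect_identical(pooled$n_reps, sum(sel_pool))

  # degenerate group: identical records give sd 0
  same <- grid[grid$method == "ZERO" & grid$mechanism == "MCAR" & grid$rate == 0.1, ]
  same$nrmse <- 0.42
  s2 <- summarize_benchmark(same)
  expect_identical(s2$mean_nrmse[s2$rate == "0.1"], 0.42)
  expect_identical(s2$sd_nrmse[s2$rate == "0.1"], 0)

  expect_error(summarize_benchmark(data.frame()), "non-empty")
})

test_that("heatmap_matrix lays out methods x rates for one mechanism", {
  set.seed(91)
  grid <- expand.grid(permutation = 1:2, mechanism = "MCAR",
                      rate = c(0.05, 0.1, 0.2, 0.3),
                      method = imputation_methods(), stringsAsFactors = FALSE)
  grid$nrmse <- runif(nrow(grid))
  grid$ok <- TRUE
  s <- summarize_benchmark(grid)
  h <- heatmap_matrix(s, "MCAR")
  expect_identical(dim(h), c(9L, 4L))
  expect_false(anyNA(h))
  expect_error(heatmap_matrix(s, "MAR"), "no summary rows")
})
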