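test_that("cut-off draws follow chi-squared(1)/30 clipped to [0, 1]", {
  set.seed(99)
  draws <- draw_cutoff_fraction(200000)
  expect_true(all(draws >= 0 & draws <= 1))
  # analytic moments of the unclipped distribution: 1/30 and sqrt(2)/30;
  # clipping at 1 is a ~5-sigma event and shifts them negligibly
  expect_equal(mean(draws), 1 / 30, tolerance = 0.03)
  expect_equal(sd(draws), sqrt(2) / 30, tolerance = 0.03)
})

test_that("masked-cell counts are exact for every mechanism and rate", {
  x <- generate_complete_matrix(datagen_config(n_samples = 25, n_features = 20, seed = 5))
  for (mech in ALL_MECHANISMS) {
    for (rate in c(0.05, 0.10, 0.20, 0.30)) {
      for (seed in 1:4) {
        m <- simulate_missingness(x, missingness_spec(mech, rate), seed = seed)
        expect_identical(sum(m$mask), as.integer(round(rate * length(x))),
                         info = sprintf("%s rate %.2f seed %d", mech, rate, seed))
        expect_identical(dim(m$mask), dim(x))
        expect_identical(which(is.na(m$values)), which(m$mask))
      }
    }
  }
})

test_that("MCAR masking is uniform over cells", {
  x <- small_positive_matrix(10, 10, seed = 2)
  counts <- matrix(0, 10, 10)
  n_runs <- 400
  for (s in seq_len(n_runs)) {
    counts <- counts + simulate_mcar(x, 0.2, seed = s)$mask
  }
  expected <- n_runs * 0.2
  stat <- sum((counts - expected)^2 / expected)
  # chi-square GOF, df = 99; generous alpha so only gross non-uniformity fails
  expect_gt(pchisq(stat, df = 99, lower.tail = FALSE), 1e-4)
})

test_that("a single MAR event masks the target at the top driver samples", {
  x <- matrix(c(1:10, rep(5, 10)), ncol = 2,
              dimnames = list(NULL, c("driver", "target")))
  mask <- matrix(FALSE, 10, 2)
  rows <- lcimpute:::mar_step_cells(x, mask, driver = 1L, target = 2L, cutoff = 0.2)
  expect_setequal(rows, c(9L, 10L))   # samples holding driver values 9 and 10

  # already-masked target cells are skipped
  mask[10, 2] <- TRUE
  expect_setequal(lcimpute:::mar_step_cells(x, mask, 1L, 2L, 0.2), 9L)
})

test_that("a single MNAR event left-truncates the still-observed values", {
  x <- matrix(c(5, 1, 4, 2, 3), ncol = 1, dimnames = list(NULL, "f"))
  mask <- matrix(FALSE, 5, 1)
  rows <- lcimpute:::mnar_step_cells(x, mask, feature = 1L, cutoff = 0.4, side = "left")
  expect_setequal(x[rows, 1], c(1, 2))
  # right truncation takes the largest values instead
  rows_r <- lcimpute:::mnar_step_cells(x, mask, 1L, 0.4, side = "right")
  expect_setequal(x[rows_r, 1], c(5, 4))
  # with value 1 already masked, only still-observed values are ranked
  mask[2, 1] <- TRUE
  rows2 <- lcimpute:::mnar_step_cells(x, mask, 1L, 0.3, side = "left")
  expect_setequal(x[rows2, 1], c(2, 3))   # ceiling(0.3 * 4 observed) = 2 cells
})

test_that("MAR missingness concentrates at high driver abundances", {
  x <- generate_complete_matrix(datagen_config(n_samples = 30, n_features = 15, seed = 8))
  mean_ranks <- vapply(1:20, function(s) {
    m <- simulate_mar(x, 0.2, seed = s)
    ev <- m$events
    ranks <- unlist(lapply(ev, function(e) {
      rank(x[, e$driver_feature])[e$masked_cells[, 1]]
    }))
    mean(ranks)
  }, numeric(1))
  expect_gt(mean(mean_ranks), (nrow(x) + 1) / 2)
})

test_that("MNAR events never mask a value above one still observed at that step", {
  x <- generate_complete_matrix(datagen_config(n_samples = 40, n_features = 12, seed = 9))
  for (s in 1:5) {
    m <- simulate_mnar(x, 0.25, seed = s)
    replay <- matrix(FALSE, nrow(x), ncol(x))
    for (e in m$events) {
      j <- match(e$target_feature, colnames(x))
      masked_vals <- x[e$masked_cells[, 1], j]
      still_obs <- x[!replay[, j], j]
      still_obs <- setdiff(still_obs, masked_vals)
      if (length(still_obs) > 0) {
        expect_lte(max(masked_vals), min(still_obs))
      }
      replay[e$masked_cells] <- TRUE
    }
    expect_identical(replay, m$mask)
  }
})

test_that("MNAR at 30% removes the left tail of each affected feature", {
  x <- generate_complete_matrix(datagen_config(seed = 10))
  m <- simulate_mnar(x, 0.3, seed = 1)
  affected <- which(colSums(m$mask) > 0)
  # surviving values sit above the feature median far more often than below
  frac_above <- vapply(affected, function(j) {
    mean(x[!m$mask[, j], j] > median(x[, j]))
  }, numeric(1))
  expect_gt(mean(frac_above), 0.5)
})

test_that("mixed mechanisms split the total equally with full provenance", {
  x <- generate_complete_matrix(datagen_config(n_samples = 25, n_features = 24, seed = 11))
  m <- simulate_mixed(x, c("MCAR", "MAR", "MNAR"), 0.3, seed = 4)
  ev <- masking_events(m)
  per_step <- tapply(ev$n_cells, ev$step_mechanism, sum)
  total <- round(0.3 * length(x))
  expect_identical(sort(names(per_step)), c("MAR", "MCAR", "MNAR"))
  expect_true(all(per_step == total / 3))
  expect_identical(sum(m$mask), as.integer(total))
  # each masked cell is claimed by exactly one event
  claimed <- do.call(rbind, lapply(m$events, `[[`, "masked_cells"))
  expect_identical(nrow(claimed), as.integer(total))
  expect_identical(anyDuplicated(claimed), 0L)

  # two components split in two
  m2 <- simulate_mixed(x, c("MCAR", "MAR"), 0.2, seed = 5)
  ev2 <- masking_events(m2)
  per2 <- tapply(ev2$n_cells, ev2$step_mechanism, sum)
  expect_true(all(per2 == round(0.2 * length(x)) / 2))

  expect_error(simulate_mixed(x, c("MCAR", "MCAR"), 0.2), "distinct")
  expect_error(simulate_mixed(x, "MCAR", 0.2), "distinct")
})

test_that("simulate_missingness dispatches, validates, and is deterministic", {
  x <- small_positive_matrix(15, 10, seed = 3)
  spec <- missingness_spec("MCAR_MNAR", 0.2)
  m1 <- simulate_missingness(x, spec, seed = 21)
  m2 <- simulate_missingness(x, spec, seed = 21)
  expect_identical(m1$mask, m2$mask)
  expect_identical(m1$values, m2$values)
  m3 <- simulate_missingness(x, spec, seed = 22)
  expect_false(identical(m1$mask, m3$mask))

  expect_error(missingness_spec("MACR", 0.1), "unknown mechanism")
  expect_error(missingness_spec("MCAR", 0), "rate")
  expect_error(missingness_spec("MCAR", 1), "rate")
  expect_warning(missingness_spec("MCAR", 0.5), "30%")
  expect_error(simulate_mnar(x, 0.1, side = "up"), "arg")
  expect_error(simulate_mar(x[, 1, drop = FALSE], 0.1), "2 features")

  # degenerate rate 0 on the single-mechanism simulators
  for (f in list(simulate_mcar, simulate_mar)) {
    m0 <- f(x, 0, seed = 1)
    expect_identical(sum(m0$mask), 0L)
    expect_length(m0$events, 0)
  }
  m0 <- simulate_mnar(x, 0, seed = 1)
  expect_identical(sum(m0$mask), 0L)
})

test_that("rates above 30% still conserve the exact count, with a warning", {
  x <- small_positive_matrix(20, 10, seed = 6)
  expect_warning(spec <- missingness_spec("MAR_MNAR", 0.45), "30%")
  expect_warning(m <- simulate_missingness(x, spec, seed = 2), "30%")
  expect_identical(sum(m$mask), as.integer(round(0.45 * length(x))))
})
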