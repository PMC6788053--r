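#' Normalized root mean squared error of an imputation
#'
#' `NRMSE = sqrt( mean((X_comp - X_imp)^2) / var(X_comp) )`, evaluated over
#' the originally masked cells: since every imputation method preserves
#' observed cells exactly, including them would only dilute the error. The
#' denominator is the unbiased (n-1) sample variance of the true values at
#' the masked cells, so 0 means perfect imputation and values near 1 mean
#' the method did no better than the masked cells' own mean. The ratio is
#' invariant to rescaling both matrices by a common positive constant.
#'
#' With `per_feature = TRUE` the same ratio is computed separately for
#' every feature holding at least two masked cells with non-degenerate
#' variance, and the per-feature values are averaged — an alternative
#' aggregation that weights features equally rather than cells.
#'
#' @param complete The complete (true) matrix.
#' @param imputed An `imputed_matrix` or a plain numeric matrix of the same
#'   shape.
#' @param mask Logical matrix, `TRUE` at the cells that were masked, or a
#'   [masked_matrix()] to take the mask from.
#' @param per_feature Average per-feature NRMSEs instead of pooling all
#'   masked cells.
#' @return A single non-negative number.
#' @export
#' @examples
#' comp <- matrix(c(1, 3, 5, 7), 2)
#' imp <- matrix(c(2, 2, 5, 7), 2)
#' mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' nrmse(comp, imp, mask)  # sqrt(1 / 2)
nrmse <- function(complete, imputed, mask, per_feature = FALSE) {
  if (inherits(imputed, "imputed_matrix")) imputed <- imputed$values
  if (inherits(mask, "masked_matrix")) mask <- mask$mask
  if (!identical(dim(complete), dim(imputed)) ||
      !identical(dim(complete), dim(mask))) {
    stop("`complete`, `imputed` and `mask` must share the same shape",
         call. = FALSE)
  }
  if (sum(mask) < 2L) {
    stop("NRMSE needs at least 2 masked cells (variance undefined)",
         call. = FALSE)
  }
  if (!per_feature) {
    truth <- complete[mask]
    err <- mean((truth - imputed[mask])^2)
    v <- var(truth)
    if (v <= 0) {
      stop("true values at the masked cells are constant; NRMSE undefined",
           call. = FALSE)
    }
    return(sqrt(err / v))
  }
  vals <- vapply(which(colSums(mask) >= 2L), function(j) {
    truth <- complete[mask[, j], j]
    v <- var(truth)
    if (v <= 0) return(NA_real_)
    sqrt(mean((truth - imputed[mask[, j], j])^2) / v)
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    stop("no feature has >= 2 masked cells with non-degenerate variance",
         call. = FALSE)
  }
  mean(vals)
}

#' Run one benchmark trial: one mask, all requested methods
#'
#' Simulates a single mask from `spec`, imputes it with every requested
#' method, and scores each by [nrmse()]. All methods see the identical
#' mask, so comparisons within a trial are paired. A method that errors
#' (non-convergence, degenerate feature) yields a flagged record
#' (`ok = FALSE`, `nrmse = NA`) instead of aborting the trial.
#'
#' @param x Complete intensity matrix for this trial.
#' @param spec A [missingness_spec()].
#' @param methods Character vector of methods (default all nine).
#' @param config An [imputer_config()]; its seed is overridden per method
#'   by a value derived from `seed`.
#' @param seed Integer seed for the mask and the stochastic imputers.
#' @param dataset_id,permutation Identifiers copied into the records.
#' @param per_feature Passed to [nrmse()].
#' @return A data frame of benchmark records, one row per method:
#'   `permutation`, `dataset_id`, `mechanism`, `rate`, `method`, `nrmse`,
#'   `seed`, `runtime_s`, `ok`, `note`.
#' @export
run_single_trial <- function(x, spec, methods = imputation_methods(),
                             config = imputer_config(), seed = NULL,
                             dataset_id = "dataset", permutation = 1L,
                             per_feature = FALSE) {
  x <- validate_intensity_matrix(x)
  methods <- toupper(methods)
  bad <- setdiff(methods, imputation_methods())
  if (length(bad) > 0L) {
    stop(sprintf("unknown method(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  masked <- simulate_missingness(x, spec, seed = derive_seed(seed %||% 0L, "mask"))
  rows <- lapply(methods, function(m) {
    cfg <- config
    cfg$seed <- derive_seed(seed %||% 0L, "impute", m)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(impute(masked, m, cfg), error = function(e) e)
    runtime <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      score <- NA_real_
      ok <- FALSE
      note <- conditionMessage(res)
    } else {
      score <- nrmse(x, res, masked$mask, per_feature = per_feature)
      ok <- TRUE
      note <- ""
    }
    data.frame(permutation = as.integer(permutation), dataset_id = dataset_id,
               mechanism = spec$mechanism, rate = spec$rate, method = m,
               nrmse = score, seed = as.integer(seed %||% NA_integer_),
               runtime_s = runtime, ok = ok, note = note,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Default synthetic dataset pool
#'
#' Twelve generator configurations emulating the variety of complete LC-MS
#' feature tables a benchmark draws from: four cohort-style shapes (258
#' samples, 204–509 complete features) and eight intervention-style shapes
#' (47 samples, 383–1152 complete features), spanning the range where the
#' number of features exceeds the per-trial subset of 200.
#'
#' @param seed Integer seed from which each configuration's seed is
#'   derived.
#' @return A list of 12 [datagen_config()] objects.
#' @export
default_dataset_pool <- function(seed = 1L) {
  shapes <- list(
    c(258, 204), c(258, 299), c(258, 509), c(258, 498),
    c(47, 518), c(47, 508), c(47, 383), c(47, 383),
    c(47, 1066), c(47, 1152), c(47, 578), c(47, 559)
  )
  lapply(seq_along(shapes), function(i) {
    datagen_config(n_samples = shapes[[i]][1], n_features = shapes[[i]][2],
                   seed = derive_seed(seed, "pool", i))
  })
}

#' Benchmark configuration
#'
#' Defaults reproduce the full study design: 100 permutations, 200 features
#' per trial, all 7 mechanisms, rates 5/10/20/30%, all 9 methods. Scale
#' `n_permutations`, `mechanisms`, `rates` or `methods` down for quicker
#' runs.
#'
#' @param n_permutations Number of repetitions of the whole trial.
#' @param n_features_per_trial Features subsampled for each trial.
#' @param mechanisms Character vector of mechanisms to simulate.
#' @param rates Numeric vector of total missingness rates.
#' @param methods Character vector of imputation methods.
#' @param datasets Pool to draw from each permutation: a list whose
#'   elements are complete numeric matrices and/or [datagen_config()]
#'   objects (generated on demand). Defaults to [default_dataset_pool()]
#'   seeded from `master_seed`.
#' @param imputer An [imputer_config()].
#' @param master_seed Integer master seed; every per-trial seed is derived
#'   from it deterministically, so any single grid cell can be replayed.
#' @param truncation_side Truncation side for MNAR-containing mechanisms.
#' @param per_feature Use per-feature NRMSE aggregation (see [nrmse()]).
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(n_permutations = 100,
                             n_features_per_trial = 200,
                             mechanisms = MECHANISMS,
                             rates = c(0.05, 0.10, 0.20, 0.30),
                             methods = imputation_methods(),
                             datasets = NULL,
                             imputer = imputer_config(),
                             master_seed = 1L,
                             truncation_side = "left",
                             per_feature = FALSE) {
  n_permutations <- assert_count(n_permutations, "n_permutations")
  n_features_per_trial <- assert_count(n_features_per_trial, "n_features_per_trial")
  mechanisms <- toupper(mechanisms)
  if (!all(mechanisms %in% MECHANISMS)) {
    stop("unknown mechanism(s) in `mechanisms`", call. = FALSE)
  }
  for (r in rates) assert_scalar_number(r, "rates", lower = 0, upper = 1,
                                        strict_lower = TRUE, strict_upper = TRUE)
  methods <- toupper(methods)
  if (!all(methods %in% imputation_methods())) {
    stop("unknown method(s) in `methods`", call. = FALSE)
  }
  master_seed <- assert_count(master_seed, "master_seed", min = 0L)
  datasets <- datasets %||% default_dataset_pool(master_seed)
  if (!is.list(datasets) || length(datasets) == 0L) {
    stop("`datasets` must be a non-empty list of matrices or datagen configs",
         call. = FALSE)
  }
  structure(
    list(n_permutations = n_permutations,
         n_features_per_trial = n_features_per_trial,
         mechanisms = mechanisms, rates = rates, methods = methods,
         datasets = datasets, imputer = imputer, master_seed = master_seed,
         truncation_side = truncation_side, per_feature = per_feature),
    class = "benchmark_config"
  )
}

resolve_dataset <- function(d) {
  if (inherits(d, "datagen_config")) {
    generate_complete_matrix(d)
  } else {
    validate_intensity_matrix(d)
  }
}

#' Run the permutation benchmark
#'
#' For each permutation: pick one dataset from the pool uniformly at
#' random, subsample `n_features_per_trial` complete features, then for
#' every mechanism x rate simulate one mask and score every method on it
#' (see [run_single_trial()]). Per-trial seeds are derived from
#' `master_seed`, the permutation index, mechanism and rate, making the
#' whole run — and any individual cell of it — deterministic. Datasets with
#' fewer features than requested are skipped with a warning.
#'
#' @param config A [benchmark_config()].
#' @param progress Print a line per permutation.
#' @return A data frame of benchmark records (see [run_single_trial()]),
#'   `n_permutations * length(mechanisms) * length(rates) * length(methods)`
#'   rows when nothing is skipped.
#' @export
#' @examples
#' cfg <- benchmark_config(
#'   n_permutations = 2, n_features_per_trial = 20,
#'   mechanisms = c("MCAR", "MNAR"), rates = 0.1,
#'   methods = c("ZERO", "MEAN", "MIN"),
#'   datasets = list(datagen_config(n_samples = 30, n_features = 25, seed = 5)),
#'   master_seed = 42)
#' rec <- run_benchmark(cfg)
#' nrow(rec)  # 2 * 2 * 1 * 3
run_benchmark <- function(config, progress = FALSE) {
  if (!inherits(config, "benchmark_config")) {
    stop("`config` must be created by benchmark_config()", call. = FALSE)
  }
  out <- vector("list", config$n_permutations)
  for (perm in seq_len(config$n_permutations)) {
    ds_idx <- with_seed(derive_seed(config$master_seed, "dataset", perm),
                        sample.int(length(config$datasets), 1L))
    x_full <- resolve_dataset(config$datasets[[ds_idx]])
    if (ncol(x_full) < config$n_features_per_trial) {
      warning(sprintf(
        "permutation %d: dataset %d has %d < %d complete features; skipped",
        perm, ds_idx, ncol(x_full), config$n_features_per_trial), call. = FALSE)
      next
    }
    x <- subsample_features(x_full, config$n_features_per_trial,
                            seed = derive_seed(config$master_seed, "subset", perm))
    if (progress) {
      message(sprintf("permutation %d/%d (dataset %d)", perm,
                      config$n_permutations, ds_idx))
    }
    trials <- list()
    for (mech in config$mechanisms) {
      for (rate in config$rates) {
        spec <- missingness_spec(mech, rate, config$truncation_side)
        trial_seed <- derive_seed(config$master_seed, perm, mech, rate)
        trials[[length(trials) + 1L]] <- run_single_trial(
          x, spec, methods = config$methods, config = config$imputer,
          seed = trial_seed, dataset_id = sprintf("dataset%02d", ds_idx),
          permutation = perm, per_feature = config$per_feature)
      }
    }
    out[[perm]] <- do.call(rbind, trials)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    stop("no benchmark records produced (all datasets skipped?)", call. = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Summarize benchmark records
#'
#' Mean and standard deviation of the NRMSE per (method, mechanism, rate),
#' plus a pooled row per (method, mechanism) across all rates (labelled
#' `rate = "all"`). Flagged records (`ok = FALSE`) are excluded, with a
#' message giving the count.
#'
#' @param records Data frame of benchmark records from [run_benchmark()]
#'   or [run_single_trial()].
#' @return A data frame with columns `method`, `mechanism`, `rate`
#'   (character; `"all"` for the pooled rows), `mean_nrmse`, `sd_nrmse`
#'   (`NA` for a single record), `n_reps`.
#' @export
summarize_benchmark <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("`records` must be a non-empty data frame of benchmark records",
         call. = FALSE)
  }
  if ("ok" %in% names(records) && any(!records$ok)) {
    message(sprintf("excluding %d flagged record(s) from summaries",
                    sum(!records$ok)))
    records <- records[records$ok, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    stop("no usable records after excluding failures", call. = FALSE)
  }
  grp <- function(keys) {
    agg <- aggregate(records$nrmse, by = keys, FUN = mean)
    names(agg)[ncol(agg)] <- "mean_nrmse"
    agg$sd_nrmse <- aggregate(records$nrmse, by = keys, FUN = sd)$x
    agg$n_reps <- aggregate(records$nrmse, by = keys, FUN = length)$x
    agg
  }
  by_rate <- grp(list(method = records$method, mechanism = records$mechanism,
                      rate = records$rate))
  by_rate$rate <- as.character(by_rate$rate)
  pooled <- grp(list(method = records$method, mechanism = records$mechanism))
  pooled$rate <- "all"
  pooled <- pooled[, names(by_rate)]
  out <- rbind(by_rate, pooled)
  out <- out[order(out$mechanism, out$rate, out$method), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Heatmap-shaped summary for one mechanism
#'
#' @param summary A summary table from [summarize_benchmark()].
#' @param mechanism Mechanism to extract.
#' @return A numeric matrix, methods x rates, of mean NRMSE (pooled `"all"`
#'   column excluded) — the layout of a per-mechanism benchmark heatmap.
#' @export
heatmap_matrix <- function(summary, mechanism) {
  mechanism <- toupper(mechanism)
  sub <- summary[summary$mechanism == mechanism & summary$rate != "all", ,
                 drop = FALSE]
  if (nrow(sub) == 0L) {
    stop(sprintf("no summary rows for mechanism '%s'", mechanism), call. = FALSE)
  }
  rates <- sort(unique(as.numeric(sub$rate)))
  methods <- intersect(imputation_methods(), unique(sub$method))
  m <- matrix(NA_real_, length(methods), length(rates),
              dimnames = list(methods, as.character(rates)))
  for (i in seq_len(nrow(sub))) {
    m[sub$method[i], as.character(as.numeric(sub$rate[i]))] <- sub$mean_nrmse[i]
  }
  m
}
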