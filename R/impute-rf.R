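#' Iterative random-forest (missForest-style) imputation
#'
#' The iterative scheme of the missForest algorithm: missing cells are
#' initialized with the feature's observed mean; features are visited in
#' order of ascending missingness; each visited feature is regressed on all
#' other features (using the samples where it is observed, and the current
#' working matrix as predictors) with a random forest, and its missing
#' cells are replaced by the forest's predictions, updating the working
#' matrix in place. Full sweeps repeat until the normalized sum of squared
#' changes between consecutive sweeps increases — at which point the matrix
#' from the previous (best) sweep is returned — or `rf_maxiter` sweeps have
#' run.
#'
#' The forests are grown by [ranger::ranger()] with `rf_ntree` trees,
#' `mtry = floor(sqrt(p))` predictors per split and a minimum node size of
#' 5 (the regression defaults of this method's lineage), single-threaded
#' and seeded, so the imputation is reproducible for a fixed
#' `config$seed`.
#'
#' @inheritParams impute
#' @return An `imputed_matrix`; `diagnostics$converged` is `TRUE` when the
#'   stopping criterion (first increase of the sweep-to-sweep change)
#'   fired before the sweep cap, and `diagnostics$iterations` counts the
#'   sweeps actually used for the returned matrix.
#' @export
impute_rf <- function(masked, config = imputer_config()) {
  um <- unpack_masked(masked)
  v <- um$values
  mask <- um$mask
  if (!any(mask)) {
    return(imputed_matrix(v, v, mask, "RF"))
  }
  p <- ncol(v)
  if (p < 2L) {
    stop("RF imputation requires at least 2 features", call. = FALSE)
  }
  mtry <- config$rf_mtry %||% max(1L, floor(sqrt(p)))
  mtry <- min(mtry, p - 1L)
  miss_by_col <- colSums(mask)
  targets <- order(miss_by_col)                       # ascending missingness
  targets <- targets[miss_by_col[targets] > 0L]
  if (is.null(colnames(v))) colnames(v) <- sprintf("F%03d", seq_len(p))

  with_seed(config$seed, {
    x <- feature_mean_fill(v, mask)
    best <- x
    diff_prev <- Inf
    iterations <- 0L
    converged <- FALSE
    for (iter in seq_len(config$rf_maxiter)) {
      x_old <- x
      for (j in targets) {
        obs <- !mask[, j]
        fit <- ranger::ranger(
          x = x[obs, -j, drop = FALSE], y = v[obs, j],
          num.trees = config$rf_ntree, mtry = mtry, min.node.size = 5,
          num.threads = 1, seed = sample.int(2147483646L, 1L),
          oob.error = FALSE, verbose = FALSE)
        x[!obs, j] <- predict(fit, data = x[!obs, -j, drop = FALSE],
                              num.threads = 1, verbose = FALSE)$predictions
      }
      diff_new <- sum((x - x_old)^2) / sum(x^2)
      if (diff_new > diff_prev) {                     # got worse: keep previous
        converged <- TRUE
        break
      }
      best <- x
      diff_prev <- diff_new
      iterations <- iter
    }
    imputed_matrix(best, v, mask, "RF", iterations = iterations,
                   converged = converged, criterion = diff_prev)
  })
}
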