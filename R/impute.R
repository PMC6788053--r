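#' The nine imputation methods
#'
#' @return Character vector of method identifiers, in the package's
#'   canonical order: the four single-value replacements (`ZERO`, `MEAN`,
#'   `MIN`, `HALF_MIN`), the two local-structure methods (`KNN`, `RF`), and
#'   the three global-structure methods (`SVD`, `PPCA`, `BPCA`).
#' @export
imputation_methods <- function() {
  c("ZERO", "MEAN", "MIN", "HALF_MIN", "KNN", "RF", "SVD", "PPCA", "BPCA")
}

#' Imputer configuration
#'
#' Tuning parameters shared by the imputation methods. Defaults follow the
#' conventions of the methods' reference implementations: K = 10 neighbours
#' for KNN; 100 trees, at most 10 sweeps and `mtry = floor(sqrt(p))` for the
#' missForest-style random-forest imputer; rank 5 for the three low-rank
#' methods (small relative to a 200-feature table, adjustable when the true
#' structure is known).
#'
#' @param knn_k Number of nearest neighbours voting for each missing cell.
#' @param knn_orientation `"feature"` (default: a feature is imputed from
#'   the most similar features, the expression-matrix KNN convention) or
#'   `"sample"` (a sample is imputed from the most similar samples).
#' @param rf_ntree Trees per random forest.
#' @param rf_maxiter Maximum missForest-style sweeps over all features.
#' @param rf_mtry Predictors tried per split; `NULL` means
#'   `floor(sqrt(n_features))`.
#' @param pca_components Latent dimension for SVD, PPCA and BPCA.
#' @param tol Relative-change convergence tolerance of the iterative
#'   methods.
#' @param max_em_iter Iteration cap for SVD/PPCA/BPCA.
#' @param seed Integer seed making the stochastic methods (KNN tie-breaks
#'   aside, RF, PPCA, BPCA) reproducible; `NULL` uses the current stream.
#' @return An object of class `imputer_config`.
#' @export
imputer_config <- function(knn_k = 10, knn_orientation = c("feature", "sample"),
                           rf_ntree = 100, rf_maxiter = 10, rf_mtry = NULL,
                           pca_components = 5, tol = 1e-5, max_em_iter = 100,
                           seed = NULL) {
  knn_k <- assert_count(knn_k, "knn_k")
  rf_ntree <- assert_count(rf_ntree, "rf_ntree")
  rf_maxiter <- assert_count(rf_maxiter, "rf_maxiter")
  if (!is.null(rf_mtry)) rf_mtry <- assert_count(rf_mtry, "rf_mtry")
  pca_components <- assert_count(pca_components, "pca_components")
  assert_scalar_number(tol, "tol", lower = 0, strict_lower = TRUE)
  max_em_iter <- assert_count(max_em_iter, "max_em_iter")
  structure(
    list(knn_k = knn_k, knn_orientation = match.arg(knn_orientation),
         rf_ntree = rf_ntree, rf_maxiter = rf_maxiter, rf_mtry = rf_mtry,
         pca_components = pca_components, tol = tol,
         max_em_iter = max_em_iter, seed = seed),
    class = "imputer_config"
  )
}

# Internal: shared entry validation for all imputers. Returns list(values,
# mask) with values a numeric matrix carrying NA exactly at mask.
unpack_masked <- function(masked) {
  masked <- as_masked_matrix(masked)
  v <- masked$values
  if (any(is.na(v) != masked$mask)) {
    stop("masked matrix is inconsistent: NA positions differ from the mask",
         call. = FALSE)
  }
  list(values = v, mask = masked$mask)
}

# Internal: wrap an imputation result, restoring observed cells exactly.
imputed_matrix <- function(values, observed, mask, method,
                           iterations = 0L, converged = TRUE,
                           criterion = NA_real_, notes = character()) {
  values[!mask] <- observed[!mask]
  if (anyNA(values)) {
    stop(sprintf("%s imputation left missing entries", method), call. = FALSE)
  }
  structure(
    list(values = values, method = method,
         diagnostics = list(iterations = as.integer(iterations),
                            converged = isTRUE(converged),
                            criterion = criterion, notes = notes)),
    class = "imputed_matrix"
  )
}

#' @export
print.imputed_matrix <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<imputed_matrix> %d x %d, method %s (%d iterations, %s)\n",
              nrow(x$values), ncol(x$values), x$method, d$iterations,
              if (d$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Impute a masked matrix with a named method
#'
#' Uniform dispatcher over the nine supported methods. Every method leaves
#' observed cells bit-identical to the input and returns a fully filled
#' matrix with convergence diagnostics.
#'
#' @param masked A [masked_matrix()] or a numeric matrix with `NA` at the
#'   missing cells.
#' @param method One of [imputation_methods()] (case-insensitive).
#' @param config An [imputer_config()].
#' @return An `imputed_matrix`: list with `values` (complete numeric
#'   matrix), `method`, and `diagnostics` (`iterations`, `converged`,
#'   `criterion`, `notes`).
#' @export
#' @examples
#' x <- generate_complete_matrix(datagen_config(n_samples = 30, n_features = 20, seed = 3))
#' m <- simulate_mcar(x, 0.1, seed = 4)
#' imp <- impute(m, "MEAN")
#' anyNA(imp$values)
impute <- function(masked, method, config = imputer_config()) {
  method <- toupper(as.character(method)[1L])
  if (!method %in% imputation_methods()) {
    stop(sprintf("unknown imputation method '%s'; expected one of %s",
                 method, paste(imputation_methods(), collapse = ", ")),
         call. = FALSE)
  }
  if (!inherits(config, "imputer_config")) {
    stop("`config` must be created by imputer_config()", call. = FALSE)
  }
  switch(method,
         ZERO = impute_constant(masked, "zero"),
         MEAN = impute_constant(masked, "mean"),
         MIN = impute_constant(masked, "min"),
         HALF_MIN = impute_constant(masked, "half_min"),
         KNN = impute_knn(masked, config),
         RF = impute_rf(masked, config),
         SVD = impute_svd(masked, config),
         PPCA = impute_ppca(masked, config),
         BPCA = impute_bpca(masked, config))
}
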