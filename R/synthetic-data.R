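#' Configuration for the synthetic intensity-matrix generator
#'
#' Bundles and validates the parameters of the log-scale latent-factor model
#' used by [generate_complete_matrix()]. The generator stands in for complete
#' (no-missing) untargeted LC-MS feature tables, which are positive, strongly
#' right-skewed, and carry low-rank correlation structure among features
#' (isotopes, adducts, co-regulated metabolites).
#'
#' @param n_samples Number of samples (matrix rows).
#' @param n_features Number of molecular features (matrix columns).
#' @param latent_rank Number of shared latent factors inducing feature-feature
#'   correlation. Must be smaller than both dimensions.
#' @param noise_sd Residual standard deviation on the log scale. Smaller
#'   values give cleaner low-rank structure.
#' @param mean_log Centre of the per-feature log-intensity baselines.
#'   The default 12 puts raw intensities near `exp(12) ~ 1.6e5`, a typical
#'   LC-MS peak-height magnitude.
#' @param sd_log Scale of the per-feature log-intensity variation contributed
#'   by the latent factors. Values >= 0.5 give clearly right-skewed raw
#'   intensities.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#'
#' @return An object of class `datagen_config` (a validated list).
#' @seealso [generate_complete_matrix()]
#' @export
#' @examples
#' cfg <- datagen_config(n_samples = 50, n_features = 40, seed = 1)
#' x <- generate_complete_matrix(cfg)
#' dim(x)
datagen_config <- function(n_samples = 100, n_features = 200, latent_rank = 5,
                           noise_sd = 0.5, mean_log = 12, sd_log = 1,
                           seed = NULL) {
  n_samples <- assert_count(n_samples, "n_samples")
  n_features <- assert_count(n_features, "n_features")
  latent_rank <- assert_count(latent_rank, "latent_rank")
  assert_scalar_number(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  assert_scalar_number(mean_log, "mean_log")
  assert_scalar_number(sd_log, "sd_log", lower = 0, strict_lower = TRUE)
  if (latent_rank >= min(n_samples, n_features)) {
    stop("`latent_rank` must be smaller than both matrix dimensions",
         call. = FALSE)
  }
  structure(
    list(n_samples = n_samples, n_features = n_features,
         latent_rank = latent_rank, noise_sd = noise_sd,
         mean_log = mean_log, sd_log = sd_log, seed = seed),
    class = "datagen_config"
  )
}

#' @export
print.datagen_config <- function(x, ...) {
  cat(sprintf(
    "<datagen_config> %d samples x %d features, rank %d, noise_sd %.3g, log-N(%.3g, sd %.3g)\n",
    x$n_samples, x$n_features, x$latent_rank, x$noise_sd, x$mean_log, x$sd_log))
  invisible(x)
}

#' Generate a complete synthetic intensity matrix
#'
#' Draws a samples x features matrix from an exponentiated latent-factor
#' model: `log X = mu + F L + E`, where each feature loads primarily on one
#' of `latent_rank` factors (features `j` and `j + latent_rank` share a
#' factor), with small cross-loadings on the others, a per-feature baseline
#' `mu_j ~ N(mean_log, 1)`, and i.i.d. residual noise of sd `noise_sd`.
#' Exponentiation makes every entry strictly positive and right-skewed while
#' preserving the low-rank correlation structure on the log scale — the
#' three properties of real LC-MS feature tables that the missingness
#' mechanisms and multivariate imputers in this package rely on.
#'
#' @param config A [datagen_config()].
#' @return A numeric matrix (`n_samples` x `n_features`) with row names
#'   `S001, ...` and column names `F001, ...`; all entries finite and
#'   strictly positive, no missing values. Deterministic for a fixed
#'   `config$seed`.
#' @export
#' @examples
#' x <- generate_complete_matrix(datagen_config(n_samples = 30, n_features = 20, seed = 7))
#' all(x > 0)
generate_complete_matrix <- function(config) {
  if (!inherits(config, "datagen_config")) {
    stop("`config` must be created by datagen_config()", call. = FALSE)
  }
  n <- config$n_samples
  p <- config$n_features
  k <- config$latent_rank
  with_seed(config$seed, {
    mu <- rnorm(p, mean = config$mean_log, sd = 1)
    # Block-structured loadings: primary factor block(j) = ((j-1) mod k) + 1,
    # positive primary loading with magnitude jitter, weak cross-loadings.
    block <- ((seq_len(p) - 1L) %% k) + 1L
    loadings <- matrix(rnorm(k * p, sd = 0.3 * config$sd_log / sqrt(k)), k, p)
    loadings[cbind(block, seq_len(p))] <- runif(p, 0.6, 1.4) * config$sd_log
    factors <- matrix(rnorm(n * k), n, k)
    noise <- matrix(rnorm(n * p, sd = config$noise_sd), n, p)
    logx <- sweep(factors %*% loadings + noise, 2L, mu, "+")
    x <- exp(logx)
    dimnames(x) <- list(sprintf("S%03d", seq_len(n)), sprintf("F%03d", seq_len(p)))
    x
  })
}

#' Randomly subsample features from a complete matrix
#'
#' Restricts a complete intensity matrix to `n_select` features drawn
#' uniformly without replacement; the sample set is unchanged and selected
#' columns are carried over unmodified. This mirrors the benchmark's
#' per-permutation draw of a fresh feature subset.
#'
#' @param x Complete numeric matrix, samples x features.
#' @param n_select Number of features to keep (`<= ncol(x)`).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A matrix with the same rows and `n_select` of the original
#'   columns, in the sampled order.
#' @export
subsample_features <- function(x, n_select, seed = NULL) {
  x <- validate_intensity_matrix(x)
  n_select <- assert_count(n_select, "n_select")
  if (n_select > ncol(x)) {
    stop(sprintf("cannot select %d features from a matrix with %d",
                 n_select, ncol(x)), call. = FALSE)
  }
  keep <- with_seed(seed, sample.int(ncol(x), n_select))
  x[, keep, drop = FALSE]
}

#' Validate a complete intensity matrix
#'
#' Checks the contract assumed throughout the package: a numeric matrix,
#' samples in rows and features in columns, with no missing entries, all
#' values finite and strictly positive, and dimension names (generated if
#' absent) matching the matrix shape.
#'
#' @param x Matrix to validate.
#' @return The validated matrix (with dimnames filled in if missing),
#'   invisibly usable in place.
#' @export
validate_intensity_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("an intensity matrix must be a numeric matrix (samples x features)",
         call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("intensity matrix contains missing or non-finite entries",
         call. = FALSE)
  }
  if (any(x <= 0)) {
    stop("intensity matrix entries must be strictly positive", call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- sprintf("S%03d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("F%03d", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    stop("sample and feature identifiers must be unique", call. = FALSE)
  }
  x
}
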