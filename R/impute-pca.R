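#' Iterative low-rank SVD imputation
#'
#' Missing cells start at zero; the algorithm then alternates between a
#' rank-r truncated singular value decomposition of the current matrix and
#' overwriting the missing cells with the rank-r reconstruction, until the
#' relative change at the missing cells drops below `config$tol` or
#' `config$max_em_iter` sweeps have run. The matrix is used on its raw
#' scale (no centering), matching the zero-initialization convention of
#' this method's lineage: with positive intensity data a zero start is a
#' deliberately crude guess, which is why this method often trails the
#' probabilistic low-rank imputers.
#'
#' @inheritParams impute
#' @return An `imputed_matrix`; `diagnostics$converged` is `FALSE` when the
#'   iteration cap was reached first.
#' @export
impute_svd <- function(masked, config = imputer_config()) {
  um <- unpack_masked(masked)
  v <- um$values
  mask <- um$mask
  if (!any(mask)) {
    return(imputed_matrix(v, v, mask, "SVD"))
  }
  r <- config$pca_components
  if (r >= min(dim(v))) {
    stop("`pca_components` must be smaller than both matrix dimensions",
         call. = FALSE)
  }
  x <- v
  x[mask] <- 0
  iterations <- 0L
  converged <- FALSE
  delta <- NA_real_
  for (iter in seq_len(config$max_em_iter)) {
    dec <- svd(x, nu = r, nv = r)
    recon <- dec$u %*% (dec$d[seq_len(r)] * t(dec$v))
    new_vals <- recon[mask]
    delta <- sqrt(sum((new_vals - x[mask])^2)) /
      max(sqrt(sum(new_vals^2)), .Machine$double.eps)
    x[mask] <- new_vals
    iterations <- iter
    if (delta < config$tol) {
      converged <- TRUE
      break
    }
  }
  imputed_matrix(x, v, mask, "SVD", iterations = iterations,
                 converged = converged, criterion = delta)
}

# Shared machinery for the probabilistic low-rank imputers ---------------

# Column-center using observed means; returns list(xc, center, filled)
# where `filled` has missing cells at 0 on the centered scale (i.e. at the
# observed feature mean on the raw scale).
center_by_observed <- function(v, mask) {
  center <- colMeans(v, na.rm = TRUE)
  if (anyNA(center)) {
    stop("feature(s) with no observed values cannot be imputed by a low-rank model",
         call. = FALSE)
  }
  xc <- sweep(v, 2L, center)
  xc[mask] <- 0
  list(xc = xc, center = center)
}

# Solve a symmetric positive (semi-)definite system with a tiny relative
# ridge: keeps the EM updates defined when a loading column collapses
# (ARD pruning) or a feature is almost fully masked.
solve_spd <- function(a) {
  ridge <- 1e-10 * (sum(diag(a)) / nrow(a)) + 1e-300
  solve(a + diag(ridge, nrow(a)))
}

# Deterministic initialization of the loading matrix from the mean-filled
# data: scaled right singular vectors.
init_loadings <- function(xc, r) {
  n <- nrow(xc)
  dec <- svd(xc, nu = 0, nv = r)
  w <- dec$v %*% diag(dec$d[seq_len(r)] / sqrt(n), r, r)
  sigma2 <- max((sum(xc^2) - sum(dec$d[seq_len(r)]^2)) / (length(xc)), 1e-8)
  list(w = w, sigma2 = sigma2)
}

#' Probabilistic PCA imputation
#'
#' Fits the probabilistic PCA model `x = W z + mu + eps`,
#' `eps ~ N(0, sigma2 I)`, by expectation–maximization, treating the
#' missing cells as latent: each EM sweep computes the posterior factor
#' scores of every sample, updates the loadings and the isotropic residual
#' variance, and refills the missing cells with their model reconstruction
#' (their conditional expectation given the current scores). Data are
#' column-centered on the observed values internally and the center is
#' added back. Initialization is a deterministic SVD of the mean-filled
#' matrix, so results are reproducible without randomness.
#'
#' On complete data the fitted loading subspace converges to the ordinary
#' principal-component subspace, the maximum-likelihood solution of PPCA.
#'
#' @inheritParams impute
#' @return An `imputed_matrix`.
#' @export
impute_ppca <- function(masked, config = imputer_config()) {
  fit_lowrank_em(masked, config, ard = FALSE)
}

#' Bayesian PCA imputation
#'
#' Extends [impute_ppca()]'s EM loop with automatic relevance determination
#' (ARD): each loading column w_j carries a Gaussian prior with its own
#' precision alpha_j, re-estimated as `p / ||w_j||^2` every sweep, and the
#' loading update is ridge-penalized by `sigma2 * diag(alpha)`. Columns
#' that do not help explain the data are driven towards zero, so the
#' effective rank can shrink below `pca_components` — making the method
#' robust to a generous rank choice. Missing cells are filled with the
#' posterior-mean reconstruction.
#'
#' @inheritParams impute
#' @return An `imputed_matrix`.
#' @export
impute_bpca <- function(masked, config = imputer_config()) {
  fit_lowrank_em(masked, config, ard = TRUE)
}

# EM core shared by PPCA (ard = FALSE) and BPCA (ard = TRUE).
fit_lowrank_em <- function(masked, config, ard) {
  method <- if (ard) "BPCA" else "PPCA"
  um <- unpack_masked(masked)
  v <- um$values
  mask <- um$mask
  has_missing <- any(mask)
  r <- config$pca_components
  n <- nrow(v)
  p <- ncol(v)
  if (r >= p) {
    stop("`pca_components` must be smaller than the number of features",
         call. = FALSE)
  }
  cen <- center_by_observed(v, mask)
  x <- cen$xc
  init <- init_loadings(x, r)
  w <- init$w
  sigma2 <- init$sigma2
  alpha <- if (ard) p / pmax(colSums(w^2), 1e-10) else NULL

  iterations <- 0L
  converged <- FALSE
  delta <- NA_real_
  eye <- diag(1, r, r)
  for (iter in seq_len(config$max_em_iter)) {
    m <- crossprod(w) + sigma2 * eye
    minv <- solve_spd(m)
    z <- x %*% w %*% minv                      # posterior means of scores
    sz <- n * sigma2 * minv + crossprod(z)     # sum of E[z z']
    penalty <- if (ard) sigma2 * diag(pmin(alpha, 1e12), r, r) else 0
    w_new <- crossprod(x, z) %*% solve_spd(sz + penalty)
    sigma2_new <- (sum(x^2) - 2 * sum((x %*% w_new) * z) +
                     sum(sz * crossprod(w_new))) / (n * p)
    if (!is.finite(sigma2_new) || sigma2_new < 1e-12) {
      stop(sprintf("%s: residual variance collapsed (degenerate input)", method),
           call. = FALSE)
    }
    if (has_missing) {
      recon <- z %*% t(w_new)
      old_vals <- x[mask]
      x[mask] <- recon[mask]
      delta <- sqrt(sum((x[mask] - old_vals)^2)) /
        max(sqrt(sum(x[mask]^2)), .Machine$double.eps)
    } else {
      delta <- 0
    }
    if (ard) alpha <- p / pmax(colSums(w_new^2), 1e-10)
    rel_w <- sqrt(sum((w_new - w)^2)) / max(sqrt(sum(w^2)), .Machine$double.eps)
    w <- w_new
    sigma2 <- sigma2_new
    iterations <- iter
    if (max(delta, rel_w) < config$tol) {
      converged <- TRUE
      break
    }
  }
  out <- sweep(x, 2L, cen$center, "+")
  res <- imputed_matrix(out, v, mask, method, iterations = iterations,
                        converged = converged, criterion = delta)
  res$loadings <- w
  res$sigma2 <- sigma2
  if (ard) res$alpha <- alpha
  res
}
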