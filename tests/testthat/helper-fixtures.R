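# Shared fixtures and independent oracles used across the test files.

# Small positive matrix with mild structure, built directly (not via the
# package generator) so generator bugs cannot hide simulator/imputer bugs.
small_positive_matrix <- function(n = 12, p = 8, seed = 1) {
  set.seed(seed)
  x <- matrix(exp(rnorm(n * p, mean = 4, sd = 0.6)), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("f%02d", seq_len(p))))
  x
}

# Linear low-rank factor data plus Gaussian noise, shifted positive: the
# structure SVD/PPCA/BPCA model directly.
linear_factor_matrix <- function(n, p, rank, noise_sd = 0.3, shift = 50,
                                 seed = 1) {
  set.seed(seed)
  scores <- matrix(rnorm(n * rank), n, rank)
  loadings <- matrix(rnorm(rank * p, sd = 2), rank, p)
  x <- scores %*% loadings + matrix(rnorm(n * p, sd = noise_sd), n, p) + shift
  dimnames(x) <- list(sprintf("s%02d", seq_len(n)), sprintf("f%02d", seq_len(p)))
  x
}

random_mcar_mask <- function(n, p, n_missing, seed) {
  set.seed(seed)
  mask <- matrix(FALSE, n, p)
  mask[sample(n * p, n_missing)] <- TRUE
  mask
}

# Independent NRMSE recomputation: plain loops, no shared code path.
nrmse_oracle <- function(complete, imputed, mask) {
  truth <- c()
  est <- c()
  for (j in seq_len(ncol(mask))) {
    for (i in seq_len(nrow(mask))) {
      if (mask[i, j]) {
        truth <- c(truth, complete[i, j])
        est <- c(est, imputed[i, j])
      }
    }
  }
  sqrt(mean((truth - est)^2) / var(truth))
}

# Brute-force feature-wise KNN imputation: recompute distances and weighted
# means with explicit loops, mirroring the documented definition only.
knn_oracle <- function(v, k) {
  p <- ncol(v)
  n <- nrow(v)
  d <- matrix(Inf, p, p)
  for (j in seq_len(p)) {
    for (l in seq_len(p)) {
      if (j == l) next
      both <- !is.na(v[, j]) & !is.na(v[, l])
      if (!any(both)) next
      d[j, l] <- sqrt(mean((v[both, j] - v[both, l])^2))
    }
  }
  out <- v
  for (j in seq_len(p)) {
    miss <- which(is.na(v[, j]))
    if (length(miss) == 0L) next
    ord <- order(d[, j])
    nb <- ord[is.finite(d[ord, j])]
    nb <- nb[seq_len(min(k, length(nb)))]
    for (i in miss) {
      has <- nb[!is.na(v[i, nb])]
      if (length(has) == 0L) {
        out[i, j] <- mean(v[, j], na.rm = TRUE)
      } else {
        w <- 1 / pmax(d[has, j], 1e-12)
        out[i, j] <- sum(w * v[i, has]) / sum(w)
      }
    }
  }
  out
}

# Principal angle (radians) between the column spaces of two matrices.
principal_angle <- function(a, b) {
  qa <- qr.Q(qr(a))
  qb <- qr.Q(qr(b))
  acos(min(pmin(svd(crossprod(qa, qb))$d, 1)))
}

ALL_MECHANISMS <- c("MCAR", "MAR", "MNAR", "MCAR_MAR", "MCAR_MNAR",
                    "MAR_MNAR", "MCAR_MAR_MNAR")
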