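#' K-nearest-neighbour imputation
#'
#' Feature-wise KNN in the expression-matrix tradition: for each feature
#' with missing cells, the K most similar features vote. Similarity is the
#' root-mean-square Euclidean distance computed over the samples where both
#' features are observed (normalizing by the overlap size keeps distances
#' comparable when overlaps differ); features sharing no observed sample
#' are never neighbours. Each missing cell is filled with the
#' inverse-distance-weighted average of the neighbours' values at that
#' sample, skipping neighbours that are themselves missing there; if no
#' neighbour has a value, the cell falls back to the feature's observed
#' mean and the fallback is counted in the diagnostics notes. Distance ties
#' are broken by feature index, so the method is fully deterministic.
#'
#' With `knn_orientation = "sample"` the same algorithm runs on the
#' transposed matrix (samples vote for samples).
#'
#' @inheritParams impute
#' @return An `imputed_matrix`.
#' @export
impute_knn <- function(masked, config = imputer_config()) {
  um <- unpack_masked(masked)
  v <- um$values
  mask <- um$mask
  if (!any(mask)) {
    return(imputed_matrix(v, v, mask, "KNN"))
  }
  if (config$knn_orientation == "sample") {
    res <- knn_engine(t(v), t(mask), config$knn_k)
    out <- t(res$filled)
  } else {
    res <- knn_engine(v, mask, config$knn_k)
    out <- res$filled
  }
  notes <- if (res$n_fallback > 0L) {
    sprintf("%d cell(s) fell back to the mean (no neighbour observed)",
            res$n_fallback)
  } else character()
  imputed_matrix(out, v, mask, "KNN", notes = notes)
}

# Core feature-wise engine: impute columns of `v` from their nearest
# columns. Returns list(filled, n_fallback).
knn_engine <- function(v, mask, k) {
  p <- ncol(v)
  if (p <= k) {
    stop(sprintf("KNN needs more than knn_k = %d candidate neighbours (have %d)",
                 k, p), call. = FALSE)
  }
  obs <- !mask
  a <- v
  a[mask] <- 0
  o <- obs * 1
  # Pairwise mean squared difference over mutually observed samples:
  # sum_i o_ij o_ik (a_ij - a_ik)^2, expanded into three cross-products.
  n_mut <- crossprod(o)
  a2o <- crossprod(a * a, o)
  s <- a2o + t(a2o) - 2 * crossprod(a)
  d <- sqrt(pmax(s, 0) / pmax(n_mut, 1))
  d[n_mut == 0] <- Inf
  diag(d) <- Inf

  col_mean <- colMeans(v, na.rm = TRUE)
  filled <- v
  n_fallback <- 0L
  for (j in which(colSums(mask) > 0L)) {
    ord <- order(d[, j])            # stable: ties resolved by column index
    nb <- ord[is.finite(d[ord, j])]
    nb <- nb[seq_len(min(k, length(nb)))]
    w_all <- 1 / pmax(d[nb, j], 1e-12)
    for (i in which(mask[, j])) {
      has <- obs[i, nb]
      if (!any(has)) {
        if (is.nan(col_mean[j])) {
          stop(sprintf("feature %s has no observed values; KNN is undefined",
                       colnames(v)[j] %||% j), call. = FALSE)
        }
        filled[i, j] <- col_mean[j]
        n_fallback <- n_fallback + 1L
      } else {
        w <- w_all[has]
        filled[i, j] <- sum(w * v[i, nb[has]]) / sum(w)
      }
    }
  }
  list(filled = filled, n_fallback = n_fallback)
}
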