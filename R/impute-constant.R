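#' Single-value replacement imputation
#'
#' Fills every missing cell of feature j with a single per-feature value:
#' zero, the mean of the feature's observed values, its minimum observed
#' value, or half that minimum. Minimum-based strategies target
#' detection-limit (left-truncated) missingness, where the absent values
#' are known to lie below everything observed.
#'
#' @inheritParams impute
#' @param strategy `"zero"`, `"mean"`, `"min"` or `"half_min"`.
#' @return An `imputed_matrix`.
#' @export
#' @examples
#' m <- matrix(c(1, NA, 3, 4, 5, 6), nrow = 3)
#' impute_constant(m, "half_min")$values
impute_constant <- function(masked, strategy = c("zero", "mean", "min", "half_min")) {
  strategy <- match.arg(strategy)
  um <- unpack_masked(masked)
  v <- um$values
  mask <- um$mask
  if (!any(mask)) {
    return(imputed_matrix(v, v, mask, toupper(strategy)))
  }
  needs_col <- which(colSums(mask) > 0L)
  if (strategy != "zero") {
    dead <- needs_col[colSums(!mask)[needs_col] == 0L]
    if (length(dead) > 0L) {
      stop(sprintf("feature(s) %s have no observed values; '%s' imputation is undefined",
                   paste(colnames(v)[dead] %||% dead, collapse = ", "), strategy),
           call. = FALSE)
    }
  }
  fill <- switch(strategy,
                 zero = rep.int(0, length(needs_col)),
                 mean = colMeans(v[, needs_col, drop = FALSE], na.rm = TRUE),
                 min = suppressWarnings(apply(v[, needs_col, drop = FALSE], 2L, min, na.rm = TRUE)),
                 half_min = suppressWarnings(apply(v[, needs_col, drop = FALSE], 2L, min, na.rm = TRUE)) / 2)
  out <- v
  for (i in seq_along(needs_col)) {
    j <- needs_col[i]
    out[mask[, j], j] <- fill[i]
  }
  method <- switch(strategy, zero = "ZERO", mean = "MEAN", min = "MIN",
                   half_min = "HALF_MIN")
  imputed_matrix(out, v, mask, method)
}

# Internal: per-feature observed means, used as fallback/initial fill.
feature_mean_fill <- function(v, mask) {
  mu <- colMeans(v, na.rm = TRUE)
  if (anyNA(mu)) {
    stop("feature(s) with no observed values cannot be mean-initialized",
         call. = FALSE)
  }
  out <- v
  idx <- which(mask, arr.ind = TRUE)
  out[idx] <- mu[idx[, 2L]]
  out
}
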