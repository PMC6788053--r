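#' Missingness mechanisms
#'
#' @description
#' Seven mechanisms are supported, the three canonical ones plus their
#' sequential combinations:
#'
#' * `MCAR` — cells removed uniformly at random.
#' * `MAR` — high abundance of a randomly chosen driver feature X1 causes
#'   missingness of a different target feature X2 in the same samples.
#' * `MNAR` — left truncation: a feature's smallest values fall below an
#'   effective detection limit and are removed (right truncation is
#'   available behind `truncation_side` but is not a benchmark default).
#' * `MCAR_MAR`, `MCAR_MNAR`, `MAR_MNAR`, `MCAR_MAR_MNAR` — the named
#'   mechanisms applied sequentially, each removing an equal share of the
#'   total, each step operating on the output of the previous one.
#'
#' @name missing-mechanisms
NULL

MECHANISMS <- c("MCAR", "MAR", "MNAR",
                "MCAR_MAR", "MCAR_MNAR", "MAR_MNAR", "MCAR_MAR_MNAR")

#' Specify a missingness simulation
#'
#' @param mechanism One of `"MCAR"`, `"MAR"`, `"MNAR"`, `"MCAR_MAR"`,
#'   `"MCAR_MNAR"`, `"MAR_MNAR"`, `"MCAR_MAR_MNAR"`.
#' @param rate Fraction of all matrix cells to set missing, in (0, 1). The
#'   benchmark uses 0.05, 0.10, 0.20 and 0.30; rates above 0.30 are allowed
#'   but warned about, because heavy masking of any kind starts to resemble
#'   MNAR truncation patterns.
#' @param truncation_side `"left"` (default; detection-limit censoring) or
#'   `"right"`. Affects MNAR-containing mechanisms only.
#' @return An object of class `missingness_spec`.
#' @export
#' @examples
#' missingness_spec("MCAR_MAR_MNAR", rate = 0.3)
missingness_spec <- function(mechanism, rate, truncation_side = c("left", "right")) {
  mechanism <- toupper(as.character(mechanism)[1L])
  if (!mechanism %in% MECHANISMS) {
    stop(sprintf("unknown mechanism '%s'; expected one of %s",
                 mechanism, paste(MECHANISMS, collapse = ", ")), call. = FALSE)
  }
  assert_scalar_number(rate, "rate", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  truncation_side <- match.arg(truncation_side)
  if (rate > 0.3) {
    warning("rates above 30% tend to create MNAR-like patterns regardless of mechanism",
            call. = FALSE)
  }
  structure(list(mechanism = mechanism, rate = rate,
                 truncation_side = truncation_side),
            class = "missingness_spec")
}

#' @export
print.missingness_spec <- function(x, ...) {
  side <- if (grepl("MNAR", x$mechanism)) sprintf(", %s truncation", x$truncation_side) else ""
  cat(sprintf("<missingness_spec> %s at %.0f%%%s\n", x$mechanism, 100 * x$rate, side))
  invisible(x)
}

#' Draw truncation cut-off fractions
#'
#' Cut-off percentages for the MAR and MNAR steps are drawn from a
#' chi-squared(1) distribution divided by 30 and clipped to \[0, 1\].
#' Unclipped, this has mean 1/30 (3.33%) and sd sqrt(2)/30 (4.71%); the
#' clip at 1 is an ~5-sigma event and changes the moments negligibly, so
#' individual masking events remove a few percent of a feature's values
#' at a time, with occasional much larger wipe-outs.
#'
#' @param n Number of draws.
#' @return Numeric vector of `n` fractions in \[0, 1\], drawn from the
#'   current RNG stream.
#' @export
#' @examples
#' set.seed(1)
#' mean(draw_cutoff_fraction(10000))  # ~ 0.033
draw_cutoff_fraction <- function(n = 1) {
  n <- assert_count(n, "n", min = 0L)
  pmin(rchisq(n, df = 1) / 30, 1)
}

## Masked-matrix container ----------------------------------------------

#' Construct a masked matrix
#'
#' A `masked_matrix` couples the values visible to an imputer (`values`,
#' with `NA` at masked cells) with the boolean mask, the complete source
#' matrix when known, the generating [missingness_spec()], and the list of
#' masking events recording how each cell came to be missing.
#'
#' @param source Complete numeric matrix the mask was applied to, or `NULL`
#'   when unknown (e.g. data read from a file with missing cells).
#' @param mask Logical matrix, `TRUE` = missing, same shape as the data.
#' @param spec Optional [missingness_spec()].
#' @param events Optional list of masking events (see [masking_events()]).
#' @param seed Optional integer seed used to generate the mask.
#' @param values Matrix with `NA` at masked positions; derived from
#'   `source` when omitted.
#' @return An object of class `masked_matrix`.
#' @export
masked_matrix <- function(source = NULL, mask, spec = NULL, events = list(),
                          seed = NULL, values = NULL) {
  if (is.null(values)) {
    stopifnot(is.matrix(source))
    values <- source
    values[mask] <- NA_real_
  }
  if (!is.matrix(mask) || !is.logical(mask) || !identical(dim(mask), dim(values))) {
    stop("`mask` must be a logical matrix with the same shape as the data",
         call. = FALSE)
  }
  structure(list(values = values, mask = mask, source = source,
                 spec = spec, events = events, seed = seed),
            class = "masked_matrix")
}

#' Coerce to a masked matrix
#'
#' A plain numeric matrix with `NA` entries becomes a `masked_matrix` whose
#' mask is `is.na(x)`; an existing `masked_matrix` is returned unchanged.
#'
#' @param x Matrix with `NA`s, or a `masked_matrix`.
#' @return A `masked_matrix`.
#' @export
as_masked_matrix <- function(x) {
  if (inherits(x, "masked_matrix")) return(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix or a masked_matrix", call. = FALSE)
  }
  masked_matrix(values = x, mask = is.na(x))
}

#' @export
print.masked_matrix <- function(x, ...) {
  n_miss <- sum(x$mask)
  cat(sprintf("<masked_matrix> %d x %d, %d missing cells (%.1f%%)%s\n",
              nrow(x$values), ncol(x$values), n_miss,
              100 * n_miss / length(x$mask),
              if (!is.null(x$spec)) paste0(", mechanism ", x$spec$mechanism) else ""))
  invisible(x)
}

#' Tabulate masking events
#'
#' @param masked A `masked_matrix` produced by a simulator in this package.
#' @return A data frame with one row per masking event: `step_mechanism`,
#'   `driver_feature` (the abundance-driving feature for MAR, `NA`
#'   otherwise), `target_feature` (the feature losing values; equals the
#'   driver for MNAR, `NA` for MCAR whose cells span features),
#'   `cutoff_fraction`, and `n_cells`.
#' @export
masking_events <- function(masked) {
  stopifnot(inherits(masked, "masked_matrix"))
  ev <- masked$events
  data.frame(
    step_mechanism = vapply(ev, `[[`, character(1), "step_mechanism"),
    driver_feature = vapply(ev, function(e) e$driver_feature %||% NA_character_, character(1)),
    target_feature = vapply(ev, function(e) e$target_feature %||% NA_character_, character(1)),
    cutoff_fraction = vapply(ev, function(e) e$cutoff_fraction %||% NA_real_, numeric(1)),
    n_cells = vapply(ev, function(e) nrow(e$masked_cells), integer(1)),
    stringsAsFactors = FALSE
  )
}

## Single-step primitives (internal; exercised directly by tests) --------

# Cells of `target` masked by one MAR event: the samples holding the top
# ceiling(cutoff * n_samples) values of `driver` (ranked on the full
# original values), excluding cells already masked.
mar_step_cells <- function(x, mask, driver, target, cutoff) {
  n <- nrow(x)
  k <- min(ceiling(cutoff * n), n)
  if (k < 1) return(integer(0))
  top <- order(x[, driver], decreasing = TRUE)[seq_len(k)]
  top[!mask[top, target]]
}

# Cells of `feature` masked by one MNAR event: the smallest (left) or
# largest (right) ceiling(cutoff * n_observed) of its still-observed values.
mnar_step_cells <- function(x, mask, feature, cutoff, side = "left") {
  obs <- which(!mask[, feature])
  if (length(obs) == 0L) return(integer(0))
  k <- min(ceiling(cutoff * length(obs)), length(obs))
  if (k < 1) return(integer(0))
  obs[order(x[obs, feature], decreasing = identical(side, "right"))[seq_len(k)]]
}

# Apply one mechanism on top of an existing mask until `n_target` newly
# masked cells are reached. Returns list(mask = updated mask, events).
# The final event is trimmed (uniform random subset retained) so the count
# is exact. Ranks are always computed on the complete original values.
apply_mechanism <- function(x, mask, mechanism, n_target, side = "left") {
  events <- list()
  remaining <- n_target
  if (remaining <= 0L) return(list(mask = mask, events = events))
  n <- nrow(x)
  p <- ncol(x)
  fid <- colnames(x)

  if (mechanism == "MCAR") {
    open <- which(!mask)
    if (length(open) < remaining) {
      stop("not enough unmasked cells left for the requested MCAR rate",
           call. = FALSE)
    }
    cells <- if (length(open) == 1L) open else sample(open, remaining)
    mask[cells] <- TRUE
    rc <- arrayInd(cells, dim(x))
    events[[1L]] <- list(step_mechanism = "MCAR", driver_feature = NULL,
                         target_feature = NULL, cutoff_fraction = NULL,
                         masked_cells = rc)
    return(list(mask = mask, events = events))
  }

  if (mechanism == "MAR" && p < 2L) {
    stop("MAR requires at least 2 features", call. = FALSE)
  }
  guard <- 0L
  while (remaining > 0L) {
    guard <- guard + 1L
    if (guard > 1e6L) {
      stop("missingness simulation failed to reach the requested rate",
           call. = FALSE)
    }
    cutoff <- draw_cutoff_fraction(1L)
    if (mechanism == "MAR") {
      pair <- sample.int(p, 2L)
      driver <- pair[1L]
      target <- pair[2L]
      rows <- mar_step_cells(x, mask, driver, target, cutoff)
    } else { # MNAR
      target <- sample.int(p, 1L)
      driver <- target
      rows <- mnar_step_cells(x, mask, target, cutoff, side)
    }
    if (length(rows) == 0L) next
    # Trim the final event so the total count is exact. Selections arrive
    # ordered most-extreme-first (highest driver for MAR, smallest value for
    # MNAR-left), so keeping the head preserves the per-event order rules.
    if (length(rows) > remaining) {
      rows <- rows[seq_len(remaining)]
    }
    mask[rows, target] <- TRUE
    events[[length(events) + 1L]] <- list(
      step_mechanism = mechanism,
      driver_feature = fid[driver],
      target_feature = fid[target],
      cutoff_fraction = cutoff,
      masked_cells = cbind(rows, rep.int(target, length(rows)))
    )
    remaining <- remaining - length(rows)
  }
  list(mask = mask, events = events)
}

## Public simulators -----------------------------------------------------

finish_masked <- function(x, res, spec, seed) {
  masked_matrix(source = x, mask = res$mask, spec = spec,
                events = res$events, seed = seed)
}

#' Simulate MCAR missingness
#'
#' Removes exactly `round(rate * length(x))` cells chosen uniformly at
#' random without replacement over all cells.
#'
#' @param x Complete numeric intensity matrix (samples x features).
#' @param rate Fraction of cells to mask, in \[0, 1).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A [masked_matrix()].
#' @export
simulate_mcar <- function(x, rate, seed = NULL) {
  x <- validate_intensity_matrix(x)
  assert_scalar_number(rate, "rate", lower = 0, upper = 1, strict_upper = TRUE)
  n_target <- round(rate * length(x))
  with_seed(seed, {
    res <- apply_mechanism(x, matrix(FALSE, nrow(x), ncol(x)), "MCAR", n_target)
    finish_masked(x, res,
                  if (rate > 0) missingness_spec("MCAR", rate) else NULL, seed)
  })
}

#' Simulate MAR missingness
#'
#' Repeatedly picks a random pair of distinct features (driver X1, target
#' X2), draws a cut-off fraction c from [draw_cutoff_fraction()], and masks
#' X2 at the samples holding the top `ceiling(c * n_samples)` values of X1,
#' skipping cells already masked, until `round(rate * length(x))` cells are
#' missing; the final event is trimmed (keeping the highest-driver cells)
#' so the count is exact. Driver ranks are computed on the complete
#' original values.
#'
#' @inheritParams simulate_mcar
#' @return A [masked_matrix()] whose events record driver, target and
#'   cut-off for every step.
#' @export
simulate_mar <- function(x, rate, seed = NULL) {
  x <- validate_intensity_matrix(x)
  assert_scalar_number(rate, "rate", lower = 0, upper = 1, strict_upper = TRUE)
  n_target <- round(rate * length(x))
  with_seed(seed, {
    res <- apply_mechanism(x, matrix(FALSE, nrow(x), ncol(x)), "MAR", n_target)
    finish_masked(x, res,
                  if (rate > 0) missingness_spec("MAR", rate) else NULL, seed)
  })
}

#' Simulate MNAR missingness (truncation)
#'
#' Repeatedly picks a random feature, draws a cut-off fraction c, and masks
#' the smallest (left truncation, the default — mimicking a lower detection
#' limit) or largest (right) `ceiling(c * n_observed)` of the feature's
#' still-observed values, until `round(rate * length(x))` cells are missing;
#' the final event is trimmed (keeping the most extreme values) so the
#' count is exact.
#'
#' @inheritParams simulate_mcar
#' @param side `"left"` or `"right"` truncation.
#' @return A [masked_matrix()].
#' @export
simulate_mnar <- function(x, rate, side = c("left", "right"), seed = NULL) {
  x <- validate_intensity_matrix(x)
  side <- match.arg(side)
  assert_scalar_number(rate, "rate", lower = 0, upper = 1, strict_upper = TRUE)
  n_target <- round(rate * length(x))
  with_seed(seed, {
    res <- apply_mechanism(x, matrix(FALSE, nrow(x), ncol(x)), "MNAR",
                           n_target, side = side)
    finish_masked(x, res,
                  if (rate > 0) missingness_spec("MNAR", rate, side) else NULL,
                  seed)
  })
}

#' Simulate sequentially mixed missingness
#'
#' Applies 2–3 distinct component mechanisms one after another, each
#' removing an equal share of the total (`rate / length(components)` of all
#' cells, with any rounding remainder spread over the later steps), each
#' step operating on the output of the previous one: cells already masked
#' are never re-masked, and MNAR steps rank only the still-observed values.
#'
#' @inheritParams simulate_mnar
#' @param components Ordered character vector, a subset of
#'   `c("MCAR", "MAR", "MNAR")` with 2 or 3 distinct entries, applied in the
#'   given order.
#' @return A [masked_matrix()] whose events tag each masked cell with the
#'   step mechanism that removed it.
#' @export
simulate_mixed <- function(x, components, rate, side = c("left", "right"),
                           seed = NULL) {
  x <- validate_intensity_matrix(x)
  side <- match.arg(side)
  components <- toupper(components)
  if (length(components) < 2L || length(components) > 3L ||
      anyDuplicated(components) || !all(components %in% c("MCAR", "MAR", "MNAR"))) {
    stop("`components` must be 2-3 distinct mechanisms among MCAR, MAR, MNAR",
         call. = FALSE)
  }
  assert_scalar_number(rate, "rate", lower = 0, upper = 1, strict_upper = TRUE)
  total <- round(rate * length(x))
  k <- length(components)
  step_totals <- diff(c(0, round(seq_len(k) * total / k)))
  with_seed(seed, {
    mask <- matrix(FALSE, nrow(x), ncol(x))
    events <- list()
    for (i in seq_len(k)) {
      res <- apply_mechanism(x, mask, components[i], step_totals[i], side = side)
      mask <- res$mask
      events <- c(events, res$events)
    }
    spec <- if (rate > 0)
      missingness_spec(paste(components, collapse = "_"), rate, side) else NULL
    finish_masked(x, list(mask = mask, events = events), spec, seed)
  })
}

#' Simulate missingness under a mechanism specification
#'
#' Dispatches to [simulate_mcar()], [simulate_mar()], [simulate_mnar()] or
#' [simulate_mixed()] according to `spec$mechanism`. The returned mask
#' always contains exactly `round(spec$rate * length(x))` missing cells and
#' is deterministic for a fixed `seed`.
#'
#' @param x Complete numeric intensity matrix (samples x features).
#' @param spec A [missingness_spec()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A [masked_matrix()].
#' @export
#' @examples
#' x <- generate_complete_matrix(datagen_config(n_samples = 40, n_features = 30, seed = 2))
#' m <- simulate_missingness(x, missingness_spec("MCAR_MAR", 0.2), seed = 9)
#' sum(m$mask)  # exactly 0.2 * 40 * 30
simulate_missingness <- function(x, spec, seed = NULL) {
  if (!inherits(spec, "missingness_spec")) {
    stop("`spec` must be created by missingness_spec()", call. = FALSE)
  }
  parts <- strsplit(spec$mechanism, "_", fixed = TRUE)[[1L]]
  if (length(parts) == 1L) {
    switch(parts,
           MCAR = simulate_mcar(x, spec$rate, seed = seed),
           MAR = simulate_mar(x, spec$rate, seed = seed),
           MNAR = simulate_mnar(x, spec$rate, side = spec$truncation_side,
                                seed = seed))
  } else {
    simulate_mixed(x, parts, spec$rate, side = spec$truncation_side,
                   seed = seed)
  }
}
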