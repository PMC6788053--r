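#' Read an intensity matrix from CSV
#'
#' Expects the package's matrix layout: a header row of feature
#' identifiers, a first column of sample identifiers, and a numeric body.
#' Cells equal to `missing_sentinel` (or empty) are treated as missing: a
#' file without them yields a complete numeric matrix, a file with them
#' yields a [masked_matrix()]. Ragged rows, duplicate identifiers and
#' non-numeric cells raise errors naming the offending location.
#'
#' @param path CSV file path.
#' @param missing_sentinel String marking a missing cell (default `"NA"`;
#'   empty cells always count as missing).
#' @return A numeric matrix (complete file) or a [masked_matrix()].
#' @export
read_matrix_csv <- function(path, missing_sentinel = "NA") {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                  na.strings = NULL, fill = FALSE)
  if (ncol(raw) < 2L) {
    stop("matrix CSV needs a sample-id column plus at least one feature",
         call. = FALSE)
  }
  ids <- raw[[1L]]
  features <- names(raw)[-1L]
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sample id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(features)) {
    stop(sprintf("duplicate feature id(s): %s",
                 paste(unique(features[duplicated(features)]), collapse = ", ")),
         call. = FALSE)
  }
  body <- as.matrix(raw[, -1L, drop = FALSE])
  sentinel <- body == missing_sentinel | body == ""
  values <- suppressWarnings(as.numeric(body))
  bad <- !sentinel & is.na(values)
  if (any(bad)) {
    loc <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell '%s' at row %d (sample %s), column %s",
                 body[bad][1L], loc[1L], ids[loc[1L]], features[loc[2L]]),
         call. = FALSE)
  }
  values <- matrix(values, nrow = nrow(body),
                   dimnames = list(ids, features))
  if (any(sentinel)) {
    masked_matrix(values = values, mask = matrix(sentinel, nrow = nrow(body),
                                                 dimnames = dimnames(values)))
  } else {
    values
  }
}

#' Write a matrix (or masked matrix) to CSV
#'
#' Inverse of [read_matrix_csv()]: sample ids in the first column
#' (`sample_id`), feature ids in the header, missing cells written as
#' `missing_sentinel`. For a [masked_matrix()] produced by a simulator, a
#' JSON sidecar (`<path>.json`) records the mechanism spec, seed and
#' per-event provenance so the mask can be audited or replayed.
#'
#' @param x Numeric matrix or [masked_matrix()].
#' @param path Output CSV path.
#' @param missing_sentinel String written for missing cells.
#' @param sidecar Write the JSON provenance sidecar for masked matrices.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(x, path, missing_sentinel = "NA", sidecar = TRUE) {
  if (inherits(x, "masked_matrix")) {
    values <- x$values
    if (sidecar) {
      meta <- list(
        spec = if (!is.null(x$spec)) unclass(x$spec),
        seed = x$seed,
        n_missing = sum(x$mask),
        events = if (length(x$events) > 0L) masking_events(x)
      )
      jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                           null = "null", digits = NA)
    }
  } else {
    values <- x
  }
  df <- data.frame(sample_id = rownames(values) %||% seq_len(nrow(values)),
                   values, check.names = FALSE, stringsAsFactors = FALSE)
  body <- vapply(seq_len(nrow(df)), function(i) {
    cells <- c(as.character(df[i, 1L]),
               vapply(as.numeric(df[i, -1L]), function(v) {
                 if (is.na(v)) missing_sentinel else format(v, digits = 15)
               }, character(1)))
    paste(cells, collapse = ",")
  }, character(1))
  writeLines(c(paste(c("sample_id", colnames(values)), collapse = ","), body),
             path)
  invisible(path)
}
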