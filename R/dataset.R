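# The curated_dataset container: an ordered activity-record table plus a
# pipeline stage tag and an ordered provenance log. Records are rows of a
# plain data.frame with a fixed column set so that downstream stages can rely
# on positions and types.

.record_cols <- c("molecule_id", "smiles_raw", "smiles_std", "standard_type",
                  "value", "units", "relation", "assay_id",
                  "assay_description", "source_id", "pic50")

.stage_order <- c("raw", "standard_cleaned", "filtered", "sc_cleaned")

#' Construct a curated bioactivity dataset
#'
#' @param records data.frame of activity records; missing columns from the
#'   canonical set are added as `NA`.
#' @param stage pipeline stage, one of `"raw"`, `"standard_cleaned"`,
#'   `"filtered"`, `"sc_cleaned"`.
#' @param provenance ordered list of step descriptors.
#' @return a `curated_dataset` object.
#' @export
curated_dataset <- function(records, stage = "raw", provenance = list()) {
  stage <- match.arg(stage, .stage_order)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in .record_cols) {
    if (!col %in% names(records)) {
      records[[col]] <- if (col %in% c("value", "pic50")) {
        rep(NA_real_, nrow(records))
      } else {
        rep(NA_character_, nrow(records))
      }
    }
  }
  records <- records[, .record_cols, drop = FALSE]
  records$value <- as.numeric(records$value)
  records$pic50 <- as.numeric(records$pic50)
  chr <- setdiff(.record_cols, c("value", "pic50"))
  for (col in chr) records[[col]] <- as.character(records[[col]])
  rownames(records) <- NULL
  structure(list(records = records, stage = stage, provenance = provenance),
            class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat(sprintf("<curated_dataset> %d records, stage '%s', %d pipeline step(s)\n",
              nrow(x$records), x$stage, length(x$provenance)))
  if (nrow(x$records) > 0) {
    utils::str(utils::head(x$records, 3), give.attr = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.curated_dataset <- function(x, ...) x$records

#' Number of records in a curated dataset
#' @param x a `curated_dataset`.
#' @return integer record count.
#' @export
n_records <- function(x) nrow(x$records)

# Append a provenance step; enforces the in/out chaining invariant.
add_provenance <- function(ds, step, params, n_in, n_out, notes = NULL) {
  entry <- list(step = step, params = params, n_in = n_in, n_out = n_out)
  if (!is.null(notes)) entry$notes <- notes
  prev <- ds$provenance
  if (length(prev) > 0) {
    last <- prev[[length(prev)]]
    if (!identical(last$n_out, n_in)) {
      stopf("provenance chain broken: previous step emitted %d, next consumes %d",
            last$n_out, n_in)
    }
  }
  ds$provenance <- c(prev, list(entry))
  ds
}

# Forward-only stage transition.
set_stage <- function(ds, stage) {
  stage <- match.arg(stage, .stage_order)
  if (match(stage, .stage_order) < match(ds$stage, .stage_order)) {
    stopf("stage may not move backwards (%s -> %s)", ds$stage, stage)
  }
  ds$stage <- stage
  ds
}

assert_stage <- function(ds, allowed, op) {
  if (!inherits(ds, "curated_dataset")) {
    stopf("%s expects a curated_dataset", op)
  }
  if (!ds$stage %in% allowed) {
    stopf("%s requires stage in {%s}, got '%s'", op,
          paste(allowed, collapse = ", "), ds$stage)
  }
  invisible(ds)
}
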