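# Standard cleaning and molecular-weight filtering.
#
# Standard cleaning removes records that cannot carry a point potency (null
# or unparseable values, invalid SMILES, disallowed measurement types,
# censored relations, unsupported units, non-positive concentrations),
# standardizes structures to a canonical parent, converts concentrations to
# pIC50, and collapses EXACT duplicates (same parent SMILES, assay and pIC50).
# Conflicting cross-assay or cross-value duplicates are deliberately retained:
# choosing a representative among them is the job of selective cleaning.

.censored_relations <- c(">", "<", ">=", "<=")

# mol/L per unit; the log10 happens after conversion.
.unit_factors <- c("M" = 1, "mM" = 1e-3, "uM" = 1e-6, "µM" = 1e-6,
                   "μM" = 1e-6, "nM" = 1e-9, "pM" = 1e-12)

#' Cleaning configuration
#'
#' @param mw_low,mw_high molecular-weight window in Da, exclusive bounds
#'   (default 100 and 750).
#' @param allowed_types measurement-type labels admitted (default `"IC50"`).
#' @param drop_censored drop records whose relation is an inequality
#'   (`">"`, `"<"`, `">="`, `"<="`); default `TRUE`.
#' @param stereo_mode `"as_given"` keeps stereo descriptors so stereoisomers
#'   are distinct molecule keys; `"collapse"` strips them so enantiomeric
#'   duplicates merge.
#' @return a `cleaning_config` object.
#' @export
cleaning_config <- function(mw_low = 100, mw_high = 750,
                            allowed_types = "IC50", drop_censored = TRUE,
                            stereo_mode = c("as_given", "collapse")) {
  stereo_mode <- match.arg(stereo_mode)
  if (!(mw_low > 0 && mw_low < mw_high)) {
    stopf("require 0 < mw_low < mw_high")
  }
  structure(list(mw_low = mw_low, mw_high = mw_high,
                 allowed_types = allowed_types,
                 drop_censored = isTRUE(drop_censored),
                 stereo_mode = stereo_mode),
            class = "cleaning_config")
}

new_cleaning_report <- function(counts, n_in, n_out) {
  stopifnot(n_in - n_out == sum(counts))
  structure(list(counts = counts, records_in = n_in, records_out = n_out),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> %d -> %d records\n", x$records_in,
              x$records_out))
  kept <- x$counts[x$counts > 0]
  for (nm in names(kept)) cat(sprintf("  removed %-18s %d\n", nm, kept[[nm]]))
  invisible(x)
}

#' Standardize SMILES to a canonical parent form
#'
#' Keeps the largest organic fragment (salt stripping), neutralizes charges
#' where possible and emits the canonical form. Deterministic and idempotent.
#'
#' @param raw character vector of SMILES.
#' @param stereo_mode `"as_given"` retains stereo descriptors, `"collapse"`
#'   removes them.
#' @return character vector of canonical parent SMILES; `NA` for unparsable
#'   input.
#' @export
standardize_smiles <- function(raw, stereo_mode = c("as_given", "collapse")) {
  stereo_mode <- match.arg(stereo_mode)
  out <- rep(NA_character_, length(raw))
  usable <- !is.na(raw) & nzchar(trimws(as.character(raw)))
  if (any(usable)) {
    res <- chem_standardize(as.character(raw[usable]), stereo_mode)
    out[usable] <- ifelse(res$ok, res$std, NA_character_)
  }
  out
}

#' Convert a concentration measurement to pIC50
#'
#' pIC50 = -log10(concentration in mol/L). Vectorized; a rejected entry
#' (missing/non-positive value, unsupported units, or a censored relation
#' when `drop_censored` is set) yields `NA`.
#'
#' @param value numeric concentration values.
#' @param units unit labels; supported: M, mM, uM/µM, nM, pM.
#' @param relation relation labels; `"="` or missing means a point value.
#' @param config a [cleaning_config()].
#' @return numeric vector of pIC50 values with `NA` for rejections.
#' @export
to_pic50 <- function(value, units, relation = "=",
                     config = cleaning_config()) {
  n <- max(length(value), length(units), length(relation))
  value <- rep_len(as.numeric(value), n)
  units <- rep_len(as.character(units), n)
  relation <- rep_len(as.character(relation), n)
  reason <- pic50_reject_reason(value, units, relation, config)
  out <- rep(NA_real_, n)
  ok <- is.na(reason)
  out[ok] <- -log10(value[ok] * unname(.unit_factors[units[ok]]))
  out
}

# NA = accepted; otherwise the rejection reason (first applicable).
pic50_reject_reason <- function(value, units, relation, config) {
  reason <- rep(NA_character_, length(value))
  reason[is.na(value)] <- "null value"
  censored <- !is.na(relation) & relation %in% .censored_relations
  idx <- is.na(reason) & config$drop_censored & censored
  reason[idx] <- "censored relation"
  idx <- is.na(reason) & (is.na(units) | !units %in% names(.unit_factors))
  reason[idx] <- "unit failure"
  idx <- is.na(reason) & (!is.finite(value) | value <= 0)
  reason[idx] <- "unit failure"
  reason
}

#' Standard cleaning of a raw activity dataset
#'
#' Applies, in order: null-value removal, SMILES standardization (dropping
#' invalid structures), measurement-type restriction, censored-relation and
#' unit/domain handling via [to_pic50()], and exact-duplicate collapse
#' (identical parent SMILES, assay id and pIC50 keep their first occurrence).
#' Duplicates that disagree in assay or value are retained for selective
#' cleaning. Idempotent on its own output.
#'
#' @param dataset `curated_dataset` at stage `"raw"` (or `"standard_cleaned"`,
#'   for idempotent re-runs).
#' @param config a [cleaning_config()].
#' @return list with elements `dataset` (stage `"standard_cleaned"`) and
#'   `report` (a `cleaning_report`).
#' @export
standard_clean <- function(dataset, config = cleaning_config()) {
  assert_stage(dataset, c("raw", "standard_cleaned"), "standard_clean")
  rec <- dataset$records
  n_in <- nrow(rec)
  counts <- c("null value" = 0L, "invalid SMILES" = 0L,
              "disallowed type" = 0L, "censored relation" = 0L,
              "unit failure" = 0L, "exact duplicate" = 0L)
  reason <- rep(NA_character_, n_in)

  has_pic50 <- !is.na(rec$pic50)
  reason[!has_pic50 & is.na(rec$value)] <- "null value"

  todo <- is.na(reason)
  std <- standardize_smiles(rec$smiles_raw, config$stereo_mode)
  reason[todo & is.na(std)] <- "invalid SMILES"

  todo <- is.na(reason)
  bad_type <- !is.na(rec$standard_type) &
    !rec$standard_type %in% config$allowed_types
  bad_type <- bad_type | is.na(rec$standard_type)
  reason[todo & bad_type] <- "disallowed type"

  # pIC50 conversion for records that do not already carry one
  todo <- is.na(reason)
  conv_reason <- pic50_reject_reason(rec$value, rec$units, rec$relation,
                                     config)
  idx <- todo & !has_pic50 & !is.na(conv_reason)
  reason[idx] <- conv_reason[idx]

  pic50 <- rec$pic50
  calc <- is.na(reason) & !has_pic50
  if (any(calc)) {
    pic50[calc] <- to_pic50(rec$value[calc], rec$units[calc],
                            rec$relation[calc], config)
  }

  keep <- is.na(reason)
  out <- rec[keep, , drop = FALSE]
  out$smiles_std <- std[keep]
  out$pic50 <- pic50[keep]

  dup <- duplicated(data.frame(out$smiles_std, out$assay_id, out$pic50))
  counts["exact duplicate"] <- sum(dup)
  out <- out[!dup, , drop = FALSE]

  tab <- table(factor(reason, levels = names(counts)))
  counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  report <- new_cleaning_report(counts, n_in, nrow(out))

  ds <- curated_dataset(out, stage = "standard_cleaned",
                        provenance = dataset$provenance)
  notes <- if (nrow(out) == 0) "empty output after standard cleaning" else NULL
  ds <- add_provenance(ds, "standard_clean",
                       list(allowed_types = config$allowed_types,
                            drop_censored = config$drop_censored,
                            stereo_mode = config$stereo_mode),
                       n_in = n_in, n_out = nrow(out), notes = notes)
  if (!is.null(notes)) warning(notes, call. = FALSE)
  list(dataset = ds, report = report)
}

#' Molecular-weight filtering
#'
#' Retains records with `mw_low < MW < mw_high` (strict bounds), where MW is
#' the average molecular weight of the standardized parent structure.
#'
#' @param dataset `curated_dataset` at stage `"standard_cleaned"` (or
#'   `"filtered"` for idempotent re-runs) with `smiles_std` set.
#' @param config a [cleaning_config()].
#' @return list with elements `dataset` (stage `"filtered"`) and `report`.
#' @export
filter_mw <- function(dataset, config = cleaning_config()) {
  assert_stage(dataset, c("standard_cleaned", "filtered"), "filter_mw")
  rec <- dataset$records
  n_in <- nrow(rec)
  if (n_in > 0 && anyNA(rec$smiles_std)) {
    stopf("filter_mw requires smiles_std on every record")
  }
  mw <- if (n_in > 0) chem_mw(rec$smiles_std) else numeric(0)
  keep <- !is.na(mw) & mw > config$mw_low & mw < config$mw_high
  counts <- c("out-of-range MW" = sum(!keep))
  out <- rec[keep, , drop = FALSE]
  report <- new_cleaning_report(counts, n_in, nrow(out))
  ds <- curated_dataset(out, stage = "filtered",
                        provenance = dataset$provenance)
  ds <- add_provenance(ds, "filter_mw",
                       list(mw_low = config$mw_low, mw_high = config$mw_high),
                       n_in = n_in, n_out = nrow(out))
  list(dataset = ds, report = report)
}
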