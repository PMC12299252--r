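# Reading and writing of activity, docking-score and interaction tables.
# Comma and tab delimiters are auto-detected from the header line; numeric
# fields accept the Unicode minus that typeset tables often carry; missing
# cells ("" or NA) stay missing and are never coerced to 0.

.colmap_required <- c("molecule_id", "smiles", "type", "value", "units",
                      "assay_id")
.colmap_optional <- c("relation", "assay_description", "source_id",
                      "smiles_std", "pic50")

#' Define a column mapping for activity tables
#'
#' Maps the semantic fields of an activity record onto source column names.
#' `molecule_id`, `smiles`, `type`, `value`, `units` and `assay_id` are
#' required; `relation`, `assay_description`, `source_id`, `smiles_std` and
#' `pic50` are optional and filled with `NA` when unmapped or absent from the
#' file.
#'
#' @param ... named character scalars, e.g. `molecule_id = "Molecule ChEMBL ID"`.
#' @return a `column_map` object.
#' @seealso [chembl_colmap()], [native_colmap()]
#' @export
column_map <- function(...) {
  m <- c(...)
  if (is.null(names(m)) || any(!nzchar(names(m)))) {
    stopf("column_map() entries must all be named")
  }
  unknown <- setdiff(names(m), c(.colmap_required, .colmap_optional))
  if (length(unknown) > 0) {
    stopf("unknown column_map field(s): %s", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(.colmap_required, names(m))
  if (length(missing) > 0) {
    stopf("column_map is missing required field(s): %s",
          paste(missing, collapse = ", "))
  }
  structure(as.list(m), class = "column_map")
}

#' Built-in column map for ChEMBL web-export headers
#' @return a `column_map` for ChEMBL activity exports.
#' @export
chembl_colmap <- function() {
  column_map(
    molecule_id = "Molecule ChEMBL ID",
    smiles = "Smiles",
    type = "Standard Type",
    value = "Standard Value",
    units = "Standard Units",
    relation = "Standard Relation",
    assay_id = "Assay ChEMBL ID",
    assay_description = "Assay Description",
    source_id = "Document ChEMBL ID"
  )
}

#' Column map for tables written by [write_activity_table()]
#' @return a `column_map` matching the package's own output columns.
#' @export
native_colmap <- function() {
  column_map(
    molecule_id = "molecule_id", smiles = "smiles_raw",
    smiles_std = "smiles_std", type = "standard_type", value = "value",
    units = "units", relation = "relation", assay_id = "assay_id",
    assay_description = "assay_description", source_id = "source_id",
    pic50 = "pic50"
  )
}

resolve_colmap <- function(colmap) {
  if (inherits(colmap, "column_map")) return(colmap)
  if (is.character(colmap) && length(colmap) == 1) {
    return(switch(colmap,
                  chembl = chembl_colmap(),
                  native = native_colmap(),
                  stopf("unknown column map preset '%s'", colmap)))
  }
  stopf("colmap must be a column_map or a preset name")
}

# Sniff comma vs tab from the header line (ChEMBL ships both dialects).
detect_delim <- function(path) {
  header <- readLines(path, n = 1L, encoding = "UTF-8", warn = FALSE)
  if (length(header) == 0) return(",")
  ntab <- lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE)))
  ncom <- lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))
  if (ntab > ncom) "\t" else ","
}

read_delim_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  delim <- detect_delim(path)
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0) {
    return(data.frame())
  }
  utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                    comment.char = "", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE,
                    encoding = "UTF-8", fileEncoding = "UTF-8")
}

#' Read an activity table into a curated dataset
#'
#' One activity record is created per data row, in file order; the dataset is
#' tagged `stage = "raw"` with a seeded provenance log. Unparseable numeric
#' values are kept as missing (standard cleaning removes and counts them).
#'
#' @param path CSV/TSV file with a header row.
#' @param colmap a [column_map()], or a preset name (`"chembl"`, `"native"`).
#' @param source_id optional provenance label stored on every record.
#' @return a `curated_dataset` at stage `"raw"`.
#' @export
read_activity_table <- function(path, colmap = chembl_colmap(),
                                source_id = NULL) {
  colmap <- resolve_colmap(colmap)
  tab <- read_delim_table(path)
  missing <- setdiff(unlist(colmap[.colmap_required]), names(tab))
  if (nrow(tab) > 0 && length(missing) > 0) {
    stopf("mapped column(s) not in header: %s",
          paste(missing, collapse = ", "))
  }
  pick <- function(field) {
    col <- colmap[[field]]
    if (is.null(col) || !col %in% names(tab)) return(rep(NA_character_,
                                                         nrow(tab)))
    x <- as.character(tab[[col]])
    x[!is.na(x) & x %in% c("", "NA")] <- NA_character_  # missing, never 0
    x
  }
  rec <- data.frame(
    molecule_id = pick("molecule_id"),
    smiles_raw = pick("smiles"),
    smiles_std = pick("smiles_std"),
    standard_type = pick("type"),
    value = parse_num(pick("value")),
    units = pick("units"),
    relation = pick("relation"),
    assay_id = pick("assay_id"),
    assay_description = pick("assay_description"),
    source_id = if (is.null(source_id)) pick("source_id")
                else rep(source_id, nrow(tab)),
    pic50 = parse_num(pick("pic50")),
    stringsAsFactors = FALSE
  )
  ds <- curated_dataset(rec, stage = "raw")
  add_provenance(ds, "read_activity_table",
                 list(path = path), n_in = nrow(rec), n_out = nrow(rec))
}

#' Write a curated dataset to a delimited file
#'
#' The written table round-trips through [read_activity_table()] with the
#' [native_colmap()] preset, field for field.
#'
#' @param dataset non-empty `curated_dataset`.
#' @param path output path; `.tsv` extension selects tab, otherwise comma.
#' @return invisibly, `path`.
#' @export
write_activity_table <- function(dataset, path) {
  if (!inherits(dataset, "curated_dataset")) {
    stopf("write_activity_table expects a curated_dataset")
  }
  if (nrow(dataset$records) == 0) stopf("refusing to write an empty dataset")
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  ok <- tryCatch({
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.table(dataset$records, con, sep = delim, row.names = FALSE,
                       qmethod = "double", na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stopf("could not write '%s': %s", path,
                         conditionMessage(ok))
  invisible(path)
}

#' Read a docking-score table
#'
#' Expects a CSV/TSV with a ligand-id column followed by per-engine/target
#' numeric score columns. Blank cells are returned as `NA` (absent), never 0.
#'
#' @param path CSV/TSV file.
#' @param ligand_col name of the ligand id column; default the first column.
#' @return data.frame with `ligand_id` plus one numeric column per score.
#' @export
read_dock_scores <- function(path, ligand_col = NULL) {
  tab <- read_delim_table(path)
  if (nrow(tab) == 0) {
    return(data.frame(ligand_id = character(0), stringsAsFactors = FALSE))
  }
  ligand_col <- ligand_col %||% names(tab)[1]
  if (!ligand_col %in% names(tab)) {
    stopf("ligand column '%s' not in header", ligand_col)
  }
  ids <- as.character(tab[[ligand_col]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stopf("duplicate ligand id(s): %s", paste(dup, collapse = ", "))
  }
  score_cols <- setdiff(names(tab), ligand_col)
  out <- data.frame(ligand_id = ids, stringsAsFactors = FALSE)
  for (col in score_cols) out[[col]] <- parse_num(tab[[col]])
  out
}

#' Read a per-interaction energy table
#'
#' Expects columns for residue label, ligand id, interaction type and energy
#' (kcal/mol). Residue labels are kept verbatim; the energy sign is preserved
#' and a Unicode minus is accepted.
#'
#' @param path CSV/TSV file.
#' @param columns named character vector mapping `residue`, `ligand`, `type`,
#'   `energy` to source column names; defaults to those names.
#' @return data.frame with columns `residue`, `ligand_id`, `type`, `energy`.
#' @export
read_interaction_table <- function(path,
                                   columns = c(residue = "residue",
                                               ligand = "ligand",
                                               type = "type",
                                               energy = "energy")) {
  tab <- read_delim_table(path)
  if (nrow(tab) == 0) {
    return(data.frame(residue = character(0), ligand_id = character(0),
                      type = character(0), energy = numeric(0),
                      stringsAsFactors = FALSE))
  }
  for (f in c("residue", "ligand", "type", "energy")) {
    if (!columns[[f]] %in% names(tab)) {
      stopf("interaction table lacks mapped column '%s'", columns[[f]])
    }
  }
  energy <- parse_num(tab[[columns[["energy"]]]])
  bad <- which(is.na(energy))
  if (length(bad) > 0) {
    stopf("non-numeric energy in data row(s): %s",
          paste(bad, collapse = ", "))
  }
  data.frame(
    residue = as.character(tab[[columns[["residue"]]]]),
    ligand_id = as.character(tab[[columns[["ligand"]]]]),
    type = as.character(tab[[columns[["type"]]]]),
    energy = energy,
    stringsAsFactors = FALSE
  )
}
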