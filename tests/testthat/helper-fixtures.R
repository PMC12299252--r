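# Shared fixtures and small builders used across test files.

# Build a curated_dataset at a given stage directly from record fields.
make_dataset <- function(..., stage = "filtered") {
  df <- data.frame(..., stringsAsFactors = FALSE)
  screenclean::curated_dataset(df, stage = stage)
}

# A standard-cleanable raw CSV written to a temp file; returns the path.
write_fixture_csv <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path, useBytes = FALSE)
  path
}

# The "Molecule X" two-layer fixture: assay A is globally most prevalent
# (count 5: two records of X plus three of other molecules), assay B rarer
# (count 2) but holding X's global maximum. SC must keep 7.8 from A.
molecule_x_dataset <- function() {
  make_dataset(
    molecule_id = c("X", "X", "X", "Y", "Y", "Z", "Z"),
    smiles_std = c("CX", "CX", "CX", "CY", "CY", "CZ", "CZ"),
    smiles_raw = c("CX", "CX", "CX", "CY", "CY", "CZ", "CZ"),
    pic50 = c(7.2, 7.8, 8.9, 6.0, 6.1, 5.5, 5.6),
    assay_id = c("A", "A", "B", "A", "A", "A", "B"),
    stage = "filtered"
  )
}

# Random multi-assay record tables for property tests (synthetic keys, no
# chemistry involved).
random_record_table <- function(n_records, n_assays = 5, n_molecules = 8) {
  keys <- sprintf("MOLKEY_%02d", seq_len(n_molecules))
  assays <- sprintf("AS_%02d", seq_len(n_assays))
  make_dataset(
    molecule_id = sample(keys, n_records, replace = TRUE),
    smiles_std = NA_character_,
    pic50 = round(stats::runif(n_records, 4, 10), 2),
    assay_id = sample(assays, n_records, replace = TRUE),
    stage = "filtered"
  ) -> ds
  ds$records$smiles_std <- ds$records$molecule_id  # key == id for these
  ds
}

# Known structures used in chemistry-dependent tests.
SMILES_BENZENE_KEKULE <- "C1=CC=CC=C1"
SMILES_BENZENE <- "c1ccccc1"
SMILES_TOLUENE <- "Cc1ccccc1"
SMILES_ETHANE <- "CC"
SMILES_ATORVASTATIN <- paste0("CC(C)c1c(C(=O)Nc2ccccc2)c(-c2ccccc2)",
                              "c(-c2ccc(F)cc2)n1CC[C@@H](O)C[C@@H](O)CC(=O)O")
SMILES_SODIUM_ACETATE <- "CC(=O)[O-].[Na+]"
SMILES_STEARIC_ACID <- "CCCCCCCCCCCCCCCCCC(=O)O"
SMILES_CHLORO_TERPHENYL <- "Clc1ccc(-c2ccc(-c3ccccc3)cc2)cc1"
SMILES_PENTA_ALANINE <- paste0("CC(N)C(=O)NC(C)C(=O)NC(C)C(=O)NC(C)",
                               "C(=O)NC(C)C(=O)O")
SMILES_AMP <- "Nc1ncnc2c1ncn2C1OC(COP(=O)(O)O)C(O)C1O"

# Docking-score table mirroring the published five-ligand redocking layout.
dock_fixture_path <- function() {
  system.file("extdata", "mdm2_redock_scores.csv", package = "screenclean")
}

hits_fixture_path <- function() {
  system.file("extdata", "mdm2_screen_hits.csv", package = "screenclean")
}
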