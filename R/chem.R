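# Bridge to the bundled RDKit helper (inst/python/chemtool.py).
#
# Every chemistry primitive in the package funnels through chem_call(), which
# ships a whole batch of SMILES to one short-lived Python process and parses
# the JSON reply. Results are memoized per (op, arguments, smiles) in a
# package-local environment, so repeated pipeline runs in one session (e.g.
# the recovery experiment's replicates) pay the interpreter start-up cost only
# for previously unseen structures.

.chem_cache <- new.env(parent = emptyenv())

chem_python <- function() {
  py <- getOption("screenclean.python", NULL)
  if (is.null(py)) {
    py <- Sys.which("python")
    if (!nzchar(py)) py <- Sys.which("python3")
  }
  if (!nzchar(py)) {
    stopf("no Python interpreter found; set options(screenclean.python=...)")
  }
  py
}

chem_script <- function() {
  path <- system.file("python", "chemtool.py", package = "screenclean")
  if (!nzchar(path)) stopf("bundled chemtool.py not found")
  path
}

# One raw batched call; returns a list of per-SMILES result lists.
chem_call <- function(op, smiles, args = list()) {
  req <- jsonlite::toJSON(c(list(op = op, smiles = as.list(smiles)), args),
                          auto_unbox = TRUE, null = "null", digits = NA)
  out <- suppressWarnings(system2(chem_python(), shQuote(chem_script()),
                                  input = req, stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stopf("chemistry helper failed (exit %s) for op '%s'", status, op)
  }
  res <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
  if (length(res) != length(smiles) && op != "descriptor_names") {
    stopf("chemistry helper returned %d results for %d inputs",
          length(res), length(smiles))
  }
  res
}

# Memoized batch call: `key_extra` distinguishes argument variants of one op.
chem_cached <- function(op, smiles, args = list(), key_extra = "") {
  if (length(smiles) == 0) return(list())
  keys <- paste0(op, "\r", key_extra, "\r", smiles)
  hit <- vapply(keys, exists, logical(1), envir = .chem_cache,
                USE.NAMES = FALSE)
  if (any(!hit)) {
    miss_idx <- which(!hit)
    uniq <- !duplicated(smiles[miss_idx])
    todo_idx <- miss_idx[uniq]
    res <- chem_call(op, smiles[todo_idx], args)
    for (j in seq_along(todo_idx)) {
      assign(keys[todo_idx[j]], res[[j]], envir = .chem_cache)
    }
  }
  lapply(keys, get, envir = .chem_cache)
}

#' Clear the memoized chemistry cache
#'
#' Mainly useful in long sessions or after changing the Python interpreter.
#' @return invisibly, the number of entries dropped.
#' @export
chem_cache_clear <- function() {
  n <- length(ls(.chem_cache, all.names = TRUE))
  rm(list = ls(.chem_cache, all.names = TRUE), envir = .chem_cache)
  invisible(n)
}

# Standardization results for a character vector of SMILES.
# Returns a data.frame with columns ok, std, mw (NA where invalid).
chem_standardize <- function(smiles, stereo_mode = c("as_given", "collapse")) {
  stereo_mode <- match.arg(stereo_mode)
  res <- chem_cached("standardize", smiles,
                     args = list(stereo_mode = stereo_mode),
                     key_extra = stereo_mode)
  data.frame(
    ok  = vapply(res, function(r) isTRUE(r$ok), logical(1)),
    std = vapply(res, function(r) if (isTRUE(r$ok)) r$std else NA_character_,
                 character(1)),
    mw  = vapply(res, function(r) if (isTRUE(r$ok)) as.numeric(r$mw %||% NA)
                 else NA_real_, numeric(1)),
    stringsAsFactors = FALSE
  )
}

chem_mw <- function(smiles) {
  res <- chem_cached("mw", smiles)
  vapply(res, function(r) if (isTRUE(r$ok)) as.numeric(r$mw %||% NA)
         else NA_real_, numeric(1))
}

chem_scaffold <- function(smiles) {
  res <- chem_cached("scaffold", smiles)
  vapply(res, function(r) if (isTRUE(r$ok)) r$scaffold else NA_character_,
         character(1))
}

chem_features <- function(smiles) {
  res <- chem_cached("features", smiles)
  get_num <- function(r, f) if (isTRUE(r$ok)) as.numeric(r[[f]]) else NA_real_
  get_lgl <- function(r, f) if (isTRUE(r$ok)) isTRUE(r[[f]]) else NA
  data.frame(
    ok = vapply(res, function(r) isTRUE(r$ok), logical(1)),
    n_halogen = vapply(res, get_num, numeric(1), "n_halogen"),
    n_aromatic_rings = vapply(res, get_num, numeric(1), "n_aromatic_rings"),
    n_rotatable_bonds = vapply(res, get_num, numeric(1), "n_rotatable_bonds"),
    n_backbone_amide = vapply(res, get_num, numeric(1), "n_backbone_amide"),
    has_carboxylic_acid = vapply(res, get_lgl, logical(1),
                                 "has_carboxylic_acid"),
    has_phosphate = vapply(res, get_lgl, logical(1), "has_phosphate"),
    has_glycosidic = vapply(res, get_lgl, logical(1), "has_glycosidic"),
    longest_aliphatic_chain = vapply(res, get_num, numeric(1),
                                     "longest_aliphatic_chain"),
    stringsAsFactors = FALSE
  )
}

chem_descriptors <- function(smiles, names) {
  res <- chem_cached("descriptors", smiles,
                     args = list(names = as.list(names)),
                     key_extra = paste(names, collapse = ","))
  mat <- matrix(NA_real_, nrow = length(smiles), ncol = length(names),
                dimnames = list(NULL, names))
  for (i in seq_along(res)) {
    r <- res[[i]]
    if (!isTRUE(r$ok)) stopf("invalid SMILES for featurization: '%s'",
                             smiles[i])
    mat[i, ] <- vapply(r$values, function(v) as.numeric(v %||% NA), numeric(1))
  }
  mat
}
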