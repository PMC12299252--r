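# Post-prediction hit triage: a 2D potency/affinity region gate plus
# structural admissibility rules.
#
# The gate keeps candidates inside a "sweet spot" box of predicted potency
# (pIC50 6-10) and docking affinity (-9 to -6 kcal/mol): potent enough to
# matter, not so extreme as to suggest artifacts or liabilities. The
# structural rules demand a sigma-hole carrier (halogen), a modest aromatic
# ring count and limited flexibility, and exclude peptide-, nucleotide- and
# fatty-acid-like molecules and long aliphatic chains. The numeric
# operationalizations of those class exclusions are package decisions, all
# configurable here.

#' Hit-triage criteria
#'
#' @param pic50_low,pic50_high favorable predicted-potency window
#'   (dimensionless pIC50; defaults 6.0 and 10.0, inclusive).
#' @param affinity_low,affinity_high favorable docking-affinity window in
#'   kcal/mol (defaults -9.0 and -6.0, inclusive).
#' @param min_aromatic_rings,max_aromatic_rings admissible aromatic ring
#'   count (defaults 2 and 4).
#' @param require_sigma_hole require a halogen (F/Cl/Br/I) as the sigma-hole
#'   carrier (default `TRUE`).
#' @param max_rotatable_bonds flexibility cap (default 10); stand-in for a
#'   "constrained spatial arrangement" requirement with no canonical numeric
#'   definition.
#' @param peptide_amide_min peptide-likeness trigger: number of backbone
#'   amide bonds (default 3).
#' @param chain_min_carbons unbranched acyclic sp3 carbon chain length that
#'   triggers the fatty-acid / long-aliphatic exclusions (default 8).
#' @return a `triage_criteria` object.
#' @export
triage_criteria <- function(pic50_low = 6.0, pic50_high = 10.0,
                            affinity_low = -9.0, affinity_high = -6.0,
                            min_aromatic_rings = 2L, max_aromatic_rings = 4L,
                            require_sigma_hole = TRUE,
                            max_rotatable_bonds = 10L,
                            peptide_amide_min = 3L,
                            chain_min_carbons = 8L) {
  if (!(pic50_low < pic50_high)) stopf("require pic50_low < pic50_high")
  if (!(affinity_low < affinity_high)) {
    stopf("require affinity_low < affinity_high")
  }
  if (!(min_aromatic_rings <= max_aromatic_rings)) {
    stopf("aromatic ring bounds out of order")
  }
  structure(list(pic50_low = pic50_low, pic50_high = pic50_high,
                 affinity_low = affinity_low, affinity_high = affinity_high,
                 min_aromatic_rings = min_aromatic_rings,
                 max_aromatic_rings = max_aromatic_rings,
                 require_sigma_hole = isTRUE(require_sigma_hole),
                 max_rotatable_bonds = max_rotatable_bonds,
                 peptide_amide_min = peptide_amide_min,
                 chain_min_carbons = chain_min_carbons),
            class = "triage_criteria")
}

#' Potency/affinity region gate
#'
#' A candidate is `"favorable"` iff `pic50_low <= pic50 <= pic50_high` and
#' `affinity_low <= affinity <= affinity_high`, boundaries inclusive;
#' otherwise `"outside"` with the failing condition(s) recorded.
#'
#' @param pic50 predicted potency values.
#' @param affinity docking affinities (kcal/mol).
#' @param criteria a [triage_criteria()].
#' @return data.frame with columns `region`, `pic50_in`, `affinity_in`.
#' @export
region_gate <- function(pic50, affinity, criteria = triage_criteria()) {
  if (length(pic50) != length(affinity)) stopf("length mismatch")
  if (any(!is.finite(pic50)) || any(!is.finite(affinity))) {
    stopf("region_gate requires finite inputs")
  }
  pic50_in <- pic50 >= criteria$pic50_low & pic50 <= criteria$pic50_high
  affinity_in <- affinity >= criteria$affinity_low &
    affinity <= criteria$affinity_high
  data.frame(region = ifelse(pic50_in & affinity_in, "favorable", "outside"),
             pic50_in = pic50_in, affinity_in = affinity_in,
             stringsAsFactors = FALSE)
}

#' Structural admissibility filter
#'
#' A molecule passes iff it carries a sigma-hole halogen (when required), its
#' aromatic ring count lies within the admissible window, its rotatable-bond
#' count is at or below the cap, and no exclusion rule fires (`peptide_like`,
#' `nucleotide_like`, `fatty_acid_like`, `long_aliphatic`). Every violated
#' rule is named in `reasons`.
#'
#' @param smiles character vector of valid SMILES.
#' @param criteria a [triage_criteria()].
#' @return data.frame with `smiles`, `pass` and a `reasons` list-column.
#' @export
structural_filter <- function(smiles, criteria = triage_criteria()) {
  feats <- chem_features(as.character(smiles))
  if (any(!feats$ok)) {
    stopf("invalid SMILES in structural_filter: '%s'",
          smiles[which(!feats$ok)[1]])
  }
  reasons <- lapply(seq_along(smiles), function(i) {
    f <- feats[i, ]
    r <- character(0)
    if (criteria$require_sigma_hole && f$n_halogen < 1) {
      r <- c(r, "no_sigma_hole")
    }
    if (f$n_aromatic_rings < criteria$min_aromatic_rings) {
      r <- c(r, "too_few_aromatic_rings")
    }
    if (f$n_aromatic_rings > criteria$max_aromatic_rings) {
      r <- c(r, "too_many_aromatic_rings")
    }
    if (f$n_rotatable_bonds > criteria$max_rotatable_bonds) {
      r <- c(r, "too_flexible")
    }
    if (f$n_backbone_amide >= criteria$peptide_amide_min) {
      r <- c(r, "peptide_like")
    }
    if (f$has_phosphate && f$has_glycosidic) r <- c(r, "nucleotide_like")
    long_chain <- f$longest_aliphatic_chain >= criteria$chain_min_carbons
    if (f$has_carboxylic_acid && long_chain) r <- c(r, "fatty_acid_like")
    if (long_chain) r <- c(r, "long_aliphatic")
    r
  })
  out <- data.frame(smiles = as.character(smiles),
                    pass = lengths(reasons) == 0,
                    stringsAsFactors = FALSE)
  out$reasons <- reasons
  out
}

#' Triage virtual-screening candidates
#'
#' Applies the region gate and the structural filter; candidates that are
#' favorable and structurally admissible are ranked by descending predicted
#' pIC50, ties by more negative affinity, then by id. The full verdict is
#' retained for every input (rejected candidates carry `rank = NA`).
#'
#' @param candidates data.frame with columns `id`, `smiles`, `pic50`,
#'   `affinity`.
#' @param criteria a [triage_criteria()].
#' @return data.frame of all candidates with `region`, `structural_pass`,
#'   `reasons`, and `rank`, ordered ranked hits first.
#' @export
triage <- function(candidates, criteria = triage_criteria()) {
  need <- c("id", "smiles", "pic50", "affinity")
  if (!all(need %in% names(candidates))) {
    stopf("candidates must have columns %s", paste(need, collapse = ", "))
  }
  out <- as.data.frame(candidates, stringsAsFactors = FALSE)
  if (nrow(out) == 0) {
    out$region <- character(0); out$structural_pass <- logical(0)
    out$reasons <- list(); out$rank <- integer(0)
    return(out)
  }
  gate <- region_gate(out$pic50, out$affinity, criteria)
  sf <- structural_filter(out$smiles, criteria)
  out$region <- gate$region
  out$structural_pass <- sf$pass
  out$reasons <- sf$reasons
  out$rank <- NA_integer_
  hit <- out$region == "favorable" & out$structural_pass
  if (any(hit)) {
    ord <- order(-out$pic50[hit], out$affinity[hit], out$id[hit])
    out$rank[which(hit)[ord]] <- seq_len(sum(hit))
  }
  out[order(is.na(out$rank), out$rank), , drop = FALSE]
}
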