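# Post-docking analysis: pocket-selectivity deltas, rank-mean consensus over
# docking engines, and interaction-energy classification into the
# -/+/++/+++ strength grades.

#' Pocket selectivity delta (p1 vs p2)
#'
#' Computed as `score_p2 - score_p1`: docking scores are energies (more
#' negative = stronger), so a positive delta means stronger binding at the
#' primary pocket p1. This matches the sign convention of published
#' "p1-p2" columns, whose printed label reads the other way around.
#'
#' @param score_p1,score_p2 docking scores (kcal/mol) at the primary and
#'   secondary pocket.
#' @return numeric delta in kcal/mol.
#' @export
selectivity_delta <- function(score_p1, score_p2) {
  if (any(!is.finite(score_p1)) || any(!is.finite(score_p2))) {
    stopf("selectivity_delta requires finite scores")
  }
  score_p2 - score_p1
}

#' Rank-mean consensus over docking engines
#'
#' Each engine ranks ligands with its own polarity (rank 1 = best): energy
#' scores rank ascending (most negative first), fitness scores such as GOLD
#' rank descending. The consensus is the mean rank over the engines that
#' scored the ligand; missing engines are simply excluded from that ligand's
#' mean. Rank-based aggregation makes the result invariant to any strictly
#' monotone per-engine rescaling, which is what makes incommensurable score
#' scales comparable.
#'
#' @param rows data.frame from [read_dock_scores()]: `ligand_id` plus one
#'   numeric column per engine/target.
#' @param higher_better character vector of column names where larger scores
#'   are better (default: columns matching `"GOLD"`, case-insensitively).
#' @param score_cols columns to use; default all non-id columns.
#' @return data.frame with per-engine ranks, `consensus`, and `consensus_rank`,
#'   ordered by consensus then ligand id.
#' @export
consensus_rank <- function(rows, higher_better = NULL, score_cols = NULL) {
  if (!"ligand_id" %in% names(rows)) stopf("rows must have ligand_id")
  score_cols <- score_cols %||% setdiff(names(rows), "ligand_id")
  if (is.null(higher_better)) {
    higher_better <- grep("GOLD", score_cols, ignore.case = TRUE,
                          value = TRUE)
  }
  no_scores <- rowSums(!is.na(rows[score_cols])) == 0
  if (any(no_scores)) {
    warning(sprintf("excluding %d ligand(s) with no scores: %s",
                    sum(no_scores),
                    paste(rows$ligand_id[no_scores], collapse = ", ")),
            call. = FALSE)
    rows <- rows[!no_scores, , drop = FALSE]
  }
  out <- data.frame(ligand_id = rows$ligand_id, stringsAsFactors = FALSE)
  for (col in score_cols) {
    s <- rows[[col]]
    if (col %in% higher_better) s <- -s
    r <- rep(NA_real_, length(s))
    ok <- !is.na(s)
    r[ok] <- rank(s[ok], ties.method = "average")
    out[[paste0("rank_", col)]] <- r
  }
  rank_cols <- grep("^rank_", names(out), value = TRUE)
  out$consensus <- rowMeans(out[rank_cols], na.rm = TRUE)
  out <- out[order(out$consensus, out$ligand_id), , drop = FALSE]
  out$consensus_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Interaction strength thresholds
#'
#' @param t0,t1,t2 class boundaries in kcal/mol; defaults -0.1, -1.0, -3.0
#'   with `t2 < t1 < t0 < 0`.
#' @return an `interaction_class` threshold object.
#' @export
interaction_class <- function(t0 = -0.1, t1 = -1.0, t2 = -3.0) {
  if (!(t2 < t1 && t1 < t0 && t0 < 0)) stopf("require t2 < t1 < t0 < 0")
  structure(list(t0 = t0, t1 = t1, t2 = t2), class = "interaction_class")
}

#' Classify a non-covalent interaction energy
#'
#' Grades: `'-'` (insignificant) for `E > -0.1`; `'+'` (weak) for
#' `-1.0 < E <= -0.1`; `'++'` (moderate) for `-3.0 < E <= -1.0`; `'+++'`
#' (strong) for `E <= -3.0` kcal/mol. Boundaries belong to the stronger
#' class.
#'
#' @param energy numeric energies (kcal/mol).
#' @param thresholds an [interaction_class()].
#' @return character vector of symbols.
#' @export
classify_interaction <- function(energy, thresholds = interaction_class()) {
  if (any(!is.finite(energy))) stopf("classify_interaction requires finite energies")
  ifelse(energy > thresholds$t0, "-",
         ifelse(energy > thresholds$t1, "+",
                ifelse(energy > thresholds$t2, "++", "+++")))
}

#' Residue-by-ligand interaction profile
#'
#' Multiple records for one (residue, ligand) cell are aggregated by summing
#' their energies before classification; absent pairs are `'-'`. Row and
#' column order follow first appearance in the input.
#'
#' @param records data.frame from [read_interaction_table()] (`residue`,
#'   `ligand_id`, `energy`, optionally `type`).
#' @param thresholds an [interaction_class()].
#' @return character matrix, residues as rows and ligands as columns.
#' @export
build_profile <- function(records, thresholds = interaction_class()) {
  if (nrow(records) == 0) {
    return(matrix(character(0), nrow = 0, ncol = 0))
  }
  residues <- unique(records$residue)
  ligands <- unique(records$ligand_id)
  sums <- tapply(records$energy,
                 list(factor(records$residue, levels = residues),
                      factor(records$ligand_id, levels = ligands)),
                 sum)
  profile <- matrix("-", nrow = length(residues), ncol = length(ligands),
                    dimnames = list(residues, ligands))
  present <- !is.na(sums)
  profile[present] <- classify_interaction(sums[present], thresholds)
  profile
}

#' Agreement between two interaction-profile columns
#'
#' @param a,b named character vectors of symbols over the same residue set
#'   (e.g. columns of [build_profile()] output).
#' @return fraction of residues with identical symbols, in `[0, 1]`.
#' @export
profile_similarity <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)) ||
      !setequal(names(a), names(b))) {
    stopf("profile_similarity requires identical residue sets")
  }
  mean(a == b[names(a)])
}
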