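# Selective cleaning (SC): assay-aware duplicate resolution.
#
# When a molecule carries several bioactivity entries, SC applies a two-layer
# rule: (1) restrict the candidates to the molecule's most globally prevalent
# assay — the assay contributing the most records to the whole dataset —
# and (2) keep the maximum pIC50 within that assay. Layer 1 protects against
# the classic failure of "take the global maximum": a spuriously high value
# reported by a rarely used assay procedure becomes the molecule's label.
#
# Tie rules (the data do not decide these, so they are declared): equal assay
# prevalence breaks by assay_id ascending; equal pIC50 within the chosen
# assay keeps the earliest input row.

#' Per-assay record counts and prevalence ranks
#'
#' @param dataset `curated_dataset` at stage `"standard_cleaned"` or
#'   `"filtered"` (also accepted: `"sc_cleaned"`, for reporting).
#' @return data.frame with columns `assay_id`, `count`, `rank`, sorted by
#'   count descending with ties broken by `assay_id` ascending.
#' @export
compute_assay_prevalence <- function(dataset) {
  assert_stage(dataset, c("standard_cleaned", "filtered", "sc_cleaned"),
               "compute_assay_prevalence")
  rec <- dataset$records
  tab <- table(rec$assay_id)
  out <- data.frame(assay_id = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$assay_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

molecule_key <- function(records) records$smiles_std

#' Selective cleaning: one representative record per molecule
#'
#' Keeps, for every molecule key (standardized parent SMILES under the active
#' stereo mode), the maximum-pIC50 record from that molecule's most globally
#' prevalent assay. Equivalent to a stable sort of all records by (assay
#' prevalence rank ascending, pIC50 descending, input row) followed by taking
#' the first occurrence of each molecule key.
#'
#' @param dataset `curated_dataset` at stage `"standard_cleaned"` or
#'   `"filtered"`, with `pic50` set on every record.
#' @return list with elements `dataset` (stage `"sc_cleaned"`, one record per
#'   molecule) and `report` (an `sc_report`: per-molecule choice, candidate
#'   count and discarded records with reasons).
#' @export
selective_clean <- function(dataset) {
  assert_stage(dataset, c("standard_cleaned", "filtered"), "selective_clean")
  rec <- dataset$records
  n_in <- nrow(rec)
  if (n_in > 0 && anyNA(rec$pic50)) {
    bad <- which(is.na(rec$pic50))[1]
    stopf("selective_clean: record %d (molecule '%s') has no pic50",
          bad, rec$molecule_id[bad])
  }
  prevalence <- compute_assay_prevalence(dataset)
  rank_of <- stats::setNames(prevalence$rank, prevalence$assay_id)

  key <- molecule_key(rec)
  arank <- unname(rank_of[rec$assay_id])
  ord <- order(arank, -rec$pic50, seq_len(n_in))
  first <- !duplicated(key[ord])
  kept_rows <- ord[first]

  out <- rec[kept_rows, , drop = FALSE]
  ds <- curated_dataset(out, stage = "sc_cleaned",
                        provenance = dataset$provenance)
  ds <- add_provenance(ds, "selective_clean", list(),
                       n_in = n_in, n_out = nrow(out))

  chosen_of <- stats::setNames(kept_rows, key[kept_rows])
  molecules <- unique(key)
  per_mol <- lapply(molecules, function(k) {
    rows <- which(key == k)
    chosen <- chosen_of[[k]]
    discarded <- setdiff(rows, chosen)
    reasons <- ifelse(rec$assay_id[discarded] == rec$assay_id[chosen],
                      "lower value in chosen assay", "less prevalent assay")
    list(molecule = k,
         chosen_row = chosen,
         chosen_record = rec[chosen, , drop = FALSE],
         chosen_assay = rec$assay_id[chosen],
         chosen_assay_rank = unname(rank_of[rec$assay_id[chosen]]),
         n_candidates = length(rows),
         discarded = data.frame(row = discarded, reason = reasons,
                                assay_id = rec$assay_id[discarded],
                                pic50 = rec$pic50[discarded],
                                stringsAsFactors = FALSE))
  })
  names(per_mol) <- molecules
  report <- structure(list(molecules = per_mol, prevalence = prevalence),
                      class = "sc_report")
  list(dataset = ds, report = report)
}

#' @export
print.sc_report <- function(x, ...) {
  n_disc <- sum(vapply(x$molecules, function(m) nrow(m$discarded), integer(1)))
  cat(sprintf("<sc_report> %d molecule(s), %d discarded record(s), %d assay(s)\n",
              length(x$molecules), n_disc, nrow(x$prevalence)))
  invisible(x)
}

#' Brute-force reference for the selective-cleaning rule
#'
#' Testing aid: applies the two-layer rule to the records of a single
#' molecule by plain enumeration, without any sorting machinery. Independent
#' of [selective_clean()] on purpose.
#'
#' @param records data.frame of activity records sharing one molecule key.
#' @param stats assay prevalence data.frame from [compute_assay_prevalence()].
#' @return the single chosen record (one-row data.frame) with attribute
#'   `"row"` giving its index within `records`.
#' @export
sc_oracle <- function(records, stats) {
  if (nrow(records) == 0) stopf("sc_oracle: no records")
  count_of <- stats::setNames(stats$count, stats$assay_id)
  # layer 1: most prevalent assay among those this molecule appears in
  best_assay <- NULL
  best_count <- -Inf
  for (i in seq_len(nrow(records))) {
    a <- records$assay_id[i]
    cnt <- count_of[[a]]
    if (cnt > best_count || (cnt == best_count && a < best_assay)) {
      best_assay <- a
      best_count <- cnt
    }
  }
  # layer 2: maximum pIC50 within that assay, earliest row on ties
  best_row <- NA_integer_
  best_val <- -Inf
  for (i in seq_len(nrow(records))) {
    if (records$assay_id[i] != best_assay) next
    if (records$pic50[i] > best_val) {
      best_val <- records$pic50[i]
      best_row <- i
    }
  }
  out <- records[best_row, , drop = FALSE]
  attr(out, "row") <- best_row
  out
}

#' Naive duplicate-resolution strategies
#'
#' Baselines against which selective cleaning is compared: `random` picks a
#' seeded random candidate, `average` synthesizes a record carrying the mean
#' pIC50 under an `"aggregate"` assay label, `global_max` keeps the overall
#' maximum pIC50 (the strategy SC is designed to improve on), and
#' `most_recent` uses input row order as the recency proxy (last row wins).
#'
#' @param dataset `curated_dataset` at stage `"standard_cleaned"` or
#'   `"filtered"` with `pic50` set.
#' @param strategy one of `"random"`, `"average"`, `"global_max"`,
#'   `"most_recent"`.
#' @param seed integer seed (used by `"random"`).
#' @return a `curated_dataset` at stage `"sc_cleaned"`, one record per
#'   molecule key.
#' @export
naive_clean <- function(dataset, strategy = c("random", "average",
                                              "global_max", "most_recent"),
                        seed = 1L) {
  strategy <- match.arg(strategy)
  assert_stage(dataset, c("standard_cleaned", "filtered"), "naive_clean")
  rec <- dataset$records
  n_in <- nrow(rec)
  if (n_in > 0 && anyNA(rec$pic50)) stopf("naive_clean requires pic50 set")
  key <- molecule_key(rec)
  keys <- unique(key)
  rows_by_key <- split(seq_len(n_in), factor(key, levels = keys))
  pick <- with_seed(seed, lapply(rows_by_key, function(rows) {
    switch(strategy,
      random = rows[sample.int(length(rows), 1L)],
      global_max = rows[which.max(rec$pic50[rows])],
      most_recent = rows[length(rows)],
      average = rows  # handled below
    )
  }))
  if (strategy == "average") {
    out <- do.call(rbind, lapply(pick, function(rows) {
      r <- rec[rows[1], , drop = FALSE]
      r$pic50 <- mean(rec$pic50[rows])
      r$assay_id <- "aggregate"
      r$value <- NA_real_
      r$relation <- NA_character_
      r
    }))
  } else {
    out <- rec[unlist(pick, use.names = FALSE), , drop = FALSE]
  }
  ds <- curated_dataset(out, stage = "sc_cleaned",
                        provenance = dataset$provenance)
  add_provenance(ds, paste0("naive_clean:", strategy),
                 list(strategy = strategy, seed = seed),
                 n_in = n_in, n_out = nrow(out))
}
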