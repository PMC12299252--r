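# Scaffold-aware and random train/validation/test splitting.
#
# Scaffold splitting assigns whole Bemis-Murcko scaffold groups to a single
# partition so no scaffold spans two partitions; it stresses generalization
# to unseen chemotypes. The assignment policy is the common convention:
# largest groups fill the training partition first, the remaining groups are
# shuffled by the seed and assigned greedily to the partition furthest below
# its target size.

#' Bemis-Murcko scaffold of a molecule
#'
#' Ring systems plus the linkers connecting them, side chains removed.
#' Stereo descriptors are stripped first so enantiomers share one scaffold.
#' Acyclic molecules map to the empty scaffold `""`.
#'
#' @param smiles character vector of valid SMILES.
#' @return character vector of scaffold SMILES.
#' @export
murcko_scaffold <- function(smiles) {
  out <- chem_scaffold(as.character(smiles))
  if (anyNA(out)) {
    stopf("invalid SMILES for scaffold extraction: '%s'",
          smiles[which(is.na(out))[1]])
  }
  out
}

new_split_assignment <- function(assignment, scaffolds, fractions, seed,
                                 mode) {
  structure(list(assignment = assignment, scaffolds = scaffolds,
                 fractions = fractions, seed = seed, mode = mode),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  sizes <- table(factor(x$assignment, levels = c("train", "val", "test")))
  cat(sprintf("<split_assignment> mode '%s', sizes train=%d val=%d test=%d, seed %s\n",
              x$mode, sizes[["train"]], sizes[["val"]], sizes[["test"]],
              x$seed))
  invisible(x)
}

check_fractions <- function(fractions) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stopf("fractions must be three non-negative numbers summing to 1")
  }
  stats::setNames(fractions, c("train", "val", "test"))
}

split_keys <- function(dataset) {
  if (inherits(dataset, "curated_dataset")) {
    keys <- dataset$records$smiles_std
  } else {
    keys <- as.character(dataset)
  }
  if (anyNA(keys)) stopf("splitting requires smiles_std on every record")
  if (anyDuplicated(keys)) {
    stopf("splitting requires one record per molecule; run selective_clean or naive_clean first")
  }
  keys
}

#' Scaffold split
#'
#' @param dataset a one-record-per-molecule `curated_dataset` (typically stage
#'   `"sc_cleaned"`), or a character vector of unique SMILES keys.
#' @param fractions numeric triple (train, val, test) summing to 1.
#' @param seed integer seed for the shuffle of the small scaffold groups.
#' @return a `split_assignment` whose `assignment` is a named character
#'   vector (molecule key -> `"train"`/`"val"`/`"test"`), with the scaffold
#'   map attached. No scaffold appears in more than one partition.
#' @export
scaffold_split <- function(dataset, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  fractions <- check_fractions(fractions)
  keys <- split_keys(dataset)
  n <- length(keys)
  scaffolds <- murcko_scaffold(keys)
  names(scaffolds) <- keys
  groups <- split(keys, scaffolds)
  sizes <- lengths(groups)
  targets <- fractions * n

  # phase 1: largest groups (ties by scaffold string) fill train
  ord <- order(-sizes, names(groups))
  groups <- groups[ord]
  sizes <- sizes[ord]
  if (sizes[1] > targets[["train"]]) {
    warning("a scaffold group exceeds the train target; assigned to train",
            call. = FALSE)
  }
  counts <- c(train = 0, val = 0, test = 0)
  assignment <- stats::setNames(rep(NA_character_, n), keys)
  i <- 1L
  while (i <= length(groups) && counts[["train"]] < targets[["train"]]) {
    assignment[groups[[i]]] <- "train"
    counts[["train"]] <- counts[["train"]] + sizes[[i]]
    i <- i + 1L
  }
  # phase 2: shuffle the rest, greedily fill the most deficient partition
  remaining <- if (i <= length(groups)) seq(i, length(groups)) else integer(0)
  remaining <- with_seed(seed,
                         remaining[sample.int(length(remaining))])
  for (g in remaining) {
    deficit <- targets - counts
    part <- names(deficit)[which.max(deficit)]  # ties: train > val > test
    assignment[groups[[g]]] <- part
    counts[[part]] <- counts[[part]] + sizes[[g]]
  }
  if ((fractions[["val"]] > 0 && counts[["val"]] == 0) ||
      (fractions[["test"]] > 0 && counts[["test"]] == 0)) {
    warning("a requested partition is empty (scaffold groups are atomic)",
            call. = FALSE)
  }
  new_split_assignment(assignment, scaffolds, fractions, seed, "scaffold")
}

#' Random split
#'
#' Seeded uniform shuffle followed by contiguous slicing at the requested
#' fractions.
#'
#' @inheritParams scaffold_split
#' @return a `split_assignment`.
#' @export
random_split <- function(dataset, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  fractions <- check_fractions(fractions)
  keys <- split_keys(dataset)
  n <- length(keys)
  shuffled <- with_seed(seed, sample(keys))
  n_train <- round(fractions[["train"]] * n)
  n_val <- round(fractions[["val"]] * n)
  n_val <- min(n_val, n - n_train)
  labels <- rep("test", n)
  if (n_train > 0) labels[seq_len(n_train)] <- "train"
  if (n_val > 0) labels[n_train + seq_len(n_val)] <- "val"
  assignment <- stats::setNames(labels, shuffled)[keys]
  new_split_assignment(assignment, scaffolds = NULL, fractions, seed,
                       "random")
}
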