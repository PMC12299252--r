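# Synthetic multi-assay bioactivity tables with known ground truth.
#
# The generator emulates the duplicate structure of public bioactivity
# extracts: every molecule has a latent potency; assays contribute records
# according to a Zipf prevalence law and carry additive biases in pIC50
# space (a multiplicative IC50 systematic is additive after the log);
# individual measurements add Gaussian noise; a fraction of molecules is
# re-emitted with a stereo descriptor added, mimicking stereo-ambiguous
# registrations. Observed values are emitted as IC50 in nM so that the full
# cleaning path, including unit conversion, is exercised end to end. The
# stress scenario concentrates a positive bias on the least prevalent assay:
# exactly the setting in which "take the global maximum" mislabels molecules
# and assay-aware selective cleaning should not.

# -- fragment grammar (deterministic candidate pool) -------------------------

.grammar_subs <- c("F", "Cl", "Br", "I", "C", "CC", "O", "OC", "N",
                   "C(F)(F)F", "C#N", "C(=O)O", "C(C)C", "[N+](=O)[O-]")
.grammar_tails <- c("C", "CC", "CCO", "CCN", "C(O)CC", "CCC(=O)O", "CCOC",
                    "CCC", "CCCO", "C(C)C", "CC(=O)C", "CCNC")
.grammar_tiny <- c("CCO", "CCC", "CCN", "C1CC1", "CCOC", "CC(C)O", "CC=O",
                   "OCCO", "CC#N", "C1CCC1", "NCCO", "CCCC")

build_grammar_pool <- function() {
  subs <- .grammar_subs
  tails <- .grammar_tails
  combos <- expand.grid(sub = subs, tail = tails, stringsAsFactors = FALSE)
  mono <- sprintf("c1ccc(%s)cc1%s", combos$sub, combos$tail)
  pyr <- sprintf("c1cc(%s)cnc1%s", combos$sub, combos$tail)
  naph <- sprintf("c1ccc2cc(%s)ccc2c1%s", combos$sub, combos$tail)
  biaryl <- sprintf("c1ccc(-c2ccc(%s)cc2)cc1%s", combos$sub, combos$tail)
  triaryl <- sprintf("c1ccc(-c2ccc(-c3ccc(%s)cc3)cc2)cc1%s",
                     combos$sub, combos$tail)
  amide_grid <- expand.grid(s1 = subs, s2 = subs, stringsAsFactors = FALSE)
  amide <- sprintf("O=C(Nc1ccc(%s)cc1)c1ccc(%s)cc1",
                   amide_grid$s1, amide_grid$s2)
  heavy <- sprintf(
    "C(I)(I)c1ccc(-c2ccc(-c3ccc(-c4ccc(%s)cc4)cc3)cc2)cc1CCCCCCCCCCCCCC",
    subs)
  pool <- data.frame(
    smiles = c(.grammar_tiny, mono, pyr, naph, biaryl, triaryl, amide, heavy),
    family = c(rep("tiny", length(.grammar_tiny)),
               rep("mono", length(mono)), rep("pyridyl", length(pyr)),
               rep("naphthyl", length(naph)), rep("biaryl", length(biaryl)),
               rep("triaryl", length(triaryl)), rep("amide", length(amide)),
               rep("heavy", length(heavy))),
    stringsAsFactors = FALSE
  )
  pool <- pool[!duplicated(pool$smiles), , drop = FALSE]
  # tails ending in the secondary-alcohol motif admit stereo annotation
  pool$chiral_capable <- grepl("C\\(O\\)CC$", pool$smiles)
  # up-weight the MW tails so both filter boundaries are exercised
  pool$weight <- ifelse(pool$family %in% c("tiny", "heavy"), 4, 1)
  rownames(pool) <- NULL
  pool
}

.grammar_pool_cache <- new.env(parent = emptyenv())

grammar_pool <- function() {
  if (is.null(.grammar_pool_cache$pool)) {
    .grammar_pool_cache$pool <- build_grammar_pool()
  }
  .grammar_pool_cache$pool
}

#' Generate valid synthetic molecules
#'
#' Draws `n` distinct SMILES from an embedded fragment grammar (aryl cores,
#' halogen and polar decorations, linkers, aliphatic tails) spanning roughly
#' MW 45-900 so molecular-weight filtering is exercised. Deterministic per
#' seed.
#'
#' @param n number of molecules (at most the grammar pool size, ~1100).
#' @param seed integer seed.
#' @return data.frame with columns `smiles` and `chiral_capable`.
#' @export
generate_molecules <- function(n, seed = 1L) {
  pool <- grammar_pool()
  if (n < 1) stopf("n must be >= 1")
  if (n > nrow(pool)) {
    stopf("n = %d exceeds the grammar pool size (%d)", n, nrow(pool))
  }
  idx <- with_seed(seed, sample.int(nrow(pool), n, prob = pool$weight))
  pool[idx, c("smiles", "chiral_capable"), drop = FALSE]
}

stereo_variant <- function(smiles) {
  sub("C\\(O\\)CC$", "[C@H](O)CC", smiles)
}

#' Synthetic-data configuration
#'
#' Defaults describe a mid-size curation scenario: 300 molecules, 6 assays
#' with Zipf(1.5) prevalence, on average 2 extra records per molecule,
#' assay biases of 0.3 pIC50 units, measurement noise of 0.2 pIC50 units,
#' latent potencies N(6.5, 1.2) (the realistic range of an IC50 assay
#' panel), and 5% stereo-ambiguous re-emissions.
#'
#' @param n_molecules number of base molecules.
#' @param n_assays number of assays (>= 1).
#' @param zipf_exponent assay prevalence decay; sampling probability of assay
#'   i is proportional to `i^-zipf_exponent`.
#' @param lambda_dup per-molecule extra records ~ Poisson(lambda_dup).
#' @param sigma_assay sd of per-assay additive biases (pIC50 units).
#' @param sigma_noise sd of per-record measurement noise (pIC50 units).
#' @param latent_mean,latent_sd latent potency law N(mean, sd).
#' @param latent_mode `"gaussian"` draws latent potencies directly;
#'   `"descriptor"` builds them as a seeded linear form over a random subset
#'   of core descriptors, rescaled to the same mean/sd, so that the latent
#'   signal is recoverable from structure.
#' @param stereo_dup_rate fraction of molecules re-emitted once with a
#'   stereo descriptor added (applied among stereo-capable molecules).
#' @param stereo_dup_offset latent-potency offset of the stereo re-emission
#'   (default 0: same underlying compound).
#' @param rare_assay_bias extra additive bias (pIC50 units) on the least
#'   prevalent assay; the generator's stress knob.
#' @param seed integer seed.
#' @return a `synthetic_config` object.
#' @export
synthetic_config <- function(n_molecules = 300, n_assays = 6,
                             zipf_exponent = 1.5, lambda_dup = 2,
                             sigma_assay = 0.3, sigma_noise = 0.2,
                             latent_mean = 6.5, latent_sd = 1.2,
                             latent_mode = c("gaussian", "descriptor"),
                             stereo_dup_rate = 0.05,
                             stereo_dup_offset = 0,
                             rare_assay_bias = 0, seed = 1L) {
  latent_mode <- match.arg(latent_mode)
  if (n_assays < 1) stopf("n_assays must be >= 1")
  if (sigma_assay < 0 || sigma_noise < 0 || latent_sd < 0 || lambda_dup < 0) {
    stopf("scales must be >= 0")
  }
  if (stereo_dup_rate < 0 || stereo_dup_rate > 1) {
    stopf("stereo_dup_rate must be in [0, 1]")
  }
  structure(list(n_molecules = n_molecules, n_assays = n_assays,
                 zipf_exponent = zipf_exponent, lambda_dup = lambda_dup,
                 sigma_assay = sigma_assay, sigma_noise = sigma_noise,
                 latent_mean = latent_mean, latent_sd = latent_sd,
                 latent_mode = latent_mode,
                 stereo_dup_rate = stereo_dup_rate,
                 stereo_dup_offset = stereo_dup_offset,
                 rare_assay_bias = rare_assay_bias,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic raw activity table with ground truth
#'
#' Every molecule receives `1 + Poisson(lambda_dup)` records; each record's
#' assay is drawn from the Zipf prevalence law; the observed potency is
#' `latent + assay bias + N(0, sigma_noise)` and is emitted as an IC50 value
#' in nM (inverting the pIC50 transform). A `stereo_dup_rate` fraction of
#' stereo-capable molecules is additionally emitted once more under a
#' stereo-annotated SMILES and a suffixed molecule id.
#'
#' @param config a [synthetic_config()].
#' @return list with `dataset` (a raw `curated_dataset`) and `truth`
#'   (list: `molecules` data.frame with latent potencies, `assays`
#'   data.frame with biases and sampling probabilities).
#' @export
generate_activity_table <- function(config = synthetic_config()) {
  mols <- generate_molecules(config$n_molecules, seed = config$seed)
  n <- nrow(mols)
  k <- config$n_assays
  out <- with_seed(config$seed + 1L, {
    prob <- (seq_len(k))^(-config$zipf_exponent)
    prob <- prob / sum(prob)
    assay_ids <- sprintf("ASSAY_%02d", seq_len(k))
    bias <- stats::rnorm(k, 0, config$sigma_assay)
    bias[k] <- bias[k] + config$rare_assay_bias

    latent <- switch(config$latent_mode,
      gaussian = stats::rnorm(n, config$latent_mean, config$latent_sd),
      descriptor = {
        x <- featurize(mols$smiles, "core")
        keep <- which(apply(x, 2, stats::sd) > 0)
        cols <- keep[sample.int(length(keep), min(8, length(keep)))]
        beta <- stats::rnorm(length(cols))
        raw <- as.numeric(scale(x[, cols, drop = FALSE]) %*% beta)
        config$latent_mean +
          config$latent_sd * (raw - mean(raw)) / stats::sd(raw)
      })

    ids <- sprintf("MOL_%04d", seq_len(n))
    n_rec <- 1L + stats::rpois(n, config$lambda_dup)

    emit <- function(id, smiles, lat, m) {
      a <- sample.int(k, m, replace = TRUE, prob = prob)
      observed <- lat + bias[a] + stats::rnorm(m, 0, config$sigma_noise)
      data.frame(molecule_id = id, smiles_raw = smiles,
                 standard_type = "IC50", value = 10^(9 - observed),
                 units = "nM", relation = "=", assay_id = assay_ids[a],
                 assay_description = paste("synthetic assay", assay_ids[a]),
                 source_id = "synthetic", stringsAsFactors = FALSE)
    }
    records <- vector("list", n)
    for (i in seq_len(n)) {
      records[[i]] <- emit(ids[i], mols$smiles[i], latent[i], n_rec[i])
    }

    capable <- which(mols$chiral_capable)
    n_dup <- round(config$stereo_dup_rate * n)
    dup_idx <- if (n_dup > 0 && length(capable) > 0) {
      capable[sample.int(length(capable), min(n_dup, length(capable)))]
    } else integer(0)
    dup_records <- lapply(dup_idx, function(i) {
      emit(paste0(ids[i], "_S"), stereo_variant(mols$smiles[i]),
           latent[i] + config$stereo_dup_offset, 1L)
    })

    dup_ids <- if (length(dup_idx)) paste0(ids[dup_idx], "_S")
               else character(0)
    truth_mols <- data.frame(
      molecule_id = c(ids, dup_ids),
      smiles_raw = c(mols$smiles, stereo_variant(mols$smiles[dup_idx])),
      latent = c(latent, latent[dup_idx] + config$stereo_dup_offset),
      stringsAsFactors = FALSE)
    list(records = do.call(rbind, c(records, dup_records)),
         truth = list(molecules = truth_mols,
                      assays = data.frame(assay_id = assay_ids, bias = bias,
                                          prob = prob,
                                          stringsAsFactors = FALSE)))
  })
  ds <- curated_dataset(out$records, stage = "raw")
  ds <- add_provenance(ds, "generate_activity_table",
                       list(seed = config$seed,
                            n_molecules = config$n_molecules),
                       n_in = nrow(out$records), n_out = nrow(out$records))
  list(dataset = ds, truth = out$truth)
}

#' Curated-label recovery experiment
#'
#' Quantifies how well each duplicate-resolution strategy recovers latent
#' potencies: for each replicate, generate a table, run standard cleaning and
#' MW filtering, apply each strategy, and measure the mean absolute deviation
#' of the curated labels from the latent truth (joined by molecule id).
#'
#' @param config a [synthetic_config()]; its seed is re-derived per replicate.
#' @param strategies subset of `"sc"`, `"random"`, `"average"`,
#'   `"global_max"`, `"most_recent"`.
#' @param n_reps number of replicates.
#' @param seed integer master seed.
#' @param clean_config a [cleaning_config()].
#' @return a `recovery_report`: `per_rep` (rep x strategy MAE), `summary`
#'   (per-strategy mean/median MAE), `wins` (pairwise strict-win counts,
#'   row strategy beats column strategy).
#' @export
evaluate_curation_recovery <- function(config = synthetic_config(),
                                       strategies = c("sc", "global_max"),
                                       n_reps = 20L, seed = 1L,
                                       clean_config = cleaning_config()) {
  valid <- c("sc", "random", "average", "global_max", "most_recent")
  if (!all(strategies %in% valid)) {
    stopf("strategies must be a subset of {%s}", paste(valid, collapse = ", "))
  }
  per_rep <- vector("list", n_reps)
  for (rep in seq_len(n_reps)) {
    rep_seed <- as.integer(seed) + 7919L * rep
    cfg <- config
    cfg$seed <- rep_seed
    gen <- generate_activity_table(cfg)
    truth <- gen$truth$molecules
    std <- standard_clean(gen$dataset, clean_config)$dataset
    flt <- filter_mw(std, clean_config)$dataset
    maes <- vapply(strategies, function(strat) {
      cur <- if (strat == "sc") selective_clean(flt)$dataset
             else naive_clean(flt, strat, seed = rep_seed)
      lat <- truth$latent[match(cur$records$molecule_id, truth$molecule_id)]
      mean(abs(cur$records$pic50 - lat))
    }, numeric(1))
    per_rep[[rep]] <- data.frame(rep = rep, strategy = strategies,
                                 mae = unname(maes),
                                 stringsAsFactors = FALSE)
  }
  per_rep <- do.call(rbind, per_rep)
  summary <- do.call(rbind, lapply(strategies, function(s) {
    m <- per_rep$mae[per_rep$strategy == s]
    data.frame(strategy = s, mean_mae = mean(m), median_mae = stats::median(m),
               stringsAsFactors = FALSE)
  }))
  wins <- matrix(0L, length(strategies), length(strategies),
                 dimnames = list(strategies, strategies))
  for (a in strategies) for (b in strategies) {
    if (a == b) next
    ma <- per_rep$mae[per_rep$strategy == a]
    mb <- per_rep$mae[per_rep$strategy == b]
    wins[a, b] <- sum(ma < mb)
  }
  structure(list(per_rep = per_rep, summary = summary, wins = wins,
                 n_reps = n_reps, seed = seed, config = config),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d replicate(s)\n", x$n_reps))
  print(x$summary, row.names = FALSE)
  cat("pairwise strict wins (row beats column):\n")
  print(x$wins)
  invisible(x)
}
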