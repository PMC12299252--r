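# Benchmark harness: 2D-descriptor featurization, k-fold cross-validated
# regression with a pluggable learner registry, standard regression metrics,
# and curation-strategy comparison. The harness deliberately ships only
# classical regressors; the point of a curation benchmark is to hold the
# learner fixed while the data treatment varies, and heavier learners can be
# plugged in through register_learner().

# ---- descriptor sets --------------------------------------------------------

# "core": a frozen, documented 2D descriptor panel (constitution, topology,
# electronic surrogates, ring and H-bond counts). Order is the vector order.
.descriptor_sets <- new.env(parent = emptyenv())

.core_descriptors <- c(
  "MolWt", "HeavyAtomMolWt", "ExactMolWt", "NumValenceElectrons",
  "FractionCSP3", "TPSA", "MolLogP", "MolMR", "LabuteASA",
  "HeavyAtomCount", "NumHAcceptors", "NumHDonors", "NumHeteroatoms",
  "NumRotatableBonds", "NHOHCount", "NOCount", "RingCount",
  "NumAromaticRings", "NumSaturatedRings", "NumAliphaticRings",
  "NumAromaticHeterocycles", "NumAromaticCarbocycles",
  "NumSaturatedHeterocycles", "NumSaturatedCarbocycles",
  "NumAliphaticHeterocycles", "NumAliphaticCarbocycles",
  "BalabanJ", "BertzCT", "HallKierAlpha",
  "Chi0", "Chi0n", "Chi0v", "Chi1", "Chi1n", "Chi1v",
  "Chi2n", "Chi2v", "Chi3n", "Chi3v", "Chi4n", "Chi4v",
  "Kappa1", "Kappa2", "Kappa3",
  "MaxPartialCharge", "MinPartialCharge", "MaxAbsPartialCharge",
  "MinAbsPartialCharge", "qed",
  "SlogP_VSA1", "SlogP_VSA2", "SlogP_VSA3", "SlogP_VSA4", "SlogP_VSA5",
  "SMR_VSA1", "SMR_VSA5", "SMR_VSA10",
  "PEOE_VSA1", "PEOE_VSA2", "PEOE_VSA6",
  "fr_halogen", "fr_benzene", "fr_amide", "fr_ether"
)

#' Names of a registered descriptor set
#'
#' Two sets ship with the package: `"core"`, a frozen 64-descriptor 2D panel
#' (the default everywhere), and `"full"`, every 2D descriptor the chemistry
#' backend exposes (resolved once per session, order alphabetical).
#'
#' @param descriptor_set set name.
#' @return character vector of descriptor names, in vector order.
#' @export
descriptor_set_names <- function(descriptor_set = "core") {
  if (descriptor_set == "core") return(.core_descriptors)
  if (descriptor_set == "full") {
    if (is.null(.descriptor_sets$full)) {
      res <- chem_call("descriptor_names", character(0))
      .descriptor_sets$full <- unlist(res[[1]]$names)
    }
    return(.descriptor_sets$full)
  }
  custom <- .descriptor_sets[[descriptor_set]]
  if (is.null(custom)) stopf("unknown descriptor set '%s'", descriptor_set)
  custom
}

#' Featurize molecules with 2D descriptors
#'
#' Computes a fixed-length numeric vector per molecule with a stable,
#' documented ordering (that of [descriptor_set_names()]). Descriptors are
#' graph-based, so two SMILES spellings of one molecule yield identical
#' vectors. Non-finite values are imputed to 0 and reported via a message.
#'
#' @param smiles character vector of valid SMILES.
#' @param descriptor_set descriptor set name (default `"core"`).
#' @return numeric matrix, one row per molecule, descriptor names as columns.
#' @export
featurize <- function(smiles, descriptor_set = "core") {
  names <- descriptor_set_names(descriptor_set)
  mat <- chem_descriptors(as.character(smiles), names)
  bad <- !is.finite(mat)
  if (any(bad)) {
    message(sprintf("featurize: imputed %d non-finite descriptor value(s) to 0",
                    sum(bad)))
    mat[bad] <- 0
  }
  mat
}

# ---- metrics ---------------------------------------------------------------

#' Regression metrics: RMSE, MAE and R-squared
#'
#' @param y observed values (length >= 2).
#' @param yhat predictions, same length.
#' @return list with `rmse`, `mae`, `r2`. `r2` is `NA` (with a warning) when
#'   `y` has zero variance.
#' @export
metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stopf("y and yhat lengths differ")
  if (length(y) < 2) stopf("metrics require at least 2 observations")
  resid <- y - yhat
  rmse <- sqrt(mean(resid^2))
  mae <- mean(abs(resid))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("r2 undefined: y has zero variance", call. = FALSE)
    r2 <- NA_real_
  } else {
    r2 <- 1 - sum(resid^2) / ss_tot
  }
  list(rmse = rmse, mae = mae, r2 = r2)
}

#' Fraction of predictions within a potency band
#'
#' @param y observed values.
#' @param yhat predictions.
#' @param band half-width of the acceptance band in pIC50 units
#'   (default 0.5).
#' @return list with `fraction_within_band` and the parity `pairs`
#'   data.frame.
#' @export
parity_summary <- function(y, yhat, band = 0.5) {
  if (length(y) != length(yhat)) stopf("y and yhat lengths differ")
  within <- abs(y - yhat) <= band
  list(fraction_within_band = if (length(y) == 0) NA_real_ else mean(within),
       pairs = data.frame(y = y, yhat = yhat, within_band = within))
}

#' Percent improvement between two RMSE values
#'
#' `100 * (rmse_baseline - rmse_final) / rmse_baseline`: the headline figure
#' of a curation-strategy comparison.
#'
#' @param rmse_baseline baseline RMSE (> 0).
#' @param rmse_final RMSE after the treatment under study.
#' @return percent improvement (positive = final is better).
#' @export
pct_improvement <- function(rmse_baseline, rmse_final) {
  if (any(rmse_baseline == 0)) {
    stopf("percent improvement undefined: baseline rmse is 0")
  }
  100 * (rmse_baseline - rmse_final) / rmse_baseline
}

# ---- learner registry ------------------------------------------------------

.learners <- new.env(parent = emptyenv())

#' Register a regression learner
#'
#' The adapter seam for external models. `fit(x, y, hyper, seed)` must return
#' an opaque model object; `predict(model, x)` a numeric vector. Learners
#' must route any stochasticity through `seed`.
#'
#' @param name learner name.
#' @param fit,predict functions as described above.
#' @return invisibly, `name`.
#' @export
register_learner <- function(name, fit, predict) {
  .learners[[name]] <- list(fit = fit, predict = predict)
  invisible(name)
}

#' Names of registered learners
#' @return character vector.
#' @export
learner_names <- function() sort(ls(.learners))

get_learner <- function(name) {
  l <- .learners[[name]]
  if (is.null(l)) {
    stopf("unknown learner '%s' (registered: %s)", name,
          paste(learner_names(), collapse = ", "))
  }
  l
}

#' Model specification for the benchmark harness
#'
#' @param learner registered learner name (see [learner_names()]).
#' @param hyper named list of hyperparameters understood by the learner.
#' @param seed integer seed consumed by the learner's stochastic parts.
#' @return a `model_spec` object.
#' @export
model_spec <- function(learner = "ridge", hyper = list(), seed = 1L) {
  get_learner(learner)
  structure(list(learner = learner, hyper = hyper, seed = as.integer(seed)),
            class = "model_spec")
}

register_builtin_learners <- function() {
  # Ordinary least squares via QR; rank-deficient coefficients drop to 0.
  register_learner("lm",
    fit = function(x, y, hyper, seed) {
      xm <- cbind(1, x)
      fit <- stats::lm.fit(xm, y)
      coefs <- fit$coefficients
      coefs[is.na(coefs)] <- 0
      list(coefs = coefs)
    },
    predict = function(model, x) as.numeric(cbind(1, x) %*% model$coefs))

  glmnet_learner <- function(alpha) {
    list(
      fit = function(x, y, hyper, seed) {
        lambda <- hyper$lambda
        if (is.null(lambda)) {
          # deterministic fold ids derived from the spec seed
          foldid <- with_seed(seed,
                              sample(rep_len(1:5, length(y))))
          # extend the path downwards: glmnet's default ridge path stops at
          # lambdas far too large for low-noise targets
          cv <- glmnet::cv.glmnet(x, y, alpha = alpha, foldid = foldid,
                                  nlambda = 150, lambda.min.ratio = 1e-8)
          lambda <- cv$lambda.min
        }
        glmnet::glmnet(x, y, alpha = alpha, lambda = lambda)
      },
      predict = function(model, x) as.numeric(stats::predict(model, newx = x))
    )
  }
  rl <- glmnet_learner(0)
  register_learner("ridge", rl$fit, rl$predict)
  ll <- glmnet_learner(1)
  register_learner("lasso", ll$fit, ll$predict)

  register_learner("mean",
    fit = function(x, y, hyper, seed) list(mu = mean(y)),
    predict = function(model, x) rep(model$mu, nrow(x)))
}

# ---- cross-validation ------------------------------------------------------

#' k-fold cross-validated benchmark of a curated dataset
#'
#' Featurizes `smiles_std`, partitions molecules into `k` seeded folds (fold
#' assignment is by molecule, never by record), holds each fold out once and
#' reports per-fold and mean RMSE/MAE/R2 plus the pooled parity pairs.
#'
#' @param dataset one-record-per-molecule `curated_dataset` with `pic50` set.
#' @param spec a [model_spec()].
#' @param k number of folds (>= 2, <= dataset size).
#' @param seed integer seed for the fold partition.
#' @param descriptor_set descriptor set name passed to [featurize()].
#' @return a `bench_result` with `folds`, `aggregate`, `k`, `parity`.
#' @export
cross_validate <- function(dataset, spec = model_spec(), k = 5L, seed = 1L,
                           descriptor_set = "core") {
  rec <- if (inherits(dataset, "curated_dataset")) dataset$records
         else as.data.frame(dataset)
  n <- nrow(rec)
  if (k < 2) stopf("k must be >= 2")
  if (n < k) stopf("dataset size %d smaller than k=%d", n, k)
  if (anyNA(rec$pic50)) stopf("cross_validate requires pic50 on every record")
  if (anyDuplicated(rec$smiles_std)) {
    stopf("cross_validate requires one record per molecule")
  }
  x <- featurize(rec$smiles_std, descriptor_set)
  y <- rec$pic50
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  learner <- get_learner(spec$learner)

  fold_metrics <- vector("list", k)
  parity <- vector("list", k)
  for (fold in seq_len(k)) {
    hold <- folds == fold
    model <- learner$fit(x[!hold, , drop = FALSE], y[!hold], spec$hyper,
                         spec$seed)
    yhat <- learner$predict(model, x[hold, , drop = FALSE])
    m <- metrics(y[hold], yhat)
    fold_metrics[[fold]] <- data.frame(fold = fold, rmse = m$rmse,
                                       mae = m$mae, r2 = m$r2)
    parity[[fold]] <- data.frame(fold = fold, y = y[hold], yhat = yhat)
  }
  folds_df <- do.call(rbind, fold_metrics)
  aggregate <- list(rmse = mean(folds_df$rmse), mae = mean(folds_df$mae),
                    r2 = mean(folds_df$r2))
  structure(list(folds = folds_df, aggregate = aggregate, k = k,
                 seed = seed, spec = spec,
                 parity = do.call(rbind, parity)),
            class = "bench_result")
}

#' @export
print.bench_result <- function(x, ...) {
  cat(sprintf("<bench_result> learner '%s', %d-fold CV: RMSE %.4f, MAE %.4f, R2 %.4f\n",
              x$spec$learner, x$k, x$aggregate$rmse, x$aggregate$mae,
              x$aggregate$r2))
  invisible(x)
}

#' Compare curation strategies through a fixed learner
#'
#' Cross-validates each labelled dataset with one model specification and
#' reports per-strategy record counts and metrics plus the percent RMSE
#' improvement of `final` over `baseline`.
#'
#' @param datasets named list of one-record-per-molecule `curated_dataset`s.
#' @param spec a [model_spec()] applied to every dataset.
#' @param k,seed,descriptor_set passed to [cross_validate()].
#' @param baseline,final labels (names of `datasets`) entering the percent
#'   improvement.
#' @return a `curation_comparison` with `table` and `pct_improvement`.
#' @export
compare_strategies <- function(datasets, spec = model_spec(), k = 5L,
                               seed = 1L, baseline, final,
                               descriptor_set = "core") {
  if (length(datasets) < 2 || is.null(names(datasets))) {
    stopf("compare_strategies needs >= 2 named datasets")
  }
  for (lbl in c(baseline, final)) {
    if (!lbl %in% names(datasets)) stopf("label '%s' not in datasets", lbl)
  }
  rows <- lapply(names(datasets), function(lbl) {
    res <- cross_validate(datasets[[lbl]], spec, k, seed, descriptor_set)
    data.frame(strategy = lbl, n_records = n_records(datasets[[lbl]]),
               rmse = res$aggregate$rmse, r2 = res$aggregate$r2,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rmse_b <- tab$rmse[tab$strategy == baseline]
  rmse_f <- tab$rmse[tab$strategy == final]
  structure(list(table = tab,
                 baseline = baseline, final = final,
                 pct_improvement = pct_improvement(rmse_b, rmse_f)),
            class = "curation_comparison")
}

#' @export
print.curation_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("RMSE improvement (%s -> %s): %.1f%%\n", x$baseline, x$final,
              x$pct_improvement))
  invisible(x)
}
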