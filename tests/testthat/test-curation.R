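test_that("standardize_smiles canonicalizes, strips salts, rejects garbage", {
  # kekulized and aromatic spellings of one molecule converge
  expect_equal(standardize_smiles(SMILES_BENZENE_KEKULE),
               standardize_smiles(SMILES_BENZENE))
  # a two-fragment salt reduces to a single parent fragment
  parent <- standardize_smiles(SMILES_SODIUM_ACETATE)
  expect_false(grepl(".", parent, fixed = TRUE))
  expect_equal(parent, standardize_smiles("CC(=O)O"))  # and is neutralized
  # unparsable input is a rejection, not an error
  expect_true(is.na(standardize_smiles("not_a_smiles")))
  # idempotence: re-standardization is the identity
  std <- standardize_smiles(SMILES_ATORVASTATIN)
  expect_equal(standardize_smiles(std), std)
  # stereo handling
  expect_true(grepl("@", standardize_smiles(SMILES_ATORVASTATIN,
                                            "as_given")))
  expect_false(grepl("@", standardize_smiles(SMILES_ATORVASTATIN,
                                             "collapse")))
})

test_that("to_pic50 converts units and rejects censored/invalid input", {
  expect_equal(to_pic50(1, "nM"), 9.0)
  expect_equal(to_pic50(1, "uM"), 6.0)
  expect_equal(to_pic50(1, "µM"), 6.0)
  # -log10(57e-9) computed independently: 7.2441
  expect_equal(round(to_pic50(57, "nM"), 4), 7.2441)
  expect_true(is.na(to_pic50(100, "nM", ">")))
  expect_true(is.na(to_pic50(-5, "nM")))
  expect_true(is.na(to_pic50(0, "nM")))
  expect_true(is.na(to_pic50(10, "furlongs")))
  # censored records survive when drop_censored is off
  cfg <- cleaning_config(drop_censored = FALSE)
  expect_equal(to_pic50(1, "nM", ">", cfg), 9.0)
})

test_that("to_pic50 is unit-invariant and strictly decreasing", {
  withr::with_seed(7, {
    x <- runif(50, 0.01, 5000)
    expect_equal(to_pic50(x, "uM"), to_pic50(1000 * x, "nM"),
                 tolerance = 1e-12)
    expect_equal(to_pic50(x, "M"), to_pic50(1e9 * x, "nM"),
                 tolerance = 1e-12)
    ord <- order(x)
    expect_true(all(diff(to_pic50(x[ord], "nM")) < 0))
  })
})

raw_fixture <- function() {
  make_dataset(
    molecule_id = sprintf("M%d", 1:8),
    smiles_raw = c("CCO", "CCO", "CCN", "bad_smiles", "CCC", "CCCl",
                   "CCO", "CCBr"),
    standard_type = c("IC50", "IC50", "IC50", "IC50", "Ki", "IC50",
                      "IC50", "IC50"),
    value = c(100, 100, NA, 50, 20, 30, 200, 40),
    units = c("nM", "nM", "nM", "nM", "nM", "nM", "nM", "nM"),
    relation = c("=", "=", "=", "=", "=", ">", "=", "="),
    assay_id = c("A", "A", "A", "A", "A", "A", "B", "B"),
    stage = "raw"
  )
}

test_that("standard_clean removes, converts and counts correctly", {
  res <- standard_clean(raw_fixture())
  rep <- res$report
  # M1/M2 identical -> one exact duplicate removed; M3 null value; M4 invalid
  # SMILES; M5 disallowed type; M6 censored
  expect_equal(unname(rep$counts["exact duplicate"]), 1L)
  expect_equal(unname(rep$counts["null value"]), 1L)
  expect_equal(unname(rep$counts["invalid SMILES"]), 1L)
  expect_equal(unname(rep$counts["disallowed type"]), 1L)
  expect_equal(unname(rep$counts["censored relation"]), 1L)
  expect_equal(rep$records_in, 8)
  expect_equal(rep$records_out, 3)
  expect_equal(rep$records_in - rep$records_out, sum(rep$counts))
  ds <- res$dataset
  expect_equal(ds$stage, "standard_cleaned")
  expect_false(anyNA(ds$records$smiles_std))
  expect_false(anyNA(ds$records$pic50))
  # CCO in assay A at 100 nM and in assay B at 200 nM: cross-assay/value
  # duplicates are retained for SC
  expect_equal(sum(ds$records$smiles_std == standardize_smiles("CCO")), 2)
})

test_that("cross-assay duplicates with distinct values all survive", {
  ds <- make_dataset(
    molecule_id = "M1", smiles_raw = "CCO", standard_type = "IC50",
    value = c(10, 20, 30), units = "nM", relation = "=",
    assay_id = c("A", "A", "B"), stage = "raw")
  res <- standard_clean(ds)
  expect_equal(n_records(res$dataset), 3)
})

test_that("standard_clean is idempotent and balances on random fixtures", {
  withr::with_seed(11, {
    for (i in 1:5) {
      n <- sample(5:25, 1)
      ds <- make_dataset(
        molecule_id = sprintf("M%d", seq_len(n)),
        smiles_raw = sample(c("CCO", "CCN", "bad", "c1ccccc1", NA), n,
                            replace = TRUE),
        standard_type = sample(c("IC50", "Ki"), n, replace = TRUE,
                               prob = c(0.8, 0.2)),
        value = ifelse(runif(n) < 0.15, NA, round(runif(n, 1, 1000), 1)),
        units = sample(c("nM", "uM", "parsec"), n, replace = TRUE,
                       prob = c(0.6, 0.3, 0.1)),
        relation = sample(c("=", ">", "<"), n, replace = TRUE,
                          prob = c(0.8, 0.1, 0.1)),
        assay_id = sample(c("A", "B"), n, replace = TRUE),
        stage = "raw")
      res <- standard_clean(ds)
      expect_equal(res$report$records_in - res$report$records_out,
                   sum(res$report$counts))
      again <- standard_clean(res$dataset)
      expect_equal(again$dataset$records, res$dataset$records)
      expect_equal(sum(again$report$counts), 0L)
    }
  })
})

test_that("filter_mw applies strict bounds on the standardized parent", {
  ds <- make_dataset(
    molecule_id = c("benzene", "atorvastatin"),
    smiles_raw = c(SMILES_BENZENE, SMILES_ATORVASTATIN),
    smiles_std = c(standardize_smiles(SMILES_BENZENE),
                   standardize_smiles(SMILES_ATORVASTATIN)),
    pic50 = c(5, 7), stage = "standard_cleaned")
  res <- filter_mw(ds)
  # benzene (MW ~78, below 100) removed; atorvastatin (~558) retained
  expect_equal(res$dataset$records$molecule_id, "atorvastatin")
  expect_equal(unname(res$report$counts["out-of-range MW"]), 1L)

  # strictness: a bound equal to the molecule's own MW excludes it
  mw_benzene <- screenclean:::chem_mw(standardize_smiles(SMILES_BENZENE))
  cfg <- cleaning_config(mw_low = mw_benzene, mw_high = 750)
  res2 <- filter_mw(ds, cfg)
  expect_false("benzene" %in% res2$dataset$records$molecule_id)
  cfg3 <- cleaning_config(mw_low = mw_benzene - 1e-9, mw_high = 750)
  res3 <- filter_mw(ds, cfg3)
  expect_true("benzene" %in% res3$dataset$records$molecule_id)

  # idempotence
  again <- filter_mw(res$dataset)
  expect_equal(again$dataset$records, res$dataset$records)
})

test_that("provenance chains through the pipeline stages", {
  gen <- generate_activity_table(synthetic_config(n_molecules = 20, seed = 5))
  std <- standard_clean(gen$dataset)$dataset
  flt <- filter_mw(std)$dataset
  sc <- selective_clean(flt)$dataset
  steps <- vapply(sc$provenance, `[[`, character(1), "step")
  expect_equal(steps, c("generate_activity_table", "standard_clean",
                        "filter_mw", "selective_clean"))
  for (i in seq_along(sc$provenance)[-1]) {
    expect_equal(sc$provenance[[i]]$n_in, sc$provenance[[i - 1]]$n_out)
  }
  expect_error(screenclean:::set_stage(sc, "raw"), "backwards")
})
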