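test_that("generate_molecules yields distinct, standardizable SMILES", {
  mols <- generate_molecules(10, seed = 101)
  expect_equal(nrow(mols), 10)
  expect_false(anyDuplicated(mols$smiles) > 0)
  std <- standardize_smiles(mols$smiles)
  expect_false(anyNA(std))
  # determinism
  expect_equal(generate_molecules(10, seed = 101), mols)
  expect_false(identical(generate_molecules(10, seed = 102)$smiles,
                         mols$smiles))
  expect_error(generate_molecules(0), ">= 1")
})

test_that("a 200-molecule draw spans both MW filter boundaries", {
  mols <- generate_molecules(200, seed = 103)
  mw <- screenclean:::chem_standardize(mols$smiles)$mw
  expect_true(any(mw < 100))
  expect_true(any(mw > 750))
})

test_that("generate_activity_table obeys the duplication law", {
  cfg <- synthetic_config(n_molecules = 40, lambda_dup = 0,
                          stereo_dup_rate = 0, seed = 107)
  gen <- generate_activity_table(cfg)
  # lambda = 0, no stereo dups: exactly one record per molecule
  expect_equal(n_records(gen$dataset), 40)
  expect_equal(sort(unique(gen$dataset$records$molecule_id)),
               sort(gen$truth$molecules$molecule_id))

  cfg2 <- synthetic_config(n_molecules = 40, lambda_dup = 0,
                           stereo_dup_rate = 0.5, seed = 107)
  gen2 <- generate_activity_table(cfg2)
  n_stereo <- sum(grepl("_S$", gen2$dataset$records$molecule_id))
  expect_gt(n_stereo, 0)
  expect_equal(n_records(gen2$dataset), 40 + n_stereo)
  # stereo re-emissions carry a stereo descriptor and share the latent value
  s_ids <- grep("_S$", gen2$truth$molecules$molecule_id, value = TRUE)
  for (sid in s_ids) {
    base <- sub("_S$", "", sid)
    tm <- gen2$truth$molecules
    expect_equal(tm$latent[tm$molecule_id == sid],
                 tm$latent[tm$molecule_id == base])
    expect_true(grepl("@", tm$smiles_raw[tm$molecule_id == sid]))
  }
})

test_that("noiseless generation round-trips pIC50 through the IC50 encoding", {
  cfg <- synthetic_config(n_molecules = 30, sigma_assay = 0, sigma_noise = 0,
                          seed = 109)
  gen <- generate_activity_table(cfg)
  rec <- gen$dataset$records
  lat <- gen$truth$molecules$latent[
    match(rec$molecule_id, gen$truth$molecules$molecule_id)]
  expect_equal(to_pic50(rec$value, rec$units, rec$relation), lat,
               tolerance = 1e-9)
})

test_that("pIC50 recovery holds with assay bias and noise switched on", {
  cfg <- synthetic_config(n_molecules = 25, seed = 127)
  gen <- generate_activity_table(cfg)
  rec <- gen$dataset$records
  # recomputed pIC50 = latent + assay bias + record noise; with sd capped by
  # sqrt(sigma_assay^2 + sigma_noise^2) the deviation stays bounded
  lat <- gen$truth$molecules$latent[
    match(rec$molecule_id, gen$truth$molecules$molecule_id)]
  pic <- to_pic50(rec$value, rec$units, rec$relation)
  bias <- gen$truth$assays$bias[
    match(rec$assay_id, gen$truth$assays$assay_id)]
  resid <- pic - lat - bias
  expect_equal(sd(resid), cfg$sigma_noise, tolerance = 0.5)
  expect_lt(max(abs(resid)), 5 * cfg$sigma_noise)
})

test_that("Zipf prevalence orders the top assay counts", {
  cfg <- synthetic_config(n_molecules = 300, n_assays = 6,
                          zipf_exponent = 1.5, lambda_dup = 2, seed = 113)
  gen <- generate_activity_table(cfg)
  counts <- sort(table(gen$dataset$records$assay_id), decreasing = TRUE)
  top3 <- as.integer(counts[match(c("ASSAY_01", "ASSAY_02", "ASSAY_03"),
                                  names(counts))])
  expect_true(all(diff(top3) < 0))  # strictly ordered
  # determinism of the full table
  gen2 <- generate_activity_table(cfg)
  expect_equal(gen2$dataset$records, gen$dataset$records)
  expect_equal(gen2$truth, gen$truth)
})

test_that("descriptor latent mode produces a structure-linked, scaled target", {
  cfg <- synthetic_config(n_molecules = 60, latent_mode = "descriptor",
                          seed = 131)
  gen <- generate_activity_table(cfg)
  lat <- gen$truth$molecules$latent[!grepl("_S$",
                                           gen$truth$molecules$molecule_id)]
  expect_equal(mean(lat), cfg$latent_mean, tolerance = 1e-6)
  expect_equal(sd(lat), cfg$latent_sd, tolerance = 1e-6)
})

test_that("noiseless recovery is exact for every strategy", {
  cfg <- synthetic_config(n_molecules = 30, sigma_assay = 0, sigma_noise = 0,
                          stereo_dup_rate = 0)
  rep <- evaluate_curation_recovery(cfg,
                                    strategies = c("sc", "random", "average",
                                                   "global_max",
                                                   "most_recent"),
                                    n_reps = 2, seed = 3)
  expect_equal(rep$summary$mean_mae, rep(0, 5), tolerance = 1e-9)
})

test_that("recovery reports are deterministic given the seed", {
  cfg <- synthetic_config(n_molecules = 40)
  r1 <- evaluate_curation_recovery(cfg, c("sc", "global_max"), n_reps = 1,
                                   seed = 9)
  r2 <- evaluate_curation_recovery(cfg, c("sc", "global_max"), n_reps = 1,
                                   seed = 9)
  expect_equal(r1$per_rep, r2$per_rep)
  expect_equal(r1$wins, r2$wins)
})

test_that("without assay bias, SC and global_max deviate similarly", {
  cfg <- synthetic_config(n_molecules = 500, sigma_assay = 0,
                          sigma_noise = 0.1, stereo_dup_rate = 0)
  rep <- evaluate_curation_recovery(cfg, c("sc", "global_max"), n_reps = 1,
                                    seed = 17)
  m <- rep$summary$mean_mae
  expect_lt(abs(m[1] - m[2]), 0.05)
})

test_that("rare-assay bias makes SC beat the global maximum", {
  cfg <- synthetic_config(n_molecules = 100, rare_assay_bias = 1.5)
  rep <- evaluate_curation_recovery(cfg, c("sc", "global_max"), n_reps = 5,
                                    seed = 21)
  expect_gte(rep$wins["sc", "global_max"], 4)
  expect_lt(rep$summary$mean_mae[rep$summary$strategy == "sc"],
            rep$summary$mean_mae[rep$summary$strategy == "global_max"])
})

test_that("synthetic_config validates its domain", {
  expect_error(synthetic_config(n_assays = 0), "n_assays")
  expect_error(synthetic_config(sigma_noise = -1), "scales")
  expect_error(synthetic_config(stereo_dup_rate = 1.5), "stereo_dup_rate")
  expect_error(evaluate_curation_recovery(strategies = "sc_plus"), "subset")
})
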