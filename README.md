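# screenclean

Curation of multi-assay bioactivity data for QSAR modelling, and triage of
virtual-screening output — with the **selective cleaning (SC)** algorithm for
assay-aware duplicate resolution at its core.

## The problem

Public bioactivity extracts (ChEMBL-style activity tables) routinely contain
several IC50 entries for one molecule: different assay procedures report
different values, and stereo-ambiguous registrations duplicate compounds
outright. A QSAR model needs one label per molecule. The common fixes —
take the average, the most recent entry, or the global maximum pIC50 — all
ignore *where* each value came from. In particular, "take the maximum" is
biased upward whenever the maximum happens to come from a rarely used assay
whose systematics run hot.

**Selective cleaning** resolves each molecule's duplicates with a two-layer
rule:

1. restrict the candidates to the molecule's **most globally prevalent
   assay** — the assay contributing the most records to the whole dataset;
2. keep the **maximum pIC50** within that assay.

With pIC50 = −log10(IC50 in mol/L), the curated label for molecule *m* is

```
label(m) = max { pIC50(r) : r in records(m), assay(r) = argmax_a count(a) }
```

where `count(a)` is the global record count of assay `a` over the dataset
(prevalence ties break by assay id, value ties by input order).

The package implements the full pipeline around that rule:

| stage | function(s) |
|---|---|
| I/O with explicit column maps (ChEMBL dialect built in) | `read_activity_table()`, `write_activity_table()` |
| standard cleaning: SMILES standardization, pIC50 normalization, null/exact-duplicate handling | `standard_clean()`, `standardize_smiles()`, `to_pic50()` |
| molecular-weight filter (100 < MW < 750, strict) | `filter_mw()` |
| selective cleaning + naive baselines | `selective_clean()`, `naive_clean()`, `compute_assay_prevalence()` |
| Bemis–Murcko scaffold / random splits | `scaffold_split()`, `random_split()`, `murcko_scaffold()` |
| descriptor featurization + k-fold CV benchmark | `featurize()`, `cross_validate()`, `compare_strategies()`, `metrics()` |
| hit triage: potency/affinity region gate + structural rules | `region_gate()`, `structural_filter()`, `triage()` |
| post-docking: consensus ranks, pocket selectivity, interaction grades | `consensus_rank()`, `selectivity_delta()`, `classify_interaction()`, `build_profile()` |
| synthetic multi-assay data with known truth | `generate_activity_table()`, `evaluate_curation_recovery()` |

Chemistry primitives (standardization, molecular weight, scaffolds, 2D
descriptors, substructure features) are computed by a bundled RDKit helper
invoked through the system Python (`SystemRequirements`), batched and
memoized so repeated pipeline runs are cheap.

## Worked example

```r
library(screenclean)

# a synthetic 300-molecule extract in which the least prevalent assay runs
# +1.5 pIC50 units hot -- the setting that defeats "take the maximum"
cfg <- synthetic_config(n_molecules = 300, rare_assay_bias = 1.5,
                        sigma_noise = 0.2, seed = 42)
gen <- generate_activity_table(cfg)
std <- standard_clean(gen$dataset)$dataset
flt <- filter_mw(std)$dataset
sc  <- selective_clean(flt)

print(sc$dataset)
#> <curated_dataset> 296 records, stage 'sc_cleaned', 4 pipeline step(s)

rep <- evaluate_curation_recovery(cfg, c("sc", "global_max"),
                                  n_reps = 20, seed = 42)
print(rep)
#> <recovery_report> 20 replicate(s)
#>    strategy  mean_mae median_mae
#>          sc 0.2963731  0.2451412
#>  global_max 0.4419929  0.4250659
#> pairwise strict wins (row beats column):
#>            sc global_max
#> sc          0         19
#> global_max  1          0
```

The 300 generated molecules curate down to 296 one-record-per-molecule
entries (the MW filter trims the tails, stereo re-emissions add distinct
keys). The mean absolute deviation of the curated labels from the latent
truth is ~0.30 pIC50 units under selective cleaning versus ~0.44 under the
global-maximum strategy, and SC wins 19 of 20 replicates: restricting to
the prevalent assay removes exactly the rare-assay outliers that the
maximum otherwise latches onto.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "screenclean", package="screenclean"))')
$CLI convert --in chembl_export.csv --colmap chembl --out raw.csv
$CLI clean   --in raw.csv --out std.csv --report clean.json
$CLI filter  --in std.csv --mw-low 100 --mw-high 750 --out filt.csv
$CLI scclean --in filt.csv --out sc.csv --report sc.json
$CLI split   --in sc.csv --mode scaffold --fractions 0.9,0,0.1 --seed 7 --out splits.json
```

See `vignettes/curation-methods.Rmd` for the model, its assumptions, every
tunable default, and known limitations.
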