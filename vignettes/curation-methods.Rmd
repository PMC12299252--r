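---
title: "Assay-aware bioactivity curation: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assay-aware bioactivity curation: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(screenclean)
```

This vignette is the package's own account of its methods: the curation
model and its assumptions, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the places where the design was genuinely open and a
choice had to be made. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The curation model

A record is one bioactivity measurement: a molecule (SMILES), a measurement
type (IC50 by default), a value with concentration units and a relation, an
assay identifier, and provenance fields. The pipeline is a fixed forward
sequence of dataset stages:

```
raw -> standard_cleaned -> filtered -> sc_cleaned
```

each step appending to a provenance log whose record counts must chain
(`records out` of step *k* equals `records in` of step *k*+1). Stages only
move forward; this is enforced, not advisory.

**Standard cleaning** removes what cannot carry a point potency: null or
unparseable values, unparsable SMILES, disallowed measurement types,
censored relations (`>`, `<`, `>=`, `<=` — an inequality is not a point
potency; configurable via `drop_censored`), unsupported units, and
non-positive concentrations (the logarithm is undefined there, so rejection
precedes the transform). Surviving structures are standardized — largest
organic fragment, charge neutralization where possible, canonical form —
and converted to pIC50 = −log10(IC50 in mol/L). Only *exact* duplicates
(identical parent SMILES, assay and pIC50) are collapsed at this stage.
Conflicting duplicates are deliberately retained: which of them represents
the molecule is a scientific decision owned by the next stage, and a
benchmarked record count that does not change under selective cleaning is
the observable consequence of that split.

**Molecular-weight filtering** keeps `100 < MW < 750` (Da, average mass of
the standardized parent, bounds strict). The window excludes fragments too
small to be drug-like and structures too bulky for the binding sites of
interest. Strictness at the boundary follows the printed inequality signs
of the convention we adopt; it matters only on a set of measure zero, but
tests pin it down so it cannot drift.

**Selective cleaning (SC)** resolves each molecule's remaining duplicates
with a two-layer rule: restrict to the molecule's most *globally* prevalent
assay, then keep the maximum pIC50 within it. The statistical argument: the
maximum over all records is upward-biased whenever a rare assay runs hot,
because a single biased draw becomes the label. Conditioning on the most
prevalent assay first keeps the "best capability" reading of the maximum
while sampling it from the best-characterized measurement context.

Implementation note: `selective_clean()` is a stable sort by (assay
prevalence rank ascending, pIC50 descending, input row) followed by taking
the first occurrence per molecule key; `sc_oracle()` re-derives the same
choice by plain enumeration, without sorting machinery, and the test suite
requires the two to agree on every molecule of 200 random tables.

### Declared tie rules

The data cannot decide ties, so the package does, deterministically:

* equal assay prevalence — assay id ascending;
* equal pIC50 within the chosen assay — earliest input row;
* recency for the `most_recent` baseline — input row order (public
  extracts rarely carry usable timestamps).

### Molecule identity and stereochemistry

The molecule key is the standardized parent SMILES under the active
`stereo_mode`. The default `as_given` treats SMILES differing in stereo
descriptors as different molecules — a conservative reading, since
unspecified stereo in a registry genuinely may denote a different substance.
`collapse` strips stereo before keying, merging enantiomeric duplicates.
Both are exposed because stereo-ambiguous duplication is one of the two
duplicate sources the curation model addresses; neither choice is "correct"
in general.

## 2. Parameters with units, defaults and rationale

| parameter | default | units | why |
|---|---|---|---|
| `mw_low`, `mw_high` | 100, 750 (strict) | Da | drug-likeness window; see above |
| `allowed_types` | `"IC50"` | — | mixing Ki/EC50 with IC50 conflates different observables; widen deliberately |
| `drop_censored` | `TRUE` | — | inequalities are bounds, not values |
| `stereo_mode` | `"as_given"` | — | conservative identity; see above |
| `pic50_low/high` (triage) | 6.0, 10.0, inclusive | pIC50 | sub-micromolar potency floor; values above 10 are implausible predictions |
| `affinity_low/high` (triage) | −9.0, −6.0, inclusive | kcal/mol | docking "sweet spot"; far more negative values usually flag artifacts |
| aromatic rings (triage) | 2–4 | count | enough aromatic surface for a hydrophobic cleft, not a PAH |
| `max_rotatable_bonds` | 10 | count | stand-in for a "constrained spatial arrangement" requirement that has no canonical numeric form; flagged as such |
| `peptide_amide_min` | 3 | amide bonds | three backbone amides ≈ tetrapeptide; smaller amide counts are common in drugs |
| `chain_min_carbons` | 8 | sp3 carbons | an unbranched C8 chain is the classic fatty-acid motif |
| interaction thresholds | −0.1, −1.0, −3.0 | kcal/mol | the published grading convention; boundaries belong to the stronger class (the ≤ convention of the tabulated grades, which tests pin at exactly −0.1/−1.0/−3.0) |
| CV folds `k` | 5 | — | the community default for mid-sized QSAR sets |
| parity band | 0.5 | pIC50 | the customary ±0.5 log-unit acceptance corridor |

The sigma-hole requirement is satisfied by *any* halogen (F, Cl, Br, I).
Strictly, fluorine's sigma hole is marginal; the permissive rule is chosen
because screening hits of record carry only F or Cl, and a Cl/Br/I-only
rule would reject molecules the gate is meant to admit. Tighten via
`triage_criteria()` if fluorine should not count.

## 3. Chemistry backend

There is no R-native cheminformatics dependency in the supported stack, so
the chemistry primitives — standardization, molecular weight, Bemis–Murcko
scaffolds, the 64-descriptor `"core"` panel, and the substructure features
behind `structural_filter()` — are computed by a bundled Python helper
built on RDKit, invoked per batch and memoized per SMILES within the
session. All science-bearing logic (the SC rule, split policy, benchmark,
gating, aggregation) is R code on top of those primitives; the helper
returns facts about molecules, never decisions.

Descriptor sets are versioned by name: `"core"` is a frozen, explicitly
enumerated 64-descriptor panel (constitution, topology, surface and
charge surrogates, ring and H-bond counts) whose order is documented by
`descriptor_set_names()`; `"full"` resolves to every 2D descriptor the
backend exposes, alphabetically. Non-finite descriptor values are imputed
to 0 and reported. The panel size is a property of the named set, not a
constant the code assumes.

## 4. Splitting policy

`murcko_scaffold()` reduces a molecule to its ring systems plus linkers,
stereo stripped first so enantiomers share a scaffold; acyclic molecules
map to the empty scaffold (and therefore travel together — with many
acyclic molecules, prefer `random_split()`). `scaffold_split()` assigns
whole scaffold groups: largest groups fill the training partition first
(they are the hardest to place anywhere else), the remainder is shuffled by
the seed and assigned greedily to the partition furthest below its target.
Consequences, both tested: no scaffold ever spans two partitions, and
partition sizes deviate from their targets by at most the largest group
size. A scaffold group larger than the train target goes to train with a
warning. The common 10% scaffold holdout is `fractions = c(0.9, 0, 0.1)`;
an 80/20 validation split then operates within the remaining 90%.

## 5. The benchmark harness

`cross_validate()` holds each seeded fold out once, with fold assignment at
the molecule level (never the record level, so duplicate leakage is
structurally impossible even pre-SC). The learner registry ships classical
regressors only — `lm`, `ridge`, `lasso` (glmnet), and a `mean` baseline —
because the harness's purpose is to hold the learner fixed while the data
treatment varies; graph networks and their tuning are explicitly out of
scope, and `register_learner()` is the adapter seam for anything external.
Two numerical notes: the glmnet ridge path is extended downwards
(`lambda.min.ratio = 1e-8`) because the default path stops far above the
optimum on low-noise targets; and with many collinear descriptors and a
sparse linear truth, selection (lasso) rather than shrinkage (ridge) is the
right inductive bias — ordinary least squares can extrapolate wildly for
descriptor-space outliers, which is a property of the problem, not a bug,
and is why the noise-floor test uses lasso.

`compare_strategies()` reports `100 × (rmse_baseline − rmse_final) /
rmse_baseline`; the acceptance suite checks the formula against published
benchmark numbers (0.74 → 0.58 gives 21.6%).

## 6. The synthetic-data generator: what a green test establishes

`generate_activity_table()` draws molecules from an embedded fragment
grammar (~1100 combinations of aryl cores, decorations and tails spanning
MW ≈ 41–894, so both MW boundaries are exercised), assigns each a latent
pIC50 (Gaussian by default, mean 6.5, sd 1.2 — the realistic range of an
IC50 panel; optionally a descriptor-linear form so the signal is
recoverable from structure), and emits `1 + Poisson(λ = 2)` records per
molecule. Records land in assays under a Zipf(1.5) prevalence law over 6
assays; each assay carries an additive N(0, 0.3) bias in pIC50 space
(multiplicative IC50 systematics are additive after the log); records add
N(0, 0.2) noise; 5% of stereo-capable molecules are re-emitted once with a
stereo descriptor. Values are written as IC50 in nM so the cleaning path,
unit conversion included, runs end to end. The stress knob
`rare_assay_bias` (acceptance setting: +1.5 pIC50 on the least prevalent
assay) reproduces precisely the failure mode that motivates SC.

What the generator does **not** emulate: real assay metadata text,
correlated biases between related assays, censored-value mechanisms,
activity cliffs, or realistic chemical-space density. A green recovery test
therefore establishes that SC beats the global maximum *when rare assays
are systematically biased and noise is homoscedastic* — the mechanism, not
a field result on any particular public extract. Absolute benchmark figures
from the literature (headline RMSE/R² of deep models on curated extracts)
are out of reach at desk scale by design and are not asserted anywhere.

## 7. Post-docking conventions

The pocket-selectivity delta is `score_p2 − score_p1`: energies are
more-negative-better, so a positive delta means stronger primary-pocket
binding. Published tables print this column under the label "p1−p2"; the
operation adopts the printed *values'* convention and documents the label
discrepancy. (One published row is internally inconsistent by one printed
ulp — its delta column says 0.5 where its own scores give 0.6; the package
reports the recomputed value.) Consensus over engines is rank-mean, never
score-mean: GOLD-style fitness (higher better) and energy scores live on
incommensurable scales, and rank aggregation buys invariance under any
strictly monotone per-engine rescaling, which is property-tested.
Interaction profiles aggregate multiple contacts of a (residue, ligand)
pair by summing energies before classification; absent pairs read `'-'`.

## 8. Known limitations

* Standardization follows the backend's default cleanup: no tautomer
  canonicalization beyond it, no pKa/protonation modelling, no 3D.
* Assay prevalence is computed on the dataset being cleaned (post filter,
  per the default pipeline order); prevalence from a larger parent corpus
  is not supported. Assay-quality metadata weighting is out of scope.
* The structural exclusion rules are heuristic SMARTS/graph
  operationalizations of class names ("peptide", "nucleotide", "fatty acid
  derivative"); they are configurable and their thresholds documented, but
  they are not ontologies.
* `sc_oracle()` is a testing aid and intentionally quadratic-ish; do not
  use it for curation.
* The Python/RDKit subprocess adds ~1–3 s per *uncached* batch; long
  sessions amortize this via the memo cache (`chem_cache_clear()` resets).
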