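---
title: "Cutoff-scanning signatures for mutation effect prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cutoff-scanning signatures for mutation effect prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csmpred)
```

## The model

csmpred predicts the effect of a single-point missense mutation on protein
stability or binding affinity from the *wild-type* structure alone. The
central object is a structural signature built from the residue environment
of the mutation site:

1. **Residue environment.** All heavy atoms of the structure (any chain,
   protein or retained hetero atoms) within a radius $r$ of the geometric
   centre of the mutated residue. No mutant model is ever built; the method
   deliberately reads only the wild-type environment.
2. **Cutoff scanning.** The environment is viewed as an atomic contact
   graph whose edges are pairs of atoms closer than a cutoff distance. As
   the cutoff sweeps a grid $d_{min}, d_{min}+d_{step}, \dots, d_{max}$,
   the cumulative number of edges at each step is recorded. The counts are
   segmented by atom-class pairs under three classifications — one class
   (1 pair label), polar/hydrophobic (3 unordered pair labels), and eight
   pharmacophore classes (36 unordered pair labels) — giving
   $21 \times (1 + 3 + 36) = 840$ features with the default grid. Edge
   counting is inclusive ($d \le$ cutoff), matching cumulative-distribution
   semantics.
3. **Pharmacophore change.** Each standard residue has an 8-vector of
   atom-class counts (hydrophobic, positive, negative, hydrogen-bond
   acceptor, hydrogen-bond donor, aromatic, sulphur, neutral). The
   difference `mutant - wild type` is appended: 8 features that encode
   what the mutation swaps in and out chemically.
4. **Conditions.** pH, temperature (°C) and the relative solvent
   accessibility (RSA) of the mutated residue complete the vector:
   851 features in total by default.

Signatures train a Gaussian-process model; the free-energy change in
kcal/mol is the regression target, its sign the classification target.
Affinity data are converted through $\Delta G = RT\ln K_D$ with
$R = 1.9872\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$, and
$\Delta\Delta G = \Delta G_{mt}-\Delta G_{wt}$ at a common temperature.

## Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `r` (environment radius) | 10 | Å | the signature is designed to capture long-range distance patterns, out to 10 Å from the residue centre; larger radii add mostly redundant pairs, smaller ones discard the long-range block that carries much of the discriminative power |
| `dMin`, `dMax`, `dStep` | 0, 10, 0.5 | Å | 21 cutoffs; 0.5 Å resolves the short-range hydrogen-bond band while keeping the vector compact |
| schemes | all three | — | the three classifications are concatenated; each can be toggled, and the per-cutoff sums across the 36 (or 3) pair classes always reproduce the one-class count, which the tests enforce |
| centre mode | `"all"` | — | geometric centre over all heavy atoms of the residue; a side-chain-only centre is available (`"sidechain"`, glycine falls back to all atoms) |
| self pairs | counted | — | pairs within the mutated residue itself are included; configurable because either convention is defensible |
| probe radius | 1.4 | Å | water-sized rolling probe for accessible surface area |
| pH / temperature imputation | 7.0 / 25 | — / °C | missing conditions occur in curated tables; a fixed neutral default keeps the vector dense, and the imputation is flagged in the signature provenance |
| GP noise variance | `0.1 * var(y)` | (kcal/mol)² | a fixed fraction of target variance; override with `modelSpec(noiseVar=)` |

## Pharmacophore table

The proprietary atom typing used in the original formulation of this
signature family is not publicly available, so the package ships its own
explicit table (`extdata/pharmacophore_classes.tsv`) covering every heavy
atom of the 20 standard amino acids. Atoms that plausibly carry several
roles receive one class by a fixed priority order — sulphur > positive >
negative > aromatic > donor > acceptor > hydrophobic > neutral — so the
labelling is a single-valued function. Consequences worth knowing:
hydroxyl oxygens (Ser/Thr/Tyr), which both donate and accept, are `donor`;
His and Trp ring nitrogens are `aromatic`; the proline backbone nitrogen,
which has no amide hydrogen, is `neutral`. Atoms of non-standard residues
(nucleic acids, ligands, ions) are typed by an element fallback so that
protein–DNA interfaces contribute atoms to the environment. The binary
scheme maps {hydrophobic, aromatic, neutral, sulphur} to hydrophobic and
{positive, negative, donor, acceptor} to polar.

## Relative solvent accessibility

Accessible surface area is computed with the rolling-probe (Shrake–Rupley)
method implemented in the package: a deterministic golden-spiral mesh of
960 points per atom on the solvent-expanded sphere (Bondi-style van der
Waals radii, probe 1.4 Å). Residue ASA divided by a per-residue maximum
reference (theoretical Gly-X-Gly values of Tien et al. 2013, shipped as
`extdata/max_accessibility.tsv`) gives RSA, clipped to 1. The mesh is
fixed in space, so RSA is rotation-invariant only up to mesh resolution
(observed variation < 0.01); the tests treat the scan and pharmacophore
blocks as exactly invariant and the RSA slot to that tolerance.

## Datasets, filtering and conventions

Three table dialects are supported (ProTherm-style stability tables with a
measured ΔΔG; SKEMPI- and ProNIT-style affinity tables with wild-type and
mutant $K_D$), with column maps in editable YAML configs because database
exports drift across versions. Temperatures are normalized to Kelvin
internally; a binding record without a temperature uses 298 K, flagged.
The single-point filter keeps records that are single substitutions with a
resolvable structure and a usable target, and logs every exclusion with a
reason code; it is pure and idempotent.

**Sign convention.** Negative ΔΔG = destabilizing / affinity-reducing,
applied uniformly; `loadMutationTable(flipSign = TRUE)` accommodates tables
with the opposite convention. Exactly zero classifies as destabilizing and
is flagged as a boundary case. Repeated measurements of one mutation under
different conditions are kept by default; `collapseReplicates()` offers a
median collapse without claiming fidelity to any historical deduplication.

## Learning and evaluation

Noise reduction drops zero-variance features and one of each feature pair
with |correlation| > 0.999, recording the kept-feature mask so test data is
reduced identically, by name. Features are standardized before the kernel.

The default regressor is Gaussian-process regression with a stationary RBF
kernel. The kernel inverse width is fitted by a deterministic
median-squared-distance heuristic (seeded subsampling beyond 300 rows),
and the posterior mean is computed in closed form,
$k_*^\top (K+\sigma_n^2 I)^{-1}(y-\bar y)+\bar y$, which keeps the
observation-noise variance freely settable down to the near-interpolation
regime and makes training fully deterministic. The classifier is the
kernlab Gaussian-process classifier with the same kernel handling, scores
being class probabilities. A linear least-squares family is included for
diagnostics.

Cross-validation supports 5/10/20 folds with three grouping modes:
per-mutation, and the low-redundancy per-protein and per-position modes in
which no group ever spans folds (groups are shuffled, then assigned
largest-first to the smallest fold). Metrics are **pooled** over all
held-out predictions, not averaged per fold, so they correspond to the
single truth-vs-prediction scatter; the full audit table is retained and
every reported number can be recomputed from it. σ is the root-mean-square
held-out error in kcal/mol — the error statistic conventionally reported
beside Pearson's ρ, and deliberately not the standard error of the mean.
Post-hoc outlier removal (default 10%) drops the largest-|residual| points
without refitting; both choices are labelled in the report. Accuracy is
complemented by MCC and rank-based AUC because class imbalance makes
accuracy alone misleading; no resampling is applied.

## What the synthetic generator emulates — and what it does not

`generateStructure()` produces three deterministic families: random point
clouds (raw pair-counting regime), a poly-alanine α-helix built from a
canonical backbone template on the standard helical screw (100° twist,
1.5 Å rise — a realistic dense protein neighbourhood, though not a
refined structure), and a two-chain contact whose minimum inter-chain
distance equals the requested gap exactly. `generateMutationDataset()`
samples distinct (site, mutant) combinations and draws
$\Delta\Delta G = \beta_0 + w^\top x + \varepsilon$, linear in a named
subset of signature features (pharmacophore changes, RSA, long-range
one-class counts) so that recovery is analytically interpretable; a
quadratic option adds mild nonlinearity. The default noise level draws
$\varepsilon$ with SD equal to half the signal SD, and an intercept of
−1 kcal/mol reflects that typical mutations are mildly destabilizing.

These fixtures validate the *machinery* — counting, invariances, protocol
integrity, recovery of a known generative law — not biological accuracy.
Real mutation corpora have heteroscedastic errors, strongly non-uniform
mutation sampling, correlated measurement conditions and genuinely
nonlinear structure–energy relationships; passing the synthetic suite
demonstrates none of that, and headline correlations on historical corpora
require the corresponding hundreds of PDB structures, which the package
does not download.

**Defining recovery.** With noise SD at half the signal SD, the
correlation between any prediction and the *noisy* held-out target is
bounded by $1/\sqrt{1.25} \approx 0.894$ in expectation, however good the
model. The generator therefore returns the generative truth, and the
recovery experiment scores pooled held-out predictions against the
noise-free signal (observed ρ ≈ 0.98 at n = 500, 10-fold CV), while σ is
checked against the observed targets, whose floor is the injected noise SD
(observed within ~10%). Reports on real data, where no generative truth
exists, always score against the observed values.

## Numerical choices and degenerate inputs

- Cutoff membership and the environment boundary are inclusive (≤); the
  brute-force oracles in the test suite use the same convention, and the
  comparison is exact-integer, not tolerance-based.
- Altloc handling keeps the highest-occupancy conformer, ties to the first
  encountered; multi-model files reduce to the first model; hydrogens and
  waters are removed (crystal structures rarely resolve hydrogens, and the
  water shell is not part of the residue environment by default — both
  choices configurable at the normalization surface).
- A single-atom environment yields a 1×1 zero distance matrix and all-zero
  scans rather than an error; an empty residue selection is an error that
  names the residue.
- A cutoff grid starting at 0 simply contributes an all-zero first row
  (no pair has distance ≤ 0).
- Zero-variance predictions make Pearson's ρ undefined; the metrics code
  raises an explicit error instead of returning NaN.
- Fold assignment with fewer groups than folds is refused as a protocol
  error, not silently reduced.

## Problem sizes used by the shipped experiments

The test suite and the acceptance script run entirely on generated
fixtures: helices of 8–30 residues (40–150 atoms), point clouds of up to
200 atoms, 100 random cutoff-scan environments of ≤ 60 atoms, a
500-mutation synthetic recovery set with 10-fold cross-validation, and
1000 randomized fold-integrity trials. These sizes exercise every code
path at interactive cost while keeping the brute-force oracles exact.

## Known limitations

- The pharmacophore table is an open re-creation of the eight-class
  semantics, not a byte-level clone of any proprietary typing; per-atom
  assignments at the donor/acceptor and aromatic-nitrogen boundaries are
  priority-order decisions.
- Only PDB-format input is parsed (no mmCIF); no hydrogen placement,
  side-chain repacking or mutant modelling is performed — by design the
  method never looks at a mutant structure.
- Insertion-code positions are carried through the data model, but the
  compact `R282W` mutation syntax cannot express them; records with
  insertion codes must be supplied through the table interface.
- The GP uses a single isotropic kernel width; no per-feature relevance
  determination is fitted.
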