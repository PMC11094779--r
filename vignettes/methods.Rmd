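---
title: "Graph-based signatures and tree ensembles for GPCR thermostability prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based signatures and tree ensembles for GPCR thermostability prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

G protein-coupled receptors are flexible membrane proteins that often have
to be thermostabilised by point mutations before they can be purified,
crystallised or screened. Experimentally scanning the mutational space is
slow and expensive, so `gpcrstab` estimates, from the wild-type structure
alone, the change in apparent melting temperature (dTm, in degrees C) that a
single-point mutation causes, and ranks candidate substitutions so that the
most promising stabilising mutations can be tried first. Positive predicted
dTm means stabilising.

## The model

### Graph-based structural signatures

The environment of the mutated residue is the set of heavy atoms within a
radius `r` of the residue's geometric centre (unweighted mean over all of
its heavy atoms, backbone included). Every heavy atom carries one or more of
eight pharmacophore classes - hydrophobic, positive, negative, hydrogen-bond
acceptor, hydrogen-bond donor, aromatic, sulfur, neutral - assigned by exact
lookup of (residue, atom name) in a packaged table that encodes canonical
amino-acid chemistry (an aromatic ring carbon bonded only to C/H is both
aromatic and hydrophobic; unknown atoms degrade to neutral with a warning).

Viewing the environment as a contact graph whose edges switch on as a
distance cutoff grows, the signature records, for every unordered class pair
and every cutoff `d` in a grid, the cumulative count of atom pairs at
distance at most `d` in which one atom carries the first class and the other
the second. A pair of multi-label atoms contributes to every class pair it
satisfies, once per class pair. Feature names follow the
`Hydro:Hydro-4.00` convention: class pair in fixed order, cutoff with two
decimals.

Two readings of the published feature names are possible: the cutoff could
bound the pair's inter-atomic distance or the distance to the mutation site.
We bind it to the inter-atomic distance of the pair - the reading consistent
with the cutoff-scanning contact-graph construction the signatures derive
from - and let the environment radius control the distance to the site.

The mutant side is never modelled structurally. Each residue type has a
pharmacophore frequency vector (class multiplicities over its canonical
heavy atoms); the mutation contributes the componentwise difference
`PChange = p_mt - p_wt`. Backbone atoms are included in both templates; they
cancel in the difference.

### Auxiliary features

* **Substitution matrices**: BLOSUM62 and PAM30 lookups (from Biostrings).
* **AAindex2 pair matrices**: the genetic-code matrix `BENS940104`
  (Benner et al. 1994), packaged as an AAindex2-dialect flat file, and
  `HELX_SYN01`, a *synthetic* helix-class substitution similarity table
  derived from Chou-Fasman alpha-helix propensities. `HELX_SYN01` stands in
  for a published structure-based helix-class exchange table and is clearly
  labelled synthetic in its file; any AAindex2-format matrix can be dropped
  in instead.
* **Relative solvent accessibility**: Shrake-Rupley SASA (1.4 A probe,
  deterministic golden-spiral point sampling, 100 points per atom) divided
  by the residue type's theoretical maximum (Tien et al. 2013). Because the
  reference is tripeptide-normalised, very exposed residues can exceed 1.
* **Residue depth**: mean distance of the residue's atoms to the
  solvent-accessible surface, the latter sampled by the exposed
  Shrake-Rupley test points. Both SASA and depth are implemented in the
  package and cross-validated in the test suite against an independent
  implementation (values agree within 5%, mostly within 1%).
* **Membrane topology**: per-residue flags `mem` (inside the membrane slab)
  and `non_cytosol`. Preferred source is an annotation file; the fallback
  assumes a membrane-oriented structure (normal along z, extracellular up)
  and uses a symmetric slab of half-width 15 A, the approximate hydrophobic
  half-thickness of a lipid bilayer.
* **Identity indicators**: `FromPro`, `ToAla`, `FromGly`, `ToPro`. These
  realise the "special amino acids" substitution block: proline's backbone
  rigidity and the alanine-scanning bias of stability datasets make these
  substitutions systematically different.

Feature families based on external energy or contact engines (interatomic
contact typing, normal-mode analysis, empirical potentials) are exposed only
as an extension point: none survive feature selection in practice and the
package does not depend on them.

### Learning

Four tree-ensemble regressors are supported: Random Forest and Extremely
Randomized Trees (via `ranger`), Gradient Boosting (xgboost with
classic-GBM settings: depth 3, learning rate 0.1, no subsampling) and
Extreme Gradient Boosting (xgboost defaults). All use 300 trees; every other
hyperparameter stays at the backend default. Random Forest is the package
default.

Feature selection is bottom-up greedy forward selection: starting from the
empty set, each round scores every remaining candidate joined to the current
set by 10-fold cross-validation - one seeded fold partition fixed for the
whole run so candidate scores are comparable - and keeps the candidate with
the best pooled out-of-fold Pearson's r. Selection stops at the first round
with no strict improvement (epsilon = 0); ties break by candidate order. MSE
is recorded at every step but never drives selection; Pearson's r is the
sole criterion, which means the selected model optimises correlation, not
squared error, and the two can disagree.

Predictions are ranked in descending dTm; ties keep input order. The
classification-by-regression utilities convert continuous values to
destabilizing / neutral / stabilizing with a closed neutral band (boundary
values are neutral; the published wording leaves boundaries open, and the
closed choice is this package's convention). The binary rule maps positives
to 1 and everything else, including exact zero, to 0. The threshold scan
evaluates symmetric bands from 0.1 to 3.0 in 0.05 steps (59 bands);
asymmetric bands are not scanned. In benchmarking, each method's predictions
are classified with that method's own band, the truth with the band under
scan. Multiclass MCC follows the generalised (Gorodkin) definition;
weighted F1 is the support-weighted mean of per-class F1.

## Synthetic data and what it shows

`make_helical_bundle()` builds parametric alpha-helices (rise 1.5 A per
residue, 3.6 residues per turn; consecutive CA-CA distances come out at
3.83 A) placed antiparallel on a ring, z along the bundle axis so the
membrane slab heuristic applies. Side chains are reduced to a single
pseudo-atom at the C-beta position carrying the union of the residue's
side-chain pharmacophore classes - the geometry stays analytically
checkable while signatures remain chemically non-trivial. The default is a
GPCR-like seven-helix bundle of 25-residue helices (ring radius 10 A, which
puts neighbouring helix axes 8.7 A apart, typical of packed helices).

`make_mutation_table()` samples (site, mutant) pairs uniformly without
replacement; `plant_labels()` makes dTm a linear function of standardised
known feature columns plus Gaussian noise, giving a closed-form recovery
oracle (ordinary least squares recovers the planted weights exactly at zero
noise). Planted labels are linear by design: tree ensembles recover monotone
nonlinear signals too, but linearity is what makes the ground truth
checkable.

The package validates itself with two calibration experiments run over ten
seeds each:

* **Recovery** (`recovery_experiment()`): 300 mutations on the default
  bundle, labels planted on `Hydro:Hydro-4.00`, `Acc:Don-4.00` and
  `PChange.Hydro` with weights (2, 1, -1.5) and noise sigma 0.5 degrees;
  selection runs over the three planted features plus 30 decoy columns.
  Decoys are taken from the real featurised matrix after a deterministic
  redundancy screen (drop columns correlated above 0.95 with an already-kept
  column - neighbouring cutoffs of the same class pair are nearly
  collinear). The planted features were chosen from three distinct blocks
  (an apolar pair count, a polar pair count, a substitution-side component)
  so that the ground truth is not itself redundant. Expected outcome, and
  what the acceptance suite asserts: all three planted features recovered
  with final CV Pearson >= 0.9 in at least 8 of 10 seeds.
* **Noise guard** (`noise_guard_experiment()`): 200 mutations, 50 candidate
  features, pure-noise labels; the final CV Pearson after a full greedy
  selection stays below 0.3 in at least 9 of 10 seeds. This bounds how much
  spurious correlation the Pearson-maximising selection can manufacture at
  this sample size.

The experiment sizes (300 and 200 mutations) are the package's calibration
choices: large enough that recovery is sharp and the guard is tight, small
enough that the full 2 x 10-seed suite runs in minutes. What passing shows:
the pipeline's plumbing, selection and ensemble machinery find real signal
and refuse fabricated signal under controlled conditions. What it does not
show: performance on experimental receptor data - synthetic bundles have
idealised geometry, pseudo-atom side chains, uniform mutation sampling and
linear label structure, none of which hold for curated thermostability
datasets. Training on real data goes through exactly the same code path via
`run_train()`.

## Numerical choices and degenerate inputs

* Distance comparisons use a 1e-9 tolerance so pairs exactly at a cutoff
  count as within it.
* Environment radius default 10 A: roughly two coordination shells; the
  published signature construction leaves the radius unstated, so it is a
  configuration parameter. The cutoff grid default 2.0-6.0 A in 0.5 A steps
  covers every published selected-signature cutoff.
* The wild-type residue's own atoms stay in the environment: they are the
  mutation's immediate chemistry.
* Altloc resolution keeps the highest occupancy, ties by label order.
  Author residue numbering is used verbatim; structures with engineered
  numbering need an annotation or renumbered input. Loop excision is the
  data preparer's responsibility; the cleaner only removes waters, ligands,
  other chains and hydrogens.
* Constant pooled CV predictions make Pearson undefined; the score is NaN
  and treated as -Inf by selection. Constant true labels raise a degenerate
  error in `regression_metrics()`. Single-class label vectors give MCC 0
  with a warning.
* All stochastic steps (sequence draw, mutation sampling, label noise, fold
  shuffle, fits) are pure functions of their seed arguments; global RNG
  state is saved and restored.

## Known limitations

* Trained and validated machinery, but no packaged experimental dataset and
  no pre-trained production model: real curated dTm tables must be supplied
  as CSV.
* Class A GPCR conventions (membrane-oriented z-axis, single chain) are
  assumed by the topology heuristic.
* The helix-class substitution matrix is a synthetic stand-in (see above).
* UniProt-to-structure position mapping is assumed to be the identity, as
  holds for full-sequence receptor models; other inputs need renumbering.
* SASA point sampling (100 points/atom) trades ~1-3% accuracy for speed;
  raise `n_points` for publication-grade accessibility values.
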