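# gpcrstab

Structure-based prediction and ranking of mutation effects on GPCR
thermostability.

G protein-coupled receptors usually need thermostabilising point mutations
before they can be purified, crystallised or screened, and finding those
mutations experimentally means scanning a huge sequence space. `gpcrstab`
estimates the change in apparent melting temperature ΔTm (°C) caused by a
single-point mutation, directly from the wild-type structure, and ranks
candidate mutations so the most promising stabilising ones (ΔTm > 0) are
tried first.

The core of the method is a **graph-based structural signature** of the
mutated residue's environment. Every heavy atom within a radius *r* of the
residue's geometric centre is typed with one or more of eight pharmacophore
classes (hydrophobic, positive, negative, H-bond acceptor, H-bond donor,
aromatic, sulfur, neutral); for every unordered class pair (C₁, C₂) and
every distance cutoff *d* in a grid, the signature stores the cumulative
count

> N(C₁, C₂, d) = #{ {a, b} : dist(a, b) ≤ d, a carries C₁, b carries C₂ },

yielding features named like `Hydro:Hydro-4.00`. The substitution itself is
encoded by the pharmacophore change vector **PChange = p_mt − p_wt**, the
componentwise difference of the mutant and wild-type residue pharmacophore
frequency vectors — no mutant structure is built. Auxiliary features add
substitution-matrix scores (BLOSUM62, PAM30), AAindex2 pair-matrix scores,
relative solvent accessibility, residue depth, membrane topology flags and
proline/alanine/glycine indicators.

A tree-ensemble regressor (Random Forest by default, 300 trees) is trained
on the features surviving **bottom-up greedy forward selection**: starting
from zero features, each round adds the candidate that maximises pooled
out-of-fold Pearson's r under 10-fold cross-validation, stopping when no
candidate improves it. Evaluation covers regression (Pearson, MSE, Kendall
τ, Spearman ρ) and classification-by-regression with a neutral band,
including a symmetric band scan (0.1 → 3.0, step 0.05) for benchmarking
against ΔΔG predictors.

A synthetic-data module generates α-helical bundle structures and mutation
tables with planted linear labels, so the entire pipeline is testable and
self-calibrating without external data.

## Worked example

Train on a synthetic bundle with planted labels, then rank three mutations:

```r
library(gpcrstab)

bundle <- make_helical_bundle(bundle_spec())        # 7 helices x 25 residues
muts   <- make_mutation_table(bundle, 300, seed = 1)
fm     <- featurize(muts, setNames(list(bundle), muts$uniprot_id[1]))
y      <- plant_labels(fm, c("Hydro:Hydro-4.00", "Acc:Don-4.00", "PChange.Hydro"),
                       c(2, 1, -1.5), noise_sigma = 0.5, seed = 1)

cand  <- candidate_features(fm$x, c("Hydro:Hydro-4.00", "Acc:Don-4.00",
                                    "PChange.Hydro"), n_decoys = 30)
trace <- greedy_forward_selection(fm$x[, cand], y, seed = 1)
trace
#> <gs_selection_trace> random_forest, 10-fold CV, 4 features selected
#>                           feature cv_pearson    cv_mse
#> Hydro:Hydro-4.00 Hydro:Hydro-4.00  0.7902015 3.4931975
#> PChange.Hydro       PChange.Hydro  0.9171647 1.5477049
#> Acc:Don-4.00         Acc:Don-4.00  0.9707079 0.7001915
#> Aro:Don-2.50         Aro:Don-2.50  0.9710576 0.5820832
```

The trace shows the greedy rounds: each added feature, the pooled 10-fold
CV Pearson's r after adding it (strictly increasing by construction) and the
corresponding MSE. The three planted determinants are recovered first, and
the final CV r ≈ 0.97 against the noise ceiling of ≈ 0.98 implied by
σ = 0.5 on a signal of variance 7.25.

```r
model  <- train_model(fm$x, y, trace$selected, "random_forest", seed = 1)
ranked <- predict_and_rank(model, featurize(muts[1:3, ],
                           setNames(list(bundle), muts$uniprot_id[1])))
ranked
#>   mutation chain predicted_dTm rank          flag
#> 1    Q115K     A    2.27622025    1   stabilizing
#> 2     E54L     A    0.23951822    2   stabilizing
#> 3     D36P     A   -0.01854005    3 destabilizing
```

Positive predicted ΔTm is read as stabilising; rows are sorted by rank.
With experimental data the flow is identical: `read_mutation_table()` +
`run_train()` take CSV tables (`uniprot_id, chain, position, wt_aa, mt_aa,
dTm, source`) and cleaned PDB structures.

A command-line wrapper with `predict`, `train`, `eval`, `benchmark` and
`synth` subcommands ships at `inst/cli/gpcrstab.R`:

```sh
Rscript inst/cli/gpcrstab.R predict --structure rec.pdb --chain A \
    --mutations muts.txt --model fit_model.rds --out ranked.csv
```

Mutation lists use one `"<wt><position><mt> <chain>"` entry per line, e.g.
`A123V A`.

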