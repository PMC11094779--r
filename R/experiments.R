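# Calibration experiments on fully synthetic data. These drive the
# package's self-validation: a planted-signal recovery experiment (can the
# selection + ensemble pipeline find known determinants of dTm?) and a
# pure-noise guard (does it hallucinate signal where there is none?).

#' Planted-signal recovery experiment
#'
#' Builds a helical bundle, draws a mutation table, featurises it through
#' the standard pipeline, plants linear labels on three known features
#' (plus Gaussian noise), and runs greedy forward selection with a 300-tree
#' Random Forest over the planted features and `n_decoys` weakly redundant
#' decoy columns. Reports whether the planted features were recovered and
#' the final cross-validated Pearson's r.
#'
#' @param seed Experiment seed (drives mutation sampling, label noise and
#'   fold shuffling).
#' @param n_mutations Mutations in the synthetic table.
#' @param planted Names of the three planted features.
#' @param weights Planted linear weights (on standardised features).
#' @param noise_sigma Label noise standard deviation (degrees C).
#' @param n_decoys Decoy candidate features.
#' @param algorithm Ensemble algorithm for selection.
#' @param bundle Optional pre-built bundle `gs_structure` (rebuilt from the
#'   default [bundle_spec()] when `NULL`).
#' @param fm Optional pre-computed `gs_feature_matrix` for the mutation
#'   table of this seed (computed when `NULL`).
#' @return List: `trace`, `selected`, `recovered` (logical), `cv_pearson`,
#'   `cv_mse`, `candidates`.
#' @export
recovery_experiment <- function(seed = 1L, n_mutations = 300L,
                                planted = c("Hydro:Hydro-4.00", "Acc:Don-4.00",
                                            "PChange.Hydro"),
                                weights = c(2, 1, -1.5), noise_sigma = 0.5,
                                n_decoys = 30L, algorithm = "random_forest",
                                bundle = NULL, fm = NULL) {
  if (is.null(fm)) {
    if (is.null(bundle)) bundle <- make_helical_bundle(bundle_spec())
    muts <- make_mutation_table(bundle, n_mutations, seed = seed)
    fm <- featurize(muts, stats::setNames(list(bundle), muts$uniprot_id[1]))
  }
  y <- plant_labels(fm, planted, weights, noise_sigma, seed = seed)
  cand <- candidate_features(fm$x, planted, n_decoys = n_decoys)
  trace <- greedy_forward_selection(fm$x[, cand, drop = FALSE], y,
                                    algorithm = algorithm, k = 10L, seed = seed)
  final <- utils::tail(trace$steps, 1L)
  list(trace = trace, selected = trace$selected,
       recovered = all(planted %in% trace$selected),
       cv_pearson = final$cv_pearson, cv_mse = final$cv_mse,
       candidates = cand)
}

#' Pure-noise overfitting guard
#'
#' Runs the full greedy selection on labels that are pure Gaussian noise,
#' over `n_features` weakly redundant feature columns of a featurised
#' synthetic mutation table. The final cross-validated Pearson's r measures
#' how much spurious signal the selection can manufacture.
#'
#' @param seed Experiment seed.
#' @param n_mutations Rows in the synthetic table.
#' @param n_features Candidate features offered to the selection.
#' @param algorithm Ensemble algorithm.
#' @param bundle,fm Optional pre-built inputs as in [recovery_experiment()].
#' @return List: `trace`, `cv_pearson` (final; `-Inf` if no feature ever
#'   scored), `n_selected`.
#' @export
noise_guard_experiment <- function(seed = 1L, n_mutations = 200L,
                                   n_features = 50L,
                                   algorithm = "random_forest",
                                   bundle = NULL, fm = NULL) {
  if (is.null(fm)) {
    if (is.null(bundle)) bundle <- make_helical_bundle(bundle_spec())
    muts <- make_mutation_table(bundle, n_mutations, seed = seed)
    fm <- featurize(muts, stats::setNames(list(bundle), muts$uniprot_id[1]))
  }
  y <- plant_labels(fm, character(0), numeric(0), noise_sigma = 1, seed = seed)
  cand <- candidate_features(fm$x, character(0), n_decoys = n_features)
  trace <- greedy_forward_selection(fm$x[, cand, drop = FALSE], y,
                                    algorithm = algorithm, k = 10L, seed = seed)
  final <- utils::tail(trace$steps, 1L)
  list(trace = trace,
       cv_pearson = if (is.null(final)) -Inf else final$cv_pearson,
       n_selected = length(trace$selected))
}
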