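# Graph-based structural signatures: the residue environment is viewed as a
# contact graph on heavy atoms whose edges appear as the distance cutoff
# grows; for every unordered pair of pharmacophore classes the signature
# stores the cumulative count of atom pairs in contact at each cutoff.

#' Signature/feature configuration
#'
#' Collects the tunable parameters of feature generation in one object.
#'
#' @param radius Environment sphere radius about the mutated residue's
#'   geometric centre, in Angstrom.
#' @param cutoffs Strictly ascending grid of inter-atomic distance cutoffs
#'   (Angstrom) at which the cumulative pair counts are recorded.
#' @param membrane_half_width Half-width of the membrane z-slab (Angstrom)
#'   used by the topology heuristic when no annotation file is given.
#' @param aaindex_ids AAindex2 accessions (from the packaged flat files) to
#'   emit as substitution features.
#' @param matrices Substitution matrix names to emit (`"BLOSUM62"`,
#'   `"PAM30"`).
#' @return A list of class `gs_config`.
#' @export
gs_config <- function(radius = 10,
                      cutoffs = seq(2, 6, by = 0.5),
                      membrane_half_width = 15,
                      aaindex_ids = c("BENS940104", "HELX_SYN01"),
                      matrices = c("BLOSUM62", "PAM30")) {
  if (length(cutoffs) < 1L || any(cutoffs <= 0) || is.unsorted(cutoffs, strictly = TRUE)) {
    gs_error("gs_config_error", "cutoffs must be strictly ascending and positive")
  }
  if (radius <= 0) gs_error("gs_config_error", "radius must be positive")
  structure(list(radius = radius, cutoffs = cutoffs,
                 membrane_half_width = membrane_half_width,
                 aaindex_ids = aaindex_ids, matrices = matrices),
            class = "gs_config")
}

# Unordered class pairs in canonical (sorted short-label) order.
class_pairs <- function() {
  sh <- names(pharmacophore_classes())
  out <- list()
  for (i in seq_along(sh)) for (j in i:length(sh)) {
    out[[length(out) + 1L]] <- c(sh[i], sh[j])
  }
  out
}

#' Names of all signature count features for a cutoff grid
#'
#' @param cutoffs Ascending cutoff grid in Angstrom.
#' @return Character vector `"Class1:Class2-cutoff"`, cutoff printed with two
#'   decimals, class pairs in sorted order.
#' @export
signature_feature_names <- function(cutoffs) {
  unlist(lapply(class_pairs(), function(p) {
    sprintf("%s:%s-%.2f", p[1], p[2], cutoffs)
  }))
}

# n x 8 logical membership matrix keyed by short class label.
membership_matrix <- function(classes) {
  sh <- names(pharmacophore_classes())
  long <- unname(pharmacophore_classes())
  m <- matrix(FALSE, length(classes), length(sh), dimnames = list(NULL, sh))
  for (i in seq_along(classes)) {
    m[i, match(classes[[i]], long)] <- TRUE
  }
  m
}

#' Cumulative pharmacophore pair-count signature
#'
#' For every unordered pharmacophore class pair (C1, C2) and every cutoff d
#' in the grid, counts the unordered pairs of distinct atoms whose
#' inter-atomic distance is at most d and where one atom carries C1 and the
#' other C2. A multi-label atom pair contributes to every class pair it
#' satisfies, but at most once per class pair. Counts are cumulative in d by
#' construction.
#'
#' @param atoms Data frame of environment atoms with `x`, `y`, `z` columns.
#' @param classes Class sets per atom, as from [assign_pharmacophores()]
#'   (long class names).
#' @param cutoffs Strictly ascending positive cutoff grid (Angstrom).
#' @return Named integer vector over [signature_feature_names()].
#' @export
pair_count_signature <- function(atoms, classes, cutoffs = gs_config()$cutoffs) {
  if (any(cutoffs <= 0) || is.unsorted(cutoffs, strictly = TRUE)) {
    gs_error("gs_config_error", "cutoffs must be strictly ascending and positive")
  }
  n <- nrow(atoms)
  feat <- signature_feature_names(cutoffs)
  counts <- stats::setNames(integer(length(feat)), feat)
  if (n < 2L) return(counts)
  stopifnot(length(classes) == n)

  d <- as.matrix(stats::dist(cbind(atoms$x, atoms$y, atoms$z)))
  iu <- which(upper.tri(d), arr.ind = TRUE)
  dp <- d[iu]
  within <- dp <= max(cutoffs) + 1e-9
  if (!any(within)) return(counts)
  iu <- iu[within, , drop = FALSE]
  dp <- dp[within]
  # index of the first cutoff each pair distance fits under (<= semantics)
  first_bin <- findInterval(dp - 1e-9, cutoffs) + 1L

  m <- membership_matrix(classes)
  K <- length(cutoffs)
  a <- iu[, 1L]; b <- iu[, 2L]
  for (p in class_pairs()) {
    c1 <- p[1]; c2 <- p[2]
    hit <- if (c1 == c2) {
      m[a, c1] & m[b, c1]
    } else {
      (m[a, c1] & m[b, c2]) | (m[a, c2] & m[b, c1])
    }
    if (!any(hit)) next
    cum <- cumsum(tabulate(first_bin[hit], nbins = K))
    counts[sprintf("%s:%s-%.2f", c1, c2, cutoffs)] <- as.integer(cum)
  }
  counts
}

#' Full signature of one mutation site
#'
#' Convenience wrapper: extracts the residue environment, types its atoms
#' and returns the pair-count signature together with the pharmacophore
#' change vector of the substitution.
#'
#' @param s A cleaned `gs_structure`.
#' @param chain,position,wt_aa,mt_aa The mutation (1-letter codes).
#' @param config A [gs_config()].
#' @param table A [pharmacophore_table()].
#' @return Named numeric vector: signature counts followed by the eight
#'   `PChange.<class>` components.
#' @export
mutation_signature <- function(s, chain, position, wt_aa, mt_aa,
                               config = gs_config(),
                               table = pharmacophore_table()) {
  env <- residue_environment(s, chain, position, wt_aa, radius = config$radius)
  cls <- assign_pharmacophores(env, table)
  counts <- pair_count_signature(env, cls, config$cutoffs)
  pc <- pchange(wt_aa, mt_aa, table)
  names(pc) <- paste0("PChange.", class_short(names(pc)))
  c(counts, pc)
}
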