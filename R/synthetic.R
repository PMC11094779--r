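# Synthetic data: parametric alpha-helical bundles with single side-chain
# pseudo-atoms, random mutation tables, and planted linear labels. These
# stand in for receptor models and curated mutation datasets so that every
# pipeline stage can be exercised and validated without external data.

#' Specification of a synthetic helical bundle
#'
#' @param n_helices Number of helices (7 mimics a GPCR fold).
#' @param residues_per_helix Residues per helix.
#' @param helix_spacing Radius (Angstrom) of the ring on which helix axes
#'   are placed.
#' @param rise_per_residue Helical rise (Angstrom per residue).
#' @param residues_per_turn Residues per helical turn.
#' @param sequence Either a 1-letter sequence string of length
#'   `n_helices * residues_per_helix`, or `NULL` to draw one uniformly using
#'   `seed`.
#' @param seed Seed used when drawing a random sequence.
#' @return A list of class `gs_bundle_spec`.
#' @export
bundle_spec <- function(n_helices = 7L, residues_per_helix = 25L,
                        helix_spacing = 10, rise_per_residue = 1.5,
                        residues_per_turn = 3.6, sequence = NULL, seed = 42L) {
  if (n_helices < 1L || residues_per_helix < 1L || helix_spacing <= 0) {
    gs_error("gs_spec_error", "need n_helices >= 1, residues_per_helix >= 1, spacing > 0")
  }
  if (n_helices > 1L) {
    gap <- 2 * helix_spacing * sin(pi / n_helices)
    if (gap < 4) {
      gs_error("gs_spec_error",
               sprintf("helix axes only %.1f A apart: helices overlap", gap))
    }
  }
  n_res <- n_helices * residues_per_helix
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != n_res ||
        !all(strsplit(sequence, "")[[1]] %in% aa_standard1())) {
      gs_error("gs_spec_error",
               sprintf("sequence must be %d standard 1-letter codes", n_res))
    }
  }
  structure(list(n_helices = n_helices, residues_per_helix = residues_per_helix,
                 helix_spacing = helix_spacing, rise_per_residue = rise_per_residue,
                 residues_per_turn = residues_per_turn, sequence = sequence,
                 seed = seed),
            class = "gs_bundle_spec")
}

# Point on the per-atom helix: t in residue units, r the atom's own radius.
helix_point <- function(t, r, omega, rise, phase = 0) {
  c(r * cos(omega * t + phase), r * sin(omega * t + phase), rise * t)
}

#' Build a synthetic alpha-helical bundle structure
#'
#' Each residue contributes an ideal backbone (N, CA, C, O on concentric
#' helices with the requested rise and periodicity) and, except glycine, a
#' single side-chain pseudo-atom `SC` at the C-beta position. The
#' pharmacophore table assigns `SC` the union of the residue's side-chain
#' classes, so signatures over bundles remain chemically non-trivial while
#' the geometry stays analytically checkable. Helices run antiparallel on a
#' ring, z along the bundle axis (membrane normal). Deterministic in
#' (spec, seed).
#'
#' @param spec A [bundle_spec()].
#' @return A `gs_structure` with one chain `A` and residues numbered
#'   consecutively from 1.
#' @export
make_helical_bundle <- function(spec = bundle_spec()) {
  stopifnot(inherits(spec, "gs_bundle_spec"))
  n_res <- spec$n_helices * spec$residues_per_helix
  seq1 <- spec$sequence
  if (is.null(seq1)) {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
    set.seed(spec$seed)
    seq1 <- paste(sample(aa_standard1(), n_res, replace = TRUE), collapse = "")
  }
  aa <- strsplit(seq1, "")[[1]]
  omega <- 2 * pi / spec$residues_per_turn
  rise <- spec$rise_per_residue
  height <- (spec$residues_per_helix - 1) * rise

  rows <- vector("list", n_res * 5L)
  nrow_used <- 0L
  serial <- 0L
  res_idx <- 0L
  for (h in seq_len(spec$n_helices)) {
    ang <- 2 * pi * (h - 1) / spec$n_helices
    origin <- c(spec$helix_spacing * cos(ang), spec$helix_spacing * sin(ang), 0)
    flip <- h %% 2L == 0L            # antiparallel bundle
    for (k in seq_len(spec$residues_per_helix)) {
      res_idx <- res_idx + 1L
      res3 <- aa_one_to_three()[[aa[res_idx]]]
      t <- k - 1L
      # per-atom helices: radius and offset along the chain direction
      local <- list(
        N  = helix_point(t - 0.35, 1.60, omega, rise, phase = ang),
        CA = helix_point(t,        2.30, omega, rise, phase = ang),
        C  = helix_point(t + 0.40, 2.00, omega, rise, phase = ang),
        O  = helix_point(t + 0.42, 3.20, omega, rise, phase = ang),
        SC = helix_point(t - 0.05, 3.55, omega, rise, phase = ang + 0.25))
      atoms <- c("N", "CA", "C", "O", if (res3 != "GLY") "SC")
      for (at in atoms) {
        p <- local[[at]]
        if (flip) p <- c(p[1], -p[2], height - p[3])
        p <- p + origin
        serial <- serial + 1L
        nrow_used <- nrow_used + 1L
        rows[[nrow_used]] <- data.frame(
          serial = serial, name = at,
          element = if (at == "N") "N" else if (at == "O") "O" else "C",
          res_name = res3, res_seq = res_idx, ins = "", chain = "A",
          x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
      }
    }
  }
  atoms <- do.call(rbind, rows[seq_len(nrow_used)])
  # centre the bundle on z = 0 so the membrane slab heuristic applies
  atoms$z <- atoms$z - mean(range(atoms$z))
  new_structure(atoms, sprintf("bundle_%dx%d_seed%d", spec$n_helices,
                               spec$residues_per_helix, spec$seed))
}

#' Draw a random mutation table over a structure
#'
#' Uniform sampling without replacement of (position, mutant residue) pairs
#' with mutant different from wild type. Deterministic in `seed`.
#'
#' @param s A `gs_structure` (typically a synthetic bundle).
#' @param n_mutations Number of mutations to draw.
#' @param seed Integer seed.
#' @param uniprot_id Receptor identifier to stamp on the records.
#' @return Mutation record data frame (unlabelled: `dTm = NA`).
#' @export
make_mutation_table <- function(s, n_mutations, seed = 42L, uniprot_id = "SYNREC1") {
  res <- structure_residues(s)
  wt1 <- aa_three_to_one()[res$res_name]
  combos <- do.call(rbind, lapply(seq_len(nrow(res)), function(i) {
    mts <- setdiff(aa_standard1(), wt1[i])
    data.frame(chain = res$chain[i], position = res$res_seq[i],
               wt_aa = unname(wt1[i]), mt_aa = mts, stringsAsFactors = FALSE)
  }))
  if (n_mutations > nrow(combos)) {
    gs_error("gs_spec_error",
             sprintf("requested %d mutations but only %d (site, mutant) combinations exist",
                     n_mutations, nrow(combos)))
  }
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  pick <- sample.int(nrow(combos), n_mutations)
  out <- combos[pick, , drop = FALSE]
  out$uniprot_id <- uniprot_id
  out$dTm <- NA_real_
  out$source <- "synthetic"
  rownames(out) <- NULL
  out[MUTATION_COLS]
}

#' Plant linear labels on a feature matrix
#'
#' Labels are a linear combination of the z-standardised planted feature
#' columns plus Gaussian noise:
#' `y = sum_i w_i * z(f_i) + Normal(0, noise_sigma^2)`. With
#' `noise_sigma = 0` the labels are an exact linear function of the planted
#' features.
#'
#' @param fm A `gs_feature_matrix` (or plain numeric matrix).
#' @param true_features Feature names carrying signal (may be empty for
#'   pure-noise labels).
#' @param weights Numeric weights, one per planted feature.
#' @param noise_sigma Noise standard deviation (degrees C).
#' @param seed Integer seed.
#' @return Numeric label vector (length = rows of the matrix).
#' @export
plant_labels <- function(fm, true_features, weights, noise_sigma = 0.5, seed = 42L) {
  x <- if (inherits(fm, "gs_feature_matrix")) fm$x else fm
  if (length(true_features) != length(weights)) {
    gs_error("gs_spec_error", "true_features and weights must have equal length")
  }
  if (noise_sigma < 0) gs_error("gs_spec_error", "noise_sigma must be >= 0")
  missing <- setdiff(true_features, colnames(x))
  if (length(missing)) {
    gs_error("gs_schema_error",
             sprintf("planted features absent from matrix: %s",
                     paste(missing, collapse = ", ")))
  }
  y <- numeric(nrow(x))
  for (i in seq_along(true_features)) {
    col <- x[, true_features[i]]
    s <- stats::sd(col)
    if (s == 0) gs_error("gs_spec_error",
                         sprintf("planted feature '%s' has zero variance", true_features[i]))
    y <- y + weights[i] * (col - mean(col)) / s
  }
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  y + stats::rnorm(nrow(x), 0, noise_sigma)
}

#' Pick weakly redundant candidate features
#'
#' Deterministic screen used by the synthetic experiments: keeps the
#' planted features, then walks the remaining columns in matrix order and
#' keeps those with positive variance whose absolute Pearson correlation
#' with every already-kept column is at most `max_cor`, until `n_decoys`
#' decoys are collected. Standard redundancy filtering -- cumulative
#' signature counts of neighbouring cutoffs are nearly collinear.
#'
#' @param x Numeric feature matrix.
#' @param planted Feature names that must be kept.
#' @param n_decoys Number of decoy features to add.
#' @param max_cor Redundancy threshold on absolute pairwise correlation.
#' @return Character vector: planted features followed by decoys.
#' @export
candidate_features <- function(x, planted, n_decoys = 30L, max_cor = 0.95) {
  keep <- planted
  for (f in setdiff(colnames(x), planted)) {
    if (length(keep) - length(planted) >= n_decoys) break
    col <- x[, f]
    if (stats::sd(col) == 0) next
    r <- suppressWarnings(abs(stats::cor(col, x[, keep, drop = FALSE])))
    if (all(is.na(r) | r <= max_cor)) keep <- c(keep, f)
  }
  if (length(keep) - length(planted) < n_decoys) {
    gs_error("gs_spec_error",
             sprintf("only %d decoys available under max_cor = %.2f",
                     length(keep) - length(planted), max_cor))
  }
  keep
}
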