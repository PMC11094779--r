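# Fixtures are built in code: handcrafted fixed-column PDB records for the
# loader/cleaner tests, random atom environments for the signature property
# suite, and a brute-force pair-counting oracle kept deliberately naive.

pdb_line <- function(serial, name, res_name, chain, res_seq, x, y, z,
                     altloc = "", occ = 1, element = NULL, record = "ATOM") {
  if (is.null(element)) element <- substr(name, 1, 1)
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altloc, res_name, chain, res_seq,
          x, y, z, occ, 0, element)
}

write_pdb_fixture <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# Three glycines (N, CA, C each): 9 heavy atoms.
fixture_three_residues <- function() {
  lines <- character(0)
  s <- 0
  for (r in 1:3) {
    base <- (r - 1) * 3.5
    lines <- c(lines,
               pdb_line(s + 1, "N",  "GLY", "A", r, base, 0, 0),
               pdb_line(s + 2, "CA", "GLY", "A", r, base + 1.2, 0.8, 0),
               pdb_line(s + 3, "C",  "GLY", "A", r, base + 2.4, 0, 0))
    s <- s + 3
  }
  write_pdb_fixture(lines)
}

# Chain A protein (12 atoms), chain B protein, waters, and a heme ligand.
fixture_mixed_content <- function() {
  lines <- character(0)
  s <- 0
  for (r in 1:4) {                                   # 4 x 3 = 12 chain A atoms
    base <- (r - 1) * 3.5
    lines <- c(lines,
               pdb_line(s + 1, "N",  "ALA", "A", r, base, 0, 0),
               pdb_line(s + 2, "CA", "ALA", "A", r, base + 1.2, 0.8, 0),
               pdb_line(s + 3, "CB", "ALA", "A", r, base + 1.2, 2.1, 0.5))
    s <- s + 3
  }
  lines <- c(lines,
             pdb_line(s + 1, "N",  "SER", "B", 1, 0, 8, 0),
             pdb_line(s + 2, "CA", "SER", "B", 1, 1.2, 8.8, 0),
             pdb_line(s + 3, "O",  "HOH", "A", 90, 5, 5, 5, record = "HETATM"),
             pdb_line(s + 4, "O",  "HOH", "A", 91, 6, 6, 6, record = "HETATM"),
             pdb_line(s + 5, "FE", "HEM", "A", 99, 7, 7, 7, element = "FE",
                      record = "HETATM"))
  write_pdb_fixture(lines)
}

# Mutation site = 2-atom ALA residue centred at the origin, plus 5 probe
# atoms at hand-placed distances {2.0, 3.9, 4.0, 4.1, 7.3} from the centre.
fixture_environment <- function() {
  lines <- c(
    pdb_line(1, "CA", "ALA", "A", 1, -1.0, 0, 0),
    pdb_line(2, "CB", "ALA", "A", 1,  1.0, 0, 0),
    pdb_line(3, "CA", "GLY", "A", 2, 2.0, 0, 0),
    pdb_line(4, "CA", "GLY", "A", 3, 0, 3.9, 0),
    pdb_line(5, "CA", "GLY", "A", 4, 0, 0, 4.0),
    pdb_line(6, "CA", "GLY", "A", 5, 0, -4.1, 0),
    pdb_line(7, "CA", "GLY", "A", 6, 0, 0, -7.3))
  write_pdb_fixture(lines)
}

fixture_altloc <- function(occ_a, occ_b) {
  lines <- c(
    pdb_line(1, "N",  "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "ALA", "A", 1, 1.0, 0, 0, altloc = "A", occ = occ_a),
    pdb_line(3, "CA", "ALA", "A", 1, 2.0, 0, 0, altloc = "B", occ = occ_b),
    pdb_line(4, "CB", "ALA", "A", 1, 1.0, 1.4, 0))
  write_pdb_fixture(lines)
}

# Random classified environment for property tests.
random_environment <- function(n, seed, box = 15) {
  set.seed(seed)
  atoms <- data.frame(x = runif(n, 0, box), y = runif(n, 0, box),
                      z = runif(n, 0, box))
  classes <- lapply(seq_len(n), function(i) {
    sample(pharmacophore_classes(), sample(1:3, 1))
  })
  list(atoms = atoms, classes = classes)
}

# Brute-force O(n^2) oracle: loop every unordered atom pair and every class
# combination explicitly. Kept independent of the package's counting path.
oracle_pair_counts <- function(atoms, classes, cutoffs) {
  feat <- signature_feature_names(cutoffs)
  counts <- setNames(integer(length(feat)), feat)
  n <- nrow(atoms)
  if (n < 2) return(counts)
  short <- setNames(names(pharmacophore_classes()), pharmacophore_classes())
  cls_short <- lapply(classes, function(cl) unname(short[cl]))
  for (i in seq_len(n - 1)) {
    ci <- cls_short[[i]]
    for (j in (i + 1):n) {
      d <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
                  (atoms$z[i] - atoms$z[j])^2)
      hit <- cutoffs[d <= cutoffs]
      if (!length(hit)) next
      seen <- character(0)
      for (a in ci) for (b in cls_short[[j]]) {
        nm <- if (a <= b) paste0(a, ":", b) else paste0(b, ":", a)
        if (nm %in% seen) next
        seen <- c(seen, nm)
        keys <- sprintf("%s-%.2f", nm, hit)
        counts[keys] <- counts[keys] + 1L
      }
    }
  }
  counts
}

# Rigid motion: fixed rotation about an arbitrary axis plus translation.
apply_rigid_motion <- function(atoms, seed = 1) {
  set.seed(seed)
  ang <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]), 0, sin(ang[1]), cos(ang[1])), 3, byrow = TRUE)
  Ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0, -sin(ang[2]), 0, cos(ang[2])), 3, byrow = TRUE)
  Rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0, sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, byrow = TRUE)
  R <- Rx %*% Ry %*% Rz
  tr <- runif(3, -20, 20)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + tr[1]
  atoms$y <- xyz[, 2] + tr[2]
  atoms$z <- xyz[, 3] + tr[3]
  atoms
}

# Small shared bundle + feature matrix, computed once per test session.
shared_env <- new.env()

shared_small_fm <- function() {
  if (is.null(shared_env$fm)) {
    b <- make_helical_bundle(bundle_spec(n_helices = 3, residues_per_helix = 12,
                                         helix_spacing = 5.5, seed = 11))
    muts <- make_mutation_table(b, 40, seed = 11)
    shared_env$bundle <- b
    shared_env$muts <- muts
    shared_env$fm <- featurize(muts, setNames(list(b), muts$uniprot_id[1]))
  }
  shared_env
}
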