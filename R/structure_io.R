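# PDB ingestion and the preprocessing applied before feature extraction:
# keep one chain of standard amino-acid residues, drop waters, ligands,
# other chains and hydrogens. Author numbering is used verbatim.

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

new_structure <- function(atoms, id) {
  structure(list(id = id, atoms = atoms), class = "gs_structure")
}

#' @export
print.gs_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<gs_structure> '%s': %d atoms, %d residues, chains: %s\n",
              x$id, nrow(a),
              length(unique(paste(a$chain, a$res_seq, a$ins))),
              paste(sort(unique(a$chain)), collapse = ",")))
  invisible(x)
}

infer_element <- function(name) {
  # PDB element column may be absent in hand-made files; fall back to the
  # first alphabetic character of the atom name (adequate for protein atoms).
  el <- sub("^[0-9']*", "", name)
  substr(el, 1L, 1L)
}

#' Load a structure from a PDB file
#'
#' Reads all ATOM and HETATM records of a PDB file into an atom table.
#' No filtering is performed at load time (waters and ligands are retained);
#' see [clean_structure()] for preprocessing. Alternate locations are
#' resolved to the highest-occupancy record, ties broken by altloc label
#' order, so each (chain, residue, atom name) appears once.
#'
#' @param path Path to a PDB file.
#' @param id Structure label; defaults to the filename stem.
#' @return A `gs_structure`: a list with `id` and an `atoms` data frame
#'   (`serial`, `name`, `element`, `res_name`, `res_seq`, `ins`, `chain`,
#'   `x`, `y`, `z`).
#' @export
load_structure <- function(path, id = NULL) {
  if (!file.exists(path)) {
    gs_error("gs_format_error", sprintf("file '%s' does not exist", path))
  }
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) gs_error("gs_format_error",
                                 sprintf("cannot parse PDB file '%s': %s",
                                         path, conditionMessage(e))))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) {
    gs_error("gs_empty_structure_error", sprintf("no atoms in '%s'", path))
  }
  xyz <- cbind(a$x, a$y, a$z)
  if (any(!is.finite(xyz))) {
    gs_error("gs_format_error",
             sprintf("non-finite coordinates in '%s' (truncated or malformed records)", path))
  }
  el <- a$elesy
  miss <- is.na(el) | el == ""
  el[miss] <- infer_element(a$elety[miss])
  atoms <- data.frame(
    serial   = a$eleno,
    name     = a$elety,
    alt      = ifelse(is.na(a$alt), "", a$alt),
    occ      = ifelse(is.na(a$o), 1, a$o),
    element  = toupper(el),
    res_name = a$resid,
    res_seq  = a$resno,
    ins      = ifelse(is.na(a$insert), "", a$insert),
    chain    = ifelse(is.na(a$chain), " ", a$chain),
    x = a$x, y = a$y, z = a$z,
    stringsAsFactors = FALSE)
  atoms <- resolve_altloc(atoms)
  atoms$alt <- NULL
  atoms$occ <- NULL
  rownames(atoms) <- NULL
  new_structure(atoms, id)
}

resolve_altloc <- function(atoms) {
  if (all(atoms$alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$res_seq, atoms$ins, atoms$res_name, atoms$name)
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[atoms$alt != ""])) {
    i <- which(key == k)
    if (length(i) < 2L) next
    # highest occupancy wins; ties by altloc label order ('' sorts first)
    ord <- order(-atoms$occ[i], atoms$alt[i])
    keep[i[-ord[1L]]] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

#' Clean a structure for feature extraction
#'
#' Applies the standard preprocessing: retain only standard amino-acid
#' residues of one chain; remove waters, ligands, other chains and
#' hydrogen/deuterium atoms. Atom order is preserved. Idempotent.
#'
#' @param s A `gs_structure` from [load_structure()].
#' @param chain Chain identifier to keep.
#' @return A cleaned `gs_structure` containing a single chain.
#' @export
clean_structure <- function(s, chain) {
  stopifnot(inherits(s, "gs_structure"))
  a <- s$atoms
  if (!chain %in% a$chain) {
    gs_error("gs_missing_chain_error",
             sprintf("chain '%s' not present in structure '%s' (chains: %s)",
                     chain, s$id, paste(sort(unique(a$chain)), collapse = ",")))
  }
  keep <- a$chain == chain &
    a$res_name %in% names(aa_three_to_one()) &
    !a$res_name %in% WATER_NAMES &
    !a$element %in% c("H", "D")
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L) {
    gs_error("gs_empty_structure_error",
             sprintf("no standard amino-acid atoms survive cleaning of chain '%s' in '%s'",
                     chain, s$id))
  }
  rownames(a) <- NULL
  new_structure(a, s$id)
}

# Atom rows of one residue (author numbering, optional insertion code).
residue_atoms <- function(s, chain, res_seq, ins = "") {
  a <- s$atoms
  a[a$chain == chain & a$res_seq == res_seq & a$ins == ins, , drop = FALSE]
}

# Unweighted mean of the residue's heavy-atom coordinates.
residue_center <- function(res) {
  c(mean(res$x), mean(res$y), mean(res$z))
}

#' List residues of a structure
#'
#' @param s A `gs_structure`.
#' @return Data frame with one row per residue: `chain`, `res_seq`, `ins`,
#'   `res_name`, in atom order.
#' @export
structure_residues <- function(s) {
  a <- s$atoms
  key <- paste(a$chain, a$res_seq, a$ins, sep = "\r")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], res_seq = a$res_seq[first],
             ins = a$ins[first], res_name = a$res_name[first],
             stringsAsFactors = FALSE)
}

check_wildtype <- function(s, chain, position, wt_aa) {
  res <- residue_atoms(s, chain, position)
  if (nrow(res) == 0L) {
    gs_error("gs_missing_residue_error",
             sprintf("residue %s%d not found in structure '%s'", chain, position, s$id))
  }
  found3 <- res$res_name[1L]
  found1 <- unname(aa_three_to_one()[found3])
  if (!is.null(wt_aa) && !is.na(wt_aa)) {
    check_aa1(wt_aa, "wt_aa")
    if (is.na(found1) || found1 != wt_aa) {
      gs_error("gs_wildtype_mismatch_error",
               sprintf("wild-type mismatch at %s%d: expected %s, found %s (%s)",
                       chain, position, wt_aa,
                       ifelse(is.na(found1), "?", found1), found3))
    }
  }
  res
}

#' Extract the structural environment of a mutation site
#'
#' Returns every heavy atom of `s` whose Euclidean distance to the
#' wild-type residue's geometric centre (unweighted mean over all of the
#' residue's heavy atoms) is at most `radius`, including the residue's own
#' atoms. The wild-type identity is verified against `wt_aa` when given.
#'
#' @param s A cleaned `gs_structure`.
#' @param chain Chain identifier of the mutated residue.
#' @param position Author residue number of the mutated residue.
#' @param wt_aa 1-letter wild-type code to verify, or `NULL` to skip the check.
#' @param radius Environment radius in Angstrom.
#' @return Data frame of atoms (same columns as `s$atoms`) within the sphere.
#' @export
residue_environment <- function(s, chain, position, wt_aa = NULL, radius = 10) {
  stopifnot(inherits(s, "gs_structure"), radius >= 0)
  res <- check_wildtype(s, chain, position, wt_aa)
  ctr <- residue_center(res)
  a <- s$atoms
  d2 <- (a$x - ctr[1])^2 + (a$y - ctr[2])^2 + (a$z - ctr[3])^2
  out <- a[d2 <= radius^2 + 1e-12, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a structure to a PDB file
#'
#' Writes the atom table as fixed-column ATOM records so synthetic
#' structures round-trip through the same loader as experimental models.
#'
#' @param s A `gs_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  stopifnot(inherits(s, "gs_structure"))
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(cbind(a$x, a$y, a$z))),
                   type = rep("ATOM", nrow(a)),
                   eleno = a$serial, elety = a$name,
                   resid = a$res_name, chain = a$chain, resno = a$res_seq,
                   insert = ifelse(a$ins == "", NA, a$ins),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}
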