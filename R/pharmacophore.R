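# Pharmacophore typing of protein heavy atoms. Every heavy atom of a
# standard residue carries one or more of eight coarse physicochemical
# classes; the shipped table encodes canonical amino-acid chemistry and is
# keyed exactly on (res_name, atom_name).

#' The eight pharmacophore classes
#'
#' @return Character vector of the eight class names in canonical order,
#'   with the short labels used in feature names as vector names.
#' @export
pharmacophore_classes <- function() {
  c(Acc = "acceptor", Aro = "aromatic", Don = "donor",
    Hydro = "hydrophobic", Neg = "negative", Neu = "neutral",
    Pos = "positive", Sul = "sulfur")
}

class_short <- function(classes) {
  pc <- pharmacophore_classes()
  stats::setNames(names(pc), unname(pc))[classes]
}

#' Load the packaged pharmacophore table
#'
#' Reads the versioned (res_name, atom_name) to class-set assignment table
#' shipped with the package. Entries may be multi-label (an aromatic ring
#' carbon is also hydrophobic). `SC` rows describe the single side-chain
#' pseudo-atoms used by the synthetic bundle generator and are excluded,
#' together with the terminal `OXT`, from residue template tallies.
#'
#' @param path Optional path to an alternative table with the same schema.
#' @return Data frame with columns `res_name`, `atom_name` and a list column
#'   `classes` of character vectors, plus a fast lookup environment in
#'   attribute `"index"`.
#' @export
pharmacophore_table <- function(path = NULL) {
  if (is.null(path)) path <- gs_extdata("pharmacophore_atoms.csv")
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  tab$classes <- strsplit(tab$classes, ";", fixed = TRUE)
  bad <- !vapply(tab$classes, function(cl) all(cl %in% pharmacophore_classes()), TRUE)
  if (any(bad)) {
    gs_error("gs_data_error",
             sprintf("unknown pharmacophore class in table rows: %s",
                     paste(which(bad), collapse = ",")))
  }
  idx <- new.env(parent = emptyenv(), size = nrow(tab))
  for (i in seq_len(nrow(tab))) {
    assign(paste0(tab$res_name[i], "|", tab$atom_name[i]), tab$classes[[i]], envir = idx)
  }
  attr(tab, "index") <- idx
  tab
}

table_index <- function(table) {
  idx <- attr(table, "index")
  if (is.null(idx)) gs_error("gs_data_error", "pharmacophore table lacks its lookup index")
  idx
}

#' Assign pharmacophore classes to atoms
#'
#' Exact lookup on (res_name, atom_name). Atoms absent from the table fall
#' back to the single class `neutral` and raise a warning, so one unusual
#' atom does not abort a whole run.
#'
#' @param atoms Data frame with `res_name` and `name` columns (e.g. the
#'   output of [residue_environment()]).
#' @param table A [pharmacophore_table()].
#' @return List of character vectors, one class set per atom row.
#' @export
assign_pharmacophores <- function(atoms, table = pharmacophore_table()) {
  idx <- table_index(table)
  keys <- paste0(atoms$res_name, "|", atoms$name)
  out <- vector("list", length(keys))
  unknown <- character(0)
  for (i in seq_along(keys)) {
    cl <- get0(keys[i], envir = idx, inherits = FALSE)
    if (is.null(cl)) {
      unknown <- c(unknown, keys[i])
      cl <- "neutral"
    }
    out[[i]] <- cl
  }
  if (length(unknown)) {
    gs_warn("gs_unknown_atom_warning",
            sprintf("%d atom(s) not in pharmacophore table, assigned 'neutral': %s",
                    length(unknown), paste(unique(unknown), collapse = ", ")))
  }
  out
}

# Canonical heavy-atom template rows of one residue (no SC pseudo-atom, no
# terminal OXT).
residue_template <- function(res3, table) {
  rows <- table[table$res_name == res3 & !table$atom_name %in% c("SC", "OXT"), , drop = FALSE]
  if (nrow(rows) == 0L) {
    gs_error("gs_invalid_residue_error", sprintf("no template entries for residue '%s'", res3))
  }
  rows
}

#' Residue pharmacophore frequency vector
#'
#' Tallies (heavy atom, class) memberships over the canonical heavy atoms
#' (backbone and side chain) of a residue type. Component order follows
#' [pharmacophore_classes()].
#'
#' @param aa 1-letter code of a standard amino acid.
#' @param table A [pharmacophore_table()].
#' @return Named integer 8-vector of class multiplicities.
#' @export
residue_pharmacophore_vector <- function(aa, table = pharmacophore_table()) {
  check_aa1(aa)
  res3 <- aa_one_to_three()[[aa]]
  rows <- residue_template(res3, table)
  tally <- table(factor(unlist(rows$classes), levels = pharmacophore_classes()))
  stats::setNames(as.integer(tally), pharmacophore_classes())
}

#' Pharmacophore change vector of a mutation
#'
#' Componentwise difference between the mutant and wild-type residue
#' pharmacophore frequency vectors (mutant minus wild type). This is the
#' only representation of the mutant side: no mutant structure is built.
#'
#' @param wt,mt 1-letter codes of the wild-type and mutant residues.
#' @param table A [pharmacophore_table()].
#' @return Named integer 8-vector.
#' @export
pchange <- function(wt, mt, table = pharmacophore_table()) {
  residue_pharmacophore_vector(mt, table) - residue_pharmacophore_vector(wt, table)
}
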