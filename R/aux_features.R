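# Auxiliary (non-signature) features: substitution-matrix scores, AAindex2
# pair-matrix scores, relative solvent accessibility, residue depth,
# membrane topology flags and residue identity indicators.

subst_matrix_env <- new.env(parent = emptyenv())

get_subst_matrix <- function(name) {
  if (!name %in% c("BLOSUM62", "PAM30")) {
    gs_error("gs_config_error", sprintf("unknown substitution matrix '%s'", name))
  }
  if (is.null(subst_matrix_env[[name]])) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      gs_error("gs_data_error", "package 'Biostrings' is required for substitution matrices")
    }
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    m <- e[[name]]
    aa <- aa_standard1()
    subst_matrix_env[[name]] <- m[aa, aa]
  }
  subst_matrix_env[[name]]
}

#' Substitution-matrix scores for a mutation
#'
#' Exact lookups of the (wild type, mutant) pair in the named standard
#' scoring matrices (symmetric, so orientation does not matter).
#'
#' @param wt,mt 1-letter codes.
#' @param matrices Matrix names (`"BLOSUM62"`, `"PAM30"`).
#' @return Named numeric vector, one value per matrix.
#' @export
substitution_scores <- function(wt, mt, matrices = c("BLOSUM62", "PAM30")) {
  check_aa1(wt, "wt"); check_aa1(mt, "mt")
  vapply(matrices, function(nm) {
    m <- get_subst_matrix(nm)
    v <- m[wt, mt]
    if (is.na(v)) gs_error("gs_data_error",
                           sprintf("pair (%s,%s) missing from %s", wt, mt, nm))
    as.numeric(v)
  }, numeric(1))
}

#' Parse an AAindex2-dialect flat file
#'
#' Reads entries of the AAindex2 matrix dialect: an `H` accession line, an
#' `M rows = ..., cols = ...` header, then the lower-triangular (or full)
#' numeric rows, terminated by `//`. Lower triangles are reflected into full
#' symmetric matrices.
#'
#' @param paths Character vector of flat-file paths. Defaults to the files
#'   packaged under `extdata` (the genetic-code matrix BENS940104 and a
#'   synthetic helix-class table HELX_SYN01).
#' @return Named list of 20x20 numeric matrices with 1-letter dimnames.
#' @export
read_aaindex2 <- function(paths = NULL) {
  if (is.null(paths)) {
    paths <- c(gs_extdata("aaindex2_bens940104.txt"),
               gs_extdata("aaindex2_helix_synthetic.txt"))
  }
  out <- list()
  for (path in paths) {
    lines <- readLines(path)
    acc <- NULL; rows_alpha <- NULL; vals <- list()
    flush_entry <- function() {
      if (is.null(acc)) return()
      n <- length(rows_alpha)
      m <- matrix(NA_real_, n, n, dimnames = list(rows_alpha, rows_alpha))
      for (i in seq_along(vals)) {
        v <- vals[[i]]
        if (length(v) == i) {            # lower triangle row
          m[i, seq_len(i)] <- v
        } else if (length(v) == n) {     # full row
          m[i, ] <- v
        } else {
          gs_error("gs_data_error",
                   sprintf("entry %s: row %d has %d values (expected %d or %d)",
                           acc, i, length(v), i, n))
        }
      }
      low <- is.na(m) & !is.na(t(m))
      m[low] <- t(m)[low]
      if (any(is.na(m))) {
        gs_error("gs_data_error", sprintf("entry %s: incomplete matrix", acc))
      }
      out[[acc]] <<- m
    }
    for (ln in lines) {
      tag <- substr(ln, 1L, 1L)
      if (tag == "H") {
        acc <- trimws(substr(ln, 2L, nchar(ln)))
      } else if (tag == "M") {
        spec <- sub("^M\\s*", "", ln)
        rows <- sub(".*rows\\s*=\\s*([A-Z]+).*", "\\1", spec)
        rows_alpha <- strsplit(rows, "")[[1]]
        vals <- list()
      } else if (grepl("^//", ln)) {
        flush_entry()
        acc <- NULL; rows_alpha <- NULL; vals <- list()
      } else if (!is.null(rows_alpha) && grepl("^\\s+[-0-9]", ln)) {
        vals[[length(vals) + 1L]] <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
      }
    }
  }
  out
}

aaindex_db_env <- new.env(parent = emptyenv())

packaged_aaindex <- function() {
  if (is.null(aaindex_db_env$db)) aaindex_db_env$db <- read_aaindex2()
  aaindex_db_env$db
}

#' AAindex2 pair-matrix scores for a mutation
#'
#' @param wt,mt 1-letter codes.
#' @param ids AAindex2 accessions present in the packaged (or supplied)
#'   database.
#' @param db Database from [read_aaindex2()]; defaults to the packaged one.
#' @return Named numeric vector, one value per accession.
#' @export
aaindex_scores <- function(wt, mt, ids = gs_config()$aaindex_ids, db = NULL) {
  check_aa1(wt, "wt"); check_aa1(mt, "mt")
  if (is.null(db)) db <- packaged_aaindex()
  vapply(ids, function(id) {
    m <- db[[id]]
    if (is.null(m)) gs_error("gs_data_error", sprintf("AAindex entry '%s' not packaged", id))
    v <- m[wt, mt]
    if (is.na(v)) gs_error("gs_data_error",
                           sprintf("pair (%s,%s) missing from %s", wt, mt, id))
    as.numeric(v)
  }, numeric(1))
}

#' Residue identity indicator features
#'
#' Binary flags for substitutions the stability literature singles out:
#' loss of proline or glycine (backbone flexibility) and mutation to
#' alanine or proline.
#'
#' @param wt,mt 1-letter codes.
#' @return Named 0/1 integer vector: `FromPro`, `ToAla`, `FromGly`, `ToPro`.
#' @export
identity_flags <- function(wt, mt) {
  check_aa1(wt, "wt"); check_aa1(mt, "mt")
  c(FromPro = as.integer(wt == "P"), ToAla = as.integer(mt == "A"),
    FromGly = as.integer(wt == "G"), ToPro = as.integer(mt == "P"))
}

#' Membrane topology flags for a residue
#'
#' Two modes. With an annotation table (columns `chain`, `res_seq`, `mem`,
#' `non_cytosol`) flags are read verbatim. Without one, the structure is
#' assumed membrane-oriented with the membrane normal along z and the
#' extracellular side up: `mem = 1` iff the residue's geometric centre has
#' `|z| <= half_width`, `non_cytosol = 1` iff `z >= -half_width`.
#'
#' @param s A cleaned `gs_structure`.
#' @param chain,position Residue identifier.
#' @param annotation Optional annotation data frame.
#' @param half_width Slab half-width in Angstrom (z-slab mode).
#' @return Named integer vector `c(mem =, non_cytosol =)`.
#' @export
topology_flags <- function(s, chain, position, annotation = NULL, half_width = 15) {
  if (!is.null(annotation)) {
    need <- c("chain", "res_seq", "mem", "non_cytosol")
    if (!all(need %in% names(annotation))) {
      gs_error("gs_config_error",
               "topology annotation needs columns chain, res_seq, mem, non_cytosol")
    }
    i <- which(annotation$chain == chain & annotation$res_seq == position)
    if (length(i) != 1L) {
      gs_error("gs_config_error",
               sprintf("no (or ambiguous) topology annotation for %s%d", chain, position))
    }
    return(c(mem = as.integer(annotation$mem[i]),
             non_cytosol = as.integer(annotation$non_cytosol[i])))
  }
  res <- residue_atoms(s, chain, position)
  if (nrow(res) == 0L) {
    gs_error("gs_missing_residue_error",
             sprintf("residue %s%d not found in structure '%s'", chain, position, s$id))
  }
  z <- residue_center(res)[3]
  c(mem = as.integer(abs(z) <= half_width),
    non_cytosol = as.integer(z >= -half_width))
}

# --- Solvent accessibility (Shrake-Rupley) and residue depth ---------------

vdw_radius <- function(element) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  out <- unname(r[element])
  out[is.na(out)] <- 1.70
  out
}

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(k) {
  i <- seq_len(k) - 0.5
  phi <- acos(1 - 2 * i / k)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

# Shrake-Rupley SASA for every atom; also returns the exposed test points,
# which sample the solvent-accessible surface and are reused for depth.
shrake_rupley <- function(atoms, probe = 1.4, n_points = 100L) {
  n <- nrow(atoms)
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  rad <- vdw_radius(atoms$element) + probe
  pts <- sphere_points(n_points)
  d2 <- as.matrix(stats::dist(xyz))^2
  area <- numeric(n)
  surf <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    p <- sweep(pts * rad[i], 2L, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj >= rad[j]^2
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(exposed) / n_points
    if (any(exposed)) surf[[i]] <- p[exposed, , drop = FALSE]
  }
  list(area = area, surface = do.call(rbind, surf))
}

sasa_cache <- new.env(parent = emptyenv())

structure_sasa <- function(s, probe = 1.4, n_points = 100L) {
  key <- paste0(s$id, "|", nrow(s$atoms), "|", probe, "|", n_points, "|",
                sum(s$atoms$x) + sum(s$atoms$z))
  hit <- get0(key, envir = sasa_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  res <- shrake_rupley(s$atoms, probe, n_points)
  assign(key, res, envir = sasa_cache)
  res
}

max_sasa_table <- function() {
  tab <- utils::read.csv(gs_extdata("max_sasa.csv"), comment.char = "#",
                         stringsAsFactors = FALSE)
  stats::setNames(tab$max_sasa, tab$res_name)
}

#' Relative solvent accessibility of a residue
#'
#' Shrake-Rupley solvent-accessible surface area of the residue (1.4 A
#' probe, deterministic golden-spiral sampling) divided by the packaged
#' per-residue-type maximum reference area. Values slightly above 1 can
#' occur for exposed termini.
#'
#' @param s A cleaned `gs_structure`.
#' @param chain,position Residue identifier.
#' @param probe Probe radius in Angstrom.
#' @param n_points Sphere sample points per atom.
#' @return RSA fraction (typically in 0..1.2).
#' @export
relative_solvent_accessibility <- function(s, chain, position,
                                           probe = 1.4, n_points = 100L) {
  res <- residue_atoms(s, chain, position)
  if (nrow(res) == 0L) {
    gs_error("gs_missing_residue_error",
             sprintf("residue %s%d not found in structure '%s'", chain, position, s$id))
  }
  sr <- structure_sasa(s, probe, n_points)
  idx <- which(s$atoms$chain == chain & s$atoms$res_seq == position)
  ref <- max_sasa_table()[res$res_name[1L]]
  if (is.na(ref)) {
    gs_error("gs_feature_error",
             sprintf("no max-SASA reference for residue type '%s'", res$res_name[1L]))
  }
  sum(sr$area[idx]) / unname(ref)
}

#' Residue depth
#'
#' Mean distance of the residue's heavy atoms to the solvent-accessible
#' molecular surface, the latter sampled by the exposed Shrake-Rupley test
#' points of the whole structure.
#'
#' @inheritParams relative_solvent_accessibility
#' @return Depth in Angstrom (>= 0).
#' @export
residue_depth <- function(s, chain, position, probe = 1.4, n_points = 100L) {
  res <- residue_atoms(s, chain, position)
  if (nrow(res) == 0L) {
    gs_error("gs_missing_residue_error",
             sprintf("residue %s%d not found in structure '%s'", chain, position, s$id))
  }
  sr <- structure_sasa(s, probe, n_points)
  if (is.null(sr$surface) || nrow(sr$surface) == 0L) {
    gs_error("gs_feature_error",
             sprintf("degenerate geometry: no solvent-accessible surface for '%s'", s$id))
  }
  dmin <- vapply(seq_len(nrow(res)), function(i) {
    dx <- sr$surface[, 1] - res$x[i]
    dy <- sr$surface[, 2] - res$y[i]
    dz <- sr$surface[, 3] - res$z[i]
    sqrt(min(dx * dx + dy * dy + dz * dz))
  }, numeric(1))
  mean(dmin)
}
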