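# Mutation-table ingestion, deduplication, train/test splitting and
# featurisation into a model-ready matrix.

MUTATION_COLS <- c("uniprot_id", "chain", "position", "wt_aa", "mt_aa", "dTm", "source")

#' Read a mutation table
#'
#' CSV schema: `uniprot_id, chain, position, wt_aa, mt_aa, dTm, source`;
#' `dTm` (degrees C) may be missing for prediction-only records.
#'
#' @param path CSV file path.
#' @return Data frame of validated mutation records.
#' @export
read_mutation_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(setdiff(MUTATION_COLS, c("dTm", "source")), names(tab))
  if (length(miss)) {
    gs_error("gs_format_error",
             sprintf("mutation table '%s' lacks columns: %s", path, paste(miss, collapse = ",")))
  }
  if (is.null(tab$dTm)) tab$dTm <- NA_real_
  if (is.null(tab$source)) tab$source <- basename(path)
  validate_mutation_records(tab)
}

validate_mutation_records <- function(tab, allow_identity = FALSE) {
  if (any(tab$position < 1L)) {
    gs_error("gs_format_error", "mutation positions must be >= 1")
  }
  ok <- tab$wt_aa %in% aa_standard1() & tab$mt_aa %in% aa_standard1()
  if (!all(ok)) {
    gs_error("gs_format_error",
             sprintf("non-standard residue codes in rows: %s",
                     paste(which(!ok), collapse = ",")))
  }
  if (!allow_identity && any(tab$wt_aa == tab$mt_aa)) {
    gs_error("gs_format_error",
             sprintf("identity mutations in rows: %s",
                     paste(which(tab$wt_aa == tab$mt_aa), collapse = ",")))
  }
  tab[MUTATION_COLS]
}

#' Merge mutation tables and remove redundant records
#'
#' Records are redundant when they share (uniprot_id, position, mt_aa) --
#' same protein, same site, mutated to the same residue. The first-listed
#' record wins and output order is first-occurrence order. Records agreeing
#' on the key but disagreeing on the wild-type residue indicate corrupt
#' input and raise an error.
#'
#' @param tables A list of mutation record data frames (or a single one).
#' @return Deduplicated data frame.
#' @export
merge_and_deduplicate <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  all_tab <- do.call(rbind, tables)
  key <- paste(all_tab$uniprot_id, all_tab$position, all_tab$mt_aa, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    wts <- unique(all_tab$wt_aa[key == k])
    if (length(wts) > 1L) {
      parts <- strsplit(k, "\r")[[1]]
      gs_error("gs_data_conflict_error",
               sprintf("conflicting wild-type residues (%s) for %s position %s -> %s",
                       paste(wts, collapse = " vs "), parts[1], parts[2], parts[3]))
    }
  }
  out <- all_tab[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Random blind split of mutation records
#'
#' Uniform random split without replacement at the mutation level:
#' `round(fraction * n)` records form the test set, the rest the training
#' set. Receptors may be shared between the sides; mutations never are.
#'
#' @param records Mutation record data frame.
#' @param fraction Test fraction in (0, 1).
#' @param seed Integer seed; the split is a pure function of
#'   (records, fraction, seed).
#' @return List with elements `train` and `test`.
#' @export
blind_split <- function(records, fraction = 0.13, seed = 42L) {
  n <- nrow(records)
  if (n < 2L) gs_error("gs_insufficient_data_error", "need at least 2 records to split")
  if (fraction <= 0 || fraction >= 1) {
    gs_error("gs_config_error", "fraction must be in (0, 1)")
  }
  n_test <- round(fraction * n)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  idx <- sample.int(n, n_test)
  list(train = records[setdiff(seq_len(n), idx), , drop = FALSE],
       test  = records[sort(idx), , drop = FALSE])
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

aux_feature_names <- function(config) {
  c(config$matrices, config$aaindex_ids, "RSA", "depth",
    "mem", "non_cytosol", "FromPro", "ToAla", "FromGly", "ToPro")
}

#' All feature names for a configuration
#'
#' @param config A [gs_config()].
#' @return Character vector: signature counts, PChange components, auxiliary
#'   features, in the fixed order used by [featurize()].
#' @export
feature_names <- function(config = gs_config()) {
  c(signature_feature_names(config$cutoffs),
    paste0("PChange.", names(pharmacophore_classes())),
    aux_feature_names(config))
}

featurize_one <- function(rec, s, config, table, annotation) {
  sig <- mutation_signature(s, rec$chain, rec$position, rec$wt_aa, rec$mt_aa,
                            config, table)
  subs <- substitution_scores(rec$wt_aa, rec$mt_aa, config$matrices)
  aai <- aaindex_scores(rec$wt_aa, rec$mt_aa, config$aaindex_ids)
  rsa <- relative_solvent_accessibility(s, rec$chain, rec$position)
  dep <- residue_depth(s, rec$chain, rec$position)
  topo <- topology_flags(s, rec$chain, rec$position, annotation,
                         config$membrane_half_width)
  idf <- identity_flags(rec$wt_aa, rec$mt_aa)
  c(sig, subs, aai, RSA = unname(rsa), depth = unname(dep), topo, idf)
}

#' Featurise mutation records against structures
#'
#' Computes, for every record, the graph-based signature of its wild-type
#' residue environment, the pharmacophore change vector and all auxiliary
#' features, producing a rectangular feature matrix aligned with the
#' records. Featurisation is pure: identical inputs give identical output.
#'
#' @param records Mutation record data frame.
#' @param structures Named list mapping `uniprot_id` to cleaned
#'   `gs_structure` objects.
#' @param config A [gs_config()].
#' @param annotation Optional topology annotation table (see
#'   [topology_flags()]).
#' @param strict If `TRUE` (default) any per-record failure aborts the run;
#'   if `FALSE` failing records are dropped with a warning.
#' @return List of class `gs_feature_matrix`: `x` (numeric matrix), `records`
#'   (the featurised records), `labels` (dTm vector), `feature_names`, and a
#'   `report` data frame (record key, status, message).
#' @export
featurize <- function(records, structures, config = gs_config(),
                      annotation = NULL, strict = TRUE) {
  table <- pharmacophore_table()
  fn <- feature_names(config)
  n <- nrow(records)
  x <- matrix(NA_real_, n, length(fn), dimnames = list(NULL, fn))
  status <- character(n); msg <- character(n)
  for (i in seq_len(n)) {
    rec <- records[i, ]
    s <- structures[[rec$uniprot_id]]
    row <- tryCatch({
      if (is.null(s)) gs_error("gs_config_error",
                               sprintf("no structure for receptor '%s'", rec$uniprot_id))
      featurize_one(rec, s, config, table, annotation)
    }, gs_error = function(e) e)
    if (inherits(row, "gs_error")) {
      status[i] <- "error"; msg[i] <- conditionMessage(row)
    } else {
      stopifnot(identical(names(row), fn))
      x[i, ] <- row
      status[i] <- "ok"; msg[i] <- ""
    }
  }
  report <- data.frame(
    key = paste0(records$uniprot_id, ":", records$wt_aa, records$position, records$mt_aa),
    status = status, message = msg, stringsAsFactors = FALSE)
  failed <- status != "ok"
  if (any(failed)) {
    if (strict) {
      gs_error("gs_featurize_error",
               sprintf("%d record(s) failed featurisation (strict mode): %s",
                       sum(failed),
                       paste(utils::head(report$key[failed], 5), collapse = ", ")))
    }
    gs_warn("gs_featurize_warning",
            sprintf("dropping %d record(s) that failed featurisation", sum(failed)))
    x <- x[!failed, , drop = FALSE]
    records <- records[!failed, , drop = FALSE]
  }
  structure(list(x = x, records = records, labels = records$dTm,
                 feature_names = fn, report = report),
            class = "gs_feature_matrix")
}

#' @export
print.gs_feature_matrix <- function(x, ...) {
  cat(sprintf("<gs_feature_matrix> %d mutations x %d features (%d labelled)\n",
              nrow(x$x), ncol(x$x), sum(!is.na(x$labels))))
  invisible(x)
}
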