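#' @keywords internal
"_PACKAGE"

# Classed conditions so callers/tests can discriminate failure modes.
gs_error <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "gs_error"), call = call))
}

gs_warn <- function(class, msg) {
  warning(warningCondition(msg, class = c(class, "gs_warning")))
}

#' Amino-acid code tables
#'
#' Mapping between 3-letter and 1-letter codes for the 20 standard amino
#' acids, in alphabetical 3-letter order.
#'
#' @return `aa_three_to_one()` returns a named character vector mapping
#'   3-letter codes to 1-letter codes; `aa_one_to_three()` the inverse.
#' @export
aa_three_to_one <- function() {
  c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
    GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
    LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
    SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
}

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function() {
  m <- aa_three_to_one()
  stats::setNames(names(m), unname(m))
}

aa_standard1 <- function() unname(aa_three_to_one())

check_aa1 <- function(aa, arg = "aa") {
  if (!is.character(aa) || length(aa) != 1L || !aa %in% aa_standard1()) {
    gs_error("gs_invalid_residue_error",
             sprintf("'%s' must be one of the 20 standard 1-letter codes, got '%s'",
                     arg, paste(aa, collapse = ",")))
  }
  invisible(aa)
}

# File path of a packaged data file.
gs_extdata <- function(file) {
  p <- system.file("extdata", file, package = "gpcrstab")
  if (p == "") gs_error("gs_data_error", sprintf("packaged data file '%s' not found", file))
  p
}
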