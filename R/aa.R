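#' @keywords internal
"_PACKAGE"

# Canonical amino-acid code tables used across the package.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
names(AA1) <- AA3
AA3_FROM_1 <- stats::setNames(AA3, AA1)

#' Convert 3-letter residue codes to 1-letter codes
#'
#' @param codes character vector of 3-letter codes.
#' @return character vector of 1-letter codes; unknown codes become `"X"`.
#' @keywords internal
aa3to1 <- function(codes) {
  out <- AA1[toupper(codes)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Convert 1-letter residue codes to 3-letter codes
#' @param letters character vector of single letters.
#' @return 3-letter codes; errors on unknown letters.
#' @keywords internal
aa1to3 <- function(letters) {
  out <- AA3_FROM_1[toupper(letters)]
  if (anyNA(out)) {
    stop("invalid amino-acid letter(s): ",
         paste(unique(letters[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

is_canonical_aa <- function(codes) toupper(codes) %in% AA3

#' Load the tolerated non-canonical residue substitution table
#'
#' The table maps tolerated modified residues to their canonical parent and
#' the atoms that must be deleted (e.g. phosphoserine loses its phospho
#' group and becomes serine). Users may supply an extended table in the same
#' tab-delimited layout (`code`, `canonical`, `delete_atoms` comma list).
#'
#' @param path path to a TSV table; default the table shipped with the package.
#' @return data.frame with columns `code`, `canonical`, `delete_atoms` (list).
#' @export
load_substitution_table <- function(path = system.file("extdata",
                                      "noncanonical_substitutions.tsv",
                                      package = "anchormod")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("code", "canonical", "delete_atoms") %in% names(tab)))
  tab$delete_atoms <- lapply(strsplit(tab$delete_atoms, ","), trimws)
  tab
}
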