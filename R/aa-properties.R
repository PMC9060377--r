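#' @keywords internal
"_PACKAGE"

# canonical one-letter codes, fixed order
AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.kv <- new.env(parent = emptyenv())

#' Load a per-residue property table
#'
#' Reads a TSV with one row per canonical amino acid and one column per
#' scalar property. The package ships a default table
#' (`system.file("extdata", "aa_properties.tsv", package = "kvarann")`)
#' with hydrophobicity, polarizability, a graph-shape steric parameter,
#' side-chain hydrogen-bond donor/acceptor counts and van der Waals
#' volume; its header documents units and sign conventions. Users may
#' supply their own file with the same layout to substitute scales.
#'
#' @param path Path to a TSV file; `NULL` (default) loads the shipped table.
#' @return A data frame with rownames `A`..`V` (20 canonical residues) and
#'   one numeric column per property.
#' @export
#' @examples
#' tab <- load_property_table()
#' tab["W", "vdw_volume"]
load_property_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_properties.tsv", package = "kvarann")
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"aa" %in% names(tab)) {
    stop("property table must have an 'aa' column")
  }
  missing <- setdiff(AA_CODES, tab$aa)
  if (length(missing)) {
    stop("property table is missing residues: ", paste(missing, collapse = ", "))
  }
  rownames(tab) <- tab$aa
  tab <- tab[AA_CODES, setdiff(names(tab), "aa"), drop = FALSE]
  bad <- !vapply(tab, is.numeric, logical(1))
  if (any(bad)) stop("non-numeric property columns: ",
                     paste(names(tab)[bad], collapse = ", "))
  tab
}

default_property_table <- function() {
  if (is.null(.kv$aa_table)) .kv$aa_table <- load_property_table()
  .kv$aa_table
}

check_aa <- function(aa, what = "residue") {
  aa <- toupper(trimws(aa))
  bad <- !(aa %in% AA_CODES)
  if (any(bad)) {
    stop("unknown ", what, " code: ", paste(unique(aa[bad]), collapse = ", "))
  }
  aa
}

#' Look up a scalar property of an amino acid
#'
#' @param aa One-letter residue code(s) (case-insensitive).
#' @param property Property name, one of the columns of the table (see
#'   [load_property_table()]).
#' @param table A property table as returned by [load_property_table()];
#'   defaults to the shipped table.
#' @return Numeric vector of property values.
#' @export
#' @examples
#' get_property("G", "n_h_donors")
get_property <- function(aa, property, table = default_property_table()) {
  aa <- check_aa(aa)
  if (length(property) != 1L || !property %in% colnames(table)) {
    stop("unknown property: ", paste(property, collapse = ", "),
         " (available: ", paste(colnames(table), collapse = ", "), ")")
  }
  table[aa, property]
}

#' Signed substitution change of an amino-acid property
#'
#' Returns `property(mut) - property(wt)`, the quantity used as a
#' "delta" feature. Antisymmetric in its two residue arguments, and zero
#' for a residue substituted by itself, so non-perturbing variants carry
#' an all-zero delta signature.
#'
#' @inheritParams get_property
#' @param wt_aa,mut_aa One-letter codes of the native and variant residue.
#' @return Numeric vector of signed differences.
#' @export
#' @examples
#' delta_property("G", "W", "vdw_volume") # > 0: Trp is larger than Gly
delta_property <- function(wt_aa, mut_aa, property,
                           table = default_property_table()) {
  get_property(mut_aa, property, table) - get_property(wt_aa, property, table)
}
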