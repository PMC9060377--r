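#' Parse a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Reads the `-out_ascii_pssm` dialect: header lines, then one row per
#' query position carrying the position index, the query (wild-type)
#' residue letter and at least 20 integer log-odds scores in the column
#' order given by the header's residue letters. Only the log-odds block
#' (first 20 score columns) is used; the weighted-percentage block, if
#' present, is ignored.
#'
#' @param path PSSM file.
#' @param source Tag recorded on the matrix (e.g. `"NR"`, `"UniRef50"`).
#' @return A `kv_pssm`: list with `length`, `wt` (letter per position),
#'   `scores` (L x 20 integer matrix, columns named by residue), `source`.
#' @export
parse_pssm <- function(path, source = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  # locate the column-header line: 20+ single residue letters
  is_header <- vapply(lines, function(l) {
    toks <- strsplit(trimws(l), "\\s+")[[1]]
    length(toks) >= 20 && all(nchar(toks) == 1) &&
      all(AA_CODES %in% toupper(toks))
  }, logical(1), USE.NAMES = FALSE)
  h <- which(is_header)[1]
  if (is.na(h)) stop("PSSM parse error: no residue-letter header line found")
  col_aa <- toupper(strsplit(trimws(lines[h]), "\\s+")[[1]][1:20])
  pos <- integer(0); wt <- character(0); rows <- list()
  for (ln in seq(h + 1, length(lines))) {
    l <- trimws(lines[ln])
    if (l == "") break
    toks <- strsplit(l, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", toks[1])) break  # footer (K, Lambda, ...)
    if (length(toks) < 22) {
      stop("PSSM parse error at line ", ln, ": truncated row")
    }
    sc <- suppressWarnings(as.numeric(toks[3:22]))
    if (any(is.na(sc)) || any(sc != round(sc))) {
      stop("PSSM parse error at line ", ln, ": non-integer score")
    }
    pos <- c(pos, as.integer(toks[1]))
    wt <- c(wt, toupper(toks[2]))
    rows[[length(rows) + 1L]] <- as.integer(sc)
  }
  if (!length(rows)) stop("PSSM parse error: no score rows found")
  if (!identical(pos, seq_along(pos))) {
    stop("PSSM parse error: positions not contiguous from 1")
  }
  scores <- do.call(rbind, rows)
  colnames(scores) <- col_aa
  scores <- scores[, AA_CODES, drop = FALSE]
  structure(list(length = length(pos), wt = wt, scores = scores,
                 source = source),
            class = "kv_pssm")
}

#' Write a scoring matrix in PSI-BLAST ASCII format
#'
#' Counterpart of [parse_pssm()], used mainly by the synthetic fixture
#' generator; `parse_pssm(write_pssm(m, f))` recovers `m` exactly.
#'
#' @param pssm A `kv_pssm`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "kv_pssm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position,",
          "and relative weight of gapless real matches to pseudocounts"),
    paste0("            ", paste(sprintf("%3s", AA_CODES), collapse = ""))),
    con)
  for (i in seq_len(pssm$length)) {
    writeLines(sprintf("%5d %s  %s", i, pssm$wt[i],
                       paste(sprintf("%3d", pssm$scores[i, AA_CODES]),
                             collapse = "")), con)
  }
  writeLines("", con)
  invisible(path)
}

#' PSSM substitution score difference of a variant
#'
#' The evolutionary feature: log-odds score of the mutant residue minus
#' that of the wild-type residue at the variant position. Zero for a
#' residue substituted by itself, so non-perturbing variants carry a
#' zero evolutionary signature.
#'
#' @param pssm A `kv_pssm` from [parse_pssm()].
#' @param position 1-based position in the query sequence.
#' @param wt_aa,mut_aa One-letter residue codes; `wt_aa` must match the
#'   matrix's query letter at `position`.
#' @return Signed integer score difference.
#' @export
delta_pssm <- function(pssm, position, wt_aa, mut_aa) {
  stopifnot(inherits(pssm, "kv_pssm"))
  wt_aa <- check_aa(wt_aa); mut_aa <- check_aa(mut_aa)
  if (position < 1 || position > pssm$length) {
    stop("position ", position, " outside PSSM range 1..", pssm$length)
  }
  if (pssm$wt[position] != wt_aa) {
    stop("wild-type mismatch at position ", position, ": PSSM has ",
         pssm$wt[position], ", variant says ", wt_aa)
  }
  as.numeric(pssm$scores[position, mut_aa] - pssm$scores[position, wt_aa])
}
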