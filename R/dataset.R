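PARAMS <- c("iks", "vhalf", "tau_act", "tau_deact")

#' Dysfunction criteria for the four electrophysiological parameters
#'
#' Builds the table of loss-of-function (LOF) and gain-of-function (GOF)
#' bounds, in % of wild type, that classify each functional parameter as
#' dysfunctional. Defaults: peak current density (I_Ks) LOF < 55, GOF >
#' 115; activation V1/2 LOF > 130, GOF < 80; activation time constant
#' LOF > 170, GOF < 70; deactivation time constant LOF < 75, GOF > 125.
#' Inequalities are strict: a value exactly at a bound is normal. A
#' severe loss of peak current (I_Ks at or below `severe_lof_cutoff`,
#' default 17 %WT) cascades: all four parameters are then labeled
#' dysfunctional regardless of their own values.
#'
#' @param tau_act_band Normal band for the activation time constant,
#'   `c(lower, upper)` in %WT. The default 70-170 reflects the observation
#'   that several otherwise wild-type-like variants activate slowly;
#'   `c(80, 120)` restores the narrower band for ablation studies.
#' @param severe_lof_cutoff %WT peak current at or below which all four
#'   parameters are considered dysfunctional.
#' @return A `kv_criteria` object: a data frame with one row per parameter
#'   (`iks`, `vhalf`, `tau_act`, `tau_deact`) and columns `lof_bound`,
#'   `lof_dir` (`"below"`/`"above"`), `gof_bound`, `gof_dir`, plus a
#'   `severe_lof_cutoff` attribute.
#' @export
#' @examples
#' criteria_table()
criteria_table <- function(tau_act_band = c(70, 170), severe_lof_cutoff = 17) {
  stopifnot(length(tau_act_band) == 2, tau_act_band[1] < 100,
            tau_act_band[2] > 100, severe_lof_cutoff > 0)
  crit <- data.frame(
    param     = PARAMS,
    lof_bound = c(55, 130, tau_act_band[2], 75),
    lof_dir   = c("below", "above", "above", "below"),
    gof_bound = c(115, 80, tau_act_band[1], 125),
    gof_dir   = c("above", "below", "below", "above"),
    stringsAsFactors = FALSE
  )
  rownames(crit) <- crit$param
  attr(crit, "severe_lof_cutoff") <- severe_lof_cutoff
  class(crit) <- c("kv_criteria", class(crit))
  crit
}

# strict one-sided test against a bound; NA (unmeasurable) handled by callers
.beyond <- function(value, bound, dir) {
  switch(dir, below = value < bound, above = value > bound,
         stop("bad direction: ", dir))
}

check_record_values <- function(record) {
  vals <- unlist(record[PARAMS], use.names = TRUE)
  if (length(vals) != 4L) stop("record must carry all four parameters")
  if (any(!is.na(vals) & vals < 0)) {
    stop("invalid record: negative measured value in ",
         paste(PARAMS[!is.na(vals) & vals < 0], collapse = ", "))
  }
  vals
}

#' Classify one functional record as normal/dysfunctional per parameter
#'
#' Applies the criteria bounds to the four normalized measurements of a
#' variant. A parameter is dysfunctional (label 1) if it exceeds its LOF
#' or GOF bound or could not be measured (`NA`); it is normal (label 0)
#' otherwise. If peak current density is at or below the severe-LOF
#' cutoff, all four parameters are labeled dysfunctional.
#'
#' @param record A list or one-row data frame with numeric elements
#'   `iks`, `vhalf`, `tau_act`, `tau_deact` in %WT (`NA` = unmeasurable).
#' @param criteria A [criteria_table()].
#' @return Named integer vector of four 0/1 labels.
#' @export
#' @examples
#' classify_record(list(iks = 50, vhalf = 100, tau_act = 100, tau_deact = 100))
classify_record <- function(record, criteria = criteria_table()) {
  vals <- check_record_values(record)
  labels <- vapply(PARAMS, function(p) {
    v <- vals[[p]]
    if (is.na(v)) return(1L)
    as.integer(.beyond(v, criteria[p, "lof_bound"], criteria[p, "lof_dir"]) ||
               .beyond(v, criteria[p, "gof_bound"], criteria[p, "gof_dir"]))
  }, integer(1))
  iks <- vals[["iks"]]
  if (!is.na(iks) && iks <= attr(criteria, "severe_lof_cutoff")) {
    labels[] <- 1L
  }
  labels
}

#' Classify the direction of dysfunction per parameter
#'
#' Like [classify_record()] but reports the direction of any dysfunction:
#' `"LOF"` if the LOF bound is crossed, the value is unmeasurable, or the
#' severe peak-current cascade applies; `"GOF"` if the GOF bound is
#' crossed; `"WT-like"` otherwise.
#'
#' @inheritParams classify_record
#' @return Named character vector over the four parameters.
#' @export
classify_direction <- function(record, criteria = criteria_table()) {
  vals <- check_record_values(record)
  iks <- vals[["iks"]]
  cascade <- !is.na(iks) && iks <= attr(criteria, "severe_lof_cutoff")
  vapply(PARAMS, function(p) {
    v <- vals[[p]]
    if (cascade || is.na(v) ||
        .beyond(v, criteria[p, "lof_bound"], criteria[p, "lof_dir"])) return("LOF")
    if (.beyond(v, criteria[p, "gof_bound"], criteria[p, "gof_dir"])) return("GOF")
    "WT-like"
  }, character(1))
}

#' Parse a variant name such as "R195Q"
#'
#' @param name Character vector of names in the form
#'   `<wt letter><position><mutant letter>`; whitespace is trimmed and
#'   residue letters are case-insensitive.
#' @return Data frame with columns `position`, `wt_aa`, `mut_aa`.
#' @export
parse_variant <- function(name) {
  raw <- trimws(as.character(name))
  m <- regmatches(raw, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", raw))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("unparseable variant name: ", paste(unique(raw[bad]), collapse = ", "))
  }
  wt  <- check_aa(vapply(m, `[`, "", 2L), "wild-type residue")
  pos <- as.integer(vapply(m, `[`, "", 3L))
  mut <- check_aa(vapply(m, `[`, "", 4L), "mutant residue")
  if (any(pos < 1L)) stop("variant position must be >= 1")
  data.frame(position = pos, wt_aa = wt, mut_aa = mut,
             stringsAsFactors = FALSE)
}

UNMEASURABLE_SENTINELS <- c("", "NA", "ND", "N.D.", "NAN")

.parse_pct <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  x[toupper(x) %in% UNMEASURABLE_SENTINELS] <- NA
  suppressWarnings(out <- as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) stop("non-numeric measurement: ",
                     paste(unique(x[bad]), collapse = ", "))
  out
}

#' Load and label a variant functional table
#'
#' Reads a CSV or XLSX table of per-variant normalized electrophysiology
#' (%WT), parses the variant names, and attaches normal/dysfunctional
#' labels per [classify_record()] and direction classes per
#' [classify_direction()]. Blank cells and the sentinels `NA`/`ND` mean
#' the parameter could not be measured.
#'
#' @param path CSV (default) or XLSX file. XLSX requires the `readxl`
#'   package.
#' @param criteria A [criteria_table()].
#' @param col_map Named character vector mapping the required fields
#'   `variant`, `iks`, `vhalf`, `tau_act`, `tau_deact` to the file's
#'   column names; defaults to identically named columns.
#' @return A data frame (class `kv_dataset`) with columns `variant`,
#'   `position`, `wt_aa`, `mut_aa`, the four measurements `iks`, `vhalf`,
#'   `tau_act`, `tau_deact`, four 0/1 label columns `label_*`, four
#'   direction columns `dir_*`, and `is_experimental = TRUE`.
#' @export
load_variant_table <- function(path, criteria = criteria_table(),
                               col_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the 'readxl' package")
    }
    raw <- as.data.frame(readxl::read_excel(path))
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  }
  fields <- c("variant", PARAMS)
  map <- stats::setNames(fields, fields)
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  missing <- setdiff(unname(map), names(raw))
  if (nrow(raw) == 0 && length(missing)) missing <- character(0)
  if (length(missing)) {
    stop("variant table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    return(label_dataset(data.frame(variant = character(0),
                                    position = integer(0),
                                    wt_aa = character(0),
                                    mut_aa = character(0),
                                    iks = numeric(0), vhalf = numeric(0),
                                    tau_act = numeric(0),
                                    tau_deact = numeric(0)), criteria))
  }
  spec <- tryCatch(parse_variant(raw[[map[["variant"]]]]),
                   error = function(e) stop("row parse failure: ",
                                            conditionMessage(e), call. = FALSE))
  dat <- data.frame(variant = trimws(raw[[map[["variant"]]]]), spec,
                    stringsAsFactors = FALSE)
  for (p in PARAMS) dat[[p]] <- .parse_pct(raw[[map[[p]]]])
  dup <- duplicated(dat$variant)
  if (any(dup)) {
    stop("duplicate variant at row ", paste(which(dup), collapse = ", "),
         ": ", paste(unique(dat$variant[dup]), collapse = ", "))
  }
  label_dataset(dat, criteria)
}

label_dataset <- function(dat, criteria = criteria_table()) {
  n <- nrow(dat)
  labs <- matrix(0L, n, 4, dimnames = list(NULL, paste0("label_", PARAMS)))
  dirs <- matrix("WT-like", n, 4, dimnames = list(NULL, paste0("dir_", PARAMS)))
  for (i in seq_len(n)) {
    rec <- as.list(dat[i, PARAMS, drop = FALSE])
    labs[i, ] <- classify_record(rec, criteria)
    dirs[i, ] <- classify_direction(rec, criteria)
  }
  out <- cbind(dat, as.data.frame(labs), as.data.frame(dirs))
  if (!"is_experimental" %in% names(out)) out$is_experimental <- rep(TRUE, n)
  class(out) <- c("kv_dataset", "data.frame")
  out
}

#' Augment a dataset with non-perturbing variants
#'
#' Creates one record per structurally resolved position in which the
#' wild-type residue is "substituted" by itself. All four measurements
#' are set to 100 %WT and all labels to normal. These records expose a
#' model to every structural neighborhood and anchor the all-zero delta
#' feature signature to the benign class.
#'
#' @param positions Data frame with columns `position` and `wt_aa`
#'   (unique positions), e.g. a structure model's residue table.
#' @param criteria A [criteria_table()].
#' @return A `kv_dataset` with `is_experimental = FALSE`.
#' @export
augment_nonperturbing <- function(positions, criteria = criteria_table()) {
  stopifnot(all(c("position", "wt_aa") %in% names(positions)))
  if (anyDuplicated(positions$position)) {
    stop("positions must be unique")
  }
  n <- nrow(positions)
  wt <- if (n) check_aa(positions$wt_aa) else character(0)
  dat <- data.frame(
    variant = if (n) paste0(wt, positions$position, wt) else character(0),
    position = as.integer(positions$position),
    wt_aa = wt, mut_aa = wt,
    iks = rep(100, n), vhalf = rep(100, n),
    tau_act = rep(100, n), tau_deact = rep(100, n),
    stringsAsFactors = FALSE
  )
  out <- label_dataset(dat, criteria)
  out$is_experimental <- rep(FALSE, n)
  out
}

#' Combine experimental and non-perturbing datasets
#'
#' @param ... `kv_dataset` objects with identical columns.
#' @return A single `kv_dataset`.
#' @export
bind_datasets <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("kv_dataset", "data.frame")
  out
}

#' Extract the four-column 0/1 label matrix of a dataset
#'
#' @param dataset A `kv_dataset`.
#' @return Integer matrix with columns `label_iks`, `label_vhalf`,
#'   `label_tau_act`, `label_tau_deact`.
#' @export
label_matrix <- function(dataset) {
  as.matrix(dataset[, paste0("label_", PARAMS), drop = FALSE])
}
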