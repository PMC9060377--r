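ALL_FEATURES <- c(
  "hydrophobicity_mut", "polarizability_mut",
  "fd_polarizability_6.5A", "fd_polarizability_12A",
  "fd_hydrophobicity_1A", "fd_hydrophobicity_6.5A",
  "delta_h_donors", "delta_h_acceptors", "delta_vdw_volume",
  "pore_axis_distance", "membrane_burial",
  "neighbor_vector", "steric_mut", "steric_native",
  "delta_pssm_nr", "delta_pssm_uniref50"
)

FEATURE_SETS <- list(
  BIOPHYS14  = ALL_FEATURES[1:14],
  EVO2       = ALL_FEATURES[15:16],
  COMBINED12 = ALL_FEATURES[c(1:11, 15)]
)

#' Canonical feature names of a feature set
#'
#' Three published input sets are supported: `"BIOPHYS14"` (14
#' structure-derived descriptors), `"EVO2"` (PSSM score differences from
#' the NR and UniRef50 searches), and `"COMBINED12"` (the 11 biophysical
#' descriptors that survive combination - neighbor vector and the two
#' steric parameters are dropped - plus the NR PSSM difference).
#'
#' @param feature_set One of `"BIOPHYS14"`, `"EVO2"`, `"COMBINED12"`.
#' @return Character vector of feature names in canonical order.
#' @export
feature_names <- function(feature_set) {
  if (!feature_set %in% names(FEATURE_SETS)) {
    stop("unknown feature set: ", feature_set, " (use ",
         paste(names(FEATURE_SETS), collapse = ", "), ")")
  }
  FEATURE_SETS[[feature_set]]
}

#' Feature vector of one variant
#'
#' Computes the named, ordered descriptor vector of a single amino-acid
#' substitution from the structure model, the property table and the
#' PSSM matrices. Delta-type features (H-bond donors/acceptors, vdW
#' volume, PSSM scores) are zero when a residue is substituted by
#' itself, so non-perturbing variants are featurally wild type.
#'
#' @param variant One-row data frame or list with `position`, `wt_aa`,
#'   `mut_aa` (see [parse_variant()]).
#' @param structure A `kv_structure` (needed for the biophysical sets);
#'   its residue at `position` must match `wt_aa`.
#' @param pssms Named list of `kv_pssm` objects; `nr` is required by
#'   `COMBINED12`/`EVO2`, `uniref50` by `EVO2`.
#' @param feature_set See [feature_names()].
#' @param membrane A [membrane_model()].
#' @param table Property table.
#' @return Named numeric vector in canonical feature order.
#' @export
build_feature_vector <- function(variant, structure = NULL, pssms = list(),
                                 feature_set = "COMBINED12",
                                 membrane = membrane_model(),
                                 table = default_property_table()) {
  wanted <- feature_names(feature_set)
  pos <- variant$position
  wt <- check_aa(variant$wt_aa)
  mut <- check_aa(variant$mut_aa)
  vals <- stats::setNames(numeric(length(wanted)), wanted)
  need_struct <- any(wanted %in% ALL_FEATURES[1:14])
  if (need_struct) {
    if (is.null(structure)) stop("feature set ", feature_set,
                                 " requires a structure model")
    i <- .site_row(structure, pos)
    if (structure$aa[i] != wt) {
      stop("wild-type mismatch at position ", pos, ": structure has ",
           structure$aa[i], ", variant says ", wt)
    }
  }
  for (f in wanted) {
    vals[f] <- switch(f,
      hydrophobicity_mut = get_property(mut, "hydrophobicity", table),
      polarizability_mut = get_property(mut, "polarizability", table),
      "fd_polarizability_6.5A" = functional_density(structure, pos,
        "polarizability", 6.5, mut, table),
      fd_polarizability_12A = functional_density(structure, pos,
        "polarizability", 12, mut, table),
      fd_hydrophobicity_1A = functional_density(structure, pos,
        "hydrophobicity", 1, mut, table),
      "fd_hydrophobicity_6.5A" = functional_density(structure, pos,
        "hydrophobicity", 6.5, mut, table),
      delta_h_donors = delta_property(wt, mut, "n_h_donors", table),
      delta_h_acceptors = delta_property(wt, mut, "n_h_acceptors", table),
      delta_vdw_volume = delta_property(wt, mut, "vdw_volume", table),
      pore_axis_distance = pore_axis_distance(structure, pos),
      membrane_burial = membrane_burial(structure, pos, membrane),
      neighbor_vector = neighbor_vector(structure, pos),
      steric_mut = get_property(mut, "steric_parameter", table),
      steric_native = get_property(wt, "steric_parameter", table),
      delta_pssm_nr = {
        if (is.null(pssms$nr)) stop("feature set needs an 'nr' PSSM")
        delta_pssm(pssms$nr, pos, wt, mut)
      },
      delta_pssm_uniref50 = {
        if (is.null(pssms$uniref50)) stop("feature set needs a 'uniref50' PSSM")
        delta_pssm(pssms$uniref50, pos, wt, mut)
      },
      stop("unhandled feature: ", f))
  }
  vals
}

#' Feature matrix of a variant dataset
#'
#' @param dataset A `kv_dataset` (rows define variants).
#' @inheritParams build_feature_vector
#' @return Numeric matrix, one row per variant, columns in canonical
#'   feature order, rownames = variant names.
#' @export
build_feature_matrix <- function(dataset, structure = NULL, pssms = list(),
                                 feature_set = "COMBINED12",
                                 membrane = membrane_model(),
                                 table = default_property_table()) {
  wanted <- feature_names(feature_set)
  X <- matrix(NA_real_, nrow(dataset), length(wanted),
              dimnames = list(dataset$variant, wanted))
  for (i in seq_len(nrow(dataset))) {
    X[i, ] <- build_feature_vector(dataset[i, ], structure, pssms,
                                   feature_set, membrane, table)
  }
  X
}

#' Fit a per-feature standardizer on training vectors
#'
#' Z-scores each feature with the training mean and standard deviation;
#' constant features (sd 0) are mapped to 0. Fit only on training folds
#' so held-out data never leaks into the scaling.
#'
#' @param X Numeric training matrix (>= 2 rows).
#' @return A `kv_scaler` with `center` and `scale` vectors.
#' @export
fit_scaler <- function(X) {
  if (is.null(dim(X)) || nrow(X) < 2) stop("need at least 2 training vectors")
  center <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- Inf  # constant feature -> scaled value 0
  structure(list(center = center, scale = s, names = colnames(X)),
            class = "kv_scaler")
}

#' Apply / invert a fitted standardizer
#'
#' @param scaler A `kv_scaler` from [fit_scaler()].
#' @param X Matrix or vector with the scaler's feature count.
#' @return Standardized (or unstandardized) matrix.
#' @export
apply_scaler <- function(scaler, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(scaler$center)) stop("feature dimension mismatch")
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(scaler, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  sc <- ifelse(is.finite(scaler$scale), scaler$scale, 1)
  # constant features were collapsed to 0; restore their center
  sweep(sweep(X, 2, sc, "*"), 2, scaler$center, "+")
}
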