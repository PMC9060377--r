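#' Build a structure model from residue representative points
#'
#' A structure model is the minimal geometric view of a membrane protein
#' used for featurization: one representative point per residue, in a
#' frame whose z axis is the membrane normal and whose origin plane
#' (z = 0) is the membrane mid-plane, plus a pore axis.
#'
#' @param residues Data frame with columns `position` (unique integers),
#'   `aa` (one-letter codes) and coordinates `x`, `y`, `z` in Angstrom.
#' @param pore_axis Optional list `list(point = c(x, y, z), dir = c(..))`
#'   defining the pore axis. By default the axis runs along z through the
#'   x-y centroid of all representative points.
#' @param pore_residues Optional integer vector of pore-lining positions;
#'   if given, the axis runs along z through their x-y centroid.
#' @return A `kv_structure`: the residue data frame with a `pore_axis`
#'   attribute.
#' @export
structure_model <- function(residues, pore_axis = NULL, pore_residues = NULL) {
  stopifnot(all(c("position", "aa", "x", "y", "z") %in% names(residues)))
  if (anyDuplicated(residues$position)) stop("residue positions must be unique")
  if (!all(is.finite(as.matrix(residues[, c("x", "y", "z")])))) {
    stop("non-finite coordinates")
  }
  residues$aa <- check_aa(residues$aa)
  residues <- residues[order(residues$position), , drop = FALSE]
  rownames(residues) <- NULL
  if (is.null(pore_axis)) {
    ref <- residues
    if (!is.null(pore_residues)) {
      ref <- residues[residues$position %in% pore_residues, , drop = FALSE]
      if (!nrow(ref)) stop("no pore residues resolved in structure")
    }
    pore_axis <- list(point = c(mean(ref$x), mean(ref$y), 0),
                      dir = c(0, 0, 1))
  }
  pore_axis$dir <- pore_axis$dir / sqrt(sum(pore_axis$dir^2))
  attr(residues, "pore_axis") <- pore_axis
  class(residues) <- c("kv_structure", "data.frame")
  residues
}

#' Read a membrane-oriented structure from PDB or mmCIF
#'
#' Parses the first model of a coordinate file (via `bio3d`) and reduces
#' each residue to a representative point: the centroid of its side-chain
#' heavy atoms, falling back to the alpha-carbon for glycine or residues
#' with no resolved side chain (`rep_point = "ca"` forces alpha-carbons,
#' `"cb"` beta-carbons with alpha fallback). The file must already be
#' oriented in a membrane frame (z = membrane normal, z = 0 mid-plane),
#' as in OPM-style depositions; no re-orientation is attempted.
#'
#' @param path PDB (`.pdb`/`.ent`) or mmCIF (`.cif`) file.
#' @param chain Optional chain identifier(s) to keep.
#' @param rep_point `"sidechain"` (default), `"cb"`, or `"ca"`.
#' @inheritParams structure_model
#' @return A `kv_structure`.
#' @export
read_structure <- function(path, chain = NULL, rep_point = "sidechain",
                           pore_axis = NULL, pore_residues = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, verbose = FALSE)
  }
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (!nrow(at)) stop("no protein atoms found in ", path)
  at <- at[!grepl("^H", trimws(at$elesy)), , drop = FALSE]  # drop hydrogens
  key <- paste(at$chain, at$resno)
  res <- lapply(split(seq_len(nrow(at)), factor(key, unique(key))), function(i) {
    sub <- at[i, , drop = FALSE]
    aa3 <- sub$resid[1]
    aa1 <- bio3d::aa321(aa3)
    if (is.na(aa1) || !(aa1 %in% AA_CODES)) return(NULL)
    pick <- switch(rep_point,
      sidechain = sub[!sub$elety %in% c("N", "CA", "C", "O", "OXT"), ,
                      drop = FALSE],
      cb = sub[sub$elety == "CB", , drop = FALSE],
      ca = sub[sub$elety == "CA", , drop = FALSE],
      stop("rep_point must be 'sidechain', 'cb' or 'ca'"))
    if (!nrow(pick)) pick <- sub[sub$elety == "CA", , drop = FALSE]
    if (!nrow(pick)) return(NULL)
    data.frame(position = sub$resno[1], aa = aa1,
               x = mean(pick$x), y = mean(pick$y), z = mean(pick$z),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || !nrow(res)) stop("no standard residues found in ", path)
  structure_model(res, pore_axis = pore_axis, pore_residues = pore_residues)
}

.site_row <- function(structure, position) {
  i <- match(position, structure$position)
  if (is.na(i)) stop("position ", position, " is not resolved in the structure")
  i
}

#' Perpendicular distance of a residue from the pore axis
#'
#' @param structure A `kv_structure`.
#' @param position Residue position (must be resolved).
#' @return Distance in Angstrom (>= 0).
#' @export
pore_axis_distance <- function(structure, position) {
  i <- .site_row(structure, position)
  ax <- attr(structure, "pore_axis")
  v <- c(structure$x[i], structure$y[i], structure$z[i]) - ax$point
  perp <- v - sum(v * ax$dir) * ax$dir
  sqrt(sum(perp^2))
}

#' Implicit slab membrane model
#'
#' Three-layer membrane along z: a hydrophobic core of half-thickness
#' `core_half` in which the burial weight plateaus at 1, an interface of
#' thickness `interface` on each side across which the weight decays to 0
#' by a half-cosine, and bulk solvent (weight 0) beyond. The weight is a
#' continuous, even function of z bounded in [0, 1].
#'
#' @param core_half Core half-thickness in Angstrom (default 15).
#' @param interface Interface thickness in Angstrom (default 5).
#' @return A `kv_membrane` parameter list.
#' @export
membrane_model <- function(core_half = 15, interface = 5) {
  stopifnot(core_half > 0, interface > 0)
  structure(list(core_half = core_half, interface = interface),
            class = "kv_membrane")
}

#' Membrane-burial weight of a residue
#'
#' Depth-dependent weight of the residue's representative point under a
#' [membrane_model()]: 1 inside the hydrophobic core, half-cosine decay
#' across each interface, 0 in bulk solvent.
#'
#' @inheritParams pore_axis_distance
#' @param membrane A [membrane_model()].
#' @param z Alternatively, evaluate the weight directly at depth(s) `z`
#'   (Angstrom); overrides `structure`/`position`.
#' @return Weight(s) in [0, 1].
#' @export
membrane_burial <- function(structure = NULL, position = NULL,
                            membrane = membrane_model(), z = NULL) {
  if (is.null(z)) z <- structure$z[.site_row(structure, position)]
  a <- abs(z)
  w <- numeric(length(a))
  w[a <= membrane$core_half] <- 1
  mid <- a > membrane$core_half & a < membrane$core_half + membrane$interface
  w[mid] <- 0.5 * (1 + cos(pi * (a[mid] - membrane$core_half) /
                             membrane$interface))
  w
}

.site_distances <- function(structure, i) {
  dx <- structure$x - structure$x[i]
  dy <- structure$y - structure$y[i]
  dz <- structure$z - structure$z[i]
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Functional density of an amino-acid property around a site
#'
#' Inverse-distance-weighted average of a scalar residue property over
#' the residues whose representative points lie within `radius` of the
#' site (the site itself excluded), with distances floored at 1 Angstrom
#' to bound the weights:
#' \deqn{FD = \sum_j p_j / d_j \; / \; \sum_j 1 / d_j .}
#' Neighbors contribute their native property; if no neighbor falls
#' inside the radius the site's mutant-residue property is returned, so
#' the feature degrades gracefully to a point property at small radii.
#'
#' @inheritParams pore_axis_distance
#' @param property Property column name (see [load_property_table()]).
#' @param radius Neighborhood radius in Angstrom (> 0).
#' @param mutant_aa Residue assumed at the site (used only when the
#'   neighborhood is empty); defaults to the native residue.
#' @param table Property table.
#' @return Scalar functional density, in the property's units.
#' @export
functional_density <- function(structure, position, property, radius,
                               mutant_aa = NULL,
                               table = default_property_table()) {
  stopifnot(radius > 0)
  i <- .site_row(structure, position)
  if (is.null(mutant_aa)) mutant_aa <- structure$aa[i]
  d <- .site_distances(structure, i)
  keep <- which(d <= radius & seq_along(d) != i)
  if (!length(keep)) return(get_property(mutant_aa, property, table))
  d <- pmax(d[keep], 1)
  p <- get_property(structure$aa[keep], property, table)
  sum(p / d) / sum(1 / d)
}

#' Neighbor-vector solvent exposure of a residue
#'
#' Norm of the weighted mean of unit vectors from the site to its
#' neighbors. Each neighbor at distance d contributes weight 1 for
#' d <= `lower`, 0 for d >= `upper`, and a cosine-smooth transition in
#' between. A residue surrounded symmetrically scores near 0 (buried);
#' a residue with all neighbors on one side, or none at all, scores 1
#' (exposed).
#'
#' @inheritParams pore_axis_distance
#' @param lower,upper Transition bounds in Angstrom (defaults 3.3, 11.4).
#' @return Exposure in [0, 1].
#' @export
neighbor_vector <- function(structure, position, lower = 3.3, upper = 11.4) {
  i <- .site_row(structure, position)
  d <- .site_distances(structure, i)
  keep <- which(d < upper & seq_along(d) != i & d > 0)
  if (!length(keep)) return(1)
  w <- ifelse(d[keep] <= lower, 1,
              0.5 * (1 + cos(pi * (d[keep] - lower) / (upper - lower))))
  ux <- (structure$x[keep] - structure$x[i]) / d[keep]
  uy <- (structure$y[keep] - structure$y[i]) / d[keep]
  uz <- (structure$z[keep] - structure$z[i]) / d[keep]
  sw <- sum(w)
  if (sw == 0) return(1)
  sqrt(sum(c(sum(w * ux), sum(w * uy), sum(w * uz))^2)) / sw
}
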