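#' Idealized membrane helix-bundle structure
#'
#' Generates an alpha-helical bundle arranged symmetrically around the z
#' axis (the pore axis) and centered on the membrane mid-plane: each
#' helix runs along z with a rise of 1.5 A and a twist of 100 degrees
#' per residue, its axis at `ring_radius` from the pore axis and its
#' residue representative points on a cylinder of `helix_radius` around
#' it. Residue identities are drawn uniformly unless a sequence is
#' given. Coordinates are rounded to 0.001 A so that a written PDB file
#' ([write_structure_pdb()]) reads back exactly.
#'
#' @param n_helices,res_per_helix Bundle geometry; the model resolves
#'   `n_helices * res_per_helix` consecutive positions.
#' @param ring_radius Distance of each helix axis from the pore axis (A).
#' @param helix_radius Radius of the residue cylinder around each helix
#'   axis (A, default 2.3, the C-alpha radius of an ideal helix).
#' @param sequence Optional residue string/vector of the full length.
#' @param seed Seed for residue sampling.
#' @return A `kv_structure`.
#' @export
synthetic_structure <- function(n_helices = 15, res_per_helix = 23,
                                ring_radius = 16, helix_radius = 2.3,
                                sequence = NULL, seed = 1) {
  if (ring_radius <= 0 || helix_radius <= 0 || n_helices < 1 ||
      res_per_helix < 1) {
    stop("non-physical bundle specification")
  }
  n <- n_helices * res_per_helix
  if (is.null(sequence)) {
    set.seed(seed)
    sequence <- sample(AA_CODES, n, replace = TRUE)
  } else {
    if (length(sequence) == 1L) sequence <- strsplit(sequence, "")[[1]]
    if (length(sequence) != n) stop("sequence length must be ", n)
    sequence <- check_aa(sequence)
  }
  rise <- 1.5; twist <- 100 * pi / 180
  rows <- vector("list", n)
  pos <- 0L
  for (h in seq_len(n_helices)) {
    th <- 2 * pi * (h - 1) / n_helices
    cx <- ring_radius * cos(th); cy <- ring_radius * sin(th)
    for (i in seq_len(res_per_helix)) {
      pos <- pos + 1L
      phi <- th + (i - 1) * twist
      rows[[pos]] <- data.frame(
        position = pos, aa = sequence[pos],
        x = round(cx + helix_radius * cos(phi), 3),
        y = round(cy + helix_radius * sin(phi), 3),
        z = round((i - 1) * rise - (res_per_helix - 1) * rise / 2, 3),
        stringsAsFactors = FALSE)
    }
  }
  structure_model(do.call(rbind, rows))
}

#' Write a structure model as a minimal PDB file
#'
#' One C-alpha record per residue at its representative point, chain A.
#'
#' @param structure A `kv_structure`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  lines <- vapply(seq_len(nrow(structure)), function(i) {
    sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, bio3d::aa123(structure$aa[i]), structure$position[i],
            structure$x[i], structure$y[i], structure$z[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Synthetic PSSM with tunable conservation
#'
#' Builds a scoring matrix in which the wild-type residue of each
#' position scores high and all others low, with integer noise that
#' shrinks as `conservation` approaches 1 (at full conservation the
#' wild-type score is strictly maximal everywhere and the matrix is
#' noise-free).
#'
#' @param sequence Residue string/vector (the query sequence).
#' @param conservation Degree of conservation in \[0, 1\].
#' @param seed Noise seed.
#' @param source Tag recorded on the matrix.
#' @return A `kv_pssm` (write with [write_pssm()]).
#' @export
synthetic_pssm <- function(sequence, conservation = 0.8, seed = 1,
                           source = "NR") {
  if (length(sequence) == 1L) sequence <- strsplit(sequence, "")[[1]]
  if (!length(sequence)) stop("empty sequence")
  sequence <- check_aa(sequence)
  stopifnot(conservation >= 0, conservation <= 1)
  set.seed(seed)
  L <- length(sequence)
  noise_sd <- 1.5 * (1 - conservation)
  scores <- matrix(as.integer(round(-1 - 3 * conservation +
                                      stats::rnorm(L * 20, 0, noise_sd))),
                   L, 20, dimnames = list(NULL, AA_CODES))
  wt_score <- as.integer(round(4 + 4 * conservation +
                                 stats::rnorm(L, 0, noise_sd)))
  scores[cbind(seq_len(L), match(sequence, AA_CODES))] <- wt_score
  structure(list(length = L, wt = sequence, scores = scores,
                 source = source),
            class = "kv_pssm")
}

DEFAULT_PLANTED_BETA <- list(
  iks       = c(delta_pssm_nr = -4, delta_vdw_volume = 4),
  vhalf     = c(membrane_burial = 4, polarizability_mut = 4),
  tau_act   = c(pore_axis_distance = -4, delta_h_donors = -4),
  tau_deact = c(hydrophobicity_mut = 4, "fd_hydrophobicity_6.5A" = -4)
)

#' Synthetic variant dataset with planted label rules
#'
#' Samples missense variants uniformly over the structure's resolved
#' positions (non-identical substitutions, unique variants), computes
#' their real feature vectors through the package's own pipeline, and
#' draws each of the four binary labels from a planted rule: the label
#' is dysfunctional when `beta . z + eps > 0`, where `z` are the planted
#' features standardized over the experimental subset and
#' `eps ~ N(0, sigma^2)`. One non-perturbing record per resolved
#' position (all labels normal) is appended, mirroring the augmented
#' composition of the real study (125 + 345 by default). The planted
#' truth (beta, sigma, seed, standardization constants) is recorded in
#' the manifest so recovery experiments are falsifiable.
#'
#' @param structure A `kv_structure` (e.g. [synthetic_structure()]).
#' @param pssms Named list of `kv_pssm`s (needs `nr` for the default
#'   feature set; see [build_feature_vector()]).
#' @param n_experimental Number of missense records (default 125).
#' @param beta Named list (one element per output) of named coefficient
#'   vectors over feature names; defaults plant two features of
#'   magnitude 4 per output.
#' @param sigma Label noise standard deviation (default 0.5).
#' @param seed Seed governing sampling and noise.
#' @param feature_set Feature set used both for the planted rule and the
#'   returned feature matrix.
#' @param membrane,table Passed to the feature pipeline.
#' @return List with `dataset` (a `kv_dataset` of experimental +
#'   non-perturbing records), `features` (raw feature matrix over all
#'   records) and `manifest` (planted truth).
#' @export
synthetic_variant_dataset <- function(structure, pssms,
                                      n_experimental = 125,
                                      beta = DEFAULT_PLANTED_BETA,
                                      sigma = 0.5, seed = 1,
                                      feature_set = "COMBINED12",
                                      membrane = membrane_model(),
                                      table = default_property_table()) {
  fnames <- feature_names(feature_set)
  planted <- unique(unlist(lapply(beta, names)))
  if (!length(planted)) stop("empty planted feature subset")
  if (!all(planted %in% fnames)) {
    stop("planted features outside feature set: ",
         paste(setdiff(planted, fnames), collapse = ", "))
  }
  set.seed(seed)
  seen <- character(0)
  vars <- vector("list", n_experimental)
  k <- 0L
  while (k < n_experimental) {
    i <- sample.int(nrow(structure), 1)
    wt <- structure$aa[i]
    mut <- sample(setdiff(AA_CODES, wt), 1)
    key <- paste0(wt, structure$position[i], mut)
    if (key %in% seen) next
    seen <- c(seen, key)
    k <- k + 1L
    vars[[k]] <- data.frame(position = structure$position[i], wt_aa = wt,
                            mut_aa = mut, stringsAsFactors = FALSE)
  }
  exp_dat <- do.call(rbind, vars)
  exp_dat <- data.frame(variant = seen, exp_dat, stringsAsFactors = FALSE)
  for (p in PARAMS) exp_dat[[p]] <- NA_real_

  Xexp <- build_feature_matrix(exp_dat, structure, pssms, feature_set,
                               membrane, table)
  ctr <- colMeans(Xexp)
  sdv <- apply(Xexp, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(Xexp, 2, ctr), 2, sdv, "/")
  labs <- matrix(0L, n_experimental, 4,
                 dimnames = list(NULL, paste0("label_", PARAMS)))
  for (j in seq_along(PARAMS)) {
    b <- beta[[PARAMS[j]]]
    score <- Z[, names(b), drop = FALSE] %*% b +
      stats::rnorm(n_experimental, 0, sigma)
    labs[, j] <- as.integer(score > 0)
  }
  for (p in PARAMS) {
    exp_dat[[paste0("label_", p)]] <- labs[, paste0("label_", p)]
    exp_dat[[paste0("dir_", p)]] <- NA_character_
  }
  exp_dat$is_experimental <- TRUE
  class(exp_dat) <- c("kv_dataset", "data.frame")

  np <- augment_nonperturbing(structure[, c("position", "wt_aa" = "aa")] |>
                                stats::setNames(c("position", "wt_aa")))
  dataset <- bind_datasets(exp_dat, np)
  Xnp <- build_feature_matrix(np, structure, pssms, feature_set,
                              membrane, table)
  features <- rbind(Xexp, Xnp)
  rownames(features) <- dataset$variant
  manifest <- list(beta = beta, sigma = sigma, seed = seed,
                   feature_set = feature_set,
                   n_experimental = n_experimental,
                   n_nonperturbing = nrow(np),
                   standardization = list(center = ctr, sd = sdv))
  list(dataset = dataset, features = features, manifest = manifest)
}

#' Synthetic stand-in for the deposited variant functional table
#'
#' Generates a table in the layout of the study's deposited dataset
#' (variant name plus four %WT measurements) whose values are drawn
#' inside the criteria regions of [criteria_table()] to realize a chosen
#' peak-current class composition; defaults reproduce the published
#' composition (71 LOF / 15 GOF / 39 WT-like among 125 variants,
#' including severe-loss records at or below 17 %WT and unmeasurable
#' entries). This is a synthetic object for tests and examples - the
#' real measurements are an external deposit - but classifying it must
#' recover the intended composition, which is what the dataset tests
#' assert.
#'
#' @param n_lof,n_gof,n_wt Peak-current class sizes.
#' @param seed Sampling seed.
#' @param criteria A [criteria_table()] whose bounds the values respect.
#' @return Data frame with columns `variant`, `iks`, `vhalf`, `tau_act`,
#'   `tau_deact` (NA = unmeasurable), in shuffled row order.
#' @export
synthetic_functional_table <- function(n_lof = 71, n_gof = 15, n_wt = 39,
                                       seed = 1,
                                       criteria = criteria_table()) {
  set.seed(seed)
  n <- n_lof + n_gof + n_wt
  if (n < 1) stop("empty table requested")
  pos <- sample(seq_len(345), n, replace = FALSE)
  wt <- sample(AA_CODES, n, replace = TRUE)
  mut <- vapply(wt, function(a) sample(setdiff(AA_CODES, a), 1), "")
  cls <- sample(rep(c("LOF", "GOF", "WT"), c(n_lof, n_gof, n_wt)))

  margin <- 2  # keep generated values strictly inside open regions
  normal <- function(p, m) {
    lo <- if (criteria[p, "gof_dir"] == "below") criteria[p, "gof_bound"]
          else criteria[p, "lof_bound"]
    hi <- if (criteria[p, "gof_dir"] == "above") criteria[p, "gof_bound"]
          else criteria[p, "lof_bound"]
    stats::runif(m, lo + margin, hi - margin)
  }
  cutoff <- attr(criteria, "severe_lof_cutoff")
  iks <- numeric(n); other <- matrix(NA_real_, n, 3)
  colnames(other) <- PARAMS[-1]
  for (i in seq_len(n)) {
    if (cls[i] == "WT") {
      iks[i] <- normal("iks", 1)
      for (p in PARAMS[-1]) other[i, p] <- normal(p, 1)
    } else if (cls[i] == "GOF") {
      iks[i] <- stats::runif(1, criteria["iks", "gof_bound"] + margin, 180)
      for (p in PARAMS[-1]) other[i, p] <- normal(p, 1)
    } else {
      # severe loss (cascade region), moderate loss, or unmeasurable
      u <- stats::runif(1)
      iks[i] <- if (u < 0.55) stats::runif(1, 0, cutoff)
                else if (u < 0.9) {
                  stats::runif(1, cutoff + 1,
                               criteria["iks", "lof_bound"] - margin)
                } else NA_real_
      for (p in PARAMS[-1]) {
        v <- stats::runif(1)
        other[i, p] <- if (v < 0.15) NA_real_
                       else if (v < 0.55) normal(p, 1)
                       else if (criteria[p, "lof_dir"] == "above") {
                         stats::runif(1, criteria[p, "lof_bound"] + margin, 400)
                       } else {
                         stats::runif(1, 0, criteria[p, "lof_bound"] - margin)
                       }
      }
    }
  }
  out <- data.frame(variant = paste0(wt, pos, mut), iks = iks,
                    vhalf = other[, "vhalf"], tau_act = other[, "tau_act"],
                    tau_deact = other[, "tau_deact"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
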