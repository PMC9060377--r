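# Shared fixtures. Everything is generated in code at test time; the
# expensive cross-validation runs are computed once per session and
# cached here so several test files can assert on the same run.

fixture_env <- new.env(parent = emptyenv())

# small bundle for geometry/feature unit tests (60 residues)
small_structure <- function() {
  if (is.null(fixture_env$small_struct)) {
    fixture_env$small_struct <- synthetic_structure(
      n_helices = 4, res_per_helix = 15, ring_radius = 10, seed = 11)
  }
  fixture_env$small_struct
}

small_pssms <- function() {
  if (is.null(fixture_env$small_pssms)) {
    s <- small_structure()
    fixture_env$small_pssms <- list(
      nr = synthetic_pssm(s$aa, conservation = 0.7, seed = 21, source = "NR"),
      uniref50 = synthetic_pssm(s$aa, conservation = 0.5, seed = 22,
                                source = "UniRef50"))
  }
  fixture_env$small_pssms
}

# random point-cloud structure for brute-force geometry oracles
random_cloud <- function(n = 50, seed = 1, box = 20) {
  set.seed(seed)
  structure_model(data.frame(
    position = seq_len(n),
    aa = sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                n, replace = TRUE),
    x = runif(n, -box, box), y = runif(n, -box, box),
    z = runif(n, -box, box)))
}

# brute-force double-loop oracle for functional density (site excluded,
# distance floored at 1 A, empty neighborhood -> mutant property)
fd_oracle <- function(struct, position, property, radius, mutant_aa,
                      table = load_property_table()) {
  i <- which(struct$position == position)
  num <- 0; den <- 0
  for (j in seq_len(nrow(struct))) {
    if (j == i) next
    d <- sqrt(sum((c(struct$x[j], struct$y[j], struct$z[j]) -
                   c(struct$x[i], struct$y[i], struct$z[i]))^2))
    if (d > radius) next
    d <- max(d, 1)
    num <- num + table[struct$aa[j], property] / d
    den <- den + 1 / d
  }
  if (den == 0) return(table[mutant_aa, property])
  num / den
}

# brute-force oracle for the neighbor-vector exposure
nv_oracle <- function(struct, position, lower = 3.3, upper = 11.4) {
  i <- which(struct$position == position)
  acc <- c(0, 0, 0); sw <- 0
  for (j in seq_len(nrow(struct))) {
    if (j == i) next
    v <- c(struct$x[j] - struct$x[i], struct$y[j] - struct$y[i],
           struct$z[j] - struct$z[i])
    d <- sqrt(sum(v^2))
    if (d >= upper || d == 0) next
    w <- if (d <= lower) 1 else 0.5 * (1 + cos(pi * (d - lower) / (upper - lower)))
    acc <- acc + w * v / d
    sw <- sw + w
  }
  if (sw == 0) return(1)
  sqrt(sum(acc^2)) / sw
}

# pair-counting oracle for AUC (ties count one half)
auc_oracle <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1
                 else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# planted-rule recovery experiment at the study's scale (470 records,
# 25-fold CV); computed once and shared by several acceptance blocks
recovery_run <- function() {
  if (is.null(fixture_env$recovery)) {
    struct <- synthetic_structure(seed = 101)
    pssms <- list(nr = synthetic_pssm(struct$aa, conservation = 0.7,
                                      seed = 102, source = "NR"))
    sim <- synthetic_variant_dataset(struct, pssms, seed = 1)
    plan <- make_cv_plan(nrow(sim$dataset), 25, seed = 1)
    res <- run_cv(sim$features, label_matrix(sim$dataset),
                  sim$dataset$is_experimental,
                  config = network_config("COMBINED12"),
                  plan = plan, seed = 1)
    fixture_env$recovery <- list(struct = struct, pssms = pssms, sim = sim,
                                 plan = plan, res = res)
  }
  fixture_env$recovery
}

# replicate ensembles (reshuffled CV) for the sensitivity analysis;
# reuses the recovery ensemble as the first replicate
replicate_ensembles <- function(n_extra = 2) {
  if (is.null(fixture_env$replicates)) {
    rec <- recovery_run()
    ens <- list(rec$res$ensemble)
    for (r in seq_len(n_extra)) {
      plan <- make_cv_plan(nrow(rec$sim$dataset), 25, seed = 100 + r)
      res <- run_cv(rec$sim$features, label_matrix(rec$sim$dataset),
                    rec$sim$dataset$is_experimental,
                    config = network_config("COMBINED12"),
                    plan = plan, seed = 1000 + r)
      ens[[r + 1]] <- res$ensemble
    }
    fixture_env$replicates <- ens
  }
  fixture_env$replicates
}
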