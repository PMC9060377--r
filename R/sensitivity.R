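#' Consistency-based input sensitivity of trained ensembles
#'
#' Perturbs each (scaled) input feature by a small positive amount and
#' records, for every member model and every record, the direction in
#' which each of the four outputs moves. The net consistency of a
#' (feature, output) pair is `(n_positive - n_negative) / n_total`
#' pooled over records, member models and replicate ensembles: +1 when
#' every prediction moves up, -1 when every prediction moves down, 0
#' when the directions split evenly. Responses smaller than `zero_tol`
#' in magnitude count to neither side and shrink `n_total`. Because only
#' the sign of the movement enters, the measure is insensitive to
#' feature rescaling (magnitudes of input sensitivity are not
#' comparable across features and are deliberately not reported).
#'
#' @param ensembles A `kv_ensemble` or list of them (replicates trained
#'   on reshuffled data); all must share a feature set.
#' @param X Raw feature matrix of the records to probe (typically the
#'   full dataset).
#' @param delta Perturbation size in scaled-feature standard deviations
#'   (default 0.1), applied after standardization; a negative value
#'   probes the opposite direction and negates every entry.
#' @param zero_tol Magnitude below which a response is treated as zero.
#' @return A `kv_sensitivity`: matrix (features x 4 outputs) of net
#'   consistencies in \[-1, 1\], with attributes `n_models`, `n_records`
#'   and `delta`.
#' @export
input_sensitivity <- function(ensembles, X, delta = 0.1, zero_tol = 1e-12) {
  if (inherits(ensembles, "kv_ensemble")) ensembles <- list(ensembles)
  fsets <- unique(vapply(ensembles, `[[`, "", "feature_set"))
  if (length(fsets) > 1) {
    stop("ensembles use different feature sets: ",
         paste(fsets, collapse = ", "))
  }
  stopifnot(delta != 0)
  d <- ncol(X)
  pos <- neg <- matrix(0, d, 4)
  n_models <- 0L
  for (ens in ensembles) {
    for (model in ens$models) {
      if (model$config$n_inputs != d) stop("feature dimension mismatch")
      Xs <- apply_scaler(model$scaler, X)
      base <- nn_forward(model, Xs)
      for (f in seq_len(d)) {
        Xp <- Xs
        Xp[, f] <- Xp[, f] + delta
        move <- nn_forward(model, Xp) - base
        pos[f, ] <- pos[f, ] + colSums(move > zero_tol)
        neg[f, ] <- neg[f, ] + colSums(move < -zero_tol)
      }
      n_models <- n_models + 1L
    }
  }
  tot <- pos + neg
  out <- ifelse(tot > 0, (pos - neg) / tot, 0)
  dimnames(out) <- list(colnames(X), names(PARAM_LABELS))
  structure(out, class = c("kv_sensitivity", "matrix"),
            n_models = n_models, n_records = nrow(X), delta = delta)
}
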