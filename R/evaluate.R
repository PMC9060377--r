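#' Matthews correlation coefficient from confusion counts
#'
#' `(TP*TN - FP*FN) / sqrt((TN+FN)(TP+FP)(TP+FN)(TN+FP))`; defined as 0
#' when any factor of the denominator is 0 (the usual convention for
#' degenerate margins).
#'
#' @param tp,tn,fp,fn Non-negative counts, or a single named list/vector
#'   in `tp` with elements `tp`, `tn`, `fp`, `fn`.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.null(tn)) {
    cm <- tp; tp <- cm[["tp"]]; tn <- cm[["tn"]]
    fp <- cm[["fp"]]; fn <- cm[["fn"]]
  }
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  den <- as.numeric(tn + fn) * (tp + fp) * (tp + fn) * (tn + fp)
  if (den == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
}

confusion <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  pos <- labels == 1
  c(tp = sum(pred & pos), tn = sum(!pred & !pos),
    fp = sum(pred & !pos), fn = sum(!pred & pos))
}

#' MCC of scores against labels at a decision threshold
#'
#' Scores at or above the threshold are called dysfunctional.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold.
#' @return MCC in \[-1, 1\].
#' @export
mcc_at <- function(scores, labels, threshold) {
  mcc(confusion(scores, labels, threshold))
}

#' ROC curve and AUC
#'
#' Sweeps all score thresholds to trace (FPR, TPR) points; the AUC is
#' computed as the rank statistic - the fraction of positive-negative
#' pairs in which the positive scores higher, ties counting one half -
#' which equals the trapezoidal area under the curve.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return A `kv_roc`: list with `points` (data frame `fpr`, `tpr`,
#'   ordered by increasing FPR) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- labels == 1
  npos <- sum(pos); nneg <- sum(!pos)
  if (npos == 0 || nneg == 0) {
    stop("ROC undefined: need at least one positive and one negative label")
  }
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  # collapse ties: keep the last point of each distinct score
  keep <- c(diff(scores[ord]) != 0, TRUE)
  pts <- data.frame(fpr = c(0, fp[keep] / nneg), tpr = c(0, tp[keep] / npos))
  r <- rank(scores)  # midranks handle ties as half-concordant pairs
  auc <- (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
  structure(list(points = pts, auc = auc), class = "kv_roc")
}

#' Tune the decision threshold for best MCC
#'
#' Scans thresholds from 0 to 1 inclusive at the given step (scores at
#' or above the threshold are called dysfunctional) and returns the
#' maximal MCC; ties are broken toward the smallest threshold.
#'
#' @inheritParams roc_curve
#' @param step Scan step (default 0.01).
#' @return List with `threshold` and `mcc`.
#' @export
optimize_threshold <- function(scores, labels, step = 0.01) {
  if (length(unique(labels)) < 2) {
    stop("ROC undefined: need at least one positive and one negative label")
  }
  grid <- seq(0, 1, by = step)
  vals <- vapply(grid, function(t) mcc_at(scores, labels, t), numeric(1))
  i <- which.max(vals)  # which.max returns the first (smallest) maximizer
  list(threshold = grid[i], mcc = vals[i])
}

#' Cross-validation plan: shuffle, partition, rotate
#'
#' Randomly shuffles the records with the given seed and partitions them
#' round-robin into `k` subsets whose sizes differ by at most one. Each
#' rotation holds one subset out for testing and the next for
#' monitoring, training on the remaining `k - 2`.
#'
#' @param n Number of records (>= k).
#' @param k Number of subsets (default 25).
#' @param seed Shuffle seed.
#' @return A `kv_cv_plan`: list with `k`, `seed`, `assignment` (subset
#'   index per record) and `rotations` (list of `test`/`monitor`/`train`
#'   index vectors).
#' @export
make_cv_plan <- function(n, k = 25, seed = 1) {
  if (n < k) stop("cannot split ", n, " records into ", k, " subsets")
  set.seed(seed)
  perm <- sample.int(n)
  assignment <- integer(n)
  assignment[perm] <- rep_len(seq_len(k), n)
  rotations <- lapply(seq_len(k), function(i) {
    mon <- if (i == k) 1L else i + 1L
    list(test = which(assignment == i),
         monitor = which(assignment == mon),
         train = which(assignment != i & assignment != mon))
  })
  structure(list(k = k, seed = seed, assignment = assignment,
                 rotations = rotations),
            class = "kv_cv_plan")
}

#' Oversample experimental records within a training fold
#'
#' Replicates each experimental record `ratio` times (non-perturbing
#' records appear once) and shuffles the result, counteracting the
#' dominance of non-perturbing records during training.
#'
#' @param idx Record indices of the training fold.
#' @param is_experimental Logical vector over all records.
#' @param ratio Replication factor for experimental records (default 3).
#' @return Shuffled index vector with replicates. Consumes the session
#'   RNG; seed upstream for reproducibility.
#' @export
oversample_fold <- function(idx, is_experimental, ratio = 3) {
  out <- c(rep(idx[is_experimental[idx]], ratio), idx[!is_experimental[idx]])
  out[sample.int(length(out))]
}

#' Entropy separation of two prediction populations at a boundary
#'
#' Split entropy: records are divided at the decision boundary and each
#' side contributes the binary Shannon entropy (base 2) of its class
#' composition, weighted by its share of the records. 0 means the
#' boundary separates the classes perfectly; 1 means both sides are
#' maximally mixed.
#'
#' @param scores Prediction scores of the pooled records.
#' @param classes Binary class per record (e.g. non-perturbing vs
#'   benign); both classes must be present.
#' @param boundary Decision boundary (default 0.05); scores strictly
#'   below fall on the left side.
#' @return Entropy in \[0, 1\].
#' @export
entropy_separation <- function(scores, classes, boundary = 0.05) {
  cls <- as.integer(factor(classes))
  if (length(unique(cls)) < 2) {
    stop("entropy separation undefined: both classes must be present")
  }
  side <- scores < boundary
  h <- function(sel) {
    n <- sum(sel)
    if (n == 0) return(0)
    p <- mean(cls[sel] == 1)
    if (p == 0 || p == 1) return(0)
    -(p * log2(p) + (1 - p) * log2(1 - p))
  }
  mean(side) * h(side) + mean(!side) * h(!side)
}

PARAM_LABELS <- c(iks = "label_iks", vhalf = "label_vhalf",
                  tau_act = "label_tau_act", tau_deact = "label_tau_deact")

#' Cross-validated training and evaluation of an ensemble
#'
#' Runs the full published protocol on a featurized dataset: for each of
#' the `k` rotations, fits a per-feature scaler on the training fold,
#' oversamples experimental records, trains one network, and collects
#' predictions on the held-out monitoring and test folds. Decision
#' thresholds are tuned per output on the pooled monitoring predictions
#' and applied to the pooled test predictions. Headline metrics (MCC at
#' the tuned threshold, ROC/AUC) are computed on the experimental
#' records; overall pooled metrics, non-perturbing benign accuracy,
#' peak-current direction-class accuracy and the non-perturbing/benign
#' entropy separation are reported alongside.
#'
#' @param X Raw feature matrix (rows = records, canonical column order).
#' @param Y 0/1 label matrix with four columns (see [label_matrix()]).
#' @param is_experimental Logical vector over records.
#' @param config A [network_config()] matching `ncol(X)`.
#' @param plan A [make_cv_plan()] for `nrow(X)` records.
#' @param seed Base seed; member model `i` trains with `seed + i`.
#' @param directions Optional character vector of peak-current direction
#'   classes (`"LOF"`/`"GOF"`/`"WT-like"`) for experimental records.
#' @param oversample_ratio Experimental replication factor (default 3).
#' @param boundary Entropy-separation decision boundary (default 0.05).
#' @return List with `ensemble` (a `kv_ensemble`) and `report` (a
#'   `kv_eval_report`).
#' @export
run_cv <- function(X, Y, is_experimental, config = network_config(),
                   plan = make_cv_plan(nrow(X)), seed = 1,
                   directions = NULL, oversample_ratio = 3,
                   boundary = 0.05) {
  n <- nrow(X)
  stopifnot(nrow(Y) == n, length(is_experimental) == n,
            length(plan$assignment) == n)
  test_pred <- matrix(NA_real_, n, 4,
                      dimnames = list(rownames(X), names(PARAM_LABELS)))
  mon_pred <- NULL; mon_lab <- NULL; mon_exp <- logical(0)
  models <- vector("list", plan$k)
  for (r in seq_len(plan$k)) {
    rot <- plan$rotations[[r]]
    scaler <- fit_scaler(X[rot$train, , drop = FALSE])
    set.seed((plan$seed %% 100000L) * 10000L + r)  # keep below 2^31
    tr_idx <- oversample_fold(rot$train, is_experimental, oversample_ratio)
    model <- tryCatch(
      nn_train(apply_scaler(scaler, X[tr_idx, , drop = FALSE]),
               Y[tr_idx, , drop = FALSE],
               apply_scaler(scaler, X[rot$monitor, , drop = FALSE]),
               Y[rot$monitor, , drop = FALSE],
               config, seed = seed + r),
      error = function(e) stop("rotation ", r, ": ", conditionMessage(e),
                               call. = FALSE))
    model$scaler <- scaler
    models[[r]] <- model
    test_pred[rot$test, ] <- nn_forward(
      model, apply_scaler(scaler, X[rot$test, , drop = FALSE]))
    mon_pred <- rbind(mon_pred, nn_forward(
      model, apply_scaler(scaler, X[rot$monitor, , drop = FALSE])))
    mon_lab <- rbind(mon_lab, Y[rot$monitor, , drop = FALSE])
    mon_exp <- c(mon_exp, is_experimental[rot$monitor])
  }
  thresholds <- vapply(1:4, function(j) {
    optimize_threshold(mon_pred[, j], mon_lab[, j])$threshold
  }, numeric(1))
  names(thresholds) <- names(PARAM_LABELS)

  exp_i <- which(is_experimental)
  per_output <- lapply(1:4, function(j) {
    s <- test_pred[exp_i, j]; y <- Y[exp_i, j]
    roc <- if (length(unique(y)) > 1) roc_curve(s, y) else NULL
    list(threshold = thresholds[j],
         mcc = mcc_at(s, y, thresholds[j]),
         mcc_all = mcc_at(test_pred[, j], Y[, j], thresholds[j]),
         auc = if (!is.null(roc)) roc$auc else NA_real_,
         roc = roc)
  })
  names(per_output) <- names(PARAM_LABELS)

  np_i <- which(!is_experimental)
  np_acc <- if (length(np_i)) {
    mean(vapply(1:4, function(j) {
      mean(test_pred[np_i, j] < thresholds[j])
    }, numeric(1)))
  } else NA_real_

  entropy <- vapply(1:4, function(j) {
    benign <- exp_i[Y[exp_i, j] == 0]
    if (!length(np_i) || !length(benign)) return(NA_real_)
    entropy_separation(c(test_pred[np_i, j], test_pred[benign, j]),
                       c(rep(0L, length(np_i)), rep(1L, length(benign))),
                       boundary)
  }, numeric(1))
  names(entropy) <- names(PARAM_LABELS)

  class_acc <- NULL
  if (!is.null(directions)) {
    iks_t <- thresholds["iks"]
    class_acc <- vapply(c("LOF", "GOF", "WT-like"), function(cl) {
      i <- exp_i[directions[exp_i] == cl]
      if (!length(i)) return(NA_real_)
      mean((test_pred[i, "iks"] >= iks_t) == (Y[i, 1] == 1))
    }, numeric(1))
  }

  mccs <- vapply(per_output, `[[`, numeric(1), "mcc")
  mccs_all <- vapply(per_output, `[[`, numeric(1), "mcc_all")
  report <- structure(list(
    per_output = per_output,
    thresholds = thresholds,
    mcc_average = mean(mccs),
    mcc_average_all = mean(mccs_all),
    auc_average = mean(vapply(per_output, `[[`, numeric(1), "auc"),
                       na.rm = TRUE),
    nonperturbing_accuracy = np_acc,
    entropy = entropy,
    class_accuracy = class_acc,
    n = n, n_experimental = length(exp_i)
  ), class = "kv_eval_report")

  ensemble <- structure(list(models = models, feature_set = config$feature_set,
                             thresholds = thresholds, plan = plan),
                        class = "kv_ensemble")
  list(ensemble = ensemble, report = report, test_predictions = test_pred)
}

#' @export
print.kv_eval_report <- function(x, ...) {
  cat("Cross-validated evaluation (", x$n_experimental,
      " experimental / ", x$n, " total records)\n", sep = "")
  for (p in names(x$per_output)) {
    po <- x$per_output[[p]]
    cat(sprintf("  %-9s MCC %5.2f (threshold %.2f)  AUC %s\n", p, po$mcc,
                po$threshold,
                ifelse(is.na(po$auc), "NA", sprintf("%.2f", po$auc))))
  }
  cat(sprintf("  MCC_average %.3f (all records: %.3f)\n",
              x$mcc_average, x$mcc_average_all))
  if (!is.na(x$nonperturbing_accuracy)) {
    cat(sprintf("  non-perturbing benign accuracy %.1f%%\n",
                100 * x$nonperturbing_accuracy))
  }
  if (any(!is.na(x$entropy))) {
    cat("  entropy separation:",
        paste(sprintf("%s %.2f", names(x$entropy), x$entropy),
              collapse = ", "), "\n")
  }
  invisible(x)
}
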