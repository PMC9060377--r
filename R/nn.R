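#' Leaky rectifier activation
#'
#' `f(x) = x` for `x > 0`, `0.05 x` otherwise (slope configurable). Used
#' by every hidden neuron of the network.
#'
#' @param x Numeric vector/matrix.
#' @param slope Slope for non-positive inputs.
#' @return Same shape as `x`.
#' @export
leaky_relu <- function(x, slope = 0.05) {
  pmax(x, slope * x)  # equals x for x > 0, slope*x otherwise (slope < 1)
}

.leaky_grad <- function(x, slope) {
  g <- x > 0
  g + slope * (1 - g)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Network hyper-parameter configuration
#'
#' Returns the published architecture for a feature set: input layer
#' sized to the feature count, first hidden layer of 32 neurons with 33%
#' dropout, second hidden layer of 12 neurons with 33% dropout
#' (`EVO2`/`COMBINED12`) or 8 neurons without dropout (`BIOPHYS14`),
#' four sigmoid output neurons (one per functional parameter), input
#' dropout 20% (`BIOPHYS14`) or 5% (others), leaky-ReLU slope 0.05,
#' learning rate 0.001, momentum 0.5, 1200 full-batch iterations.
#' Any field can be overridden through `...`.
#'
#' @param feature_set `"COMBINED12"`, `"BIOPHYS14"` or `"EVO2"`.
#' @param ... Overrides for any configuration field (`n_inputs`, `h1`,
#'   `h2`, `p_in`, `p_h1`, `p_h2`, `leaky_slope`, `lr`, `momentum`,
#'   `iters`, `monitor_every`, `loss` = `"bce"` or `"mse"`).
#' @return A `kv_net_config` list.
#' @export
network_config <- function(feature_set = "COMBINED12", ...) {
  base <- switch(feature_set,
    COMBINED12 = list(n_inputs = 12L, h2 = 12L, p_in = 0.05, p_h2 = 1 / 3),
    EVO2       = list(n_inputs = 2L,  h2 = 12L, p_in = 0.05, p_h2 = 1 / 3),
    BIOPHYS14  = list(n_inputs = 14L, h2 = 8L,  p_in = 0.20, p_h2 = 0),
    stop("unknown feature set: ", feature_set))
  cfg <- utils::modifyList(c(base, list(
    feature_set = feature_set, h1 = 32L, p_h1 = 1 / 3, n_outputs = 4L,
    leaky_slope = 0.05, lr = 0.001, momentum = 0.5, iters = 1200L,
    monitor_every = 10L, loss = "bce")), list(...))
  stopifnot(cfg$n_inputs >= 1, cfg$h1 >= 1, cfg$h2 >= 1,
            cfg$p_in >= 0, cfg$p_in < 1, cfg$p_h1 >= 0, cfg$p_h1 < 1,
            cfg$p_h2 >= 0, cfg$p_h2 < 1, cfg$loss %in% c("bce", "mse"))
  class(cfg) <- "kv_net_config"
  cfg
}

#' Number of trainable parameters of a configuration
#'
#' Sum of `fan_in * fan_out + fan_out` over the three layer transitions.
#'
#' @param config A [network_config()].
#' @return Integer parameter count.
#' @export
parameter_count <- function(config) {
  d <- config$n_inputs; h1 <- config$h1; h2 <- config$h2; k <- config$n_outputs
  as.integer(d * h1 + h1 + h1 * h2 + h2 + h2 * k + k)
}

# Glorot-uniform initial weights; biases zero. Consumes RNG.
init_network <- function(config) {
  mk <- function(fi, fo) {
    a <- sqrt(6 / (fi + fo))
    matrix(stats::runif(fi * fo, -a, a), fi, fo)
  }
  list(W1 = mk(config$n_inputs, config$h1), b1 = numeric(config$h1),
       W2 = mk(config$h1, config$h2),       b2 = numeric(config$h2),
       W3 = mk(config$h2, config$n_outputs), b3 = numeric(config$n_outputs))
}

# inverted-dropout mask: Bernoulli(keep)/keep, or NULL when rate is 0
.mask <- function(n, m, rate) {
  if (rate <= 0) return(NULL)
  keep <- 1 - rate
  matrix((stats::runif(n * m) < keep) / keep, n, m)
}

# forward pass keeping intermediates for backprop; masks NULL at inference
.add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

.forward_full <- function(w, X, config, masks = NULL) {
  Xd <- if (!is.null(masks$m0)) X * masks$m0 else X
  Z1 <- .add_bias(Xd %*% w$W1, w$b1)
  G1 <- .leaky_grad(Z1, config$leaky_slope)  # activation = Z * grad factor
  A1d <- Z1 * G1
  if (!is.null(masks$m1)) A1d <- A1d * masks$m1
  Z2 <- .add_bias(A1d %*% w$W2, w$b2)
  G2 <- .leaky_grad(Z2, config$leaky_slope)
  A2d <- Z2 * G2
  if (!is.null(masks$m2)) A2d <- A2d * masks$m2
  Z3 <- .add_bias(A2d %*% w$W3, w$b3)
  list(P = .sigmoid(Z3), G1 = G1, A1d = A1d, G2 = G2, A2d = A2d, Xd = Xd)
}

# Surrogate training loss: cross-entropy (or squared error) summed over
# the batch and averaged over the four outputs. Normalizing by outputs
# only keeps the gradient scale independent of batch size, which is what
# makes the published learning rate (0.001) effective within the
# published 1200 full-batch iterations. Clamped logs for safety.
nn_loss_value <- function(P, Y, loss = "bce") {
  k <- ncol(Y)
  if (loss == "mse") return(sum((P - Y)^2) / k)
  eps <- 1e-12
  -sum(Y * log(pmax(P, eps)) + (1 - Y) * log(pmax(1 - P, eps))) / k
}

# gradients of the mean loss wrt all weights, given a forward cache
.backward <- function(w, fw, Y, config, masks = NULL) {
  k <- ncol(Y)
  dZ3 <- if (config$loss == "mse") {
    2 * (fw$P - Y) * fw$P * (1 - fw$P) / k
  } else {
    (fw$P - Y) / k
  }
  dW3 <- crossprod(fw$A2d, dZ3); db3 <- colSums(dZ3)
  dA2 <- tcrossprod(dZ3, w$W3)
  if (!is.null(masks$m2)) dA2 <- dA2 * masks$m2
  dZ2 <- dA2 * fw$G2
  dW2 <- crossprod(fw$A1d, dZ2); db2 <- colSums(dZ2)
  dA1 <- tcrossprod(dZ2, w$W2)
  if (!is.null(masks$m1)) dA1 <- dA1 * masks$m1
  dZ1 <- dA1 * fw$G1
  dW1 <- crossprod(fw$Xd, dZ1); db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

#' Loss and analytic gradients of a model on a batch (no dropout)
#'
#' Exposed for gradient verification and diagnostics.
#'
#' @param model A `kv_model` (or a bare weight list plus `config`).
#' @param X Scaled input matrix.
#' @param Y 0/1 label matrix with `n_outputs` columns.
#' @param config Configuration; defaults to the model's.
#' @return List with `loss` and `grads` (same shapes as the weights).
#' @export
nn_gradients <- function(model, X, Y, config = model$config) {
  w <- model$weights
  fw <- .forward_full(w, X, config)
  list(loss = nn_loss_value(fw$P, Y, config$loss),
       grads = .backward(w, fw, Y, config))
}

#' Forward pass of a trained model
#'
#' Inference applies no dropout and is deterministic for fixed weights.
#' In training mode, inverted-scaling dropout masks are drawn from the
#' session RNG (rates from the configuration), so activations need no
#' rescaling at inference.
#'
#' @param model A `kv_model`.
#' @param X Input matrix (already standardized), `n_inputs` columns.
#' @param training Apply dropout masks drawn from the RNG?
#' @return Matrix of `n_outputs` probabilities in \[0, 1\] per row.
#' @export
nn_forward <- function(model, X, training = FALSE) {
  config <- model$config
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != config$n_inputs) {
    stop("input has ", ncol(X), " features; network expects ",
         config$n_inputs)
  }
  masks <- NULL
  if (training) {
    n <- nrow(X)
    masks <- list(m0 = .mask(n, config$n_inputs, config$p_in),
                  m1 = .mask(n, config$h1, config$p_h1),
                  m2 = .mask(n, config$h2, config$p_h2))
  }
  .forward_full(model$weights, X, config, masks)$P
}

#' Train one multitask network with momentum SGD
#'
#' Full-batch backpropagation for `config$iters` iterations minimizing
#' mean binary cross-entropy (or squared error) over the four outputs,
#' with inverted-scaling dropout and classical momentum. Every
#' `config$monitor_every` iterations the accuracy at threshold 0.5 on
#' the monitoring set (averaged over the four outputs, no dropout) is
#' recorded, and the returned model carries the weight snapshot with the
#' best monitor accuracy (ties resolved toward the later snapshot).
#'
#' @param X,Y Scaled training inputs and 0/1 labels (matrix, 4 columns).
#' @param Xmon,Ymon Monitoring set in the same representation.
#' @param config A [network_config()].
#' @param seed Integer seed; fixes initialization and dropout, making
#'   training bit-for-bit reproducible.
#' @return A `kv_model`: list with `weights`, `config`, `seed`,
#'   `monitor_accuracy`, `monitor_iter`, and optionally a `scaler`
#'   attached by the cross-validation driver.
#' @export
nn_train <- function(X, Y, Xmon, Ymon, config = network_config(), seed = 1) {
  stopifnot(nrow(X) > 0, nrow(Xmon) > 0, nrow(X) == nrow(Y),
            ncol(X) == config$n_inputs, ncol(Y) == config$n_outputs)
  set.seed(seed)
  w <- init_network(config)
  v <- lapply(w, function(m) m * 0)
  n <- nrow(X)
  best <- list(acc = -Inf, iter = NA_integer_, w = w)
  for (it in seq_len(config$iters)) {
    masks <- list(m0 = .mask(n, config$n_inputs, config$p_in),
                  m1 = .mask(n, config$h1, config$p_h1),
                  m2 = .mask(n, config$h2, config$p_h2))
    fw <- .forward_full(w, X, config, masks)
    if (any(!is.finite(fw$P))) {
      stop("training diverged (non-finite output) at iteration ", it)
    }
    g <- .backward(w, fw, Y, config, masks)
    for (nm in names(w)) {
      v[[nm]] <- config$momentum * v[[nm]] - config$lr * g[[nm]]
      w[[nm]] <- w[[nm]] + v[[nm]]
    }
    if (it %% config$monitor_every == 0 || it == config$iters) {
      if (!all(vapply(w, function(m) all(is.finite(m)), logical(1)))) {
        stop("training diverged (non-finite weights) at iteration ", it)
      }
      Pm <- .forward_full(w, Xmon, config)$P
      if (any(!is.finite(Pm))) {
        stop("training diverged (non-finite monitor output) at iteration ", it)
      }
      acc <- mean((Pm >= 0.5) == (Ymon >= 0.5))
      if (acc >= best$acc) best <- list(acc = acc, iter = it, w = w)
    }
  }
  structure(list(weights = best$w, config = config, seed = seed,
                 monitor_accuracy = best$acc, monitor_iter = best$iter,
                 scaler = NULL),
            class = "kv_model")
}

#' Predict with a single trained model
#'
#' Applies the model's stored scaler (if any) and runs an inference
#' forward pass.
#'
#' @param object A `kv_model`.
#' @param newdata Feature matrix in the model's raw feature space.
#' @param ... Unused.
#' @return Matrix of probabilities.
#' @export
predict.kv_model <- function(object, newdata, ...) {
  X <- newdata
  if (!is.null(object$scaler)) X <- apply_scaler(object$scaler, X)
  nn_forward(object, X)
}

#' Ensemble prediction: mean over member models
#'
#' @param object A `kv_ensemble` (see [run_cv()]).
#' @param newdata Raw (unscaled) feature matrix; each member applies its
#'   own training-fold scaler.
#' @param ... Unused.
#' @return Matrix of mean probabilities, 4 columns named by parameter.
#' @export
predict.kv_ensemble <- function(object, newdata, ...) {
  preds <- lapply(object$models, predict, newdata = newdata)
  out <- Reduce(`+`, preds) / length(preds)
  colnames(out) <- names(object$thresholds)
  out
}

#' Serialize / restore a trained ensemble as JSON
#'
#' Stores configurations, per-member weights, scalers and tuned decision
#' thresholds in a single JSON document.
#'
#' @param ensemble A `kv_ensemble`.
#' @param path Output (input) file.
#' @return `path` invisibly; `ensemble_from_json()` returns the ensemble.
#' @export
ensemble_to_json <- function(ensemble, path) {
  ser <- list(
    feature_set = ensemble$feature_set,
    thresholds = as.list(ensemble$thresholds),
    models = lapply(ensemble$models, function(m) list(
      seed = m$seed, monitor_accuracy = m$monitor_accuracy,
      monitor_iter = m$monitor_iter,
      config = unclass(m$config),
      weights = lapply(m$weights, function(x) {
        if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
        else list(dim = length(x), data = as.numeric(x))
      }),
      scaler = if (!is.null(m$scaler)) {
        list(center = as.numeric(m$scaler$center),
             scale = as.numeric(m$scaler$scale),
             names = m$scaler$names)
      }))
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname ensemble_to_json
#' @export
ensemble_from_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  models <- lapply(ser$models, function(m) {
    cfg <- m$config
    class(cfg) <- "kv_net_config"
    w <- lapply(m$weights, function(x) {
      if (length(x$dim) == 2) matrix(x$data, x$dim[1], x$dim[2])
      else as.numeric(x$data)
    })
    scaler <- NULL
    if (!is.null(m$scaler)) {
      sc <- m$scaler$scale
      sc[!is.finite(sc)] <- Inf
      scaler <- structure(list(center = m$scaler$center, scale = sc,
                               names = m$scaler$names), class = "kv_scaler")
    }
    structure(list(weights = w, config = cfg, seed = m$seed,
                   monitor_accuracy = m$monitor_accuracy,
                   monitor_iter = m$monitor_iter, scaler = scaler),
              class = "kv_model")
  })
  structure(list(models = models, feature_set = ser$feature_set,
                 thresholds = unlist(ser$thresholds)),
            class = "kv_ensemble")
}
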