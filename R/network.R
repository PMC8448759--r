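#' Training configuration
#'
#' Bundles the optimization hyperparameters of the training loop. Defaults
#' follow the framework's standard settings: Adam, batch size 64, early
#' stopping after 10 epochs without validation-loss improvement.
#'
#' @param optimizer `"adam"` or `"adadelta"`.
#' @param learning_rate positive step size (Adadelta conventionally uses 1).
#' @param l1 L1 kernel regularization penalty (applies to link weights, not
#'   biases), >= 0.
#' @param batch_size mini-batch size; `Inf` trains full-batch.
#' @param patience epochs without validation-loss improvement tolerated
#'   before stopping.
#' @param max_epochs hard cap on epochs.
#' @param class_weights optional numeric pair `c(control, case)` for the
#'   weighted cross-entropy; default is inverse class frequency normalized to
#'   mean 1 (`n/(2*n_controls)`, `n/(2*n_cases)`), computed from the data.
#' @param seed integer seed making runs reproducible.
#' @return a list of class `"train_config"`.
#' @export
train_config <- function(optimizer = c("adam", "adadelta"),
                         learning_rate = 0.001, l1 = 0, batch_size = 64,
                         patience = 10, max_epochs = 500,
                         class_weights = NULL, seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, l1 >= 0, batch_size >= 1,
            patience >= 1, max_epochs >= 1)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 l1 = l1, batch_size = batch_size, patience = patience,
                 max_epochs = max_epochs, class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' The standard hyperparameter grid
#'
#' Cartesian product of the four optimizer settings (Adadelta with learning
#' rate 1; Adam with learning rates 0.01, 0.001, 0.0001) and the
#' de-duplicated L1 penalty set, giving 16 configurations by default. The
#' best configuration is chosen by validation AUC (ties: lower penalty);
#' the held-out test set is touched only for the final report.
#'
#' @param penalties L1 penalties to scan. The default is the de-duplicated
#'   standard list `c(0.1, 0.001, 1e-5, 0)`; pass
#'   `c(0.1, 0.01, 0.001, 1e-5, 0)` to include the 0.01 reading.
#' @param ... further arguments forwarded to every [train_config()].
#' @return list of [train_config()] objects.
#' @export
hyperparameter_grid <- function(penalties = c(0.1, 0.001, 1e-5, 0), ...) {
  penalties <- sort(unique(penalties), decreasing = TRUE)
  opts <- list(list(optimizer = "adadelta", learning_rate = 1),
               list(optimizer = "adam", learning_rate = 0.01),
               list(optimizer = "adam", learning_rate = 0.001),
               list(optimizer = "adam", learning_rate = 0.0001))
  grid <- list()
  for (o in opts) {
    for (p in penalties) {
      grid[[length(grid) + 1L]] <-
        train_config(optimizer = o$optimizer,
                     learning_rate = o$learning_rate, l1 = p, ...)
    }
  }
  grid
}

#' Pick the best configuration from grid results
#'
#' Selection rule: highest validation AUC; exact ties resolved in favour of
#' the lower L1 penalty (the less constrained reading of equal evidence).
#'
#' @param results data.frame with columns `val_auc` and `l1` (one row per
#'   configuration).
#' @return integer row index of the winning configuration.
#' @export
select_config <- function(results) {
  stopifnot(all(c("val_auc", "l1") %in% names(results)))
  order(-results$val_auc, results$l1)[1]
}

#' Balanced class weights for the weighted cross-entropy
#'
#' `w0 = n / (2 * n_controls)`, `w1 = n / (2 * n_cases)`: inverse class
#' frequency normalized so a balanced dataset gets unit weights.
#'
#' @param labels binary labels.
#' @return named numeric pair `c(control = w0, case = w1)`.
#' @export
class_weights <- function(labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("cannot compute class weights: dataset contains a single class")
  }
  n <- n1 + n0
  c(control = n / (2 * n0), case = n / (2 * n1))
}

#' Weighted binary cross-entropy
#'
#' Mean over the batch of
#' `-(w1 * y * log p + w0 * (1 - y) * log(1 - p))`, with predictions clipped
#' to `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param y binary labels.
#' @param p predicted probabilities.
#' @param weights numeric pair `c(control, case)`; default unweighted.
#' @return scalar loss.
#' @examples
#' weighted_bce(1, 0.5)  # log(2)
#' @export
weighted_bce <- function(y, p, weights = c(1, 1)) {
  y <- as_binary_labels(y)
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(weights[2] * y * log(p) + weights[1] * (1 - y) * log(1 - p))
}

#' L1 regularization term of a network
#'
#' `penalty * sum(|w|)` over every link weight of every layer; biases are
#' excluded.
#'
#' @param object an `"annonet"` fit, an internal network, or a list of
#'   [sparse_layer()]s.
#' @param penalty penalty coefficient; defaults to the penalty the network
#'   was configured with (0 if unknown).
#' @return scalar penalty term.
#' @export
l1_term <- function(object, penalty = NULL) {
  layers <- network_layers(object)
  penalty <- penalty %||% object$config$l1 %||% 0
  if (penalty == 0) return(0)
  penalty * sum(vapply(layers, function(l) sum(abs(l$w)), numeric(1)))
}

## Internal: pull the layer list out of any of the accepted objects.
network_layers <- function(object) {
  if (inherits(object, "annonet")) return(object$net$layers)
  if (!is.null(object$layers)) return(object$layers)
  stopifnot(all(vapply(object, inherits, logical(1), "sparse_layer")))
  object
}

#' Assemble a network from a validated connectivity stack
#'
#' Creates one sparse layer per connectivity matrix; if the last matrix does
#' not already end in a single node, a final all-to-one sparse layer is
#' appended. Classification networks use tanh hidden activations and a
#' sigmoid output; regression networks use ReLU hidden activations and a
#' linear output (trained with mean squared error).
#'
#' @param matrices a [connectivity()] object or list of them (validated with
#'   [validate_stack()]; an invalid stack is an error).
#' @param task `"classification"` or `"regression"`.
#' @param hidden_activation override for hidden layers.
#' @param batchnorm precede each layer with batch normalization (without
#'   scaling and centering)? Default TRUE.
#' @param allow_empty_outputs forwarded to [validate_stack()] (for masked
#'   layers).
#' @return an object of class `"annonet_net"` (untrained).
#' @export
assemble <- function(matrices, task = c("classification", "regression"),
                     hidden_activation = NULL, batchnorm = TRUE,
                     allow_empty_outputs = FALSE) {
  task <- match.arg(task)
  if (inherits(matrices, "connectivity")) matrices <- list(matrices)
  validate_stack(matrices, allow_empty_outputs = allow_empty_outputs)
  hidden <- hidden_activation %||%
    if (task == "classification") "tanh" else "relu"
  out_act <- if (task == "classification") "sigmoid" else "linear"
  last <- matrices[[length(matrices)]]
  if (length(last$output_names) > 1L) {
    onames <- last$output_names
    top <- connectivity(onames, "output",
                        cbind(seq_along(onames), 1L), label = "output")
    matrices <- c(matrices, list(top))
  }
  L <- length(matrices)
  layers <- lapply(seq_len(L), function(k) {
    sparse_layer(matrices[[k]],
                 activation = if (k == L) out_act else hidden,
                 batchnorm = batchnorm)
  })
  structure(list(layers = layers, task = task, initialized = FALSE),
            class = "annonet_net")
}

#' @export
print.annonet_net <- function(x, ...) {
  cat(sprintf("Sparse network (%s), %d layers, %d parameters\n",
              x$task, length(x$layers), n_parameters(x)))
  for (l in x$layers) {
    cat(sprintf("  %-14s %6d -> %5d nodes, %7d links, %s%s\n",
                l$cm$label, length(l$cm$input_names),
                length(l$cm$output_names), n_links(l$cm), l$activation,
                if (l$use_bn) " (batchnorm)" else ""))
  }
  invisible(x)
}

#' Trainable parameter count of a network
#'
#' Equals the total number of links plus one bias per output node; a dense
#' network of the same shape would need `n_in * n_out` weights per layer.
#'
#' @param object an `"annonet"` fit or `"annonet_net"`.
#' @return integer count.
#' @export
n_parameters <- function(object) {
  layers <- network_layers(object)
  sum(vapply(layers, function(l) length(l$w) + length(l$b), integer(1)))
}

## Glorot-style init per output node: each output j draws its incoming
## weights uniform in +/- sqrt(6 / (fan_in_j + 1)); biases start at zero.
init_weights <- function(net) {
  net$layers <- lapply(net$layers, function(l) {
    fan_in <- tabulate(l$cm$links[, 2], nbins = length(l$cm$output_names))
    lim <- sqrt(6 / (fan_in[l$cm$links[, 2]] + 1))
    l$w <- stats::runif(length(l$w), -lim, lim)
    l$b <- numeric(length(l$b))
    l$bn <- list(t = 0L, m_acc = numeric(length(l$cm$input_names)),
                 v_acc = numeric(length(l$cm$input_names)))
    l
  })
  net$initialized <- TRUE
  net
}

BN_EPS <- 1e-3

## Full forward pass. training=TRUE uses batch moments (and optionally
## updates running moments); otherwise debias-corrected running moments.
## Returns list(output, caches) where caches[[k]] holds the layer's pre-bn
## input x, post-bn z, activation a, and bn sd.
nn_forward <- function(net, x, training = FALSE, update_stats = FALSE,
                       keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  a <- as.matrix(x)
  for (k in seq_along(net$layers)) {
    l <- net$layers[[k]]
    x_in <- a
    if (l$use_bn) {
      if (training) {
        z <- batchnorm_plain(x_in, eps = BN_EPS)
        mo <- attr(z, "moments")
        if (update_stats) {
          net$layers[[k]]$bn <- bn_update(l$bn, mo$mean, mo$var)
        }
      } else {
        z <- batchnorm_plain(x_in, eps = BN_EPS, moments = bn_moments(l$bn))
        mo <- attr(z, "moments")
      }
      sd_k <- sqrt(mo$var + BN_EPS)
    } else {
      z <- x_in
      sd_k <- NULL
    }
    s <- as.matrix(z %*% layer_weight_matrix(l))
    s <- sweep(s, 2, l$b, "+")
    a <- activation_fun(l$activation)(s)
    if (keep_cache) {
      caches[[k]] <- list(x = x_in, z = z, a = a, sd = sd_k)
    }
  }
  list(output = a, caches = caches, net = net)
}

## Backward pass. dS is the gradient of the loss w.r.t. the final layer's
## pre-activation. Returns per-layer gradients list(w =, b =).
nn_backward <- function(net, caches, dS) {
  L <- length(net$layers)
  grads <- vector("list", L)
  for (k in L:1) {
    l <- net$layers[[k]]
    z <- caches[[k]]$z
    ii <- l$cm$links[, 1]
    jj <- l$cm$links[, 2]
    gw <- if (length(ii)) {
      colSums(z[, ii, drop = FALSE] * dS[, jj, drop = FALSE])
    } else numeric(0)
    gb <- colSums(dS)
    grads[[k]] <- list(w = gw, b = gb)
    if (k > 1L) {
      W <- layer_weight_matrix(l)
      dZ <- as.matrix(Matrix::tcrossprod(dS, W))
      dX <- if (l$use_bn) {
        batchnorm_backward(dZ, z, caches[[k]]$sd)
      } else dZ
      prev <- net$layers[[k - 1]]
      dS <- dX * activation_grad(prev$activation, caches[[k - 1]]$a)
    }
  }
  grads
}

## Gradient of the data loss w.r.t. the output pre-activation, divided by n.
output_delta <- function(task, s_or_p, y, weights) {
  n <- length(y)
  if (task == "classification") {
    p <- s_or_p
    matrix((weights[2] * y * (p - 1) + weights[1] * (1 - y) * p) / n, ncol = 1)
  } else {
    matrix(2 * (s_or_p - y) / n, ncol = 1)
  }
}

data_loss <- function(task, pred, y, weights) {
  if (task == "classification") {
    weighted_bce(y, pred, weights)
  } else {
    mean((pred - y)^2)
  }
}

## ---- optimizers ------------------------------------------------------------

opt_init <- function(config, params) {
  list(kind = config$optimizer, lr = config$learning_rate, t = 0L,
       m = lapply(params, function(p) numeric(length(p))),
       v = lapply(params, function(p) numeric(length(p))))
}

opt_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  if (state$kind == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (i in seq_along(params)) {
      state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * grads[[i]]
      state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * grads[[i]]^2
      mhat <- state$m[[i]] / (1 - b1^state$t)
      vhat <- state$v[[i]] / (1 - b2^state$t)
      params[[i]] <- params[[i]] - state$lr * mhat / (sqrt(vhat) + eps)
    }
  } else {  # adadelta
    rho <- 0.95; eps <- 1e-6
    for (i in seq_along(params)) {
      state$m[[i]] <- rho * state$m[[i]] + (1 - rho) * grads[[i]]^2
      dx <- -sqrt(state$v[[i]] + eps) / sqrt(state$m[[i]] + eps) * grads[[i]]
      state$v[[i]] <- rho * state$v[[i]] + (1 - rho) * dx^2
      params[[i]] <- params[[i]] + state$lr * dx
    }
  }
  list(params = params, state = state)
}

## flatten layer parameters to a plain list and back
get_params <- function(net) {
  out <- list()
  for (l in net$layers) out <- c(out, list(l$w), list(l$b))
  out
}

set_params <- function(net, params) {
  i <- 1L
  for (k in seq_along(net$layers)) {
    net$layers[[k]]$w <- params[[i]]
    net$layers[[k]]$b <- params[[i + 1L]]
    i <- i + 2L
  }
  net
}

## ---- early stopping --------------------------------------------------------

## Pure patience bookkeeping so the mechanism is testable with scripted
## losses: returns updated state with $stop set once `patience` epochs pass
## without improvement; $best_epoch tracks the minimum.
early_stopping_update <- function(state, loss, patience) {
  if (is.null(state)) {
    state <- list(best = Inf, best_epoch = 0L, wait = 0L,
                  epoch = 0L, stop = FALSE)
  }
  state$epoch <- state$epoch + 1L
  if (loss < state$best) {
    state$best <- loss
    state$best_epoch <- state$epoch
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= patience) state$stop <- TRUE
  }
  state
}

## ---- training loop ---------------------------------------------------------

#' Train a sparse network
#'
#' Minimizes the task loss (weighted binary cross-entropy for
#' classification, mean squared error for regression) plus the L1 penalty by
#' mini-batch Adam or Adadelta, monitoring the validation loss (including
#' the penalty term) for early stopping: training halts after `patience`
#' epochs without improvement and the weights of the best-validation-loss
#' epoch are restored. Fully reproducible given `config$seed` (training is
#' single-threaded and deterministic).
#'
#' Most users call [annonet()] instead, which assembles the network,
#' handles the validation split, and returns a full model object.
#'
#' @param net an `"annonet_net"` from [assemble()].
#' @param x,y training genotype matrix (samples x inputs, column order =
#'   network input order) and labels/outcomes.
#' @param x_val,y_val validation set, disjoint from training.
#' @param config a [train_config()].
#' @param warm_start keep the network's current weights instead of
#'   re-initializing (used for staged optimization schedules).
#' @param verbose print per-epoch progress?
#' @return list with elements `net` (trained, best weights), `history`
#'   (per-epoch data.frame), `best_epoch`.
#' @export
train_network <- function(net, x, y, x_val, y_val, config = train_config(),
                          warm_start = FALSE, verbose = FALSE) {
  stopifnot(inherits(net, "annonet_net"), inherits(config, "train_config"))
  x <- as.matrix(x); x_val <- as.matrix(x_val)
  n <- nrow(x)
  task <- net$task
  if (task == "classification") {
    y <- as_binary_labels(y); y_val <- as_binary_labels(y_val)
    cw <- config$class_weights %||% class_weights(y)
  } else {
    y <- as.numeric(y); y_val <- as.numeric(y_val)
    cw <- c(1, 1)
  }
  set.seed(config$seed)
  if (!warm_start || !isTRUE(net$initialized)) net <- init_weights(net)
  params <- get_params(net)
  state <- opt_init(config, params)
  bs <- min(config$batch_size, n)
  pen_idx <- seq(1L, by = 2L, length.out = length(net$layers))  # w slots
  es <- NULL
  best <- list(params = params, layers = net$layers)
  hist <- vector("list", config$max_epochs)
  metric_name <- if (task == "classification") "auc" else "rmse"

  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = bs)
    batches <- lapply(starts, function(s0) idx[s0:min(s0 + bs - 1L, n)])
    ## merge a trailing singleton batch into its neighbour (batchnorm needs
    ## at least two rows)
    nb <- length(batches)
    if (nb > 1L && length(batches[[nb]]) == 1L) {
      batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
      batches[[nb]] <- NULL
    }
    for (bidx in batches) {
      xb <- x[bidx, , drop = FALSE]
      yb <- y[bidx]
      fw <- nn_forward(net, xb, training = TRUE, update_stats = TRUE,
                       keep_cache = TRUE)
      net <- fw$net
      pred <- fw$output[, 1]
      if (any(!is.finite(pred))) {
        stop(sprintf(
          "non-finite predictions at epoch %d (optimizer %s, lr %g)",
          epoch, config$optimizer, config$learning_rate))
      }
      dS <- output_delta(task, pred, yb, cw)
      grads <- nn_backward(net, fw$caches, dS)
      gl <- list()
      for (g in grads) gl <- c(gl, list(g$w), list(g$b))
      if (config$l1 > 0) {
        for (i in pen_idx) gl[[i]] <- gl[[i]] + config$l1 * sign(params[[i]])
      }
      st <- opt_step(state, params, gl)
      params <- st$params
      state <- st$state
      net <- set_params(net, params)
    }
    tr <- nn_forward(net, x, training = FALSE)$output[, 1]
    vl <- nn_forward(net, x_val, training = FALSE)$output[, 1]
    pen <- l1_term(net, config$l1)
    train_loss <- data_loss(task, tr, y, cw) + pen
    val_loss <- data_loss(task, vl, y_val, cw) + pen
    if (!is.finite(train_loss) || !is.finite(val_loss)) {
      stop(sprintf("non-finite loss at epoch %d (optimizer %s, lr %g)",
                   epoch, config$optimizer, config$learning_rate))
    }
    metr <- function(p, yy) {
      if (task == "classification") {
        if (length(unique(yy)) < 2L) NA_real_ else auc_score(p, yy)
      } else sqrt(mean((p - yy)^2))
    }
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_loss = train_loss, val_loss = val_loss,
      train_metric = metr(tr, y), val_metric = metr(vl, y_val))
    if (verbose) {
      cat(sprintf("epoch %3d  loss %.4f  val_loss %.4f  val_%s %.4f\n",
                  epoch, train_loss, val_loss, metric_name,
                  hist[[epoch]]$val_metric))
    }
    prev_best <- if (is.null(es)) Inf else es$best
    es <- early_stopping_update(es, val_loss, config$patience)
    if (val_loss < prev_best) {
      best <- list(params = params, layers = net$layers)
    }
    if (es$stop) break
  }
  net <- set_params(net, best$params)
  ## restore the batchnorm running moments that accompanied the best weights
  for (k in seq_along(net$layers)) net$layers[[k]]$bn <- best$layers[[k]]$bn
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  names(history)[names(history) == "train_metric"] <-
    paste0("train_", metric_name)
  names(history)[names(history) == "val_metric"] <- paste0("val_", metric_name)
  list(net = net, history = history, best_epoch = es$best_epoch,
       class_weights = cw)
}
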