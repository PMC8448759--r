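#' Fit an annotation-guided sparse neural network
#'
#' The main modelling function of the package. Takes a genotype dosage
#' matrix, a phenotype, and a connectivity stack built from biological
#' annotations (see [build_snp_gene_matrix()] and friends), assembles the
#' corresponding sparse network, trains it with mini-batch gradient descent
#' and early stopping, and returns a fitted model object with the usual
#' accessor methods (`print`, `summary`, `coef`, `predict`, `fitted`,
#' `residuals`, `plot`).
#'
#' Each layer computes `activation(sum of linked inputs * weights + bias)`
#' and is preceded by batch normalization without scaling and centering, so
#' that learned weights are directly comparable across nodes — the basis of
#' the interpretation machinery in [relative_importance()].
#'
#' @param x numeric matrix, samples x variants, dosages in `[0, 2]`. Column
#'   names must cover the network's input nodes; columns are re-ordered to
#'   the connectivity input order (unnamed matrices must already be in
#'   order).
#' @param y phenotype: binary (0/1, logical or 2-level factor) for
#'   classification, numeric for regression.
#' @param connectivity a [connectivity()] object or list of them (a
#'   validated stack).
#' @param task `"classification"` or `"regression"`.
#' @param config a [train_config()].
#' @param validation fraction of samples held out (stratified for
#'   classification) for early-stopping validation when `x_val` is not
#'   given.
#' @param x_val,y_val optional explicit validation set.
#' @param hidden_activation,batchnorm forwarded to [assemble()].
#' @param allow_empty_outputs forwarded to [assemble()] (for masked stacks).
#' @param verbose print training progress?
#' @return an object of class `"annonet"`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 300, n_variants = 40,
#'                                   n_genes = 8, h2 = 0.8, seed = 1))
#' cm <- build_snp_gene_matrix(sim$annotation, colnames(sim$genotypes))
#' fit <- annonet(sim$genotypes, sim$labels, cm,
#'                config = train_config(batch_size = Inf, max_epochs = 30,
#'                                      learning_rate = 0.01, seed = 1))
#' fit
#' head(coef(fit))
#' @export
annonet <- function(x, y, connectivity,
                    task = c("classification", "regression"),
                    config = train_config(), validation = 0.2,
                    x_val = NULL, y_val = NULL, hidden_activation = NULL,
                    batchnorm = TRUE, allow_empty_outputs = FALSE,
                    verbose = FALSE) {
  task <- match.arg(task)
  cl <- match.call()
  net <- assemble(connectivity, task = task,
                  hidden_activation = hidden_activation,
                  batchnorm = batchnorm,
                  allow_empty_outputs = allow_empty_outputs)
  input_names <- net$layers[[1]]$cm$input_names
  x <- align_inputs(as.matrix(x), input_names)
  stopifnot(nrow(x) == length(y))
  if (is.null(x_val)) {
    set.seed(config$seed)
    hold <- holdout_index(y, validation,
                          stratify = task == "classification")
    x_val <- x[hold, , drop = FALSE]
    y_val <- y[hold]
    x_tr <- x[-hold, , drop = FALSE]
    y_tr <- y[-hold]
  } else {
    x_val <- align_inputs(as.matrix(x_val), input_names)
    x_tr <- x
    y_tr <- y
  }
  res <- train_network(net, x_tr, y_tr, x_val, y_val, config,
                       verbose = verbose)
  fit <- structure(
    list(net = res$net, task = task, config = config,
         history = res$history, best_epoch = res$best_epoch,
         class_weights = res$class_weights, input_names = input_names,
         n_train = nrow(x_tr), n_val = nrow(x_val), call = cl),
    class = "annonet")
  fit$fitted_values <- predict(fit, x)
  fit$y <- if (task == "classification") as_binary_labels(y) else as.numeric(y)
  fit
}

## stratified holdout indices
holdout_index <- function(y, fraction, stratify = TRUE) {
  n <- length(y)
  if (!stratify) return(sample.int(n, max(1L, round(fraction * n))))
  idx <- unlist(lapply(split(seq_len(n), y), function(ii) {
    sample(ii, max(1L, round(fraction * length(ii))))
  }), use.names = FALSE)
  sort(idx)
}

## reorder data columns to the network input order
align_inputs <- function(x, input_names) {
  if (!is.null(colnames(x))) {
    missing <- setdiff(input_names, colnames(x))
    if (length(missing)) {
      stop("data lacks network inputs: ",
           paste(utils::head(missing, 10), collapse = ", "))
    }
    x <- x[, input_names, drop = FALSE]
  } else if (ncol(x) != length(input_names)) {
    stop(sprintf("unnamed data has %d columns but the network has %d inputs",
                 ncol(x), length(input_names)))
  }
  x
}

#' @export
print.annonet <- function(x, ...) {
  cat("Annotation-guided sparse network fit\n\n")
  print(x$net)
  h <- x$history
  metric <- grep("^val_", names(h), value = TRUE)[2]
  cat(sprintf("\nTrained %d epochs (best epoch %d, patience %d)\n",
              nrow(h), x$best_epoch, x$config$patience))
  cat(sprintf("Best validation loss %.4f, validation %s %.4f\n",
              min(h$val_loss), sub("val_", "", metric),
              h[[metric]][x$best_epoch]))
  invisible(x)
}

#' @export
summary.annonet <- function(object, ...) {
  layers <- object$net$layers
  tab <- data.frame(
    label = vapply(layers, function(l) l$cm$label, character(1)),
    inputs = vapply(layers, function(l) length(l$cm$input_names), integer(1)),
    outputs = vapply(layers, function(l) length(l$cm$output_names), integer(1)),
    links = vapply(layers, function(l) n_links(l$cm), integer(1)),
    activation = vapply(layers, function(l) l$activation, character(1)),
    stringsAsFactors = FALSE)
  structure(list(layers = tab, n_parameters = n_parameters(object),
                 history = object$history, best_epoch = object$best_epoch,
                 task = object$task, config = object$config),
            class = "summary.annonet")
}

#' @export
print.summary.annonet <- function(x, ...) {
  cat(sprintf("Sparse network (%s), %d trainable parameters\n\n",
              x$task, x$n_parameters))
  print(x$layers, row.names = FALSE)
  h <- x$history
  cat(sprintf("\n%d epochs, best %d; final val_loss %.4f (best %.4f)\n",
              nrow(h), x$best_epoch, h$val_loss[nrow(h)], min(h$val_loss)))
  invisible(x)
}

#' Extract learned connection weights
#'
#' @param object an `"annonet"` fit.
#' @param layer optional layer index to restrict to.
#' @param ... unused.
#' @return data.frame with columns `layer`, `label`, `child`, `parent`,
#'   `weight` (one row per link).
#' @export
coef.annonet <- function(object, layer = NULL, ...) {
  layers <- object$net$layers
  ks <- layer %||% seq_along(layers)
  do.call(rbind, lapply(ks, function(k) {
    l <- layers[[k]]
    data.frame(layer = k, label = l$cm$label,
               child = l$cm$input_names[l$cm$links[, 1]],
               parent = l$cm$output_names[l$cm$links[, 2]],
               weight = l$w, stringsAsFactors = FALSE)
  }))
}

#' Predict from a fitted annotation-guided network
#'
#' Runs the network in inference mode (batch normalization uses the running
#' moments accumulated during training).
#'
#' @param object an `"annonet"` fit.
#' @param newdata samples x variants dosage matrix.
#' @param type `"response"` (probability / value) or `"link"` (pre-sigmoid
#'   log-odds; identical to response for regression).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.annonet <- function(object, newdata,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  x <- align_inputs(as.matrix(newdata), object$input_names)
  out <- nn_forward(object$net, x, training = FALSE)$output[, 1]
  if (type == "link" && object$task == "classification") {
    p <- pmin(pmax(out, 1e-7), 1 - 1e-7)
    out <- log(p / (1 - p))
  }
  unname(out)
}

#' @export
fitted.annonet <- function(object, ...) object$fitted_values

#' @export
residuals.annonet <- function(object, ...) {
  object$y - object$fitted_values
}

#' Plot the training history of a fit
#'
#' Draws train/validation loss per epoch and marks the early-stopping
#' optimum.
#'
#' @param x an `"annonet"` fit.
#' @param ... forwarded to [graphics::matplot()].
#' @export
plot.annonet <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Grid search over training configurations
#'
#' Fits one network per configuration, selects the winner by validation AUC
#' (classification) or validation loss (regression); ties favour the lower
#' L1 penalty.
#'
#' @inheritParams annonet
#' @param grid list of [train_config()]s, e.g. [hyperparameter_grid()].
#' @return list with `fit` (best model), `results` (per-config data.frame),
#'   `best` (winning row index).
#' @export
annonet_grid <- function(x, y, connectivity, grid = hyperparameter_grid(),
                         task = c("classification", "regression"), ...) {
  task <- match.arg(task)
  fits <- lapply(grid, function(cfg) {
    annonet(x, y, connectivity, task = task, config = cfg, ...)
  })
  metric <- vapply(fits, function(f) {
    h <- f$history
    if (task == "classification") h$val_auc[f$best_epoch]
    else -h$val_loss[f$best_epoch]
  }, numeric(1))
  results <- data.frame(
    optimizer = vapply(grid, function(g) g$optimizer, character(1)),
    learning_rate = vapply(grid, function(g) g$learning_rate, numeric(1)),
    l1 = vapply(grid, function(g) g$l1, numeric(1)),
    val_auc = metric)
  best <- select_config(results)
  list(fit = fits[[best]], results = results, best = best)
}
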