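#' Sparse network layer
#'
#' One trainable layer of an annotation-guided network: a connectivity matrix
#' plus one learnable weight per link and one bias per output node. The layer
#' computes, for each output node j,
#' `activation( sum_{i linked to j} x_i * w_ij + B_j )` — a pruned dense
#' layer in which non-links are structurally absent, not zeroed.
#'
#' @param cm a [connectivity()] object.
#' @param weights numeric vector, one value per link (row order of
#'   `cm$links`); default all zero.
#' @param bias numeric vector, one per output node; default all zero.
#' @param activation one of `"tanh"`, `"relu"`, `"linear"`, `"sigmoid"`.
#' @param batchnorm precede the layer with batch normalization (without
#'   scaling and centering) during network training?
#' @return an object of class `"sparse_layer"`.
#' @export
sparse_layer <- function(cm, weights = NULL, bias = NULL,
                         activation = c("tanh", "relu", "linear", "sigmoid"),
                         batchnorm = TRUE) {
  activation <- match.arg(activation)
  stopifnot(inherits(cm, "connectivity"))
  m <- nrow(cm$links)
  p <- length(cm$output_names)
  weights <- weights %||% numeric(m)
  bias <- bias %||% numeric(p)
  stopifnot(length(weights) == m, length(bias) == p)
  ## cache a sparse template whose @x slot holds the link index, giving the
  ## permutation from link order to the dgCMatrix storage order
  tmpl <- Matrix::sparseMatrix(i = cm$links[, 1], j = cm$links[, 2],
                               x = seq_len(m), dims = dim(cm))
  structure(
    list(cm = cm, w = as.numeric(weights), b = as.numeric(bias),
         activation = activation, use_bn = batchnorm,
         perm = as.integer(tmpl@x), tmpl = tmpl,
         bn = list(t = 0L, m_acc = numeric(length(cm$input_names)),
                   v_acc = numeric(length(cm$input_names)))),
    class = "sparse_layer"
  )
}

## Internal: the layer's weight matrix as a dgCMatrix.
layer_weight_matrix <- function(layer) {
  W <- layer$tmpl
  W@x <- layer$w[layer$perm]
  W
}

activation_fun <- function(name) {
  switch(name,
    tanh = tanh,
    relu = function(s) pmax(s, 0),
    linear = identity,
    sigmoid = function(s) 1 / (1 + exp(-s)),
    stop("unknown activation: ", name)
  )
}

## derivative of the activation expressed through its output a
activation_grad <- function(name, a) {
  switch(name,
    tanh = 1 - a^2,
    relu = (a > 0) * 1,
    linear = array(1, dim(a)) ,
    sigmoid = a * (1 - a),
    stop("unknown activation: ", name)
  )
}

#' Forward pass through a single sparse layer
#'
#' Applies `activation(x %*% W + B)` with `W` the sparse weight matrix of the
#' layer (no batch normalization; see [predict.annonet()] for full-network
#' inference). The result is independent of link storage order up to
#' floating-point summation.
#'
#' @param layer a [sparse_layer()].
#' @param x numeric matrix (batch x inputs) or a single input vector.
#' @return numeric matrix, batch x outputs.
#' @export
sparse_forward <- function(layer, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(layer$cm$input_names)) {
    stop(sprintf("input width %d != layer inputs %d",
                 ncol(x), length(layer$cm$input_names)))
  }
  s <- as.matrix(x %*% layer_weight_matrix(layer))
  s <- sweep(s, 2, layer$b, "+")
  activation_fun(layer$activation)(s)
}

#' Batch normalization without scaling and centering
#'
#' Normalizes each feature column to zero mean and unit standard deviation
#' using the batch's own (population) moments — with no learnable scale or
#' shift, so downstream weights stay directly comparable. In inference mode,
#' pass previously accumulated `moments` instead.
#'
#' @param x numeric matrix (batch x features); training mode needs >= 2 rows.
#' @param eps variance floor guarding zero-variance features, default 1e-3.
#' @param moments optional `list(mean =, var =)` of running moments for
#'   inference mode.
#' @return normalized matrix with attribute `"moments"` (the moments used).
#' @export
batchnorm_plain <- function(x, eps = 1e-3, moments = NULL) {
  x <- as.matrix(x)
  if (is.null(moments)) {
    if (nrow(x) < 2L) stop("training-mode batch normalization needs >= 2 rows")
    m <- colMeans(x)
    v <- colMeans(x^2) - m^2
    v <- pmax(v, 0)  # guard tiny negative round-off
  } else {
    m <- moments$mean
    v <- moments$var
  }
  z <- sweep(sweep(x, 2, m, "-"), 2, sqrt(v + eps), "/")
  attr(z, "moments") <- list(mean = m, var = v)
  z
}

## Gradient of batchnorm_plain (training mode, population variance):
## given dZ and the cached z and per-column sd = sqrt(var + eps).
batchnorm_backward <- function(dZ, z, sd) {
  n <- nrow(dZ)
  term <- sweep(dZ, 2, colMeans(dZ), "-") - z * rep(colMeans(dZ * z), each = n)
  sweep(term, 2, sd, "/")
}

## Debias-corrected running moments (exponential average with correction,
## so that after the first update the running stats equal the batch stats).
bn_update <- function(bn, m, v, momentum = 0.99) {
  bn$t <- bn$t + 1L
  bn$m_acc <- momentum * bn$m_acc + (1 - momentum) * m
  bn$v_acc <- momentum * bn$v_acc + (1 - momentum) * v
  bn
}

bn_moments <- function(bn) {
  if (bn$t == 0L) {
    return(list(mean = bn$m_acc * 0, var = bn$v_acc * 0 + 1))
  }
  corr <- 1 - 0.99^bn$t
  list(mean = bn$m_acc / corr, var = bn$v_acc / corr)
}
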