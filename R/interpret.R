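#' Activation-scaled (normalized) connection weights
#'
#' Batch normalization makes weights comparable only approximately (it is a
#' batch-wise estimate), so for reporting, each learned weight is multiplied
#' by the empirical standard deviation of its source node's activation over
#' a batch drawn from the training distribution. Standard deviations use the
#' population denominator, matching the batch-normalization convention.
#'
#' @param object an `"annonet"` fit.
#' @param x data batch (>= 2 samples) from the training distribution.
#' @return data.frame with one row per link: `layer`, `label`, `child`,
#'   `parent`, `weight`, `sd_activation`, `normalized_weight`.
#' @export
normalized_weights <- function(object, x) {
  stopifnot(inherits(object, "annonet"))
  x <- align_inputs(as.matrix(x), object$input_names)
  if (nrow(x) < 2L) stop("need at least 2 samples to estimate activation sd")
  fw <- nn_forward(object$net, x, training = FALSE, keep_cache = TRUE)
  layers <- object$net$layers
  acts <- c(list(x), lapply(fw$caches[-length(layers)], `[[`, "a"))
  do.call(rbind, lapply(seq_along(layers), function(k) {
    l <- layers[[k]]
    a <- acts[[k]]
    sdp <- sqrt(pmax(colMeans(a^2) - colMeans(a)^2, 0))
    data.frame(layer = k, label = l$cm$label,
               child = l$cm$input_names[l$cm$links[, 1]],
               parent = l$cm$output_names[l$cm$links[, 2]],
               weight = l$w,
               sd_activation = sdp[l$cm$links[, 1]],
               normalized_weight = l$w * sdp[l$cm$links[, 1]],
               stringsAsFactors = FALSE)
  }))
}

#' Path-product relative importance of every network node
#'
#' The contribution of an input variant is the sum, over all paths from that
#' variant to the output node, of the product of the learned weights along
#' the path. The importance of any higher node is the sum of contributions
#' of the paths passing through it (equivalently: its summed inflow of path
#' products times its summed outflow). Because batch normalization carries
#' no learnable scale or shift, no extra factors enter the products; the
#' activation nonlinearity is deliberately ignored, making this a
#' first-order importance, akin to an effect size rather than a p-value.
#' Sign is retained in the raw importance (direction of effect); relative
#' importance is each node's share of the summed absolute importance within
#' its layer, so shares are well defined even when signs mix.
#'
#' @param object an `"annonet"` fit (or internal network).
#' @return data.frame of class `"importance_table"`: `node_id`, `layer`
#'   (0 = inputs), `layer_label`, `importance`, `relative_importance`,
#'   `parents` (comma-joined next-layer nodes).
#' @examples
#' ## a single path SNP -> gene -> output with weights 0.5 and 0.8
#' ## contributes 0.5 * 0.8 = 0.4 to the SNP
#' @export
relative_importance <- function(object) {
  layers <- network_layers(object)
  L <- length(layers)
  Ws <- lapply(layers, function(l) as.matrix(layer_weight_matrix(l)))
  ## outflow: sum of path products from each node of layer k to the output
  outflow <- vector("list", L + 1L)
  outflow[[L + 1L]] <- 1
  for (k in L:1) outflow[[k]] <- as.numeric(Ws[[k]] %*% outflow[[k + 1L]])
  ## inflow: sum over inputs of path products into each node of layer k
  inflow <- vector("list", L + 1L)
  inflow[[1L]] <- rep(1, length(layers[[1]]$cm$input_names))
  for (k in seq_len(L)) {
    inflow[[k + 1L]] <- as.numeric(inflow[[k]] %*% Ws[[k]])
  }
  node_names <- c(list(layers[[1]]$cm$input_names),
                  lapply(layers, function(l) l$cm$output_names))
  labels <- c("input", vapply(layers, function(l) {
    if (nzchar(l$cm$label)) l$cm$label else "layer"
  }, character(1)))
  parent_str <- function(k, nodes) {
    if (k > L) return(rep(NA_character_, length(nodes)))
    cm <- layers[[k]]$cm
    vapply(seq_along(nodes), function(j) {
      paste(cm$output_names[cm$links[cm$links[, 1] == j, 2]], collapse = ",")
    }, character(1))
  }
  out <- do.call(rbind, lapply(seq_len(L + 1L), function(k) {
    imp <- inflow[[k]] * outflow[[k]]
    tot <- sum(abs(imp))
    data.frame(node_id = node_names[[k]], layer = k - 1L,
               layer_label = labels[[k]], importance = imp,
               relative_importance = if (tot > 0) abs(imp) / tot
                                     else rep(0, length(imp)),
               parents = parent_str(k, node_names[[k]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Manhattan-plot export of per-gene weights
#'
#' A Manhattan view is the cross-section between one layer (typically the
#' gene layer) and the output: per node, the absolute normalized weight of
#' its outgoing links, placed at its genomic coordinate and sorted by
#' position.
#'
#' @param nw data.frame from [normalized_weights()].
#' @param coords data.frame with columns `node_id`, `chrom`, `pos` (1-based).
#' @param layer layer index whose outgoing links are plotted; default the
#'   last layer (gene/pathway -> output).
#' @return data.frame `chrom`, `pos`, `node_id`, `value` sorted by
#'   chromosome then position.
#' @export
manhattan_export <- function(nw, coords, layer = max(nw$layer)) {
  rows <- nw[nw$layer == layer, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no links in layer ", layer)
  val <- tapply(abs(rows$normalized_weight), rows$child, sum)
  out <- data.frame(node_id = names(val), value = as.numeric(val),
                    stringsAsFactors = FALSE)
  coords <- as.data.frame(coords, stringsAsFactors = FALSE)
  stopifnot(all(c("node_id", "chrom", "pos") %in% names(coords)))
  m <- match(out$node_id, coords$node_id)
  if (anyNA(m)) {
    stop("missing coordinates for: ",
         paste(out$node_id[is.na(m)], collapse = ", "))
  }
  out$chrom <- coords$chrom[m]
  out$pos <- coords$pos[m]
  out <- out[order(out$chrom, out$pos), c("chrom", "pos", "node_id", "value")]
  rownames(out) <- NULL
  out
}

#' Sunburst export of the pathway-importance hierarchy
#'
#' Produces the nested records behind a sunburst chart: the root is the
#' output node, each ring is one network layer, and a node's angular share
#' is its relative importance within its layer. Zero-importance nodes keep a
#' zero-width sector and remain present. Nodes linking to several parents
#' are placed under their first parent (shares remain layer-wide). Lower
#' rings (typically the gene and variant layers) can be omitted with
#' `min_layer`.
#'
#' @param object an `"annonet"` fit.
#' @param importance optional precomputed [relative_importance()] table.
#' @param min_layer lowest layer index to include (default 1: genes and all
#'   pathway levels; inputs omitted).
#' @return nested list `(name, importance, share, children = ...)`, JSON
#'   serializable.
#' @export
sunburst_export <- function(object, importance = NULL, min_layer = 1L) {
  imp <- importance %||% relative_importance(object)
  layers <- network_layers(object)
  L <- length(layers)
  build <- function(node, k) {
    row <- imp[imp$layer == k & imp$node_id == node, ]
    rec <- list(name = node, importance = row$importance,
                share = row$relative_importance)
    if (k > min_layer) {
      cm <- layers[[k]]$cm
      jj <- match(node, cm$output_names)
      kids <- cm$input_names[cm$links[cm$links[, 2] == jj, 1]]
      ## a child under several parents is drawn under its first parent
      kids <- kids[vapply(kids, function(ch) {
        i <- match(ch, cm$input_names)
        cm$output_names[cm$links[cm$links[, 1] == i, 2][1]] == node
      }, logical(1))]
      rec$children <- lapply(kids, build, k = k - 1L)
    }
    rec
  }
  build(layers[[L]]$cm$output_names[1], L)
}
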