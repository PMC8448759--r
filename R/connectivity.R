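#' Sparse connectivity matrix between two layers of named nodes
#'
#' A connectivity matrix is the blueprint of one network layer: it states
#' which input nodes (e.g. variants) are connected to which output nodes
#' (e.g. genes). Only listed links become trainable weights; everything else
#' is structurally absent from the model.
#'
#' @param input_names character vector of input node identifiers (no
#'   duplicates); their order fixes the column order of the data matrix the
#'   layer consumes.
#' @param output_names character vector of output node identifiers (no
#'   duplicates).
#' @param links two-column integer matrix (or data.frame) of
#'   (input index, output index) pairs; duplicates collapse to one link.
#' @param label free-text description of the layer (e.g. `"SNP->gene"`).
#' @return an object of class `"connectivity"`.
#' @seealso [build_snp_gene_matrix()], [build_pathway_stack()],
#'   [build_expression_matrix()], [apply_mask()], [validate_stack()]
#' @export
connectivity <- function(input_names, output_names, links, label = "") {
  input_names <- as.character(input_names)
  output_names <- as.character(output_names)
  if (anyDuplicated(input_names)) stop("duplicate input node names")
  if (anyDuplicated(output_names)) stop("duplicate output node names")
  links <- as.matrix(links)
  if (length(links) == 0L) links <- matrix(integer(), ncol = 2)
  if (ncol(links) != 2L) stop("links must have two columns (from, to)")
  storage.mode(links) <- "integer"
  if (nrow(links)) {
    if (min(links) < 1L || max(links[, 1]) > length(input_names) ||
        max(links[, 2]) > length(output_names)) {
      stop("link index out of range")
    }
    links <- links[!duplicated(paste(links[, 1], links[, 2])), , drop = FALSE]
    links <- links[order(links[, 2], links[, 1]), , drop = FALSE]
  }
  dimnames(links) <- list(NULL, c("from", "to"))
  structure(
    list(input_names = input_names, output_names = output_names,
         links = links, label = label),
    class = "connectivity"
  )
}

#' @export
print.connectivity <- function(x, ...) {
  cat(sprintf(
    "Connectivity%s: %d inputs -> %d outputs, %d links (density %.3g)\n",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
    length(x$input_names), length(x$output_names), nrow(x$links),
    nrow(x$links) / (length(x$input_names) * length(x$output_names))
  ))
  invisible(x)
}

#' @export
dim.connectivity <- function(x) {
  c(length(x$input_names), length(x$output_names))
}

#' Number of links in a connectivity matrix
#' @param cm a [connectivity()] object.
#' @return integer link count.
#' @export
n_links <- function(cm) nrow(cm$links)

#' Sparse-matrix view of a connectivity matrix
#'
#' @param cm a [connectivity()] object.
#' @param values optional numeric vector (one per link, in the row order of
#'   `cm$links`) placed at the linked positions; default 1 (binary pattern).
#' @return a `Matrix::dgCMatrix` of dimension n_inputs x n_outputs.
#' @export
as_sparse <- function(cm, values = NULL) {
  values <- values %||% rep(1, nrow(cm$links))
  stopifnot(length(values) == nrow(cm$links))
  Matrix::sparseMatrix(
    i = cm$links[, 1], j = cm$links[, 2], x = values,
    dims = dim(cm), dimnames = list(cm$input_names, cm$output_names)
  )
}

## Internal: basic structural checks shared by validate_stack().
check_connectivity <- function(cm, allow_empty_outputs = FALSE) {
  stopifnot(inherits(cm, "connectivity"))
  empty <- setdiff(seq_along(cm$output_names), unique(cm$links[, 2]))
  if (length(empty) && !allow_empty_outputs) {
    stop("output nodes without any link: ",
         paste(cm$output_names[empty], collapse = ", "))
  }
  cm$output_names[empty]
}

## Internal: coerce a two-column child/parent table.
as_annotation <- function(table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (ncol(table) < 2L) stop("annotation table needs child and parent columns")
  nm <- tolower(names(table))
  ci <- if ("child" %in% nm) which(nm == "child")[1] else 1L
  pi <- if ("parent" %in% nm) which(nm == "parent")[1] else 2L
  out <- data.frame(child = as.character(table[[ci]]),
                    parent = as.character(table[[pi]]),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$child)) || any(!nzchar(out$parent)) ||
      anyNA(out$child) || anyNA(out$parent)) {
    stop("annotation ids must be non-empty")
  }
  unique(out)
}

#' Build the variant-to-gene connectivity matrix
#'
#' Translates a variant/gene annotation table into the first network layer:
#' each annotated (variant, gene) pair becomes one link. Gene order is
#' lexicographic so that architectures are reproducible. Variants present in
#' `variant_order` but absent from the annotation are by default dropped from
#' the inputs (the network trains only on connected inputs) and reported; set
#' `keep_unannotated = TRUE` to retain them as zero-link inputs, e.g. for
#' masking workflows where column positions must be preserved.
#'
#' @param table data.frame with columns `child` (variant id) and `parent`
#'   (gene id); duplicate rows collapse.
#' @param variant_order character vector fixing the input (variant) order,
#'   normally the column order of the genotype matrix.
#' @param keep_unannotated keep unannotated variants as zero-link inputs?
#' @return a [connectivity()] object with attribute `"unannotated"` listing
#'   variants of `variant_order` that carried no annotation.
#' @examples
#' tab <- data.frame(child = c("v1", "v2", "v3", "v4"),
#'                   parent = c("gA", "gA", "gB", "gB"))
#' build_snp_gene_matrix(tab, paste0("v", 1:4))
#' @export
build_snp_gene_matrix <- function(table, variant_order,
                                  keep_unannotated = FALSE) {
  table <- as_annotation(table)
  n_pairs <- nrow(table)
  variant_order <- as.character(variant_order)
  if (anyDuplicated(variant_order)) stop("duplicate ids in variant_order")
  table <- table[table$child %in% variant_order, , drop = FALSE]
  if (nrow(table) == 0L) {
    stop(sprintf(
      "no overlap between annotation (%d pairs) and variant_order (%d variants)",
      n_pairs, length(variant_order)))
  }
  annotated <- variant_order[variant_order %in% table$child]
  unannotated <- setdiff(variant_order, annotated)
  inputs <- if (keep_unannotated) variant_order else annotated
  genes <- sort(unique(table$parent))
  links <- cbind(match(table$child, inputs), match(table$parent, genes))
  cm <- connectivity(inputs, genes, links, label = "SNP->gene")
  if (length(unannotated)) {
    message(sprintf("%d unannotated variant(s) %s: %s",
                    length(unannotated),
                    if (keep_unannotated) "kept without links" else "dropped",
                    paste(utils::head(unannotated, 10), collapse = ", ")))
  }
  attr(cm, "unannotated") <- unannotated
  cm
}

#' Build a stack of connectivity matrices from a pathway hierarchy
#'
#' Turns an ordered list of child/parent tables (e.g. gene -> local pathway,
#' local -> mid-level, mid-level -> top-level, as in the three-level KEGG
#' hierarchy) into chained connectivity matrices with consistent node
#' orderings: the outputs of matrix k are exactly the inputs of matrix k+1.
#' The same machinery expresses variant -> exon -> gene stacks.
#'
#' @param tables list of data.frames with `child`/`parent` columns, ordered
#'   bottom-up.
#' @param input_order optional character vector fixing the input order of the
#'   first matrix (e.g. the gene order of a variant-to-gene matrix); children
#'   of the first table not present are errors, inputs without any pathway
#'   are dropped and reported as uncovered.
#' @param labels optional character vector of layer labels.
#' @return list of [connectivity()] objects with attribute `"uncovered"`
#'   (inputs of the first level with no parent).
#' @export
build_pathway_stack <- function(tables, input_order = NULL, labels = NULL) {
  stopifnot(length(tables) >= 1L)
  tables <- lapply(tables, as_annotation)
  labels <- labels %||% paste0("level", seq_along(tables))
  uncovered <- character()
  if (is.null(input_order)) {
    inputs <- sort(unique(tables[[1]]$child))
  } else {
    input_order <- as.character(input_order)
    extra <- setdiff(unique(tables[[1]]$child), input_order)
    if (length(extra)) {
      stop("children of level 1 missing from input_order: ",
           paste(extra, collapse = ", "))
    }
    uncovered <- setdiff(input_order, tables[[1]]$child)
    inputs <- input_order[input_order %in% tables[[1]]$child]
  }
  out <- vector("list", length(tables))
  for (k in seq_along(tables)) {
    tab <- tables[[k]]
    orphans <- setdiff(unique(tab$child), inputs)
    if (length(orphans)) {
      stop(sprintf("level %d children not produced by level %d: %s",
                   k, k - 1L, paste(orphans, collapse = ", ")))
    }
    tab <- tab[tab$child %in% inputs, , drop = FALSE]
    parents <- sort(unique(tab$parent))
    links <- cbind(match(tab$child, inputs), match(tab$parent, parents))
    out[[k]] <- connectivity(inputs, parents, links, label = labels[[k]])
    ## every node of level k must chain upward, except past the last table
    if (k < length(tables)) {
      dead <- setdiff(parents, unique(tables[[k + 1]]$child))
      if (length(dead)) {
        stop(sprintf("level %d node(s) with no parent at level %d: %s",
                     k, k + 1L, paste(dead, collapse = ", ")))
      }
    }
    inputs <- parents
  }
  if (length(uncovered)) {
    message(sprintf("%d input(s) not covered by the hierarchy: %s",
                    length(uncovered),
                    paste(utils::head(uncovered, 10), collapse = ", ")))
  }
  attr(out, "uncovered") <- uncovered
  out
}

#' Build a gene-to-tissue connectivity matrix from expression t-scores
#'
#' For each tissue, connects the genes with the top fraction (default 10%)
#' highest group-wise t-statistic to that tissue node, so that tissue nodes
#' are uniquely defined by their gene sets. Exactly
#' `ceiling(top_fraction * n_genes)` genes link to each tissue; ties at the
#' boundary are broken in favour of the lexicographically smaller gene id.
#'
#' @param expr data.frame: first column gene id, remaining numeric columns
#'   one per tissue holding t-scores (all finite; at least 10 genes).
#' @param top_fraction fraction of genes to connect per tissue, in (0, 1\].
#' @return a [connectivity()] object, inputs = genes (lexicographic),
#'   outputs = tissues (lexicographic).
#' @export
build_expression_matrix <- function(expr, top_fraction = 0.10) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  expr <- as.data.frame(expr, stringsAsFactors = FALSE)
  if (ncol(expr) < 2L) stop("expression table needs gene id + tissue columns")
  genes_raw <- as.character(expr[[1]])
  if (anyDuplicated(genes_raw)) stop("duplicate gene ids in expression table")
  scores <- as.matrix(expr[, -1, drop = FALSE])
  if (nrow(scores) < 10L) stop("expression table needs at least 10 genes")
  if (!all(is.finite(scores))) stop("non-finite t-scores in expression table")
  genes <- sort(genes_raw)
  tissues <- sort(colnames(scores))
  k <- ceiling(top_fraction * length(genes))
  links <- do.call(rbind, lapply(tissues, function(ts) {
    sc <- scores[, ts]
    ## highest t-score first; ties at the boundary by lexicographic gene id
    top <- genes_raw[order(-sc, genes_raw)][seq_len(k)]
    cbind(match(top, genes), match(ts, tissues))
  }))
  connectivity(genes, tissues, links, label = "gene->tissue")
}

#' Mask input nodes of a connectivity matrix
#'
#' Removes every link that originates from the given input nodes (e.g.
#' misaligned variants or sex chromosomes) while preserving the input node
#' list and its positions, so the genotype matrix does not need re-cutting.
#' Output nodes left without any link are flagged, not dropped.
#'
#' @param cm a [connectivity()] object.
#' @param masked_inputs character vector of input ids to disconnect; unknown
#'   ids are an error.
#' @return the masked [connectivity()] with attribute `"empty_outputs"`.
#' @export
apply_mask <- function(cm, masked_inputs) {
  masked_inputs <- as.character(masked_inputs)
  unknown <- setdiff(masked_inputs, cm$input_names)
  if (length(unknown)) {
    stop("masked ids not present among inputs: ",
         paste(unknown, collapse = ", "))
  }
  idx <- match(masked_inputs, cm$input_names)
  keep <- !(cm$links[, 1] %in% idx)
  out <- connectivity(cm$input_names, cm$output_names,
                      cm$links[keep, , drop = FALSE], label = cm$label)
  n_removed <- sum(!keep)
  if (n_removed) {
    message(sprintf("masked %d input(s), removed %d link(s)",
                    length(masked_inputs), n_removed))
  }
  empty <- setdiff(cm$output_names, cm$output_names[unique(out$links[, 2])])
  if (length(empty)) {
    message("output node(s) left without links: ",
            paste(empty, collapse = ", "))
  }
  attr(out, "empty_outputs") <- empty
  out
}

#' Validate a stack of connectivity matrices
#'
#' Checks that consecutive matrices chain (outputs of layer k are, in order,
#' the inputs of layer k+1), that every output node has at least one link,
#' and that no two output nodes of a layer share an identical link set (such
#' nodes would not be uniquely defined by their connections, undermining
#' interpretability; a warning names both).
#'
#' @param matrices list of [connectivity()] objects (a single object is
#'   wrapped).
#' @param allow_empty_outputs tolerate zero-link output nodes (e.g. after
#'   [apply_mask()]).
#' @return invisibly, a data.frame with per-layer node and link counts, with
#'   attribute `"warnings"` collecting duplicate-signature messages.
#' @export
validate_stack <- function(matrices, allow_empty_outputs = FALSE) {
  if (inherits(matrices, "connectivity")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L)
  warns <- character()
  for (k in seq_along(matrices)) {
    cm <- matrices[[k]]
    check_connectivity(cm, allow_empty_outputs = allow_empty_outputs)
    if (k > 1L) {
      prev <- matrices[[k - 1]]
      if (!identical(prev$output_names, cm$input_names)) {
        stop(sprintf(
          "chaining violation between layers %d and %d: outputs != inputs",
          k - 1L, k))
      }
    }
    sig <- vapply(seq_along(cm$output_names), function(j) {
      paste(sort(cm$links[cm$links[, 2] == j, 1]), collapse = ",")
    }, character(1))
    dup <- which(duplicated(sig) & nzchar(sig))
    for (j in dup) {
      first <- cm$output_names[which(sig == sig[j])[1]]
      msg <- sprintf(
        "layer %d: nodes '%s' and '%s' have identical link sets",
        k, first, cm$output_names[j])
      warns <- c(warns, msg)
      warning(msg, call. = FALSE)
    }
  }
  report <- data.frame(
    layer = seq_along(matrices),
    label = vapply(matrices, function(m) m$label, character(1)),
    n_inputs = vapply(matrices, function(m) length(m$input_names), integer(1)),
    n_outputs = vapply(matrices, function(m) length(m$output_names), integer(1)),
    n_links = vapply(matrices, n_links, integer(1)),
    stringsAsFactors = FALSE
  )
  attr(report, "warnings") <- warns
  invisible(report)
}

#' Write / read a connectivity matrix in the text interchange format
#'
#' The interchange format is a diffable pair of files: `<path>.tsv` with
#' columns `child`, `parent`, `label` (one row per link) and `<path>.json`
#' recording the full input/output node orders (needed to restore zero-link
#' nodes and ordering exactly).
#'
#' @param cm a [connectivity()] object.
#' @param path file path stem (without extension).
#' @return `write_connectivity()` returns `path` invisibly;
#'   `read_connectivity()` the reconstructed [connectivity()].
#' @export
write_connectivity <- function(cm, path) {
  df <- data.frame(child = cm$input_names[cm$links[, 1]],
                   parent = cm$output_names[cm$links[, 2]],
                   label = cm$label, stringsAsFactors = FALSE)
  utils::write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(input_names = cm$input_names, output_names = cm$output_names,
         label = cm$label),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(paste0(path, ".tsv"), sep = "\t", header = TRUE,
                          colClasses = "character")
  links <- cbind(match(df$child, meta$input_names),
                 match(df$parent, meta$output_names))
  if (nrow(df) && anyNA(links)) stop("link ids missing from sidecar node order")
  connectivity(meta$input_names, meta$output_names, links,
               label = meta$label %||% "")
}
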