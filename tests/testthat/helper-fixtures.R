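## Shared fixtures and independent oracles for the test suite.

## the canonical 4-variant / 2-gene toy annotation
toy_annotation <- function() {
  data.frame(child = c("v1", "v2", "v3", "v4"),
             parent = c("gA", "gA", "gB", "gB"),
             stringsAsFactors = FALSE)
}

toy_cm <- function() {
  build_snp_gene_matrix(toy_annotation(), paste0("v", 1:4))
}

## random connectivity with every output connected
random_cm <- function(n_in, n_out, density = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    m <- max(n_out, rbinom(1, n_in * n_out, density))
    cells <- sample.int(n_in * n_out, m)
    from <- ((cells - 1L) %% n_in) + 1L
    to <- ((cells - 1L) %/% n_in) + 1L
    if (length(unique(to)) == n_out) break
  }
  connectivity(sprintf("in%03d", seq_len(n_in)),
               sprintf("out%03d", seq_len(n_out)),
               cbind(from, to), label = "random")
}

## wrap one layer as a minimal trainable network object
single_layer_net <- function(layer, task = "regression") {
  structure(list(layers = list(layer), task = task, initialized = TRUE),
            class = "annonet_net")
}

## masked-dense oracle: forward pass through a sparse layer computed as a
## dense matrix product with a 0/1 mask
dense_forward <- function(layer, x) {
  W <- matrix(0, length(layer$cm$input_names), length(layer$cm$output_names))
  W[layer$cm$links] <- layer$w
  s <- x %*% W
  s <- sweep(s, 2, layer$b, "+")
  switch(layer$activation,
         tanh = tanh(s), relu = pmax(s, 0), linear = s,
         sigmoid = 1 / (1 + exp(-s)))
}

## masked-dense oracle for the gradients of loss = sum(dA * a) given dA
## (i.e. dL/da supplied); returns per-link weight grads, bias grads, dX
dense_grads <- function(layer, x, dA) {
  W <- matrix(0, length(layer$cm$input_names), length(layer$cm$output_names))
  W[layer$cm$links] <- layer$w
  s <- sweep(x %*% W, 2, layer$b, "+")
  a <- dense_forward(layer, x)
  dact <- switch(layer$activation,
                 tanh = 1 - a^2, relu = (s > 0) * 1,
                 linear = array(1, dim(s)), sigmoid = a * (1 - a))
  dS <- dA * dact
  Gw <- crossprod(x, dS)       # dense gradient ...
  list(w = Gw[layer$cm$links], # ... masked at the linked positions
       b = colSums(dS),
       x = dS %*% t(W))
}

## exhaustive path-product oracle: importance of every node as the sum of
## full root-to-input path products over the paths passing through it
enumerate_path_importance <- function(layers) {
  L <- length(layers)
  imp <- c(list(numeric(length(layers[[1]]$cm$input_names))),
           lapply(layers, function(l) numeric(length(l$cm$output_names))))
  walk <- function(k, j, prod, visited) {
    if (k > L) {
      for (lev in seq_along(visited)) {
        imp[[lev]][visited[lev]] <<- imp[[lev]][visited[lev]] + prod
      }
      return(invisible())
    }
    cm <- layers[[k]]$cm
    rows <- which(cm$links[, 1] == j)
    for (r in rows) {
      walk(k + 1L, cm$links[r, 2], prod * layers[[k]]$w[r],
           c(visited, cm$links[r, 2]))
    }
  }
  for (i in seq_along(imp[[1]])) walk(1L, i, 1, i)
  imp
}

## small multi-sample VCF written as text (GT field)
write_toy_vcf <- function(path, gts = c("0/0", "0/1", "1/1")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("S", seq_along(gts))), collapse = "\t"),
    paste(c("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT", gts),
          collapse = "\t"),
    paste(c("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
            rev(gts)), collapse = "\t")
  )
  writeLines(lines, path)
  path
}

## liability-threshold Monte-Carlo oracle for the AUC ceiling
mc_max_auc <- function(h2, prevalence, n = 1e6, seed = 11) {
  set.seed(seed)
  g <- rnorm(n, 0, sqrt(h2))
  liab <- g + rnorm(n, 0, sqrt(1 - h2))
  y <- as.integer(liab > qnorm(1 - prevalence))
  auc_score(g, y)
}

## standard small training configuration used across simulation tests
sim_train_config <- function(seed, ...) {
  train_config(batch_size = 64, learning_rate = 0.01, l1 = 1e-4,
               max_epochs = 40, patience = 8, seed = seed, ...)
}
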