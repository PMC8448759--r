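## build a small trained-like network with chosen weights, no batchnorm,
## linear activations (path products ignore nonlinearity by definition)
manual_net <- function(cms, weights, activation = "linear",
                       batchnorm = FALSE) {
  layers <- Map(function(cm, w) {
    sparse_layer(cm, weights = w, activation = activation,
                 batchnorm = batchnorm)
  }, cms, weights)
  structure(list(layers = layers, task = "regression", initialized = TRUE),
            class = "annonet_net")
}

as_fit <- function(net, input_names) {
  structure(list(net = net, task = net$task, input_names = input_names,
                 config = train_config()),
            class = "annonet")
}

test_that("normalized weights scale by the source activation sd", {
  cm <- connectivity(c("a", "b"), "out", cbind(1:2, 1))
  net <- manual_net(list(cm), list(c(0.4, -0.6)))
  fit <- as_fit(net, c("a", "b"))
  ## batch constructed with exact population sds 2 and 0.5
  x <- cbind(a = c(2, -2, 2, -2), b = c(0.5, -0.5, 0.5, -0.5))
  nw <- normalized_weights(fit, x)
  expect_equal(nw$sd_activation, c(2, 0.5))
  expect_equal(nw$normalized_weight, c(0.4 * 2, -0.6 * 0.5))

  ## unit-sd activations leave weights unchanged
  x1 <- cbind(a = c(1, -1), b = c(-1, 1))
  expect_equal(normalized_weights(fit, x1)$normalized_weight,
               nw$weight)

  ## constant activation zeroes the normalized weight
  xc <- cbind(a = c(3, 3), b = c(1, -1))
  expect_equal(normalized_weights(fit, xc)$normalized_weight[1], 0)

  expect_error(normalized_weights(fit, x[1, , drop = FALSE]), "2 samples")
})

test_that("path-product importance matches hand computations", {
  ## single path SNP -> gene -> output with weights 0.5 and 0.8
  cm1 <- connectivity("snp1", "gene1", cbind(1, 1))
  cm2 <- connectivity("gene1", "out", cbind(1, 1))
  net <- manual_net(list(cm1, cm2), list(0.5, 0.8))
  imp <- relative_importance(net)
  expect_equal(imp$importance[imp$node_id == "snp1"], 0.4)

  ## two genes with importances +3 and -1 share 0.75 / 0.25
  cmA <- connectivity(c("s1", "s2"), c("gA", "gB"), cbind(1:2, 1:2))
  cmB <- connectivity(c("gA", "gB"), "out", cbind(1:2, 1))
  net2 <- manual_net(list(cmA, cmB), list(c(1, 1), c(3, -1)))
  imp2 <- relative_importance(net2)
  genes <- imp2[imp2$layer == 1, ]
  expect_equal(genes$importance, c(3, -1))
  expect_equal(genes$relative_importance, c(0.75, 0.25))
})

test_that("importance equals exhaustive path enumeration on random networks", {
  for (seed in 1:5) {
    set.seed(seed)
    n_layers <- sample(2:4, 1)
    sizes <- c(sample(5:8, 1), sort(sample(2:6, n_layers - 1),
                                    decreasing = TRUE), 1)
    cms <- list()
    for (k in seq_len(n_layers)) {
      cms[[k]] <- random_cm(sizes[k], sizes[k + 1], 0.5,
                            seed = 100 * seed + k)
      ## rename nodes so consecutive matrices chain
      if (k > 1) {
        cms[[k]]$input_names <- cms[[k - 1]]$output_names
      }
      cms[[k]]$output_names <- sprintf("L%d_%03d", k,
                                       seq_along(cms[[k]]$output_names))
    }
    ws <- lapply(cms, function(cm) rnorm(n_links(cm)))
    net <- manual_net(cms, ws)
    imp <- relative_importance(net)
    oracle <- enumerate_path_importance(net$layers)
    for (lev in seq_along(oracle)) {
      got <- imp$importance[imp$layer == lev - 1L]
      expect_equal(got, oracle[[lev]], tolerance = 1e-10)
    }
    ## every layer's relative importance sums to one (when nonzero)
    for (lev in unique(imp$layer)) {
      tot <- sum(imp$relative_importance[imp$layer == lev])
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("relabeling nodes permutes the importance table identically", {
  cmA <- connectivity(c("s1", "s2", "s3"), c("gA", "gB"),
                      rbind(c(1, 1), c(2, 1), c(3, 2)))
  cmB <- connectivity(c("gA", "gB"), "out", cbind(1:2, 1))
  net <- manual_net(list(cmA, cmB), list(c(0.3, -0.2, 0.7), c(1.5, -2)))
  imp <- relative_importance(net)

  perm <- c(3, 1, 2)
  cmA2 <- connectivity(c("s3", "s1", "s2"), c("gA", "gB"),
                       rbind(c(2, 1), c(3, 1), c(1, 2)))
  ## weights follow their links (link order is canonical: by output, input)
  net2 <- manual_net(list(cmA2, cmB), list(c(0.3, -0.2, 0.7)[c(1, 2, 3)],
                                           c(1.5, -2)))
  imp2 <- relative_importance(net2)
  for (s in c("s1", "s2", "s3")) {
    expect_equal(imp2$importance[imp2$node_id == s],
                 imp$importance[imp$node_id == s])
  }
})

test_that("Manhattan export sorts by position and uses absolute weights", {
  cm1 <- connectivity(c("s1", "s2"), c("gA", "gB"), cbind(1:2, 1:2))
  cm2 <- connectivity(c("gA", "gB"), "out", cbind(1:2, 1))
  net <- manual_net(list(cm1, cm2), list(c(1, 1), c(0.1, -0.9)))
  fit <- as_fit(net, c("s1", "s2"))
  x <- cbind(s1 = c(1, -1, 1, -1), s2 = c(1, 1, -1, -1))
  nw <- normalized_weights(fit, x)
  coords <- data.frame(node_id = c("gA", "gB"), chrom = c("1", "1"),
                       pos = c(500L, 100L))
  man <- manhattan_export(nw, coords)
  expect_equal(man$node_id, c("gB", "gA"))      # sorted by position
  expect_equal(man$value, c(0.9, 0.1))          # absolute magnitudes
  expect_equal(nrow(man), 2L)                   # one record per gene
})

test_that("sunburst rings carry layer-wise shares that sum to one", {
  ## 3 local -> 2 mid -> 1 global toy
  cms <- list(
    connectivity(sprintf("g%d", 1:6), c("l1", "l2", "l3"),
                 cbind(1:6, rep(1:3, each = 2))),
    connectivity(c("l1", "l2", "l3"), c("m1", "m2"),
                 rbind(c(1, 1), c(2, 1), c(3, 2))),
    connectivity(c("m1", "m2"), "root", cbind(1:2, 1))
  )
  ws <- list(c(1, 1, 1, 1, 0, 0), c(0.5, 0.5, 2), c(1, -1))
  net <- manual_net(cms, ws)
  fit <- as_fit(net, sprintf("g%d", 1:6))
  sb <- sunburst_export(fit)
  expect_equal(sb$name, "root")
  mids <- sb$children
  expect_equal(sum(vapply(mids, `[[`, numeric(1), "share")), 1)
  locals <- unlist(lapply(mids, `[[`, "children"), recursive = FALSE)
  expect_equal(sum(vapply(locals, `[[`, numeric(1), "share")), 1)
  ## zero-importance nodes keep a zero-width sector but stay present
  imp <- relative_importance(net)
  shares <- vapply(locals, `[[`, numeric(1), "share")
  names(shares) <- vapply(locals, `[[`, character(1), "name")
  expect_true(all(c("l1", "l2", "l3") %in% names(shares)))
})
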