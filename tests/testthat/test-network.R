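test_that("weighted cross-entropy matches closed forms", {
  expect_lt(weighted_bce(1, 1 - 1e-9), 1e-6)
  expect_equal(weighted_bce(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(weighted_bce(c(1, 0), c(0.5, 0.5), c(2, 3)),
               mean(c(3, 2) * log(2)), tolerance = 1e-12)
  ## clipping keeps the loss finite at p = 0 and p = 1
  expect_true(is.finite(weighted_bce(c(1, 0), c(0, 1))))

  expect_equal(unname(class_weights(c(0, 0, 1, 1))), c(1, 1))
  expect_equal(unname(class_weights(c(0, 0, 0, 1))), c(4 / 6, 2))
  expect_error(class_weights(c(1, 1, 1)), "single class")
})

test_that("the L1 term sums absolute link weights and excludes biases", {
  cm <- toy_cm()
  layer <- sparse_layer(cm, weights = c(0.5, -0.5, 0, 0),
                        bias = c(100, 100))
  net <- single_layer_net(layer)
  expect_equal(l1_term(net, 0.1), 0.1)
  expect_equal(l1_term(net, 0), 0)
  layer0 <- sparse_layer(cm)
  expect_equal(l1_term(single_layer_net(layer0), 0.1), 0)
})

test_that("assembly follows the task conventions and parameter economy", {
  cm <- toy_cm()
  net <- assemble(cm, task = "classification")
  expect_length(net$layers, 2)       # gene layer + single output node
  expect_equal(net$layers[[1]]$activation, "tanh")
  expect_equal(net$layers[[2]]$activation, "sigmoid")
  expect_equal(length(net$layers[[2]]$cm$output_names), 1L)

  reg <- assemble(cm, task = "regression")
  expect_equal(reg$layers[[1]]$activation, "relu")
  expect_equal(reg$layers[[2]]$activation, "linear")

  ## parameter count = links + biases; dense equivalent strictly larger
  expect_equal(n_parameters(net), (4L + 2L) + (2L + 1L))
  dense_params <- 4 * 2 + 2
  expect_gt(dense_params, length(net$layers[[1]]$w))

  expect_error(assemble(list(cm, toy_cm())), "chaining")
})

test_that("the hyperparameter grid has 16 configurations and a documented tie-break", {
  grid <- hyperparameter_grid()
  expect_length(grid, 16)
  expect_equal(sort(unique(vapply(grid, `[[`, numeric(1), "l1"))),
               c(0, 1e-5, 0.001, 0.1))
  opt <- table(vapply(grid, `[[`, character(1), "optimizer"))
  expect_equal(as.numeric(opt[c("adadelta", "adam")]), c(4, 12))
  ## the typo-corrected reading stays available
  expect_length(hyperparameter_grid(c(0.1, 0.01, 0.001, 1e-5, 0)), 20)

  results <- data.frame(val_auc = c(0.7, 0.8, 0.8), l1 = c(0, 0.1, 0.001))
  expect_equal(select_config(results), 3L)  # tie -> lower penalty
})

test_that("early stopping waits out the patience and keeps the best epoch", {
  ## validation loss decreasing to epoch 4, then strictly increasing
  losses <- c(1.0, 0.8, 0.7, 0.65, 0.66, 0.7, 0.8, 0.9, 1.0, 1.1, 1.2,
              1.3, 1.4, 1.5, 1.6)
  st <- NULL
  for (i in seq_along(losses)) {
    st <- annonet:::early_stopping_update(st, losses[i], patience = 10)
    if (st$stop) break
  }
  expect_true(st$stop)
  expect_equal(st$epoch, 14L)        # stops 10 epochs past the optimum
  expect_equal(st$best_epoch, 4L)
})

test_that("training is deterministic given a seed", {
  sim <- simulate_cohort(sim_config(n_samples = 300, n_variants = 40,
                                    n_genes = 8, h2 = 0.8, seed = 4))
  cm <- build_snp_gene_matrix(sim$annotation, colnames(sim$genotypes))
  cfg <- train_config(batch_size = 64, learning_rate = 0.01,
                      max_epochs = 8, patience = 8, seed = 42)
  f1 <- annonet(sim$genotypes, sim$labels, cm, config = cfg)
  f2 <- annonet(sim$genotypes, sim$labels, cm, config = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1)$weight, coef(f2)$weight)
})

test_that("a strongly heritable additive signal is learned quickly", {
  sim <- simulate_cohort(sim_config(n_samples = 2000, n_variants = 60,
                                    n_genes = 12, h2 = 1, polygenicity = 0.2,
                                    seed = 6))
  cm <- build_snp_gene_matrix(sim$annotation, colnames(sim$genotypes))
  fit <- annonet(sim$genotypes, sim$labels, cm,
                 config = train_config(batch_size = 64,
                                       learning_rate = 0.01,
                                       max_epochs = 50, patience = 50,
                                       seed = 1))
  expect_gt(fit$history$val_auc[fit$best_epoch], 0.95)
})

test_that("a strong L1 penalty drives all weights to zero on pure noise", {
  set.seed(9)
  n <- 400
  x <- matrix(rbinom(n * 40, 2, 0.3), n, 40,
              dimnames = list(NULL, sprintf("v%02d", 1:40)))
  y <- rbinom(n, 1, 0.5)
  annot <- data.frame(child = colnames(x),
                      parent = rep(sprintf("g%d", 1:8), each = 5))
  cm <- build_snp_gene_matrix(annot, colnames(x))
  net <- assemble(cm, task = "classification")
  for (lr in c(0.01, 0.001, 1e-4)) {
    cfg <- train_config(batch_size = Inf, learning_rate = lr, l1 = 0.1,
                        max_epochs = 100, patience = 100, seed = 2)
    net <- train_network(net, x, y, x, y, cfg, warm_start = lr < 0.01)$net
  }
  w <- unlist(lapply(net$layers, function(l) l$w))
  expect_lt(max(abs(w)), 1e-3)
})

test_that("non-finite states abort with diagnostics instead of silently continuing", {
  cm <- toy_cm()
  net <- assemble(cm, task = "classification")
  set.seed(1)
  net <- annonet:::init_weights(net)
  params <- annonet:::get_params(net)
  params[[1]][1] <- NaN
  net <- annonet:::set_params(net, params)
  x <- matrix(runif(40, 0, 2), 10, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  y <- rep(c(0, 1), 5)
  cfg <- train_config(batch_size = Inf, learning_rate = 0.01,
                      max_epochs = 2, seed = 1)
  expect_error(train_network(net, x, y, x, y, cfg, warm_start = TRUE),
               "non-finite")
})
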