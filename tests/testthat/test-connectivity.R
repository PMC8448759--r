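test_that("variant-to-gene construction matches the annotation exactly", {
  cm <- toy_cm()
  expect_equal(dim(cm), c(4L, 2L))
  expect_equal(n_links(cm), 4L)
  expect_equal(n_links(cm) / prod(dim(cm)), 0.5)
  expect_equal(cm$output_names, c("gA", "gB"))  # lexicographic

  ## duplicate rows collapse to one link
  tab <- rbind(toy_annotation(), data.frame(child = "v1", parent = "gA"))
  cm2 <- build_snp_gene_matrix(tab, paste0("v", 1:4))
  expect_equal(n_links(cm2), 4L)

  ## unannotated variants dropped by default, kept on request
  cm3 <- suppressMessages(
    build_snp_gene_matrix(toy_annotation(), paste0("v", 1:5)))
  expect_equal(length(cm3$input_names), 4L)
  expect_equal(attr(cm3, "unannotated"), "v5")
  cm4 <- suppressMessages(build_snp_gene_matrix(toy_annotation(),
                                                paste0("v", 1:5),
                                                keep_unannotated = TRUE))
  expect_equal(length(cm4$input_names), 5L)
  expect_equal(n_links(cm4), 4L)

  expect_error(build_snp_gene_matrix(toy_annotation(), c("x1", "x2")),
               "no overlap")
})

test_that("link count equals a brute-force scan of annotated pairs", {
  for (seed in 1:5) {
    set.seed(seed)
    variants <- sprintf("v%03d", 1:30)
    tab <- data.frame(child = sample(variants, 60, replace = TRUE),
                      parent = sample(sprintf("g%02d", 1:8), 60,
                                      replace = TRUE))
    keep <- sample(variants, 20)
    cm <- suppressMessages(build_snp_gene_matrix(tab, keep))
    brute <- sum(!duplicated(paste(tab$child, tab$parent)) &
                   tab$child %in% keep)
    expect_equal(n_links(cm), brute)
  }
})

test_that("pathway stacks chain consistently and report coverage", {
  genes <- sprintf("g%d", 1:6)
  t1 <- data.frame(child = genes, parent = rep(c("L1", "L2", "L3"), each = 2))
  t2 <- data.frame(child = c("L1", "L2", "L3"), parent = c("M1", "M1", "M2"))
  t3 <- data.frame(child = c("M1", "M2"), parent = "G1")
  stack <- build_pathway_stack(list(t1, t2, t3))
  expect_length(stack, 3)
  expect_equal(lapply(stack, dim), list(c(6L, 3L), c(3L, 2L), c(2L, 1L)))
  rep <- validate_stack(stack)
  expect_equal(rep$n_links, c(6L, 3L, 2L))
  expect_length(attr(rep, "warnings"), 0)

  ## a gene not annotated to any pathway is excluded and reported
  stack2 <- suppressMessages(
    build_pathway_stack(list(t1, t2, t3), input_order = c(genes, "g7")))
  expect_equal(attr(stack2, "uncovered"), "g7")
  expect_equal(length(stack2[[1]]$input_names), 6L)

  ## a local pathway under two mid-level parents carries two links
  t2b <- rbind(t2, data.frame(child = "L3", parent = "M1"))
  stack3 <- build_pathway_stack(list(t1, t2b, t3))
  l3 <- match("L3", stack3[[2]]$input_names)
  expect_equal(sum(stack3[[2]]$links[, 1] == l3), 2L)

  ## a mid-level pathway with no top-level parent breaks the chain
  t3_broken <- data.frame(child = "M1", parent = "G1")
  expect_error(build_pathway_stack(list(t1, t2, t3_broken)), "no parent")
})

test_that("expression layers take the top fraction per tissue", {
  set.seed(3)
  expr <- data.frame(gene = sprintf("g%03d", 1:100),
                     brain = rnorm(100), liver = rnorm(100),
                     skin = rnorm(100))
  cm <- build_expression_matrix(expr, 0.10)
  expect_equal(n_links(cm), 30L)                  # 3 tissues x 10 genes
  expect_equal(as.numeric(table(cm$links[, 2])), rep(10, 3))

  cm_full <- build_expression_matrix(expr, 1.0)
  expect_equal(n_links(cm_full), 300L)            # fully bipartite

  ## exact tie at the boundary: the lexicographically smaller gene id wins
  expr2 <- data.frame(gene = sprintf("g%02d", 1:20), t1 = c(rep(2, 1), rep(1, 19)))
  expr2$t1[c(5, 3)] <- 1.5                        # ties for the 2nd slot
  cm2 <- build_expression_matrix(expr2, 0.10)     # ceil(0.1*20) = 2 genes
  picked <- cm2$input_names[cm2$links[, 1]]
  expect_setequal(picked, c("g01", "g03"))

  expr_bad <- expr
  expr_bad$brain[1] <- NA
  expect_error(build_expression_matrix(expr_bad), "non-finite")

  ## generic count identity
  expect_equal(n_links(build_expression_matrix(expr, 0.07)),
               3L * ceiling(0.07 * 100))
})

test_that("masking removes links but preserves input positions", {
  cm <- toy_cm()
  m1 <- suppressMessages(apply_mask(cm, "v1"))
  expect_equal(n_links(m1), 3L)
  expect_identical(m1$input_names, cm$input_names)

  m0 <- apply_mask(cm, character(0))
  expect_equal(m0$links, cm$links)

  mA <- suppressMessages(apply_mask(cm, c("v1", "v2")))
  expect_equal(attr(mA, "empty_outputs"), "gA")

  expect_error(apply_mask(cm, "nope"), "not present")
})

test_that("stack validation flags duplicate signatures and broken chains", {
  ## two genes with identical variant sets are not uniquely defined
  cm_dup <- connectivity(paste0("v", 1:2), c("gA", "gB"),
                         rbind(c(1, 1), c(2, 1), c(1, 2), c(2, 2)))
  expect_warning(validate_stack(list(cm_dup)), "identical link sets")

  cm1 <- toy_cm()
  cm_mismatch <- connectivity(c("gB", "gA"), "out", rbind(c(1, 1), c(2, 1)))
  expect_error(
    suppressWarnings(validate_stack(list(cm1, cm_mismatch))), "chaining")
})

test_that("the text interchange format round-trips exactly", {
  for (seed in 1:3) {
    cm <- random_cm(12, 5, 0.3, seed = seed)
    path <- file.path(withr::local_tempdir(), "cm")
    write_connectivity(cm, path)
    back <- read_connectivity(path)
    expect_identical(back$input_names, cm$input_names)
    expect_identical(back$output_names, cm$output_names)
    expect_identical(back$links, cm$links)
    expect_identical(back$label, cm$label)
  }
})
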