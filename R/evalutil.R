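#' L1-regularized logistic baseline (single sigmoid neuron)
#'
#' The baseline against which annotation-guided networks are compared: a
#' dense layer of a single neuron with sigmoid activation and L1
#' regularization on the weights — LASSO logistic regression — trained with
#' the same loop as the sparse networks. With `l1_penalty = 0` the solution
#' approaches the unpenalized logistic maximum likelihood estimate; with a
#' large penalty all weights shrink to zero and the prediction collapses to
#' the base rate.
#'
#' No batch normalization is applied (matching plain logistic regression);
#' optimization runs full-batch Adam over a decreasing learning-rate ladder
#' so the optimum is reached to high precision on desk-scale data.
#'
#' @param x samples x variants dosage matrix.
#' @param y binary labels.
#' @param l1_penalty L1 penalty, >= 0.
#' @param learning_rates decreasing Adam step sizes of the ladder.
#' @param epochs_per_stage full-batch epochs per ladder stage.
#' @param class_weights optional `c(control, case)` weights.
#' @param seed integer seed.
#' @return an `"annonet"` fit (single dense layer); `coef()` returns the
#'   per-variant weights.
#' @export
lasso_baseline <- function(x, y, l1_penalty = 0,
                           learning_rates = c(0.1, 0.01, 0.001, 1e-4),
                           epochs_per_stage = 500L, class_weights = NULL,
                           seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("v%05d", seq_len(ncol(x)))
  cm <- connectivity(colnames(x), "output",
                     cbind(seq_len(ncol(x)), 1L), label = "dense")
  net <- assemble(cm, task = "classification", batchnorm = FALSE)
  y <- as_binary_labels(y)
  fit <- NULL
  for (i in seq_along(learning_rates)) {
    cfg <- train_config(optimizer = "adam",
                        learning_rate = learning_rates[i], l1 = l1_penalty,
                        batch_size = Inf, patience = epochs_per_stage,
                        max_epochs = epochs_per_stage,
                        class_weights = class_weights, seed = seed)
    res <- train_network(net, x, y, x, y, cfg, warm_start = i > 1L)
    net <- res$net
    fit <- res
  }
  out <- structure(
    list(net = net, task = "classification",
         config = train_config(optimizer = "adam",
                               learning_rate = learning_rates[1],
                               l1 = l1_penalty, batch_size = Inf,
                               seed = seed),
         history = fit$history, best_epoch = fit$best_epoch,
         class_weights = fit$class_weights, input_names = colnames(x),
         n_train = nrow(x), n_val = nrow(x), call = match.call()),
    class = c("lasso_baseline", "annonet"))
  out$fitted_values <- predict(out, x)
  out$y <- y
  out
}

#' Randomly connected comparator network
#'
#' Produces a connectivity matrix with the same node counts and exactly the
#' same number of links as a template, but with links placed uniformly at
#' random (no duplicates). Every output node retains at least one link so
#' the comparison is structurally fair; draws are repeated (up to 100
#' times) until that holds. Parameter counts therefore match the template
#' exactly, making capacity comparisons fair by construction.
#'
#' @param template a [connectivity()] object.
#' @param seed integer seed.
#' @return a [connectivity()] with label `"random"`.
#' @export
random_connectivity <- function(template, seed = 1L) {
  n_in <- length(template$input_names)
  n_out <- length(template$output_names)
  m <- n_links(template)
  if (m < n_out) {
    stop("template has fewer links than output nodes; ",
         "every output cannot stay connected")
  }
  set.seed(seed)
  for (try in seq_len(100L)) {
    cells <- sample.int(n_in * n_out, m)
    from <- ((cells - 1L) %% n_in) + 1L
    to <- ((cells - 1L) %/% n_in) + 1L
    if (length(unique(to)) == n_out) {
      return(connectivity(template$input_names, template$output_names,
                          cbind(from, to), label = "random"))
    }
  }
  stop("failed to draw a random connectivity covering every output ",
       "node in 100 attempts")
}

#' Heritability-informed upper bound on classification performance
#'
#' Genetics-only classifiers cannot beat the information in the genome: the
#' best achievable true-positive rate among cases is the monozygotic-twin
#' concordance rate `c` (the rate the trait recurs in a genetically
#' identical individual), and the false-positive rate among controls cannot
#' beat the prevalence `K`. The implied ceiling on accuracy is
#' `(c * n_cases + (1 - K) * n_controls) / (n_cases + n_controls)`.
#'
#' @param mz_concordance monozygotic-twin concordance rate in \[0, 1\].
#' @param prevalence population prevalence in (0, 1).
#' @param n_cases,n_controls sample composition.
#' @return list with `accuracy`, `sensitivity`, `specificity` bounds.
#' @examples
#' upper_bound(0.5, 1e-4, 100, 100)  # accuracy bound ~ 0.75
#' @export
upper_bound <- function(mz_concordance, prevalence, n_cases, n_controls) {
  stopifnot(mz_concordance >= 0, mz_concordance <= 1,
            prevalence > 0, prevalence < 1, n_cases > 0, n_controls > 0)
  list(
    accuracy = (mz_concordance * n_cases + (1 - prevalence) * n_controls) /
      (n_cases + n_controls),
    sensitivity = mz_concordance,
    specificity = 1 - prevalence
  )
}
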