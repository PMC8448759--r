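#' Area under the ROC curve
#'
#' Computes the AUC by the trapezoidal rule over all thresholds, equivalent to
#' the Mann-Whitney statistic with midranks for ties: the probability that a
#' randomly chosen case is scored above a randomly chosen control.
#'
#' @param scores numeric vector of predicted scores (any monotone scale).
#' @param labels binary vector (0/1, logical, or two-level factor) of truth.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_score(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
auc_score <- function(scores, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y))
  n1 <- as.numeric(sum(y == 1))
  n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0) {
    stop("auc_score() needs both cases and controls")
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification accuracy at a fixed threshold
#'
#' @param scores predicted probabilities.
#' @param labels binary truth.
#' @param threshold decision threshold, default 0.5.
#' @return fraction of correct calls.
#' @export
accuracy_score <- function(scores, labels, threshold = 0.5) {
  y <- as_binary_labels(labels)
  mean((scores > threshold) == (y == 1))
}

## Coerce labels to 0/1 integer; factors use the second level as "case".
as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    labels <- as.integer(labels) - 1L
  }
  y <- as.integer(labels)
  if (any(is.na(y)) || !all(y %in% c(0L, 1L))) {
    stop("labels must be binary (0/1)")
  }
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Trapezoidal integration on an ordered grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}
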