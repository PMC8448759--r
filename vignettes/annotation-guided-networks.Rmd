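---
title: "Annotation-guided sparse networks: model, simulator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-guided sparse networks: model, simulator, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annonet)
```

## The model

`annonet` fits neural networks for genotype-to-phenotype prediction in which
every connection is licensed by a biological annotation. A connectivity
matrix (`connectivity()`) pins each layer's links: variants connect only to
the genes they are annotated to, genes only to their pathways (or to tissues
whose expression profile they dominate), and so on up a hierarchy that ends
in a single output node. Each layer computes, for output node $j$,

$$ y_j = \mathrm{Activation}\Big( \sum_{i \in \mathrm{links}(j)} x_i \, w_{ij} + B_j \Big), $$

with one learnable weight per link and one bias per node — a fully connected
layer pruned to the biologically plausible wiring. The parameter count is
the number of annotation links plus one bias per node, which is what makes
millions of input variants tractable and, more importantly, what makes the
network interpretable: every node *is* a biological entity, uniquely defined
by its link set (`validate_stack()` warns when two nodes share one), and
every weight is the effect of one entity on another.

Classification networks use tanh hidden activations and a sigmoid output,
trained with class-weighted binary cross-entropy (weights
$n/(2 n_\mathrm{controls})$, $n/(2 n_\mathrm{cases})$, i.e. inverse class
frequency normalized to mean one on balanced data). Regression networks use
ReLU hidden activations, a linear output, and mean squared error. Every
layer is preceded by batch normalization *without* scale or shift terms, so
that inputs to each layer are zero-mean/unit-variance and learned weights
remain mutually comparable — the property the interpretation rests on.

The simplest instance — one variant-to-gene layer followed by the output
node — behaves like thousands of small parallel regressions (one per gene)
feeding a single logistic regression, which is a useful mental model for
reading the fitted weights.

## Training

`annonet()` (and the lower-level `train_network()`) minimizes the task loss
plus an L1 penalty on link weights (biases excluded) with mini-batch Adam or
Adadelta. Defaults follow the framework's standard settings: batch size 64,
early stopping once the validation loss has not improved for 10 epochs, and
restoration of the weights from the best-validation-loss epoch. The
`hyperparameter_grid()` spans Adadelta (learning rate 1) and Adam (0.01,
0.001, 0.0001) against L1 penalties $\{0.1, 0.001, 10^{-5}, 0\}$ — 16
configurations. The published description of that penalty list repeats
"0.001", which we read as a likely typo for 0.01; the grid therefore
de-duplicates the printed list by default and `penalties =` restores the
0.01 reading (20 configurations) for users who prefer it. Model selection is
by validation AUC with exact ties resolved toward the smaller penalty, and
the test set is touched only once, for the final report.

Numerical choices, all of which matter at the margins:

* Batch normalization uses the population variance with $\epsilon = 10^{-3}$
  and keeps exponential running moments (momentum 0.99) for inference. The
  running moments are debias-corrected (divided by $1 - 0.99^t$), so
  full-batch training — where only a handful of updates occur — still yields
  calibrated inference statistics.
* Predictions are clipped to $[10^{-7}, 1 - 10^{-7}]$ before logarithms;
  zero-variance features normalize to 0 rather than NaN; a trailing
  mini-batch of size one is merged into its neighbour.
* Weights initialize uniformly in $\pm\sqrt{6 / (\mathrm{fan}_j + 1)}$ per
  output node's fan-in (a per-node Glorot rule — fan-ins vary wildly across
  genes, so a single layer-wide limit would mis-scale sparse nodes); biases
  start at zero.
* Training aborts with diagnostics (epoch, optimizer, learning rate) on any
  non-finite loss or prediction rather than continuing from a poisoned
  state.
* Runs are deterministic given `train_config(seed =)`; all computation is
  single-threaded base R plus `Matrix` sparse algebra.

## Interpretation

`relative_importance()` implements path-product attribution: a variant's
contribution is the sum over all variant-to-output paths of the product of
link weights along the path, and any node's importance is the sum over the
paths passing through it. Because batch normalization carries no learnable
affine terms, no extra factors enter the products. The activation
nonlinearity is deliberately ignored — this is a first-order importance,
closer to an effect size than to a significance test, and it retains sign
(direction of effect). Relative importance normalizes by the sum of
*absolute* importances within a layer; the published percentages do not
state their normalization, and the absolute-sum convention is the one that
keeps shares well defined when signs mix. On purely linear networks the
path products are exact: the output equals the dot product of inputs with
the per-variant contributions, a property the test suite checks against
exhaustive path enumeration.

`normalized_weights()` rescales each weight by the empirical (population)
standard deviation of its source activation over a supplied batch, since
batch normalization is only a batch-wise approximation; Manhattan exports
use the absolute normalized weights between a layer and the output, and
`sunburst_export()` nests layer-wise shares for pathway hierarchies (a node
with several parents is drawn under its first parent; shares remain
layer-wide, so each ring sums to one).

## The synthetic cohort generator

No real cohort ships with the package; `simulate_cohort()` generates the
study conditions the method is validated under.

* **Genotypes**: per-variant MAF uniform on `maf_range` (default 0.1–0.5,
  typical of common genotyping-array variants after frequency filtering),
  dosages Binomial(2, MAF), independent across variants and samples.
* **Additive architecture**: `polygenicity` (default 0.1) of variants are
  causal with standard-normal effects; the standardized genetic score $g$
  enters a liability $\sqrt{h^2}\, g + \sqrt{1 - h^2}\,\varepsilon$ and
  cases are individuals above the $1 - K$ quantile (prevalence $K$, default
  0.5). The construction has heritability exactly $h^2$ by design.
* **Two-SNP interaction (proof of concept)**: each causal gene carries two
  causal variants and contributes 1 to the score only when *both* carry at
  least one minor allele — a non-linearity a single-variant linear model
  cannot capture fully. Control genes carry no signal. The default
  heritability for this design is 0.9: a "these SNPs cause the disease"
  scenario with mild environmental noise.
* `theoretical_max_auc()` integrates the conditional distributions of $g$
  given case/control status on a 20,001-point grid, giving the ceiling no
  genotype-only classifier can beat; it is verified against a $10^6$-draw
  Monte-Carlo oracle in the tests.
* `ascertain()` downsamples to a chosen case fraction, mirroring
  equal-cases-and-controls sampling.

What the generator deliberately does **not** emulate: linkage
disequilibrium, population stratification, imputation uncertainty, rare
variants, and covariates. Tests passing on these simulations therefore
demonstrate correctness of the machinery and recoverability of signal under
idealized conditions — not performance on real cohorts, where annotation
quality and LD structure dominate.

## Data handling

`convert_genotypes()` reads VCF (GT, or DS dosages when present) and
PLINK-raw-style additive text; missing genotypes are mean-imputed per
variant with a reported count, and non-diploid records are errors.
Monomorphic variants are removed by `filter_zero_variance()`.
`split_cohort()` produces the 60/20/20 train/validation/test partition,
stratified to preserve the case/control ratio per set, and places entire
connected components of the kinship graph (coefficient > 0.0625, roughly
second degree) in the training set — the per-pair rule stated for cohort
studies is only consistent under transitive closure, so components are the
unit of assignment. Validation and test thus contain only mutually
unrelated samples. The dataset container is an in-memory dosage matrix with
variant-major chunked accessors (`variant_chunks()`, default 4,096 variants
per chunk); this desk-scale backend keeps the conversion and iteration
semantics of a chunked binary store without imposing one on small problems.

## Baselines and bounds

`lasso_baseline()` is LASSO logistic regression expressed in the same
machinery: a dense single-neuron sigmoid layer with L1 on the weights and no
batch normalization, optimized full-batch over a decreasing learning-rate
ladder (0.1 → 10⁻⁴, 500 epochs each) so that the zero-penalty solution
reaches the logistic maximum-likelihood estimate to high precision — the
test suite requires agreement with `stats::glm` coefficients to $10^{-3}$.
`random_connectivity()` rewires a template with the same node counts and
exactly the same number of links (resampling, at most 100 times, until
every output stays connected), so comparisons between annotated and random
architectures are capacity-matched by construction. `upper_bound()` turns a
monozygotic-twin concordance rate $c$ and a prevalence $K$ into the
confusion-matrix ceiling for genetics-only classification: sensitivity at
most $c$, specificity at most $1 - K$, accuracy at most
$(c\,n_\mathrm{cases} + (1-K)\,n_\mathrm{controls}) / n$. Concordance is an
explicit input, not a literature constant baked in.

## Problem sizes used in the test suite

The shipped tests run the full pipeline at deliberately desk-scale sizes
chosen to keep the suite fast while leaving the measured properties clearly
resolved: the interpretability proof of concept uses 5,000 samples, 20
genes × 10 variants and 10 seeds; the heritability-by-sample-size grid
spans $h^2 \in \{0.1, 0.5, 0.9\}$ × $n \in \{1000, 5000, 20000\}$ with 100
variants and 5 seeds; oracle-equivalence checks use layers up to 50×20; and
the ceiling is validated at $10^5$–$10^6$ simulated individuals. The same
generator exposes every knob for larger experiments.

## Known limitations

* Path-product importance ignores activation nonlinearity; strongly
  interacting pathways can be mis-ranked relative to a full attribution
  method.
* The importance shares of nodes under multiple parents are layer-wide;
  ring-nesting in the sunburst places such nodes under one parent only.
* The trainer is a single-threaded CPU implementation intended for
  method-level work and desk-scale studies, not a GPU engine for
  biobank-scale variant sets.
* Genotype storage is in-memory; the chunked access pattern is an
  interface, not an out-of-core store.
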