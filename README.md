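# annonet

Annotation-guided sparse neural networks for genotype-to-phenotype
prediction in R.

## The problem

Fully connected neural networks are impractical and uninterpretable on
genome-scale genotype data: millions of input variants make dense layers
memory-infeasible, and even when such a network trains, its weights say
nothing biological. `annonet` takes the opposite approach: the network's
architecture *is* the biology. Connections exist only where an annotation
licenses them — variants connect to the genes they sit in, genes to their
pathways (a three-level KEGG-style hierarchy) or to the tissues in whose
expression profile they rank in the top 10% of t-statistics. Each layer
computes

```
y_j = Activation( Σ_{i ∈ links(j)} x_i · w_ij + B_j )
```

with one learnable weight per annotation link and one bias per node,
preceded by batch normalization without scale/shift so weights stay
comparable. Every node is a biological entity uniquely defined by its
connections, and every learned weight is interpretable as the effect of one
entity on another. Path-product attribution (`relative_importance()`) turns
a trained network into a ranked table of variants, genes, and pathways;
Manhattan and sunburst exports visualize it.

The package is written for statistical geneticists and method developers:
alongside the model it ships a liability-threshold phenotype simulator
(additive and two-SNP-interaction architectures with tunable heritability,
polygenicity and prevalence), the theoretical AUC ceiling implied by
heritability, a LASSO logistic baseline, capacity-matched random-wiring
comparators, a monozygotic-concordance performance bound, and a
kinship-aware cohort splitter — everything needed to validate the method
end to end without any real cohort.

## Worked example

Simulate the non-linear proof-of-concept design — 20 genes of 10 variants
each, two causal genes whose pair of causal variants must *both* carry a
minor allele to contribute — then fit a variant→gene network and ask it
which genes matter:

```r
library(annonet)

sim <- simulate_cohort(sim_config(
  n_samples = 3000, n_variants = 200, n_genes = 20, causal_genes = 2,
  h2 = 0.9, prevalence = 0.5, interaction_mode = "pairwise_and", seed = 7))

cm  <- build_snp_gene_matrix(sim$annotation, colnames(sim$genotypes))
fit <- annonet(sim$genotypes, sim$labels, cm,
               config = train_config(batch_size = 64, learning_rate = 0.01,
                                     l1 = 1e-4, max_epochs = 50,
                                     patience = 10, seed = 1))
fit
#> Annotation-guided sparse network fit
#>
#> Sparse network (classification), 2 layers, 241 parameters
#>   SNP->gene         200 ->    20 nodes,     200 links, tanh (batchnorm)
#>   output             20 ->     1 nodes,      20 links, sigmoid (batchnorm)
#>
#> Trained 33 epochs (best epoch 23, patience 10)
#> Best validation loss 0.2200, validation auc 0.9536

imp   <- relative_importance(fit)
genes <- imp[imp$layer == 1, ]
head(genes[order(-genes$relative_importance),
           c("node_id", "importance", "relative_importance")], 4)
#>  node_id importance relative_importance
#>     g020 12.0309734          0.45655443
#>     g002 11.5209961          0.43720168
#>     g011 -0.5800257          0.02201096
#>     g019  0.3797752          0.01441181

sim$causal_genes
#> [1] "g002" "g020"
```

The 241-parameter network (a dense equivalent would need 4,220) reaches a
validation AUC of 0.95 against a heritability ceiling of
`theoretical_max_auc(0.9, 0.5)` ≈ 0.968, and the two truly causal genes
absorb ~90% of the relative importance between them. `coef(fit)` returns
per-link weights, `predict(fit, newdata)` risk scores,
`normalized_weights()` activation-scaled weights for Manhattan plots, and
`plot(fit)` the training curves.

A thin command-line front end (`exec/annonet`) wraps the same functions:
`annonet simulate`, `annonet train`, `annonet interpret`, `annonet bound`.

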