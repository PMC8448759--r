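#' Simulation configuration
#'
#' Describes a synthetic genotype-phenotype study under the liability
#' threshold model: biallelic variants with given minor allele frequencies,
#' an additive or two-SNP-interaction causal architecture, a target
#' narrow-sense heritability, and case/control labels from thresholding the
#' latent liability at the quantile set by the prevalence.
#'
#' @param n_samples number of individuals.
#' @param n_variants number of biallelic variants.
#' @param maf_range minor-allele-frequency range `(low, high)` in (0, 0.5];
#'   per-variant MAFs are drawn uniformly. Default (0.1, 0.5), typical of
#'   common genotyping-array variants.
#' @param n_genes number of genes the variants partition into (default:
#'   one gene per 10 variants).
#' @param causal_genes number of causal genes (interaction mode).
#' @param causal_snps_per_gene causal variants per causal gene (interaction
#'   mode; the proof-of-concept design uses 2).
#' @param h2 narrow-sense heritability of the liability, in \[0, 1\].
#' @param polygenicity fraction of variants that are causal (additive mode).
#' @param prevalence population fraction of cases, in (0, 1).
#' @param interaction_mode `"additive"` (independent standard-normal effect
#'   sizes) or `"pairwise_and"` (a gene contributes 1 iff both its causal
#'   variants carry at least one minor allele).
#' @param seed integer seed.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples, n_variants, maf_range = c(0.1, 0.5),
                       n_genes = max(1L, n_variants %/% 10L),
                       causal_genes = min(2L, n_genes),
                       causal_snps_per_gene = 2L,
                       h2 = 0.5, polygenicity = 0.1, prevalence = 0.5,
                       interaction_mode = c("additive", "pairwise_and"),
                       seed = 1L) {
  interaction_mode <- match.arg(interaction_mode)
  stopifnot(n_samples >= 2, n_variants >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_genes >= 1, n_genes <= n_variants,
            causal_genes <= n_genes, causal_snps_per_gene >= 1,
            h2 >= 0, h2 <= 1, polygenicity >= 0, polygenicity <= 1,
            prevalence > 0, prevalence < 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants),
                 maf_range = maf_range, n_genes = as.integer(n_genes),
                 causal_genes = as.integer(causal_genes),
                 causal_snps_per_gene = as.integer(causal_snps_per_gene),
                 h2 = h2, polygenicity = polygenicity,
                 prevalence = prevalence,
                 interaction_mode = interaction_mode,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genotype dosage matrix
#'
#' Per-variant MAFs are drawn uniformly from `maf_range`; dosages are
#' independent Binomial(2, MAF) draws (no linkage disequilibrium or
#' population structure).
#'
#' @param cfg a [sim_config()].
#' @return integer matrix, samples x variants, values 0/1/2, with variant
#'   column names and attribute `"maf"`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  maf <- stats::runif(cfg$n_variants, cfg$maf_range[1], cfg$maf_range[2])
  g <- vapply(maf, function(p) stats::rbinom(cfg$n_samples, 2L, p),
              integer(cfg$n_samples))
  colnames(g) <- sprintf("v%05d", seq_len(cfg$n_variants))
  rownames(g) <- sprintf("s%05d", seq_len(cfg$n_samples))
  attr(g, "maf") <- maf
  g
}

## Internal: standardize a genetic score, guarding zero variance.
standardize_score <- function(g) {
  s <- stats::sd(g)
  if (!is.finite(s) || s == 0) stop("genetic score has zero variance")
  (g - mean(g)) / s
}

## Internal: liability from a standardized genetic score.
liability_from_score <- function(g_std, h2, prevalence, n) {
  eps <- stats::rnorm(n)
  liab <- sqrt(h2) * g_std + sqrt(1 - h2) * eps
  thr <- stats::qnorm(1 - prevalence)
  list(liability = liab, labels = as.integer(liab > thr), threshold = thr)
}

#' Simulate an additive liability-threshold phenotype
#'
#' A fraction `polygenicity` of variants is causal with independent
#' standard-normal effect sizes; the genetic score is standardized so the
#' liability `sqrt(h2) * g + sqrt(1 - h2) * e` has heritability `h2` by
#' construction. Individuals above the `1 - prevalence` quantile of a
#' standard normal are cases.
#'
#' @param genotypes dosage matrix from [simulate_genotypes()].
#' @param cfg a [sim_config()] (additive mode).
#' @return list: `labels` (0/1), `liabilities`, `genetic_score`
#'   (standardized), `causal_variants`, `effects`.
#' @export
simulate_liability_phenotype <- function(genotypes, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  m <- ncol(genotypes)
  n_causal <- round(cfg$polygenicity * m)
  if (n_causal == 0L && cfg$h2 > 0) {
    stop("h2 > 0 requires at least one causal variant ",
         "(round(polygenicity * n_variants) is 0)")
  }
  set.seed(cfg$seed + 1L)
  causal <- sort(sample.int(m, n_causal))
  beta <- stats::rnorm(n_causal)
  g_std <- if (cfg$h2 > 0) {
    standardize_score(as.numeric(genotypes[, causal, drop = FALSE] %*% beta))
  } else {
    numeric(nrow(genotypes))
  }
  lab <- liability_from_score(g_std, cfg$h2, cfg$prevalence, nrow(genotypes))
  list(labels = lab$labels, liabilities = lab$liability,
       genetic_score = g_std,
       causal_variants = colnames(genotypes)[causal], effects = beta)
}

## Internal: partition variants into genes (contiguous blocks, near-equal
## sizes) and return the annotation table.
gene_partition <- function(variant_names, n_genes) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  assign <- sort(rep_len(seq_len(n_genes), length(variant_names)))
  data.frame(child = variant_names, parent = genes[assign],
             stringsAsFactors = FALSE)
}

#' Simulate a complete cohort (genotypes, genes, phenotype, truth)
#'
#' One-stop generator returning genotypes, a variant-to-gene annotation
#' partition, labels, and the hidden truth kept for testing. In
#' `"additive"` mode the causal variants are drawn genome-wide by
#' `polygenicity`; in `"pairwise_and"` mode (the non-linear proof-of-concept
#' design) each of `causal_genes` genes carries two causal variants and
#' contributes 1 to the genetic score only when a sample carries at least
#' one minor allele at *both* — a pattern no single-variant linear model
#' captures fully. Control genes carry no signal.
#'
#' @param cfg a [sim_config()].
#' @return list of class `"sim_dataset"`: `genotypes`, `labels`,
#'   `annotation` (child = variant, parent = gene), `causal_variants`,
#'   `causal_genes`, `liabilities`, `genetic_score`, `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  g <- simulate_genotypes(cfg)
  annot <- gene_partition(colnames(g), cfg$n_genes)
  if (cfg$interaction_mode == "additive") {
    ph <- simulate_liability_phenotype(g, cfg)
    causal_genes <- sort(unique(
      annot$parent[annot$child %in% ph$causal_variants]))
    ds <- list(genotypes = g, labels = ph$labels, annotation = annot,
               causal_variants = ph$causal_variants,
               causal_genes = causal_genes, liabilities = ph$liabilities,
               genetic_score = ph$genetic_score, config = cfg)
  } else {
    ds <- simulate_proof_of_concept_impl(g, annot, cfg)
  }
  structure(ds, class = "sim_dataset")
}

#' Simulate the two-SNP-interaction proof-of-concept dataset
#'
#' Convenience wrapper around [simulate_cohort()] enforcing
#' `interaction_mode = "pairwise_and"`.
#'
#' @param cfg a [sim_config()] with `causal_snps_per_gene = 2`.
#' @return a `"sim_dataset"`, see [simulate_cohort()].
#' @export
simulate_proof_of_concept <- function(cfg) {
  cfg$interaction_mode <- "pairwise_and"
  simulate_cohort(cfg)
}

simulate_proof_of_concept_impl <- function(g, annot, cfg) {
  if (cfg$causal_snps_per_gene != 2L) {
    stop("the pairwise_and design uses exactly 2 causal variants per gene")
  }
  per_gene <- split(annot$child, annot$parent)
  sizes <- lengths(per_gene)
  eligible <- names(per_gene)[sizes >= 2L]
  if (length(eligible) < cfg$causal_genes) {
    stop("genes with < 2 variants cannot be causal; only ",
         length(eligible), " eligible gene(s)")
  }
  set.seed(cfg$seed + 1L)
  causal_genes <- sort(sample(eligible, cfg$causal_genes))
  pairs <- lapply(causal_genes, function(gn) sort(sample(per_gene[[gn]], 2L)))
  contrib <- vapply(pairs, function(pr) {
    as.numeric(g[, pr[1]] >= 1L & g[, pr[2]] >= 1L)
  }, numeric(nrow(g)))
  score <- rowSums(contrib)
  g_std <- standardize_score(score)
  lab <- liability_from_score(g_std, cfg$h2, cfg$prevalence, nrow(g))
  list(genotypes = g, labels = lab$labels, annotation = annot,
       causal_variants = sort(unlist(pairs)), causal_genes = causal_genes,
       liabilities = lab$liability, genetic_score = g_std, config = cfg)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Simulated cohort: %d samples x %d variants in %d genes (%s mode)\n",
    nrow(x$genotypes), ncol(x$genotypes), cfg$n_genes,
    cfg$interaction_mode))
  cat(sprintf("h2 = %.2f, prevalence = %.2f, %d cases / %d controls\n",
              cfg$h2, cfg$prevalence, sum(x$labels == 1),
              sum(x$labels == 0)))
  invisible(x)
}

#' Downsample a cohort to a target case fraction
#'
#' Case-control ascertainment: after liability thresholding, the majority
#' class is randomly downsampled so the dataset reaches the requested case
#' fraction (e.g. an equal number of cases and controls).
#'
#' @param ds a `"sim_dataset"`.
#' @param case_fraction target fraction of cases, default 0.5.
#' @param seed integer seed.
#' @return the subsampled `"sim_dataset"`.
#' @export
ascertain <- function(ds, case_fraction = 0.5, seed = 1L) {
  stopifnot(inherits(ds, "sim_dataset"),
            case_fraction > 0, case_fraction < 1)
  set.seed(seed)
  cases <- which(ds$labels == 1L)
  controls <- which(ds$labels == 0L)
  ## keep all of the limiting class, downsample the other
  n_cases <- min(length(cases),
                 floor(length(controls) * case_fraction / (1 - case_fraction)))
  n_controls <- min(length(controls),
                    floor(length(cases) * (1 - case_fraction) / case_fraction))
  keep <- sort(c(sample(cases, n_cases), sample(controls, n_controls)))
  ds$genotypes <- ds$genotypes[keep, , drop = FALSE]
  ds$labels <- ds$labels[keep]
  ds$liabilities <- ds$liabilities[keep]
  ds$genetic_score <- ds$genetic_score[keep]
  ds
}

#' Theoretical maximum AUC under the liability threshold model
#'
#' AUC of the Bayes-optimal genetic score (the true genetic liability `g ~
#' N(0, h2)`) for cases versus controls, when cases are individuals whose
#' total liability `g + e`, `e ~ N(0, 1 - h2)`, exceeds the
#' `1 - prevalence` quantile. Computed by numerical integration of the
#' conditional distributions of `g` given case/control status. No
#' classifier using genotype information alone can exceed this value, which
#' is independent of the case fraction in the analysed sample (AUC is a
#' ranking probability conditional on status).
#'
#' @param h2 narrow-sense heritability in \[0, 1\].
#' @param prevalence population case fraction in (0, 1).
#' @param case_fraction_in_sample accepted for interface completeness; the
#'   AUC does not depend on it.
#' @return AUC in \[0.5, 1\].
#' @examples
#' theoretical_max_auc(0, 0.5)    # 0.5
#' theoretical_max_auc(1, 0.5)    # 1
#' theoretical_max_auc(0.5, 0.5)
#' @export
theoretical_max_auc <- function(h2, prevalence = 0.5,
                                case_fraction_in_sample = NULL) {
  stopifnot(h2 >= 0, h2 <= 1, prevalence > 0, prevalence < 1)
  if (h2 == 0) return(0.5)
  if (h2 == 1) return(1.0)
  s <- sqrt(h2)
  thr <- stats::qnorm(1 - prevalence)
  x <- seq(-9 * s, 9 * s, length.out = 20001L)
  p_case <- stats::pnorm((x - thr) / sqrt(1 - h2))
  dens <- stats::dnorm(x, 0, s)
  f_case <- dens * p_case
  f_ctrl <- dens * (1 - p_case)
  ## normalize numerically to guard truncation error
  f_case <- f_case / trapz(x, f_case)
  f_ctrl <- f_ctrl / trapz(x, f_ctrl)
  F_ctrl <- cumtrapz(x, f_ctrl)
  trapz(x, f_case * F_ctrl)
}
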