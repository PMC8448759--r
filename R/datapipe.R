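#' Genotype dataset container
#'
#' Samples x variants dosage matrix plus variant metadata (id, chromosome,
#' 1-based position), sample metadata, and optional labels and kinship
#' pairs. Dosages are minor-allele counts in `{0, 1, 2}` or fractional in
#' `[0, 2]` for imputed data. Variant-major access for large stores is
#' provided through [variant_chunks()].
#'
#' @param dosages numeric matrix, samples x variants, with dimnames.
#' @param variants data.frame with columns `id`, `chrom`, `pos`.
#' @param samples data.frame with column `id`.
#' @param labels optional named binary vector (names = sample ids).
#' @param kinship optional data.frame `id1`, `id2`, `coefficient`.
#' @return an object of class `"genotype_dataset"`.
#' @export
genotype_dataset <- function(dosages, variants = NULL, samples = NULL,
                             labels = NULL, kinship = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- sprintf("v%05d", seq_len(ncol(dosages)))
  }
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("s%05d", seq_len(nrow(dosages)))
  }
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE)) {
    stop("dosages must lie in [0, 2]")
  }
  variants <- variants %||% data.frame(
    id = colnames(dosages), chrom = NA_character_, pos = NA_integer_,
    stringsAsFactors = FALSE)
  samples <- samples %||% data.frame(id = rownames(dosages),
                                     stringsAsFactors = FALSE)
  stopifnot(identical(as.character(variants$id), colnames(dosages)),
            identical(as.character(samples$id), rownames(dosages)))
  structure(list(dosages = dosages, variants = variants, samples = samples,
                 labels = labels, kinship = kinship),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("Genotype dataset: %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  if (!is.null(x$labels)) {
    cat(sprintf("labels: %d cases / %d controls\n",
                sum(x$labels == 1), sum(x$labels == 0)))
  }
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosages)

#' Variant-major chunk index
#'
#' Splits the variant index into chunks of at most `chunk_size` for
#' variant-major iteration (the transposed access pattern used when
#' converting or streaming large stores), so per-chunk working memory does
#' not scale with the total variant count.
#'
#' @param ds a [genotype_dataset()].
#' @param chunk_size variants per chunk, default 4096.
#' @return list of integer index vectors.
#' @export
variant_chunks <- function(ds, chunk_size = 4096L) {
  m <- ncol(ds$dosages)
  unname(split(seq_len(m), ceiling(seq_len(m) / chunk_size)))
}

#' Convert a genotype file into a dataset
#'
#' Reads a VCF (using the `GT` genotype field, or per-sample `DS` dosages
#' when present, supporting imputed data) or a PLINK-raw-style additive text
#' file into a [genotype_dataset()]. Conversion is lossless for dosages.
#' Missing genotypes are imputed to the per-variant mean dosage, with the
#' count reported; non-diploid GT entries are an error naming the locus.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"`, or `"raw"`.
#' @return a [genotype_dataset()] with attribute `"n_imputed"`.
#' @export
convert_genotypes <- function(path, format = c("auto", "vcf", "raw")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
      "vcf"
    } else "raw"
  }
  if (format == "vcf") read_vcf_dosages(path) else read_plink_raw(path)
}

read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) {  # single-variant files come back as a vector
    fixm <- matrix(fixm, nrow = 1, dimnames = list(NULL, names(fixm)))
  }
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  fmt <- v@gt[, 1]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    dose <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    dose <- apply(gt, c(1, 2), gt_to_dosage)
  }
  rownames(dose) <- ids
  ds_matrix <- t(dose)  # samples x variants
  n_imputed <- impute_missing(ds_matrix)
  ds_matrix <- attr(n_imputed, "matrix")
  variants <- data.frame(id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), stringsAsFactors = FALSE)
  out <- genotype_dataset(ds_matrix, variants = variants)
  attr(out, "n_imputed") <- as.integer(n_imputed)
  out
}

gt_to_dosage <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (length(alleles) != 2L) {
    stop("non-diploid genotype '", gt, "'")
  }
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles != "0")
}

## mean-impute missing entries per variant; returns count with the matrix
## attached (avoids copying twice)
impute_missing <- function(m) {
  n_missing <- sum(is.na(m))
  if (n_missing) {
    for (j in which(colSums(is.na(m)) > 0)) {
      mu <- mean(m[, j], na.rm = TRUE)
      if (is.nan(mu)) stop("variant ", colnames(m)[j], " entirely missing")
      m[is.na(m[, j]), j] <- mu
    }
    message(sprintf("imputed %d missing genotype(s) to per-variant means",
                    n_missing))
  }
  structure(n_missing, matrix = m)
}

read_plink_raw <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta_cols <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                         names(tab))
  id_col <- if ("IID" %in% names(tab)) "IID" else names(tab)[1]
  if (length(meta_cols) == 0L) meta_cols <- names(tab)[1]
  sample_ids <- as.character(tab[[id_col]])
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in ", path)
  g <- as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE])
  storage.mode(g) <- "double"
  rownames(g) <- sample_ids
  n_imputed <- impute_missing(g)
  g <- attr(n_imputed, "matrix")
  out <- genotype_dataset(g)
  attr(out, "n_imputed") <- as.integer(n_imputed)
  out
}

#' Export a dataset as PLINK-raw-style additive text
#'
#' Writes the header `FID IID PAT MAT SEX PHENOTYPE` followed by one column
#' per variant; re-reading with [convert_genotypes()] restores the dosage
#' matrix exactly.
#'
#' @param ds a [genotype_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_plink_raw <- function(ds, path) {
  labels <- ds$labels %||% rep(NA_integer_, nrow(ds$dosages))
  tab <- data.frame(FID = rownames(ds$dosages), IID = rownames(ds$dosages),
                    PAT = 0L, MAT = 0L, SEX = 0L,
                    PHENOTYPE = labels, check.names = FALSE,
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(ds$dosages, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove variants without variance
#'
#' Monomorphic variants (a single distinct dosage value) carry no signal
#' and are dropped before training; the count is reported.
#'
#' @param ds a [genotype_dataset()].
#' @return the filtered dataset with attribute `"n_removed"`.
#' @export
filter_zero_variance <- function(ds) {
  keep <- apply(ds$dosages, 2, function(col) length(unique(col)) > 1L)
  n_removed <- sum(!keep)
  if (n_removed) {
    message(sprintf("removed %d zero-variance variant(s)", n_removed))
  }
  ds$dosages <- ds$dosages[, keep, drop = FALSE]
  ds$variants <- ds$variants[keep, , drop = FALSE]
  attr(ds, "n_removed") <- as.integer(n_removed)
  ds
}

#' Attach labels / kinship to a dataset
#'
#' @param ds a [genotype_dataset()].
#' @param labels data.frame `sample`, `label` or a named vector.
#' @param kinship optional data.frame `id1`, `id2`, `coefficient`.
#' @return the updated dataset.
#' @export
attach_phenotypes <- function(ds, labels, kinship = NULL) {
  if (is.data.frame(labels)) {
    lv <- stats::setNames(labels[[2]], as.character(labels[[1]]))
  } else {
    lv <- labels
  }
  missing <- setdiff(rownames(ds$dosages), names(lv))
  if (length(missing)) {
    stop("labels missing for sample(s): ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  ds$labels <- lv[rownames(ds$dosages)]
  ds$kinship <- kinship
  ds
}

#' Kinship-aware stratified train/validation/test split
#'
#' Splits samples 60/20/20 (by default) while preserving the case/control
#' ratio in every set. Relatedness is respected transitively: connected
#' components of the kinship graph above the threshold (default 0.0625,
#' about 2nd degree) are placed wholly in the training set, so validation
#' and test contain only samples unrelated within and between sets.
#' Unrelated samples are randomly assigned, stratified by class, to fill the
#' validation and test quotas computed from the full per-class totals.
#'
#' @param labels binary labels, named by sample id (or a
#'   [genotype_dataset()] with labels attached).
#' @param kinship data.frame `id1`, `id2`, `coefficient`; may be `NULL` or
#'   empty.
#' @param kinship_threshold pairs above this coefficient count as related.
#' @param ratios train/validation/test fractions summing to 1.
#' @param seed integer seed.
#' @return factor with levels `train`, `val`, `test`, named by sample id.
#' @export
split_cohort <- function(labels, kinship = NULL,
                         kinship_threshold = 0.0625,
                         ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (inherits(labels, "genotype_dataset")) {
    kinship <- kinship %||% labels$kinship
    labels <- labels$labels
  }
  stopifnot(!is.null(labels), abs(sum(ratios) - 1) < 1e-8,
            length(ratios) == 3L)
  y <- as_binary_labels(labels)
  ids <- names(labels) %||% as.character(seq_along(labels))
  names(y) <- ids
  set.seed(seed)

  related <- character()
  if (!is.null(kinship) && nrow(kinship) > 0) {
    kin <- kinship[kinship[[3]] > kinship_threshold, , drop = FALSE]
    if (nrow(kin)) {
      unknown <- setdiff(unique(c(kin[[1]], kin[[2]])), ids)
      if (length(unknown)) {
        stop("kinship ids absent from labels: ",
             paste(unknown, collapse = ", "))
      }
      gr <- igraph::graph_from_data_frame(kin[, 1:2], directed = FALSE)
      comp <- igraph::components(gr)
      related <- names(comp$membership)  # every vertex in a related pair
    }
  }
  assignment <- stats::setNames(rep("train", length(ids)), ids)
  pool <- setdiff(ids, related)
  for (cls in c(0L, 1L)) {
    cls_ids <- ids[y == cls]
    n_val <- round(ratios[2] * length(cls_ids))
    n_test <- round(ratios[3] * length(cls_ids))
    cls_pool <- intersect(pool, cls_ids)
    if (length(cls_pool) < n_val + n_test) {
      ach <- length(cls_pool) / length(cls_ids) / 2
      stop(sprintf(
        paste0("not enough unrelated samples of class %d for a %.0f/%.0f/%.0f",
               " split; achievable validation+test fraction is %.2f"),
        cls, 100 * ratios[1], 100 * ratios[2], 100 * ratios[3], 2 * ach))
    }
    chosen <- sample(cls_pool, n_val + n_test)
    assignment[chosen[seq_len(n_val)]] <- "val"
    assignment[chosen[n_val + seq_len(n_test)]] <- "test"
  }
  factor(assignment, levels = c("train", "val", "test"))
}

#' Evaluate a fitted model on one split of a dataset
#'
#' Computes the AUC (trapezoidal over all thresholds) and accuracy at 0.5
#' on the samples assigned to `set`.
#'
#' @param model an `"annonet"` fit (or any object with a `predict` method
#'   returning probabilities).
#' @param ds a [genotype_dataset()] with labels.
#' @param split factor from [split_cohort()].
#' @param set one of `"train"`, `"val"`, `"test"`.
#' @return list with `auc`, `accuracy`, `n`.
#' @export
evaluate_split <- function(model, ds, split, set = "test") {
  stopifnot(set %in% levels(split))
  idx <- names(split)[split == set]
  x <- ds$dosages[idx, , drop = FALSE]
  y <- as_binary_labels(ds$labels[idx])
  p <- predict(model, x)
  list(auc = auc_score(p, y), accuracy = accuracy_score(p, y),
       n = length(y))
}
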