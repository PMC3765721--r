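# Cross-sample variability: the rescaled-RPKM matrix, CVs, pooled-SD
# t-statistics, hierarchical clustering of samples and per-exon
# median/CV dispersion summaries.

#' Assemble an exon-by-sample rescaled-RPKM matrix
#'
#' One row per (exon, host gene) pair of the requested classes, one column
#' per sample. Entries are capped rescaled RPKMs and are missing (`NA`)
#' where the host gene is un-expressed in that sample.
#'
#' @param samples list of `sample_expression` objects quantified against a
#'   common annotation
#' @param classes exon classes to include (default the TE classes C3, C4)
#' @return an object of class `expression_matrix`: list with `values`
#'   (numeric matrix), `exons` (tibble `exon_id`, `gene_id`, `class`) and
#'   `samples` (tibble `sample_id`)
#' @export
expression_matrix <- function(samples, classes = c("C3", "C4")) {
  stopifnot(length(samples) >= 1)
  base <- samples[[1]]$exons
  rows <- base[base$class %in% classes, c("exon_id", "gene_id", "class")]
  key <- paste(rows$exon_id, rows$gene_id)
  vals <- vapply(samples, function(s) {
    ex <- s$exons
    ex <- ex[ex$class %in% classes, ]
    ex$rescaled[match(key, paste(ex$exon_id, ex$gene_id))]
  }, numeric(nrow(rows)))
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  colnames(vals) <- ids
  rownames(vals) <- key
  structure(list(values = vals, exons = rows,
                 samples = tibble(sample_id = ids)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " exons x ", ncol(x$values),
      " samples (", round(100 * mean(is.na(x$values)), 1), "% missing)\n",
      sep = "")
  invisible(x)
}

#' Coefficient of variance, in percent
#'
#' `100 * sd / mean` over the non-missing values. Undefined (fewer than two
#' non-missing values, or zero mean) results are `NA`.
#'
#' @param values numeric vector, possibly with `NA`
#' @return CV in percent, or `NA`
#' @export
cv <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) return(NA_real_)
  m <- mean(v)
  if (m <= 0) return(NA_real_)
  100 * sd(v) / m
}

#' Exons whose host gene is expressed in enough samples
#'
#' @param matrix an `expression_matrix`
#' @param min_samples minimum number of samples with the host gene
#'   expressed (default half the samples, rounded up)
#' @return the `expression_matrix` restricted to eligible rows
#' @export
eligible_exons <- function(matrix,
                           min_samples = ceiling(ncol(matrix$values) / 2)) {
  keep <- rowSums(!is.na(matrix$values)) >= min_samples
  matrix$values <- matrix$values[keep, , drop = FALSE]
  matrix$exons <- matrix$exons[keep, ]
  matrix
}

#' Two-group t-statistic with pooled standard deviation
#'
#' `(mean_a - mean_b) / (s_p * sqrt(1/n_a + 1/n_b))` with the equal-variance
#' pooled SD `s_p`. Undefined (a group smaller than 2, or zero pooled SD)
#' results are `NA`.
#'
#' @param group_a,group_b value vectors; `NA`s are dropped
#' @return the t statistic, or `NA`
#' @export
pooled_t <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) return(NA_real_)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) return(NA_real_)
  (mean(a) - mean(b)) / (sqrt(sp2) * sqrt(1 / na + 1 / nb))
}

#' Per-exon t-statistics for a two-group sample contrast
#'
#' @param matrix an `expression_matrix`
#' @param samples_a,samples_b sample ids of the two groups
#' @return tibble `exon_id`, `gene_id`, `class`, `t`
#' @export
contrast_t <- function(matrix, samples_a, samples_b) {
  ia <- match(samples_a, matrix$samples$sample_id)
  ib <- match(samples_b, matrix$samples$sample_id)
  if (anyNA(ia) || anyNA(ib)) abort("unknown sample id in contrast")
  t <- apply(matrix$values, 1, function(r) pooled_t(r[ia], r[ib]))
  dplyr::mutate(matrix$exons, t = unname(t))
}

#' Complete-linkage hierarchical clustering of samples
#'
#' Clusters the samples (columns) by Euclidean distance over the exon
#' values with complete linkage. Missing values (host gene un-expressed)
#' are imputed as 0 for the distance computation by default. `hclust`'s
#' merge order is deterministic; equal-height ties are merged in input
#' (lowest sample index) order.
#'
#' @param matrix an `expression_matrix`, or a plain samples-by-features
#'   numeric matrix
#' @param k number of flat clusters to cut (default 2)
#' @param impute_zero replace `NA` by 0 before computing distances
#' @return list with `tree` (an `hclust`), `labels` (named cluster vector)
#' @export
hcluster <- function(matrix, k = 2, impute_zero = TRUE) {
  m <- if (inherits(matrix, "expression_matrix")) t(matrix$values) else matrix
  if (nrow(m) < 2) abort("hcluster: need at least 2 samples")
  if (impute_zero) m[is.na(m)] <- 0
  if (anyNA(m)) abort("hcluster: missing values present; set impute_zero")
  tree <- hclust(dist(m, method = "euclidean"), method = "complete")
  list(tree = tree, labels = cutree(tree, k = k))
}

#' Export a sample dendrogram in Newick format
#' @param tree an `hclust`, e.g. `hcluster(...)$tree`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_dendrogram_newick <- function(tree, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    abort("Newick export needs the 'ape' package")
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Per-exon median and CV across samples
#'
#' For each exon hosted by a gene expressed in at least `min_samples`
#' samples, the median `m` and coefficient of variance `v` (percent) of its
#' rescaled RPKMs across samples, missing values excluded.
#'
#' @param matrix an `expression_matrix`
#' @param min_samples eligibility threshold (default 13, half of 26)
#' @return tibble `exon_id`, `gene_id`, `class`, `m`, `v`,
#'   `n_expressed_samples`
#' @export
dispersion_summary <- function(matrix, min_samples = 13) {
  elig <- eligible_exons(matrix, min_samples)
  vals <- elig$values
  dplyr::mutate(
    elig$exons,
    m = unname(apply(vals, 1, function(r) median(r, na.rm = TRUE))),
    v = unname(apply(vals, 1, cv)),
    n_expressed_samples = unname(rowSums(!is.na(vals)))
  )
}

#' Kendall rank correlation between paired statistics
#'
#' Tau-b (tie-corrected); the p-value uses the exact distribution for at
#' most 10 untied pairs and the normal approximation otherwise.
#'
#' @param m_list,v_list paired numeric vectors (pairs with `NA` dropped)
#' @return list with `tau` and `p_value` (both `NA` for degenerate input)
#' @export
kendall_tau <- function(m_list, v_list) {
  keep <- !is.na(m_list) & !is.na(v_list)
  x <- m_list[keep]; y <- v_list[keep]
  if (length(x) < 2) abort("kendall_tau: need at least 2 pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(tau = NA_real_, p_value = NA_real_))
  exact <- length(x) <= 10 && !any(duplicated(x)) && !any(duplicated(y))
  ct <- suppressWarnings(cor.test(x, y, method = "kendall", exact = exact))
  list(tau = unname(ct$estimate), p_value = ct$p.value)
}
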