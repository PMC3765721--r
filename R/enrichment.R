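# Enrichment of highly expressed TE exons in C2H2 zinc-finger genes:
# per-family 2x2 contingency tables and Fisher's exact test.

#' Flag highly expressed TE exons
#'
#' An exon is highly expressed when its rescaled RPKM is strictly above
#' `threshold` in at least `min_samples` samples.
#'
#' @param matrix an `expression_matrix` of TE exons
#' @param threshold rescaled-RPKM threshold (default 0.25)
#' @param min_samples minimum number of qualifying samples (default 2)
#' @return character vector of flagged exon ids
#' @export
flag_highly_expressed <- function(matrix, threshold = 0.25, min_samples = 2) {
  hits <- rowSums(matrix$values > threshold, na.rm = TRUE) >= min_samples
  unique(matrix$exons$exon_id[hits])
}

#' Host genes of a set of exons
#'
#' @param exon_ids exon ids (e.g. from [flag_highly_expressed()])
#' @param annotation a `te_annotation`
#' @return character vector of host gene ids (union over all hosts;
#'   fictional genes excluded)
#' @export
host_gene_set <- function(exon_ids, annotation) {
  eg <- annotation$exon_genes
  hosts <- unique(eg$gene_id[eg$exon_id %in% exon_ids &
                               eg$role %in% c("annotated", "hosted")])
  real <- annotation$genes$gene_id[!annotation$genes$fictional]
  intersect(hosts, real)
}

#' Per-family contingency tables of highly expressed TE exons in ZNF genes
#'
#' For each TE family, TE exons are cross-classified by expression
#' ("highly expressed" vs "other") and host-gene class ("C2H2 ZNF" vs
#' "other"): `n1` other exons in non-ZNF genes, `n2` highly expressed in
#' non-ZNF genes, `n3` other in ZNF genes, `n4` highly expressed in ZNF
#' genes. Families that contribute no exonized TE to a ZNF gene
#' (`n3 + n4 = 0`) are marked excluded and their p-value is missing.
#'
#' @param te_features TE-exon feature tibble
#' @param flagged highly-expressed exon ids
#' @param znf_genes character vector of C2H2 ZNF gene ids
#' @param annotation a `te_annotation` (for exon-host membership)
#' @param sided `"two"` (default) or `"greater"` for the Fisher test
#' @return tibble: `family`, `n1`..`n4`, `p_value`, `excluded`
#' @export
family_znf_tables <- function(te_features, flagged, znf_genes, annotation,
                              sided = c("two", "greater")) {
  sided <- match.arg(sided)
  eg <- annotation$exon_genes
  eg <- eg[eg$role %in% c("annotated", "hosted"), ]
  te <- dplyr::distinct(te_features, .data$exon_id, .keep_all = TRUE)
  in_znf <- vapply(te$exon_id, function(id)
    any(eg$gene_id[eg$exon_id == id] %in% znf_genes), logical(1))
  high <- te$exon_id %in% flagged
  purrr::map_dfr(sort(unique(te$family)), function(fam) {
    i <- te$family == fam
    n1 <- sum(i & !high & !in_znf); n2 <- sum(i & high & !in_znf)
    n3 <- sum(i & !high & in_znf); n4 <- sum(i & high & in_znf)
    excluded <- (n3 + n4) == 0
    p <- if (excluded) NA_real_ else
      fisher_exact(n1, n2, n3, n4, sided = sided)
    tibble(family = fam, n1 = n1, n2 = n2, n3 = n3, n4 = n4,
           p_value = p, excluded = excluded)
  })
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test of independence. Two-sided p-values sum the
#' probabilities of all tables (at fixed margins) no more probable than the
#' observed one; `sided = "greater"` tests for over-representation of
#' highly expressed exons among ZNF hosts. A zero row or column margin
#' leaves the test undefined (`NA`).
#'
#' @param n1 other exons in non-ZNF genes
#' @param n2 highly expressed exons in non-ZNF genes
#' @param n3 other exons in ZNF genes
#' @param n4 highly expressed exons in ZNF genes
#' @param sided `"two"` or `"greater"`
#' @return the p-value, or `NA` for a degenerate table
#' @export
fisher_exact <- function(n1, n2, n3, n4, sided = c("two", "greater")) {
  sided <- match.arg(sided)
  if (any(c(n1, n2, n3, n4) < 0)) abort("fisher_exact: negative count")
  tab <- matrix(c(n1, n3, n2, n4), nrow = 2)  # rows: non-ZNF/ZNF; cols: other/high
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
  alternative <- if (sided == "two") "two.sided" else "greater"
  fisher.test(tab, alternative = alternative)$p.value
}

#' Read a ZNF gene list (one gene id per line)
#' @param path text file, one gene symbol/id per line; blank lines and
#'   `#` comments ignored
#' @return character vector of gene ids
#' @export
read_znf_list <- function(path) {
  x <- trimws(readr::read_lines(path, progress = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write the per-family enrichment table as TSV
#' @param tables tibble from [family_znf_tables()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_enrichment_table <- function(tables, path) {
  readr::write_tsv(tables, path, progress = FALSE)
  invisible(path)
}
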