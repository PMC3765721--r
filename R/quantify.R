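# Quantification: exon RPKM, gene-level expression, rescaled RPKM with cap,
# and the decoy-based expressed-gene cutoff.

#' Exon RPKM
#'
#' Reads Per Kilobase of exon model per Million mapped reads:
#' `count / ((exon_length / 1000) * (total_reads / 1e6))`.
#'
#' @param count reads mapped to the exon region
#' @param exon_length exon length in bp (>= 1)
#' @param total_reads library size after ambiguity filtering (>= 1)
#' @return RPKM value(s)
#' @export
rpkm <- function(count, exon_length, total_reads) {
  if (any(total_reads < 1)) abort("total_reads must be >= 1")
  if (any(exon_length < 1)) abort("exon_length must be >= 1")
  count / ((exon_length / 1000) * (total_reads / 1e6))
}

#' Gene-level expression from exon RPKMs
#'
#' A gene's expression is the arithmetic mean of the RPKMs of its annotated
#' exons, zero-count exons included. Un-annotated TE exons (C4) and
#' simulated exons (C5) never enter this mean.
#'
#' @param exon_rpkms RPKMs of the gene's annotated exons
#' @return mean RPKM
#' @export
gene_expression <- function(exon_rpkms) {
  if (length(exon_rpkms) == 0) abort("gene has no annotated exons")
  mean(exon_rpkms)
}

#' Rescaled RPKM of an exon within its host gene
#'
#' The exon RPKM divided by the host gene's expression, truncated at `cap`.
#' This double-normalised measure proxies the exon's retention (inclusion)
#' rate in the host gene's transcripts.
#'
#' @param exon_rpkm exon RPKM
#' @param gene_rpkm host-gene expression (> 0; callers must filter
#'   un-expressed genes first)
#' @param cap upper truncation limit (default 10)
#' @return `min(exon_rpkm / gene_rpkm, cap)`
#' @export
rescaled_rpkm <- function(exon_rpkm, gene_rpkm, cap = 10) {
  if (any(gene_rpkm <= 0))
    abort("gene_rpkm must be > 0; filter un-expressed genes before rescaling")
  pmin(exon_rpkm / gene_rpkm, cap)
}

#' Sample-specific expressed-gene cutoff from fictional-gene RPKMs
#'
#' The cutoff is an upper quantile (nearest-rank, quantile type 1) of the
#' RPKM distribution of the fictional decoy genes; genes whose expression
#' falls below it are treated as un-expressed in that sample.
#'
#' @param fictional_gene_rpkms RPKMs of the fictional genes
#' @param quantile_prob quantile in (0, 1] (default 0.95)
#' @return the cutoff RPKM
#' @export
determine_cutoff <- function(fictional_gene_rpkms, quantile_prob = 0.95) {
  if (length(fictional_gene_rpkms) == 0)
    abort("no fictional-gene RPKMs supplied")
  if (quantile_prob <= 0 || quantile_prob > 1)
    abort("quantile_prob must be in (0, 1]")
  unname(quantile(fictional_gene_rpkms, quantile_prob, type = 1, names = FALSE))
}

#' Quantify one sample from exon counts
#'
#' Runs the per-sample quantification chain: exon RPKM, gene-level
#' expression (annotated exons of real genes; member exons of fictional
#' genes), the fictional-gene cutoff, the expressed-gene filter, and capped
#' rescaled RPKMs. C4 and C5 exons are rescaled by their host (paired)
#' gene's expression without ever contributing to it; exons of un-expressed
#' genes get a missing rescaled value.
#'
#' @param counts named integer vector or tibble (`exon_id`, `count`) of
#'   per-exon read counts; exons absent from `counts` get 0
#' @param annotation a `te_annotation`
#' @param total_reads filtered library size used as the RPKM denominator
#' @param sample_id sample label
#' @param cap rescaled-RPKM truncation limit (default 10)
#' @param cutoff_quantile quantile for [determine_cutoff()] (default 0.95)
#' @return an object of class `sample_expression`: a list with `sample_id`,
#'   `total_reads`, `cutoff`, tibble `genes` (`gene_id`, `fictional`,
#'   `gene_rpkm`, `expressed`) and tibble `exons` with one row per
#'   (exon, host gene) pair (`exon_id`, `gene_id`, `class`, `length`,
#'   `count`, `rpkm`, `rescaled`); `rescaled` is capped and `NA` when the
#'   host gene is un-expressed
#' @export
quantify_sample <- function(counts, annotation, total_reads,
                            sample_id = "sample", cap = 10,
                            cutoff_quantile = 0.95) {
  if (is.data.frame(counts)) counts <- setNames(counts$count, counts$exon_id)
  if (total_reads < 1) abort("sample has zero filtered reads")
  ex <- annotation$exons
  cnt <- counts[ex$exon_id]
  cnt[is.na(cnt)] <- 0
  ex$count <- as.numeric(cnt)
  ex$rpkm <- rpkm(ex$count, ex$length, total_reads)

  links <- dplyr::inner_join(annotation$exon_genes,
                             ex[, c("exon_id", "class", "length", "count", "rpkm")],
                             by = "exon_id")
  contributes <- links$role %in% c("annotated", "member")
  gene_rpkm <- links[contributes, ] |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(gene_rpkm = mean(.data$rpkm), .groups = "drop")
  genes <- dplyr::left_join(annotation$genes[, c("gene_id", "fictional")],
                            gene_rpkm, by = "gene_id")
  if (anyNA(genes$gene_rpkm))
    abort("gene(s) without any expression-contributing exon in annotation")
  cutoff <- determine_cutoff(genes$gene_rpkm[genes$fictional], cutoff_quantile)
  genes$expressed <- genes$gene_rpkm >= cutoff

  out <- links[links$role %in% c("annotated", "hosted"),
               c("exon_id", "gene_id", "class", "length", "count", "rpkm")]
  out <- dplyr::left_join(out,
                          genes[, c("gene_id", "gene_rpkm", "expressed")],
                          by = "gene_id")
  out$rescaled <- ifelse(out$expressed & out$gene_rpkm > 0,
                         pmin(out$rpkm / out$gene_rpkm, cap), NA_real_)
  structure(list(
    sample_id = sample_id, total_reads = total_reads, cutoff = cutoff,
    genes = genes,
    exons = out[, c("exon_id", "gene_id", "class", "length", "count",
                    "rpkm", "rescaled")]
  ), class = "sample_expression")
}

#' Quantify one sample from a SAM file
#'
#' Reads the alignments, removes non-primary and repetitive-hit records,
#' counts reads per exon and runs [quantify_sample()]; the RPKM denominator
#' is the number of retained (filtered) alignment records.
#'
#' @param path SAM file
#' @inheritParams quantify_sample
#' @param ... passed to [quantify_sample()]
#' @return a `sample_expression` object
#' @export
quantify_sam <- function(path, annotation, sample_id = "sample", ...) {
  aln <- filter_alignments(read_sam(path))
  counts <- count_reads_per_exon(aln, annotation$exons)
  quantify_sample(counts, annotation, total_reads = nrow(aln$records),
                  sample_id = sample_id, ...)
}

#' @export
print.sample_expression <- function(x, ...) {
  cat("<sample_expression> ", x$sample_id, ": ",
      format(x$total_reads, big.mark = ","), " filtered reads, cutoff ",
      signif(x$cutoff, 4), " RPKM, ",
      sum(x$genes$expressed & !x$genes$fictional), "/",
      sum(!x$genes$fictional), " real genes expressed\n", sep = "")
  invisible(x)
}

#' Write per-sample exon and gene quantification tables
#'
#' Exports two TSVs: `<prefix>_exons.tsv` (`exon_id`, `gene_id`, `class`,
#' `count`, `rpkm`, `rescaled`) and `<prefix>_genes.tsv` (`gene_id`,
#' `fictional`, `gene_rpkm`, `expressed`, `cutoff`).
#'
#' @param sample a `sample_expression` object
#' @param prefix output path prefix
#' @return the two paths, invisibly
#' @export
write_sample_expression <- function(sample, prefix) {
  p1 <- paste0(prefix, "_exons.tsv")
  p2 <- paste0(prefix, "_genes.tsv")
  readr::write_tsv(sample$exons[, c("exon_id", "gene_id", "class", "count",
                                    "rpkm", "rescaled")], p1, progress = FALSE)
  g <- sample$genes
  g$cutoff <- sample$cutoff
  readr::write_tsv(g, p2, progress = FALSE)
  invisible(c(p1, p2))
}
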