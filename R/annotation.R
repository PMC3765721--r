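# Annotation: gene models, TE-exon features, exon classification (C1-C5),
# simulated decoy exons and fictional genes.
#
# All internal coordinates are 0-based half-open (BED convention), matching
# UCSC exonStarts/exonEnds. Parsers accept 1-based fully-closed dialects via
# `one_based = TRUE` and convert on ingestion.

#' Canonical exon identifier from coordinates
#'
#' Exons are identified by their genomic interval, so an exon shared by
#' several genes maps to a single record.
#'
#' @param chrom,start,end coordinate vectors (0-based half-open)
#' @return character vector of identifiers of the form `chrom:start-end`
#' @export
exon_id <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

check_intervals <- function(start, end, strand = NULL, where = "interval") {
  if (any(start < 0)) abort(sprintf("%s: start must be >= 0", where))
  if (any(end <= start)) abort(sprintf("%s: end must be > start", where))
  if (!is.null(strand) && !all(strand %in% c("+", "-")))
    abort(sprintf("%s: strand must be '+' or '-'", where))
  invisible(TRUE)
}

#' Parse a refGene-like gene model table
#'
#' Reads a TSV with columns `gene_id`, `chrom`, `strand`, `txStart`, `txEnd`,
#' `exonStarts`, `exonEnds`; the last two are comma-separated coordinate
#' lists as in the UCSC refGene dump. Gzip input is handled transparently.
#'
#' @param path path to the TSV (optionally gzipped)
#' @param one_based set `TRUE` if coordinates are 1-based fully-closed;
#'   they are converted to the internal 0-based half-open convention
#' @return an object of class `gene_models`: a list with tibbles `genes`
#'   (`gene_id`, `chrom`, `strand`, `start`, `end`, `fictional`) and `exons`
#'   (`gene_id`, `exon_id`, `chrom`, `start`, `end`, `strand`)
#' @export
parse_gene_table <- function(path, one_based = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), chrom = readr::col_character(),
    strand = readr::col_character(), txStart = readr::col_double(),
    txEnd = readr::col_double(), exonStarts = readr::col_character(),
    exonEnds = readr::col_character()
  ), progress = FALSE)
  if (anyDuplicated(raw$gene_id))
    abort(paste0("duplicate gene_id in gene table: ",
                 paste(unique(raw$gene_id[duplicated(raw$gene_id)]), collapse = ", ")))
  split_coords <- function(x) lapply(strsplit(x, ",", fixed = TRUE),
                                     function(v) as.numeric(v[nzchar(v)]))
  starts <- split_coords(raw$exonStarts)
  ends <- split_coords(raw$exonEnds)
  if (one_based) {
    raw$txStart <- raw$txStart - 1
    starts <- lapply(starts, function(v) v - 1)
  }
  n_s <- lengths(starts); n_e <- lengths(ends)
  bad <- which(n_s != n_e | n_s == 0)
  if (length(bad))
    abort(sprintf("gene table line %d (gene %s): exonStarts/exonEnds count mismatch",
                  bad[1] + 1L, raw$gene_id[bad[1]]))
  bad_tx <- which(raw$txStart >= raw$txEnd)
  if (length(bad_tx))
    abort(sprintf("gene table line %d (gene %s): txStart >= txEnd",
                  bad_tx[1] + 1L, raw$gene_id[bad_tx[1]]))
  genes <- tibble(
    gene_id = raw$gene_id, chrom = raw$chrom, strand = raw$strand,
    start = raw$txStart, end = raw$txEnd, fictional = FALSE
  )
  check_intervals(genes$start, genes$end, genes$strand, "gene table")
  exons <- tibble(
    gene_id = rep(raw$gene_id, n_s),
    chrom = rep(raw$chrom, n_s),
    start = as.numeric(unlist(starts)),
    end = as.numeric(unlist(ends)),
    strand = rep(raw$strand, n_s)
  )
  check_intervals(exons$start, exons$end, where = "gene table exons")
  exons <- dplyr::arrange(exons, .data$gene_id, .data$start)
  # exons must be non-overlapping within a gene
  ov <- exons |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::filter(dplyr::row_number() > 1 &
                    .data$start < dplyr::lag(.data$end)) |>
    dplyr::ungroup()
  if (nrow(ov))
    abort(sprintf("gene %s has overlapping exons", ov$gene_id[1]))
  exons$exon_id <- exon_id(exons$chrom, exons$start, exons$end)
  structure(list(genes = genes,
                 exons = exons[, c("gene_id", "exon_id", "chrom",
                                   "start", "end", "strand")]),
            class = "gene_models")
}

#' Write gene models back to the refGene-like TSV dialect
#' @param models a `gene_models` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gene_table <- function(models, path) {
  ex <- dplyr::arrange(models$exons, .data$gene_id, .data$start)
  per_gene <- ex |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      exonStarts = paste0(paste(.data$start, collapse = ","), ","),
      exonEnds = paste0(paste(.data$end, collapse = ","), ","),
      .groups = "drop")
  out <- models$genes |>
    dplyr::transmute(.data$gene_id, .data$chrom, .data$strand,
                     txStart = .data$start, txEnd = .data$end) |>
    dplyr::inner_join(per_gene, by = "gene_id")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' TE nucleotide proportion (RTE) of an exon
#'
#' Proportion of an exon's nucleotides that originate from its cognate
#' transposable element.
#'
#' @param te_nucleotides number of TE-derived bases in the exon
#' @param exon_length exon length in bp (>= 1)
#' @return `te_nucleotides / exon_length`, a proportion in \[0, 1\]
#' @export
compute_rte <- function(te_nucleotides, exon_length) {
  if (any(exon_length < 1)) abort("exon_length must be >= 1")
  if (any(te_nucleotides < 0) || any(te_nucleotides > exon_length))
    abort("te_nucleotides must lie in [0, exon_length]")
  te_nucleotides / exon_length
}

# Location synonyms accepted on input
normalize_location <- function(x) {
  map <- c(CDS = "CDS", UTR3 = "UTR3", UTR5 = "UTR5",
           "3UTR" = "UTR3", "5UTR" = "UTR5",
           "3'UTR" = "UTR3", "5'UTR" = "UTR5")
  out <- unname(map[x])
  if (anyNA(out))
    abort(paste0("unknown location token(s): ",
                 paste(unique(x[is.na(out)]), collapse = ", "),
                 "; allowed: CDS, UTR3/3UTR, UTR5/5UTR"))
  out
}

#' Parse an exonized-TE table
#'
#' Reads a TSV modelled on the TranspoGene "Human Exonized TEs" table:
#' columns `chrom`, `start`, `end`, `gene_id` (host gene), `location`
#' (CDS / 3UTR / 5UTR), `family` (TE family), and either `te_nucleotides`
#' (TE-derived base count, from which RTE is computed) or a precomputed
#' `rte`; an optional `est_inclusion` column carries the EST-based
#' inclusion level.
#'
#' @inheritParams parse_gene_table
#' @return a tibble of TE-exon features: `exon_id`, `chrom`, `start`, `end`,
#'   `gene_id`, `location`, `family`, `eln` (exon length, bp), `rte`,
#'   `est_inclusion`
#' @export
parse_te_exon_table <- function(path, one_based = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("chrom", "start", "end", "gene_id", "location", "family")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    abort(paste0("TE exon table is missing column(s): ", paste(miss, collapse = ", ")))
  if (one_based) raw$start <- raw$start - 1
  check_intervals(raw$start, raw$end, where = "TE exon table")
  bad_fam <- setdiff(unique(raw$family), TE_FAMILIES_ALL)
  if (length(bad_fam))
    abort(paste0("unknown TE family token(s): ", paste(bad_fam, collapse = ", "),
                 "; allowed: ", paste(TE_FAMILIES_ALL, collapse = ", ")))
  eln <- as.integer(raw$end - raw$start)
  if ("rte" %in% names(raw)) {
    rte <- raw$rte
    if (any(rte < 0 | rte > 1)) abort("rte outside [0, 1] in TE exon table")
  } else if ("te_nucleotides" %in% names(raw)) {
    rte <- compute_rte(raw$te_nucleotides, eln)
  } else {
    abort("TE exon table needs a 'te_nucleotides' or 'rte' column")
  }
  tibble(
    exon_id = exon_id(raw$chrom, raw$start, raw$end),
    chrom = raw$chrom, start = raw$start, end = raw$end,
    gene_id = raw$gene_id,
    location = normalize_location(raw$location),
    family = raw$family, eln = eln, rte = rte,
    est_inclusion = if ("est_inclusion" %in% names(raw))
      as.numeric(raw$est_inclusion) else NA_real_
  )
}

#' Write a TE-exon feature table
#'
#' The TE-derived base count is written as an integer (`te_nucleotides`)
#' rather than the derived `rte` ratio, so a parse/write/parse round trip
#' reproduces the features exactly.
#'
#' @param te_features tibble as returned by [parse_te_exon_table()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_te_exon_table <- function(te_features, path) {
  out <- te_features[, c("chrom", "start", "end", "gene_id", "location",
                         "family", "est_inclusion")]
  out$te_nucleotides <- as.integer(round(te_features$rte * te_features$eln))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Parse an alternative-exon table (BED3)
#' @param path BED3 file: `chrom`, `start`, `end` (0-based half-open)
#' @return tibble with columns `chrom`, `start`, `end`
#' @export
parse_alt_table <- function(path) {
  raw <- readr::read_tsv(path,
                         col_names = c("chrom", "start", "end"),
                         col_types = "cdd", comment = "#", progress = FALSE)
  check_intervals(raw$start, raw$end, where = "alt exon table")
  raw
}

#' Write an alternative-exon table as BED3
#' @param alt tibble with `chrom`, `start`, `end`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_alt_table <- function(alt, path) {
  readr::write_tsv(alt[, c("chrom", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Classify exons into classes C1-C4
#'
#' Builds the integrated exon annotation. An exon present in the TE table
#' with an exact-coordinate counterpart among the gene-model exons is an
#' annotated TE exon (C3); a TE-table exon without such a counterpart is an
#' un-annotated TE exon (C4). Non-TE gene-model exons are cassette exons
#' (C2) when they match an alternative-exon interval exactly, otherwise
#' constitutive exons (C1). Exact matching compares chromosome, start and
#' end; strand is not compared.
#'
#' @param models a `gene_models` object
#' @param te_features TE-exon feature tibble ([parse_te_exon_table()])
#' @param alt alternative-exon tibble ([parse_alt_table()]); may be empty
#' @return an object of class `te_annotation`: a list with tibbles
#'   * `genes` — as in `gene_models`
#'   * `exons` — `exon_id`, `chrom`, `start`, `end`, `strand`, `length`, `class`
#'   * `exon_genes` — `exon_id`, `gene_id`, `role`; role `"annotated"` marks
#'     membership in the host gene's annotated exon set (contributes to the
#'     gene-level expression mean), `"hosted"` marks C4/C5 exons rescaled by
#'     a gene whose expression they never contribute to, `"member"` marks C5
#'     exons inside fictional genes
#'   * `te_features` — with `annotated` flag added
#'   * `c5_pairs` — empty until [build_simulated_exons()] is run
#' @export
classify_exons <- function(models, te_features, alt = NULL) {
  gex <- models$exons
  te_ids <- unique(te_features$exon_id)
  alt_ids <- if (is.null(alt) || nrow(alt) == 0) character(0) else
    exon_id(alt$chrom, alt$start, alt$end)

  uex <- dplyr::distinct(gex, .data$exon_id, .data$chrom, .data$start,
                         .data$end, .data$strand)
  uex$class <- ifelse(uex$exon_id %in% te_ids, "C3",
                      ifelse(uex$exon_id %in% alt_ids, "C2", "C1"))

  # C4: TE exons with no exact counterpart among gene-model exons
  te_u <- dplyr::distinct(te_features, .data$exon_id, .keep_all = TRUE)
  c4 <- te_u[!(te_u$exon_id %in% uex$exon_id), ]
  if (nrow(c4)) {
    host_strand <- setNames(models$genes$strand, models$genes$gene_id)
    c4_strand <- unname(host_strand[c4$gene_id])
    if (anyNA(c4_strand))
      abort("TE exon table refers to host gene(s) absent from the gene table")
    uex <- dplyr::bind_rows(uex, tibble(
      exon_id = c4$exon_id, chrom = c4$chrom, start = c4$start,
      end = c4$end, strand = c4_strand, class = "C4"))
  }
  uex$length <- as.integer(uex$end - uex$start)

  # validate ELN against exon intervals
  eln_chk <- dplyr::inner_join(te_u[, c("exon_id", "eln")],
                               uex[, c("exon_id", "length")], by = "exon_id")
  if (any(eln_chk$eln != eln_chk$length))
    abort("TE exon table: eln does not equal the exon interval length")

  exon_genes <- dplyr::bind_rows(
    tibble(exon_id = gex$exon_id, gene_id = gex$gene_id, role = "annotated"),
    if (nrow(c4)) tibble(exon_id = c4$exon_id, gene_id = c4$gene_id,
                         role = "hosted")
  )
  te_out <- te_features
  te_out$annotated <- te_out$exon_id %in% gex$exon_id
  structure(list(
    genes = models$genes,
    exons = uex[, c("exon_id", "chrom", "start", "end", "strand",
                    "length", "class")],
    exon_genes = dplyr::distinct(exon_genes),
    te_features = te_out,
    c5_pairs = tibble(c5_exon_id = character(0), c4_exon_id = character(0))
  ), class = "te_annotation")
}

#' Construct simulated decoy exons (class C5)
#'
#' For every un-annotated TE exon (C4) a decoy exon of equal length is
#' placed on the intronic sequence immediately downstream, where
#' "downstream" is taken in the transcriptional (3') direction of the host
#' gene: a C4 exon `[s, e)` on the + strand yields `[e, e + (e - s))`, on
#' the - strand `[s - (e - s), s)`. Setting `strand_aware = FALSE` applies
#' the + strand rule everywhere. C5 exons are index-paired with their C4
#' exons (required by the paired signed-rank comparison); decoys that would
#' extend below position 0 are clipped with a warning, and decoys that
#' happen to overlap an annotated exon are kept but flagged.
#'
#' @param annotation a `te_annotation` from [classify_exons()]
#' @param strand_aware take "downstream" in the host gene's 3' direction
#' @return the annotation with C5 exons appended to `exons`, `"hosted"`
#'   rows linking each C5 exon to its paired C4 exon's host gene, and
#'   `c5_pairs` (`c5_exon_id`, `c4_exon_id`, `clipped`, `overlaps_exon`)
#' @export
build_simulated_exons <- function(annotation, strand_aware = TRUE) {
  c4 <- annotation$exons[annotation$exons$class == "C4", ]
  if (nrow(c4) == 0) {
    warn("no C4 exons; no simulated exons built")
    return(annotation)
  }
  len <- c4$end - c4$start
  plus <- if (strand_aware) c4$strand == "+" else rep(TRUE, nrow(c4))
  s5 <- ifelse(plus, c4$end, c4$start - len)
  e5 <- ifelse(plus, c4$end + len, c4$start)
  clipped <- s5 < 0
  if (any(clipped)) {
    warn(sprintf("%d simulated exon(s) clipped at position 0; lengths reduced",
                 sum(clipped)))
    s5[clipped] <- 0
  }
  empty <- e5 <= s5
  if (any(empty))
    abort("simulated exon(s) clipped to empty intervals; annotation invalid")
  c5 <- tibble(
    exon_id = exon_id(c4$chrom, s5, e5),
    chrom = c4$chrom, start = s5, end = e5, strand = c4$strand,
    length = as.integer(e5 - s5), class = "C5"
  )
  # flag collisions with any real exon
  real <- annotation$exons
  gr_real <- GenomicRanges::GRanges(real$chrom,
                                    IRanges::IRanges(real$start + 1, real$end))
  gr_c5 <- GenomicRanges::GRanges(c5$chrom, IRanges::IRanges(s5 + 1, e5))
  overlaps <- GenomicRanges::countOverlaps(gr_c5, gr_real) > 0

  hosts <- annotation$exon_genes[annotation$exon_genes$role == "hosted", ]
  c4_host <- hosts$gene_id[match(c4$exon_id, hosts$exon_id)]
  annotation$exons <- dplyr::bind_rows(annotation$exons, c5)
  annotation$exon_genes <- dplyr::bind_rows(
    annotation$exon_genes,
    tibble(exon_id = c5$exon_id, gene_id = c4_host, role = "hosted"))
  annotation$c5_pairs <- tibble(c5_exon_id = c5$exon_id,
                                c4_exon_id = c4$exon_id,
                                clipped = clipped,
                                overlaps_exon = overlaps)
  annotation
}

#' Assemble fictional genes from simulated exons
#'
#' Fictional (decoy) genes are bags of C5 exons; the distribution of their
#' gene-level RPKMs across a sample sets that sample's expressed-gene
#' cutoff. Each fictional gene draws its exon count uniformly from
#' `[min_exons, max_exons]` and samples C5 exons without replacement within
#' the gene (exons may recur across genes).
#'
#' @param annotation a `te_annotation` containing C5 exons
#' @param n_genes number of fictional genes (default 500)
#' @param min_exons,max_exons exon-count range per fictional gene (4-40)
#' @param seed integer seed making the assembly reproducible
#' @return the annotation with fictional genes appended to `genes` and
#'   `"member"` rows added to `exon_genes`
#' @export
build_fictional_genes <- function(annotation, n_genes = 500,
                                  min_exons = 4, max_exons = 40,
                                  seed = NULL) {
  c5_ids <- annotation$exons$exon_id[annotation$exons$class == "C5"]
  if (length(c5_ids) < min_exons)
    abort(sprintf("only %d C5 exons available but min_exons = %d",
                  length(c5_ids), min_exons))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  max_exons <- min(max_exons, length(c5_ids))
  k_range <- seq(min_exons, max_exons)
  k <- if (length(k_range) == 1) rep(k_range, n_genes) else
    sample(k_range, n_genes, replace = TRUE)
  fg_id <- sprintf("FG%04d", seq_len(n_genes))
  members <- tibble(
    gene_id = rep(fg_id, k),
    exon_id = unlist(lapply(k, function(ki) sample(c5_ids, ki))),
    role = "member"
  )
  annotation$genes <- dplyr::bind_rows(
    annotation$genes,
    tibble(gene_id = fg_id, chrom = NA_character_, strand = NA_character_,
           start = NA_real_, end = NA_real_, fictional = TRUE))
  annotation$exon_genes <- dplyr::bind_rows(annotation$exon_genes,
                                            members[, c("exon_id", "gene_id", "role")])
  annotation
}

#' Export C5 exons as BED6 with the paired C4 exon in the name field
#' @param annotation a `te_annotation` with C5 exons
#' @param path output path
#' @return `path`, invisibly
#' @export
write_c5_bed <- function(annotation, path) {
  c5 <- dplyr::inner_join(annotation$exons, annotation$c5_pairs,
                          by = c(exon_id = "c5_exon_id"))
  out <- tibble(chrom = c5$chrom, start = c5$start, end = c5$end,
                name = c5$c4_exon_id, score = 0L, strand = c5$strand)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @export
print.te_annotation <- function(x, ...) {
  cls <- table(factor(x$exons$class, levels = EXON_CLASSES))
  cat("<te_annotation> ", sum(!x$genes$fictional), " genes (",
      sum(x$genes$fictional), " fictional), ", nrow(x$exons), " exons: ",
      paste(sprintf("%s=%d", names(cls), cls), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", nrow(x$genes), " genes, ", nrow(x$exons),
      " exon records\n", sep = "")
  invisible(x)
}
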