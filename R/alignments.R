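# Read alignments: SAM ingestion, ambiguity filtering, per-exon counting.
#
# An alignment set is a list of two tibbles: `records` (one row per
# alignment record: aln_id, read_id, is_primary, hit_count) and `blocks`
# (aligned reference segments of each record, 0-based half-open). A spliced
# read contributes one record with several blocks.

new_alignments <- function(records, blocks) {
  structure(list(records = records, blocks = blocks), class = "alignments")
}

#' @export
print.alignments <- function(x, ...) {
  cat("<alignments> ", nrow(x$records), " records, ",
      nrow(x$blocks), " aligned blocks\n", sep = "")
  invisible(x)
}

#' Read alignments from a SAM file
#'
#' Converts the SAM to BAM internally (Rsamtools) and loads the alignments
#' with GenomicAlignments. Secondary alignments are identified via the 0x100
#' flag and the reported hit count via the `NH` tag.
#'
#' @param path path to a SAM file with a valid header
#' @return an `alignments` object
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag"), tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  meta <- S4Vectors::mcols(gal)
  records <- tibble(
    aln_id = seq_along(gal),
    read_id = as.character(meta$qname),
    is_primary = bitwAnd(meta$flag, 0x100L) == 0L,
    hit_count = as.integer(meta$NH)
  )
  grl <- GenomicAlignments::grglist(gal)
  flat <- unlist(grl, use.names = FALSE)
  blocks <- tibble(
    aln_id = rep(records$aln_id, S4Vectors::elementNROWS(grl)),
    chrom = as.character(GenomicRanges::seqnames(flat)),
    start = GenomicRanges::start(flat) - 1,  # to 0-based half-open
    end = GenomicRanges::end(flat)
  )
  new_alignments(records, blocks)
}

#' Filter ambiguously mapped reads
#'
#' Drops non-primary alignment records and reads with repetitive hits
#' (reported hit count > 1), keeping only primary, uniquely mapped records.
#'
#' @param alignments an `alignments` object
#' @param missing_hit_count what to do when the hit count (`NH` tag) is
#'   absent: `"unique"` treats the read as uniquely mapped (with a warning),
#'   `"fail"` raises an error
#' @return the filtered `alignments` object; a message reports how many
#'   records were dropped per reason
#' @export
filter_alignments <- function(alignments,
                              missing_hit_count = c("unique", "fail")) {
  missing_hit_count <- match.arg(missing_hit_count)
  rec <- alignments$records
  if (anyNA(rec$hit_count)) {
    if (missing_hit_count == "fail")
      abort("alignment records without a hit count (NH tag)")
    warn(sprintf("%d record(s) lack a hit count; treated as uniquely mapped",
                 sum(is.na(rec$hit_count))))
    rec$hit_count[is.na(rec$hit_count)] <- 1L
  }
  drop_secondary <- !rec$is_primary
  drop_repetitive <- rec$is_primary & rec$hit_count > 1L
  inform(sprintf(
    "filtered alignments: %d kept, %d non-primary dropped, %d repetitive-hit dropped",
    sum(!drop_secondary & !drop_repetitive),
    sum(drop_secondary), sum(drop_repetitive)))
  keep <- rec$aln_id[!drop_secondary & !drop_repetitive]
  new_alignments(
    rec[rec$aln_id %in% keep, ],
    alignments$blocks[alignments$blocks$aln_id %in% keep, ]
  )
}

#' Count reads overlapping each exon
#'
#' A read increments an exon's count when any of its aligned blocks
#' overlaps the exon interval by at least one base. A read may increment
#' several exons (e.g. a junction-spanning read), but increments any given
#' exon at most once.
#'
#' @param alignments a filtered `alignments` object
#' @param exons tibble with `exon_id`, `chrom`, `start`, `end`
#'   (0-based half-open); typically `annotation$exons`
#' @return named integer vector of counts, one entry per row of `exons`
#' @export
count_reads_per_exon <- function(alignments, exons) {
  counts <- setNames(integer(nrow(exons)), exons$exon_id)
  if (nrow(alignments$blocks) == 0) return(counts)
  gr_ex <- GenomicRanges::GRanges(
    exons$chrom, IRanges::IRanges(exons$start + 1, exons$end))
  bl <- alignments$blocks
  gr_bl <- GenomicRanges::GRanges(bl$chrom, IRanges::IRanges(bl$start + 1, bl$end))
  hits <- GenomicRanges::findOverlaps(gr_bl, gr_ex, minoverlap = 1L)
  if (length(hits) == 0) return(counts)
  read_of <- alignments$records$read_id[
    match(bl$aln_id[S4Vectors::queryHits(hits)], alignments$records$aln_id)]
  pairs <- unique(data.frame(read = read_of, exon = S4Vectors::subjectHits(hits)))
  tab <- table(pairs$exon)
  counts[as.integer(names(tab))] <- as.integer(tab)
  counts
}

#' Write alignments as SAM text
#'
#' Serialises an `alignments` object to SAM. Multi-block records are
#' emitted with `M`/`N` CIGAR runs; the hit count goes to the `NH` tag and
#' non-primary records get the 0x100 flag.
#'
#' @param alignments an `alignments` object
#' @param chrom_lengths named integer vector of reference lengths
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sam <- function(alignments, chrom_lengths, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  rec <- alignments$records
  if (nrow(rec) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  bl <- alignments$blocks[order(alignments$blocks$aln_id,
                                alignments$blocks$start), ]
  spl <- split(bl, bl$aln_id)
  body <- vapply(seq_len(nrow(rec)), function(i) {
    b <- spl[[as.character(rec$aln_id[i])]]
    widths <- b$end - b$start
    cig <- paste0(widths[1], "M")
    if (nrow(b) > 1) {
      gaps <- b$start[-1] - b$end[-nrow(b)]
      cig <- paste0(cig, paste0(gaps, "N", widths[-1], "M", collapse = ""))
    }
    flag <- if (rec$is_primary[i]) 0L else 256L
    seq <- strrep("A", sum(widths))
    paste(rec$read_id[i], flag, b$chrom[1], b$start[1] + 1, 60L, cig,
          "*", 0L, 0L, seq, "*",
          sprintf("NH:i:%d", rec$hit_count[i]), sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
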