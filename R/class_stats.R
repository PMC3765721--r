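# Per-sample class summaries, the stepwise nonparametric test ladder, and
# histogram summaries of the expression distributions.

#' Summary statistics for one exon class in one sample
#'
#' Computes the un-expressed ratio `r` (fraction of exons with zero count),
#' and the mean `m` and sample standard deviation `sd` of the rescaled
#' RPKMs over the exons with at least one read. Statistics that are
#' undefined (no expressed exon) are reported as `NA`, never as 0.
#'
#' @param rescaled rescaled RPKM values of the class's exons (within
#'   expressed genes)
#' @param count read counts of the same exons
#' @param sample_id,exon_class labels carried into the output
#' @return a one-row tibble: `sample_id`, `exon_class`, `n_total`,
#'   `n_expressed`, `r_unexpressed`, `m_mean`, `sd`
#' @export
class_summary <- function(rescaled, count, sample_id = NA_character_,
                          exon_class = NA_character_) {
  if (length(rescaled) == 0) abort("class_summary: no exons supplied")
  if (length(count) != length(rescaled))
    abort("class_summary: rescaled and count lengths differ")
  expressed <- count >= 1
  vals <- rescaled[expressed]
  tibble(
    sample_id = sample_id, exon_class = exon_class,
    n_total = length(rescaled), n_expressed = sum(expressed),
    r_unexpressed = mean(!expressed),
    m_mean = if (length(vals)) mean(vals) else NA_real_,
    sd = if (length(vals) >= 2) sd(vals) else
      if (length(vals) == 1) 0 else NA_real_
  )
}

#' Extract per-class rescaled RPKM vectors from a quantified sample
#'
#' Restricts to (exon, host) pairs whose host gene is expressed in the
#' sample. The C4 and C5 vectors are index-paired via the decoy pairing so
#' that the paired signed-rank comparison is well defined.
#'
#' @param sample a `sample_expression`
#' @param annotation the `te_annotation` the sample was quantified against
#' @return a list with one element per class (`C1`..`C5`), each a tibble
#'   (`exon_id`, `rescaled`, `count`); `C4` and `C5` are row-aligned
#' @export
class_values <- function(sample, annotation) {
  ex <- sample$exons[!is.na(sample$exons$rescaled), ]
  out <- lapply(setNames(EXON_CLASSES, EXON_CLASSES), function(cl) {
    sub <- ex[ex$class == cl, c("exon_id", "rescaled", "count")]
    dplyr::distinct(sub, .data$exon_id, .keep_all = TRUE)
  })
  # align C4 and C5 on the decoy pairing, keeping pairs where both usable
  pairs <- annotation$c5_pairs
  if (nrow(pairs)) {
    i4 <- match(pairs$c4_exon_id, out$C4$exon_id)
    i5 <- match(pairs$c5_exon_id, out$C5$exon_id)
    keep <- !is.na(i4) & !is.na(i5)
    out$C4 <- out$C4[i4[keep], ]
    out$C5 <- out$C5[i5[keep], ]
  }
  out
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact null distribution when the pooled sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y value vectors of the two independent groups
#' @return list with `statistic` (U, computed for `x`) and `p_value`
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    abort("mann_whitney: both groups must be non-empty")
  exact <- (length(x) + length(y) <= 20) && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Wilcoxon signed-rank test for paired values (two-sided)
#'
#' Zero differences are dropped before ranking (`zero_method = "wilcox"`,
#' the default) or retained in the ranking and dropped from the statistic
#' (`"pratt"`, normal approximation). The exact sign-flip distribution is
#' used when at most 15 informative pairs remain and the absolute
#' differences are untied; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param a,b paired value vectors
#' @param zero_method `"wilcox"` or `"pratt"`
#' @return list with `statistic` (V, sum of positive ranks) and `p_value`
#' @export
wilcoxon_signed_rank <- function(a, b, zero_method = c("wilcox", "pratt")) {
  zero_method <- match.arg(zero_method)
  if (length(a) != length(b)) abort("wilcoxon_signed_rank: unpaired input")
  d <- a - b
  if (all(d == 0)) abort("wilcoxon_signed_rank: all differences are zero")
  if (zero_method == "pratt") {
    r <- rank(abs(d))
    nz <- d != 0
    v <- sum(r[nz & d > 0])
    n <- length(d); z <- sum(!nz)
    mu <- (n * (n + 1) / 2 - z * (z + 1) / 2) / 2
    sigma2 <- (n * (n + 1) * (2 * n + 1) - z * (z + 1) * (2 * z + 1)) / 24
    ties <- table(r[nz])
    sigma2 <- sigma2 - sum(ties^3 - ties) / 48
    zstat <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    return(list(statistic = v, p_value = min(1, 2 * pnorm(-abs(zstat)))))
  }
  d <- d[d != 0]
  exact <- length(d) <= 15 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(wilcox.test(d, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' The stepwise class-comparison ladder
#'
#' Four comparisons along the class order: C1 vs C2, C2 vs C3 and C3 vs C4
#' by the Mann-Whitney test (independent groups); C4 vs C5 by the Wilcoxon
#' signed-rank test (decoy-paired groups). Values compared are rescaled
#' RPKMs with zeros included, the full digital-expression distributions.
#'
#' @param values named list of per-class value vectors (`C1`..`C5`), e.g.
#'   from [class_values()] (pass `rescaled` columns); `C4` and `C5` must be
#'   index-paired
#' @param expressed_only drop zero values before testing (alternative mode)
#' @return tibble with `comparison`, `statistic`, `p_value`; a comparison
#'   involving an empty class is reported as `NA`
#' @export
stepwise_class_tests <- function(values, expressed_only = FALSE) {
  get <- function(cl) {
    v <- values[[cl]]
    if (is.data.frame(v)) v <- v$rescaled
    v
  }
  v <- lapply(setNames(EXON_CLASSES, EXON_CLASSES), get)
  if (expressed_only) {
    keep45 <- v$C4 > 0 | v$C5 > 0  # keep pairing intact
    v$C4 <- v$C4[keep45]; v$C5 <- v$C5[keep45]
    v$C1 <- v$C1[v$C1 > 0]; v$C2 <- v$C2[v$C2 > 0]; v$C3 <- v$C3[v$C3 > 0]
  }
  run_mw <- function(x, y) {
    if (length(x) == 0 || length(y) == 0) return(c(NA_real_, NA_real_))
    r <- mann_whitney(x, y); c(r$statistic, r$p_value)
  }
  run_wsr <- function(x, y) {
    if (length(x) == 0 || all(x == y)) return(c(NA_real_, NA_real_))
    r <- wilcoxon_signed_rank(x, y); c(r$statistic, r$p_value)
  }
  res <- rbind(run_mw(v$C1, v$C2), run_mw(v$C2, v$C3),
               run_mw(v$C3, v$C4), run_wsr(v$C4, v$C5))
  tibble(comparison = c("C1_vs_C2", "C2_vs_C3", "C3_vs_C4", "C4_vs_C5"),
         statistic = res[, 1], p_value = res[, 2])
}

#' Class summary table for a set of quantified samples
#'
#' The per-sample, per-class summary with the stepwise test p-values
#' attached to the higher class of each comparison (C2 carries the C1-C2
#' p-value, and so on).
#'
#' @param samples list of `sample_expression` objects
#' @param annotation the shared `te_annotation`
#' @return tibble: `sample_id`, `exon_class`, `n_total`, `n_expressed`,
#'   `r_unexpressed`, `m_mean`, `sd`, `p_value`
#' @export
class_summary_table <- function(samples, annotation) {
  purrr::map_dfr(samples, function(s) {
    cv <- class_values(s, annotation)
    sums <- purrr::map_dfr(EXON_CLASSES, function(cl) {
      if (nrow(cv[[cl]]) == 0)
        return(tibble(sample_id = s$sample_id, exon_class = cl,
                      n_total = 0L, n_expressed = 0L,
                      r_unexpressed = NA_real_, m_mean = NA_real_,
                      sd = NA_real_))
      class_summary(cv[[cl]]$rescaled, cv[[cl]]$count, s$sample_id, cl)
    })
    tests <- stepwise_class_tests(cv)
    sums$p_value <- c(NA, tests$p_value)
    sums
  })
}

#' Histogram summary of log10 expression values
#'
#' Zeros are split off as a separate proportion (the black bar of the
#' distribution plots); positive values are binned on the log10 scale
#' between the smallest positive value and `cap`, the last bin closed on
#' the right so values at the cap are included.
#'
#' @param values non-negative expression values
#' @param n_bins number of bins for the positive part
#' @param cap upper limit of the value range (default 10)
#' @return list with `zero_proportion`, `breaks` (log10 scale) and `counts`
#' @export
histogram_log10 <- function(values, n_bins = 30, cap = 10) {
  if (any(values < 0)) abort("histogram_log10: negative values")
  pos <- values[values > 0]
  zp <- if (length(values)) mean(values == 0) else NA_real_
  if (length(pos) == 0)
    return(list(zero_proportion = zp, breaks = numeric(0),
                counts = integer(0)))
  lo <- min(log10(pos)); hi <- log10(cap)
  if (lo >= hi) lo <- hi - 1  # degenerate: everything at the cap
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  counts <- tabulate(findInterval(log10(pos), breaks,
                                  rightmost.closed = TRUE, all.inside = TRUE),
                     nbins = n_bins)
  list(zero_proportion = zp, breaks = breaks, counts = counts)
}

#' Export per-class histogram summaries as JSON
#' @param samples list of `sample_expression` objects
#' @param annotation the shared `te_annotation`
#' @param path output JSON path
#' @param ... passed to [histogram_log10()]
#' @return `path`, invisibly
#' @export
write_histograms_json <- function(samples, annotation, path, ...) {
  out <- lapply(samples, function(s) {
    cv <- class_values(s, annotation)
    lapply(cv, function(tb) histogram_log10(tb$rescaled, ...))
  })
  names(out) <- vapply(samples, function(s) s$sample_id, character(1))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
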