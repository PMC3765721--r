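test_that("generation is a pure function of (config, seed)", {
  cfg <- small_config()
  a1 <- generate_annotation(cfg, seed = 5)
  a2 <- generate_annotation(cfg, seed = 5)
  expect_identical(a1$exons, a2$exons)
  expect_identical(a1$te_features, a2$te_features)
  expect_identical(a1$exon_genes, a2$exon_genes)
  a3 <- generate_annotation(cfg, seed = 6)
  expect_false(identical(a1$exons, a3$exons))

  tr <- default_truth()
  c1 <- generate_counts(a1, tr, cfg, seed = 9)$counts
  c2 <- generate_counts(a1, tr, cfg, seed = 9)$counts
  expect_identical(c1, c2)
})

test_that("generated class frequencies follow the configured proportions", {
  cfg <- small_config()
  ann <- generate_annotation(cfg, seed = 7)
  cls <- table(factor(ann$exons$class, levels = c("C1", "C2", "C3", "C4")))
  n <- sum(cls)
  p <- cfg$class_props[names(cls)]
  # within 3 sigma of the multinomial expectation (C4 slots can be
  # reassigned when a gene lacks introns, so allow the C4 deficit there)
  sig <- sqrt(n * p * (1 - p))
  expect_true(all(abs(cls - n * p) <= 3 * sig + 5))
  # decoys pair 1:1 with C4 exons
  expect_equal(sum(ann$exons$class == "C5"), sum(ann$exons$class == "C4"))
})

test_that("decoy intervals are intronic and disjoint from every exon", {
  ann <- generate_annotation(small_config(), seed = 8)
  ex <- ann$exons
  c5 <- ex[ex$class == "C5", ]
  real <- ex[ex$class != "C5", ]
  gr5 <- GenomicRanges::GRanges(c5$chrom,
                                IRanges::IRanges(c5$start + 1, c5$end))
  grr <- GenomicRanges::GRanges(real$chrom,
                                IRanges::IRanges(real$start + 1, real$end))
  expect_equal(sum(GenomicRanges::countOverlaps(gr5, grr)), 0)
  expect_false(any(ann$c5_pairs$overlaps_exon))
  expect_false(any(ann$c5_pairs$clipped))
  # decoys inherit their host gene for rescaling
  hosted <- ann$exon_genes[ann$exon_genes$role == "hosted", ]
  expect_true(all(c5$exon_id %in% hosted$exon_id))
})

test_that("fixed-length chromosomes reject infeasible packings", {
  expect_error(generate_annotation(small_config(chrom_length = 10000),
                                   seed = 1), "infeasible")
})

test_that("counts follow the planted hurdle structure", {
  cfg <- small_config()
  ann <- generate_annotation(cfg, seed = 10)
  # zero background -> decoy regions stay read-free
  cfg0 <- small_config(c5_background_rpkm = 0)
  sim0 <- generate_counts(ann, default_truth(), cfg0, seed = 11)
  c5_ids <- ann$exons$exon_id[ann$exons$class == "C5"]
  expect_equal(sum(sim0$counts[c5_ids, ]), 0)

  # a strongly negative planted RTE effect lowers presence monotonically
  # across RTE quartiles (Monte-Carlo trend at large n)
  m1 <- utils::modifyList(default_truth()$model1, list(phi = -4))
  sim <- generate_counts(ann, default_truth(model1 = m1), cfg, seed = 12)
  te <- ann$te_features[ann$exons$class[match(ann$te_features$exon_id,
                                              ann$exons$exon_id)] == "C4", ]
  pres <- rowMeans(sim$counts[te$exon_id, ] >= 1)
  q <- cut(te$rte, breaks = quantile(te$rte, 0:4 / 4),
           include.lowest = TRUE)
  rate <- tapply(pres, q, mean)
  expect_true(all(diff(rate) < 0))

  # library sizes and sample layout
  expect_equal(colnames(sim$counts), sim$sample_meta$sample_id)
  expect_equal(nrow(sim$sample_meta), 26)
  expect_setequal(sim$sample_meta$pr_group[19:24], c("tumor", "normal"))

  # overflow guard
  expect_error(generate_counts(ann, default_truth(),
                               small_config(library_size = 1e14),
                               seed = 1), "overflow")

  # negative-binomial option over-disperses relative to Poisson
  simnb <- generate_counts(ann, default_truth(),
                           small_config(dispersion = 0.5), seed = 12)
  c1 <- ann$exons$exon_id[ann$exons$class == "C1"]
  expect_gt(mean(apply(simnb$counts[c1, ], 1, var)),
            mean(apply(sim$counts[c1, ], 1, var)))
})

test_that("SAM fixtures reproduce target counts and decoys filter out", {
  ann <- tiny_annotation()
  dir <- withr::local_tempdir()
  counts <- c("chr1:100-200" = 5L, "chr1:500-700" = 3L,
              "chr1:750-850" = 2L)
  sam <- file.path(dir, "fix.sam")
  generate_alignments(ann, counts, read_length = 50, seed = 2,
                      decoy_frac = 0.4, path = sam)
  aln <- read_sam(sam)
  # decoys present before filtering, gone after
  expect_gt(nrow(aln$records), sum(counts))
  kept <- suppressMessages(filter_alignments(aln))
  expect_equal(nrow(kept$records), sum(counts))
  got <- count_reads_per_exon(kept, ann$exons)
  expect_equal(got[names(counts)], counts)
  # all other exons untouched (reads are placed strictly inside exons)
  expect_equal(sum(got), sum(counts))

  # empty counts give a header-only SAM
  sam0 <- file.path(dir, "empty.sam")
  generate_alignments(ann, integer(0), path = sam0)
  expect_true(all(startsWith(readLines(sam0), "@")))
  expect_error(generate_alignments(ann, c("chr1:100-200" = 20000L)),
               "10,000")
})

test_that("truth serialisation round-trips and rejects tampering", {
  tr <- default_truth()
  tr$seed <- 99L
  path <- withr::local_tempfile(fileext = ".json")
  save_truth(tr, path)
  back <- load_truth(path)
  expect_equal(back$model1, tr$model1)
  expect_equal(back$model2, tr$model2)
  expect_equal(back$noise_sd, tr$noise_sd)
  expect_equal(back$group_effects, tr$group_effects)
  expect_equal(back$seed, 99L)

  writeLines("{\"not\": \"a truth file\"}", path)
  expect_error(load_truth(path), "missing required fields")
  writeLines("garbage{", path)
  expect_error(load_truth(path), "valid JSON")
  bad <- tr; bad$version <- 99L
  save_truth(bad, path)
  expect_error(load_truth(path), "version")
})

test_that("dataset directories hold every artefact the parsers consume", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(small_config(), default_truth(), seed = 3,
                         dir = dir)
  expect_setequal(list.files(dir),
                  c("genes.tsv", "te_exons.tsv", "alt_exons.bed",
                    "counts.tsv", "samples.tsv", "lib_sizes.tsv",
                    "znf_genes.txt", "truth.json"))
  # the written tables re-parse into the same classification
  ann2 <- classify_exons(parse_gene_table(file.path(dir, "genes.tsv")),
                         parse_te_exon_table(file.path(dir, "te_exons.tsv")),
                         parse_alt_table(file.path(dir, "alt_exons.bed")))
  cls1 <- ds$annotation$exons[ds$annotation$exons$class != "C5", ]
  expect_equal(dplyr::arrange(ann2$exons, exon_id)$class,
               dplyr::arrange(cls1, exon_id)$class)
  expect_equal(load_truth(file.path(dir, "truth.json"))$seed, 3L)
  # count matrix round trip
  cnt <- readr::read_tsv(file.path(dir, "counts.tsv"),
                         show_col_types = FALSE)
  expect_equal(unname(as.matrix(cnt[, -1])) + 0,
               unname(ds$counts[cnt$exon_id, ]) + 0)
})
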