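test_that("gene table parsing maps refGene-like rows to gene models", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "g.tsv")
  writeLines(c("gene_id\tchrom\tstrand\ttxStart\ttxEnd\texonStarts\texonEnds",
               "g1\tchr1\t+\t100\t1000\t100,500,\t200,700,"), p)
  gm <- parse_gene_table(p)
  expect_equal(nrow(gm$genes), 1)
  expect_equal(gm$exons$start, c(100, 500))
  expect_equal(gm$exons$end, c(200, 700))
  expect_equal(gm$exons$exon_id, c("chr1:100-200", "chr1:500-700"))

  # header-only file -> empty models
  writeLines("gene_id\tchrom\tstrand\ttxStart\ttxEnd\texonStarts\texonEnds", p)
  expect_equal(nrow(parse_gene_table(p)$genes), 0)

  # exonStarts/exonEnds length mismatch names the offending line
  writeLines(c("gene_id\tchrom\tstrand\ttxStart\ttxEnd\texonStarts\texonEnds",
               "g1\tchr1\t+\t100\t1000\t100,\t200,300,"), p)
  expect_error(parse_gene_table(p), "line 2")

  # txStart >= txEnd and duplicated ids rejected
  writeLines(c("gene_id\tchrom\tstrand\ttxStart\ttxEnd\texonStarts\texonEnds",
               "g1\tchr1\t+\t1000\t100\t100,\t200,"), p)
  expect_error(parse_gene_table(p), "txStart")
  writeLines(c("gene_id\tchrom\tstrand\ttxStart\ttxEnd\texonStarts\texonEnds",
               "g1\tchr1\t+\t100\t1000\t100,\t200,",
               "g1\tchr1\t+\t2000\t3000\t2000,\t2100,"), p)
  expect_error(parse_gene_table(p), "duplicate")
})

test_that("RTE is the TE-derived fraction of the exon", {
  expect_equal(compute_rte(150, 300), 0.5)
  expect_equal(compute_rte(300, 300), 1.0)
  expect_equal(compute_rte(0, 300), 0.0)
  expect_error(compute_rte(10, 0), "exon_length")
  expect_error(compute_rte(400, 300), "te_nucleotides")
})

test_that("TE exon table parsing validates families, locations and RTE", {
  tabs <- tiny_tables()
  te <- parse_te_exon_table(tabs$te)
  expect_equal(nrow(te), 3)
  expect_equal(te$rte[1], 100 / 200)  # 200 bp exon, 100 TE bases
  expect_equal(te$location[2], "UTR5")  # "5UTR" token normalised
  expect_equal(te$eln, c(200L, 100L, 100L))

  dir <- withr::local_tempdir()
  p <- file.path(dir, "te.tsv")
  writeLines(c(paste("chrom", "start", "end", "gene_id", "location",
                     "family", "te_nucleotides", sep = "\t"),
               "chr1\t0\t300\tg1\tCDS\tNotAFamily\t10"), p)
  expect_error(parse_te_exon_table(p), "allowed")
  writeLines(c(paste("chrom", "start", "end", "gene_id", "location",
                     "family", "te_nucleotides", sep = "\t"),
               "chr1\t0\t300\tg1\tCDS\tAlu\t400"), p)
  expect_error(parse_te_exon_table(p), "te_nucleotides")
  writeLines(c(paste("chrom", "start", "end", "gene_id", "location",
                     "family", "rte", sep = "\t"),
               "chr1\t0\t300\tg1\tCDS\tAlu\t1.4"), p)
  expect_error(parse_te_exon_table(p), "rte")
})

test_that("exon classification follows the TE/alt membership rules", {
  ann <- tiny_annotation()
  cls <- setNames(ann$exons$class, ann$exons$exon_id)
  # TE-table exon with an exact gene-model counterpart
  expect_equal(unname(cls["chr1:500-700"]), "C3")
  # TE-table exons with no counterpart
  expect_equal(unname(cls["chr1:750-850"]), "C4")
  expect_equal(unname(cls["chr1:5500-5600"]), "C4")
  # non-TE exon in the alt table, and plain constitutive exons
  expect_equal(unname(cls["chr1:1000-1100"]), "C2")
  expect_equal(unname(cls["chr1:100-200"]), "C1")
  expect_true(ann$te_features$annotated[ann$te_features$exon_id == "chr1:500-700"])

  # partition: every real exon gets exactly one class C1-C4
  real <- ann$exons[ann$exons$class != "C5", ]
  expect_equal(nrow(real), 8)  # 6 gene-model exons + 2 C4
  expect_true(all(real$class %in% c("C1", "C2", "C3", "C4")))
})

test_that("decoy exons sit immediately 3' of their C4 exon, equal length", {
  ann <- tiny_annotation()
  p <- ann$c5_pairs
  ex <- ann$exons
  # + strand host: [750,850) -> [850,950)
  expect_true("chr1:850-950" %in% p$c5_exon_id[p$c4_exon_id == "chr1:750-850"])
  # - strand host: [5500,5600) -> [5400,5500)
  expect_true("chr1:5400-5500" %in% p$c5_exon_id[p$c4_exon_id == "chr1:5500-5600"])
  # index pairing and length equality
  len <- setNames(ex$length, ex$exon_id)
  expect_equal(unname(len[p$c5_exon_id]), unname(len[p$c4_exon_id]))
  expect_false(any(p$overlaps_exon))

  # strand-ignorant variant applies the + rule everywhere
  ann2 <- build_simulated_exons(tiny_annotation_without_c5(),
                                strand_aware = FALSE)
  expect_true("chr1:5600-5700" %in% ann2$c5_pairs$c5_exon_id)

  # decoys falling below position 0 are clipped with a warning
  clip <- tiny_annotation_without_c5()
  clip$exons$start[clip$exons$exon_id == "chr1:5500-5600"] <- 50
  clip$exons$end[clip$exons$exon_id == "chr1:5500-5600"] <- 200
  expect_warning(build_simulated_exons(clip), "clipped")
})

test_that("fictional gene assembly is seeded and bounded", {
  ann <- tiny_annotation()
  fg1 <- build_fictional_genes(ann, n_genes = 5, min_exons = 1,
                               max_exons = 2, seed = 7)
  fg2 <- build_fictional_genes(ann, n_genes = 5, min_exons = 1,
                               max_exons = 2, seed = 7)
  expect_identical(fg1$exon_genes, fg2$exon_genes)
  members <- fg1$exon_genes[fg1$exon_genes$role == "member", ]
  sizes <- table(members$gene_id)
  expect_true(all(sizes >= 1 & sizes <= 2))
  expect_equal(sum(fg1$genes$fictional), 5)
  # exons sampled without replacement within a gene
  expect_false(any(duplicated(paste(members$gene_id, members$exon_id))))
  expect_error(build_fictional_genes(ann, n_genes = 5, min_exons = 10,
                                     max_exons = 12, seed = 1),
               "min_exons")
})

test_that("annotation tables survive a parse/write/parse round trip", {
  ds <- small_dataset()
  tabs <- ds$annotation$tables
  dir <- withr::local_tempdir()

  write_gene_table(tabs$gene_models, file.path(dir, "g.tsv"))
  gm2 <- parse_gene_table(file.path(dir, "g.tsv"))
  expect_equal(as.data.frame(tabs$gene_models$genes),
               as.data.frame(gm2$genes))
  expect_equal(as.data.frame(dplyr::arrange(tabs$gene_models$exons,
                                            gene_id, start)),
               as.data.frame(dplyr::arrange(gm2$exons, gene_id, start)))

  write_te_exon_table(tabs$te_features, file.path(dir, "te.tsv"))
  te2 <- parse_te_exon_table(file.path(dir, "te.tsv"))
  expect_equal(as.data.frame(te2), as.data.frame(tabs$te_features))

  write_alt_table(tabs$alt, file.path(dir, "alt.bed"))
  expect_equal(as.data.frame(parse_alt_table(file.path(dir, "alt.bed"))),
               as.data.frame(tabs$alt))

  # gzip ingestion
  gz <- file.path(dir, "g.tsv.gz")
  con <- gzfile(gz, "w"); writeLines(readLines(file.path(dir, "g.tsv")), con)
  close(con)
  expect_equal(as.data.frame(parse_gene_table(gz)$genes),
               as.data.frame(tabs$gene_models$genes))
})
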