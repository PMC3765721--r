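# Shared fixtures, built in code. Expensive objects are generated once per
# session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

# A hand-written three-gene annotation exercising every class:
#   gA (+): exons [100,200) C1, [500,700) C3/TE, [1000,1100) C2; C4 TE exon
#           [750,850) in the second intron (decoy [850,950))
#   gB (-): exons [5000,5150) C1, [6000,6200) C1; C4 exon [5500,5600)
#           (decoy [5400,5500))
#   gC (+): single C1 exon [9000,9400), shares no TE exons
tiny_tables <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  gene_path <- file.path(dir, "genes.tsv")
  writeLines(c(
    "gene_id\tchrom\tstrand\ttxStart\ttxEnd\texonStarts\texonEnds",
    "gA\tchr1\t+\t100\t1100\t100,500,1000,\t200,700,1100,",
    "gB\tchr1\t-\t5000\t6200\t5000,6000,\t5150,6200,",
    "gC\tchr1\t+\t9000\t9400\t9000,\t9400,"),
    gene_path)
  te_path <- file.path(dir, "te.tsv")
  writeLines(c(
    paste("chrom", "start", "end", "gene_id", "location", "family",
          "te_nucleotides", sep = "\t"),
    "chr1\t500\t700\tgA\tCDS\tMIR\t100",
    "chr1\t750\t850\tgA\t5UTR\tAlu\t80",
    "chr1\t5500\t5600\tgB\tCDS\tL1\t100"),
    te_path)
  alt_path <- file.path(dir, "alt.bed")
  writeLines("chr1\t1000\t1100", alt_path)
  list(genes = gene_path, te = te_path, alt = alt_path)
}

tiny_annotation_without_c5 <- function() {
  paths <- tiny_tables()
  classify_exons(parse_gene_table(paths$genes),
                 parse_te_exon_table(paths$te),
                 parse_alt_table(paths$alt))
}

tiny_annotation <- function(fictional = FALSE) {
  paths <- tiny_tables()
  ann <- classify_exons(parse_gene_table(paths$genes),
                        parse_te_exon_table(paths$te),
                        parse_alt_table(paths$alt))
  ann <- build_simulated_exons(ann)
  if (fictional)
    ann <- build_fictional_genes(ann, n_genes = 3, min_exons = 1,
                                 max_exons = 2, seed = 1)
  ann
}

# Small generated dataset for module-level tests: fewer genes than the
# default study conditions, with the TE classes over-represented and the
# TE families balanced so that per-class and per-family statistics stay
# stable (and rare-level logistic fits stay unseparated) at this scale.
small_families <- c(Alu = 0.30, ERV1 = 0.06, ERVL = 0.05, L1 = 0.12,
                    L2 = 0.12, MaLR = 0.10, MER1 = 0.05, MER2 = 0.05,
                    MIR = 0.15)
small_config <- function(...) {
  generator_config(n_genes = 300, exons_per_gene = c(4, 8),
                   class_props = c(C1 = 0.60, C2 = 0.20,
                                   C3 = 0.08, C4 = 0.12),
                   family_probs_c4 = small_families,
                   family_probs_c3 = small_families,
                   n_fictional = 100, fictional_exons = c(4, 10),
                   n_samples = 26, ...)
}

small_dataset <- function() {
  cached("small_dataset", function() simulate_dataset(small_config(),
                                                      default_truth(),
                                                      seed = 77))
}

small_quantified <- function() {
  cached("small_quantified", function() {
    ds <- small_dataset()
    quantify_samples(ds$counts, ds$annotation, ds$lib_sizes)
  })
}

# Full-scale study replicates shared by the acceptance properties:
# 20 datasets at the default generator conditions, each with all 26
# samples quantified and the hurdle fit of the first sample.
ACC_SEEDS <- 101:120

acc_replicate <- function(i) {
  cached(paste0("acc_", i), function() {
    ds <- simulate_dataset(generator_config(), default_truth(),
                           seed = ACC_SEEDS[i])
    samples <- quantify_samples(ds$counts, ds$annotation, ds$lib_sizes)
    fit <- suppressWarnings(two_step_fit(samples[[1]],
                                         ds$annotation$te_features))
    list(ds = ds, samples = samples, fit = fit)
  })
}
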