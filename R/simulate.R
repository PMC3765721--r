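# Synthetic-data generator: toy genomes with C1-C4 exon classes and TE
# covariates, hurdle-structured counts across group-labelled pseudo-samples,
# and small SAM fixtures -- all with recorded ground truth.

#' Generator configuration
#'
#' Defaults describe the emulated study: ~1750 genes with 4-12 exons each
#' (~14,000 exons, of which ~1400 are TE exons split ~15:85 between
#' annotated C3 and un-annotated C4), 26 pseudo-samples with the tissue
#' layout and two two-group contrasts of the emulated sample panel, deep
#' libraries of ~8e7 filtered reads, and a near-zero intronic background so
#' decoy (C5) regions stay almost read-free.
#'
#' @param n_genes number of real genes
#' @param exons_per_gene inclusive range of exon slots per gene
#' @param class_props named proportions over C1, C2, C3, C4 (sum to 1)
#' @param exon_len_meanlog,exon_len_sdlog,exon_len_range log-normal length
#'   model for non-TE exons (bp, clamped to the range)
#' @param te_len_meanlog,te_len_sdlog,te_len_range same for TE exons (ELN)
#' @param intron_range ordinary intron length range (bp)
#' @param pad clearance between a C4/C5 block and intron boundaries (bp)
#' @param gene_gap intergenic gap (bp)
#' @param n_chroms toy chromosomes to distribute genes over
#' @param chrom_length optional fixed chromosome length; generation fails
#'   if the packing does not fit
#' @param loc_probs_c4,loc_probs_c3 location-category probabilities
#'   (CDS/UTR3/UTR5) for C4 and C3 exons
#' @param family_probs_c4,family_probs_c3 TE-family probabilities over the
#'   nine modelled families; un-annotated exons are Alu/L1-heavy while
#'   annotated ones are enriched for the ancient MIR/L2 families
#' @param rte_beta_c4,rte_beta_c3 Beta(a, b) parameters of the TE
#'   nucleotide proportion per class
#' @param gene_rpkm_meanlog,gene_rpkm_sdlog log-normal model of gene
#'   expression (RPKM)
#' @param sample_jitter_sdlog per-sample log-normal jitter of gene
#'   expression
#' @param library_size,library_jitter filtered library size and its
#'   uniform per-sample multiplier range
#' @param c5_background_rpkm pre-mRNA/DNA background read density on decoy
#'   regions, in RPKM units (near zero by default; raise to emulate
#'   pre-RNA-rich samples)
#' @param n_fictional,fictional_exons fictional decoy genes and their
#'   exon-count range
#' @param n_samples number of pseudo-samples (26 gives the emulated panel
#'   layout with its breast and prostate contrasts)
#' @param dispersion `NULL` for Poisson counts, or a negative-binomial
#'   dispersion (counts ~ NB with size `1/dispersion`)
#' @param znf_fraction fraction of genes labelled as C2H2 ZNF genes
#' @param read_length read length for SAM fixtures
#' @return a `generator_config` list
#' @export
generator_config <- function(
    n_genes = 1750,
    exons_per_gene = c(4, 12),
    class_props = c(C1 = 0.72, C2 = 0.18, C3 = 0.015, C4 = 0.085),
    exon_len_meanlog = log(160), exon_len_sdlog = 0.35,
    exon_len_range = c(100, 1200),
    te_len_meanlog = log(150), te_len_sdlog = 0.4,
    te_len_range = c(100, 1000),
    intron_range = c(300, 800), pad = 100, gene_gap = 5000,
    n_chroms = 2, chrom_length = NULL,
    loc_probs_c4 = c(CDS = 0.667, UTR3 = 0.014, UTR5 = 0.319),
    loc_probs_c3 = c(CDS = 0.50, UTR3 = 0.15, UTR5 = 0.35),
    family_probs_c4 = c(Alu = 0.55, ERV1 = 0.03, ERVL = 0.03, L1 = 0.12,
                        L2 = 0.07, MaLR = 0.06, MER1 = 0.02, MER2 = 0.02,
                        MIR = 0.10),
    family_probs_c3 = c(Alu = 0.20, ERV1 = 0.03, ERVL = 0.03, L1 = 0.05,
                        L2 = 0.20, MaLR = 0.10, MER1 = 0.07, MER2 = 0.02,
                        MIR = 0.30),
    rte_beta_c4 = c(4, 2), rte_beta_c3 = c(2, 4),
    gene_rpkm_meanlog = log(40), gene_rpkm_sdlog = 0.4,
    sample_jitter_sdlog = 0.1,
    library_size = 8e7, library_jitter = c(0.7, 1.3),
    c5_background_rpkm = 0.005,
    n_fictional = 500, fictional_exons = c(4, 40),
    n_samples = 26,
    dispersion = NULL,
    znf_fraction = 0.05,
    read_length = 50) {
  cfg <- as.list(environment())
  if (abs(sum(class_props) - 1) > 1e-8) abort("class_props must sum to 1")
  if (!setequal(names(class_props), c("C1", "C2", "C3", "C4")))
    abort("class_props must be named C1..C4")
  for (fp in list(family_probs_c4, family_probs_c3))
    if (!setequal(names(fp), TE_FAMILIES_MODELED))
      abort("family probabilities must cover the nine modelled families")
  structure(cfg, class = "generator_config")
}

#' Planted ground truth of the count generator
#'
#' The default effect pattern defines the qualitative signal the recovery
#' tests look for: positive UTR5/UTR3, MIR, L2 and MaLR effects on
#' both presence and level; a positive length effect on presence but a
#' negative one on level; a negative TE-proportion (RTE) effect on both;
#' class-level retention probabilities and multipliers ordering C1 above
#' C2; and a presence/level knock-down in the prostate-adenocarcinoma
#' group (the emulated weak-signal cluster).
#'
#' @param model1 logistic presence model parameters: `mu` intercept,
#'   `alpha` location effects (CDS pinned to 0), `beta` family effects
#'   (Alu pinned to 0), `gamma` log10-length effect, `phi` RTE effect
#' @param model2 log10-level model parameters, same layout
#' @param noise_sd SD of the level model's Gaussian noise (log10 units)
#' @param class_presence per-sample presence probability of C1/C2 exons
#' @param class_level level multiplier of C1/C2 exons
#' @param znf_boost log10-level boost for TE exons hosted by ZNF genes
#' @param group_effects named list (by sample condition) of
#'   `c(dz = <logit shift>, dy = <log10 level shift>)`
#' @param seed seed recorded with the truth (set by [simulate_dataset()])
#' @return a `synthetic_truth` list
#' @export
default_truth <- function(
    model1 = list(
      mu = -0.5,
      alpha = c(CDS = 0, UTR3 = 0.5, UTR5 = 0.8),
      beta = c(Alu = 0, ERV1 = -0.2, ERVL = -0.2, L1 = 0, L2 = 1.0,
               MaLR = 0.8, MER1 = 0.2, MER2 = 0.2, MIR = 1.5),
      gamma = 0.5, phi = -2.0),
    model2 = list(
      mu = 0.5,
      alpha = c(CDS = 0, UTR3 = 0.2, UTR5 = 0.3),
      beta = c(Alu = 0, ERV1 = -0.1, ERVL = -0.1, L1 = 0, L2 = 0.3,
               MaLR = 0.25, MER1 = 0.1, MER2 = 0.1, MIR = 0.4),
      gamma = -0.5, phi = -1.0),
    noise_sd = 0.3,
    class_presence = c(C1 = 0.96, C2 = 0.92),
    class_level = c(C1 = 1.0, C2 = 0.9),
    znf_boost = 0,
    group_effects = list(pr_ad = c(dz = -1.5, dy = -0.6)),
    seed = NULL) {
  for (m in list(model1, model2)) {
    if (m$alpha[["CDS"]] != 0 || m$beta[["Alu"]] != 0)
      abort("baseline entries alpha[CDS] and beta[Alu] must be zero")
  }
  if (noise_sd <= 0) abort("noise_sd must be > 0")
  structure(list(version = 1L, model1 = model1, model2 = model2,
                 noise_sd = noise_sd, class_presence = class_presence,
                 class_level = class_level, znf_boost = znf_boost,
                 group_effects = group_effects, seed = seed),
            class = "synthetic_truth")
}

#' Planted coefficients in design-column order
#'
#' @param truth a `synthetic_truth`
#' @param model `"model1"` or `"model2"`
#' @return named numeric vector aligned with the fitted coefficient tables
#' @export
truth_coefficients <- function(truth, model = c("model1", "model2")) {
  m <- truth[[match.arg(model)]]
  setNames(
    c(m$mu, m$alpha[c("UTR3", "UTR5")], m$beta[TE_FAMILIES_MODELED[-1]],
      m$gamma, m$phi),
    DESIGN_TERMS)
}

clamp <- function(x, range) pmin(pmax(x, range[1]), range[2])

# uniform integer draw over an inclusive range, safe for collapsed ranges
sample_int_range <- function(n, range) {
  vals <- seq(range[1], range[2])
  if (length(vals) == 1) rep(vals, n) else sample(vals, n, replace = TRUE)
}

rlen <- function(n, meanlog, sdlog, range) {
  as.integer(round(clamp(rlnorm(n, meanlog, sdlog), range)))
}

#' The emulated 26-sample panel (tissue layout and contrasts)
#'
#' @param n_samples 26 for the emulated panel; any other value yields
#'   generic samples with condition `"generic"`
#' @return tibble `sample_id`, `condition`, `br_group` (ER status contrast
#'   within the breast lines), `pr_group` (adenocarcinoma vs normal
#'   prostate tissue contrast)
#' @export
make_sample_meta <- function(n_samples = 26) {
  if (n_samples != 26) {
    return(tibble(sample_id = sprintf("S%02d", seq_len(n_samples)),
                  condition = "generic",
                  br_group = NA_character_, pr_group = NA_character_))
  }
  tibble(
    sample_id = c(sprintf("BRneg_%d", 1:3), sprintf("BRpos_%d", 1:4),
                  "BRnorm", "PRcaCell", "PRnormCell",
                  sprintf("LCL_%d", 1:2), sprintf("OV_%d", 1:6),
                  sprintf("prAd_%d", 1:3), sprintf("prNorm_%d", 1:3),
                  "Brain", "Liver"),
    condition = c(rep("br_er_neg", 3), rep("br_er_pos", 4), "br_normal",
                  "pr_cell_tumor", "pr_cell_normal", rep("lcl", 2),
                  rep("ovarian", 6), rep("pr_ad", 3), rep("pr_norm", 3),
                  "brain", "liver"),
    br_group = c(rep("ER-", 3), rep("ER+", 4), rep(NA, 19)),
    pr_group = c(rep(NA, 18), rep("tumor", 3), rep("normal", 3), NA, NA)
  )
}

#' Generate a synthetic annotation with known exon classes
#'
#' Lays out non-overlapping genes on toy chromosomes, assigns each exon
#' slot a class by the configured proportions, embeds un-annotated TE (C4)
#' exons in introns sized so that their downstream decoy (C5) intervals
#' stay intronic and clear of every exon, draws TE covariates (location,
#' family, ELN, RTE), and then runs the annotation pipeline itself
#' ([classify_exons()], [build_simulated_exons()],
#' [build_fictional_genes()]) on the generated tables, so generated class
#' labels are recovered, not asserted.
#'
#' @param config a [generator_config()]
#' @param seed integer seed; the output is a pure function of
#'   (config, seed)
#' @return a `te_annotation` with extra elements `znf_genes` (planted ZNF
#'   gene ids) and `tables` (the raw `gene_models`, `te_features`, `alt`
#'   inputs, for serialisation and parser round-trips)
#' @export
generate_annotation <- function(config = generator_config(), seed = 1) {
  set.seed(seed)
  cfg <- config
  ng <- cfg$n_genes
  k_tot <- sample_int_range(ng, cfg$exons_per_gene)
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  chrom_of <- sprintf("chrS%d", (seq_len(ng) - 1L) %% cfg$n_chroms + 1L)

  gene_rows <- vector("list", ng)
  exon_rows <- vector("list", ng)
  te_rows <- vector("list", ng)
  alt_rows <- vector("list", ng)
  cursor <- setNames(rep(1000, cfg$n_chroms),
                     sprintf("chrS%d", seq_len(cfg$n_chroms)))
  cls_lv <- c("C1", "C2", "C3", "C4")

  for (g in seq_len(ng)) {
    k <- k_tot[g]
    cls <- sample(cls_lv, k, replace = TRUE,
                  prob = cfg$class_props[cls_lv])
    if (sum(cls != "C4") < 2) cls[1:2] <- "C1"
    annot_cls <- cls[cls != "C4"]
    n_intron <- length(annot_cls) - 1L
    n_c4 <- min(sum(cls == "C4"), n_intron)
    # lengths
    is_te_annot <- annot_cls == "C3"
    len_a <- integer(length(annot_cls))
    len_a[!is_te_annot] <- rlen(sum(!is_te_annot), cfg$exon_len_meanlog,
                                cfg$exon_len_sdlog, cfg$exon_len_range)
    len_a[is_te_annot] <- rlen(sum(is_te_annot), cfg$te_len_meanlog,
                               cfg$te_len_sdlog, cfg$te_len_range)
    len_c4 <- rlen(n_c4, cfg$te_len_meanlog, cfg$te_len_sdlog,
                   cfg$te_len_range)
    c4_intron <- if (n_c4) sort(sample.int(n_intron, n_c4)) else integer(0)
    intron_len <- if (n_intron)
      sample_int_range(n_intron, cfg$intron_range) else integer(0)
    intron_len[c4_intron] <- 2L * len_c4 + 3L * cfg$pad

    chrom <- chrom_of[g]
    pos <- cursor[[chrom]]
    starts <- integer(length(annot_cls)); ends <- integer(length(annot_cls))
    c4_start <- integer(n_c4)
    p <- pos
    for (i in seq_along(annot_cls)) {
      starts[i] <- p; ends[i] <- p + len_a[i]
      p <- ends[i]
      if (i <= n_intron) {
        hit <- match(i, c4_intron)
        if (!is.na(hit)) {
          # reserve room for the decoy on the 3' side of the C4 exon
          c4_start[hit] <- if (strand[g] == "+") p + cfg$pad else
            p + intron_len[i] - cfg$pad - len_c4[hit]
        }
        p <- p + intron_len[i]
      }
    }
    gid <- sprintf("G%05d", g)
    gene_rows[[g]] <- list(gene_id = gid, chrom = chrom, strand = strand[g],
                           start = pos, end = p)
    exon_rows[[g]] <- list(gene_id = gid, chrom = chrom, strand = strand[g],
                           start = starts, end = ends, class = annot_cls)
    if (n_c4 || any(is_te_annot)) {
      te_start <- c(starts[is_te_annot], c4_start)
      te_len <- c(len_a[is_te_annot], len_c4)
      te_rows[[g]] <- list(gene_id = gid, chrom = chrom, start = te_start,
                           end = te_start + te_len,
                           annotated = rep(c(TRUE, FALSE),
                                           c(sum(is_te_annot), n_c4)))
    }
    if (any(annot_cls == "C2")) {
      alt_rows[[g]] <- list(chrom = chrom, start = starts[annot_cls == "C2"],
                            end = ends[annot_cls == "C2"])
    }
    cursor[[chrom]] <- p + cfg$gene_gap
  }
  if (!is.null(cfg$chrom_length) && any(cursor > cfg$chrom_length))
    abort(sprintf(
      "infeasible packing: %d genes need %d bp but chrom_length is %d",
      ng, max(cursor), cfg$chrom_length))

  genes <- dplyr::bind_rows(lapply(gene_rows, as_tibble))
  genes$fictional <- FALSE
  gexons <- dplyr::bind_rows(lapply(exon_rows, as_tibble))
  te_raw <- dplyr::bind_rows(lapply(te_rows[!vapply(te_rows, is.null,
                                                    logical(1))], as_tibble))
  alt <- dplyr::bind_rows(lapply(alt_rows[!vapply(alt_rows, is.null,
                                                  logical(1))], as_tibble))

  # TE covariates; annotated (C3) exons draw from the ancient-family-rich,
  # low-RTE mixtures, un-annotated (C4) from the Alu-heavy, high-RTE ones
  n_te <- nrow(te_raw)
  is_c3 <- te_raw$annotated
  pick <- function(p3, p4) ifelse(is_c3,
                                  sample(names(p3), n_te, TRUE, prob = p3),
                                  sample(names(p4), n_te, TRUE, prob = p4))
  family <- pick(cfg$family_probs_c3, cfg$family_probs_c4)
  location <- pick(cfg$loc_probs_c3, cfg$loc_probs_c4)
  eln <- as.integer(te_raw$end - te_raw$start)
  rte_raw <- ifelse(is_c3,
                    rbeta(n_te, cfg$rte_beta_c3[1], cfg$rte_beta_c3[2]),
                    rbeta(n_te, cfg$rte_beta_c4[1], cfg$rte_beta_c4[2]))
  te_nt <- pmax(1L, pmin(eln, as.integer(round(rte_raw * eln))))
  te_features <- tibble(
    exon_id = exon_id(te_raw$chrom, te_raw$start, te_raw$end),
    chrom = te_raw$chrom, start = te_raw$start, end = te_raw$end,
    gene_id = te_raw$gene_id, location = location, family = family,
    eln = eln, rte = te_nt / eln, est_inclusion = NA_real_)

  gexons$exon_id <- exon_id(gexons$chrom, gexons$start, gexons$end)
  models <- structure(list(
    genes = genes[, c("gene_id", "chrom", "strand", "start", "end",
                      "fictional")],
    exons = gexons[, c("gene_id", "exon_id", "chrom", "start", "end",
                       "strand")]), class = "gene_models")

  ann <- classify_exons(models, te_features, alt)
  ann <- build_simulated_exons(ann)
  ann <- build_fictional_genes(ann, n_genes = cfg$n_fictional,
                               min_exons = cfg$fictional_exons[1],
                               max_exons = cfg$fictional_exons[2])
  ann$znf_genes <- sort(sample(genes$gene_id,
                               round(cfg$znf_fraction * ng)))
  ann$tables <- list(gene_models = models, te_features = te_features,
                     alt = alt)
  ann
}

group_shift <- function(meta, effects, which) {
  out <- numeric(nrow(meta))
  for (cond in names(effects))
    out[meta$condition == cond] <- effects[[cond]][[which]]
  out
}

#' Generate hurdle-structured counts for all pseudo-samples
#'
#' For each TE exon and sample, presence is Bernoulli on the logit scale of
#' the planted Model-1 predictor; present exons get an expected rescaled
#' level of `10^(Model-2 predictor + noise)`. The level is converted to an
#' expected read count through the host gene's expression, the exon length
#' and the library size, and the observed count is Poisson (or negative
#' binomial). Non-TE exons use the class-level retention probabilities and
#' multipliers; decoy (C5) regions receive reads at the configured
#' near-zero background density.
#'
#' @param annotation from [generate_annotation()]
#' @param truth a `synthetic_truth`
#' @param config the [generator_config()]
#' @param seed integer seed
#' @return list with `counts` (integer matrix, exons x samples),
#'   `sample_meta`, `lib_sizes` (named, the filtered-read denominators),
#'   `gene_rpkm_base` (planted per-gene expression) and `truth`
#' @export
generate_counts <- function(annotation, truth, config = generator_config(),
                            seed = 1) {
  set.seed(seed)
  cfg <- config
  meta <- make_sample_meta(cfg$n_samples)
  ns <- nrow(meta)
  lib <- cfg$library_size * runif(ns, cfg$library_jitter[1],
                                  cfg$library_jitter[2])
  names(lib) <- meta$sample_id

  ex <- annotation$exons
  nx <- nrow(ex)
  links <- annotation$exon_genes
  host <- links[links$role %in% c("annotated", "hosted"), ]
  host_of <- host$gene_id[match(ex$exon_id, host$exon_id)]
  real_genes <- annotation$genes$gene_id[!annotation$genes$fictional]
  G <- setNames(rlnorm(length(real_genes), cfg$gene_rpkm_meanlog,
                       cfg$gene_rpkm_sdlog), real_genes)
  jitter <- matrix(rlnorm(length(real_genes) * ns, 0,
                          cfg$sample_jitter_sdlog),
                   nrow = length(real_genes),
                   dimnames = list(real_genes, meta$sample_id))

  # per-exon scale: reads per unit rescaled level, per sample
  len_kb <- ex$length / 1000
  gene_scale <- G[host_of] * jitter[host_of, , drop = FALSE]
  scale_mat <- gene_scale * len_kb  # exon x sample
  scale_mat <- sweep(scale_mat, 2, lib / 1e6, `*`)

  lambda <- matrix(0, nx, ns, dimnames = list(ex$exon_id, meta$sample_id))

  # classes C1/C2: Bernoulli retention times a class multiplier
  for (cl in c("C1", "C2")) {
    i <- which(ex$class == cl)
    pres <- matrix(rbinom(length(i) * ns, 1, truth$class_presence[[cl]]),
                   nrow = length(i))
    lambda[i, ] <- pres * truth$class_level[[cl]] * scale_mat[i, ]
  }

  # TE exons (C3 and C4): the planted hurdle model
  te <- dplyr::distinct(annotation$te_features, .data$exon_id,
                        .keep_all = TRUE)
  te <- te[te$exon_id %in% ex$exon_id, ]
  design <- build_design(te)
  X <- cbind(1, as.matrix(design[, DESIGN_TERMS[-1]]))
  eta1 <- drop(X %*% truth_coefficients(truth, "model1"))
  eta2 <- drop(X %*% truth_coefficients(truth, "model2"))
  if (truth$znf_boost != 0) {
    in_znf <- te$gene_id %in% annotation$znf_genes
    eta2 <- eta2 + truth$znf_boost * in_znf
  }
  dz <- group_shift(meta, truth$group_effects, "dz")
  dy <- group_shift(meta, truth$group_effects, "dy")
  i_te <- match(te$exon_id, ex$exon_id)
  nt <- length(i_te)
  p_mat <- plogis(outer(eta1, dz, `+`))
  pres <- matrix(rbinom(nt * ns, 1, p_mat), nrow = nt)
  level <- 10^(outer(eta2, dy, `+`) +
                 matrix(rnorm(nt * ns, 0, truth$noise_sd), nrow = nt))
  lambda[i_te, ] <- pres * level * scale_mat[i_te, ]

  # decoy (C5) background, independent of the host gene
  i5 <- which(ex$class == "C5")
  if (length(i5)) {
    bg <- outer(cfg$c5_background_rpkm * len_kb[i5], lib / 1e6)
    lambda[i5, ] <- bg
  }

  if (max(lambda) > 1e9)
    abort("expected counts overflow; use a smaller library size")
  counts <- if (is.null(cfg$dispersion)) {
    matrix(rpois(nx * ns, lambda), nx, ns,
           dimnames = dimnames(lambda))
  } else {
    matrix(rnbinom(nx * ns, mu = lambda, size = 1 / cfg$dispersion), nx, ns,
           dimnames = dimnames(lambda))
  }
  list(counts = counts, sample_meta = meta, lib_sizes = lib,
       gene_rpkm_base = G, truth = truth)
}

#' Quantify every sample of a count matrix
#'
#' @param counts integer matrix, exons x samples (rownames = exon ids)
#' @param annotation the `te_annotation`
#' @param lib_sizes named vector of filtered-read totals per sample
#' @param ... passed to [quantify_sample()]
#' @return named list of `sample_expression` objects
#' @export
quantify_samples <- function(counts, annotation, lib_sizes, ...) {
  ids <- colnames(counts)
  setNames(lapply(ids, function(s)
    quantify_sample(counts[, s], annotation, total_reads = lib_sizes[[s]],
                    sample_id = s, ...)), ids)
}

#' Generate a SAM fixture reproducing given exon counts
#'
#' Emits primary, uniquely mapped single-block reads placed inside each
#' exon so that the pipeline's per-exon overlap counts reproduce `counts`
#' exactly, plus a configurable fraction of decoy records (non-primary or
#' repetitive-hit) that [filter_alignments()] must remove. Exons shorter
#' than the read length get reads anchored at the exon start with a
#' warning (overlap is still guaranteed, but spill-over into a neighbour
#' is possible).
#'
#' @param annotation a `te_annotation`
#' @param counts named vector of target counts (exon id -> reads); total
#'   at most 10,000
#' @param read_length read length in bp
#' @param seed integer seed
#' @param decoy_frac fraction of additional decoy records
#' @param path optional output path; when given the SAM text is written
#' @return an `alignments` object (clean and decoy records); when `path`
#'   is given the SAM is also written there
#' @export
generate_alignments <- function(annotation, counts, read_length = 50,
                                seed = 1, decoy_frac = 0.1, path = NULL) {
  set.seed(seed)
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (total > 10000) abort("SAM fixtures are capped at 10,000 reads")
  ex <- annotation$exons[match(names(counts), annotation$exons$exon_id), ]
  if (anyNA(ex$exon_id)) abort("counts refer to unknown exon ids")
  if (total > 0 && any(ex$length < read_length))
    warn("exon(s) shorter than the read length; reads may spill over")
  starts <- integer(0); chroms <- character(0)
  if (total > 0) {
    reps <- rep(seq_len(nrow(ex)), counts)
    room <- pmax(ex$length[reps] - read_length, 0)
    starts <- ex$start[reps] + floor(runif(total) * (room + 1))
    chroms <- ex$chrom[reps]
  }
  n_dec <- round(decoy_frac * total)
  dec_idx <- if (n_dec > 0) sample.int(total, n_dec, replace = TRUE) else integer(0)
  dec_secondary <- seq_len(n_dec) <= ceiling(n_dec / 2)
  records <- tibble(
    aln_id = seq_len(total + n_dec),
    read_id = c(sprintf("r%06d", seq_len(total)),
                sprintf("d%06d", seq_len(n_dec))),
    is_primary = c(rep(TRUE, total), !dec_secondary),
    hit_count = c(rep(1L, total), ifelse(dec_secondary, 1L, 3L))
  )
  blocks <- tibble(
    aln_id = records$aln_id,
    chrom = c(chroms, chroms[dec_idx]),
    start = c(starts, starts[dec_idx]),
    end = c(starts, starts[dec_idx]) + read_length
  )
  aln <- new_alignments(records, blocks)
  if (!is.null(path)) {
    lens <- annotation$exons |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(len = max(.data$end) + 1000, .groups = "drop")
    write_sam(aln, setNames(lens$len, lens$chrom), path)
  }
  aln
}

#' Generate uniformly random (possibly spliced) reads over the toy genome
#'
#' Fixture generator for exercising the overlap-counting stage against a
#' brute-force oracle: read positions are uniform over each chromosome and
#' a fraction of reads are spliced into two blocks.
#'
#' @param annotation a `te_annotation` (defines the chromosome extents)
#' @param n_reads number of reads
#' @param read_length total aligned bases per read
#' @param spliced_frac fraction of two-block reads
#' @param seed integer seed
#' @return an `alignments` object of primary, unique-hit records
#' @export
random_alignments <- function(annotation, n_reads, read_length = 50,
                              spliced_frac = 0.3, seed = 1) {
  set.seed(seed)
  ext <- annotation$exons |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(lo = min(.data$start), hi = max(.data$end),
                     .groups = "drop")
  pick <- sample.int(nrow(ext), n_reads, replace = TRUE)
  start <- ext$lo[pick] +
    floor(runif(n_reads) * (ext$hi[pick] - ext$lo[pick] - read_length))
  spliced <- runif(n_reads) < spliced_frac
  half <- read_length %/% 2
  gap <- sample(50:2000, n_reads, replace = TRUE)
  records <- tibble(aln_id = seq_len(n_reads),
                    read_id = sprintf("q%06d", seq_len(n_reads)),
                    is_primary = TRUE, hit_count = 1L)
  end1 <- start + ifelse(spliced, half, read_length)
  s2 <- start + half + gap
  b1 <- tibble(aln_id = records$aln_id, chrom = ext$chrom[pick],
               start = start, end = end1)
  b2 <- tibble(aln_id = records$aln_id[spliced],
               chrom = ext$chrom[pick][spliced],
               start = s2[spliced],
               end = s2[spliced] + (read_length - half))
  new_alignments(records, dplyr::arrange(dplyr::bind_rows(b1, b2),
                                         .data$aln_id, .data$start))
}

#' Save / load the planted ground truth
#'
#' Lossless JSON round-trip of a `synthetic_truth`, including the seed it
#' was used with; loading validates the format version and field layout
#' and fails on tampered or incompatible files.
#'
#' @param truth a `synthetic_truth`
#' @param path JSON path
#' @return `path` invisibly (save); the reloaded `synthetic_truth` (load)
#' @export
save_truth <- function(truth, path) {
  # named atomic vectors must become lists so JSON keeps their names
  dictify <- function(x) as.list(x)
  out <- unclass(truth)
  out$model1$alpha <- dictify(out$model1$alpha)
  out$model1$beta <- dictify(out$model1$beta)
  out$model2$alpha <- dictify(out$model2$alpha)
  out$model2$beta <- dictify(out$model2$beta)
  out$class_presence <- dictify(out$class_presence)
  out$class_level <- dictify(out$class_level)
  out$group_effects <- lapply(out$group_effects, dictify)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_truth
#' @export
load_truth <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) abort("truth file is not valid JSON"))
  need <- c("version", "model1", "model2", "noise_sd", "class_presence",
            "class_level", "znf_boost", "group_effects")
  if (!all(need %in% names(raw)))
    abort("truth file is missing required fields (tampered or incompatible?)")
  if (!identical(as.integer(raw$version), 1L))
    abort(sprintf("unsupported truth file version: %s", raw$version))
  num <- function(x) unlist(x)
  parse_model <- function(m) {
    if (!all(c("mu", "alpha", "beta", "gamma", "phi") %in% names(m)))
      abort("truth file model block malformed")
    list(mu = m$mu, alpha = num(m$alpha), beta = num(m$beta),
         gamma = m$gamma, phi = m$phi)
  }
  default_truth(
    model1 = parse_model(raw$model1), model2 = parse_model(raw$model2),
    noise_sd = raw$noise_sd,
    class_presence = num(raw$class_presence),
    class_level = num(raw$class_level),
    znf_boost = raw$znf_boost,
    group_effects = lapply(raw$group_effects, num),
    seed = if (is.null(raw$seed)) NULL else as.integer(raw$seed))
}

#' Simulate a complete, self-consistent dataset
#'
#' Generates the annotation and the count matrix from one seed (annotation
#' under `seed`, counts under `seed + 1`) and optionally writes every
#' artefact in the dialects the parsers consume: the refGene-like gene
#' table, the TE-exon table, the alt-exon BED, the count matrix, sample
#' metadata, library sizes, the ZNF gene list and the truth JSON.
#'
#' @param config a [generator_config()]
#' @param truth a `synthetic_truth`
#' @param seed integer seed
#' @param dir optional output directory
#' @return list with `annotation`, `counts`, `sample_meta`, `lib_sizes`,
#'   `truth`, `config`
#' @export
simulate_dataset <- function(config = generator_config(),
                             truth = default_truth(), seed = 1,
                             dir = NULL) {
  truth$seed <- as.integer(seed)
  ann <- generate_annotation(config, seed = seed)
  sim <- generate_counts(ann, truth, config, seed = seed + 1)
  out <- list(annotation = ann, counts = sim$counts,
              sample_meta = sim$sample_meta, lib_sizes = sim$lib_sizes,
              truth = truth, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_gene_table(ann$tables$gene_models, file.path(dir, "genes.tsv"))
    write_te_exon_table(ann$tables$te_features,
                        file.path(dir, "te_exons.tsv"))
    write_alt_table(ann$tables$alt, file.path(dir, "alt_exons.bed"))
    counts_tb <- as_tibble(sim$counts, rownames = "exon_id")
    readr::write_tsv(counts_tb, file.path(dir, "counts.tsv"),
                     progress = FALSE)
    readr::write_tsv(sim$sample_meta, file.path(dir, "samples.tsv"),
                     progress = FALSE)
    readr::write_tsv(tibble(sample_id = names(sim$lib_sizes),
                            filtered_reads = unname(sim$lib_sizes)),
                     file.path(dir, "lib_sizes.tsv"), progress = FALSE)
    writeLines(ann$znf_genes, file.path(dir, "znf_genes.txt"))
    save_truth(truth, file.path(dir, "truth.json"))
  }
  out
}
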