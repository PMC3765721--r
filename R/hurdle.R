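# Two-step hurdle regression of genomic covariates on TE exon expression:
# Model-1, a logistic regression on presence/absence; Model-2, ordinary
# least squares on the log10 expression level of the expressed subset.
# CDS is the baseline location and Alu the baseline TE family, so their
# indicator coefficients are pinned to zero by omission.

DESIGN_TERMS <- c("(Intercept)", "UTR3", "UTR5",
                  "ERV1", "ERVL", "L1", "L2", "MaLR", "MER1", "MER2", "MIR",
                  "log10_eln", "rte")

#' Build the regression design from TE-exon features
#'
#' Columns, in fixed order: location indicators UTR3, UTR5 (CDS baseline);
#' family indicators ERV1, ERVL, L1, L2, MaLR, MER1, MER2, MIR (Alu
#' baseline); `log10_eln`, the log10 exon length; and `rte`, the TE
#' nucleotide proportion. Exons from the rare CR1 and other_DNA families
#' are not modelled and must be filtered out by the caller.
#'
#' @param features TE-exon feature tibble with `exon_id`, `location`,
#'   `family`, `eln`, `rte`
#' @return tibble: `exon_id` plus the 12 design columns
#' @export
build_design <- function(features) {
  bad <- setdiff(unique(features$family), TE_FAMILIES_MODELED)
  if (length(bad))
    abort(paste0("unmodelled TE family in design input: ",
                 paste(bad, collapse = ", "),
                 " (exclude CR1/other_DNA exons first)"))
  if (!all(features$location %in% TE_LOCATIONS))
    abort("unknown location category in design input")
  d <- tibble(exon_id = features$exon_id)
  d$UTR3 <- as.numeric(features$location == "UTR3")
  d$UTR5 <- as.numeric(features$location == "UTR5")
  for (f in TE_FAMILIES_MODELED[-1])
    d[[f]] <- as.numeric(features$family == f)
  d$log10_eln <- log10(features$eln)
  d$rte <- features$rte
  d
}

coef_table <- function(fit) {
  sm <- summary(fit)$coefficients
  tibble(term = rownames(sm), estimate = unname(sm[, 1]),
         se = unname(sm[, 2]), p_value = unname(sm[, 4]))
}

design_formula <- function(design) {
  cols <- setdiff(names(design), c("exon_id", ".response"))
  rhs <- if (length(cols)) paste(sprintf("`%s`", cols), collapse = " + ") else "1"
  stats::as.formula(paste(".response ~", rhs))
}

#' Fit Model-1: logistic regression on exon presence
#'
#' Maximum-likelihood logit fit of the presence indicator (at least one
#' read mapped) on the genomic covariates; Wald standard errors and
#' two-sided p-values. Convergence: relative deviance change below 1e-8,
#' at most 100 iterations.
#'
#' @param design design tibble from [build_design()]
#' @param z 0/1 presence indicators, one per design row
#' @return tibble `term`, `estimate`, `se`, `p_value`
#' @export
fit_model1 <- function(design, z) {
  if (length(z) != nrow(design)) abort("fit_model1: z length mismatch")
  if (!all(z %in% c(0, 1))) abort("fit_model1: z must be 0/1")
  if (all(z == 0) || all(z == 1))
    abort("fit_model1: all responses identical; both outcomes required")
  dat <- design[, setdiff(names(design), "exon_id"), drop = FALSE]
  dat$.response <- z
  fit <- glm(design_formula(dat), family = binomial(), data = dat,
             control = list(epsilon = 1e-8, maxit = 100))
  if (!fit$converged)
    abort("fit_model1: IRLS did not converge in 100 iterations")
  big <- abs(coef(fit)) > 15
  if (any(big, na.rm = TRUE))
    abort(paste0("fit_model1: apparent separation; diverging coefficient(s): ",
                 paste(names(coef(fit))[which(big)], collapse = ", ")))
  coef_table(fit)
}

#' Fit Model-2: linear regression on log10 expression level
#'
#' Ordinary least squares of `log10(y)` on the genomic covariates for the
#' expressed exons (`y > 0`); t-based standard errors and two-sided
#' p-values.
#'
#' @param design design tibble from [build_design()] (expressed rows only)
#' @param y strictly positive rescaled RPKMs, one per design row
#' @return list with `coefficients` (tibble `term`, `estimate`, `se`,
#'   `p_value`), `residuals`, `sigma` and `r_squared`
#' @export
fit_model2 <- function(design, y) {
  if (length(y) != nrow(design)) abort("fit_model2: y length mismatch")
  if (any(y <= 0)) abort("fit_model2: y must be strictly positive")
  dat <- design[, setdiff(names(design), "exon_id"), drop = FALSE]
  p <- ncol(dat) + 1
  if (length(y) <= p)
    abort(sprintf("fit_model2: %d observations for %d coefficients",
                  length(y), p))
  dat$.response <- log10(y)
  fit <- lm(design_formula(dat), data = dat)
  alias <- is.na(coef(fit))
  if (any(alias))
    abort(paste0("fit_model2: singular design; collinear column(s): ",
                 paste(names(coef(fit))[alias], collapse = ", ")))
  sm <- summary(fit)
  list(coefficients = coef_table(fit),
       residuals = unname(stats::residuals(fit)),
       sigma = sm$sigma, r_squared = sm$r.squared)
}

#' Two-step (hurdle) fit for one sample
#'
#' Restricts to TE exons (C3/C4) of the modelled families whose host gene
#' is expressed in the sample; fits Model-1 on all of them with presence
#' defined as count >= 1, and Model-2 on the expressed subset with the
#' capped rescaled RPKM as the level. Both models share one design
#' construction.
#'
#' @param sample a `sample_expression`
#' @param features TE-exon feature tibble (`annotation$te_features`)
#' @return an object of class `hurdle_fit`: list with `model1`, `model2`
#'   (coefficient tibbles), `model2_details`, `n1`, `n2`, `sample_id`
#' @export
two_step_fit <- function(sample, features) {
  ex <- sample$exons
  te <- ex[ex$class %in% c("C3", "C4") & !is.na(ex$rescaled), ]
  te <- dplyr::distinct(te, .data$exon_id, .keep_all = TRUE)
  feats <- features[features$family %in% TE_FAMILIES_MODELED, ]
  te <- dplyr::inner_join(te, feats[, c("exon_id", "location", "family",
                                        "eln", "rte")], by = "exon_id")
  if (nrow(te) == 0) abort("two_step_fit: no usable TE exons in sample")
  design <- build_design(te)
  z <- as.numeric(te$count >= 1)
  if (all(z == 1) || all(z == 0)) {
    # degenerate hurdle: no presence/absence contrast in this sample
    warn("two_step_fit: presence indicator is constant; Model-1 skipped")
    model1 <- NULL
  } else {
    model1 <- fit_model1(design, z)
  }
  pos <- z == 1
  model2 <- fit_model2(design[pos, ], te$rescaled[pos])
  structure(list(model1 = model1, model2 = model2$coefficients,
                 model2_details = model2[c("residuals", "sigma", "r_squared")],
                 n1 = nrow(te), n2 = sum(pos),
                 sample_id = sample$sample_id),
            class = "hurdle_fit")
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat("<hurdle_fit> ", x$sample_id, ": Model-1 n=", x$n1,
      ", Model-2 n=", x$n2, "\n", sep = "")
  invisible(x)
}

#' Summary-statistic regressions on per-exon median and CV
#'
#' Refits the level regression with two cross-sample descriptive statistics
#' as dependent variables: `log10(m)` for the per-exon median (mirroring
#' Model-2's transformation) and the raw coefficient of variance `v`. Both
#' fits use the same exon subset: eligible exons with `m > 0` and a defined
#' CV.
#'
#' @param dispersion tibble from [dispersion_summary()]
#' @param features TE-exon feature tibble
#' @return list with coefficient tibbles `m_model` and `v_model`, the
#'   shared `n`, and `subset` (the exon ids used)
#' @export
fit_summary_models <- function(dispersion, features) {
  feats <- features[features$family %in% TE_FAMILIES_MODELED, ]
  d <- dplyr::inner_join(
    dispersion[!is.na(dispersion$m) & dispersion$m > 0 & !is.na(dispersion$v), ],
    feats[, c("exon_id", "location", "family", "eln", "rte")], by = "exon_id")
  design <- build_design(d)
  m_fit <- fit_model2(design, d$m)
  v_dat <- design[, setdiff(names(design), "exon_id")]
  v_dat$.response <- d$v
  v_lm <- lm(design_formula(v_dat), data = v_dat)
  list(m_model = m_fit$coefficients, v_model = coef_table(v_lm),
       n = nrow(d), subset = d$exon_id)
}

#' Discretise an effect's p-value by sign and significance
#'
#' Categories: `pos p<0.01`, `pos p<0.05`, `ns`, `neg p<0.05`,
#' `neg p<0.01`, using the only two thresholds reported (0.01, 0.05) and
#' the coefficient's sign.
#'
#' @param coefficient effect estimate(s)
#' @param p two-sided p-value(s) in \[0, 1\]
#' @return character vector of categories
#' @export
discretize_p <- function(coefficient, p) {
  if (any(p < 0 | p > 1)) abort("discretize_p: p outside [0, 1]")
  sig <- ifelse(p < 0.01, "p<0.01", ifelse(p < 0.05, "p<0.05", "ns"))
  ifelse(sig == "ns", "ns",
         paste(ifelse(coefficient >= 0, "pos", "neg"), sig))
}

#' Effect-category matrix across samples
#'
#' The per-sample discretised effect display: one row per design term, one
#' column per sample, entries from [discretize_p()].
#'
#' @param fits list of `hurdle_fit` objects
#' @param model `"model1"` or `"model2"`
#' @return character matrix, terms x samples
#' @export
effect_category_matrix <- function(fits, model = c("model1", "model2")) {
  model <- match.arg(model)
  cols <- vapply(fits, function(f) {
    tb <- f[[model]]
    discretize_p(tb$estimate, tb$p_value)
  }, character(nrow(fits[[1]][[model]])))
  rownames(cols) <- fits[[1]][[model]]$term
  colnames(cols) <- vapply(fits, function(f) f$sample_id, character(1))
  cols
}
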