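test_that("the design matrix uses CDS/Alu baselines in fixed column order", {
  f <- tibble::tibble(exon_id = c("a", "b"),
                      location = c("UTR5", "CDS"),
                      family = c("MIR", "Alu"),
                      eln = c(100, 10), rte = c(0.8, 0))
  d <- build_design(f)
  expect_named(d, c("exon_id", "UTR3", "UTR5", "ERV1", "ERVL", "L1", "L2",
                    "MaLR", "MER1", "MER2", "MIR", "log10_eln", "rte"))
  expect_equal(unlist(d[1, c("UTR5", "MIR", "log10_eln", "rte")],
                      use.names = FALSE), c(1, 1, 2, 0.8))
  # baseline row: all indicators zero
  expect_equal(sum(unlist(d[2, 2:11])), 0)
  expect_equal(d$log10_eln[2], 1)
  expect_error(build_design(tibble::tibble(
    exon_id = "x", location = "CDS", family = "CR1", eln = 100, rte = 0.5)),
    "CR1")
})

test_that("the presence model is the Bernoulli-logit MLE with Wald tests", {
  # intercept-only closed form: 7 of 10 present -> mu = log(7/3)
  d0 <- tibble::tibble(exon_id = paste0("e", 1:10))
  z <- c(rep(1, 7), rep(0, 3))
  fit <- fit_model1(d0, z)
  expect_equal(fit$estimate, log(7 / 3), tolerance = 1e-8)

  # matches a generic numerical likelihood maximiser on a real design
  # (moderate success probabilities keep rare family levels unseparated)
  ds <- small_dataset()
  design <- build_design(ds$annotation$te_features)
  X <- cbind(1, as.matrix(design[, -1]))
  set.seed(30)
  zz <- rbinom(nrow(X), 1, plogis(0.5 * drop(
    X %*% truth_coefficients(default_truth(), "model1"))))
  fit2 <- fit_model1(design, zz)
  expect_equal(fit2$estimate, unname(oracle_logit(X, zz)), tolerance = 1e-5)

  # duplicating every row keeps estimates, shrinks SE by sqrt(2)
  fit3 <- fit_model1(dplyr::bind_rows(design, design), c(zz, zz))
  expect_equal(fit3$estimate, fit2$estimate, tolerance = 1e-6)
  expect_equal(fit3$se, fit2$se / sqrt(2), tolerance = 1e-4)

  expect_error(fit_model1(d0, rep(1, 10)), "identical")
  # complete separation is reported, naming a column
  sep <- tibble::tibble(exon_id = paste0("e", 1:40), x = rep(0:1, each = 20))
  expect_error(fit_model1(sep, rep(0:1, each = 20)), "separation")
})

test_that("the level model is OLS on log10 with exact normal equations", {
  d <- tibble::tibble(exon_id = paste0("e", 1:3), x = c(0, 1, 2))
  fit <- suppressWarnings(fit_model2(d, 10^c(0, 1, 2)))  # noiseless fit
  expect_equal(fit$coefficients$estimate, c(0, 1), tolerance = 1e-12)
  # constant response: non-intercept coefficients 0
  d2 <- tibble::tibble(exon_id = paste0("e", 1:6), x = rnorm(6))
  fit2 <- suppressWarnings(fit_model2(d2, rep(2, 6)))
  expect_equal(fit2$coefficients$estimate[2], 0, tolerance = 1e-12)
  expect_error(fit_model2(d, c(1, -1, 2)), "positive")
  # n must exceed the coefficient count; singular designs are named
  expect_error(fit_model2(tibble::tibble(exon_id = "a", x = 1), 2),
               "observations")
  d3 <- tibble::tibble(exon_id = paste0("e", 1:10), x = rnorm(10))
  d3$y2 <- 2 * d3$x
  expect_error(fit_model2(d3, rlnorm(10)), "collinear")

  # matches the closed-form normal equations on a full design
  ds <- small_dataset()
  feats <- ds$annotation$te_features[1:150, ]
  design <- build_design(feats)
  X <- cbind(1, as.matrix(design[, -1]))
  set.seed(31)
  y <- 10^(drop(X %*% truth_coefficients(default_truth(), "model2")) +
             rnorm(150, 0, 0.3))
  fit3 <- fit_model2(design, y)
  expect_equal(fit3$coefficients$estimate,
               unname(oracle_ols(X, log10(y))), tolerance = 1e-9)
})

test_that("two-step fits split the sample correctly and recover signs", {
  ds <- small_dataset()
  s1 <- small_quantified()[[1]]
  fit <- two_step_fit(s1, ds$annotation$te_features)
  expect_gte(fit$n1, fit$n2)
  te_rows_all <- s1$exons$class %in% c("C3", "C4") & !is.na(s1$exons$rescaled)
  expect_equal(fit$n1, sum(te_rows_all))
  expect_equal(fit$n2, sum(te_rows_all & s1$exons$count >= 1))
  # planted negative RTE effect on the level is recovered
  rte_row <- fit$model2[fit$model2$term == "rte", ]
  expect_lt(rte_row$estimate, 0)
  expect_lt(rte_row$p_value, 0.05)
  # positive MIR presence effect is recovered
  mir_row <- fit$model1[fit$model1$term == "MIR", ]
  expect_gt(mir_row$estimate, 0)

  # a sample where every TE exon is expressed: Model-1 skipped with a
  # warning, Model-2 still returned
  s2 <- s1
  te_rows <- s2$exons$class %in% c("C3", "C4")
  s2$exons$count[te_rows] <- pmax(s2$exons$count[te_rows], 1)
  s2$exons$rescaled[te_rows] <- pmax(s2$exons$rescaled[te_rows], 1e-3)
  expect_warning(fit2 <- two_step_fit(s2, ds$annotation$te_features),
                 "Model-1 skipped")
  expect_null(fit2$model1)
  expect_s3_class(fit2$model2, "tbl_df")
})

test_that("baseline identifiability: pinned levels do not shift the rest", {
  # refitting with the baseline indicator columns added back (constant
  # zeros removed by construction) must leave the fitted effects unchanged
  ds <- small_dataset()
  design <- build_design(ds$annotation$te_features)
  set.seed(32)
  z <- rbinom(nrow(design), 1, 0.5)
  f1 <- fit_model1(design, z)
  # relabel the baseline: add CDS/Alu columns as the complement indicators;
  # the model is then over-parameterised, glm drops them, effects persist
  aug <- design
  aug$CDSdummy <- 0
  f2 <- fit_model1(aug, z)
  expect_equal(f2$estimate[seq_len(13)], f1$estimate, tolerance = 1e-10)
})

test_that("summary-model fits mirror Model-2 and p-values discretise", {
  sq <- small_quantified()
  em <- expression_matrix(sq)
  disp <- dispersion_summary(em, min_samples = 13)
  fsm <- fit_summary_models(disp, small_dataset()$annotation$te_features)
  expect_named(fsm, c("m_model", "v_model", "n", "subset"))
  expect_equal(nrow(fsm$m_model), 13)
  expect_equal(fsm$n, length(fsm$subset))
  # level and dispersion effects of RTE run in opposite directions
  m_rte <- fsm$m_model$estimate[fsm$m_model$term == "rte"]
  v_rte <- fsm$v_model$estimate[fsm$v_model$term == "rte"]
  expect_lt(m_rte, 0)
  expect_gt(v_rte, 0)

  expect_equal(discretize_p(2.1, 0.003), "pos p<0.01")
  expect_equal(discretize_p(-0.4, 0.2), "ns")
  expect_equal(discretize_p(-0.4, 0.049), "neg p<0.05")
  expect_equal(discretize_p(0.4, 0.05), "ns")  # boundary is exclusive
  expect_error(discretize_p(1, 1.2), "p outside")

  fits <- lapply(sq[1:3], two_step_fit,
                 features = small_dataset()$annotation$te_features)
  mat <- effect_category_matrix(fits, "model2")
  expect_equal(dim(mat), c(13, 3))
  expect_true(all(mat %in% c("pos p<0.01", "pos p<0.05", "ns",
                             "neg p<0.05", "neg p<0.01")))
})
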