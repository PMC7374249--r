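test_that("stratified folds balance strata and partition the samples", {
  grp <- rep(c("TOL", "ST", "CR"), c(18, 186, 34))
  set.seed(3)
  f <- stratified_folds(grp, 6)
  # 18 TOL into 6 folds: exactly 3 per fold
  expect_true(all(table(f[grp == "TOL"]) == 3))
  # fold sizes within each stratum differ by at most one
  for (g in unique(grp))
    expect_lte(diff(range(table(factor(f[grp == g], 1:6)))), 1)
  # partition: every sample in exactly one fold
  expect_length(f, length(grp))
  expect_setequal(unique(f), 1:6)
  # determinism under the same seed
  set.seed(99); f1 <- stratified_folds(grp, 6)
  set.seed(99); f2 <- stratified_folds(grp, 6)
  expect_identical(f1, f2)
  expect_error(stratified_folds(grp, 1), "at least 2")
})

test_that("run_cv produces the structural ensemble counts", {
  coh <- small_cohort()
  spec <- tol_signatures()[["COMBINED-g7"]]
  cv <- run_cv(coh$expr, coh$samples, spec,
               cv_config(folds = 3, repeats = 2, inner_repeats = 2, seed = 4))
  n_ktr <- sum(coh$samples$timepoint == "T1" & coh$samples$group != "HC")
  expect_equal(dim(cv$probabilities), c(n_ktr, 2L))
  expect_equal(nrow(cv$coefficients), 6L)            # folds x repeats
  expect_equal(dim(cv$adjustment_r2), c(6L, 7L))     # per-gene drug models
  expect_false(anyNA(cv$probabilities))              # each patient scored per cycle
  # each patient predicted exactly once per repeat: fold assignment complete
  expect_true(all(cv$folds %in% 1:3))
})

test_that("cross-validation is deterministic under the master seed", {
  coh <- small_cohort()
  spec <- tol_signatures()[["GAMSTER-g4"]]
  cfg <- cv_config(folds = 3, repeats = 2, inner_repeats = 2, seed = 7)
  cv1 <- run_cv(coh$expr, coh$samples, spec, cfg)
  cv2 <- run_cv(coh$expr, coh$samples, spec, cfg)
  expect_identical(cv1$probabilities, cv2$probabilities)
  expect_identical(cv1$coefficients, cv2$coefficients)
})

test_that("held-out predictions never use the test sample's own data", {
  coh <- small_cohort()
  spec <- tol_signatures()[["GAMSTER-g4"]]
  cfg <- cv_config(folds = 3, repeats = 1, inner_repeats = 2, seed = 13)
  cv1 <- run_cv(coh$expr, coh$samples, spec, cfg)
  # corrupt one sample's expression; with the same seed, fold geometry is
  # identical, so only the corrupted sample's own prediction may change
  victim <- cv1$sample_ids[5]
  expr2 <- coh$expr
  expr2[victim, ] <- expr2[victim, ] + 50
  cv2 <- run_cv(expr2, coh$samples, spec, cfg)
  expect_identical(cv1$folds, cv2$folds)
  same_fold <- cv1$folds[, 1] == cv1$folds[victim, 1]
  others <- setdiff(cv1$sample_ids[same_fold], victim)
  expect_equal(cv1$probabilities[others, 1], cv2$probabilities[others, 1],
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cv1$probabilities[victim, 1],
                                cv2$probabilities[victim, 1])))
})

test_that("finalize_signature assembles the median bundle and TOL cutoff", {
  fit <- small_fit()
  coh <- small_cohort()
  bundle <- fit$bundle
  # median coefficients match a direct column-wise median of the ensemble
  expect_equal(unname(bundle$enet$beta),
               unname(apply(fit$cv$coefficients[, -1], 2, median)))
  expect_equal(bundle$enet$intercept, median(fit$cv$coefficients[, 1]))
  # cutoff equals the median TOL probability computed independently
  t1 <- coh$samples$timepoint == "T1"
  p <- predict_cohort(bundle, coh$expr[coh$samples$sample_id[t1], ],
                      coh$samples[t1, ])
  expect_equal(bundle$cutoff, median(p[coh$samples$group[t1] == "TOL"]))
  # both adjustment variants are stored, with plausible R^2
  expect_identical(dim(bundle$adjustment$full), c(6L, 7L))
  expect_identical(dim(bundle$adjustment$median), c(6L, 7L))
  expect_true(all(bundle$adjustment$full_r2 >= 0 & bundle$adjustment$full_r2 <= 1))
})

test_that("predict_cohort reproduces in-sample scores and handles HC off-drug", {
  fit <- small_fit()
  coh <- small_cohort()
  t1 <- coh$samples$timepoint == "T1"
  p <- predict_cohort(fit$bundle, coh$expr[coh$samples$sample_id[t1], ],
                      coh$samples[t1, ])
  expect_equal(p, fit$probabilities, tolerance = 1e-12)
  # HC samples are scored with all drugs off: equal expression implies a
  # TOL sample and an HC sample get the same probability
  hc_id <- coh$samples$sample_id[t1 & coh$samples$group == "HC"][1]
  tol_id <- coh$samples$sample_id[t1 & coh$samples$group == "TOL"][1]
  expr_same <- coh$expr[c(hc_id, tol_id), , drop = FALSE]
  expr_same[2, ] <- expr_same[1, ]
  p2 <- predict_cohort(fit$bundle, expr_same,
                       coh$samples[t1, ][c(hc_id, tol_id), ])
  expect_equal(unname(p2[1]), unname(p2[2]), tolerance = 1e-12)
  expect_error(predict_cohort(fit$bundle, coh$expr[, 1:3], coh$samples),
               "lacks gene")
})

test_that("follow-up samples with unchanged biology agree with baseline", {
  # T2 keeps each patient's tolerance status and gene set-points, so
  # TOL-positivity should agree well across timepoints (kappa > 0.6)
  coh <- generate_cohort(synthetic_config(), seed = 2)
  fit <- suppressWarnings(tolsig(coh$expr, coh$samples, "COMBINED-g7",
                                 repeats = 2, inner_repeats = 2, seed = 32))
  s2 <- coh$samples[coh$samples$timepoint == "T2", ]
  p2 <- predict(fit, coh$expr[s2$sample_id, ], s2)
  s1_ids <- paste0(s2$patient_id, "_T1")
  k <- cohens_kappa(fit$probabilities[s1_ids] > fit$bundle$cutoff,
                    p2 > fit$bundle$cutoff)
  expect_gt(k$kappa, 0.6)
})

test_that("null and strong planted signals bracket the CV AUC", {
  # engine-integrity null: no expression-group association of any kind and
  # no drug adjustment, so any AUC lift would indicate engine leakage
  panel0 <- default_gene_panel(tolerance_genes = c())
  panel0[, c("d_pred", "d_cyc", "d_tac", "d_aza", "d_mmf")] <- 0
  panel0$f <- NA_real_
  aucs <- vapply(1:9, function(seed) {
    cfg <- synthetic_config(n_tol = 12, n_st = 48, n_cr = 12, n_hc = 0,
                            n_t2 = c(tol = 0, st = 0, cr = 0), panel = panel0)
    coh0 <- generate_cohort(cfg, seed = seed + 800)
    cv0 <- suppressWarnings(run_cv(
      coh0$expr, coh0$samples, tol_signatures()[["COMBINED-g7"]],
      cv_config(folds = 6, repeats = 2, inner_repeats = 2, seed = seed),
      drug_adjusted = FALSE))
    median(apply(cv0$probabilities, 2,
                 function(p) auc_delong(p, cv0$y)[["auc"]]))
  }, 0)
  expect_gte(median(aucs), 0.40)
  expect_lte(median(aucs), 0.60)

  # strong planted signal: |tau| over 1.5x the total residual SD
  tol7 <- tol_signatures()[["COMBINED-g7"]]$genes
  strong <- default_gene_panel(
    tolerance_genes = setNames(c(2.6, -2.6, -2.6, 2.6, 2.6, 2.6, -2.6), tol7))
  cfg_s <- synthetic_config(n_tol = 12, n_st = 48, n_cr = 12, n_hc = 0,
                            n_t2 = c(tol = 0, st = 0, cr = 0), panel = strong)
  coh_s <- generate_cohort(cfg_s, seed = 900)
  cv_s <- suppressWarnings(run_cv(
    coh_s$expr, coh_s$samples, tol_signatures()[["COMBINED-g7"]],
    cv_config(folds = 6, repeats = 3, inner_repeats = 2, seed = 901)))
  auc1 <- median(apply(cv_s$probabilities, 2,
                       function(p) auc_delong(p, cv_s$y)[["auc"]]))
  expect_gte(auc1, 0.85)
})
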