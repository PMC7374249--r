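# brute-force AUC by exhaustive pair counting (independent oracle)
auc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

test_that("AUC equals exhaustive pair counting, with DeLong CI behaviour", {
  expect_equal(auc_delong(c(0.9, 0.4, 0.6, 0.5, 0.1),
                          c(1, 1, 0, 0, 0))[["auc"]], 4 / 6)
  # perfect separation
  expect_equal(auc_delong(c(5, 6, 1, 2), c(1, 1, 0, 0))[["auc"]], 1)
  set.seed(12)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    scores <- round(rnorm(n), 1)  # rounding forces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    a <- auc_delong(scores, labels)
    expect_equal(a[["auc"]], auc_pairs(scores, labels))
    expect_true(a[["ci_low"]] <= a[["auc"]] && a[["auc"]] <= a[["ci_high"]])
    expect_true(a[["ci_low"]] >= 0 && a[["ci_high"]] <= 1)
  }
  expect_error(auc_delong(1:5, rep(1, 5)), "both classes")
})

test_that("DeLong AUC and CI agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.3)
  ours <- auc_delong(scores, labels)
  ref <- pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE, direction = "<", levels = c(0, 1)), method = "delong")
  expect_equal(ours[["auc"]], as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(ours[["ci_low"]], as.numeric(ref[1]), tolerance = 1e-3)
  expect_equal(ours[["ci_high"]], as.numeric(ref[3]), tolerance = 1e-3)
})

test_that("paired DeLong test is rank-invariant and matches pROC", {
  set.seed(15)
  labels <- rbinom(80, 1, 0.3)
  a <- rnorm(80) + labels
  # identical scores and monotone transforms give p = 1
  expect_equal(delong_paired_test(a, a, labels)[["p"]], 1)
  expect_equal(delong_paired_test(a, plogis(3 * a - 1), labels)[["p"]], 1)
  # AUC from probabilities equals AUC from the linear predictor
  expect_equal(auc_delong(a, labels)[["auc"]],
               auc_delong(plogis(a), labels)[["auc"]])
  skip_if_not_installed("pROC")
  b <- rnorm(80) + 0.5 * labels
  ours <- delong_paired_test(a, b, labels)
  ref <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE, direction = "<", levels = c(0, 1)),
                        pROC::roc(labels, b, quiet = TRUE, direction = "<", levels = c(0, 1)),
                        method = "delong", paired = TRUE)
  expect_equal(ours[["p"]], ref$p.value, tolerance = 1e-8)
})

test_that("median-TOL cutoff fixes sensitivity at 50% for even TOL counts", {
  samples <- sample_table(data.frame(
    sample_id = paste0("s", 1:10), patient_id = paste0("p", 1:10),
    timepoint = "T1", group = rep(c("TOL", "ST", "CR"), c(4, 4, 2)),
    pred = "off", cni = "off", ap = "off", stringsAsFactors = FALSE))
  probs <- setNames(c(0.2, 0.4, 0.6, 0.8, 0.1, 0.3, 0.55, 0.05, 0.7, 0.15),
                    samples$sample_id)
  cls <- tol_cutoff_classify(probs, samples)
  expect_equal(cls$cutoff, 0.5)
  expect_equal(cls$sensitivity, 0.5)
  expect_equal(cls$specificity, 4 / 6)
  expect_equal(cls$tol_pos_st, 1L)   # 0.55 among ST
  expect_equal(cls$tol_pos_cr, 1L)   # 0.70 among CR

  # strictly-greater comparison: a Non-TOL sample exactly at the cutoff is
  # negative
  probs["s5"] <- 0.5
  expect_false(tol_cutoff_classify(probs, samples)$positive[["s5"]])

  # property: any even TOL group with distinct probabilities
  set.seed(16)
  for (i in 1:20) {
    n_tol <- 2 * sample(1:6, 1)
    p_tol <- sample(seq(0.01, 0.99, by = 0.01), n_tol)
    s <- sample_table(data.frame(
      sample_id = paste0("t", seq_len(n_tol)),
      patient_id = paste0("t", seq_len(n_tol)), timepoint = "T1",
      group = "TOL", pred = "off", cni = "off", ap = "off",
      stringsAsFactors = FALSE))
    cls <- tol_cutoff_classify(setNames(p_tol, s$sample_id), s)
    expect_equal(cls$sensitivity, 0.5)
  }
})

test_that("Cohen's kappa follows the closed form and its symmetries", {
  a <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  b <- c(1, 1, 1, 1, 0, 1, 0, 0, 0, 0)  # counts 4/1/1/4
  expect_equal(cohens_kappa(a, b)$kappa, 0.6)
  expect_equal(cohens_kappa(b, a)$kappa, 0.6)         # symmetric
  expect_equal(cohens_kappa(a, a)$kappa, 1)           # identity
  expect_equal(cohens_kappa(rep(1, 5), rep(1, 5))$kappa, 1)  # p_e = 1 case
  skip_if_not_installed("e1071")
  tab <- table(a, b)
  expect_equal(cohens_kappa(a, b)$kappa,
               e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  # independent raters: kappa near zero
  set.seed(17)
  x <- rbinom(1e4, 1, 0.5); y <- rbinom(1e4, 1, 0.5)
  expect_lt(abs(cohens_kappa(x, y)$kappa), 0.05)
})

test_that("drug influence regression quantifies residual drug signal", {
  coh <- small_cohort()
  s <- coh$samples[coh$samples$timepoint == "T1", ]
  # probabilities built directly from the regimen: R^2 must be high
  lp <- drug_design(s, intercept = FALSE) %*% c(1.5, -1, 0.5, 0.8, -0.6)
  probs <- setNames(plogis(lp + rnorm(nrow(s), 0, 0.1)), s$sample_id)
  di <- drug_influence(probs, s)
  expect_gt(di$r_squared, 0.8)
  expect_identical(di$coefficients$term,
                   c("pred_on", "cni_cyc", "cni_tac", "ap_aza", "ap_mmf"))
  # probabilities independent of regimen: R^2 near zero
  set.seed(18)
  di0 <- drug_influence(setNames(plogis(rnorm(nrow(s))), s$sample_id), s)
  expect_lt(di0$r_squared, 0.15)
})

test_that("dose-response excludes paired drugs and recovers a planted slope", {
  set.seed(44)
  coh <- small_cohort(seed = 401, n_tol = 0, n_st = 150, n_cr = 30, n_hc = 0,
                      n_t2 = c(tol = 0, st = 0, cr = 0))
  s <- coh$samples
  dose <- ifelse(s$cni == "tac", s$dose_tac, 0)
  y <- setNames(0.01 * dose + 0.5 * (s$pred == "on") + rnorm(nrow(s), 0, 0.3),
                s$sample_id)
  res <- dose_response(y, s, "tac")
  expect_lt(abs(res[["slope"]] - 0.01), 2 * res[["se"]])
  # CYC-treated patients are excluded from the TAC dose model
  expect_equal(unname(res[["n"]]),
               sum(s$cni != "cyc" &
                     (is.na(s$dose_tac) |
                        s$dose_tac <= quantile(s$dose_tac[s$cni == "tac"], 0.975))))
  # constant dose after exclusions errors
  s0 <- s[s$cni == "off" & s$ap == "off", ]
  y0 <- y[s0$sample_id]
  expect_error(dose_response(y0, s0, "tac"))
})

test_that("rank-sum test is exact for small samples, approximate for large", {
  # {1,2} vs {3,4}: U = 0, exact two-sided p = 2/6
  expect_equal(rank_sum_test(c(1, 2), c(3, 4)), 1 / 3)
  # equal multisets: p = 1
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3)), 1)
  # matches stats::wilcox.test in the large-sample branch
  set.seed(20)
  a <- rnorm(40); b <- rnorm(40)
  expect_equal(rank_sum_test(a, b),
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("cycle summaries use the median and 2.5-97.5 centile convention", {
  s <- summarize_cycles(1:100)
  expect_equal(s[["median"]], 50.5)
  expect_equal(summarize_cycles(rep(3, 10)),
               c(median = 3, p2.5 = 3, p97.5 = 3))
  expect_equal(summarize_cycles(7), c(median = 7, p2.5 = 7, p97.5 = 7))
})
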