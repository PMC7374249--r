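# oracle helpers -------------------------------------------------------------

# independent OLS via stats::lm on a data.frame, for cross-checking lm.fit use
oracle_lm <- function(y, samples, terms) {
  X <- drug_design(samples, intercept = FALSE)[, terms, drop = FALSE]
  df <- data.frame(y = y, X)
  fit <- lm(y ~ ., data = df)
  list(coef = coef(fit), r2 = summary(fit)$r.squared)
}

test_that("closed-form OLS on a prednisolone-only design is recovered", {
  # PRED-on values {1,2,3}, PRED-off {3,4,5}: group means 2 and 4, so
  # intercept 4, pred effect -2; TSS = 10, RSS = 4 -> R^2 = 0.6
  samples <- sample_table(data.frame(
    sample_id = paste0("s", 1:6), patient_id = paste0("p", 1:6),
    timepoint = "T1", group = "ST",
    pred = rep(c("on", "off"), each = 3), cni = "off", ap = "off",
    dose_pred = c(5, 5, 5, NA, NA, NA), stringsAsFactors = FALSE))
  expr <- matrix(c(1, 2, 3, 3, 4, 5), 6, 1,
                 dimnames = list(paste0("s", 1:6), "G"))
  m <- fit_adjustment(expr, samples, "G", terms = "pred_on")
  expect_equal(unname(m$coefficients["(Intercept)"]), 4)
  expect_equal(unname(m$coefficients["pred_on"]), -2)
  expect_equal(m$r_squared, 0.6)
  expect_equal(m$n_fit, 6L)
})

test_that("planted coefficients are recovered exactly without noise", {
  coh <- small_cohort()
  s <- coh$samples[coh$samples$timepoint == "T1", ]
  X <- drug_design(s)
  beta <- c(2, -1.5, 0.8, -0.3, 1.1, 0.6)
  expr <- matrix(X %*% beta, ncol = 1,
                 dimnames = list(s$sample_id, "G"))
  m <- fit_adjustment(expr, s, "G")
  expect_equal(unname(m$coefficients), beta, tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
})

test_that("fit matches an independent lm oracle on noisy data", {
  coh <- small_cohort()
  s <- coh$samples[coh$samples$timepoint == "T1" & coh$samples$group %in% c("ST", "CR"), ]
  y <- coh$expr[s$sample_id, "TCL1A"]
  m <- fit_adjustment(coh$expr, coh$samples, "TCL1A")
  orc <- oracle_lm(y, s, c("pred_on", "cni_cyc", "cni_tac", "ap_aza", "ap_mmf"))
  expect_equal(unname(m$coefficients), unname(orc$coef), tolerance = 1e-9)
  expect_equal(m$r_squared, orc$r2, tolerance = 1e-9)
})

test_that("rank deficiency names the collinear column", {
  coh <- small_cohort()
  s <- coh$samples
  s$ap[s$ap == "aza"] <- "mmf"   # nobody on AZA any more
  s$dose_aza <- NA_real_
  s <- sample_table(as.data.frame(s))
  expect_error(fit_adjustment(coh$expr, s, "TCL1A"), "ap_aza")
})

test_that("drug-term variance fraction near 0.5 is recovered for the TCL1A analogue", {
  cfg <- synthetic_config(n_tol = 0, n_st = 186, n_cr = 34, n_hc = 0,
                          n_t2 = c(tol = 0, st = 0, cr = 0))
  coh <- generate_cohort(cfg, seed = 19)
  m <- fit_adjustment(coh$expr, coh$samples, "TCL1A")
  expect_lt(abs(m$r_squared - 0.5), 0.07)
})

test_that("residualization sets TOL/HC to off-treatment and zeroes drug signal", {
  coh <- small_cohort()
  t1 <- coh$samples$timepoint == "T1"
  s <- coh$samples[t1, ]
  expr <- coh$expr[s$sample_id, ]
  models <- fit_adjustment_models(expr, s)
  res <- residualize(expr, s, models)

  # TOL sample residual = observed - intercept
  tol_id <- s$sample_id[s$group == "TOL"][1]
  g <- "CD40"
  expect_equal(res[tol_id, g],
               expr[tol_id, g] - models[[g]]$coefficients["(Intercept)"],
               ignore_attr = TRUE)

  # direct-evaluation oracle: observed 3.5, intercept 4 -> residual -0.5
  cf <- matrix(0, 6, 1, dimnames = list(c("(Intercept)", "pred_on", "cni_cyc",
                                          "cni_tac", "ap_aza", "ap_mmf"), "G"))
  cf["(Intercept)", ] <- 4
  one <- matrix(3.5, 1, 1, dimnames = list(tol_id, "G"))
  expect_equal(unname(residualize(one, s, cf)[1, 1]), -0.5)

  # fit-set residuals sum to zero and are orthogonal to every design column
  fitset <- s$group %in% c("ST", "CR")
  X <- drug_design(s[fitset, ])
  ip <- crossprod(X, res[fitset, ])
  expect_lt(max(abs(ip)) / nrow(X), 1e-8)

  # regressing residuals on drugs explains nothing (R^2 at machine precision)
  refit <- fit_adjustment_models(res, s)
  expect_lt(max(vapply(refit, `[[`, 0, "r_squared")), 1e-10)

  # identity under the zero model
  zero <- matrix(0, 6, ncol(expr),
                 dimnames = list(rownames(cf), colnames(expr)))
  expect_equal(residualize(expr, s, zero), expr, ignore_attr = TRUE)

  # residualizing twice with refitted models equals once
  res2 <- residualize(res, s, refit)
  expect_equal(unclass(res2)[fitset, ], unclass(res)[fitset, ], tolerance = 1e-8)

  expect_error(residualize(expr[, 1:3], s, cf), "no adjustment model")
})

test_that("coefficient estimates are unbiased with nominal CI coverage", {
  # 200 synthetic replicates at n = 220 with planted drug effects
  # planted effects of magnitude ~1 so the Monte-Carlo error of the mean
  # (about 0.02 at 200 replicates) is small relative to each effect
  beta <- c(`(Intercept)` = 1, pred_on = -1.2, cni_cyc = 1.0, cni_tac = 0.9,
            ap_aza = -1.1, ap_mmf = -0.8)
  cfg <- synthetic_config(n_tol = 0, n_st = 186, n_cr = 34, n_hc = 0,
                          n_t2 = c(tol = 0, st = 0, cr = 0))
  est <- matrix(NA_real_, 200, 6)
  cover <- matrix(NA, 200, 6)
  set.seed(55)
  for (r in 1:200) {
    reg <- rbind(sample_regimens(cfg, "ST", 186), sample_regimens(cfg, "CR", 34))
    s <- sample_table(data.frame(
      sample_id = paste0("s", 1:220), patient_id = paste0("p", 1:220),
      timepoint = "T1", group = rep(c("ST", "CR"), c(186, 34)), reg,
      stringsAsFactors = FALSE))
    X <- drug_design(s)
    y <- as.numeric(X %*% beta) + rnorm(220)
    expr <- matrix(y, ncol = 1, dimnames = list(s$sample_id, "G"))
    m <- fit_adjustment(expr, s, "G")
    est[r, ] <- m$coefficients
    # Wald CI from the independent lm oracle's standard errors
    fit <- lm(y ~ X - 1)
    se <- sqrt(diag(vcov(fit)))
    cover[r, ] <- abs(coef(fit) - beta) <= 1.96 * se
  }
  bias <- colMeans(est) - beta
  expect_lt(max(abs(bias[-1]) / abs(beta[-1])), 0.05)
  expect_true(all(colMeans(cover) >= 0.90 & colMeans(cover) <= 0.98))
})

test_that("explained variability summarizes model ensembles", {
  expect_equal(unname(explained_variability(list(G = c(0.1, 0.2, 0.3)))$median), 0.2)
  ev <- explained_variability(list(G = rep(0.4, 10)))
  expect_equal(ev$p97.5 - ev$p2.5, 0)
  expect_error(explained_variability(list()), "empty")
  # matrix input (as stored by run_cv)
  m <- cbind(A = c(0.1, 0.3), B = c(0.5, 0.7))
  ev2 <- explained_variability(m)
  expect_equal(ev2$median, c(0.2, 0.6))
})
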