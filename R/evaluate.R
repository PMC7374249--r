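# Evaluation battery: DeLong ROC statistics, median-cutoff classification,
# Cohen's kappa, drug influence on the predicted probability, dose response,
# rank-sum comparisons and per-cycle summaries.

# DeLong structural components: for each positive, the mean of the
# Mann-Whitney kernel over negatives (V10), and vice versa (V01).
# Midranks handle ties (kernel value 1/2).
delong_components <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("missing values in scores or labels")
  pos <- scores[labels]; neg <- scores[!labels]
  m <- length(pos); n <- length(neg)
  if (m == 0L || n == 0L) stop("both classes must be present")
  r_all <- rank(c(pos, neg))
  r_pos <- rank(pos); r_neg <- rank(neg)
  V10 <- (r_all[seq_len(m)] - r_pos) / n
  V01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(auc = (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n),
       V10 = V10, V01 = V01, m = m, n = n)
}

#' AUC with DeLong 95% confidence interval
#'
#' The AUC is the Mann-Whitney statistic (ties count one half). The
#' confidence interval is `auc +/- 1.96 * SE` with the DeLong
#' structural-components variance estimate, truncated to `[0, 1]`.
#'
#' @param scores Numeric predictions (higher = more tolerant-like).
#' @param labels Binary labels (TRUE/1 = tolerant).
#' @return Named vector `c(auc, ci_low, ci_high)`.
#' @export
#' @examples
#' auc_delong(c(0.9, 0.4, 0.6, 0.5, 0.1), c(1, 1, 0, 0, 0))
auc_delong <- function(scores, labels) {
  d <- delong_components(scores, labels)
  se <- sqrt(stats::var(d$V10) / d$m + stats::var(d$V01) / d$n)
  if (is.na(se)) se <- 0  # single observation in a class
  c(auc = d$auc,
    ci_low = max(0, d$auc - 1.96 * se),
    ci_high = min(1, d$auc + 1.96 * se))
}

#' DeLong test for two paired ROC curves
#'
#' Two-sided normal test on the AUC difference of two score vectors computed
#' on the same samples, using the paired DeLong covariance. Identical ROC
#' curves (e.g. scores related by a monotone transform) give p = 1.
#'
#' @param scores_a,scores_b Two score vectors on the same samples.
#' @param labels Binary labels (TRUE/1 = tolerant).
#' @return Named vector `c(auc_a, auc_b, p)`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop("paired scores must have equal length")
  da <- delong_components(scores_a, labels)
  db <- delong_components(scores_b, labels)
  v <- stats::var(da$V10 - db$V10) / da$m + stats::var(da$V01 - db$V01) / da$n
  if (is.na(v)) v <- 0
  diff <- da$auc - db$auc
  p <- if (v <= .Machine$double.eps) {
    if (abs(diff) < sqrt(.Machine$double.eps)) 1 else 0
  } else 2 * stats::pnorm(-abs(diff) / sqrt(v))
  c(auc_a = da$auc, auc_b = db$auc, p = p)
}

#' Classify TOL-positivity at the median-TOL cutoff
#'
#' The conservative uniform cutoff is the median predicted probability among
#' tolerant (TOL) patients; a sample is TOL-positive when its probability is
#' strictly greater than the cutoff. With an even number of TOL patients and
#' distinct probabilities this fixes sensitivity at exactly 50%. Specificity
#' is computed over treated Non-TOL (ST and CR) samples, and the TOL-positive
#' Non-TOL patients are counted by clinical group.
#'
#' @param probs Named probabilities (names = sample ids).
#' @param samples Matching `"tol_samples"` rows.
#' @param cutoff Optional externally supplied cutoff (e.g. the T1-derived
#'   bundle cutoff applied to a follow-up cohort); default: median TOL
#'   probability within `probs`.
#' @return Object of class `"tol_class"`: `cutoff`, logical `positive`,
#'   `sensitivity`, `specificity`, and counts `tol_pos_st`, `tol_pos_cr`.
#' @export
tol_cutoff_classify <- function(probs, samples, cutoff = NULL) {
  idx <- match(names(probs), samples$sample_id)
  if (anyNA(idx)) stop("probabilities contain samples absent from the table")
  grp <- samples$group[idx]
  if (is.null(cutoff)) {
    if (sum(grp == "TOL") < 2L) stop("need at least 2 TOL samples for the cutoff")
    cutoff <- stats::median(probs[grp == "TOL"])
  }
  positive <- probs > cutoff
  nontol <- grp %in% c("ST", "CR")
  structure(list(
    cutoff = cutoff, positive = positive,
    sensitivity = if (any(grp == "TOL")) mean(positive[grp == "TOL"]) else NA_real_,
    specificity = if (any(nontol)) mean(!positive[nontol]) else NA_real_,
    tol_pos_st = sum(positive[grp == "ST"]),
    tol_pos_cr = sum(positive[grp == "CR"])),
    class = "tol_class")
}

#' @export
print.tol_class <- function(x, ...) {
  cat(sprintf("Cutoff %.3f: sensitivity %.2f, specificity %.2f, TOL-pos ST/CR %d/%d\n",
              x$cutoff, x$sensitivity, x$specificity, x$tol_pos_st, x$tol_pos_cr))
  invisible(x)
}

#' Cohen's kappa for two binary classifications
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` from the 2x2
#' contingency table. When both raters are constant and equal (`p_e = 1`)
#' kappa is defined as 1.
#'
#' @param class_a,class_b Logical (or 0/1) vectors of equal length.
#' @return Object of class `"tol_kappa"`: `kappa` and the contingency
#'   `table`.
#' @export
#' @examples
#' cohens_kappa(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
#'              c(1, 1, 1, 1, 0, 1, 0, 0, 0, 0))$kappa  # 0.6
cohens_kappa <- function(class_a, class_b) {
  a <- as.logical(class_a); b <- as.logical(class_b)
  if (length(a) != length(b)) stop("classifications must have equal length")
  if (anyNA(a) || anyNA(b)) stop("missing values in classifications")
  tab <- table(factor(a, c(FALSE, TRUE)), factor(b, c(FALSE, TRUE)))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps) 1 else (po - pe) / (1 - pe)
  structure(list(kappa = kappa, table = tab), class = "tol_kappa")
}

#' @export
print.tol_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f\n", x$kappa))
  print(x$table)
  invisible(x)
}

#' Influence of immunosuppressive drugs on the predicted probability
#'
#' OLS of the log-odds of the predicted probability of tolerance on the drug
#' regimen dummies, over treated (Non-TOL) T1 samples. A drug-adjusted
#' signature should leave essentially no drug signal in its probabilities
#' (R-squared near zero); unadjusted signatures calibrated on drug-affected
#' genes can show substantial R-squared.
#'
#' @param probs Named predicted probabilities. Clipped to
#'   `[1e-12, 1 - 1e-12]` before the log-odds transform.
#' @param samples Matching `"tol_samples"` table.
#' @param fit_groups,timepoint Fit-set definition (defaults ST/CR at T1).
#' @return Object of class `"tol_druginf"`: `r_squared` and a coefficient
#'   table with Wald p-values.
#' @export
drug_influence <- function(probs, samples, fit_groups = c("ST", "CR"),
                           timepoint = "T1") {
  idx <- match(names(probs), samples$sample_id)
  if (anyNA(idx)) stop("probabilities contain samples absent from the table")
  keep <- samples$group[idx] %in% fit_groups & samples$timepoint[idx] == timepoint
  s <- samples[idx[keep], , drop = FALSE]
  y <- qlogis(pmin(pmax(probs[keep], 1e-12), 1 - 1e-12))
  X <- drug_design(s, intercept = FALSE)
  if (qr(cbind(1, X))$rank < ncol(X) + 1L)
    stop("drug design is rank deficient on the fit set")
  df <- data.frame(y = y, X)
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  cf <- sm$coefficients[-1L, , drop = FALSE]
  structure(list(
    r_squared = sm$r.squared,
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1L],
                              p = cf[, 4L], row.names = NULL),
    n = nrow(s)),
    class = "tol_druginf")
}

#' @export
print.tol_druginf <- function(x, ...) {
  cat(sprintf("Drug influence on log-odds: R^2 = %.3f (n = %d)\n",
              x$r_squared, x$n))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Dose-response model for one drug
#'
#' Replaces the categorical indicator of one drug with its continuous dose
#' (mg/day, zero when off) while keeping the adjustment for the other drug
#' classes. Patients on the paired same-class drug are excluded (CYC when
#' modelling TAC dose and vice versa; AZA when modelling MMF dose and vice
#' versa), as are patients with doses in the top 2.5 centiles (leverage
#' control).
#'
#' @param values Named outcome vector on a continuous scale: -dCt expression
#'   of one gene, or predicted-probability log-odds.
#' @param samples Matching `"tol_samples"` table.
#' @param drug One of `"pred"`, `"cyc"`, `"tac"`, `"aza"`, `"mmf"`.
#' @param fit_groups,timepoint Fit-set definition (defaults ST/CR at T1).
#' @return Named vector `c(slope, se, p, n)`; slope is per mg/day.
#' @export
dose_response <- function(values, samples, drug = c("pred", "cyc", "tac", "aza", "mmf"),
                          fit_groups = c("ST", "CR"), timepoint = "T1") {
  drug <- match.arg(drug)
  paired <- c(pred = NA, cyc = "tac", tac = "cyc", aza = "mmf", mmf = "aza")[[drug]]
  idx <- match(names(values), samples$sample_id)
  if (anyNA(idx)) stop("values contain samples absent from the table")
  s <- samples[idx, , drop = FALSE]
  keep <- s$group %in% fit_groups & s$timepoint == timepoint
  if (!is.na(paired)) keep <- keep & !drug_on(s, paired)
  dose <- s[[paste0("dose_", drug)]]
  dose[!drug_on(s, drug)] <- 0
  if (anyNA(dose[keep]))
    stop("missing dose for sample(s) on ", drug)
  on_doses <- dose[keep & drug_on(s, drug)]
  if (length(on_doses)) {
    top <- stats::quantile(on_doses, 0.975, names = FALSE)
    keep <- keep & dose <= top
  }
  if (sum(keep) < 10L) stop("fewer than 10 samples after exclusions")
  X <- drug_design(s[keep, , drop = FALSE], intercept = FALSE)
  own <- switch(drug, pred = "pred_on", cyc = , tac = c("cni_cyc", "cni_tac"),
                aza = , mmf = c("ap_aza", "ap_mmf"))
  X <- X[, setdiff(colnames(X), own), drop = FALSE]
  X <- X[, apply(X, 2L, function(col) stats::var(col) > 0), drop = FALSE]
  d <- dose[keep]
  if (stats::var(d) == 0) stop("dose has no variance after exclusions")
  df <- data.frame(y = values[keep], dose = d, X)
  fit <- stats::lm(y ~ ., data = df)
  cf <- summary(fit)$coefficients["dose", ]
  c(slope = unname(cf[1L]), se = unname(cf[2L]), p = unname(cf[4L]),
    n = sum(keep))
}

#' Wilcoxon-Mann-Whitney rank-sum comparison
#'
#' Two-sided exact p-value when the combined sample size is at most 25 and
#' there are no ties; tie-corrected normal approximation otherwise.
#'
#' @param values_a,values_b Numeric vectors for the two groups.
#' @return The two-sided p-value.
#' @export
rank_sum_test <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both groups must be non-empty")
  total <- length(values_a) + length(values_b)
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  if (total <= 25L && !ties)
    stats::wilcox.test(values_a, values_b, exact = TRUE)$p.value
  else
    stats::wilcox.test(values_a, values_b, exact = FALSE, correct = TRUE)$p.value
}

#' Median and 2.5th-97.5th centile range
#'
#' The summary convention used for all per-cycle cross-validation statistics
#' (empirical centiles, linear-interpolation quantile convention, R type 7).
#'
#' @param values Numeric vector (at least one value).
#' @return Named vector `c(median, p2.5, p97.5)`.
#' @export
summarize_cycles <- function(values) {
  if (length(values) < 1L) stop("need at least one value")
  q <- stats::quantile(values, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
  c(median = q[1L], p2.5 = q[2L], p97.5 = q[3L])
}
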