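#' Calibrate a gene-expression signature of operational tolerance
#'
#' The package's main fitting function. Runs repeated stratified
#' cross-validation ([run_cv()]) for the given signature on the T1 cohort
#' and aggregates the ensemble into a deployable bundle
#' ([finalize_signature()]): median elastic-net coefficients, drug-adjustment
#' models (full-data fit and cross-validation medians) when the signature is
#' drug-adjusted, and the 50%-sensitivity probability cutoff (median
#' predicted probability among tolerant patients).
#'
#' @param expr Complete samples x genes -dCt matrix (post QC, outlier
#'   recoding and imputation) covering at least the signature genes and all
#'   T1 samples.
#' @param samples Matching `"tol_samples"` clinical table.
#' @param signature A `"tol_signature"` (see [tol_signatures()]) or a
#'   signature name from [tol_signatures()].
#' @param drug_adjusted Calibrate on drug-adjusted residuals? Defaults to the
#'   signature's original form; override to fit the other variant.
#' @param folds,repeats Outer cross-validation geometry (defaults 6 and 100).
#' @param inner_folds,inner_repeats Internal lambda-selection geometry
#'   (defaults 6 and 10; see [cv_config()]).
#' @param lambda_rule Lambda pick per inner repeat, `"min"` or `"1se"`
#'   (see [select_lambda()]).
#' @param seed Master seed for the whole calibration.
#' @return Object of class `"tolsig"` with components `cv` (the
#'   `"tolsig_cv"` ensemble), `bundle` (the `"tol_bundle"`), `probabilities`
#'   (final-model T1 probabilities) and the calibration data references.
#'   Methods: `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `simulate`, `plot`.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_st = 40, n_cr = 10, n_hc = 4,
#'                                            n_t2 = c(tol = 0, st = 0, cr = 0)),
#'                           seed = 7)
#' fit <- tolsig(cohort$expr, cohort$samples, "COMBINED-g7",
#'               repeats = 2, inner_repeats = 2, seed = 7)
#' fit
#' coef(fit)
tolsig <- function(expr, samples, signature,
                   drug_adjusted = NULL,
                   folds = 6, repeats = 100,
                   inner_folds = 6, inner_repeats = 10, seed = 1,
                   lambda_rule = c("min", "1se")) {
  if (is.character(signature)) {
    sigs <- tol_signatures()
    if (!signature %in% names(sigs))
      stop("unknown signature '", signature, "'; see tol_signatures()")
    signature <- sigs[[signature]]
  }
  if (!inherits(signature, "tol_signature")) stop("signature must be a tol_signature")
  if (is.null(drug_adjusted)) drug_adjusted <- signature$drug_adjusted
  config <- cv_config(folds = folds, repeats = repeats,
                      inner_folds = inner_folds, inner_repeats = inner_repeats,
                      seed = seed, lambda_rule = match.arg(lambda_rule))
  cv <- run_cv(expr, samples, signature, config, drug_adjusted = drug_adjusted)
  bundle <- finalize_signature(expr, samples, signature, cv)
  t1 <- samples$timepoint == "T1" & samples$sample_id %in% rownames(expr)
  p1 <- predict_cohort(bundle, expr[samples$sample_id[t1], , drop = FALSE],
                       samples[t1, , drop = FALSE])
  structure(list(call = match.call(), signature = signature,
                 drug_adjusted = drug_adjusted, config = config,
                 cv = cv, bundle = bundle,
                 probabilities = p1,
                 t1_samples = samples[t1, , drop = FALSE]),
            class = "tolsig")
}

#' @export
print.tolsig <- function(x, ...) {
  cat(sprintf("Tolerance signature fit: %s (%s)\n", x$signature$name,
              if (x$drug_adjusted) "drug-adjusted" else "unadjusted"))
  cat(sprintf("  %d cycles x %d folds (alpha = %g), %d T1 patients (%d TOL)\n",
              x$config$repeats, x$config$folds, x$signature$alpha,
              length(x$cv$y), sum(x$cv$y)))
  cat(sprintf("  cutoff = %.3f; genes retained in final model: %d/%d\n",
              x$bundle$cutoff, sum(x$bundle$enet$beta != 0),
              length(x$bundle$enet$beta)))
  invisible(x)
}

#' Per-cycle cross-validated performance of a fitted signature
#'
#' For each cross-validation cycle: the out-of-fold AUC and, at the cycle's
#' own median-TOL cutoff, the specificity. Cycles are summarized with the
#' median and 2.5th-97.5th centile range. Also reports the final model's
#' apparent T1 AUC with DeLong 95% CI, the classification at the bundle
#' cutoff, and gene retention frequencies.
#'
#' @param object A `"tolsig"` fit.
#' @param ... Unused.
#' @return Object of class `"summary.tolsig"`.
#' @export
summary.tolsig <- function(object, ...) {
  cvp <- object$cv$probabilities
  y <- object$cv$y
  auc_cycle <- apply(cvp, 2L, function(p) auc_delong(p, y)[["auc"]])
  spec_cycle <- apply(cvp, 2L, function(p) {
    cut <- stats::median(p[y == 1])
    mean(p[y == 0] <= cut)
  })
  ktr <- object$t1_samples$group %in% c("TOL", "ST", "CR")
  cls <- tol_cutoff_classify(object$probabilities[ktr],
                             object$t1_samples[ktr, , drop = FALSE],
                             cutoff = object$bundle$cutoff)
  final_auc <- auc_delong(object$probabilities[ktr],
                          object$t1_samples$group[ktr] == "TOL")
  structure(list(
    signature = object$signature, drug_adjusted = object$drug_adjusted,
    config = object$config,
    cv_auc = summarize_cycles(auc_cycle),
    cv_specificity = summarize_cycles(spec_cycle),
    final_auc = final_auc, classification = cls,
    retention = retention_frequency(object$cv),
    adjustment = if (!is.null(object$cv$adjustment_r2))
      explained_variability(object$cv$adjustment_r2)),
    class = "summary.tolsig")
}

#' @export
print.summary.tolsig <- function(x, ...) {
  cat(sprintf("Signature %s (%s), %d x %d cross-validation\n",
              x$signature$name,
              if (x$drug_adjusted) "drug-adjusted" else "unadjusted",
              x$config$repeats, x$config$folds))
  cat(sprintf("  CV AUC          %.2f (%.2f-%.2f)\n",
              x$cv_auc[1L], x$cv_auc[2L], x$cv_auc[3L]))
  cat(sprintf("  CV specificity  %.2f (%.2f-%.2f)\n",
              x$cv_specificity[1L], x$cv_specificity[2L], x$cv_specificity[3L]))
  cat(sprintf("  T1 AUC (final)  %.2f (%.2f-%.2f)\n",
              x$final_auc[["auc"]], x$final_auc[["ci_low"]], x$final_auc[["ci_high"]]))
  cat(sprintf("  cutoff %.3f: sensitivity %.2f, specificity %.2f, TOL-pos ST/CR %d/%d\n",
              x$classification$cutoff, x$classification$sensitivity,
              x$classification$specificity,
              x$classification$tol_pos_st, x$classification$tol_pos_cr))
  if (!is.null(x$adjustment)) {
    cat("  drug-explained variability (R^2), top genes:\n")
    top <- x$adjustment[order(-x$adjustment$median), ][seq_len(min(5L, nrow(x$adjustment))), ]
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %-10s %.2f (%.2f-%.2f)\n", top$gene[i], top$median[i],
                  top$p2.5[i], top$p97.5[i]))
  }
  invisible(x)
}

#' @export
coef.tolsig <- function(object, ...) coef(object$bundle$enet)

#' Predict tolerance probabilities for new samples
#'
#' @param object A `"tolsig"` fit.
#' @param expr Samples x genes matrix for the new cohort (e.g. T2 follow-up
#'   samples or healthy controls).
#' @param samples Matching `"tol_samples"` rows.
#' @param type `"response"` (probability), `"link"` (log-odds) or `"class"`
#'   (TOL-positivity at the bundle cutoff: probability strictly above it).
#' @param ... Unused.
#' @return Named numeric (or logical, for `"class"`) vector.
#' @export
predict.tolsig <- function(object, expr, samples,
                           type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  p <- predict_cohort(object$bundle, expr, samples)
  switch(type,
         response = p,
         link = qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)),
         class = p > object$bundle$cutoff)
}

#' @export
fitted.tolsig <- function(object, ...) object$probabilities

#' @export
residuals.tolsig <- function(object, type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  ktr <- object$t1_samples$group %in% c("TOL", "ST", "CR")
  p <- pmin(pmax(object$probabilities[ktr], 1e-12), 1 - 1e-12)
  y <- as.numeric(object$t1_samples$group[ktr] == "TOL")
  if (type == "response") return(y - p)
  sign(y - p) * sqrt(-2 * (y * log(p) + (1 - y) * log(1 - p)))
}

#' @export
simulate.tolsig <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ktr <- object$t1_samples$group %in% c("TOL", "ST", "CR")
  p <- object$probabilities[ktr]
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  rownames(out) <- names(p)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot the cross-validation coefficient ensemble
#'
#' One box per gene summarizing its elastic-net coefficient across the
#' cross-validation models (median, quartiles, 2.5th-97.5th centile
#' whiskers); genes whose final (median) coefficient is zero are drawn in
#' white, retained genes in grey.
#'
#' @param x A `"tolsig"` fit.
#' @param ... Passed to [graphics::boxplot()].
#' @return Invisibly, `x`.
#' @export
plot.tolsig <- function(x, ...) {
  B <- x$cv$coefficients[, -1L, drop = FALSE]
  med <- apply(B, 2L, stats::median)
  cols <- ifelse(med == 0, "white", "grey70")
  graphics::boxplot(B, las = 2, col = cols, outline = FALSE,
                    ylab = "elastic-net coefficient",
                    main = sprintf("%s (%s)", x$signature$name,
                                   if (x$drug_adjusted) "drug-adjusted" else "unadjusted"),
                    ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
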