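#' Gene retention frequency across a cross-validation ensemble
#'
#' The fraction of ensemble models in which a gene kept a non-zero
#' elastic-net coefficient. Under a lasso-leaning penalty (alpha near 1)
#' this is a stability measure: genes that survive the penalty in most
#' random training subsets carry reproducible signal.
#'
#' @param ensemble A `"tolsig_cv"`, a `"tolsig"` fit, or a models x genes
#'   coefficient matrix (intercept column, if present, is ignored).
#' @return Named vector of frequencies in `[0, 1]`, one per gene.
#' @export
retention_frequency <- function(ensemble) {
  B <- if (inherits(ensemble, "tolsig")) ensemble$cv$coefficients
       else if (inherits(ensemble, "tolsig_cv")) ensemble$coefficients
       else as.matrix(ensemble)
  if (nrow(B) == 0L) stop("empty model ensemble")
  B <- B[, colnames(B) != "(Intercept)", drop = FALSE]
  colMeans(B != 0)
}

#' Consensus gene selection by retention frequency
#'
#' Keeps the genes retained in at least `threshold` of the ensemble models
#' (inclusive), in input order.
#'
#' @param frequencies Named frequency vector from [retention_frequency()].
#' @param threshold Minimum retention frequency (default 0.75).
#' @return Character vector of selected genes (possibly empty, with a
#'   warning).
#' @export
select_consensus <- function(frequencies, threshold = 0.75) {
  sel <- names(frequencies)[frequencies >= threshold]
  if (length(sel) == 0L)
    warning("no gene reaches retention frequency ", threshold)
  sel
}

#' Two-stage consensus signature development
#'
#' Stage 1 calibrates a drug-adjusted model over the union gene set with a
#' lasso-leaning penalty (`alpha_select`, default 0.95) so that the penalty
#' performs gene selection inside every cross-validation fold. Stage 2 keeps
#' the genes retained in at least `threshold` of the stage-1 models and
#' refits a fresh drug-adjusted cross-validated model restricted to them
#' with a retention-leaning penalty (`alpha_final`, default 0.05). The
#' parsimonious model is refit from scratch, not subset from stage-1
#' coefficients, so its cross-validated performance is honestly estimated.
#'
#' @inheritParams tolsig
#' @param genes Union gene set (default: the 24-gene union of the five
#'   published signatures).
#' @param housekeeping Reference gene(s) recorded in the stage specs
#'   (default HPRT).
#' @param threshold Retention-frequency threshold (default 0.75).
#' @param alpha_select,alpha_final Elastic-net mixing for the two stages.
#' @return Object of class `"tol_consensus"`: the retention `report`
#'   (frequencies, selected genes, threshold), `fit_all` (stage-1
#'   `"tolsig"`) and `fit_consensus` (stage-2 `"tolsig"`, `NULL` when no
#'   gene is selected).
#' @export
build_combined_pipeline <- function(expr, samples,
                                    genes = tol_signatures()[["COMBINED-all"]]$genes,
                                    housekeeping = "HPRT",
                                    threshold = 0.75,
                                    alpha_select = 0.95, alpha_final = 0.05,
                                    folds = 6, repeats = 100,
                                    inner_folds = 6, inner_repeats = 10,
                                    seed = 1, lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  spec_all <- signature_spec("COMBINED-all", genes, housekeeping,
                             drug_adjusted = TRUE, alpha = alpha_select)
  fit_all <- tolsig(expr, samples, spec_all, folds = folds, repeats = repeats,
                    inner_folds = inner_folds, inner_repeats = inner_repeats,
                    seed = seed, lambda_rule = lambda_rule)
  freq <- retention_frequency(fit_all)
  selected <- select_consensus(freq, threshold)
  report <- list(frequency = freq, selected = selected, threshold = threshold)
  fit_consensus <- NULL
  if (length(selected) > 0L) {
    spec_sel <- signature_spec(sprintf("COMBINED-g%d", length(selected)),
                               selected, housekeeping,
                               drug_adjusted = TRUE, alpha = alpha_final)
    fit_consensus <- tolsig(expr, samples, spec_sel, folds = folds,
                            repeats = repeats, inner_folds = inner_folds,
                            inner_repeats = inner_repeats, seed = seed + 1L)
  }
  structure(list(report = report, fit_all = fit_all,
                 fit_consensus = fit_consensus),
            class = "tol_consensus")
}

#' @export
print.tol_consensus <- function(x, ...) {
  cat(sprintf("Consensus selection at retention >= %.0f%%: %d of %d genes\n",
              100 * x$report$threshold, length(x$report$selected),
              length(x$report$frequency)))
  if (length(x$report$selected))
    cat("  ", paste(x$report$selected, collapse = ", "), "\n")
  if (!is.null(x$fit_consensus)) {
    cat("Parsimonious refit:\n")
    print(x$fit_consensus)
  }
  invisible(x)
}
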