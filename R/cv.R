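#' Stratified fold assignment
#'
#' Within each stratum, a random permutation of members is dealt round-robin
#' (with a random starting offset) into `k` folds, so fold sizes within each
#' stratum differ by at most one. Uses the current RNG state; seed the
#' generator for reproducibility.
#'
#' @param strata Factor (or vector) of stratum labels, e.g. clinical group.
#' @param k Number of folds (>= 2).
#' @return Integer vector of fold ids in 1..k, same length as `strata`.
#' @export
#' @examples
#' set.seed(1)
#' table(stratified_folds(rep(c("TOL", "ST"), c(18, 186)), 6),
#'       rep(c("TOL", "ST"), c(18, 186)))
stratified_folds <- function(strata, k) {
  if (k < 2L) stop("k must be at least 2")
  strata <- as.factor(strata)
  folds <- integer(length(strata))
  for (s in levels(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    offset <- sample.int(k, 1L) - 1L
    folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
  }
  folds
}

#' Cross-validation configuration
#'
#' @param folds Outer folds per cycle (default 6).
#' @param repeats Outer cross-validation cycles (default 100).
#' @param inner_folds Folds for internal lambda selection (default 6).
#' @param inner_repeats Repeats for internal lambda selection. The default
#'   10 keeps calibration desk-scale; set 100 for the full nested search
#'   (structural outputs are unaffected).
#' @param lambda_rule Per-repeat lambda pick inside [select_lambda()]:
#'   `"min"` (default) or the conservative `"1se"`.
#' @param seed Master seed; cycle r uses a seed derived from it, so the 100
#'   cycles are individually reproducible.
#' @return List of class `"cv_config"`.
#' @export
cv_config <- function(folds = 6, repeats = 100, inner_folds = 6,
                      inner_repeats = 10, seed = 1,
                      lambda_rule = c("min", "1se")) {
  stopifnot(folds >= 2, repeats >= 1, inner_folds >= 2, inner_repeats >= 1)
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 inner_folds = as.integer(inner_folds),
                 inner_repeats = as.integer(inner_repeats),
                 seed = as.integer(seed),
                 lambda_rule = match.arg(lambda_rule)),
            class = "cv_config")
}

#' Run repeated stratified cross-validation for one signature
#'
#' Each cycle splits the T1 transplant recipients (TOL, ST, CR; healthy
#' controls are excluded from training and only scored later) into `folds`
#' stratified folds. Per fold, every calibration step is redone on the
#' training subset only: if the signature is drug-adjusted, the per-gene
#' adjustment models are fitted on the training subset's treated (ST/CR)
#' samples and both subsets are residualized; lambda is selected by internal
#' cross-validation on the training subset; the elastic net is fitted and the
#' held-out fold is scored. Each cycle therefore yields one out-of-fold
#' probability per patient, and `folds * repeats` elastic-net models (and as
#' many drug-adjustment models per gene).
#'
#' @param expr Complete samples x genes -dCt matrix containing at least the
#'   signature genes for all T1 samples.
#' @param samples Matching `"tol_samples"` table.
#' @param spec A `"tol_signature"`.
#' @param config A [cv_config()].
#' @param drug_adjusted Override of `spec$drug_adjusted` (to calibrate the
#'   other variant of a signature).
#' @return Object of class `"tolsig_cv"`: out-of-fold `probabilities`
#'   (patients x repeats), `coefficients` (models x (intercept + genes)),
#'   `lambdas`, per-model per-gene `adjustment_r2`, the per-model adjustment
#'   coefficient array `adjustment_coef`, fold assignments, and labels.
#' @export
run_cv <- function(expr, samples, spec, config = cv_config(),
                   drug_adjusted = spec$drug_adjusted) {
  check_expr(expr)
  genes <- spec$genes
  missing_g <- setdiff(genes, colnames(expr))
  if (length(missing_g))
    stop("expression matrix lacks signature gene(s): ",
         paste(missing_g, collapse = ", "))
  keep <- samples$timepoint == "T1" & samples$group %in% c("TOL", "ST", "CR")
  ktr <- samples[keep, , drop = FALSE]
  if (!all(ktr$sample_id %in% rownames(expr)))
    stop("expression matrix lacks rows for some T1 samples")
  X0 <- expr[ktr$sample_id, genes, drop = FALSE]
  if (anyNA(X0)) stop("missing expression values; impute first")
  y <- as.numeric(ktr$group == "TOL")
  n <- nrow(ktr)
  k <- config$folds
  nmod <- k * config$repeats

  probs <- matrix(NA_real_, n, config$repeats,
                  dimnames = list(ktr$sample_id, NULL))
  fold_mat <- matrix(NA_integer_, n, config$repeats,
                     dimnames = list(ktr$sample_id, NULL))
  coefs <- matrix(NA_real_, nmod, length(genes) + 1L,
                  dimnames = list(NULL, c("(Intercept)", genes)))
  lambdas <- numeric(nmod)
  adj_r2 <- if (drug_adjusted)
    matrix(NA_real_, nmod, length(genes), dimnames = list(NULL, genes)) else NULL
  adj_coef <- if (drug_adjusted)
    array(NA_real_, c(nmod, 6L, length(genes)),
          dimnames = list(NULL, c("(Intercept)", DRUG_TERMS), genes)) else NULL

  set.seed(config$seed)
  repeat_seeds <- sample.int(.Machine$integer.max - 1L, config$repeats)
  mi <- 0L
  for (r in seq_len(config$repeats)) {
    set.seed(repeat_seeds[r])
    folds <- stratified_folds(ktr$group, k)
    fold_mat[, r] <- folds
    for (f in seq_len(k)) {
      mi <- mi + 1L
      test <- folds == f
      train <- !test
      if (sum(y[train]) < 1L)
        stop("a training fold contains no TOL sample; use fewer folds")
      if (drug_adjusted) {
        models <- fit_adjustment_models(X0[train, , drop = FALSE],
                                        ktr[train, , drop = FALSE],
                                        genes = genes)
        cfm <- models_to_matrix(models)
        Xtr <- residualize(X0[train, , drop = FALSE], ktr[train, , drop = FALSE], cfm)
        Xte <- residualize(X0[test, , drop = FALSE], ktr[test, , drop = FALSE], cfm)
        adj_r2[mi, ] <- vapply(models, `[[`, 0, "r_squared")
        adj_coef[mi, , ] <- cfm
      } else {
        Xtr <- X0[train, , drop = FALSE]
        Xte <- X0[test, , drop = FALSE]
      }
      sel <- select_lambda(Xtr, y[train], spec$alpha,
                           inner_folds = config$inner_folds,
                           inner_repeats = config$inner_repeats,
                           rule = config$lambda_rule)
      model <- fit_enet(Xtr, y[train], spec$alpha, sel$lambda)
      coefs[mi, ] <- coef(model)
      lambdas[mi] <- sel$lambda
      probs[test, r] <- predict_probability(model, Xte)
    }
  }
  structure(list(probabilities = probs, coefficients = coefs,
                 lambdas = lambdas, adjustment_r2 = adj_r2,
                 adjustment_coef = adj_coef, folds = fold_mat,
                 signature = spec, drug_adjusted = drug_adjusted,
                 config = config, sample_ids = ktr$sample_id, y = y,
                 groups = ktr$group),
            class = "tolsig_cv")
}

#' @export
print.tolsig_cv <- function(x, ...) {
  cat(sprintf("Cross-validation ensemble for %s (%s): %d cycles x %d folds = %d models\n",
              x$signature$name,
              if (x$drug_adjusted) "drug-adjusted" else "unadjusted",
              x$config$repeats, x$config$folds, nrow(x$coefficients)))
  invisible(x)
}

ensemble_adjustment_median <- function(ensemble) {
  if (is.null(ensemble$adjustment_coef)) return(NULL)
  apply(ensemble$adjustment_coef, c(2L, 3L), stats::median)
}

#' Aggregate a cross-validation ensemble into a deployable model bundle
#'
#' The final elastic-net model is the coefficient-wise median of the
#' ensemble. For drug-adjusted signatures the bundle stores two adjustment
#' variants: the full-data fit (all treated T1 samples) and the
#' coefficient-wise medians across the cross-validation fits; the median
#' variant is the default used for prediction. The classification cutoff is
#' the median predicted probability of tolerance over TOL patients at T1
#' under the final model, which fixes sensitivity at 50%.
#'
#' @inheritParams run_cv
#' @param ensemble A `"tolsig_cv"` from [run_cv()].
#' @return Object of class `"tol_bundle"`.
#' @export
finalize_signature <- function(expr, samples, spec, ensemble,
                               drug_adjusted = ensemble$drug_adjusted) {
  genes <- spec$genes
  B <- ensemble$coefficients
  enet <- structure(list(
    alpha = spec$alpha,
    lambda = stats::median(ensemble$lambdas),
    intercept = stats::median(B[, 1L]),
    beta = setNames(apply(B[, -1L, drop = FALSE], 2L, stats::median), genes),
    genes = genes, center = NULL, scale = NULL), class = "enet_model")
  adjustment <- NULL
  if (drug_adjusted) {
    full <- fit_adjustment_models(expr[, genes, drop = FALSE], samples, genes = genes)
    adjustment <- list(full = models_to_matrix(full),
                       median = ensemble_adjustment_median(ensemble),
                       full_r2 = vapply(full, `[[`, 0, "r_squared"))
  }
  bundle <- structure(list(signature = spec, drug_adjusted = drug_adjusted,
                           adjustment = adjustment, enet = enet,
                           adjustment_variant = "median", cutoff = NA_real_),
                      class = "tol_bundle")
  t1 <- samples$timepoint == "T1" & samples$sample_id %in% rownames(expr)
  p <- predict_cohort(bundle, expr[samples$sample_id[t1], genes, drop = FALSE],
                      samples[t1, , drop = FALSE])
  tol <- samples$group[t1] == "TOL"
  if (!any(tol)) stop("no TOL samples at T1; cannot set the cutoff")
  bundle$cutoff <- stats::median(p[tol])
  bundle
}

#' @export
print.tol_bundle <- function(x, ...) {
  cat(sprintf("Model bundle: %s (%s), cutoff = %.3f\n", x$signature$name,
              if (x$drug_adjusted) "drug-adjusted" else "unadjusted", x$cutoff))
  nz <- sum(x$enet$beta != 0)
  cat(sprintf("  final model: intercept %.3f, %d/%d genes with non-zero coefficient\n",
              x$enet$intercept, nz, length(x$enet$beta)))
  invisible(x)
}

#' Score a cohort with a finalized model bundle
#'
#' For drug-adjusted bundles, expression is first residualized with the
#' stored adjustment coefficients (TOL and HC samples are scored with every
#' drug set to off), then the logistic model is applied.
#'
#' @param bundle A `"tol_bundle"`.
#' @param expr Samples x genes matrix containing the bundle's genes.
#' @param samples Matching `"tol_samples"` rows (regimens used for
#'   residualization).
#' @param variant Which stored adjustment coefficients to use: the bundle
#'   default, `"median"` (cross-validation medians) or `"full"` (full-data
#'   fit).
#' @return Named vector of predicted probabilities of tolerance.
#' @export
predict_cohort <- function(bundle, expr, samples,
                           variant = bundle$adjustment_variant) {
  genes <- bundle$signature$genes
  missing_g <- setdiff(genes, colnames(expr))
  if (length(missing_g))
    stop("expression matrix lacks gene(s): ", paste(missing_g, collapse = ", "))
  X <- expr[, genes, drop = FALSE]
  if (bundle$drug_adjusted) {
    variant <- match.arg(variant, c("median", "full"))
    X <- residualize(X, samples, bundle$adjustment[[variant]])
  }
  predict_probability(bundle$enet, X)
}
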