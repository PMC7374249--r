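DRUG_TERMS <- c("pred_on", "cni_cyc", "cni_tac", "ap_aza", "ap_mmf")

#' Drug-regimen design matrix
#'
#' Encodes the immunosuppressive regimen of each sample as five dummy
#' variables with "off" as the reference level for each drug class:
#' `pred_on`, `cni_cyc`, `cni_tac`, `ap_aza`, `ap_mmf`, plus an intercept.
#' TOL and HC samples are off every drug by construction, so all their
#' dummies are zero ("off treatment").
#'
#' @param samples A `"tol_samples"` table.
#' @param intercept Include an intercept column? (default TRUE)
#' @return Numeric matrix with one row per sample.
#' @export
drug_design <- function(samples, intercept = TRUE) {
  X <- cbind(
    pred_on = as.numeric(samples$pred == "on"),
    cni_cyc = as.numeric(samples$cni == "cyc"),
    cni_tac = as.numeric(samples$cni == "tac"),
    ap_aza  = as.numeric(samples$ap == "aza"),
    ap_mmf  = as.numeric(samples$ap == "mmf"))
  rownames(X) <- samples$sample_id
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  X
}

fit_set_idx <- function(samples, fit_groups, timepoint) {
  samples$group %in% fit_groups & samples$timepoint == timepoint
}

#' Fit per-gene drug-adjustment models
#'
#' For each gene, ordinary least squares of -dCt expression on the drug
#' regimen dummies (`-dCt_GENE ~ PRED + CNI + AP`), fitted on treated
#' (Non-TOL) samples at the calibration timepoint. The fitted models support
#' "in-silico drug withdrawal": residuals from these models are expression
#' values freed of the linear drug-therapy component.
#'
#' @param expr Samples x genes -dCt matrix (complete).
#' @param samples Matching `"tol_samples"` table.
#' @param genes Genes to fit (default: all columns of `expr`).
#' @param fit_groups Clinical groups forming the fit set (default ST and CR,
#'   i.e. treated Non-TOL patients).
#' @param timepoint Calibration timepoint (default `"T1"`).
#' @param terms Drug dummies to include (default all five). A reduced design
#'   is useful when only part of the regimen varies in a cohort; absent
#'   terms get coefficient zero at residualization time.
#' @return For `fit_adjustment_models()`, a named list of `"drug_model"`
#'   objects (one per gene); each holds the fitted coefficients, the fit-set
#'   R-squared and the fit-set size. `fit_adjustment()` returns the single
#'   model for one gene.
#' @export
fit_adjustment_models <- function(expr, samples, genes = colnames(expr),
                                  fit_groups = c("ST", "CR"), timepoint = "T1",
                                  terms = DRUG_TERMS) {
  check_expr(expr[, genes, drop = FALSE], complete = FALSE)
  terms <- match.arg(terms, DRUG_TERMS, several.ok = TRUE)
  idx <- fit_set_idx(samples, fit_groups, timepoint)
  idx <- idx & samples$sample_id %in% rownames(expr)
  n_fit <- sum(idx)
  if (n_fit <= length(terms) + 1L)
    stop("drug-adjustment fit set has ", n_fit,
         " samples; need more samples than the ", length(terms) + 1L,
         " model parameters")
  X <- drug_design(samples[idx, , drop = FALSE])[, c("(Intercept)", terms),
                                                 drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("drug design is rank deficient on the fit set; collinear column(s): ",
         paste(dropped, collapse = ", "),
         " (no variation in the corresponding drug indicator)")
  }
  Y <- expr[samples$sample_id[idx], genes, drop = FALSE]
  if (anyNA(Y)) stop("missing expression values on the fit set; impute first")
  fit <- lm.fit(X, Y)
  cf <- as.matrix(fit$coefficients)
  res <- as.matrix(fit$residuals)
  rss <- colSums(res^2)
  tss <- colSums(scale(Y, center = TRUE, scale = FALSE)^2)
  r2 <- pmin(pmax(ifelse(tss > 0, 1 - rss / tss, 0), 0), 1)
  out <- lapply(seq_along(genes), function(j) {
    structure(list(gene = genes[j],
                   coefficients = setNames(cf[, j], colnames(X)),
                   r_squared = unname(r2[j]), n_fit = n_fit),
              class = "drug_model")
  })
  names(out) <- genes
  out
}

#' @rdname fit_adjustment_models
#' @param gene A single gene id.
#' @export
fit_adjustment <- function(expr, samples, gene, fit_groups = c("ST", "CR"),
                           timepoint = "T1", terms = DRUG_TERMS) {
  fit_adjustment_models(expr, samples, genes = gene, fit_groups = fit_groups,
                        timepoint = timepoint, terms = terms)[[1L]]
}

#' @export
print.drug_model <- function(x, ...) {
  cat(sprintf("Drug-adjustment model for %s (n = %d, R^2 = %.3f)\n",
              x$gene, x$n_fit, x$r_squared))
  print(round(x$coefficients, 4))
  invisible(x)
}

# 6 x genes coefficient matrix; terms a model was fitted without are zero
models_to_matrix <- function(models) {
  rows <- c("(Intercept)", DRUG_TERMS)
  out <- matrix(0, 6L, length(models), dimnames = list(rows, names(models)))
  for (g in names(models))
    out[names(models[[g]]$coefficients), g] <- models[[g]]$coefficients
  out
}

#' Residualize expression against fitted drug-adjustment models
#'
#' The drug-adjusted value is the residual: observed -dCt minus the value
#' predicted from the sample's regimen. TOL and HC samples carry all-zero
#' drug dummies, so for them the residual is simply observed minus intercept
#' ("in-silico drug withdrawal"). Applies to every sample passed in,
#' including follow-up (T2) samples.
#'
#' @param expr Samples x genes -dCt matrix.
#' @param samples Matching `"tol_samples"` table (rows for every sample in
#'   `expr`).
#' @param models Per-gene models from [fit_adjustment_models()], or a
#'   6 x genes coefficient matrix with rows `(Intercept)`, `pred_on`,
#'   `cni_cyc`, `cni_tac`, `ap_aza`, `ap_mmf`.
#' @return Matrix of drug-adjusted expression values, same shape as `expr`.
#' @export
residualize <- function(expr, samples, models) {
  check_expr(expr)
  cf <- if (is.matrix(models)) models else models_to_matrix(models)
  missing_m <- setdiff(colnames(expr), colnames(cf))
  if (length(missing_m))
    stop("no adjustment model for gene(s): ", paste(missing_m, collapse = ", "))
  cf <- cf[, colnames(expr), drop = FALSE]
  missing_s <- setdiff(rownames(expr), samples$sample_id)
  if (length(missing_s))
    stop("sample(s) missing from the clinical table: ",
         paste(missing_s, collapse = ", "))
  X <- drug_design(samples[match(rownames(expr), samples$sample_id), , drop = FALSE])
  pred <- X %*% cf
  out <- expr - pred
  attr(out, "layout") <- "residual"
  out
}

#' Summarize drug-explained variability across a model ensemble
#'
#' Per gene, the median and 2.5th-97.5th centile range of the drug-model
#' R-squared across an ensemble of cross-validation fits (one adjustment
#' model per training fold).
#'
#' @param r2 Either a models x genes matrix of R-squared values (as stored in
#'   a [tolsig()] cross-validation ensemble) or a named list of numeric
#'   vectors, one per gene.
#' @return Data frame with columns `gene`, `median`, `p2.5`, `p97.5`.
#' @export
explained_variability <- function(r2) {
  if (is.list(r2) && !is.data.frame(r2)) {
    genes <- names(r2)
    vals <- r2
  } else {
    r2 <- as.matrix(r2)
    genes <- colnames(r2)
    vals <- lapply(seq_len(ncol(r2)), function(j) r2[, j])
  }
  if (length(vals) == 0L || any(!lengths(vals)))
    stop("empty R-squared ensemble")
  summ <- t(vapply(vals, summarize_cycles, numeric(3L)))
  data.frame(gene = genes, median = summ[, 1L], p2.5 = summ[, 2L],
             p97.5 = summ[, 3L], row.names = NULL)
}
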