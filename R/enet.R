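# Elastic-net penalized logistic regression for signature calibration.
# The solver is glmnet; this layer fixes the parameterization used throughout
# the pipeline: per-observation (1/n) likelihood scaling, penalty
# lambda * sum_j [ alpha*|b_j| + (1-alpha)/2 * b_j^2 ], unpenalized intercept,
# internal standardization to unit population SD (divisor n), coefficients
# reported on the input scale.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Largest penalty with a non-null solution
#'
#' For the binomial elastic net, every coefficient is zero once
#' `lambda >= max_j |<x_j_std, y - mean(y)>| / (n * max(alpha, 0.001))`,
#' with predictors standardized to unit population SD. The floor on alpha
#' keeps the bound finite near pure ridge.
#'
#' @param X Numeric n x p predictor matrix.
#' @param y Binary response (1 = tolerant).
#' @param alpha Elastic-net mixing parameter.
#' @return The critical penalty value.
#' @export
lambda_max <- function(X, y, alpha) {
  n <- nrow(X)
  sds <- apply(X, 2L, pop_sd)
  sds[sds == 0] <- 1
  Xs <- scale(X, center = TRUE, scale = sds)
  max(abs(crossprod(Xs, y - mean(y)))) / (n * max(alpha, 0.001))
}

#' Regularization path for lambda selection
#'
#' 100 log-spaced values from [lambda_max()] down to
#' `lambda_max * ratio`, with `ratio` 1e-4 when n > p and 1e-2 otherwise.
#'
#' @inheritParams lambda_max
#' @param nlambda Number of path points.
#' @param ratio Smallest-to-largest lambda ratio; default depends on n vs p.
#' @return Strictly decreasing numeric vector.
#' @export
lambda_path <- function(X, y, alpha, nlambda = 100, ratio = NULL) {
  if (is.null(ratio)) ratio <- if (nrow(X) > ncol(X)) 1e-4 else 1e-2
  lmax <- lambda_max(X, y, alpha)
  exp(seq(log(lmax), log(lmax * ratio), length.out = nlambda))
}

check_Xy <- function(X, y) {
  if (!is.matrix(X) || !is.numeric(X)) stop("X must be a numeric matrix")
  if (any(!is.finite(X))) stop("X contains non-finite values")
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)")
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1 (1 = TOL)")
  if (length(unique(y)) < 2L) stop("y has a single class; both classes required")
  if (nrow(X) < 10L) stop("need at least 10 observations")
  y
}

#' Fit a penalized logistic signature model at fixed (alpha, lambda)
#'
#' Minimizes `-(1/n) * binomial log-likelihood +
#' lambda * sum_j [alpha*|b_j| + (1-alpha)/2 * b_j^2]` with an unpenalized
#' intercept. Predictors are standardized internally (population SD);
#' coefficients are returned on the input scale. The lasso component yields
#' exact zeros; coefficients below 1e-8 in magnitude are reported as 0.
#' At `lambda >= lambda_max(X, y, alpha)` the solution is returned in closed
#' form: all slopes zero and intercept `qlogis(mean(y))`.
#'
#' @inheritParams lambda_max
#' @param lambda Penalty strength (>= 0).
#' @param thresh Solver convergence threshold (passed to glmnet).
#' @return Object of class `"enet_model"`: `alpha`, `lambda`, `intercept`,
#'   named coefficient vector `beta`, genes, and the internal
#'   standardization `center`/`scale`.
#' @export
fit_enet <- function(X, y, alpha, lambda, thresh = 1e-12) {
  y <- check_Xy(X, y)
  if (length(lambda) != 1L || lambda < 0) stop("lambda must be a single value >= 0")
  genes <- colnames(X)
  if (is.null(genes)) genes <- paste0("x", seq_len(ncol(X)))
  sds <- apply(X, 2L, pop_sd)
  mns <- colMeans(X)
  lmax <- lambda_max(X, y, alpha)
  if (lambda >= lmax) {
    beta <- setNames(numeric(ncol(X)), genes)
    intercept <- qlogis(mean(y))
  } else {
    path <- lambda_path(X, y, alpha)
    lams <- sort(unique(c(path[path > lambda], lambda)), decreasing = TRUE)
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                          lambda = lams, standardize = TRUE,
                          thresh = thresh, maxit = 10^7)
    cf <- as.numeric(coef(fit, s = lambda, exact = TRUE, x = X, y = y))
    intercept <- cf[1L]
    beta <- setNames(cf[-1L], genes)
    beta[abs(beta) < 1e-8] <- 0
  }
  structure(list(alpha = alpha, lambda = lambda, intercept = intercept,
                 beta = beta, genes = genes, center = mns, scale = sds),
            class = "enet_model")
}

#' @export
print.enet_model <- function(x, ...) {
  cat(sprintf("Elastic-net logistic model (alpha = %g, lambda = %.5g)\n",
              x$alpha, x$lambda))
  cat(sprintf("  intercept %.4f; %d of %d genes retained\n", x$intercept,
              sum(x$beta != 0), length(x$beta)))
  invisible(x)
}

#' @export
coef.enet_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta)
}

#' Select lambda by repeated internal cross-validation
#'
#' Builds the [lambda_path()] for the data, then for each repeat draws
#' stratified folds and computes the mean out-of-fold binomial deviance per
#' lambda (via `cv.glmnet`); the repeat's selection is the
#' deviance-minimizing lambda and the final selection is the median over
#' repeats.
#'
#' @inheritParams lambda_max
#' @param inner_folds Folds per repeat (default 6).
#' @param inner_repeats Number of repeats (default 100).
#' @param criterion Out-of-fold loss; `"deviance"` (default) or `"auc"`.
#' @param rule Per-repeat pick: `"min"` (deviance-minimizing lambda, the
#'   default for signature calibration) or `"1se"` (largest lambda within
#'   one standard error of the minimum — the conservative choice used in
#'   the consensus selection stage, where the penalty does gene selection
#'   and sparser per-fold models make retention frequencies discriminating).
#' @return Object of class `"lambda_selection"`: the `path`, the per-repeat
#'   `selected` lambdas, and the final `lambda` (their median).
#' @export
select_lambda <- function(X, y, alpha, inner_folds = 6, inner_repeats = 100,
                          criterion = c("deviance", "auc"),
                          rule = c("min", "1se")) {
  y <- check_Xy(X, y)
  criterion <- match.arg(criterion)
  rule <- match.arg(rule)
  path <- lambda_path(X, y, alpha)
  selected <- vapply(seq_len(inner_repeats), function(r) {
    foldid <- stratified_folds(factor(y), inner_folds)
    cvfit <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = alpha,
                               lambda = path, foldid = foldid,
                               type.measure = criterion, standardize = TRUE)
    if (rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  }, 0)
  structure(list(path = path, selected = selected,
                 lambda = stats::median(selected), rule = rule),
            class = "lambda_selection")
}

#' @export
print.lambda_selection <- function(x, ...) {
  cat(sprintf("lambda selection: median %.5g over %d repeats (path %.3g..%.3g)\n",
              x$lambda, length(x$selected), max(x$path), min(x$path)))
  invisible(x)
}

#' Predicted probability of tolerance
#'
#' `p = 1 / (1 + exp(-(b0 + X b)))`. Columns of `X` must match the model's
#' genes (same names, same order).
#'
#' @param model An `"enet_model"`.
#' @param X Samples x genes matrix on the scale the model was fitted on
#'   (-dCt or drug-adjusted residuals).
#' @return Named vector of probabilities in (0, 1).
#' @export
predict_probability <- function(model, X) {
  if (is.null(colnames(X)) || !identical(colnames(X), model$genes))
    stop("gene columns of X do not match the model's genes")
  drop(plogis(model$intercept + X %*% model$beta))
}

#' Coefficient-wise median of an elastic-net ensemble
#'
#' The final signature model: intercept and each gene coefficient are the
#' medians of the corresponding values across the cross-validation ensemble
#' (for even ensembles, the mean of the two middle values); lambda is
#' recorded as the median selected lambda. All models must share gene order
#' and alpha.
#'
#' @param ensemble List of `"enet_model"` objects.
#' @return A single `"enet_model"`.
#' @export
median_model <- function(ensemble) {
  if (length(ensemble) == 0L) stop("empty model ensemble")
  genes <- ensemble[[1L]]$genes
  alpha <- ensemble[[1L]]$alpha
  for (m in ensemble) {
    if (!identical(m$genes, genes)) stop("inconsistent gene order in ensemble")
    if (!identical(m$alpha, alpha)) stop("inconsistent alpha in ensemble")
  }
  B <- vapply(ensemble, function(m) m$beta, numeric(length(genes)))
  B <- matrix(B, nrow = length(genes))
  structure(list(
    alpha = alpha,
    lambda = stats::median(vapply(ensemble, `[[`, 0, "lambda")),
    intercept = stats::median(vapply(ensemble, `[[`, 0, "intercept")),
    beta = setNames(apply(B, 1L, stats::median), genes),
    genes = genes,
    center = ensemble[[1L]]$center, scale = ensemble[[1L]]$scale),
    class = "enet_model")
}
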