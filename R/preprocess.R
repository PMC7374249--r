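#' Compute -dCt relative expression from Ct values
#'
#' -dCt(g, i) = Ct_ref(i) - Ct_g(i) on the log2 scale, so higher values mean
#' more expression. When several housekeeping genes are given, the reference
#' Ct is the arithmetic mean of their Cts, i.e. the geometric mean of their
#' linear expression levels.
#'
#' @param ct Samples x genes Ct matrix (targets and housekeeping genes).
#' @param housekeeping Either a character vector of housekeeping genes used
#'   as the common reference for every target, or a named list mapping each
#'   target gene to its own housekeeping gene vector (as when different
#'   signatures use different references).
#' @return Samples x targets -dCt matrix; housekeeping columns are dropped.
#'   Missing target Cts stay missing; a missing housekeeping Ct is an error.
#' @export
#' @examples
#' ct <- matrix(c(25, 27), 1, dimnames = list("s1", c("GENE", "HPRT")))
#' compute_delta_ct(ct, "HPRT")  # -dCt = 2
compute_delta_ct <- function(ct, housekeeping) {
  check_expr(ct)
  ref_for <- function(hk) {
    missing_hk <- setdiff(hk, colnames(ct))
    if (length(missing_hk))
      stop("housekeeping gene(s) not in matrix: ", paste(missing_hk, collapse = ", "))
    ref <- rowMeans(ct[, hk, drop = FALSE])
    if (anyNA(ref)) {
      bad <- rownames(ct)[is.na(ref)]
      stop("missing housekeeping Ct for sample(s): ", paste(bad, collapse = ", "))
    }
    ref
  }
  if (is.list(housekeeping)) {
    targets <- names(housekeeping)
    missing_t <- setdiff(targets, colnames(ct))
    if (length(missing_t))
      stop("target gene(s) not in matrix: ", paste(missing_t, collapse = ", "))
    out <- vapply(targets,
                  function(g) ref_for(housekeeping[[g]]) - ct[, g],
                  numeric(nrow(ct)))
    if (nrow(ct) == 1L) out <- matrix(out, 1L, dimnames = list(rownames(ct), targets))
  } else {
    ref <- ref_for(housekeeping)
    targets <- setdiff(colnames(ct), housekeeping)
    out <- ref - ct[, targets, drop = FALSE]
  }
  out <- as.matrix(out)
  rownames(out) <- rownames(ct)
  attr(out, "layout") <- "delta_ct"
  out
}

#' Flag genes failing the high-Ct quality screen
#'
#' A gene is flagged when the fraction of samples with Ct strictly above
#' `ct_threshold` exceeds `max_fraction`. Missing Cts count as above the
#' threshold, since non-amplification is exactly the failure mode screened.
#'
#' @param ct Samples x genes Ct matrix.
#' @param ct_threshold Reliability threshold in cycles (default 35, the
#'   conventional limit for quantitative RT-qPCR).
#' @param max_fraction Maximum tolerated fraction of unreliable samples
#'   (default 0.10).
#' @return An object of class `"tol_qc"`: list with per-gene `fraction`,
#'   the `flagged` gene names, and the parameters used.
#' @export
qc_flag_genes <- function(ct, ct_threshold = 35, max_fraction = 0.10) {
  check_expr(ct)
  frac <- colMeans(is.na(ct) | ct > ct_threshold)
  structure(
    list(fraction = frac, flagged = names(frac)[frac > max_fraction],
         ct_threshold = ct_threshold, max_fraction = max_fraction),
    class = "tol_qc")
}

#' @export
print.tol_qc <- function(x, ...) {
  cat(sprintf("QC screen: Ct > %g in more than %.0f%% of samples\n",
              x$ct_threshold, 100 * x$max_fraction))
  if (length(x$flagged)) {
    cat("Flagged genes:\n")
    for (g in x$flagged)
      cat(sprintf("  %s (%.1f%%)\n", g, 100 * x$fraction[g]))
  } else cat("No genes flagged.\n")
  invisible(x)
}

#' Recode extreme expression values to the nearest retained value
#'
#' Per gene, values outside the Tukey outer fences (Q1 - `fence_mult` * IQR,
#' Q3 + `fence_mult` * IQR) are replaced by the most extreme observed value
#' still inside the fence on that side ("next highest or lowest value").
#' Recoding is idempotent, never changes the rank order of non-outliers, and
#' never creates values outside the observed range.
#'
#' @param expr Samples x genes -dCt matrix; each gene needs at least 4
#'   non-missing values.
#' @param fence_mult IQR multiplier for the fences (default 3, the outer
#'   "far out" fence, conservative so only grossly extreme values move).
#' @return Matrix of the same shape with outliers recoded.
#' @export
#' @examples
#' m <- matrix(c(1, 2, 2, 3, 3, 4, 100), ncol = 1,
#'             dimnames = list(paste0("s", 1:7), "G"))
#' recode_outliers(m)[7, ]  # 100 -> 4
recode_outliers <- function(expr, fence_mult = 3) {
  check_expr(expr)
  out <- expr
  for (g in colnames(expr)) {
    x <- expr[, g]
    obs <- x[!is.na(x)]
    if (length(obs) < 4L)
      stop("gene '", g, "' has fewer than 4 non-missing values")
    q <- stats::quantile(obs, c(0.25, 0.75), names = FALSE)
    iqr <- q[2L] - q[1L]
    lo <- q[1L] - fence_mult * iqr
    hi <- q[2L] + fence_mult * iqr
    inside <- obs[obs >= lo & obs <= hi]
    x[!is.na(x) & x > hi] <- max(inside)
    x[!is.na(x) & x < lo] <- min(inside)
    out[, g] <- x
  }
  attr(out, "layout") <- attr(expr, "layout")
  out
}

#' Impute missing expression values with k nearest neighbour genes
#'
#' Gene-space imputation: a missing cell (gene g, sample i) is replaced by
#' the mean value at sample i over the `k` genes closest to g. Distance
#' between two genes is the root mean squared difference of their values
#' across the samples where both are observed (Euclidean distance normalized
#' by overlap, so genes with different missingness patterns are comparable).
#' Only genes observed at sample i are candidate neighbours.
#'
#' @param expr Samples x genes -dCt matrix.
#' @param k Number of neighbour genes (default 10).
#' @return Complete matrix; non-missing entries are untouched.
#' @export
impute_knn <- function(expr, k = 10) {
  check_expr(expr)
  if (!anyNA(expr)) return(expr)
  all_missing <- colSums(!is.na(expr)) == 0L
  if (any(all_missing))
    stop("gene(s) entirely missing: ",
         paste(colnames(expr)[all_missing], collapse = ", "))
  out <- expr
  holes <- which(is.na(expr), arr.ind = TRUE)
  for (h in seq_len(nrow(holes))) {
    i <- holes[h, 1L]; g <- holes[h, 2L]
    target <- expr[, g]
    cand <- setdiff(which(!is.na(expr[i, ])), g)
    if (length(cand) < 1L)
      stop("sample '", rownames(expr)[i], "' has no observed gene to impute from")
    d <- vapply(cand, function(j) {
      both <- !is.na(target) & !is.na(expr[, j])
      if (!any(both)) return(Inf)
      sqrt(mean((target[both] - expr[both, j])^2))
    }, 0)
    usable <- cand[is.finite(d)]
    if (length(usable) < k)
      stop("gene '", colnames(expr)[g], "': fewer than k = ", k,
           " genes with overlapping observations")
    nn <- usable[order(d[is.finite(d)])][seq_len(k)]
    out[i, g] <- mean(expr[i, nn])
  }
  attr(out, "layout") <- attr(expr, "layout")
  out
}
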