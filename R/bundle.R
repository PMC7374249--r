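BUNDLE_SCHEMA_VERSION <- 1L

#' Export a model bundle to JSON
#'
#' Serializes everything needed to score a new cohort: the signature
#' definition, the drug-adjustment coefficients (both the full-data fit and
#' the cross-validation medians, for drug-adjusted signatures), the final
#' elastic-net model, and the probability cutoff. The round trip through
#' [read_model_bundle()] is lossless to full double precision.
#'
#' @param bundle A `"tol_bundle"` from [finalize_signature()] or [tolsig()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_model_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "tol_bundle"))
  adj <- NULL
  if (!is.null(bundle$adjustment)) {
    mat_to_list <- function(m) {
      lapply(setNames(colnames(m), colnames(m)),
             function(g) as.list(setNames(m[, g], rownames(m))))
    }
    adj <- list(full = mat_to_list(bundle$adjustment$full),
                median = mat_to_list(bundle$adjustment$median),
                full_r2 = as.list(bundle$adjustment$full_r2))
  }
  payload <- list(
    schema_version = BUNDLE_SCHEMA_VERSION,
    signature = list(name = bundle$signature$name,
                     genes = bundle$signature$genes,
                     housekeeping = bundle$signature$housekeeping,
                     drug_adjusted = bundle$signature$drug_adjusted,
                     alpha = bundle$signature$alpha),
    drug_adjusted = bundle$drug_adjusted,
    adjustment = adj,
    adjustment_variant = bundle$adjustment_variant,
    enet = list(alpha = bundle$enet$alpha, lambda = bundle$enet$lambda,
                intercept = bundle$enet$intercept,
                beta = as.list(bundle$enet$beta)),
    cutoff = bundle$cutoff)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Import a model bundle from JSON
#'
#' Validates the schema and every structural invariant (gene order of the
#' elastic-net coefficients equals the signature gene order; cutoff strictly
#' inside (0, 1); adjustment coefficient rows complete) before
#' reconstructing the bundle.
#'
#' @param path JSON path written by [write_model_bundle()].
#' @return A `"tol_bundle"`.
#' @export
read_model_bundle <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- c("schema_version", "signature", "drug_adjusted", "enet", "cutoff")
  missing_f <- setdiff(need, names(x))
  if (length(missing_f))
    stop("bundle schema mismatch; missing field(s): ",
         paste(missing_f, collapse = ", "))
  if (!identical(as.integer(x$schema_version), BUNDLE_SCHEMA_VERSION))
    stop("unsupported bundle schema version: ", x$schema_version)
  sig <- signature_spec(x$signature$name,
                        unlist(x$signature$genes),
                        unlist(x$signature$housekeeping),
                        x$signature$drug_adjusted,
                        x$signature$alpha)
  beta <- unlist(x$enet$beta)
  if (!identical(names(beta), sig$genes))
    stop("bundle enet gene order does not match the signature gene order")
  cutoff <- as.numeric(x$cutoff)
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= 1)
    stop("bundle cutoff must be strictly inside (0, 1); got ", x$cutoff)
  lambda <- as.numeric(x$enet$lambda)
  if (!is.finite(lambda) || lambda < 0) stop("bundle lambda must be >= 0")
  enet <- structure(list(alpha = as.numeric(x$enet$alpha), lambda = lambda,
                         intercept = as.numeric(x$enet$intercept),
                         beta = beta, genes = sig$genes,
                         center = NULL, scale = NULL),
                    class = "enet_model")
  adjustment <- NULL
  if (isTRUE(x$drug_adjusted)) {
    if (is.null(x$adjustment))
      stop("drug-adjusted bundle without adjustment coefficients")
    list_to_mat <- function(lst) {
      terms <- c("(Intercept)", DRUG_TERMS)
      m <- vapply(sig$genes, function(g) {
        v <- unlist(lst[[g]])
        if (!identical(names(v), terms))
          stop("bundle adjustment coefficients malformed for gene ", g)
        v
      }, numeric(6L))
      rownames(m) <- terms
      m
    }
    adjustment <- list(full = list_to_mat(x$adjustment$full),
                       median = list_to_mat(x$adjustment$median),
                       full_r2 = unlist(x$adjustment$full_r2))
  }
  structure(list(signature = sig, drug_adjusted = isTRUE(x$drug_adjusted),
                 adjustment = adjustment, enet = enet,
                 adjustment_variant = if (is.null(x$adjustment_variant))
                   "median" else x$adjustment_variant,
                 cutoff = cutoff),
            class = "tol_bundle")
}
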