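#' Read an expression matrix (Ct or -dCt layout) from CSV/TSV
#'
#' Expects a wide table: first column sample id, remaining columns gene
#' symbols, one row per sample. Cells that are empty, `NA` or `Undetermined`
#' (the qPCR instrument's non-amplification flag) are read as missing; the
#' number of missing cells is recorded in the `missing_count` attribute.
#'
#' @param path Path to a delimited file (`.tsv`/`.txt` = tab, else comma).
#' @param layout `"ct"` for raw cycle-threshold values, `"delta_ct"` for
#'   -dCt (log2 relative expression) values.
#' @return Numeric matrix (samples x genes) with attributes `layout` and
#'   `missing_count`.
#' @export
read_expression <- function(path, layout = c("ct", "delta_ct")) {
  layout <- match.arg(layout)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a sample id column plus gene columns")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicated sample id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  genes <- colnames(df)[-1L]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  missing_mask <- raw %in% c("", "NA", "Undetermined") | is.na(raw)
  dim(missing_mask) <- dim(raw)
  vals <- suppressWarnings(as.numeric(raw))
  bad <- !missing_mask & is.na(vals)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-numeric value '", raw[bad][1L], "' at sample '", ids[idx[1L]],
         "', gene '", genes[idx[2L]], "'")
  }
  vals[missing_mask] <- NA_real_
  m <- matrix(vals, nrow = length(ids), dimnames = list(ids, genes))
  if (any(is.finite(m) & (is.infinite(m))))
    stop("non-finite expression values")
  attr(m, "layout") <- layout
  attr(m, "missing_count") <- sum(missing_mask)
  m
}

#' Write an expression matrix to CSV
#'
#' Inverse of [read_expression()]: first column `sample_id`, one gene per
#' remaining column.
#'
#' @param m Numeric samples x genes matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# shared checks for samples x genes matrices
check_expr <- function(m, complete = FALSE) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs sample ids as rownames and genes as colnames")
  if (complete && anyNA(m))
    stop("expression matrix contains missing values; impute first")
  invisible(m)
}
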