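#' Expression matrix container
#'
#' A lightweight container pairing a genes x samples numeric matrix with its
#' measurement scale and platform of origin. Row names are gene identifiers,
#' column names are sample identifiers; both must be unique.
#'
#' @param values Numeric matrix (genes in rows, samples in columns) with
#'   unique, non-empty row and column names.
#' @param scale Measurement scale: `"raw_intensity"` (background-subtracted
#'   microarray intensities), `"raw_count"` (RNA-seq read counts) or `"log2"`.
#' @param platform Platform of origin: `"array"`, `"seq"` or `"merged"`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `scale` and `platform`.
#' @export
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expr_matrix(m, scale = "log2", platform = "array")
#' dim(em)
expr_matrix <- function(values,
                        scale = c("raw_intensity", "raw_count", "log2"),
                        platform = c("array", "seq", "merged")) {
  scale <- match.arg(scale)
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("expression matrix must have at least one gene and one sample")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("gene identifiers (row names) must be present and unique")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("sample identifiers (column names) must be present and unique")
  if (scale == "log2" && platform == "merged" && anyNA(values))
    stop("merged log2 matrices must not contain missing values")
  if (scale == "raw_count" && any(values < 0, na.rm = TRUE))
    stop("raw counts must be non-negative")
  structure(list(values = values, scale = scale, platform = platform),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
as.matrix.expr_matrix <- function(x, ...) x$values

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [scale=%s, platform=%s]\n",
              nrow(x$values), ncol(x$values), x$scale, x$platform))
  invisible(x)
}

#' Gene and sample identifiers of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

# internal: replace values, keeping/overriding tags
em_update <- function(x, values, scale = x$scale, platform = x$platform) {
  out <- expr_matrix(values, scale = scale, platform = platform)
  out
}
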