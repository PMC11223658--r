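#' Expression matrix container
#'
#' A thin S3 wrapper around a numeric genes x samples matrix that records the
#' measurement scale. The scale tag gates downstream operations: count-based
#' filters and median-of-ratios normalization require `"counts"`, the
#' zero-TPM filter and log transform require `"tpm"`, and network construction
#' expects `"log2tpm"`.
#'
#' @param values Numeric matrix, rows = genes, columns = samples. Rownames and
#'   colnames are required and must be unique.
#' @param scale One of `"counts"`, `"tpm"`, `"log2tpm"`.
#' @return An object of class `"expr_matrix"`: the matrix with a `scale_tag`
#'   attribute.
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expression_matrix(m, "counts")
#' expr_scale(em)
#' @export
expression_matrix <- function(values, scale = c("counts", "tpm", "log2tpm")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  dup_g <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_g))
    stop("duplicated gene id(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s))
    stop("duplicated sample id(s): ", paste(unique(dup_s), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression matrix contains non-finite values")
  if (scale %in% c("counts", "tpm") && any(values < 0))
    stop("negative values are not allowed on the '", scale, "' scale")
  structure(values, scale_tag = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expression_matrix
#' @param x An `expr_matrix`.
#' @export
expr_scale <- function(x) {
  tag <- attr(x, "scale_tag")
  if (is.null(tag)) stop("not an expr_matrix: no scale_tag")
  tag
}

.assert_scale <- function(x, scale) {
  if (!identical(expr_scale(x), scale))
    stop("expected an expression matrix on the '", scale,
         "' scale, got '", expr_scale(x), "'")
  invisible(x)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d genes x %d samples\n",
              expr_scale(x), nrow(x), ncol(x)))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

# Subsetting keeps the class and scale tag.
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, scale_tag = attr(x, "scale_tag"),
                     class = c("expr_matrix", "matrix", "array"))
  out
}

#' Read an expression table from TSV
#'
#' Expects a tab-separated file whose header row holds sample identifiers and
#' whose first column holds gene identifiers. Parse failures are reported with
#' row/column context.
#'
#' @param path File path.
#' @param scale Measurement scale tag for the resulting matrix.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, scale = c("counts", "tpm", "log2tpm")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("format error in ", path, ": need a header and at least one gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n_col <- length(header)
  samples <- header[-1L]
  if (length(samples) == 0L) stop("format error in ", path, ": no sample columns")
  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1L]
    stop("format error in ", path, ": row ", bad + 1L, " has ", widths[bad],
         " fields, expected ", n_col)
  }
  genes <- vapply(body, `[[`, character(1), 1L)
  vals <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
  for (r in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[r]][-1L]))
    if (anyNA(v)) {
      c_bad <- which(is.na(v))[1L]
      stop("format error in ", path, ": non-numeric value at row ", r + 1L,
           " (gene ", genes[r], "), column ", samples[c_bad])
    }
    vals[r, ] <- v
  }
  expression_matrix(vals, scale)
}

#' Write an expression matrix as TSV
#'
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table from TSV
#'
#' Validates the fixed design vocabularies: `sex` in {M, F}, `treatment` in
#' {E, NM, NP}. Columns beyond the design columns (e.g. behavior frequencies)
#' are carried through.
#'
#' @param path File path.
#' @return A data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  required <- c("sample_id", "bird_id", "sex", "region", "treatment", "trial")
  missing <- setdiff(required, names(md))
  if (length(missing))
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicated sample_id in metadata")
  bad_sex <- setdiff(unique(md$sex), c("M", "F"))
  if (length(bad_sex)) stop("unknown sex label(s): ", paste(bad_sex, collapse = ", "))
  bad_trt <- setdiff(unique(md$treatment), c("E", "NM", "NP"))
  if (length(bad_trt)) stop("unknown treatment label(s): ", paste(bad_trt, collapse = ", "))
  md
}
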