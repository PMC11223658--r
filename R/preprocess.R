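#' Low-expression filter for differential-expression input
#'
#' Within one (region, sex) stratum of count data, keeps genes that pass both
#' low-expression rules: total counts across the stratum's samples of at least
#' one read per sample on average (total >= n_samples), and a zero count in no
#' more than 10/30 of the samples. The cutoffs are stated for a 30-sample
#' stratum and scale proportionally with stratum size; the zero rule is a
#' strict "more than" (a gene with zeros in exactly 10 of 30 samples is kept).
#'
#' @param m An [expression_matrix()] on the `"counts"` scale, columns already
#'   restricted to one stratum.
#' @return The filtered `expr_matrix`. The dropped genes and the rule that
#'   removed them are attached as attribute `"filter_report"` (a data.frame
#'   with columns gene_id, reason).
#' @export
filter_deg_genes <- function(m) {
  .assert_scale(m, "counts")
  n <- ncol(m)
  total <- rowSums(m)
  zeros <- rowSums(m == 0)
  zero_cutoff <- 10 / 30 * n
  low_total <- total < n            # < 1 count per sample on average
  too_many_zero <- zeros > zero_cutoff
  keep <- !(low_total | too_many_zero)
  reason <- ifelse(low_total, "low_total",
                   ifelse(too_many_zero, "too_many_zeros", ""))
  report <- data.frame(gene_id = rownames(m)[!keep],
                       reason = reason[!keep],
                       stringsAsFactors = FALSE)
  out <- m[keep, , drop = FALSE]
  attr(out, "filter_report") <- report
  out
}

#' Zero-expression filter for network input
#'
#' Removes genes with no expression (TPM = 0) in more than 20/60 of the
#' samples of any region group. The cutoff is stated for 60 samples per region
#' and scales proportionally; the inequality is strict, so a gene with exactly
#' the cutoff number of zeros is retained.
#'
#' @param m An [expression_matrix()] on the `"tpm"` scale.
#' @param region Character vector of region labels, one per column of `m`.
#' @return Filtered `expr_matrix` with attribute `"filter_report"`.
#' @export
filter_wgcna_genes <- function(m, region) {
  .assert_scale(m, "tpm")
  if (length(region) != ncol(m))
    stop("'region' must have one label per sample column")
  if (anyNA(region)) stop("missing region labels")
  keep <- rep(TRUE, nrow(m))
  for (r in unique(region)) {
    sub <- m[, region == r, drop = FALSE]
    cutoff <- 20 / 60 * ncol(sub)
    keep <- keep & (rowSums(sub == 0) <= cutoff)
  }
  report <- data.frame(gene_id = rownames(m)[!keep],
                       reason = rep("too_many_zero_tpm", sum(!keep)),
                       stringsAsFactors = FALSE)
  out <- m[keep, , drop = FALSE]
  attr(out, "filter_report") <- report
  out
}

#' Log2 transform of TPM values
#'
#' @param m An [expression_matrix()] on the `"tpm"` scale.
#' @param pseudocount Positive offset added before taking log2 (default 1). A
#'   pseudocount of 0 is allowed only when every value is strictly positive.
#' @return An `expr_matrix` on the `"log2tpm"` scale.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  .assert_scale(m, "tpm")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (any(unclass(m) + pseudocount <= 0))
    stop("log2 of a non-positive value: increase the pseudocount")
  expression_matrix(log2(unclass(m) + pseudocount), "log2tpm")
}

#' Median-of-ratios size factors and normalization
#'
#' Computes per-sample size factors from count data: a pseudo-reference sample
#' is built as the genewise geometric mean across samples (genes with a zero in
#' any sample are excluded), each sample's size factor is the median over genes
#' of count/reference, and counts are divided by their sample's factor.
#'
#' @param m An [expression_matrix()] on the `"counts"` scale with >= 2 samples.
#' @return A list with `normalized` (an `expr_matrix`, counts scale) and
#'   `size_factors` (named numeric, one per sample).
#' @export
normalize_median_ratios <- function(m) {
  .assert_scale(m, "counts")
  if (ncol(m) < 2L) stop("need at least two samples")
  v <- unclass(m)
  all_pos <- rowSums(v == 0) == 0
  if (!any(all_pos))
    stop("no gene is expressed in all samples; size factors are undefined")
  ref <- exp(rowMeans(log(v[all_pos, , drop = FALSE])))
  sf <- apply(v[all_pos, , drop = FALSE], 2L,
              function(col) stats::median(col / ref))
  normalized <- sweep(v, 2L, sf, "/")
  list(normalized = expression_matrix(normalized, "counts"),
       size_factors = sf)
}

#' PCA embedding of samples
#'
#' Principal components of the samples, computed on genes as variables
#' (centered, unscaled). Provided as plumbing for visualising the overall
#' design structure (regions, sexes, treatments).
#'
#' @param m An `expr_matrix` (any scale).
#' @param n_components Number of components to return.
#' @return A list with `coordinates` (samples x components), `variance_fraction`
#'   (per component, in [0,1]) and `degenerate` (TRUE when total variance is
#'   zero, e.g. all samples identical).
#' @export
pca_embed <- function(m, n_components = 2) {
  if (ncol(m) < 2L) stop("need at least two samples")
  max_k <- min(nrow(m), ncol(m))
  if (n_components > max_k)
    stop("n_components exceeds min(genes, samples) = ", max_k)
  x <- t(unclass(m))
  total_var <- sum(apply(x, 2L, stats::var))
  if (!is.finite(total_var) || total_var <= 0) {
    return(list(coordinates = matrix(0, nrow(x), n_components,
                                     dimnames = list(rownames(x), paste0("PC", seq_len(n_components)))),
                variance_fraction = rep(0, n_components),
                degenerate = TRUE))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  frac <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  list(coordinates = pc$x[, seq_len(n_components), drop = FALSE],
       variance_fraction = frac,
       degenerate = FALSE)
}
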