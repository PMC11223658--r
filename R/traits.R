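#' Module eigengene vs behavior-frequency correlation (NBF test)
#'
#' Pearson correlation between a module eigengene (restricted to the nesting
#' E-group samples of one stratum) and a behavior frequency, with the
#' two-sided P-value from the t-distribution with n - 2 degrees of freedom.
#' Modules whose eigengene correlates significantly with a nesting-action
#' frequency are "nesting behavior frequency" (NBF) modules. P-values are
#' reported raw (no multiplicity adjustment), as is conventional for this
#' screen.
#'
#' @param me_scores Named numeric eigengene scores (sample id -> score), or a
#'   [module_eigengene()] object.
#' @param freq Named numeric behavior frequencies (seconds/hour) for the same
#'   samples.
#' @param trait Trait name recorded in the result.
#' @param alpha Significance level (default 0.05).
#' @return A one-row data.frame: trait, n, r, p, significant.
#' @export
nbf_correlation <- function(me_scores, freq, trait = "frequency", alpha = 0.05) {
  if (inherits(me_scores, "module_eigengene")) me_scores <- me_scores$scores
  common <- intersect(names(me_scores), names(freq))
  if (length(common) < 4L) stop("need at least 4 paired samples")
  x <- me_scores[common]; y <- freq[common]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(data.frame(trait = trait, n = length(common), r = NA_real_,
                      p = NA_real_, significant = NA, stringsAsFactors = FALSE))
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(trait = trait, n = length(common),
             r = unname(ct$estimate), p = ct$p.value,
             significant = ct$p.value < alpha, stringsAsFactors = FALSE)
}

#' Gene significance
#'
#' Pearson correlation between a gene's expression and a trait vector: either
#' a binary nesting state (E = 1 vs a nonnesting group = 0, treated as 0/1
#' numeric, i.e. the point-biserial correlation) or a behavior frequency.
#'
#' @param m Expression matrix.
#' @param trait Named numeric (or 0/1) trait values by sample id.
#' @param gene Gene id.
#' @return Correlation in [-1, 1], or NA for a constant gene or trait.
#' @export
gene_significance <- function(m, trait, gene) {
  common <- intersect(colnames(m), names(trait))
  v <- unclass(m)[gene, common]
  tr <- as.numeric(trait[common])
  if (stats::sd(v) == 0 || stats::sd(tr) == 0) return(NA_real_)
  stats::cor(v, tr)
}

#' Empirical quantile threshold for |GS|
#'
#' The hub-gene GS cutoff is defined as an upper quantile of the |GS| values
#' pooled over a module family (default the 0.99 quantile, i.e. the top 1%).
#' Uses the interpolating empirical quantile (R type 7).
#'
#' @param gs_values Numeric GS values (signs ignored).
#' @param q Quantile in [0, 1] (default 0.99).
#' @return The threshold.
#' @export
gs_quantile_threshold <- function(gs_values, q = 0.99) {
  gs_values <- gs_values[!is.na(gs_values)]
  if (!length(gs_values)) stop("empty GS family")
  unname(stats::quantile(abs(gs_values), probs = q, type = 7))
}

#' Select hub genes by module membership and gene significance
#'
#' A gene is a hub when |MM| > `mm_threshold` and |GS| > `gs_threshold`
#' (both strict). The conventional cutoffs are |MM| > 0.8 together with a
#' top-1% |GS| quantile of the relevant module family.
#'
#' @param mm Named numeric module-membership values by gene.
#' @param gs Named numeric gene-significance values by gene.
#' @param mm_threshold MM cutoff (default 0.8).
#' @param gs_threshold GS cutoff (e.g. from [gs_quantile_threshold()]).
#' @return Data.frame (gene, MM, GS, is_hub), sorted by |GS| descending.
#'   Genes with a missing MM or GS are dropped with a message.
#' @export
select_hub_genes <- function(mm, gs, mm_threshold = 0.8, gs_threshold) {
  if (mm_threshold < 0 || mm_threshold > 1 || gs_threshold < 0 || gs_threshold > 1)
    stop("thresholds must lie in [0, 1]")
  genes <- intersect(names(mm), names(gs))
  mm <- mm[genes]; gs <- gs[genes]
  bad <- is.na(mm) | is.na(gs)
  if (any(bad)) {
    message(sum(bad), " gene(s) skipped (missing MM or GS)")
    mm <- mm[!bad]; gs <- gs[!bad]; genes <- genes[!bad]
  }
  out <- data.frame(gene = genes, MM = unname(mm), GS = unname(gs),
                    is_hub = abs(mm) > mm_threshold & abs(gs) > gs_threshold,
                    stringsAsFactors = FALSE)
  out[order(-abs(out$GS)), , drop = FALSE]
}
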