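#' Load a gene-category map from TSV
#'
#' Reads a two-column TSV (gene_id, category) whose categories come from the
#' fixed vocabulary {neuron_projection, in_situ_neurogenesis,
#' other_neurogenesis}. The composite "neurogenesis" category is derived with
#' [derive_neurogenesis()]; because neuron-projection annotations sit under
#' the neurogenesis branch of the GO hierarchy, a neuron_projection gene also
#' counts as neurogenesis, but neurogenesis genes do not flow back into
#' neuron_projection.
#'
#' @param path TSV path.
#' @return Data.frame (gene_id, category), deduplicated.
#' @export
load_category_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!nrow(df))
    return(data.frame(gene_id = character(0), category = character(0),
                      stringsAsFactors = FALSE))
  if (!all(c("gene_id", "category") %in% names(df)))
    stop("category map needs columns gene_id, category")
  vocab <- c("neuron_projection", "in_situ_neurogenesis", "other_neurogenesis")
  bad <- which(!df$category %in% vocab)
  if (length(bad))
    stop("unknown category '", df$category[bad[1L]], "' at row ", bad[1L] + 1L)
  unique(df[, c("gene_id", "category")])
}

#' Gene set of one category, with the composite neurogenesis rule
#'
#' @param map Category map data.frame (gene_id, category).
#' @param category One of the three base categories or `"neurogenesis"`, the
#'   composite in_situ_neurogenesis + other_neurogenesis + neuron_projection
#'   (the last via the GO-hierarchy rule; see [load_category_map()]).
#' @return Character vector of gene ids.
#' @export
category_genes <- function(map, category) {
  if (category == "neurogenesis") return(derive_neurogenesis(map))
  vocab <- c("neuron_projection", "in_situ_neurogenesis", "other_neurogenesis")
  if (!category %in% vocab) stop("unknown category: ", category)
  unique(map$gene_id[map$category == category])
}

#' @rdname category_genes
#' @export
derive_neurogenesis <- function(map) {
  unique(map$gene_id[map$category %in%
                       c("in_situ_neurogenesis", "other_neurogenesis",
                         "neuron_projection")])
}

#' One-tailed over-representation test
#'
#' Fisher exact test (alternative = greater) asking whether a gene list
#' contains more members of a category than expected from an expressed-gene
#' background: the 2x2 table is (k, K - k; n - k, N - K - n + k) with
#' k = |list ∩ category|, K = |list|, n = |background ∩ category|,
#' N = |background|. Category members outside the background are ignored.
#'
#' @param gene_list Character vector (must be a subset of `background`).
#' @param category_set Character vector of category member gene ids.
#' @param background Character vector of expressed background genes.
#' @param label Optional label for the tested list.
#' @return One-row data.frame: label, k, K, n, N, p, significant (p < 0.05).
#' @export
over_representation_test <- function(gene_list, category_set, background,
                                     label = NA_character_) {
  offenders <- setdiff(gene_list, background)
  if (length(offenders))
    stop("gene list is not a subset of the background: ",
         paste(utils::head(offenders, 5L), collapse = ", "),
         if (length(offenders) > 5L) ", ..." else "")
  background <- unique(background)
  gene_list <- unique(gene_list)
  category_set <- intersect(unique(category_set), background)
  N <- length(background); K <- length(gene_list)
  n <- length(category_set)
  k <- length(intersect(gene_list, category_set))
  tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), 2L, 2L)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  data.frame(label = label, k = k, K = K, n = n, N = N, p = p,
             significant = p < 0.05, stringsAsFactors = FALSE)
}

#' Over-representation of categories across all modules
#'
#' Runs [over_representation_test()] for every module against each requested
#' category and BH-adjusts the P-values across modules within each category
#' family.
#'
#' @param part A [module_partition()].
#' @param map Category map data.frame.
#' @param background Expressed-gene background (defaults to all partitioned
#'   genes).
#' @param categories Categories to test (default neuron_projection and the
#'   composite neurogenesis, with in_situ_neurogenesis as the follow-up).
#' @return Data.frame with one row per module x category: module, category,
#'   k, K, n, N, p, adj_p, significant (adj_p < 0.05).
#' @export
module_over_representation <- function(part, map, background = names(part),
                                       categories = c("neuron_projection",
                                                      "neurogenesis",
                                                      "in_situ_neurogenesis")) {
  mods <- names(module_sizes(part))
  if (!length(mods)) stop("partition contains no modules")
  rows <- list()
  for (cat in categories) {
    cat_set <- category_genes(map, cat)
    for (mod in mods) {
      members <- intersect(names(part)[unclass(part) == mod], background)
      r <- over_representation_test(members, cat_set, background, label = mod)
      names(r)[1L] <- "module"
      r$category <- cat
      rows[[length(rows) + 1L]] <- r
    }
  }
  res <- do.call(rbind, rows)
  res$adj_p <- NA_real_
  for (cat in categories) {
    idx <- res$category == cat
    res$adj_p[idx] <- bh_adjust(res$p[idx])
  }
  res$significant <- res$adj_p < 0.05
  res[, c("module", "category", "k", "K", "n", "N", "p", "adj_p", "significant")]
}
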