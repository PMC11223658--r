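#' Gene-gene correlation matrix
#'
#' Computes the genes x genes correlation matrix over samples, by Pearson
#' correlation or by biweight midcorrelation (bicor). Bicor downweights
#' per-sample outliers: with `med = median(x)` and `mad = median(|x - med|)`,
#' each observation gets weight `w = (1 - u^2)^2` for `u = (x - med)/(9 mad)`,
#' zero outside |u| < 1, and the correlation is the normalized weighted
#' cross-product of the median-centered values. Pairs involving a gene with
#' zero median absolute deviation but nonzero variance fall back to Pearson
#' for that gene; constant genes yield correlation 0 with a warning, and are
#' flagged in the `"constant_genes"` attribute.
#'
#' @param m An [expression_matrix()] (log2 scale expected for network use) or
#'   a plain genes x samples matrix.
#' @param method `"bicor"` or `"pearson"`.
#' @return Symmetric genes x genes matrix with unit diagonal, attribute
#'   `"method"`, and attribute `"constant_genes"` (character vector).
#' @export
correlation_matrix <- function(m, method = c("bicor", "pearson")) {
  method <- match.arg(method)
  x <- unclass(m)
  if (ncol(x) < 3L) stop("need at least 3 samples for correlations")
  constant <- apply(x, 1L, function(v) stats::sd(v) == 0)
  cc <- switch(method,
    pearson = suppressWarnings(stats::cor(t(x))),
    bicor = .bicor_matrix(x)
  )
  if (any(constant)) {
    warning(sum(constant), " constant gene(s); their correlations set to 0")
    cc[constant, ] <- 0
    cc[, constant] <- 0
  }
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  cc <- (cc + t(cc)) / 2  # enforce exact symmetry
  attr(cc, "method") <- method
  attr(cc, "constant_genes") <- rownames(x)[constant]
  cc
}

# Biweight midcorrelation of all gene rows; genes whose MAD is zero use
# ordinary standardization (Pearson fallback) as in standard practice.
.bicor_matrix <- function(x) {
  w_mat <- x
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    med <- stats::median(v)
    madv <- stats::median(abs(v - med))
    if (madv > 0) {
      u <- (v - med) / (9 * madv)
      w <- (1 - u^2)^2 * (abs(u) < 1)
      num <- (v - med) * w
    } else {
      num <- v - mean(v)  # Pearson fallback for this gene
    }
    denom <- sqrt(sum(num^2))
    w_mat[i, ] <- if (denom > 0) num / denom else 0
  }
  out <- tcrossprod(w_mat)
  pmin(pmax(out, -1), 1)
}

#' Signed-hybrid adjacency
#'
#' Raises positive correlations to the soft-thresholding power `beta` and sets
#' negative correlations to zero: `a_ij = max(cor_ij, 0)^beta`. The diagonal
#' is set to zero so that row sums are connectivities.
#'
#' @param cc Correlation matrix (from [correlation_matrix()]).
#' @param beta Soft-thresholding power (integer >= 1; default 6).
#' @return Symmetric adjacency matrix in [0, 1] with zero diagonal and
#'   attribute `"beta"`.
#' @export
signed_hybrid_adjacency <- function(cc, beta = 6) {
  if (beta < 1) stop("beta must be >= 1")
  a <- pmax(cc, 0)^beta
  diag(a) <- 0
  attr(a, "beta") <- beta
  a
}

#' Topological overlap matrix
#'
#' The (unsigned) topological overlap of an adjacency matrix:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu`, and `TOM_ii = 1`. Two genes overlap strongly when they
#' are directly connected and share network neighbors.
#'
#' @param a Adjacency matrix (zero diagonal, values in [0, 1]).
#' @return Symmetric matrix in [0, 1] with unit diagonal.
#' @export
tom_similarity <- function(a) {
  if (any(a < 0) || any(a > 1)) stop("adjacency values must lie in [0, 1]")
  k <- rowSums(a)
  shared <- a %*% a
  kmin <- outer(k, k, pmin)
  tom <- (shared + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Module partition container
#'
#' @param labels Named character vector gene -> module label; the reserved
#'   label `"unassigned"` marks genes outside any module.
#' @return Object of class `"module_partition"`.
#' @export
module_partition <- function(labels) {
  if (is.null(names(labels))) stop("labels must be named by gene id")
  structure(labels, class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  sizes <- module_sizes(x)
  cat(sprintf("module_partition: %d genes, %d modules (+%d unassigned)\n",
              length(x), length(sizes),
              sum(unclass(x) == "unassigned")))
  if (length(sizes)) print(sizes)
  invisible(x)
}

#' @rdname module_partition
#' @param part A `module_partition`.
#' @export
module_sizes <- function(part) {
  tab <- table(unclass(part))
  tab <- tab[names(tab) != "unassigned"]
  sort(tab, decreasing = TRUE)
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a fixed height; clusters smaller than `min_module_size` are labeled
#' `"unassigned"`. Module labels are canonicalized by decreasing size (ties by
#' first gene id in sorted order), so the result is invariant to gene input
#' order.
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @param min_module_size Minimum genes per retained module (default 30).
#' @param cut_height Static cut height on 1 - TOM, in (0, 1); default 0.99.
#' @return A [module_partition()].
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.99) {
  if (cut_height <= 0 || cut_height >= 1) stop("cut_height must be in (0, 1)")
  genes <- rownames(tom)
  if (is.null(genes)) stop("TOM needs gene dimnames")
  ord <- order(genes)
  d <- stats::as.dist(1 - tom[ord, ord])
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  labels <- rep("unassigned", length(cl))
  tab <- table(cl)
  big <- names(tab)[tab >= min_module_size]
  # order retained clusters by size desc, tie-break by first member gene id
  if (length(big)) {
    first_gene <- vapply(big, function(b) sort(genes[ord][cl == b])[1L], character(1))
    big <- big[order(-tab[big], first_gene)]
    for (i in seq_along(big))
      labels[cl == big[i]] <- sprintf("M%d", i)
  }
  names(labels) <- genes[ord]
  module_partition(labels[genes])  # restore input order
}

#' Module eigengene
#'
#' First principal component of the module's gene-standardized expression
#' submatrix over the chosen samples, returned as a unit-norm per-sample
#' score vector. The sign is fixed so that the mean correlation of member
#' genes with the eigengene (mean module membership) is nonnegative. A
#' single-gene module degenerates to the standardized gene itself and is
#' flagged.
#'
#' @param m Expression matrix (log2 scale), genes x samples.
#' @param part A [module_partition()].
#' @param module Module label.
#' @param samples Optional sample ids (columns) to restrict to.
#' @return A list of class `"module_eigengene"`: `module`, `scores` (named,
#'   unit norm), `variance_explained`, `degenerate`.
#' @export
module_eigengene <- function(m, part, module, samples = colnames(m)) {
  genes <- names(part)[unclass(part) == module]
  if (!length(genes)) stop("no genes in module ", module)
  x <- unclass(m)[genes, samples, drop = FALSE]
  xs <- t(scale(t(x)))  # standardize each gene over the samples
  if (any(!is.finite(xs))) {
    keep <- apply(xs, 1L, function(v) all(is.finite(v)))
    xs <- xs[keep, , drop = FALSE]
    if (!nrow(xs)) stop("all genes constant in module ", module)
  }
  if (nrow(xs) == 1L) {
    scores <- xs[1L, ] / sqrt(sum(xs[1L, ]^2))
    return(structure(list(module = module, scores = scores,
                          variance_explained = 1, degenerate = TRUE),
                     class = "module_eigengene"))
  }
  sv <- svd(xs, nu = 0, nv = 1)
  scores <- sv$v[, 1L]
  names(scores) <- colnames(xs)
  if (mean(stats::cor(t(xs), scores)) < 0) scores <- -scores
  structure(list(module = module, scores = scores,
                 variance_explained = sv$d[1L]^2 / sum(sv$d^2),
                 degenerate = FALSE),
            class = "module_eigengene")
}

#' Module membership of one gene
#'
#' Pearson correlation between a gene's expression (over the eigengene's
#' samples) and the module eigengene scores. Constant genes return NA.
#'
#' @param m Expression matrix.
#' @param me A [module_eigengene()].
#' @param gene Gene id.
#' @return Numeric in [-1, 1], or NA for a constant gene.
#' @export
module_membership <- function(m, me, gene) {
  v <- unclass(m)[gene, names(me$scores)]
  if (stats::sd(v) == 0) return(NA_real_)
  stats::cor(v, me$scores)
}

#' Fit a weighted co-expression network and detect modules
#'
#' The full network-construction pipeline: correlation (bicor by default),
#' signed-hybrid soft thresholding, topological overlap, average-linkage
#' clustering with a static cut, module eigengenes and a gene x module
#' membership matrix.
#'
#' @param m An [expression_matrix()] on the `"log2tpm"` scale.
#' @param method Correlation type for the network (default `"bicor"`).
#' @param beta Soft-thresholding power (default 6).
#' @param min_module_size Minimum module size (default 30).
#' @param cut_height Static cut height on 1 - TOM (default 0.99).
#' @param samples Optional sample subset for eigengene computation (defaults
#'   to all samples).
#' @return Object of class `"coexpr_fit"` with elements `partition`,
#'   `eigengenes` (samples x modules score matrix), `variance_explained`,
#'   `membership` (genes x modules MM matrix), `dendrogram` (hclust), and the
#'   call parameters.
#' @seealso [mdc_test()] for differential connectivity on the fitted modules.
#' @export
coexpr_modules <- function(m, method = c("bicor", "pearson"), beta = 6,
                           min_module_size = 30, cut_height = 0.99,
                           samples = colnames(m)) {
  method <- match.arg(method)
  .assert_scale(m, "log2tpm")
  cc <- correlation_matrix(m, method)
  a <- signed_hybrid_adjacency(cc, beta)
  tom <- tom_similarity(a)
  part <- detect_modules(tom, min_module_size, cut_height)
  mods <- names(module_sizes(part))
  genes <- rownames(m)
  me_scores <- NULL
  varex <- numeric(0)
  membership <- NULL
  if (length(mods)) {
    mes <- lapply(mods, function(mod) module_eigengene(m, part, mod, samples))
    me_scores <- do.call(cbind, lapply(mes, `[[`, "scores"))
    colnames(me_scores) <- mods
    varex <- stats::setNames(vapply(mes, `[[`, numeric(1), "variance_explained"), mods)
    xs <- unclass(m)[, samples, drop = FALSE]
    membership <- suppressWarnings(stats::cor(t(xs), me_scores))
  }
  ord <- order(genes)
  hc <- stats::hclust(stats::as.dist(1 - tom[ord, ord]), method = "average")
  structure(list(partition = part, eigengenes = me_scores,
                 variance_explained = varex, membership = membership,
                 dendrogram = hc,
                 params = list(method = method, beta = beta,
                               min_module_size = min_module_size,
                               cut_height = cut_height)),
            class = "coexpr_fit")
}

#' @export
print.coexpr_fit <- function(x, ...) {
  sizes <- module_sizes(x$partition)
  cat(sprintf("coexpr_fit: %d genes, %d modules (%s, beta=%d, cut=%.2f)\n",
              length(x$partition), length(sizes), x$params$method,
              x$params$beta, x$params$cut_height))
  if (length(sizes)) {
    cat("module sizes:\n"); print(sizes)
  }
  invisible(x)
}

#' @export
summary.coexpr_fit <- function(object, ...) {
  sizes <- module_sizes(object$partition)
  out <- data.frame(module = names(sizes), n_genes = as.integer(sizes),
                    variance_explained = object$variance_explained[names(sizes)],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("summary.coexpr_fit", "data.frame")
  out
}

#' @export
plot.coexpr_fit <- function(x, ...) {
  plot(x$dendrogram, labels = FALSE, hang = -1,
       main = "Gene dendrogram (1 - TOM, average linkage)",
       xlab = "", sub = "", ...)
  graphics::abline(h = x$params$cut_height, col = "red", lty = 2)
  invisible(x)
}

#' Export a module partition as TSV
#' @param part A [module_partition()].
#' @param path Output path.
#' @export
write_partition <- function(part, path) {
  utils::write.table(data.frame(gene_id = names(part),
                                module = unclass(part),
                                stringsAsFactors = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
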