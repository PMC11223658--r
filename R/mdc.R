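#' Intra-modular connectivity (kwithin)
#'
#' For every gene in a module, the sum of its Pearson correlations with all
#' other module genes, computed over one group's samples (self-correlation
#' excluded). Genes constant within the group contribute pairwise
#' correlations of 0 (with a warning). The profile's genes are kept in sorted
#' id order so that downstream permutation draws do not depend on input
#' order.
#'
#' @param m Expression matrix (log2 scale), genes x samples.
#' @param part A [module_partition()].
#' @param module Module label.
#' @param samples Sample ids of the group (>= 3).
#' @param group Optional group label stored in the profile.
#' @return Object of class `"connectivity_profile"`: list with `module`,
#'   `group`, `kwithin` (named numeric, one value per module gene).
#' @export
kwithin <- function(m, part, module, samples, group = NA_character_) {
  genes <- sort(names(part)[unclass(part) == module])
  if (length(genes) < 2L) stop("module ", module, " has fewer than 2 genes")
  if (length(samples) < 3L) stop("need at least 3 samples in the group")
  x <- unclass(m)[genes, samples, drop = FALSE]
  constant <- apply(x, 1L, function(v) stats::sd(v) == 0)
  cc <- suppressWarnings(stats::cor(t(x)))
  if (any(constant)) {
    warning(sum(constant), " gene(s) constant within group; correlations set to 0")
  }
  cc[is.na(cc)] <- 0
  diag(cc) <- 0
  structure(list(module = module, group = group,
                 kwithin = rowSums(cc)),
            class = "connectivity_profile")
}

#' Modular differential connectivity ratio
#'
#' `MDC = sum(kwithin in the E group) / sum(kwithin in the reference group)`
#' for one module. MDC > 1 indicates a gain of intra-modular expression
#' connectivity in the E (nesting) group, MDC < 1 a loss. When the
#' denominator's magnitude falls below `denom_floor` the ratio is unstable
#' and NA is returned.
#'
#' @param profile_e Connectivity profile in the E group ([kwithin()]).
#' @param profile_ref Connectivity profile in the reference group (NM or NP).
#' @param denom_floor Minimum |sum of reference kwithin| (default 0.1).
#' @return The MDC ratio, or NA when undefined.
#' @export
mdc <- function(profile_e, profile_ref, denom_floor = 0.1) {
  .check_matched_profiles(profile_e, profile_ref)
  den <- sum(profile_ref$kwithin)
  if (abs(den) < denom_floor) return(NA_real_)
  sum(profile_e$kwithin) / den
}

.check_matched_profiles <- function(a, b) {
  if (!identical(a$module, b$module))
    stop("profiles are for different modules")
  if (!identical(names(a$kwithin), names(b$kwithin)))
    stop("profiles cover different gene sets")
  invisible(NULL)
}

#' Permutation test for MDC gain and loss
#'
#' Builds the null by label-swapping kwithin values between the two groups:
#' in each of `M` permutations every gene's (E, reference) kwithin pair is
#' independently swapped with probability 1/2 (`scheme = "paired"`), or the
#' pooled 2n values are reshuffled into two groups (`scheme = "pooled"`), and
#' the MDC ratio is recomputed. The P-values follow the strict-inequality
#' count rule
#' `p_gain = 1 - (1/M) * #\{MDC_obs > MDC_p\}` and
#' `p_loss = 1 - (1/M) * #\{MDC_obs < MDC_p\}`.
#' Permutations with an unstable denominator are dropped; more than 1% of
#' them is an error.
#'
#' @param profile_e,profile_ref Matched [kwithin()] profiles.
#' @param M Number of permutations (default 10000; < 100 warns).
#' @param seed Optional integer seed (the caller may instead manage the RNG
#'   stream).
#' @param scheme Permutation scheme, `"paired"` (default) or `"pooled"`.
#' @param denom_floor Passed to [mdc()].
#' @param plus_one If TRUE, apply the (+1)/(M+1) finite-sample correction
#'   (off by default, matching the count formula above).
#' @return List with `mdc` (observed), `p_gain`, `p_loss`, `M` (effective
#'   permutation count), `n_dropped`.
#' @export
mdc_permutation_test <- function(profile_e, profile_ref, M = 10000,
                                 seed = NULL,
                                 scheme = c("paired", "pooled"),
                                 denom_floor = 0.1, plus_one = FALSE) {
  scheme <- match.arg(scheme)
  .check_matched_profiles(profile_e, profile_ref)
  if (M < 100) warning("M < 100 permutations gives a coarse P-value")
  if (!is.null(seed)) set.seed(seed)
  ke <- profile_e$kwithin
  kr <- profile_ref$kwithin
  obs <- mdc(profile_e, profile_ref, denom_floor)
  if (is.na(obs)) stop("observed MDC undefined (reference sum below floor)")
  g <- length(ke)
  if (scheme == "paired") {
    swap <- matrix(stats::runif(g * M) < 0.5, g, M)
    num <- sum(ke) + crossprod(swap, kr - ke)[, 1L]
    den <- sum(kr) + crossprod(swap, ke - kr)[, 1L]
  } else {
    pool <- c(ke, kr)
    num <- den <- numeric(M)
    for (p in seq_len(M)) {
      idx <- sample.int(2L * g, g)
      num[p] <- sum(pool[idx])
      den[p] <- sum(pool[-idx])
    }
  }
  ok <- abs(den) >= denom_floor
  if (mean(!ok) > 0.01)
    stop("MDC undefined in more than 1% of permutations; ",
         "the reference connectivity is too close to zero")
  mdc_p <- num[ok] / den[ok]
  m_eff <- length(mdc_p)
  if (plus_one) {
    p_gain <- (sum(obs <= mdc_p) + 1) / (m_eff + 1)
    p_loss <- (sum(obs >= mdc_p) + 1) / (m_eff + 1)
  } else {
    p_gain <- 1 - sum(obs > mdc_p) / m_eff
    p_loss <- 1 - sum(obs < mdc_p) / m_eff
  }
  list(mdc = obs, p_gain = p_gain, p_loss = p_loss,
       M = m_eff, n_dropped = sum(!ok))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment over one family of
#' P-values.
#'
#' @param p Numeric vector of P-values in [0, 1].
#' @return Adjusted P-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) stop("empty P-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("P-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify a module's differential connectivity
#'
#' A module shows a significant gain of connectivity when its BH-adjusted
#' gain P-value is below `alpha` and MDC > `gain_threshold` (default 2), and
#' a significant loss when the adjusted loss P-value is below `alpha` and
#' MDC < `loss_threshold` (default 0.5) — i.e. at least a twofold
#' connectivity difference in either direction. Anything else, including an
#' undefined MDC, is `"none"`.
#'
#' @param mdc_value Observed MDC (may be NA).
#' @param adj_p_gain,adj_p_loss BH-adjusted permutation P-values.
#' @param gain_threshold,loss_threshold MDC cutoffs (default 2 and 0.5).
#' @param alpha Significance level (default 0.05).
#' @return `"gain"`, `"loss"`, or `"none"`.
#' @export
classify_mdc <- function(mdc_value, adj_p_gain, adj_p_loss,
                         gain_threshold = 2, loss_threshold = 0.5,
                         alpha = 0.05) {
  if (is.na(mdc_value)) return("none")
  if (!is.na(adj_p_gain) && adj_p_gain < alpha && mdc_value > gain_threshold)
    return("gain")
  if (!is.na(adj_p_loss) && adj_p_loss < alpha && mdc_value < loss_threshold)
    return("loss")
  "none"
}

#' Modular differential connectivity test across strata and comparisons
#'
#' The package's central fit: for every module, (region, sex) stratum and
#' treatment comparison, computes kwithin profiles in the E group and the
#' reference group, the MDC ratio, gain/loss permutation P-values,
#' BH-adjusts within each (stratum x comparison x direction) family over its
#' modules, and classifies gains and losses at the standard thresholds.
#'
#' @param m Expression matrix (log2 scale), genes x samples.
#' @param metadata Sample metadata with columns sample_id, sex, region,
#'   treatment matching the columns of `m`.
#' @param part A [module_partition()] (e.g. from [coexpr_modules()]).
#' @param comparisons Character vector of comparisons, `"E-NM"` and/or
#'   `"E-NP"`.
#' @param M Permutations per module (default 10000).
#' @param seed Master seed controlling all permutation draws.
#' @param scheme Permutation scheme, see [mdc_permutation_test()].
#' @param denom_floor Denominator floor for the ratio.
#' @param bh_scope `"stratum_comparison"` (default; one BH family per stratum
#'   x comparison x direction) or `"global"` (one family per direction over
#'   everything).
#' @param gain_threshold,loss_threshold,alpha Classification cutoffs.
#' @param min_group_size Minimum samples per group (default 3).
#' @return Object of class `"mdc_fit"`; `as.data.frame()` yields one row per
#'   module x stratum x comparison with columns module, region, sex,
#'   comparison, n_genes, mdc, p_gain, p_loss, adj_p_gain, adj_p_loss,
#'   classification, M.
#' @export
mdc_test <- function(m, metadata, part,
                     comparisons = c("E-NM", "E-NP"),
                     M = 10000, seed = 1L,
                     scheme = c("paired", "pooled"),
                     denom_floor = 0.1,
                     bh_scope = c("stratum_comparison", "global"),
                     gain_threshold = 2, loss_threshold = 0.5, alpha = 0.05,
                     min_group_size = 3L) {
  scheme <- match.arg(scheme)
  bh_scope <- match.arg(bh_scope)
  bad_cmp <- setdiff(comparisons, c("E-NM", "E-NP"))
  if (length(bad_cmp)) stop("unknown comparison(s): ", paste(bad_cmp, collapse = ", "))
  md <- metadata[metadata$sample_id %in% colnames(m), , drop = FALSE]
  mods <- sort(names(module_sizes(part)))
  if (!length(mods)) stop("partition contains no modules")
  set.seed(seed)
  rows <- list()
  for (region in sort(unique(md$region))) {
    for (sex in sort(unique(md$sex))) {
      in_stratum <- md$region == region & md$sex == sex
      e_samples <- md$sample_id[in_stratum & md$treatment == "E"]
      for (cmp in comparisons) {
        ref_grp <- sub("^E-", "", cmp)
        ref_samples <- md$sample_id[in_stratum & md$treatment == ref_grp]
        if (length(e_samples) < min_group_size ||
            length(ref_samples) < min_group_size) next
        for (mod in mods) {
          pe <- kwithin(m, part, mod, e_samples, group = "E")
          pr <- kwithin(m, part, mod, ref_samples, group = ref_grp)
          obs <- mdc(pe, pr, denom_floor)
          if (is.na(obs)) {
            rows[[length(rows) + 1L]] <- data.frame(
              module = mod, region = region, sex = sex, comparison = cmp,
              n_genes = length(pe$kwithin), mdc = NA_real_,
              p_gain = NA_real_, p_loss = NA_real_, M = NA_integer_,
              stringsAsFactors = FALSE)
            next
          }
          pt <- mdc_permutation_test(pe, pr, M = M, scheme = scheme,
                                     denom_floor = denom_floor)
          rows[[length(rows) + 1L]] <- data.frame(
            module = mod, region = region, sex = sex, comparison = cmp,
            n_genes = length(pe$kwithin), mdc = pt$mdc,
            p_gain = pt$p_gain, p_loss = pt$p_loss, M = pt$M,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) stop("no stratum had enough samples in both groups")
  res <- do.call(rbind, rows)
  fam <- if (bh_scope == "stratum_comparison")
    interaction(res$region, res$sex, res$comparison, drop = TRUE)
  else factor(rep("all", nrow(res)))
  res$adj_p_gain <- NA_real_
  res$adj_p_loss <- NA_real_
  for (f in levels(fam)) {
    idx <- which(fam == f & !is.na(res$p_gain))
    if (length(idx)) {
      res$adj_p_gain[idx] <- bh_adjust(res$p_gain[idx])
      res$adj_p_loss[idx] <- bh_adjust(res$p_loss[idx])
    }
  }
  res$classification <- mapply(classify_mdc, res$mdc, res$adj_p_gain,
                               res$adj_p_loss,
                               MoreArgs = list(gain_threshold = gain_threshold,
                                               loss_threshold = loss_threshold,
                                               alpha = alpha))
  structure(list(results = res,
                 params = list(comparisons = comparisons, M = M, seed = seed,
                               scheme = scheme, denom_floor = denom_floor,
                               bh_scope = bh_scope,
                               gain_threshold = gain_threshold,
                               loss_threshold = loss_threshold, alpha = alpha)),
            class = "mdc_fit")
}

#' @export
as.data.frame.mdc_fit <- function(x, ...) x$results

#' @export
print.mdc_fit <- function(x, ...) {
  res <- x$results
  cat(sprintf("mdc_fit: %d module x stratum x comparison tests (M = %d, scheme = %s)\n",
              nrow(res), x$params$M, x$params$scheme))
  cat(sprintf("  gain: %d   loss: %d   none: %d\n",
              sum(res$classification == "gain"),
              sum(res$classification == "loss"),
              sum(res$classification == "none")))
  sig <- res[res$classification != "none", , drop = FALSE]
  if (nrow(sig)) {
    cat("significant modules:\n")
    print(sig[, c("module", "region", "sex", "comparison", "mdc",
                  "adj_p_gain", "adj_p_loss", "classification")],
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.mdc_fit <- function(object, ...) {
  res <- object$results
  agg <- stats::aggregate(list(n = res$module),
                          by = list(region = res$region, sex = res$sex,
                                    comparison = res$comparison,
                                    classification = res$classification),
                          FUN = length)
  agg[order(agg$region, agg$sex, agg$comparison), ]
}

#' @export
plot.mdc_fit <- function(x, ...) {
  res <- x$results[!is.na(x$results$mdc), , drop = FALSE]
  cols <- c(gain = "firebrick", loss = "steelblue", none = "grey70")
  graphics::plot(log2(res$mdc),
                 col = cols[res$classification], pch = 19,
                 xlab = "module x stratum x comparison",
                 ylab = "log2 MDC", main = "Modular differential connectivity", ...)
  graphics::abline(h = log2(c(0.5, 1, 2)), lty = c(2, 1, 2), col = "grey40")
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19, bty = "n")
  invisible(x)
}

#' Write MDC results as TSV
#' @param fit An `mdc_fit`.
#' @param path Output path.
#' @export
write_mdc_results <- function(fit, path) {
  res <- fit$results
  res$seed <- fit$params$seed
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
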