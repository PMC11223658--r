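#' Action frequency in seconds per hour
#'
#' Converts per-second occurrence annotations of one action over a recording
#' window into a frequency: occurrence-seconds x 3600 / recording-seconds.
#' Recordings are at most 80 minutes (4800 s); shortened recordings are
#' normalized by their actual length.
#'
#' @param occurrences Either a 0/1 per-second indicator vector or a single
#'   occurrence-second count.
#' @param recording_seconds Recording length in seconds (> 0, <= 4800).
#' @return Frequency in [0, 3600] seconds/hour.
#' @export
action_frequency <- function(occurrences, recording_seconds) {
  if (recording_seconds <= 0) stop("zero-length recording")
  if (recording_seconds > 4800) stop("recording longer than 80 minutes")
  n <- if (length(occurrences) > 1L) {
    if (!all(occurrences %in% c(0, 1)))
      stop("per-second indicators must be 0/1")
    sum(occurrences)
  } else occurrences
  if (n < 0 || n > recording_seconds)
    stop("occurrence seconds outside [0, recording length]")
  n * 3600 / recording_seconds
}

#' Read per-second action annotations and build a frequency table
#'
#' Input TSV columns: bird_id, action, second (1-based second index in the
#' recording). Optionally a per-bird recording length table overrides the
#' default 4800 s window.
#'
#' @param path Annotation TSV path.
#' @param recording_seconds Default recording length, or a named vector by
#'   bird_id.
#' @return Data.frame: bird_id plus one frequency column per action.
#' @export
read_action_records <- function(path, recording_seconds = 4800) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("bird_id", "action", "second") %in% names(df)))
    stop("annotation file needs columns bird_id, action, second")
  birds <- sort(unique(df$bird_id))
  actions <- sort(unique(df$action))
  len_of <- function(b) {
    if (length(recording_seconds) > 1L) {
      if (is.null(names(recording_seconds)) || !b %in% names(recording_seconds))
        stop("no recording length for bird ", b)
      recording_seconds[[b]]
    } else recording_seconds
  }
  out <- data.frame(bird_id = birds, stringsAsFactors = FALSE)
  for (a in actions) {
    out[[a]] <- vapply(birds, function(b) {
      secs <- unique(df$second[df$bird_id == b & df$action == a])
      action_frequency(length(secs), len_of(b))
    }, numeric(1))
  }
  out
}

# Mann-Whitney U statistic of x vs y (ties counted half).
.u_statistic <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exact two-sided P by enumeration of all group-A assignments of the pooled
# values: P(U <= min(U, U')) + P(U >= max(U, U')), U' = nA*nB - U. Uses the
# midrank identity U_A = (sum of group-A ranks) - nA(nA+1)/2 so the whole
# enumeration is one matrix reduction.
.mw_exact_p <- function(x, y) {
  pool <- c(x, y)
  n <- length(pool); na <- length(x)
  u_obs <- .u_statistic(x, y)
  u_lo <- min(u_obs, na * length(y) - u_obs)
  u_hi <- max(u_obs, na * length(y) - u_obs)
  r <- rank(pool)
  idx <- utils::combn(n, na)
  us <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
  eps <- 1e-9
  (sum(us <= u_lo + eps) + sum(us >= u_hi - eps)) / ncol(idx)
}

# Normal approximation with tie correction (no continuity correction).
.mw_approx_p <- function(x, y) {
  na <- length(x); nb <- length(y); n <- na + nb
  u <- .u_statistic(x, y)
  ties <- table(c(x, y))
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u - na * nb / 2) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

#' Mann-Whitney U test between two treatment groups
#'
#' Two-sided test of one action's frequency between a pair of treatment
#' groups within one sex. With at most 8 birds per group the P-value is exact
#' (full enumeration of group assignments, ties handled by midranking);
#' larger groups use the normal approximation with tie correction. When both
#' groups are a single identical constant the P-value is 1 with a flag.
#'
#' @param freq Bird-level frequency table (columns bird_id, sex, treatment,
#'   plus one column per action), e.g. from [bird_frequencies()].
#' @param action Action column name.
#' @param sex `"M"` or `"F"`.
#' @param pair Length-2 character vector of treatments, e.g. `c("E", "NM")`.
#' @return One-row data.frame: action, sex, comparison, n_a, n_b, U, p,
#'   method, degenerate.
#' @export
compare_treatments <- function(freq, action, sex, pair) {
  if (!action %in% names(freq)) stop("unknown action column: ", action)
  a <- freq[[action]][freq$sex == sex & freq$treatment == pair[1L]]
  b <- freq[[action]][freq$sex == sex & freq$treatment == pair[2L]]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("empty group in comparison")
  u <- .u_statistic(a, b)
  degenerate <- length(unique(c(a, b))) == 1L
  if (degenerate) {
    p <- 1; method <- "degenerate"
  } else if (length(a) <= 8L && length(b) <= 8L) {
    p <- .mw_exact_p(a, b); method <- "exact"
  } else {
    p <- .mw_approx_p(a, b); method <- "normal"
  }
  data.frame(action = action, sex = sex,
             comparison = paste(pair, collapse = "-"),
             n_a = length(a), n_b = length(b), U = u, p = min(p, 1),
             method = method, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Collapse sample metadata to one row per bird
#'
#' Behavior frequencies are bird-level quantities; sample metadata repeats
#' them once per brain region. Deduplicates by bird_id.
#'
#' @param metadata Sample metadata with behavior frequency columns.
#' @param actions Frequency column names (default: the three nesting actions).
#' @return Data.frame bird_id, sex, treatment, trial + frequency columns.
#' @export
bird_frequencies <- function(metadata,
                             actions = intersect(c("fetch_material_male",
                                                   "stay_nestbox_male",
                                                   "stay_nestbox_female"),
                                                 names(metadata))) {
  keep <- c("bird_id", "sex", "treatment", "trial", actions)
  out <- unique(metadata[, intersect(keep, names(metadata)), drop = FALSE])
  if (anyDuplicated(out$bird_id))
    stop("inconsistent per-bird frequencies across samples")
  out
}

#' All pairwise treatment comparisons with BH adjustment
#'
#' Runs [compare_treatments()] for every action x treatment pair within each
#' sex and BH-adjusts the P-values within the sex's family (all actions x all
#' pairs), the family the multiplicity statement defines.
#'
#' @param freq Bird-level frequency table ([bird_frequencies()]).
#' @param actions Action column names.
#' @param pairs List of treatment pairs (default E-NM, E-NP, NM-NP).
#' @return Data.frame with adj_p added.
#' @export
behavior_tests <- function(freq, actions,
                           pairs = list(c("E", "NM"), c("E", "NP"),
                                        c("NM", "NP"))) {
  rows <- list()
  for (sex in sort(unique(freq$sex))) {
    sex_rows <- list()
    for (a in actions) {
      if (all(is.na(freq[[a]][freq$sex == sex]))) next
      for (pr in pairs)
        sex_rows[[length(sex_rows) + 1L]] <- compare_treatments(freq, a, sex, pr)
    }
    if (!length(sex_rows)) next
    sr <- do.call(rbind, sex_rows)
    sr$adj_p <- bh_adjust(sr$p)
    rows[[length(rows) + 1L]] <- sr
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Correlation between nest-material usage and action frequency
#'
#' Pearson correlation (two-sided t-based P) between per-pair nest-material
#' usage in grams and an action frequency, across nesting-group pairs.
#' Listed pairs (e.g. one that exhausted its material allotment) are excluded
#' before testing.
#'
#' @param usage Named numeric grams by pair/bird id.
#' @param freq Named numeric frequency by the same ids.
#' @param exclude Ids to drop (logged via message).
#' @return One-row data.frame: n, r, p, excluded.
#' @export
material_usage_correlation <- function(usage, freq, exclude = character(0)) {
  dropped <- intersect(names(usage), exclude)
  if (length(dropped))
    message("excluding pair(s): ", paste(dropped, collapse = ", "))
  usage <- usage[setdiff(names(usage), exclude)]
  common <- intersect(names(usage), names(freq))
  if (length(common) < 4L) stop("need at least 4 pairs after exclusions")
  x <- usage[common]; y <- freq[common]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(data.frame(n = length(common), r = NA_real_, p = NA_real_,
                      excluded = paste(dropped, collapse = ","),
                      stringsAsFactors = FALSE))
  ct <- stats::cor.test(x, y)
  data.frame(n = length(common), r = unname(ct$estimate), p = ct$p.value,
             excluded = paste(dropped, collapse = ","),
             stringsAsFactors = FALSE)
}
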