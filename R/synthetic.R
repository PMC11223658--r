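#' Study design for the synthetic generator
#'
#' Describes a fully crossed stratified design: every (trial, treatment, sex,
#' region) combination yields exactly one sample, so the total sample count is
#' `n_trials * |treatments| * |sexes| * |regions|`. The defaults reproduce the
#' emulated study layout: 10 trials x 3 treatments (E = mates + nest material,
#' NM = mates without material, NP = material without mates) x 2 sexes x 5
#' brain regions = 300 samples, i.e. 10 samples per treatment within each
#' (region, sex) stratum of 30.
#'
#' @param n_trials Number of experimental trials (>= 2).
#' @param treatments Treatment labels.
#' @param sexes Sex labels.
#' @param regions Brain-region labels.
#' @param seed Integer seed recorded with the design.
#' @return An object of class `"sim_design"`.
#' @export
sim_design <- function(n_trials = 10,
                       treatments = c("E", "NM", "NP"),
                       sexes = c("M", "F"),
                       regions = c("AMP", "SBN", "DNP", "PM", "Others"),
                       seed = 1L) {
  if (n_trials < 2) stop("invalid config: n_trials must be >= 2")
  if (!length(treatments)) stop("invalid config: empty treatment list")
  if (!length(regions)) stop("invalid config: empty region list")
  if (!length(sexes)) stop("invalid config: empty sex list")
  structure(list(n_trials = as.integer(n_trials),
                 treatments = treatments, sexes = sexes, regions = regions,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  n <- x$n_trials * length(x$treatments) * length(x$sexes) * length(x$regions)
  cat(sprintf("sim_design: %d trials x %d treatments x %d sexes x %d regions = %d samples\n",
              x$n_trials, length(x$treatments), length(x$sexes),
              length(x$regions), n))
  invisible(x)
}

#' Specification of one planted co-expression module
#'
#' Genes in the module load on a shared latent factor; the effective loading
#' in treatment `t` is `base_loading * multipliers[t]`, which gives an
#' expected within-module Pearson correlation of
#' `loading(t)^2 / (loading(t)^2 + noise_sd^2)` in that treatment. A
#' treatment-dependent multiplier therefore plants a gain or loss of
#' intra-modular connectivity.
#'
#' @param module_id Module label.
#' @param n_genes Number of member genes.
#' @param base_loading Base factor loading in (0, 1] (shared by all members).
#' @param multipliers Named nonnegative vector of per-treatment loading
#'   multipliers; must cover every treatment in the design.
#' @param trait_coupling Coupling in [-1, 1] between the module factor and a
#'   behavior frequency in E-group samples (used by [generate_behavior()]).
#' @return An object of class `"sim_module"`.
#' @export
sim_module <- function(module_id, n_genes, base_loading = 0.7,
                       multipliers = c(E = 1, NM = 1, NP = 1),
                       trait_coupling = 0) {
  if (n_genes < 1) stop("invalid config: n_genes must be >= 1")
  if (base_loading <= 0 || base_loading > 1)
    stop("invalid config: base_loading must be in (0, 1]")
  if (any(multipliers < 0)) stop("invalid config: multipliers must be >= 0")
  if (abs(trait_coupling) > 1)
    stop("invalid config: trait_coupling must be in [-1, 1]")
  structure(list(module_id = module_id, n_genes = as.integer(n_genes),
                 base_loading = base_loading, multipliers = multipliers,
                 trait_coupling = trait_coupling),
            class = "sim_module")
}

#' Loading that yields a target within-module correlation
#'
#' Inverts the factor-model relation `rho = loading^2 / (loading^2 +
#' noise_sd^2)`: returns `noise_sd * sqrt(rho / (1 - rho))`. Errors when the
#' required loading exceeds 1 (lower `noise_sd` in that case).
#'
#' @param rho Target within-module Pearson correlation in [0, 1).
#' @param noise_sd Gene noise standard deviation.
#' @return The loading.
#' @export
loading_for_correlation <- function(rho, noise_sd = 1) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  l <- noise_sd * sqrt(rho / (1 - rho))
  if (l > 1)
    stop("target correlation ", rho, " needs loading ", round(l, 3),
         " > 1 at noise_sd = ", noise_sd, "; lower noise_sd")
  l
}

#' Generate the sample metadata table for a design
#'
#' Deterministic given the design: one row per (trial, treatment, sex, region)
#' combination, so treatments are exactly balanced within every (region, sex)
#' stratum.
#'
#' @param design A [sim_design()].
#' @return A data.frame with columns sample_id, bird_id, sex, region,
#'   treatment, trial.
#' @export
generate_design <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  grid <- expand.grid(region = design$regions, sex = design$sexes,
                      treatment = design$treatments,
                      trial = seq_len(design$n_trials),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$trial, grid$treatment, grid$sex, grid$region), ]
  rownames(grid) <- NULL
  grid$bird_id <- sprintf("bird_T%02d_%s_%s", grid$trial, grid$treatment, grid$sex)
  grid$sample_id <- sprintf("%s_%s", grid$bird_id, grid$region)
  grid[, c("sample_id", "bird_id", "sex", "region", "treatment", "trial")]
}

#' Generate a synthetic expression matrix with planted modules
#'
#' Factor model per (region, sex) stratum: each module has one latent factor
#' per stratum, drawn independently as standard normal per sample; a member
#' gene's latent value is `loading(treatment) * factor + noise` with Gaussian
#' noise of standard deviation `noise_sd`, and background genes are pure
#' noise. Latent values are emitted on a nonnegative TPM-like scale through
#' the monotone map `2^(z + tpm_shift)`, so that log2 transformation recovers
#' the latent scale (up to the additive shift) and zero-TPM filtering is
#' exercisable via `dropout`.
#'
#' @param design A [sim_design()].
#' @param modules List of [sim_module()] specifications.
#' @param n_background_genes Number of unstructured noise genes.
#' @param noise_sd Standard deviation of the per-gene noise (> 0).
#' @param seed Integer seed.
#' @param tpm_shift Additive shift on the log2 scale before exponentiation.
#' @param dropout Probability that an emitted TPM value is zeroed.
#' @return A list with `expression` (an [expression_matrix()], tpm scale),
#'   `metadata` (from [generate_design()]) and `truth`, a list recording the
#'   gene -> module assignment, the per-module per-treatment expected
#'   intra-module correlation, and the per-sample factor values
#'   (samples x modules matrix).
#' @export
generate_expression <- function(design, modules, n_background_genes = 100,
                                noise_sd = 1, seed = design$seed,
                                tpm_shift = 6, dropout = 0) {
  stopifnot(inherits(design, "sim_design"))
  if (noise_sd <= 0) stop("invalid config: noise_sd must be > 0")
  if (dropout < 0 || dropout >= 1) stop("invalid config: dropout must be in [0, 1)")
  for (mod in modules) {
    stopifnot(inherits(mod, "sim_module"))
    missing_t <- setdiff(design$treatments, names(mod$multipliers))
    if (length(missing_t))
      stop("invalid config: module ", mod$module_id,
           " lacks multipliers for treatment(s) ", paste(missing_t, collapse = ", "))
  }
  n_module_genes <- sum(vapply(modules, `[[`, integer(1), "n_genes"))
  if (n_module_genes + n_background_genes < 1)
    stop("invalid config: no genes to generate")

  md <- generate_design(design)
  n_samples <- nrow(md)
  gene_ids <- character(0)
  assignment <- character(0)
  for (mod in modules) {
    ids <- sprintf("%s_g%03d", mod$module_id, seq_len(mod$n_genes))
    gene_ids <- c(gene_ids, ids)
    assignment <- c(assignment, rep(mod$module_id, mod$n_genes))
  }
  if (n_background_genes > 0) {
    ids <- sprintf("bg_g%04d", seq_len(n_background_genes))
    gene_ids <- c(gene_ids, ids)
    assignment <- c(assignment, rep("background", n_background_genes))
  }
  names(assignment) <- gene_ids

  set.seed(seed)
  z <- matrix(0, length(gene_ids), n_samples,
              dimnames = list(gene_ids, md$sample_id))
  factors <- matrix(NA_real_, n_samples,
                    length(modules),
                    dimnames = list(md$sample_id,
                                    vapply(modules, `[[`, character(1), "module_id")))
  strata <- interaction(md$region, md$sex, drop = TRUE)
  for (st in levels(strata)) {
    idx <- which(strata == st)
    for (mod in modules) {
      f <- stats::rnorm(length(idx))
      factors[idx, mod$module_id] <- f
      loading <- mod$base_loading * mod$multipliers[md$treatment[idx]]
      members <- which(assignment == mod$module_id)
      z[members, idx] <- rep(loading * f, each = length(members)) +
        stats::rnorm(length(members) * length(idx), sd = noise_sd)
    }
  }
  bg <- which(assignment == "background")
  if (length(bg))
    z[bg, ] <- stats::rnorm(length(bg) * n_samples, sd = noise_sd)

  tpm <- 2^(z + tpm_shift)
  if (dropout > 0) {
    drop_mask <- matrix(stats::runif(length(tpm)) < dropout, nrow(tpm))
    tpm[drop_mask] <- 0
  }

  treatments <- design$treatments
  expected_cor <- t(vapply(modules, function(mod) {
    l <- mod$base_loading * mod$multipliers[treatments]
    l^2 / (l^2 + noise_sd^2)
  }, stats::setNames(numeric(length(treatments)), treatments)))
  rownames(expected_cor) <- vapply(modules, `[[`, character(1), "module_id")

  list(expression = expression_matrix(tpm, "tpm"),
       metadata = md,
       truth = list(assignment = assignment,
                    expected_correlation = expected_cor,
                    factors = factors,
                    coupling = stats::setNames(
                      vapply(modules, `[[`, numeric(1), "trait_coupling"),
                      rownames(expected_cor)),
                    noise_sd = noise_sd, tpm_shift = tpm_shift, seed = seed))
}

#' Generate behavior frequencies coupled to module factors
#'
#' For E-group samples of the action's sex, the frequency (seconds per hour)
#' is an affine function of the coupled module's latent factor plus Gaussian
#' noise: `base + slope * (coupling * factor + e)`, `e ~ N(0, noise_sd)`.
#' Samples in the nonnesting groups (NM, NP) draw from a near-zero
#' half-normal. All stored frequencies are clamped to [0, 3600]. Samples of
#' the other sex get NA for that action.
#'
#' @param metadata Design table from [generate_design()].
#' @param coupled Data.frame with columns `action` (one of
#'   "fetch_material_male", "stay_nestbox_male", "stay_nestbox_female"),
#'   `module`, `coupling`, and optionally `region` (the stratum whose module
#'   factor drives the behavior; defaults to the design's first region in
#'   sorted order). Behavior is a bird-level quantity, so each bird gets one
#'   frequency per action, repeated across its region samples.
#' @param factors Samples x modules matrix of latent factor values (from the
#'   `truth` of [generate_expression()]).
#' @param noise_sd Behavior noise standard deviation (on the factor scale).
#' @param seed Integer seed.
#' @param base,slope Affine parameters mapping the factor scale to
#'   seconds/hour.
#' @param nonnesting_sd Scale of the half-normal for NM/NP frequencies.
#' @return `metadata` with one frequency column per action.
#' @export
generate_behavior <- function(metadata, coupled, factors, noise_sd = 0.2,
                              seed = 1L, base = 1800, slope = 400,
                              nonnesting_sd = 10) {
  actions <- c("fetch_material_male", "stay_nestbox_male", "stay_nestbox_female")
  if (!all(coupled$action %in% actions))
    stop("unknown action(s): ",
         paste(setdiff(coupled$action, actions), collapse = ", "))
  bad <- setdiff(coupled$module, colnames(factors))
  if (length(bad)) stop("unknown module id(s): ", paste(bad, collapse = ", "))
  default_region <- sort(unique(metadata$region))[1L]
  birds <- unique(metadata[, c("bird_id", "sex", "treatment")])
  set.seed(seed)
  out <- metadata
  for (a in actions) {
    sex <- if (grepl("_male$", a)) "M" else "F"
    freq <- rep(NA_real_, nrow(birds))
    is_e <- birds$sex == sex & birds$treatment == "E"
    is_non <- birds$sex == sex & birds$treatment != "E"
    row <- coupled[coupled$action == a, , drop = FALSE]
    if (nrow(row)) {
      region <- if ("region" %in% names(row)) row$region[1L] else default_region
      # the bird's factor value in the coupling region's stratum
      samp <- metadata$sample_id[match(paste(birds$bird_id[is_e], region),
                                       paste(metadata$bird_id, metadata$region))]
      if (anyNA(samp)) stop("no sample in region ", region, " for some birds")
      f <- factors[samp, row$module[1L]]
      signal <- row$coupling[1L] * f + stats::rnorm(sum(is_e), sd = noise_sd)
      freq[is_e] <- base + slope * signal
    } else {
      freq[is_e] <- base + slope * stats::rnorm(sum(is_e), sd = noise_sd)
    }
    freq[is_non] <- abs(stats::rnorm(sum(is_non), sd = nonnesting_sd))
    freq <- pmin(pmax(freq, 0), 3600)
    out[[a]] <- freq[match(metadata$bird_id, birds$bird_id)]
  }
  out
}

#' Generate a synthetic gene-category map
#'
#' Assigns the three neural-function categories at configurable background
#' rates, optionally planting one category into a chosen gene list:
#' planted-list members carry `planted_category` with probability
#' `planted_fraction`, all other gene/category pairs are assigned at rate
#' `category_sizes[cat] / n_genes`. The composite "neurogenesis" category is
#' derived downstream (see [derive_neurogenesis()]), never stored.
#'
#' @param genes Character vector of gene ids.
#' @param category_sizes Named target sizes for the three base categories;
#'   the default scales the emulated study's annotation rates (about 6.0%,
#'   0.6% and 9.7% of annotated genes) to `length(genes)`.
#' @param planted_list Gene ids to enrich (must be a subset of `genes`).
#' @param planted_category Category planted into `planted_list`.
#' @param planted_fraction Probability a planted gene carries the category.
#' @param seed Integer seed.
#' @return A data.frame (gene_id, category) in long form; a gene may appear in
#'   several categories or in none.
#' @export
generate_categories <- function(genes, category_sizes = NULL,
                                planted_list = character(0),
                                planted_category = "neuron_projection",
                                planted_fraction = 0.5, seed = 1L) {
  base_cats <- c("neuron_projection", "in_situ_neurogenesis", "other_neurogenesis")
  if (is.null(category_sizes))
    category_sizes <- round(c(neuron_projection = 0.060,
                              in_situ_neurogenesis = 0.006,
                              other_neurogenesis = 0.097) * length(genes))
  if (!all(names(category_sizes) %in% base_cats))
    stop("unknown category in category_sizes")
  if (any(category_sizes > length(genes)))
    stop("invalid config: category size exceeds number of genes")
  bad <- setdiff(planted_list, genes)
  if (length(bad))
    stop("planted list contains unknown gene(s): ", paste(bad, collapse = ", "))
  if (!planted_category %in% base_cats) stop("unknown planted category")
  set.seed(seed)
  rows <- list()
  planted <- genes %in% planted_list
  for (cat in names(category_sizes)) {
    rate <- category_sizes[[cat]] / length(genes)
    p <- rep(rate, length(genes))
    if (cat == planted_category) p[planted] <- planted_fraction
    hit <- stats::runif(length(genes)) < p
    if (any(hit))
      rows[[cat]] <- data.frame(gene_id = genes[hit], category = cat,
                                stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), category = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene_id, out$category), , drop = FALSE]
}

#' Write a simulated dataset to disk
#'
#' Emits the expression TSV (genes x samples), metadata TSV, category-map TSV
#' and a ground-truth JSON next to each other.
#'
#' @param sim Result of [generate_expression()] (optionally with behavior
#'   columns merged into `$metadata`).
#' @param dir Output directory (created if absent).
#' @param categories Optional category map data.frame.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(sim, dir, categories = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression(sim$expression, paths[["expression"]])
  utils::write.table(sim$metadata, paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$expected_correlation <- as.data.frame(truth$expected_correlation)
  truth$factors <- NULL  # large; recoverable from seed
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  if (!is.null(categories)) {
    paths[["categories"]] <- file.path(dir, "categories.tsv")
    utils::write.table(categories, paths[["categories"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
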