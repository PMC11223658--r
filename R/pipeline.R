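#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. In synthetic mode the
#' generator settings are used; otherwise `expression_path` (TPM TSV),
#' `metadata_path` and optionally `category_path` are read from disk.
#'
#' @param synthetic Logical; generate inputs with the built-in simulator.
#' @param seed Master seed; every stochastic stage derives from it.
#' @param n_trials,regions Generator design (synthetic mode).
#' @param modules List of [sim_module()] (synthetic mode); NULL for a small
#'   default of four modules, one with a planted connectivity gain and one
#'   trait-coupled.
#' @param n_background_genes,noise_sd Generator settings. The default noise
#'   level (0.6325) keeps factor loadings for within-module correlations up
#'   to ~0.7 inside (0, 1].
#' @param expression_path,metadata_path,category_path Input files (file mode).
#' @param network Named list: method, beta, cut_height, min_module_size.
#' @param mdc Named list: M, scheme, denom_floor, bh_scope.
#' @param thresholds Named list: gain, loss, alpha, mm, gs_quantile.
#' @param comparisons Treatment comparisons.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(synthetic = TRUE, seed = 1L,
                            n_trials = 10,
                            regions = c("AMP", "SBN", "DNP", "PM", "Others"),
                            modules = NULL, n_background_genes = 100,
                            noise_sd = 0.6325,
                            expression_path = NULL, metadata_path = NULL,
                            category_path = NULL,
                            network = list(method = "bicor", beta = 6,
                                           cut_height = 0.99,
                                           min_module_size = 30),
                            mdc = list(M = 10000, scheme = "paired",
                                       denom_floor = 0.1,
                                       bh_scope = "stratum_comparison"),
                            thresholds = list(gain = 2, loss = 0.5,
                                              alpha = 0.05, mm = 0.8,
                                              gs_quantile = 0.99),
                            comparisons = c("E-NM", "E-NP")) {
  if (!synthetic) {
    for (p in c(expression_path, metadata_path))
      if (is.null(p) || !file.exists(p))
        stop("file mode requires existing expression_path and metadata_path")
  }
  structure(list(synthetic = synthetic, seed = as.integer(seed),
                 n_trials = n_trials, regions = regions, modules = modules,
                 n_background_genes = n_background_genes, noise_sd = noise_sd,
                 expression_path = expression_path,
                 metadata_path = metadata_path,
                 category_path = category_path,
                 network = network, mdc = mdc, thresholds = thresholds,
                 comparisons = comparisons),
            class = "pipeline_config")
}

# Deterministic polynomial rolling hash of the serialized config (mod the
# Mersenne prime 2^31 - 1), for the manifest.
.config_hash <- function(config) {
  s <- utils::capture.output(utils::str(config, digits.d = 12))
  bytes <- utf8ToInt(paste(s, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# Default demo fixture: one module with a planted connectivity gain in E
# (within-group correlation 0.7 vs 0.25, strong enough to classify yet still
# coherent when the network pools all treatments), one trait-coupled module,
# and two stable modules.
.default_modules <- function(noise_sd) {
  l <- function(rho) loading_for_correlation(rho, noise_sd)
  list(sim_module("gainmod", 50, base_loading = l(0.7),
                  multipliers = c(E = 1, NM = l(0.25) / l(0.7),
                                  NP = l(0.25) / l(0.7))),
       sim_module("traitmod", 50, base_loading = l(0.6),
                  trait_coupling = 0.95),
       sim_module("flatmod1", 50, base_loading = l(0.6)),
       sim_module("flatmod2", 50, base_loading = l(0.6)))
}

#' Run the full analysis pipeline
#'
#' synthetic-generate (or load) -> zero-TPM filter -> log2 -> co-expression
#' modules -> MDC permutation tests -> eigengene-behavior (NBF) correlations
#' and hub genes -> category over-representation -> behavior comparisons.
#' Every stage's table is written to `out_dir` together with a JSON manifest
#' (package version, seed, config hash, file list); re-running the same
#' config reproduces all outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with all in-memory stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("mdcnet_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  step <- function(name, expr) {
    message("[mdcnet] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  sim <- NULL
  if (config$synthetic) {
    sim <- step("simulate", {
      design <- sim_design(n_trials = config$n_trials,
                           regions = config$regions, seed = config$seed)
      modules <- if (is.null(config$modules))
        .default_modules(config$noise_sd) else config$modules
      out <- generate_expression(design, modules,
                                 n_background_genes = config$n_background_genes,
                                 noise_sd = config$noise_sd,
                                 seed = config$seed)
      coupled <- do.call(rbind, lapply(modules, function(mod) {
        if (mod$trait_coupling == 0) return(NULL)
        data.frame(action = "fetch_material_male", module = mod$module_id,
                   coupling = mod$trait_coupling, stringsAsFactors = FALSE)
      }))
      if (is.null(coupled))
        coupled <- data.frame(action = character(0), module = character(0),
                              coupling = numeric(0))
      out$metadata <- generate_behavior(out$metadata, coupled,
                                        out$truth$factors,
                                        seed = config$seed + 1L)
      out
    })
    expr_tpm <- sim$expression
    metadata <- sim$metadata
    categories <- step("categories", {
      genes <- rownames(expr_tpm)
      planted <- genes[sim$truth$assignment == "gainmod"]
      generate_categories(genes, planted_list = planted,
                          planted_fraction = if (length(planted)) 0.5 else 0,
                          seed = config$seed + 2L)
    })
  } else {
    expr_tpm <- step("read", read_expression(config$expression_path, "tpm"))
    metadata <- step("read", read_metadata(config$metadata_path))
    categories <- if (!is.null(config$category_path))
      step("read", load_category_map(config$category_path)) else NULL
  }

  filtered <- step("filter", {
    region_of <- metadata$region[match(colnames(expr_tpm), metadata$sample_id)]
    if (anyNA(region_of)) stop("metadata missing for some samples")
    filter_wgcna_genes(expr_tpm, region_of)
  })
  logm <- step("log2", log2_transform(filtered, pseudocount = 1))

  net <- step("network", coexpr_modules(
    logm, method = config$network$method, beta = config$network$beta,
    min_module_size = config$network$min_module_size,
    cut_height = config$network$cut_height))

  fit <- step("mdc", mdc_test(
    logm, metadata, net$partition, comparisons = config$comparisons,
    M = config$mdc$M, seed = config$seed + 3L, scheme = config$mdc$scheme,
    denom_floor = config$mdc$denom_floor, bh_scope = config$mdc$bh_scope,
    gain_threshold = config$thresholds$gain,
    loss_threshold = config$thresholds$loss,
    alpha = config$thresholds$alpha))

  actions <- intersect(c("fetch_material_male", "stay_nestbox_male",
                         "stay_nestbox_female"), names(metadata))
  nbf <- step("nbf", {
    rows <- list()
    for (region in unique(metadata$region)) {
      for (sex in c("M", "F")) {
        sel <- metadata$region == region & metadata$sex == sex &
          metadata$treatment == "E"
        samples <- intersect(metadata$sample_id[sel], colnames(logm))
        if (length(samples) < 4L) next
        sex_actions <- actions[grepl(if (sex == "M") "_male$" else "_female$", actions)]
        for (mod in names(module_sizes(net$partition))) {
          me <- module_eigengene(logm, net$partition, mod, samples)
          for (a in sex_actions) {
            fr <- stats::setNames(metadata[[a]][match(samples, metadata$sample_id)],
                                  samples)
            if (anyNA(fr)) next
            r <- nbf_correlation(me, fr, trait = a,
                                 alpha = config$thresholds$alpha)
            r <- cbind(data.frame(module = mod, region = region, sex = sex,
                                  stringsAsFactors = FALSE), r)
            rows[[length(rows) + 1L]] <- r
          }
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })

  hubs <- step("hubs", {
    sig <- nbf[!is.na(nbf$significant) & nbf$significant, , drop = FALSE]
    rows <- list()
    for (i in seq_len(nrow(sig))) {
      mod <- sig$module[i]
      sel <- metadata$region == sig$region[i] & metadata$sex == sig$sex[i] &
        metadata$treatment == "E"
      samples <- intersect(metadata$sample_id[sel], colnames(logm))
      me <- module_eigengene(logm, net$partition, mod, samples)
      genes <- names(net$partition)[unclass(net$partition) == mod]
      mm <- vapply(genes, function(g) module_membership(logm, me, g), numeric(1))
      fr <- stats::setNames(metadata[[sig$trait[i]]][match(samples, metadata$sample_id)],
                            samples)
      gs <- vapply(genes, function(g)
        gene_significance(logm[, samples, drop = FALSE], fr, g), numeric(1))
      gs_thr <- gs_quantile_threshold(gs, config$thresholds$gs_quantile)
      h <- select_hub_genes(mm, gs, config$thresholds$mm, gs_thr)
      h$module <- mod; h$region <- sig$region[i]; h$sex <- sig$sex[i]
      h$trait <- sig$trait[i]; h$gs_threshold <- gs_thr
      rows[[length(rows) + 1L]] <- h
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })

  enrich <- if (!is.null(categories) && nrow(categories)) {
    step("enrich", module_over_representation(net$partition, categories,
                                              background = names(net$partition)))
  } else NULL

  behavior <- step("behavior", {
    if (!length(actions)) return(NULL)
    freq <- bird_frequencies(metadata, actions)
    behavior_tests(freq, actions)
  })

  step("write", {
    if (!is.null(sim)) write_simulation(sim, file.path(out_dir, "simulated"),
                                        categories = categories)
    write_partition(net$partition, file.path(out_dir, "modules.tsv"))
    if (!is.null(net$eigengenes))
      utils::write.table(data.frame(sample_id = rownames(net$eigengenes),
                                    net$eigengenes, check.names = FALSE),
                         file.path(out_dir, "eigengenes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    write_mdc_results(fit, file.path(out_dir, "mdc_results.tsv"))
    for (nm in c("nbf", "hubs", "enrich", "behavior")) {
      obj <- get(nm)
      if (!is.null(obj))
        utils::write.table(obj, file.path(out_dir, paste0(nm, "_results.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })

  manifest <- list(package = "mdcnet",
                   version = as.character(utils::packageVersion("mdcnet")),
                   seed = config$seed,
                   config_hash = .config_hash(config),
                   files = list.files(out_dir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(config = config, network = net, mdc = fit, nbf = nbf,
                 hubs = hubs, enrichment = enrich, behavior = behavior,
                 out_dir = out_dir, manifest = manifest))
}
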