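test_that("design generation is balanced, complete and deterministic", {
  d <- sim_design(seed = 1)
  md <- generate_design(d)
  expect_equal(nrow(md), 300)
  # exactly one sample per (trial, treatment, sex, region) combination
  expect_equal(anyDuplicated(md[, c("trial", "treatment", "sex", "region")]), 0L)
  # treatments balanced within every (region, sex) stratum
  tab <- table(md$region, md$sex, md$treatment)
  expect_true(all(tab == d$n_trials))

  tiny <- generate_design(sim_design(n_trials = 2, regions = "AMP", sexes = "M"))
  expect_equal(nrow(tiny), 6)  # 2 trials x 3 treatments x 1 x 1

  expect_identical(generate_design(sim_design(seed = 5)),
                   generate_design(sim_design(seed = 5)))
  expect_error(sim_design(n_trials = 1), "n_trials")
  expect_error(sim_design(regions = character(0)), "empty region")
})

test_that("planted within-module correlation matches the factor-model closed form", {
  d <- sim_design(n_trials = 2, regions = "AMP", sexes = "M")
  mods <- list(sim_module("m1", 5, base_loading = 1,
                          multipliers = c(E = 1, NM = 1, NP = 0)))
  sim <- generate_expression(d, mods, n_background_genes = 0, noise_sd = 1,
                             seed = 1)
  # closed form: 1 / (1 + 1) = 0.5; multiplier 0 kills the correlation
  expect_equal(unname(sim$truth$expected_correlation["m1", "E"]), 0.5)
  expect_equal(unname(sim$truth$expected_correlation["m1", "NP"]), 0)

  # Monte-Carlo check of the closed form: 50-gene module, 10 samples/group,
  # loadings for corr 0.6 (E) and 0.3 (NP); empirical mean within-module
  # correlation within +-0.1 of target over 100 replicates
  set.seed(42)
  mean_cor <- function(x) { cc <- cor(t(x)); mean(cc[upper.tri(cc)]) }
  reps <- t(replicate(100, {
    sm <- sim_two_group_module(50, 10, 0.6, 0.3)
    c(mean_cor(sm$a), mean_cor(sm$b))
  }))
  expect_lt(abs(mean(reps[, 1]) - 0.6), 0.1)
  expect_lt(abs(mean(reps[, 2]) - 0.3), 0.1)
})

test_that("intra-module correlation converges to loading^2/(loading^2+noise^2) at n=1000", {
  d <- sim_design(n_trials = 334, regions = "AMP", sexes = "M", seed = 2)
  l <- loading_for_correlation(0.5, 0.8)
  mods <- list(sim_module("m1", 40, base_loading = l,
                          multipliers = c(E = 1, NM = 1, NP = 1)))
  sim <- generate_expression(d, mods, n_background_genes = 0, noise_sd = 0.8,
                             seed = 3)
  lg <- log2_transform(sim$expression, 0)
  cc <- cor(t(unclass(lg)))
  expect_lt(abs(mean(cc[upper.tri(cc)]) - 0.5), 0.02)
})

test_that("expression generation is reproducible and validates its config", {
  d <- sim_design(n_trials = 2, regions = "AMP")
  mods <- list(sim_module("m1", 10))
  s1 <- generate_expression(d, mods, 20, seed = 9)
  s2 <- generate_expression(d, mods, 20, seed = 9)
  expect_identical(unclass(s1$expression), unclass(s2$expression))
  expect_error(sim_module("m", 10, multipliers = c(E = -1, NM = 1, NP = 1)),
               "multipliers")
  expect_error(generate_expression(d, list(sim_module("m", 3,
                                                      multipliers = c(E = 1, NM = 1))),
                                   0, seed = 1),
               "NP")
  # dropout injects TPM zeros for the zero-expression filter to act on
  s3 <- generate_expression(d, mods, 20, seed = 9, dropout = 0.3)
  expect_gt(sum(unclass(s3$expression) == 0), 0)
})

test_that("behavior coupling, null behavior and clamping follow the contract", {
  d <- sim_design(n_trials = 10, regions = "AMP", seed = 4)
  mods <- list(sim_module("m1", 5, trait_coupling = 1))
  sim <- generate_expression(d, mods, 0, seed = 4)
  coupled <- data.frame(action = "fetch_material_male", module = "m1",
                        coupling = 1)
  md <- generate_behavior(sim$metadata, coupled, sim$truth$factors,
                          noise_sd = 0, seed = 5)
  is_e_m <- md$treatment == "E" & md$sex == "M"
  expect_equal(cor(md$fetch_material_male[is_e_m],
                   sim$truth$factors[is_e_m, "m1"]), 1)
  # nonnesting groups sit near zero
  expect_true(all(md$fetch_material_male[md$treatment != "E" & md$sex == "M"] < 100))
  expect_true(all(md$fetch_material_male[is_e_m] >= 0 &
                    md$fetch_material_male[is_e_m] <= 3600))
  expect_error(generate_behavior(sim$metadata,
                                 data.frame(action = "fetch_material_male",
                                            module = "nope", coupling = 1),
                                 sim$truth$factors),
               "unknown module")

  # negative affine output is clamped to 0
  md0 <- generate_behavior(sim$metadata, coupled, sim$truth$factors,
                           noise_sd = 0, seed = 5, base = -5, slope = 0)
  expect_true(all(md0$fetch_material_male[is_e_m] == 0))
})

test_that("uncoupled behavior gives null correlations at the t-distribution rate", {
  # with trait independent of the factor at n=10, P(|r| < 0.4) from the null
  # t transform is 1 - 2*pt(-0.4*sqrt(8/(1-0.16)), 8) = 0.748
  expected <- 1 - 2 * pt(-0.4 * sqrt(8 / (1 - 0.16)), df = 8)
  set.seed(11)
  frac <- mean(replicate(1000, abs(cor(rnorm(10), rnorm(10))) < 0.4))
  expect_lt(abs(frac - expected), 0.05)
})

test_that("category planting controls enrichment signal", {
  genes <- sprintf("g%04d", 1:500)
  planted <- genes[1:50]
  # planted_fraction 1 on a zero-background category: Fisher P is the
  # all-successes hypergeometric tail
  cm <- generate_categories(genes,
                            category_sizes = c(neuron_projection = 0,
                                               in_situ_neurogenesis = 0,
                                               other_neurogenesis = 0),
                            planted_list = planted,
                            planted_category = "neuron_projection",
                            planted_fraction = 1, seed = 2)
  set_np <- category_genes(cm, "neuron_projection")
  expect_setequal(set_np, planted)
  res <- over_representation_test(planted, set_np, genes)
  expect_equal(res$p, oracle_hyper_upper(50, 50, 50, 500), tolerance = 1e-12)

  # planted fraction equal to the background rate: P roughly uniform
  set.seed(3)
  ps <- replicate(200, {
    cm0 <- generate_categories(genes,
                               category_sizes = c(neuron_projection = 50,
                                                  in_situ_neurogenesis = 0,
                                                  other_neurogenesis = 0),
                               planted_list = planted,
                               planted_category = "neuron_projection",
                               planted_fraction = 0.1,
                               seed = sample.int(1e6, 1))
    over_representation_test(planted, category_genes(cm0, "neuron_projection"),
                             genes)$p
  })
  expect_lt(mean(ps < 0.05), 0.1)  # close to nominal given discreteness
  expect_gt(mean(ps), 0.35)

  # empty planted list is a valid, signal-free map
  cm_empty <- generate_categories(genes, planted_list = character(0), seed = 1)
  expect_true(is.data.frame(cm_empty))
  expect_error(generate_categories(genes, planted_list = "nope"),
               "unknown gene")
})
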