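lg_matrix <- function(v) {
  dimnames(v) <- list(sprintf("g%02d", seq_len(nrow(v))),
                      sprintf("s%02d", seq_len(ncol(v))))
  expression_matrix(v, "log2tpm")
}

test_that("correlation matrix honors duplicates, negation and the bicor formula", {
  set.seed(21)
  base <- matrix(rnorm(10 * 20), 10, 20)
  base[2, ] <- base[1, ]          # duplicate gene
  base[3, ] <- -base[1, ]         # negated gene
  m <- lg_matrix(base)
  for (method in c("pearson", "bicor")) {
    cc <- correlation_matrix(m, method)
    expect_equal(cc[1, 2], 1, tolerance = 1e-12)
    expect_equal(cc[1, 3], -1, tolerance = 1e-12)
    expect_equal(cc, t(cc))
    expect_true(all(diag(cc) == 1))
    expect_true(all(abs(cc) <= 1))
  }
  # bicor equals the direct elementwise formula on every pair
  cc <- correlation_matrix(m, "bicor")
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(cc[i, j], oracle_bicor(base[i, ], base[j, ]),
                 tolerance = 1e-12)
  # constant gene: flagged, correlations forced to 0
  base[4, ] <- 7
  expect_warning(cc2 <- correlation_matrix(lg_matrix(base), "bicor"),
                 "constant")
  expect_true(all(cc2[4, -4] == 0))
  expect_identical(attr(cc2, "constant_genes"), "g04")
  expect_error(correlation_matrix(lg_matrix(base[, 1:2]), "pearson"),
               "3 samples")
})

test_that("signed-hybrid adjacency zeroes negatives and powers positives", {
  cc <- matrix(c(1, 0.5, -0.5, 0.5, 1, 1, -0.5, 1, 1), 3, 3)
  a <- signed_hybrid_adjacency(cc, beta = 6)
  expect_equal(a[1, 2], 0.5^6)         # 0.015625
  expect_equal(a[1, 3], 0)             # negative correlation -> 0
  expect_equal(a[2, 3], 1)             # perfect correlation -> 1
  expect_true(all(diag(a) == 0))
  expect_error(signed_hybrid_adjacency(cc, beta = 0), "beta")
  # monotone in correlation on the positive side
  r <- seq(0, 1, by = 0.05)
  expect_true(all(diff(r^6) >= 0))
  cc2 <- outer(r, r, function(x, y) pmin(x, y)); diag(cc2) <- 1
  a2 <- signed_hybrid_adjacency(cc2, 6)
  expect_true(all(a2 >= 0 & a2 <= 1))
})

test_that("topological overlap matches its formula", {
  # two genes connected only to each other with a = 1 -> TOM = 1
  a <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(tom_similarity(a)[1, 2], 1)
  # no direct link, no shared neighbors -> TOM = 0
  a2 <- diag(0, 4); a2[1, 2] <- a2[2, 1] <- 1; a2[3, 4] <- a2[4, 3] <- 1
  dimnames(a2) <- list(letters[1:4], letters[1:4])
  expect_equal(tom_similarity(a2)[1, 3], 0)
  # random 6-node adjacency equals the triple-loop oracle
  set.seed(22)
  r <- matrix(runif(36, 0, 0.9), 6, 6); r <- (r + t(r)) / 2; diag(r) <- 0
  dimnames(r) <- list(paste0("n", 1:6), paste0("n", 1:6))
  tom <- tom_similarity(r)
  expect_equal(unname(tom), oracle_tom(r), tolerance = 1e-12)
  expect_true(all(tom >= 0 & tom <= 1))
  expect_error(tom_similarity(r - 0.5), "\\[0, 1\\]")
})

test_that("module detection separates planted blocks and canonicalizes labels", {
  set.seed(23)
  sm <- sim_two_group_module(40, 30, 0.7, 0.7)
  x <- rbind(sm$a, sim_two_group_module(35, 30, 0.7, 0.7)$a)
  rownames(x) <- sprintf("g%03d", 1:75)
  m <- lg_matrix(x)
  cc <- correlation_matrix(m, "pearson")
  tom <- tom_similarity(signed_hybrid_adjacency(cc))
  part <- detect_modules(tom, min_module_size = 30)
  expect_equal(length(module_sizes(part)), 2L)
  # the larger block is labeled M1
  expect_equal(unname(module_sizes(part)[1]), 40)
  expect_true(all(unclass(part)[1:40] == unclass(part)[1]))
  # invariant to gene input order
  perm <- sample(nrow(tom))
  part2 <- detect_modules(tom[perm, perm], min_module_size = 30)
  expect_identical(unclass(part2)[names(part)], unclass(part))
  # all-zero adjacency -> everything unassigned
  z <- diag(0, 40); dimnames(z) <- list(paste0("g", 1:40), paste0("g", 1:40))
  pz <- detect_modules(tom_similarity(z), min_module_size = 5)
  expect_true(all(unclass(pz) == "unassigned"))
  expect_error(detect_modules(tom, cut_height = 1.2), "cut_height")
})

test_that("module eigengene is the top PC with the nonnegative-MM sign convention", {
  set.seed(24)
  # identical member genes -> variance explained 1 and each MM = 1
  v <- matrix(rep(rnorm(12), each = 4), 4, 12, byrow = FALSE)
  v <- v + 0  # 4 identical genes
  m <- lg_matrix(v)
  part <- module_partition(setNames(rep("mod", 4), rownames(m)))
  me <- module_eigengene(m, part, "mod")
  expect_equal(me$variance_explained, 1, tolerance = 1e-12)
  expect_equal(module_membership(m, me, "g01"), 1, tolerance = 1e-12)
  expect_equal(sum(me$scores^2), 1, tolerance = 1e-12)

  # two anti-correlated halves: convention keeps mean MM >= 0
  v2 <- rbind(matrix(rep(rnorm(12), each = 3), 3, 12), 0)
  v2[4, ] <- -v2[1, ]
  m2 <- lg_matrix(v2)
  part2 <- module_partition(setNames(rep("mod", 4), rownames(m2)))
  me2 <- module_eigengene(m2, part2, "mod")
  mm2 <- vapply(rownames(m2), function(g) module_membership(m2, me2, g),
                numeric(1))
  expect_gte(mean(mm2), 0)

  # random module: scores equal the top eigenvector of the standardized
  # gene covariance (independent eigendecomposition oracle)
  v3 <- matrix(rnorm(8 * 15), 8, 15)
  m3 <- lg_matrix(v3)
  part3 <- module_partition(setNames(rep("mod", 8), rownames(m3)))
  me3 <- module_eigengene(m3, part3, "mod")
  xs <- t(scale(t(v3)))
  ev <- eigen(crossprod(xs))$vectors[, 1]
  expect_equal(abs(sum(me3$scores * ev)), 1, tolerance = 1e-10)

  # single-gene module degenerates to the standardized gene
  part1 <- module_partition(setNames(c("solo", rep("mod", 7)), rownames(m3)))
  me1 <- module_eigengene(m3, part1, "solo")
  expect_true(me1$degenerate)
  expect_equal(abs(cor(me1$scores, v3[1, ])), 1, tolerance = 1e-12)
})

test_that("module membership handles exact and null cases", {
  set.seed(25)
  m <- lg_matrix(matrix(rnorm(5 * 30), 5, 30))
  v <- unclass(m)
  part <- module_partition(setNames(rep("mod", 5), rownames(m)))
  me <- module_eigengene(m, part, "mod")
  # a gene equal to the eigengene scores has MM = 1; its negation -1
  v2 <- rbind(v, pos = me$scores[colnames(v)], neg = -me$scores[colnames(v)])
  m2 <- expression_matrix(v2, "log2tpm")
  expect_equal(module_membership(m2, me, "pos"), 1, tolerance = 1e-12)
  expect_equal(module_membership(m2, me, "neg"), -1, tolerance = 1e-12)
  # constant gene -> NA
  v3 <- rbind(v2, const = rep(2, 30))
  expect_true(is.na(module_membership(expression_matrix(v3, "log2tpm"), me, "const")))
  # null MM at n=30 rarely exceeds 0.5 (t-tail gives ~0.5% two-sided)
  frac <- mean(replicate(1000, abs(cor(rnorm(30), rnorm(30))) < 0.5))
  expect_gte(frac, 0.95)
})

test_that("coexpr_modules fit object carries partition, eigengenes and methods", {
  set.seed(26)
  sm1 <- sim_two_group_module(35, 15, 0.7, 0.7)
  sm2 <- sim_two_group_module(32, 15, 0.7, 0.7)
  x <- rbind(sm1$a, sm2$a)
  rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  fit <- coexpr_modules(lg_matrix(x), method = "pearson", min_module_size = 20)
  expect_s3_class(fit, "coexpr_fit")
  expect_equal(length(module_sizes(fit$partition)), 2L)
  expect_equal(nrow(fit$eigengenes), 15L)
  expect_true(all(abs(fit$membership) <= 1 + 1e-12, na.rm = TRUE))
  s <- summary(fit)
  expect_true(all(s$variance_explained > 0 & s$variance_explained <= 1))
  expect_output(print(fit), "coexpr_fit")
})
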