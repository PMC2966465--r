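test_that("randomize_dataset preserves per-gene moments and is seed-reproducible", {
  set.seed(1)
  m <- matrix(rnorm(200 * 50, mean = rep(seq(-2, 2, length.out = 200), 50),
                    sd = 1.5), 200, 50,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:50)))
  r1 <- randomize_dataset(m, seed = 11)
  r2 <- randomize_dataset(m, seed = 11)
  expect_identical(r1, r2)
  expect_identical(dimnames(r1), dimnames(m))
  # per-gene means within 3 standard errors of the originals
  se <- apply(m, 1, sd) / sqrt(ncol(m))
  expect_gt(mean(abs(rowMeans(r1) - rowMeans(m)) < 3 * se), 0.95)
  # zero-SD gene becomes a constant row at its mean
  mc <- rbind(m, g_const = rep(4, 50))
  rc <- randomize_dataset(mc, seed = 2)
  expect_equal(unname(rc["g_const", ]), rep(4, 50))
})

test_that("null AUC interval is symmetric, calibrated, and narrows with n", {
  z56 <- rep(c(0L, 1L), each = 28)
  set.seed(4)
  src56 <- matrix(rnorm(4000 * 56), 4000, 56,
                  dimnames = list(sprintf("g%04d", 1:4000),
                                  paste0("s", 1:56)))
  m <- randomize_dataset(src56, seed = 5)
  nd <- null_auc_interval(m, z56, coverage = 0.99)
  expect_lt(nd$lower, 0.5); expect_gt(nd$upper, 0.5)
  # symmetry about 0.5
  expect_lt(abs((nd$upper - 0.5) - (0.5 - nd$lower)), 0.02)
  # agreement with the normal approximation of the Mann-Whitney null
  approx_half_width <- qnorm(0.995) * sqrt((56 + 1) / (12 * 28 * 28))
  expect_lt(abs((nd$upper - nd$lower) / 2 - approx_half_width), 0.02)
  # stated coverage is achieved empirically
  inside <- mean(nd$aucs >= nd$lower & nd$aucs <= nd$upper)
  expect_lt(abs(inside - 0.99), 0.01)
  # coverage 1 gives the full range
  nd_full <- null_auc_interval(m, z56, coverage = 1)
  expect_equal(c(nd_full$lower, nd_full$upper), range(nd$aucs))
  # larger n -> narrower interval
  z100 <- rep(c(0L, 1L), each = 50)
  set.seed(5)
  m100 <- randomize_dataset(matrix(rnorm(4000 * 100), 4000, 100,
                                   dimnames = list(sprintf("g%04d", 1:4000),
                                                   paste0("s", 1:100))),
                            seed = 6)
  nd100 <- null_auc_interval(m100, z100, coverage = 0.99)
  expect_lt(nd100$upper - nd100$lower, nd$upper - nd$lower)
  expect_warning(null_auc_interval(m[1:50, ], z56), "100 genes")
})

test_that("informative_fraction measures the excess beyond the false-discovery share", {
  nd <- structure(list(coverage = 0.99, lower = 0.3, upper = 0.7,
                       n_genes = 100, aucs = NULL), class = "null_auc")
  # 31% outside a 99% envelope -> 30% informative excess
  aucs <- c(rep(0.8, 25), rep(0.2, 6), rep(0.5, 69))
  res <- informative_fraction(aucs, nd)
  expect_equal(res$fraction_outside, 0.31)
  expect_equal(res$excess, 0.30)
  expect_equal(informative_fraction(rep(0.5, 10), nd),
               list(fraction_outside = 0, excess = 0))
  expect_error(informative_fraction(numeric(0), nd), "empty")
})

test_that("informative_fraction on null data converges to 1 - coverage", {
  z <- rep(c(0L, 1L), each = 25)
  set.seed(20)
  base <- matrix(rnorm(5000 * 50), 5000, 50,
                 dimnames = list(sprintf("g%04d", 1:5000), paste0("s", 1:50)))
  nd <- null_auc_interval(randomize_dataset(base, seed = 21), z)
  fresh <- randomize_dataset(base, seed = 22)
  aucs <- vapply(seq_len(nrow(fresh)), function(i) gene_auc(fresh[i, ], z),
                 numeric(1))
  res <- informative_fraction(aucs, nd)
  expect_lt(abs(res$fraction_outside - 0.01), 0.01)
})

test_that("auc_concordance reports Pearson r and envelope categories", {
  nd <- structure(list(coverage = 0.99, lower = 0.3, upper = 0.7,
                       n_genes = 100, aucs = NULL), class = "null_auc")
  a <- c(0.9, 0.1, 0.8, 0.5, 0.5)
  res_self <- auc_concordance(a, a, nd, nd)
  expect_equal(res_self$pearson_r, 1.0)
  expect_equal(as.character(res_self$category),
               c("concordant_high", "concordant_low", "concordant_high",
                 "uninformative", "uninformative"))
  res_anti <- auc_concordance(a, 1 - a, nd, nd)
  expect_equal(res_anti$pearson_r, -1.0)
  # informative in both but opposite directions = discordant
  expect_equal(as.character(res_anti$category)[1], "discordant")
  # informative in exactly one dataset is also discordant
  res_mix <- auc_concordance(c(0.9, 0.5, 0.4), c(0.5, 0.5, 0.6), nd, nd)
  expect_equal(as.character(res_mix$category),
               c("discordant", "uninformative", "uninformative"))
  expect_error(auc_concordance(c(0.5, 0.5), c(0.5, 0.5), nd, nd), "3")
  expect_error(auc_concordance(a, a[1:3], nd, nd), "same order")
})

test_that("independent null AUC vectors show near-zero concordance", {
  z <- rep(c(0L, 1L), each = 20)
  set.seed(30)
  base <- matrix(rnorm(3000 * 40), 3000, 40,
                 dimnames = list(sprintf("g%04d", 1:3000), paste0("s", 1:40)))
  nd_a <- null_auc_interval(randomize_dataset(base, seed = 31), z)
  nd_b <- null_auc_interval(randomize_dataset(base, seed = 32), z)
  res <- auc_concordance(nd_a$aucs, nd_b$aucs, nd_a, nd_b)
  expect_lt(abs(res$pearson_r), 0.06)
  # chance rate of double-exceedance is (0.005)^2 per tail, tiny
  conc <- mean(res$category %in% c("concordant_high", "concordant_low"))
  expect_lt(conc, 0.005)
})

test_that("normality profiling is calibrated under Gaussian rows and detects bimodality", {
  set.seed(41)
  gauss <- matrix(rnorm(500 * 60), 500, 60,
                  dimnames = list(sprintf("g%03d", 1:500), paste0("s", 1:60)))
  prof <- normality_variance_profile(gauss)
  pvals <- 10^(-prof$shapiro_neglog10_p)
  # uniform p-values under the null: ~5% below 0.05
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.04)
  # strongly bimodal rows are flagged
  bimod <- matrix(rnorm(20 * 60, mean = rep(c(-3, 3), each = 10 * 60)),
                  20, 60, byrow = FALSE,
                  dimnames = list(sprintf("b%02d", 1:20), paste0("s", 1:60)))
  bimod <- t(apply(bimod, 1, sample))  # interleave the two modes
  prof_b <- normality_variance_profile(bimod)
  expect_gt(median(prof_b$shapiro_neglog10_p, na.rm = TRUE), 2)
  # sample SD column: sd(1,2,3) = 1
  prof_s <- normality_variance_profile(rbind(g = c(1, 2, 3)))
  expect_equal(prof_s$sd, 1)
  # constant gene -> NA p-value
  prof_c <- normality_variance_profile(rbind(g = c(2, 2, 2, 2)))
  expect_true(is.na(prof_c$shapiro_neglog10_p))
  # groups are carried through
  pg <- normality_variance_profile(gauss[1:4, ], gene_groups = c(1, 1, 2, 2))
  expect_equal(pg$group, c("1", "1", "2", "2"))
  expect_error(normality_variance_profile(gauss[, 1:2]), "3 samples")
  expect_error(normality_variance_profile(gauss, gene_groups = 1:3),
               "per gene")
})
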