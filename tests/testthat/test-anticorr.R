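# Pearson / bootstrap-null / KS anticorrelation machinery.

test_that("pearson follows the product-moment definition and contracts", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  y <- c(2, 1, 4, 3, 5)
  expect_equal(pearson(x, y), 0.8)           # frozen from the formula
  expect_equal(pearson(x, y), oracle_pearson(x, y))
  expect_error(pearson(x, rep(1, 5)), "zero variance")
  expect_error(pearson(x, c(1, 2)), "equal length")
  expect_error(pearson(1:2, 2:1), "at least 3")
})

test_that("target correlations respect gene order, layouts, and edge cases", {
  cfg <- sim_config(coupling = 1, noise_sigma = 0, n_genes = 30,
                    n_targets = 8, rng_seed = 4)
  se <- simulate_expression(cfg)
  rt <- target_correlations(se$expr, se$mirna, se$truth$target_gene_ids)
  expect_identical(names(rt), sort(se$truth$target_gene_ids))
  expect_true(all(rt < 0))
  # empty target set
  expect_length(target_correlations(se$expr, se$mirna, character(0)), 0)
  # a gene tracking the miRNA exactly correlates at 1
  expr2 <- rbind(se$expr, tracker = as.numeric(se$mirna))
  expect_equal(unname(target_correlations(expr2, se$mirna, "tracker")), 1)
  expect_error(target_correlations(se$expr, se$mirna, "nope"), "subset")
  # per-age-mean layout collapses replicates to one point per age
  acfg <- anticorr_config(sample_layout = "per-age-mean")
  rt2 <- target_correlations(se$expr, se$mirna,
                             se$truth$target_gene_ids, acfg,
                             samples = se$samples)
  expect_true(all(rt2 < 0))
})

test_that("bootstrap null has the contracted size, seed behaviour, and center", {
  cfg <- sim_config(coupling = 0, noise_sigma = 0.3, n_genes = 400,
                    n_targets = 50, rng_seed = 6)
  se <- simulate_expression(cfg)
  tg <- se$truth$target_gene_ids
  r1 <- bootstrap_null(se$expr, se$mirna, tg, anticorr_config(B = 1))
  expect_length(r1, 50)
  rB <- bootstrap_null(se$expr, se$mirna, tg,
                       anticorr_config(B = 20, rng_seed = 9))
  rB2 <- bootstrap_null(se$expr, se$mirna, tg,
                        anticorr_config(B = 20, rng_seed = 9))
  expect_identical(rB, rB2)
  expect_length(rB, 1000)
  # under the null the pooled correlations center on zero (3 SE band)
  expect_lt(abs(mean(rB)), 3 * stats::sd(rB) / sqrt(350))
  # pool smaller than the target set
  small <- se$expr[c(tg, rownames(se$expr)[1:10]), ][1:55, ]
  expect_error(bootstrap_null(small[1:52, ], se$mirna, tg,
                              anticorr_config()), "pool smaller")
})

test_that("KS comparison matches the exhaustive ECDF-gap oracle", {
  cfg <- anticorr_config()
  same <- c(-0.5, -0.1, 0, 0.2, 0.9)
  expect_equal(ks_compare(same, same, cfg)$D, 0)
  expect_equal(ks_compare(rep(-1, 5), rep(1, 5), cfg)$D, 1)
  a <- c(-0.8, -0.3, -0.2, 0.1, 0.4)
  b <- c(-0.4, -0.1, 0.2, 0.3, 0.7)
  expect_equal(ks_compare(a, b, cfg)$D, oracle_ks_D(a, b))
  set.seed(14)
  for (i in 1:20) {
    a <- rnorm(sample(3:30, 1))
    b <- rnorm(sample(3:30, 1))
    expect_equal(ks_compare(a, b, cfg)$D, oracle_ks_D(a, b))
  }
  expect_error(ks_compare(numeric(0), b, cfg), "non-empty")
})

test_that("effective-null-size p-values are sane and one-sided option detects left shifts", {
  set.seed(15)
  a <- rnorm(200)
  b <- rnorm(5000)
  p_plain <- ks_compare(a, b, anticorr_config())$p
  p_eff <- ks_compare(a, b, anticorr_config(), null_size = 800)$p
  expect_gt(p_eff, 0)
  expect_lte(p_eff, 1)
  expect_gte(p_eff, p_plain)  # smaller effective null = less information
  shifted <- rnorm(200, -1)
  one <- ks_compare(shifted, b,
                    anticorr_config(ks_alternative = "targets-less"),
                    null_size = 800)
  expect_lt(one$p, 1e-6)
})

test_that("the full anticorrelation test separates coupled from null data", {
  se <- simulate_expression(sim_config(coupling = 1, noise_sigma = 0.3,
                                       n_genes = 300, n_targets = 60,
                                       rng_seed = 10))
  res <- anticorr_test(se$expr, se$mirna, se$truth$target_gene_ids,
                       anticorr_config(B = 200, rng_seed = 1))
  expect_lt(res$p, 1e-6)
  expect_lt(median(res$r_t), median(res$r_0))
  se0 <- simulate_expression(sim_config(coupling = 0, noise_sigma = 0.3,
                                        n_genes = 300, n_targets = 60,
                                        rng_seed = 12))
  res0 <- anticorr_test(se0$expr, se0$mirna, se0$truth$target_gene_ids,
                        anticorr_config(B = 200, rng_seed = 1))
  expect_gt(res0$p, 0.01)
})
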