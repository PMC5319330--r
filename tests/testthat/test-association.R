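test_that("median split balances groups and handles ties deterministically", {
  s <- median_split(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(s$threshold, 2.5)
  expect_equal(sort(names(s$groups[s$groups == "high"])), c("c", "d"))

  set.seed(1)
  e <- stats::setNames(rnorm(30), sprintf("v%02d", 1:30))
  s <- median_split(e)
  expect_equal(unname(table(s$groups)["high"]), 15L)
  expect_equal(unname(table(s$groups)["low"]), 15L)

  # ties at the median assigned alternately by sorted id, reproducibly
  e2 <- stats::setNames(c(1, 5, 5, 5, 5, 9), letters[1:6])
  s1 <- median_split(e2); s2 <- median_split(e2)
  expect_identical(s1, s2)
  expect_lte(abs(sum(s1$groups == "high") - sum(s1$groups == "low")), 1)

  expect_error(median_split(c(a = 5, b = 5, c = 5, d = 5)), "degenerate")
})

make_meth <- function(fraction, sites = NULL) {
  if (is.null(sites))
    sites <- data.frame(c_position = seq_len(nrow(fraction)) * 10L,
                        status = "fixed", variant_class = NA, snp_position = NA)
  rownames(fraction) <- as.character(sites$c_position)
  structure(list(meth = fraction, unmeth = 1 - fraction, fraction = fraction,
                 sites = sites, individuals = colnames(fraction)),
            class = "meth_matrix")
}

test_that("per-site differential tests have power and exact null behaviour", {
  inds <- sprintf("i%02d", 1:30)
  split <- list(threshold = 0,
                groups = stats::setNames(rep(c("high", "low"), each = 15), inds))

  # identical groups: t = 0, p = 1
  f <- matrix(0.4, 3, 30, dimnames = list(NULL, inds))
  res <- site_differential(make_meth(f), split)
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 1))

  # a 3-pooled-sd shift is detected
  set.seed(2)
  f <- matrix(rnorm(5 * 30, 0.5, 0.05), 5, 30, dimnames = list(NULL, inds))
  f[3, 1:15] <- f[3, 1:15] + 0.15
  res <- site_differential(make_meth(f), split)
  expect_lt(res$p[3], 0.01)
  expect_equal(which.min(res$p), 3L)
  expect_true(all(res$p_adj >= res$p))
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  set.seed(3)
  for (i in 1:5) {
    p <- runif(20)^2
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p))
  }
  # and through the site_differential interface
  inds <- sprintf("i%02d", 1:20)
  split <- list(groups = stats::setNames(rep(c("high", "low"), 10), inds))
  f <- matrix(runif(8 * 20), 8, 20, dimnames = list(NULL, inds))
  res <- site_differential(make_meth(f), split)
  expect_equal(res$p_adj, oracle_bh(res$p))
})

test_that("feature tests recover a simulated enhancer-expression link", {
  w <- shared_world()
  set.seed(4)
  ex <- simulate_expression(w$cohort, w$meth_truth, w$sim, model = "density",
                            seed = 41)
  counts <- simulate_counts(w$meth_truth, w$cohort, w$sim, coverage = 100,
                            seed = 42)
  split <- median_split(ex$expression)
  ft <- feature_tests(counts$meth, w$features, split, ex$expression)
  enh <- ft[ft$feature == "Enhancer", ]
  prom <- ft[ft$feature == "Promoter", ]
  expect_lt(enh$r, -0.4)
  expect_lt(enh$p_r, 0.01)
  expect_gt(prom$p_r, 0.05)

  # permuting expression destroys the association
  set.seed(5)
  perm_p <- replicate(30, {
    pe <- stats::setNames(sample(ex$expression), names(ex$expression))
    ftp <- feature_tests(counts$meth, w$features, NULL, pe)
    ftp$p_r[ftp$feature == "Enhancer"]
  })
  expect_gt(mean(perm_p > 0.05), 0.8)
})

test_that("genotype tests match brute-force ANOVA and Kendall extremes", {
  y <- c(10, 12, 14, 20, 22, 24, 30, 31, 35)
  g <- stats::setNames(rep(0:2, each = 3), paste0("i", 1:9))
  names(y) <- names(g)
  res <- genotype_tests(g, y)
  expect_equal(res$anova_F, oracle_anova_f(y, g), tolerance = 1e-12)

  # equal group means: F near zero
  y2 <- stats::setNames(rep(c(1, 2, 3), 3), names(g))
  expect_lt(genotype_tests(g, y2)$anova_F, 1e-10)

  # counts perfectly decreasing in HI dosage: tau-b = -1
  cnt <- stats::setNames(c(16, 16, 16, 14, 14, 14, 12, 12, 12), names(g))
  res <- genotype_tests(g, y, enhancer_cpg_counts = -cnt)
  expect_equal(res$kendall_tau, 1)
  res <- genotype_tests(g, y, enhancer_cpg_counts = cnt)
  expect_equal(res$kendall_tau, -1)
})

test_that("the matching generative model wins the predictor comparison", {
  w <- shared_world()
  counts <- simulate_counts(w$meth_truth, w$cohort, w$sim, coverage = 100,
                            seed = 43)
  meas <- suppressWarnings(polycpg_measures(counts$meth, counts$genotypes))
  focal <- w$sim$truth$focal_polycpg
  for (model in c("density", "tf_genotype", "tf_meth_sensitive")) {
    ex <- simulate_expression(w$cohort, w$meth_truth, w$sim, model = model,
                              seed = 44)
    cmp <- polycpg_model_comparison(meas, ex$expression)
    top <- cmp$top[cmp$top$c_position == focal, ]
    want <- switch(model, density = "total_meth", tf_genotype = "genotype",
                   tf_meth_sensitive = "meth_per_cpg")
    expect_equal(top$predictor, want)
  }
  # constant expression: no defined correlations
  const <- stats::setNames(rep(5000, 30), w$cohort$individuals)
  cmp <- polycpg_model_comparison(meas, const)
  expect_true(all(is.na(cmp$results$r)))
})

test_that("variant spectrum test matches the direct chi-square formula", {
  mk_cat <- function(counts) {
    classes <- c("CpG/CpA", "CpG/CpC", "CpG/CpT",
                 "CpG/ApG", "CpG/GpG", "CpG/TpG")
    data.frame(c_position = seq_len(sum(counts)),
               status = "polymorphic",
               variant_class = rep(classes, counts),
               snp_position = seq_len(sum(counts)))
  }
  res <- spectrum_test(mk_cat(rep(5L, 6)))
  expect_equal(res$chi_square, 0)
  expect_equal(res$p, 1)

  counts <- c(13L, 1L, 2L, 2L, 1L, 10L)
  res <- spectrum_test(mk_cat(counts))
  expect_equal(res$chi_square, oracle_chisq_uniform(counts), tolerance = 1e-12)
  expect_equal(res$df, 5)
  expect_lt(res$p, 1e-4)

  empty <- data.frame(c_position = 1L, status = "fixed",
                      variant_class = NA_character_, snp_position = NA)
  expect_error(spectrum_test(empty), "no bi-allelic")
})

test_that("Fisher two-sided p equals exhaustive hypergeometric enumeration", {
  expect_equal(distribution_fisher(5, 5, 5, 5)$p_two_sided, 1)
  set.seed(6)
  for (i in 1:20) {
    tot <- sample(20:300, 1)
    a <- sample(0:min(tot, 40), 1); b <- sample(0:40, 1)
    c <- sample(0:40, 1)
    d <- tot - a - b - c
    if (d < 0 || a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    expect_equal(distribution_fisher(a, b, c, d)$p_two_sided,
                 oracle_fisher_p(a, b, c, d), tolerance = 1e-9)
  }
  expect_error(distribution_fisher(0, 0, 5, 5), "positive margins")
})

test_that("PWM affinity differences are allele- and strand-consistent", {
  pwm <- matrix(c(0, 10, 0, 0,   # C
                  0, 0, 10, 0,   # G
                  0, 10, 0, 0,   # C
                  0, 0, 10, 0),  # G
                nrow = 4)
  wa <- "AACGCGTTAA"; wb <- "AACACGTTAA"
  res <- pwm_allele_affinity(list(cg_motif = pwm), wa, wb)
  expect_gt(res$difference, 0)  # consensus matches allele A's core only

  expect_equal(pwm_allele_affinity(list(m = pwm), wa, wa)$difference, 0)

  rc <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  res_rc <- pwm_allele_affinity(list(m = pwm), rc(wa), rc(wb))
  expect_equal(res_rc$difference, res$difference)

  long <- matrix(1, 4, 30)
  expect_warning(out <- pwm_allele_affinity(list(too_long = long), wa, wb),
                 "longer than window")
  expect_null(out)

  # supplied motif p-values are BH-adjusted alongside
  res2 <- pwm_allele_affinity(list(a = pwm, b = pwm[, 1:2]), wa, wb,
                              p_values = c(a = 0.01, b = 0.04))
  expect_true(all(res2$p_adj >= c(0.01, 0.04)[match(res2$motif, c("a", "b"))]))
})
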