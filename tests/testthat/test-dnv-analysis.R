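# De novo burden, weights, weighted enrichment and gene-set permutation.

test_that("poisson tail P matches direct pmf summation", {
  expect_equal(poisson_tail_p(0, 5), 1)
  expect_equal(poisson_tail_p(0, 1e-9), 1)
  # oracle: direct summation of the pmf
  expect_equal(poisson_tail_p(5, 0.2027), sum(dpois(5:200, 0.2027)),
               tolerance = 1e-12)
  for (k in c(1, 3, 10))
    expect_equal(poisson_tail_p(k, 2.5), 1 - ppois(k - 1, 2.5))
  expect_error(poisson_tail_p(2, 0), "positive")
})

test_that("DNV preprocessing collapses 100-bp clusters to the most severe variant", {
  rec <- data.frame(
    individual_id = c("i1", "i1", "i2", "i2"),
    gene_id = "G1",
    variant_class = c("lof", "dmis", "syn", "syn"),
    position = c(100L, 150L, 100L, 300L),
    twin_group = NA_character_, stringsAsFactors = FALSE)
  out <- preprocess_dnvs(rec)
  expect_equal(out$variant_class[out$individual_id == "i1"], "lof")  # 50 bp apart
  expect_equal(sum(out$individual_id == "i2"), 2)                    # 200 bp apart
  # idempotent
  expect_identical(preprocess_dnvs(out), out)
})

test_that("DNVs shared by monozygotic twins count once", {
  rec <- data.frame(
    individual_id = c("tw_a", "tw_b", "i3"),
    gene_id = "G1", variant_class = "lof",
    position = c(500L, 500L, 500L),
    twin_group = c("T1", "T1", NA), stringsAsFactors = FALSE)
  out <- preprocess_dnvs(rec)
  expect_equal(nrow(out), 2)  # one twin event + the unrelated singleton
  expect_identical(preprocess_dnvs(out), out)
})

test_that("preprocessing is idempotent on random record sets", {
  set.seed(99)
  for (rep in 1:5) {
    rec <- data.frame(
      individual_id = sample(paste0("i", 1:6), 40, replace = TRUE),
      gene_id = sample(c("G1", "G2"), 40, replace = TRUE),
      variant_class = sample(c("lof", "dmis", "other_mis", "syn"), 40, TRUE),
      position = sample.int(1000, 40, replace = TRUE),
      twin_group = NA_character_, stringsAsFactors = FALSE)
    once <- preprocess_dnvs(rec)
    expect_identical(preprocess_dnvs(once), once)
  }
})

test_that("cohort burden reports rates, ratio, and the PAR-style rate difference", {
  mk <- function(n, gene = "G1", cls = "lof")
    data.frame(individual_id = paste0("i", seq_len(n)), gene_id = gene,
               variant_class = cls, position = 1L, stringsAsFactors = FALSE)
  eq <- cohort_burden(mk(20), mk(10), 1000, 500)
  expect_equal(eq$rate_ratio, 1)
  expect_equal(eq$rate_difference, 0)

  b <- cohort_burden(mk(300), mk(100), 1000, 500)  # 0.30 vs 0.20 per offspring
  expect_equal(b$rate_difference, 0.10)
  expect_equal(b$rate_case, 0.30)

  # doubling counts and trios leaves the rates unchanged
  b2 <- cohort_burden(mk(600), mk(200), 2000, 1000)
  expect_equal(b2$rate_case, b$rate_case)
  expect_equal(b2$rate_control, b$rate_control)
  expect_error(cohort_burden(mk(1), mk(1), 0, 10), "positive")
})

test_that("PPV weights are the clipped excess fraction", {
  w <- derive_ppv_weights(c(a = 300, b = 100, c = 100),
                          c(a = 100, b = 100, c = 150))
  expect_equal(unname(w["a"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(w["b"]), 0)
  expect_equal(unname(w["c"]), 0)  # O < E clipped
  expect_error(derive_ppv_weights(c(a = 1), c(a = 0)), "positive")
})

test_that("weighted enrichment with one unit-weight class reduces to the Poisson tail", {
  lambda <- 0.8
  obs <- c(lof = 4)
  exact <- poisson_tail_p(4, lambda)
  res <- weighted_enrichment_test(obs, c(lof = lambda), c(lof = 1),
                                  n_sim = 2e4, seed = 123)
  mc_se <- sqrt(exact * (1 - exact) / 2e4)
  expect_lt(abs(res$p_value - exact), 3 * mc_se + 2 / 2e4)
})

test_that("weighted enrichment edge cases and enumeration oracle", {
  # all observed zero -> P = 1
  res0 <- weighted_enrichment_test(c(lof = 0, dmis = 0),
                                   c(lof = 0.3, dmis = 0.2),
                                   n_sim = 1000, seed = 1)
  expect_equal(res0$p_value, 1)
  # degenerate: zero expectation with nonzero observation
  expect_warning(
    resd <- weighted_enrichment_test(c(lof = 2), c(lof = 0), c(lof = 1),
                                     n_sim = 1000, seed = 1),
    "zero")
  expect_equal(resd$p_value, 1 / 1001)
  # two classes, tiny expectations: matches exhaustive enumeration
  e <- c(lof = 0.05, dmis = 0.08)
  w <- c(lof = 1, dmis = 0.5)
  obs <- c(lof = 1, dmis = 1)
  exact <- weighted_two_class_tail(sum(w * obs), e["lof"], e["dmis"],
                                   w["lof"], w["dmis"])
  res <- weighted_enrichment_test(obs, e, w, n_sim = 5e4, seed = 7)
  mc_se <- sqrt(exact * (1 - exact) / 5e4)
  expect_lt(abs(res$p_value - exact), 4 * mc_se + 2 / 5e4)
  # reproducible given seed
  res2 <- weighted_enrichment_test(obs, e, w, n_sim = 5e4, seed = 7)
  expect_identical(res$p_value, res2$p_value)
})

test_that("weighted enrichment is conservative under the null", {
  set.seed(2024)
  n_genes <- 1000
  e <- c(lof = 0.5, dmis = 0.8)
  w <- c(lof = 1, dmis = 0.6)
  rej <- 0
  for (i in seq_len(n_genes)) {
    obs <- c(lof = rpois(1, e["lof"]), dmis = rpois(1, e["dmis"]))
    names(obs) <- names(e)
    p <- weighted_enrichment_test(obs, e, w, n_sim = 1000)$p_value
    rej <- rej + (p < 0.05)
  }
  expect_lte(rej / n_genes, 0.06)
})

test_that("gene-set permutation matches the analytic two-gene case", {
  genes <- data.frame(gene_id = c("g1", "g2"), mu_lof = c(1e-6, 1e-6),
                      stringsAsFactors = FALSE)
  rec <- data.frame(individual_id = c("i1", "i2", "i3"), gene_id = "g1",
                    variant_class = "lof", stringsAsFactors = FALSE)
  res <- geneset_permutation_test(rec, "g1", genes, n_perm = 8000, seed = 5)
  # all 3 mutations land in g1 with probability (1/2)^3 = 1/8
  expect_lt(abs(res$p_value - 1 / 8), 4 * sqrt(0.125 * 0.875 / 8000))
  # fold enrichment invariant to uniform mu scaling (same seed, same draws)
  genes2 <- genes; genes2$mu_lof <- genes$mu_lof * 10
  res2 <- geneset_permutation_test(rec, "g1", genes2, n_perm = 8000, seed = 5)
  expect_identical(res$fold_enrichment, res2$fold_enrichment)
  # bit-reproducible under a fixed seed
  res3 <- geneset_permutation_test(rec, "g1", genes, n_perm = 8000, seed = 5)
  expect_identical(res$p_value, res3$p_value)
  expect_identical(res$fold_enrichment, res3$fold_enrichment)
})

test_that("gene-set permutation over the full gene universe is null", {
  genes <- data.frame(gene_id = paste0("g", 1:5),
                      mu_lof = c(1, 2, 3, 4, 5) * 1e-6,
                      stringsAsFactors = FALSE)
  rec <- data.frame(individual_id = paste0("i", 1:6),
                    gene_id = sample(genes$gene_id, 6, replace = TRUE),
                    variant_class = "lof", stringsAsFactors = FALSE)
  res <- geneset_permutation_test(rec, genes$gene_id, genes,
                                  n_perm = 200, seed = 2)
  expect_equal(res$fold_enrichment, 1)
  expect_gte(res$p_value, 0.99)
  expect_error(geneset_permutation_test(rec, character(0), genes), "empty")
})
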