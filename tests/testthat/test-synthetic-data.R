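# The cohort generator: determinism, equilibrium structure, transmission
# distortion, de novo rates and population controls.

test_that("gene panel is reproducible, respects f = mu/s and the fitness constraint", {
  cfg <- sim_config(seed = 3, n_genes = 100, risk_gene_fraction = 0.1,
                    n_trios = 10, n_controls = 100)
  p1 <- simulate_gene_panel(cfg)
  p2 <- simulate_gene_panel(cfg)
  expect_identical(p1$genes, p2$genes)
  expect_identical(p1$truth, p2$truth)
  expect_equal(p1$truth$f, p1$truth$mu_lof / p1$truth$s)
  risk <- p1$truth$gamma > 1
  expect_equal(sum(risk), 10)
  expect_true(all(p1$truth$s[risk] >= 0.013 * p1$truth$gamma[risk]))

  cfg0 <- sim_config(seed = 3, n_genes = 50, risk_gene_fraction = 0,
                     n_trios = 10, n_controls = 100)
  expect_true(all(simulate_gene_panel(cfg0)$truth$gamma == 1))

  # infeasible (gamma, s): constraint cannot be satisfied within the s range
  cfg_bad <- sim_config(seed = 3, n_genes = 10, risk_gene_fraction = 0.5,
                        gamma_dist = 50, s_dist = c(0.01, 0.5),
                        n_trios = 10, n_controls = 100)
  expect_error(simulate_gene_panel(cfg_bad), "infeasible")
  # rare-variant regime guard
  cfg_f <- sim_config(seed = 3, n_genes = 5, risk_gene_fraction = 0,
                      s_dist = 0.01, mu_lof_dist = 1e-3,
                      n_trios = 10, n_controls = 100)
  expect_error(simulate_gene_panel(cfg_f), "2f")
})

test_that("transmission to affected offspring is distorted by gamma/(1+gamma)", {
  # gamma = 4: P(transmit | affected child) = 0.8
  cfg <- sim_config(seed = 19, n_genes = 4, risk_gene_fraction = 1,
                    gamma_dist = 4, s_dist = 0.012, mu_lof_dist = 3e-4,
                    n_trios = 4000, n_controls = 100,
                    enforce_constraint = FALSE, include_synonymous = FALSE)
  co <- simulate_cohort(cfg)
  tr <- tally_transmissions(co$variants, co$pedigrees)
  tr <- tr[tr$offspring_affected, ]
  n <- nrow(tr)
  expect_gt(n, 1000)
  p_hat <- mean(tr$transmitted)
  expect_lt(abs(p_hat - 0.8), 4 * sqrt(0.8 * 0.2 / n))

  # gamma = 1: both offspring types transmit at 1/2
  cfg1 <- sim_config(seed = 20, n_genes = 4, risk_gene_fraction = 0,
                     s_dist = 0.012, mu_lof_dist = 3e-4,
                     n_trios = 2000, n_control_trios = 2000, n_controls = 100,
                     include_synonymous = FALSE)
  co1 <- simulate_cohort(cfg1)
  tr1 <- tally_transmissions(co1$variants, co1$pedigrees)
  for (aff in c(TRUE, FALSE)) {
    sub <- tr1[tr1$offspring_affected == aff, ]
    expect_lt(abs(mean(sub$transmitted) - 0.5),
              4 * sqrt(0.25 / nrow(sub)))
  }
})

test_that("unaffected-offspring transmission follows the conditional probability", {
  # gamma = 8, pi = 1/54: q = (1 - 8/54) / ((1 - 8/54) + (53/54))
  gam <- 8; pi_ <- 1 / 54
  q_expected <- (1 - gam * pi_) / ((1 - gam * pi_) + (1 - pi_))
  cfg <- sim_config(seed = 21, n_genes = 4, risk_gene_fraction = 1,
                    gamma_dist = gam, s_dist = 0.104, mu_lof_dist = 1e-3,
                    n_trios = 0, n_control_trios = 8000, n_controls = 100,
                    include_synonymous = FALSE)
  co <- simulate_cohort(cfg)
  tr <- tally_transmissions(co$variants, co$pedigrees)
  tr <- tr[!tr$offspring_affected, ]
  expect_gt(nrow(tr), 500)
  expect_lt(abs(mean(tr$transmitted) - q_expected),
            4 * sqrt(q_expected * (1 - q_expected) / nrow(tr)))
})

test_that("de novo counts are exchangeable at gamma = 1 and Poisson-consistent", {
  cfg <- sim_config(seed = 29, n_genes = 50, risk_gene_fraction = 0,
                    s_dist = 0.1, mu_lof_dist = c(1e-6, 1e-5),
                    n_trios = 2000, n_control_trios = 2000, n_controls = 100)
  co <- simulate_cohort(cfg)
  aff <- co$pedigrees$affected[match(co$dnvs$individual_id, co$pedigrees$id)]
  n_case_lof <- sum(aff & co$dnvs$variant_class == "lof")
  n_ctrl_lof <- sum(!aff & co$dnvs$variant_class == "lof")
  expected <- 2 * 2000 * sum(co$genes$mu_lof)
  expect_lt(abs(n_case_lof - expected), 4 * sqrt(expected) + 1)
  expect_lt(abs(n_ctrl_lof - expected), 4 * sqrt(expected) + 1)
  # synonymous total matches its own expectation
  n_syn <- sum(co$dnvs$variant_class == "syn")
  e_syn <- 2 * 4000 * sum(co$genes$mu_syn)
  expect_lt(abs(n_syn - e_syn), 4 * sqrt(e_syn) + 1)
})

test_that("population controls draw carriers at 2 n f and recover s", {
  cfg <- sim_config(seed = 37, n_genes = 40, risk_gene_fraction = 0,
                    s_dist = c(0.02, 0.1), mu_lof_dist = c(5e-6, 2e-5),
                    n_trios = 10, n_controls = 100000)
  panel <- simulate_gene_panel(cfg)
  acs <- simulate_population_controls(panel, 100000, source = "ref")
  lof <- acs[acs$variant_class == "lof", ]
  expect_equal(lof$gene_id, panel$truth$gene_id)
  expected <- 2 * 100000 * panel$truth$f
  big <- expected >= 50
  expect_gt(sum(big), 10)
  # s_hat = mu / f_hat within 30% when >= 50 carriers are expected
  f_hat <- lof$carriers / (2 * lof$sample_size)
  s_hat <- panel$truth$mu_lof / f_hat
  rel_err <- abs(s_hat - panel$truth$s) / panel$truth$s
  expect_true(all(rel_err[big] < 0.3))
  # seed determinism of the whole cohort draw
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$variants, c2$variants)
  expect_identical(c1$dnvs, c2$dnvs)
  expect_identical(c1$controls, c2$controls)
})

test_that("phenotype flags depend on carrier status and are reproducible", {
  cfg <- sim_config(seed = 43, n_genes = 10, risk_gene_fraction = 0.2,
                    gamma_dist = 6, s_dist = c(0.078, 0.5),
                    mu_lof_dist = 1e-4, n_trios = 2000, n_controls = 100,
                    impairment_base_rate = 0.5, impairment_carrier_rate = 0.88,
                    include_synonymous = FALSE)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$pedigrees$cognitive_impairment,
                   c2$pedigrees$cognitive_impairment)
  ped <- c1$pedigrees
  risk_genes <- c1$truth$gene_id[c1$truth$gamma > 1]
  carriers <- unique(c1$variants$individual_id[
    c1$variants$gene_id %in% risk_genes & c1$variants$variant_class == "lof"])
  aff <- ped[ped$affected, ]
  rate_car <- mean(aff$cognitive_impairment[aff$id %in% carriers])
  rate_non <- mean(aff$cognitive_impairment[!aff$id %in% carriers])
  expect_gt(rate_car, rate_non)
  expect_lt(abs(rate_non - 0.5), 0.05)
})

test_that("carrier-dependent impairment is detectable by the group comparison", {
  # 0.88 vs 0.50 at ~100 per group, as a chi-square on the 2x2 table
  set.seed(47)
  power_hits <- 0
  for (rep in 1:20) {
    car <- rbinom(1, 100, 0.88)
    non <- rbinom(1, 100, 0.50)
    m <- matrix(c(car, 100 - car, non, 100 - non), 2, byrow = TRUE)
    p <- suppressWarnings(chisq.test(m, correct = FALSE)$p.value)
    power_hits <- power_hits + (p < 0.001)
  }
  expect_gte(power_hits / 20, 0.9)
})
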