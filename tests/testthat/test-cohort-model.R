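# Pedigree model: kinship, relatedness graph, unrelated selection,
# contributing sample sizes and pseudo-sample construction.

test_that("recursive kinship matches textbook values and the gene-dropping oracle", {
  fam <- data.frame(
    id = c("f", "m", "c1", "c2", "m2", "h1"),
    family_id = "F1",
    father_id = c(NA, NA, "f", "f", NA, "f"),
    mother_id = c(NA, NA, "m", "m", NA, "m2"),
    sex = c("male", "female", "male", "female", "female", "male"),
    affected = FALSE, stringsAsFactors = FALSE)
  expect_equal(kinship_coefficient(fam, "f", "c1"), 0.25)   # parent-child
  expect_equal(kinship_coefficient(fam, "f", "f"), 0.5)     # non-inbred founder
  expect_equal(kinship_coefficient(fam, "c1", "c2"), 0.25)  # full siblings
  expect_equal(kinship_coefficient(fam, "c1", "h1"), 0.125) # half siblings
  expect_equal(kinship_coefficient(fam, "c1", "f"),
               kinship_coefficient(fam, "f", "c1"))

  set.seed(42)
  expect_equal(gene_drop_kinship(fam, "c1", "c2", n_drops = 1e6), 0.25,
               tolerance = 0.01)
  expect_equal(gene_drop_kinship(fam, "c1", "h1", n_drops = 1e6), 0.125,
               tolerance = 0.01)
  expect_error(kinship_coefficient(fam, "f", "nobody"), "unknown")
})

test_that("kinship recursion agrees with gene dropping on random 3-generation pedigrees", {
  set.seed(7)
  for (rep in 1:10) {
    fam <- random_three_gen_pedigree()
    pair <- sample(fam$id, 2)
    phi <- kinship_coefficient(fam, pair[1], pair[2])
    n_drops <- 5e4
    phi_hat <- gene_drop_kinship(fam, pair[1], pair[2], n_drops = n_drops)
    # 4 binomial-scale standard errors plus a floor for tiny phi
    tol <- 4 * sqrt(max(phi * (1 - phi), 0.01) / n_drops) + 1e-3
    expect_lt(abs(phi - phi_hat), tol + 0.01)
  }
})

test_that("relatedness graph contains declared and thresholded inferred edges", {
  trio <- make_trio()
  g <- build_relatedness_graph(trio)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)  # two parent-child edges, no spousal edge

  singles <- data.frame(id = c("a", "b"), family_id = c("FA", "FB"),
                        father_id = NA_character_, mother_id = NA_character_,
                        sex = "male", affected = FALSE, stringsAsFactors = FALSE)
  g0 <- build_relatedness_graph(singles,
    inferred = data.frame(id1 = "a", id2 = "b", kinship = 0.05))
  expect_equal(igraph::ecount(g0), 0)  # below threshold
  g1 <- build_relatedness_graph(singles,
    inferred = data.frame(id1 = "a", id2 = "b", kinship = 0.12))
  expect_equal(igraph::ecount(g1), 1)
  expect_equal(igraph::E(g1)$source, "inferred_kinship")
  expect_error(build_relatedness_graph(singles,
    inferred = data.frame(id1 = "a", id2 = "b", kinship = 0.7)), "0, 0.5")
})

test_that("X-mode drops father-son edges", {
  trio <- make_trio(child_sex = "male")
  gx <- build_relatedness_graph(trio, x_mode = TRUE)
  expect_equal(igraph::ecount(gx), 1)  # mother-son only
  trio_f <- make_trio(child_sex = "female")
  expect_equal(igraph::ecount(build_relatedness_graph(trio_f, x_mode = TRUE)), 2)
})

test_that("select_unrelated picks exactly one individual per component", {
  trio <- make_trio()
  g <- build_relatedness_graph(trio)
  sel <- select_unrelated(g, trio)
  expect_length(sel, 1)
  expect_equal(sel, "F1_ch")  # affected has priority

  singles <- data.frame(id = letters[1:5], family_id = paste0("F", 1:5),
                        father_id = NA_character_, mother_id = NA_character_,
                        sex = "male", affected = FALSE, stringsAsFactors = FALSE)
  g5 <- build_relatedness_graph(singles)
  expect_equal(select_unrelated(g5, singles), letters[1:5])  # n isolated -> n

  gab <- build_relatedness_graph(singles,
    inferred = data.frame(id1 = "a", id2 = "b", kinship = 0.2))
  sel2 <- select_unrelated(gab, singles)
  expect_length(sel2, 4)  # {a,b} collapse to one pick
  # deterministic: smallest id wins without affection priority
  expect_true("a" %in% sel2 && !"b" %in% sel2)
  # independent set: no selected pair shares an edge
  expect_equal(igraph::ecount(igraph::induced_subgraph(gab, sel2)), 0)
})

test_that("contributing sample size follows the kinship-sum formula", {
  trio <- make_trio()
  expect_equal(contributing_sample_size(trio, "F1_ch")$weight, 0.5)

  duo <- trio[-1, ]  # father not sampled
  duo$father_id <- NA_character_
  expect_equal(contributing_sample_size(duo, "F1_ch")$weight, 0.75)

  singleton <- data.frame(id = "s", family_id = "FS",
                          father_id = NA_character_, mother_id = NA_character_,
                          sex = "male", affected = TRUE, stringsAsFactors = FALSE)
  expect_equal(contributing_sample_size(singleton, "s")$weight, 1)

  # excluded parent is skipped; search continues to the grandparents
  fam <- data.frame(
    id = c("gf", "gm", "mo", "fa", "ch"),
    family_id = "F1",
    father_id = c(NA, NA, "gf", NA, "fa"),
    mother_id = c(NA, NA, "gm", NA, "mo"),
    sex = c("male", "female", "female", "male", "male"),
    affected = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    excluded_parent = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  res <- contributing_sample_size(fam, "ch")
  expect_setequal(res$ancestors, c("gf", "gm"))
  expect_equal(res$weight, 1 - 0.125 - 0.125)
})

test_that("pseudocontrols count untransmitted alleles of eligible parents", {
  peds <- rbind(make_trio("F1"), make_trio("F2"))
  v <- rbind(
    variant_row("F1_fa", "GENE1", "a1"),          # untransmitted
    variant_row("F2_mo", "GENE2", "a2"),          # transmitted
    variant_row("F2_ch", "GENE2", "a2"))
  pc <- construct_pseudocontrols(peds, v)
  expect_equal(pc$n_eff, 2.0)                      # 4 eligible parents x 0.5
  expect_equal(pc$counts$gene_id, "GENE1")
  expect_equal(pc$counts$carriers, 1L)             # transmitted allele absent

  peds2 <- peds
  peds2$excluded_parent[peds2$id == "F1_fa"] <- TRUE  # parent with a diagnosis
  pc2 <- construct_pseudocontrols(peds2, v)
  expect_equal(pc2$n_eff, 1.5)
  expect_equal(nrow(pc2$counts), 0)                # excluded parent contributes nothing
})

test_that("pseudocases drop ancestor-seen alleles and de novo alleles", {
  duo <- make_trio("D1")[-1, ]
  duo$father_id <- NA_character_
  v <- rbind(
    variant_row("D1_mo", "GENE1", "m1"),
    variant_row("D1_ch", "GENE1", "m1"),   # seen in the sampled mother
    variant_row("D1_ch", "GENE2", "c1"),   # unattributable -> kept
    variant_row("D1_ch", "GENE3", "dnv1")) # de novo -> removed
  pc <- construct_pseudocases(duo, v, dnv_alleles = "dnv1")
  expect_equal(pc$n_eff, 0.75)
  expect_equal(pc$counts$gene_id, "GENE2")
  expect_equal(pc$counts$carriers, 1L)
})

test_that("pseudocase alleles are disjoint from ancestor-transmitted alleles in a simulated cohort", {
  cfg <- sim_config(seed = 31, n_genes = 30, risk_gene_fraction = 0.1,
                    gamma_dist = 4, s_dist = c(0.052, 0.5),
                    mu_lof_dist = c(1e-5, 1e-4),
                    n_trios = 300, n_duos = 100, n_singleton_cases = 50,
                    n_controls = 1000, include_synonymous = FALSE)
  co <- simulate_cohort(cfg)
  pc <- construct_pseudocases(co$pedigrees, co$variants,
                              dnv_alleles = co$dnvs$allele_id)
  # alleles transmitted from sampled parents never reach pseudocases
  expect_false(any(pc$rows$origin == "inherited"))
  # effective N identity for pseudocontrols
  ctl <- construct_pseudocontrols(co$pedigrees, co$variants)
  expect_equal(ctl$n_eff, 0.5 * length(ctl$parents))
})

test_that("PED reader round-trips core and extension columns", {
  path <- tempfile(fileext = ".ped")
  writeLines(c(
    "FID\tIID\tPAT\tMAT\tSEX\tPHENO\texcluded_parent\ttwin_group",
    "F1\tfa\t0\t0\t1\t1\tFALSE\t0",
    "F1\tmo\t0\t0\t2\t1\tTRUE\t0",
    "F1\tch\tfa\tmo\t1\t2\tFALSE\ttw1"), path)
  ped <- read_ped(path)
  expect_equal(nrow(ped), 3)
  expect_true(is.na(ped$father_id[1]))
  expect_equal(ped$father_id[3], "fa")
  expect_true(ped$affected[3])
  expect_true(ped$excluded_parent[2])
  expect_equal(ped$twin_group[3], "tw1")
  # malformed pedigree: father referenced but missing
  bad <- data.frame(id = "c", family_id = "F", father_id = "ghost",
                    mother_id = NA_character_, sex = "male", affected = TRUE,
                    stringsAsFactors = FALSE)
  expect_error(as_pedigree(bad), "not found")
})
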