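# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Monte Carlo gene-dropping estimate of the kinship coefficient: drop founder
# alleles down the pedigree and average the probability that a randomly drawn
# allele from each individual is identical by descent.
gene_drop_kinship <- function(fam, a, b, n_drops = 1e5) {
  ids <- fam$id
  fa <- fam$father_id
  mo <- fam$mother_id
  ## founder-first ordering
  ord <- character(0)
  remaining <- ids
  while (length(remaining) > 0) {
    idx <- match(remaining, ids)
    ready <- (is.na(fa[idx]) | fa[idx] %in% ord) &
             (is.na(mo[idx]) | mo[idx] %in% ord)
    ord <- c(ord, remaining[ready])
    remaining <- remaining[!ready]
  }
  al1 <- al2 <- list()
  counter <- 0L
  for (id in ord) {
    i <- match(id, ids)
    if (is.na(fa[i]) && is.na(mo[i])) {
      al1[[id]] <- rep(counter + 1L, n_drops)
      al2[[id]] <- rep(counter + 2L, n_drops)
      counter <- counter + 2L
    } else {
      pick <- function(p) {
        if (is.na(p)) {  # unsampled parent: fresh founder alleles
          counter <<- counter + 2L
          u <- stats::runif(n_drops) < 0.5
          ifelse(u, counter - 1L, counter)
        } else {
          u <- stats::runif(n_drops) < 0.5
          ifelse(u, al1[[p]], al2[[p]])
        }
      }
      al1[[id]] <- pick(fa[i])
      al2[[id]] <- pick(mo[i])
    }
  }
  mean((al1[[a]] == al1[[b]]) + (al1[[a]] == al2[[b]]) +
       (al2[[a]] == al1[[b]]) + (al2[[a]] == al2[[b]])) / 4
}

# three-generation pedigree with randomized sibship sizes
random_three_gen_pedigree <- function(family_id = "F1") {
  n_kids1 <- sample(1:3, 1)
  n_kids2 <- sample(1:3, 1)
  rows <- list(
    data.frame(id = c("gf", "gm", "s1", "s2"), family_id = family_id,
               father_id = NA_character_, mother_id = NA_character_,
               sex = c("male", "female", "male", "female"),
               affected = FALSE, stringsAsFactors = FALSE),
    data.frame(id = c("p1", "p2"), family_id = family_id,
               father_id = "gf", mother_id = "gm",
               sex = c("female", "male"), affected = FALSE,
               stringsAsFactors = FALSE),
    data.frame(id = paste0("k1_", seq_len(n_kids1)), family_id = family_id,
               father_id = "s1", mother_id = "p1", sex = "male",
               affected = TRUE, stringsAsFactors = FALSE),
    data.frame(id = paste0("k2_", seq_len(n_kids2)), family_id = family_id,
               father_id = "p2", mother_id = "s2", sex = "female",
               affected = TRUE, stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# exact tail of the conditional binomial two-rate comparison
cond_binom_oracle <- function(k_case, K, p0) {
  if (K == 0) return(1)
  if (k_case == 0) return(1)
  sum(stats::dbinom(k_case:K, K, p0))
}

# textbook 2x2 chi-square without continuity correction
chisq_2x2_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# exact distribution of a weighted score of two independent Poisson counts,
# truncated at k_max (expectations are tiny so the truncation is negligible)
weighted_two_class_tail <- function(obs_score, e1, e2, w1, w2, k_max = 10) {
  p <- 0
  for (x in 0:k_max)
    for (y in 0:k_max)
      if (w1 * x + w2 * y >= obs_score)
        p <- p + stats::dpois(x, e1) * stats::dpois(y, e2)
  p
}

# small canonical trio pedigree used by several tests
make_trio <- function(family_id = "F1", affected_child = TRUE,
                      child_sex = "male") {
  data.frame(
    id = paste0(family_id, c("_fa", "_mo", "_ch")),
    family_id = family_id,
    father_id = c(NA, NA, paste0(family_id, "_fa")),
    mother_id = c(NA, NA, paste0(family_id, "_mo")),
    sex = c("male", "female", child_sex),
    affected = c(FALSE, FALSE, affected_child),
    stringsAsFactors = FALSE)
}

variant_row <- function(ind, gene, allele, class = "lof", af = 1e-6,
                        hc = TRUE, chrom = "autosomal") {
  data.frame(individual_id = ind, gene_id = gene, allele_id = allele,
             variant_class = class, af = af, high_confidence = hc,
             chrom_class = chrom, stringsAsFactors = FALSE)
}
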