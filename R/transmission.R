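## Transmission disequilibrium analysis of ultra-rare inherited alleles.

#' Tally transmissions of rare parental alleles to offspring
#'
#' Builds one record per eligible heterozygous parental allele x sequenced
#' offspring. Eligible parents are sequenced, unaffected and non-excluded (no
#' diagnosis of the disorder or intellectual disability). On the non-PAR X
#' only transmissions from unaffected mothers are considered (father-son X
#' pairs produce no record). Offspring in a declared monozygotic twin group
#' are counted once. A transmission is resolved by looking the allele up in
#' the offspring's observations; `transmitted = TRUE` when the offspring
#' carries it.
#'
#' @param variants variant observation data.frame (`individual_id`,
#'   `gene_id`, `allele_id`, `variant_class`, `af`, `high_confidence`,
#'   optional `chrom_class`).
#' @param peds pedigree `data.frame`.
#' @param max_af allele frequency ceiling (default 1e-5, ultra-rare).
#' @param require_high_confidence keep only high-confidence alleles.
#' @param classes variant classes analysed (default `"lof"`; damaging
#'   missense transmission uses the same machinery with `classes = "dmis"`).
#' @return data.frame with `gene_id`, `parent_id`, `offspring_id`,
#'   `transmitted`, `offspring_affected`, `offspring_sex`, `chrom_class`,
#'   `phenotype_group` (offspring cognitive impairment flag, `NA` when
#'   unknown).
#' @export
tally_transmissions <- function(variants, peds, max_af = 1e-5,
                                require_high_confidence = TRUE,
                                classes = "lof") {
  peds <- as_pedigree(peds)
  v <- .filter_variants(variants, max_af, require_high_confidence, classes)
  if (!"chrom_class" %in% names(v)) v$chrom_class <- "autosomal"
  eligible <- peds$id[peds$sequenced & !peds$affected & !peds$excluded_parent]
  pv <- v[v$individual_id %in% eligible, , drop = FALSE]
  if (nrow(pv) == 0)
    return(data.frame(gene_id = character(0), parent_id = character(0),
                      offspring_id = character(0), transmitted = logical(0),
                      offspring_affected = logical(0),
                      offspring_sex = character(0),
                      chrom_class = character(0),
                      phenotype_group = logical(0),
                      stringsAsFactors = FALSE))
  ## offspring, one per monozygotic twin group
  kids <- peds[peds$sequenced, , drop = FALSE]
  drop <- duplicated(kids$twin_group) & !is.na(kids$twin_group)
  kids <- kids[!drop, , drop = FALSE]
  child_keys <- paste(v$individual_id, v$allele_id)

  ## X non-PAR: only maternal transmissions are informative
  on_x <- pv$chrom_class == "x_nonpar"
  p_sex <- peds$sex[match(pv$individual_id, peds$id)]
  pv <- pv[!on_x | p_sex == "female", , drop = FALSE]

  ## expand each parental allele over that parent's sequenced offspring
  kidx <- rep(seq_len(nrow(kids)), 2)
  pid <- c(kids$father_id, kids$mother_id)
  parent_map <- split(kidx[!is.na(pid)], pid[!is.na(pid)])
  m <- parent_map[pv$individual_id]
  len <- lengths(m)
  ri <- rep(seq_len(nrow(pv)), len)
  ki <- unlist(m, use.names = FALSE)
  out <- data.frame(
    gene_id = pv$gene_id[ri], parent_id = pv$individual_id[ri],
    offspring_id = kids$id[ki],
    transmitted = paste(kids$id[ki], pv$allele_id[ri]) %in% child_keys,
    offspring_affected = kids$affected[ki], offspring_sex = kids$sex[ki],
    chrom_class = pv$chrom_class[ri],
    phenotype_group = kids$cognitive_impairment[ki],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Transmitted / nontransmitted counts
#'
#' Sums transmission records into a `T`/`NT` pair, by default restricted to
#' affected offspring.
#'
#' @param records output of [tally_transmissions()].
#' @param affected_only count transmissions to affected offspring only.
#' @return List with `t` and `nt`.
#' @export
tdt_counts <- function(records, affected_only = TRUE) {
  if (affected_only) records <- records[records$offspring_affected, , drop = FALSE]
  list(t = sum(records$transmitted), nt = sum(!records$transmitted))
}

#' Exact binomial TDT P value
#'
#' One-sided `P(X >= T)` for `X ~ Binomial(T + NT, 1/2)`: under the null each
#' heterozygous parental allele is transmitted with probability one half.
#'
#' @param t,nt transmitted / nontransmitted counts.
#' @return One-sided exact P value (1 when `T + NT = 0`).
#' @examples
#' tdt_binomial(17, 2)  # 3.6e-4
#' tdt_binomial(3, 1)   # 0.31
#' @export
tdt_binomial <- function(t, nt) {
  n <- t + nt
  ifelse(n == 0, 1, stats::pbinom(t - 1, n, 0.5, lower.tail = FALSE))
}

#' TDT z statistic
#'
#' `z = (T - NT) / sqrt(T + NT)`, 0 when there are no informative
#' transmissions.
#'
#' @inheritParams tdt_binomial
#' @export
tdt_z <- function(t, nt) {
  n <- t + nt
  ifelse(n == 0, 0, (t - nt) / sqrt(n))
}

#' Overtransmission per trio
#'
#' `(T - NT) / (n_trios + 0.5 * n_duos)`: single-parent duos are counted as
#' half-trios.
#'
#' @inheritParams tdt_binomial
#' @param n_trios,n_duos family counts; their weighted sum must be positive.
#' @export
overtransmission_rate <- function(t, nt, n_trios, n_duos = 0) {
  denom <- n_trios + 0.5 * n_duos
  if (denom <= 0) stop("n_trios + 0.5 * n_duos must be positive")
  (t - nt) / denom
}

#' Per-gene TDT table
#'
#' @param records output of [tally_transmissions()].
#' @return data.frame with `gene_id`, `t`, `nt`, `z`, `p_tdt`, sorted by
#'   gene id.
#' @export
tdt_table <- function(records) {
  records <- records[records$offspring_affected, , drop = FALSE]
  gid <- factor(records$gene_id)
  genes <- levels(gid)
  t <- as.vector(tapply(records$transmitted, gid, sum, default = 0))
  n <- as.vector(table(gid))
  nt <- n - t
  data.frame(gene_id = genes, t = t, nt = nt,
             z = tdt_z(t, nt), p_tdt = tdt_binomial(t, nt),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene-set enrichment of transmission events
#'
#' Compares transmitted vs nontransmitted counts in a gene set against those
#' in the background (all other constrained genes) in a 2x2 table. The odds
#' ratio is `(T_set * NT_bg) / (NT_set * T_bg)`; the P value is a two-sided
#' chi-square test without continuity correction (large-count regime).
#'
#' @param t_set,nt_set counts in the gene set.
#' @param t_bg,nt_bg counts in the background genes.
#' @return List with `odds_ratio` (NA with `flag = "zero_marginal"` when
#'   undefined) and `p_value`.
#' @export
geneset_tdt_enrichment <- function(t_set, nt_set, t_bg, nt_bg) {
  m <- matrix(c(t_set, nt_set, t_bg, nt_bg), nrow = 2, byrow = TRUE)
  if (any(m < 0)) stop("counts must be non-negative")
  flag <- NULL
  or <- (t_set * nt_bg) / (nt_set * t_bg)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0) || !is.finite(or)) {
    or <- NA_real_
    flag <- "zero_marginal"
    p <- NA_real_
  } else {
    p <- suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
  }
  list(odds_ratio = or, p_value = p, flag = flag)
}

#' Compare overtransmission between two phenotype groups
#'
#' Ratio of per-trio overtransmission rates between two groups (for example
#' cases with vs without cognitive impairment) and a chi-square test on the
#' 2x2 (T, NT) x group table, without continuity correction.
#'
#' @param group_a,group_b lists with `t`, `nt`, `n_trios` and optional
#'   `n_duos`.
#' @return List with `rate_ratio` (`Inf` with `flag = "zero_denominator"`
#'   when group B shows no overtransmission) and `p_value`.
#' @export
compare_overtransmission <- function(group_a, group_b) {
  get <- function(g, k, default = 0) if (is.null(g[[k]])) default else g[[k]]
  ra <- overtransmission_rate(group_a$t, group_a$nt, group_a$n_trios,
                              get(group_a, "n_duos"))
  rb <- overtransmission_rate(group_b$t, group_b$nt, group_b$n_trios,
                              get(group_b, "n_duos"))
  flag <- NULL
  ratio <- ra / rb
  if (!is.finite(ratio)) flag <- "zero_denominator"
  m <- matrix(c(group_a$t, group_a$nt, group_b$t, group_b$nt),
              nrow = 2, byrow = TRUE)
  p <- if (any(rowSums(m) == 0) || any(colSums(m) == 0)) NA_real_ else
    suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
  list(rate_ratio = ratio, p_value = p, flag = flag)
}

#' Stage-1 TDT gene prioritisation
#'
#' Candidate genes for meta-analysis: `z > 1` and either in the top decile of
#' LOEUF, or in the top two deciles with a gene prioritisation score
#' (`a_risk`) of at least 0.4.
#'
#' @param tdt per-gene table from [tdt_table()].
#' @param genes gene table with `loeuf_decile` and optional `a_risk`.
#' @param z_min z threshold (default 1).
#' @param a_risk_min prioritisation score threshold (default 0.4).
#' @return Character vector of prioritised gene ids.
#' @export
prioritize_tdt_genes <- function(tdt, genes, z_min = 1, a_risk_min = 0.4) {
  idx <- match(tdt$gene_id, genes$gene_id)
  dec <- genes$loeuf_decile[idx]
  ar <- if ("a_risk" %in% names(genes)) genes$a_risk[idx] else rep(NA_real_, length(idx))
  ar[is.na(ar)] <- -Inf
  keep <- tdt$z > z_min & (dec == 1 | (dec <= 2 & ar >= a_risk_min))
  keep[is.na(keep)] <- FALSE
  tdt$gene_id[keep]
}
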