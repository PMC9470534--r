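## Two-stage discovery workflow: a first exome-wide scan prioritises
## candidate genes from de novo enrichment and transmission disequilibrium;
## the second stage meta-analyses the three evidence types per candidate.

#' Stage 1: exome-wide scan and candidate prioritisation
#'
#' Runs the severity-weighted de novo enrichment test on every gene (with
#' positive-predictive-value weights derived from the cohort's own burden,
#' stratified by constrained status and variant class) and the per-gene TDT
#' on ultra-rare high-confidence LoF alleles. Candidate genes for
#' meta-analysis are those with de novo enrichment `P` below
#' `dnv_p_threshold` or passing the TDT prioritisation rule
#' ([prioritize_tdt_genes()]).
#'
#' @param cohort a cohort list as produced by [simulate_cohort()] (or
#'   assembled from real tables with the same element names: `genes`,
#'   `pedigrees`, `variants`, `dnvs`).
#' @param dnv_p_threshold de novo P threshold for candidacy (default 0.001).
#' @param n_sim simulations per gene for the weighted test (default 1e4).
#' @param max_af,require_high_confidence TDT allele filters.
#' @param seed seed for the per-gene simulation tests (default: the
#'   cohort's).
#' @return List of class `result_bundle` with `dnv_table`, `tdt`,
#'   `weights`, `candidates` (data.frame `gene_id`, `reason`), `n_trios`,
#'   `n_duos`, `log` (filter attrition counts) and `seed`.
#' @export
run_stage1 <- function(cohort, dnv_p_threshold = 0.001, n_sim = 1e4,
                       max_af = 1e-5, require_high_confidence = TRUE,
                       seed = NULL) {
  genes <- cohort$genes
  peds <- cohort$pedigrees
  if (is.null(seed)) seed <- if (!is.null(cohort$seed)) cohort$seed else 1L
  log <- list(dnvs_in = nrow(cohort$dnvs))

  ## --- de novo arm -------------------------------------------------------
  dnvs <- preprocess_dnvs(cohort$dnvs)
  log$dnvs_after_dedup <- nrow(dnvs)
  kid_aff <- peds$affected[match(dnvs$individual_id, peds$id)]
  case_dnvs <- dnvs[kid_aff, , drop = FALSE]
  ## trio counts: affected vs unaffected children with both parents present
  kids <- peds[!is.na(peds$father_id) & !is.na(peds$mother_id), , drop = FALSE]
  n_case_trios <- sum(kids$affected)
  n_ctrl_trios <- sum(!kids$affected)

  classes <- c("lof", "dmis", "syn")
  mu_cols <- c(lof = "mu_lof", dmis = "mu_dmis", syn = "mu_syn")
  constrained <- genes$pli >= 0.5 | genes$loeuf_decile <= 2

  ## PPV weights from the cohort's own burden, per constrained x class stratum
  obs <- exp <- numeric(0)
  for (con in c(TRUE, FALSE)) {
    gset <- genes$gene_id[constrained == con]
    for (cl in classes) {
      stratum <- paste0(ifelse(con, "constrained_", "other_"), cl)
      obs[stratum] <- sum(case_dnvs$gene_id %in% gset &
                          case_dnvs$variant_class == cl)
      exp[stratum] <- 2 * n_case_trios *
        sum(genes[[mu_cols[cl]]][constrained == con] *
            genes$callable_fraction_case[constrained == con])
    }
  }
  exp <- pmax(exp, 1e-12)
  ppv <- derive_ppv_weights(obs, exp)

  ## per-gene weighted enrichment
  set.seed(seed)
  n_genes <- nrow(genes)
  counts <- matrix(0L, n_genes, length(classes),
                   dimnames = list(genes$gene_id, classes))
  tab <- table(factor(case_dnvs$gene_id, levels = genes$gene_id),
               factor(case_dnvs$variant_class, levels = classes))
  counts[] <- as.integer(tab)
  p_dnv <- numeric(n_genes)
  score <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    e <- vapply(classes, function(cl)
      2 * n_case_trios * genes[[mu_cols[cl]]][i] *
        genes$callable_fraction_case[i], numeric(1))
    w <- ppv[paste0(ifelse(constrained[i], "constrained_", "other_"), classes)]
    names(w) <- classes
    res <- weighted_enrichment_test(counts[i, ], e, w, n_sim = n_sim)
    p_dnv[i] <- res$p_value
    score[i] <- res$observed_score
  }
  dnv_table <- data.frame(gene_id = genes$gene_id,
                          n_lof = counts[, "lof"], n_dmis = counts[, "dmis"],
                          n_syn = counts[, "syn"], score = score,
                          p_dnv = p_dnv, n_sim = n_sim, seed = seed,
                          stringsAsFactors = FALSE)

  ## --- transmission arm --------------------------------------------------
  log$variants_in <- nrow(cohort$variants)
  trans <- tally_transmissions(cohort$variants, peds, max_af = max_af,
                               require_high_confidence = require_high_confidence)
  log$transmission_records <- nrow(trans)
  tdt <- tdt_table(trans)
  fam_counts <- count_family_types(peds)

  cand_dnv <- genes$gene_id[p_dnv < dnv_p_threshold]
  cand_tdt <- prioritize_tdt_genes(tdt, genes)
  candidates <- data.frame(
    gene_id = union(cand_dnv, cand_tdt),
    stringsAsFactors = FALSE)
  candidates$reason <- ifelse(
    candidates$gene_id %in% cand_dnv & candidates$gene_id %in% cand_tdt,
    "de novo+TDT",
    ifelse(candidates$gene_id %in% cand_dnv, "de novo", "TDT"))
  candidates <- candidates[order(candidates$gene_id), , drop = FALSE]
  rownames(candidates) <- NULL

  structure(list(dnv_table = dnv_table, tdt = tdt, transmissions = trans,
                 weights = ppv, candidates = candidates,
                 n_case_trios = n_case_trios, n_ctrl_trios = n_ctrl_trios,
                 n_trios = fam_counts$n_trios, n_duos = fam_counts$n_duos,
                 log = log, seed = seed),
            class = "result_bundle")
}

#' Stage 2: meta-analysis of candidate genes
#'
#' For each candidate gene, combines the de novo enrichment P, the TDT P and
#' the conservative case-control P (largest across the population reference
#' panels; pseudocases are built from case alleles unattributable to sampled
#' unaffected ancestors, with de novo alleles removed) by Fisher's method,
#' and flags exome-wide (`0.05 / (20,000)`) and study-wide
#' (`0.05 / n_constrained_genes`) significance. Candidates lacking
#' case-control data receive `P_CC = 1` with a flag rather than exclusion.
#'
#' @param cohort cohort list (see [run_stage1()]); `controls` must hold one
#'   allele count set per reference panel.
#' @param stage1 the stage-1 [run_stage1()] bundle.
#' @param candidates optional character vector of gene ids (default: the
#'   stage-1 candidate list).
#' @param n_constrained_genes number of constrained genes behind the
#'   study-wide Bonferroni threshold (default 5,754).
#' @param alpha_exome exome-wide threshold (default 2.5e-6).
#' @return List of class `result_bundle` with `results` (per-gene table
#'   sorted by (`p_meta`, `gene_id`)), `pseudocases`, `thresholds`, `seed`.
#' @export
run_stage2 <- function(cohort, stage1, candidates = NULL,
                       n_constrained_genes = 5754,
                       alpha_exome = bonferroni_threshold(20000)) {
  if (is.null(candidates)) candidates <- stage1$candidates$gene_id
  alpha_study <- bonferroni_threshold(n_constrained_genes)
  peds <- cohort$pedigrees

  pc <- construct_pseudocases(peds, cohort$variants,
                              dnv_alleles = cohort$dnvs$allele_id)
  n_case_eff <- pc$n_eff
  k_case <- stats::setNames(pc$counts$carriers, pc$counts$gene_id)

  res <- data.frame(gene_id = candidates, stringsAsFactors = FALSE)
  di <- match(candidates, stage1$dnv_table$gene_id)
  res$p_dnv <- stage1$dnv_table$p_dnv[di]
  res$p_dnv[is.na(res$p_dnv)] <- 1
  ti <- match(candidates, stage1$tdt$gene_id)
  res$p_tdt <- ifelse(is.na(ti), 1, stage1$tdt$p_tdt[ti])
  res$t <- ifelse(is.na(ti), 0, stage1$tdt$t[ti])
  res$nt <- ifelse(is.na(ti), 0, stage1$tdt$nt[ti])

  gi <- match(candidates, cohort$genes$gene_id)
  cf_case <- cohort$genes$callable_fraction_case[gi]
  cc_flag <- rep("", length(candidates))
  p_cc_mat <- matrix(1, length(candidates), length(cohort$controls))
  for (k in seq_along(cohort$controls)) {
    ctrl <- cohort$controls[[k]]
    if ("variant_class" %in% names(ctrl))
      ctrl <- ctrl[ctrl$variant_class == "lof", , drop = FALSE]
    ci <- match(candidates, ctrl$gene_id)
    kc <- ifelse(is.na(match(candidates, names(k_case))), 0,
                 k_case[candidates])
    cf_ctrl <- cohort$genes$callable_fraction_control[gi]
    if (n_case_eff > 0 && nrow(ctrl) > 0) {
      p_cc_mat[, k] <- poisson_two_rate_test(
        ifelse(is.na(ci), 0, kc),
        n_case_eff * cf_case,
        ifelse(is.na(ci), 0, ctrl$carriers[ci]),
        ifelse(is.na(ci), ctrl$sample_size[1], ctrl$sample_size[ci]) * cf_ctrl)
    } else {
      cc_flag[] <- "no_case_control_data"
    }
  }
  res$p_cc <- apply(p_cc_mat, 1, max)
  for (k in seq_len(ncol(p_cc_mat)))
    res[[paste0("p_cc_ref", k)]] <- p_cc_mat[, k]
  res$cc_flag <- cc_flag
  res$p_meta <- mapply(function(a, b, cc) fisher_combine(c(a, b, cc)),
                       res$p_dnv, res$p_tdt, res$p_cc)
  res$sig_exome <- res$p_meta < alpha_exome
  res$sig_study <- res$p_meta < alpha_study
  res <- res[order(res$p_meta, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(results = res, pseudocases = pc,
                 thresholds = c(exome = alpha_exome, study = alpha_study),
                 seed = stage1$seed),
            class = "result_bundle")
}

#' Run both stages on a simulated cohort and score recovery against truth
#'
#' Generates a cohort from `cfg`, runs [run_stage1()] and [run_stage2()],
#' joins the per-gene results to the generator truth, and reports recovery
#' metrics: sensitivity among risk genes (overall and by relative-risk bin),
#' the false-flag rate on null genes, and the per-gene effect-size estimates
#' `gamma_hat = T/NT` and `s_hat = mu / f_hat` (from the first reference
#' panel's carrier frequencies).
#'
#' @param cfg a [sim_config()].
#' @param ... passed to [run_stage1()].
#' @return List with `per_gene` (truth joined to all stage statistics),
#'   `summary` (named numeric vector), `stage1`, `stage2`.
#' @export
run_simulation_study <- function(cfg, ...) {
  cohort <- simulate_cohort(cfg)
  s1 <- run_stage1(cohort, ...)
  s2 <- run_stage2(cohort, s1)
  per_gene <- cohort$truth
  di <- match(per_gene$gene_id, s1$dnv_table$gene_id)
  per_gene$p_dnv <- s1$dnv_table$p_dnv[di]
  ti <- match(per_gene$gene_id, s1$tdt$gene_id)
  per_gene$t <- ifelse(is.na(ti), 0, s1$tdt$t[ti])
  per_gene$nt <- ifelse(is.na(ti), 0, s1$tdt$nt[ti])
  per_gene$gamma_hat <- ifelse(per_gene$nt > 0, per_gene$t / per_gene$nt, NA)
  ctrl <- cohort$controls[[1]]
  if ("variant_class" %in% names(ctrl))
    ctrl <- ctrl[ctrl$variant_class == "lof", , drop = FALSE]
  ci <- match(per_gene$gene_id, ctrl$gene_id)
  f_hat <- ctrl$carriers[ci] / (2 * ctrl$sample_size[ci])
  per_gene$f_hat <- f_hat
  per_gene$s_hat <- ifelse(f_hat > 0,
                           pmin(per_gene$mu_lof / f_hat, 1), NA)
  mi <- match(per_gene$gene_id, s2$results$gene_id)
  per_gene$p_meta <- s2$results$p_meta[mi]
  per_gene$sig_study <- !is.na(mi) & s2$results$sig_study[mi]
  per_gene$candidate <- per_gene$gene_id %in% s1$candidates$gene_id

  risk <- per_gene$gamma > 1
  summary <- c(
    n_genes = nrow(per_gene),
    n_risk = sum(risk),
    sensitivity = if (any(risk)) mean(per_gene$sig_study[risk]) else NA,
    false_flag_rate = if (any(!risk)) mean(per_gene$sig_study[!risk]) else NA,
    candidate_rate_null = if (any(!risk)) mean(per_gene$candidate[!risk]) else NA)
  list(per_gene = per_gene, summary = summary, stage1 = s1, stage2 = s2,
       seed = cfg$seed)
}
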