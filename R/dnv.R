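## De novo variant analysis: preprocessing, burden, severity-weighted
## enrichment and gene-set permutation.

.severity_levels <- c("lof", "dmis", "other_mis", "syn")

#' Exome-wide significance threshold for the weighted de novo test
#'
#' `0.05 / (18,000 genes x 2 tests) = 1.3889e-6`, conventionally printed as
#' 1.3e-6.
#' @param n_genes number of genes tested (default 18,000).
#' @param n_tests tests per gene (default 2).
#' @export
dnv_exome_wide_alpha <- function(n_genes = 18000, n_tests = 2) {
  0.05 / (n_genes * n_tests)
}

#' Preprocess de novo variant records
#'
#' Two rules: (i) identical de novo events shared within a declared
#' monozygotic twin group represent one mutational event and are counted
#' once; (ii) when an individual carries multiple de novo variants within
#' 100 bp in the same gene, only the single most severe variant is kept
#' (severity order lof > dmis > other_mis > syn; ties by smallest position).
#' The operation is idempotent.
#'
#' @param records data.frame with `individual_id`, `gene_id`,
#'   `variant_class`, `position` and optionally `twin_group`.
#' @param window clustering window in bp (default 100).
#' @return Filtered records, original row order preserved.
#' @export
preprocess_dnvs <- function(records, window = 100) {
  if (nrow(records) == 0) return(records)
  sev <- match(records$variant_class, .severity_levels)
  if (anyNA(sev)) stop("unknown variant_class in DNV records")
  keep <- rep(TRUE, nrow(records))
  ## one event per twin group x gene x position x class
  if ("twin_group" %in% names(records)) {
    tg <- as.character(records$twin_group)
    has_tg <- !is.na(tg) & tg != ""
    key <- paste(tg, records$gene_id, records$position, records$variant_class)
    keep[has_tg & duplicated(key) & has_tg] <- FALSE
  }
  ## 100-bp within-gene clustering per individual
  idx <- which(keep)
  grp <- paste(records$individual_id[idx], records$gene_id[idx])
  for (g in unique(grp[duplicated(grp)])) {
    rows <- idx[grp == g]
    pos <- records$position[rows]
    ord <- order(pos)
    rows <- rows[ord]; pos <- pos[ord]
    cl <- cumsum(c(1, diff(pos) > window))  # single-linkage position clusters
    for (cc in unique(cl)) {
      members <- rows[cl == cc]
      if (length(members) == 1) next
      best <- members[order(sev[members], records$position[members])][1]
      keep[setdiff(members, best)] <- FALSE
    }
  }
  records[keep, , drop = FALSE]
}

#' One-sided Poisson tail probability
#'
#' `P(X >= observed)` for `X ~ Poisson(expected)`, the exact test used for
#' de novo burden comparisons.
#'
#' @param observed observed count(s).
#' @param expected expected count(s) under the null; must be positive unless
#'   `observed` is 0.
#' @return One-sided P value(s).
#' @export
poisson_tail_p <- function(observed, expected) {
  if (any(expected < 0) || any(expected == 0 & observed > 0))
    stop("expected must be positive when observed > 0")
  ifelse(observed == 0, 1,
         stats::ppois(observed - 1, expected, lower.tail = FALSE))
}

#' Cohort-level de novo burden between affected and unaffected trios
#'
#' Per-offspring rates of qualifying de novo variants in cases and controls,
#' their ratio and difference (the rate difference is the population
#' attributable risk contribution of the variant group), a normal 95%
#' confidence interval for each, and a one-sided Poisson comparison of the
#' two rates (exact conditional binomial given the total count).
#'
#' @param case_records,control_records preprocessed DNV data.frames.
#' @param n_case_trios,n_control_trios trio counts (> 0).
#' @param gene_subset optional character vector restricting both record sets.
#' @param classes variant classes counted (default damaging: lof + dmis).
#' @return List of class `burden_result` with `rate_case`, `rate_control`,
#'   `rate_ratio`, `rate_difference`, `ci_low`, `ci_high` (for the
#'   difference) and `p_value`.
#' @export
cohort_burden <- function(case_records, control_records, n_case_trios,
                          n_control_trios, gene_subset = NULL,
                          classes = c("lof", "dmis")) {
  if (n_case_trios <= 0 || n_control_trios <= 0)
    stop("trio counts must be positive")
  pick <- function(rec) {
    k <- rec$variant_class %in% classes
    if (!is.null(gene_subset)) k <- k & rec$gene_id %in% gene_subset
    sum(k)
  }
  x_case <- pick(case_records)
  x_ctrl <- pick(control_records)
  rate_case <- x_case / n_case_trios
  rate_control <- x_ctrl / n_control_trios
  diff <- rate_case - rate_control
  se <- sqrt(rate_case / n_case_trios + rate_control / n_control_trios)
  p <- poisson_two_rate_test(x_case, n_case_trios, x_ctrl, n_control_trios)
  structure(list(rate_case = rate_case, rate_control = rate_control,
                 rate_ratio = rate_case / rate_control,
                 rate_difference = diff,
                 ci_low = diff - 1.96 * se, ci_high = diff + 1.96 * se,
                 p_value = p,
                 n_case = x_case, n_control = x_ctrl),
            class = "burden_result")
}

#' Positive-predictive-value weights per variant stratum
#'
#' From observed and expected de novo counts per stratum (typically
#' constrained-status x variant class), the weight is the empirical positive
#' predictive value `max(0, (O - E) / O)`: the estimated fraction of observed
#' events in excess of the mutational expectation. Strata with `O <= E` get
#' weight 0.
#'
#' @param observed,expected named numeric vectors on the same strata;
#'   `expected` must be positive.
#' @return Named numeric weights in `[0, 1]`.
#' @export
derive_ppv_weights <- function(observed, expected) {
  if (any(expected <= 0)) stop("expected counts must be positive")
  if (!is.null(names(observed)) && !is.null(names(expected)))
    expected <- expected[names(observed)]
  w <- ifelse(observed > 0, pmax(0, (observed - expected) / observed), 0)
  names(w) <- names(observed)
  w
}

#' Severity-weighted de novo enrichment test for one gene
#'
#' The observed score is the weighted sum of de novo counts over variant
#' classes. Under the null, class counts are independent Poisson draws with
#' the gene's mutational expectations; the one-sided P value is the smoothed
#' simulation tail `(1 + #[sim score >= observed]) / (1 + n_sim)`. With one
#' class at weight 1 this reduces to the exact Poisson tail up to Monte Carlo
#' error.
#'
#' @param observed named counts per class.
#' @param expected named expected counts per class (same names).
#' @param weights named weights in `[0, 1]` per class; defaults to 1.
#' @param n_sim number of null simulations (>= 1e4 recommended).
#' @param seed optional integer seed for reproducibility.
#' @return List of class `enrichment_result` with `observed_score`,
#'   `p_value`, `n_sim`, `seed`.
#' @export
weighted_enrichment_test <- function(observed, expected, weights = NULL,
                                     n_sim = 1e4, seed = NULL) {
  classes <- names(observed)
  if (is.null(classes)) stop("observed counts must be named by class")
  expected <- expected[classes]
  if (anyNA(expected)) stop("expected counts missing for some classes")
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(classes)), classes)
  weights <- weights[classes]
  if (anyNA(weights)) stop("weights missing for some classes")
  if (!is.null(seed)) set.seed(seed)
  obs_score <- sum(weights * observed)
  if (all(expected == 0) && any(observed > 0)) {
    warning("all expectations are zero with nonzero observed counts")
    return(structure(list(observed_score = obs_score,
                          p_value = 1 / (1 + n_sim), n_sim = n_sim,
                          seed = seed), class = "enrichment_result"))
  }
  sims <- matrix(stats::rpois(n_sim * length(classes), rep(expected, each = n_sim)),
                 nrow = n_sim)
  scores <- as.vector(sims %*% weights)
  p <- (1 + sum(scores >= obs_score)) / (1 + n_sim)
  structure(list(observed_score = obs_score, p_value = p,
                 n_sim = n_sim, seed = seed),
            class = "enrichment_result")
}

#' Gene-set permutation test for de novo mutations
#'
#' Tests whether damaging de novo mutations concentrate in a gene set beyond
#' what gene mutation rates predict, conditioning on the total number of
#' mutations per class. Each observed mutation is randomly re-placed onto a
#' gene with probability proportional to the gene's class-specific mutation
#' rate. The statistic is the weighted fraction of case mutations falling in
#' the set, divided by the same fraction for control mutations when controls
#' are supplied. Fold enrichment is the observed statistic over the
#' permutation mean; the 95% CI assumes log(fold enrichment) is normal with
#' s.d. implied by the permutation P value.
#'
#' @param records case DNV data.frame (`gene_id`, `variant_class`).
#' @param geneset character vector of gene ids (subset of `genes$gene_id`).
#' @param genes gene table with `gene_id` and `mu_<class>` columns.
#' @param weights optional named per-class weights (default 1).
#' @param control_records optional control DNV data.frame.
#' @param n_perm number of permutations (>= 1e3 recommended).
#' @param seed optional integer seed.
#' @return List with `fold_enrichment`, `p_value`, `ci_low`, `ci_high`,
#'   `observed_stat`, `n_perm`, `seed`.
#' @export
geneset_permutation_test <- function(records, geneset, genes, weights = NULL,
                                     control_records = NULL, n_perm = 1e3,
                                     seed = NULL) {
  if (length(geneset) == 0) stop("geneset is empty")
  if (!all(geneset %in% genes$gene_id)) stop("geneset must be a subset of genes")
  if (!is.null(seed)) set.seed(seed)
  wt_of <- function(cls) {
    if (is.null(weights)) rep(1, length(cls)) else unname(weights[cls])
  }
  in_set <- function(gid) gid %in% geneset
  frac <- function(gid, cls) {
    w <- wt_of(cls)
    if (sum(w) == 0) return(NA_real_)
    sum(w[in_set(gid)]) / sum(w)
  }
  obs <- frac(records$gene_id, records$variant_class)
  has_ctrl <- !is.null(control_records) && nrow(control_records) > 0
  if (has_ctrl)
    obs <- obs / frac(control_records$gene_id, control_records$variant_class)

  place <- function(rec) {
    out <- character(nrow(rec))
    for (cls in unique(rec$variant_class)) {
      mu_col <- paste0("mu_", cls)
      if (!mu_col %in% names(genes))
        mu_col <- switch(cls, other_mis = "mu_mis", stop("no rate column for class ", cls))
      pr <- genes[[mu_col]]
      rows <- rec$variant_class == cls
      out[rows] <- sample(genes$gene_id, sum(rows), replace = TRUE, prob = pr)
    }
    out
  }
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    st <- frac(place(records), records$variant_class)
    if (has_ctrl)
      st <- st / frac(place(control_records), control_records$variant_class)
    perm[b] <- st
  }
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  fe <- obs / mean(perm)
  sigma <- if (p < 0.5 && is.finite(fe) && fe > 0)
    abs(log(fe)) / stats::qnorm(1 - p) else NA_real_
  list(fold_enrichment = fe, p_value = p,
       ci_low = exp(log(fe) - 1.96 * sigma),
       ci_high = exp(log(fe) + 1.96 * sigma),
       observed_stat = obs, n_perm = n_perm, seed = seed)
}
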