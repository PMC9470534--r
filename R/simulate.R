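## Synthetic family cohorts and population controls with known per-gene
## truth (mu, s, gamma), reproducing the statistical structure each analysis
## stage assumes: Poisson de novo counts at rate 2 N mu, transmission from
## heterozygous parents distorted by the relative risk gamma, and population
## cumulative allele frequencies at mutation-selection equilibrium f = mu/s.

#' Simulation configuration
#'
#' Distribution arguments accept a single value (fixed) or a length-2 range
#' sampled log-uniformly. Defaults mirror the structure of a large
#' family-based autism cohort: trio families with an affected child, a
#' male-biased case sex ratio, two population reference panels of roughly
#' 104,000 and 132,000 samples, disorder prevalence 1/54, and risk genes
#' restricted to the feasible region `s >= 0.013 gamma` of the
#' mutation-selection model.
#'
#' @param seed integer seed; recorded in all outputs.
#' @param n_genes number of genes in the panel.
#' @param risk_gene_fraction fraction of genes with `gamma > 1`.
#' @param gamma_dist relative risk of risk genes: fixed value or log-uniform
#'   range (default `c(2, 20)`).
#' @param s_dist selection coefficient: fixed or range within `[0.01, 0.5]`.
#' @param mu_lof_dist haploid LoF mutation rate, log-uniform range (default
#'   `c(1e-7, 1e-5)`).
#' @param n_trios,n_duos,n_control_trios,n_singleton_cases cohort layout:
#'   affected-child trios, single-parent duos, unaffected-child trios, and
#'   parentless cases.
#' @param n_controls sizes of the population reference panels (one entry per
#'   panel; default two panels as in a dual-reference design).
#' @param prevalence_pi disorder prevalence (default 1/54).
#' @param impairment_base_rate,impairment_carrier_rate probability of
#'   cognitive impairment for affected non-carriers vs carriers of risk-gene
#'   LoF alleles (defaults 0.5 and 0.88).
#' @param male_case_fraction sex mix of affected offspring (default 4.2:1
#'   male:female).
#' @param enforce_constraint restrict risk genes to `s >= 0.013 gamma`.
#' @param include_synonymous also draw undistorted synonymous alleles (used
#'   by calibration checks; disable for large pure-transmission runs).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 200L, risk_gene_fraction = 0.02,
                       gamma_dist = c(2, 20), s_dist = c(0.01, 0.5),
                       mu_lof_dist = c(1e-7, 1e-5),
                       n_trios = 5000L, n_duos = 0L, n_control_trios = 0L,
                       n_singleton_cases = 0L,
                       n_controls = c(104068L, 132345L),
                       prevalence_pi = 1 / 54,
                       impairment_base_rate = 0.5,
                       impairment_carrier_rate = 0.88,
                       male_case_fraction = 4.2 / 5.2,
                       enforce_constraint = TRUE,
                       include_synonymous = TRUE) {
  counts <- c(n_genes, n_trios, n_duos, n_control_trios, n_singleton_cases,
              n_controls)
  if (any(counts < 0)) stop("all counts must be non-negative")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 risk_gene_fraction = risk_gene_fraction,
                 gamma_dist = gamma_dist, s_dist = s_dist,
                 mu_lof_dist = mu_lof_dist,
                 n_trios = as.integer(n_trios), n_duos = as.integer(n_duos),
                 n_control_trios = as.integer(n_control_trios),
                 n_singleton_cases = as.integer(n_singleton_cases),
                 n_controls = as.integer(n_controls),
                 prevalence_pi = prevalence_pi,
                 impairment_base_rate = impairment_base_rate,
                 impairment_carrier_rate = impairment_carrier_rate,
                 male_case_fraction = male_case_fraction,
                 enforce_constraint = enforce_constraint,
                 include_synonymous = include_synonymous),
            class = "sim_config")
}

.draw_dist <- function(spec, n) {
  if (length(spec) == 1) return(rep(spec, n))
  exp(stats::runif(n, log(spec[1]), log(spec[2])))
}

#' Simulate a gene panel with known truth
#'
#' Draws per-gene LoF mutation rates, selection coefficients and relative
#' risks, computes the equilibrium cumulative allele frequency `f = mu / s`,
#' and tags risk genes. Rates for the other variant classes are scaled from
#' the LoF rate (damaging missense 1.5x, all missense 5x, synonymous 2.5x),
#' reflecting typical exome-wide class ratios. Risk genes are constrained
#' (top LOEUF decile, high pLI, high prioritisation score); null genes are
#' spread over all deciles. Reproducible given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return List with `genes` (gene table, see [read_gene_table()]) and
#'   `truth` (data.frame `gene_id`, `gamma`, `s`, `mu_lof`, `f`,
#'   `expected_t_nt_ratio`).
#' @export
simulate_gene_panel <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))
  mu_lof <- .draw_dist(cfg$mu_lof_dist, n)
  n_risk <- round(n * cfg$risk_gene_fraction)
  is_risk <- seq_len(n) <= n_risk
  gamma <- rep(1, n)
  if (n_risk > 0) gamma[is_risk] <- .draw_dist(cfg$gamma_dist, n_risk)
  s <- .draw_dist(cfg$s_dist, n)
  if (cfg$enforce_constraint && n_risk > 0) {
    s_min <- 0.013 * gamma[is_risk]
    s_max <- max(cfg$s_dist)
    bad <- s_min > s_max
    if (any(bad))
      stop("infeasible (gamma, s) combinations: gamma = ",
           paste(signif(gamma[is_risk][bad], 3), collapse = ", "),
           " requires s > ", s_max)
    s[is_risk] <- exp(stats::runif(n_risk, log(s_min), log(s_max)))
  }
  f <- equilibrium_caf(mu_lof, s)
  if (any(2 * f > 0.1))
    stop("rare-variant regime violated: 2f > 0.1 for ",
         paste(gene_id[2 * f > 0.1], collapse = ", "))
  genes <- data.frame(
    gene_id = gene_id, chrom_class = "autosomal",
    mu_lof = mu_lof, mu_dmis = 1.5 * mu_lof, mu_mis = 5 * mu_lof,
    mu_syn = 2.5 * mu_lof,
    pli = ifelse(is_risk, stats::runif(n, 0.9, 1), stats::runif(n, 0, 1)),
    loeuf_decile = ifelse(is_risk, 1L, sample(1:10, n, replace = TRUE)),
    shet = NA_real_,
    a_risk = ifelse(is_risk, stats::runif(n, 0.5, 1), stats::runif(n, 0, 1)),
    callable_fraction_case = 1, callable_fraction_control = 1,
    pext_threshold = NA_real_, known_asd_ndd = FALSE,
    stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = gene_id, gamma = gamma, s = s,
                      mu_lof = mu_lof, f = f,
                      expected_t_nt_ratio = gamma,
                      stringsAsFactors = FALSE)
  list(genes = genes, truth = truth, seed = cfg$seed)
}

## pedigree scaffold for trios, duos, unaffected-child trios and singletons
.simulate_pedigrees <- function(cfg) {
  rows <- list()
  child_sex <- function(n, male_frac)
    ifelse(stats::runif(n) < male_frac, "male", "female")
  add_family <- function(prefix, n, affected_child, male_frac, parents) {
    if (n == 0) return(NULL)
    famid <- sprintf("%s%05d", prefix, seq_len(n))
    out <- list()
    if ("father" %in% parents)
      out$fa <- data.frame(id = paste0(famid, "_fa"), family_id = famid,
                           father_id = NA_character_, mother_id = NA_character_,
                           sex = "male", affected = FALSE, stringsAsFactors = FALSE)
    if ("mother" %in% parents)
      out$mo <- data.frame(id = paste0(famid, "_mo"), family_id = famid,
                           father_id = NA_character_, mother_id = NA_character_,
                           sex = "female", affected = FALSE, stringsAsFactors = FALSE)
    out$ch <- data.frame(id = paste0(famid, "_ch"), family_id = famid,
                         father_id = if ("father" %in% parents)
                           paste0(famid, "_fa") else NA_character_,
                         mother_id = if ("mother" %in% parents)
                           paste0(famid, "_mo") else NA_character_,
                         sex = child_sex(n, male_frac),
                         affected = affected_child, stringsAsFactors = FALSE)
    do.call(rbind, out)
  }
  ## duos: drop one parent at random (data not collected)
  duo_parent <- if (cfg$n_duos > 0)
    ifelse(stats::runif(cfg$n_duos) < 0.5, "father", "mother") else character(0)
  rows$trio <- add_family("T", cfg$n_trios, TRUE, cfg$male_case_fraction,
                          c("father", "mother"))
  if (cfg$n_duos > 0) {
    d_fa <- add_family("DF", sum(duo_parent == "father"), TRUE,
                       cfg$male_case_fraction, "father")
    d_mo <- add_family("DM", sum(duo_parent == "mother"), TRUE,
                       cfg$male_case_fraction, "mother")
    rows$duo <- rbind(d_fa, d_mo)
  }
  rows$ctrl <- add_family("U", cfg$n_control_trios, FALSE, 0.5,
                          c("father", "mother"))
  if (cfg$n_singleton_cases > 0)
    rows$single <- add_family("S", cfg$n_singleton_cases, TRUE,
                              cfg$male_case_fraction, character(0))
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  ped$excluded_parent <- FALSE
  ped$cognitive_impairment <- NA
  ped$sequenced <- TRUE
  ped$twin_group <- NA_character_
  ped
}

#' Simulate parental carriers and transmission to offspring
#'
#' Each sequenced parent carries a heterozygous LoF allele of gene `g` with
#' probability `2 f_g` (rare-variant approximation). A heterozygous parent
#' transmits to an affected child with probability `gamma / (1 + gamma)` and
#' to an unaffected child with probability
#' `(1 - gamma * pi) / ((1 - gamma * pi) + (1 - pi))`, the exact conditional
#' probability given the child's phenotype under prevalence `pi`. Duo
#' children may additionally inherit from the unsampled parent. Synonymous
#' parental alleles are drawn at class-specific frequencies with no
#' transmission distortion.
#'
#' @param panel output of [simulate_gene_panel()].
#' @param cfg the [sim_config()] used for the panel.
#' @param peds optional pre-built pedigree scaffold (internal use).
#' @return List with `pedigrees` and `variants` (one row per heterozygous
#'   allele observation: `individual_id`, `family_id`, `gene_id`,
#'   `allele_id`, `variant_class`, `af`, `high_confidence`, `chrom_class`,
#'   `origin`).
#' @export
simulate_parents_and_transmission <- function(panel, cfg, peds = NULL) {
  truth <- panel$truth
  if (any(2 * truth$f > 0.1))
    stop("rare-variant regime violated: 2f > 0.1")
  if (is.null(peds)) peds <- .simulate_pedigrees(cfg)
  parents <- peds[grepl("_(fa|mo)$", peds$id), , drop = FALSE]
  children <- peds[grepl("_ch$", peds$id), , drop = FALSE]
  kid_of <- stats::setNames(paste0(parents$family_id, "_ch"), parents$id)
  kid_affected <- stats::setNames(children$affected, children$id)
  singles <- peds$id[grepl("^S", peds$family_id) & peds$affected]
  duo_children <- children$id[is.na(children$father_id) != is.na(children$mother_id)]

  pi_ <- cfg$prevalence_pi
  np <- nrow(parents)
  acc <- list()
  add <- function(ind, fam, gene, allele, class, origin)
    acc[[length(acc) + 1]] <<- list(ind = ind, fam = fam, gene = gene,
                                    allele = allele, class = class,
                                    origin = origin)
  for (i in seq_len(nrow(truth))) {
    g <- truth$gene_id[i]
    gam <- truth$gamma[i]
    f2 <- 2 * truth$f[i]
    q_aff <- gam / (1 + gam)
    q_unaff <- (1 - gam * pi_) / ((1 - gam * pi_) + (1 - pi_))
    ## heterozygous parents
    ncar <- stats::rbinom(1, np, f2)
    if (ncar > 0) {
      idx <- sample.int(np, ncar)
      pids <- parents$id[idx]
      alleles <- paste0(g, ":", pids)
      add(pids, parents$family_id[idx], rep(g, ncar), alleles,
          rep("lof", ncar), rep("founder", ncar))
      kids <- unname(kid_of[pids])
      aff <- unname(kid_affected[kids])
      q <- ifelse(aff, q_aff, q_unaff)
      tr <- stats::runif(ncar) < q
      if (any(tr))
        add(kids[tr], parents$family_id[idx][tr], rep(g, sum(tr)),
            alleles[tr], rep("lof", sum(tr)), rep("inherited", sum(tr)))
    }
    ## duo children: allele from the unsampled parent
    if (length(duo_children) > 0) {
      p_extra <- f2 * q_aff
      hit <- stats::runif(length(duo_children)) < p_extra
      if (any(hit)) {
        ids <- duo_children[hit]
        add(ids, sub("_ch$", "", ids), rep(g, sum(hit)),
            paste0(g, ":unsampled:", ids), rep("lof", sum(hit)),
            rep("inherited_unsampled", sum(hit)))
      }
    }
    ## singleton cases: carrier probability conditioned on affection
    if (length(singles) > 0) {
      p_case <- f2 * gam / (1 + f2 * (gam - 1))
      hit <- stats::runif(length(singles)) < p_case
      if (any(hit)) {
        ids <- singles[hit]
        add(ids, sub("_ch$", "", ids), rep(g, sum(hit)),
            paste0(g, ":case:", ids), rep("lof", sum(hit)),
            rep("case_unknown", sum(hit)))
      }
    }
  }
  ## synonymous background, no distortion, in all sequenced individuals
  f2_syn <- if (isFALSE(cfg$include_synonymous)) rep(0, nrow(truth)) else
    pmin(2 * panel$genes$mu_syn / 1e-3, 0.1)  # weakly selected class
  all_ids <- peds$id
  for (i in seq_len(nrow(truth))) {
    ncar <- stats::rbinom(1, length(all_ids), f2_syn[i])
    if (ncar == 0) next
    idx <- sample.int(length(all_ids), ncar)
    ids <- all_ids[idx]
    add(ids, peds$family_id[idx], rep(truth$gene_id[i], ncar),
        paste0(truth$gene_id[i], ":syn:", ids), rep("syn", ncar),
        rep("founder", ncar))
  }
  pull <- function(k) as.character(unlist(lapply(acc, `[[`, k)))
  variants <- data.frame(
    individual_id = pull("ind"), family_id = pull("fam"),
    gene_id = pull("gene"), allele_id = pull("allele"),
    variant_class = pull("class"), stringsAsFactors = FALSE)
  variants$af <- rep(1e-6, nrow(variants))
  variants$high_confidence <- rep(TRUE, nrow(variants))
  variants$chrom_class <- rep("autosomal", nrow(variants))
  variants$origin <- pull("origin")
  list(pedigrees = as_pedigree(peds), variants = variants, seed = cfg$seed)
}

#' Simulate de novo variants
#'
#' Per-gene de novo counts are Poisson with mean `2 mu` per offspring for
#' every class in unaffected offspring; in affected offspring the LoF class
#' mean is multiplied by the gene's relative risk `gamma` (the same truth
#' parameter that drives transmission distortion), while synonymous and
#' missense classes stay unenriched.
#'
#' @param panel output of [simulate_gene_panel()].
#' @param cfg the [sim_config()].
#' @param peds pedigree data.frame (children are drawn from it).
#' @return data.frame of DNV records: `individual_id`, `gene_id`,
#'   `variant_class`, `position`, `twin_group`, `allele_id`.
#' @export
simulate_dnvs <- function(panel, cfg, peds) {
  genes <- panel$genes
  truth <- panel$truth
  ## de novo calls require both parents: trio children only
  trio_kids <- peds[grepl("_ch$", peds$id) & !is.na(peds$father_id) &
                    !is.na(peds$mother_id), , drop = FALSE]
  case_kids <- trio_kids$id[trio_kids$affected]
  ctrl_kids <- trio_kids$id[!trio_kids$affected]
  acc <- list()
  draw <- function(kids, mu_mean, class, gene) {
    if (length(kids) == 0 || mu_mean == 0) return(NULL)
    k <- stats::rpois(1, length(kids) * mu_mean)
    if (k == 0) return(NULL)
    ids <- sample(kids, k, replace = TRUE)
    data.frame(individual_id = ids, gene_id = gene, variant_class = class,
               position = sample.int(5e4, k, replace = TRUE),
               twin_group = NA_character_, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]
    gam <- truth$gamma[i]
    acc[[length(acc) + 1]] <- rbind(
      draw(case_kids, 2 * genes$mu_lof[i] * gam, "lof", g),
      draw(case_kids, 2 * genes$mu_dmis[i], "dmis", g),
      draw(case_kids, 2 * genes$mu_syn[i], "syn", g),
      draw(ctrl_kids, 2 * genes$mu_lof[i], "lof", g),
      draw(ctrl_kids, 2 * genes$mu_dmis[i], "dmis", g),
      draw(ctrl_kids, 2 * genes$mu_syn[i], "syn", g))
  }
  out <- do.call(rbind, acc[!vapply(acc, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(individual_id = character(0), gene_id = character(0),
                      variant_class = character(0), position = integer(0),
                      twin_group = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$allele_id <- if (nrow(out) > 0)
    paste0("dnv:", out$gene_id, ":", out$individual_id, ":", out$position)
  else character(0)
  out
}

#' Simulate population reference carrier counts
#'
#' LoF carriers per gene are `Binomial(n_controls, 2 f)` draws at the
#' equilibrium frequency; synonymous carriers use the class frequency of the
#' generator. Callable fractions default to 1.
#'
#' @param panel output of [simulate_gene_panel()].
#' @param n_controls panel size.
#' @param source label.
#' @return [allele_count_set()] data.frame with an extra `variant_class`
#'   column (`"lof"` and `"syn"` rows).
#' @export
simulate_population_controls <- function(panel, n_controls,
                                         source = "simpop") {
  truth <- panel$truth
  lof <- allele_count_set(truth$gene_id,
                          stats::rbinom(nrow(truth), n_controls, 2 * truth$f),
                          n_controls, 1, source)
  lof$variant_class <- "lof"
  f2_syn <- pmin(2 * panel$genes$mu_syn / 1e-3, 0.1)
  syn <- allele_count_set(truth$gene_id,
                          stats::rbinom(nrow(truth), n_controls, f2_syn),
                          n_controls, 1, source)
  syn$variant_class <- "syn"
  rbind(lof, syn)
}

#' Simulate carrier-dependent cognitive phenotypes
#'
#' Affected offspring carrying a qualifying allele of a risk gene are
#' impaired with probability `impairment_carrier_rate`; all other affected
#' offspring with probability `impairment_base_rate`.
#'
#' @param peds pedigree data.frame.
#' @param variants variant observations.
#' @param truth truth table from [simulate_gene_panel()].
#' @param cfg the [sim_config()].
#' @return The pedigree with `cognitive_impairment` filled for affected
#'   offspring.
#' @export
simulate_phenotypes <- function(peds, variants, truth, cfg) {
  risk_genes <- truth$gene_id[truth$gamma > 1]
  carriers <- unique(variants$individual_id[
    variants$gene_id %in% risk_genes & variants$variant_class == "lof"])
  aff <- which(peds$affected)
  is_car <- peds$id[aff] %in% carriers
  pr <- ifelse(is_car, cfg$impairment_carrier_rate, cfg$impairment_base_rate)
  peds$cognitive_impairment[aff] <- stats::runif(length(aff)) < pr
  peds
}

#' Simulate a complete cohort
#'
#' Runs the full generator: gene panel, pedigrees, parental carriers and
#' transmissions, de novo variants, population reference panels and
#' phenotypes. All randomness derives from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return List with `config`, `genes`, `truth`, `pedigrees`, `variants`,
#'   `dnvs`, `controls` (list of allele count sets, one per reference
#'   panel) and `seed`.
#' @export
simulate_cohort <- function(cfg) {
  panel <- simulate_gene_panel(cfg)
  fam <- simulate_parents_and_transmission(panel, cfg)
  dnvs <- simulate_dnvs(panel, cfg, fam$pedigrees)
  controls <- lapply(seq_along(cfg$n_controls), function(k)
    simulate_population_controls(panel, cfg$n_controls[k],
                                 source = paste0("ref", k)))
  peds <- simulate_phenotypes(fam$pedigrees, fam$variants, panel$truth, cfg)
  list(config = cfg, genes = panel$genes, truth = panel$truth,
       pedigrees = peds, variants = fam$variants, dnvs = dnvs,
       controls = controls, seed = cfg$seed)
}
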