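#' Sex-specific mutation rate model for the X chromosome
#'
#' Holds the two constants used to adjust haploid X mutation rates: the
#' male:female case ratio of the cohort (default 4.2, used to set the default
#' offspring sex mix) and the ratio of mutation rates in spermatogenesis vs
#' oogenesis (default 3.4).
#'
#' @param male_female_case_ratio positive real, default 4.2.
#' @param sperm_oo_ratio positive real, default 3.4.
#' @return A list of class `sex_rate_model`.
#' @export
sex_rate_model <- function(male_female_case_ratio = 4.2, sperm_oo_ratio = 3.4) {
  if (male_female_case_ratio <= 0 || sperm_oo_ratio <= 0)
    stop("sex rate model ratios must be positive")
  structure(list(male_female_case_ratio = male_female_case_ratio,
                 sperm_oo_ratio = sperm_oo_ratio),
            class = "sex_rate_model")
}

#' Frameshift mutation rate from the stop-gained SNV rate
#'
#' Frameshift indels are presumed to arise at 1.3 times the rate of
#' stop-gained SNVs, so a gene's LoF rate can be assembled from an SNV-only
#' rate table.
#'
#' @param mu_stop_gained haploid per-generation stop-gained rate(s), >= 0.
#' @return `1.3 * mu_stop_gained`.
#' @export
frameshift_rate <- function(mu_stop_gained) {
  if (any(mu_stop_gained < 0)) stop("mutation rates must be non-negative")
  1.3 * mu_stop_gained
}

#' Expected number of de novo variants in a cohort of trios
#'
#' Autosomal expectation is `2 * n_trios * mu * callable_fraction` (two
#' haploid genomes per offspring, depth-adjusted by the fraction of callable
#' trios summarised per gene). On the non-PAR X the two parental-origin rates
#' are split `mu_pat : mu_mat = sperm_oo_ratio : 1`, normalised so the
#' sex-averaged autosomal-equivalent rate is preserved
#' (`(mu_pat + mu_mat) / 2 = mu`); male offspring carry one maternal X,
#' females one maternal plus one paternal X, and the two expectations are
#' mixed by `offspring_sex_mix`.
#'
#' @param n_trios number of sequenced trios (>= 0).
#' @param mu haploid per-generation mutation rate of the variant class.
#' @param callable_fraction fraction of the gene callable in the cohort.
#' @param chrom_class `"autosomal"` or `"x_nonpar"`.
#' @param sex_model a [sex_rate_model()].
#' @param offspring_sex_mix named proportions `c(male = , female = )` summing
#'   to 1; default derives from the model's male:female case ratio.
#' @return Expected de novo count (linear in `n_trios`, `mu` and
#'   `callable_fraction`).
#' @export
expected_dnv_count <- function(n_trios, mu, callable_fraction = 1,
                               chrom_class = c("autosomal", "x_nonpar"),
                               sex_model = sex_rate_model(),
                               offspring_sex_mix = NULL) {
  chrom_class <- match.arg(chrom_class)
  if (n_trios < 0) stop("n_trios must be non-negative")
  if (any(mu < 0)) stop("mutation rates must be non-negative")
  if (chrom_class == "autosomal")
    return(2 * n_trios * mu * callable_fraction)
  if (is.null(offspring_sex_mix)) {
    r <- sex_model$male_female_case_ratio
    offspring_sex_mix <- c(male = r / (1 + r), female = 1 / (1 + r))
  }
  if (abs(sum(offspring_sex_mix) - 1) > 1e-8)
    stop("offspring_sex_mix must sum to 1")
  k <- sex_model$sperm_oo_ratio
  mu_mat <- 2 * mu / (1 + k)
  mu_pat <- 2 * mu * k / (1 + k)
  per_male <- mu_mat
  per_female <- mu_mat + mu_pat
  n_trios * callable_fraction *
    (offspring_sex_mix[["male"]] * per_male +
     offspring_sex_mix[["female"]] * per_female)
}

#' Read or write a gene model table
#'
#' The gene table is the unit of association testing: one row per gene with
#' class-specific haploid mutation rates, constraint metrics, callable
#' fractions and flags. Tab-separated with a header; columns are written in a
#' fixed order for deterministic diffs.
#'
#' @param path file path.
#' @return `read_gene_table()` returns a data.frame.
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "chrom_class", "mu_lof", "mu_dmis", "mu_mis", "mu_syn")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0)
    stop("gene table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(tab[, c("mu_lof", "mu_dmis", "mu_mis", "mu_syn")] < 0))
    stop("mutation rates must be non-negative")
  tab
}

.gene_table_columns <- c("gene_id", "chrom_class", "mu_lof", "mu_dmis",
                         "mu_mis", "mu_syn", "pli", "loeuf_decile", "shet",
                         "a_risk", "callable_fraction_case",
                         "callable_fraction_control", "pext_threshold",
                         "known_asd_ndd")

#' @rdname read_gene_table
#' @param genes gene table data.frame.
#' @export
write_gene_table <- function(genes, path) {
  cols <- intersect(.gene_table_columns, names(genes))
  cols <- c(cols, setdiff(names(genes), cols))
  utils::write.table(genes[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
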