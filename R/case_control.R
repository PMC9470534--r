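## Case-control burden of rare alleles with exposure adjustment.

#' Allele count set
#'
#' Per-gene carrier counts for one sample source, with a (possibly
#' fractional) sample size and a per-gene callable fraction adjusting for
#' depth of coverage. The effective exposure of a gene is
#' `sample_size * callable_fraction`.
#'
#' @param gene_id character vector of gene ids.
#' @param carriers non-negative carrier counts.
#' @param sample_size sample size (fractional allowed, e.g. pseudo-samples).
#' @param callable_fraction per-gene callable fraction in `[0, 1]`.
#' @param source label of the sample source.
#' @return data.frame with the five columns above.
#' @export
allele_count_set <- function(gene_id, carriers, sample_size,
                             callable_fraction = 1, source = "unknown") {
  if (any(carriers < 0)) stop("carriers must be non-negative")
  if (any(callable_fraction < 0 | callable_fraction > 1))
    stop("callable_fraction must lie in [0, 1]")
  if (any(carriers > 0 & sample_size * callable_fraction <= 0))
    stop("positive carrier count with zero effective sample size")
  data.frame(gene_id = as.character(gene_id), carriers = carriers,
             sample_size = sample_size,
             callable_fraction = callable_fraction,
             source = source, stringsAsFactors = FALSE)
}

#' Carrier rate per effective sample
#'
#' `carriers / (sample_size * callable_fraction)`.
#'
#' @param carriers carrier count(s).
#' @param sample_size sample size(s).
#' @param callable_fraction callable fraction(s); halving it doubles the rate
#'   at fixed carriers.
#' @return Carrier rate(s).
#' @examples
#' carrier_rate(22, 15780)  # 1.4e-3
#' @export
carrier_rate <- function(carriers, sample_size, callable_fraction = 1) {
  eff <- sample_size * callable_fraction
  if (any(eff <= 0)) stop("effective sample size must be positive")
  carriers / eff
}

#' Exact one-sided two-rate Poisson comparison
#'
#' The canonical exact test for comparing two Poisson rates: conditional on
#' the total count `K = k_case + k_control`, the case count is
#' `Binomial(K, e_case / (e_case + e_control))` under equal rates, where the
#' `e` are effective exposures. Returns `P(X >= k_case)`, one-sided for an
#' elevated case rate; `P = 1` when `K = 0`. Vectorised over genes.
#'
#' @param k_case,k_control carrier counts.
#' @param n_case,n_control effective exposures (sample size x callable
#'   fraction), > 0.
#' @return One-sided P value(s) in `(0, 1]`.
#' @export
poisson_two_rate_test <- function(k_case, n_case, k_control, n_control) {
  if (any(n_case <= 0) || any(n_control <= 0))
    stop("effective sample sizes must be positive")
  K <- k_case + k_control
  p0 <- n_case / (n_case + n_control)
  ifelse(K == 0, 1, stats::pbinom(k_case - 1, K, p0, lower.tail = FALSE))
}

#' Rate test between a case and a control allele count set
#'
#' Convenience wrapper joining two [allele_count_set()] tables by gene and
#' applying [poisson_two_rate_test()] with exposure adjustment.
#'
#' @param case,control allele count set data.frames.
#' @return data.frame with `gene_id`, `rate_case`, `rate_control`,
#'   `p_one_sided`, `source`.
#' @export
rate_test <- function(case, control) {
  genes <- union(case$gene_id, control$gene_id)
  ci <- match(genes, case$gene_id)
  oi <- match(genes, control$gene_id)
  k1 <- ifelse(is.na(ci), 0, case$carriers[ci])
  k0 <- ifelse(is.na(oi), 0, control$carriers[oi])
  e1 <- ifelse(is.na(ci), case$sample_size[1] * case$callable_fraction[1],
               case$sample_size[ci] * case$callable_fraction[ci])
  e0 <- ifelse(is.na(oi), control$sample_size[1] * control$callable_fraction[1],
               control$sample_size[oi] * control$callable_fraction[oi])
  data.frame(gene_id = genes,
             rate_case = k1 / e1, rate_control = k0 / e0,
             p_one_sided = poisson_two_rate_test(k1, e1, k0, e0),
             source = paste(case$source[1], control$source[1], sep = "_vs_"),
             stringsAsFactors = FALSE)
}

#' Conservative dual-reference rule
#'
#' When a gene is tested against two independent population references, the
#' larger of the two one-sided P values enters the meta-analysis, so no
#' significant gene depends on the choice of reference.
#'
#' @param p_ref1,p_ref2 P values in `(0, 1]`, vectorised.
#' @return `pmax(p_ref1, p_ref2)`.
#' @examples
#' dual_control_max_p(4.4e-7, 2.1e-8)  # 4.4e-7
#' @export
dual_control_max_p <- function(p_ref1, p_ref2) {
  if (any(c(p_ref1, p_ref2) <= 0) || any(c(p_ref1, p_ref2) > 1))
    stop("P values must lie in (0, 1]")
  pmax(p_ref1, p_ref2)
}

#' Synonymous-variant calibration of the burden test
#'
#' Per-gene one-sided two-rate tests on ultra-rare synonymous counts, which
#' carry no differential burden under a well-calibrated pipeline. Returns
#' quantile-quantile points of observed vs expected -log10 P and the
#' genomic-control inflation factor
#' `lambda = median(qchisq(1 - P, 1)) / qchisq(0.5, 1)`.
#'
#' @param case,control allele count set data.frames of synonymous counts on
#'   at least 20 shared genes.
#' @return List with `qq_points` (data.frame `expected`, `observed`, both
#'   -log10) and `inflation_lambda`.
#' @export
synonymous_calibration <- function(case, control) {
  res <- rate_test(case, control)
  if (nrow(res) < 20)
    stop("synonymous calibration needs at least 20 genes")
  p <- res$p_one_sided
  obs <- sort(-log10(p))
  exp_ <- sort(-log10(stats::ppoints(length(p))))
  lambda <- stats::median(stats::qchisq(1 - p, df = 1)) / stats::qchisq(0.5, df = 1)
  list(qq_points = data.frame(expected = exp_, observed = obs),
       inflation_lambda = lambda)
}

#' Read per-gene control carrier counts from a site-only VCF
#'
#' Builds an [allele_count_set()] from a small site-only VCF whose INFO field
#' carries `AC` (allele count), `AN` (allele number) and a `GENE` annotation.
#' Carriers are approximated by the summed allele counts per gene (rare
#' variants; at most one copy per carrier), and the sample size by
#' `max(AN) / 2`.
#'
#' @param path path to an (uncompressed or bgzipped) VCF.
#' @param source source label for the resulting table.
#' @param callable_fraction callable fraction applied to every gene.
#' @return An [allele_count_set()] data.frame.
#' @export
read_control_counts_vcf <- function(path, source = basename(path),
                                    callable_fraction = 1) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_control_counts_vcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  for (f in c("AC", "AN", "GENE"))
    if (!f %in% names(info)) stop("VCF INFO lacks field ", f)
  ac <- vapply(info$AC, function(x) sum(as.numeric(x)), numeric(1))
  an <- vapply(info$AN, function(x) max(as.numeric(x)), numeric(1))
  gene <- vapply(info$GENE, function(x) as.character(x)[1], character(1))
  carriers <- tapply(ac, gene, sum)
  allele_count_set(gene_id = names(carriers),
                   carriers = as.vector(carriers),
                   sample_size = max(an) / 2,
                   callable_fraction = callable_fraction,
                   source = source)
}
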