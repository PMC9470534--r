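## Fisher meta-analysis, mutation-selection-balance estimators, and
## noncentral-chi-square power / sample-size machinery.

#' Combine independent P values by Fisher's method
#'
#' `X = -2 * sum(log(p))` follows a chi-square distribution with `2k` degrees
#' of freedom under the joint null; the combined P value is its upper tail.
#'
#' @param p_values numeric vector of one-sided P values in `(0, 1]`.
#' @return Combined P value.
#' @examples
#' fisher_combine(c(0.23, 3.6e-4, 4.4e-7))  # ~1.2e-8
#' @export
fisher_combine <- function(p_values) {
  if (any(p_values <= 0) || any(p_values > 1))
    stop("P values must lie in (0, 1]")
  x <- -2 * sum(log(p_values))
  stats::pchisq(x, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Gene-level meta-analysis of the three evidence stages
#'
#' Combines the de novo enrichment P, the TDT P and the conservative
#' case-control P (the larger of the two population references, see
#' [dual_control_max_p()]) by Fisher's method with 6 degrees of freedom.
#'
#' @param p_dnv,p_tdt one-sided stage P values.
#' @param p_cc_pair numeric length-2 vector: case-control P values against
#'   the two references (a single value is used as is).
#' @return Combined P value.
#' @export
meta_gene <- function(p_dnv, p_tdt, p_cc_pair) {
  p_cc <- if (length(p_cc_pair) >= 2)
    dual_control_max_p(p_cc_pair[1], p_cc_pair[2]) else p_cc_pair[1]
  fisher_combine(c(p_dnv, p_tdt, p_cc))
}

#' Bonferroni significance threshold
#'
#' `0.05 / n_tests`; with the 5,754 constrained genes this is the study-wide
#' threshold 8.7e-6, and with the conventional 20,000 genes the exome-wide
#' threshold 2.5e-6.
#'
#' @param n_tests number of tests (>= 1).
#' @export
bonferroni_threshold <- function(n_tests) {
  if (any(n_tests < 1)) stop("n_tests must be at least 1")
  0.05 / n_tests
}

#' Cumulative allele frequency at mutation-selection equilibrium
#'
#' For a deleterious allele class with haploid mutation rate `mu` and
#' heterozygous selection coefficient `s`, the equilibrium cumulative allele
#' frequency is `f = mu / s`.
#'
#' @param mu haploid LoF mutation rate(s), >= 0.
#' @param s selection coefficient(s), > 0.
#' @export
equilibrium_caf <- function(mu, s) {
  if (any(s <= 0)) stop("selection coefficient must be positive")
  if (any(mu < 0)) stop("mutation rate must be non-negative")
  mu / s
}

#' Point estimate of the selection coefficient from an observed CAF
#'
#' Inverts the mutation-selection balance: `s_hat = mu / f`, capped at 1
#' (capped estimates carry attribute `capped = TRUE`).
#'
#' @param mu haploid LoF mutation rate(s).
#' @param f observed cumulative allele frequency(ies), > 0.
#' @export
selection_from_caf <- function(mu, f) {
  if (any(f <= 0)) stop("cumulative allele frequency must be positive")
  s <- mu / f
  capped <- s > 1
  s <- pmin(s, 1)
  if (any(capped)) attr(s, "capped") <- capped
  s
}

#' Relative risk from carrier rates
#'
#' For rare variants the relative risk is estimated by the ratio of carrier
#' rates in cases over controls.
#'
#' @param rate_case,rate_control carrier rates per effective sample.
#' @return Estimated relative risk; `Inf` with attribute
#'   `flag = "zero_control_rate"` when the control rate is 0.
#' @export
relative_risk_from_rates <- function(rate_case, rate_control) {
  rr <- rate_case / rate_control
  if (any(rate_control == 0)) attr(rr, "flag") <- "zero_control_rate"
  rr
}

#' Population-attributable-risk contribution as an excess carrier rate
#'
#' `max(0, rate_case - rate_control)`: the excess carrier frequency among
#' cases attributable to the variant group.
#'
#' @inheritParams relative_risk_from_rates
#' @export
par_excess <- function(rate_case, rate_control) {
  if (any(rate_case < 0 | rate_control < 0)) stop("rates must be non-negative")
  pmax(0, rate_case - rate_control)
}

#' Noncentrality parameter of the case-control CAF comparison
#'
#' For `N` cases with per-haplotype risk-allele frequency `f` in the
#' population and relative risk `gamma`, the association test statistic is
#' asymptotically noncentral chi-square with 1 d.f. The default
#' `"corrected"` integrand is
#' `lambda = 4N [gamma f log(gamma) + (1 - gamma f) log((1 - gamma f) / (1 - f))]`,
#' whose small-`f` limit `4 N f (gamma log gamma - gamma + 1)` matches the
#' sample-size approximation used by [required_sample_size()]. The
#' `"as_printed"` form replaces the `(1 - gamma f)` factor with
#' `(1 - gamma)`; both are available because published statements of the two
#' formulas are mutually inconsistent, and the corrected form is internally
#' consistent with the sample-size inversion.
#'
#' @param n_cases number of unrelated cases.
#' @param gamma relative risk (>= 1; `gamma = 1` gives 0).
#' @param f population cumulative allele frequency, with `gamma * f < 1`.
#' @param form `"corrected"` (default) or `"as_printed"`.
#' @return Noncentrality parameter lambda (linear in `n_cases`).
#' @export
ncp_lambda <- function(n_cases, gamma, f,
                       form = c("corrected", "as_printed")) {
  form <- match.arg(form)
  if (any(f <= 0) || any(f >= 1)) stop("f must lie in (0, 1)")
  if (any(gamma * f >= 1)) stop("gamma * f must be below 1")
  factor2 <- if (form == "corrected") (1 - gamma * f) else (1 - gamma)
  4 * n_cases * (gamma * f * log(gamma) +
                 factor2 * log((1 - gamma * f) / (1 - f)))
}

#' Analytic power at a given noncentrality parameter
#'
#' `1 - F(F^{-1}(1 - alpha; 0); lambda)` where `F(.; lambda)` is the CDF of
#' the (noncentral) chi-square distribution with 1 d.f. At `lambda = 0` the
#' power equals `alpha`.
#'
#' @param lambda_ncp noncentrality parameter(s), >= 0.
#' @param alpha significance level.
#' @return Power in `[0, 1]`, monotone increasing in `lambda_ncp`.
#' @export
power_at <- function(lambda_ncp, alpha) {
  if (any(lambda_ncp < 0)) stop("lambda must be non-negative")
  crit <- stats::qchisq(1 - alpha, df = 1)
  stats::pchisq(crit, df = 1, ncp = lambda_ncp, lower.tail = FALSE)
}

#' Power parameters
#'
#' Bundles the constants of the power model: significance level (default the
#' study-wide 9e-6), target power 0.9, disorder prevalence 1/54 and the
#' sex-averaged fitness reduction of affected individuals 0.71, whose product
#' 0.013 scales the fitness constraint `s >= 0.013 gamma`.
#'
#' @param alpha significance level.
#' @param target_power desired power.
#' @param n_cases number of unrelated cases.
#' @param gamma relative risk.
#' @param s selection coefficient (alternative to `f`).
#' @param f population CAF (computed from `mu_lof / s` when missing).
#' @param mu_lof haploid LoF mutation rate.
#' @param prevalence_pi disorder prevalence.
#' @param fitness_reduction_sd fitness reduction among affected individuals.
#' @param fitness_constraint the constant of `s >= constant * gamma`; the
#'   default 0.013 is the rounded product
#'   `prevalence_pi * fitness_reduction_sd`.
#' @return List of class `power_params`.
#' @export
power_params <- function(alpha = 9e-6, target_power = 0.9, n_cases = NULL,
                         gamma = NULL, s = NULL, f = NULL, mu_lof = NULL,
                         prevalence_pi = 1 / 54,
                         fitness_reduction_sd = 0.71,
                         fitness_constraint = 0.013) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!is.null(gamma) && any(gamma < 1)) stop("gamma must be >= 1")
  if (!is.null(s) && any(s <= 0 | s > 1)) stop("s must lie in (0, 1]")
  if (is.null(f) && !is.null(s) && !is.null(mu_lof))
    f <- equilibrium_caf(mu_lof, s)
  structure(list(alpha = alpha, target_power = target_power,
                 n_cases = n_cases, gamma = gamma, s = s, f = f,
                 mu_lof = mu_lof, prevalence_pi = prevalence_pi,
                 fitness_reduction_sd = fitness_reduction_sd,
                 fitness_constraint = fitness_constraint),
            class = "power_params")
}

## lambda needed for target power at level alpha
.lambda_for_power <- function(alpha, target_power) {
  stats::uniroot(function(l) power_at(l, alpha) - target_power,
                 lower = 0, upper = 1e4, tol = 1e-10)$root
}

#' Required number of cases for a target power
#'
#' `method = "approx"` uses the closed form
#' `n = lambda_{alpha,beta} / (4 f [gamma log gamma - (gamma - 1)])`;
#' `method = "exact"` (default) finds the smallest integer `N` whose analytic
#' power at [ncp_lambda()] reaches the target, by bracketed integer search.
#' The two agree within a few percent for small `f`.
#'
#' @param params a [power_params()] with `gamma` and `f` (or `s` + `mu_lof`).
#' @param method `"exact"` or `"approx"`.
#' @return Required number of cases (integer for `"exact"`).
#' @export
required_sample_size <- function(params, method = c("exact", "approx")) {
  method <- match.arg(method)
  gamma <- params$gamma; f <- params$f
  if (is.null(gamma) || is.null(f)) stop("params must supply gamma and f")
  if (gamma == 1) {
    warning("gamma = 1: no association signal, required sample size diverges")
    return(Inf)
  }
  lam <- .lambda_for_power(params$alpha, params$target_power)
  n_approx <- lam / (4 * f * (gamma * log(gamma) - (gamma - 1)))
  if (method == "approx") return(n_approx)
  power_of <- function(n) power_at(ncp_lambda(n, gamma, f), params$alpha)
  lo <- max(1, floor(n_approx / 4))
  hi <- max(2, ceiling(n_approx * 4))
  while (power_of(hi) < params$target_power) hi <- hi * 2
  while (lo > 1 && power_of(lo) >= params$target_power)
    lo <- max(1, floor(lo / 2))
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (power_of(mid) >= params$target_power) hi <- mid else lo <- mid
  }
  if (power_of(lo) >= params$target_power) lo else hi
}

#' Power and sample-size grid over (gamma, s) under the fitness constraint
#'
#' Evaluates [ncp_lambda()], [power_at()] and (optionally) the exact
#' required sample size on a grid of relative risks and selection
#' coefficients for one or more mutation rates, masking combinations that
#' violate the fitness constraint `s >= constraint * gamma` (default
#' constant `0.013 = prevalence * fitness reduction = (1/54) * 0.71`).
#' Default ranges are `s` in `[0.01, 0.5]` and `gamma` in `[1, 20]`.
#'
#' @param gamma_range,s_range numeric vectors of grid values.
#' @param mu_values haploid LoF mutation rates.
#' @param params a [power_params()] supplying `alpha`, `n_cases`,
#'   `target_power` and the constraint constants.
#' @param compute_n also invert for the required sample size (slower).
#' @return data.frame with `gamma`, `s`, `mu_lof`, `f`, `feasible`,
#'   `lambda_ncp`, `power` and (if requested) `n_required`; infeasible rows
#'   carry `NA` results.
#' @export
feasible_grid <- function(gamma_range = seq(1, 20, by = 1),
                          s_range = seq(0.01, 0.5, by = 0.02),
                          mu_values = 2e-6,
                          params = power_params(n_cases = 31976),
                          compute_n = FALSE) {
  constraint <- params$fitness_constraint
  grid <- expand.grid(gamma = gamma_range, s = s_range, mu_lof = mu_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$f <- equilibrium_caf(grid$mu_lof, grid$s)
  grid$feasible <- grid$s >= constraint * grid$gamma
  grid$lambda_ncp <- NA_real_
  grid$power <- NA_real_
  ok <- grid$feasible & grid$gamma * grid$f < 1
  grid$lambda_ncp[ok] <- ncp_lambda(params$n_cases, grid$gamma[ok], grid$f[ok])
  grid$power[ok] <- power_at(grid$lambda_ncp[ok], params$alpha)
  if (compute_n) {
    grid$n_required <- NA_real_
    for (i in which(ok & grid$gamma > 1)) {
      pp <- power_params(alpha = params$alpha,
                         target_power = params$target_power,
                         gamma = grid$gamma[i], f = grid$f[i])
      grid$n_required[i] <- required_sample_size(pp)
    }
  }
  grid
}
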