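---
title: "Methods: integrated rare-variant gene discovery in family cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated rare-variant gene discovery in family cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raretrio)
```

# The problem

For a common neurodevelopmental condition under strong negative selection,
individual risk genes of moderate effect (relative risk $\gamma \approx$
2–10 for heterozygous loss-of-function, LoF) are hard to find: de novo
mutations in any one gene are rare (a handful per tens of thousands of
trios), inherited risk alleles are held at very low population frequency by
selection, and case-control burden signals are diluted by annotation noise.
`raretrio` implements a two-stage design that pools three nearly independent
evidence types per gene — de novo enrichment, transmission disequilibrium of
ultra-rare inherited LoF alleles, and case-control carrier-rate burden — and
combines them by Fisher's method.

# Models and assumptions

## De novo enrichment

For gene $g$ and variant class $c$ with haploid per-generation mutation rate
$\mu_{gc}$, the expected count in $N$ trios is $2N\mu_{gc}\kappa_g$, where
$\kappa_g$ is the fraction of callable trios summarised per gene
(`expected_dnv_count()`). Frameshift rates, when absent from an SNV-only
rate table, are taken as $1.3\times$ the stop-gained rate
(`frameshift_rate()`). On the non-PAR X we split the haploid rate by
parental origin in the ratio of spermatogenesis to oogenesis rates (default
3.4:1), normalised so the sex-averaged rate is preserved; male offspring
carry one maternal X, females one of each, mixed by the cohort's offspring
sex ratio (default 4.2:1 male:female). The exact normalisation of the X
adjustment is a package convention — it is fixed by the invariant that an
all-female cohort at equal parental rates reproduces the autosomal formula —
since only the qualitative adjustment is publicly specified.

Gene-level testing weights classes by their empirical positive predictive
value: with observed $O$ and expected $E$ counts in a stratum (constrained
status $\times$ class), the weight is $\max(0, (O - E)/O)$, the estimated
fraction of observed events in excess of the mutational background
(`derive_ppv_weights()`). The per-gene statistic is the weighted sum of
class counts; its null distribution is simulated with independent Poisson
class counts at the gene's expectations, and the one-sided P value is the
smoothed tail $(1 + \#\{\text{sim} \ge \text{obs}\})/(1 + n_{\mathrm{sim}})$.
The $+1$ smoothing is deliberately conservative (a raw fraction can return
0). With a single class at weight 1 the test reduces to the exact Poisson
tail, a property the test suite checks against `poisson_tail_p()`.

Missense spatial clustering is not part of the gene-level statistic here;
the de novo P value is the enrichment P alone. Gene-set questions use a
placement permutation (`geneset_permutation_test()`): holding the number of
mutations per class fixed, each mutation is re-placed onto a gene with
probability proportional to the gene's class-specific rate. Placement by
trinucleotide context is collapsed to class-specific gene rates, since
context dependence is already folded into the per-gene rate inputs. The
confidence interval for fold enrichment assumes log fold enrichment is
normal with a standard deviation implied by the permutation P value.

## Transmission disequilibrium

Ultra-rare (allele frequency $< 10^{-5}$), high-confidence LoF alleles are
identified in sequenced parents who are unaffected and carry no
diagnosis-exclusion flag; each heterozygous parental allele contributes one
Bernoulli transmission per offspring. Under the null each allele transmits
with probability $\tfrac12$; the per-gene P value is the exact one-sided
binomial tail, and $z = (T - NT)/\sqrt{T + NT}$ summarises the distortion.
Overtransmission per trio divides $T - NT$ by trios plus half the duos. On
the non-PAR X only maternal transmissions are informative and father–son
pairs are ignored. Monozygotic twins are counted once. Trios and duos are
pooled into a single binomial per gene. Candidate prioritisation follows the
rule: $z > 1$ and (top LOEUF decile, or top two deciles with a gene
prioritisation score $\ge 0.4$).

## Pedigree-aware case-control

Kinship is computed by the standard recursion over founder-first orderings
(founders non-inbred and mutually unrelated); cryptic relatedness enters as
externally estimated kinship coefficients, with edges added at $\phi \ge
0.1$. One individual per connected component of the resulting relatedness
graph is kept (affected preferred, then smallest id — a deterministic rule
that maximises case yield).

A case's *contributing sample size* is $1 - \sum \phi(\text{case},
\text{ancestor})$ over its most recent sequenced, unaffected, non-excluded
ancestors (the closest qualifying ancestor per parental lineage, floored at
0 for pathological pedigrees; the printed formula gives a duo case 0.75,
which we implement as stated rather than the 0.5 an untransmitted-haplotype
argument might suggest). Pseudocases keep only alleles unseen in those
ancestors, with de novo alleles removed; pseudocontrols take untransmitted
parental alleles, each eligible parent contributing 0.5.

The two-rate "Poisson test" is implemented as the canonical exact
conditional binomial: given total carriers $K$, the case count is
$\mathrm{Bin}(K, e_1/(e_1 + e_0))$ under equal rates, with effective
exposures $e = \text{sample size} \times \text{callable fraction}$. Testing
against two population references and carrying the *larger* P value forward
ensures no finding depends on the choice of reference. Synonymous variants,
which carry no differential burden, calibrate the machinery via a Q–Q plot
and the genomic-control factor $\lambda$. Ancestry stratification is not
implemented; references are pooled, mirroring the headline analysis design.

## Meta-analysis, selection and power

Per-gene evidence combines as $-2\sum\ln p \sim \chi^2_6$. Study-wide
significance uses $0.05/5{,}754$ (the constrained-gene count), exome-wide
$0.05/20{,}000$. At mutation–selection equilibrium $f = \mu/s$, so observed
cumulative allele frequencies yield $\hat s = \mu/\hat f$ (capped at 1) and
carrier-rate ratios estimate $\gamma$. The association test statistic for
$N$ cases is asymptotically noncentral $\chi^2_1$ with

$$\lambda = 4N\left[\gamma f\ln\gamma + (1-\gamma f)\ln\frac{1-\gamma f}{1-f}\right],$$

whose small-$f$ limit $4Nf(\gamma\ln\gamma - \gamma + 1)$ underlies the
closed-form sample-size approximation
$n \approx \lambda_{\alpha,\beta} / (4f[\gamma\ln\gamma - (\gamma-1)])$.
A published variant of the integrand replaces $(1-\gamma f)$ with
$(1-\gamma)$; the two printed forms are mutually inconsistent, and we default
to the form consistent with the sample-size approximation while keeping the
other selectable (`ncp_lambda(form = "as_printed")`). Power is
$1 - F[F^{-1}(1-\alpha; 0); \lambda]$; the default sample-size answer is the
exact integer inversion (bracketed search), with the approximation retained
for comparison. Feasible $(s, \gamma)$ combinations satisfy $s \ge
0.013\gamma$, where $0.013$ is the rounded product of prevalence ($1/54$)
and the sex-averaged fitness reduction of affected individuals ($0.71$);
default ranges are $s \in [0.01, 0.5]$ and $\gamma \in [1, 20]$.

# The synthetic cohort generator

The generator (`sim_config()`, `simulate_cohort()`) emulates the statistical
structure the pipeline assumes, with known per-gene truth:

- **Gene panel.** $\mu_{\mathrm{LoF}}$ log-uniform on $[10^{-7}, 10^{-5}]$
  by default; other class rates scaled from it (damaging missense 1.5x,
  all missense 5x, synonymous 2.5x — typical exome-wide class ratios);
  risk genes drawn with $\gamma$ log-uniform on $[2, 20]$ and $s$ restricted
  to the feasible region $s \ge 0.013\gamma$ within $[0.01, 0.5]$; null
  genes have $\gamma = 1$. $f = \mu/s$ exactly; the rare-variant
  approximation is enforced by refusing $2f > 0.1$.
- **Families.** Trios, single-parent duos (the unsampled parent's allele
  can still reach the child), unaffected-child trios and parentless
  singleton cases; affected offspring are 4.2:1 male:female.
- **Transmission.** Each parent is a heterozygous carrier with probability
  $2f$; a carrier parent transmits to an affected child with probability
  $\gamma/(1+\gamma)$ and to an unaffected child with the exact conditional
  probability $(1-\gamma\pi)/((1-\gamma\pi)+(1-\pi))$ at prevalence $\pi =
  1/54$ — so undertransmission to unaffected offspring emerges naturally.
- **De novo counts.** Poisson at $2\mu$ per offspring, multiplied by
  $\gamma$ for the LoF class in affected offspring. Using the same $\gamma$
  for de novo and inherited risk is a simplification standing in for a full
  liability architecture; it keeps one truth parameter per gene and makes
  recovery tests interpretable. Missense and synonymous classes are
  unenriched.
- **Population references.** Carriers are $\mathrm{Bin}(n, 2f)$ draws
  (carrier-level, not allele-level; no linkage, no ancestry structure).
  Synonymous carriers use a weakly selected class frequency
  ($s_{\mathrm{syn}} = 10^{-3}$) so calibration checks have counts to work
  with. Two references of 104,068 and 132,345 samples mirror a
  dual-reference design.
- **Phenotypes.** Affected carriers of risk-gene LoF alleles are
  cognitively impaired with probability 0.88, others 0.50 — magnitudes
  chosen to echo the reported contrast between highly penetrant and
  moderate-risk genes.

What the generator does *not* emulate — sequence context, calling
artifacts, relatedness beyond declared families, ancestry stratification,
site-frequency spectra beyond the equilibrium point mass — bounds what
passing tests show: they validate the statistical machinery, not robustness
to real-data artifacts.

# Numerical choices and test scales

- One-sided P values everywhere upstream of Fisher; a candidate gene
  lacking a data type receives $P = 1$ with a flag rather than exclusion.
- Output tables sort by $(P_{\mathrm{meta}}, \text{gene})$ for
  deterministic diffs; all simulation functions record their seed.
- Chi-square tests on 2x2 tables omit the continuity correction, matching
  the large-count regime in which they are used.
- Unrelated-selection and clustering tie-breaks are lexicographic; the
  100-bp within-gene rule keeps the most severe variant
  (LoF > damaging missense > other missense > synonymous), ties by
  position.
- Test and validation scales are chosen to give stable Monte Carlo
  estimates on one CPU in minutes: $10^4$ null genes with $\sim$100
  transmission events each for TDT calibration (expected rejection at
  $\alpha = 0.05$ is 0.040 analytically, inside the $[0.035, 0.06]$ band
  for the event-count mixture used); 5,000-trio cohorts for effect-size
  recovery; $10^5$ simulations for the Poisson-tail reduction check.

# Known limitations

- The de novo arm tests enrichment only; a missense-clustering component
  would add power for genes acting through localized missense variation.
- Pseudocase construction in pure trio cohorts is empty by design (every
  inherited allele is visible in the sampled parents and de novo alleles
  are removed), so the case-control arm contributes only when duos,
  singletons or external case panels are present.
- A cohort of 5,000 trios alone cannot push a $\gamma = 8$, $s = 0.2$,
  $\mu = 2\times10^{-6}$ gene to study-wide significance: at $f = 10^{-5}$
  the expected evidence is $\approx 0.16$ case de novo events and
  $\approx 0.2$ heterozygous parents, orders of magnitude short of
  $P < 8.7\times10^{-6}$, consistent with the package's own power
  calculation (`required_sample_size()` reports $\sim$85,000 cases for that
  gene). End-to-end recovery at trio-cohort scale therefore requires either
  larger cohorts or a case-control arm with external case panels.
- Genotype-based kinship estimation, phasing, ancestry inference and
  variant-level quality control are out of scope; they are consumed as
  inputs.
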