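---
title: "Parent-of-origin analysis of case-parent trios: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parent-of-origin analysis of case-parent trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triopoo)
```

## The problem

Two distinct parent-of-origin mechanisms can make a disease allele's
effect depend on the parent it came from. Under *genomic imprinting*
one parental copy of a locus is silenced, so a heterozygous child's
risk depends on whether the active copy is the risk allele. Under a
*maternal effect* the mother's own genotype shapes the intra-uterine
environment and alters the child's risk regardless of what the child
inherited. Ordinary case-control association and the
transmission-disequilibrium test confound the two; a design that
genotypes affected children together with both parents can separate
them.

`triopoo` implements the log-linear likelihood analysis of such
case-parent trios at biallelic SNPs: an imprinting term (alpha), and
maternal-effect terms for mothers carrying two (beta) or one (gamma)
copies of the risk allele, each tested by likelihood ratio.

## The 15-cell triad model

At one SNP, code each trio by the risk-allele doses of mother, father
and child, (M, P, C), each in {0, 1, 2}. Of the 27 conceivable triples
only 15 are compatible with Mendelian transmission (`triad_cells()`
lists them in the package's canonical order); the remaining 12 are
genotyping or pedigree errors and are tallied separately, never
analysed. With one affected child per family the observed cell counts
form a 15-cell multinomial.

The expected count of cell *i* is modelled log-linearly as

    log m_i = mu_s(i) + c1 I(C=1) + c2 I(C=2)
              + alpha I(origin maternal) + beta I(M=2) + gamma I(M=1)

where `mu_1..mu_6` are free intercepts for the six unordered parental
mating types (2x2, 2x1, 2x0, 1x1, 1x0, 0x0). Freeing the mating-type
intercepts makes the Poisson likelihood equivalent to the multinomial
conditional on its total, and absorbs allele-frequency and
ascertainment effects that act at the mating-type level: the method
needs only Mendelian transmission, parental symmetry within mating
types (mother and father genotypes exchangeable in the source
population), and no linkage disequilibrium with another susceptibility
locus. The child-dose terms `c1`, `c2` absorb ordinary allelic
association, so the parent-of-origin terms are tested on top of — not
instead of — a conventional child genotype effect.

Parental origin is determinate in exactly six cells: a heterozygous
child's copy must be maternal in (2,1,1), (2,0,1) and (1,0,1) and
paternal in (1,2,1), (0,2,1) and (0,1,1). The double heterozygote
(1,1,1) is ambiguous; its expected count is the *sum of its two latent
transmission paths*,

    m_9 = exp(mu_{1x1} + c1 + gamma) * (exp(alpha) + 1),

which collapses to the familiar two-fold Mendelian multiplicity of that
cell when alpha = 0. We model this merged cell directly rather than via
EM over the latent origin: the merged likelihood is exact, simpler, and
straightforward to validate against a brute-force grid oracle (the
test suite does exactly that). Homozygous children carry no origin
information, so alpha enters no C=2 or C=0 cell.

Interpretation of exponentiated coefficients: `exp(alpha) > 1` means
the risk allele reaches affected children more often from the mother
(consistent with paternal silencing); `exp(beta)` and `exp(gamma)` are
the risk multipliers conferred by a mother carrying two or one risk
alleles. Under ascertainment of affected children with a rare disease
these equal the corresponding relative risks.

## Testing conventions

Each term is tested by a likelihood-ratio statistic
2(logLik_full − logLik_reduced) on 1 df. By default the full model
contains all included terms jointly and the reduced model drops only
the tested term (`model_spec(alternative = "joint")`); testing each
term against a strata-plus-child-dose-only alternative is available as
`alternative = "marginal"`. Joint fitting is the default because the
method's point is to estimate imprinting *while* accounting for
maternal effects — a transmission asymmetry produced by a maternal
effect would otherwise masquerade as imprinting.

A statistic that is zero to numerical precision (|stat| < 1e-8,
including perfectly symmetric transmission tables) is reported as
exactly 0 with p = 1. The odds ratio reported for a term is the
exponentiated coefficient from the full fit.

## Estimability, boundaries and degenerate tables

Sparse tables routinely cannot identify every term:

* **alpha** is inestimable when no heterozygous affected child was
  observed at all (no counts in any C=1 cell);
* **beta** (resp. **gamma**) is inestimable when the I(M=2) (resp.
  I(M=1)) indicator is constant across the cells with nonzero counts —
  e.g. no homozygous mothers anywhere in the cohort;
* a mating type with zero total count contributes nothing and its
  intercept is reported as `-Inf`.

Inestimable terms are reported with an explicit `"inestimable"` status
(rendered `N/A` in reports) rather than a number. One-sided tables —
say, maternal-origin transmissions observed but no paternal ones — have
a maximum on the parameter boundary; coefficients are constrained to
|coef| <= 12 (odds ratio about 1.6e5) so the likelihood stays finite,
and such fits are flagged `boundary`. Very large finite odds ratios at
small counts are expected behaviour of this model, not an error.

## Numerical strategy

The mating-type intercepts are profiled out in closed form
(`exp(mu_s) = N_s / sum of within-stratum relative means`), leaving at
most five free parameters, which are maximized by L-BFGS-B with
analytic gradients from two starts (all zeros and a count-ratio start);
likelihood-ratio pairs additionally hand the full fit's estimates to
the reduced fit and vice versa, and the statistic is recomputed if a
reduced fit ever beats its full fit beyond 1e-8. The test suite checks
the optimizer against an independent dense coarse-to-fine grid search
with the same closed-form profile: agreement is required within 1e-6 in
log-likelihood and 1e-4 in LRT statistics on fixed tables (observed
agreement is ~1e-13). Fitting is fully deterministic; no seeds are
involved.

## What the simulator emulates

`sim_config()` + `simulate_trios()` generate trios by rejection
sampling: parental doses are drawn independently from Hardy-Weinberg
proportions at the configured risk-allele frequency (parental symmetry
holds by construction), children receive one fairly chosen allele per
parent with origin tracked, and a trio is kept only if the child is
affected under

    P(affected) = baseline_risk * R1^I(C=1) * R2^I(C=2)
                  * Im^I(C=1, maternal origin) * S1^I(M=1) * S2^I(M=2).

The default `baseline_risk = 0.005` keeps the model in the rare-disease
regime where the fitted odds ratios estimate these relative risks; the
test suite verifies consistency (e.g. mean `exp(alpha-hat)` about 3.1
over 500 replicates of 1000 trios simulated at Im = 3, and maternal
relative risks 1.5/2.5 recovered within 15% at 5000 trios).
Configurable genotype dropout and child-allele corruption exercise the
QC path. Rejection sampling was chosen over inverting the analytic
ascertained-cell distribution because it is transparent and makes
origin tracking trivial; the analytic null distribution is still
derived independently (`triad_null_probs()`) and used as the oracle in
tests.

The simulator deliberately does *not* emulate linkage disequilibrium
between SNPs, population stratification or admixture, genotyping-batch
artefacts, or deviations from parental mating symmetry. Passing tests
therefore demonstrate correctness of the statistical machinery under
the model's own assumptions, not robustness of the method to violations
of those assumptions in real cohorts.

## Power: simulation versus analytic claims

Published power statements for this design are often produced with
analytic tools (e.g. Quanto) whose modelled test is a single
parent-of-origin contrast. Simulating the actual joint
imprinting-plus-maternal-effects LRT gives materially lower power at
rare alleles: at the two cohort designs shipped as named scenarios —
181 trios at risk-allele frequency 0.025 and 62 trios at 0.075, each
with imprinting relative risk 3 and 1000 replicates — the acceptance
script measures about 23% and 20% power (Monte-Carlo s.e. ~1.3%),
against analytic claims of at least 80% for the same designs. The
gap is expected: the joint test spends information protecting the
imprinting estimate from maternal-effect confounding (the parental
asymmetry test, which ignores maternal effects, is known to be more
powerful but invalid when they exist), and at MAF 0.025 a 181-trio
study yields only a handful of origin-determinate transmissions per
replicate. Both numbers are recomputed, not asserted, by
`scripts/acceptance.R` and the test suite; type-I error of all three
terms is simultaneously verified at 0.050-0.052 against the [0.035,
0.065] acceptance band (2000 null replicates of 500 trios at MAF 0.3),
so the low power is not mis-calibration.

A related inconsistency in the source material is preserved rather than
resolved: the main-text power sentence for the smaller cohort (OR >= 3
at MAF >= 0.075) differs from the corresponding supplementary figure
legend (OR 4 at MAF 4.0%). Both scenarios can be run through
`estimate_power()`; the shipped acceptance scenario follows the main
text.

## Quality control

`apply_qc()` removes individuals with call rate < 0.95, then SNPs with
call rate < 0.98 recomputed on the survivors — thresholds exposed as
parameters, strict inequalities. Because each step can push entities on
the other axis below threshold, the two steps are repeated to a fixed
point (individuals first in every round), which makes QC idempotent;
the first round coincides with the conventional one-pass order.
Removing any member of a case-parent trio removes the whole trio.
Relatedness checking by identity-by-descent is out of scope; a per-trio
Mendelian-error-rate screen (flag at > 5% inconsistent complete
triples, `mendel_screen()`) catches gross sample swaps instead. A
sex-versus-pedigree-role check in `build_trios()` (a recorded mother
must not be male) stands in for array-based sex verification, which
autosomal PED input cannot support. Per-SNP analysis drops a trio only
at SNPs where that trio's triple is incomplete, maximizing information.

## Reporting

`run_analysis()` emits one row per configured SNP with raw p-values and
odds ratios for all three terms. Bonferroni correction is applied
within user-declared analysis families (the grouping is a column of the
SNP configuration, never inferred), and the family size counts SNPs by
default — matching the convention in which a raw p of 0.013 among three
variants remains significant at 0.05 — with `tests_per_snp = 3`
available for the stricter SNP-by-term convention. Raw p-values are
always reported unadjusted; the flag, not the p-value, carries the
correction.

## Problem sizes used in the shipped checks

Power scenarios run 1000 replicates; type-I calibration 2000 replicates
of 500 trios; imprinting recovery 500 replicates of 1000 trios;
maternal-effect recovery 10 replicates of 5000 trios; power
monotonicity 300 replicates per design point. These sizes give
Monte-Carlo standard errors comfortably below the tolerances they are
checked against.

## Known limitations

* Dyads (missing-parent likelihoods), X-linked loci, multi-SNP or
  haplotype models are not implemented.
* The chi-square reference for the LRT is asymptotic; at very sparse
  tables (a handful of informative trios) it can be anticonservative,
  and boundary-flagged odds ratios should be read as order-of-magnitude
  statements.
* Wald confidence intervals are not printed by default; the canonical
  output is the per-term p-value and odds ratio.
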