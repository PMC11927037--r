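---
title: "Drug-target MR with mediation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target MR with mediation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sepsis is a common antecedent of acute respiratory distress syndrome (ARDS),
and a gene that raises ARDS risk *through* sepsis is a different therapeutic
proposition from one that acts on the lung directly.  `mrtriage` implements a
staged, genome-wide drug-target screen over GWAS and cis-eQTL summary
statistics that separates the two: it asks, for each gene, whether its
expression causally raises the mediator (sepsis), whether the mediator
causally raises the outcome (ARDS), whether any gene-to-outcome effect
survives conditioning on the mediator, and finally whether existing drugs act
against the gene in the direction the causal estimate requires.  Everything
operates on summary statistics — per-SNP betas, standard errors, p-values,
alleles — plus an LD correlation matrix per locus; no individual-level data
are touched.

## The screening cascade

The pipeline (`run_cascade()`) chains six stages.  Every stage's Bonferroni
denominator is the realized number of genes entering that stage, recorded in
the stage report; nothing is hard-coded.

1. **SMR screen.**  At each gene's top cis-eQTL SNP, the summary-data MR
   Wald ratio is $\hat b_{xy} = \hat\beta_{GWAS}/\hat\beta_{eQTL}$ with test
   statistic
   $T_{SMR} = z^2_{eQTL} z^2_{GWAS} / (z^2_{eQTL} + z^2_{GWAS}) \sim \chi^2_1$.
   Genes pass with $p_{SMR} < 0.05$.
2. **HEIDI.**  A significant SMR signal can reflect two distinct causal
   variants in LD rather than one shared variant.  HEIDI tests the
   deviations $d_i = \hat b_{xy}(\mathrm{snp}_i) - \hat b_{xy}(\mathrm{top})$
   jointly against zero with a delta-method covariance that carries the LD
   correlation of both studies' sampling noise.  Genes *pass* with
   $p_{HEIDI} > 0.05$ (heterogeneity is evidence of linkage, the
   configuration we must discard), and a missing test (fewer than 3 eligible
   SNPs) fails conservatively.  Genes without a gene symbol are removed here
   as untargetable.
3. **TSMR validation (gene → mediator).**  Instruments are clumped
   (p < 5e-8, 10 000 kb window, r² < 0.001), harmonized, and fed to the
   estimator suite; the inverse-variance-weighted estimator with
   multiplicative random effects (IVW-MRE) is primary.  Genes pass at
   $p < 0.05/n$ for the realized $n$.
4. **Mediator → outcome.**  One IVW-MRE estimate $\hat b$ shared by all
   genes, from the mediator's own genome-wide instruments.
5. **Total and direct effects.**  The total effect is univariable TSMR of
   the gene on the outcome; the direct effect is the gene coefficient of a
   pairwise multivariable IVW regression (gene + mediator jointly), each
   judged at $0.05/n$.
6. **Mediation decomposition.**  The mediated effect is the product
   $\hat a \hat b$ of the gene → mediator and mediator → outcome paths, with
   the distribution-of-product confidence interval described below.  A gene
   is classified `total_significant`, else `direct_significant`, else
   `mediation_only` when its 95% CI excludes zero, else `none`.  The screen
   keeps `mediation_only` genes: those whose entire effect flows through the
   mediator.

### Sensitivity suite and the recommendation rule

For every TSMR fit with at least three instruments the suite computes IVW
(fixed and MRE), MR-Egger, MR-Egger bootstrap, and the weighted median,
together with Cochran's Q and the Egger intercept.  The recommendation rule
is: Egger bootstrap when the intercept (pleiotropy) test is significant at
0.05; otherwise IVW-MRE, which both absorbs over-dispersion when Q is
significant and is the primary estimator in the clean case.  Pleiotropy takes
precedence over heterogeneity when both fire — directional pleiotropy biases
IVW while mere over-dispersion only widens it — and 0.05 is used for both
calls; neither the precedence nor the alpha was prescribed, so both are
config-exposed (`sensitivity_suite(alpha = )`).

## The distribution-of-product interval

The mediated effect is a product of two estimated coefficients, and the
product of two normals is not normal — it is skewed whenever either factor
has modest precision, so symmetric Wald intervals under-cover on one side.
`dop_ci()` computes quantiles of $X Y$ with $X \sim N(a, se_a^2)$,
$Y \sim N(b, se_b^2)$ independent:

* **analytic** (default): the CDF $P(XY \le q)$ is integrated by adaptive
  quadrature over the standardized $X$ (substituting $x = a + se_a t$ keeps
  the integrand O(1) for any $z = a/se_a$, with the domain split at $x = 0$
  and truncated at $|t| = 12$, beyond which the Gaussian weight is ~1e-32),
  then inverted by bisection to a tolerance of $10^{-9}$ standard deviations;
* **monte_carlo**: empirical quantiles of at least $10^6$ seeded draws.

The two methods agree to well within 0.005; the test suite checks a 20-point
grid against $10^7$-draw quantiles.  `product_effect()` reports the exact
product variance $a^2 se_b^2 + b^2 se_a^2 + se_a^2 se_b^2$ by default, with
the first-order (delta-method) variance as an option.  The two paths are
treated as independent — they are estimated from non-overlapping stages and
largely non-overlapping cohorts — and a correlation term is deliberately not
modelled.

### Back-derivation of a path from a reported product

Published mediation tables often report only $\hat a \hat b$, its SE, and the
shared $\hat b$.  `back_derive_path()` inverts the product-variance formula
for $(a, se_a)$, which makes every reported row independently checkable.  The
inversion fails with an explicit infeasibility error when
$se_{ab}^2 < a^2 se_b^2$ — with $b$ and $se_b$ rounded to two decimals this
genuinely happens (two of the fifty shipped rows, PKD1P3 and ERVH48-1, admit
no real $se_a$), and those rows are excluded from the worked-example checks
rather than forced.

## The synthetic-data generator

`simulate_study()` draws summary statistics directly at the summary level
under the graph instruments → expression → mediator → outcome.  Effects are
per-allele on the SD scale for expression and the log-odds scale for the two
disease traits.  Standard errors follow the single-SNP formulas
$se = 1/\sqrt{2\,maf(1-maf)\,n}$ (quantitative) and
$se = \sqrt{4/(n_{eff}\, 2\,maf(1-maf))}$ with
$n_{eff} = 4/(1/cases + 1/controls)$ (case-control).  Each gene carries a
15-SNP cis locus with AR(1) LD ($\rho = 0.8$ between adjacent SNPs, causal
variant at the centre) for SMR/HEIDI, plus 30 independent instrument loci
placed outside the 10 Mb clumping window for TSMR/MVMR; cis-block sampling
noise is multivariate normal with the LD correlation.  Allele coding is
randomly flipped between studies (probability 0.3) and 5% of SNPs are
palindromic, so harmonization is exercised end to end.

Key defaults and why:

* **Sample sizes** — 30 000 (eQTL panel), 10 154/454 764 (mediator
  cases/controls), 100/216 428 (outcome): the scale of a large blood eQTL
  consortium, a biobank sepsis GWAS, and a registry GWAS of a genuinely rare
  ICU outcome.  The rare outcome is what makes the design's signature
  pattern possible: a gene can be decisively causal for the mediator
  ($z \approx 7$) while its total effect on the outcome stays below the
  Bonferroni bar, leaving mediation as the only detectable channel.
* **Effects** — mediator → outcome $b = 1.8$ log-odds per log-odds;
  mediation-only genes $a = 0.15$ per SD of expression; direct-effect genes
  add $\delta = 1.5$; cis causal eQTL effect 0.7 SD (top cis-eQTLs are
  strong); instrument effects U(0.08, 0.2) with random sign.
* **`simulate_tsmr_pairs()`** (the instrument-level view used for estimator
  calibration) draws exposure effects U(0.2, 0.35): the table it returns
  represents *already clumped* instruments, so every instrument must clear
  genome-wide significance at the worst-case MAF, and the implied
  regression-dilution bias (~0.4%) stays far below Monte-Carlo noise in
  recovery checks.  Directional pleiotropy is applied along each
  instrument's exposure-increasing direction — the quantity the Egger
  intercept actually estimates.

The generator does **not** emulate realistic minor-allele spectra,
imputation noise, sample overlap between cohorts, winner's-curse selection
beyond explicit clumping, or trans-eQTL architecture.  Passing tests
therefore show the machinery is correct and calibrated under the stated
graph, not that any particular real dataset satisfies MR assumptions.

`standard_scenario()` fixes the study conditions used throughout the tests:
20 genes (12 mediation-only, 3 with strong direct effects, 5 null).  The
acceptance checks run the cascade on 10 independently seeded studies
(200 genes) and require ≥80% recovery of mediation-only genes with ≤5%
false-positive categorization; a single study is dominated by binomial noise
at these counts, so pooling measures the same thing more precisely.

## Numerical and policy choices

* **p-value floor.**  Underflowing p-values are floored at the smallest
  positive double so the (0, 1] invariant holds; consequently top-SNP
  selection breaks p-value ties by |z| (then SNP id), otherwise strong cis
  loci would pick their "top" SNP lexicographically.
* **Clumping** is PLINK-convention greedy: smallest p first (ties by SNP
  id), removing same-chromosome SNPs within the *full* pairwise distance
  `window_kb` at r² above threshold.  An instrument-less gene is a recorded
  outcome, not an error.
* **Palindromic SNPs** (A/T, C/G) are dropped when either study's MAF
  exceeds 0.42 or a frequency is missing, otherwise oriented by frequency
  agreement; the threshold follows common harmonization practice and is
  config-exposed.
* **IVW-MRE dispersion is not floored at 1** (the multiplicative
  random-effects convention); `floor_dispersion = TRUE` restores the floor.
* **HEIDI null** is computed by seeded Monte Carlo from the multivariate
  normal with the delta-method correlation (default 2e4 draws) rather than a
  moment-matching approximation: it is assumption-light and exactly
  reproducible.  Selection thresholds (eQTL p < 1.57e-3, r² with the top SNP
  in [0.05, 0.9], at most 20 SNPs, minimum 3) follow the method's customary
  defaults and are config-exposed.  SNPs are processed in a canonical sorted
  order so results are invariant to input row order.
* **Egger orientation** flips rows so all exposure betas are non-negative
  before fitting; the bootstrap variant resamples instrument rows and
  reports the empirical median/SD.  Intercept and slope p-values use the t
  distribution with k − 2 df.
* **MVMR** is pairwise (one gene + the mediator per fit), matching the
  per-gene direct effects the screen needs; instruments are the union of the
  gene's and the mediator's clumped instruments present in all three
  datasets, and weights are fixed at $1/se_{outcome}^2$ (mediator-beta
  uncertainty is not propagated — a documented limitation).
* **Druggability directions** are dichotomized by the sign of the mediated
  effect.  Compatibility requires an inhibitor for a positive direction or
  an agonist for a negative one; modulators, cofactors and unknown
  mechanisms never qualify, because the triage logic turns on opposing the
  causal direction, which those labels do not establish.

## Worked example

```{r example}
library(mrtriage)

# recompute a published mediation interval from its reported row
med <- published_mediation_effects()
b <- published_mediator_effect()                  # beta 1.80, se 0.36
row <- med[med$gene == "PSMA4", ]
path <- back_derive_path(row$estimate, row$se, b$beta, b$se)
dop_ci(path$a, path$se_a, b$beta, b$se)

# simulate a study and run the full cascade
bundle <- simulate_study(standard_scenario(seed = 1))
cascade <- run_cascade(bundle, cascade_config(seed = 1))
cascade$genes[, c("gene_id", "total_p", "direct_p", "mediated",
                  "ci_low", "ci_high", "category")]
```

## Known limitations

* The HEIDI delta-method covariance treats eQTL effects as estimated but
  ignores higher-order ratio terms; with the strong cis signals the screen
  requires this is negligible, but the test is mildly miscalibrated for weak
  loci.
* The mediation decomposition reuses one mediator → outcome estimate for all
  genes; heterogeneity of $b$ across genetic backgrounds is not modelled.
* Bonferroni is applied within each stage, as the screen defines it;
  multiplicity across stages is not adjusted.
* Classification certainty is not quantified: a gene a hair's breadth from
  the total-effect threshold lands in a single category.
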