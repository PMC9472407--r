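---
title: "Methods: PRS portability analysis on synthetic two-population studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRS portability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsport)
```

# The problem

Polygenic risk scores aggregate many small genotype effects into one
per-individual risk estimate. Because discovery GWAS are dominated by
European-ancestry samples, the variants in published prostate-cancer scores
were ascertained where they are informative in Europeans: at intermediate
European allele frequencies, on European linkage-disequilibrium
backgrounds. In other populations the same variants sit closer to fixation
(less per-SNP heritability), are tagged by weaker proxies, and carry
attenuated effect sizes — so case/control discrimination degrades. The
genotype datasets behind these analyses are access-restricted, so this
package pairs the full analysis machinery with a synthetic generator that
reproduces the *structure* of such a study; every result below is about
method correctness on that stated world, not a re-estimate of the
restricted data.

# The disease model

We use a liability-threshold model. Individual liability is

$$ L = G + \varepsilon, \qquad G \sim \text{(scaled genetic score)}, \quad
\varepsilon \sim N(0, 1 - v), $$

where the genetic score over causal doses is standardized and scaled so it
explains a proportion $v$ of the unit liability variance, and an individual
is a case when $L > \Phi^{-1}(1-K)$ for prevalence $K$. The default
prevalence is $K = 0.1$, in the range of lifetime prostate-cancer risk
estimates; the choice matters only through the threshold, and AUC targets
are calibrated at the configured $K$.

The model was chosen over logistic generation because it admits an
*independent oracle*: for any score jointly Gaussian with liability at
correlation $\rho$, the expected AUC is

$$ \mathrm{AUC}(\rho, K) =
 E\!\left[\Phi\!\left(\frac{\rho (L_1 - L_2)}{\sqrt{2 - 2\rho^2}}\right)\right],
 \qquad L_1 \sim L \mid L > t,\; L_2 \sim L \mid L \le t, $$

evaluated by quadrature on equal-probability grids of the two truncated
normals (`liability_auc()`, 2000 nodes, accurate well below $10^{-4}$; the
test suite verifies it against direct simulation). `liability_rho_for_auc()`
inverts it by root finding. Case/control ascertainment does not change the
AUC — it is a within-class rank probability — so a 1:1 sampled cohort
estimates the same quantity as the population.

# The synthetic two-population world

`design_prs_world()` builds a complete generating design:

- **Allele frequencies.** Ancestral frequencies are uniform on
  (0.05, 0.95); each population drifts by a Balding–Nichols draw,
  $f \sim \mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ with $E=p$ and
  $\mathrm{Var}=Fp(1-p)$, clamped to $[10^{-6}, 1-10^{-6}]$. Defaults
  $F_{\mathrm{EUR}} = 0.05$, $F_{\mathrm{AFR}} = 0.10$ give a between-
  population divergence in the range typical of continental comparisons.
  Variants are *ascertained* in population 1: redrawn until their EUR MAF
  exceeds 0.10, which is what tilts the joint SFS into the asymmetric
  bow-tie pattern.
- **Effects.** Per-variant liability effects are Gaussian, with a
  cross-population correlation of 0.8 (published trans-ancestry genetic
  correlations for prostate cancer are high but below 1). Each population's
  score-file column carries its own effects, interpreted as log odds
  ratios.
- **Tagging.** Population 1 genotypes 80% of score variants directly, tags
  12% by proxies with $r^2 \sim U(0.6, 1)$, and lacks the rest; population
  2 genotypes 60% directly with proxies at $r^2 \sim U(0.4, 1)$ for 25%.
  Ten percent of proxies tag the other allele (`same_direction = FALSE`),
  exercising the sign-flip path. Proxy haplotypes copy the causal allele
  with probability $r$ and redraw otherwise, so the haplotype correlation is
  exactly $r$ and frequency is preserved.
- **Calibration.** For weights $\beta_i = b_i r_i^2$ the correlation
  between the pipeline's PRS and liability has the closed form implemented
  in `implied_score_correlation()` ($\rho = \sqrt{v}\sum b^2 r^3 \tau /
  (\sigma_g \sqrt{\sum b^2 r^4 \tau})$ with $\tau = 2f(1-f)$). The
  per-population explained variance $v$ is solved so the expected AUC
  equals the stated targets (0.70 / 0.58 by default). The drifted
  population needs lower $v$ — the generative counterpart of ascertainment
  bias. These targets, not any observed test outcome, fix the generator's
  parameters.
- **Clinical labels.** Cases draw tumour stage (T1–T4 at
  37.4/44.6/10.2/7.8%) and a Gleason band (≤6/7/≥8 at 17.1/43.6/39.2%,
  renormalized from printed rounding) independently of each other, with
  label missingness matching the available-case fractions (1002/1298 and
  1068/1298). A proportional-odds coupling knob can tie both labels to
  liability; the default is 0 (independence), because the motivating study
  design frequency-matches by age and site and reports no within-site
  coupling. Ages are uniform within three recruitment bands (40–69, 70–79,
  80–95) at the study's case/control band probabilities, with 2% missing to
  exercise median filling.
- **Seeds.** A single seed fans out to per-stage child seeds through a
  fixed counter scheme (`fanout_seed()`), so adding a stage never perturbs
  another stage's stream and identical seeds give bit-identical cohorts.

What the generator does **not** emulate: realistic LD beyond single-proxy
tagging (no recombination maps or coalescent structure), within-population
site differentiation, age–risk coupling, genotyping batch effects, and any
effect-size estimation noise beyond the cross-ancestry correlation. A green
test therefore establishes that the *pipeline machinery* is correct and
calibrated on this world — not that the paper-scale effect sizes would be
recovered from real genotypes.

# Score resolution and scoring

Resolution (`resolve_variants()`) places every score variant in exactly one
state: used directly ($r^2 = 1$), used through the best proxy at
$r^2 \ge 0.4$ (ties broken by genomic distance, then lexicographic ID),
expanded by a two-marker rule (the replacement markers carry caller-supplied
weights, growing the marker count by one), or dropped with a reason
(below-threshold proxies, ungenotyped proxies, or absence from the variant
dictionary — the dbSNP-style drop that shrinks a 147-variant score to 146
markers). A `shared` mode intersects the usable markers of two datasets,
mirroring the alternative shared-variant analysis; `optimal` (default)
resolves each dataset independently. Opposite-direction proxies get negated
weights; the constant offset this induces is absorbed by standardization.

Missing doses are filled with per-site means (cohort mean as fallback),
which is exactly neutral for complete samples; the per-entry missingness
default, 0.67%, matches the motivating study's average. Raw scores are the
weighted dose sums in variant-index order; standardization uses the sample
SD ($n-1$), which makes `c(1,2,3)` map exactly to `c(-1,0,1)` and is applied
within each cohort (a pooled option exists via `standardize_scores()` on
concatenated raws).

# Statistical components and numerical choices

- **Bow-tie test.** Classification is on *folded* MAF, so scoring-file
  allele orientation cannot change the verdict; equal MAFs (within
  $10^{-12}$, absorbing fold noise like $1 - 0.7 \ne 0.3$) are ties and are
  excluded by default — the conservative conditional choice; a `split`
  policy is available. The binomial test is exact and two-sided by
  summing outcome probabilities ≤ the observed one (equivalent to tail
  doubling at $p_0 = 0.5$). At 147 informative variants the exact test's
  size is 0.047, within the calibration bounds the acceptance suite
  checks.
- **Mann–Whitney.** Exact p-values for combined $n \le 20$ without ties;
  otherwise normal approximation with continuity and tie corrections.
- **EHH/iHS.** EHH is the pairwise-identity probability from the core
  outward; iHH integrates it by the trapezoid rule over bp, truncating each
  flank where EHH crosses 0.05 (linear interpolation at the crossing).
  Flanks that never decay flag the site unreliable rather than failing.
  Standardization uses 20 equal-width derived-frequency bins on
  [0.05, 0.95], merging undersized bins into the nearest populated
  neighbour. Percentiles against the reference use |iHS|, since enrichment
  concerns extreme scores of either sign. On small fixture panels the core
  of a planted sweep dominates its own frequency bin, so enrichment tests
  rank the unstandardized core score against the same panel's neutral
  sites.
- **PCA/MDS.** Genotype PCA uses the $\sqrt{2f(1-f)}$ scaling; classical
  MDS double-centers 1 − IBS distances. Both apply a
  largest-|loading|-positive sign convention so axes are deterministic and
  permutation-equivariant.
- **AUC and DeLong.** AUC by midrank counting (ties worth 1/2); variance
  from DeLong structural components; CIs normal-theory on the AUC scale
  (pROC's default style), with a logit-scale option. Cross-cohort
  comparisons use the unpaired variant (independent samples); same-cohort
  weight-column comparisons the paired one — the distinction matters even
  though the motivating analysis did not need to spell it out.
- **Odds ratios.** Top decile is a rank fraction strictly above 0.90; the
  middle band is inclusive on [0.40, 0.60]; average ranks for ties. With
  no covariates the logistic estimate equals the 2×2 cross-product exactly;
  with covariates (age, 10 PCs) missing ages are median-filled. "AUC after
  covariate correction" is reported both ways — the fitted-probability AUC
  of the full model and the PRS-only AUC — because the phrase is ambiguous.

# Degenerate inputs

Zero-variance scores refuse to standardize; single-class label vectors
refuse an ROC; empty high/mid cells refuse a Wald OR (pointing at exact
methods); EHH needs two carriers per allele; all-tied Mann–Whitney inputs
return p = 1 with a warning; a variant missing in every sample is excluded
from scoring with a warning rather than poisoning the score.

# Limitations

Real-data features deliberately out of scope: genome-scale iHS on reference
panels (external iHS tables are accepted as input), polygenic-adaptation
graph tests, ADMIXTURE-style deconvolution, imputation from reference
panels, BGEN/PLINK-BED input, and LD-aware effect-size re-estimation. The
published headline AUCs and odds ratios require the restricted cohorts; the
package reproduces the *pattern* (matched ancestry weights win; the drifted
population's AUC is materially lower) generatively, with targets stated in
advance, and the test suite checks exactly that.
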