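---
title: "Models and methods behind rilqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rilqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rilqtl)
```

# The problem

`rilqtl` analyses multi-environment field trials of a biparental maize
recombinant inbred line (RIL) population grown under two irrigation
scenarios (irrigated `I`, non-irrigated `NI`) over several years, with the
goal of locating quantitative trait loci (QTLs) for agronomic and cell-wall
quality traits and classifying each QTL as **constitutive** (the allele
effect is expressed whatever the water regime) or **responsive** (the
allele effect differs between regimes, i.e. the locus controls the trait's
response to water deficit).

The package implements the full chain — field-bloc correction, variance
components and heritability, trait descriptives, a per-marker mixed-model
genome scan, QTL declaration, variance attribution, normalized allele
effects, and cross-trait clustering — together with a synthetic trial
generator with planted ground truth, so that every stage is verifiable
end-to-end without access to field data.

# The synthetic trial generator

The generator's defaults emulate the reference trial the package targets:

* **Genetic map**: 10 chromosomes of 235.5 cM (2,355 cM total) carrying
  1,000 markers; positions uniform with pinned chromosome ends.
* **Population**: 261 RILs derived by selfing from two inbred parents.
  Between adjacent markers at distance $d$ cM the parental-origin genotype
  switches with probability $R = 2r/(1+2r)$, where
  $r = (1 - e^{-2d/100})/2$ is the Haldane single-meiosis recombination
  fraction. This is the standard expected mosaic for single-seed-descent
  RILs, applied marker-to-marker as a Markov chain without interference.
  Residual heterozygosity (a few percent after six selfing generations) is
  ignored: lines are fully homozygous, so the scan contrasts exactly two
  allele classes.
* **Design**: randomized augmented blocs, both parents replicated once per
  bloc as checks; 3 years with 15 blocs per scenario in the first year and
  8 in the two following years; each RIL once per bloc. The realized
  number of observations per RIL is configurable because field losses
  make it trial-specific; the default (complete design, 62 plots per RIL)
  is the uncorrupted layout.
* **Phenotypes**: plot value = intercept + year + scenario +
  year×scenario + bloc draw + line draw + line×year draw +
  line×scenario draw + planted QTL terms + residual, all random draws
  independent zero-mean Gaussians. A planted QTL adds
  $x_i \cdot a$ in every plot and $x_i \cdot b$ in `NI` plots only, with
  $x_i = \pm 1$ the line's allele; $a$ is the constitutive (additive)
  effect and $b$ the responsive (interaction) effect. Bloc effects are
  i.i.d. Gaussian per (year, scenario, bloc): no spatial field trend is
  modeled, matching the exchangeable-bloc assumption of the correction
  model.

Default fixed-effect magnitudes and variances are sized like a plant-height
trait in such a trial (strong genotypic variance, a water-deficit
depression of around 15% of the mean, modest year effects), and every value
is configurable. What the generator deliberately does **not** emulate:
genotyping error, segregation distortion, spatially correlated field
trends, non-Gaussian residuals, or trait-specific NIRS prediction error.
Passing tests on synthetic data therefore demonstrate the correctness of
the estimators under the stated model, not robustness to those
real-data pathologies.

The generator retains its complete ground truth (per-line genetic draws,
bloc effects, per-plot component decomposition) so that recovery tests can
compare estimates against the generating values, and one master seed
drives documented per-stage substreams (map, genotypes, missingness,
phenotypes).

# Bloc correction (BLUP subtraction)

Plot values are corrected by subtracting the best linear unbiased
prediction of their bloc effect, from the plot-level mixed model

$$Y_{ijkl} = \mu + g_i(1-t_i) + C_i t_i + y_j + e_k + B_{jkl}
           + gy_{ij} + ge_{ik} + ye_{jk} + E_{ijkl},$$

with $t_i = 1$ for the replicated parental checks ($C_i$ fixed) and 0 for
RILs ($g_i$ random i.i.d.), blocs $B_{jkl}$ and the genotype×year and
genotype×scenario interactions random, and year, scenario and their
interaction fixed. The RIL-only random terms enter through a 0/1 indicator
random slope, which implements $g_i(1-t_i)$ literally in `lme4`. Fitting
is REML; the corrected table is the raw table minus each plot's bloc BLUP,
preserving all keys. Because BLUPs shrink toward zero, corrected data
never over-correct: the variance of corrected bloc means is strictly below
the raw one, and re-running the correction on corrected data yields
near-zero BLUPs (idempotence in expectation — both properties are tested).

The model is fitted jointly across years (the year term is in the model);
a per-year variant is not implemented.

# Variance components, heritability, ls-means, ANOVA shares

On corrected RIL data, variance components come from the REML fit of

$$Y'_{ijk} = \mu + g_i + gy_{ij} + ge_{ik} + y_j + e_k + ye_{jk} + E_{ijk},$$

with the three genotypic terms random and the environmental terms fixed.
Estimates are non-negative by construction (boundary REML). Broad-sense
heritability of line means is

$$h^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ge}/k + \sigma^2_{gy}/j
        + \sigma^2_E/(obs/i)},$$

with $k$ scenarios, $j$ years and $obs/i$ the average number of
observations per line, recomputed per trait after dropping missing values.

Least-square means per line are fixed-effects model-adjusted means:
jointly (`all` scope: genotype + year + scenario + year×scenario) or per
scenario (`I`/`NI` scope: genotype + year on the subset), computed via
`emmeans`; on balanced data they coincide with arithmetic means.

The per-factor ANOVA $r^2$ table enters all terms of the variance model as
fixed effects and attributes 100·SS/TSS sequentially, main effects first
(genotype, year, scenario, then the two-way interactions). An
interactions-after-main-effects order is the only sequential order
compatible with reporting non-trivial year and scenario shares, which is
how such tables are conventionally read. The decomposition is computed
exactly on count-weighted (line, year, scenario) cell means — every model
term is a function of that cell — with the within-cell sum of squares
folded into the residual; this is algebraically identical to the
plot-level sequential ANOVA (tested) and fast at trial scale.

# Trait descriptives

* **Percent response**: $100\,|\bar{Y}_{NI} - \bar{Y}_I|/\bar{Y}_I$. The
  magnitude convention reproduces published parental worked examples
  exactly at one-decimal rounding; a signed variant is exposed for
  direction-aware analyses. Undefined when the irrigated mean is zero.
* **Correlations**: pairwise-complete Pearson matrices per scenario;
  zero-variance traits are flagged rather than silently propagated.
* **PCA**: eigen-decomposition of the correlation matrix (centered,
  unit-variance-scaled traits), percent variance = 100·eigenvalue/p.
  Plot-level corrected observations are used by default with the scenario
  kept as a grouping label, so scenario separation along components is
  inspectable; per-line summaries can be supplied instead. Sign
  convention: the largest-magnitude loading of each component is positive.
* **Van Soest derived traits**: cellulose
  $CL.NDF = 100(ADF-ADL)/NDF$ and hemicellulose
  $HC.NDF = 100(NDF-ADF)/NDF$, guarded by the biochemical ordering
  $NDF \ge ADF \ge ADL \ge 0$.

# The genome scan

Each marker is tested one at a time on corrected data with the mixed model

$$Y'_{ijk} = \mu + g_i + y_j + e_k + ye_{jk} + m_p x_{ip}
           + (m_p{\times}e_k) x_{ip} + E_{ijkp},$$

where $x_{ip} = \pm 1$ codes the line's parental allele at marker $p$ and
$g_i$ is the residual polygenic line effect, the only random term. The
marker main effect $m_p$ carries the constitutive signal; the
marker×scenario interaction carries the responsive signal.

**Test definition.** Significance is assessed by likelihood-ratio tests
between nested maximum-likelihood fits (full model vs the model without
the tested term), referred to a 1-df chi-square. This is exact to define,
conservative at large $n$, and avoids denominator-degrees-of-freedom
approximations. When the polygenic variance is zero and the design is
balanced, the p-values coincide with a fixed-effects least-squares
analysis, which is verified against an independent `lm()`-based oracle.

**Computation.** Observations are first averaged to (line, year,
scenario) cell means: the scan model contains no bloc term, so replicates
within a cell carry no marker information beyond their mean. The engine
then exploits the structure of the single-random-intercept model: a
per-line orthonormal (Helmert-type) rotation diagonalizes the random
structure, after which the profiled likelihood at any variance ratio is a
small weighted least-squares problem. The rotation is computed once per
trait; each marker refits only its own fixed-effect columns (the engine
is exact, not an approximation, and reproduces `lme4` criteria to
numerical precision — tested). Lines with a missing call at a marker are
dropped for that marker only; markers left with a single allele class are
flagged untestable with p = 1 rather than raising.

**Threshold.** The declaration threshold reads the conventional
"p-value inferior to 0.005%" rule literally: $\alpha = 5\times10^{-5}$,
strict inequality. Note that 0.005% is 5e-5, not 0.005 — a frequent
misreading. No genome-wide multiplicity correction is applied beyond this
fixed threshold; at 1,000 markers the expected count of false constitutive
QTLs per genome scan is well below one (verified by simulation).

**A calibration caveat.** The responsive (interaction) test inherits a
structural liberality from the model itself: genotype×scenario variance is
not a term of the scan model, so when $\sigma^2_{ge} > 0$ each line's
scenario response contains a shared random component that the test treats
as independent noise. Null simulations show the constitutive p-values
calibrated (fraction below 0.01 compatible with 0.01) while responsive
p-values are inflated under $\sigma^2_{ge} > 0$. This is a property of the
single-marker model class, not of the implementation; it is consistent
with such scans declaring responsive QTLs for all traits even when the
genotype×scenario ANOVA share is marginal. Users comparing constitutive
and responsive counts should keep this asymmetry in mind.

# QTL declaration, attribution, effects, clusters

* **Declaration**: per chromosome, maximal runs of map-adjacent markers
  with p below the threshold form one QTL each; a single non-significant
  marker terminates a run, and runs are not split at internal p-value
  minima. The confidence interval spans the run's first and last marker
  positions; the peak is the run's minimum p, ties resolved toward the
  marker closest to the run midpoint, then the lowest position. Output
  ordering is deterministic: (trait, chromosome, interval start).
* **$r^2$**: per-scenario ls-means of the genotyped lines are stacked and
  the fixed model intercept + scenario + marker + marker×scenario is
  fitted at the peak; the QTL's share is the drop in $R^2$ when its
  defining term (marker for constitutive, interaction for responsive) is
  removed — the squared semipartial correlation of that column (verified
  algebraically against `lm()`).
* **Normalized effect**: the allele-class difference of means (of joint
  ls-means for constitutive QTLs; of per-line NI−I responses for
  responsive QTLs) divided by the observed range (max − min) over the RIL
  progeny of the same quantity — ls-means rather than plot values, since
  the range refers to the progeny. The magnitude is bounded by 1; the
  sign is positive when the first-parent (`A`) allele increases the trait
  or its response. Relabeling the parents flips every sign and changes
  nothing else (tested).
* **Clusters**: single-linkage grouping of same-kind QTLs on a chromosome
  whose closed confidence intervals overlap (touching endpoints count);
  groups with at least two members from at least two distinct traits are
  clusters, the rest are singletons. This reconstruction of the
  co-localization rule is a package choice: cluster counts on real data
  depend on it and are not asserted anywhere.

# Numerical choices

* Scan likelihood optimization: golden-section search on
  $\log \lambda \in [-18, 18]$ ($\lambda$ = line-to-residual variance
  ratio) with tolerance 1e-6, endpoints checked; likelihood-ratio
  statistics are clamped at zero against optimizer round-off.
* REML fits of the correction and components models use `lme4` defaults;
  convergence diagnostics are captured and re-raised as warnings, never
  discarded. Negative variance estimates cannot occur (boundary REML).
* Missing trait values are dropped casewise per trait; `obs/i` is
  recomputed per trait after dropping. Checks are excluded from
  components, ls-means and the scan, per the check/RIL switch of the
  correction model.
* Constant-response data short-circuit to all-zero components rather than
  entering a degenerate REML fit; degenerate designs (no replication
  axis) raise explicit identifiability errors.

# Problem sizes used in the test suite

The packaged verification suite runs on synthetic data sized to exercise
the estimators meaningfully: null calibration on the full emulated trial
(261 RILs, 1,000 markers, 20 replicate traits), power and recovery on a
two-chromosome version of the same map (50 replicates), and
variance-component recovery at 250 lines over 20 replicates. These sizes
were chosen as the smallest that make the Monte-Carlo acceptance bands
informative.

# Known limitations

* The responsive test's liberality under genotype×scenario variance,
  discussed above.
* Whether the original analyses used Wald F tests with
  degrees-of-freedom approximations rather than likelihood-ratio tests is
  not determinable from the published description; one choice is
  implemented and documented, and the OLS-oracle equivalence bounds the
  difference in the collapsible case.
* No interval mapping or multi-QTL models: the scan is strictly
  single-marker, and nearby QTLs merged by linkage into one significant
  run are reported as one QTL.
* No spatial field-trend correction and no narrow-sense heritability.
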