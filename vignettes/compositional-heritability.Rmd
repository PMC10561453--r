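---
title: "Heritability of microbiome taxa from compositional data: model, estimator, and what can go wrong"
author: "compherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heritability of microbiome taxa from compositional data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compherit)
```

# The problem

The heritability of a microbial taxon's abundance — the fraction of its
phenotypic variance across hosts attributable to host genetic variation —
is almost always estimated from *relative* abundance data, because
sequencing yields proportions, not loads. Relative abundances are
compositional: every taxon's value depends on every other taxon's
abundance, so a genetic signal in one member of the community leaks into
all of them. `compherit` quantifies exactly how much this leakage distorts
heritability estimation, provides the machinery to reproduce the
distortion in simulation, and implements the normalizations that can (and
cannot) undo it.

# Model

Absolute abundance of taxon $i$ in host $j$ follows the standard
quantitative-genetic decomposition

$$P_{ij} = \alpha_i + G_{ij} + E_{ij},$$

with mean abundance $\alpha_i$, breeding value
$G \sim \mathrm{MVN}(0, \Sigma_G)$ shared by all replicate hosts of a
genotype (a clonal, broad-sense design: genotype enters as a random
intercept), and residual $E \sim \mathrm{MVN}(0, \Sigma_E)$ drawn per
host. The covariance matrices are parameterized by per-taxon variances
$V_{G_i}, V_{E_i}$ and correlation matrices
($\mathrm{cov}(j,k) = r_{jk}\sqrt{V_j V_k}$); a scalar correlation builds
the equicorrelated structure used in all co-abundance scenarios, and any
positive semi-definite matrix is accepted. The true heritability is
$h_i^2 = V_{G_i}/V_{P_i}$ with $V_{P_i} = V_{G_i} + V_{E_i}$.

Relative abundance is the ratio $f_i = P_i / C$ with community total
$C = \sum_j P_j$, itself normal with variance equal to the summed
variances plus twice the summed pairwise covariances. The heritability one
obtains from relative data is
$\varphi^2 = \mathrm{var}(f_{G_i})/\mathrm{var}(f_{P_i})$, the
genotype-level over total variance of the ratio.

## The delta-method approximation

The variance of a ratio of correlated normals has no closed form (and
strictly speaking no finite value — the denominator can cross zero), but
its second-order Taylor (delta-method) approximation

$$\mathrm{var}\!\left(\frac{X}{Y}\right) \approx
  \frac{\mu_X^2}{\mu_Y^2}\left(\frac{\sigma_X^2}{\mu_X^2}
  - \frac{2\,\mathrm{cov}(X,Y)}{\mu_X\mu_Y}
  + \frac{\sigma_Y^2}{\mu_Y^2}\right)$$

is excellent in the regime that matters here: the denominator aggregates
the whole community, so its coefficient of variation is roughly
$\mathrm{CV}_{\text{taxon}}/\sqrt{M}$ and the truncation error scales
with $\mathrm{CV}_Y^2$. At the reference noise level used throughout
(per-taxon $\sigma/\mu = 1/6$) and a background 10–500 times the focal
abundance, the approximation tracks brute-force Monte-Carlo to well
within 2%. It degrades as $\mathrm{CV}_Y$ approaches the per-taxon CV:
an exact moment expansion shows the relative error grows like
$\sim 5.5\,\mathrm{CV}_Y^2$ when numerator and denominator are equally
noisy, reaching ~15% at $\mathrm{CV}_Y = 1/6$. `ratioVarianceDelta()`
exposes the primitive; the accuracy claim is made — and tested — for
community-aggregate denominators.

Applying the approximation to $\mathrm{var}(f_G)$ and
$\mathrm{var}(f_P)$ and writing the result in terms of background
aggregates (computed by `backgroundAggregates()`: $A$, $\omega$, $z$ the
background's summed mean abundance, genetic and phenotypic variance;
$\gamma$, $\epsilon$ the summed focal–background genetic and
environmental covariances; $\kappa$, $\nu$ the within-background pair
sums) gives the closed form implemented by `phiSquared()`:

$$\varphi^2 \approx \frac{A^2 V_G + \alpha^2\omega
  - 2\alpha(A\gamma - \alpha\kappa)}
  {A^2 V_P + \alpha^2 z - 2\alpha(A(\gamma+\epsilon)
  - \alpha(\nu+\kappa))}.$$

The algebraic identity between this form and the ratio of the two
delta-method variances holds to machine precision and is enforced as a
property test.

A structural fact worth recording: because numerator and denominator are
each a second-order delta variance of a taxon-over-total ratio, and a
delta variance $c^2(\mathrm{CV}_X^2 - 2\rho\,\mathrm{CV}_X\mathrm{CV}_Y +
\mathrm{CV}_Y^2)$ is bounded below by $c^2(\mathrm{CV}_X -
\mathrm{CV}_Y)^2 \ge 0$ whenever $|\rho| \le 1$, the approximation is
confined to $[0, 1]$ for every valid (PSD, correlation-bounded)
parameterization. The implementation still warns if rounding ever
produces a value outside that range, but no valid input can.

## What the approximation says

```{r phi-examples}
# two equally abundant taxa, one fully heritable, one not
cp <- CommunityParams(alpha = c(1, 1), vG = c(1, 0) / 36, vE = c(0, 1) / 36)
phiSquared(cp)
```

Both taxa come out at 0.5: closure transfers half the genetic signal of
the heritable taxon onto its non-heritable partner. Three regimes follow
directly from the formula (`phiLimits()` returns the two limits):

* **Rare focal taxon** ($\alpha/A \to 0$): $\varphi^2 \to h^2$. Over the
  grid with focal $h^2 = 0.2$, $A = 100$, $z = 100\,(1/6)^2$, $V_P$
  proportional to $\alpha$ and background heritability anywhere in
  $[0, 1]$, the absolute error stays below 0.04 for all focal relative
  abundances under 5% (the acceptance suite recomputes the whole grid;
  the paper-level bound is 0.10).
* **Dominant focal taxon** ($\alpha/A \to \infty$):
  $\varphi^2 \to \omega/z$, the background's heritability — the focal
  taxon's own genetics drop out entirely.
* **Non-heritable focal taxon** ($V_G = 0$, no covariances):
  $\varphi^2 = \alpha^2\omega / (\alpha^2 z + A^2 V_P)$, which is
  strictly positive whenever the background carries any genetic
  variance. This is the seed of the false-discovery problem: the signal
  is genuinely there, so no multiple-testing correction removes it.
* **Co-abundances**: perfect genetic correlation between two equal taxa
  ($r_G = 1$, both $h^2 = 0.5$) drives $\varphi^2$ to exactly 0 (the
  genotype-level variation cancels in the ratio); perfect environmental
  correlation drives it to exactly 1 (within-genotype variation
  cancels). At $r = 0.99$ the values are 0.0099 and 0.990.

  A caveat specific to this near-degenerate regime: when $r \to 1$
  cancels the leading term of one variance component, second-order
  contributions the delta method drops become the dominant remainder. In
  particular the within-genotype variance of the ratio carries a
  breeding-value–residual coupling term
  $\approx V_E\,(2(1-r_E) + 2V_G)/16$ (two equal taxa, unit means): its
  $V_GV_E$ part inflates the true within-variance by a factor
  $1 + V_G/(1-r_E)$ relative to the approximation — 3.5% at
  $r_E = 0.6$ but 139% at $r_E = 0.99$ for $\sigma/\mu = 1/6$. High-
  precision simulation accordingly gives a true relative-abundance ICC
  of 0.974 where the approximation says 0.990; indistinguishable on a
  0–1 plot, but a real, measurable limitation of the closed form near
  perfect correlation, and the one place the package's simulation
  cross-checks deviate from it beyond Monte-Carlo error.

# The simulator

`simulatePopulation()` draws one breeding-value vector per genotype and
one residual vector per host from the two multivariate normals and adds
them to $\alpha$. Design defaults are deliberately scaled for desk use
(the tests mostly run 100–500 genotypes with 10–1000 replicates; the
published reference designs, 500 genotypes × 1000 replicates for the
interdependency analyses and 500 × 500 for the co-abundance analyses, are
plain parameter choices and run in minutes). A seed fully determines the
output; the draw order is fixed (all breeding values, then all
residuals).

What the generator emulates: Gaussian abundance variation with genetic
and environmental correlation structure, exact clonal replication within
genotype, total-sum closure (`toRelative()`), and sequencing as
per-host multinomial thinning at arbitrary depths
(`simulateReadCounts()`). What it does not emulate: non-Gaussian
abundance distributions, zero inflation, pedigree or SNP-based
relatedness (genotype is a clean random effect), genotype-by-environment
interaction, and measurement bias from extraction or amplification.
Passing tests therefore validate the compositional arithmetic and the
estimation machinery, not the full messiness of real surveys.

Gaussian abundances can go negative; at $\sigma/\mu = 1/6$ this happens
with probability $\Phi(-6) \approx 10^{-9}$ per cell. The default policy
truncates at zero and warns if more than 0.1% of cells are affected;
`error` and `allow` policies are available for strict-model work.

# Estimation

`fitVarianceComponents()` fits the Gaussian random-intercept model per
taxon. Two routes:

* `anova` (balanced designs): exact mean-square estimator,
  $\hat V_G = \max(0, (\mathrm{MSB}-\mathrm{MSW})/r)$,
  $\hat V_E = \mathrm{MSW}$; negative components are clamped to zero,
  standard practice.
* `reml`: restricted maximum likelihood via `lme4::lmer`, required for
  unbalanced designs. On balanced data with an interior optimum the two
  coincide (tested to $10^{-6}$).

`lrtGenotypeEffect()` tests $H_0\!: V_G = 0$ by maximum likelihood (not
REML, so the likelihoods are comparable across models). For balanced
designs the profile ML has a closed form — the grand mean is the ML mean,
and the likelihood separates in the within- and between-genotype mean
squares — which the implementation uses and the tests verify against
`lme4` to six decimals; it is what makes the Monte-Carlo experiments
cheap. The statistic is referred to $\chi^2_1$. Since the null value sits
on the boundary of the parameter space, the correct reference is the
50:50 $\chi^2_0/\chi^2_1$ mixture and plain $\chi^2_1$ is conservative;
the mixture is available via `mixture = TRUE` but the conservative
default matches common practice in the power tooling this mirrors.

`scanCommunity()` runs the fit and test across all taxa and applies
Benjamini–Hochberg step-up adjustment. Failures of individual taxa are
reported as missing rows, not scan failures.

# Power and false discovery

`powerCurve()` measures, by simulation, the probability that the LRT
rejects for a focal taxon as a function of total sample size. The
headline experiment sets the focal taxon non-heritable ($V_G = 0$,
$\alpha = 1$, $V_P = (1/6)^2$) in front of a heritable background
($A = 100$, $z = 100(1/6)^2$, $\omega/z \in \{0.1, 0.25\}$): the
rejection probability climbs with sample size and reaches ~100% near
$6\times 10^5$ hosts at $\omega/z = 0.25$, because $\varphi^2 \approx
0.0025$ really is positive. Under the global null ($\omega = 0$) the
test holds its size. Sample sizes are split as genotypes × 10 replicates
by default (the split is a free parameter; it is exposed because the
published analyses do not pin it down). Monte-Carlo error
$\sqrt{p(1-p)/n_{\mathrm{sim}}}$ is reported so tolerance checks are
principled; the experiments run 200 simulations per point.

`communityFalseDiscovery()` scales this to whole communities: with 10%
of 50 taxa truly heritable ($h^2 = 0.5$) and the rest null, the
BH-adjusted proportion called significant rises with sample size and
overshoots the true 10% by $2\times 10^5$ hosts, with the excess coming
entirely from the $V_G = 0$ taxa. The focal-abundance grid for power
scenarios defaults to $\alpha \in \{1, 5, 10\}$ against $A = 100$ where
one is needed; the published figure does not print its exact values, so
these are package choices.

# Normalizations

`normalizeAbundance()` implements total-sum scaling, additive log-ratio
(ALR) against a designated reference taxon, centered log-ratio (CLR),
cumulative-sum scaling (CSS, quantile default median), plain log, and —
for descriptive completeness, with no recovery claims — arcsine-square-root
and rank-based inverse-normal marginal transforms. Zeros in log-based
methods are an error unless a pseudocount is supplied (default 0.5 in the
recovery experiments, announced loudly, because any offset is arbitrary).

`recoveryExperiment()` runs the full chain — simulate absolute
abundances, thin to counts at host-specific depths (log-uniform across a
10× range by default), normalize, estimate — and pairs true with
recovered heritabilities. The two canonical scenarios encode the two
sufficient conditions under which normalization provably works:

* a **constant reference taxon** (zero genetic and environmental
  variance): ALR returns log-abundances comparable across hosts, and the
  recovered $\hat h^2$ land within 0.05 of truth for every taxon at the
  200 × 100 design, despite 10-fold depth variation. The log scale
  multiplies both variance components by the same first-order factor, so
  their ratio survives; residual bias from counting noise
  ($\approx 1/\mathbb{E}[c_i] + 1/\mathbb{E}[c_{\mathrm{ref}}]$ added to
  the environmental variance) stays within that tolerance at depths
  $\ge 10^4$.
* **total-sum scaling on the same data** recovers $\hat\varphi^2$, not
  $h^2$: the non-heritable taxon in that community shows a clearly
  positive estimate (analytically $\approx 0.024$), reproducing the
  interdependency bias.

# The study compilation

`loadTable1()` ships a checksummed transcription of the published
compilation of 23 studies (30 rows; seasons, ancestries, breeds,
timepoints and field-years as sub-rows) of per-taxon microbiome
heritability. `summarizeTable1()` reports the headline descriptives: the
per-row average significant heritability spans 0.056–0.58; the
cross-study mean is 0.31 under the package's averaging rule (multi-row
studies averaged within study first, studies without a value excluded —
the rule ships with the output because the mean, unlike the range, is
sensitive to it); taxa counts span 3–2933 with a computed median of 215
across rows (the source text quotes 221; the computed value is reported
as-is rather than forced). `regressProportionHeritable()` fits the
binomial (logistic) model of heritable-taxon counts on log10 sample size
— slope positive, McFadden pseudo-$R^2$ = 0.38 — and
`regressAverageHeritability()` the linear model of average heritability
on log10 sample size — slope negative, $p = 0.002$, $R^2 = 0.37$. Each
table row enters as one observation; that rule reproduces the published
p-value exactly and is retained. Rows flagged as lacking a significance
measure can be excluded via `loadTable1(excludeUnvalidated = TRUE)` as a
sensitivity toggle.

# Numerical choices and limitations

* Covariance factors come from a symmetric eigendecomposition with
  negative eigenvalues clamped at zero below a $10^{-8}$ relative
  tolerance, so exactly singular structures ($r = 1$) simulate cleanly.
* The $\varphi^2$ denominator must exceed $10^{-12} A^2 V_P$; below that
  the parameter combination has removed essentially all variance from
  the relative abundance (e.g. two identical, perfectly correlated taxa)
  and an error naming the situation is raised instead of a
  cancellation-dominated number.
* ANOVA variance components are clamped at zero; a zero residual
  variance yields $\hat h^2 = 1$ with a warning.
* Relative abundances are modelled as Gaussian responses without
  transformation in all estimation steps, matching the simulation design
  the approximation is compared against; transformations are a separate,
  explicit step.
* Statistical tolerances in the test suite follow the estimators'
  actual sampling rates: quantities estimated from genotype clusters
  carry relative error $\sim\sqrt{2/a}$, not $\sqrt{2/n}$, and
  genotype-mean correlations are attenuated by $V_G/(V_G + V_E/r)$.
* Out of scope by design: kinship/GRM narrow-sense estimation,
  count-likelihood (negative-binomial / Dirichlet-multinomial) models,
  non-Gaussian link functions, GxE, and measurement-bias modelling.
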