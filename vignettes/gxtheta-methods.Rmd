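---
title: "Mapping polygenic epistasis with the Gxtheta test"
author: "gxtheta package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping polygenic epistasis with the Gxtheta test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxtheta)
```

## The problem

In a mapping panel descended from two inbred founders — recombinant
inbred (RI) strains, advanced intercross lines (AILs), haploid yeast
segregants — every individual is a mosaic of the two founder genomes.
The fraction of an individual's markers inherited from a designated
reference founder, its global ancestry $\theta \in [0,1]$, summarizes
its genetic background in a single number.  If the phenotypic effect of
a SNP depends on that background — because the SNP interacts epistatically
with many loci across the genome — the SNP's effect size will covary with
$\theta$.  Testing each SNP for an interaction with $\theta$ therefore
detects *polygenic epistasis* with a single extra degree of freedom per
SNP, instead of the quadratically many tests of pairwise SNP–SNP scans.

## The model

For one SNP with dosage vector $x$ (reference-founder allele dosage,
$\{0, \tfrac12, 1\}$) and trait $y$:

$$
y = \mu + C\gamma + \beta_G\, x + \delta\, \theta
    + \beta_{G\times\theta}\, (\theta \circ x) + u + e,
$$

with optional covariates $C$ (e.g. sex), a polygenic random effect
$u \sim N(0, \sigma_g^2 K)$ on the genetic relationship matrix
$K = ZZ^\top / m$ of centered dosages, optionally a second component
$N(0, \sigma_\theta^2 K^A)$ on an ancestry GRM, and
$e \sim N(0, \sigma_e^2 I)$.  The Gxtheta test is the likelihood-ratio
test of $\beta_{G\times\theta} = 0$ against
$\beta_{G\times\theta} \neq 0$, referred to $\chi^2_1$; the main-effect
p-value is the Wald $z$ of $\beta_G$ in the alternative model.

### Fitting

Variance components are estimated by maximum likelihood, not REML, to
keep nested fixed-effect models comparable.  The single-GRM fit
eigendecomposes $K$ once and profiles the likelihood over the
heritability ratio $h = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$ with the
scale profiled out, a 1-D optimization; the two-GRM fit optimizes the
two variance ratios by L-BFGS-B with a Cholesky factorization per
evaluation.  Following the standard approximation of this model family,
components are estimated once per trait under the no-SNP covariate model
(intercept, covariates, $\theta$) and the implied covariance is then
held fixed for all per-SNP generalized least squares fits; with the
scale re-profiled per model the LRT statistic is
$n \log(\mathrm{RSS}_0 / \mathrm{RSS}_1)$, which collapses to the
classic nested-OLS likelihood ratio when $K = I$ — that identity is one
of the package's oracle tests.  `gxthetaTest(..., exact = TRUE)`
re-optimizes the components under both per-SNP models when the
approximation is in doubt.

### Numerical choices

* Eigenvalues of $K$ are clipped at zero; the heritability ratio is
  optimized on $[10^{-6}, 1 - 10^{-6}]$ with both boundaries checked.
* LRT values in $[-10^{-8}, 0)$ are set to 0; more negative values are
  an error in the held-covariance path.
* p-values are floored at $10^{-300}$.
* A SNP constant among analyzed samples, or an interaction regressor
  collinear with the model (e.g. a singleton carrier), is an error at
  the single-SNP level and a skipped row in scans.
* Constant $\theta$ aborts the scan: the test is undefined without
  ancestry variance.
* $\theta$ is not centered by default ($\delta$ absorbs the location;
  the LRT is invariant to centering).  `centerTheta = TRUE` switches to
  the centered parameterization, which mainly decorrelates $x$ from
  $\theta \circ x$ and thereby sharpens the main-effect Wald statistic.
  With the default, the collinearity between $x$ and $\theta\circ x$
  (correlation often above 0.95) inflates the variance of
  $\hat\beta_G$, so main-effect power grows with $\beta_G$ much more
  slowly than a plain association scan would — visible in the power
  curves below.

### Scales and thresholds

Dosages and $\theta$ share the $[0,1]$ scale, so $\beta_G$ and
$\beta_{G\times\theta}$ are commensurable.  A consequence worth stating
plainly: the part of $\theta \circ x$ not explained by $\{1, x,
\theta\}$ has variance of roughly $\tfrac12\mathrm{var}(\theta)$
(about 0.01 in an RI panel), so on this scale interaction effects below
$|\beta_{G\times\theta}| \approx 2$ carry little power at
$n \approx 100$; the power machinery in this package treats the
$[0,1]$-scale grid as a shape and independence diagnostic, not as a
claim that unit-scale interactions are detectable in small panels.

Genome-wide significance defaults to $4.2\times10^{-6}$ (the RI-panel
convention; $8.06\times10^{-6}$ is the AIL convention, both
configurable), with per-scan Benjamini–Hochberg control at 5% as an
alternative for segregant panels.  Scan calibration is summarized by the
genomic inflation factors $\lambda_{GC}$ (main effect) and
$\lambda_{G\times\theta C}$ (interaction), the median
$\chi^2_1$-equivalent of the p-value set over its null median.

## Ancestry calling and the ancestry GRM

Ancestry-informative sites are those where the two founder lines carry
different homozygous alleles; $\theta$ is the unweighted mean
reference-founder dosage over those sites (SNP-proportion semantics, not
map-weighted).  In a composite resource whose sub-panels share one
common founder but differ in the other, a site is informative only in
the crosses that segregate it; per-site founder frequencies (used by the
imbalance scan) and the ancestry GRM $K^A$ therefore include an
individual only where its own cross segregates the site, with the
remaining cells treated as missing and mean-imputed for $K^A$.  In a
single biparental cross every segregating SNP is informative, and $K^A$
coincides with $K$; the two-GRM machinery is only meaningfully distinct
on multi-cross panels, which is why `simulateMultiCrossRiPanel()`
exists.

## Synthetic panels

All tests run on forward-simulated panels with tracked truth:

* **RI**: per strain, an F2 sibling pair from the F1 cross is sib-mated
  with Haldane (no-interference) meiosis — Poisson crossover counts,
  uniform positions, random phase — until fixation (cap 60 generations,
  then a coin flip per residual heterozygous block, counted and asserted
  rare).  Genotypes are fully homozygous.
* **AIL**: random-pair mating at constant population size for a chosen
  number of generations (default 50); heterozygous dosages persist and
  the $\theta$ distribution is visibly tighter than an RI panel's — the
  main reason AIL scans are less powered for Gxtheta effects.
* **Haploid cross**: one meiosis per segregant from the F1 diploid.

Viability selection at chosen loci rejects offspring carrying a
disfavored allele with probability $s$, emulating the transmission-ratio
distortion that the imbalance scan is built to find (gametic drive would
act at meiosis instead; viability rejection was chosen as the default
mechanism and the distinction is immaterial to the frequency shift the
scan sees).

The default geometry — 100 strains, 5 chromosomes × 80 cM × 400 SNPs,
2 Mb per cM — runs in a few seconds and gives $\theta$ a standard
deviation of about 0.12, a little wider than a 19-autosome mouse panel
(more chromosomes would narrow it); panel-mean $\theta$ stays near 0.5
under neutrality.  What the simulator does **not** model: genotyping
error, mutation, sex chromosomes, crossover interference, assortative
mating, and real LD irregularity.  Passing tests on these panels
establish statistical correctness of the machinery, not performance on
any particular real resource.

## The simulation framework

Four generative models are supported, with $\sigma_g^2 = 0.4$,
$\sigma_\theta^2 = 0.2$ when present, and the residual taking the
remainder to 1:

$$
y = \beta x + \mathrm{mvn}(0, \sigma_g^2 K + [\sigma_\theta^2 K^A] +
\sigma_e^2 I)
\quad\text{or}\quad
y = \beta_{G\times\theta}\,\theta\circ x + \mathrm{mvn}(\cdot)
$$

Phenotypes are standardized to unit variance before testing (the
variance fractions sum to one by construction).  `powerCurve()` sweeps
an effect-size grid (defaults 20 points × 200 replicates; the
full-scale convention of 200 points × 1,000 replicates is a flag away),
drawing a random SNP with reference-allele frequency in (0.25, 0.75)
per replicate.  Two properties are the point of the exercise: each arm's
power responds only to its own effect type (the alternative model
contains $\theta \circ x$ exactly, so a pure interaction signal leaves
$\hat\beta_G$ untouched, and vice versa), and adding the second GRM
neither helps nor hurts when $\sigma_\theta^2 = 0$.

### Higher-order epistasis

To emulate a SNP whose effect exists only in a particular multi-locus
background, a *composite SNP* carries the minor allele exactly in the
strains carrying the minor allele at every member of a drawn set (test
SNP + 1..10 partners).  "Minor" defaults to the non-reference-founder
allele: each member then pushes composite carriers toward low $\theta$,
which is what a deleterious-combination architecture on a common
background looks like; a `"rarer"` mode uses each SNP's less frequent
allele.  The composite's effect size is calibrated so the 1-df GLS
association non-centrality equals a target (default 20, so realized
statistics fluctuate around 21); monomorphic composites are redrawn
within a budget.

Two detection summaries are reported per partner count, and they move in
opposite directions: detection of the **original test SNP's** main
effect decays as the composite's carriers dwindle, while detection of an
interaction **anywhere in the involved SNP set** (`anyGxtPower`) rises
with the number of partners, because every member locus carries a share
of the background-dependent signal.  The per-test-SNP interaction rate
itself is nearly flat at this panel size — a single composite carrier
cannot anchor an interaction slope — so the system-wide rate is the
meaningful "detect a Gxtheta locus" quantity; both are in the output,
along with genomic-inflation diagnostics of the test-SNP p-value sets.

## The allelic-imbalance (transmission-ratio-distortion) scan

Under neutral transmission each site's founder frequency
$\theta_i$ is centered on the panel mean $\bar\theta$.  The scan tests
each site with
$W_i = (\bar\theta - \theta_i)^2 / \mathrm{var}(\theta)$, using the
**global** variance of $\theta_i$ across sites — a choice that assumes
most sites are null and is conservative otherwise (a per-site binomial
variance is available for sensitivity analysis).  $\bar\theta$ uses the
per-SNP mean.  p-values from $\chi^2_1$ are BH-controlled at 5%, and
significant sites are chained into distortion regions: same chromosome,
inter-SNP gap at most 2 Mb (a typical RI-panel LD block size; the
clustering rule is this package's operationalization of "several
significant SNPs located together"), at least 5 SNPs per region, each
region reporting its mean founder ancestry (as a percentage) and mean
p-value.

For orientation, the scale of chance imbalance in an $n$-line panel is
the exact two-sided Bernoulli tail: with 122 lines, an 80%/20% split has
probability $8.3\times10^{-12}$, i.e. about $1.7\times10^{-6}$ expected
sites across 200,000 SNPs — so recurrent large imbalances are evidence
of selection during panel derivation, not drift.  (Linked sites are
dependent, so this expectation governs the count's mean, not its
variance.)

## Problem sizes and what the checks establish

The package's acceptance suite runs, at fixed seeds: 1,000 null tests
on the default panel (type-I error within the 95% binomial band around
0.05, pooled $\lambda \in [0.9, 1.1]$); 20-point × 200–400-replicate
power curves for the independence and two-GRM-overlap properties;
partners 1–10 × 500 replicates for the epistasis trade-off; 200
replicates of heritability recovery at $\sigma_g^2 = 0.4$ (±0.05); 50
null panels for empirical FDR of the imbalance pipeline (≤ 7.5% at the
5% target) and 50 panels with a planted $s = 0.9$ locus (top-ranked
Wald statistic in ≥ 90%); plus exact small-instance oracles (nested-OLS
LRT identity, grid-search likelihood bound, BH step-up, composite-AND,
region chaining, binomial enumeration).  These sizes were chosen so the
whole suite runs on one CPU in minutes while leaving every Monte-Carlo
bound at 3 standard errors or better.

## Known limitations

* The EMMAX-style held-covariance approximation is mildly conservative
  for SNPs strongly loaded on $K$ (the SNP is itself part of the GRM;
  no leave-one-chromosome-out option is provided).
* The $\sigma_g^2/\sigma_\theta^2$ split is weakly identified when $K$
  and $K^A$ are highly correlated, as in any single-cross panel; the
  fitted total covariance (what the test needs) remains stable.
* Two founders per cross only; no local-ancestry or HMM decoding.
* The imbalance scan's global-variance Wald test trades power for
  robustness, and region chaining is greedy single-linkage — regions
  separated by a single gap above 2 Mb are split.
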