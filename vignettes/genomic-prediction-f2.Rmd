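---
title: "Genomic prediction in a small F2 intercross: models, simulator and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction in a small F2 intercross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

`chickgp` studies how well genomic selection works in a population that is
small in every sense: a three-generation intercross between two divergent
chicken lines (a fast-growing commercial line and a slow-growing local
breed), with 20 founders, 51 F1 birds and 511 phenotyped F2 birds in 8
half-sib sire families. Such populations have a tiny effective size and long
LD blocks, so a modest SNP panel captures most of the additive genetic
variance — but the reference population available for training is also tiny,
and almost everyone is related to everyone else, which makes honest
validation delicate. The package provides the full chain: a population
simulator, SNP quality control, relationship matrices, variance-component
estimation, four prediction models, and a two-scenario cross-validation
harness.

# Models

All models share the observation equation for the phenotype vector $y$ of
the F2 birds, with fixed effects of sex and hatch in $X b$:

* **Pedigree BLUP**: $y = Xb + Za + e$, $a \sim N(0, A\sigma_a^2)$, with $A$
  the numerator relationship matrix from the pedigree (tabular method;
  diagonal $1 + F$).
* **GBLUP**: $y = Xb + Zu + e$, $u \sim N(0, G\sigma_u^2)$, with $G = Z_m
  Z_m' / (2\sum_j p_j(1-p_j))$ from column-centred dosages (VanRaden's first
  method, the field's default construction; observed-sample allele
  frequencies are the default, configurable to founder-based or external
  frequencies).
* **BayesLASSO**: $y = Xb + Mq + e$ with a double-exponential prior
  $p(q_j) = \tfrac{\lambda}{2} e^{-\lambda |q_j|}$ on every marker effect.
* **BayesMix4**: the same regression with a four-component normal-mixture
  prior with fixed proportions $\pi = (0.889, 0.1, 0.01, 0.001)$, ordered
  from the smallest to the largest component variance.

GEBV are marker sums $\sum_j m_{ij} \hat q_j$ for the Bayesian models and
the MME solutions for (G)BLUP. Marker matrices are column-centred by twice
the training allele frequency; centring constants are stored with the fit so
that prediction individuals are coded identically. Centring makes the
SNP-BLUP/GBLUP equivalence exact, which the test suite exploits as an
algebraic oracle.

# Variance components: AI-REML

`ai_reml()` maximises the REML log-likelihood of the one-random-effect
animal model in $(\sigma_a^2, \sigma_e^2)$ with average-information updates.
The observation-level covariance $ZKZ'$ is eigendecomposed once per fit,
after which every iteration is $O(np^2)$; an AI step that would leave the
parameter space falls back to a positivity-preserving fixed-point step
$\sigma_i^2 \leftarrow \sigma_i^2 \, (y'PV_iPy)/\mathrm{tr}(PV_i)$.
Convergence is declared when the parameter change relative to the total
variance drops below `tol` (default `1e-8`, `max_iter = 200`; start values
are half the phenotypic variance each). Standard errors come from the
inverse AI matrix and the heritability SE from the delta method. These
choices follow standard practice; with 511 F2 in 8 families the reported
SE($h^2$) is around 0.13 for $h^2 = 0.26$, i.e. the design, not the
algorithm, limits precision.

# The Gibbs samplers

Both Bayesian models run single-site Gibbs samplers written in C++ (this is
the one hot loop in the package; everything else is plain R). Fixed effects
get flat priors and coordinate-wise normal updates; the residual variance a
flat scaled-inverse-chi-square ($\nu = -2$, scale 0). The production chain
schedule is 50,000 cycles, 20,000 burn-in, every 20th sample saved; the
desk-scale default is 10,000/4,000/10.

**BayesLASSO.** The double-exponential prior is represented as a normal
scale mixture: $q_j \mid \tau_j^2 \sim N(0, \tau_j^2)$ with exponential
mixing, giving inverse-Gaussian full conditionals for $1/\tau_j^2$. The
rate $\lambda$ carries a bounded uniform prior and is drawn from its
truncated-Gamma full conditional $\mathrm{Ga}(k+1, \sum_j |q_j|)$ by
inverse CDF.

Three implementation details matter and are worth recording:

1. *The support of the uniform prior is a modelling choice with teeth.*
   Under an unbounded uniform, the marginal posterior of $\lambda$ is flat
   at large $\lambda$: the prior factor $\lambda^k$ exactly offsets the
   vanishing prior mass around the shrinking effects, so the posterior
   assigns mass proportional to the length of the support to a degenerate
   regime in which markers explain nothing. The default support is
   therefore genetic: $\lambda_{\max}$ is the rate at which the markers
   would jointly explain only 2% of the phenotypic variance. For traits
   worth selecting on (here $h^2 \ge 0.13$) everything beyond that is
   implausible a priori.
2. *Chains are warm-started.* $\lambda$ starts at the rate corresponding to
   markers explaining half the phenotypic variance and is held there for
   the first few hundred cycles (within burn-in) while the marker effects
   grow from zero to data-supported magnitudes.
3. *A joint rescaling move crosses the scale direction.* Single-site
   updates change $\lambda$ by $O(1/\sqrt{k})$ per cycle and mix very
   slowly along the joint scale of $(q, \lambda)$. Once per cycle the
   sampler proposes $(q, \tau^2, \lambda) \to (cq, c^2\tau^2, \lambda/c)$
   with $c = e^z$, $z \sim U(-1.5, 1.5)$; the posterior-times-Jacobian
   ratio collapses to $\exp(\Delta\ell - z)$, so the move is cheap ($O(n)$)
   and leaves the stationary distribution unchanged. Without it, pooled
   cross-validation correlations are corrupted by fold-to-fold shrinkage
   heterogeneity even though within-fold correlations look fine — a useful
   cautionary tale, since the pooled correlation is scale-sensitive while
   per-fold correlations are not.

**BayesMix4.** Component indicators are drawn from their collapsed
multinomial conditionals (the marker effect integrated out), effects from
normal conditionals given the assigned component variance, and the four
component variances from scaled-inverse-chi-square conditionals with 4.2
prior degrees of freedom and scale hyperparameters spanning four orders of
magnitude ($10^{-3}$ to $1$ times a base scale chosen so the prior-mean
genetic variance is about half the phenotypic variance). The ordering
"$\pi_1$ goes with the smallest variance" is enforced by sorting the
variances after each update and remapping the indicators, which also
prevents label switching. The mixture proportions are fixed, never
estimated.

# Cross-validation design

Two 4-fold scenarios over the 511 phenotyped F2:

* **family sample** — whole half-sib sire families are assigned to folds by
  deterministic greedy bin-packing (largest family first into the smallest
  fold that still has room; at most $\lceil 8/4 \rceil = 2$ families per
  fold), so no test bird has a half or full sib in training;
* **random sample** — a seeded uniform shuffle with fold sizes
  128/128/128/127 (training 383/383/383/384).

Within each fold, every model is refit on the training data only; test
phenotypes are masked. The validation response is the corrected phenotype
$y_c = y - \widehat{\text{sex}} - \widehat{\text{hatch}}$ with fixed
effects estimated once from the conventional pedigree BLUP on the *full*
data ("sex and hatch" and "sex and batch" are treated as the same factor
pair). Accuracy is the Pearson correlation between predictions and $y_c$
pooled over the concatenated test folds — not the mean of per-fold
correlations, which differs whenever fold prediction scales differ. Bias
is the OLS slope of $y_c$ on the prediction; model pairs are compared by a
paired t-test over the four folds ($t = \bar d / (S_D/\sqrt{n})$, df = 3,
no multiplicity correction); and each pooled correlation gets a power value for the test of zero
correlation at $\alpha = 0.05$, computed by the Fisher-z normal
approximation (with 0.85 the conventional bar for an acceptable power).

# The synthetic-data generator

The generator *is* the study population for every empirical check. Its
defaults encode the design constants: 10 founders per line, 51 F1, 511 F2
in 8 half-sib families (balanced-remainder sizes 64×7 + 63), four hatches
assigned round-robin within family, and the five traits with their design
means, phenotypic SDs and heritabilities (BW6 0.26, BW12 0.13, EP 0.44,
BMP 0.39, LMP 0.39).
Founder lines follow a Balding–Nichols construction: per-SNP ancestral
frequency uniform on (0.05, 0.95), line frequencies Beta-distributed around
it with divergence parameter 0.3 by default. Meiosis is Haldane (Poisson
crossovers, no interference). Trait architectures place 200 QTL uniformly
among the simulated SNPs with normal effects rescaled so the realised F2
additive variance hits $h^2 \sigma_P^2$ exactly; QTL stay inside the marker
panel, mirroring the observation that the chip captured almost all additive
variance. Sex effects default to half a phenotypic SD (sexual dimorphism is
substantial in broilers) and hatch effects to a ±0.2 SD spread; the F1
family structure and the number of hatches are not recorded in the source
material, so both are configurable with these documented defaults.

What the generator does *not* emulate: genotyping-intensity artefacts (so
the chip-quality filter is only a pass-through mask), dominance and
epistasis, selection between generations, and genotype-by-environment
structure. Passing tests therefore demonstrate that the pipeline recovers
the statistical structure it assumes — additive traits on a realistic
pedigree — not that real chicken data would behave identically.

# Numerical choices

* $G$ receives a ridge of $10^{-6}$ (recorded in metadata) before any
  inversion; column-centring with observed frequencies always leaves one
  null direction in $G$. Tests of exact algebraic identities use a ridge of
  $10^{-10}$ and tolerance $10^{-6}$.
* The MME are solved densely; the solution's relative residual is checked
  against $10^{-8}$ and the condition number is reported.
* Predictions for individuals absent from a fit use the
  conditional-expectation extension $K_{\text{new,fit}}
  K_{\text{fit,fit}}^{-1}\hat u$, which equals the MME solution that
  includes them without records (a tested identity).
* Fixed effects use treatment coding with the first level absorbed into the
  intercept; aliased columns are dropped, so any full-rank choice yields
  the same predictions.
* All stochastic stages draw seeds from one root seed through named
  substreams (`substream_seed`), so each stage is independently
  reproducible and re-running with the same configuration is bit-identical.

# Problem sizes used by the tests and the acceptance script

Simulation checks run at desk scale, chosen so the whole suite completes on
one CPU: the cross-validation study uses the full design cohort (582 birds)
with a 2,000-SNP panel and chains of 3,000/1,000/4; the
heritability-recovery checks use 2,000 F2; the meiosis check uses 100,000
gametes; gene-dropping uses 200,000 replicates; marker-panel defaults
remain 5,000 SNPs for the analysis scripts. Chain-length robustness is
tested directly (doubling the saved samples moves GEBV accuracy by less
than 0.01), which is what justifies the reduced schedules.

# Where the synthetic study departs from the real one

Most qualitative findings transfer cleanly to the synthetic population:
random-sample validation beats family-sample validation for every model,
the three genomic models agree to within a few hundredths of correlation,
GBLUP slopes sit near 1 in the random scenario, and pedigree EBV lose far
more accuracy than GEBV when whole families are held out. One quantitative
property falls short of its theoretical ideal: with no close relatives of
the test birds in training, pedigree EBV should carry almost no
information, yet their family-scenario accuracy averages about 0.12 on
simulated replicates rather than near zero. This is a property of the
simulated base population rather than a bug: with 20 founders and 51 F1,
every test
family's parents have full sibs among the training families' parents, so
EBV retain real between-family information; and the simulator is *kind* to
pedigree BLUP in two ways real data are not — founders are unrelated within
line, exactly matching the base-population assumption of A, and hatches are
assigned round-robin within family, so the hatch correction in $y_c$ never
strips between-family genetic signal, whereas real hatch batches tend to
confound with family. The package reports the property as measured instead
of adjusting the generator to force agreement.

# Known limitations

* The Bayesian lasso's uniform-prior parameterisation is intrinsically
  fragile for $k \gg n$; the bounded support above makes it behave, but a
  proper (e.g. Gamma) hyperprior on $\lambda^2$ would be the more robust
  model. It is not offered because the uniform-prior parameterisation is
  part of the model family this package implements.
* Variance-component SEs are asymptotic (inverse average information); at
  n = 511 with 8 families they are honest in scale but not exact.
* The family scenario's pooled correlations have large sampling error —
  test folds contain two whole families, so the effective sample size is
  far below 128; single-replicate comparisons between models in that
  scenario should not be over-read.
* Only additive single-trait models are implemented; no polygenic term is
  added to the marker models (explicitly out of scope), and no H-matrix
  blending of A and G is provided.
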