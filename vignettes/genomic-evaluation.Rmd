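---
title: "Genomic evaluation with deregressed EBVs and Bayesian whole-genome regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic evaluation with deregressed EBVs and Bayesian whole-genome regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swinegs)
```

## The problem

Pig breeding programs select on estimated breeding values (EBVs) computed
from pedigree and phenotype. Genotyping a subset of animals on a
moderate-density SNP panel allows *molecular* breeding values (MBVs) — sums
of estimated marker effects — which raise accuracy for young animals without
phenotypes. This package implements the complete evaluation loop for that
setting: panel quality control, construction of response variables from
EBVs, Bayesian marker-effect estimation, window-based association scanning,
and honest cross-validated accuracy assessment on relationship-clustered
folds. A synthetic-data module generates pedigrees, genotypes and traits
with the statistical structure the analysis assumes, so the whole pipeline
is testable end to end.

## Models and procedures

### Pedigree BLUP and reliability

EBVs come from a single-trait animal model
$y = Xb + Z_a u + Z_l c + e$ with fixed contemporary groups $b$, additive
effects $u \sim N(0, A\sigma^2_a)$ over the full pedigree, common-litter
effects $c \sim N(0, I\sigma^2_c)$ and residuals $e \sim N(0, I\sigma^2_e)$.
$A^{-1}$ is assembled directly from the pedigree by Henderson's rules with
inbreeding; inbreeding coefficients come from the tabular relationship
matrix. Reliability is defined through the prediction error variance,
$r^2_i = 1 - \mathrm{PEV}_i / ((1+F_i)\sigma^2_a)$, with PEV taken from the
inverse of the mixed-model coefficient matrix — a definition we adopt
because no single convention is universal; it is exact under the model. The
parent average is $\mathrm{PA} = (\hat g_{sire} + \hat g_{dam})/2$, an
unknown parent contributing 0 (the base-population mean). Variance
components are treated as known: in the synthetic setting they are the
simulation values, mirroring practice where REML estimates come from a
separate national evaluation. Multi-trait modelling is deliberately out of
scope: genetic correlations would be additional unknowable inputs here, and
per-trait EBVs carry everything the downstream stages use.

### Deregression

BLUP shrinks an animal's EBV toward its parent average, and regressing
marker effects directly on EBVs would double-count parental information. We
therefore deregress: $\mathrm{DEBVexcPA} = (\hat g - \mathrm{PA})/r^2$
removes the parental contribution, while
$\mathrm{DEBVincPA} = \mathrm{PA} + (\hat g - \mathrm{PA})/r^2$ adds the
parent average back to retain between-family differences. Each record
carries the Garrick weighting factor
$w = (1-h^2)\,/\,\{[c + (1-r^2)/r^2]\,h^2\}$, consumed downstream as a
residual-precision multiplier (record residual variance $\sigma^2_e/w$).
Two conventions deserve note. First, the weight formula is read with the
whole bracket in the denominator (the Garrick et al. form); the printed
fraction in some sources is typographically ambiguous. Second, $r^2$ is the
reliability of the EBV itself, not of the deregressed deviation — the
simpler literal reading; the full information-partitioning deregression is a
non-goal. Records with $r^2 < 0.10$ are removed (a record at exactly 0.10
survives, per the strict "less than" rule); $c = 0.40$ by default, the
conventional share of genetic variance not captured by markers.

### BayesB / BayesC Gibbs samplers

Marker effects follow the mixture model
$y_i = \mu + \sum_j Z_{ij} u_j \delta_j + e_i$, where $\delta_j = 0$ with
prior probability $\pi$ (default 0.99 at moderate density), $u_j \sim
N(0, \sigma^2_u)$ with a single common variance (BayesC) or locus-specific
variances with scaled-inverse-$\chi^2$ priors, marginally a t prior
(BayesB). Genotypes are centered by twice the allele frequency;
monomorphic columns are dropped. $\delta_j$ and $u_j$ are sampled jointly —
$u_j$ is integrated out of the $\delta_j$ update — because plain
conditional sampling of $\delta_j$ given $u_j$ mixes far too slowly at high
$\pi$. $\pi$ is fixed, not estimated.

Priors are weakly informative with $\nu = 4.2$ for both variance
components. The scale of the effect-variance prior is set so that its prior
mean equals $\sigma^2_{a,\text{prior}} / [(1-\pi)\sum_j 2p_jq_j]$ — the
anticipated genetic variance spread over the markers expected in the model;
$\sigma^2_{a,\text{prior}}$ and the residual prior default to half the
response variance. A `fix_variances` switch freezes both variances at their
prior means, which makes the BayesC/$\pi=0$ chain an exact conjugate
sampler whose posterior mean is the closed-form ridge solution — the main
correctness oracle in the test suite. Chains use R's RNG and are bit-
reproducible given a seed. The full-scale schedule (110,000 iterations,
10,000 burn-in, thinning 10) is the package default;
`convergence_compare()` re-runs a chain at several lengths and reports the
differences in posterior-mean variances, the pragmatic convergence check
used at full scale (75,000 vs 110,000 vs 150,000) and replicated desk-scale
in the tests at roughly one-tenth those lengths.

Thinned effect samples are kept in the returned object as an ordinary
matrix rather than streamed to a chain file: at the problem sizes this
package targets (up to a few thousand animals and tens of thousands of
markers) they fit comfortably in memory, and keeping the object
self-contained simplifies the window-variance stage.

### Window GWAS and Bayes factors

Markers are tiled into 1-Mb windows by `floor(bp / 1 Mb)`; the window count
is a property of the supplied map, not a constant (a genome-wide pig map
yields about 2454 autosomal windows). For each stored sample $s$ the
genomic values $g_w = Z_w u_w^{(s)}$ give a window variance across animals
and a total variance of $\sum_w g_w$; the window's share is
$\%GV_w = 100\,\overline{\mathrm{var}_w}/\overline{\mathrm{var}_{tot}}$ — a
ratio of posterior means, chosen over the mean of per-sample ratios because
near-zero per-sample totals make the latter unstable. Windows are called
informative above 0.8%, i.e. twenty times the uniform share
$100/2454 \approx 0.04\%$; both this threshold and the Bayes-factor
categories use strict inequalities, per the conventional "above". Per-SNP
evidence is the posterior-to-prior odds ratio
$BF = [\hat p/(1-\hat p)]/[(1-\pi)/\pi]$ with Kass–Raftery categories
(suggestive > 3.2, strong > 20, decisive > 100); $\hat p = 1$ is reported
as infinite BF, decisive.

### Relationship-clustered cross-validation

Random folds leak family information: a validation animal with full sibs in
training looks artificially easy. Folds are therefore built by K-means on
the rows of the genotyped submatrix of $A$ — each animal's vector of
relationships to every other genotyped animal — so relatives cluster
together and between-fold relatedness is minimised. The feature space is a
design choice (the clustering literature this follows does not pin one
down); relationship-vector rows reproduce the intended
within-high/between-low pattern, which `fold_relationship_summary()`
quantifies (per-fold mean inbreeding, mean/sd of per-animal maximum and of
pairwise relationships, within and between). Clustering uses Hartigan–Wong
K-means with 25 random restarts, deterministically seeded; a requested
fold count equal to the number of animals degenerates to singleton folds.
Accuracy is the Pearson correlation between held-out MBVs and the response,
summarised as the fold mean with $SE = sd(r)/\sqrt{k}$ (a pooled
correlation over all held-out predictions is also reported, since sources
differ on which is meant). Validation genotypes are centered with
training-set allele frequencies — the prediction set must not inform the
model even through centering.

## The synthetic-data generator

`simulate_pedigree()` builds a base population and litter-structured
generations (each litter one sire/dam pair). `simulate_genotypes()` drops
founder haplotypes drawn at Hardy–Weinberg equilibrium down the pedigree:
each non-founder inherits one intact haplotype per linkage block from each
parent, with free recombination between blocks and none within. With the
default map every marker is its own block (independent loci); setting
`ld_rho` near 1 and multi-marker blocks creates the marker–QTL linkage
disequilibrium that window GWAS needs — each haplotype draws a block "core"
allele that individual markers copy with probability `ld_rho`. Full
recombination maps, selection across generations and genotype-calling error
are deliberately not modelled. `simulate_trait()` draws QTL effects and
rescales them so the realized additive variance matches the target exactly,
then adds contemporary-group effects, litter effects and residual noise;
`make_defect_manifest()` fabricates marker manifests carrying the defect
classes QC must remove (unmapped, sex-chromosome, low call rate, duplicate
position, with the duplicate always the lower-call-rate member of its
pair). Unknown parents are coded 0, founders are taken unrelated and
non-inbred, and contemporary groups are a single categorical code — the
joint farm-year-season-sex class is what the model uses, so its components
are not simulated separately. Each operation seeds its own RNG stream from
a caller-supplied seed, so any stage can be reproduced in isolation.

Default trait architectures follow published Duroc estimates
(`trait_params()`): backfat 1.21/3.42 (h² 0.35), days-to-90kg 34.57/85.10
(0.41), loin muscle area 1.14/7.15 (0.16), lean percent 2.09/5.52 (0.38).

What passing tests on this generator do **not** show: performance under
real linkage-disequilibrium decay, genotyping error, selection-induced
disequilibrium, or multi-breed structure. The generator makes the
*assumptions of the analysis* true by construction; results on it validate
the implementation, not the biology.

## Numerical choices and degenerate inputs

* QC rules apply in a fixed order (unmapped, sex-chromosome, call rate,
  duplicate position) so per-rule counts are well defined when categories
  overlap; duplicate positions keep the higher-call-rate member, ties
  broken by lexicographic marker id.
* MAF bins for imputation concordance default to width 0.05 over (0, 0.5];
  a bin with no masked genotypes reports `NA`, never 0. Cross-platform
  duplicate animals are flagged at genotype concordance > 0.9 on shared
  markers (configurable). Imputation itself is external; only its
  evaluation is implemented.
* `build_A()` uses the tabular method in double precision; the test suite
  checks it element-wise against a brute-force recursive oracle and checks
  positive semidefiniteness on simulated pedigrees.
* A zero-effect chain makes every window share 0/0; `window_variances()`
  reports `NA` with a warning rather than fabricating zeros.
* Deregression refuses $r^2 = 0$ (undefined) and $r^2 > 1$ (invalid);
  folds with fewer than 3 animals are refused (a correlation on 2 points
  is meaningless).
* Per-fold chains use seed = master seed + fold index; the pipeline derives
  per-stage seeds from one master seed, and `run_pipeline()` writes a
  manifest with configuration and output digests so a run is bit-
  reproducible.

## Problem sizes used in the tests

The suite exercises the samplers at desk scale, chosen to keep the full run
in the tens of minutes on one core while leaving each check statistically
meaningful: the conjugate-oracle check on a 50×30 problem; prior-behaviour
checks at n = 1000, m = 200; a 20-replicate planted-QTL localization study
at n = 500, m = 2000 (10-marker LD blocks, h² = 0.4, chains of 11,000 with
1,000 burn-in); and a 10-replicate paired comparison of the two response
variables on 10-family datasets with 1,000-iteration chains. The
chain-length convergence comparison runs at 7,500/11,000/15,000.

## Known limitations

Single-trait BLUP only; no REML (variances are inputs); no genomic
relationship matrices (folds cluster on pedigree information only, as
intended); no imputation algorithm; no gene annotation of GWAS hits; π is
fixed, not estimated; the LD model is block-exchangeable rather than a
recombination map. These boundaries are deliberate — each omitted piece is
either an external tool in practice or an input the package treats as
known.
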