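---
title: "Estimating breed composition in composite cattle: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating breed composition in composite cattle: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedcomp)
```

# The problem

A composite breed is built by a planned sequence of crosses between
founder breeds and subsequent inter se mating.  The Canchim design is the
motivating case: three backcross generations between Charolais (CH) and
Zebu (ZB) ending in a 5/8-CH × 5/8-CH cross (the CA group), and the MA
group produced by a Charolais bull on a ½ Canchim + ½ Zebu dam, giving
21/32 CH.  `pedigree_expected_fraction(canchim_scheme())` propagates these
fractions in exact rational arithmetic:

```{r}
ped <- pedigree_expected_fraction(canchim_scheme())
ped$exact
```

Pedigree arithmetic gives expectations only.  Each animal's realized
genome fraction deviates from the expectation through segregation and
recombination, and pedigree errors add more noise, so the realized breed
composition is estimated from SNP genotypes.  This package implements the
three standard estimator families — maximum-likelihood admixture,
Bayesian admixture, and regression on reference allele frequencies —
together with the genotype QC, LD and population-structure machinery that
surrounds them in practice.

# The admixture model

All three estimators target the same quantity: the ancestry matrix
$Q = \{q_{ik}\}$, where population $k$ contributes a fraction $q_{ik}$ of
individual $i$'s genome ($\sum_k q_{ik} = 1$).  Genotypes are coded as
$g_{ij} \in \{0, 1, 2\}$, the number of copies of allele 1 (the minor
allele) at SNP $j$.  Under random union of gametes with loci in linkage
equilibrium within populations,

$$ g_{ij} \sim \mathrm{Binomial}\!\left(2,\; \textstyle\sum_k q_{ik} f_{kj}\right), $$

with $f_{kj}$ the allele-1 frequency in population $k$, and the sample
log-likelihood is

$$ L(Q, F) = \sum_{i,j}\Big\{ g_{ij} \ln \sum_k q_{ik} f_{kj}
   + (2 - g_{ij}) \ln \sum_k q_{ik} (1 - f_{kj}) \Big\}, $$

over non-missing entries.  Missing genotypes contribute nothing to the
likelihood or to update sums; each individual's ancestry update is
normalized by its own number of non-missing allele copies.

## Maximum likelihood (`fit_admixture`)

Fitting is by EM block ascent: the E-step attributes each allele copy to
a population of origin with responsibility proportional to
$q_{ik} f_{kj}$ (allele-1 copies) or $q_{ik}(1 - f_{kj})$ (allele-2
copies); the M-step sets $q_{ik}$ to the individual's mean responsibility
and $f_{kj}$ to the attributed allele-1 fraction.  EM is a block
relaxation scheme and never decreases $L$; the test suite asserts
monotonicity of every trace.  Convergence is declared when the absolute
change in $L$ between iterations falls below `tol` (default $10^{-6}$;
the quantity the criterion applies to is a documented choice).  Defaults:
5 random restarts (Dirichlet(1) ancestry rows, observed frequencies
perturbed by ±U(0, 0.05)), boundary clamping at $\varepsilon = 10^{-6}$
so the likelihood stays finite.  A supervised mode pins the ancestry rows
of labelled purebred reference animals to unit vectors; it never hurts
recovery and resolves the label-switching ambiguity by construction.
Unsupervised fits are the default, with populations named post hoc —
mixture likelihoods are invariant to label permutation, so all
comparisons go through `align_labels()`, which maximizes the summed
column agreement over all permutations (exhaustive, $k \le 8$).

The number of populations is chosen by ADMIXTURE-style cross-validation
(`cross_validate_k`): non-missing genotype entries are partitioned into
5 folds, each fold is masked and the model refitted, and masked entries
are scored by average negative binomial log-likelihood at the refit's
predicted dosage probability.  On two-population cohorts the $k = 1$
error is clearly highest; on one-population cohorts the profile is flat
— both patterns are asserted in tests.

## Bayesian version (`fit_structure`)

The same model with conjugate priors: $q^{(i)} \sim$ Dirichlet($\alpha$,
…, $\alpha$) and $p_{kj} \sim$ Beta($\lambda$, $\lambda$), and a latent
population-of-origin label for every allele copy.  The Gibbs sampler
cycles the three full conditionals (copy origins multinomially given
$(p, q)$; frequencies Beta given assigned copy counts; ancestries
Dirichlet given per-population copy counts).  The latent labels are
carried in count form — copies are exchangeable given the genotype, so
drawing per-(individual, SNP, population) assignment counts by sequential
binomial decomposition of the multinomial is an exact draw of the latent
state and lets the whole sweep run as vectorized matrix operations.

Defaults: $\alpha = 1$, $\lambda = 1$ (uniform priors; the reference
analysis settings of the software this mirrors are not published, so the
flattest conjugate choice is used and documented), no thinning, posterior
means over all retained sweeps.  The reference chain length is 30,000
sweeps with 10,000 burn-in; the package's own validation uses shorter
chains (1,500–3,000 sweeps with a third burnt in) at its simulated cohort
sizes, where traces stabilize within a few hundred sweeps.  Sampler
correctness is tested against the exact Beta conjugate posterior at
$k = 1$ and by cross-seed agreement after alignment.

A practical note borne out on synthetic cohorts: at modest information
levels (around 1,000 SNPs at divergence 0.10) the posterior mean of a
purebred's ancestry sits visibly inside the simplex (about 0.90 rather
than 1.0) even with long chains — the posterior genuinely has mass away
from the corner, and the point summary inherits it.  This is the familiar
underestimation of extreme ancestry by Bayesian admixture estimates.
Agreement between the Bayesian and ML point estimates stays within 0.05
mean absolute difference on well-separated cohorts, and recovery of true
ancestry to the same tolerance holds at divergence 0.2; both are asserted
in the test suite at those settings.

## Regression on reference frequencies (`fit_breed_composition`)

Genotypes are transformed to $y_j = g_j / 2 \in \{0, 0.5, 1\}$ and
regressed on the reference breeds' allele-frequency vectors; the
coefficients are read as breed contributions, negative values are set to
0, values above 1 to 1, and the clipped coefficients are divided by their
sum (the only renormalization that yields fractions summing to 1).
Animals whose coefficients all clip to zero are flagged undefined rather
than silently set uniform.

Two fitting modes exist because the method's description admits both
readings; the choice matters and was resolved on statistical grounds.
Under the admixture model $E[y_j] = \sum_k q_k f_{kj}$ exactly, so the
**joint** no-intercept multiple regression on all breed columns estimates
$q$ consistently and is the default.  The **per-breed** simple regression
(one slope per breed) is retained as an option but is biased whenever the
reference frequency vectors are correlated — which they always are, since
breeds share ancestral polymorphism.  Concretely, with Balding–Nichols
references at drift $F$, the per-breed slope of a purebred-A animal on
breed B's frequencies converges to
$\mathrm{var}(p) / (\mathrm{var}(p) + F \cdot E[p(1-p)])$ — about 0.77 at
$F = 0.1$ — so purebreds are attributed only ~0.57 to their own breed.
The joint mode recovers purebreds at ≥ 0.99 and the 0.625 Canchim design
point within 0.01 on 5,000-SNP cohorts.  Missing entries are dropped
pairwise per regression, not imputed.

# Surrounding machinery

**Quality control.**  `qc_filter()` applies, in a fixed documented order:
chromosome restriction (1–29), per-sample missingness > 0.10, per-SNP
missingness > 0.05, exact Hardy–Weinberg test below $10^{-5}$, optional
MAF < 0.05.  Sample filters run before SNP filters; order changes counts,
so it is pinned and the report itemizes every removal.  The HWE test is
the standard conditional exact test without mid-p correction, computed on
the pooled panel by default (per-group testing is available); it is
validated against an independent recurrence-based enumeration oracle to
$10^{-12}$.

**Minor-allele coding.**  Allele 1 is the minor allele; exact-0.5 ties
keep the lexicographically smaller allele so coding is deterministic.
Binary PLINK files carry their own allele order and round-trip exactly;
text PED files carry none, so reading applies the minor-allele rule and
round-trips exactly for minor-coded matrices.

**F<sub>st</sub>.**  Two ratio-of-averages estimators from frequency
vectors.  The Wright form
$\sum_j (p_{aj} - p_{bj})^2/4 \,/\, \sum_j \bar p_j (1 - \bar p_j)$ is
the primary definition (a single locus at 0.2 vs 0.8 gives exactly 0.36).
For recovering the per-breed drift parameter of the Balding–Nichols
generator the Hudson form
$\sum_j (p_{aj} - p_{bj})^2 \,/\, \sum_j [p_{aj}(1 - p_{bj}) + p_{bj}(1 - p_{aj})]$
is used: when two populations drift independently from a common ancestor
with parameter $F$, its numerator and denominator have expectations
$2Fp(1-p)$ and $2p(1-p)$, so it is unbiased for $F$, whereas the Wright
form's expectation is $\approx (F/2)/(1 - F/2)$ by the same moment
calculation.  Both are exposed; divergence-recovery checks use Hudson.

**LD.**  Data are unphased, so Hill–Robertson r² needs haplotype
frequencies: `two_locus_haplotype_em()` resolves the double-heterozygote
phase ambiguity by EM (everything else has unambiguous gametes) and is
validated against phased simulated haplotypes.  A genotype-correlation r²
(squared Pearson correlation of dosages) is the default inside
sliding-window pruning for parity with standard pruning tools.  The
pruning tie rule — remove the lower-MAF member of the first offending
pair, later position on ties — is pinned because pruned kept-sets are
otherwise irreproducible.  Sved's relation converts mean r² at genetic
distance $c$ (fixed 1 cM/Mbp) into $N_e$ at horizon $1/(2c)$ generations;
r² "at distance $c$" is the mean over pairs within a relative ±10 % band
around the target distance, configurable because no canonical binning
exists and published decay tables generally do not determine the
$N_e$ inputs exactly.

**PCA and outlier exclusion.**  PCA is the eigendecomposition of the
VanRaden method-1 GRM (missing dosages mean-imputed per SNP — the
standard choice); coordinates are eigenvectors scaled by root
eigenvalues with a fixed sign convention.  Published analyses typically
exclude out-of-cluster animals by eye; `pca_outlier_filter()` replaces
that with an explicit rule — more than `n_sd` (default 3) robust SDs
(MAD) from the group median on any of the first 2 components, single
pass — so exclusions are reproducible.

# The synthetic-data generators

Real multi-breed cattle panels are rarely redistributable, so validation
runs on synthetic cohorts whose truth is known.

* `simulate_breed_frequencies()` draws Balding–Nichols frequencies:
  ancestral $p_j \sim U(0.05, 0.95)$, breed frequencies Beta with mean
  $p_j$ and variance $p_j(1 - p_j)F$.  Default divergence settings in the
  package's fixtures are 0.05–0.15, the scale of published pairwise
  breed divergences in taurine–indicine panels; they are calibrated to
  that range, not claimed to reproduce any real panel.
* `simulate_admixed_cohort()` draws genotypes from the admixture model's
  own generative law, so the ML estimator is correctly specified on these
  cohorts; missingness is uniform at random (real missingness is not, but
  only call-rate thresholds are specified anywhere).
* `simulate_crossing_scheme()` simulates gametes through the mating graph
  with per-locus breed-of-origin tags; expected ancestry equals the
  parental mean exactly and realized ancestry converges to it at rate
  $1/n_{\text{loci}}$ in variance, which the tests verify.
* `simulate_ld_haplotypes()` produces first-order Markov haplotypes
  (copy-with-probability-$c$), giving geometrically decaying LD for the
  LD module; the admixture generators deliberately produce linkage
  equilibrium, matching the estimators' assumption.

What passing tests on these cohorts shows — and does not show: the
estimators recover truth when their model is correctly specified and
breeds are Balding–Nichols-divergent.  Real panels add LD between loci,
ascertainment bias in SNP discovery, relatedness within breeds, and
non-random missingness, none of which the generators emulate (LD pruning
before ancestry estimation, as in the standard workflow, addresses the
first).  Absolute error levels on real data are therefore expected to be
worse than on fixtures; the qualitative contrasts (estimator agreement,
degradation at low SNP density) are the transferable conclusions.

# Numerical choices and problem sizes

* Boundary clamping $\varepsilon = 10^{-6}$ for frequencies and
  ancestries; likelihood evaluations floor mixture probabilities at the
  same $\varepsilon$.
* EM convergence on absolute log-likelihood change; iteration-capped runs
  return `converged = FALSE` rather than erroring.
* All generators and fitters take explicit seeds; there is no hidden
  global random state, and identical seeds give bit-identical outputs
  (fixture bundles are checksum-stable).
* Exact rational arithmetic (integer numerator/denominator) for pedigree
  fractions; no floating point until formatting.
* The validation suite runs at deliberately desk-sized problems — up to
  300 animals × 5,000 SNPs for ML recovery, 10,000 SNPs for
  F<sub>st</sub> and EM-stationarity checks, 2,000 individuals for
  phased-truth LD checks, Gibbs chains of 1,500–3,000 sweeps — chosen so
  the full suite completes in minutes while keeping Monte-Carlo margins
  (3–5 SE) meaningful.

# Known limitations

* No VCF input; no sex chromosomes; strand-ambiguous allele pairs are
  resolved only by allele-pair matching.
* The Bayesian sampler implements the independent-loci admixture model
  only — no correlated-frequencies prior, no linkage model, no
  model-evidence estimation (k selection is delegated to ML
  cross-validation).
* No standard errors on ancestry estimates.
* Constrained (simplex) least squares would likely improve the regression
  method but is deliberately not implemented; the clipping/renormalization
  rule is the method as practiced.
* Inferred-population F<sub>st</sub> from unsupervised fits runs higher
  than the generating divergence because ML sharpens the inferred gene
  pools; supervised fits recover the simulated value (tested).
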