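---
title: "Dosage-aware Q+K association mapping: models and methods"
author: "tetraQK"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage-aware Q+K association mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetraQK)
```

# Overview

tetraQK implements a complete candidate-gene association pipeline for
autotetraploid crops such as potato, where each locus carries four
allele copies and the copy number (dosage, 0--4) of an allele is itself
informative about the phenotype. The pipeline has five stages:

1. **Dosage calling** from raw marker signals: microsatellite (SSR)
   peak areas, bidirectional Sanger trace fractions for SNPs, and
   agarose band intensities for an insertion/deletion.
2. **Spatial phenotype adjustment**: plot-level phenotypes from a
   replicated field trial are converted to per-line adjusted means with
   a REML mixed model carrying an AR(1) x AR(1) residual.
3. **Population structure**: an admixture model fitted by EM over a
   range of subpopulation counts K, with the Evanno delta-K criterion
   selecting K, gives the Q matrix of membership proportions.
4. **Kinship**: the Loiselle allele-frequency-correlation estimator of
   pairwise relatedness, truncated at zero.
5. **Association**: each marker allele is tested against each
   trait-year dataset with a Q+K mixed model on the adjusted means,
   and the pooled p-values receive Storey bootstrap q-values.

A synthetic-data generator reproduces the statistical structure that
these stages assume, so every stage is testable end to end without any
external data. This vignette documents the models, the default
parameters and why they have the values they do, the numerical
choices, and what the simulation studies do and do not demonstrate.

# The synthetic study panel

The generator emulates a diversity panel of 192 tetraploid test lines
plus one repeated control line, genotyped at 21 multi-allelic structure
SSRs (3--17 alleles each, about 200 distinct alleles panel-wide) and a
candidate-gene set of 104 biallelic SNPs, four SSRs with 11, 11, 12 and
5 alleles, and one biallelic InDel. Counting each SSR allele as its own
tested column, the candidate set supplies 144 marker columns; against
four trait-year datasets this yields 576 association tests.

**Ancestry.** Each line receives an admixture row
$q_i \sim \mathrm{Dirichlet}(\alpha\,\mathbf{1}_K)$ with $K = 4$
ancestral subpopulations and concentration $\alpha = 0.5$ by default --
detectable but heavily admixed structure, the regime reported for
diverse potato collections. Subpopulation allele frequencies diverge
from a panel-level base frequency by a Balding--Nichols/hierarchical
Dirichlet model with divergence $F = 0.1$.

**Dosages.** The four allele copies of a line at a locus are drawn
i.i.d.: an ancestry from $q_i$, then an allele from that
subpopulation's frequencies. Double reduction and preferential pairing
are deliberately not modelled: the downstream analysis treats dosage as
a free 0--4 count, so the generator does the same.

**Genetic values.** For traits C6 and C3 (starch phosphorylation at
the C6 and C3 glucosyl positions, nmol/mg starch),
$$ g_{it} = \sum_m d_{im}\,\beta_{mt} + u_{it}, $$
with $d_{im}$ the copy number of the causal allele and $\beta_{mt}$ its
per-copy effect. The default causal architecture assigns a GWD-gene SNP
a C6 effect of 1.42 nmol/mg per copy at allele frequency 0.42, an
SBEI-gene SNP effects 1.24 (C6) and 0.21 (C3) at frequency 0.475, and
an SSIII-gene SNP a C3 effect of 0.32 at frequency 0.27 -- effect and
frequency magnitudes typical of the strongest candidate-gene
associations reported for this trait. The polygenic term $u$ has
covariance built from shared ancestry: $QQ^\top$ scaled so that its
across-line variance is 1, blended half-and-half with an independent
line-specific component. A pure $QQ^\top$ covariance has rank $K$ and
would make the "polygenic" term a subpopulation effect; the blend keeps
ancestry confounding while giving every line its own deviation. A
fraction `polyShare = 0.7` of the polygenic signal is shared between C6
and C3, which (with the shared causal markers) produces the strong
cross-trait correlation (about 0.65 in expectation, computable with
`geneticCovariance()`) observed between the two phosphorylation
measures. Polygenic variances default to 16 (C6) and 1 (C3) nmol²/mg²,
chosen so the span of adjusted means across 193 lines is roughly 20
nmol/mg for C6 and 5 nmol/mg for C3, matching the reported ranges.

**Trait-years.** Genetic values are reused across the two seasons;
each season redraws the non-genetic components and shifts the baseline
(C6: 15.8 vs 23.0; C3: 4.7 vs 4.9 nmol/mg), emulating the observed
between-season mean difference. Between-year correlation of adjusted
means is therefore an emergent property, not a dialled parameter; no
claim is made that the generator's year model reflects the biological
mechanism of season effects.

**Raw signals.** SSR peak areas are `copies x 500` with multiplicative
lognormal noise (`sdlog = signalNoise`, default 0.1); with probability
`nullAlleleProb` (default 0.02) one allele of a genotype is a null and
its peak disappears. SNP trace fractions are `dosage/4` plus clipped
Gaussian noise of sd `signalNoise/4`, independently per strand, each
with a uniform quality score; InDel band intensities are proportional
to copies. These are the simplest noise models on the scale of each
signal; they do not simulate electropherogram artefacts, stutter or
quantitative PCR biases, so calling accuracy on real traces will be
lower than on synthetic ones.

# Dosage calling

SSR genotypes are scored from filtered peak lists. Four peaks are one
copy each; a single peak is four copies. Two peaks are classified by
their area ratio $r$ (larger/smaller) to the nearest expected ratio:
$r \le \sqrt{2}$ gives 2:2, $\sqrt 2 < r \le \sqrt 6$ gives 2:1 plus an
assumed null allele, larger ratios give 3:1. The boundaries are the
geometric midpoints between the expected ratios 1, 2 and 3; ratios
exactly on a boundary deterministically take the lower class. With
three peaks, all areas within a 1.5-fold range imply 1:1:1 plus a null;
otherwise the largest peak is two copies. The boundary values and the
1.5 similarity threshold are package choices -- the scoring rules they
implement are stated qualitatively in the literature without numeric
thresholds.

SNP dosage is read per strand as $\arg\min_d |f - d/4|$ with ties to
the lower dosage; disagreeing strands are resolved by sequence quality,
and equal qualities average the fractions before classification (a
package choice; published descriptions of this workflow do not cover
exact ties). InDel
heterozygotes are grouped by intensity fraction to the nearest of 0.25,
0.5, 0.75.

Missing genotypes are explicit and never imputed; markers with more
than 20% missing calls are flagged (configurable). On noise-free
synthetic signals the caller reproduces the generating truth exactly --
this is asserted for every cell of a full-size panel in the test suite
-- and its accuracy degrades monotonically as signal noise grows.

# Field-trial layout and spatial adjustment

The emulated trial plants 432 plots in a 72 x 6 array: two replicates
of each test line (one per 3-column block) and 48 control plots placed
by randomized constraint satisfaction so that every column holds 8
controls, every consecutive 9-row set holds 6, and no row holds more
than one. Plots are processed down each column; starch extraction
batches cover 36 consecutive plots and measurement runs 72.

Per trait-year, plot values are modelled as
$$ y = X\tau + Z_c u_c + Z_b u_b + e, \qquad
   \mathrm{Cov}(e_{rc}, e_{r'c'}) =
   \sigma^2_e\, \rho_{row}^{|r-r'|}\, \rho_{col}^{|c-c'|}, $$
with line (193 levels, control included) fixed, column-set and 36-plot
batch effects random, and a separable AR(1) x AR(1) residual absorbing
spatial trend and processing drift. The measurement-run batches of 72
are generated but not modelled, matching the model statement being
emulated; they remain in the data for sensitivity checks.

REML estimation profiles $\sigma^2_e$ and maximizes over
$(\rho_{row}, \rho_{col}, \gamma_c, \gamma_b)$ -- the correlations on an
atanh scale capped at |0.95| and the variance ratios on a log scale --
with Nelder-Mead from two deterministic starting points plus optional
random restarts. A nested profiling scheme (outer over the
correlations, inner over the ratios) was considered and rejected: with
two crossed variance ratios the inner problem has no closed form. The
objective is evaluated by a compiled kernel; on complete grids it
exploits the analytic tridiagonal inverse of an AR(1) correlation
matrix, so $S^{-1} = R_{row}^{-1} \otimes R_{col}^{-1}$ has at most
nine nonzeros per row, and folds in the block components by the
Woodbury identity. A dense $O(n^3)$ route in both C++ and pure R
handles incomplete grids (missing plots subset the covariance; nothing
is imputed) and serves as the reference implementation the fast path is
tested against (agreement to 1e-12).

Adjusted line means are the generalized-least-squares cell means
$\hat\tau$ -- the predicted value for an average plot, since the random
effects have mean zero. The overall line F-test uses the Wald statistic
for the 192-df contrast with denominator df $n - \mathrm{rank}(X)$; a
Kenward-Roger-type small-sample correction is deliberately not
implemented (a large machinery for marginal effect at 432 plots), and
the residual-df approximation is calibrated by simulation in the test
suite (null rejection rate within [0.02, 0.09] at the 5% level).

# Population structure and kinship

**Admixture by EM.** The likelihood treats each of the four copies as
an independent draw:
$$ \log L = \sum_i \sum_l \sum_a d_{ila}
   \log\!\Big(\sum_k q_{ik} f_{kla}\Big), $$
maximized by EM (monotone by construction, asserted per iteration in
tests) until the log-likelihood changes by less than 1e-6 or 2000
iterations, best of several random restarts. An MCMC sampler in the
STRUCTURE tradition is out of scope; an externally computed Q matrix
can be imported from TSV instead (`importExternalQ()`). Copies hidden
by null alleles or missing genotypes are dropped and the remaining
copies renormalized to weight 4.

**Evanno delta-K.** For replicate log-likelihoods over a contiguous K
range, $\Delta K = \mathrm{mean}_r |L_r(K{+}1) - 2L_r(K) + L_r(K{-}1)|
/ \mathrm{sd}_r L(K)$, with the replicate pairing retained in the
numerator. Replicates here are independently seeded EM runs: their
scatter comes from random initialization at finite tolerance rather
than from MCMC noise, so the K-selection study below uses more
replicates (5) at a moderate tolerance (1e-3) rather than a few
tightly converged ones -- tightly converged EM replicates can be
numerically identical, which degenerates the denominator (such cases
are reported as missing with a warning). $\Delta K$ is invariant to
shifting or positively scaling all log-likelihoods.

**Loiselle kinship.** With individual allele frequencies
$p_{ila} = d_{ila} / (\text{observed copies})$ and panel means
$\bar p_{la}$ over the $n_l$ genotyped lines,
$$ f_{ij} = \frac{\sum_{l,a} (p_{ila} - \bar p_{la})
           (p_{jla} - \bar p_{la}) + \bar p_{la}(1-\bar p_{la})/(n_l-1)}
           {\sum_{l,a} \bar p_{la}(1 - \bar p_{la})}, $$
accumulated over loci at which both lines are genotyped. The
small-sample correction divides by the number of genotyped
*individuals*; software manuals state this term ambiguously
(individuals vs gene copies), so the choice is isolated in one place
and documented here. Unrelated pairs have negative expected estimates;
negatives are truncated to zero and positive semidefiniteness is then
restored by alternating projections between the PSD cone and the
nonnegative orthant (both convex, so the iteration converges; in
practice 2--3 rounds). The raw estimator is available for diagnostics
and is what the brute-force oracle test checks, to 1e-12.

# Association testing

For each trait-year the adjusted means are modelled as
$$ y = W\alpha + G\gamma + u + \varepsilon, \qquad
   u \sim (0, \sigma^2_g\,\mathrm{KIN}), \quad
   \varepsilon \sim (0, \sigma^2_e I), $$
where $W$ holds the intercept and the first $K-1$ columns of Q (the
last is dropped because the simplex rows alias the intercept) and $G$
holds one indicator per observed dosage class beyond the reference
class (the most frequent dosage), giving up to four degrees of freedom
-- a biallelic locus can show up to five genotypes in a tetraploid. The
control line is excluded from association, matching the genotyped test
panel.

The kinship matrix is eigendecomposed once per trait-year; the
variance ratio $\delta = \sigma^2_e / \sigma^2_g$ is estimated by
one-dimensional REML under the marker-free null model and reused across
markers (the fast mode in the EMMAX tradition). The exact mode refits
$\delta$ per marker; the two agree closely on the synthetic panel and
the rotated-space computation is verified against a dense GLS
evaluation to 1e-10. The p-value is a Wald F on the genotype block with
denominator df $n - \mathrm{rank}(X)$; with identity kinship and no Q
this reduces exactly to classical ANCOVA, which the tests assert to
1e-8. The allele substitution effect is defined as the additive
(per-copy) coefficient refit at the same variance components --
whether published effect columns came from an additive or a factor
contrast is unstated, so the package fixes the additive definition and
documents it. Dosage-class means are model-based (class effect plus
the average non-genotype fixed part). Missing genotypes drop lines
marker-wise (complete case per test, with the rotation rebuilt on the
subset). Adjusted means enter unweighted; weighting by their standard
errors is a possible refinement the package does not implement.

**Multiple testing.** P-values from all four datasets are pooled, and
$\pi_0$ is estimated on the grid $\lambda \in \{0, 0.05, \ldots,
0.90\}$ with the bootstrap (B = 100) choice of $\lambda$: the value
minimizing the bootstrap MSE of $\hat\pi_0(\lambda)$ around the minimum
grid estimate. Q-values follow the step-down rule; forcing $\pi_0 = 1$
reproduces Benjamini-Hochberg exactly, which is tested. The helper
`expectedFalseDiscoveries(q, n)` implements the accounting that makes
a threshold choice interpretable -- e.g. 13 discoveries at q = 0.02
carry 0.26 expected false positives.

# Simulation studies in the test suite

The acceptance tests run four studies whose designs are fixed here:

* **Type-I error under confounding**: 5 independent panels of 192
  lines (K = 3, concentration 0.3, divergence 0.2) x 100 null SNPs
  whose frequencies differ across subpopulations; the phenotype is
  ancestry-structured polygenic noise. The Q+K scan's rejection rate at
  the 5% level must lie in [0.03, 0.07] over the 500 tests, while the
  naive scan (no Q, identity kinship) inflates several-fold.
* **REML parameter recovery**: 100 trials on the 432-plot layout at
  $(\rho_{row}, \rho_{col}, \sigma^2_c, \sigma^2_b, \sigma^2_e) =
  (0.6, 0.4, 1, 1, 4)$, medians compared to truth at 15%. The
  correlations and $\sigma^2_e$ recover to within a few percent. The
  block variances are the weakly identified corner of this design: 6
  column sets and 12 batches give their REML estimates roughly scaled
  chi-square sampling distributions with few effective df, about one
  trial in ten lands on the boundary $\hat\sigma^2_c = 0$ (a genuine
  REML boundary solution, matched by an independent mixed-model
  implementation on the iid special case), and their medians therefore
  sit several percent below truth -- within the 15% band at this
  design size, but the quantity a user should trust least.
* **Effect recovery**: 200 panels of 192 lines with the single
  GWD-like causal SNP (1.42 nmol/mg per copy); adjusted-mean-scale
  noise of sd 1.2; the mean Q+K additive estimate must fall within 10%
  of 1.42.
* **K selection**: 50 well-separated panels (60 lines, 12 SSRs,
  K = 3, concentration 0.05, divergence 0.35); Evanno delta-K over
  K = 1..5 with 5 EM replicates per K must identify K = 3 in at least
  90% of panels.

Problem sizes were chosen so the whole suite runs comfortably on a
single core; they are stated above so the studies can be scaled up.
Passing these studies demonstrates internal statistical coherence on
data satisfying the generator's assumptions -- i.i.d. copy draws, known
noise models, a panel with block-structured ancestry. It does not
certify performance on real electropherograms, on panels with
pedigree-structured kinship that QQ'-style covariances underfit, or
under double reduction.

# Known limitations

* The SSR caller implements the stated area-ratio rules only; it will
  misread genotypes whose null-allele configuration mimics a legal
  ratio (e.g. two hidden copies leaving a 1:1 pattern), as any
  area-based scorer must.
* The EM admixture stand-in finds point estimates, not posteriors;
  label switching across runs is unresolved (only likelihood-invariant
  quantities are compared across replicates).
* Denominator degrees of freedom use the residual-df approximation
  throughout; p-values very close to a decision threshold deserve a
  small-sample correction the package does not provide.
* The generator draws allele copies independently; organisms with
  substantial double reduction violate this.
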