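---
title: "Detecting epistatic transmission ratio distortion from genotyped trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting epistatic transmission ratio distortion from genotyped trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitrd)
```

## The problem

Transmission ratio distortion (TRD) is a departure of offspring genotype
frequencies from Mendelian expectations given the parents' genotypes. In a
genotyped trio (sire, dam, offspring) every transmission event is observed,
so distortion can be measured locus by locus without phenotypes. Epistatic
TRD extends this to *pairs* of loci: some two-locus allele or genotype
combinations (for instance, incompatible variants in the style of
Bateson–Dobzhansky–Muller interactions, or a two-locus recessive lethal)
are under- or over-transmitted even though neither locus is distorted on
its own. Livestock populations are the natural setting: hundreds of
thousands of trios with dense SNP genotypes and a half-sib structure (few
sires, many dams).

`epitrd` implements three complementary detectors for biallelic SNP pairs
on different chromosomes, plus the genome-scan filtering cascade around
them and a seeded simulator used to validate every stage:

1. a **genotypic** model: distortion on the nine unphased two-locus
   offspring genotype classes;
2. an **allelic** (gamete-transmission) model: distortion on the four
   "artificial haplotype" gametes `AB`, `Ab`, `aB`, `ab`, with a
   simplified one-parameter screen for fast preliminary scans;
3. a **recessive depletion screen**: pairs whose double-homozygote class
   is expected in numbers but never observed.

## The genotypic model

For the double-heterozygous mating AaBb × AaBb the unnormalized weight of
offspring class $g$ is

$$w(g) = \mathrm{base}(g) + c(g)^\top \theta, \qquad
\theta = (\alpha_A, \alpha_B, \delta_A, \delta_B,
\alpha\alpha_e, \alpha\delta_e, \delta\alpha_e, \delta\delta_e),$$

where $\mathrm{base} = (1,2,1,2,4,2,1,2,1)$ is sixteen times the Mendelian
vector over the classes (AABB, AaBB, aaBB, AABb, AaBb, aaBb, AAbb, Aabb,
aabb), $\alpha$/$\delta$ are additive and dominance direct distortions per
locus in $[-1, 1]$, and the four epistatic terms are
additive-by-additive through dominance-by-dominance combinations, also in
$[-1, 1]$. The coefficient rows are fixed model constants
(`genotypic_coefficients()`). Two conventions matter and are deliberate:

* **The epistatic coefficient signs are not plain products** of the
  additive and dominance contrast codes: the
  $\alpha\delta_e$/$\delta\alpha_e$/$\delta\delta_e$ columns follow the
  model's own (negated-product) convention. The table is transcribed as a
  constant rather than derived, and the transcription is itself tested
  against a term-by-term oracle.
* **Adaptation to arbitrary matings**: for any ordered (sire, dam) mating
  the base becomes $16 \times$ the mating's Mendelian class probability
  while the coefficient rows stay unchanged, restricted to
  Mendelian-feasible classes. This reproduces the canonical adapted case
  — under AaBB × AaBB the AABB base is 4 and AABb is infeasible — exactly.

Weights can go negative inside the parameter box, so negative weights are
**clipped to zero first and the vector renormalized second** (this order
follows the model's definition). If clipping zeroes a class that was
observed, the log-likelihood is $-\infty$ rather than an error, which
keeps the sampler well defined on the boundary: such proposals are simply
rejected.

```{r genotypic-example}
offspring_probabilities("AaBb", "AaBb", genotypic_params(aa_e = 1)) * 16
```

## The allelic model

Each parent transmits one of four gametes. For a parent heterozygous at a
locus, the transmitted allele carries a factor $0.5 \pm \beta$ (direct
terms, bounded by $[-0.5, 0.5]$ so that marginal transmission stays in
$[0, 1]$); each pair of *competing* gametes carries a factor
$1 \pm \beta_{x/y}$ with six heterozygous pairwise parameters in
$[-1, 1]$, the sign being $+$ for the canonically earlier gamete
(`AB < Ab < aB < ab`). For a double heterozygote the competitor is the
complementary gamete; for a single heterozygote it is the parent's other
gamete; homozygous loci contribute no factor (any constant cancels in the
normalization). Offspring class probabilities are the convolution of the
two parents' normalized gamete distributions; because the joint weight
factorizes by parent, normalizing per parent or jointly is equivalent
(verified numerically), and parental origin never enters the likelihood.

The **simplified screen** collapses this to one parameter per designated
artificial haplotype $j$: $P(\text{transmit } j) = 0.5 + \alpha_j$. It
counts transmissions only from parents heterozygous at exactly one locus
that carry $j$: for them the Mendelian null is exactly $1/2$ and the
transmitted gamete is deducible from the offspring given the other parent
(ambiguous events are skipped and tallied). Unphased double heterozygotes
have a $1/4$ null for any specific gamete and would bias $\alpha_j$
upward, so they are left to the full model. Candidates are promoted to
full-model re-analysis when the haplotype explains at least 0.05 more
|TRD| than its best single SNP and at least as many under/over-represented
offspring (both thresholds configurable).

## Inference

All models are fitted by a single-chain Metropolis–Hastings sampler with
flat priors over the bounded parametric space: single-parameter Gaussian
random-walk updates in fixed cyclic order, proposals reflected at the
bounds, initial state at the Mendelian null. The proposal standard
deviation defaults to 0.05 and is auto-tuned during burn-in toward a
20–40% acceptance rate (tuning stops at burn-in, so the retained chain is
a valid fixed-kernel chain). Chain presets follow the scan design: 11,000
sweeps (1,000 burn-in) for the preliminary scan, 550,000 (50,000) for
accurate re-estimation of selected regions, 110,000 (10,000) for the
simplified screen. The accurate-stage length is sometimes quoted as
500,000 sweeps instead; the package default is 550,000/50,000, and the
preset is a plain argument either way. The core runs in compiled code; a pure-R
reference sampler consumes the RNG identically and yields bit-identical
chains under the same seed, which the tests exploit as a cross-check.

Summaries per parameter: posterior mean, SD, coefficient of variation
(SD/|mean|, undefined at mean zero) and a **Savage–Dickey Bayes factor**
against the point null — prior density at zero (1/width) over the
posterior density at zero, the latter estimated by a Gaussian kernel
density with Silverman's bandwidth (a histogram estimator is an easy
cross-check in the tests). When every draw sits far from zero the density
underflows and the log10 BF is reported as `Inf` with the count of draws
within one bandwidth of zero attached. Model level: the log10 likelihood
ratio against the null at the posterior mean (clipped to bounds) and the
DIC, $2\,\overline{D} - D(\bar\theta)$; DIC differences above 3 are
treated as relevant when comparing the genotypic and allelic fits.

A note on the accuracy of the Savage–Dickey estimate: its Monte-Carlo
error is governed by how many draws land near the null. With the null
inside the posterior bulk the estimate is accurate to a few percent at
$10^5$ draws; for strongly distorted data (null several posterior SDs out)
the *relative* error of the KDE at the null is of order 10–30% even on
independent draws, although the error on the log10 scale stays small.
Validation therefore checks relative BF accuracy on moderately distorted
binomial data and log10-scale accuracy on strongly distorted data.

## The scan cascade

`trd_scan()` / `trd_scan_pairs()` chain the published filtering design,
in order:

1. **Pre-filter**: ≥ 1,000 informative offspring and (≥ 20 heterozygous
   sires or ≥ 50 heterozygous dams). A parent counts as heterozygous when
   heterozygous at one locus or more (least restrictive reading; a
   "both-loci" mode exists).
2. **Deviation screen**: some (mating, class) cell deviates from its
   Mendelian expectation by ≥ 1,000 offspring *and* ≥ 10% of the
   expectation. Relative deviations are reported both against expected
   and against observed counts, since published percentages mix the two.
3. **Preliminary chain**, then the **epistatic relevance filter**: max
   epistatic BF ≥ 1,000, max-epistatic/max-direct BF ratio > 1,000 (if
   direct effects are entirely absent the ratio passes by convention) and
   CV ≤ 20% for every significant epistatic parameter.
4. **Accurate chain** on survivors, overwriting preliminary statistics,
   then the same filter again.
5. **Categorization** by the largest epistatic BF
   (additive-by-additive / additive-by-dominance-or-reverse /
   dominance-by-dominance), **top 0.1% selection** within each category
   (ceiling of 0.001·n, ties broken by pair identifier) and **linked-SNP
   collapsing**: when one SNP recurs with several partners within 10 Mb of
   each other on one chromosome (single-linkage chaining; the window is
   configurable since "physically linked" has no published number), only
   the highest-BF pair survives.

The absolute-deviation constant (1,000) was calibrated for a population of
~284,000 trios analyzed over *pooled* mating classes; with the 65 ordered
configurations analyzed directly and desk-scale simulations, the same
per-trio rate implies proportionally smaller constants. Validation runs
therefore use `scan_config(min_abs_deviation = 50)` at 20,000 trios per
pair, with every other rule unchanged.

## The recessive screen

For a target haplotype $h$, the expected number of offspring homozygous
for $h$ at both loci is the sum over trios of the product of each parent's
Mendelian transmission probability of the $h$ allele at each locus. A pair
is flagged when this expectation is ≥ 15, no such offspring is observed,
and all *other* offspring classes in the carrier matings conform to
Mendelian proportions. The conformity band per cell is
$\max(0.10 \cdot E,\ z\sqrt{E})$ with $z$ set by a Bonferroni bound at
familywise 1% across the checked cells — a fixed per-cell $z$ would
reject true lethals merely through the number of cells examined (about a
hundred per pair). Two caveats are documented rather than hidden: a fully
penetrant lethal itself renormalizes its carrier matings (other classes
inflate by $1/(1-P_{\text{target}})$), so conformity is only expected to
hold when carrier-mating cells are modest — the regime of rare lethal
haplotypes, which is where the screen is scientifically meaningful; and
the per-mating breakdown mirrors carrier status (both-carrier,
carrier-by-noncarrier) rather than any particular published table layout.
This screen deliberately bypasses the Bayes-factor machinery, which would
discard exactly this pattern. The reported haplotype frequency assumes
independence of the two loci (inter-chromosomal pairs).

## The simulator

`sim_config()` emulates the half-sib design: parent genotypes from
Hardy–Weinberg proportions at each locus independently (the loci are on
different chromosomes by construction), dams assigned to sires with
Dirichlet-weighted usage (`family_imbalance`; small values give the
top-heavy sire usage typical of dairy cattle). Defaults — 50 sires ×
2,000 dams × 1 offspring, allele frequencies 0.30 — give pair data at the
pre-filter's order of magnitude in well under a second; tests that need
maximal informative-mating density state frequency 0.5 explicitly.
Mechanisms: `none` (Mendelian), `genotypic` and `allelic` (offspring drawn
from the corresponding model), `viability` (Mendelian draw then per-class
survival) and `recessive_lethal` (survival $1-$penetrance for one
double-homozygote class). Two survival modes exist because the TRD
likelihood conditions on observed offspring: `drop` (default, biologically
faithful — lost trios disappear) and `redraw` (fixed trio count;
distributionally identical to sampling the survival-weighted Mendelian
vector, which the tests use as a semi-independent check of the genotypic
likelihood). Everything is bit-reproducible under a seed, and
`truth_record()` serializes the generating mechanism for recovery scoring.

What the simulator does *not* emulate: linkage disequilibrium between the
pair (inter-chromosomal by design), genotyping or imputation error,
multi-generation pedigrees, and selection. Passing tests therefore show
correct recovery of the models' own generative processes under a realistic
mating structure — not robustness to imputation artifacts in real data,
where Mendelian-inconsistency exclusion and the CV filter carry that load.

## Numerical choices and degenerate inputs

* Genotype calls are dosages of an arbitrary per-SNP "capital" allele; no
  frequency-based re-orientation is done because both models are
  label-symmetric (tested as locus-swap and allele-flip invariances).
* Mendelian-inconsistent trios (impossible offspring class under the
  parental mating) are excluded and tallied, not fatal: imputed data
  contain errors and the likelihood is undefined on them.
* A mating whose weights all clip to zero is a degenerate error at the
  probability level and $-\infty$ at the likelihood level.
* Chain determinism is part of the contract: same seed, same
  configuration, same chain — across both sampler implementations.
* Validation problem sizes: recovery uses 2,000 double-heterozygous trios
  and 55,000-sweep chains over 20 seeds; null calibration uses 5,000-trio
  pairs; the end-to-end scan plants one additive-by-additive pair
  (aa_e = 0.8) among 200 nulls of 20,000 trios each.

## Known limitations

* No intra-chromosomal (linked) pairs, no three-locus interactions, no
  phasing, no imputation — all outside the package's scope.
* The published analysis pooled the 65 ordered matings into 27 combined
  classes by a rule that is not public; this package analyzes the 65
  ordered configurations directly and accepts a user-supplied grouping
  only implicitly (aggregation happens upstream of the likelihood, which
  is invariant to pooling identical-distribution matings).
* Savage–Dickey accuracy degrades in relative terms for parameters whose
  posterior excludes the null by many SDs (see above); log10 BFs of such
  parameters are enormous anyway, and filters compare them only to other
  enormous values.
* Single chain, as in the published design: no Gelman–Rubin diagnostics.
  The CV filter doubles as the convergence guard, which is exactly its
  published role.
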