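---
title: "Linkage analysis and QTL mapping from tetraploid SNP dosages: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage analysis and QTL mapping from tetraploid SNP dosages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetramap)
```

tetramap builds genetic linkage maps and maps quantitative trait loci in an
autotetraploid F1 (full-sib) population genotyped with SNP allele-intensity
ratios ("theta scores" in [0, 1]). This vignette explains the models behind
each stage, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices made where the
design was genuinely open.

## The segregation model

All genetics in the package assume *random chromosomal segregation*: at
meiosis the four homologous chromosomes of each parent (labelled a–d and e–h)
pair into two bivalents, with the three possible pairings equally likely; no
preferential pairing, no double reduction, no crossover interference. Under
this model a parent carrying $d$ copies of the B allele transmits a diploid
gamete with $k$ copies with probability $\binom{d}{k}\binom{4-d}{2-k} /
\binom{4}{2}$, and the offspring dosage distribution at a SNP is the
convolution of the two parental gamete distributions
(`dosage_probabilities()`). Thirteen canonical parental configurations exist
up to allele relabeling — null, simplex, triplex, duplex, double-simplex,
X-double-simplex, simplex-duplex, duplex-simplex, double-duplex
(`snp_configurations()`). Orientation (which parent is heterozygous) is
tracked throughout because the downstream phase logic needs it.

## Dosage calling

Theta scores for one SNP are modelled as a normal mixture with one component
per admissible dosage class. The mixture proportions are *fixed* at the
expected class frequencies of the candidate configuration; only the class
means (one per class, allowed to be unevenly spaced, because the
intensity-to-dosage response can differ between alleles) and a single common
variance are estimated. `fit_dosage_mixture()` seeds with a k-means step at
the theta anchors $g/4$ and then alternates an E-step (posterior class
membership with the fixed weights) and an M-step (posterior-weighted class
means, treated as categorical, plus a pooled variance) until the
log-likelihood changes by less than 1e-6, capped at 200 iterations.
Monotonicity of the class means in the dosage is enforced by sorting.
Configurations are compared with BIC on the full likelihood, which adds the
parental densities at their configuration classes to the offspring mixture
likelihood; the parameter count is the number of class means plus one. Classes
absent from the offspring keep their theoretical anchors for the parent terms.

Implementation choices fixed here once: the EM tolerance
(1e-6), the k-means variant (Hartigan–Wong with fixed anchor starts, falling
back to the anchors when a cluster empties), and missing parents (their terms
are simply dropped from the full likelihood). Distorted SNPs with three or
more classes whose two-class alternative lies within ΔBIC ≤ 10 and is
undistorted are recoded as simplex — an automated, reproducible surrogate for
a graphical re-check of such SNPs.

Pre-processing screens SNPs before calling: trimmed range (2%–98% quantiles)
at least 0.1; no missing values; and no strong trend of theta on sample
order. The trend screen fits a natural regression spline with 4 degrees of
freedom and compares it with a constant model by an F-test, failing the SNP
at p < 1e-4. A loess smooth with 4 equivalent degrees of freedom behaves the
same way; the spline form gives an exact F reference distribution.

Double-reduction screening (`detect_double_reduction()`) applies only to
two-class (simplex/triplex) SNPs: theta is regressed on the called class, the
inter-class gap $d$ estimated, and individuals with residuals beyond $0.75d$
flagged. Because trend artefacts mimic such outliers, an individual is
*confirmed* only when flagged at two or more SNPs in coupling on the same
homologue at separate map positions.

## Two-locus machinery and pairwise linkage

For two linked SNPs, every gamete genotype is reached by $x_0$
non-recombinant, $x_1$ single-recombinant and $x_2$ double-recombinant
routes, with frequency $[x_0(1-r)^2 + x_1 r(1-r) + x_2 r^2]/12$
(`gamete_coefficients()`, `gamete_frequency()`). Random union of gametes
gives zygote dosage classes with coefficients $y_{ij}$ on $r^j(1-r)^{4-j}$,
$j = 0\ldots4$ (`zygote_table()`). The recombination fraction is estimated by
an EM algorithm on the latent recombination count: the E-step distributes
each class count over $j$ in proportion to $y_{ij} r^j (1-r)^{4-j}$ and the
M-step divides the expected recombination total by $4n$. Iteration starts at
$r_0 = 0.25$ and stops when $|\Delta r| < 10^{-8}$; the estimate is clamped
to $[10^{-6}, 0.5]$ so the boundary LOD stays finite. The log-likelihood is
evaluated per enumerable phase (phases are the inequivalent placements of the
B alleles on the homologues, characterised per parent by the overlap of the
two loci's B-sets; coupling/mixed/repulsion labels are assigned on the
minor-allele placement so triplex loci behave like simplex). The most likely
phase wins and the LOD is the base-10 log-likelihood difference between
$\hat r$ and $r = 0.5$. With simplex/triplex merged there are exactly 67
distinct configuration/phase pairings (`linkage_pairings()`).

`pairwise_linkage()` additionally reports, per pair, the log-likelihood
margin of the best phase over the runner-up (`phase_gap`; ties such as the
CxM/MxC ambiguity of double-duplex pairs are reported, not broken
arbitrarily) and a standard error for $\hat r$ from the expected Fisher
information of the class likelihood. Both are used by the ordering stage.

## Grouping and ordering

Linkage groups come from average-linkage hierarchical clustering on the
p-value of a chi-square test of independent segregation of the joint dosage
classes — the p-value, not the statistic, because it is comparable across
pair types with different degrees of freedom. The default cut height is 0.1.
Two runs are clustered (parent-1 simplex/duplex plus the SNPs heterozygous
in both parents; parent-2 likewise) and merged, retaining a both-parents SNP
only when the two runs agree (`merge_cluster_runs()`). Same-parent simplex
SNPs form per-homologue framework groups by single-linkage at coupling
$\hat r \le 0.25$ — for populations near 190 offspring this corresponds to a
coupling LOD of about 10.8. Duplex+simplex association tests (p < 0.001)
link homologues into per-parent chromosome groups, and significant
simplex+double-simplex *coupling* pairs match groups across parents
(repulsion pairs have much lower power and are excluded).

Ordering within a group uses only pairs with $\hat r < 0.45$ and LOD > 0.05,
converts $\hat r$ to distance with the Haldane function
$d = -\tfrac12\ln(1-2r)$, and minimises the weighted least-squares stress
$\sum w_{ij}(D_{ij} - |x_i - x_j|)^2$ with $w_{ij} = \mathrm{LOD}_{ij}^2$,
solving the interval lengths by non-negative least squares (active-set;
clamping after an unconstrained solve corrupts the objective and is not
used). Pairs whose best phase is ambiguous (margin below 2.3 log-likelihood
units, 10:1 odds) are excluded: on simulated data, essentially all grossly
wrong distances trace back to wrong-phase or near-tied-phase estimates. The
order itself is searched from several deterministic seeds — a sequential
build that inserts each SNP (strongest total linkage first) at its
stress-optimal slot with a ripple after every five additions, and
principal-coordinate seriations of the distance matrix completed by shortest
paths through high-weight edges — each refined by sweeps of a window-5
ripple (all 120 permutations), single-SNP relocation and 2-opt segment
reversal, screened with a fast fixed-slot stress and accepted on the full
WLS stress. A second round drops SNPs whose mean stress contribution exceeds
three times the group median and re-fits. Unplaced SNPs are binned next to
their highest-LOD mapped anchor when $\hat r < 0.05$ (LOD ties resolved
toward the smaller rf); near-duplicates (Hamming distance ≤ 2 over the
offspring, missing counting as a mismatch) are removed before ordering by a
greedy first-by-id representative rule.

A resolution caveat that matters for interpreting simulated-recovery
results: with ~190 offspring, adjacent-pair recombination-fraction estimates
carry a standard error comparable to sub-cM marker spacing, so the *local*
order of markers closer than a few cM is not statistically identifiable from
pairwise data — which is exactly why markers inside an $\hat r < 0.05$
neighbourhood are binned rather than ordered. On dense simulated
chromosomes (about 1.2 SNPs/cM) the search routinely attains stress at or
below the value obtained by refining from the true order, yet the Kendall
correlation between true and estimated orders plateaus around 0.85–0.9:
remaining discordances are local inversions below the method's resolution,
not failures of the global map.

Full phase reconstruction tests every mapped/binned SNP against the
framework simplex SNPs of each parent and assigns a B allele to a homologue
when coupling is supported at LOD > 5. Incomplete assignments are completed
from the strongest remaining candidate pairs (an automated stand-in for a
manual step); a SNP supported on more homologues than its dosage allows is
flagged as contradictory and left unphased.

## Genotype reconstruction and QTL mapping

Offspring genotypes along a chromosome are the 36 states {2-subset of a–d} ×
{2-subset of e–h}. Conditional on a bivalent pairing in each parent (9
combinations) only 16 states are reachable, and moving between states across
an interval with recombination fraction $r$ has probability
$r^{d_{kl}}(1-r)^{4-d_{kl}}$, where $d_{kl}$ counts the bivalents whose
transmitted homologue changes. Emissions compare each state's B-allele total
with the observed dosage, with a mis-scoring probability λ (default 0.001 — small enough to leave
clean data untouched while keeping every dosage sequence explicable; λ = 0
recovers the error-free model). Scaled forward–backward recursions per pairing (uniform
1/16 start) give posterior state probabilities and sequence likelihoods
$p(x|B)$; the combined genotype probabilities are the posterior average over
pairings weighted by the normalised $p(x|B)$. Missing dosages emit
uninformatively rather than being imputed. Adjacent recombination fractions
are recovered from map distances by the inverse Haldane function; the
position-dependent variant taking pairwise estimates directly is available
through the `rf` argument. Probabilities are interpolated to a 1 cM grid
with natural cubic splines, clipped to [0, 1], renormalised at each grid
point, and held constant beyond the terminal SNPs.

The trait model is the main-effects (additive allele) decomposition for a
tetraploid full-sib family: an offspring inheriting alleles $\{i,j\}$ from
parent 1 and $\{k,l\}$ from parent 2 has expectation $\mu + \alpha_i +
\alpha_j + \alpha_k + \alpha_l$, with $\alpha_a$ and $\alpha_e$ absorbed by
the constraints $X_a + X_b + X_c + X_d = 2$ and $X_e + X_f + X_g + X_h = 2$.
Interaction terms are deliberately zero. The model is fitted by iterative
weighted regression on the genotype probabilities: weights start at the
probabilities, each iteration fits the weighted regression over the
offspring × state expansion, re-estimates the residual variance, and updates
the weights to the posterior state probabilities given the trait value. The
iteration count is capped at ten to limit over-fitting; the residual
variance used in the weighting density is refreshed every iteration.

Scanning a chromosome fits the model at every grid point. The QTL position
is taken at the maximum of the *mixture log-likelihood* profile, not the
$R^2$ profile: once the weights adapt to the trait, $R^2$ saturates at a
near-constant high value across the chromosome, while the likelihood retains
the penalty for assigning offspring to states that are improbable under the
HMM prior and therefore localises sharply. Percent variance explained is
reported at each position as $100(1 - \mathrm{RSS_w}/\mathrm{TSS})$ with the
weighted residual sum of squares of the final regression.

Map checking maps each SNP's theta scores as a trait on its own chromosome
and verifies (i) displacement between marker and QTL positions, (ii)
percent variance against a soft 85% threshold, and (iii) concordance between
the significant coefficients (|α|/se > 3, configurable) and the homologues carrying B in the SNP's
phase, allowing for the complemented pattern when a reference homologue (a
or e) carries B. Failing SNPs are excluded and the mapping re-run once. A
noise reference comes from scanning standard-normal traits the same way
(`random_trait_null()`).

## The synthetic-data generator

`synth_genome()`/`synth_population()` define the simulated study conditions:
by default 12 chromosomes of 26 cM carrying 32 SNPs each (≈1.2 SNPs/cM), 190
offspring, and a per-chromosome configuration mix of eight simplex SNPs per
parent (two per homologue, so the framework step can identify all four
homologues), four duplex SNPs per parent, and a balance of double-simplex,
simplex-duplex, duplex-simplex and double-duplex SNPs — proportions chosen
to resemble a dense tetraploid array experiment in which roughly a third of
segregating SNPs are simplex. Theta emission draws from normal classes at
means (0.02, 0.26, 0.50, 0.74, 0.98) with common standard deviation 0.02 and
clips to [0, 1]; an optional linear drift across sample order exercises the
trend screen. Meiosis is simulated exactly under the package's segregation
model: one bivalent pairing drawn uniformly per parent per meiosis, each
bivalent walked along the SNPs with independent per-interval crossover
probability (Haldane).

What the generator does *not* emulate — and what passing recovery tests
therefore cannot show about real data: spatial/plate trend structure beyond
a linear drift, dosage-dependent or asymmetric theta variances, null
alleles, segregation distortion, preferential pairing, and double reduction
(a spiking utility injects DR-like outliers for detector tests instead of
modelling multivalents).

## Degenerate inputs and numerical conventions

Chi-square tests merge classes whose expected count falls below 1 (degrees
of freedom follow the table actually used); p-values used as distances are
floored at 1e-300; boundary recombination estimates are clamped rather than
reported at 0; map orientation is a convention (first SNP at 0 cM, reversal
is an equivalent solution); clustering and ordering are deterministic given
their inputs, with ties broken by SNP id order. Every stochastic routine
takes an explicit seed argument.

## Problem sizes used in validation

The packaged validation suite reproduces the exact coefficient tables
instantly; runs the pairwise simulation study at 20 populations × 200
offspring; checks the HMM against brute-force path enumeration on 3–4 SNP
instances; verifies the EM maximiser against golden-section search on 200
random tables; and runs the genome-recovery study on the default 12 × 32
synthetic genome with 190 offspring and the noise-trait reference with 100
random traits on one chromosome. These sizes were chosen to give stable
statistics while keeping the full suite comfortably runnable on a laptop.

## Known limitations

* Local marker order below ~2–3 cM is not identifiable from two-point data
  at n ≈ 190; rely on binning, not on the within-bin order.
* Recombination-fraction estimates for weakly informative pairings
  (simplex repulsion, X-double-simplex/double-simplex repulsion) are
  strongly biased at large distances; they are excluded from ordering by
  the phase-margin rule but still appear in the pairwise table.
* The QTL machinery here targets marker-quality traits (theta self-checks);
  thresholds for genuine phenotypes (permutation nulls, multi-QTL models,
  interactions) are out of scope.
* No support for preferential pairing, multivalent meiosis or
  double-reduction-aware genotype states.
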