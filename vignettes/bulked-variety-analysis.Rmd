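---
title: "Distinguishing open-pollinated varieties from bulked SNP samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing open-pollinated varieties from bulked SNP samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the sampling design

Open-pollinated varieties (OPVs) of outcrossing grasses are populations,
not genotypes: each variety harbours substantial internal variation and
only modest divergence from its neighbours. The design `bulkpop`
analyses genotypes each variety through several *bulks* — pooled DNA of
~50 plants — called as ordinary diploid samples, so a bulk's "genotype"
at a biallelic SNP is a three-state summary of the pool: homozygous
reference (dosage 0) when essentially only the reference allele was
seen, homozygous alternate (dosage 2) when only the alternate was seen,
and heterozygous (dosage 1) when the pool visibly segregates. The
reference configuration is 11 varieties × 3 bulks × 50 plants.

The scientific questions, in pipeline order: are the varieties
meaningfully diverse internally (diversity indices, π)? Is among-variety
divergence significant (AMOVA / Φ~ST~)? Can every bulk be assigned to
its variety (kinship, tree, PCA, cluster number)? And how few SNPs
suffice to separate the most similar pair (panel sizing)?

## Site screening

`apply_screens()` retains loci with minor-allele frequency ≥ `maf_min`
(default 0.05) and call rate ("integrity") ≥ `integrity_min` (default
0.95), then applies hard filters QD ≥ 2, FS ≤ 60, MQ ≥ 40 where those
VCF INFO annotations exist; `read_vcf()` masks individual calls with
GQ < 20 beforehand. Boundary semantics are *keep at equality*: a locus
at MAF exactly 0.05 or call rate exactly 0.95 passes. Call rate is
computed across all bulks jointly; rules are applied in the order
MAF → integrity → hard filters and the filter report counts removals
per rule in that order, so the counts sum to the total removed.
Multi-allelic and non-SNP records are dropped at import (every
statistic downstream is biallelic), and screening is idempotent.

## Diversity indices

Within a variety, a locus with $n$ non-missing diploid bulks and
alternate-allele frequency $p$ ($q = 1-p$) contributes

* $He = 1 - p^2 - q^2$, $\;Ne = 1/(p^2+q^2) = 1/(1-He)$,
* $Ho$ = fraction of heterozygous calls,
* $Shi = -(p\ln p + q\ln q)$ (0 at fixation, $\ln 2$ maximum),
* $Nei = \frac{2n}{2n-1} He$ (the small-sample unbiased correction),
* $Na$ = distinct alleles observed (1 or 2),
* $\pi = \frac{c}{c-1} 2pq$ with $c = 2n$ allele copies — identical to
  the mean pairwise difference among the sampled copies.

Each index is averaged over the loci callable in that variety (loci
entirely missing there are excluded from the denominator, the GenAlEx
convention). The `"all"` row pools every bulk as a single population;
`summarize_means()` is the unweighted column mean over variety rows.
π is reported per screened SNP, not per genomic site — monomorphic
sites are absent after screening, so only orderings, not genome-wide
absolute values, are comparable across studies.

## Distance-based AMOVA and its permutation null

All differentiation statistics run on one distance: $d^2(i,j)$ = mean
squared dosage difference over the loci called in both samples.
Averaging (not summing) makes distances comparable across panels of
different sizes, which the marker-panel module relies on. The
two-level AMOVA uses the standard algebra
$SS_{total} = \frac{1}{N}\sum_{i<j} d^2(i,j)$,
$SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j\in g} d^2(i,j)$,
$MS = SS/df$ with $df = (G-1, N-G)$,
$n_0 = (N - \sum n_g^2/N)/(G-1)$,
$VC_{among} = (MS_{among}-MS_{within})/n_0$,
$VC_{within} = MS_{within}$, and
$\Phi_{ST} = VC_{among}/(VC_{among}+VC_{within})$. Negative
$VC_{among}$ is clamped to zero for the percentage-of-variation columns
only; the raw components are kept in the result.

Significance permutes sample-to-variety labels. When the number of
distinct label assignments is small (≤ 500, e.g. the 20 assignments =
10 distinct splits of a 3 + 3 pairwise comparison) the null is
enumerated exactly and P is the exact proportion of assignments with
Φ~ST~ at least the observed value — the identity assignment guarantees
P > 0 and implies a floor of 0.1 for 3-versus-3 bulks. Otherwise
`n_perm` random permutations are drawn and $P = (1+b)/(1+B)$, which is
also never zero. Numerical choices: permuted statistics are compared
with a $10^{-12}$ slack so floating-point ties count as ties; a dataset
with zero total variance is defined to have Φ~ST~ = 0 and P = 1
(degenerate, no information); pairwise Φ~ST~ re-uses the full
distance matrix because each entry is already restricted to the loci
shared by that pair. `fst_extremes()` breaks ties lexicographically on
the sorted pair of variety names, so results are deterministic.

## Marker-panel subsampling

For the least differentiated pair (`select_focal_pair()`, the
off-diagonal minimum), `subsampling_curve()` draws `n_reps` marker
panels per size *without replacement within a draw* — a panel is a set
of distinct markers, so resampling the same SNP twice would be
meaningless — and records the two-group AMOVA Φ~ST~ and exact
permutation P per draw. `recommend_panel_size()` returns the smallest
size whose mean P is at most `alpha` *and* whose mean Φ~ST~ strictly
exceeds `stability` (default 0.95) of the curve's maximum; comparisons
are rounded at 12 digits so decimal thresholds behave as written, and
if no size qualifies the largest size is returned with a warning.

With 3 bulks per variety the exact null has only 10 distinct splits,
so no panel, however large, can reach P < 0.1 for a single pair. The
default `alpha = 0.05` therefore always falls through to the largest
size on a 3 + 3 design; analyses of such designs should use
`alpha = 0.1` (the attainable floor), which is what the package's own
stability analyses do. How a smaller AMOVA P could be reported for a
3 + 3 comparison is a property of the resampling scheme of whatever
software produced it, not of the design; we expose the choice through
`alpha` and `n_perm` rather than hard-coding one.

## Relatedness, tree, PCA, ΔK

`vanraden_kinship()` is the first VanRaden genomic relationship matrix:
$K = ZZ'/(2\sum p(1-p))$ on centered dosages $Z = x - 2p$, with $p$
estimated from all samples, missing dosages imputed at the mean
($Z = 0$), and monomorphic loci excluded from numerator and denominator
alike. PCA uses the same mean-imputation, column-centers, and takes
scores from the SVD.

The bulk tree is Saitou–Nei neighbor joining on the mean squared dosage
distance, with negative branch lengths clamped to zero and bootstrap
supports computed by resampling loci with replacement and counting
bipartitions of the reference tree. Neighbor joining is a deliberate
design choice: maximum-likelihood phylogenetics requires a substitution
model, and no such model is meaningful for unlinked SNP dosages of
pooled bulks; the quantity of interest is cluster recovery (are the
three bulks of each variety a clade?), which NJ answers directly and
which the test suite measures.

`evanno_delta_k()` implements the second-difference statistic on
clustering log-likelihood runs: per run $L'(K) = L(K)-L(K-1)$,
$L''(K) = |L'(K+1)-L'(K)|$, and $\Delta K = \mathrm{mean}(L'')/
\mathrm{sd}(L(K))$, undefined at the endpoint K values, with an
infinite sentinel when the run-to-run deviation is zero. The Bayesian
clustering itself is out of scope — the statistic operates on an
externally supplied (or simulated) run table, which is sufficient to
test the formula and the modal-K rule. Note that ΔK peaks at the
*elbow* of the likelihood curve (the last K before the plateau).

## The synthetic generator and its calibration

`simulation_config()` defaults encode the reference design: 11
varieties, 3 bulks, 50 plants per bulk, 5% missingness. Per locus the
ancestral alternate frequency is uniform on `ancestral_maf_range`
(default 0.05–0.5, the post-screening spectrum); per variety the
frequency is Balding–Nichols,
$\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ with $F$ = `fst_target`, whose
among-variety variance is exactly $F\,p(1-p)$ — the standard
Fst-parameterised divergence model, with independent loci. Observation
follows the pooling physics: alternate copies per bulk are
$\mathrm{Binomial}(2\cdot 50, p_v)$, depth is Poisson with mean 30,
alternate reads are binomial in the realized pool fraction, and the
call is 0/1/2 by whether the alternate-read fraction falls below 0.10,
inside (0.10, 0.90), or above 0.90 — the heterozygote-dominant
behaviour of a diploid caller applied to pooled DNA. Calls need depth
≥ 5 (`min_depth_call`), and one master seed drives separate named
streams for frequencies, genotypes, missingness, permutations and
bootstrapping, so identical configurations are byte-identical and each
stage is independently reproducible. Default `n_loci` is 2000 — ample
for stable distance estimates at desk scale; the recovery analyses in
the test suite use 20,000 where a genome-scale panel is the point.

**Two Fst scales, and what "recovery" means.** The drift parameter $F$
lives on the allele-frequency scale, and is recovered from the
generator's truth table to within ±0.02 (a Weir–Cockerham-style ratio
of among-variety variance to $\bar p \bar q$, part of the test suite).
The dosage-level AMOVA Φ~ST~ lives on a different scale: for diploid
genotype-coded units the among-variety variance of dosage is $4Fpq$
while the within-variety variance is at most $2pq(1-F)$ (binomial
allele sampling), so even with perfect calls
$\Phi_{ST} \approx 2F/(1+F) > F$, and deep pooled reads — which make
within-variety calls nearly deterministic — push it higher still
(about 0.54 at the default depth 30 with $F = 0.15$; the acceptance
script computes this at run time). This is not an artifact of the
implementation: real bulked studies show the same split, reporting
pairwise allele-level Fst in the 0.10–0.25 range alongside an overall
genotype-level AMOVA Φ~ST~ near 0.37. Comparisons of Φ~ST~ values are
therefore meaningful *within* a scale (between pairs, across panel
sizes, against a permutation null) but a dosage-level Φ~ST~ should not
be read as an estimate of the allele-level $F$.

**What the generator does not emulate.** Linkage and LD (loci are
independent), selection, pedigree structure within varieties, read
errors and reference bias, a realistic (rare-allele-skewed) frequency
spectrum — the uniform MAF range makes simulated bulks more often
heterozygous than typical real data — and locus dropout correlated
across samples (missingness is independent per call). Passing tests on
synthetic data therefore validate the statistical machinery and its
calibration against planted truth, not the full error structure of a
real sequencing experiment.

## Problem sizes and runtime choices

The test suite runs module checks at a few hundred to a few thousand
loci, the drift-recovery and null-control analyses at 20 seeds ×
20,000 and 2,000 loci respectively, the panel-shape analysis at 5
seeds × 50 replicates per size, and cluster recovery at 20 seeds ×
2,000 loci — sizes chosen so distance estimates are stable while the
whole suite completes in about a minute. The acceptance script uses
20,000 loci for the main simulation and 2,000 for the tree, kinship
and panel analyses.

## Known limitations

* Two-level AMOVA only: bulks are the lowest units; there is no
  within-bulk stratum (individual plants are unobserved by design).
* Pairwise significance on 3 + 3 bulks is floor-limited at P = 0.1 by
  exhaustive enumeration; more bulks per variety, not more markers,
  would sharpen it.
* π is per-SNP, not per-site; Na follows the distinct-allele-count
  definition (values in [1, 2] per locus).
* The VCF writer emits a minimal GT-only VCF v4.2; INFO annotations
  present at import are carried in the locus table, not re-emitted.
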