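---
title: "Methods and design notes for popdiffr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for popdiffr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popdiffr)
```

This vignette documents the statistical models behind `popdiffr`, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where more than
one defensible option existed.

## The problem

Closely related populations — regional cohorts within one country, say —
differ genetically at a scale (mean pairwise F_ST of 0.001–0.01) that is
invisible to casual inspection yet consequential at highly polymorphic
loci like the HLA genes, where the same extended haplotypes segregate in
all populations but at different frequencies. Those frequency differences
matter practically: genotype imputation copies haplotypes from a
reference panel, so a panel whose haplotype frequencies match the target
population transfers information more efficiently than a larger but
mismatched panel. `popdiffr` provides the chain of analyses that makes
this argument quantitative: QC, SNP- and haplotype-level F_ST,
structure PCA/PCoA, major-haplotype cataloguing, and a masked-SNP
imputation benchmark.

## Quality control

`call_rate_filter()` retains markers whose non-missing fraction *strictly
exceeds* the threshold (default 0.95). The strictness is a literal
reading of a "greater than 95%" rule; `strict = FALSE` switches to `>=`.

`hwe_exact_test()` is the two-sided exact test conditional on allele
counts: over all attainable heterozygote counts (same parity as the minor
allele count) we accumulate the probability of every outcome no more
probable than the observed one. Probabilities are computed from the
log-gamma closed form and normalized within the conditional distribution,
so no factorial overflow occurs up to cohort sizes far beyond typical
use. `hwe_filter()` applies the test **within each population** by
default and requires every population to pass: pooling differentiated
populations induces a Wahlund deficit of heterozygotes, so a pooled
filter would preferentially discard exactly the differentiated markers
the analysis is about. A pooled mode (`per_population = FALSE`) exists
for single-population data. Filters are idempotent by construction and
never impute missing genotypes.

`intersect_markers()` keys on `(chrom, pos)` and requires a resolvable
allele match — identical, allele-swapped (coding is flipped to align), or
strand-complemented. A/T and C/G SNPs are dropped by default because
their strand cannot be resolved when datasets come from different
genotyping arrays.

## F_ST estimators

The SNP-level statistic is the Nei-style two-population form
$(p_1-p_2)^2 / (4\bar p(1-\bar p))$, identical to $(H_T-H_S)/H_T$. It is
a *frequency* statistic: no sample-size correction, so with $2n$ sampled
alleles per population it carries an upward sampling bias of order
$1/(2n)$. That is intentional — it matches the conventional definition
used in descriptive population comparisons — and the Hudson estimator
(`snp_fst_hudson()`, or `mean_fst_matrix(estimator = "hudson")`) is
provided when an unbiased estimate is wanted for sensitivity analysis.
Monomorphic-in-pair markers contribute 0 and are included in averages by
default (`drop_monomorphic = TRUE` excludes them); markers with zero
called alleles in either population of a pair are always skipped for
that pair.

`mean_fst_matrix()` averages over all markers of the common map unless a
subset is passed. For real chromosome-6 data the canonical subset is
`markers_in_window(map, "6", 25e6, 35e6)`; we deliberately did not make a
coordinate window an implicit default, because on arbitrary maps it would
silently select nothing.

The haplotype-level statistic is the multi-allelic G_ST over observed
haplotype frequencies, $H_S = \tfrac12\sum_k (1-\sum_h p_{kh}^2)$ and
$H_T = 1-\sum_h \bar p_h^2$. This is the heterozygosity-based form, not
an AMOVA variance decomposition; the two differ by sample-size weighting
terms, and no bit-equality with AMOVA implementations is claimed. With
two haplotype classes G_ST reduces exactly to the SNP formula, which the
test suite exploits as a cross-check.

`top_fst_enrichment()` pools per-pair, per-SNP F_ST records over all
$\binom{K}{2}$ pairs, cuts the top fraction with `ceiling` and a
deterministic tie-break (descending F_ST, then pair, then marker id — the
quantile cut is otherwise ambiguous under ties), and tests the count of
tail records involving a focal population against
Binomial$(n_{top},\,2/K)$, upper tail. The null probability is
$(K-1)/\binom{K}{2} = 2/K$ because each of the $K-1$ pairs containing the
focal population is equally represented under exchangeability.

## Haplotype catalogues and dissimilarity

Regions are 1-based, inclusive on both ends. `extend_region()` adds
symmetric flanks (100 kb is the convention for HLA genes) and clamps at
position 1. The packaged `hla_regions()` table ships the six classical
HLA regions *with flanks already included* — their spans exceed the gene
bodies by roughly 200 kb — so they are used directly; `extend_region()`
is for user-supplied raw gene coordinates.

Distinct haplotypes are ordered by first appearance in row order, making
catalogues deterministic for a given panel; frequencies use
2 × sample-count denominators. Major haplotypes are selected by maximum
per-population frequency with an *inclusive* threshold (a haplotype at
exactly 10% in one population qualifies) and labelled `H1, H2, …` in
descending order of that maximum, ties broken by haplotype string. The
labelling rule is a package convention chosen for reproducibility; any
labelling is defensible since the classes are arbitrary identifiers, not
HLA allele names.

Dissimilarity between two haplotypes is the percent of SNP sites with
different alleles (`100 × Hamming/n`). It is a metric, and every value is
an integer multiple of `100/n` — worked examples: 12, 11 and 1 differing
sites out of 39 give 30.77%, 28.21% and 2.56%. With a single major
haplotype the minimum dissimilarity is undefined and reported `NA`
(rendered "–" in text output). Ancestry-group sharing uses a strict
non-zero frequency criterion: presence in a group means frequency > 0 in
at least one member population.

## PCA and principal coordinates

Genotype standardization centers each marker and divides by
$\sqrt{\hat p(1-\hat p)}$ with the shrunk estimate
$\hat p = (1+\sum g)/(2+2n_{called})$ — the posterior mean under a
uniform prior, which keeps rare-allele denominators bounded away from
zero (`shrink = FALSE` gives the plain frequency). Missing entries become
0 after centering (mean imputation in standardized units), zero-variance
markers are dropped, and columns are re-centered at the end so sample
scores are exactly mean-zero even with missingness. Eigenvector signs are
fixed by making the largest-magnitude loading positive; PCA signs are
otherwise arbitrary and this convention makes runs comparable.

`population_pcoa()` is classical multidimensional scaling:
$B = -\tfrac12 C D^{(2)} C$, eigen-decomposed, coordinates from positive
eigenpairs (via `stats::cmdscale`). F_ST matrices are generally
non-Euclidean, so negative eigenvalues occur; their axes are discarded
and the eigenvalues kept as a diagnostic
(`glance()$negative_eigenvalue_mass`). Whether to double-center squared
distances or eigen-decompose the raw matrix was genuinely open; classical
MDS was chosen because it is the standard, reproducible reading of
"eigen-decomposition of a distance matrix", and it recovers exact
Euclidean configurations to machine precision (a property the tests
assert). A fully degenerate (all-zero) distance matrix returns all
populations at the origin.

## The Li–Stephens copying model

A target haplotype is modelled as a mosaic of the $N$ reference
haplotypes: hidden state = reference row, uniform initial distribution,
per-interval transition "stay with $1-\rho$, else jump to a uniform
row" (the diagonal is included in the jump, so the effective stay
probability is $1-\rho+\rho/N$), emission $1-\epsilon$ on allele match
and $\epsilon$ on mismatch at typed markers, no emission at masked
markers. Posteriors come from the scaled forward–backward recursion,
normalized per marker (the scaling makes 1,600-marker chains numerically
safe; posteriors sum to 1 to 1e-10 by construction). The masked-site
dosage is the posterior expectation of the *emitted* allele,
$\sum_s \gamma_s(\epsilon + (1-2\epsilon)h_{s})$, hence bounded in
$[\epsilon, 1-\epsilon]$; at $\epsilon = 0.5$ the model is uninformative
and every genotype dosage is exactly 1.

Defaults $\epsilon = 0.01$, $\rho = 0.05$ are sensible for
panel-of-hundreds, dense-marker settings; both are configurable and
$\rho$ is deliberately constant per interval (no recombination-map
scaling) — the benchmark compares panels under one fixed model, so only
relative accuracy matters. Targets are imputed as phased haplotypes and
the two haplotype dosages summed; unphased-target imputation would
require phasing, which is out of scope.

The accuracy protocol: one `make_mask()` plan is shared across all panels
and target populations of a run, so differences in discordance are
attributable to panels, not masks. Per masked marker the squared Pearson
correlation between true genotype and dosage is computed across samples;
the discordance rate is $1-\overline{r^2}$ with a per-marker-then-mean
convention (a pooled-pairs mode exists behind `pooled = TRUE`, since the
convention is ambiguous in parts of the literature). Markers with zero
variance in truth or dosage have undefined $r^2$; they are skipped and
counted (`n_skipped`), never scored 0, because an uninformative marker is
not evidence of failure. Note $r^2$ is sign-blind: a perfectly
anticorrelated dosage scores discordance 0; this is a property of the
statistic, documented rather than patched.

## The synthetic-data generator

The generator emulates the study design the package targets: K
populations of ~200 diploid samples at ~1,600 biallelic SNPs in a 10 Mb
window, weak allele-frequency differentiation, shared founder haplotypes
with population-varying frequencies, and held-out target samples (19 per
population by convention) for imputation benchmarking.

Two layers:

* `balding_nichols_freqs()` — ancestral frequency per marker from
  Uniform(0.05, 0.95) (clipped so markers stay polymorphic and F_ST
  estimators well-conditioned), then per-population frequencies from
  Beta$(p(1-F)/F,\,(1-p)(1-F)/F)$. `sample_haplotype_panel()` draws
  linkage-equilibrium haplotypes from these frequencies — the right
  input for SNP-level statistics, where only marginals matter. A note on
  calibration: the *pairwise two-population* Nei F_ST implied by this
  model is approximately $F/2$ on true frequencies (analytically,
  $(H_T-H_S)/H_T$ on expectations equals $(F/2)/(1-F/2)$, since each
  population diverges from the ancestor independently), plus a
  $1/(2n)$ sampling inflation. The recovery tests therefore compare the
  pipeline against a Monte-Carlo oracle that embodies this same model
  rather than against the nominal $F$.
* `founder_mosaic_panel()` — founders drawn from one ancestral frequency
  profile; per-population founder-usage weights from a symmetric
  Dirichlet (concentration small ⇒ skewed, population-specific usage);
  each haplotype a left-to-right founder mosaic with per-interval switch
  probability and per-site mutation. This produces the regime where
  major haplotypes are *shared* across populations but their frequencies
  differ — the structure that gives haplotype-G_ST, major-haplotype and
  panel-comparison analyses their signal. The object returns the true
  expected frequencies $W\!F(1-\mu) + (1-W\!F)\mu$ for convergence
  checks.

A single master seed governs all draws; each operation derives a
deterministic sub-stream (kept below $2^{31}$), so datasets are
bit-reproducible and reference/target splits are disjoint by
construction.

What the generator does **not** emulate: coalescent genealogies and
realistic LD decay, demographic history, genotyping error beyond a flip
rate, allele-frequency spectra with rare variants (frequencies are
clipped), and phasing error (panels are generated phased — statistical
phasing is explicitly out of scope). Passing tests therefore demonstrate
the correctness and calibration of the estimators and the copying model
under controlled conditions, not robustness to real-data artefacts such
as switch errors or array batch effects.

## Problem sizes used in tests and the acceptance script

The differentiation-recovery check uses K = 2, F = 0.01, 200 diploids per
population, 1,607 markers and 50 seed replicates, matched against a
400,000-draw Monte-Carlo oracle; the copying-model check enumerates all
state paths for every configuration up to 4 markers × 3 reference
samples; the panel-comparison check runs 20 replicates of a 2-population,
150-SNP, 60 + 10 samples-per-population design with skewed founder usage
(Dirichlet concentration 0.25), masking 40 SNPs. These sizes were chosen
to keep full runs in the tens of seconds on a single core while leaving
Monte-Carlo error an order of magnitude below the asserted tolerances.

## Known limitations

* The haplotype-level statistic is G_ST, not an AMOVA-based F_ST;
  values on the same data can differ by sample-size weighting.
* `snp_fst()` carries finite-sample bias by design; use the Hudson
  estimator for unbiased point estimates.
* The copying model uses a constant switch probability rather than a
  genetic-map-scaled one; absolute discordance values are therefore not
  comparable to production imputation engines, though panel *rankings*
  are.
* Multi-allelic variants are unsupported throughout (biallelic SNPs
  only), and liftover between genome builds is out of scope.
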