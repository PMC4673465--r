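# popdiffr

Quantify genetic differentiation between closely related populations at
dense SNP regions — the MHC being the motivating case — and measure what
that differentiation costs in genotype-imputation accuracy.

Fine-scale population structure (e.g. between regional cohorts of a single
country) is too subtle for most genome-wide summaries, but it shows up
clearly in three places: allele-frequency differences at individual SNPs,
frequency differences of extended haplotypes at polymorphic loci such as
the HLA genes, and the accuracy of imputing masked genotypes from
reference panels of different ancestry. `popdiffr` implements that whole
analysis chain as composable, tibble-returning functions, plus a
synthetic-data generator so every stage can be exercised and tested
without restricted cohort genotypes.

## What it computes

**SNP-level F_ST.** For two populations with allele frequencies `p1`, `p2`:

    F_ST = (p1 - p2)^2 / (4 p̄ (1 - p̄)),   p̄ = (p1 + p2)/2

equivalently `(H_T - H_S)/H_T` with Nei's expected heterozygosities.
`mean_fst_matrix()` averages this over markers for every population pair,
producing the K × K distance matrix used for population-level principal
coordinates (`population_pcoa()`, classical MDS of the double-centered
squared distances). A Hudson-style sample-size-corrected estimator is
available via `estimator = "hudson"`.

**Haplotype-level F_ST (G_ST).** For a gene region, the distinct phased
haplotypes are catalogued per population (`extract_region_haplotypes()`)
and the multi-allelic index

    G_ST = (H_T - H_S) / H_T,   H_S = mean(1 - Σ p_h²),  H_T = 1 - Σ p̄_h²

is computed from observed haplotype frequencies (`haplotype_gst()`,
`haplotype_fst_matrix()`). Major haplotypes — those reaching a frequency
threshold (typically 10%, or 6% at highly diverse loci) in at least one
population — get dissimilarity statistics (`% of SNP sites differing`,
`min_dissimilarity_table()`) and ancestry-group sharing classification
(`sharing_classification()`).

**Structure analyses.** `subject_pca()` runs PCA on genotypes standardized
per marker by `sqrt(p̂(1-p̂))` with a shrunk frequency estimate;
`average_population_coords()` collapses sample scores to population
centroids; `top_fst_enrichment()` tests whether the top 1% of pooled
per-pair F_ST values over-represents pairs involving one focal population
(exact binomial, null probability `2/K`).

**Imputation accuracy.** `li_stephens_dosage()` implements the
Li–Stephens haplotype-copying HMM (forward–backward over reference rows,
miscopy rate ε, switch rate ρ). The evaluation protocol masks a random
SNP subset (`make_mask()`), imputes each target haplotype from a phased
reference panel, and scores per masked SNP the squared correlation r²
between true genotype and imputed dosage; the **discordance rate is
1 − mean r²** (`evaluate_discordance()`, `panel_comparison()`).

**Synthetic data.** `balding_nichols_freqs()` draws population allele
frequencies around an ancestral frequency with differentiation parameter
F; `founder_mosaic_panel()` builds phased panels where populations share
founder haplotypes at Dirichlet-varying usage frequencies — the regime in
which major haplotypes are shared but their frequencies differ.
`split_reference_target()` produces disjoint reference/target splits.

## Worked example

```r
library(popdiffr)

cfg <- synth_config(n_pops = 3, n_samples_per_pop = 100, n_snps = 400,
                    n_founders = 8, founder_weight_concentration = 0.4,
                    seed = 2024)
ds  <- founder_mosaic_panel(cfg)

fst <- mean_fst_matrix(ds$panel)
tidy(fst)
#> # A tibble: 3 × 4
#>   pop_i pop_j    fst n_markers
#>   <chr> <chr>  <dbl>     <int>
#> 1 pop1  pop2  0.136        400
#> 2 pop1  pop3  0.0770       400
#> 3 pop2  pop3  0.171        400
```

Pairwise mean F_ST of 0.08–0.17 says these synthetic populations are far
more differentiated than typical within-country cohorts (where values of
0.001–0.01 are the norm); the Dirichlet concentration 0.4 gives each
population a strongly skewed founder usage. Embedding the matrix:

```r
population_pcoa(fst, 2)$coordinates
#>         PCo1    PCo2
#> pop1 -0.0288  0.0369
#> pop2  0.0995 -0.0091
#> pop3 -0.0707 -0.0278
```

Haplotype structure at a 2 Mb sub-region, with the nearest-neighbour
dissimilarity of each major haplotype (percent of its 77 SNP sites that
differ from the closest other major haplotype):

```r
region <- gene_region("geneX", "6", 28e6, 30e6)
cat_   <- extract_region_haplotypes(ds$panel, region)
glance(cat_)
#> # A tibble: 1 × 4
#>   region n_snps n_distinct_haplotypes n_populations
#> 1 geneX      77                   366             3
min_dissimilarity_table(major_haplotypes(cat_, 0.10))$min_dissimilarity
#> [1] 37.7 37.7 33.8 33.8
```

Imputation benchmarking — 19 held-out samples per population, 100 of 400
SNPs masked, three reference panels:

```r
sp   <- split_reference_target(ds$panel, 19, seed = 1)
mask <- make_mask(ds$panel$map, 100, seed = 1)
refs <- split(seq_along(sp$reference$sample_id), sp$reference$population)
panels <- list(pop1 = subset_samples(sp$reference, refs$pop1),
               pop2 = subset_samples(sp$reference, refs$pop2),
               combined = sp$reference)
panel_comparison(sp$target, panels, copying_params(), mask)
#> # A tibble: 9 × 6
#>   target_pop panel    n_eval n_skipped mean_r2 discordance
#> 1 pop1       pop1         91         9   0.928      0.0718
#> 2 pop1       pop2         90        10   0.495      0.505
#> 3 pop1       combined     92         8   0.920      0.0798
#> 4 pop2       pop1         78        22   0.876      0.124
#> ...
```

The matched panel (pop1 → pop1: discordance 0.072) beats the mismatched
one (pop1 ← pop2 panel: 0.505) and is competitive with the combined
panel — the qualitative signature of population-specific reference panels
at differentiated loci. Zero-variance masked markers are skipped and
reported in `n_skipped`, not scored.

`autoplot()` methods exist for PCA/PCoA results, F_ST matrices and
major-haplotype sets; `plot_discordance()` charts a panel comparison.
`hla_regions()` ships the six classical HLA region definitions (Build 37,
flanks included) for use on real chromosome-6 data.

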