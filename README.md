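# peakodds

Probabilistic assignment of transcription-factor ChIP-seq peaks to the genes
they most likely regulate.

## The problem

ChIP-seq gives you *where* a transcription factor binds; the biology needs
*which genes* it regulates. The standard shortcut — assign each peak to the
nearest transcription start site (TSS), usually only within ±2 kb — throws
away most binding sites (for many factors only a small minority of sites sit
in annotated promoters) and misses genes regulated by several modest distal
sites. `peakodds` is for regulatory-genomics analysts who want peak→gene
assignment that is learned from the data instead of assumed.

## The model

Every (peak summit, candidate TSS) pair falls into one of **16 location
categories**: the signed TSS distance (positive = upstream in the gene's
orientation) binned at 2 kb / 25 kb / 1 Mb, crossed with a structural
context (upstream; or, downstream: exon, intron, outside the transcript).
For each category *c* the **regulation odds** are learned from the data:

    odds(c) = f_obs(c) / f_null(c)

the frequency of *c* among observed peak summits divided by its mean
frequency under uniform random placement of the same peaks (estimated
separately for + and − strand genes; mean ± SD across the two). Each peak is
then assigned to the candidate gene whose category has maximal odds — with
no distance cutoff — contributing probability `p = odds/(odds+1)`, and a
gene's score integrates all of its peaks by noisy-OR,
`1 − Π(1 − p_i)`, so several weak sites can outrank one moderate site.
The conventional promoter-window method (±2 kb, summed MACS significance
scores) is provided for comparison.

Around this core the package provides PWM motif validation with an exact
best-site null and Bonferroni correction, hypergeometric motif
enrichment/depletion against *empirical* genome frequency, motif spacing and
co-occurrence (χ²) statistics, permutation nulls for feature and TF-overlap
enrichment (mappability-aware, non-overlapping random placement; label
shuffling), and a deterministic synthetic-fixture generator so that the
whole pipeline runs and is tested entirely offline. See the methods
vignette (`vignettes/peakodds-methods.Rmd`) for the full model description.

## Worked example

Simulate a genome with a 5× planted promoter enrichment, learn the odds,
and rank genes:

```r
library(peakodds)

spec <- fixture_spec(seed = 42, n_peaks = 400,
                     category_factors = c("0-2k|upstream" = 5))
fx    <- make_genome(spec)
peaks <- plant_peaks(spec, fx$annotation)$peaks

odds <- learn_odds(peaks, fx$annotation, n_null_replicates = 10, seed = 1)
print(odds)
#> Regulation odds by location category:
#>        bin                       context mean_odds sd_odds
#>       0-2k                      upstream      4.49    0.34
#>     2k-25k                      upstream      0.48    0.20
#>    25k-1Mb                      upstream      0.43    0.04
#>       >1Mb                      upstream       N/A     N/A
#>  -1Mb--25k                        intron       N/A     N/A
#>  ...
```

The planted factor 5 is recovered as learned odds ≈ 4.5 in the 0–2k
upstream category (the planting redistributes mass, so the other categories
sit below 1); categories that are geometrically impossible in this genome
are `N/A`. Then:

```r
assignments <- assign_peaks(peaks, fx$annotation, odds)
ranked      <- score_genes(assignments, mode = "noisy_or")
head(ranked[, c("gene_id", "score", "n_peaks")], 5)
#>    gene_id  score n_peaks
#> 1:   G0100 1.0000      19
#> 2:   G0301 1.0000      20
#> 3:   G0103 1.0000      17
#> 4:   G0125 0.9998       5
#> 5:   G0085 0.9989       4

trad <- traditional_assign(peaks, fx$annotation, window = 2000)
compare_assignments(ranked, trad, 50)
#> [1] 0.58
```

The top genes accumulate many assigned peaks (noisy-OR score near 1), and
the probabilistic ranking overlaps only partially (58% here) with the
±2 kb promoter-window ranking — distal and intronic evidence that the
traditional method discards.

A command-line interface wrapping every step (simulate, learn-odds, assign,
score, traditional, compare, motif-validate, distances, cooccur,
enrich-features, enrich-tf, overlap-test, tss-hist) is installed at
`inst/cli/peakodds`; run it with `--help` for usage. Every output file
records the seed, version and parameters in its header.

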