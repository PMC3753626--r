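---
title: "Probabilistic peak-to-gene assignment: models and methods"
author: "peakodds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic peak-to-gene assignment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakodds)
```

## The problem

A ChIP-seq experiment for a transcription factor (TF) yields thousands of
binding-site peaks, but the scientific question is which *genes* those sites
regulate. The common shortcut — assign each peak to the gene with the nearest
transcription start site (TSS), often only if it lies within an arbitrary
window such as ±2 kb — discards most of the signal: for many TFs only a small
minority of binding sites sit in annotated promoters, and a strong distal
site may well regulate a gene whose TSS is not the nearest one.

`peakodds` implements an alternative: *learn from the data itself* how
informative each kind of peak location is, then use those learned odds to
pick the most plausible target gene for every peak, with no distance cutoff,
and integrate the evidence from all of a gene's peaks into a single score.

## Location categories and regulation odds

Every (peak summit, candidate TSS) pair is described by a signed distance
$d$ — positive when the summit lies upstream of the TSS in the gene's
transcription orientation — and a structural context. Distances are binned
at 2 kb, 25 kb and 1 Mb; downstream positions are further split by whether
the summit falls in an exon, an intron, or beyond the transcript end. Four
upstream bins plus $4 \times 3$ downstream (bin, context) combinations give
exactly 16 categories (`location_categories()`).

For category $c$ the **regulation odds** are

$$ \mathrm{odds}(c) \;=\;
   \frac{f_{\mathrm{obs}}(c)}{\bar f_{\mathrm{null}}(c)}, $$

where $f_{\mathrm{obs}}(c)$ is the frequency of $c$ among observed peak
summits (each classified against its candidate TSS) and
$\bar f_{\mathrm{null}}(c)$ is the mean frequency of $c$ over replicate
uniform random placements of the same number of summits. Odds are estimated
separately for genes on the + and − strands; the reported mean and SD are
taken across the two strand estimates, which makes the SD an internal
consistency check rather than a sampling-theory standard error. A category
with no null mass cannot be estimated and is reported `N/A`; categories that
are geometrically impossible in a given genome (for example an exonic
location more than 1 Mb from the TSS when no transcript is that long) come
out `N/A` naturally.

### The classification circularity, and why learning is single-pass

Classifying a summit requires choosing *which* gene (and which TSS) it is
measured against, and the stated rule — take the candidate whose category has
maximal odds — requires the odds themselves. `learn_odds()` resolves this by
classifying summits against the **nearest TSS** (the uniform-odds special
case) and learning the odds in one pass; the learned table then drives
`assign_peaks()`.

We deliberately do *not* iterate learn→assign to a fixed point by default,
although `max_iter > 1` exposes that refinement. The reason is a
winner-take-all instability: almost every summit in a gene-dense genome has
*some* distant candidate gene in any given distal category, so when the true
odds landscape is flat (as under the null), whichever category's estimate is
highest by Monte-Carlo noise attracts every summit with a candidate in it —
in the observed *and* the null sets — zeroing out the other categories. The
fixed point is degenerate and the calibration property (odds ≈ 1 under
uniform placement) is lost. With a single nearest-TSS learning pass the
estimator is calibrated: on synthetic uniform peaks all estimable categories
recover odds within a few percent of 1, and a planted promoter enrichment
factor is recovered essentially exactly (see the acceptance tests).

### From odds to gene scores

A peak assigned to gene $g$ with category odds $o$ contributes probability
$p = o/(o+1)$, the canonical odds→probability bijection. Per gene, the
contributions of all its peaks are combined (`score_genes()`):

* **noisy-OR** (default): $1 - \prod_i (1 - p_i)$ — each site is an
  independent chance of regulation, so several weak sites can outrank one
  moderate site. This matches the motivating observation that genes
  regulated by multiple modest binding sites should be discoverable.
* **product**: $\prod_i p_i$ — the literal multiply-the-probabilities
  reading; it *penalises* extra sites and is provided for comparison.
* **log-sum**: $\sum_i \log o_i$, a rank-equivalent unbounded variant.

The traditional method (`traditional_assign()`) is retained as the
comparator: peaks within ±2 kb of a TSS are assigned to the nearest gene and
the per-gene score is the sum of MACS significance scores (log-scale, so the
sum is a log-product of p-values). MACS scores deliberately do not enter the
probabilistic score: the learned model describes *location*, and mixing in
peak intensity is left as an explicit hook, off by default.

Ties everywhere break deterministically: smaller |distance|, then
lexicographic gene id, then transcript id.

## Motif statistics

Motif discovery tools report theoretical significance that can badly
overstate enrichment for low-complexity motifs that are simply frequent in
the genome. `peakodds` recomputes significance empirically.

* **Scoring.** A window $w$ is scored by the log likelihood ratio
  $\sum_j \log(\mathrm{PWM}[b_j, j]/\mathrm{bkg}[b_j])$. PWM entries get a
  pseudocount of $10^{-3}$ on read (columns renormalised) so the ratio is
  finite; an ambiguous base contributes the background-weighted column mean
  ratio, i.e. 0 for a normalised column. The default background is the
  0th-order composition of the supplied genome.
* **Best-site p-value.** Under the at-most-one-true-site-per-fragment
  assumption, a fragment of length $L$ is summarised by its best window over
  both strands among $m = 2(L - w + 1)$ tests; the raw p-value of that score
  comes from the null score distribution of the background model and is
  Bonferroni-corrected to $\min(1, m\,p_{\mathrm{raw}})$.
* **The null distribution** is built by column-wise convolution of the
  per-column score distribution. For motif widths up to 10 the convolution
  runs on the exact score support (at most $4^w$ values), so tail
  probabilities agree with exhaustive enumeration of all windows to machine
  precision — this is what makes the enumeration-oracle tests meaningful.
  Wider motifs switch to a discretised convolution with 0.001 score bins.
* **Occurrence counting** tiles regions into 500-bp fragments (one
  occurrence at most per tile) and counts tiles whose corrected p-value is
  ≤ α (default 0.05). Enrichment of a motif in peaks versus the genome is
  then a hypergeometric tail: $k$ of $n$ peak fragments versus $K$ of $N$
  genome tiles, with $P(X \ge k)$ for enrichment and $P(X \le k)$ for
  depletion (`hypergeom_test()`, computed with the stable log-space tails).
  A motif planted densely across the genome background but present only at
  background rate inside peaks is correctly re-called *depleted* even though
  a theoretical E-value would call it enriched — the regression test
  reproduces this phenomenon in kind.

## Spacing and co-occurrence

For *cis*-regulatory module structure, each gene keeps one occurrence per
motif kind — the minimum corrected p, ties to the 5′-most position — and
pairwise signed distances (query start minus datum start, in genome
orientation; the anchor choice is ours, as the convention is not otherwise
fixed) are histogrammed within ±500 bp. Planted offsets of ±50–200 bp are
recovered as histogram modes. Presence/absence co-occurrence across peaks
uses the Pearson χ² on the 2×2 table with 1 df and no continuity correction
(a Yates flag exists); degenerate margins return χ² = 0 with direction
"neither".

## Permutation nulls

All enrichment statements about genomic features are empirical:

* `feature_enrichment()` measures the fraction of mappable peak nucleotides
  covered by a feature and compares it with $n$ random placements of
  intervals of the peaks' *mappable lengths* (our reading of "respective
  mappable lengths"), non-overlapping, uniform in the concatenated mappable
  space. The sampler draws starts uniformly and rejects draws that overlap
  an earlier placement within the replicate (resampling, capped at 1000
  rounds).
* `tf_overlap_enrichment()` computes, per TF, the mean over its peaks of
  (bp overlap with the reference set)/(peak length), and shuffles TF labels
  over the pooled peaks, preserving per-TF counts.
* The empirical p-value is $\max(r, 1)/n$, where $r$ counts null values at
  least as extreme, so the floor is exactly $1/n$: $10^{-5}$ at
  $n = 100{,}000$ placements and a resolution of 0.000025 at 40,000
  shuffles. Under null-generated data the p-values are uniform to binomial
  accuracy.

## The synthetic-fixture generator

`fixture_spec()`/`simulate_dataset()` produce a complete, deterministic toy
dataset: an i.i.d. genome, a multi-exon gene annotation, peaks with planted
per-category enrichment, planted motif sites with configured spacings, a
feature track and a mappability mask — everything needed to exercise the
full pipeline offline, with truth files sufficient to compute every recovery
metric.

Peak planting uses a mixture: with probability $f_c\,q_c$ a summit is drawn
uniformly from category $c$'s territory ($q_c$ estimated from uniform probe
positions), and the remaining mass is uniform over the rest, so the planted
density ratio in category $c$ is exactly the requested factor $f_c$ — the
planting oracle the tests assert against.

The default geometry is a deliberate power calculation: 2 chromosomes of
2.5 Mb; 400 genes of 4–12 kb so that categories requiring more than 25 kb of
intragenic distance are *impossible* (and surface as `N/A`, mirroring how
real compact genomes produce unestimable cells); a first exon of 0.8–1.2 kb
with a first intron of ≥ 2 kb so that both the proximal-downstream exon and
intron categories carry mass; and a central gene-free desert (30% of each
chromosome) whose four edge genes have fixed strands (+ on odd chromosomes,
− on even) so the 25 kb–1 Mb categories are populated for *both* per-strand
estimates. With 2000 peaks this puts at least ~60 observed summits per
strand in every estimable category, which keeps the Monte-Carlo error of an
odds ratio near ±10% — comfortably inside the ±25% recovery bands the tests
use. Test problem sizes (5 Mb genomes, 2000 peaks, 10 null replicates,
100–150 peaks for motif planting) were chosen as the smallest scales at
which these frequencies are stable.

What the generator does **not** emulate: read-level noise and mapping
artefacts, GC or chromatin bias in binding, peak-calling errors, overlapping
genes, and realistic motif degeneracy (planted sites are near-consensus).
Passing recovery tests therefore demonstrate correctness of the estimators
under the stated model, not robustness to every property of real ChIP-seq
data.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open internally; GTF (1-based inclusive) is
  converted on read and on write. Distance bins are half-open on |d|;
  distance 0 belongs to the 0–2 kb upstream bin.
* Context is resolved against the transcript owning the chosen TSS; isoform
  conflicts (exon of one transcript, intron of another) follow the chosen
  transcript only.
* All stochastic operations take an explicit seed and are bit-reproducible;
  the CLI stamps seed, version and parameters into every output header.
* Degenerate cases are defined, not errors: empty annotations classify
  nothing; a chromosome without genes yields an unassigned marker; a
  timepoint with zero DE genes is `NA` in expression profiles; χ² with a
  degenerate margin is 0/"neither"; a PWM equal to its background gives
  corrected p = 1.

## Known limitations

* The learned odds share one table across the genome; no chromatin-state,
  expression or 3D-contact information enters the assignment.
* The per-strand SD on two strand estimates is a coarse dispersion measure;
  with a single estimable strand the SD is reported as 0.
* The best-site model assumes at most one true site per 500-bp fragment;
  tandem sites within a tile count once.
* The label-shuffling null for TF overlap conditions on the pooled peak
  set; TFs with systematically different peak lengths are compared against
  a pooled-length null.
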