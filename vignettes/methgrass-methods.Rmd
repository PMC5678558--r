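---
title: "Methods: two-genotype plant methylome analysis with methgrass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-genotype plant methylome analysis with methgrass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methgrass)
```

# Scope

methgrass analyses plant methylomes of two genotypes measured by
whole-genome bisulfite sequencing (WGBS) and MeDIP-seq. It starts from
per-cytosine methylation call tables (Bismark-style CX reports), GFF3
gene/TE annotation and BED-family interval files, and provides:

* weighted methylation statistics — genome-wide, per feature instance,
  per tiling window, per arbitrary region set, per homeologous gene pair;
* scaled-body + fixed-flank metaprofiles over genes and TE classes;
* a differentially-methylated-region (DMR) caller: per-cytosine Fisher
  exact tests, FDR control, proximity clustering, count/span/effect-size
  filters, cross-context merging;
* feature assignment with hypergeometric overrepresentation tests,
  nearest-TE association and gene extraction near DMRs;
* MeDIP peak summaries (per-Mb densities, common peaks) and BS-seq/MeDIP
  concordance reports;
* a deterministic synthetic two-genotype methylome generator so that every
  stage is testable without any external download.

Read trimming, alignment, peak calling (MACS2), repeat discovery and
collinear-pair identification are upstream of this package: it consumes
their standard outputs.

# The weighted methylation level

For a set of cytosines in one sequence context, the weighted level is

$$ W = \frac{\sum_i m_i}{\sum_i (m_i + u_i)} $$

with $m_i$/$u_i$ the methylated/unmethylated read counts at site $i$.
This is a read-count-weighted statistic, *not* the mean of per-site
levels: a deeply covered unmethylated site pulls $W$ down more than a
shallow methylated site pulls it up, which makes $W$ robust to uneven
depth. The two definitions disagree materially on real data, and the test
suite pins the weighted definition with a fixture where they differ by
more than 0.5. `weighted_level()` is additive over disjoint region sets
(numerators and denominators pool), which the suite also checks.

Defaults: `min_depth = 1` for level computation (a site with no reads
cannot contribute anyway), because the depth-5 gate in the source design
applies to differential testing, not to descriptive levels. The per-site
*distribution* (`level_distribution()`) defaults to `min_depth = 5`,
matching the support used for differential testing; both are arguments.
The distribution uses strict outer bins — low is level `< 0.2`, high is
level `> 0.6`, the middle bin is closed — so a site at exactly 0.2 or 0.6
is intermediate.

# Metaprofiles

`meta_profile()` bins each region into 20 equal body fractions plus 2 kb
flanks cut into 100 bp windows (all configurable; flank length must be a
multiple of the flank bin width). Per-bin levels are count-pooled across
regions, so the profile is invariant to region order, and a
constant-methylation genome gives a flat profile to within 1e-12 —
both properties are tested. Minus-strand regions are reversed so bin 1 is
always 5′; TEs are profiled strand-agnostically unless the annotation
carries strands, since repeat annotations often do not. Regions shorter
than the bin count are handled by fractional assignment
(`floor(bins * offset / width)`). Flank sites are counted even when the
flank overlaps a neighbouring feature: no masking is applied, and users
who want TE-free gene profiles can pre-filter with
`genes_without_intronic_tes()` (a gene is excluded when any intron
overlaps any TE by at least 1 bp). Gene profiles use the gene span (not
the mRNA span); with one representative transcript per gene the
difference is only UTR trimming, and the gene span matches how most
published meta-plots are drawn.

# DMR calling

The caller follows the classic per-cytosine funnel:

1. **Testing.** Every cytosine covered by ≥ 5 reads in *both* genotypes
   is tested with a two-sided Fisher exact test on
   `[[m_A, u_A], [m_B, u_B]]` (`test_dmc()`). The implementation
   enumerates the conditional hypergeometric distribution; probabilities
   within a relative 1e-7 of the observed table's probability count as
   "as extreme", absorbing floating-point rounding. It agrees with
   exhaustive enumeration to better than 1e-10 for all tables with
   margins up to 30 (checked in the suite) and with `fisher.test()` to
   1e-15 on random tables.
2. **FDR.** Benjamini–Hochberg (`bh_adjust()`, delegating to
   `p.adjust`) is applied separately within each context, because power
   differs strongly between CG, CHG and CHH and the funnel is reported
   per context; pooled correction is available via
   `per_context_fdr = FALSE`. DMCs are sites with q < 0.05; direction is
   `hyper` when genotype B is higher, `hypo` when genotype A is higher.
3. **Clustering.** DMCs of one chromosome, context and direction join a
   cluster while consecutive gaps are strictly less than 100 bp
   (`cluster_dmcs()`); a gap of exactly 100 bp splits. Strand is ignored
   for gaps. Clustering by direction is the default because hyper and
   hypo calls are reported separately and mixed clusters would cancel the
   region-level difference; `split_direction = FALSE` disables it.
4. **Filtering.** Clusters need ≥ 4 DMCs *and* a span of ≥ 50 bp
   (conjunctive rule). For survivors, region levels per genotype are
   recomputed over *all* context sites in the cluster span passing the
   same depth gate — the conservative reading; `dmc_sites_only = TRUE`
   restricts to DMC positions. A region is a DMR when the absolute level
   difference strictly exceeds 0.4 (CG), 0.2 (CHG) or 0.1 (CHH).
5. **Merging.** Because differential regions typically co-occur across
   contexts, `merge_contexts()` unions overlapping or book-ended DMRs
   within each direction (never across directions) for downstream
   feature analysis.

Swapping the two genotypes flips every direction and the sign of every
difference while leaving p-values, q-values and boundaries unchanged;
this symmetry is a test. Biological-replicate dispersion is *not*
modelled: the design pools ramets into one sample per genotype, so the
Fisher test treats reads as the unit of replication. Methylome
differences between outbred genotypes also reflect genetic differences
(SNPs destroying cytosines, mapping bias); interpreting DMRs as purely
epigenetic is outside what the statistics can support.

# Feature annotation and enrichment

`assign_features()` gives every region exactly one label by precedence
TE > CDS > 5′UTR > 3′UTR > intron > promoter > upstream\_2kb >
downstream\_2kb > intergenic, where a ≥ 1 bp overlap makes a category a
candidate. The promoter is defined as the 1 kb immediately upstream of
the TSS and `upstream_2kb` as the remaining 1–2 kb band, keeping the two
categories disjoint (the source design names both without defining
either; widths are arguments). Flanks are strand-aware; strandless genes
are treated as plus.

`enrichment_test()` realises the named hypergeometric test on a concrete
sampling unit: the genome is tiled into 100 bp windows, each labelled by
the same precedence, and with $N$ tiles, $K$ of the category, $n$
region-overlapped and $k$ overlapped-of-category, the one-sided p-value
is $P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$. Expected
counts are $nK/N$ and sum to the number of overlapped tiles. Because
regions span several tiles, neighbouring tiles are positively correlated
and the test is mildly conservative under uniform placement — the suite
checks calibration (≈ or below the nominal 5%) and that planted
CDS-only regions put CDS at the minimal p.

`nearest_te()` reports the closest TE (distance 0 when overlapping, ties
to the leftmost), its class and its length; `genes_near()` extracts
de-duplicated genes within 2 kb (inclusive) of a region set, per
direction when given the `merge_contexts()` output.

# MeDIP summaries and concordance

`peak_density()`/`peak_density_from_counts()` compute per-chromosome
total and annotated peak counts and their per-Mb densities, rounded to
two decimals with round-half-even (the R default). "Annotated" means
assigned to a promoter or genic category. `common_peaks()` intersects two
peak sets (≥ 1 bp by default; the overlap requirement is an argument)
and is symmetric. `region_methylation()` builds the per-region ×
per-context weighted-level matrix used for heat maps, and
`compare_genotype_regions()` tests per-context differences with a paired
two-sided t-test by default — each region is measured in both genotypes,
which makes pairing the natural design; an unpaired mode exists.
`dmr_peak_concordance()` reports interval-weighted mean bedGraph coverage
per genotype over each DMR set and counts direction-concordant overlaps
(hyper DMRs vs B-upregulated peaks, hypo vs A-upregulated). Differential
peak calling itself is an input, not reimplemented.

# The synthetic methylome generator

`sim_config()` fixes every study condition; a single seed determines all
four generators (`simulate_genome`, `simulate_annotation`,
`simulate_methylome_pair`, `simulate_medip`) bit-for-bit.

**Genome and annotation.** Independent nucleotides at GC 0.46; two 1 Mb
chromosomes by default — large enough that the default run tests ~0.9 M
cytosines while the whole acceptance workload stays in minutes on one
CPU. Non-overlapping genes (80/Mb; 5′UTR, 2–5 CDS exons with introns,
3′UTR, random strand) and TEs (150/Mb intergenic, lognormal lengths
150–6000 bp, classes Copia/Gypsy/LINE/DNA/Helitron at 25/35/15/20/5%,
plus one intronic TE in 20% of genes).

**Methylation model.** Cytosine positions and contexts are derived from
the simulated sequence on both strands, so context frequencies emerge
from base composition rather than labels. Per-site true levels:

* **CG** is a three-component Beta mixture (low ≈ 0.04, mid ≈ 0.41,
  high ≈ 0.86) reproducing the strongly bimodal per-site CG
  distribution of plant genomes. Component weights depend on the feature
  class (TE sites mostly high, genic sites mostly low), and the
  intergenic weights absorb the residual so the genome-wide marginal
  (0.385/0.085/0.530) is exact whatever the annotation draw.
* **CHG/CHH** are single Betas with feature-class means (TE ≫ genic);
  the intergenic mean is solved so the read-weighted genome mean hits
  the configured target (0.25 / 0.05).
* Methylation dips at gene TSS/TTS (multiplier ramping from 0.15 at the
  boundary to 1 at 300 bp) and elevated CG/CHG in 2 kb Gypsy flanks
  (×1.6) plant the qualitative profile shapes.
* Genotype B's levels are genotype A's scaled by 0.36/0.38 (CG),
  0.24/0.25 (CHG), 0.04/0.05 (CHH) — two closely related genotypes, one
  slightly less methylated.

**Observation model.** Depth is negative binomial (size 5) with mean 22,
*except* at repeat-like sites — high-component CG sites and TE non-CG
sites — where the mean is 11. This is the one structural choice that
deserves emphasis: with equal depth everywhere, "≈ 48% of CG sites
above 0.6" and "read-weighted CG mean ≈ 0.38" are mutually
inconsistent (the mean would be ≈ 0.5). In real data the reconciliation
is mappability: heavily methylated repeats attract fewer uniquely mapped
reads, so they count fully in the per-site distribution but are
down-weighted in the read-weighted mean. The two depth means were
calibrated by simulation against those two published summary targets and
then frozen. Counts are Binomial(depth, level), and both genotypes are
written/returned as standard CX tables that round-trip through
`read_cytosine_report()` with zero rejected rows.

**Planted DMRs.** By default 30 CG regions of 300 bp with ≥ 8 CG sites
(candidates failing the site minimum are re-drawn, with a retry cap). The
less-methylated side is drawn per site from Beta(mean 0.04, conc 2)
truncated to `[0, 1 − Δ]` and the other side is that plus Δ = 0.5,
site-by-site — so the realized regional difference equals Δ by
construction and planted regions emulate epiallele switching between the
unmethylated and methylated modes, which is how discrete DMRs present in
real bisulfite data. Direction (hyper = higher in B) alternates 50/50;
the truth set is returned as a `GRanges` sufficient to score sensitivity
and precision with no external data.

**MeDIP emulation.** Windowed (200 bp) sums of observed per-site levels —
a proxy for the methylcytosines an antibody pull-down captures — pass
through a linear link (base 2, scale 1) to a Poisson coverage; peaks are
merged runs of windows exceeding both an absolute floor (12) and twice
the genome median. A fully unmethylated genome therefore yields no
peaks, and peaks concentrate in TE-rich, methylated sequence.

# What the tests do and do not show

The acceptance suite verifies, on one CPU in a few minutes: exact
arithmetic on the published per-chromosome peak-count table (totals
144,462/102,676; per-Mb cells to the printed precision, which is limited
by the table's 2-decimal chromosome lengths); Fisher/BH/cluster/filter
correctness against independent oracles and hand-computed boundary
fixtures; empirical FDR ≤ 0.05 over 50 null replicates of ~10k sites
(one 25 kb chromosome each); recovery of 100 planted CG DMRs (Δ = 0.5,
flat NegBin depth mean 20, 2 Mb genome) with sensitivity and precision
≥ 0.9 and direction agreement; and emulation of the study-shaped
summaries (CG > CHG > CHH, CG ≈ 0.38/0.36 ± 0.01, TE > genic,
low/high CG bins ≈ 40%/48% ± 2%) on the default 2 Mb configuration.

Passing these shows the *pipeline machinery* is correct and calibrated
on data whose generating process is known. It does not show that the
generator captures real switchgrass data: the synthetic genome has
i.i.d. bases (no true repeats, so "mappability" is imposed, not
emergent), depth is independent across sites, bisulfite conversion is
perfect, there is no genetic divergence between the genotypes, and DMR
effect sizes are homogeneous. Conclusions about real data still require
real data.

# Numerical choices and degenerate inputs

* Fisher "as extreme" comparison uses a 1e-7 relative tolerance;
  p-values are clamped to (0, 1].
* Weighted levels with empty support are `NA` ("missing"), never 0;
  `level_distribution()` on an empty context errors.
* Densities print with round-half-even at 2 decimals.
* `subgenome_pair_comparison()` and `compare_genotype_regions()` report
  p = NA with a note when the pair differences have zero variance (the
  t statistic is undefined); fewer than 2 complete pairs is an error.
* Clustering ties: positions are sorted; equal positions (both strands)
  always co-cluster.
* `nearest_te()` distance ties go to the leftmost TE; chromosomes
  without TEs give `NA` distance.
* All sequences in the input are kept; restricting to a chromosome
  allow-list is the caller's subsetting step.
* The default window for chromosome-scale tracks (`window_track()`) is
  chosen by the caller; 100 kb is a sensible default for plant
  chromosome paintings and is what the examples use.

# Known limitations

No smoothing or HMM-based DMR segmentation; no replicate dispersion
model (beta-binomial over-dispersion would be the next step if
biological replicates were separate); one representative transcript per
gene; no masking of flanks against neighbouring features; MeDIP
differential peak calling and CpG-density bias correction are out of
scope; BIGWIG input is not parsed (convert to bedGraph upstream).
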