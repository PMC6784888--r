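---
title: "Methods: ploidy, recovery and comparative screens for single amplified genomes"
author: "sagkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ploidy, recovery and comparative screens for single amplified genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagkit)
```

## Why this package exists

Most fungal diversity is uncultured, and for obligate biotrophs —
mycoparasitic early-diverging fungi in particular — single amplified
genomes (SAGs) are often the only route to a genome. A SAG workflow
sorts 1 to ~100 cells into a well, amplifies them by multiple
displacement amplification (MDA), sequences, and assembles. Three
analysis questions then dominate:

1. **Ploidy.** Single cells separate within-cell heterozygosity from
   population variation: a heterozygous SNP of a non-haploid individual
   recurs in *every* independent library of that organism, at allele
   fractions set by the copy number. Allele frequency spectra (AFS) and
   k-mer spectra distinguish haploid from non-haploid cells.
2. **Recovery.** MDA drops out long tracts of each genome copy, so a
   single cell yields a partial genome; pooling cells and co-assembling
   libraries recovers most of it. How does completeness scale with cell
   count, and how complete is the union?
3. **Comparative screens.** Partial genomes raise the false-negative
   rate of any single absence call, so metabolic deficiency screens must
   demand *recurrent* absence across independent genomes; phylogenomic
   supermatrices need principled single-copy orthogroup selection; and
   per-library trees need a congruence check against the co-assembly
   tree.

`sagkit` implements all three as a tested pipeline, together with a
synthetic-data generator that produces inputs with the statistical
structure the analyses assume. Everything is exercised end to end on
simulated data; nothing requires downloads.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which the analyses are validated.

### Genome and genotype

`simulate_genome(length, gc, seed)` draws i.i.d. bases at a target GC
fraction. `plant_variants(genome, ploidy_config(ploidy, het_rate,
fixed_rate), seed)` plants two kinds of sites independently per
position:

* **heterozygous** sites carry the alternate allele on `alt_copies <
  ploidy` genome copies — 1 of 2 for diploids (expected allele fraction
  1/2) and uniformly 1 or 2 of 3 for triploids (1/3 and 2/3);
* **fixed** sites (homozygous difference from the reference) carry the
  alternate on every copy.

Each variant's *phase* — which copies carry the alternate — is drawn
uniformly among subsets of size `alt_copies` and fixed at genotype
creation, so every cell of the individual shares it. This matters:
unlinked heterozygous variants in a real non-haploid sit on random
haplotypes, and it is phase averaging within amplification tracts that
lets AFS modes emerge at realistic SNP counts. Ploidy is capped at 3,
the range relevant to single-cell fungal surveys.

### The MDA amplification model

MDA bias is empirical and organism-specific; no published parametric
form exists. The model here is chosen to reproduce its phenomenology —
long covered/dropped tracts per genome copy, large gain differences
between amplified regions — while having closed forms for test oracles:

* per copy and cell, a two-state (covered/dropped) Markov chain along
  positions. With stationary covered probability $p$
  (`covered_prob`) and overall mean tract length $t$ (`mean_tract_bp`),
  covered tracts are geometric with mean $2pt$ and dropped tracts with
  mean $2(1-p)t$; tract lengths are memoryless, so a Bernoulli($p$)
  start makes the chain stationary from the first base and the expected
  covered fraction is exactly $p$;
* each covered tract receives a log-normal gain with unit mean
  (`gain_sigma` on the log scale); site depth is Poisson with mean
  `mean_depth` times the gain;
* base calls follow the copy's allele and miscall to a uniform other
  base with probability `error_rate`.

`independent_sites = TRUE` replaces the tract chain by i.i.d. per-site
coverage; the union of $k$ independent single-cell libraries then covers
a site with probability exactly $1-(1-p)^k$, the oracle used by the
closed-form recovery tests. (With tract structure the *marginal* union
probability is the same, but site correlation inflates the variance of
the observed fraction, so the closed-form check uses the independent
variant.)

Defaults, chosen once as a realistic operating point and not revisited:
`covered_prob = 0.7`, `mean_tract_bp = 2000` (kilobase-scale MDA
dropout tracts), `gain_sigma = 0.6` (moderate per-tract spread; the
extreme inequality of MDA coverage is carried by the dropout state),
`error_rate = 0.005` (Illumina scale), `mean_depth = 30` per covered
copy. A 10-cell library of a diploid at these defaults has mean site
depth around $10 \times 2 \times 0.7 \times 30 \approx 420$.

### What the generator does *not* emulate

Contaminating reads (removed upstream by screening in a real pipeline),
read-level artefacts (qualities, adapters, indels), repeats and
assembler behaviour (collapse, scaffolding, length filtering of an
actual assembler), and GC-coverage coupling. Tests passing on this
generator show the *analysis logic* is correct under the stated
statistical model; they do not certify performance on real MDA data,
whose dropout law must be fitted by the user if mimicry is needed.

## Variant calling and the heterozygous band

`call_variants()` emits one single-nucleotide call per site with total
depth ≥ 5 where the best non-reference base has ≥ 2 reads and ≥ 1% of
the depth — the pooled-frequency filter set used for SAG libraries
(MNPs and complex events are out of scope). `partition_calls()` then
splits calls by allele frequency: heterozygous means $0.25 < \text{AF} <
0.95$ (the lower bound is strict: AF exactly 25% is discarded), fixed
means $\text{AF} \ge 0.99$. The upper bound of the band is the
package's own choice: fixed differences at 100% frequency are analysed
separately (intraspecific fixed-difference sharing), so the band needs a
ceiling; both bounds are configurable.

Callable bases (sites at calling depth) are tracked per library so that
all densities are *per callable megabase*, making thresholds portable
across genome sizes.

## Ploidy classification

`classify_ploidy()` takes the heterozygous AFS and the heterozygous
density and applies, in order:

* **haploid** when density < 50 per callable Mb and the spectrum shows
  no interior peak;
* **triploid** when peaks lie within ±0.05 of both 1/3 and 2/3;
* **diploid** when the *dominant* (highest) peak lies within ±0.05 of
  1/2;
* **unknown** otherwise, including when the diploid and triploid
  patterns hold simultaneously — ties are never guessed.

The ±0.05 tolerance is the allele-fraction noise scale at depth ~30.
Peaks are trusted only when the spectrum holds at least 25 calls: below
that, a haploid's few error-derived calls produce spike histograms with
no mode information. A k-mer spectrum, when supplied, is reported as
corroborating evidence (a heterozygous mode near half the
homozygous-mode multiplicity), but AF evidence decides.

### Peak detection design

AFS at desk scale (a few hundred SNPs, dispersion inflated by
amplification gains) defeat naive argmax peak-picking, so
`detect_peaks()` is built in three stages:

1. moving-average smoothing (half-width `bandwidth` bins) and local
   maxima filtered by **topographic prominence** — height above the
   higher saddle toward strictly higher terrain — relative to the global
   maximum. Prominence, not raw height, is what rejects shoulder lobes
   and valley bumps of one broad mode;
2. flat-kernel **mean-shift** refinement of each maximum, merging fixed
   points that land within half a shift window of each other;
3. a **cluster-mean polish**: bins are assigned to their nearest mode,
   each mode moves to its cluster centroid, and low-mass clusters are
   dropped. Cluster means average over all the histogram's mass and are
   far more stable than argmax positions. For a mode within 0.15 of a
   support edge (the 1/3 mode sits one standard deviation above the
   0.25 cut), the centroid uses only the part of the cluster symmetric
   about the mode inside the support, removing the truncation bias that
   would otherwise drag it away from the edge.

The classification defaults (`bandwidth = 3` bins of the 0.02 spectrum,
prominence 0.15) balance valley preservation between the 1/3 and 2/3
modes against noise; they were calibrated on simulated spectra at the
package's validation scale.

In replicate experiments the 10-cell library of each replicate is
classified (the deepest callable fraction, as one would use the most
complete libraries of a real survey); 1-cell libraries feed the sharing
and recovery analyses.

### Sharing across libraries

`shared_het_analysis()` counts heterozygous calls matching on (position,
alternate) for every pair of libraries and the number of calls present
in ≥ 2 libraries. Genome-wide counts of roughly >10,000 shared SNPs for
suspected diploids versus <2,000 for haploids correspond, at a 40-Mb
genome, to the package's per-callable-Mb defaults: non-haploid above
250/Mb, haploid below 50/Mb. Whether such bounds should be read as
pairwise or ≥2-of-n counts is not settled; both are reported.

## Genome recovery and completeness

Coverage masks (depth ≥ `min_depth`, inclusive) stand in for per-library
assemblies; the co-assembly is modelled as their positionwise union,
which is provably at least as complete as every input. Completeness is
proxied by **marker recovery**: non-overlapping intervals standing in
for core eukaryotic marker genes count as recovered when ≥ 70% of their
length is covered (inclusive; configurable). This mirrors a
completeness estimator's "complete gene" notion without reimplementing
one — a real estimator's partial-alignment semantics, and everything an
assembler does between coverage and contigs, are out of scope, which is
the proxy's fidelity limit. Assembly size is proxied by covered base
count, preserving the completeness-size relationship without an
assembler; `completeness_size_correlation()` reports its Pearson r. The
incorporated-read fraction is the fraction of a library's reads lying
in the union mask (trivially 1 at `min_depth = 1`; informative for
stricter masks).

## Comparative screens

**Deficiency screen.** An enzyme is *core* when present in at least
$\lceil 0.75\,n_{\mathrm{free}} \rceil$ free-living species — exactly 18
of a 24-species panel — and a *deficiency* when additionally absent
from ≥ 5 target genomes. The ceiling rule reproduces the 18-of-24
semantics exactly; recurrence across targets guards against
false-negative absences from partial SAGs. The packaged
`fig_deficiency_fixture()` transcribes the presence/absence of ten
enzyme classifications (sulfate assimilation, thiamine and biotin
metabolism, spermidine-adjacent citrate reactions) across the eight
uncultured target fungi; nine of its ten enzymes are flagged, citrate
synthase (EC 2.3.3.1, present in all targets) is not.

**CAZyme-to-protease ratio.** Ordinary least squares of total CAZyme on
total protease counts per lifestyle via `stats::lm`. A lifestyle's trend
line is excluded with fewer than 3 species or $r^2 < 0.3$; the $r^2$
floor is configurable because no canonical cut-off exists.

**Orthogroup selection.** A cluster enters the supermatrix iff every
present genome has exactly one copy, at most 8 panel taxa are missing,
and at least 3 are present. Supermatrix missing-data statistics are
length-weighted per taxon, with group medians (e.g. partial single-cell
genomes versus others).

**Ancestral gains and losses.** Unit-cost Sankoff dynamic programming —
equivalent to Fitch on binary trees and well defined on multifurcations
— computes the parsimony-minimal change count per character and the MPR
(most-parsimonious-reconstruction) state set of every node. A branch is
a definite gain or loss only when both endpoint states are unambiguous
across all optimal labellings; ambiguity is surfaced, never resolved
silently. On a rooted binary tree a character confined to one clade
always admits an equally parsimonious loss-side rooting, so definite
lineage gains/losses relative to a reference ancestor require pinning
that ancestor's state (`ancestor_state`), which is how gains and losses
relative to an ancestral node are counted.

**Tree congruence.** Robinson–Foulds distance is computed from scratch:
both trees are pruned to shared leaves, unrooted, and their nontrivial
bipartitions compared as canonical sets. Because "incongruent for a
taxon" has no standard operationalisation, congruence is defined as an
identical sister group of the focal taxon — the leaves of the smallest
clade containing it, minus itself — in both pruned trees; RF is
reported alongside for transparency. Topology changes away from the
focal taxon do not make its placement incongruent.

## Numerical and degenerate-input choices

* Positions are 0-based half-open internally; VCF output is 1-based;
  round trips are exact (AF is recomputed from AO/DP on read).
* All boundary thresholds are inclusive or strict as documented:
  depth ≥ 5 callable, AF > 0.25 heterozygous (strict), coverage > 0.9
  for the fixed-difference gene gate (strict), scaffold length ≥ 2000
  retained (inclusive), marker recovery ≥ 0.70 (inclusive).
* Empty inputs return empty, typed results (empty call sets, all-zero
  spectra, empty selections); errors are reserved for contract
  violations (length mismatches, empty isolate sets, degenerate
  variance in correlation/regression, unrooted trees, missing leaf
  states).
* Every stochastic function takes an explicit seed and is
  bit-reproducible under it.

## Validation scale

The test suite validates the pipeline at a desk scale chosen to keep
the full run within a few minutes: 100-kb genomes, heterozygosity
0.005/bp, per-copy depth 30, sequencing error 0.005, 20 fixed-seed
replicates per ploidy for the recovery experiment, and 10 seeds for the
recovery-monotonicity experiment; oracle-equivalence checks run brute
force on ≤ 8-leaf trees and 1,000-cluster instances. At this scale a
triploid spectrum holds roughly 500 heterozygous SNPs — enough for the
mode structure to be resolved in ~95% of replicates; individual
replicates with washed-out spectra are labelled unknown rather than
misassigned.

## Known limitations

* The MDA model's parameters are free; nothing fits them to real data.
* The completeness proxy ignores assembler behaviour; real "assembly
  size" reflects repeat collapse and scaffold filtering that coverage
  masks cannot capture.
* k-mer spectra are computed exactly from sequences/pseudo-reads; there
  is no error-k-mer model, so they serve as corroboration only.
* Only SNVs are modelled; indels, MNPs and complex events are out of
  scope end to end.
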