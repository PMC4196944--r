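---
title: "Detecting domestication sweeps from Pool-seq data with poolsweep"
author: "poolsweep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting domestication sweeps from Pool-seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Domestication and artificial selection leave characteristic footprints in a
genome: around loci under strong selection, a favoured haplotype rises to
fixation and drags linked variation with it, producing local troughs of
heterozygosity (hard selective sweeps). In aquaculture and livestock
species these signatures can be located by comparing pooled whole-genome
sequencing (Pool-seq) of domesticated strains against a wild population:
allele frequencies are estimated directly from read counts over a pool of
individuals, without individual genotypes.

poolsweep implements that comparison as a complete, tested pipeline:

1. **Read trimming** (`mottTrim`, `qcFilter`) — quality trimming by a
   modified-Mott running sum.
2. **SNP identification** (`callCandidates`, `applyFilter`,
   `criteriaGrid`) — candidate calling from per-pool nucleotide counts
   (sync format) and a three-factor quality filter with an optimization
   grid.
3. **Differentiation** (`findSignificant`) — per-SNP two-tailed Fisher's
   exact tests of domestic versus wild allele counts with FDR correction.
4. **Sweep scanning** (`windowHp`, `callSweeps`, `annotateSweeps`) —
   windowed pooled heterozygosity over the significant SNPs, and calling
   of low-heterozygosity regions.
5. **Synthetic data** (`simulationConfig`, `simulateFrequencies`,
   `simulateCounts`, `simulateFastq`, `makeAnnotation`) — a generator
   with known ground truth against which every stage is validated.

The central containers are Bioconductor objects: `PoolCounts` and
`SnpCatalog` extend `RangedSummarizedExperiment` (sites × pools), and
windows, sweep regions and gene features are `GRanges`.

## Read trimming

Each base quality $Q$ is converted to its error probability
$P(Q) = 10^{-Q/10}$ and compared with the threshold quality $A$ (default
$A = 20$, i.e. a 1% error rate): the per-base value $v = P(A) - P(Q)$ is
positive for bases better than $A$. A running sum of $v$ is accumulated
along the read and the retained region runs from the first position where
the sum becomes positive to the position of its maximum.

Two details of that rule are underdetermined and were fixed as follows:

* **Clamping.** The running sum is clamped at zero when it goes negative
  (the standard modified-Mott behaviour). Without clamping, a short
  low-quality prefix accumulates an arbitrarily deep deficit that a long
  high-quality core may never climb out of, so whole good reads would be
  lost to a few bad leading cycles. `trimConfig(clamp = FALSE)` gives the
  literal unclamped reading for comparison.
* **Ties at the maximum.** The rightmost position attaining the maximum
  ends the retained span, so bases with $Q = A$ exactly (value zero) are
  kept rather than discarded.

After trimming, reads shorter than 30 bp are dropped, as are reads whose
retained span contains an ambiguous base (N). We read the separate
"quality score < 20" clause of the trimming protocol as the running-sum
threshold itself, not an additional whole-read mean-quality filter; an
optional mean-quality floor (`trimConfig(meanQuality = )`) is provided
but off by default.

## SNP identification and the three-factor filter

Candidate SNPs are called from A/C/G/T read counts summed over the
in-scope pools (the whole pool set for the combined catalogue; single
pools for per-strain catalogues). The highest-count allele is the major
allele, the second the minor, with ties broken alphabetically so results
are deterministic. A site is a candidate when the summed minor count is
at least 2 — the relaxed floor used to obtain all potential SNPs. N and
deletion counts are carried through the sync format but never form
alleles, and strand is ignored throughout.

The catalogue is strictly biallelic: a site is dropped when its
third-ranked allele reaches the minor-count floor, because read support
at that level is no longer credible as sequencing error. Below the floor,
third-allele reads are treated as noise.

Quality filtering applies three factors:

| factor | default | units |
|---|---|---|
| minimum total depth | 30 | reads |
| maximum total depth | 300 (or a `"top2%"` quantile spec) | reads |
| minimum minor allele count | 5 | reads |

Depth bounds exclude repetitive or collapsed regions (too deep) and
poorly covered sites (too shallow); the minor-count floor removes
error-driven singletons and doubletons. `criteriaGrid` evaluates a list
of criteria sets on one candidate catalogue, reporting the SNP count and
the *percentage of reads included* — defined as depth-weighted site
coverage retained (summed depth of sites passing the depth bounds over
summed depth of all sites). The depth-weighted definition is the one
under which a maximum-depth cut just below the mean coverage removes
almost all coverage while barely moving the SNP count, which is the
qualitative behaviour the optimization grid is designed to expose.
Whether the published per-strain totals used per-pool or combined depth
thresholds is not documented; both scopes are supported (combined is the
default for the catalogue, per-pool for strain classification), and the
summed-across-pools reading of the minor-allele count is used for the
combined catalogue.

Strain classification uses per-pool calling: a *common* SNP is
polymorphic in every pool; a *strain-specific* SNP is polymorphic in
exactly one pool while every other pool has qualifying depth and stays
below the minor-count floor there. Sites failing depth in any other pool
cannot be certified monomorphic and are reported as unclassifiable
rather than strain-specific.

MAF spectra use left-open, right-closed bins ((0–5], (5–10], (10–20], …,
(40–50]%), with the count of SNPs at exactly 0.5 also reported
separately (it remains inside the last bin, so bin counts conserve the
total).

## Differentiation testing

For each SNP the 2×2 table of major/minor allele reads in (domestic,
wild) is tested with a two-tailed Fisher's exact test. The four domestic
pools' counts are summed into one margin by default — a single published
significant-SNP list implies one test per SNP — and a per-strain mode
(smallest q across strains) is available. Two-sidedness follows the
classical convention of summing all tables (given margins) whose
probability does not exceed the observed table's. The implementation is
a vectorised hypergeometric enumeration (via `dhyper`) so 10^5 SNPs test
in under a second; it is cross-checked in the test suite against both an
independent `lchoose`-based enumeration and `stats::fisher.test`.

The test treats *reads* as the sampling units, as the pooled design
dictates; reads from one individual are not independent draws from the
population, so p-values are anti-conservative relative to an
individual-based test. This pseudo-replication is inherent to Pool-seq
differentiation testing and is partly absorbed by the FDR threshold.

Multiple testing uses Benjamini–Hochberg (the specific FDR flavour is
not documented in the source protocol; BH is the standard choice), with
Benjamini–Yekutieli available via `fdrMethod = "BY"`. Significance is
q ≤ 0.01.

Significant SNPs are categorised as *coding* (inside a coding interval),
*near-coding* (outside, but within 100 bp of a coding interval — the
boundary is inclusive at exactly 100 bp), or *non-coding*. The three
categories always partition the input. `chromosomeBins` tabulates
significant SNPs in 200-kb bins per chromosome, reporting SNPs on
unanchored sequences separately.

## The pooled heterozygosity scan

For windows tiled along each chromosome,

$$H_p = \frac{2\,\Sigma n_{MAJ}\,\Sigma n_{MIN}}
            {(\Sigma n_{MAJ} + \Sigma n_{MIN})^2}$$

where $\Sigma n_{MAJ}$ and $\Sigma n_{MIN}$ sum the major and minor
allele reads of all significant SNPs in the window over the domestic
pools. $H_p$ is 0.5 when major and minor reads balance and 0 at complete
fixation. Scores are reported as $-\log_2 H_p$, with $H_p = 0$ assigned
the cap value 7 (the published convention for plotting windows with
infinite transformed score); regions are ranked by raw $H_p$, so capped
windows rank first regardless of the cap chosen.

Design choices where the published description is open:

* **Window step.** "Sliding window" with no stated step is implemented
  as non-overlapping 20-kb tiles (step = window size); the published
  count of ~23,000 evaluated windows on a ~1-Gb genome is consistent
  with tiling, not a 1-bp slide. `step` permits overlapping scans.
* **Pool scope.** $H_p$ sums reads over the four domestic pools (the
  scan looks for fixation *in the domesticated populations*); the wild
  pool never contributes. Per-strain scanning is available by passing
  `pools =`.
* **Orientation.** Major/minor is recomputed per SNP within the domestic
  counts rather than inherited from the catalogue-wide orientation, so
  $H_p$ reflects the scanned population's allele balance (and stays in
  [0, 0.5] by construction).
* **Tiling restarts at each chromosome/scaffold**, from its first base.

Windows with fewer than five significant SNPs are omitted (too little
information to score), and windows with transformed score ≥ 4
(inclusive) are merged into sweep regions when adjacent or overlapping.
Genes overlapping a region by any amount are attached; regions without
genes keep empty lists.

## The synthetic-data generator

The generator emulates the study design the pipeline assumes: **4
domestic pools + 1 wild pool** of **30 diploid individuals** each,
**30X** mean coverage per pool, one polymorphic site per **116 bp**, and
a per-base sequencing error rate of **0.002** (a typical Illumina
post-filter rate; errors are applied read-wise after allele sampling so
that the minor-allele-count filter faces genuine false positives).

* Polymorphic sites are placed by geometric (memoryless) spacing.
* The wild minor allele frequency is drawn from a spectrum with density
  proportional to $1/f$ on $[1/(2N), 0.5]$ — the shape of the standard
  neutral site-frequency spectrum, concentrated at low MAF — and the
  alternate allele is oriented at random.
* Each domestic pool's frequency is drawn from a Balding–Nichols Beta
  distribution around the wild frequency with differentiation parameter
  `driftC` (default 0.05, moderate strain divergence). The
  Balding–Nichols form was chosen for its closed-form checkability; a
  single-founder-generation binomial bottleneck model is provided as an
  alternative (`driftModel = "bottleneck"`).
* Inside planted sweep regions, every domestic pool is fixed for the
  wild major allele (frequency exactly 0 or 1, identical across pools)
  while the wild pool stays polymorphic — the idealised hard-sweep
  geometry.
* Read counts are Poisson depths with binomial allele sampling.
* Monomorphic background sites are emitted at density 1/500 bp.
  Emitting every genome position would dwarf the polymorphic signal at
  no analytic benefit; this density suffices to supply error-driven
  false candidate SNPs so that filter comparisons (strict versus relaxed
  criteria) are exercised against real noise.

The default genome is 10 Mb over 5 chromosomes (~86,000 SNPs — large
enough for stable window statistics, small enough to simulate in
seconds) with three planted sweeps of 40–60 kb aligned to window
boundaries. The synthetic annotation places non-overlapping 2-kb genes
uniformly and arranges that some sweeps contain genes and some do not.

**What the generator does not emulate:** linkage disequilibrium and
haplotype structure (sites are independent), mapping artefacts and
reference bias, repetitive-region depth pile-ups, indel alleles, and
soft sweeps. Passing the recovery tests therefore demonstrates that the
statistics are computed correctly and that the pipeline detects
idealised hard sweeps at realistic depth and error — not that it is
robust to alignment artefacts in real data.

## Numerical and degenerate-input conventions

* Fisher p-values use the `fisher.test` relative tolerance
  ($1 + 10^{-7}$) when comparing table probabilities; tables with a zero
  margin return p = 1 with a warning.
* Quantile max-depth specs resolve with the default (type-7) quantile.
* Allele ties break alphabetically (A < C < G < T); windows with zero
  total reads report $H_p = 0$.
* Empty inputs propagate: empty FASTQ → empty read set, empty sync →
  0-site `PoolCounts`, no windows above threshold → empty region set.
* All coordinates are 1-based closed inside the package (the GRanges
  convention); sync and GFF3 convert trivially, BED converts at the I/O
  boundary via rtracklayer.

## Validation scale

The test-suite and acceptance-script runs use desk-scale problem sizes
chosen as the package's own validation design: 10-seed sweep-recovery
replicates on the 10-Mb default genome, a ~10^5-site panel for filter
monotonicity, ~10^4 null SNPs for FDR calibration, and exhaustive Fisher
enumeration for margins up to 30. Genome-scale inputs (hundreds of
gigabases of reads) are handled by the same code paths but are outside
the scope of the bundled validation.

## Known limitations

* Allele frequencies are read-count ratios; no model-based (e.g.
  likelihood) pool frequency estimation is provided.
* No FST or haplotype-based differentiation statistics; the scan detects
  hard sweeps only.
* Paired-end mate synchronisation and adapter detection are out of
  scope for the trimmer, which expects adapter-trimmed input.
* BAM/pileup input is not parsed; counts enter via the sync format.
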