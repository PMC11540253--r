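---
title: "Models and methods behind BarSeqFit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind BarSeqFit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BarSeqFit)
library(SummarizedExperiment)
```

BarSeqFit analyses pooled competition experiments with barcoded transposon
mutant libraries (RB-TnSeq). This vignette explains the underlying models,
the parameters that matter, what the synthetic-data generator does and does
not emulate, and the design decisions taken where the methodology left
choices open.

## The competition model and its inversion

Each mutant clone carries a transposon with a random 20-nt barcode. The
pool grows under a controlled regime and is sampled at fixed numbers of
population doublings (generations) *g*; barcode abundances are read out by
amplicon sequencing.

The forward model implemented in `simulateCompetition()` assigns every
barcode a relative fitness *w*, defined as doublings per population
doubling (neutral *w* = 1). Frequencies evolve as

$$p_i(g) = \frac{p_i(0)\, 2^{g w_i}}{\sum_j p_j(0)\, 2^{g w_j}},$$

and sequencing is one multinomial draw of size `depth` per sample. For a
rare mutant on a mostly-neutral background the denominator is close to
$2^g$, so the expected log2 fold change is

$$\Delta_i(g) \approx g\,(w_i - 1).$$

This definition of *w* was chosen precisely because it makes the scorer's
inversion exact in expectation: `estimateGrowthRate()` maps
$\Delta \mapsto \mu = \mu_{pop}(1 + \Delta/g)$, and with
$w = \mu/\mu_{pop}$ the round trip is the identity. The neglected
correction term — the pool's own composition shift — is below 1% relative
error while each mutant is ≲ $10^{-4}$ of the pool, the regime a
60,000-clone library operates in.

Strictly essential genes never yield viable mutants; the generator models
essentiality as the *absence* of insertions, so such genes are missing from
the fitness table rather than scored at some extreme value.

### Feeding regimes

Continuous feeding (chemostat-like, growth-rate selective) adds no noise
beyond multinomial sequencing. Pulsed feeding (substrate pulses, yield
selective) additionally passes the population through a dilution bottleneck
at each pulse: a multinomial survival draw retaining `bottleneckFrac`
(default 0.062, the 4 mL / 65 mL pulse geometry of the emulated reactor
setup) of `popSize` simulated cells, once per doubling. This is a
deliberate abstraction — a real pulsed reactor dilutes gradually — but it
reproduces the qualitatively important feature, extra drift in pulsed
trajectories, which the tests assert. Both the fraction and the population
size are configurable because the true effective bottleneck of any given
reactor is rarely known.

### Initial abundances and sequencing noise

Real libraries are uneven; initial barcode abundances are drawn once per
library from a log-normal (`p0Sdlog = 0.5`, a typical spread for
conjugation-built pools) and shared across samples, so replicate T0
columns resample the same pool. Sequencing noise is multinomial only: no
PCR-jackpot or index-hopping model. That is the simplest model consistent
with the scorer's assumptions, and it means the generator's noise floor is
a *lower bound* on real-data noise — passing recovery tests here shows the
estimators are correct and well-calibrated, not that real libraries will
reach the same precision.

## Read structure, extraction, and mapping

BarSeq reads are `leftFlank + N20 + rightFlank` (the two universal priming
sites around the random barcode); TnSeq junction reads additionally carry
genomic sequence downstream of the insertion point. `extractBarcode()`
finds the left flank allowing at most `maxMismatch` substitutions (no
indels — the amplicon is fixed-length, so indel tolerance buys nothing),
takes the next 20 bases, and verifies an anchor of the right flank
(default 6 nt) under the same budget; the leftmost acceptable placement
wins. Unknown barcodes are dropped by default because the library is
pre-mapped; an optional Hamming-distance-1 collapse onto a unique known
neighbour recovers most reads at ~1% substitution error when combined with
a 1-mismatch flank budget.

Counts are raw read counts: the protocol's reverse-primer UMI is not used
for deduplication, since the emulated workflow describes no UMI-collapse
step.

`mapInsertions()` locates the genomic tail by exact substring search
against both strands of every replicon. At desk scale (mega-base genomes,
thousands of barcodes) exact search is complete and dependency-free; a
full aligner would only add value for error-tolerant mapping of real
reads, and a hook for one can wrap the same interface. A barcode is
`unique` when all reads agree on one locus within a 3-bp jitter window or
when at least 75% of them do (majority vote); `ambiguous` when a tail hits
multiple loci or reads disagree; `unmapped` otherwise. Ambiguous barcodes
are excluded from scoring entirely rather than fractionally assigned, to
avoid double counting. The insertion position convention is the first
genome base after the transposon junction, 1-based.

`assignGenes()` accepts an insertion for a gene only if its strand-aware
relative position lies in the central window (default (0.1, 0.9)):
insertions in the terminal 10% of a coding sequence often leave function
intact. The window is configurable; the default follows common RB-TnSeq
practice.

## Fitness scoring

`normalizeCounts()` adds a pseudocount (default 0.5) before frequencies
and logs. The pseudocount keeps washout mutants finite and biases very
large |Δ| towards zero — a conservative direction. `geneFitness()` takes
the unweighted mean of barcode Δ per gene within each replicate, averages
replicates, and centers each condition by its median over scored genes.
Median-centering anchors "typical gene = neutral" without assuming a
reference gene set. The mean over barcodes is unweighted: T0 filtering
(`filterCounts()`, default minimum mean T0 count of 10) already removes
the unstable low-count barcodes that a count-weighted mean would exist to
down-weight.

Scoring uses the *g* = 8 samples by default; later generations are scored
by a second call and reported separately, because washout saturates |Δ|
at high *g* and the eight-generation snapshot is the cleanest
quasi-linear regime. Significance is |*f*| ≥ 2 (inclusive) in any
condition at *g* ≥ 8.

## Clustering and enrichment

`clusterGenes()` runs Ward-linkage (`ward.D2`) hierarchical clustering on
Euclidean distances of raw fitness profiles. No row scaling is applied:
fitness values already share a common (log2) scale, so scaling would
inflate noise for flat profiles. Missing cells are imputed to 0 before
clustering — missing means "not scored", and neutral is the closest
assumption — with the imputed count logged. The cluster number is chosen
to maximize mean silhouette width over `kRange` (default 2–12, a
declared default since nothing forces a particular scan range), ties going
to the smaller k. Identical-profile degenerate input is refused rather
than silently assigned, because silhouette width is undefined there.

`enrichClusters()` is a plain hypergeometric over-representation test:
with a universe of *N* genes, a pathway of *K*, a cluster of *n* and
overlap *x*, $p = P(X \ge x)$, $X \sim \mathrm{Hypergeom}(N, K, n)$. It
consumes a two-column gene→pathway table, so no database client is
needed. P-values are reported raw — they are used as a ranking statistic
for the top pathways per cluster — with a BH-adjusted column alongside
for convenience.

## The operon-aware protein-cost model

The protein-cost hypothesis: protein synthesis capacity is limited, so an
idle enzyme is a burden whose removal can buy growth rate. The
*individual* cost of a knockout is the proteome mass fraction ψ of its
product; the *total* cost adds every co-silenced protein.

`affectedGenes()` computes the co-silenced set assuming fully polar
transposon insertions: the gene, everything downstream in its
transcription unit, and — iterated to a fixed point — every unit whose
promoter depends on a regulator inside the set. In-frame deletion mode
(`mode = "inframe"`) removes the polar spread but keeps regulator-loss
propagation, since a markerless deletion of a regulator still silences
its targets. The regulator graph must be acyclic (validated at
construction); the hydrogenase circuit this models is acyclic.

The packaged hox/hyp fixture encodes the membrane-bound hydrogenase
operon (P_MBH: hoxK…hoxV), the soluble hydrogenase operon (P_SH:
hoxF…hypF2), the regulatory hydrogenase unit (P_RH) and the primary hyp
operon with the master regulator hoxA as its last gene; hoxA activates
P_MBH and P_SH. Placing hoxA inside the hyp unit encodes the
hypothesis-derived dependency that primary hyp knockouts also silence
hoxA — which makes a hyp knockout free the same downstream mass as a
hoxA knockout, the observed pattern. The mass-fraction table is
**synthetic** (file `hoxhyp_mass_fractions_synthetic.tsv`): values are
shaped like the real proteomics (MBH genes lowly expressed, SH
intermediate-to-high, hyp moderate) but are not measured numbers; a real
mass-fraction table in the same format is a drop-in replacement. With
this shape the model reproduces the expected knockout ordering
total(hoxA) > total(hoxF) > total(hoxK).

## Growth phenotyping

`maxGrowthRate()` slides a 5-h window (the standard choice for 15-min OD
sampling) one sample at a time — "sliding" with no stride loses nothing
and maximizes resolution — and fits the least-squares slope of ln OD
against time in each window; the maximum slope is μ_max. Windows are
defined by time span, not point count, so gaps in a series shrink a
window's support instead of shifting its extent. Natural log is used so
the slope *is* μ; OD is assumed blank-corrected upstream. The estimate is
exact on exponentials and invariant to positive scaling of the series.

`biomassYield()` is the direct formula DCW (mg) / [substrate (g/L) ×
volume (L) × 1000], in gDCW per g substrate.

## Numerical and testing choices

* All stochastic functions take an explicit `seed` and restore the
  caller's RNG state (`withr::with_seed`); nothing depends on global
  state, and per-sample streams are derived deterministically so results
  do not depend on sample order.
* The test suite and the acceptance script work at a reduced scale chosen
  to keep a laptop run comfortable while leaving no statistical room for
  a wrong estimator to pass: a 500-gene genome with 5 barcodes per gene
  plus 10% intergenic insertions, sequencing depth 2×10⁶, two replicates,
  effects planted at *f\** ∈ {−3, −2, 0, +1} via *w* = 1 + *f\**/8. At
  this depth the end-to-end Pearson correlation between planted and
  recovered effects exceeds 0.99 and the mean absolute error is a few
  hundredths of a log2 unit, and an all-neutral pool produces essentially
  no |*f*| ≥ 2 calls.
* Degenerate inputs error early and explicitly: all-zero samples in
  normalization, missing T0 columns, zero-variance clustering input,
  non-positive OD, cyclic regulator graphs.

## Known limitations

* The simulator has no PCR-amplification or per-cycle quality error
  model; error injection is i.i.d. substitution only. Overdispersion
  beyond multinomial must be added by the user via the bottleneck /
  population-size controls.
* Exact-match tail mapping does not tolerate sequencing errors in the
  genomic tail; with erroneous TnSeq reads the support threshold does the
  work, at reduced sensitivity.
* Gene fitness has no moderated variance model (no shrinkage across
  genes); the replicate SD is reported as-is.
* Real-data headline quantities (counts of significant genes, specific
  cluster structures, measured growth-rate bands) depend on the deposited
  sequencing data of the original experiments and are not reproduced
  here; the package's claims are about correctness of the machinery,
  demonstrated on ground-truthed synthetic data.

## A compact end-to-end run

```{r pipeline, eval = FALSE}
genome <- makeGenome(nGenes = 500, nReplicons = 3, seed = 1)
effects <- setNames(sample(c(-3, -2, 0, 1), 500, TRUE, c(.1, .15, .6, .15)),
                    genes(genome)$locus_tag)
lib <- makeBalancedLibrary(genome, 5, fitnessSpec = 1 + effects / 8, seed = 2)
sheet <- makeSampleSheet("fructose", "continuous", c(0, 8), 2)
counts <- simulateCompetition(lib, sheet, depth = 2e6, seed = 3)

flanks <- FlankSpec("GTCGACCTGCAGCGTACG", "AGAGACCTCGTGGACATC")
reads <- simulateReads(lib, counts, "barseq", flanks, seed = 4)
counted <- countBarcodes(reads, flanks, libraryEntries(lib)$barcode, sheet)

tn <- simulateReads(lib, setNames(rep(10L, length(lib)),
                                  libraryEntries(lib)$barcode),
                    "tnseq", flanks, genome = genome, seed = 5)[[1]]
mapped <- assignGenes(mapInsertions(tn, genome, flanks), genome)

fit <- geneFitness(barcodeLog2FC(counted), mapped, generation = 8)
sig <- significantGenes(fit, threshold = 2)
cl <- clusterGenes(assay(fit, "fitness")[sig$overall, , drop = FALSE],
                   kRange = 2:12)
```
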