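---
title: "Discovering PRC1 tethering elements from ChIP-seq coverage"
author: "pteseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering PRC1 tethering elements from ChIP-seq coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pteseq)
```

## The problem

Canonical PRC1 (the Polycomb complex containing MEL18/BMI1, CBX, PHC and
RING subunits) is textbook-recruited to chromatin through H3K27me3
deposited by PRC2. In several human cell types, however, PRC1 ChIP-seq
profiles show sharp, high-amplitude peaks that do not coincide with the
broad, CpG-island-coupled PRC2/H3K27me3 domains around them. The DNA
under such peaks — PRC1 Tethering Elements (PTEs) — is sufficient to
seed new PRC1 binding when moved elsewhere in the genome, which makes
locating these elements precisely, and separating them from generic
PRC2 territory, a well-posed computational problem.

`pteseq` implements that discovery procedure as a reusable pipeline:

1. **Bound-region scoring.** Every significantly enriched region is
   scored by its *summit window*: the 1000-bp sub-window with the
   largest signal sum. A region survives only if its summit window
   overlaps a significantly enriched region of the other replicate.
2. **Discrete peak refinement.** Regions within 100 kb are grouped.
   Signal inside each region is smoothed by local polynomial regression
   (loess, span 0.1, degree 2, tricube weights), local maxima and
   minima are located, and each extremum is scored by the mean smoothed
   signal over nine positions. Peaks scoring at least 50–60% of the
   group's highest peak and separated by valleys deeper than 30–35% of
   the flanking peak scores are kept; only peaks surviving **all six**
   (peak-fraction × valley-depth) parameter combinations go forward.
3. **Replicate pairing.** Peak lists from the two replicates are
   matched by mutual nearest neighbours. Each pair yields a consensus
   position (the median of the two summits) and a location *accuracy*
   (half the inter-summit distance). Two summits 194 bp apart, for
   example, give the midpoint as the consensus position and ±97 bp
   accuracy.
4. **Scoring and quartiles.** Each consensus peak gets a final score:
   the raw-signal sum in a 9-bp window centred on the position, per
   replicate, ranked by the replicate mean and split into quartiles
   (Q4 highest). *High-confidence PTEs* are Q4/Q3 peaks located with
   accuracy better than ±301 bp.
5. **The CCND2-like screen.** Independently of peak refinement, scored
   loci can be screened for the signature of the founding example:
   strong PRC1 signal (>3000 RPKM summit score) in the discovery cell
   line, a MEL18/SUZ12 ratio above the reference locus, and strong
   MEL18 *and* SUZ12 (>2000 RPKM) in a second cell line where the
   nearby gene is silent.
6. **Target genes.** Each high-confidence PTE is assigned to a likely
   target: the nearer of the flanking TSSs when its promoter
   (±1 kb) carries H3K27me3; the farther TSS when only that one does;
   otherwise the nearer TSS. Genes are binned into transcription groups
   G1–G4 (RNA-count quartiles over the whole gene universe, ties to the
   lower group).
7. **Sequence features.** Around the located peaks the package computes
   di-nucleotide frequency difference maps (100-bp sliding windows over
   10-kb fragments, minus matched random controls), oriented
   poly(dA)₅/poly(dT)₅ tract profiles (sequences flipped so the target
   gene is always to the right), CpG window counts, PWM motif-centrality
   profiles (best match per sequence over 5-kb fragments, normalized
   per quartile, rolling mean of 500 positions) and generic coverage
   metaprofiles.

## Data model

Two S4 classes carry the pipeline's state. `CoverageTrack` holds
depth-normalized signal as one dense numeric vector per chromosome
(about 8 bytes/bp; at the desk scale this package targets, simplicity
beats interval trees, and every scoring step is a direct index).
`ConsensusPeaks` extends `GRanges` with width-1 positions plus
`accuracy`, per-replicate and mean `score`, and `quartile` columns.
Intervals are ordinary `GRanges`; gene tables are plain data frames.
Internally all coordinates are 1-based (the Bioconductor convention);
BED and bedGraph files are read and written 0-based half-open.

Signal units: tracks are SPMR-like. The synthetic generator normalizes
each track so the genome-wide sum is exactly 10^6, which makes the sum
over any 1-kb window that window's RPKM. Summit scores therefore
compare directly against the screen's 3000/2000 RPKM gates, and all
scores scale linearly if a different normalization is supplied.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `summit_window_bp` | 1000 | summit-window width; score = max window sum |
| `group_gap_bp` | 100 000 | regions closer than this share a peak group |
| `standalone_distance_bp` | 100 000 (strict) / 10 000 (census) | PRC1-free PRC2 region definition |
| `span` | 0.10 | loess span, fraction of positions per local fit |
| `peak_fraction_grid` | 0.50, 0.55, 0.60 | relative-amplitude cutoffs |
| `valley_depth_grid` | 0.30, 0.35 | required valley depth |
| `match_radius_bp` | 50 | cross-grid peak identity radius (below the tightest reported pairing scale of 100 bp) |
| `pair_max_distance` | 5000 | mutual-NN pairing cap in the pipeline |
| `mel18_min_rpkm` / `tig3_min_rpkm` | 3000 / 2000 | screen gates |
| `hc_max_accuracy` | 300 | "better than ±301 bp" |
| `tss_window` | 1000 | promoter window for H3K27me3 status |

## Design decisions in ambiguous corners

Some steps admit more than one literal reading; the package pins these
down explicitly:

* **Valley depth.** "Valleys deeper than X% of the flanking peak
  scores" is implemented as: a valley separates two peaks when its
  score is at most (1 − X) times the *weaker* flanking peak — the most
  literal reading; comparing against the mean of the flanks is a
  one-line change in `filterPeaks()`.
* **Replicate concordance** is summit-window overlap (≥1 bp) with the
  other replicate's significant regions — the minimal reading of the
  rule.
* **Loess span** is interpreted as a fraction of positions within each
  smoothed stretch (the semantics of the smoother the procedure is
  defined with), not a fixed genomic span.
* **Pairing** is mutual nearest neighbour rather than greedy matching:
  deterministic, order-independent, one-to-one, and identical to the
  optimal matching for well-separated peaks. Unmatched peaks are
  returned, never silently dropped.
* **Cross-grid identity** uses a 50-bp radius and reports the position
  from the strictest parameter combination.
* **Overlapping homopolymer matches are counted** (a run of six A's
  contains two poly(dA)₅ tracts); the alternative undercounts long
  runs.
* **Motif-centrality normalization** is per quartile (each curve sums
  to 1 before smoothing), which makes quartiles comparable; global
  normalization would mix quartile sizes into the shapes.
* **Ratio screen with zero SUZ12** defines the MEL18/SUZ12 ratio as
  +Inf (passes the ratio criterion) and logs the event.
* **RPKM convention:** with a 1000-bp summit window the summit sum *is*
  the window RPKM on an SPMR track, so the screen thresholds are
  portable across data sets.
* **"Accuracy better than ±301 bp"** is encoded as accuracy ≤ 300
  (integer bp); the boundary case 301 fails.
* **62.4%-style overlap** between target-gene sets uses the smaller
  set as denominator by default; the convention is a parameter.
* **One gene per PTE.** Multi-gene targets are deliberately not
  modelled; the assignment emits exactly one gene (or an explicit
  "unassigned" record).

## The synthetic generator

Real Polycomb ChIP-seq is not redistributable inside a package, so
`pteseq` ships a generator that emulates the *statistical structure*
the method relies on, with planted ground truth:

* sharp Gaussian PRC1 peaks (SD 250 bp) at planted PTE positions,
  amplitudes spanning a 4-fold range (1-kb sums of 2000–8000 RPKM,
  bracketing the 3000-RPKM screen gate), jittered independently per
  replicate (SD 120 bp — chosen so that the induced pairing-distance
  distribution has most pairs under 500 bp, fewer under 250 bp, and a
  third-ish under 100 bp, the ordering seen in real replicate pairs);
* broad PRC2/H3K27me3 plateaus built from two flat-topped kernels
  offset to the CpG-island flanks of each PTE core, plus CpG-rich
  PRC2-only loci with no PRC1 signal and no motif;
* PTE core sequence (1 kb) with an AA/TT di-nucleotide boost (a
  first-order repeat process, probability 0.15, on top of mildly
  AT-shifted composition), CpG-island flanks (GC 0.65 with a CG
  transition boost), poly(dA)₅ tracts planted between the peak and its
  target gene on the gene-facing strand (80% A-tracts), and one
  consensus-motif instance at N(core centre, 100 bp);
* genes with TSSs 2–8 kb from their PTE, H3K27me3 over the target
  promoter, and log-normal RNA counts with 80% of PTE targets drawn
  from the low tail;
* negative-binomial read-start noise (dispersion 0.3 — overdispersion
  is the realistic default; Poisson is available), reads extended by a
  180-bp fragment, and per-track normalization to a 10^6 total.

Loci sit on a jittered lattice at least 110 kb apart, so each planted
locus forms its own 100-kb region group and is independently
recoverable; with denser planting the relative-amplitude filter
correctly suppresses weaker peaks that share a group with a strong one,
which is a property of the method, not a defect of the generator. The
default fixture is 4 chromosomes × 2 Mb, 24 PTEs, 12 PRC2-only loci,
60 genes — big enough for quartile statistics (6 peaks per quartile)
and small enough that generation plus the full pipeline runs in well
under a minute.

One global seed fans out to per-track seeds through a counter scheme,
so adding a track to a simulation never changes the others, and every
output (FASTA, bedGraph, BED, TSV) is byte-identical under a fixed
seed.

**What the generator does not emulate** — and hence what green tests do
*not* establish about real data: mappability and GC bias, copy-number
variation, fragment-size heterogeneity, antibody efficiency differences
between replicates (jitter is positional only), enhancer/promoter
sequence context beyond CpG islands, and real gene density (TSS spacing
is engineered so the planted target is the nearest gene). Recovery
rates on fixtures are an upper bound on real-data behaviour.

## Numerical choices

* Loess uses tricube weights, degree 2, a single pass (no robustness
  iterations); the span is widened to the minimum the polynomial needs
  when a stretch is short, and stretches longer than 200 kb are
  pre-binned to 10 bp and interpolated back (a runtime guard that does
  not change results at peak scale).
* Plateaus in smoothed signal collapse to their midpoint before
  extremum classification; 9-position extremum scores truncate at
  stretch edges.
* Summit-window and sliding-window sums use cumulative sums; ties in
  the summit search go to the leftmost window.
* Consensus positions use the floor of the midpoint; accuracies may be
  half-integers.
* Quartiles (peaks and transcription groups) use stable ranks with
  `ceiling(rank * 4 / n)`, so sizes differ by at most one; score ties
  fall back to genomic position (peaks) or to the lower group (genes).
* Rolling means are centred with partial windows at the edges, keeping
  profiles finite everywhere.
* PWM scanning is log2-odds against a uniform background with a
  threshold of 5.0 bits; the consensus-derived PWM puts 0.94 on the
  consensus base, which admits single-mismatch variants (the known
  secondary motif matches) but rejects two-mismatch noise. Both strands
  are scanned; ties prefer the plus strand, then the leftmost position.

## Worked example

```{r example, eval = FALSE}
sim <- simulatePTEData(genomeSpec(seed = 1),
                       specs = list(MEL18 = trackSpec("MEL18"),
                                    H3K27me3 = trackSpec("H3K27me3"),
                                    INPUT = trackSpec("INPUT")),
                       seed = 1)
res <- runPTEPipeline(sim$tracks$MEL18[[1]], sim$tracks$MEL18[[2]],
                      sim$regions$MEL18[[1]], sim$regions$MEL18[[2]],
                      genes = sim$truth$genes,
                      k27_regions = sim$regions$H3K27me3[[1]])
print(res)
evaluateAgainstTruth(res, sim$truth)
```

## Known limitations

* Pairing is defined for exactly two replicates, as in the source
  procedure; more replicates would need an IDR-style model, which is
  out of scope.
* The enriched-region caller shipped here (`callEnrichedRegions`) is a
  simple Poisson window test against input — a stand-in so the demo is
  self-contained, not a substitute for a production broad-peak caller;
  the pipeline is designed to consume externally called regions.
* Headline genome-wide counts from real data (hundreds of peaks,
  thousands of standalone PRC2 regions) require the original
  sequencing data and are not reproduced at fixture scale; the test
  suite checks the *properties* of every operation instead (exact
  oracle equivalence, planted-truth recovery, signature statistics).
* Scores are carried on normalized tracks; if raw read counts are
  supplied instead, every score scales linearly and the screen
  thresholds must be rescaled accordingly.
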