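---
title: "Methods: joint Nanog/Sox2 peak consensus, bipartite motif enrichment, interactome filtering and SELEX simulation"
author: "nsmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint Nanog/Sox2 peak consensus and motif analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsmotif)
```

# The scientific question

Nanog and Sox2 are core transcription factors of the embryonic stem (ES)
cell pluripotency network, and they bind each other directly through the
Nanog tryptophan-repeat region and a tyrosine-containing repeat in Sox2. A
Nanog–Sox2 complex has its own DNA sequence preference: a *bipartite*
recognition site consisting of a Nanog-like homeodomain half-site (TAA
core), a 2-bp spacer, and a Sox2-like HMG-box half-site. Written as a
degenerate pattern this is

```
A[TGA]T..[TC][AT]TT[GCT][AT]
```

eleven positions, of which positions 4–5 are unconstrained (the spacer).

This package implements the downstream computational analyses around that
motif:

1. **Joint peak calling.** Within each ChIP-seq dataset, Nanog and Sox2
   peaks are reduced to ±50 bp windows around their summits, and windows of
   the two factors overlapping by ≥ 1 bp are merged into *joint* Nanog/Sox2
   peaks. Joint peaks supported by all three datasets form the
   high-confidence *consensus* set.
2. **Motif enrichment.** Consensus spans (foreground) and single-factor
   windows (background) are scanned for the bipartite pattern on both
   strands; over-representation is quantified with the one-sided
   hypergeometric upper tail.
3. **Gene linking.** Consensus clusters are assigned to the nearest
   transcription start site within 30 kb.
4. **Interactome filtering.** AP-MS hit tables are filtered into interactor
   calls with the inclusion criteria: Mascot score > 50, at least three-fold
   over the paired control purification, and presence in two of the three
   purifications.
5. **SELEX simulation.** An in-silico version of the in-vitro selection
   protocol (random 25-bp cores between fixed flanks, five
   selection/amplification rounds) with a known binding model, used to show
   that the pipeline's PWM-building and consensus-calling steps recover a
   motif the way the wet protocol plus MEME did.

The original peak compendium is not redistributable at desk scale, so the
package ships a synthetic-data generator that emulates its structure with
known ground truth; all quantitative claims in the test suite are made
against that ground truth.

# Coordinate and clustering conventions

Coordinates are 0-based half-open (BED convention) throughout. The summit
window at flank $f$ is $[s - f,\, s + f + 1)$, width $2f + 1$ (101 bp at
the default $f = 50$): a literal reading of "± 50 bp around the summit"
that keeps the summit base itself. Windows are clipped at coordinate 0 and,
when chromosome lengths are known, at the chromosome end.

"Joint peak" needs a unit: we use the *single-linkage cluster*. Edges are
Nanog–Sox2 window pairs with ≥ `min_overlap` bp overlap (1 bp default);
connected components containing both factors are joint peaks, and a chain
of pairwise overlaps therefore counts once. The cluster span is the union
of member windows. Cross-dataset consensus applies the same single-linkage
rule to the spans of the per-dataset joint clusters and keeps components
whose members come from at least `n_required` datasets (default: all).
Overlap detection is delegated to GenomicRanges/IRanges and component
labelling to igraph; the test suite checks both operations against a
brute-force $O(n^2)$ connected-components oracle on hundreds of random
instances.

TSS linking measures from the cluster-span midpoint, strand-agnostically
(the source analysis does not state an anchor); exact distance ties go to
the lowest TSS coordinate so results are order-independent.

# Motif model and scanning

Degenerate patterns are ordered lists of allowed-base subsets, parsed from
bracket-class text or IUPAC codes and rendered back canonically. Scanning
reports every fully contained occurrence on both strands at forward-strand
coordinates; `N` bases match nothing (conservative on masked sequence), and
matches straddling a span boundary do not count. Matching is implemented
with Biostrings ambiguity matching (`fixed = "subject"`) and is tested
against an independent base-R regex oracle.

The expected per-position match rate of a pattern under a uniform
background is $\prod_i |A_i|/4$; for the bipartite pattern this is
$1152/4^{11} = 9/32768 \approx 2.75 \times 10^{-4}$ per position per
strand, verified in the tests by exhaustive enumeration of all $4^{11}$
words. Over a 101-bp window scanned on both strands the chance-hit
probability is therefore about 5%, which is why enrichment is always
scored against *realized* (post-planting scan) rather than nominal rates
on synthetic data.

PWMs carry per-position counts and pseudocount-smoothed frequencies
$f_{ib} = (c_{ib} + p)/(n + 4p)$ with default pseudocount 1 (the de-novo
discovery tool the wet analysis used has unstated priors; 1 is the
conventional additive choice). Information content per position is
$2 + \sum_b f_b \log_2 f_b$ bits under the uniform background. The
degenerate consensus admits bases with frequency ≥ 0.25 and renders a
position admitting all four bases as a wildcard.

# Enrichment statistics

The contingency treats the pooled foreground and background peaks as the
population ($N = n_{fg} + n_{bg}$, $K = k_{fg} + k_{bg}$ motif-positive)
and the foreground as the draw; `hypergeom_upper` returns
$P(X \ge k_{fg})$, one-sided and including the observed count, computed in
log space (`stats::phyper(log.p = TRUE)`) so deep tails (below $10^{-300}$
in log form) remain accurate. The background is every summit-centred window
that belongs to no within-dataset joint cluster, pooled across datasets —
the natural reading of "single-factor peaks", which the source text does
not further specify. Reported percentages are rounded half away from zero
to one decimal. No two-sided variant and no GC-matched background are
implemented (out of scope).

**Equal scan extents.** Consensus cluster spans are union intervals and can
be wider than a single summit window (jittered summits widen the union by
the summit range, ~40 bp in expectation at our jitter settings). Scanning
the raw union for the foreground while the background is scanned over
101-bp windows would hand the foreground extra chance hits
(about $2 \times 40 \times 2.75\times10^{-4} \approx 2\%$ absolute) and
make the enrichment test anti-conservative under a true null. The pipeline
therefore scans a fixed-width window (`2 * flank + 1` bp, centred on the
cluster-span midpoint; `standardize_spans()`) for the foreground — the same
extent as each background window — which is also how motif-enrichment tools
normally standardize regions. Cluster spans in all reported outputs remain
the full union intervals.

# The synthetic-data generator

`make_peak_datasets()` emulates the three-dataset compendium on a random
genome (default 2.5 Mb over 3 chromosomes, GC 0.5):

* **consensus loci** (default 300) emit a Nanog and a Sox2 peak in every
  dataset; **partial loci** (default 50) in a random proper subset of
  datasets; **single-factor peaks** (default 500 per factor per dataset,
  3000 total) emit one factor in one dataset.
* loci sit on distinct 500-bp bins, so windows of unrelated loci can never
  touch; summits jitter around the locus centre (SD 15 bp, truncated at
  ±45 bp) so that ±50 bp windows of the same locus always overlap by ≥ 1 bp
  within and across datasets — intended joint pairs always join, intended
  non-joint peaks never do, and the consensus count equals the planted
  count by construction.
* a motif word — drawn uniformly from the 1152 pattern-compatible words, on
  a random strand — is written into the genome at the locus centre with
  probability 0.29 (consensus and partial loci) or 0.16 (single-factor
  loci), the fractions reported for the real compendium. The truth table
  records both the planted and the *realized* motif status (a scan, after
  planting, of the fixed-width midpoint window the pipeline itself scans),
  so chance hits in the random background are part of the scored truth.
* peak halfwidth before centring is 150 bp, a typical ChIP-seq peak extent;
  the pipeline's summit-centring makes the raw extent immaterial.

What the generator does **not** emulate: read-level coverage, realistic
nucleotide composition or repeats, dataset-specific peak-calling noise,
or false-positive peaks. Passing tests therefore demonstrate the
correctness of the interval algebra, scanning and statistics — not
robustness to real-data artefacts.

`make_ms_tables()` builds AP-MS tables in which true interactors satisfy
all inclusion criteria in ≥ 2 runs and every decoy violates exactly one
criterion (score ≤ 50, fold < 3, or presence in a single run), including
boundary decoys at score exactly 50 and fold exactly 2.99; the filter must
achieve recall = precision = 1 on these tables, which pins down the strict
(`> 50`) versus inclusive (`≥ 3`) readings of the criteria. The
unique-peptide floor (≥ 3) is a conventional AP-MS requirement exposed as a
parameter; setting `min_peptides = 0` reproduces the literal text criteria,
which mention only score and fold.

# SELEX simulation design

Physical quantities (pmol of protein and library, ng of DNA) are abstracted
into a two-level capture model: an oligo containing a pattern site anywhere
on either strand is retained with probability `capture_bound` (0.9), any
other with `capture_base` (0.05); amplification is multinomial resampling
back to constant pool size. Five rounds are simulated by default,
matching the wet protocol's round count, and the double-stranding step
makes scanning strand-symmetric. Site extraction takes the single best
(leftmost, plus-strand-preferred) match per final-pool oligo, restricted by
default to sites fully inside the 25-bp random core — sites completed by
the fixed flanks are artefacts of the library design, excluded unless
`core_only = FALSE`.

**Pool size.** The default pool is $10^5$ oligos. This is the one place
where a desk-scale simulation has a hard statistical floor: a random 25-bp
core contains a fully-core-contained pattern site with probability
$\approx 30 \times 9/32768 \approx 0.008$, so a pool of $n$ oligos carries
only $\approx 0.008\,n$ *distinct* informative sites into the enriched
pool — amplification multiplies copies, not diversity. The recovered
consensus at a position whose planted base frequencies are $1/3$ needs that
base to stay above the 0.25 threshold, i.e. a founder sample standard
deviation $\sqrt{(1/3)(2/3)/m}$ comfortably below $1/12$; with $m \approx
40$ founders (pool 5000) recovery fails in roughly half of runs, while
$m \gtrsim 500$ founders (pool $10^5$) makes recovery essentially certain
(the test suite and the acceptance script verify recovery across 20 seeded
runs each). The
wet-lab library contains $\sim 10^{13}$ molecules, so the larger pool is
also the more faithful scale-down. Capture probabilities and the round
count stay at the two-level defaults above.

The PWM-mode binding model (Boltzmann weight on the best log2-odds score,
`temperature` in score units) is provided for graded-affinity experiments;
the recovery claims in the tests use the pattern mode.

# Numerical and determinism choices

* All randomness flows through R's RNG; every generator takes a seed, and
  `run_selex`/`make_peak_datasets` are bit-reproducible given (spec, seed).
* Cluster tables are sorted by (chromosome, span start, member ids) and
  ids assigned after sorting, so outputs are invariant under input-row
  permutation.
* `hypergeom_upper` validates $0 \le k \le n \le N$, $k \le K \le N$ and is
  exact against rational enumeration for all $N \le 30$ (full-grid test).
* Degenerate inputs: empty peak files give empty peak sets and a report
  flagged `enrichment_computable = FALSE`; an empty bound pool raises an
  extinction error naming the round; `percent(k, 0)` is an error rather
  than NaN.
* Problem sizes in the tests and analysis scripts (2.5 Mb genome, 300 + 50
  + 3000 loci, 100-seed calibrations, 20-seed SELEX recovery) were chosen
  as the smallest sizes at which the binomial/hypergeometric claims under
  test have comfortable margins.

# Known limitations

* **Detection power at desk scale.** With 300 foreground peaks, planting
  rates 0.29 vs 0.16 and the ~5% chance-hit floor of this AT-rich pattern
  in 101-bp windows of random sequence, the enrichment test reaches
  $P < 10^{-3}$ in roughly 9 of 10 seeded replicates (91 of the 100
  replicates the test suite runs); the remaining runs still show enrichment
  at $10^{-3} < P < 10^{-2}$. Reliable detection at stricter thresholds needs more foreground
  peaks (the real compendium has ten times as many) — this is a sample-size
  statement, not an implementation artefact, and the companion null
  calibration (equal planted rates) holds, with $P > 0.05$ in well over 90%
  of seeded replicates.

* The published compendium counts (16 454 joint, 3257 consensus, 948
  motif-positive) depend on three external datasets without printed
  accessions; they are inputs we deliberately do not attempt to reproduce.
  Only the in-paper arithmetic on those printed counts is recomputed.
* The background definition (pooled, non-deduplicated single-factor
  windows) is one reasonable reading of the source text; deduplicating
  across datasets would shrink the background by the between-dataset
  overlap fraction.
* The SELEX capture model has no PCR bias, no sequencing error, and no
  graded affinity in pattern mode; the trajectory claims are about the
  two-level model only.
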