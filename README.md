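# nsmotif

Joint Nanog/Sox2 ChIP-seq peak consensus, bipartite motif enrichment,
AP-MS interactome filtering, and SELEX simulation — with a synthetic-data
generator that makes the whole analysis testable offline against known
ground truth.

## The problem

Nanog and Sox2 sit at the core of the embryonic stem cell pluripotency
network and bind each other directly, and the Nanog–Sox2 complex recognises
a *bipartite* DNA element: a Nanog-like homeodomain half-site with a TAA
core, a 2-bp spacer, and a Sox2-like HMG half-site, written as the
degenerate pattern

```
A[TGA]T..[TC][AT]TT[GCT][AT]
```

Downstream of that biochemistry sit several standard computational
questions this package answers for anyone analysing co-binding of two
transcription factors:

* Which loci are bound by **both** factors in one dataset (summit-centred
  ±50 bp windows overlapping by ≥ 1 bp, single-linkage clustered), and
  which of those joint events replicate across **all** datasets (the
  high-confidence consensus set)?
* Is a motif **over-represented** in consensus peaks relative to
  single-factor peaks? The contingency is tested with the one-sided
  hypergeometric upper tail, `P(X ≥ k)`, computed in log space. For the
  published counts — 948 of 3257 consensus peaks (29.1%) versus 4898 of
  31271 single-factor peaks (15.7%) — the tail probability is ~10⁻⁷⁴, far
  below the reported 10⁻¹⁰ bound.
* Which **gene** does each consensus peak regulate (nearest TSS within
  30 kb)?
* Which AP-MS hits are **interactors** (Mascot score > 50, ≥ 3-fold over
  the paired control, ≥ 3 unique peptides, in ≥ 2 of 3 purifications)?
* Does iterative **SELEX** selection (random 25-bp cores between fixed
  primer flanks, five capture/amplification rounds) recover the motif that
  drove the selection, as a position weight matrix and its degenerate
  consensus?

The three published ChIP-seq peak compendia are not redistributable, so
`make_genome()` / `make_peak_datasets()` / `make_ms_tables()` generate
synthetic inputs that emulate their structure — co-bound loci, partially
replicating loci, single-factor peaks, motif instances planted at
controlled rates, true interactors and single-criterion decoys — with
ground-truth tables for scoring every stage.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (`Rscript analysis/01_simulate_data.R`, then `02`–`05`), writing
tables under `results/`. The core of `02_joint_consensus.R` in a session:

```r
library(nsmotif)

genome <- make_genome(2.5e6, n_chroms = 3, seed = 1)
sim <- make_peak_datasets(peak_planting_spec(seed = 1), genome)
tss <- make_tss_annotation(sim$genome, 50, loci = sim$truth, seed = 1)
report <- run_chipseq_analysis(sim$peaks, sim$genome, tss)
print(report)
```

```
Joint Nanog/Sox2 peak analysis
  joint clusters per dataset: chen=317, marson=327, whyte=328
  total joint clusters: 972
  consensus clusters (all datasets): 300
motif enrichment: 87/300 foreground (29.0%) vs 593/3000 background (19.8%)
  fold = 1.47, hypergeometric upper-tail P = 0.000179 (log10 = -3.75)
  gene links: 300 of 300 clusters linked within cutoff
```

Reading this: each of the three synthetic datasets yields ~320 joint
Nanog/Sox2 clusters (300 planted consensus loci plus its share of the 50
partially-replicating loci); exactly the 300 loci planted in all three
datasets survive the cross-dataset intersection; 29.0% of consensus windows
contain the bipartite motif versus 19.8% of single-factor windows (planting
rates 29% and 16% plus ~5% chance hits in random sequence — the fractions
match the generator's realized ground truth exactly), and the
hypergeometric tail probability calls the over-representation at
P ≈ 1.8 × 10⁻⁴. Every consensus cluster links to a TSS because the
generator guarantees a gene within 30 kb of each consensus locus.

The SELEX driver (`analysis/04_selex.R`) prints the enrichment trajectory —
the planted-motif pool frequency rising from 0.008 to ~1.0 over five
rounds — and recovers the selection pattern:

```
 round pool_size motif_frequency
     0    100000         0.00800
     1    100000         0.12483
     2    100000         0.71340
     3    100000         0.97733
     4    100000         0.99858
     5    100000         0.99997
Recovered consensus A[AGT]T[AC][AC][CT][AT]TT[CGT][AT] from 99997 sites
(IC 11.8 bits total); matches the selection pattern at all non-wildcard
positions: TRUE.
```

The interactome driver reports `Called 25 interactors; recall 1.000,
precision 1.000` against the generation truth.

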