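#!/usr/bin/env Rscript
# Generate the full synthetic input set: a 2.5 Mb genome over 3 chromosomes,
# three emulated Nanog/Sox2 ChIP-seq datasets (300 consensus loci, 50 partial,
# 500 single-factor peaks per factor per dataset; motif planted at 29% of
# consensus and 16% of single-factor loci), a TSS annotation, and an AP-MS
# hit table with 25 true interactors and 30 decoys. Everything is written
# under results/data/ together with the ground truth.

suppressPackageStartupMessages(library(nsmotif))
seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("Simulating genome and peak datasets (seed ", seed, ") ...")
genome <- make_genome(2.5e6, 3, seed = seed)
spec <- peak_planting_spec(seed = seed)
sim <- make_peak_datasets(spec, genome)
Biostrings::writeXStringSet(sim$genome, file.path(out, "genome.fa"))
for (ds in names(sim$peaks)) for (f in names(sim$peaks[[ds]])) {
  write_peaks_bed(sim$peaks[[ds]][[f]],
                  file.path(out, sprintf("peaks_%s_%s.bed", ds, f)))
}
write.table(sim$truth, file.path(out, "peak_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tss <- make_tss_annotation(sim$genome, 50, loci = sim$truth, seed = seed)
write_tss_table(tss, file.path(out, "tss.tsv"))

ms <- make_ms_tables(ms_table_spec(n_true = 25, n_decoy = 30, seed = seed))
write_ms_table(ms$hits, file.path(out, "ms_hits.tsv"))
write.table(ms$truth, file.path(out, "ms_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

writeLines(yaml::as.yaml(list(seed = seed, spec = unclass(spec))),
           file.path(out, "manifest.yaml"))
message("Wrote ", length(list.files(out)), " files to ", out, ": ",
        sum(sim$truth$class == "consensus"), " consensus loci, ",
        sum(sim$truth$class == "single"), " single-factor peaks, ",
        nrow(ms$hits), " MS hit rows.")
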