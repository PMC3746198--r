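#!/usr/bin/env Rscript
# Filter the simulated AP-MS hit table into interactor calls (Mascot > 50,
# >= 3-fold over the paired control, >= 3 unique peptides, in >= 2 of 3
# purifications) and score the calls against the generation truth.

suppressPackageStartupMessages(library(nsmotif))
datadir <- "results/data"
out <- "results/interactome"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

res <- run_interactome(file.path(datadir, "ms_hits.tsv"),
                       run_labels = ms_table_spec()$runs)
write_interactor_calls(res$calls, file.path(out, "interactor_calls.tsv"))

truth <- read.table(file.path(datadir, "ms_truth.tsv"), header = TRUE,
                    sep = "\t")
merged <- merge(res$calls, truth, by = "protein")
recall <- sum(merged$called & merged$is_true) / sum(merged$is_true)
precision <- sum(merged$called & merged$is_true) / sum(merged$called)
message(sprintf("Called %d interactors; recall %.3f, precision %.3f.",
                res$n_called, recall, precision))
write.table(data.frame(key = c("n_called", "recall", "precision"),
                       value = c(res$n_called, recall, precision)),
            file.path(out, "summary.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
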