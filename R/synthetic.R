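# Synthetic-data generators: a random genome, three emulated ChIP-seq
# datasets (Nanog + Sox2 peak sets with a controlled fraction of co-bound
# loci and planted motif instances), a TSS annotation, and AP-MS hit tables
# with true interactors and decoys. Every generator records ground truth so
# each pipeline stage can be scored without re-reading generation internals.

#' Generate a random genome
#'
#' Independent bases at the requested GC content, split over `n_chroms`
#' chromosomes named `chr1..chrN`. The total length is honoured exactly (the
#' last chromosome absorbs the division remainder).
#'
#' @param length Total genome length in bp.
#' @param n_chroms Number of chromosomes.
#' @param gc GC content (default 0.5).
#' @param seed Optional integer seed.
#' @return Named `Biostrings::DNAStringSet`.
#' @export
make_genome <- function(length, n_chroms = 1L, gc = 0.5, seed = NULL) {
  stopifnot(length >= n_chroms * 1000, gc >= 0, gc <= 1)
  if (!is.null(seed)) set.seed(seed)
  base_len <- length %/% n_chroms
  lens <- rep(base_len, n_chroms)
  lens[n_chroms] <- length - base_len * (n_chroms - 1L)
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- vapply(lens, function(l)
    paste(sample(BASES, l, replace = TRUE, prob = prob), collapse = ""),
    character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(n_chroms))
  genome
}

#' Specification for planted peak datasets
#'
#' Defines the structure of the emulated three-dataset Nanog/Sox2 ChIP-seq
#' compendium: how many loci are co-bound in all datasets (consensus), in a
#' proper subset (partial), or bound by a single factor in a single dataset,
#' and at what rate the bipartite motif is planted in each class.
#'
#' @param n_consensus_loci Loci joint in all datasets (default 300).
#' @param n_partial_loci Loci joint in a random proper subset of datasets
#'   (default 50).
#' @param n_single_factor Single-factor peaks per factor per dataset
#'   (default 500; 3000 in total at 3 datasets x 2 factors).
#' @param motif_rate_fg Motif planting rate at consensus/partial loci
#'   (default 0.29).
#' @param motif_rate_bg Motif planting rate at single-factor peaks
#'   (default 0.16).
#' @param summit_jitter SD in bp of the between-dataset summit jitter,
#'   truncated at +/- 45 bp so that 101-bp summit windows always overlap
#'   (default 15).
#' @param peak_halfwidth Half-width in bp of the raw (uncentred) peak
#'   intervals (default 150).
#' @param spacing Minimum distance between loci in bp (default 500, so
#'   unrelated windows can never touch).
#' @param seed Integer seed.
#' @return A `peak_planting_spec`.
#' @export
peak_planting_spec <- function(n_consensus_loci = 300L, n_partial_loci = 50L,
                               n_single_factor = 500L, motif_rate_fg = 0.29,
                               motif_rate_bg = 0.16, summit_jitter = 15,
                               peak_halfwidth = 150L, spacing = 500L,
                               seed = 1L) {
  stopifnot(n_consensus_loci >= 0, n_partial_loci >= 0, n_single_factor >= 0,
            motif_rate_fg >= 0, motif_rate_fg <= 1,
            motif_rate_bg >= 0, motif_rate_bg <= 1,
            summit_jitter >= 0, peak_halfwidth >= 1, spacing >= 300)
  structure(list(n_consensus_loci = as.integer(n_consensus_loci),
                 n_partial_loci = as.integer(n_partial_loci),
                 n_single_factor = as.integer(n_single_factor),
                 motif_rate_fg = motif_rate_fg, motif_rate_bg = motif_rate_bg,
                 summit_jitter = summit_jitter,
                 peak_halfwidth = as.integer(peak_halfwidth),
                 spacing = as.integer(spacing), seed = seed),
            class = "peak_planting_spec")
}

# Non-overlapping locus positions with >= spacing between any two: the genome
# is divided into spacing-wide bins (with a spacing-wide margin at both
# chromosome ends) and loci occupy distinct bin centres.
place_loci <- function(genome, n, spacing) {
  lens <- Biostrings::width(genome)
  bins <- do.call(rbind, lapply(seq_along(lens), function(i) {
    nb <- (lens[i] - 2L * spacing) %/% spacing
    if (nb <= 0) return(NULL)
    data.frame(chrom = names(genome)[i],
               pos = spacing + (seq_len(nb) - 1L) * spacing + spacing %/% 2L,
               stringsAsFactors = FALSE)
  }))
  if (is.null(bins) || nrow(bins) < n)
    stop(sprintf("locus spacing infeasible: need %d slots, genome provides %d",
                 n, if (is.null(bins)) 0L else nrow(bins)))
  bins[sample(nrow(bins), n), , drop = FALSE]
}

#' Generate three synthetic Nanog/Sox2 peak datasets with ground truth
#'
#' Consensus loci emit a Nanog and a Sox2 peak in every dataset with jittered
#' summits constrained so the +/- `flank` bp windows overlap within and across
#' datasets; partial loci do so in a random proper subset of datasets;
#' single-factor peaks emit one factor in one dataset, spaced so they overlap
#' nothing. A motif word (drawn uniformly from the words compatible with
#' `pattern`, on a random strand) is written into the genome at the locus
#' centre at rate `motif_rate_fg` (consensus/partial) or `motif_rate_bg`
#' (single-factor). The truth table records each locus's class, its planted
#' motif status, and its realized motif status: a both-strand scan, after
#' planting, of the fixed-width window centred on the locus's summit-window
#' span midpoint — the extent the analysis pipeline scans — so chance
#' background hits are part of the scored truth.
#'
#' @param spec A `peak_planting_spec`.
#' @param genome Named `DNAStringSet` (will be modified by planting).
#' @param pattern Motif to plant (default [ns_pattern()]).
#' @param datasets Dataset labels (default `c("chen", "marson", "whyte")`).
#' @param flank Summit flank in bp used downstream (defines the realized
#'   scan window; default 50).
#' @return List: `genome` (with planted motifs), `peaks` (nested list
#'   dataset -> factor -> peak `data.frame`), `truth` (per-locus
#'   `data.frame`), `spec`.
#' @export
make_peak_datasets <- function(spec, genome, pattern = ns_pattern(),
                               datasets = c("chen", "marson", "whyte"),
                               flank = 50L) {
  force(genome); force(pattern)   # evaluate before touching the RNG
  set.seed(spec$seed)
  factors <- c("Nanog", "Sox2")
  n_single_total <- spec$n_single_factor * length(datasets) * length(factors)
  n_loci <- spec$n_consensus_loci + spec$n_partial_loci + n_single_total
  loci <- place_loci(genome, n_loci, spec$spacing)
  classes <- rep(c("consensus", "partial", "single"),
                 c(spec$n_consensus_loci, spec$n_partial_loci, n_single_total))
  words <- compatible_words(pattern)
  L <- pattern_length(pattern)
  half <- L %/% 2L
  jitter_bound <- min(45L, 2L * flank - 10L)

  # datasets emitting each locus: all for consensus, a random proper subset
  # for partial, a single (dataset, factor) assignment for single-factor loci
  ds_per_locus <- vector("list", n_loci)
  fs_per_locus <- vector("list", n_loci)
  is_cons <- classes == "consensus"
  is_part <- classes == "partial"
  is_single <- classes == "single"
  ds_per_locus[is_cons] <- list(datasets)
  fs_per_locus[is_cons | is_part] <- list(factors)
  ds_per_locus[is_part] <- lapply(which(is_part), function(i)
    sample(datasets, sample(length(datasets) - 1L, 1L)))
  single_assign <- expand.grid(dataset = datasets, factor = factors,
                               k = seq_len(max(spec$n_single_factor, 1L)),
                               stringsAsFactors = FALSE)
  ds_per_locus[is_single] <- as.list(single_assign$dataset[seq_len(n_single_total)])
  fs_per_locus[is_single] <- as.list(single_assign$factor[seq_len(n_single_total)])

  n_peaks_per_locus <- lengths(ds_per_locus) * lengths(fs_per_locus)
  locus_of_peak <- rep(seq_len(n_loci), n_peaks_per_locus)
  allp <- data.frame(
    chrom = loci$chrom[locus_of_peak],
    dataset = unlist(lapply(seq_len(n_loci), function(i)
      rep(ds_per_locus[[i]], each = length(fs_per_locus[[i]])))),
    factor = unlist(lapply(seq_len(n_loci), function(i)
      rep(fs_per_locus[[i]], times = length(ds_per_locus[[i]])))),
    locus = locus_of_peak, stringsAsFactors = FALSE)
  jit <- as.integer(round(pmin(jitter_bound, pmax(-jitter_bound,
                                                  rnorm(nrow(allp), 0, spec$summit_jitter)))))
  allp$summit <- loci$pos[locus_of_peak] + jit

  # motif planting: one decision per locus, word written at the locus centre
  rate <- ifelse(is_single, spec$motif_rate_bg, spec$motif_rate_fg)
  planted <- runif(n_loci) < rate
  word <- sample(words, n_loci, replace = TRUE)
  minus <- runif(n_loci) < 0.5
  word[minus] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(word[minus])))
  for (chrom in unique(loci$chrom[planted])) {
    sel <- planted & loci$chrom == chrom
    genome[[chrom]] <- Biostrings::replaceAt(
      genome[[chrom]], IRanges::IRanges(loci$pos[sel] - half + 1L, width = L),
      Biostrings::DNAStringSet(word[sel]))
  }

  smin <- tapply(allp$summit, allp$locus, min)
  smax <- tapply(allp$summit, allp$locus, max)
  truth <- data.frame(
    locus_id = sprintf("locus_%05d", seq_len(n_loci)), class = classes,
    chrom = loci$chrom, pos = loci$pos, n_datasets = lengths(ds_per_locus),
    planted_motif = planted,
    span_start = as.integer(smin[as.character(seq_len(n_loci))]) - flank,
    span_end = as.integer(smax[as.character(seq_len(n_loci))]) + flank + 1L,
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  # realized motif status after planting: scan the fixed-width window centred
  # on the span midpoint, the same extent the analysis pipeline scans
  mid <- (truth$span_start + truth$span_end) %/% 2L
  span_seqs <- extract_span_seqs(genome, truth$chrom, mid - flank,
                                 mid + flank + 1L, truth$locus_id)
  truth$realized_motif <- spans_have_motif(span_seqs, pattern)
  peaks_out <- list()
  for (ds in datasets) {
    peaks_out[[ds]] <- list()
    for (f in factors) {
      sel <- allp[allp$dataset == ds & allp$factor == f, , drop = FALSE]
      sel <- sel[order(sel$chrom, sel$summit), , drop = FALSE]
      peaks_out[[ds]][[f]] <- peaks(
        sel$chrom, pmax(0L, sel$summit - spec$peak_halfwidth),
        sel$summit + spec$peak_halfwidth + 1L, sel$summit,
        factor = f, dataset = ds,
        id = sprintf("%s_%s_locus%05d", ds, f, sel$locus))
    }
  }
  list(genome = genome, peaks = peaks_out, truth = truth, spec = spec)
}

#' Generate a TSS annotation for a synthetic genome
#'
#' `n_genes` TSS are placed uniformly over the chromosomes. When `loci` is
#' supplied (the truth table of [make_peak_datasets()]), one extra gene is
#' guaranteed within `max_distance` of every consensus locus, and at least
#' one gene lies beyond `max_distance` of some consensus locus, so linked and
#' unlinked outcomes both occur downstream.
#'
#' @param genome Named `DNAStringSet`.
#' @param n_genes Number of uniformly placed genes.
#' @param loci Optional truth `data.frame` with columns chrom, pos, class.
#' @param max_distance Link cutoff emulated (default 30000).
#' @param seed Optional integer seed.
#' @return `data.frame`: gene, chrom, tss, strand.
#' @export
make_tss_annotation <- function(genome, n_genes, loci = NULL,
                                max_distance = 30000L, seed = NULL) {
  stopifnot(n_genes >= 1)
  force(genome); force(loci)      # evaluate before touching the RNG
  if (!is.null(seed)) set.seed(seed)
  lens <- Biostrings::width(genome)
  chrom <- sample(names(genome), n_genes, replace = TRUE,
                  prob = lens / sum(lens))
  tss <- vapply(chrom, function(ch)
    sample.int(lens[names(genome) == ch], 1L) - 1L, integer(1))
  tab <- data.frame(gene = sprintf("gene_r%04d", seq_len(n_genes)),
                    chrom = chrom, tss = as.integer(tss),
                    strand = sample(c("+", "-"), n_genes, replace = TRUE),
                    stringsAsFactors = FALSE)
  if (!is.null(loci)) {
    cons <- loci[loci$class == "consensus", , drop = FALSE]
    if (nrow(cons) > 0) {
      near <- data.frame(
        gene = paste0("gene_", cons$locus_id), chrom = cons$chrom,
        tss = pmax(0L, cons$pos +
                     as.integer(sample(seq(-max_distance, max_distance), nrow(cons),
                                       replace = TRUE))),
        strand = sample(c("+", "-"), nrow(cons), replace = TRUE),
        stringsAsFactors = FALSE)
      lens_by <- setNames(lens, names(genome))
      near$tss <- pmin(near$tss, lens_by[near$chrom] - 1L)
      tab <- rbind(tab, near)
      # guarantee a gene beyond the cutoff of some consensus locus
      d1 <- abs(tab$tss[tab$chrom == cons$chrom[1]] - cons$pos[1])
      if (all(d1 <= max_distance)) {
        ch_len <- lens_by[cons$chrom[1]]
        far_pos <- if (cons$pos[1] > ch_len / 2) 0L else ch_len - 1L
        tab <- rbind(tab, data.frame(gene = "gene_far", chrom = cons$chrom[1],
                                     tss = as.integer(far_pos), strand = "+",
                                     stringsAsFactors = FALSE))
      }
    }
  }
  rownames(tab) <- NULL
  tab
}

#' Specification for synthetic AP-MS hit tables
#'
#' @param n_true True interactors, generated to satisfy all inclusion
#'   criteria in at least 2 runs (default 20).
#' @param n_decoy Decoys, each violating exactly one criterion: low Mascot
#'   score, low fold over control, or presence in only one run
#'   (default 30, split near-evenly; the first low-score decoy sits exactly
#'   at score 50 and the first low-fold decoy exactly at fold 2.99).
#' @param runs Run labels (default: two purifications from the E14Tg2a
#'   F-Nanog line and one from the Nanog-null rescue line).
#' @param seed Integer seed.
#' @return An `ms_table_spec`.
#' @export
ms_table_spec <- function(n_true = 20L, n_decoy = 30L,
                          runs = c("E14_FNanog_1", "E14_FNanog_2",
                                   "RCN_FNanog"),
                          seed = 1L) {
  stopifnot(n_true >= 0, n_decoy >= 0, length(runs) >= 2)
  structure(list(n_true = as.integer(n_true), n_decoy = as.integer(n_decoy),
                 runs = runs, seed = seed), class = "ms_table_spec")
}

#' Generate a synthetic AP-MS hit table with truth labels
#'
#' True interactors pass all criteria (score > 50, fold >= 3, >= 3 unique
#' peptides) in 2 or 3 runs; each decoy violates exactly its assigned
#' criterion. Row order is shuffled. Boundary decoys (score exactly 50, fold
#' exactly 2.99) are always included when their failure mode is represented.
#'
#' @param spec An `ms_table_spec`.
#' @return List: `hits` (hit `data.frame`), `truth` (`data.frame` protein,
#'   is_true, failure_mode).
#' @export
make_ms_tables <- function(spec) {
  set.seed(spec$seed)
  runs <- spec$runs
  rows <- list()
  truth <- list()
  passing_row <- function(protein, run) {
    score <- runif(1, 60, 800)
    control <- if (runif(1) < 0.5) NA_real_ else score / runif(1, 3, 10)
    data.frame(protein = protein, run = run, mascot_bait = round(score, 1),
               mascot_control = round(control, 1),
               unique_peptides = sample(3:25, 1), stringsAsFactors = FALSE)
  }
  for (i in seq_len(spec$n_true)) {
    protein <- sprintf("TRUE_%03d", i)
    in_runs <- sample(runs, sample(2:length(runs), 1))
    rows <- c(rows, lapply(in_runs, function(r) passing_row(protein, r)))
    truth[[length(truth) + 1L]] <-
      data.frame(protein = protein, is_true = TRUE, failure_mode = NA_character_,
                 stringsAsFactors = FALSE)
  }
  modes <- rep(c("low_score", "low_fold", "one_run"),
               length.out = spec$n_decoy)
  for (i in seq_len(spec$n_decoy)) {
    protein <- sprintf("DECOY_%s_%03d", modes[i], i)
    in_runs <- sample(runs, sample(2:length(runs), 1))
    r <- switch(modes[i],
      low_score = lapply(in_runs, function(rn) {
        # strict > 50 criterion: the first such decoy sits exactly on 50
        score <- if (i <= 3) 50 else round(runif(1, 5, 50), 1)
        data.frame(protein = protein, run = rn, mascot_bait = score,
                   mascot_control = NA_real_,
                   unique_peptides = sample(3:25, 1), stringsAsFactors = FALSE)
      }),
      low_fold = lapply(in_runs, function(rn) {
        score <- round(runif(1, 60, 300), 1)
        fold <- if (i <= 3) 2.99 else runif(1, 1.2, 2.9)
        data.frame(protein = protein, run = rn, mascot_bait = score,
                   mascot_control = round(score / fold, 4),
                   unique_peptides = sample(3:25, 1), stringsAsFactors = FALSE)
      }),
      one_run = list(passing_row(protein, sample(runs, 1))))
    rows <- c(rows, r)
    truth[[length(truth) + 1L]] <-
      data.frame(protein = protein, is_true = FALSE, failure_mode = modes[i],
                 stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  if (nrow(hits) > 0) hits <- hits[sample(nrow(hits)), , drop = FALSE]
  rownames(hits) <- NULL
  truth <- do.call(rbind, truth)
  if (is.null(truth))
    truth <- data.frame(protein = character(), is_true = logical(),
                        failure_mode = character(), stringsAsFactors = FALSE)
  list(hits = hits, truth = truth)
}

#' Write a peak table as a BED+summit (narrowPeak-style) file
#'
#' Ten columns; column 10 is the summit offset from the interval start, so
#' the file round-trips through [read_peaks()] with `dialect = "bed-summit"`.
#'
#' @param pk Peak `data.frame`.
#' @param path Output path.
#' @export
write_peaks_bed <- function(pk, path) {
  bed <- data.frame(pk$chrom, pk$start, pk$end, pk$id, 0L, ".",
                    0, -1, -1, pk$summit - pk$start)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
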