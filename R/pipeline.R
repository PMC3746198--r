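# Orchestration: ChIP-seq peaks -> joint -> consensus -> motif scan ->
# enrichment -> gene links; AP-MS table -> interactor calls; SELEX simulate
# -> motif recovery. Every stage is also callable standalone on files
# produced by the previous stage.

#' Analysis configuration with the published default parameters
#'
#' The defaults reproduce the published analysis settings: +/- 50 bp summit
#' windows, >= 1 bp overlap to join peaks, <= 30 kb TSS link distance, the
#' bipartite Nanog/Sox2 pattern, Mascot > 50 / fold >= 3 / 2-of-3-run
#' interactome criteria, and a 5-round SELEX with the published library
#' design.
#'
#' @param flank Summit half-window in bp.
#' @param min_overlap Minimum window overlap in bp for joint peaks.
#' @param max_tss_distance Maximum cluster-to-TSS link distance in bp.
#' @param pattern_text Motif as bracket-class text.
#' @param n_required Datasets required for a consensus cluster (`NULL` = all).
#' @param min_score,min_fold,min_peptides,required_runs Interactome criteria.
#' @param selex_pool_size,selex_rounds,capture_base,capture_bound SELEX
#'   simulation parameters.
#' @param seed Integer seed for stochastic stages.
#' @return An `analysis_config` (named list).
#' @export
analysis_config <- function(flank = 50L, min_overlap = 1L,
                            max_tss_distance = 30000L,
                            pattern_text = "A[TGA]T..[TC][AT]TT[GCT][AT]",
                            n_required = NULL,
                            min_score = 50, min_fold = 3, min_peptides = 3,
                            required_runs = 2L,
                            selex_pool_size = 100000L, selex_rounds = 5L,
                            capture_base = 0.05, capture_bound = 0.9,
                            seed = 1L) {
  structure(list(flank = as.integer(flank),
                 min_overlap = as.integer(min_overlap),
                 max_tss_distance = as.integer(max_tss_distance),
                 pattern_text = pattern_text, n_required = n_required,
                 min_score = min_score, min_fold = min_fold,
                 min_peptides = min_peptides,
                 required_runs = as.integer(required_runs),
                 selex_pool_size = as.integer(selex_pool_size),
                 selex_rounds = as.integer(selex_rounds),
                 capture_base = capture_base, capture_bound = capture_bound,
                 seed = seed),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#' @param path YAML file path.
#' @return An `analysis_config`; fields absent from the file keep defaults.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- do.call(analysis_config, vals[names(vals) %in%
                                         names(formals(analysis_config))])
  cfg
}

#' Write an analysis configuration as YAML
#' @param config An `analysis_config`.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

provenance <- function(config) {
  list(package = "nsmotif",
       version = as.character(utils::packageVersion("nsmotif")),
       config = unclass(config), seed = config$seed)
}

#' Run the combined ChIP-seq joint-peak and motif analysis
#'
#' Summit-centres every peak set, calls within-dataset joint Nanog/Sox2
#' clusters, intersects them across datasets into consensus clusters, scans
#' consensus spans and non-joint (single-factor) windows for the motif,
#' computes the hypergeometric enrichment, and links consensus clusters to
#' the nearest TSS. Deterministic given its inputs.
#'
#' @param peak_sets Nested list: dataset label -> factor label -> peak
#'   `data.frame` (from [read_peaks()] or [make_peak_datasets()]).
#' @param genome Named `Biostrings::DNAStringSet`.
#' @param tss_table TSS `data.frame` (gene, chrom, tss, strand), or `NULL` to
#'   skip gene linking.
#' @param config An `analysis_config`.
#' @return An `analysis_report`: per-dataset joint counts, total joint count,
#'   consensus count and clusters, `enrichment` (`NULL` with
#'   `enrichment_computable = FALSE` when either side of the contingency is
#'   empty), gene links, and provenance.
#' @export
run_chipseq_analysis <- function(peak_sets, genome, tss_table = NULL,
                                 config = analysis_config()) {
  pattern <- parse_pattern(config$pattern_text)
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  for (ds in names(peak_sets)) for (f in names(peak_sets[[ds]])) {
    pk <- peak_sets[[ds]][[f]]
    bad <- setdiff(unique(pk$chrom), names(genome))
    if (length(bad) > 0)
      stop("peak chromosomes absent from genome: ", paste(bad, collapse = ", "))
    peak_sets[[ds]][[f]] <- center_on_summit(pk, config$flank, chrom_lengths)
  }
  joint <- list()
  bg <- list()
  for (ds in names(peak_sets)) {
    fs <- names(peak_sets[[ds]])
    nanog <- peak_sets[[ds]][[grep("nanog", fs, ignore.case = TRUE, value = TRUE)[1]]]
    sox2 <- peak_sets[[ds]][[grep("sox2", fs, ignore.case = TRUE, value = TRUE)[1]]]
    joint[[ds]] <- joint_peaks(nanog, sox2, config$min_overlap)
    members <- unlist(strsplit(joint[[ds]]$member_ids, ","))
    pooled <- rbind(nanog, sox2)
    bg[[ds]] <- pooled[!(pooled$id %in% members), , drop = FALSE]
  }
  cons <- consensus_joint(joint, config$n_required)
  bg_peaks <- do.call(rbind, bg)
  enr <- NULL
  computable <- cons$n_consensus > 0 && nrow(bg_peaks) > 0
  if (computable) {
    # scan equal extents in foreground and background: a fixed-width window
    # centred on the cluster-span midpoint, same width as the background
    # summit windows, so the null (equal motif rates) is calibrated
    fg_scan <- standardize_spans(cons$clusters, config$flank, chrom_lengths)
    enr <- motif_enrichment(fg_scan, bg_peaks, genome, pattern)
  }
  links <- NULL
  if (!is.null(tss_table) && cons$n_consensus > 0)
    links <- nearest_tss(cons$clusters, tss_table, config$max_tss_distance)
  structure(list(
    per_dataset_joint = vapply(joint, nrow, integer(1)),
    total_joint = cons$total_joint,
    n_consensus = cons$n_consensus,
    joint_clusters = joint,
    consensus_clusters = cons$clusters,
    background_peaks = bg_peaks,
    enrichment = enr,
    enrichment_computable = computable,
    gene_links = links,
    provenance = provenance(config)
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Joint Nanog/Sox2 peak analysis\n")
  cat("  joint clusters per dataset: ",
      paste(sprintf("%s=%d", names(x$per_dataset_joint), x$per_dataset_joint),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  total joint clusters: %d\n", x$total_joint))
  cat(sprintf("  consensus clusters (all datasets): %d\n", x$n_consensus))
  if (x$enrichment_computable) print(x$enrichment)
  else cat("  enrichment: not computable (empty foreground or background)\n")
  if (!is.null(x$gene_links))
    cat(sprintf("  gene links: %d of %d clusters linked within cutoff\n",
                sum(!is.na(x$gene_links$gene)), nrow(x$gene_links)))
  invisible(x)
}

#' Write the analysis report files
#'
#' Emits the consensus clusters as BED, the enrichment report (text + TSV),
#' the gene-link table, and a counts summary TSV under `dir`.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_analysis_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- data.frame(
    key = c(paste0("joint_", names(report$per_dataset_joint)),
            "total_joint", "n_consensus"),
    value = c(unname(report$per_dataset_joint), report$total_joint,
              report$n_consensus))
  write.table(counts, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (report$n_consensus > 0)
    write_clusters_bed(report$consensus_clusters,
                       file.path(dir, "consensus_clusters.bed"))
  if (report$enrichment_computable)
    write_enrichment_report(report$enrichment,
                            file.path(dir, "enrichment.txt"),
                            file.path(dir, "enrichment.tsv"))
  if (!is.null(report$gene_links))
    write_gene_links(report$gene_links, file.path(dir, "gene_links.tsv"))
  invisible(dir)
}

#' Run the interactome filter
#'
#' Wraps [call_interactors()] with the configured thresholds.
#'
#' @param hits Hit `data.frame` or path to a TSV readable by
#'   [read_ms_table()].
#' @param config An `analysis_config`.
#' @param run_labels Known run labels (default: runs present in the table).
#' @return List: `calls` (call table), `n_called`, `provenance`.
#' @export
run_interactome <- function(hits, config = analysis_config(),
                            run_labels = NULL) {
  if (is.character(hits)) hits <- read_ms_table(hits)
  calls <- call_interactors(hits, required_runs = config$required_runs,
                            run_labels = run_labels,
                            min_score = config$min_score,
                            min_fold = config$min_fold,
                            min_peptides = config$min_peptides)
  list(calls = calls, n_called = sum(calls$called),
       provenance = provenance(config))
}

#' Run the SELEX simulation and recover the selected motif
#'
#' Simulates the configured number of enrichment rounds under a two-level
#' capture model for the configured pattern, extracts the best site per
#' final-pool oligo, and rebuilds the motif as a PWM with its degenerate
#' consensus.
#'
#' @param config An `analysis_config`.
#' @param seed Seed (defaults to `config$seed`).
#' @return List: `run` (`selex_run`), `sites`, `pwm`, `consensus_pattern`,
#'   `trajectory`, `provenance`.
#' @export
run_selex_sim <- function(config = analysis_config(), seed = config$seed) {
  pattern <- parse_pattern(config$pattern_text)
  spec <- oligo_library_spec(pool_size = config$selex_pool_size, seed = seed)
  model <- binding_model(pattern, capture_base = config$capture_base,
                         capture_bound = config$capture_bound)
  run <- run_selex(spec, model, rounds = config$selex_rounds)
  sites <- extract_sites(run$final_pool, pattern, spec)
  pwm <- if (length(sites) > 0) pwm_from_sites(sites) else NULL
  list(run = run, sites = sites, pwm = pwm,
       consensus_pattern = if (!is.null(pwm)) degenerate_consensus(pwm) else NULL,
       trajectory = run$trajectory, provenance = provenance(config))
}
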