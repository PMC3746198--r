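#' @importFrom stats runif rnorm rbinom setNames
#' @importFrom utils read.table write.table
NULL

# Peaks are plain data frames with 0-based half-open coordinates
# (BED convention): chrom, start, end, summit, factor, dataset, id.
PEAK_COLS <- c("chrom", "start", "end", "summit", "factor", "dataset", "id")

#' Construct a validated peak table
#'
#' Peaks are genomic intervals in 0-based half-open (BED) coordinates with a
#' summit (position of maximal signal), a transcription-factor label and a
#' source-dataset label.
#'
#' @param chrom Chromosome names.
#' @param start 0-based inclusive start coordinates.
#' @param end Exclusive end coordinates (`end > start`).
#' @param summit Absolute summit coordinates; defaults to the interval
#'   midpoint `floor((start + end) / 2)` when `NULL`.
#' @param factor Factor label per peak (e.g. `"Nanog"`, `"Sox2"`).
#' @param dataset Source dataset label per peak.
#' @param id Unique peak identifiers; auto-generated when `NULL`.
#' @return A `data.frame` with columns chrom, start, end, summit, factor,
#'   dataset, id.
#' @export
peaks <- function(chrom, start, end, summit = NULL, factor = "Nanog",
                  dataset = "ds1", id = NULL) {
  n <- length(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 0)) stop("peak start coordinates must be >= 0")
  if (any(end <= start)) stop("peak end must exceed start (half-open intervals)")
  if (is.null(summit)) summit <- (start + end) %/% 2L
  summit <- as.integer(summit)
  if (any(summit < start | summit >= end))
    stop("summit must lie inside the peak interval [start, end)")
  if (is.null(id)) {
    id <- sprintf("%s_%s_%06d", rep_len(dataset, n), rep_len(factor, n), seq_len(n))
  }
  if (anyDuplicated(id)) stop("peak ids must be unique")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             summit = summit, factor = rep_len(as.character(factor), n),
             dataset = rep_len(as.character(dataset), n),
             id = as.character(id), stringsAsFactors = FALSE)
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             summit = integer(), factor = character(), dataset = character(),
             id = character(), stringsAsFactors = FALSE)
}

#' Read a peak file in BED3 or BED+summit dialect
#'
#' `bed3` files carry chrom/start/end; the summit defaults to the interval
#' midpoint. `bed-summit` files are narrowPeak-style (BED6+4) where the 10th
#' column is the summit offset from the interval start.
#'
#' @param path File path.
#' @param dialect `"bed3"` or `"bed-summit"`.
#' @param factor,dataset Labels attached to every peak in the file.
#' @return A peak `data.frame` (see [peaks()]).
#' @export
read_peaks <- function(path, dialect = c("bed3", "bed-summit"),
                       factor = "Nanog", dataset = "ds1") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_peaks())
  need <- if (dialect == "bed3") 3L else 10L
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < need)
      stop(sprintf("parse error in %s line %d: expected >=%d tab-separated fields, got %d",
                   path, i, need, length(f)))
    if (is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3]))))
      stop(sprintf("parse error in %s line %d: non-numeric coordinates", path, i))
  }
  start <- vapply(fields, function(f) as.integer(f[2]), integer(1))
  end <- vapply(fields, function(f) as.integer(f[3]), integer(1))
  if (any(end <= start)) {
    bad <- which(end <= start)[1]
    stop(sprintf("validation error in %s line %d: end <= start", path, bad))
  }
  chrom <- vapply(fields, `[`, character(1), 1)
  if (dialect == "bed-summit") {
    offset <- vapply(fields, function(f) as.integer(f[10]), integer(1))
    if (anyNA(offset)) stop("parse error: non-numeric summit offset column")
    summit <- start + offset
    nm <- vapply(fields, `[`, character(1), 4)
    if (anyDuplicated(nm)) nm <- NULL
    peaks(chrom, start, end, summit, factor = factor, dataset = dataset, id = nm)
  } else {
    peaks(chrom, start, end, factor = factor, dataset = dataset)
  }
}

#' Centre peaks on their summit
#'
#' Replaces each interval by the window of `flank` bp on each side of the
#' summit (width `2 * flank + 1`; 101 bp at the default), clipped at
#' coordinate 0 and, when chromosome lengths are supplied, at the chromosome
#' end. The summit itself is unchanged, so the operation is idempotent with
#' respect to the summit.
#'
#' @param pk Peak `data.frame`.
#' @param flank Half-window in bp (default 50).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   right-clipping.
#' @return Peak `data.frame` with recentred intervals.
#' @export
center_on_summit <- function(pk, flank = 50L, chrom_lengths = NULL) {
  stopifnot(flank >= 0)
  flank <- as.integer(flank)
  if (nrow(pk) == 0) return(pk)
  pk$start <- pmax(0L, pk$summit - flank)
  pk$end <- pk$summit + flank + 1L
  if (!is.null(chrom_lengths)) {
    len <- unname(chrom_lengths[pk$chrom])
    if (anyNA(len)) stop("peak chromosome missing from chrom_lengths: ",
                         paste(unique(pk$chrom[is.na(len)]), collapse = ", "))
    pk$end <- pmin(pk$end, as.integer(len))
  }
  pk
}

#' Overlap length of two genomic intervals
#'
#' Vectorised over rows. Intervals are half-open, so adjacent intervals
#' overlap by 0 bp; intervals on different chromosomes overlap by 0 bp.
#'
#' @param a,b Data frames (or single-row lists) with `chrom`, `start`, `end`.
#' @return Integer vector of overlap lengths in bp.
#' @export
overlap_length <- function(a, b) {
  ov <- pmin(a$end, b$end) - pmax(a$start, b$start)
  as.integer(ifelse(a$chrom == b$chrom, pmax(0L, ov), 0L))
}

# Single-linkage clustering of intervals by >= min_overlap bp overlap.
# Returns an integer membership vector. `edges_between` optionally restricts
# graph edges to pairs (i in set A, j in set B) given as logical masks.
single_linkage_clusters <- function(chrom, start, end, min_overlap = 1L,
                                    mask_a = NULL, mask_b = NULL) {
  n <- length(chrom)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  if (is.null(mask_a)) {
    hits <- GenomicRanges::findOverlaps(gr, minoverlap = min_overlap,
                                        drop.self = TRUE, drop.redundant = TRUE)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
  } else {
    ia <- which(mask_a); ib <- which(mask_b)
    hits <- GenomicRanges::findOverlaps(gr[ia], gr[ib], minoverlap = min_overlap)
    qh <- ia[S4Vectors::queryHits(hits)]
    sh <- ib[S4Vectors::subjectHits(hits)]
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(qh) > 0)
    g <- igraph::add_edges(g, rbind(qh, sh))
  igraph::components(g)$membership
}

# Build a cluster table from peaks plus a membership vector, keeping the
# clusters selected by `keep` (logical indexed by cluster id).
build_clusters <- function(pk, membership, keep, id_prefix) {
  sel <- keep[membership]
  if (!any(sel)) return(empty_clusters())
  idx <- split(which(sel), membership[sel])
  joinu <- function(x) paste(sort(unique(x)), collapse = ",")
  out <- data.frame(
    chrom = vapply(idx, function(i) pk$chrom[i[1]], character(1)),
    start = vapply(idx, function(i) min(pk$start[i]), integer(1)),
    end = vapply(idx, function(i) max(pk$end[i]), integer(1)),
    n_members = lengths(idx),
    datasets = vapply(idx, function(i) joinu(pk$dataset[i]), character(1)),
    factors = vapply(idx, function(i) joinu(pk$factor[i]), character(1)),
    member_ids = vapply(idx, function(i) paste(sort(pk$id[i]), collapse = ","),
                        character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$member_ids), , drop = FALSE]
  out$cluster_id <- sprintf("%s_%06d", id_prefix, seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("cluster_id", "chrom", "start", "end", "n_members",
          "datasets", "factors", "member_ids")]
}

empty_clusters <- function() {
  data.frame(cluster_id = character(), chrom = character(), start = integer(),
             end = integer(), n_members = integer(), datasets = character(),
             factors = character(), member_ids = character(),
             stringsAsFactors = FALSE)
}

#' Call joint Nanog/Sox2 peaks within one dataset
#'
#' Builds the graph whose edges are Nanog-Sox2 window pairs overlapping by at
#' least `min_overlap` bp and returns its single-linkage connected components
#' that contain both factors. Peaks are expected to be already summit-centred.
#' The cluster span is the union of member intervals.
#'
#' @param nanog,sox2 Summit-centred peak `data.frame`s from the same dataset.
#' @param min_overlap Minimum overlap in bp to create an edge (default 1).
#' @return Cluster `data.frame` sorted by (chrom, span start): cluster_id,
#'   chrom, start, end, n_members, datasets, factors, member_ids.
#' @export
joint_peaks <- function(nanog, sox2, min_overlap = 1L) {
  pk <- rbind(nanog, sox2)
  if (nrow(pk) == 0) return(empty_clusters())
  ds <- unique(pk$dataset)
  if (length(ds) > 1)
    stop("joint_peaks requires peaks from a single dataset; got: ",
         paste(ds, collapse = ", "))
  is_n <- seq_len(nrow(pk)) <= nrow(nanog)
  memb <- single_linkage_clusters(pk$chrom, pk$start, pk$end,
                                  min_overlap = as.integer(min_overlap),
                                  mask_a = is_n, mask_b = !is_n)
  # a cluster is joint iff it contains both factor sets
  tab_n <- table(factor(memb[is_n], levels = seq_len(max(memb))))
  tab_s <- table(factor(memb[!is_n], levels = seq_len(max(memb))))
  keep <- as.vector(tab_n > 0 & tab_s > 0)
  build_clusters(pk, memb, keep, paste0(ds, "_joint"))
}

#' Cross-dataset consensus of joint peak clusters
#'
#' Single-linkage clusters the spans of per-dataset joint clusters (>= 1 bp
#' overlap) and keeps clusters supported by at least `n_required` datasets
#' (default: all supplied datasets). The number of kept clusters is the
#' consensus-peak count.
#'
#' @param per_dataset_joint Named list mapping dataset label to its joint
#'   cluster `data.frame` (from [joint_peaks()]).
#' @param n_required Minimum number of distinct datasets per consensus
#'   cluster; `NULL` means all supplied datasets.
#' @return List with `clusters` (consensus cluster `data.frame`),
#'   `n_consensus`, and `total_joint` (joint clusters summed over datasets).
#' @export
consensus_joint <- function(per_dataset_joint, n_required = NULL) {
  stopifnot(length(per_dataset_joint) >= 2)
  if (is.null(n_required)) n_required <- length(per_dataset_joint)
  total_joint <- sum(vapply(per_dataset_joint, nrow, integer(1)))
  spans <- do.call(rbind, lapply(names(per_dataset_joint), function(ds) {
    cl <- per_dataset_joint[[ds]]
    if (nrow(cl) == 0) return(NULL)
    data.frame(chrom = cl$chrom, start = cl$start, end = cl$end,
               summit = (cl$start + cl$end) %/% 2L, factor = cl$factors,
               dataset = ds, id = cl$cluster_id, stringsAsFactors = FALSE)
  }))
  if (is.null(spans) || nrow(spans) == 0)
    return(list(clusters = empty_clusters(), n_consensus = 0L,
                total_joint = total_joint))
  memb <- single_linkage_clusters(spans$chrom, spans$start, spans$end, 1L)
  nds <- vapply(split(spans$dataset, memb), function(d) length(unique(d)),
                integer(1))
  keep <- logical(max(memb))
  keep[as.integer(names(nds))] <- nds >= n_required
  clusters <- build_clusters(spans, memb, keep, "consensus")
  # factors column of consensus clusters: union of member factor strings
  if (nrow(clusters) > 0) {
    clusters$factors <- vapply(strsplit(clusters$factors, ","), function(f)
      paste(sort(unique(f)), collapse = ","), character(1))
  }
  list(clusters = clusters, n_consensus = nrow(clusters),
       total_joint = total_joint)
}

#' Replace cluster spans by fixed-width midpoint windows
#'
#' Returns the clusters with each span replaced by the window of `flank` bp
#' on either side of the span midpoint (width `2 * flank + 1`), clipped at
#' coordinate 0 and at the chromosome end when lengths are given. Used to
#' scan foreground clusters over the same extent as background summit
#' windows, which keeps motif-rate comparisons calibrated.
#'
#' @param clusters Cluster `data.frame` (cluster_id, chrom, start, end, ...).
#' @param flank Half-window in bp (default 50).
#' @param chrom_lengths Optional named chromosome lengths.
#' @return Cluster `data.frame` with standardized spans.
#' @export
standardize_spans <- function(clusters, flank = 50L, chrom_lengths = NULL) {
  if (nrow(clusters) == 0) return(clusters)
  mid <- (clusters$start + clusters$end) %/% 2L
  clusters$start <- pmax(0L, mid - as.integer(flank))
  clusters$end <- mid + as.integer(flank) + 1L
  if (!is.null(chrom_lengths))
    clusters$end <- pmin(clusters$end,
                         as.integer(unname(chrom_lengths[clusters$chrom])))
  clusters
}

#' Link clusters to the nearest transcription start site
#'
#' Distance is measured from the cluster-span midpoint to the TSS on the same
#' chromosome, strand-agnostically. A link is reported only when the minimum
#' distance is at most `max_distance` (30 kb by default); exact ties are
#' broken by the lowest TSS coordinate.
#'
#' @param clusters Cluster `data.frame` (needs cluster_id, chrom, start, end).
#' @param tss_table `data.frame` with columns gene, chrom, tss, strand.
#' @param max_distance Maximum link distance in bp.
#' @return `data.frame` (cluster_id, gene, distance), one row per cluster;
#'   gene is `NA` and distance `NA` for unlinked clusters.
#' @export
nearest_tss <- function(clusters, tss_table, max_distance = 30000L) {
  stopifnot(nrow(tss_table) > 0)
  tss_table <- tss_table[order(tss_table$chrom, tss_table$tss), , drop = FALSE]
  mid <- (clusters$start + clusters$end) %/% 2L
  link <- lapply(seq_len(nrow(clusters)), function(i) {
    cand <- tss_table[tss_table$chrom == clusters$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) return(list(gene = NA_character_, distance = NA_integer_))
    d <- abs(cand$tss - mid[i])
    j <- which(d == min(d))[1]  # candidates sorted by tss => lowest coordinate wins ties
    if (d[j] > max_distance) return(list(gene = NA_character_, distance = NA_integer_))
    list(gene = cand$gene[j], distance = as.integer(d[j]))
  })
  data.frame(cluster_id = clusters$cluster_id,
             gene = vapply(link, `[[`, character(1), "gene"),
             distance = vapply(link, `[[`, integer(1), "distance"),
             stringsAsFactors = FALSE)
}

#' Write clusters as BED6 with dataset annotation
#'
#' Columns: chrom, start, end, cluster id, member count (score slot), strand
#' `.`, then a comma-joined `datasets` column.
#'
#' @param clusters Cluster `data.frame`.
#' @param path Output path.
#' @export
write_clusters_bed <- function(clusters, path) {
  bed <- data.frame(clusters$chrom, clusters$start, clusters$end,
                    clusters$cluster_id, clusters$n_members, ".",
                    clusters$datasets)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write cluster-to-gene links as TSV
#'
#' @param links Link `data.frame` from [nearest_tss()].
#' @param path Output path.
#' @export
write_gene_links <- function(links, path) {
  write.table(links, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Tab-separated with header columns gene, chrom, tss, strand.
#'
#' @param path File path.
#' @return `data.frame` of TSS records.
#' @export
read_tss_table <- function(path) {
  tt <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "strand")
  if (!all(need %in% names(tt)))
    stop("TSS table missing columns: ", paste(setdiff(need, names(tt)), collapse = ", "))
  if (any(tt$tss < 0)) stop("TSS coordinates must be >= 0")
  tt
}

#' Write a TSS annotation table
#' @param tss_table `data.frame` with gene, chrom, tss, strand.
#' @param path Output path.
#' @export
write_tss_table <- function(tss_table, path) {
  write.table(tss_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
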