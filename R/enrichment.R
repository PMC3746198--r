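# Motif over-representation in foreground (consensus joint) peaks versus
# background (single-factor) peaks, tested with the hypergeometric upper tail.

#' Percentage rounded half away from zero to one decimal
#'
#' @param k Numerator count.
#' @param n Denominator count (> 0).
#' @return `100 * k / n` rounded half away from zero to 1 decimal.
#' @export
percent <- function(k, n) {
  if (any(n == 0)) stop("percent undefined for n = 0")
  stopifnot(all(k >= 0), all(k <= n))
  p <- 100 * k / n
  sign(p) * trunc(abs(p) * 10 + 0.5) / 10
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X` hypergeometric with population size `N`, `K` success
#' states and `n` draws, one-sided and including the observed value. Computed
#' in log space, accurate for tail probabilities down to the smallest
#' representable doubles.
#'
#' @param k Observed successes in the draw.
#' @param n Number of draws.
#' @param K Success states in the population.
#' @param N Population size.
#' @param log10p Return the base-10 logarithm instead of the probability.
#' @return Probability in (0, 1] (or its log10).
#' @export
hypergeom_upper <- function(k, n, K, N, log10p = FALSE) {
  if (!(k >= 0 && k <= n && n <= N && k <= K && K <= N))
    stop("hypergeom_upper requires 0 <= k <= n <= N and k <= K <= N")
  lp <- stats::phyper(k - 1, m = K, n = N - K, k = n,
                      lower.tail = FALSE, log.p = TRUE)
  if (log10p) lp / log(10) else exp(lp)
}

#' Assemble an enrichment result from a 2x2 motif contingency
#'
#' Foreground: consensus joint peaks; background: single-factor peaks. The
#' hypergeometric population is the pooled peaks (`n_fg + n_bg`) with
#' `k_fg + k_bg` motif-positive members, from which the foreground is an
#' `n_fg`-sized draw.
#'
#' @param k_fg,n_fg Motif-positive and total foreground peaks.
#' @param k_bg,n_bg Motif-positive and total background peaks.
#' @return An `enrichment_result`: contingency counts, fractions (percent,
#'   1 decimal), fold (ratio of raw fractions), `p_upper`, `log10_p`.
#' @export
enrichment_from_counts <- function(k_fg, n_fg, k_bg, n_bg) {
  stopifnot(k_fg >= 0, k_fg <= n_fg, k_bg >= 0, k_bg <= n_bg,
            n_fg > 0, n_bg > 0)
  rate_fg <- k_fg / n_fg
  rate_bg <- k_bg / n_bg
  structure(list(
    contingency = list(k_fg = k_fg, n_fg = n_fg, k_bg = k_bg, n_bg = n_bg),
    fraction_fg = percent(k_fg, n_fg),
    fraction_bg = percent(k_bg, n_bg),
    fold = if (rate_bg > 0) rate_fg / rate_bg else Inf,
    p_upper = hypergeom_upper(k_fg, n_fg, k_fg + k_bg, n_fg + n_bg),
    log10_p = hypergeom_upper(k_fg, n_fg, k_fg + k_bg, n_fg + n_bg,
                              log10p = TRUE)
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  ct <- x$contingency
  cat(sprintf("motif enrichment: %d/%d foreground (%.1f%%) vs %d/%d background (%.1f%%)\n",
              ct$k_fg, ct$n_fg, x$fraction_fg, ct$k_bg, ct$n_bg, x$fraction_bg))
  cat(sprintf("  fold = %.3g, hypergeometric upper-tail P = %.3g (log10 = %.2f)\n",
              x$fold, x$p_upper, x$log10_p))
  invisible(x)
}

# Extract span sequences from a DNAStringSet genome; errors name the id of
# any span outside chromosome bounds. Coordinates are 0-based half-open.
extract_span_seqs <- function(genome, chrom, start, end, ids) {
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  missing <- !(chrom %in% names(genome))
  if (any(missing))
    stop("chromosome not in genome for peak ", ids[which(missing)[1]])
  bad <- start < 0 | end > lens[chrom]
  if (any(bad))
    stop("span outside genome bounds for peak ", ids[which(bad)[1]])
  out <- Biostrings::DNAStringSet(rep("", length(chrom)))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    out[sel] <- Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(start[sel] + 1L, end[sel]))
  }
  names(out) <- ids
  out
}

#' Motif enrichment of foreground clusters over background peaks
#'
#' Scans the consensus-cluster spans (foreground) and the summit-centred
#' single-factor windows (background) for the pattern on both strands, builds
#' the 2x2 contingency and computes the hypergeometric upper-tail
#' probability.
#'
#' @param fg Cluster `data.frame` (consensus joint clusters; spans scanned).
#' @param bg Peak `data.frame` (peaks in no joint cluster; windows scanned).
#' @param genome Named `Biostrings::DNAStringSet`.
#' @param pattern A `degenerate_pattern` (default [ns_pattern()]).
#' @return An `enrichment_result`.
#' @export
motif_enrichment <- function(fg, bg, genome, pattern = ns_pattern()) {
  if (nrow(fg) == 0 || nrow(bg) == 0)
    stop("motif_enrichment requires non-empty foreground and background")
  fg_seq <- extract_span_seqs(genome, fg$chrom, fg$start, fg$end, fg$cluster_id)
  bg_seq <- extract_span_seqs(genome, bg$chrom, bg$start, bg$end, bg$id)
  k_fg <- sum(spans_have_motif(fg_seq, pattern))
  k_bg <- sum(spans_have_motif(bg_seq, pattern))
  enrichment_from_counts(k_fg, nrow(fg), k_bg, nrow(bg))
}

#' Write an enrichment report
#'
#' Writes a human-readable text file and a flat key-value TSV with fields
#' k_fg, n_fg, k_bg, n_bg, fraction_fg, fraction_bg, fold, p_upper, log10_p.
#'
#' @param result An `enrichment_result`.
#' @param path_txt,path_tsv Output paths (either may be `NULL` to skip).
#' @export
write_enrichment_report <- function(result, path_txt = NULL, path_tsv = NULL) {
  ct <- result$contingency
  if (!is.null(path_txt)) {
    txt <- c(sprintf("Foreground: %d of %d peaks motif-positive (%.1f%%)",
                     ct$k_fg, ct$n_fg, result$fraction_fg),
             sprintf("Background: %d of %d peaks motif-positive (%.1f%%)",
                     ct$k_bg, ct$n_bg, result$fraction_bg),
             sprintf("Fold enrichment: %.4g", result$fold),
             sprintf("Hypergeometric upper-tail P: %.4g (log10 = %.4f)",
                     result$p_upper, result$log10_p))
    writeLines(txt, path_txt)
  }
  if (!is.null(path_tsv)) {
    tab <- data.frame(
      key = c("k_fg", "n_fg", "k_bg", "n_bg", "fraction_fg", "fraction_bg",
              "fold", "p_upper", "log10_p"),
      value = c(ct$k_fg, ct$n_fg, ct$k_bg, ct$n_bg, result$fraction_fg,
                result$fraction_bg, result$fold, result$p_upper,
                result$log10_p))
    write.table(tab, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(result)
}
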