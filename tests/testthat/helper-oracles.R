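# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the implementation paths they test.

# O(n^2) single-linkage clustering by pairwise interval overlap, via BFS on
# an explicit adjacency matrix. `edge_ok[i, j]` can further restrict edges
# (e.g. to Nanog-Sox2 pairs).
oracle_single_linkage <- function(chrom, start, end, min_overlap = 1,
                                  edge_ok = NULL) {
  n <- length(chrom)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ov <- if (chrom[i] == chrom[j])
      max(0, min(end[i], end[j]) - max(start[i], start[j])) else 0
    ok <- ov >= min_overlap
    if (!is.null(edge_ok)) ok <- ok && edge_ok[i, j]
    adj[i, j] <- ok
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Oracle for joint_peaks: cluster memberships with edges restricted to
# Nanog-Sox2 pairs, then the sorted list of member-id sets of clusters
# containing both factors.
oracle_joint_member_sets <- function(nanog, sox2, min_overlap = 1) {
  pk <- rbind(nanog, sox2)
  is_n <- c(rep(TRUE, nrow(nanog)), rep(FALSE, nrow(sox2)))
  edge_ok <- outer(is_n, is_n, FUN = function(a, b) xor(a, b))
  comp <- oracle_single_linkage(pk$chrom, pk$start, pk$end, min_overlap,
                                edge_ok)
  sets <- split(pk$id, comp)
  both <- vapply(split(is_n, comp), function(x) any(x) && any(!x), logical(1))
  unname(sort(vapply(sets[both], function(s) paste(sort(s), collapse = ","),
                     character(1)), method = "radix"))
}

# Regex-based scanning oracle: builds a per-position [ACGT...] character
# class regex (never '.', so N matches nothing) and finds overlapping
# matches with a lookahead; reverse strand scanned on the explicit reverse
# complement and mapped back to forward coordinates.
oracle_scan <- function(sequence, pattern) {
  rx_of <- function(p) paste(vapply(p$positions, function(s)
    paste0("[", paste(s, collapse = ""), "]"), character(1)), collapse = "")
  L <- length(pattern$positions)
  find0 <- function(seq, rx) {
    m <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  }
  revcomp <- function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  fwd <- find0(sequence, rx_of(pattern))
  rc_starts <- find0(revcomp(sequence), rx_of(pattern))
  rev <- sort(nchar(sequence) - rc_starts - L)
  out <- rbind(
    if (length(fwd)) data.frame(start = fwd, strand = "+") else NULL,
    if (length(rev)) data.frame(start = rev, strand = "-") else NULL)
  if (is.null(out)) return(data.frame(start = integer(), strand = character()))
  out <- out[order(out$start, out$strand != "+"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact hypergeometric upper tail by rational enumeration of
# C(K,i) C(N-K,n-i) / C(N,n) terms.
oracle_hyper_upper <- function(k, n, K, N) {
  i <- k:min(n, K)
  if (length(i) == 0 || k > min(n, K)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Random summit-centred peak instances for clustering property tests.
random_peak_instance <- function(n_nanog, n_sox2, n_chrom = 2,
                                 span = 3000, flank = 50) {
  mk <- function(n, f) {
    summit <- sample(flank:(span - flank), n, replace = TRUE)
    peaks(chrom = sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE),
          start = summit - flank, end = summit + flank + 1,
          summit = summit, factor = f, dataset = "ds1")
  }
  list(nanog = mk(n_nanog, "Nanog"), sox2 = mk(n_sox2, "Sox2"))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
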