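# Position weight matrices built from aligned binding sites.

#' Build a position weight matrix from aligned sites
#'
#' Tallies base counts per position and derives frequencies with an additive
#' pseudocount: `f[i][b] = (counts[i][b] + pseudocount) / (n_sites +
#' 4 * pseudocount)`, so each position sums to 1.
#'
#' @param sites Character vector (or `DNAStringSet`) of equal-length A/C/G/T
#'   sequences.
#' @param pseudocount Non-negative pseudocount added per base (default 1).
#' @return A `pwm` object: list with `counts` (4 x L matrix, rows A/C/G/T),
#'   `freq`, `pseudocount`, `n_sites`.
#' @export
pwm_from_sites <- function(sites, pseudocount = 1) {
  sites <- as.character(sites)
  if (length(sites) == 0) stop("pwm_from_sites requires at least one site")
  if (length(unique(nchar(sites))) != 1)
    stop("all sites must have equal length")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  ss <- Biostrings::DNAStringSet(sites)
  cm <- Biostrings::consensusMatrix(ss)
  counts <- matrix(0L, 4, nchar(sites[1]), dimnames = list(BASES, NULL))
  present <- intersect(rownames(cm), BASES)
  counts[present, ] <- cm[present, , drop = FALSE]
  if (any(colSums(counts) != length(sites)))
    stop("sites must contain only A/C/G/T")
  n <- length(sites)
  freq <- sweep(counts + pseudocount, 2, n + 4 * pseudocount, "/")
  structure(list(counts = counts, freq = freq, pseudocount = pseudocount,
                 n_sites = n), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM: %d positions from %d sites (pseudocount %g)\n",
              ncol(x$counts), x$n_sites, x$pseudocount))
  print(round(x$freq, 3))
  invisible(x)
}

#' Per-position information content of a PWM
#'
#' In bits, against a background distribution (uniform by default):
#' `sum_b f(b) * log2(f(b) / bg(b))`, with `0 * log(0) = 0`. Under a uniform
#' background this is `2 + sum_b f(b) * log2 f(b)`, the column height of a
#' sequence logo.
#'
#' @param pwm A `pwm`.
#' @param background Base probabilities in A/C/G/T order (default uniform).
#' @return Numeric vector, one value per position, each in [0, 2] for the
#'   uniform background.
#' @export
information_content <- function(pwm, background = rep(0.25, 4)) {
  stopifnot(length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-9)
  apply(pwm$freq, 2, function(f) {
    nz <- f > 0
    sum(f[nz] * log2(f[nz] / background[nz]))
  })
}

#' Degenerate consensus of a PWM
#'
#' Each position's allowed set is the bases with frequency at or above
#' `threshold`; a position admitting all four bases renders as a wildcard. If
#' no base reaches the threshold the maximum-frequency base(s) are used.
#'
#' @param pwm A `pwm`.
#' @param threshold Frequency threshold (default 0.25).
#' @return A `degenerate_pattern`.
#' @export
degenerate_consensus <- function(pwm, threshold = 0.25) {
  pos <- lapply(seq_len(ncol(pwm$freq)), function(i) {
    f <- pwm$freq[, i]
    allowed <- BASES[f >= threshold]
    if (length(allowed) == 0) allowed <- BASES[f == max(f)]
    allowed
  })
  p <- new_pattern(pos, NA_character_)
  p$source_text <- render_pattern(p)
  p
}

#' Write a PWM as a tab-separated position-count table
#'
#' Header comments record `n_sites` and `pseudocount` so [read_pwm()] can
#' reconstruct the object.
#'
#' @param pwm A `pwm`.
#' @param path Output path.
#' @export
write_pwm <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_sites=%d", pwm$n_sites),
               sprintf("# pseudocount=%g", pwm$pseudocount)), con)
  tab <- data.frame(pos = seq_len(ncol(pwm$counts)), t(pwm$counts))
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PWM written by [write_pwm()]
#' @param path File path.
#' @return A `pwm`.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  n_sites <- as.integer(sub(".*n_sites=", "", meta[grepl("n_sites=", meta)]))
  pseudo <- as.numeric(sub(".*pseudocount=", "", meta[grepl("pseudocount=", meta)]))
  tab <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE, sep = "\t")
  counts <- t(as.matrix(tab[, BASES]))
  dimnames(counts) <- list(BASES, NULL)
  freq <- sweep(counts + pseudo, 2, n_sites + 4 * pseudo, "/")
  structure(list(counts = counts, freq = freq, pseudocount = pseudo,
                 n_sites = n_sites), class = "pwm")
}

#' Write a PWM in MEME minimal motif format
#'
#' @param pwm A `pwm`.
#' @param path Output path.
#' @param name Motif name used in the MOTIF line.
#' @export
write_meme_minimal <- function(pwm, path, name = "motif_1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       ncol(pwm$freq), pwm$n_sites)), con)
  writeLines(apply(pwm$freq, 2, function(f) paste(sprintf("%.6f", f), collapse = " ")),
             con)
  invisible(path)
}

# Best log2-odds PWM score over all windows and both strands of a sequence.
# Returns -Inf when the sequence is shorter than the PWM.
pwm_best_score <- function(sequence, pwm, background = rep(0.25, 4)) {
  s <- strsplit(toupper(as.character(sequence)), "")[[1]]
  L <- ncol(pwm$freq)
  if (length(s) < L) return(-Inf)
  lo <- log2(pwm$freq / background)
  idx <- match(s, BASES)
  score_one <- function(code) {
    vapply(seq_len(length(s) - L + 1), function(st) {
      win <- code[st:(st + L - 1)]
      if (anyNA(win)) return(-Inf)
      sum(lo[cbind(win, seq_len(L))])
    }, numeric(1))
  }
  comp <- c(4L, 3L, 2L, 1L)
  rc_idx <- rev(ifelse(is.na(idx), NA, comp[idx]))
  max(score_one(idx), score_one(rc_idx))
}

# Maximum attainable score of a PWM (best base per position).
pwm_max_score <- function(pwm, background = rep(0.25, 4)) {
  sum(apply(log2(pwm$freq / background), 2, max))
}
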