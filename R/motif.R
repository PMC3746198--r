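BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes over the canonical 4-letter alphabet.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

canon_set <- function(x) BASES[BASES %in% x]

new_pattern <- function(positions, source_text) {
  structure(list(positions = lapply(positions, canon_set),
                 source_text = source_text),
            class = "degenerate_pattern")
}

#' Parse a degenerate DNA pattern
#'
#' Accepts bracket-class text as printed in motif descriptions (e.g.
#' `"A[TGA]T..[TC][AT]TT[GCT][AT]"`) or plain IUPAC code strings. `.` and `N`
#' denote a wildcard position (all four bases allowed).
#'
#' @param text Pattern text.
#' @return A `degenerate_pattern`: a list of per-position allowed-base sets
#'   plus the source text.
#' @export
parse_pattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1, nzchar(text))
  chars <- strsplit(toupper(text), "")[[1]]
  positions <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)
      if (length(close) == 0)
        stop(sprintf("pattern parse error at offset %d: unbalanced '['", i))
      close <- close[1]
      if (close == i + 1)
        stop(sprintf("pattern parse error at offset %d: empty bracket class", i))
      inner <- chars[(i + 1):(close - 1)]
      bad <- setdiff(inner, names(IUPAC_SETS))
      if (length(bad) > 0)
        stop(sprintf("pattern parse error at offset %d: invalid character '%s'",
                     i, bad[1]))
      positions[[length(positions) + 1L]] <-
        unique(unlist(IUPAC_SETS[inner], use.names = FALSE))
      i <- close + 1L
    } else if (ch == "]") {
      stop(sprintf("pattern parse error at offset %d: unbalanced ']'", i))
    } else if (ch == ".") {
      positions[[length(positions) + 1L]] <- BASES
      i <- i + 1L
    } else if (ch %in% names(IUPAC_SETS)) {
      positions[[length(positions) + 1L]] <- IUPAC_SETS[[ch]]
      i <- i + 1L
    } else {
      stop(sprintf("pattern parse error at offset %d: invalid character '%s'", i, ch))
    }
  }
  if (length(positions) == 0) stop("pattern parse error: empty pattern")
  new_pattern(positions, text)
}

#' Render a degenerate pattern as bracket-class text
#'
#' Single-base positions render as the base, full positions as `.`, others as
#' a bracket class in A/C/G/T order. `parse_pattern(render_pattern(p))`
#' reproduces `p`'s positions.
#'
#' @param pattern A `degenerate_pattern`.
#' @return Character scalar.
#' @export
render_pattern <- function(pattern) {
  paste(vapply(pattern$positions, function(s) {
    if (length(s) == 1) s
    else if (length(s) == 4) "."
    else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' @export
print.degenerate_pattern <- function(x, ...) {
  cat("degenerate pattern:", render_pattern(x),
      sprintf("(%d positions)\n", length(x$positions)))
  invisible(x)
}

#' Length of a degenerate pattern in positions
#' @param pattern A `degenerate_pattern`.
#' @return Integer.
#' @export
pattern_length <- function(pattern) length(pattern$positions)

#' The bipartite Nanog/Sox2 recognition pattern
#'
#' The composite pattern `A[TGA]T..[TC][AT]TT[GCT][AT]`: a Nanog-like
#' homeodomain half-site with a TAA core, a 2-bp spacer, and a Sox2-like
#' HMG-box half-site.
#'
#' @return A `degenerate_pattern` of 11 positions.
#' @export
ns_pattern <- function() parse_pattern("A[TGA]T..[TC][AT]TT[GCT][AT]")

# Pattern as an IUPAC code string (for Biostrings matching).
pattern_to_iupac <- function(pattern) {
  keys <- vapply(pattern$positions, paste, character(1), collapse = "")
  codes <- setNames(names(IUPAC_SETS),
                    vapply(IUPAC_SETS, function(s) paste(canon_set(s), collapse = ""),
                           character(1)))
  paste(codes[keys], collapse = "")
}

#' Reverse complement of a degenerate pattern
#' @param pattern A `degenerate_pattern`.
#' @return A `degenerate_pattern` matching the opposite strand.
#' @export
reverse_complement_pattern <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pos <- rev(lapply(pattern$positions, function(s) unname(comp[s])))
  new_pattern(pos, NA_character_)
}

#' Scan a DNA sequence for a degenerate pattern
#'
#' Reports every fully-contained (possibly overlapping) match. With
#' `both_strands = TRUE`, minus-strand matches (matches of the pattern's
#' reverse complement) are reported at their forward-strand coordinates with
#' the forward-strand text. `N` bases match no pattern position.
#'
#' @param sequence Character scalar or `Biostrings::DNAString` over A/C/G/T/N.
#' @param pattern A `degenerate_pattern`.
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return `data.frame` with columns start (0-based), strand (`+`/`-`), match
#'   (forward-strand text), ordered by (start, strand).
#' @export
scan_motif <- function(sequence, pattern, both_strands = TRUE) {
  subj <- if (inherits(sequence, "DNAString")) sequence
          else Biostrings::DNAString(sequence)
  L <- pattern_length(pattern)
  res <- list()
  if (length(subj) >= L) {
    fwd <- Biostrings::matchPattern(Biostrings::DNAString(pattern_to_iupac(pattern)),
                                    subj, fixed = "subject")
    if (length(fwd) > 0)
      res[[1]] <- data.frame(start = Biostrings::start(fwd) - 1L, strand = "+",
                             match = as.character(fwd), stringsAsFactors = FALSE)
    if (both_strands) {
      rcp <- reverse_complement_pattern(pattern)
      rev <- Biostrings::matchPattern(Biostrings::DNAString(pattern_to_iupac(rcp)),
                                      subj, fixed = "subject")
      if (length(rev) > 0)
        res[[2]] <- data.frame(start = Biostrings::start(rev) - 1L, strand = "-",
                               match = as.character(rev), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res) == 0)
    data.frame(start = integer(), strand = character(), match = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, res)
  # wildcard pattern positions must not match N in the subject; every valid
  # match is therefore pure A/C/G/T text
  out <- out[!grepl("N", out$match, fixed = TRUE), , drop = FALSE]
  out <- out[order(out$start, out$strand != "+"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Does a peak-span sequence contain the motif?
#'
#' `TRUE` iff at least one fully-contained match on either strand.
#'
#' @param sequence Span sequence (character or `DNAString`).
#' @param pattern A `degenerate_pattern`.
#' @return Logical scalar.
#' @export
peak_has_motif <- function(sequence, pattern) {
  nrow(scan_motif(sequence, pattern, both_strands = TRUE)) > 0
}

# Vectorised peak_has_motif over a DNAStringSet (both strands).
spans_have_motif <- function(seqs, pattern) {
  if (length(seqs) == 0) return(logical(0))
  fwd <- Biostrings::DNAString(pattern_to_iupac(pattern))
  rev <- Biostrings::DNAString(pattern_to_iupac(reverse_complement_pattern(pattern)))
  has <- Biostrings::vcountPattern(fwd, seqs, fixed = "subject") +
    Biostrings::vcountPattern(rev, seqs, fixed = "subject") > 0
  # a wildcard pattern position would match subject N in the fast count;
  # recheck those sequences with the N-aware scanner
  if (any(vapply(pattern$positions, length, integer(1)) == 4)) {
    suspect <- which(has &
                       Biostrings::vcountPattern("N", seqs, fixed = TRUE) > 0)
    for (i in suspect)
      has[i] <- peak_has_motif(seqs[[i]], pattern)
  }
  has
}

#' Combine two motif halves with a fixed wildcard gap
#'
#' Concatenates the left half, `gap` wildcard positions, and the right half.
#' With the Nanog-like half `A[TGA]T`, gap 2 and the Sox2-like half
#' `[TC][AT]TT[GCT][AT]` this reconstructs the bipartite Nanog/Sox2 pattern.
#'
#' @param left,right `degenerate_pattern`s.
#' @param gap Number of wildcard positions between the halves (default 2).
#' @return A `degenerate_pattern`.
#' @export
combine_halves <- function(left, right, gap = 2L) {
  stopifnot(gap >= 0)
  pos <- c(left$positions, rep(list(BASES), gap), right$positions)
  p <- new_pattern(pos, NA_character_)
  p$source_text <- render_pattern(p)
  p
}

#' Width of the internal wildcard gap of a pattern
#'
#' The length of the longest run of all-base (wildcard) positions strictly
#' inside the pattern (runs touching either end are not a gap).
#'
#' @param pattern A `degenerate_pattern`.
#' @return Integer gap width in bp (0 if none).
#' @export
wildcard_gap_width <- function(pattern) {
  wild <- vapply(pattern$positions, function(s) length(s) == 4, logical(1))
  r <- rle(wild)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  internal <- r$values & starts > 1L & ends < length(wild)
  if (!any(internal)) 0L else max(r$lengths[internal])
}

#' Expected per-position match rate of a pattern
#'
#' Probability that a pattern matches at a fixed position of one strand of an
#' i.i.d. uniform background sequence: the product over positions of
#' (allowed bases)/4.
#'
#' @param pattern A `degenerate_pattern`.
#' @return Probability in (0, 1].
#' @export
expected_match_rate <- function(pattern) {
  prod(vapply(pattern$positions, length, integer(1)) / 4)
}

#' All words compatible with a degenerate pattern
#'
#' Enumerates every sequence matching the pattern (9 * 16 * ... words for the
#' bipartite Nanog/Sox2 pattern). Used by the synthetic-data planter.
#'
#' @param pattern A `degenerate_pattern`.
#' @return Character vector of words.
#' @export
compatible_words <- function(pattern) {
  grid <- expand.grid(pattern$positions, stringsAsFactors = FALSE)
  do.call(paste0, grid)
}
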