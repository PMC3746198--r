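NS_TEXT <- "A[TGA]T..[TC][AT]TT[GCT][AT]"

test_that("parse_pattern handles bracket classes, IUPAC text and errors", {
  p <- parse_pattern(NS_TEXT)
  expect_s3_class(p, "degenerate_pattern")
  expect_equal(pattern_length(p), 11)
  wild <- vapply(p$positions, function(s) length(s) == 4, logical(1))
  expect_equal(which(wild), c(4L, 5L))
  expect_equal(p$positions[[2]], c("A", "G", "T"))  # canonical ACGT order

  taat <- parse_pattern("TAAT")
  expect_equal(lengths(taat$positions), rep(1L, 4))

  iupac <- parse_pattern("ADTNNYWTTBW")
  expect_equal(iupac$positions, p$positions)

  expect_error(parse_pattern("A[TG"), "unbalanced")
  expect_error(parse_pattern("AXT"), "offset 2")
  expect_error(parse_pattern("A]T"), "unbalanced")
  expect_error(parse_pattern("A[]T"), "empty bracket")
})

test_that("render/parse round-trips positions", {
  for (txt in c(NS_TEXT, "TAAT", "[AT]", "A.C", "NN", "[AG][CT]G")) {
    p <- parse_pattern(txt)
    expect_equal(parse_pattern(render_pattern(p))$positions, p$positions,
                 label = txt)
  }
})

test_that("scan_motif finds planted sites on both strands at forward coordinates", {
  ns <- ns_pattern()
  hit <- scan_motif("AATGGTATTGA", ns)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 0L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$match, "AATGGTATTGA")

  # the reverse complement sequence carries the site on the minus strand
  rc <- scan_motif("TCAATACCATT", ns)
  expect_equal(nrow(rc), 1)
  expect_equal(rc$start, 0L)
  expect_equal(rc$strand, "-")
  expect_equal(rc$match, "TCAATACCATT")  # forward-strand text

  expect_equal(nrow(scan_motif(strrep("A", 12), ns)), 0)
  expect_equal(nrow(scan_motif("AATGG", ns)), 0)  # shorter than pattern
  # N matches no position
  expect_equal(nrow(scan_motif("AATGGTATTGN", ns)), 0)
})

test_that("scan_motif matches an independent regex oracle on random sequences", {
  set.seed(5)
  ns <- ns_pattern()
  for (i in 1:60) {
    seq <- random_dna(sample(11:120, 1), c("A", "C", "G", "T", "N"))
    got <- scan_motif(seq, ns)
    exp <- oracle_scan(seq, ns)
    expect_equal(got$start, exp$start, label = seq)
    expect_equal(got$strand, exp$strand, label = seq)
  }
})

test_that("both-strand scan mirrors the scan of the reverse complement", {
  set.seed(6)
  ns <- ns_pattern()
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (i in 1:20) {
    seq <- random_dna(80)
    fwd <- scan_motif(seq, ns)
    mir <- scan_motif(revcomp(seq), ns)
    remapped <- sort(nchar(seq) - mir$start - pattern_length(ns))
    expect_equal(sort(fwd$start), remapped)
    expect_equal(sum(fwd$strand == "+"), sum(mir$strand == "-"))
  }
})

test_that("peak_has_motif requires full containment in the span", {
  ns <- ns_pattern()
  span <- paste0(strrep("C", 20), "AATGGTATTGA", strrep("C", 20))
  expect_true(peak_has_motif(span, ns))
  expect_false(peak_has_motif(strrep("A", 51), ns))
  # only 6 of 11 motif bases inside the span: no match
  straddle <- paste0(strrep("C", 45), substr("AATGGTATTGA", 1, 6))
  expect_false(peak_has_motif(straddle, ns))
})

test_that("pwm_from_sites applies the pseudocount arithmetic", {
  p0 <- pwm_from_sites(c("TAAT", "TAAT"), pseudocount = 0)
  expect_equal(unname(p0$freq["T", 1]), 1.0)
  expect_equal(unname(p0$freq["A", 2]), 1.0)
  expect_true(all(abs(colSums(p0$freq) - 1) < 1e-12))

  p1 <- pwm_from_sites(c("TAAT", "TAAT"), pseudocount = 1)
  expect_equal(unname(p1$freq["T", 1]), (2 + 1) / (2 + 4))  # 0.5
  expect_equal(unname(p1$freq["C", 1]), 1 / 6)
  expect_true(all(abs(colSums(p1$freq) - 1) < 1e-12))

  expect_error(pwm_from_sites(c("TAAT", "TAA")), "equal length")
  expect_error(pwm_from_sites(character(0)), "at least one")
  expect_error(pwm_from_sites(c("TAAT", "TANT")), "A/C/G/T")
})

test_that("information_content matches closed forms and stays in [0, 2]", {
  certain <- pwm_from_sites(c("A", "A"), pseudocount = 0)
  expect_equal(information_content(certain), 2)

  uniform <- pwm_from_sites(c("A", "C", "G", "T"), pseudocount = 0)
  expect_equal(information_content(uniform), 0)

  half <- pwm_from_sites(c("A", "T"), pseudocount = 0)
  expect_equal(information_content(half), 1)

  set.seed(8)
  for (i in 1:10) {
    sites <- replicate(20, random_dna(6))
    ic <- information_content(pwm_from_sites(sites))
    expect_true(all(ic >= 0 & ic <= 2 + 1e-12))
  }
})

test_that("degenerate_consensus applies the threshold and wildcard rules", {
  pure <- pwm_from_sites(c("A", "A", "A", "A"), pseudocount = 0)
  expect_equal(render_pattern(degenerate_consensus(pure)), "A")

  split <- pwm_from_sites(c("A", "A", "T", "T"), pseudocount = 0)
  expect_equal(render_pattern(degenerate_consensus(split)), "[AT]")

  flat <- pwm_from_sites(c("A", "C", "G", "T"), pseudocount = 0)
  expect_equal(render_pattern(degenerate_consensus(flat)), ".")
})

test_that("combine_halves reconstructs the bipartite pattern and its gap", {
  left <- parse_pattern("A[TGA]T")
  right <- parse_pattern("[TC][AT]TT[GCT][AT]")
  full <- combine_halves(left, right, gap = 2)
  expect_equal(render_pattern(full), render_pattern(ns_pattern()))
  expect_equal(full$positions, ns_pattern()$positions)
  expect_equal(pattern_length(full),
               pattern_length(left) + 2 + pattern_length(right))

  expect_equal(render_pattern(combine_halves(left, right, gap = 0)),
               "A[AGT]T[CT][AT]TT[CGT][AT]")
  expect_equal(wildcard_gap_width(ns_pattern()), 2L)
  expect_equal(wildcard_gap_width(parse_pattern("TAAT")), 0L)
  expect_equal(wildcard_gap_width(parse_pattern("..TAAT")), 0L)  # not internal
})

test_that("expected_match_rate is the product of allowed fractions", {
  expect_equal(expected_match_rate(parse_pattern("A")), 0.25)
  expect_equal(expected_match_rate(parse_pattern(".")), 1.0)
  expect_equal(expected_match_rate(ns_pattern()), 9 / 32768)
})

test_that("empirical match frequency agrees with expected_match_rate", {
  set.seed(21)
  pat <- parse_pattern("A[AT]T")   # rate 1/4 * 1/2 * 1/4 = 1/32
  n <- 200000
  seq <- random_dna(n + pattern_length(pat) - 1)
  hits <- sum(scan_motif(seq, pat, both_strands = FALSE)$strand == "+")
  rate <- expected_match_rate(pat)
  se <- sqrt(rate * (1 - rate) * n)
  expect_lt(abs(hits - rate * n), 3 * se)
})

test_that("compatible_words enumerates exactly the matching words", {
  p <- parse_pattern("A[TG]T")
  w <- compatible_words(p)
  expect_setequal(w, c("ATT", "AGT"))
  expect_true(all(vapply(w, function(x)
    nrow(scan_motif(x, p, both_strands = FALSE)) == 1, logical(1))))
  expect_equal(length(compatible_words(ns_pattern())), 3 * 4 * 4 * 2 * 2 * 3 * 2)
})

test_that("PWM text and MEME writers round-trip / emit valid formats", {
  set.seed(9)
  pwm <- pwm_from_sites(replicate(12, random_dna(11)))
  f <- tempfile(fileext = ".tsv")
  write_pwm(pwm, f)
  back <- read_pwm(f)
  expect_equal(back$counts, pwm$counts)
  expect_equal(back$freq, pwm$freq)
  expect_equal(back$n_sites, pwm$n_sites)

  meme <- tempfile(fileext = ".meme")
  write_meme_minimal(pwm, meme, "ns_selex")
  lines <- readLines(meme)
  expect_true(any(grepl("^MOTIF ns_selex", lines)))
  expect_true(any(grepl("w= 11", lines)))
  mat <- read.table(text = lines[(grep("letter-probability", lines) + 1):
                                   (grep("letter-probability", lines) + 11)])
  expect_true(all(abs(rowSums(mat) - 1) < 1e-4))
})
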