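test_that("generate_library honours the library design and the seed", {
  spec <- oligo_library_spec(pool_size = 200, seed = 4)
  pool <- generate_library(spec)
  expect_length(pool, 200)
  expect_true(all(nchar(pool) == 62))
  expect_true(all(startsWith(pool, "ACGTGGATCCACTGACGG")))
  expect_true(all(endsWith(pool, "GCTAGCGCCTCGAGACTTG")))
  expect_identical(generate_library(spec), pool)
  expect_length(generate_library(oligo_library_spec(pool_size = 0, seed = 1)), 0)
})

test_that("library core base composition is near uniform", {
  set.seed(15)
  spec <- oligo_library_spec(pool_size = 400, seed = 15)
  cores <- substr(generate_library(spec), 19, 43)
  tab <- table(factor(strsplit(paste(cores, collapse = ""), "")[[1]],
                      levels = c("A", "C", "G", "T")))
  expect_gt(chisq.test(tab, p = rep(0.25, 4))$p.value, 1e-3)
})

test_that("selection_round respects degenerate and sequence-blind models", {
  set.seed(16)
  ns <- ns_pattern()
  spec <- oligo_library_spec(pool_size = 300, seed = 16)
  pool <- generate_library(spec)
  has <- vapply(pool, peak_has_motif, logical(1), pattern = ns,
                USE.NAMES = FALSE)

  # capture_base 0 / capture_bound 1 retains exactly the motif-bearing oligos
  kept <- selection_round(pool, binding_model(ns, 0, 1))
  expect_setequal(kept, pool[has])

  # equal capture probabilities: retention is sequence-blind, rate binomial
  keeps <- replicate(40, length(selection_round(pool, binding_model(ns, 0.3, 0.3))))
  se <- sqrt(300 * 0.3 * 0.7)
  expect_lt(abs(mean(keeps) - 90), 3 * se / sqrt(40))

  # capture ordering: motif-bearing oligos retained at >= base rate
  mixed <- c(pool[has], pool[!has][1:100])
  rates <- replicate(50, {
    k <- selection_round(mixed, binding_model(ns, 0.2, 0.8))
    c(mean(mixed[seq_len(sum(has))] %in% k), mean(mixed[-seq_len(sum(has))] %in% k))
  })
  expect_gt(mean(rates[1, ]), mean(rates[2, ]))
})

test_that("amplify resamples to constant size and preserves composition", {
  set.seed(17)
  expect_equal(amplify(c("AAA"), 5), rep("AAA", 5))
  expect_length(amplify(c("AAA", "CCC"), 0), 0)
  expect_error(amplify(character(0), 10), "extinction")

  # multinomial property: class frequency preserved within 3 SE
  bound <- c(rep("AAA", 300), rep("CCC", 100))
  f <- replicate(50, mean(amplify(bound, 400) == "AAA"))
  se <- sqrt(0.75 * 0.25 / 400)
  expect_lt(abs(mean(f) - 0.75), 3 * se / sqrt(50))
})

test_that("run_selex is reproducible, tracks frequency, and supports rounds 0", {
  ns <- ns_pattern()
  spec <- oligo_library_spec(pool_size = 400, seed = 18)
  model <- binding_model(ns, 0.05, 0.9)
  r0 <- run_selex(spec, model, rounds = 0)
  expect_equal(nrow(r0$trajectory), 1)
  expect_identical(r0$final_pool, generate_library(spec))

  run <- run_selex(spec, model, rounds = 3)
  expect_identical(run$trajectory, run_selex(spec, model, rounds = 3)$trajectory)
  expect_equal(run$trajectory$round, 0:3)
  expect_true(all(run$trajectory$pool_size == 400))
  expect_length(run$pools, 4)

  # motif frequency grows round-on-round in expectation under selection
  set.seed(18)
  deltas <- sapply(1:10, function(s) {
    tr <- run_selex(oligo_library_spec(pool_size = 400, seed = 1000 + s),
                    model, rounds = 3)$trajectory$motif_frequency
    diff(tr)
  })
  expect_true(all(rowMeans(deltas) > 0))

  # a sequence-blind (null) model leaves the frequency near its initial value
  null_final <- sapply(1:10, function(s) {
    tr <- run_selex(oligo_library_spec(pool_size = 400, seed = 2000 + s),
                    binding_model(ns, 0.5, 0.5), rounds = 3)$trajectory
    tr$motif_frequency[4] - tr$motif_frequency[1]
  })
  p0 <- mean(sapply(1:10, function(s) run_selex(
    oligo_library_spec(pool_size = 400, seed = 2000 + s),
    binding_model(ns, 0.5, 0.5), rounds = 0)$trajectory$motif_frequency))
  se <- sqrt(p0 * (1 - p0) / 400)
  expect_lt(abs(mean(null_final)), 3 * se / sqrt(10))
})

test_that("selection extinction is reported with its round number", {
  spec <- oligo_library_spec(pool_size = 30, seed = 19)
  ns <- ns_pattern()
  # nothing can be captured: every oligo motif-free with capture 0
  model <- binding_model(ns, 0, 0)
  expect_error(run_selex(spec, model, rounds = 2), "round 1")
})

test_that("extract_sites picks the leftmost core match, plus strand on ties", {
  spec <- oligo_library_spec()
  ns <- ns_pattern()
  site1 <- "AATGGTATTGA"; site2 <- "ATTCCTATTTA"
  mk_oligo <- function(core) paste0(spec$flank5, core, spec$flank3)

  one <- mk_oligo(paste0(site1, strrep("C", 14)))
  expect_equal(extract_sites(one, ns, spec), site1)

  two <- mk_oligo(paste0(site1, "CC", site2))
  expect_equal(extract_sites(two, ns, spec), site1)  # leftmost

  # site only in the flank region is excluded under core_only
  flank_site <- paste0(site1, substr(mk_oligo(strrep("C", 25)), 12, 62))
  expect_length(extract_sites(flank_site, ns, spec), 0)
  expect_equal(extract_sites(flank_site, ns, spec, core_only = FALSE), site1)

  # minus-strand site is reported in pattern orientation
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(site1)))
  minus <- mk_oligo(paste0(rc, strrep("C", 14)))
  expect_equal(extract_sites(minus, ns, spec), site1)

  expect_length(extract_sites(mk_oligo(strrep("C", 25)), ns, spec), 0)
})

test_that("a strong five-round selection recovers the planted consensus", {
  ns <- ns_pattern()
  spec <- oligo_library_spec(seed = 42)
  run <- run_selex(spec, binding_model(ns, 0.05, 0.9), rounds = 5)
  sites <- extract_sites(run$final_pool, ns, spec)
  expect_gt(length(sites), 1000)
  rec <- degenerate_consensus(pwm_from_sites(sites))
  wild <- vapply(ns$positions, function(s) length(s) == 4, logical(1))
  expect_equal(rec$positions[!wild], ns$positions[!wild])
})

test_that("pools round-trip through FASTA and the trajectory writer works", {
  spec <- oligo_library_spec(pool_size = 25, seed = 20)
  pool <- generate_library(spec)
  f <- tempfile(fileext = ".fa")
  write_pool_fasta(pool, f)
  expect_identical(read_pool_fasta(f), pool)

  run <- run_selex(spec, binding_model(ns_pattern(), 0.5, 0.9), rounds = 1)
  tf <- tempfile(fileext = ".tsv")
  write_trajectory(run, tf)
  back <- read.table(tf, header = TRUE, sep = "\t")
  expect_equal(back$round, 0:1)
})

test_that("PWM-mode binding models interpolate capture between the two levels", {
  ns <- ns_pattern()
  pwm <- pwm_from_sites(compatible_words(ns), pseudocount = 0.01)
  model <- binding_model(pwm, capture_base = 0.1, capture_bound = 0.9)
  spec <- oligo_library_spec(pool_size = 150, seed = 21)
  pool <- generate_library(spec)
  p <- nsmotif:::capture_probs(pool, model)
  expect_true(all(p >= 0.1 - 1e-12 & p <= 0.9 + 1e-12))
  # a perfect site reaches the bound level
  perfect <- paste0(spec$flank5, "AATGGTATTGA", strrep("C", 14), spec$flank3)
  expect_equal(nsmotif:::capture_probs(perfect, model), 0.9, tolerance = 1e-6)
  expect_error(run_selex(spec, model, rounds = 1), "track_pattern")
})
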