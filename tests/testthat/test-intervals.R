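test_that("read_peaks handles both dialects, midpoint summits and errors", {
  bed3 <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t200", "chr1\t500\t801", "chr2\t10\t20"), bed3)
  pk <- read_peaks(bed3, "bed3", factor = "Nanog", dataset = "chen")
  expect_equal(nrow(pk), 3)
  expect_equal(pk$summit, c(100L, 650L, 15L))  # floor((start+end)/2)
  expect_equal(unique(pk$dataset), "chen")

  np <- tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t400\tpk1\t0\t.\t5.5\t-1\t-1\t50", np)
  pk2 <- read_peaks(np, "bed-summit", factor = "Sox2", dataset = "marson")
  expect_equal(pk2$summit, 150L)
  expect_equal(pk2$id, "pk1")

  empty <- tempfile(); writeLines(character(0), empty)
  expect_equal(nrow(read_peaks(empty, "bed3")), 0)

  bad <- tempfile(); writeLines(c("chr1\t0\t100", "chr1\tx"), bad)
  expect_error(read_peaks(bad, "bed3"), "line 2")
  rev <- tempfile(); writeLines("chr1\t100\t100", rev)
  expect_error(read_peaks(rev, "bed3"), "end <= start")
})

test_that("center_on_summit builds 2*flank+1 windows, clips, and is idempotent", {
  pk <- peaks("chr1", c(900, 0, 990), c(1100, 100, 1010),
              summit = c(1000, 20, 1000))
  cen <- center_on_summit(pk, 50)
  expect_equal(cen$start, c(950L, 0L, 950L))
  expect_equal(cen$end, c(1051L, 71L, 1051L))
  expect_equal(cen$end - cen$start, c(101L, 71L, 101L))
  expect_identical(center_on_summit(cen, 50), cen)  # idempotent
  expect_true(all(center_on_summit(pk, 50)$start >= 0))

  z <- center_on_summit(pk[1, ], 0)
  expect_equal(c(z$start, z$end), c(1000L, 1001L))

  clipped <- center_on_summit(pk[1, ], 50, chrom_lengths = c(chr1 = 1020))
  expect_equal(clipped$end, 1020L)
})

test_that("overlap_length is symmetric, half-open, and zero across chromosomes", {
  a <- list(chrom = "chr1", start = 0, end = 100)
  b <- list(chrom = "chr1", start = 99, end = 200)
  expect_equal(overlap_length(a, b), 1L)
  expect_equal(overlap_length(b, a), 1L)
  expect_equal(overlap_length(a, list(chrom = "chr1", start = 100, end = 200)), 0L)
  expect_equal(overlap_length(a, a), 100L)
  expect_equal(overlap_length(a, list(chrom = "chr2", start = 0, end = 100)), 0L)
})

test_that("joint_peaks clusters overlapping Nanog-Sox2 windows", {
  n1 <- peaks("chr1", 100, 201, 150, "Nanog", "ds1", "n1")
  s1 <- peaks("chr1", 150, 251, 200, "Sox2", "ds1", "s1")
  one <- joint_peaks(n1, s1)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(100L, 251L))  # span = union
  expect_equal(one$factors, "Nanog,Sox2")

  far <- peaks("chr1", 5000, 5101, 5050, "Sox2", "ds1", "s_far")
  expect_equal(nrow(joint_peaks(n1, far)), 0)

  # Sox2 window chaining two Nanog windows that do not overlap each other
  n2 <- peaks("chr1", c(100, 260), c(201, 361), c(150, 310), "Nanog", "ds1",
              c("nA", "nB"))
  s2 <- peaks("chr1", 180, 281, 230, "Sox2", "ds1", "sA")
  chain <- joint_peaks(n2, s2)
  expect_equal(nrow(chain), 1)
  expect_equal(chain$n_members, 3)
  expect_equal(chain$member_ids,
               oracle_joint_member_sets(n2, s2))

  mixed <- peaks("chr1", 100, 201, 150, "Sox2", "ds2", "x")
  expect_error(joint_peaks(n1, mixed), "single dataset")
})

test_that("joint_peaks matches the brute-force connected-components oracle", {
  set.seed(42)
  for (rep in 1:25) {
    inst <- random_peak_instance(sample(3:25, 1), sample(3:25, 1))
    got <- joint_peaks(inst$nanog, inst$sox2)
    expect_identical(sort(got$member_ids, method = "radix"),
                     oracle_joint_member_sets(inst$nanog, inst$sox2))
  }
})

test_that("consensus_joint keeps clusters supported by enough datasets", {
  mk_joint <- function(ds, start) {
    n <- peaks("chr1", start, start + 101, start + 50, "Nanog", ds,
               paste0(ds, "_n"))
    s <- peaks("chr1", start + 20, start + 121, start + 70, "Sox2", ds,
               paste0(ds, "_s"))
    joint_peaks(n, s)
  }
  all3 <- list(a = mk_joint("a", 1000), b = mk_joint("b", 1010),
               c = mk_joint("c", 1020))
  res <- consensus_joint(all3)
  expect_equal(res$n_consensus, 1)
  expect_equal(res$total_joint, 3)
  expect_equal(res$clusters$datasets, "a,b,c")

  two <- list(a = mk_joint("a", 1000), b = mk_joint("b", 1010),
              c = mk_joint("c", 9000))
  expect_equal(consensus_joint(two)$n_consensus, 0)
  expect_equal(consensus_joint(two, n_required = 2)$n_consensus, 1)

  # chain: a-b overlap and b-c overlap without a-c overlap still counts
  chain <- list(a = mk_joint("a", 1000), b = mk_joint("b", 1100),
                c = mk_joint("c", 1200))
  spans <- do.call(rbind, lapply(chain, function(x) x[, c("chrom", "start", "end")]))
  expect_true(overlap_length(spans[1, ], spans[3, ]) == 0)
  expect_equal(consensus_joint(chain)$n_consensus, 1)
})

test_that("consensus clusters derive from per-dataset joint clusters", {
  set.seed(7)
  per_ds <- lapply(c(a = "a", b = "b", c = "c"), function(ds) {
    inst <- random_peak_instance(15, 15)
    inst$nanog$dataset <- ds; inst$sox2$dataset <- ds
    joint_peaks(inst$nanog, inst$sox2)
  })
  res <- consensus_joint(per_ds)
  if (res$n_consensus > 0) {
    members <- unlist(strsplit(res$clusters$member_ids, ","))
    all_joint_ids <- unlist(lapply(per_ds, function(x) x$cluster_id))
    expect_true(all(members %in% all_joint_ids))
    expect_true(all(vapply(strsplit(res$clusters$datasets, ","), length,
                           integer(1)) >= 3))
  }
  # oracle comparison on the spans
  spans <- do.call(rbind, lapply(names(per_ds), function(ds) {
    cl <- per_ds[[ds]]
    if (nrow(cl)) data.frame(chrom = cl$chrom, start = cl$start, end = cl$end,
                             ds = ds, id = cl$cluster_id) else NULL
  }))
  comp <- oracle_single_linkage(spans$chrom, spans$start, spans$end, 1)
  n_oracle <- sum(vapply(split(spans$ds, comp),
                         function(d) length(unique(d)) >= 3, logical(1)))
  expect_equal(res$n_consensus, n_oracle)
})

test_that("cluster output ordering is deterministic under input permutation", {
  set.seed(99)
  inst <- random_peak_instance(20, 20)
  ref <- joint_peaks(inst$nanog, inst$sox2)
  perm <- joint_peaks(inst$nanog[sample(nrow(inst$nanog)), ],
                      inst$sox2[sample(nrow(inst$sox2)), ])
  rownames(perm) <- NULL
  expect_identical(ref, perm)
})

test_that("nearest_tss applies the 30 kb cutoff and the tie rule", {
  cl <- data.frame(cluster_id = "c1", chrom = "chr1", start = 4950, end = 5051,
                   n_members = 1, datasets = "a", factors = "Nanog,Sox2",
                   member_ids = "x")
  tss1 <- data.frame(gene = "g1", chrom = "chr1", tss = 34999, strand = "+")
  got <- nearest_tss(cl, tss1)
  expect_equal(got$gene, "g1")
  expect_equal(got$distance, 29999L)  # within the 30 kb bound

  tss2 <- data.frame(gene = "g2", chrom = "chr1", tss = 35001, strand = "+")
  expect_true(is.na(nearest_tss(cl, tss2)$gene))  # 30001 > cutoff

  ties <- data.frame(gene = c("hi", "lo"), chrom = "chr1",
                     tss = c(6000, 4000), strand = "+")
  expect_equal(nearest_tss(cl, ties)$gene, "lo")  # lowest coordinate wins

  other <- data.frame(gene = "g3", chrom = "chr9", tss = 5000, strand = "+")
  expect_true(is.na(nearest_tss(cl, other)$gene))
})

test_that("cluster BED and gene-link writers round-trip through readers", {
  n <- peaks("chr1", c(100, 900), c(201, 1001), c(150, 950), "Nanog", "d", c("n1", "n2"))
  s <- peaks("chr1", c(150, 940), c(251, 1041), c(200, 990), "Sox2", "d", c("s1", "s2"))
  cl <- joint_peaks(n, s)
  bed <- tempfile(fileext = ".bed")
  write_clusters_bed(cl, bed)
  back <- read.table(bed, sep = "\t")
  expect_equal(back$V2, cl$start)
  expect_equal(back$V4, cl$cluster_id)
  expect_equal(back$V7, cl$datasets)

  tssf <- tempfile()
  tt <- data.frame(gene = "g", chrom = "chr1", tss = 180L, strand = "+")
  write_tss_table(tt, tssf)
  expect_equal(read_tss_table(tssf), tt)
})
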