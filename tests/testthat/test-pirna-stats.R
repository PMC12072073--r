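test_that("orientation split partitions records relative to the feature", {
  gene <- feature_tbl("g", "chr", 0L, 1000L, "+", "gene")
  rec <- alignment_tbl(sprintf("r%02d", 1:10), "chr", 1:10 * 10,
                       c(rep("+", 4), rep("-", 6)), 26L)
  out <- split_orientation(rec, gene)
  expect_equal(sum(out$orientation == "sense"), 4L)
  expect_equal(sum(out$orientation == "antisense"), 6L)
  expect_equal(nrow(out), nrow(rec))
  minus_gene <- feature_tbl("g", "chr", 0L, 1000L, "-", "gene")
  out2 <- split_orientation(rec, minus_gene)
  expect_equal(sum(out2$orientation == "sense"), 6L)
  unstranded <- feature_tbl("g", "chr", 0L, 1000L, NA, "cluster")
  expect_error(split_orientation(rec, unstranded), "strand")
  # transcript mode ignores the feature strand
  out3 <- split_orientation(rec, gene, mode = "transcript")
  expect_equal(sum(out3$orientation == "sense"), 4L)
})

test_that("size distribution is complete, zero-filled and conserved", {
  rec <- alignment_tbl(c("a", "b", "c"), "chr", c(0, 10, 20), "+",
                       c(23L, 26L, 26L), count = c(2, 1, 4))
  sd1 <- size_distribution(rec, 20, 29)
  expect_equal(nrow(sd1), 10L)                     # all bins present
  expect_equal(sum(sd1$weight), sum(rec$count))    # conservation
  expect_equal(sd1$weight[sd1$length == 26], 5)
  expect_equal(sd1$weight[sd1$length == 20], 0)
  empty <- size_distribution(rec[0, ], 20, 29)
  expect_equal(sum(empty$weight), 0)
  expect_equal(nrow(empty), 10L)
})

test_that("nucleotide bias handles constructed and weighted inputs", {
  rec <- alignment_tbl("r", "chr", 0, "+", 12L,
                       sequence = "TGCATGCATGCA")
  nb <- nucleotide_bias(rec)
  expect_equal(nb$frac_1U, 1)
  expect_equal(nb$frac_10A, 0)

  # 88 of 100 weighted reads start with T
  rec2 <- alignment_tbl(c("u", "v"), "chr", c(0, 30), "+", 23L,
                        sequence = c(paste0("T", rand_dna(22)),
                                     paste0("G", rand_dna(22))),
                        count = c(88, 12))
  expect_equal(nucleotide_bias(rec2)$frac_1U, 0.88)

  und <- nucleotide_bias(rec[0, ])
  expect_true(und$undefined)
  expect_true(is.na(und$frac_1U))
})

test_that("bias on uniform random bases stays within 3-sigma binomial", {
  set.seed(31)
  n <- 10000
  seqs <- vapply(rep(26, n), function(w)
    paste(sample(c("A", "C", "G", "T"), w, TRUE), collapse = ""), "")
  rec <- alignment_tbl(sprintf("r%05d", 1:n), "chr", 1:n, "+", 26L,
                       sequence = seqs)
  nb <- nucleotide_bias(rec)
  tol <- 3 * sqrt(0.25 * 0.75 / n)
  expect_lt(abs(nb$frac_1U - 0.25), tol)
  expect_lt(abs(nb$frac_10A - 0.25), tol)
})

test_that("ping-pong overlap arithmetic and flags follow the 5'-end rule", {
  rec <- alignment_tbl(c("p", "m"), "chr", c(100, 84), c("+", "-"), 26L)
  # minus 5' end = 84 + 26 - 1 = 109; overlap = 109 - 100 + 1 = 10
  pp <- pingpong_signature(rec)
  expect_equal(unname(pp$histogram[["10"]]), 1)
  expect_equal(sum(pp$histogram), 1)
  expect_equal(pp$flag, "z_undefined")   # background bins all zero
  expect_true(is.na(pp$z10))

  none <- pingpong_signature(rec[0, ])
  expect_equal(none$flag, "no_pairs")
})

test_that("ping-pong matches the all-pairs oracle bin-for-bin", {
  set.seed(32)
  for (i in 1:10) {
    n <- sample(50:200, 1)
    rec <- alignment_tbl(sprintf("r%04d", 1:n), "chr",
                         sample.int(2000, n, TRUE),
                         sample(c("+", "-"), n, TRUE),
                         sample(23:29, n, TRUE),
                         count = sample(1:4, n, TRUE))
    got <- pingpong_signature(rec)
    want <- oracle_pingpong(rec)
    expect_equal(unname(got$histogram), want$histogram)
    if (!is.na(want$z10)) expect_equal(got$z10, want$z10, tolerance = 1e-12)
  }
})

test_that("a strong simulated ping-pong locus yields a large z-score", {
  cfg <- sim_config(seed = 33,
                    pirna = list(n_reads = 5000L, pingpong_fraction = 0.5,
                                 contaminant_fraction = 0, background_rate = 0))
  gp <- generate_genome_pair(cfg)
  cl <- gp$features_a[gp$features_a$id == "cluster_1", ]
  sim <- simulate_pirna_library(gp$assembly_a, cl, cfg)
  pp <- pingpong_signature(truth_records(sim))
  expect_gt(pp$z10, 5)
  want <- oracle_pingpong(truth_records(sim))
  expect_equal(pp$z10, want$z10, tolerance = 1e-12)
})

test_that("feature counting assigns by exon overlap and conserves weight", {
  feats <- feature_tbl(
    id = c("g1", "g1.e1", "g1.e2", "g2", "g2.e1"),
    contig = "chr",
    start = c(100L, 100L, 300L, 380L, 380L),
    end = c(400L, 200L, 400L, 600L, 600L),
    strand = "+",
    kind = c("gene", "exon", "exon", "gene", "exon"),
    parent = c(NA, "g1", "g1", NA, "g2")
  )
  rec <- alignment_tbl(
    c("in_exon", "in_intron", "spanning", "outside"),
    "chr", c(120L, 220L, 385L, 900L), "+", 26L, count = c(2, 1, 1, 1))
  cnt <- count_feature_reads(rec, feats)
  expect_equal(cnt$count[cnt$feature_id == "g1"], 2)
  expect_equal(attr(cnt, "ambiguous"), 1)      # spans g1.e2 and g2.e1
  expect_equal(attr(cnt, "unassigned"), 2)     # intron-only + outside
  expect_equal(sum(cnt$count) + attr(cnt, "unassigned") +
                 attr(cnt, "ambiguous"), sum(rec$count))
})

test_that("rpkm follows its closed form and scaling laws", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  # inverse check: a count engineered for 294 RPKM returns 294
  len <- 1700; depth <- 2.4e6
  count <- 294 * (len / 1e3) * (depth / 1e6)
  expect_equal(rpkm(count, len, depth), 294)
  # linear in count, inverse-linear in library size
  expect_equal(rpkm(20, 500, 1e6), 2 * rpkm(10, 500, 1e6))
  expect_equal(rpkm(10, 500, 2e6), rpkm(10, 500, 1e6) / 2)
  expect_error(rpkm(1, 0, 1e6), "feature_length")
  expect_error(rpkm(1, 100, 0), "library_size")
})

test_that("fold change handles ratios, pseudocounts and degenerate inputs", {
  expect_equal(fold_change(654, 54.5), 12, tolerance = 0.01)
  expect_equal(fold_change(5, 5), 1)
  expect_true(is.infinite(fold_change(3, 0)))
  expect_true(is.na(fold_change(0, 0)))
  expect_equal(fold_change(0, 0, pseudocount = 1), 1)
})
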