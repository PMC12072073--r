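test_that("stranded coverage increments covered positions by read weight", {
  genome <- assembly(c(chr = rand_dna(500)), source_label = "toy")
  rec <- alignment_tbl(c("a", "b"), "chr", c(100L, 100L), c("+", "-"),
                       26L, count = c(1, 2))
  cov <- stranded_coverage(rec, genome)
  plus <- cov[["chr|+"]]$values
  minus <- cov[["chr|-"]]$values
  expect_equal(sum(plus > 0), 26)
  expect_equal(unique(plus[101:126]), 1)
  expect_equal(unique(minus[101:126]), 2)   # collapsed count 2
  expect_equal(sum(cov[["chr|+"]]$starts), 1)
  expect_equal(sum(cov[["chr|-"]]$starts), 2)

  bad <- alignment_tbl("x", "chr", 490L, "+", 26L)
  expect_error(stranded_coverage(bad, genome), "beyond contig end")
})

test_that("multi-mapper tracks can be fractionally weighted", {
  genome <- assembly(c(chr = rand_dna(300)), source_label = "toy")
  rec <- alignment_tbl(c("m", "m"), "chr", c(50L, 150L), "+", 20L,
                       n_best = 2L)
  cov <- stranded_coverage(rec, genome, weight_by_nbest = TRUE)
  expect_equal(unique(cov[["chr|+"]]$values[51:70]), 0.5)
})

test_that("cluster calling merges gaps and filters by read support", {
  genome <- assembly(c(chr = rand_dna(20000)), source_label = "toy")
  tile <- function(from, to, by, strand) {
    st <- seq(from, to, by = by)
    alignment_tbl(sprintf("r%s%05d", strand, st), "chr", st, strand, 26L)
  }
  rec <- dplyr::bind_rows(tile(10, 5010, 50, "+"), tile(10, 5010, 60, "-"))
  cov <- stranded_coverage(rec, genome)
  cl <- call_clusters(cov[["chr|+"]], cov[["chr|-"]], min_reads = 10,
                      max_gap = 1000)
  expect_equal(nrow(cl), 1L)
  expect_true(cl$dual_strand)
  expect_lte(cl$start, 10)
  expect_gte(cl$end, 5030)

  # two islands separated by more than max_gap
  rec2 <- dplyr::bind_rows(tile(10, 2000, 40, "+"),
                           tile(8000, 10000, 40, "+"))
  cov2 <- stranded_coverage(rec2, genome)
  cl2 <- call_clusters(cov2[["chr|+"]], cov2[["chr|-"]], min_reads = 10,
                       max_gap = 1000)
  expect_equal(nrow(cl2), 2L)
  expect_true(all(diff(c(t(cl2[, c("start", "end")]))) > 0))  # sorted, disjoint
  expect_false(any(cl2$dual_strand))

  empty <- call_clusters(
    coverage_track("chr", "+", numeric(100)),
    coverage_track("chr", "-", numeric(100)))
  expect_equal(nrow(empty), 0L)
})

test_that("called boundaries track the simulated cluster within max_gap", {
  cfg <- sim_config(seed = 41, pirna = list(
    n_reads = 4000L, contaminant_fraction = 0, background_rate = 0))
  gp <- generate_genome_pair(cfg)
  cl <- gp$features_a[gp$features_a$id == "cluster_1", ]
  sim <- simulate_pirna_library(gp$assembly_a, cl, cfg)
  cov <- stranded_coverage(truth_records(sim), gp$assembly_a)
  regions <- call_clusters(cov[["contig_1|+"]], cov[["contig_1|-"]],
                           min_reads = 100, max_gap = 1000)
  expect_equal(nrow(regions), 1L)
  expect_lt(abs(regions$start - cl$start), 1000)
  expect_lt(abs(regions$end - cl$end), 1000)
  expect_true(regions$dual_strand)
})

test_that("locus extraction applies flanks and flags truncation", {
  genome <- assembly(c(chr = rand_dna(100000)), source_label = "toy")
  mid <- extract_locus(genome, tibble::tibble(contig = "chr",
                                              start = 15000, end = 20000))
  expect_equal(mid$start, 5000)
  expect_equal(mid$end, 30000)
  expect_equal(nchar(mid$sequence), 25000)
  expect_false(mid$truncated_left || mid$truncated_right)

  edge <- extract_locus(genome, tibble::tibble(contig = "chr",
                                               start = 3000, end = 5000))
  expect_equal(edge$start, 0)
  expect_true(edge$truncated_left)

  none <- extract_locus(genome, tibble::tibble(contig = "chr",
                                               start = 15000, end = 20000),
                        flank = 0)
  expect_equal(nchar(none$sequence), 5000)
})

test_that("locus diff calls nothing on identical sequences", {
  set.seed(42)
  s <- rand_dna(5000)
  d <- pairwise_locus_diff(s, s)
  expect_equal(nrow(d$snps), 0L)
  expect_equal(nrow(d$indels), 0L)
  expect_equal(d$flag, "ok")
})

test_that("locus diff recovers a 69 bp deletion and a 5403 bp insertion", {
  set.seed(43)
  a <- rand_dna(12000)
  b_del <- paste0(substr(a, 1, 4000), substr(a, 4070, 12000))  # 69 bp gone
  d1 <- pairwise_locus_diff(a, b_del)
  expect_equal(nrow(d1$indels), 1L)
  expect_equal(d1$indels$length, 69L)
  expect_equal(d1$indels$inserted_in, "a")
  expect_lt(abs(d1$indels$pos_a - 4000), 5)

  te <- rand_dna(5403)
  a_ins <- paste0(substr(a, 1, 6000), te, substr(a, 6001, 12000))
  d2 <- pairwise_locus_diff(a_ins, a)
  expect_equal(d2$gaps$length, 5403L)
  expect_equal(d2$gaps$inserted_in, "a")
})

test_that("locus diff is symmetric up to role swap", {
  set.seed(44)
  a <- rand_dna(8000)
  b <- paste0(substr(a, 1, 2000), substr(a, 2101, 5000), rand_dna(40),
              substr(a, 5001, 8000))
  dab <- pairwise_locus_diff(a, b)
  dba <- pairwise_locus_diff(b, a)
  expect_equal(sort(dab$indels$length), sort(dba$indels$length))
  swap <- c(a = "b", b = "a")
  expect_equal(sort(unname(swap[dab$indels$inserted_in])),
               sort(dba$indels$inserted_in))
  expect_equal(nrow(dab$snps), nrow(dba$snps))
})

test_that("unrelated sequences are flagged unalignable", {
  set.seed(45)
  d <- pairwise_locus_diff(rand_dna(300), strrep("AT", 150), k = 31)
  expect_equal(d$flag, "unalignable")
})

test_that("every planted variant is recovered on a generated strain pair", {
  cfg <- sim_config(seed = 46)
  gp <- generate_genome_pair(cfg)
  d <- pairwise_locus_diff(unclass(gp$assembly_a)[[1]],
                           unclass(gp$assembly_b)[[1]])
  truth <- gp$truth
  # planted SNPs: exact positions on both assemblies
  snp_truth <- truth[truth$type == "snp", ]
  expect_true(all(snp_truth$pos_a %in% d$snps$pos_a))
  expect_true(all(snp_truth$pos_b %in% d$snps$pos_b))
  # planted indel and TE gap: exact lengths
  expect_true(69L %in% d$indels$length)
  expect_true(5403L %in% d$gaps$length)
  te_call <- d$gaps[d$gaps$length == 5403L, ]
  te_truth <- truth[truth$type == "te_insertion", ]
  expect_lt(abs(te_call$pos_a - te_truth$pos_a), 25)
  # satellite copy-number difference appears as a length-difference gap
  sat_diff <- with(cfg$divergence$satellite,
                   unit_length * abs(copies_b - copies_a))
  expect_true(sat_diff %in% d$gaps$length)
})
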