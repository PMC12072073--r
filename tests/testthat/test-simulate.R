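test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 71, genome = list(contig_length = 60000L),
                    pirna = list(cluster_span = 12000L, n_reads = 500L))
  gp1 <- generate_genome_pair(cfg)
  gp2 <- generate_genome_pair(cfg)
  expect_identical(unclass(gp1$assembly_a), unclass(gp2$assembly_a))
  expect_identical(unclass(gp1$assembly_b), unclass(gp2$assembly_b))
  expect_identical(gp1$truth, gp2$truth)
  cl <- gp1$features_a[gp1$features_a$id == "cluster_1", ]
  s1 <- simulate_pirna_library(gp1$assembly_a, cl, cfg)
  s2 <- simulate_pirna_library(gp1$assembly_a, cl, cfg)
  expect_identical(s1$reads, s2$reads)
  s3 <- simulate_pirna_library(gp1$assembly_a, cl, cfg, seed = 999)
  expect_false(identical(s1$reads$sequence, s3$reads$sequence))
})

test_that("zero divergence yields identical assemblies", {
  cfg <- sim_config(seed = 72,
                    genome = list(contig_length = 60000L),
                    pirna = list(cluster_span = 12000L),
                    divergence = list(snp_rate = 0, indel_rate = 0,
                                      planted_indel_lengths = integer(0),
                                      te_insertion_length = 0L,
                                      satellite = list(unit_length = 370L,
                                                       copies_a = 5L,
                                                       copies_b = 5L)))
  gp <- generate_genome_pair(cfg)
  expect_identical(unclass(gp$assembly_a)[[1]], unclass(gp$assembly_b)[[1]])
})

test_that("the planted TE length surfaces as an exact diff gap", {
  cfg <- sim_config(seed = 73, genome = list(contig_length = 60000L),
                    pirna = list(cluster_span = 12000L))
  gp <- generate_genome_pair(cfg)
  expect_equal(gp$truth$length[gp$truth$type == "te_insertion"], 5403L)
  d <- pairwise_locus_diff(unclass(gp$assembly_a)[[1]],
                           unclass(gp$assembly_b)[[1]])
  expect_true(5403L %in% d$gaps$length)
})

test_that("full ping-pong mode pairs every partner at exactly 10 nt", {
  cfg <- sim_config(seed = 74, pirna = list(
    n_reads = 1000L, pingpong_fraction = 1, contaminant_fraction = 0,
    background_rate = 0))
  gp <- generate_genome_pair(cfg)
  cl <- gp$features_a[gp$features_a$id == "cluster_1", ]
  sim <- simulate_pirna_library(gp$assembly_a, cl, cfg)
  roles <- table(sim$truth$role)
  expect_gte(roles[["partner"]], 500)
  p5 <- ifelse(sim$truth$strand == "+", sim$truth$start,
               sim$truth$start + sim$truth$length - 1L)
  prim <- sim$truth$role == "primary"
  part <- sim$truth$role == "partner"
  # every partner 5' end sits exactly 9 bp inside some opposite-strand
  # primary 5' end (10 nt overlap)
  exp_pos <- ifelse(sim$truth$strand[prim] == "+", p5[prim] + 9L,
                    p5[prim] - 9L)
  key_primary <- paste(ifelse(sim$truth$strand[prim] == "+", "-", "+"),
                       exp_pos)
  key_partner <- paste(sim$truth$strand[part], p5[part])
  expect_true(all(key_partner %in% key_primary))
})

test_that("configured biases and fractions are recovered by the estimators", {
  cfg <- sim_config(seed = 75, pirna = list(
    n_reads = 10000L, pingpong_fraction = 0.5, frac_1U = 0.88,
    frac_10A = 0.6, contaminant_fraction = 0, background_rate = 0))
  gp <- generate_genome_pair(cfg)
  cl <- gp$features_a[gp$features_a$id == "cluster_1", ]
  sim <- simulate_pirna_library(gp$assembly_a, cl, cfg)
  rec <- truth_records(sim)
  prim <- rec[rec$read_id %in%
                sim$truth$read_id[sim$truth$role == "primary"], ]
  part <- rec[rec$read_id %in%
                sim$truth$read_id[sim$truth$role == "partner"], ]
  tol_1u <- 3 * sqrt(0.88 * 0.12 / nrow(prim))
  expect_lt(abs(nucleotide_bias(prim)$frac_1U - 0.88), tol_1u)
  tol_10a <- 3 * sqrt(0.6 * 0.4 / nrow(part))
  expect_lt(abs(nucleotide_bias(part)$frac_10A - 0.6), tol_10a)
})

test_that("contaminant fraction is recovered through subtraction", {
  cfg <- sim_config(seed = 76, pirna = list(
    n_reads = 4000L, contaminant_fraction = 0.2, background_rate = 0))
  gp <- generate_genome_pair(cfg)
  cl <- gp$features_a[gp$features_a$id == "cluster_1", ]
  sim <- simulate_pirna_library(gp$assembly_a, cl, cfg)
  res <- subtract_ncrna(sim$reads, load_contaminant_db())
  # the configured fraction applies to the primary draw; ping-pong partners
  # are emitted on top, so compare against the truth-labelled count
  is_cont <- sim$truth$role == "contaminant"
  expect_lt(abs(sum(is_cont) / 4000 - 0.2), 3 * sqrt(0.2 * 0.8 / 4000))
  expect_setequal(res$removed$id, sim$truth$read_id[is_cont])
})

test_that("hybrid libraries honor the minor-allele fraction limits", {
  cfg0 <- sim_config(seed = 77, genome = list(contig_length = 60000L),
                     pirna = list(cluster_span = 12000L, n_reads = 800L),
                     hybrid = list(minor_allele_fraction = 0))
  gp <- generate_genome_pair(cfg0)
  sa <- gp$features_a[gp$features_a$id == "allelic_span_1", ]
  sb <- gp$features_b[gp$features_b$id == "allelic_span_1", ]
  nmd <- simulate_hybrid_library(gp$assembly_a, gp$assembly_b, sa, sb, cfg0)
  expect_true(all(nmd$truth$origin == "a"))

  cfg5 <- sim_config(seed = 78, genome = list(contig_length = 60000L),
                     pirna = list(cluster_span = 12000L, n_reads = 4000L),
                     hybrid = list(minor_allele_fraction = 0.5))
  even <- simulate_hybrid_library(gp$assembly_a, gp$assembly_b, sa, sb, cfg5)
  expect_lt(abs(mean(even$truth$origin == "b") - 0.5),
            3 * sqrt(0.25 / 4000))
})

test_that("chip simulator produces the configured enrichment structure", {
  set.seed(79)
  genome <- assembly(c(chr = rand_dna(40000)), source_label = "toy")
  region <- tibble::tibble(contig = "chr", start = 10000L, end = 14000L)
  cfg <- sim_config(seed = 79, chip = list(enrichment_fold = 8,
                                           n_fragments = 30000L))
  lib <- simulate_chip_library(genome, region, cfg)
  # simulated fragments are drawn independently, so repeated positions are
  # genuine coverage, not PCR duplicates
  tr <- rpgc_normalize(binned_coverage(lib$treat, genome, dedup = FALSE),
                       genome)
  inp <- rpgc_normalize(binned_coverage(lib$input, genome, dedup = FALSE),
                        genome)
  d <- subtract_input(tr, inp)
  inside <- mean(d$chr$values[1001:1400])
  # 8x density inside a small window: treat-minus-input within the window
  # sits near (8 - 1) x the normalized background level
  bg_treat <- mean(tr$chr$values[2001:4000])
  expect_gt(inside, 4 * bg_treat)
  empty <- simulate_chip_library(genome, region,
                                 sim_config(seed = 80,
                                            chip = list(n_fragments = 0L)))
  expect_equal(nrow(empty$treat), 0L)
})
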