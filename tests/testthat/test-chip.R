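test_that("binned coverage spreads fragments proportionally to overlap", {
  genome <- assembly(c(chr = rand_dna(1000)), source_label = "toy")
  frag <- alignment_tbl("f1", "chr", 0L, "+", 200L)
  tracks <- binned_coverage(frag, genome, bin_size = 10)
  v <- tracks$chr$values
  expect_equal(v[1:20], rep(1, 20))   # bins fully covered by the fragment
  expect_equal(v[21:100], rep(0, 80))
  expect_equal(attr(tracks, "total_fragment_bases"), 200)

  zero <- binned_coverage(frag[0, ], genome, bin_size = 10)
  expect_true(all(zero$chr$values == 0))
})

test_that("single-end extension is strand-aware and duplicates collapse", {
  genome <- assembly(c(chr = rand_dna(1000)), source_label = "toy")
  rec <- alignment_tbl(c("a", "b", "dup"), "chr", c(100L, 500L, 100L),
                       c("+", "-", "+"), 36L)
  tracks <- binned_coverage(rec, genome, bin_size = 10, extend = 200L)
  v <- tracks$chr$values
  expect_equal(attr(tracks, "n_fragments"), 2L)       # duplicate removed
  expect_gt(v[11], 0)                                  # plus extends right
  expect_gt(v[40], 0)                                  # minus extends left
  expect_equal(v[60], 0)
  expect_error(binned_coverage(rec, genome, extend = 10L), "read length")
})

test_that("RPGC normalization is an exact 1x-coverage identity", {
  set.seed(61)
  genome <- assembly(c(c1 = rand_dna(30000), c2 = rand_dna(20000)),
                     source_label = "toy")
  cfg <- sim_config(seed = 61, chip = list(n_fragments = 3000L))
  lib <- simulate_chip_library(genome, tibble::tibble(contig = character(),
                                                      start = integer(),
                                                      end = integer()), cfg)
  tracks <- rpgc_normalize(binned_coverage(lib$input, genome), genome)
  total <- sum(vapply(tracks, function(tr) sum(tr$values) * tr$bin_size, 0))
  expect_equal(total / 50000, 1, tolerance = 1e-6)
  # doubling the library halves nothing after renormalization
  expect_equal(attr(tracks, "scale_factor"),
               attr(binned_coverage(lib$input, genome),
                    "total_fragment_bases") / 50000)
  tr2 <- rpgc_normalize(binned_coverage(lib$input, genome), genome,
                        total_fragment_bases = 2 * 50000)
  expect_equal(tr2$c1$values, binned_coverage(lib$input, genome)$c1$values / 2)
})

test_that("input subtraction is elementwise and keeps negatives", {
  genome <- assembly(c(chr = rand_dna(1000)), source_label = "toy")
  t1 <- binned_coverage(alignment_tbl("x", "chr", 0L, "+", 500L), genome)
  t2 <- binned_coverage(alignment_tbl("y", "chr", 250L, "+", 500L), genome)
  same <- subtract_input(t1, t1)
  expect_true(all(same$chr$values == 0))
  diff <- subtract_input(t1, t2)
  expect_true(any(diff$chr$values < 0))
  expect_gt(attr(diff, "negative_bins"), 0)
  expect_equal(diff$chr$values, t1$chr$values - t2$chr$values)
  small <- binned_coverage(alignment_tbl("z", "chr", 0L, "+", 100L),
                           genome, bin_size = 25)
  expect_error(subtract_input(t1, small), "bin grid")
})

test_that("a planted enrichment window is recovered and nulls stay quiet", {
  set.seed(62)
  genome <- assembly(c(chr = rand_dna(50000)), source_label = "toy")
  region <- tibble::tibble(contig = "chr", start = 20000L, end = 24000L)
  cfg <- sim_config(seed = 62, chip = list(enrichment_fold = 10,
                                           n_fragments = 20000L,
                                           fragment_length = 200L))
  lib <- simulate_chip_library(genome, region, cfg)
  er <- enriched_regions(lib$treat, lib$input, genome, bin_size = 200)
  expect_gte(nrow(er), 1L)
  big <- er[which.max(er$end - er$start), ]
  expect_lt(abs(big$start - region$start), 400)   # within one bin
  expect_lt(abs(big$end - region$end), 400)

  # flat treat vs input: typically no calls at alpha 0.05
  null_lib <- simulate_chip_library(genome, region[0, ], cfg, seed = 63)
  er0 <- enriched_regions(null_lib$treat, null_lib$input, genome,
                          bin_size = 200)
  expect_equal(nrow(er0), 0L)
  # limiting case: alpha = 1 admits every nonzero treat bin
  er1 <- enriched_regions(null_lib$treat, null_lib$input, genome,
                          bin_size = 200, alpha = 1)
  expect_gt(nrow(er1), 0L)
})

test_that("Mann-Whitney comparison matches exact enumeration", {
  mk_track <- function(vals) {
    list(chr = coverage_track("chr", "both", vals, bin_size = 100,
                              normalization = "treat-minus-input"))
  }
  regions <- tibble::tibble(contig = "chr",
                            start = c(0L, 100L, 200L), end = c(100L, 200L, 300L))
  cmp <- compare_enrichment(mk_track(c(1, 2, 3)), mk_track(c(10, 11, 12)),
                            regions)
  expect_equal(cmp$p_value, 0.1)
  expect_equal(unname(cmp$u), 0)
  # label swap reflects U and keeps p
  rev <- compare_enrichment(mk_track(c(10, 11, 12)), mk_track(c(1, 2, 3)),
                            regions)
  expect_equal(rev$p_value, cmp$p_value)
  expect_equal(unname(rev$u), 9)
  # all tied
  tied <- compare_enrichment(mk_track(c(2, 2, 2)), mk_track(c(2, 2, 2)),
                             regions)
  expect_equal(tied$p_value, 1)
  expect_error(compare_enrichment(mk_track(1:2), mk_track(3:4),
                                  regions[1:2, ]), "at least 3")
})

test_that("Mann-Whitney p agrees with the permutation oracle", {
  set.seed(64)
  for (i in 1:5) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    va <- stats::rnorm(na, 0, 2)
    vb <- stats::rnorm(nb, 1, 2)
    n <- na + nb
    regions <- tibble::tibble(contig = "chr",
                              start = (seq_len(max(na, nb)) - 1L) * 100L,
                              end = seq_len(max(na, nb)) * 100L)
    mk <- function(vals) {
      pad <- c(vals, rep(vals[length(vals)], max(na, nb) - length(vals)))
      list(chr = coverage_track("chr", "both", pad, bin_size = 100,
                                normalization = "treat-minus-input"))
    }
    # compare on equal region counts to keep the fixture simple
    m <- min(na, nb)
    cmp <- compare_enrichment(mk(va[1:m]), mk(vb[1:m]), regions[1:m, ])
    expect_equal(cmp$p_value, oracle_mw_exact(va[1:m], vb[1:m]),
                 tolerance = 1e-12)
  }
})

test_that("percent input and 2^-dCt follow their closed forms", {
  expect_equal(percent_input(2, 10, 2, 10), 100)
  expect_equal(percent_input(4, 10, 2, 10), 200)
  expect_error(percent_input(2, 10, 2, 0), "denominator")
  expect_equal(relative_expression_2dct(20, 20), 1)
  expect_equal(relative_expression_2dct(21, 20), 0.5)
  expect_equal(relative_expression_2dct(18, 20), 4)
})
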