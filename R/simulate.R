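#' Simulation configuration
#'
#' Builds the nested configuration for the synthetic-data generators. The
#' defaults are the package's study conditions: a 100 kb contig pair
#' diverged at 1% SNPs with a planted 69 bp indel, a 5403 bp TE insertion
#' upstream of the cluster gene present in haplotype A only, flanking
#' satellite arrays of a 370 bp unit at a ~3-fold copy-number difference
#' (15 vs 45 copies); a 20 kb dual-strand piRNA cluster emitting 23-29 nt
#' reads with an 88% 1U bias on primaries, 60% 10A on ping-pong partners
#' and a configurable ping-pong fraction; hybrid libraries with a 5.4%
#' minor-allele read fraction; and ChIP libraries with 8-fold enrichment of
#' 200 bp fragments over target regions.
#'
#' @param seed integer RNG seed.
#' @param genome,divergence,pirna,hybrid,chip named lists overriding the
#'   defaults printed by `str(sim_config())`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome = list(), divergence = list(),
                       pirna = list(), hybrid = list(), chip = list()) {
  cfg <- list(
    seed = as.integer(seed),
    genome = utils::modifyList(list(
      n_contigs = 1L, contig_length = 100000L, gc = 0.4), genome),
    divergence = utils::modifyList(list(
      snp_rate = 0.01, indel_rate = 2e-4, indel_max_len = 6L,
      planted_indel_lengths = c(69L),
      te_insertion_length = 5403L,
      satellite = list(unit_length = 370L, copies_a = 15L, copies_b = 45L)),
      divergence, keep.null = TRUE),
    pirna = utils::modifyList(list(
      cluster_span = 20000L, n_reads = 10000L, pingpong_fraction = 0.3,
      frac_1U = 0.88, frac_10A = 0.6, length_mean = 26, length_sd = 1.5,
      min_len = 23L, max_len = 29L,
      contaminant_fraction = 0.05, background_rate = 0.02), pirna),
    hybrid = utils::modifyList(list(minor_allele_fraction = 0.054), hybrid),
    chip = utils::modifyList(list(
      enrichment_fold = 8, fragment_length = 200L, n_fragments = 20000L),
      chip)
  )
  rates <- c(cfg$divergence$snp_rate, cfg$divergence$indel_rate,
             cfg$pirna$pingpong_fraction, cfg$pirna$frac_1U,
             cfg$pirna$frac_10A, cfg$pirna$contaminant_fraction,
             cfg$pirna$background_rate, cfg$hybrid$minor_allele_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates/fractions must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

.random_seq <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a diverged strain-genome pair with ground truth
#'
#' Haplotype A carries the full TE insertion upstream of the cluster gene
#' and the short satellite array; haplotype B is derived from the same
#' backbone by background SNPs and short indels, the planted indel(s)
#' (deletions in B), no TE, and the long satellite array. A gene model
#' (gene/transcript/exons/CDS/UTRs) sits inside the cluster span. Every
#' edit is recorded in the truth table with coordinates on both final
#' assemblies.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A list: `assembly_a`, `assembly_b`, `features_a`, `features_b`
#'   (cluster/gene model/TE/satellite in each assembly's coordinates) and
#'   `truth` (tibble `type`, `pos_a`, `pos_b`, `length`, `detail`).
#' @export
generate_genome_pair <- function(config = sim_config(), seed = config$seed) {
  set.seed(seed)
  g <- config$genome; dv <- config$divergence; sat <- dv$satellite
  L <- g$contig_length
  span <- config$pirna$cluster_span
  stopifnot(L >= span + 30000L)
  backbone <- .random_seq(L, g$gc)

  cluster_start <- floor(0.35 * L)
  cluster_end <- cluster_start + span
  gene_start <- cluster_start + floor(0.15 * span)
  gene_len <- floor(0.35 * span)
  gene_end <- gene_start + gene_len
  ut5 <- floor(0.05 * gene_len); ut3 <- floor(0.05 * gene_len)
  intron_start <- gene_start + floor(0.45 * gene_len)
  intron_end <- intron_start + floor(0.1 * gene_len)
  te_pos <- cluster_start + floor(0.03 * span)
  stopifnot(te_pos < gene_start)
  sat_pos <- min(cluster_end + 3000L, L - 2000L)

  n_planted <- length(dv$planted_indel_lengths)
  planted_pos <- if (n_planted > 0) {
    floor(seq(gene_end + 1000L, cluster_end - 1000L,
              length.out = n_planted + 2L))[1 + seq_len(n_planted)]
  } else integer(0)

  # background SNPs / short indels, kept clear of engineered edit points
  excl <- c(te_pos, sat_pos, planted_pos)
  ok_pos <- function(p) {
    vapply(p, function(x) all(abs(x - excl) > 200L), logical(1))
  }
  cand <- which(stats::rbinom(L, 1L, dv$snp_rate) == 1L) - 1L
  snp_pos <- cand[ok_pos(cand)]
  cand <- which(stats::rbinom(L, 1L, dv$indel_rate) == 1L) - 1L
  cand <- cand[ok_pos(cand)]
  cand <- cand[!cand %in% snp_pos]
  small_indels <- tibble::tibble(
    pos = cand,
    len = sample.int(dv$indel_max_len, length(cand), replace = TRUE),
    side = sample(c("a", "b"), length(cand), replace = TRUE)
  )
  # drop overlapping/near-adjacent edits
  if (nrow(small_indels) > 1) {
    keep <- c(TRUE, diff(small_indels$pos) > 50L)
    small_indels <- small_indels[keep, ]
  }

  bases <- c("A", "C", "G", "T")
  bb <- strsplit(backbone, "")[[1]]
  snp_new <- vapply(snp_pos, function(p) {
    sample(setdiff(bases, bb[p + 1L]), 1L)
  }, character(1))

  te_seq <- .random_seq(dv$te_insertion_length, 0.45)
  sat_unit <- .random_seq(sat$unit_length, 0.35)

  # deletions in B relative to backbone: planted indels + small "a"-side
  dels_b <- dplyr::bind_rows(
    tibble::tibble(pos = planted_pos, len = dv$planted_indel_lengths,
                   what = "planted_indel"),
    tibble::tibble(pos = small_indels$pos[small_indels$side == "a"],
                   len = small_indels$len[small_indels$side == "a"],
                   what = "small_indel")
  ) |> dplyr::arrange(.data$pos)
  # insertions in B relative to backbone: small "b"-side
  ins_b <- tibble::tibble(
    pos = small_indels$pos[small_indels$side == "b"],
    len = small_indels$len[small_indels$side == "b"]
  ) |> dplyr::arrange(.data$pos)
  ins_b$seq <- vapply(ins_b$len, .random_seq, character(1), gc = g$gc)

  # coordinate maps: backbone -> A and backbone -> B
  a_of <- function(p) {
    p + ifelse(p >= te_pos, dv$te_insertion_length, 0L) +
      ifelse(p >= sat_pos, sat$unit_length * sat$copies_a, 0L)
  }
  b_shift <- function(p) {
    del <- if (nrow(dels_b)) {
      vapply(p, function(x) sum(dels_b$len[dels_b$pos + dels_b$len <= x]), 0)
    } else 0
    ins <- if (nrow(ins_b)) {
      vapply(p, function(x) sum(ins_b$len[ins_b$pos <= x]), 0)
    } else 0
    as.integer(ins - del)
  }
  b_of <- function(p) {
    p + b_shift(p) + ifelse(p >= sat_pos, sat$unit_length * sat$copies_b, 0L)
  }

  # build sequence A
  seq_a <- paste0(
    substr(backbone, 1L, te_pos), te_seq,
    substr(backbone, te_pos + 1L, sat_pos),
    strrep(sat_unit, sat$copies_a),
    substr(backbone, sat_pos + 1L, L)
  )
  # build sequence B: apply SNPs, indels, satellite to backbone
  bb_b <- bb
  bb_b[snp_pos + 1L] <- snp_new
  pieces <- list(); cur <- 0L
  edits <- dplyr::bind_rows(
    tibble::tibble(pos = dels_b$pos, len = dels_b$len, type = "del",
                   seq = NA_character_),
    tibble::tibble(pos = ins_b$pos, len = ins_b$len, type = "ins",
                   seq = ins_b$seq),
    tibble::tibble(pos = sat_pos, len = 0L, type = "ins",
                   seq = strrep(sat_unit, sat$copies_b))
  ) |> dplyr::arrange(.data$pos)
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos[i]
    pieces[[length(pieces) + 1L]] <- paste(bb_b[(cur + 1L):p], collapse = "")
    if (edits$type[i] == "ins") {
      pieces[[length(pieces) + 1L]] <- edits$seq[i]
      cur <- p
    } else {
      cur <- p + edits$len[i]
    }
  }
  pieces[[length(pieces) + 1L]] <- paste(bb_b[(cur + 1L):L], collapse = "")
  seq_b <- paste(unlist(pieces), collapse = "")

  truth <- dplyr::bind_rows(
    tibble::tibble(type = "snp", pos_a = a_of(snp_pos), pos_b = b_of(snp_pos),
                   length = 1L,
                   detail = paste0(bb[snp_pos + 1L], ">", snp_new)),
    tibble::tibble(type = "planted_indel", pos_a = a_of(planted_pos),
                   pos_b = b_of(planted_pos),
                   length = as.integer(dv$planted_indel_lengths),
                   detail = "inserted_in=a"),
    if (nrow(small_indels)) tibble::tibble(
      type = "small_indel", pos_a = a_of(small_indels$pos),
      pos_b = b_of(small_indels$pos), length = as.integer(small_indels$len),
      detail = paste0("inserted_in=", small_indels$side)) else NULL,
    tibble::tibble(type = "te_insertion", pos_a = te_pos,
                   pos_b = b_of(te_pos),
                   length = as.integer(dv$te_insertion_length),
                   detail = "inserted_in=a"),
    tibble::tibble(type = "satellite", pos_a = a_of(sat_pos) -
                     sat$unit_length * sat$copies_a,
                   pos_b = b_of(sat_pos) - sat$unit_length * sat$copies_b,
                   length = c(sat$unit_length * sat$copies_a,
                              sat$unit_length * sat$copies_b)[1],
                   detail = paste0("copies_a=", sat$copies_a,
                                   ";copies_b=", sat$copies_b))
  ) |> dplyr::arrange(.data$pos_a)

  gene_model <- function(coord) {
    gs <- coord(gene_start); ge <- coord(gene_end)
    is0 <- coord(intron_start); ie0 <- coord(intron_end)
    feature_tbl(
      id = c("cluster_1", "gene_1", "tx_1", "tx_1.e1", "tx_1.e2",
             "tx_1.utr5", "tx_1.cds1", "tx_1.cds2", "tx_1.utr3",
             "te_gypsy_like", "sat_array"),
      contig = "contig_1",
      start = c(coord(cluster_start), gs, gs, gs, ie0,
                gs, gs + ut5, ie0, ge - ut3,
                te_pos, 0L),
      end = c(coord(cluster_end), ge, ge, is0, ge,
              gs + ut5, is0, ge - ut3, ge,
              te_pos + max(dv$te_insertion_length, 1L), 1L),
      strand = c(NA, "+", "+", "+", "+", "+", "+", "+", "+", "+", NA),
      kind = c("cluster", "gene", "transcript", "exon", "exon",
               "UTR5", "CDS", "CDS", "UTR3", "TE", "satellite"),
      parent = c(NA, NA, "gene_1", "tx_1", "tx_1", "tx_1", "tx_1", "tx_1",
                 "tx_1", NA, NA)
    )
  }
  fa <- gene_model(a_of)
  if (dv$te_insertion_length == 0) {
    fa <- fa[fa$id != "te_gypsy_like", ]
    truth <- truth[truth$type != "te_insertion", ]
  }
  fa$start[fa$id == "sat_array"] <- a_of(sat_pos) - sat$unit_length * sat$copies_a
  fa$end[fa$id == "sat_array"] <- a_of(sat_pos)
  fb <- gene_model(b_of)
  fb <- fb[fb$id != "te_gypsy_like", ]   # B lacks the TE
  fb$start[fb$id == "sat_array"] <- b_of(sat_pos) - sat$unit_length * sat$copies_b
  fb$end[fb$id == "sat_array"] <- b_of(sat_pos)
  # structurally symmetric homologous span (SNPs only) for allele accounting;
  # the TE-bearing cluster span has unequal allele-informative recall
  span_row <- function(coord) {
    feature_tbl("allelic_span_1", "contig_1", coord(gene_start),
                coord(gene_end), NA, "cluster", NA)
  }
  fa <- dplyr::bind_rows(fa, span_row(a_of))
  fb <- dplyr::bind_rows(fb, span_row(b_of))

  list(
    assembly_a = assembly(c(contig_1 = seq_a), source_label = "strain_a"),
    assembly_b = assembly(c(contig_1 = seq_b), source_label = "strain_b"),
    features_a = fa, features_b = fb,
    truth = truth
  )
}

#' Bundled synthetic ncRNA contaminant library
#'
#' A small synthetic FASTA of rRNA/tRNA/snRNA/miRNA-labelled sequences
#' (random, fixed-seed; not real sequences) shipped with the package for
#' contaminant-subtraction logic.
#'
#' @return An [assembly].
#' @export
load_contaminant_db <- function() {
  read_fasta(system.file("extdata", "synthetic_ncrna.fasta",
                         package = "pirnakit"),
             source_label = "synthetic_ncrna")
}

.draw_lengths <- function(n, cfg) {
  l <- round(stats::rnorm(n, cfg$length_mean, cfg$length_sd))
  pmin(pmax(l, cfg$min_len), cfg$max_len)
}

.extract_read <- function(seqs, contig, start, len, strand) {
  s <- substring(seqs[contig], start + 1L, start + len)
  s[strand == "-"] <- revcomp(s[strand == "-"])
  s
}

#' Simulate a dual-strand piRNA library with ground truth
#'
#' Primary reads are drawn on both strands with 5' positions uniform over
#' the cluster; with probability `pingpong_fraction` each primary also
#' emits a partner read on the opposite strand whose 5' end overlaps the
#' primary's by exactly 10 nt. The first base of primaries is set to T with
#' probability `frac_1U` (else a uniform non-T base, so the configured
#' fraction is exactly recoverable), and the 10th base of partners to A
#' with probability `frac_10A` likewise. Lengths are
#' Normal(length_mean, length_sd) rounded and clipped to the piRNA window.
#' Contaminant reads are substrings of the bundled synthetic ncRNA set;
#' background reads are uniform genome-wide.
#'
#' @param genome an [assembly].
#' @param cluster a one-row feature tibble (the cluster span).
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return A list `reads` (read tibble, one row per read, `count = 1`) and
#'   `truth` (tibble `read_id`, `contig`, `start`, `strand`, `length`,
#'   `role` in {primary, partner, background, contaminant}).
#' @export
simulate_pirna_library <- function(genome, cluster, config = sim_config(),
                                   seed = config$seed) {
  set.seed(seed)
  cfg <- config$pirna
  seqs <- unclass(genome)
  cn <- cluster$contig[1]
  if (!cn %in% names(seqs)) stop("cluster contig not in genome")
  c0 <- cluster$start[1]; c1 <- cluster$end[1]
  if (c1 - c0 <= cfg$max_len) stop("cluster shorter than the longest read")
  n <- cfg$n_reads
  n_cont <- stats::rbinom(1L, n, cfg$contaminant_fraction)
  n_bg <- stats::rbinom(1L, n - n_cont, cfg$background_rate)
  n_prim <- n - n_cont - n_bg

  # primaries
  strand <- sample(c("+", "-"), n_prim, replace = TRUE)
  p5 <- c0 + sample.int(c1 - c0, n_prim, replace = TRUE) - 1L
  len <- .draw_lengths(n_prim, cfg)
  start <- ifelse(strand == "+", p5, p5 - len + 1L)
  L <- nchar(seqs[[cn]])
  start <- pmax(0L, pmin(start, L - len))
  sq <- .extract_read(seqs, cn, start, len, strand)
  u1 <- stats::runif(n_prim) < cfg$frac_1U
  first <- ifelse(u1, "T", sample(c("A", "C", "G"), n_prim, replace = TRUE))
  substr(sq, 1L, 1L) <- first

  prim <- tibble::tibble(contig = cn, start = as.integer(start),
                         strand = strand, length = as.integer(len),
                         sequence = sq, role = "primary")

  # ping-pong partners (opposite strand, exact 10 nt 5' overlap)
  is_pp <- stats::runif(n_prim) < cfg$pingpong_fraction
  pp_idx <- which(is_pp)
  partner <- NULL
  if (length(pp_idx)) {
    p5p <- ifelse(strand[pp_idx] == "+", p5[pp_idx] + 9L, p5[pp_idx] - 9L)
    sp <- ifelse(strand[pp_idx] == "+", "-", "+")
    lp <- .draw_lengths(length(pp_idx), cfg)
    stp <- ifelse(sp == "+", p5p, p5p - lp + 1L)
    ok <- stp >= 0L & stp + lp <= L
    p5p <- p5p[ok]; sp <- sp[ok]; lp <- lp[ok]; stp <- stp[ok]
    sqp <- .extract_read(seqs, cn, stp, lp, sp)
    a10 <- stats::runif(length(sqp)) < cfg$frac_10A
    tenth <- ifelse(a10, "A", sample(c("C", "G", "T"), length(sqp),
                                     replace = TRUE))
    substr(sqp, 10L, 10L) <- tenth
    partner <- tibble::tibble(contig = cn, start = as.integer(stp),
                              strand = sp, length = as.integer(lp),
                              sequence = sqp, role = "partner")
  }

  # genome-wide background
  bg <- NULL
  if (n_bg > 0) {
    ctg <- sample(names(seqs), n_bg, replace = TRUE,
                  prob = nchar(seqs) / sum(nchar(seqs)))
    lb <- .draw_lengths(n_bg, cfg)
    stb <- vapply(seq_len(n_bg), function(i) {
      sample.int(nchar(seqs[[ctg[i]]]) - lb[i], 1L) - 1L
    }, integer(1))
    sb <- sample(c("+", "-"), n_bg, replace = TRUE)
    bg <- tibble::tibble(contig = ctg, start = stb, strand = sb,
                         length = as.integer(lb),
                         sequence = .extract_read(seqs, ctg, stb, lb, sb),
                         role = "background")
  }

  # ncRNA contaminants
  cont <- NULL
  if (n_cont > 0) {
    db <- unclass(load_contaminant_db())
    src <- sample(names(db), n_cont, replace = TRUE,
                  prob = nchar(db) / sum(nchar(db)))
    lc <- .draw_lengths(n_cont, cfg)
    lc <- pmin(lc, nchar(db)[match(src, names(db))])
    stc <- vapply(seq_len(n_cont), function(i) {
      sample.int(nchar(db[[src[i]]]) - lc[i] + 1L, 1L) - 1L
    }, integer(1))
    cont <- tibble::tibble(contig = NA_character_, start = NA_integer_,
                           strand = NA_character_, length = as.integer(lc),
                           sequence = substring(db[src], stc + 1L, stc + lc),
                           role = "contaminant")
  }

  all <- dplyr::bind_rows(prim, partner, bg, cont)
  all$read_id <- sprintf("read_%06d", seq_len(nrow(all)))
  list(
    reads = read_tbl(all$read_id, all$sequence),
    truth = dplyr::select(all, "read_id", "contig", "start", "strand",
                          "length", "role")
  )
}

#' Alignment records from simulator ground truth
#'
#' Turns genome-placed truth rows (primaries, partners, background) into an
#' alignment tibble, bypassing the aligner; convenient for calibrating the
#' downstream statistics against the generator's known placements.
#'
#' @param sim output of [simulate_pirna_library()] or
#'   [simulate_hybrid_library()].
#' @return An alignment tibble.
#' @export
truth_records <- function(sim) {
  tr <- dplyr::filter(sim$truth, !is.na(.data$contig))
  sq <- sim$reads$sequence[match(tr$read_id, sim$reads$id)]
  alignment_tbl(
    read_id = tr$read_id, target = tr$contig, start = tr$start,
    strand = tr$strand, read_length = tr$length, mismatches = 0L,
    sequence = sq, n_best = 1L, count = 1L
  )
}

#' Simulate a maternal-deposition hybrid piRNA library
#'
#' Reads are drawn from the haplotype-A cluster with probability
#' `1 - minor_allele_fraction` and from the homologous haplotype-B cluster
#' otherwise (no-maternal-deposition crosses correspond to
#' `minor_allele_fraction = 0`); the allele of origin is recorded per read.
#' Reads are error-free copies of their haplotype, as required by the
#' perfect-match allele-specific filter.
#'
#' @param genome_a,genome_b haplotype assemblies.
#' @param cluster_a,cluster_b homologous cluster features on each.
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return A list `reads` and `truth` (`read_id`, `origin` in {a, b},
#'   `contig`, `start`, `strand`, `length`).
#' @export
simulate_hybrid_library <- function(genome_a, genome_b, cluster_a, cluster_b,
                                    config = sim_config(),
                                    seed = config$seed) {
  set.seed(seed)
  cfg <- config$pirna
  maf <- config$hybrid$minor_allele_fraction
  n <- cfg$n_reads
  origin <- ifelse(stats::runif(n) < maf, "b", "a")
  seqs <- list(a = unclass(genome_a), b = unclass(genome_b))
  cl <- list(a = cluster_a, b = cluster_b)
  len <- .draw_lengths(n, cfg)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  out <- lapply(c("a", "b"), function(hap) {
    idx <- which(origin == hap)
    if (length(idx) == 0) return(NULL)
    cn <- cl[[hap]]$contig[1]
    c0 <- cl[[hap]]$start[1]; c1 <- cl[[hap]]$end[1]
    st <- c0 + sample.int(c1 - c0 - max(len), length(idx), replace = TRUE) - 1L
    sq <- .extract_read(seqs[[hap]], cn, st, len[idx], strand[idx])
    tibble::tibble(
      idx = idx, origin = hap, contig = cn, start = st,
      strand = strand[idx], length = len[idx], sequence = sq
    )
  })
  all <- dplyr::bind_rows(out) |> dplyr::arrange(.data$idx)
  all$read_id <- sprintf("hyb_%06d", all$idx)
  list(
    reads = read_tbl(all$read_id, all$sequence),
    truth = dplyr::select(all, "read_id", "origin", "contig", "start",
                          "strand", "length")
  )
}

#' Simulate ChIP treat/input fragment libraries
#'
#' Input fragments are uniform over the genome; treat fragments are uniform
#' with their density multiplied by `enrichment_fold` inside the target
#' regions. Fragment length is fixed at the configured value.
#'
#' @param genome an [assembly].
#' @param regions tibble of enriched regions (`contig`, `start`, `end`);
#'   may be empty for a null library.
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return A list `treat` and `input`, each an alignment tibble of
#'   fragments.
#' @export
simulate_chip_library <- function(genome, regions, config = sim_config(),
                                  seed = config$seed) {
  set.seed(seed)
  cfg <- config$chip
  seqs <- unclass(genome)
  flen <- cfg$fragment_length
  draw <- function(n, enrich) {
    if (n == 0) {
      return(alignment_tbl(character(), character(), integer(),
                           character(), integer()))
    }
    per_ctg <- table(sample(names(seqs), n, replace = TRUE,
                            prob = nchar(seqs) / sum(nchar(seqs))))
    pieces <- lapply(names(per_ctg), function(cn) {
      m <- per_ctg[[cn]]
      L <- nchar(seqs[[cn]])
      wpos <- rep(1, L - flen + 1L)
      if (enrich) {
        rg <- regions[regions$contig == cn, , drop = FALSE]
        for (i in seq_len(nrow(rg))) {
          lo <- max(1L, rg$start[i] - flen + 2L)
          hi <- min(L - flen + 1L, rg$end[i])
          if (hi >= lo) wpos[lo:hi] <- cfg$enrichment_fold
        }
      }
      st <- sample.int(L - flen + 1L, m, replace = TRUE, prob = wpos) - 1L
      tibble::tibble(target = cn, start = st)
    })
    df <- dplyr::bind_rows(pieces)
    alignment_tbl(
      read_id = sprintf("frag_%06d", seq_len(nrow(df))),
      target = df$target, start = df$start,
      strand = sample(c("+", "-"), nrow(df), replace = TRUE),
      read_length = flen
    )
  }
  list(treat = draw(cfg$n_fragments, TRUE),
       input = draw(cfg$n_fragments, FALSE))
}
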