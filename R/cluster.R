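#' Strand-resolved per-base coverage
#'
#' Each position covered by a record's interval is incremented by the
#' record's weight, separately per strand. Multi-placement ("all mappers")
#' records can be down-weighted by `1/n_best` with `weight_by_nbest = TRUE`,
#' the standard fractional treatment for all-mapper tracks; unique tracks
#' should be built from [filter_unique_best_stratum()] output. Each returned
#' track also carries a `starts` vector of weighted 5'-end counts per
#' position, consumed by [call_clusters()].
#'
#' @param records a genome-placed alignment tibble.
#' @param genome the target [assembly].
#' @param weight_by_nbest divide each record's weight by its `n_best`.
#' @return A named list `"<contig>|+"`, `"<contig>|-"` of
#'   [coverage_track]s.
#' @export
stranded_coverage <- function(records, genome, weight_by_nbest = FALSE) {
  stopifnot(inherits(genome, "assembly"))
  lens <- contig_lengths(genome)
  if (nrow(records) > 0) {
    beyond <- records$start + records$read_length > lens[records$target]
    if (anyNA(beyond) || any(beyond)) {
      stop("alignment beyond contig end: corrupt input")
    }
  }
  w <- records$count %||% rep(1, nrow(records))
  if (weight_by_nbest) w <- w / records$n_best
  out <- list()
  for (cn in names(lens)) {
    L <- lens[[cn]]
    for (s in c("+", "-")) {
      sel <- records$target == cn & records$strand == s
      vals <- numeric(L)
      starts5 <- numeric(L)
      if (any(sel)) {
        d <- numeric(L + 1L)
        st <- records$start[sel]; en <- st + records$read_length[sel]
        ws <- w[sel]
        for (i in seq_along(st)) {
          d[st[i] + 1L] <- d[st[i] + 1L] + ws[i]
          d[en[i] + 1L] <- d[en[i] + 1L] - ws[i]
        }
        vals <- cumsum(d[seq_len(L)])
        p5 <- five_prime_pos(records[sel, ])
        agg <- tapply(ws, p5, sum)
        starts5[as.integer(names(agg)) + 1L] <- as.numeric(agg)
      }
      out[[paste0(cn, "|", s)]] <- coverage_track(
        contig = cn, strand = s, values = vals, normalization = "raw",
        contig_length = L, starts = starts5)
    }
  }
  out
}

#' Call piRNA cluster regions from stranded coverage
#'
#' Positions with combined (plus + minus) coverage > 0 are merged into
#' intervals, closing gaps of at most `max_gap` bp ("continuous piRNA
#' mapping"); intervals receiving fewer than `min_reads` weighted reads
#' (5'-end counts summed over both strands) are dropped. A region is flagged
#' dual-strand when the minor/major strand read ratio reaches
#' `dual_ratio_threshold`.
#'
#' @param track_plus,track_minus per-base [coverage_track]s for one contig,
#'   built by [stranded_coverage()] (they carry the 5'-end `starts`
#'   vectors used for read counting).
#' @param min_reads minimum weighted reads per region.
#' @param max_gap largest coverage gap bridged, bp.
#' @param dual_ratio_threshold minor/major strand ratio for the dual-strand
#'   flag.
#' @return A tibble of regions: `contig`, `start`, `end`, `reads_plus`,
#'   `reads_minus`, `dual_strand`; intervals are disjoint and sorted.
#' @export
call_clusters <- function(track_plus, track_minus, min_reads = 100,
                          max_gap = 1000L, dual_ratio_threshold = 0.1) {
  stopifnot(inherits(track_plus, "coverage_track"),
            inherits(track_minus, "coverage_track"),
            track_plus$contig == track_minus$contig,
            length(track_plus$values) == length(track_minus$values))
  comb <- track_plus$values + track_minus$values
  covered <- which(comb > 0)
  empty <- tibble::tibble(contig = character(), start = integer(),
                          end = integer(), reads_plus = numeric(),
                          reads_minus = numeric(), dual_strand = logical())
  if (length(covered) == 0) return(empty)
  brk <- which(diff(covered) > max_gap)
  seg_start <- covered[c(1L, brk + 1L)] - 1L           # 0-based
  seg_end <- covered[c(brk, length(covered))]          # half-open
  sp <- track_plus$starts %||% track_plus$values
  sm <- track_minus$starts %||% track_minus$values
  reads_plus <- mapply(function(a, b) sum(sp[(a + 1L):b]), seg_start, seg_end)
  reads_minus <- mapply(function(a, b) sum(sm[(a + 1L):b]), seg_start, seg_end)
  out <- tibble::tibble(
    contig = track_plus$contig,
    start = as.integer(seg_start), end = as.integer(seg_end),
    reads_plus = as.numeric(reads_plus), reads_minus = as.numeric(reads_minus)
  ) |>
    dplyr::filter(.data$reads_plus + .data$reads_minus >= min_reads) |>
    dplyr::mutate(dual_strand =
      pmin(.data$reads_plus, .data$reads_minus) /
      pmax(.data$reads_plus, .data$reads_minus) >= dual_ratio_threshold)
  if (nrow(out) == 0) empty else out
}

#' Extract a locus sequence with flanks
#'
#' Returns the genomic sequence from `start - flank` to `end + flank`,
#' truncated (and flagged) at contig edges.
#'
#' @param genome an [assembly].
#' @param region a one-row tibble with `contig`, `start`, `end`.
#' @param flank flank length in bp (default 10 kb).
#' @return A list: `sequence`, `contig`, `start`, `end` (0-based half-open,
#'   flank included), `truncated_left`, `truncated_right`.
#' @export
extract_locus <- function(genome, region, flank = 10000L) {
  stopifnot(inherits(genome, "assembly"))
  cn <- region$contig[1]
  if (!cn %in% names(genome)) stop("no such contig: ", cn)
  L <- nchar(unclass(genome)[[cn]])
  s <- max(0L, region$start[1] - flank)
  e <- min(L, region$end[1] + flank)
  list(
    sequence = substr(unclass(genome)[[cn]], s + 1L, e),
    contig = cn, start = s, end = e,
    truncated_left = region$start[1] - flank < 0L,
    truncated_right = region$end[1] + flank > L
  )
}

#' Pairwise locus structural comparison
#'
#' Compares two homologous locus sequences by unique-anchor chaining:
#' k-mers (default k = 21) unique within each sequence and shared between
#' them are chained colinearly; maximal anchor runs with a constant offset
#' become identity blocks whose interiors are compared base-by-base for
#' SNPs, and inter-block segments are aligned globally
#' (Needleman-Wunsch via Biostrings) to call SNPs and indels at base
#' resolution. Segments too large or too divergent to align (e.g.
#' satellite arrays) are reported as a single length-difference gap.
#' Indels of at least `gap_min` bp are additionally surfaced as `gaps`
#' (TE-insertion-scale events).
#'
#' @param seq_a,seq_b locus sequences (character, <= ~200 kb each).
#' @param k anchor k-mer length.
#' @param gap_min minimum indel length reported as a gap, bp.
#' @param max_align_len largest inter-anchor segment length submitted to
#'   global alignment.
#' @param max_align_area cap on the dynamic-programming area
#'   (`length_a * length_b`) of a segment alignment; beyond either limit the
#'   segment contributes a length-difference gap instead.
#' @return A `locus_diff`: list with tibbles `snps`
#'   (`pos_a`, `pos_b`, `base_a`, `base_b`), `indels`
#'   (`pos_a`, `pos_b`, `length`, `inserted_in`), `gaps` (indels >=
#'   `gap_min`), and `flag` (`"ok"` or `"unalignable"`).
#' @export
pairwise_locus_diff <- function(seq_a, seq_b, k = 21L, gap_min = 500L,
                                max_align_len = 20000L,
                                max_align_area = 4e6) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  anchors <- .shared_unique_anchors(seq_a, seq_b, k)
  if (nrow(anchors) == 0) {
    return(.locus_diff(tibble::tibble(), tibble::tibble(), gap_min, "unalignable"))
  }
  blocks <- .anchor_blocks(anchors, k)
  # successive blocks may overlap by < k bp; trim both coords equally so
  # within-block offsets stay intact and segments are never negative
  while (nrow(blocks) > 1) {
    for (i in 2:nrow(blocks)) {
      trim <- max(0L, blocks$a_end[i - 1] - blocks$a_start[i],
                  blocks$b_end[i - 1] - blocks$b_start[i])
      blocks$a_start[i] <- blocks$a_start[i] + trim
      blocks$b_start[i] <- blocks$b_start[i] + trim
    }
    ok <- blocks$a_end > blocks$a_start & blocks$b_end > blocks$b_start
    blocks <- blocks[ok, , drop = FALSE]
    if (all(ok)) break
  }
  snps <- list(); indels <- list()
  # SNPs inside constant-offset blocks
  for (i in seq_len(nrow(blocks))) {
    sa <- substr(seq_a, blocks$a_start[i] + 1L, blocks$a_end[i])
    sb <- substr(seq_b, blocks$b_start[i] + 1L, blocks$b_end[i])
    mm <- which(strsplit(sa, "")[[1]] != strsplit(sb, "")[[1]])
    if (length(mm)) {
      snps[[length(snps) + 1L]] <- tibble::tibble(
        pos_a = blocks$a_start[i] + mm - 1L,
        pos_b = blocks$b_start[i] + mm - 1L,
        base_a = substring(sa, mm, mm), base_b = substring(sb, mm, mm))
    }
  }
  # inter-block (and flanking) segments
  seg_a_start <- c(0L, blocks$a_end)
  seg_a_end <- c(blocks$a_start, nchar(seq_a))
  seg_b_start <- c(0L, blocks$b_end)
  seg_b_end <- c(blocks$b_start, nchar(seq_b))
  for (i in seq_along(seg_a_start)) {
    la <- seg_a_end[i] - seg_a_start[i]
    lb <- seg_b_end[i] - seg_b_start[i]
    if (la <= 0 && lb <= 0) next
    if (la == 0 || lb == 0) {
      # pure insertion on one side
      len <- abs(la - lb)
      indels[[length(indels) + 1L]] <- tibble::tibble(
        pos_a = seg_a_start[i], pos_b = seg_b_start[i], length = len,
        inserted_in = if (la > lb) "a" else "b")
      next
    }
    if (max(la, lb) > max_align_len || as.numeric(la) * lb > max_align_area) {
      if (la != lb) {
        indels[[length(indels) + 1L]] <- tibble::tibble(
          pos_a = seg_a_start[i], pos_b = seg_b_start[i],
          length = abs(la - lb), inserted_in = if (la > lb) "a" else "b")
      }
      next
    }
    seg <- .align_segment(
      substr(seq_a, seg_a_start[i] + 1L, seg_a_end[i]),
      substr(seq_b, seg_b_start[i] + 1L, seg_b_end[i]),
      seg_a_start[i], seg_b_start[i])
    if (nrow(seg$snps)) snps[[length(snps) + 1L]] <- seg$snps
    if (nrow(seg$indels)) indels[[length(indels) + 1L]] <- seg$indels
  }
  .locus_diff(dplyr::bind_rows(snps), dplyr::bind_rows(indels), gap_min, "ok")
}

.locus_diff <- function(snps, indels, gap_min, flag) {
  if (nrow(snps) == 0) {
    snps <- tibble::tibble(pos_a = integer(), pos_b = integer(),
                           base_a = character(), base_b = character())
  }
  if (nrow(indels) == 0) {
    indels <- tibble::tibble(pos_a = integer(), pos_b = integer(),
                             length = integer(), inserted_in = character())
  }
  snps <- dplyr::arrange(snps, .data$pos_a)
  indels <- dplyr::arrange(indels, .data$pos_a)
  structure(list(snps = snps, indels = indels,
                 gaps = dplyr::filter(indels, .data$length >= gap_min),
                 gap_min = gap_min, flag = flag),
            class = "locus_diff")
}

#' @export
print.locus_diff <- function(x, ...) {
  cat("<locus_diff> ", nrow(x$snps), " SNPs, ", nrow(x$indels), " indels (",
      nrow(x$gaps), " gaps >= ", x$gap_min, " bp), flag: ", x$flag, "\n", sep = "")
  invisible(x)
}

#' @rdname pairwise_locus_diff
#' @param x a `locus_diff`.
#' @param ... unused.
#' @export
tidy.locus_diff <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$snps, type = "snp", length = 1L,
                  detail = paste0(.data$base_a, ">", .data$base_b)),
    dplyr::mutate(x$indels, type = ifelse(.data$length >= x$gap_min,
                                          "gap", "indel"),
                  base_a = NA_character_, base_b = NA_character_,
                  detail = paste0("inserted_in=", .data$inserted_in))
  ) |>
    dplyr::select("type", "pos_a", "pos_b", "length", "detail") |>
    dplyr::arrange(.data$pos_a)
}

# k-mers unique within each sequence and present in both
.shared_unique_anchors <- function(seq_a, seq_b, k) {
  km <- function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1L), k:L)
  }
  ka <- km(seq_a); kb <- km(seq_b)
  ua <- !(duplicated(ka) | duplicated(ka, fromLast = TRUE))
  ub <- !(duplicated(kb) | duplicated(kb, fromLast = TRUE))
  pa <- which(ua); pb <- which(ub)
  idx <- match(ka[pa], kb[pb])
  keep <- !is.na(idx)
  tibble::tibble(pos_a = pa[keep] - 1L, pos_b = pb[idx[keep]] - 1L)
}

# collapse anchors (sorted by pos_a) into maximal constant-offset runs, then
# pick the heaviest colinear chain of runs by weighted LIS; run count is tiny
# (one run per structural breakpoint), so the quadratic DP is cheap
.anchor_blocks <- function(anchors, k) {
  anchors <- dplyr::arrange(anchors, .data$pos_a, .data$pos_b)
  off <- anchors$pos_b - anchors$pos_a
  grp <- cumsum(c(1L, diff(off) != 0L))
  runs <- anchors |>
    dplyr::mutate(grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(a_start = min(.data$pos_a), a_end = max(.data$pos_a) + k,
                     b_start = min(.data$pos_b), b_end = max(.data$pos_b) + k,
                     w = dplyr::n(), .groups = "drop") |>
    dplyr::select(-"grp")
  r <- nrow(runs)
  best <- as.numeric(runs$w); prev <- integer(r)
  for (i in seq_len(r)) {
    for (j in seq_len(i - 1L)) {
      if (runs$b_start[j] < runs$b_start[i] &&
          runs$a_start[j] < runs$a_start[i] &&
          best[j] + runs$w[i] > best[i]) {
        best[i] <- best[j] + runs$w[i]
        prev[i] <- j
      }
    }
  }
  sel <- integer(0)
  i <- which.max(best)
  while (i > 0L) { sel <- c(i, sel); i <- prev[i] }
  dplyr::select(runs[sel, , drop = FALSE], -"w")
}

# global alignment of an inter-anchor segment; returns SNP/indel calls in
# absolute (0-based) coordinates
.align_segment <- function(sa, sb, off_a, off_b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(sa), Biostrings::DNAString(sb),
    type = "global", gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- off_a; ib <- off_b
  snps <- list(); indels <- list()
  run_len <- 0L; run_side <- ""
  flush_run <- function(ia, ib) {
    if (run_len > 0L) {
      indels[[length(indels) + 1L]] <<- tibble::tibble(
        pos_a = if (run_side == "a") ia - run_len else ia,
        pos_b = if (run_side == "b") ib - run_len else ib,
        length = run_len, inserted_in = run_side)
    }
    run_len <<- 0L; run_side <<- ""
  }
  for (j in seq_along(pa)) {
    ca <- pa[j]; cb <- pb[j]
    if (ca != "-" && cb != "-") {
      flush_run(ia, ib)
      if (ca != cb) {
        snps[[length(snps) + 1L]] <- tibble::tibble(
          pos_a = ia, pos_b = ib, base_a = ca, base_b = cb)
      }
      ia <- ia + 1L; ib <- ib + 1L
    } else if (cb == "-") {            # extra base in a
      if (run_side != "a") flush_run(ia, ib)
      run_side <- "a"; run_len <- run_len + 1L
      ia <- ia + 1L
    } else {                           # extra base in b
      if (run_side != "b") flush_run(ia, ib)
      run_side <- "b"; run_len <- run_len + 1L
      ib <- ib + 1L
    }
  }
  flush_run(ia, ib)
  list(snps = dplyr::bind_rows(snps) %||%
         tibble::tibble(pos_a = integer(), pos_b = integer(),
                        base_a = character(), base_b = character()),
       indels = dplyr::bind_rows(indels) %||%
         tibble::tibble(pos_a = integer(), pos_b = integer(),
                        length = integer(), inserted_in = character()))
}
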