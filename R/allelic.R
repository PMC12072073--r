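#' Allele-of-origin piRNA accounting over a homologous locus pair
#'
#' Counts perfect-unique diploid placements (from
#' [align_allele_specific()]) falling inside each of two homologous locus
#' regions — one per haplotype — and expresses each allele's share as a
#' percentage of the two-allele total. Reads from sequence identical
#' between haplotypes never contribute (they fail the perfect-unique
#' filter), so the analysis is effectively restricted to the
#' allele-informative span of the locus; restrict the regions to the
#' uniquely mappable span (see [compute_mappability()]) to mirror this on
#' real tracks.
#'
#' @param records alignment tibble from [align_allele_specific()].
#' @param region_a,region_b one-row feature tibbles giving the homologous
#'   locus coordinates on the two haplotype contigs (prefixed names as made
#'   by [build_diploid()]).
#' @param locus_id label for the locus pair.
#' @param library_size optional total mapped reads, to also report per-allele
#'   RPKM.
#' @return A one-row tibble: `locus_id`, `count_a`, `count_b`, `pct_a`,
#'   `pct_b`, (`rpkm_a`, `rpkm_b`,) `undefined` (TRUE when no read hit
#'   either allele; percentages are then `NA`). `pct_a + pct_b = 100`
#'   whenever the total is positive.
#' @export
allelic_counts <- function(records, region_a, region_b, locus_id = "locus",
                           library_size = NULL) {
  in_region <- function(region) {
    sel <- records$target == region$contig[1] &
      records$start < region$end[1] &
      (records$start + records$read_length) > region$start[1]
    sum(records$count[sel])
  }
  ca <- in_region(region_a)
  cb <- in_region(region_b)
  tot <- ca + cb
  out <- tibble::tibble(
    locus_id = locus_id,
    count_a = ca, count_b = cb,
    pct_a = if (tot > 0) 100 * ca / tot else NA_real_,
    pct_b = if (tot > 0) 100 * cb / tot else NA_real_,
    undefined = tot == 0
  )
  if (!is.null(library_size)) {
    out$rpkm_a <- rpkm(ca, region_a$end[1] - region_a$start[1], library_size)
    out$rpkm_b <- rpkm(cb, region_b$end[1] - region_b$start[1], library_size)
  }
  out
}

#' Allele-informative recall from a locus diff
#'
#' The observed allelic percentages conflate expression share with variant
#' density: only reads overlapping at least one diagnostic variant can be
#' assigned. This helper computes, for a read length, the fraction of 5'
#' start positions within a span whose read would overlap at least one SNP
#' or indel breakpoint from a [pairwise_locus_diff()] result — the expected
#' assignable (informative) fraction under uniform read placement.
#'
#' @param diff a `locus_diff`.
#' @param span_start,span_end 0-based half-open span of the locus on
#'   sequence a.
#' @param read_length read length in nt.
#' @return Fraction in [0, 1].
#' @export
allelic_recall <- function(diff, span_start, span_end, read_length) {
  starts <- span_start:(span_end - read_length)
  var_pos <- c(diff$snps$pos_a, diff$indels$pos_a)
  var_pos <- var_pos[var_pos >= span_start & var_pos < span_end]
  if (length(starts) == 0) return(0)
  covered <- logical(length(starts))
  for (v in var_pos) {
    lo <- max(v - read_length + 1L, span_start)
    hi <- min(v, span_end - read_length)
    if (hi >= lo) covered[(lo - span_start + 1L):(hi - span_start + 1L)] <- TRUE
  }
  mean(covered)
}
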