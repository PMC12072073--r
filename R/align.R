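#' Exhaustive desk-scale read alignment
#'
#' Places every read on both strands of every contig, reporting all
#' placements with at most `max_mismatch` mismatches. `n_best` on each
#' record is the number of placements in that read's minimal-mismatch
#' stratum, which is what [filter_unique_best_stratum()] consumes. The
#' search is exhaustive (dictionary matching at 0 mismatches,
#' sliding-pattern matching otherwise), not heuristic, so results are
#' bit-reproducible; output from an external aligner can be substituted via
#' [read_alignments()] for genomes beyond desk scale. `N` in a read or the
#' genome never matches (counts as a mismatch).
#'
#' @param reads a read tibble (see [read_tbl()]).
#' @param target an [assembly] (genome, transcript set or contaminant
#'   library).
#' @param max_mismatch maximum mismatches per placement (0-3 typical).
#' @return An alignment tibble; reads without placements are absent.
#' @export
align_all <- function(reads, target, max_mismatch = 0L) {
  stopifnot(inherits(target, "assembly"), max_mismatch >= 0)
  if (nrow(reads) == 0) {
    return(alignment_tbl(character(), character(), integer(), character(), integer()))
  }
  useq <- unique(reads$sequence)
  hits <- if (max_mismatch == 0) {
    .match_exact(useq, target)
  } else {
    .match_mm(useq, target, max_mismatch)
  }
  if (nrow(hits) == 0) {
    return(alignment_tbl(character(), character(), integer(), character(), integer()))
  }
  hits <- hits |>
    dplyr::group_by(.data$sequence) |>
    dplyr::mutate(n_best = sum(.data$mismatches == min(.data$mismatches))) |>
    dplyr::ungroup()
  out <- dplyr::inner_join(
    reads, hits,
    by = "sequence", relationship = "many-to-many"
  )
  alignment_tbl(
    read_id = out$id, target = out$target, start = out$start,
    strand = out$strand, read_length = nchar(out$sequence),
    mismatches = out$mismatches, sequence = out$sequence,
    n_best = out$n_best, count = out$count
  )
}

# exact matching via width-grouped PDict; reads containing N cannot match
.match_exact <- function(useq, target) {
  useq <- useq[!grepl("N", useq, fixed = TRUE)]
  if (length(useq) == 0) {
    return(tibble::tibble(sequence = character(), target = character(),
                          start = integer(), strand = character(),
                          mismatches = integer()))
  }
  ctg <- lapply(unclass(target), Biostrings::DNAString)
  ctg_rc <- lapply(ctg, Biostrings::reverseComplement)
  lens <- nchar(unclass(target))
  widths <- nchar(useq)
  pieces <- list()
  for (w in sort(unique(widths))) {
    sq <- useq[widths == w]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(sq))
    for (cn in names(ctg)) {
      fw <- Biostrings::startIndex(Biostrings::matchPDict(pd, ctg[[cn]]))
      rv <- Biostrings::startIndex(Biostrings::matchPDict(pd, ctg_rc[[cn]]))
      fw[vapply(fw, is.null, logical(1))] <- list(integer(0))
      rv[vapply(rv, is.null, logical(1))] <- list(integer(0))
      nf <- lengths(fw); nr <- lengths(rv)
      if (sum(nf) > 0) {
        pieces[[length(pieces) + 1L]] <- tibble::tibble(
          sequence = rep(sq, nf), target = cn,
          start = unlist(fw, use.names = FALSE) - 1L,
          strand = "+", mismatches = 0L)
      }
      if (sum(nr) > 0) {
        pieces[[length(pieces) + 1L]] <- tibble::tibble(
          sequence = rep(sq, nr), target = cn,
          start = lens[[cn]] - (unlist(rv, use.names = FALSE) - 1L) - w,
          strand = "-", mismatches = 0L)
      }
    }
  }
  dplyr::bind_rows(pieces) %||%
    tibble::tibble(sequence = character(), target = character(),
                   start = integer(), strand = character(), mismatches = integer())
}

.match_mm <- function(useq, target, max_mismatch) {
  ctg <- lapply(unclass(target), Biostrings::DNAString)
  pieces <- list()
  for (i in seq_along(useq)) {
    s <- useq[i]
    pat_f <- Biostrings::DNAString(s)
    pat_r <- Biostrings::reverseComplement(pat_f)
    for (cn in names(ctg)) {
      subj <- ctg[[cn]]
      if (length(pat_f) > length(subj)) next
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") pat_f else pat_r
        m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch,
                                      fixed = TRUE)
        st <- BiocGenerics::start(m)
        if (length(st) == 0) next
        mm <- Biostrings::neditStartingAt(pat, subj, starting.at = st,
                                          fixed = TRUE)
        pieces[[length(pieces) + 1L]] <- tibble::tibble(
          sequence = s, target = cn, start = st - 1L, strand = strand,
          mismatches = as.integer(mm))
      }
    }
  }
  dplyr::bind_rows(pieces) %||%
    tibble::tibble(sequence = character(), target = character(),
                   start = integer(), strand = character(), mismatches = integer())
}

#' Best-stratum unique filter
#'
#' For each read, keep its alignment only if the minimal-mismatch stratum
#' contains exactly one placement (classic `-m 1 --best --strata`
#' semantics); multi-best reads are discarded entirely, never tie-broken.
#'
#' @param records an alignment tibble from [align_all()] or
#'   [read_alignments()].
#' @return The retained alignment tibble; every row has `n_best = 1`.
#' @export
filter_unique_best_stratum <- function(records) {
  if (nrow(records) == 0) return(records)
  records |>
    dplyr::group_by(.data$read_id) |>
    dplyr::filter(.data$mismatches == min(.data$mismatches)) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup() |>
    dplyr::mutate(n_best = 1L)
}

#' Perfect-match allele-specific alignment to a diploid genome
#'
#' Retains a read only if it has exactly one zero-mismatch placement in the
#' whole diploid genome (the `-v 0 -m 1` regime). Reads from sequence
#' identical between haplotypes place twice and are discarded, so every
#' retained read is unambiguously attributable to one allele via its
#' haplotype-prefixed contig name.
#'
#' @param reads a read tibble.
#' @param diploid a diploid [assembly] from [build_diploid()].
#' @return An alignment tibble of uniquely, perfectly placed reads.
#' @export
align_allele_specific <- function(reads, diploid) {
  if (is.null(attr(diploid, "haplotypes"))) {
    stop("diploid must be built with build_diploid()")
  }
  aln <- align_all(reads, diploid, max_mismatch = 0L)
  filter_unique_best_stratum(aln)
}

#' k-mer mappability track
#'
#' Position `i` of a contig is 1 iff the k-mer starting there occurs exactly
#' once among all forward-strand k-mers of the genome, else 0. This is the
#' k-mer-uniqueness notion used for read-mappability masking (k = 25 for
#' piRNA-length reads, k = 50 for mRNA/ChIP reads). Set `collapse_rc = TRUE`
#' to count a k-mer and its reverse complement as one.
#'
#' @param genome an [assembly].
#' @param k k-mer length in nt.
#' @param collapse_rc collapse reverse-complement k-mers (off by default).
#' @return A named list of [coverage_track]s (one per contig, positions
#'   `0 ... L-k`), values in {0,1}.
#' @export
compute_mappability <- function(genome, k, collapse_rc = FALSE) {
  stopifnot(inherits(genome, "assembly"))
  if (k <= 0) stop("k must be positive")
  seqs <- unclass(genome)
  kmers_of <- function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1L), k:L)
  }
  km <- lapply(seqs, kmers_of)
  all_km <- unlist(km, use.names = FALSE)
  key <- if (collapse_rc) pmin(all_km, revcomp(all_km)) else all_km
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  uniq <- as.numeric(!dup)
  idx <- rep(seq_along(km), lengths(km))
  out <- lapply(seq_along(km), function(i) {
    coverage_track(contig = names(seqs)[i], strand = "both",
                   values = uniq[idx == i],
                   normalization = paste0("mappability_k", k),
                   contig_length = nchar(seqs[[i]]))
  })
  stats::setNames(out, names(seqs))
}
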