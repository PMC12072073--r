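#' Alignment record tables
#'
#' Alignments are tibbles with one row per placement: `read_id`, `target`
#' (contig or transcript), `start` (0-based), `strand`, `read_length`,
#' `mismatches`, `sequence` (read orientation), `n_best` (number of equally
#' good placements in the read's best mismatch stratum) and `count`
#' (collapsed-read multiplicity, used as the weight everywhere downstream).
#'
#' @param read_id,target,sequence character vectors.
#' @param start integer, 0-based.
#' @param strand "+" or "-".
#' @param read_length,mismatches,n_best,count integers.
#' @return An alignment tibble.
#' @export
alignment_tbl <- function(read_id, target, start, strand, read_length,
                          mismatches = 0L, sequence = NA_character_,
                          n_best = 1L, count = 1L) {
  out <- tibble::tibble(
    read_id = as.character(read_id), target = as.character(target),
    start = as.integer(start), strand = as.character(strand),
    read_length = as.integer(read_length), mismatches = as.integer(mismatches),
    sequence = as.character(sequence), n_best = as.integer(n_best),
    count = as.numeric(count)
  )
  if (any(out$mismatches < 0) || any(out$n_best < 1)) {
    stop("mismatches must be >= 0 and n_best >= 1")
  }
  if (!all(out$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  out
}

#' Genomic 5' end of an alignment
#'
#' For a plus-strand alignment the 5' end is `start`; for a minus-strand
#' alignment it is the highest coordinate of the interval,
#' `start + read_length - 1`. This convention underlies the ping-pong
#' overlap arithmetic.
#'
#' @param records an alignment tibble.
#' @return Integer vector of 0-based 5'-end positions.
#' @export
five_prime_pos <- function(records) {
  ifelse(records$strand == "+", records$start,
         records$start + records$read_length - 1L)
}

#' Read alignments from SAM or BAM
#'
#' Unmapped records are skipped. Minus-strand records have their sequence
#' reverse-complemented back into read orientation. POS is converted from
#' 1-based to 0-based. The mismatch count is taken from the `NM` tag when
#' present, otherwise recomputed against `reference` if supplied, else 0 with
#' a warning. `n_best` is taken from the `NH` or `X0` tag when present,
#' else 1.
#'
#' @param path SAM or BAM file.
#' @param dialect `"sam"` or `"bam"`; guessed from the extension by default.
#' @param reference optional [assembly] used to recompute mismatches when no
#'   `NM` tag is present.
#' @return An alignment tibble.
#' @export
read_alignments <- function(path, dialect = NULL, reference = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "sam"
  }
  dialect <- match.arg(dialect, c("sam", "bam"))
  bam <- path
  if (dialect == "sam") {
    hdr <- readLines(path, n = 200L)
    if (!any(grepl("^@SQ", hdr))) {
      stop("SAM header lacks @SQ reference names: ", path)
    }
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "seq", "cigar", "flag"),
    tag = c("NM", "NH", "X0"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  if (length(res$qname) == 0) {
    return(alignment_tbl(character(), character(), integer(), character(), integer()))
  }
  seqs <- as.character(res$seq)
  minus <- as.character(res$strand) == "-"
  seqs[minus] <- revcomp(seqs[minus])
  nm <- res$tag$NM
  if (is.null(nm) || all(is.na(nm))) {
    if (!is.null(reference)) {
      nm <- .recount_mismatches(res, reference)
    } else {
      warning("no NM tag and no reference given; mismatches set to 0")
      nm <- rep(0L, length(res$qname))
    }
  }
  nm[is.na(nm)] <- 0L
  nb <- res$tag$NH
  if (is.null(nb)) nb <- res$tag$X0
  if (is.null(nb)) nb <- rep(1L, length(res$qname))
  nb[is.na(nb)] <- 1L
  alignment_tbl(
    read_id = res$qname,
    target = as.character(res$rname),
    start = res$pos - 1L,
    strand = ifelse(minus, "-", "+"),
    read_length = nchar(seqs),
    mismatches = as.integer(nm),
    sequence = seqs,
    n_best = as.integer(nb)
  )
}

.recount_mismatches <- function(res, reference) {
  ref <- unclass(reference)
  aligned <- as.character(res$seq)  # aligned orientation (reference forward)
  mapply(function(tg, pos, s) {
    w <- nchar(s)
    refseg <- substr(ref[[tg]], pos, pos + w - 1L)
    if (nchar(refseg) < w) return(w)
    r <- strsplit(refseg, "")[[1]]; q <- strsplit(s, "")[[1]]
    sum(r != q | r == "N" | q == "N")  # N never matches
  }, as.character(res$rname), res$pos, aligned, USE.NAMES = FALSE)
}

#' Write alignments to SAM
#'
#' Minimal single-end SAM writer for pipeline interchange; mismatches go to
#' the `NM` tag, the best-stratum placement count to `X0`.
#'
#' @param records an alignment tibble.
#' @param genome the target [assembly] (for `@SQ` header lines).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  lens <- contig_lengths(genome)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens), con)
  if (nrow(records) > 0) {
    minus <- records$strand == "-"
    seq_out <- ifelse(minus, revcomp(records$sequence), records$sequence)
    writeLines(sprintf(
      "%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d\tX0:i:%d",
      records$read_id, ifelse(minus, 16L, 0L), records$target,
      records$start + 1L, records$read_length, seq_out,
      records$mismatches, records$n_best), con)
  }
  invisible(path)
}
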