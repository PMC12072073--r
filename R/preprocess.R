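#' Small-RNA read tables
#'
#' Trimmed small-RNA reads are tibbles with columns `id`, `sequence` and
#' `count` (multiplicity of the identical sequence, >= 1). Identical
#' sequences are collapsed once with [collapse_reads()]; every downstream
#' statistic is count-weighted.
#'
#' @param id,sequence character vectors.
#' @param count integer multiplicities.
#' @return A read tibble.
#' @export
read_tbl <- function(id, sequence, count = 1L) {
  out <- tibble::tibble(id = as.character(id),
                        sequence = toupper(as.character(sequence)),
                        count = as.numeric(count))
  if (any(out$count < 1)) stop("count must be >= 1")
  if (any(grepl("[^ACGTN]", out$sequence))) {
    stop("read sequences must be over {A,C,G,T,N}")
  }
  out
}

#' Read small-RNA reads from FASTA or FASTQ
#'
#' @param path input file; format guessed from extension unless given.
#' @param format `"fasta"` or `"fastq"`.
#' @param collapse collapse identical sequences into one row with a count.
#' @return A read tibble.
#' @export
read_smallrna <- function(path, format = NULL, collapse = TRUE) {
  if (is.null(format)) {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  set <- Biostrings::readDNAStringSet(path, format = format)
  reads <- read_tbl(id = sub("\\s.*$", "", names(set)),
                    sequence = as.character(set))
  if (collapse) collapse_reads(reads) else reads
}

#' Collapse identical read sequences
#'
#' @param reads a read tibble.
#' @return A read tibble with one row per distinct sequence; `id` is the
#'   first id observed and `count` the summed multiplicity.
#' @export
collapse_reads <- function(reads) {
  reads |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(id = dplyr::first(.data$id),
                     count = sum(.data$count), .groups = "drop") |>
    dplyr::select("id", "sequence", "count")
}

#' Write reads to FASTA or FASTQ
#'
#' Collapsed counts are carried in the record name as `id_xN`. FASTQ records
#' get uniform maximum qualities (the simulators have no error model by
#' default).
#'
#' @param reads a read tibble.
#' @param path output path.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  nm <- ifelse(reads$count > 1, paste0(reads$id, "_x", reads$count), reads$id)
  set <- Biostrings::DNAStringSet(stats::setNames(reads$sequence, nm))
  if (format == "fastq") {
    q <- Biostrings::PhredQuality(vapply(nchar(reads$sequence),
                                         function(w) strrep("I", w), ""))
    set <- Biostrings::QualityScaledDNAStringSet(set, q)
    Biostrings::writeQualityScaledXStringSet(set, path)
  } else {
    Biostrings::writeXStringSet(set, path)
  }
  invisible(path)
}

#' Filter reads by length
#'
#' Retains reads with `min_len <= nchar(sequence) <= max_len` (both ends
#' inclusive); counts are preserved. The piRNA class is 23-29 nt; size
#' profiles use 20-29 nt.
#'
#' @param reads a read tibble.
#' @param min_len,max_len inclusive length window in nt.
#' @return The filtered read tibble.
#' @examples
#' r <- read_tbl(paste0("r", 1:3), c("ACGTACGTACGTACGTACGTACG",
#'                                   "ACGTACGTACGTACGTACGT",
#'                                   "ACGTACGTACGTACGTACGTACGTACGTAC"))
#' filter_by_length(r, 23, 29)
#' @export
filter_by_length <- function(reads, min_len = 23L, max_len = 29L) {
  stopifnot(min_len <= max_len)
  dplyr::filter(reads, nchar(.data$sequence) >= min_len,
                nchar(.data$sequence) <= max_len)
}

#' Subtract ncRNA contaminants
#'
#' Removes every read that matches anywhere inside any contaminant sequence
#' (rRNA, tRNA, snRNA, miRNA, ...) on either strand with at most
#' `max_mismatch` mismatches. The default is exact matching
#' (`max_mismatch = 0`).
#'
#' @param reads a read tibble.
#' @param contaminant_db an [assembly] of contaminant sequences.
#' @param max_mismatch mismatch tolerance.
#' @return A list with elements `kept` and `removed` (read tibbles) and
#'   `summary` (a one-row tibble of input/removed/kept weighted counts).
#' @export
subtract_ncrna <- function(reads, contaminant_db, max_mismatch = 0L) {
  stopifnot(inherits(contaminant_db, "assembly"), length(contaminant_db) > 0)
  if (nrow(reads) == 0) {
    hit <- logical(0)
  } else if (max_mismatch == 0) {
    # substring containment on either strand via fixed-pattern search
    haystack <- paste(c(unclass(contaminant_db), revcomp(unclass(contaminant_db))),
                      collapse = "#")
    hit <- vapply(reads$sequence, function(s) grepl(s, haystack, fixed = TRUE),
                  logical(1), USE.NAMES = FALSE)
  } else {
    aln <- align_all(reads, contaminant_db, max_mismatch = max_mismatch)
    hit <- reads$id %in% unique(aln$read_id)
  }
  list(
    kept = reads[!hit, , drop = FALSE],
    removed = reads[hit, , drop = FALSE],
    summary = tibble::tibble(
      input = sum(reads$count),
      removed = sum(reads$count[hit]),
      kept = sum(reads$count[!hit])
    )
  )
}
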