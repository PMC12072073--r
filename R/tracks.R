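#' Per-position and binned coverage tracks
#'
#' A coverage track holds nonnegative finite values for one contig and one
#' strand ("+", "-" or "both"), either per base (`bin_size = 1`) or per bin.
#' The `normalization` tag records what the values mean (`"raw"`,
#' `"RPKM-like"`, `"RPGC"`, `"treat-minus-input"`). Per-base piRNA tracks
#' additionally carry a `starts` vector: the weighted count of read 5' ends
#' at each position, used by [call_clusters()].
#'
#' @param contig contig name.
#' @param strand "+", "-" or "both".
#' @param values numeric vector of per-position (or per-bin) values.
#' @param normalization normalization tag.
#' @param bin_size bin width in bp (1 = per base).
#' @param contig_length contig length in bp (defaults to
#'   `length(values) * bin_size`).
#' @param starts optional per-position 5'-end weight vector.
#' @return A `coverage_track`.
#' @export
coverage_track <- function(contig, strand, values, normalization = "raw",
                           bin_size = 1L, contig_length = NULL, starts = NULL) {
  stopifnot(strand %in% c("+", "-", "both"), bin_size >= 1)
  values <- as.numeric(values)
  structure(
    list(contig = contig, strand = strand, values = values,
         normalization = normalization, bin_size = as.integer(bin_size),
         contig_length = as.integer(contig_length %||% (length(values) * bin_size)),
         starts = starts),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> ", x$contig, " [", x$strand, "] ",
      length(x$values), " x ", x$bin_size, " bp bins, ",
      x$normalization, "\n", sep = "")
  invisible(x)
}

#' Tidy a coverage track into a position/value table
#'
#' @param x a `coverage_track`.
#' @param ... unused.
#' @return A tibble with `contig`, `strand`, `start`, `end`, `value`
#'   (0-based half-open bins).
#' @export
tidy.coverage_track <- function(x, ...) {
  n <- length(x$values)
  if (n == 0) {
    return(tibble::tibble(contig = character(), strand = character(),
                          start = integer(), end = integer(), value = numeric()))
  }
  start <- (seq_len(n) - 1L) * x$bin_size
  tibble::tibble(
    contig = x$contig, strand = x$strand,
    start = start, end = pmin(start + x$bin_size, x$contig_length),
    value = x$values
  )
}

#' @export
autoplot.coverage_track <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = .data$value)) +
    ggplot2::geom_area(fill = if (object$strand == "-") "steelblue" else "firebrick",
                       alpha = 0.7) +
    ggplot2::labs(x = paste0(object$contig, " (bp)"),
                  y = object$normalization,
                  title = paste0("Coverage [", object$strand, "]")) +
    ggplot2::theme_minimal()
}

#' Write a coverage track to bedGraph
#'
#' Runs of equal value are merged into single 0-based half-open intervals
#' which are disjoint, sorted and tile the covered region. A list of tracks
#' (e.g. one per contig) sharing a strand may be given; stranded track pairs
#' should be written to one file per strand.
#'
#' @param track a `coverage_track` or a list of them (same strand).
#' @param path output path.
#' @param drop_zero drop zero-valued runs (default keeps them so intervals
#'   tile the contig).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, drop_zero = FALSE) {
  tracks <- if (inherits(track, "coverage_track")) list(track) else track
  stopifnot(all(vapply(tracks, inherits, logical(1), "coverage_track")))
  pieces <- lapply(tracks, function(tr) {
    if (any(!is.finite(tr$values))) {
      stop("non-finite value in coverage track for ", tr$contig)
    }
    if (length(tr$values) == 0) return(NULL)
    r <- rle(tr$values)
    ends_bin <- cumsum(r$lengths)
    starts <- (ends_bin - r$lengths) * tr$bin_size
    ends <- pmin(ends_bin * tr$bin_size, tr$contig_length)
    tibble::tibble(contig = tr$contig, start = starts, end = ends,
                   value = r$values, clen = tr$contig_length)
  })
  df <- dplyr::bind_rows(pieces)
  if (!is.null(df) && nrow(df) > 0 && drop_zero) df <- df[df$value != 0, ]
  if (is.null(df) || nrow(df) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    score = df$value
  )
  lens <- tapply(df$clen, df$contig, max)
  GenomeInfoDb::seqlengths(gr) <- lens[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
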