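#' Sense/antisense orientation split
#'
#' Labels each alignment record sense or antisense relative to a feature.
#' In `"genomic"` mode a record is sense iff its strand equals the feature
#' strand; in `"transcript"` mode (records placed on a transcript sequence)
#' a record is sense iff it is on the `+` strand.
#'
#' @param records an alignment tibble.
#' @param feature a one-row feature tibble (must carry a strand in genomic
#'   mode).
#' @param mode `"genomic"` or `"transcript"`.
#' @return The records with an added `orientation` column
#'   (`"sense"`/`"antisense"`); the two classes partition the input.
#' @export
split_orientation <- function(records, feature, mode = c("genomic", "transcript")) {
  mode <- match.arg(mode)
  if (mode == "genomic") {
    fs <- feature$strand[1]
    if (is.na(fs) || !fs %in% c("+", "-")) {
      stop("feature has no strand; cannot orient records")
    }
    sense <- records$strand == fs
  } else {
    sense <- records$strand == "+"
  }
  dplyr::mutate(records, orientation = ifelse(sense, "sense", "antisense"))
}

#' Count-weighted read size distribution
#'
#' @param records an alignment or read tibble; if an `orientation` column is
#'   present the histogram is split by it.
#' @param min_len,max_len length range in nt (bins with zero reads are kept
#'   with value 0).
#' @return A tibble with `length`, (`orientation`,) `weight`.
#' @export
size_distribution <- function(records, min_len = 20L, max_len = 29L) {
  len <- if ("read_length" %in% names(records)) records$read_length
         else nchar(records$sequence)
  df <- tibble::tibble(
    length = len,
    orientation = if ("orientation" %in% names(records)) records$orientation else "all",
    weight = records$count %||% rep(1, nrow(records))
  )
  df <- df[df$length >= min_len & df$length <= max_len, , drop = FALSE]
  grid <- tidyr::expand_grid(length = min_len:max_len,
                             orientation = unique(df$orientation) %||% "all")
  if (nrow(grid) == 0) grid <- tibble::tibble(length = min_len:max_len, orientation = "all")
  df |>
    dplyr::group_by(.data$length, .data$orientation) |>
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop") |>
    dplyr::right_join(grid, by = c("length", "orientation")) |>
    dplyr::mutate(weight = tidyr::replace_na(.data$weight, 0)) |>
    dplyr::arrange(.data$orientation, .data$length)
}

#' Plot a size distribution
#'
#' @param sizes output of [size_distribution()].
#' @return A ggplot.
#' @export
plot_size_distribution <- function(sizes) {
  ggplot2::ggplot(sizes, ggplot2::aes(x = factor(.data$length), y = .data$weight,
                                      fill = .data$orientation)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(sense = "firebrick",
                                          antisense = "steelblue", all = "grey40")) +
    ggplot2::labs(x = "read length (nt)", y = "weighted reads") +
    ggplot2::theme_minimal()
}

#' 1U / 10A nucleotide bias
#'
#' Count-weighted fraction of reads with U (T in DNA) at position 1 of the
#' read-orientation sequence, and with A at position 10. Reads shorter than
#' 10 nt do not contribute to `frac_10A`. With zero weight the fractions are
#' `NA` and the result is flagged undefined.
#'
#' @param records an alignment or read tibble with `sequence` in read
#'   orientation.
#' @return A one-row tibble: `n`, `frac_1U`, `n_10`, `frac_10A`,
#'   `undefined`.
#' @export
nucleotide_bias <- function(records) {
  w <- records$count %||% rep(1, nrow(records))
  n <- sum(w)
  if (n == 0) {
    return(tibble::tibble(n = 0, frac_1U = NA_real_, n_10 = 0,
                          frac_10A = NA_real_, undefined = TRUE))
  }
  b1 <- substr(records$sequence, 1L, 1L)
  frac_1U <- sum(w[b1 %in% c("T", "U")]) / n
  long <- nchar(records$sequence) >= 10L
  n10 <- sum(w[long])
  frac_10A <- if (n10 > 0) {
    b10 <- substr(records$sequence[long], 10L, 10L)
    sum(w[long][b10 == "A"]) / n10
  } else NA_real_
  tibble::tibble(n = n, frac_1U = frac_1U, n_10 = n10, frac_10A = frac_10A,
                 undefined = FALSE)
}

#' Ping-pong signature
#'
#' Histogram of 5'-end overlaps between plus- and minus-strand piRNAs on one
#' locus, with the Z-score of the 10-nt bin. For each plus-strand 5'
#' position \eqn{p^+} and minus-strand 5' position \eqn{p^-}, the overlap is
#' \eqn{o = p^- - p^+ + 1}; pairs with \eqn{o \in [1, max\_overlap]} add the
#' product of the collapsed-read weights at the two positions to bin
#' \eqn{o}. The Z-score is
#' \deqn{z_{10} = (h[10] - mean(h[o \ne 10])) / sd(h[o \ne 10])}
#' with the sample (n-1) standard deviation over the non-10 background bins.
#'
#' @param records a genome-placed alignment tibble covering both strands of
#'   one locus (one contig).
#' @param max_overlap largest overlap bin (background = all non-10 bins in
#'   `1:max_overlap`).
#' @return A `pingpong_result`: list with `histogram` (named numeric),
#'   `z10`, `n_pairs`, `flag` (`"ok"`, `"no_pairs"` or `"z_undefined"`).
#' @export
pingpong_signature <- function(records, max_overlap = 20L) {
  stopifnot(max_overlap >= 2)
  h <- stats::setNames(numeric(max_overlap), as.character(1:max_overlap))
  if (nrow(records) > 0) {
    if (length(unique(records$target)) > 1) {
      stop("records span multiple targets; compute one locus at a time")
    }
    w <- records$count %||% rep(1, nrow(records))
    p5 <- five_prime_pos(records)
    plus <- records$strand == "+"
    wp <- tapply(w[plus], p5[plus], sum)
    wm <- tapply(w[!plus], p5[!plus], sum)
    if (length(wp) && length(wm)) {
      pp <- as.integer(names(wp)); pm <- as.integer(names(wm))
      for (o in 1:max_overlap) {
        idx <- match(pm - o + 1L, pp)
        ok <- !is.na(idx)
        if (any(ok)) h[o] <- sum(as.numeric(wm[ok]) * as.numeric(wp[idx[ok]]))
      }
    }
  }
  bg <- h[-10L]
  flag <- "ok"
  z10 <- NA_real_
  if (sum(h) == 0) {
    flag <- "no_pairs"
  } else if (stats::sd(bg) == 0) {
    flag <- "z_undefined"
  } else {
    z10 <- (h[["10"]] - mean(bg)) / stats::sd(bg)
  }
  structure(list(histogram = h, z10 = z10, n_pairs = sum(h),
                 max_overlap = as.integer(max_overlap), flag = flag),
            class = "pingpong_result")
}

#' @export
print.pingpong_result <- function(x, ...) {
  cat("<pingpong_result> pairs:", format(x$n_pairs), " z10:",
      if (is.na(x$z10)) x$flag else format(round(x$z10, 2)), "\n")
  invisible(x)
}

#' @rdname pingpong_signature
#' @param x a `pingpong_result`.
#' @param ... unused.
#' @export
tidy.pingpong_result <- function(x, ...) {
  tibble::tibble(overlap = as.integer(names(x$histogram)),
                 pairs = as.numeric(x$histogram))
}

#' @rdname pingpong_signature
#' @export
glance.pingpong_result <- function(x, ...) {
  tibble::tibble(z10 = x$z10, n_pairs = x$n_pairs,
                 max_overlap = x$max_overlap, flag = x$flag)
}

#' @rdname pingpong_signature
#' @param object a `pingpong_result`.
#' @export
autoplot.pingpong_result <- function(object, ...) {
  df <- tidy(object)
  lab <- if (is.na(object$z10)) object$flag
         else paste0("z10 = ", round(object$z10, 2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$overlap, y = .data$pairs,
                                   fill = .data$overlap == 10)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60")) +
    ggplot2::labs(x = "5' overlap (nt)", y = "weighted pairs", subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Assign reads to features by exon overlap
#'
#' A record is assigned to a feature when its interval overlaps an exon of
#' that feature (exon rows are grouped by their `parent`, or by their own
#' id when parentless); records overlapping exons of two or more features
#' are discarded as ambiguous, records overlapping none are unassigned.
#'
#' @param records an alignment tibble.
#' @param features a feature tibble containing exon rows (`kind == "exon"`);
#'   if no exon rows exist, all rows are treated as countable intervals.
#' @return A tibble `feature_id`, `count` (count-weighted), with attributes
#'   `unassigned` and `ambiguous` (weighted totals); conservation holds:
#'   assigned + unassigned + ambiguous = total weight.
#' @export
count_feature_reads <- function(records, features) {
  exons <- dplyr::filter(features, .data$kind == "exon")
  if (nrow(exons) == 0) exons <- features
  group <- ifelse(is.na(exons$parent), exons$id, exons$parent)
  w <- records$count %||% rep(1, nrow(records))
  if (nrow(records) == 0) {
    out <- tibble::tibble(feature_id = unique(group), count = 0)
    attr(out, "unassigned") <- 0; attr(out, "ambiguous") <- 0
    return(out)
  }
  rgr <- GenomicRanges::GRanges(records$target,
           IRanges::IRanges(records$start + 1L,
                            records$start + records$read_length))
  egr <- features_to_granges(exons)
  hits <- GenomicRanges::findOverlaps(rgr, egr, ignore.strand = TRUE)
  hit_df <- tibble::tibble(rec = S4Vectors::queryHits(hits),
                           feature_id = group[S4Vectors::subjectHits(hits)]) |>
    dplyr::distinct()
  per_rec <- hit_df |>
    dplyr::group_by(.data$rec) |>
    dplyr::summarise(nfeat = dplyr::n(),
                     feature_id = dplyr::first(.data$feature_id),
                     .groups = "drop")
  assigned <- per_rec[per_rec$nfeat == 1, ]
  ambiguous_w <- sum(w[per_rec$rec[per_rec$nfeat > 1]])
  unassigned_w <- sum(w) - sum(w[per_rec$rec])
  counts <- tibble::tibble(feature_id = assigned$feature_id,
                           weight = w[assigned$rec]) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(count = sum(.data$weight), .groups = "drop")
  out <- tibble::tibble(feature_id = unique(group)) |>
    dplyr::left_join(counts, by = "feature_id") |>
    dplyr::mutate(count = tidyr::replace_na(.data$count, 0))
  attr(out, "unassigned") <- unassigned_w
  attr(out, "ambiguous") <- ambiguous_w
  out
}

#' Reads per kilobase per million mapped reads
#'
#' \code{rpkm = count * 1e9 / (feature_length * library_size)}, i.e. counts
#' normalized to feature length in kb and sequencing depth in millions.
#'
#' @param count weighted read count(s).
#' @param feature_length feature length(s) in bp (> 0).
#' @param library_size total mapped reads in the library (> 0).
#' @return Numeric RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(count, feature_length, library_size) {
  if (any(feature_length <= 0)) stop("feature_length must be > 0")
  if (any(library_size <= 0)) stop("library_size must be > 0")
  count * 1e9 / (feature_length * library_size)
}

#' Expression fold change
#'
#' \code{(a + pseudocount) / (b + pseudocount)}. With the default
#' `pseudocount = 0`, a zero denominator yields `Inf` and 0/0 yields `NA`
#' (flagged undefined) rather than an error.
#'
#' @param rpkm_a,rpkm_b expression values.
#' @param pseudocount nonnegative stabilizer.
#' @return Numeric ratio(s).
#' @export
fold_change <- function(rpkm_a, rpkm_b, pseudocount = 0) {
  stopifnot(pseudocount >= 0)
  num <- rpkm_a + pseudocount
  den <- rpkm_b + pseudocount
  out <- ifelse(den == 0 & num == 0, NA_real_,
                ifelse(den == 0, Inf, num / den))
  out
}
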