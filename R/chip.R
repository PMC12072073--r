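#' Binned fragment coverage for ChIP-seq
#'
#' Single-end records are extended to `extend` bp from their 5' end
#' (strand-aware); records already representing fragments (e.g. simulated
#' or paired-end spans) are used as-is with `extend = NULL`. Optionally
#' removes duplicate fragments (identical target, 5' position and strand)
#' and multi-mapped records (`n_best > 1`). Each fragment adds its per-base
#' overlap divided by the bin size to every overlapped bin, so a bin value
#' is the mean per-base fragment coverage of that bin.
#'
#' @param records an alignment tibble of reads or fragments.
#' @param genome the target [assembly].
#' @param bin_size bin width in bp.
#' @param extend single-end extension length in bp, or `NULL`.
#' @param dedup remove duplicate fragments.
#' @param unique_only drop records with `n_best > 1`.
#' @return A named list of binned [coverage_track]s (one per contig,
#'   strand `"both"`), with attributes `total_fragment_bases`,
#'   `n_fragments` and `genome_size`.
#' @export
binned_coverage <- function(records, genome, bin_size = 10L, extend = NULL,
                            dedup = TRUE, unique_only = TRUE) {
  stopifnot(inherits(genome, "assembly"), bin_size >= 1)
  lens <- contig_lengths(genome)
  if (unique_only && nrow(records) > 0 && "n_best" %in% names(records)) {
    records <- records[records$n_best == 1L, , drop = FALSE]
  }
  if (dedup && nrow(records) > 0) {
    key <- paste(records$target, five_prime_pos(records), records$strand)
    records <- records[!duplicated(key), , drop = FALSE]
  }
  if (!is.null(extend) && nrow(records) > 0) {
    if (any(extend < records$read_length)) {
      stop("extend must be >= read length")
    }
    st <- ifelse(records$strand == "+", records$start,
                 records$start + records$read_length - extend)
    records$start <- as.integer(pmax(0L, st))
    records$read_length <- as.integer(extend)
  }
  total_bases <- 0
  out <- list()
  for (cn in names(lens)) {
    L <- lens[[cn]]
    nb <- ceiling(L / bin_size)
    sel <- which(records$target == cn)
    perbase <- numeric(L)
    if (length(sel)) {
      d <- numeric(L + 1L)
      st <- pmax(0L, records$start[sel])
      en <- pmin(L, records$start[sel] + records$read_length[sel])
      w <- (records$count %||% rep(1, nrow(records)))[sel]
      for (i in seq_along(st)) {
        if (en[i] <= st[i]) next
        d[st[i] + 1L] <- d[st[i] + 1L] + w[i]
        d[en[i] + 1L] <- d[en[i] + 1L] - w[i]
      }
      perbase <- cumsum(d[seq_len(L)])
      total_bases <- total_bases + sum((en - st) * w)
    }
    bin_id <- rep(seq_len(nb), each = bin_size, length.out = L)
    vals <- as.numeric(tapply(perbase, bin_id, sum)) / bin_size
    out[[cn]] <- coverage_track(cn, "both", vals, normalization = "raw",
                                bin_size = bin_size, contig_length = L)
  }
  attr(out, "total_fragment_bases") <- total_bases
  attr(out, "n_fragments") <- nrow(records)
  attr(out, "genome_size") <- sum(lens)
  out
}

#' RPGC (1x genome coverage) normalization
#'
#' Divides a binned track by the scaling factor
#' `total_fragment_bases / effective_genome_size`, so the genome-wide mean
#' normalized per-base coverage equals 1. The effective genome size
#' defaults to the count of non-N bases in the genome.
#'
#' @param tracks binned track list from [binned_coverage()].
#' @param genome the [assembly] (used for the default effective genome
#'   size).
#' @param effective_genome_size effective genome size in bp.
#' @param total_fragment_bases total fragment bases; defaults to the value
#'   recorded on `tracks`.
#' @return The normalized track list (tag `"RPGC"`).
#' @export
rpgc_normalize <- function(tracks, genome = NULL, effective_genome_size = NULL,
                           total_fragment_bases = NULL) {
  total_fragment_bases <- total_fragment_bases %||%
    attr(tracks, "total_fragment_bases")
  if (is.null(total_fragment_bases) || total_fragment_bases <= 0) {
    stop("total fragment bases must be positive")
  }
  if (is.null(effective_genome_size)) {
    if (is.null(genome)) stop("need genome or effective_genome_size")
    seqs <- unclass(genome)
    effective_genome_size <- sum(nchar(seqs)) -
      sum(vapply(seqs, function(s) sum(strsplit(s, "")[[1]] == "N"), 0))
  }
  if (effective_genome_size <= 0) stop("effective_genome_size must be > 0")
  factor <- total_fragment_bases / effective_genome_size
  out <- lapply(tracks, function(tr) {
    tr$values <- tr$values / factor
    tr$normalization <- "RPGC"
    tr
  })
  attributes(out) <- attributes(tracks)
  attr(out, "scale_factor") <- factor
  out
}

#' Subtract input from treat coverage
#'
#' Elementwise treat minus input on identical bin grids; negative bins are
#' retained (not clipped) and their count is recorded in the
#' `negative_bins` attribute.
#'
#' @param treat,input binned track lists (same contigs and bin grid), both
#'   RPGC-normalized.
#' @return Track list tagged `"treat-minus-input"`.
#' @export
subtract_input <- function(treat, input) {
  if (!identical(names(treat), names(input))) stop("contig set mismatch")
  neg <- 0L
  out <- purrr::map2(treat, input, function(a, b) {
    if (a$bin_size != b$bin_size || length(a$values) != length(b$values)) {
      stop("bin grid mismatch on ", a$contig)
    }
    a$values <- a$values - b$values
    neg <<- neg + sum(a$values < 0)
    a$normalization <- "treat-minus-input"
    a
  })
  attr(out, "negative_bins") <- neg
  out
}

#' Enriched-region selection by per-bin Poisson test
#'
#' A simple enrichment prefilter: per-bin fragment counts in treat are
#' tested one-sided against the library-scaled input expectation under a
#' Poisson model, with the expectation floored at the genome-wide mean
#' input count (so sparse-input bins cannot inflate significance);
#' Benjamini-Hochberg adjusted p-values at or below `alpha` define
#' significant bins, which are merged (gap <= 1 bin) into regions.
#'
#' @param treat_records,input_records alignment tibbles of fragments.
#' @param genome the [assembly].
#' @param bin_size bin width, bp.
#' @param alpha BH-adjusted significance threshold.
#' @param extend optional single-end extension (see [binned_coverage()]).
#' @return A tibble of regions `contig`, `start`, `end`, `min_padj`.
#' @export
enriched_regions <- function(treat_records, input_records, genome,
                             bin_size = 10L, alpha = 0.05, extend = NULL) {
  count_bins <- function(records) {
    lens <- contig_lengths(genome)
    unlist(lapply(names(lens), function(cn) {
      nb <- ceiling(lens[[cn]] / bin_size)
      sel <- records$target == cn
      mid <- records$start[sel] + records$read_length[sel] %/% 2L
      tabulate(pmin(mid %/% bin_size + 1L, nb), nbins = nb)
    }))
  }
  lens <- contig_lengths(genome)
  nb_per <- ceiling(lens / bin_size)
  t_cnt <- count_bins(treat_records)
  i_cnt <- count_bins(input_records)
  if (sum(i_cnt) == 0) stop("input library is empty")
  scale <- sum(t_cnt) / sum(i_cnt)
  lambda <- pmax(i_cnt, mean(i_cnt)) * scale
  p <- stats::ppois(t_cnt - 1L, lambda, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")
  sig <- which(padj <= alpha & t_cnt > 0)
  if (length(sig) == 0) {
    return(tibble::tibble(contig = character(), start = integer(),
                          end = integer(), min_padj = numeric()))
  }
  contig_of_bin <- rep(names(lens), nb_per)
  offset <- c(0L, cumsum(nb_per))[seq_along(lens)]
  names(offset) <- names(lens)
  pieces <- lapply(names(lens), function(cn) {
    s <- sig[contig_of_bin[sig] == cn] - offset[[cn]]
    if (length(s) == 0) return(NULL)
    brk <- which(diff(s) > 2L)  # gap <= 1 bin merged
    first <- s[c(1L, brk + 1L)]; last <- s[c(brk, length(s))]
    tibble::tibble(
      contig = cn,
      start = (first - 1L) * bin_size,
      end = pmin(last * bin_size, lens[[cn]]),
      min_padj = vapply(seq_along(first), function(j) {
        min(padj[offset[[cn]] + first[j]:last[j]])
      }, numeric(1))
    )
  })
  dplyr::bind_rows(pieces)
}

#' Mann-Whitney comparison of region enrichment between samples
#'
#' Compares per-region mean treat-minus-input values between two samples by
#' the two-sided Mann-Whitney U test: exact enumeration when
#' `n_a * n_b <= 10000` and the data are tie-free, otherwise the normal
#' approximation with tie correction. With all values tied, p = 1.
#'
#' @param tracks_a,tracks_b treat-minus-input binned track lists for the
#'   two samples (same genome and bin grid).
#' @param regions a tibble of regions (`contig`, `start`, `end`), e.g. from
#'   [enriched_regions()]; at least 3 are required.
#' @return An `enrichment_comparison`: list with `u`, `p_value`,
#'   `values_a`, `values_b`, `method`.
#' @export
compare_enrichment <- function(tracks_a, tracks_b, regions) {
  if (nrow(regions) < 3) stop("need at least 3 regions to compare")
  region_means <- function(tracks) {
    vapply(seq_len(nrow(regions)), function(i) {
      tr <- tracks[[regions$contig[i]]]
      if (is.null(tr)) stop("no track for contig ", regions$contig[i])
      b0 <- regions$start[i] %/% tr$bin_size + 1L
      b1 <- min(ceiling(regions$end[i] / tr$bin_size), length(tr$values))
      mean(tr$values[b0:b1])
    }, numeric(1))
  }
  va <- region_means(tracks_a)
  vb <- region_means(tracks_b)
  if (length(unique(c(va, vb))) == 1L) {
    res <- list(statistic = c(W = length(va) * length(vb) / 2), p.value = 1)
    method <- "degenerate (all tied)"
  } else {
    exact <- length(va) * length(vb) <= 10000 &&
      !anyDuplicated(c(va, vb))
    res <- suppressWarnings(
      stats::wilcox.test(va, vb, exact = exact, correct = FALSE))
    method <- if (exact) "exact" else "normal approximation, tie-corrected"
  }
  structure(list(u = unname(res$statistic), p_value = res$p.value,
                 values_a = va, values_b = vb, method = method),
            class = "enrichment_comparison")
}

#' @export
print.enrichment_comparison <- function(x, ...) {
  cat("<enrichment_comparison> U =", format(x$u), ", p =",
      format.pval(x$p_value), "(", x$method, ")\n")
  invisible(x)
}

#' @rdname compare_enrichment
#' @param x an `enrichment_comparison`.
#' @param ... unused.
#' @export
glance.enrichment_comparison <- function(x, ...) {
  tibble::tibble(u = x$u, p_value = x$p_value,
                 n_a = length(x$values_a), n_b = length(x$values_b),
                 method = x$method)
}

#' @rdname compare_enrichment
#' @export
tidy.enrichment_comparison <- function(x, ...) {
  tibble::tibble(
    region = rep(seq_along(x$values_a), 2),
    sample = rep(c("a", "b"), each = length(x$values_a)),
    mean_enrichment = c(x$values_a, x$values_b)
  )
}

#' ChIP-qPCR percent input with reference-gene normalization
#'
#' `(ip / input) / (ip_ref / input_ref) * 100`: the precipitated fraction of
#' the target region relative to the same fraction at a reference gene
#' (e.g. a housekeeping locus), in percent.
#'
#' @param ip_signal,input_signal target IP and input signals (> 0 input).
#' @param ip_ref,input_ref reference-gene IP and input signals.
#' @return Normalized percent value(s).
#' @export
percent_input <- function(ip_signal, input_signal, ip_ref, input_ref) {
  if (any(input_signal == 0) || any(input_ref == 0) || any(ip_ref == 0)) {
    stop("zero denominator in percent-input calculation")
  }
  (ip_signal / input_signal) / (ip_ref / input_ref) * 100
}

#' Relative expression by the 2^-dCt method
#'
#' `2^-(ct_target - ct_reference)`: expression of a target relative to a
#' reference gene from qPCR cycle thresholds.
#'
#' @param ct_target,ct_reference finite Ct values.
#' @return Relative expression value(s).
#' @export
relative_expression_2dct <- function(ct_target, ct_reference) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_reference)))
  2^(-(ct_target - ct_reference))
}
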