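#' Feature tables
#'
#' Annotations are plain tibbles with one row per feature and columns
#' `id`, `contig`, `start`, `end` (0-based half-open), `strand` (`"+"`,
#' `"-"` or `NA`), `kind` (gene, transcript, exon, CDS, UTR5, UTR3, TE,
#' satellite, cluster) and `parent` (optional id). [feature_tbl()] builds and
#' validates such a table.
#'
#' @param id,contig character vectors.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand character vector of "+", "-" or NA.
#' @param kind character vector of feature kinds.
#' @param parent optional character vector of parent ids.
#' @return A tibble of features.
#' @export
feature_tbl <- function(id, contig, start, end, strand = NA_character_,
                        kind = "gene", parent = NA_character_) {
  out <- tibble::tibble(
    id = as.character(id), contig = as.character(contig),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand), kind = as.character(kind),
    parent = as.character(parent)
  )
  if (any(out$start < 0) || any(out$end <= out$start)) {
    stop("features must satisfy 0 <= start < end")
  }
  bad <- !out$strand %in% c("+", "-") & !is.na(out$strand)
  if (any(bad)) stop("strand must be '+', '-' or NA")
  out
}

.kind_from_type <- function(type) {
  type <- as.character(type)
  map <- c(
    gene = "gene", mRNA = "transcript", transcript = "transcript",
    exon = "exon", CDS = "CDS",
    five_prime_UTR = "UTR5", three_prime_UTR = "UTR3",
    `5UTR` = "UTR5", `3UTR` = "UTR3",
    transposable_element = "TE", satellite_DNA = "satellite",
    satellite = "satellite", repeat_region = "TE", cluster = "cluster",
    piRNA_cluster = "cluster"
  )
  out <- unname(map[type])
  ifelse(is.na(out), type, out)
}

#' Read gene/repeat annotations from GFF3 or GTF
#'
#' File coordinates (1-based inclusive) are converted to the package's
#' 0-based half-open convention. Parent/child links are resolved from
#' `Parent` (GFF3) or `gene_id`/`transcript_id` (GTF) attributes. Records
#' with `end < start` in the file are rejected with a warning.
#'
#' @param path annotation file.
#' @param dialect `"gff3"` or `"gtf"`.
#' @return A feature tibble (see [feature_tbl()]).
#' @export
read_features <- function(path, dialect = c("gff3", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  # screen malformed intervals before GRanges (which would refuse them)
  raw <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) > 0) {
    s <- suppressWarnings(as.numeric(raw[[4]])); e <- suppressWarnings(as.numeric(raw[[5]]))
    bad <- !is.na(s) & !is.na(e) & e < s
    if (any(bad)) {
      warning(sum(bad), " record(s) with end < start rejected")
      tmp <- tempfile(fileext = paste0(".", dialect))
      readr::write_tsv(raw[!bad, ], tmp, col_names = FALSE, escape = "none")
      on.exit(unlink(tmp), add = TRUE)
      path <- tmp
    }
  }
  gr <- rtracklayer::import(path, format = if (dialect == "gff3") "gff3" else "gtf")
  md <- as.data.frame(S4Vectors::mcols(gr))
  type <- as.character(md$type)
  if (dialect == "gff3") {
    id <- if ("ID" %in% names(md)) as.character(md$ID) else NA_character_
    parent <- if ("Parent" %in% names(md)) {
      vapply(md$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
             character(1))
    } else NA_character_
  } else {
    gene_id <- if ("gene_id" %in% names(md)) as.character(md$gene_id) else NA_character_
    tx_id <- if ("transcript_id" %in% names(md)) as.character(md$transcript_id) else NA_character_
    id <- dplyr::case_when(
      type == "gene" ~ gene_id,
      type %in% c("transcript", "mRNA") ~ tx_id,
      .default = paste0(tx_id, ":", type, ":", seq_along(gr))
    )
    parent <- dplyr::case_when(
      type == "gene" ~ NA_character_,
      type %in% c("transcript", "mRNA") ~ gene_id,
      .default = tx_id
    )
  }
  id <- ifelse(is.na(id) | id == "", paste0("feat_", seq_along(gr)), id)
  strand <- as.character(BiocGenerics::strand(gr))
  feature_tbl(
    id = id,
    contig = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = ifelse(strand %in% c("+", "-"), strand, NA_character_),
    kind = .kind_from_type(type),
    parent = parent
  )
}

#' Read regions from a BED file
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged.
#'
#' @param path BED file.
#' @return A feature tibble with `kind = "cluster"`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- paste0("region_", seq_along(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  feature_tbl(
    id = nm,
    contig = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = ifelse(strand %in% c("+", "-"), strand, NA_character_),
    kind = "cluster"
  )
}

#' Write regions to a BED file
#'
#' @param features a feature tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(features, path) {
  gr <- features_to_granges(features)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = features$id)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Convert a feature tibble to GRanges
#'
#' @param features a feature tibble.
#' @return A `GRanges` (1-based closed, as GRanges requires).
#' @export
features_to_granges <- function(features) {
  GenomicRanges::GRanges(
    seqnames = features$contig,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = ifelse(is.na(features$strand), "*", features$strand)
  )
}
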