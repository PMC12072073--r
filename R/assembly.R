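#' Assembly container
#'
#' An assembly is a named set of uppercase nucleotide sequences (contigs)
#' with a free-text source label (e.g. a strain name). It is stored as a
#' named character vector of class `"assembly"` so that substring extraction
#' and per-base operations stay cheap at desk scale.
#'
#' @param contigs named character vector of sequences over {A,C,G,T,N}.
#' @param source_label free-text provenance label.
#' @return An `assembly` object.
#' @examples
#' asm <- assembly(c(chr1 = "ACGTACGT"), source_label = "toy")
#' contig_lengths(asm)
#' @export
assembly <- function(contigs, source_label = "unknown") {
  if (length(contigs) == 0) stop("assembly must contain at least one contig")
  if (is.null(names(contigs)) || any(names(contigs) == "") || anyNA(names(contigs))) {
    stop("all contigs must be named")
  }
  if (anyDuplicated(names(contigs))) {
    stop("duplicate contig name: ",
         paste(unique(names(contigs)[duplicated(names(contigs))]), collapse = ", "))
  }
  contigs <- stats::setNames(toupper(as.character(contigs)), names(contigs))
  if (any(nchar(contigs) == 0)) stop("contig sequences must be non-empty")
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    stop("contig(s) contain characters outside {A,C,G,T,N}: ",
         paste(names(contigs)[bad], collapse = ", "))
  }
  structure(contigs, source_label = source_label, class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat("<assembly> ", attr(x, "source_label"), ": ", length(x), " contig(s), ",
      sum(nchar(x)), " bp total\n", sep = "")
  invisible(x)
}

#' @rdname assembly
#' @param x an assembly.
#' @export
contig_lengths <- function(x) {
  stopifnot(inherits(x, "assembly"))
  nchar(unclass(x))
}

#' @export
`[.assembly` <- function(x, i) {
  assembly(unclass(x)[i], source_label = attr(x, "source_label"))
}

#' Tidy an assembly into a contig table
#'
#' @param x an assembly.
#' @param ... unused.
#' @return A tibble with columns `contig`, `length`, `source_label`.
#' @export
tidy.assembly <- function(x, ...) {
  tibble::tibble(
    contig = names(x),
    length = nchar(unclass(x)),
    source_label = attr(x, "source_label")
  )
}

#' Read a genome assembly from FASTA
#'
#' Sequences are folded to upper case and the description after the first
#' whitespace is dropped from each record name. Duplicate record names and
#' empty files are hard errors.
#'
#' @param path FASTA file path.
#' @param source_label provenance label; defaults to the file name.
#' @return An [assembly].
#' @export
read_fasta <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(set))
  assembly(stats::setNames(as.character(set), nm), source_label = source_label)
}

#' Write an assembly to FASTA
#'
#' @param x an [assembly].
#' @param path output file path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  stopifnot(inherits(x, "assembly"))
  set <- Biostrings::DNAStringSet(unclass(x))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of a character sequence
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Merge two haplotype assemblies into a diploid genome
#'
#' Contig names are prefixed with each assembly's source label (separated by
#' `"|"`) so every contig of the merged genome is unambiguously attributable
#' to its haplotype of origin. The haplotype labels are recorded in the
#' `haplotypes` attribute for back-mapping.
#'
#' @param assembly_a,assembly_b the two haplotype assemblies.
#' @param labels length-2 character; haplotype prefixes. Defaults to the
#'   assemblies' source labels.
#' @return An [assembly] with `haplotypes` attribute.
#' @export
build_diploid <- function(assembly_a, assembly_b, labels = NULL) {
  stopifnot(inherits(assembly_a, "assembly"), inherits(assembly_b, "assembly"))
  if (is.null(labels)) {
    labels <- c(attr(assembly_a, "source_label"), attr(assembly_b, "source_label"))
  }
  if (length(labels) != 2 || anyNA(labels)) stop("need two haplotype labels")
  if (labels[1] == labels[2]) {
    stop("haplotype label collision: both assemblies labelled '", labels[1], "'")
  }
  contigs <- c(
    stats::setNames(unclass(assembly_a), paste0(labels[1], "|", names(assembly_a))),
    stats::setNames(unclass(assembly_b), paste0(labels[2], "|", names(assembly_b)))
  )
  out <- assembly(contigs, source_label = paste0("diploid:", labels[1], "+", labels[2]))
  attr(out, "haplotypes") <- labels
  out
}

#' Haplotype of origin for diploid contig names
#'
#' @param contig character vector of prefixed contig names.
#' @return character vector of haplotype labels.
#' @export
haplotype_of <- function(contig) {
  sub("\\|.*$", "", contig)
}
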