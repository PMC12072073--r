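#' End-to-end analysis pipeline on simulated or user data
#'
#' Runs the analysis graph — simulate (or load), preprocess, map, stats,
#' cluster, allelic, chip — in dependency order, writing deterministic,
#' stage-named outputs plus a JSON run manifest (tool version, config
#' snapshot, seed, per-stage record counts, output file digests) to
#' `out_dir`. Re-running with an identical config, inputs and seed
#' reproduces identical output digests.
#'
#' @param config a [sim_config()]; drives both the simulators and the
#'   analysis parameters.
#' @param stages subset of `c("preprocess", "map", "stats", "cluster",
#'   "allelic", "chip")`; simulation always runs first (it is the input
#'   provider).
#' @param out_dir output directory (created if needed).
#' @param seed seed for every stochastic stage; defaults to `config$seed`.
#' @param dry_run print the stage plan and write nothing.
#' @return The manifest, invisibly (a list); written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config = sim_config(),
                         stages = c("preprocess", "map", "stats", "cluster",
                                    "allelic", "chip"),
                         out_dir = "pirnakit_run", seed = config$seed,
                         dry_run = FALSE) {
  all_stages <- c("preprocess", "map", "stats", "cluster", "allelic", "chip")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  deps <- list(preprocess = character(0), map = "preprocess",
               stats = "map", cluster = "map",
               allelic = character(0), chip = character(0))
  for (s in stages) {
    missing <- setdiff(deps[[s]], stages)
    if (length(missing)) {
      stop("stage '", s, "' requires stage '", missing[1],
           "'; add it to `stages` (run order: ",
           paste(all_stages, collapse = " > "), ")")
    }
  }
  plan <- c("simulate", all_stages[all_stages %in% stages])
  if (dry_run) {
    message("plan: ", paste(plan, collapse = " -> "), " (nothing written)")
    return(invisible(list(plan = plan, dry_run = TRUE)))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  note <- function(stage, what, n) {
    counts[[paste0(stage, ".", what)]] <<- n
    message(sprintf("[%s] %s: %s", stage, what, format(n)))
  }

  gp <- generate_genome_pair(config, seed = seed)
  write_fasta(gp$assembly_a, file.path(out_dir, "assembly_a.fasta"))
  write_fasta(gp$assembly_b, file.path(out_dir, "assembly_b.fasta"))
  readr::write_tsv(gp$truth, file.path(out_dir, "genome_truth.tsv"))
  cluster_a <- gp$features_a[gp$features_a$id == "cluster_1", ]
  sim <- simulate_pirna_library(gp$assembly_a, cluster_a, config,
                                seed = seed + 1L)
  write_reads(sim$reads, file.path(out_dir, "reads.fasta"))
  note("simulate", "reads", nrow(sim$reads))

  reads <- collapse_reads(sim$reads)
  mapped <- NULL
  lib_size <- NA_real_

  if ("preprocess" %in% stages) {
    reads <- filter_by_length(reads, config$pirna$min_len,
                              config$pirna$max_len)
    sub <- subtract_ncrna(reads, load_contaminant_db())
    reads <- sub$kept
    readr::write_tsv(sub$summary, file.path(out_dir, "preprocess_summary.tsv"))
    note("preprocess", "kept_weighted", sum(reads$count))
  }
  if ("map" %in% stages) {
    aln <- align_all(reads, gp$assembly_a, max_mismatch = 3L)
    mapped <- filter_unique_best_stratum(aln)
    lib_size <- sum(mapped$count)
    write_sam(mapped, gp$assembly_a, file.path(out_dir, "unique_mappers.sam"))
    note("map", "unique_mappers", nrow(mapped))
  }
  if ("stats" %in% stages) {
    gene <- gp$features_a[gp$features_a$kind == "gene", ]
    orient <- split_orientation(mapped, gene)
    bias <- dplyr::bind_rows(
      dplyr::mutate(nucleotide_bias(orient[orient$orientation == "sense", ]),
                    orientation = "sense"),
      dplyr::mutate(nucleotide_bias(orient[orient$orientation == "antisense", ]),
                    orientation = "antisense"))
    pp <- pingpong_signature(mapped)
    cnt <- count_feature_reads(mapped, gp$features_a)
    gene_len <- sum(with(gp$features_a, end - start)[gp$features_a$kind == "exon"])
    expr <- dplyr::mutate(cnt, rpkm = rpkm(.data$count, gene_len, lib_size))
    readr::write_tsv(bias, file.path(out_dir, "nucleotide_bias.tsv"))
    readr::write_tsv(tidy(pp), file.path(out_dir, "pingpong_histogram.tsv"))
    readr::write_tsv(glance(pp), file.path(out_dir, "pingpong_summary.tsv"))
    readr::write_tsv(expr, file.path(out_dir, "expression_rpkm.tsv"))
    note("stats", "pingpong_z10", round(pp$z10, 3))
  }
  if ("cluster" %in% stages) {
    cov <- stranded_coverage(mapped, gp$assembly_a)
    write_bedgraph(cov[["contig_1|+"]],
                   file.path(out_dir, "coverage_plus.bedgraph"))
    write_bedgraph(cov[["contig_1|-"]],
                   file.path(out_dir, "coverage_minus.bedgraph"))
    regions <- call_clusters(cov[["contig_1|+"]], cov[["contig_1|-"]])
    readr::write_tsv(regions, file.path(out_dir, "clusters.tsv"))
    note("cluster", "regions", nrow(regions))
    if (nrow(regions) > 0) {
      loc_a <- extract_locus(gp$assembly_a, regions[1, ])
      span_b <- gp$features_b[gp$features_b$id == "cluster_1", ]
      loc_b <- extract_locus(gp$assembly_b, span_b)
      diff <- pairwise_locus_diff(loc_a$sequence, loc_b$sequence)
      readr::write_tsv(tidy(diff), file.path(out_dir, "locus_diff.tsv"))
      note("cluster", "diff_gaps", nrow(diff$gaps))
    }
  }
  if ("allelic" %in% stages) {
    dip <- build_diploid(gp$assembly_a, gp$assembly_b)
    span_a <- gp$features_a[gp$features_a$id == "allelic_span_1", ]
    span_b <- gp$features_b[gp$features_b$id == "allelic_span_1", ]
    hyb <- simulate_hybrid_library(gp$assembly_a, gp$assembly_b,
                                   span_a, span_b, config, seed = seed + 2L)
    ar <- align_allele_specific(collapse_reads(hyb$reads), dip)
    labs <- attr(dip, "haplotypes")
    reg_a <- dplyr::mutate(span_a,
                           contig = paste0(labs[1], "|", .data$contig))
    reg_b <- dplyr::mutate(span_b, contig = paste0(labs[2], "|", .data$contig))
    ac <- allelic_counts(ar, reg_a, reg_b, locus_id = "allelic_span_1")
    readr::write_tsv(ac, file.path(out_dir, "allelic_counts.tsv"))
    note("allelic", "pct_minor", round(ac$pct_b, 3))
  }
  if ("chip" %in% stages) {
    chip_regions <- dplyr::select(cluster_a, "contig", "start", "end")
    lib <- simulate_chip_library(gp$assembly_a, chip_regions, config,
                                 seed = seed + 3L)
    tr <- rpgc_normalize(binned_coverage(lib$treat, gp$assembly_a,
                                         dedup = FALSE), gp$assembly_a)
    inp <- rpgc_normalize(binned_coverage(lib$input, gp$assembly_a,
                                          dedup = FALSE), gp$assembly_a)
    diff_tr <- subtract_input(tr, inp)
    write_bedgraph(diff_tr, file.path(out_dir, "chip_treat_minus_input.bedgraph"))
    er <- enriched_regions(lib$treat, lib$input, gp$assembly_a)
    readr::write_tsv(er, file.path(out_dir, "chip_enriched_regions.tsv"))
    note("chip", "enriched_regions", nrow(er))
  }

  manifest <- list(
    tool = "pirnakit",
    version = as.character(utils::packageVersion("pirnakit")),
    seed = seed,
    stages = plan,
    config = unclass(config),
    counts = counts,
    outputs = local({
      f <- setdiff(list.files(out_dir), "manifest.json")
      as.list(tools::md5sum(file.path(out_dir, sort(f))))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
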