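# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately avoid the code paths they validate:
# alignment by byte-matrix sliding comparison, ping-pong by all-pairs
# enumeration, mappability by k-mer tabulation, Mann-Whitney by exhaustive
# label permutation.

rand_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# all placements of each read on either strand with <= max_mismatch
# mismatches, plus best-stratum sizes; N never matches
oracle_align <- function(reads, genome, max_mismatch) {
  rawN <- charToRaw("N")
  hits <- list()
  for (cn in names(genome)) {
    g <- charToRaw(unclass(genome)[[cn]])
    L <- length(g)
    for (i in seq_len(nrow(reads))) {
      for (strand in c("+", "-")) {
        s <- reads$sequence[i]
        q <- charToRaw(if (strand == "+") s else revcomp(s))
        w <- length(q)
        if (w > L) next
        ns <- L - w + 1L
        M <- matrix(g[outer(0:(w - 1L), seq_len(ns), `+`)], nrow = w)
        mm <- colSums(M != q | M == rawN | q == rawN)
        at <- which(mm <= max_mismatch)
        if (length(at)) {
          hits[[length(hits) + 1L]] <- tibble::tibble(
            read_id = reads$id[i], sequence = s, target = cn,
            start = at - 1L, strand = strand,
            mismatches = as.integer(mm[at]))
        }
      }
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) return(out)
  out |>
    dplyr::group_by(read_id) |>
    dplyr::mutate(n_best = sum(mismatches == min(mismatches))) |>
    dplyr::ungroup()
}

# all-pairs 5'-overlap histogram + z-score
oracle_pingpong <- function(records, max_overlap = 20L) {
  h <- numeric(max_overlap)
  if (nrow(records) > 0) {
    p5 <- ifelse(records$strand == "+", records$start,
                 records$start + records$read_length - 1L)
    w <- records$count
    plus <- which(records$strand == "+")
    minus <- which(records$strand == "-")
    if (length(plus) && length(minus)) {
      o <- outer(p5[minus], p5[plus], `-`) + 1L
      wt <- outer(w[minus], w[plus])
      for (k in seq_len(max_overlap)) h[k] <- sum(wt[o == k])
    }
  }
  bg <- h[-10L]
  z <- if (stats::sd(bg) > 0) (h[10L] - mean(bg)) / stats::sd(bg) else NA_real_
  list(histogram = h, z10 = z)
}

# per-position k-mer uniqueness by tabulation
oracle_mappability <- function(genome, k) {
  seqs <- unclass(genome)
  km <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1L), k:L)
  })
  counts <- table(unlist(km, use.names = FALSE))
  lapply(km, function(x) as.numeric(counts[x] == 1L))
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of group labels
oracle_mw_exact <- function(x, y) {
  all <- c(x, y)
  n <- length(x)
  u_of <- function(idx) {
    xs <- all[idx]; ys <- all[-idx]
    sum(outer(xs, ys, `>`)) + 0.5 * sum(outer(xs, ys, `==`))
  }
  obs <- u_of(seq_len(n))
  combos <- utils::combn(length(all), n)
  us <- apply(combos, 2, u_of)
  mu <- length(x) * length(y) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# brute-force both-strand substring containment with <= mm mismatches
oracle_contains <- function(read, db, mm = 0L) {
  for (s in unclass(db)) {
    for (q in c(read, revcomp(read))) {
      w <- nchar(q)
      L <- nchar(s)
      if (w > L) next
      qs <- strsplit(q, "")[[1]]
      for (st in 1:(L - w + 1L)) {
        seg <- strsplit(substr(s, st, st + w - 1L), "")[[1]]
        if (sum(seg != qs | seg == "N" | qs == "N") <= mm) return(TRUE)
      }
    }
  }
  FALSE
}

# small genome + read set with planted exact/mutated/multi-copy reads
make_toy_mapping_case <- function(glen = 4000L, n_reads = 30L,
                                  max_mismatch = 3L) {
  g <- rand_dna(glen)
  # plant a duplication so some reads are multi-mappers
  dup <- substr(g, 101, 160)
  g <- paste0(substr(g, 1, 2000), dup, substr(g, 2061, glen))
  genome <- assembly(c(chr = g), source_label = "toy")
  starts <- sample.int(glen - 30L, n_reads)
  len <- sample(23:29, n_reads, replace = TRUE)
  sq <- substring(g, starts, starts + len - 1L)
  minus <- sample(c(TRUE, FALSE), n_reads, replace = TRUE)
  sq[minus] <- revcomp(sq[minus])
  # mutate a third of the reads at 1-3 positions
  mut <- sample(n_reads, ceiling(n_reads / 3))
  for (i in mut) {
    nm <- sample(max_mismatch, 1)
    pos <- sample(nchar(sq[i]), nm)
    ch <- strsplit(sq[i], "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    sq[i] <- paste(ch, collapse = "")
  }
  list(genome = genome,
       reads = read_tbl(sprintf("t%03d", seq_len(n_reads)), sq))
}
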