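# Brute-force O(n*m) oracles, independent of the package's sweep/index code.
# All coordinates BED-style 0-based half-open.

# overlap length of two half-open intervals on the same chromosome
bf_overlap_len <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))

# count-once overlap count by exhaustive pairwise comparison
bf_count_once <- function(qdf, rdf, min_bp = 1) {
  if (nrow(qdf) == 0 || nrow(rdf) == 0) return(0L)
  n <- 0L
  for (i in seq_len(nrow(qdf))) {
    hit <- FALSE
    for (j in seq_len(nrow(rdf))) {
      if (qdf$chrom[i] == rdf$chrom[j] &&
          bf_overlap_len(qdf$start[i], qdf$end[i], rdf$start[j], rdf$end[j]) >= min_bp) {
        hit <- TRUE
        break
      }
    }
    if (hit) n <- n + 1L
  }
  n
}

# total overlapping (query, reference) pairs
bf_count_pairs <- function(qdf, rdf, min_bp = 1) {
  n <- 0L
  for (i in seq_len(nrow(qdf))) {
    for (j in seq_len(nrow(rdf))) {
      if (qdf$chrom[i] == rdf$chrom[j] &&
          bf_overlap_len(qdf$start[i], qdf$end[i], rdf$start[j], rdf$end[j]) >= min_bp) {
        n <- n + 1L
      }
    }
  }
  n
}

# logical overlap flag per query row
bf_flags <- function(qdf, rdf, min_bp = 1) {
  vapply(seq_len(nrow(qdf)), function(i) {
    any(vapply(seq_len(nrow(rdf)), function(j) {
      qdf$chrom[i] == rdf$chrom[j] &&
        bf_overlap_len(qdf$start[i], qdf$end[i], rdf$start[j], rdf$end[j]) >= min_bp
    }, logical(1)))
  }, logical(1))
}

# covered bases by per-base accumulation (only for tiny chromosomes)
bf_coverage <- function(df, genome) {
  tot <- 0
  for (cn in genome$chrom) {
    L <- genome$length[[cn]]
    covered <- logical(L)
    sub <- df[df$chrom == cn, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      if (sub$end[i] > sub$start[i]) covered[(sub$start[i] + 1):sub$end[i]] <- TRUE
    }
    tot <- tot + sum(covered)
  }
  tot
}

# random valid region set on a genome; returns the region_set
rand_region_set <- function(genome, n, max_len = 50, name = "rand") {
  chrom <- sample(genome$chrom, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  L <- genome$length[chrom]
  len <- pmin(len, L)
  start <- floor(runif(n) * (L - len + 1))
  region_set(chrom, start, start + len, genome, name = name)
}

# small genome used across randomized oracle checks
toy_genome <- function() genome_def(c("chrA", "chrB", "chrC"), c(1000, 700, 400))

# desk-scale simulation genome
desk_config <- function(...) synthetic_config(...)
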