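#' Randomization policy for permutation nulls
#'
#' Bundles every knob that controls how a region set is re-placed across the
#' genome when building a permutation null.
#'
#' All randomness in the package flows from `seed` through a substream
#' scheme: permutation draw `i` (and, in the differential test, each of the
#' two query sets) gets its own deterministic substream, so results are
#' identical regardless of evaluation order or parallelism.
#'
#' @param strategy `"per_chromosome"` (default; each randomized region stays
#'   on its original chromosome, preserving the chromosome composition of the
#'   peak set) or `"genome_wide"` (chromosome re-drawn with probability
#'   proportional to the number of feasible start positions).
#' @param seed integer root seed.
#' @param respect_mask if `TRUE` (default) randomized intervals never
#'   intersect the genome mask, enforced by rejection sampling.
#' @param allow_self_overlap randomized regions may overlap one another
#'   (default `TRUE`: independent placement; `FALSE` is not implemented and
#'   reserved).
#' @param max_retries rejection-sampling retries per region before a
#'   placement error; default 1000.
#' @return An object of class `randomization_policy`.
#' @export
randomization_policy <- function(strategy = c("per_chromosome", "genome_wide"),
                                 seed = 1L,
                                 respect_mask = TRUE,
                                 allow_self_overlap = TRUE,
                                 max_retries = 1000L) {
  strategy <- match.arg(strategy)
  if (!isTRUE(allow_self_overlap)) {
    stop("allow_self_overlap = FALSE (non-overlapping placement) is not supported")
  }
  if (max_retries < 1L) stop("max_retries must be >= 1")
  structure(
    list(strategy = strategy, seed = as.integer(seed),
         respect_mask = isTRUE(respect_mask),
         allow_self_overlap = TRUE, max_retries = as.integer(max_retries)),
    class = "randomization_policy"
  )
}

# substream seed: distinct (seed, stream, draw) triples map to distinct
# Mersenne-Twister seeds below 2^31 - 1
.derive_seed <- function(seed, stream, draw) {
  s <- (as.double(seed) %% 2147483647) * 7919 +
    as.double(stream) * 15485863 + as.double(draw) * 104729 + 1
  as.integer(s %% 2147483647)
}

# run code under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Core placement: given region chromosomes and lengths, draw new start
# positions.  Vectorized; rejection sampling against the mask.  Returns
# list(chrom, start).  Must be the single code path used by both
# randomize_regions() and null_distribution() so their draws agree exactly.
.randomize_core <- function(qchrom, qlen, genome, policy, mask_index) {
  n <- length(qlen)
  if (n == 0L) return(list(chrom = character(), start = numeric()))
  chroms <- genome$chrom
  L <- unname(genome$length)

  draw_chrom <- function(len, k) {
    # k regions; weights per region = feasible start positions per chromosome
    w <- outer(len, L, function(l, ll) pmax(ll - l + 1, 0))
    if (any(rowSums(w) == 0)) {
      stop("region of length ", max(len), " exceeds every chromosome")
    }
    u <- stats::runif(k)
    if (length(L) == 1L) return(rep(chroms, k))
    cw <- w / rowSums(w)
    cum <- t(apply(cw, 1L, cumsum))
    idx <- max.col(cum >= u, ties.method = "first")
    chroms[idx]
  }

  if (policy$strategy == "genome_wide") {
    cur_chrom <- draw_chrom(qlen, n)
  } else {
    cur_chrom <- qchrom
  }
  npos <- L[match(cur_chrom, chroms)] - qlen + 1
  if (any(npos <= 0)) {
    i <- which(npos <= 0)[1L]
    stop("region ", i, " (length ", qlen[i], ") does not fit on ", cur_chrom[i])
  }
  start <- floor(stats::runif(n) * npos)

  use_mask <- policy$respect_mask && !is.null(mask_index)
  if (use_mask) {
    pending <- which(.hits_index(cur_chrom, start, start + qlen, mask_index))
    tries <- 0L
    while (length(pending) > 0L && tries < policy$max_retries) {
      tries <- tries + 1L
      if (policy$strategy == "genome_wide") {
        cur_chrom[pending] <- draw_chrom(qlen[pending], length(pending))
        npos[pending] <- L[match(cur_chrom[pending], chroms)] - qlen[pending] + 1
      }
      start[pending] <- floor(stats::runif(length(pending)) * npos[pending])
      ok <- !.hits_index(cur_chrom[pending], start[pending],
                         start[pending] + qlen[pending], mask_index)
      pending <- pending[!ok]
    }
    if (length(pending) > 0L) {
      i <- pending[1L]
      stop("could not place region ", i, " (length ", qlen[i],
           ") outside the mask after ", policy$max_retries, " retries")
    }
  }
  list(chrom = cur_chrom, start = start)
}

.mask_index <- function(genome) {
  if (is.null(genome$mask) || nrow(genome$mask) == 0L) return(NULL)
  lapply(split(genome$mask[, c("start", "end")],
               factor(genome$mask$chrom, levels = unique(genome$mask$chrom))),
         function(d) list(start = d$start, end = d$end))
}

#' Randomly re-place a region set across the genome
#'
#' Draws a permuted region set preserving the region count and the multiset
#' of region lengths.  Under the `per_chromosome` strategy each region stays
#' on its original chromosome; under `genome_wide` the chromosome is re-drawn
#' with probability proportional to feasible start positions.  With
#' `respect_mask`, placements intersecting the genome mask are rejected and
#' re-drawn (up to `max_retries` per region).  The draw is fully reproducible
#' from `(policy$seed, draw_index)` and independent draws use independent
#' substreams, so evaluation order does not matter.
#'
#' @param regions the `region_set` to randomize.
#' @param genome the `genome_def` to randomize over (defaults to the set's
#'   own genome).
#' @param policy a [randomization_policy()].
#' @param draw_index which permutation draw this is (1-based).
#' @return A `region_set` named `<name>.perm<draw_index>`.
#' @export
randomize_regions <- function(regions, genome = regions$genome, policy = randomization_policy(),
                              draw_index = 1L) {
  stopifnot(inherits(regions, "region_set"), inherits(genome, "genome_def"))
  if (!.same_genome(regions$genome, genome)) stop("region set is bound to a different genome")
  df <- regions$regions
  qlen <- df$end - df$start
  mask_index <- .mask_index(genome)
  placed <- .with_seed(
    .derive_seed(policy$seed, 0L, draw_index),
    .randomize_core(df$chrom, qlen, genome, policy, mask_index)
  )
  region_set(placed$chrom, placed$start, placed$start + qlen, genome,
             name = paste0(regions$name, ".perm", draw_index))
}

#' Permutation null distribution of overlap counts
#'
#' The null-generating mechanism of the permutation tests: the i-th entry is
#' the count-once overlap of the i-th randomized draw of `query` with
#' `reference`, exactly as `overlap_count(randomize_regions(query,
#' draw_index = i), reference)` would give, but computed with a fast
#' vectorized inner loop.
#'
#' @inheritParams randomize_regions
#' @param reference `region_set` the randomized draws are counted against.
#' @param n_perm number of permutations (the Fig.-style default used for
#'   peak enrichment is 500).
#' @param min_overlap_bp,count forwarded to the overlap counting.
#' @param stream internal substream id (0 in ordinary use; the differential
#'   test uses distinct streams for its two query sets).
#' @return Integer vector of length `n_perm`.
#' @export
null_distribution <- function(query, reference, genome = query$genome,
                              policy = randomization_policy(), n_perm = 500L,
                              min_overlap_bp = 1L, count = c("once", "pairs"),
                              stream = 0L) {
  count <- match.arg(count)
  .check_pair(query, reference)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  qdf <- query$regions
  qlen <- qdf$end - qdf$start
  mask_index <- .mask_index(genome)
  fast <- (min_overlap_bp == 1L && count == "once")
  ref_index <- if (fast) .ref_index(reference) else NULL
  rgr <- if (!fast) .as_granges(reference) else NULL

  out <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    placed <- .with_seed(
      .derive_seed(policy$seed, stream, i),
      .randomize_core(qdf$chrom, qlen, genome, policy, mask_index)
    )
    if (fast) {
      out[i] <- sum(.hits_index(placed$chrom, placed$start, placed$start + qlen, ref_index))
    } else {
      pgr <- GenomicRanges::GRanges(
        seqnames = factor(placed$chrom, levels = genome$chrom),
        ranges = IRanges::IRanges(start = placed$start + 1L, end = placed$start + qlen)
      )
      hits <- GenomicRanges::countOverlaps(pgr, rgr, minoverlap = as.integer(min_overlap_bp))
      out[i] <- if (count == "once") sum(hits > 0L) else sum(hits)
    }
  }
  out
}
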