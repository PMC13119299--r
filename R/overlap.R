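#' Count query regions overlapping a reference set
#'
#' The overlap statistic all the permutation tests are built on.  An overlap
#' is at least one shared base under half-open arithmetic: intervals sharing
#' only a boundary coordinate do not overlap.  By default each query region
#' is counted at most once no matter how many reference intervals it touches
#' ("count-once" semantics, the quantity drawn as the single observed bar of
#' a permutation-test plot); `count = "pairs"` instead counts every
#' (query, reference) overlapping pair.  Query sets are never merged before
#' counting: counts refer to input records.
#'
#' @param query,reference `region_set`s bound to the same `genome_def`.
#' @param min_overlap_bp minimum intersection (bp) with a single reference
#'   interval for a query region to count as overlapping; default 1.
#' @param count `"once"` (default) or `"pairs"`.
#' @return An object of class `overlap_count`: list with `query_name`,
#'   `reference_name`, `n_query`, `n_overlapping`, `min_overlap_bp`, `count`.
#' @examples
#' g <- genome_def(c("chr1", "chr2"), c(1000, 500))
#' q <- region_set(c("chr1", "chr1", "chr2"), c(100, 300, 50), c(200, 400, 60), g, "q")
#' r <- region_set(c("chr1", "chr2"), c(150, 100), c(160, 200), g, "r")
#' overlap_count(q, r)$n_overlapping  # 1
#' @export
overlap_count <- function(query, reference, min_overlap_bp = 1L, count = c("once", "pairs")) {
  count <- match.arg(count)
  .check_pair(query, reference)
  if (min_overlap_bp < 1L) stop("min_overlap_bp must be >= 1")
  n_over <- if (count == "once") {
    sum(.overlap_flags(query$regions, reference, min_overlap_bp))
  } else {
    sum(GenomicRanges::countOverlaps(.as_granges(query), .as_granges(reference),
                                     minoverlap = as.integer(min_overlap_bp)))
  }
  structure(
    list(query_name = query$name, reference_name = reference$name,
         n_query = n_regions(query), n_overlapping = as.integer(n_over),
         min_overlap_bp = as.integer(min_overlap_bp), count = count),
    class = "overlap_count"
  )
}

#' @export
print.overlap_count <- function(x, ...) {
  cat(sprintf("overlap_count: %d / %d '%s' regions overlap '%s' (>= %d bp, %s)\n",
              x$n_overlapping, x$n_query, x$query_name, x$reference_name,
              x$min_overlap_bp, x$count))
  invisible(x)
}

.check_pair <- function(a, b) {
  stopifnot(inherits(a, "region_set"), inherits(b, "region_set"))
  if (!.same_genome(a$genome, b$genome)) {
    stop("region sets are bound to different genomes")
  }
}

# Merged per-chromosome reference index for the >=1 bp count-once sweep.
# Returns list chrom -> list(start, end) of disjoint sorted intervals.
.ref_index <- function(reference) {
  df <- .merge_df(reference$regions[, c("chrom", "start", "end")], reference$genome)
  lapply(split(df[, c("start", "end")], factor(df$chrom, levels = unique(df$chrom))),
         function(d) list(start = d$start, end = d$end))
}

# Logical: does interval i overlap any indexed reference interval by >= 1 bp?
# For disjoint sorted reference intervals the first one with end > start[i]
# is the only candidate that can begin before end[i].
.hits_index <- function(chrom, start, end, index) {
  out <- logical(length(start))
  for (cn in unique(chrom)) {
    ref <- index[[cn]]
    if (is.null(ref) || length(ref$start) == 0L) next
    ii <- which(chrom == cn)
    j <- findInterval(start[ii], ref$end) + 1L
    k <- pmin(j, length(ref$start))
    out[ii] <- j <= length(ref$start) & ref$start[k] < end[ii]
  }
  out
}

# Overlap indicator per query record; general min_overlap_bp via GRanges.
.overlap_flags <- function(qdf, reference, min_overlap_bp = 1L) {
  if (nrow(qdf) == 0L || n_regions(reference) == 0L) return(logical(nrow(qdf)))
  if (min_overlap_bp == 1L) {
    .hits_index(qdf$chrom, qdf$start, qdf$end, .ref_index(reference))
  } else {
    qgr <- GenomicRanges::GRanges(
      seqnames = factor(qdf$chrom, levels = reference$genome$chrom),
      ranges = IRanges::IRanges(start = qdf$start + 1L, end = qdf$end)
    )
    GenomicRanges::countOverlaps(qgr, .as_granges(reference),
                                 minoverlap = as.integer(min_overlap_bp)) > 0L
  }
}

#' Fraction of query regions overlapping a reference
#'
#' @inheritParams overlap_count
#' @return `n_overlapping / n_query`, a number in `[0, 1]`.
#' @export
overlap_fraction <- function(query, reference, min_overlap_bp = 1L) {
  if (n_regions(query) == 0L) stop("undefined fraction: empty query set")
  oc <- overlap_count(query, reference, min_overlap_bp = min_overlap_bp)
  oc$n_overlapping / oc$n_query
}

#' Subset a query set by overlap status
#'
#' Returns the query records that do (or do not) overlap the reference,
#' preserving order.  The two subsets always partition the query:
#' `|overlapping| + |non_overlapping| == n_query`.
#'
#' @inheritParams overlap_count
#' @param keep `"overlapping"` or `"non_overlapping"`.
#' @return A `region_set` with the selected records.
#' @export
filter_overlapping <- function(query, reference,
                               keep = c("overlapping", "non_overlapping"),
                               min_overlap_bp = 1L) {
  keep <- match.arg(keep)
  .check_pair(query, reference)
  hit <- .overlap_flags(query$regions, reference, min_overlap_bp)
  sel <- if (keep == "overlapping") hit else !hit
  df <- query$regions[sel, , drop = FALSE]
  region_set(df$chrom, df$start, df$end, query$genome,
             name = paste0(query$name, "[", keep, " ", reference$name, "]"),
             extra = df[, setdiff(names(df), c("chrom", "start", "end")), drop = FALSE])
}

# merge a raw interval data.frame into disjoint sorted intervals
# (adjacent half-open intervals merge: end == next start)
.merge_df <- function(df, genome) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  df <- df[order(match(df$chrom, genome$chrom), df$start, df$end), , drop = FALSE]
  pieces <- lapply(split(seq_len(nrow(df)), factor(df$chrom, levels = unique(df$chrom))), function(ii) {
    s <- df$start[ii]; e <- df$end[ii]
    grp <- cumsum(c(TRUE, s[-1] > cummax(e[-length(e)])))
    data.frame(chrom = df$chrom[ii][1L],
               start = tapply(s, grp, min),
               end = tapply(e, grp, max),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Merge a region set into disjoint intervals
#'
#' Minimal sorted set of disjoint intervals covering the same bases.
#' Adjacent half-open intervals (`end == next start`) merge; the operation is
#' idempotent.
#'
#' @param regions a `region_set`.
#' @return A `region_set` of disjoint intervals, named `<name>.merged`.
#' @export
merge_regions <- function(regions) {
  stopifnot(inherits(regions, "region_set"))
  m <- .merge_df(regions$regions[, c("chrom", "start", "end")], regions$genome)
  region_set(m$chrom, m$start, m$end, regions$genome,
             name = paste0(regions$name, ".merged"))
}

#' Total bases covered by a region set
#'
#' Bases covered by the merged set, i.e. overlapping records are not counted
#' twice.
#'
#' @param regions a `region_set`.
#' @return numeric base-pair count.
#' @export
coverage_bp <- function(regions) {
  stopifnot(inherits(regions, "region_set"))
  m <- .merge_df(regions$regions[, c("chrom", "start", "end")], regions$genome)
  sum(m$end - m$start)
}
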