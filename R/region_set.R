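#' Construct a region set bound to a genome
#'
#' A `region_set` is a named collection of genomic intervals (0-based,
#' half-open) bound to a [genome_def()].  The constructor is the single
#' validation gate: every interval is checked against the genome and the set
#' is sorted by (genome chromosome order, start, end).  Duplicate intervals
#' are permitted — the region *count* is always the number of records, not
#' merged bases — but their presence is flagged.  Strand is ignored
#' throughout the package.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end <= ` chromosome length.
#' @param genome the `genome_def` the intervals live on.
#' @param name label for the set (used in results and reports).
#' @param extra optional data.frame of per-interval columns (e.g. a planted
#'   truth flag) carried through sorting.
#' @return An object of class `region_set`: a list with `name`, `genome` and
#'   `regions` (a data.frame with columns `chrom`, `start`, `end`, plus any
#'   extra columns), with attribute `has_duplicates`.
#' @examples
#' g <- genome_def("chr1", 1000)
#' region_set("chr1", c(100, 50), c(200, 60), g, name = "toy")
#' @export
region_set <- function(chrom, start, end, genome, name = "regions", extra = NULL) {
  stopifnot(inherits(genome, "genome_def"))
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    extra <- as.data.frame(extra)
    if (nrow(extra) != nrow(df)) stop("'extra' must have one row per interval")
    df <- cbind(df, extra)
  }
  .validate_intervals(df, genome, what = "region")
  ord <- order(match(df$chrom, genome$chrom), df$start, df$end)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  dup <- nrow(df) > 0L && anyDuplicated(df[, c("chrom", "start", "end")]) > 0L
  structure(
    list(name = as.character(name), genome = genome, regions = df),
    class = "region_set",
    has_duplicates = dup
  )
}

#' Number of regions in a set
#' @param x a `region_set`.
#' @return integer record count (duplicates counted).
#' @export
n_regions <- function(x) {
  stopifnot(inherits(x, "region_set"))
  nrow(x$regions)
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set '%s': %d region(s) on %d chromosome(s)\n",
              x$name, n_regions(x), length(unique(x$regions$chrom))))
  if (isTRUE(attr(x, "has_duplicates"))) cat("  (contains duplicate intervals)\n")
  if (n_regions(x) > 0L) {
    show <- utils::head(x$regions[, c("chrom", "start", "end")], 5L)
    for (i in seq_len(nrow(show))) {
      cat(sprintf("  %s:%s-%s\n", show$chrom[i],
                  format(show$start[i], scientific = FALSE),
                  format(show$end[i], scientific = FALSE)))
    }
    if (n_regions(x) > 5L) cat("  ...\n")
  }
  invisible(x)
}

# region_set -> GRanges (1-based closed); internal boundary conversion
.as_granges <- function(x) {
  df <- x$regions
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = x$genome$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# GRanges -> interval data.frame in BED coordinates, genome-sorted
.granges_to_df <- function(gr, genome) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  df[order(match(df$chrom, genome$chrom), df$start, df$end), , drop = FALSE]
}

#' Read a BED file into a region set
#'
#' Accepts BED3+ (tab- or space-delimited; the first three columns are
#' `chrom`, `start`, `end`, 0-based half-open); extra columns are ignored and
#' lines starting with `track`, `browser` or `#` are skipped.  Records on
#' chromosomes absent from the genome are dropped with a message; the drop
#' count is kept in attribute `n_dropped`.  Invalid coordinates (negative
#' start, `start >= end`, `end` beyond the chromosome) are a hard error in
#' strict mode (the default) or dropped with a warning in lenient mode.
#'
#' @param path BED file path.
#' @param genome a `genome_def`.
#' @param name label for the set; defaults to the file name.
#' @param strict if `FALSE`, invalid records are dropped with a warning
#'   instead of raising an error.
#' @return A sorted `region_set` with attribute `n_dropped`.
#' @export
read_bed <- function(path, genome, name = NULL, strict = TRUE) {
  if (is.null(name)) name <- sub("\\.bed$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  skip <- grepl("^(track|browser|#)", lines)
  lines <- lines[!skip]
  n_dropped <- 0L
  if (length(lines) == 0L) {
    rs <- region_set(character(), numeric(), numeric(), genome, name = name)
    attr(rs, "n_dropped") <- 0L
    return(rs)
  }
  parts <- strsplit(lines, "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 3L)) stop("malformed BED line (fewer than 3 fields): ", lines[nf < 3L][1L])
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) stop("malformed BED line: non-numeric coordinate")

  unknown <- !(chrom %in% genome$chrom)
  if (any(unknown)) {
    n_dropped <- sum(unknown)
    message(n_dropped, " record(s) on chromosomes absent from the genome dropped")
    chrom <- chrom[!unknown]; start <- start[!unknown]; end <- end[!unknown]
  }
  bad <- start < 0 | start >= end | end > genome$length[chrom]
  if (any(bad)) {
    if (strict) {
      i <- which(bad)[1L]
      if (start[i] >= end[i]) stop("invalid BED record: start >= end (", chrom[i], ":", start[i], "-", end[i], ")")
      stop("invalid BED record: out-of-bounds coordinates (", chrom[i], ":", start[i], "-", end[i], ")")
    }
    warning(sum(bad), " invalid record(s) dropped (lenient mode)")
    n_dropped <- n_dropped + sum(bad)
    chrom <- chrom[!bad]; start <- start[!bad]; end <- end[!bad]
  }
  rs <- region_set(chrom, start, end, genome, name = name)
  attr(rs, "n_dropped") <- n_dropped
  rs
}

#' Write a region set as BED3
#'
#' One tab-delimited line per interval, in the set's (sorted) order;
#' duplicates are written as many times as they occur, so
#' `read_bed(write_bed(x))` reproduces `x` exactly.
#'
#' @param regions a `region_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  df <- regions$regions
  lines <- sprintf("%s\t%s\t%s", df$chrom,
                   format(df$start, scientific = FALSE, trim = TRUE),
                   format(df$end, scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}
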