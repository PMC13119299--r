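#' Define a genome as an ordered set of chromosomes
#'
#' A `genome_def` is the randomization universe every other function in the
#' package operates on: an ordered list of chromosome names with lengths, and
#' an optional mask of excluded intervals (regions where randomized intervals
#' may never be placed).  All coordinates in the package are 0-based,
#' half-open (BED convention); chromosome order is the order given here, not
#' lexicographic, so output is deterministic and locale-independent.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length numeric vector of strictly positive chromosome lengths (bp).
#' @param mask optional data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) of excluded intervals; every interval must lie within
#'   its chromosome.  Overlapping mask intervals are merged.
#' @return An object of class `genome_def` with elements `chrom`, `length`
#'   (named numeric) and `mask` (merged data.frame or `NULL`).
#' @examples
#' g <- genome_def(c("chr1", "chr2"), c(1e7, 5e6))
#' g
#' @export
genome_def <- function(chrom, length, mask = NULL) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (base::length(chrom) == 0L) stop("empty genome: at least one chromosome is required")
  if (base::length(chrom) != base::length(length)) {
    stop("'chrom' and 'length' must have equal length")
  }
  if (anyNA(chrom) || anyNA(length)) stop("chromosome names and lengths must not be NA")
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome name: ", chrom[duplicated(chrom)][1L])
  }
  if (any(length <= 0) || any(length != floor(length))) {
    stop("non-positive length: chromosome lengths must be positive integers")
  }
  g <- structure(
    list(chrom = chrom, length = stats::setNames(length, chrom), mask = NULL),
    class = "genome_def"
  )
  if (!is.null(mask)) g <- set_mask(g, mask)
  g
}

#' Attach an exclusion mask to a genome
#'
#' @param genome a `genome_def`.
#' @param mask data.frame with columns `chrom`, `start`, `end`; intervals are
#'   validated against the genome and merged.
#' @return The genome with `$mask` set.
#' @export
set_mask <- function(genome, mask) {
  stopifnot(inherits(genome, "genome_def"))
  mask <- as.data.frame(mask)
  if (!all(c("chrom", "start", "end") %in% names(mask))) {
    stop("mask must have columns chrom, start, end")
  }
  mask$chrom <- as.character(mask$chrom)
  mask$start <- as.numeric(mask$start)
  mask$end <- as.numeric(mask$end)
  .validate_intervals(mask, genome, what = "mask interval")
  genome$mask <- .merge_df(mask[, c("chrom", "start", "end")], genome)
  genome
}

# shared interval validation: 0 <= start < end <= chrom length, chrom known
.validate_intervals <- function(df, genome, what = "interval") {
  if (nrow(df) == 0L) return(invisible(df))
  bad <- !(df$chrom %in% genome$chrom)
  if (any(bad)) stop(what, " on unknown chromosome: ", df$chrom[bad][1L])
  if (any(df$start < 0)) stop(what, " with negative start")
  if (any(df$start >= df$end)) stop(what, " with start >= end")
  len <- genome$length[df$chrom]
  if (any(df$end > len)) stop(what, " extends beyond chromosome end")
  invisible(df)
}

#' Total genome length in base pairs
#' @param genome a `genome_def`.
#' @param masked if `TRUE`, subtract masked bases.
#' @return numeric scalar.
#' @export
genome_length <- function(genome, masked = FALSE) {
  tot <- sum(genome$length)
  if (masked && !is.null(genome$mask)) {
    tot <- tot - sum(genome$mask$end - genome$mask$start)
  }
  tot
}

# masked bases per chromosome, named numeric aligned with genome$chrom
.masked_bp <- function(genome) {
  out <- stats::setNames(numeric(length(genome$chrom)), genome$chrom)
  if (!is.null(genome$mask) && nrow(genome$mask) > 0L) {
    agg <- tapply(genome$mask$end - genome$mask$start, genome$mask$chrom, sum)
    out[names(agg)] <- agg
  }
  out
}

.same_genome <- function(a, b) {
  identical(a$chrom, b$chrom) && identical(unname(a$length), unname(b$length))
}

#' @export
print.genome_def <- function(x, ...) {
  cat("genome_def:", length(x$chrom), "chromosome(s),",
      format(genome_length(x), big.mark = ","), "bp total\n")
  n <- min(length(x$chrom), 8L)
  for (i in seq_len(n)) {
    cat(sprintf("  %-12s %s bp\n", x$chrom[i], format(x$length[i], big.mark = ",")))
  }
  if (length(x$chrom) > n) cat("  ...\n")
  if (!is.null(x$mask)) {
    cat("  mask:", nrow(x$mask), "interval(s),",
        format(sum(x$mask$end - x$mask$start), big.mark = ","), "bp excluded\n")
  }
  invisible(x)
}

#' Read a UCSC chrom.sizes file
#'
#' Parses the two-column whitespace-delimited format (`name<TAB>length`) into
#' a [genome_def()].  Chromosome order follows file order.  Malformed lines,
#' non-positive lengths and duplicated names are hard errors naming the
#' offending line.
#'
#' @param path path to a chrom.sizes file.
#' @return A `genome_def` with an empty mask.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty genome: no chromosomes in ", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  chrom <- character(length(parts))
  len <- numeric(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 2L) stop("malformed line ", i, " in ", path, ": ", lines[i])
    v <- suppressWarnings(as.numeric(p[2L]))
    if (is.na(v)) stop("malformed line ", i, " in ", path, ": non-numeric length")
    if (v <= 0 || v != floor(v)) stop("non-positive length at line ", i, ": ", lines[i])
    chrom[i] <- p[1L]
    len[i] <- v
  }
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome '", chrom[duplicated(chrom)][1L], "' in ", path)
  }
  genome_def(chrom, len)
}
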