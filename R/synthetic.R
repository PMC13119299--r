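#' Region length models for the synthetic generator
#'
#' @param model `"fixed"`, `"uniform"` or `"lognormal"` (truncated).
#' @param ... model parameters: `fixed` takes a single length `L`; `uniform`
#'   takes `min`, `max` (bp); `lognormal` takes `meanlog`, `sdlog`, `min`,
#'   `max` (resampled until within `[min, max]`).
#' @return A classed `length_model` list.
#' @examples
#' length_model("uniform", min = 200, max = 600)
#' @export
length_model <- function(model = c("fixed", "uniform", "lognormal"), ...) {
  model <- match.arg(model)
  args <- list(...)
  lm <- switch(model,
    fixed = {
      L <- if (length(args)) args[[1]] else stop("fixed model needs a length")
      list(model = "fixed", L = as.numeric(L))
    },
    uniform = list(model = "uniform", min = as.numeric(args$min), max = as.numeric(args$max)),
    lognormal = list(model = "lognormal", meanlog = as.numeric(args$meanlog),
                     sdlog = as.numeric(args$sdlog),
                     min = as.numeric(args$min), max = as.numeric(args$max))
  )
  if (lm$model != "fixed" && (is.na(lm$min) || is.na(lm$max) || lm$min > lm$max || lm$min < 1)) {
    stop("invalid length bounds")
  }
  if (lm$model == "fixed" && (is.na(lm$L) || lm$L < 1)) stop("invalid fixed length")
  structure(lm, class = "length_model")
}

.draw_lengths <- function(lm, n) {
  switch(lm$model,
    fixed = rep(lm$L, n),
    uniform = lm$min + floor(stats::runif(n) * (lm$max - lm$min + 1)),
    lognormal = {
      out <- numeric(0)
      while (length(out) < n) {
        x <- round(stats::rlnorm(n, lm$meanlog, lm$sdlog))
        out <- c(out, x[x >= lm$min & x <= lm$max])
      }
      out[seq_len(n)]
    })
}

#' Configuration for the synthetic region-set generator
#'
#' Bundles the parameters of the desk-scale simulation the calibration and
#' power experiments run on.  Defaults emulate ATAC/ChIP-peak-scale data: a
#' 15 Mb two-chromosome genome, 500 reference peaks and 300 query peaks of
#' 200-600 bp, giving a background (unplanted) query-reference collision
#' rate of a few percent.
#'
#' @param genome a `genome_def`, or a named numeric vector of chromosome
#'   lengths.
#' @param n_reference,n_query region counts.
#' @param lengths a [length_model()] for both sets.
#' @param planted_fraction probability `f` in `[0, 1]` that each query
#'   region is anchored to overlap a reference region (the ground-truth
#'   effect size).
#' @param jitter maximum absolute offset (bp) of a planted query start from
#'   its anchor's start; planted overlaps of >= 1 bp are guaranteed by
#'   clipping after jitter.
#' @param seed integer root seed; the reference set, query sets and truth
#'   vector all derive deterministic substreams from it.
#' @return A classed `synthetic_config` list.
#' @export
synthetic_config <- function(genome = c(chr1 = 1e7, chr2 = 5e6),
                             n_reference = 500L, n_query = 300L,
                             lengths = length_model("uniform", min = 200, max = 600),
                             planted_fraction = 0.5, jitter = 200L, seed = 1L) {
  if (!inherits(genome, "genome_def")) genome <- genome_def(names(genome), genome)
  stopifnot(inherits(lengths, "length_model"))
  if (planted_fraction < 0 || planted_fraction > 1) stop("planted_fraction must be in [0, 1]")
  if (n_reference < 0 || n_query < 0) stop("region counts must be non-negative")
  maxlen <- switch(lengths$model, fixed = lengths$L, lengths$max)
  if (maxlen > min(genome$length)) stop("region lengths exceed the shortest chromosome")
  structure(
    list(genome = genome, n_reference = as.integer(n_reference),
         n_query = as.integer(n_query), lengths = lengths,
         planted_fraction = planted_fraction, jitter = as.integer(jitter),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Sample background regions uniformly over a genome
#'
#' Chromosomes are chosen with probability proportional to the number of
#' feasible start positions for each region's length; starts are uniform.
#' Deterministic under `seed`.
#'
#' @param genome a `genome_def`.
#' @param n number of regions.
#' @param lengths a [length_model()].
#' @param seed integer seed.
#' @param name label for the returned set.
#' @return A `region_set` of `n` regions.
#' @export
sample_regions <- function(genome, n, lengths = length_model("uniform", min = 200, max = 600),
                           seed = 1L, name = "background") {
  stopifnot(inherits(genome, "genome_def"))
  n <- as.integer(n)
  if (n == 0L) return(region_set(character(), numeric(), numeric(), genome, name = name))
  placed <- .with_seed(seed, {
    len <- .draw_lengths(lengths, n)
    pol <- randomization_policy(strategy = "genome_wide", seed = 0L)
    core <- .randomize_core(rep(genome$chrom[1L], n), len, genome, pol, .mask_index(genome))
    list(chrom = core$chrom, start = core$start, len = len)
  })
  region_set(placed$chrom, placed$start, placed$start + placed$len, genome, name = name)
}

#' Generate a query set with a planted fraction of reference overlaps
#'
#' Each of `n_query` regions is, independently with probability
#' `planted_fraction`, anchored to a uniformly chosen reference region — its
#' start is the anchor start plus a uniform jitter in `[-jitter, jitter]`,
#' clipped so at least 1 bp of overlap with the anchor is guaranteed — and
#' is otherwise placed as background exactly as [sample_regions()] places
#' it.  The planted/background truth is returned as a logical `planted`
#' column of the region table, for power accounting.
#'
#' @param reference anchor `region_set` (nonempty when
#'   `planted_fraction > 0`).
#' @param config a [synthetic_config()].
#' @param seed seed for this draw (default: substream of `config$seed`).
#' @param name label for the query set.
#' @return A `region_set` with an extra logical column `planted`.
#' @export
plant_enriched_query <- function(reference, config, seed = NULL, name = "query") {
  stopifnot(inherits(config, "synthetic_config"), inherits(reference, "region_set"))
  genome <- config$genome
  if (!.same_genome(reference$genome, genome)) stop("reference bound to a different genome")
  f <- config$planted_fraction
  n <- config$n_query
  if (f > 0 && n_regions(reference) == 0L) stop("reference must be nonempty when planted_fraction > 0")
  if (is.null(seed)) seed <- .derive_seed(config$seed, 3L, 0L)

  placed <- .with_seed(seed, {
    len <- .draw_lengths(config$lengths, n)
    planted <- stats::runif(n) < f
    pol <- randomization_policy(strategy = "genome_wide", seed = 0L)
    core <- .randomize_core(rep(genome$chrom[1L], n), len, genome, pol, .mask_index(genome))
    chrom <- core$chrom
    start <- core$start
    k <- sum(planted)
    if (k > 0L) {
      anchor <- sample.int(n_regions(reference), k, replace = TRUE)
      a <- reference$regions[anchor, , drop = FALSE]
      off <- floor(stats::runif(k) * (2 * config$jitter + 1)) - config$jitter
      s <- a$start + off
      # clip so [s, s+len) keeps >= 1 bp overlap with the anchor, then to the
      # chromosome; the chromosome clip can never undo the overlap guarantee
      lp <- len[planted]
      s <- pmin(pmax(s, a$start - lp + 1), a$end - 1)
      s <- pmin(pmax(s, 0), genome$length[a$chrom] - lp)
      chrom[planted] <- a$chrom
      start[planted] <- s
    }
    list(chrom = chrom, start = start, len = len, planted = planted)
  })
  region_set(placed$chrom, placed$start, placed$start + placed$len, genome,
             name = name, extra = data.frame(planted = placed$planted))
}

#' Build a ready-made simulation scenario
#'
#' Bundles a genome, a reference peak set and query set(s) with known
#' ground truth, reproducible from `config$seed`:
#' * `"null"` — two query sets with planted fraction 0 (for type-I-error
#'   calibration of both the single-set and the differential test);
#' * `"enriched"` — one query set with the configured planted fraction;
#' * `"differential"` — `query_1` with the configured fraction, `query_2`
#'   unplanted, equal sizes.
#'
#' @param name scenario name.
#' @param config a [synthetic_config()].
#' @return List with `genome`, `reference`, and `query` (enriched) or
#'   `query_1`/`query_2` (null, differential); query sets carry their
#'   `planted` truth column.
#' @export
make_scenario <- function(name = c("null", "enriched", "differential"),
                          config = synthetic_config()) {
  name <- match.arg(name)
  stopifnot(inherits(config, "synthetic_config"))
  genome <- config$genome
  reference <- sample_regions(genome, config$n_reference, config$lengths,
                              seed = .derive_seed(config$seed, 1L, 0L),
                              name = "reference")
  cfg0 <- config; cfg0$planted_fraction <- 0
  out <- switch(name,
    null = list(
      query_1 = plant_enriched_query(reference, cfg0,
                                     seed = .derive_seed(config$seed, 3L, 0L), name = "query_1"),
      query_2 = plant_enriched_query(reference, cfg0,
                                     seed = .derive_seed(config$seed, 4L, 0L), name = "query_2")),
    enriched = list(
      query = plant_enriched_query(reference, config,
                                   seed = .derive_seed(config$seed, 3L, 0L), name = "query")),
    differential = list(
      query_1 = plant_enriched_query(reference, config,
                                     seed = .derive_seed(config$seed, 3L, 0L), name = "query_1"),
      query_2 = plant_enriched_query(reference, cfg0,
                                     seed = .derive_seed(config$seed, 4L, 0L), name = "query_2"))
  )
  c(list(scenario = name, genome = genome, reference = reference), out)
}

#' Write a scenario to disk as chrom.sizes + BED + truth TSV
#'
#' @param scenario result of [make_scenario()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- scenario$genome
  writeLines(sprintf("%s\t%s", g$chrom,
                     format(unname(g$length), scientific = FALSE, trim = TRUE)),
             file.path(dir, "genome.chrom.sizes"))
  sets <- scenario[vapply(scenario, inherits, logical(1), "region_set")]
  truth <- NULL
  for (nm in names(sets)) {
    write_bed(sets[[nm]], file.path(dir, paste0(nm, ".bed")))
    if ("planted" %in% names(sets[[nm]]$regions)) {
      df <- sets[[nm]]$regions
      truth <- rbind(truth, data.frame(set = nm, chrom = df$chrom, start = df$start,
                                       end = df$end, planted = df$planted))
    }
  }
  if (!is.null(truth)) {
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
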