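#' Apply an ordered chain of overlap filters to a region set
#'
#' Sequentially subsets `base` by overlap status against a series of
#' reference sets — the idiom behind statements like "of the N peaks that
#' lost accessibility, K overlapped X".  Per-step region counts are
#' monotonically non-increasing.
#'
#' @param base the starting `region_set`.
#' @param steps list of steps, each a list with elements `reference` (a
#'   `region_set`) and `keep` (`"overlapping"` or `"non_overlapping"`).
#' @return List with `regions` (the final set) and `counts` (named integer
#'   vector: the base count followed by the count after each step).
#' @export
filter_chain <- function(base, steps = list()) {
  stopifnot(inherits(base, "region_set"))
  counts <- stats::setNames(n_regions(base), base$name)
  current <- base
  for (st in steps) {
    if (!inherits(st$reference, "region_set")) stop("unresolved reference in filter chain")
    current <- filter_overlapping(current, st$reference, keep = st$keep)
    counts <- c(counts, stats::setNames(n_regions(current),
                                        paste0(st$keep, ":", st$reference$name)))
  }
  list(regions = current, counts = counts)
}

.fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

.log_line <- function(con, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", paste0(...))
  writeLines(line, con)
}

#' Run a declarative analysis manifest
#'
#' Executes a batch of enrichment permutation tests, differential
#' permutation tests, colocalization chi-square tests and filter chains
#' described by a YAML manifest, writing TSV tables, a JSON report and a
#' log to `out_dir`.  All randomness flows from the manifest-level seed:
#' job `k` runs with a seed deterministically derived from it, so re-running
#' an identical manifest reproduces every numeric field bit-for-bit.
#' Job-level failures are recorded in the report and do not abort the run.
#'
#' Manifest schema (YAML):
#' \preformatted{
#' genome: genome.chrom.sizes
#' mask: excluded.bed            # optional
#' region_sets: {setA: a.bed, setB: b.bed, ref: r.bed}
#' policy: {strategy: per_chromosome, seed: 1}
#' multiple_testing: none        # or BH
#' enrichment:
#'   - {query: setA, reference: ref, n_perm: 200, alternative: greater}
#' differential:
#'   - {query_1: setA, query_2: setB, reference: ref, n_perm: 200}
#' colocalization:
#'   - {set_1: setA, set_2: setB, companions: [ref], mode: any}
#' filters:
#'   - {name: chainA, base: setA,
#'      steps: [{reference: ref, keep: overlapping}]}
#' }
#'
#' @param manifest path to a YAML manifest, or an equivalent named list.
#' @param out_dir output directory (created if missing); receives
#'   `enrichment.tsv`, `differential.tsv`, `colocalization.tsv`,
#'   `filters.tsv`, `run.json` and `run.log`.
#' @return Invisibly, a list with the four result data.frames and
#'   `n_failed`; attribute `exit_status` is 0 when every job succeeded.
#' @export
run_manifest <- function(manifest, out_dir) {
  if (is.character(manifest)) manifest <- yaml::read_yaml(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)

  pol_cfg <- manifest$policy %||% list()
  seed <- as.integer(pol_cfg$seed %||% 1L)
  strategy <- pol_cfg$strategy %||% "per_chromosome"
  mt <- manifest$multiple_testing %||% "none"
  version <- as.character(utils::packageVersion("regionperm"))

  genome <- read_chrom_sizes(manifest$genome)
  if (!is.null(manifest$mask)) {
    mask_rs <- read_bed(manifest$mask, genome, name = "mask")
    genome <- set_mask(genome, mask_rs$regions)
  }
  .log_line(log_con, "genome: ", length(genome$chrom), " chromosomes, ",
            genome_length(genome), " bp; policy: ", strategy, ", seed ", seed)

  sets <- list()
  for (nm in names(manifest$region_sets)) {
    sets[[nm]] <- read_bed(manifest$region_sets[[nm]], genome, name = nm)
    .log_line(log_con, "loaded set '", nm, "': ", n_regions(sets[[nm]]), " regions")
  }
  get_set <- function(nm) {
    if (is.null(sets[[nm]])) stop("unresolved set '", nm, "'")
    sets[[nm]]
  }

  failures <- 0L
  job_idx <- 0L
  run_job <- function(kind, label, expr) {
    job_idx <<- job_idx + 1L
    t0 <- Sys.time()
    res <- tryCatch(list(ok = TRUE, value = force(expr)),
                    error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    dt <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    if (res$ok) {
      .log_line(log_con, kind, " '", label, "' ok (", dt, "s)")
    } else {
      failures <<- failures + 1L
      .log_line(log_con, kind, " '", label, "' FAILED: ", res$error)
    }
    res
  }
  job_policy <- function() {
    randomization_policy(strategy = strategy, seed = .derive_seed(seed, 100L + job_idx, 0L))
  }

  enr <- data.frame()
  for (job in manifest$enrichment %||% list()) {
    label <- paste0(job$query, "~", job$reference)
    res <- run_job("enrichment", label, {
      pt <- perm_test(get_set(job$query), get_set(job$reference), genome,
                      policy = job_policy(),
                      n_perm = as.integer(job$n_perm %||% 500L),
                      alternative = job$alternative %||% "greater")
      data.frame(query = job$query, reference = job$reference,
                 n_query = pt$n_query, n_reference = pt$n_reference,
                 observed = pt$observed, null_mean = pt$null_mean,
                 null_sd = pt$null_sd, z = pt$z, p_empirical = pt$p_empirical,
                 threshold_count_at_p05 = pt$threshold_count_at_p05,
                 n_perm = pt$n_perm, alternative = pt$alternative,
                 strategy = strategy, seed = seed, version = version,
                 status = "ok")
    })
    enr <- rbind(enr, if (res$ok) res$value else
      data.frame(query = job$query, reference = job$reference, n_query = NA, n_reference = NA,
                 observed = NA, null_mean = NA, null_sd = NA, z = NA, p_empirical = NA,
                 threshold_count_at_p05 = NA, n_perm = NA, alternative = NA,
                 strategy = strategy, seed = seed, version = version,
                 status = paste0("error: ", res$error)))
  }

  dif <- data.frame()
  for (job in manifest$differential %||% list()) {
    label <- paste0(job$query_1, "-", job$query_2, "~", job$reference)
    res <- run_job("differential", label, {
      dt <- diff_perm_test(get_set(job$query_1), get_set(job$query_2),
                           get_set(job$reference), genome,
                           policy = job_policy(),
                           n_perm = as.integer(job$n_perm %||% 1000L),
                           alternative = job$alternative %||% "greater",
                           randomize = job$randomize %||% "both")
      data.frame(query_1 = job$query_1, query_2 = job$query_2, reference = job$reference,
                 observed_1 = dt$observed_1, observed_2 = dt$observed_2,
                 observed_diff = dt$observed_diff, null_mean = dt$null_mean,
                 null_sd = dt$null_sd, z = dt$z, p_empirical = dt$p_empirical,
                 n_perm = dt$n_perm, alternative = dt$alternative,
                 randomize = dt$randomize, strategy = strategy, seed = seed,
                 version = version, status = "ok")
    })
    dif <- rbind(dif, if (res$ok) res$value else
      data.frame(query_1 = job$query_1, query_2 = job$query_2, reference = job$reference,
                 observed_1 = NA, observed_2 = NA, observed_diff = NA, null_mean = NA,
                 null_sd = NA, z = NA, p_empirical = NA, n_perm = NA, alternative = NA,
                 randomize = NA, strategy = strategy, seed = seed, version = version,
                 status = paste0("error: ", res$error)))
  }

  col <- data.frame()
  for (job in manifest$colocalization %||% list()) {
    label <- paste0(job$set_1, "/", job$set_2)
    res <- run_job("colocalization", label, {
      comp <- lapply(unlist(job$companions), get_set)
      tab <- colocalization_table(get_set(job$set_1), get_set(job$set_2), comp,
                                  mode = job$mode %||% "any")
      ct <- yates_chi2(tab)
      data.frame(set_1 = job$set_1, set_2 = job$set_2,
                 companions = paste(unlist(job$companions), collapse = "+"),
                 mode = job$mode %||% "any",
                 a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2],
                 chi2 = ct$statistic, p = ct$p, version = version, status = "ok")
    })
    col <- rbind(col, if (res$ok) res$value else
      data.frame(set_1 = job$set_1, set_2 = job$set_2,
                 companions = paste(unlist(job$companions), collapse = "+"),
                 mode = job$mode %||% "any", a = NA, b = NA, c = NA, d = NA,
                 chi2 = NA, p = NA, version = version,
                 status = paste0("error: ", res$error)))
  }

  flt <- data.frame()
  for (job in manifest$filters %||% list()) {
    label <- job$name %||% job$base
    res <- run_job("filter", label, {
      steps <- lapply(job$steps, function(st)
        list(reference = get_set(st$reference), keep = st$keep %||% "overlapping"))
      fc <- filter_chain(get_set(job$base), steps)
      data.frame(chain = label, stage = seq_along(fc$counts) - 1L,
                 step = names(fc$counts), count = unname(fc$counts),
                 version = version, status = "ok")
    })
    flt <- rbind(flt, if (res$ok) res$value else
      data.frame(chain = label, stage = NA, step = NA, count = NA,
                 version = version, status = paste0("error: ", res$error)))
  }

  if (identical(mt, "BH")) {
    # adjust across all empirical p's of the run; raw p's are kept
    pool <- c(enr$p_empirical, dif$p_empirical)
    adj <- stats::p.adjust(pool, method = "BH")
    if (nrow(enr)) enr$p_adjusted <- adj[seq_len(nrow(enr))]
    if (nrow(dif)) dif$p_adjusted <- adj[nrow(enr) + seq_len(nrow(dif))]
  }

  write_tsv <- function(df, name) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], .fmt_num, digits = 10)
    utils::write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_tsv(enr, "enrichment.tsv")
  write_tsv(dif, "differential.tsv")
  write_tsv(col, "colocalization.tsv")
  write_tsv(flt, "filters.tsv")
  report <- list(
    version = version,
    policy = list(strategy = strategy, seed = seed),
    multiple_testing = mt,
    n_jobs = job_idx, n_failed = failures,
    enrichment = enr, differential = dif, colocalization = col, filters = flt
  )
  jsonlite::write_json(report, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows")
  .log_line(log_con, "run complete: ", job_idx, " job(s), ", failures, " failed")
  out <- list(enrichment = enr, differential = dif, colocalization = col,
              filters = flt, n_failed = failures)
  attr(out, "exit_status") <- if (failures > 0L) 1L else 0L
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
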