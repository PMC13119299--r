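# add-one empirical p-value against a null vector
.emp_p <- function(null, observed, alternative) {
  n <- length(null)
  p_gr <- (1 + sum(null >= observed)) / (n + 1)
  p_ls <- (1 + sum(null <= observed)) / (n + 1)
  switch(alternative,
         greater = p_gr,
         less = p_ls,
         two_sided = min(1, 2 * min(p_gr, p_ls)))
}

# smallest integer count c with (1 + #{null_i >= c}) / (n+1) <= alpha
# (the "threshold of significance" bar of an enrichment plot); NA if no
# count can reach alpha at this n_perm
.threshold_count <- function(null, alpha = 0.05) {
  n <- length(null)
  kmax <- floor(alpha * (n + 1) + 1e-9) - 1L
  if (kmax < 0L) return(NA_integer_)
  d <- sort(null, decreasing = TRUE)
  as.integer(d[kmax + 1L] + 1L)
}

#' Permutation test for overlap enrichment between two region sets
#'
#' Compares the observed count-once overlap of `query` with `reference`
#' against a null distribution obtained by randomly re-placing the query set
#' across the genome [randomize_regions()], and summarizes the comparison by
#' a z-score `(observed - null_mean) / null_sd` and an add-one empirical
#' p-value `(1 + exceedances) / (n_perm + 1)`.  The result also carries the
#' smallest overlap count that would reach empirical p = 0.05 given the
#' realized null — the significance-threshold bar of the classical
#' enrichment plot, alongside the observed and null-mean bars (see
#' [plot.perm_test()]).
#'
#' When the null is degenerate (`null_sd == 0`) the z-score is reported as
#' `NA` (an explicit undefined marker, never infinity); the empirical
#' p-value remains valid.
#'
#' @param query,reference `region_set`s on the same `genome_def`.
#' @param genome the randomization universe; defaults to the query's genome.
#' @param policy a [randomization_policy()] (strategy, seed, mask handling).
#' @param n_perm number of permutations; at least 20, and a warning is
#'   issued below 100.  500 is a typical choice for peak-set enrichment.
#' @param alternative `"greater"` (default), `"less"` or `"two_sided"`;
#'   two-sided p is `2 * min(one-sided)` capped at 1.
#' @param min_overlap_bp,count forwarded to [overlap_count()].
#' @param keep_null keep the full null vector in the result (default TRUE;
#'   needed by [plot.perm_test()] and the TSV/JSON audit trail).
#' @param stream internal substream id, see [null_distribution()].
#' @return An object of class `perm_test` with elements `observed`,
#'   `null_mean`, `null_sd`, `z`, `p_empirical`, `p_z` (normal-tail p from
#'   the z-score, `NA` when z is undefined), `threshold_count_at_p05`,
#'   `n_perm`, `alternative`, `policy`, `n_query`, `n_reference`,
#'   `query_name`, `reference_name`, and (if kept) `null`.
#' @examples
#' g <- genome_def(c("chr1", "chr2"), c(1e6, 5e5))
#' set.seed(7)
#' r <- sample_regions(g, 50, length_model("fixed", 500), seed = 7)
#' q <- sample_regions(g, 30, length_model("fixed", 400), seed = 8)
#' perm_test(q, r, n_perm = 99, policy = randomization_policy(seed = 1))
#' @export
perm_test <- function(query, reference, genome = query$genome,
                      policy = randomization_policy(), n_perm = 500L,
                      alternative = c("greater", "less", "two_sided"),
                      min_overlap_bp = 1L, count = c("once", "pairs"),
                      keep_null = TRUE, stream = 0L) {
  alternative <- match.arg(alternative)
  count <- match.arg(count)
  .check_pair(query, reference)
  if (n_perm < 20L) stop("n_perm must be >= 20")
  if (n_perm < 100L) warning("n_perm < 100: empirical p-values will be coarse")

  observed <- overlap_count(query, reference, min_overlap_bp, count)$n_overlapping
  null <- null_distribution(query, reference, genome, policy, n_perm,
                            min_overlap_bp, count, stream = stream)
  null_mean <- mean(null)
  null_sd <- stats::sd(null)  # denominator n_perm - 1
  z <- if (null_sd > 0) (observed - null_mean) / null_sd else NA_real_
  p_z <- if (is.na(z)) NA_real_ else switch(alternative,
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z),
    two_sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))

  structure(
    list(observed = as.integer(observed),
         null_mean = null_mean, null_sd = null_sd,
         z = z, p_empirical = .emp_p(null, observed, alternative), p_z = p_z,
         threshold_count_at_p05 = .threshold_count(null, 0.05),
         n_perm = as.integer(n_perm), alternative = alternative,
         policy = policy, min_overlap_bp = as.integer(min_overlap_bp),
         count = count,
         n_query = n_regions(query), n_reference = n_regions(reference),
         query_name = query$name, reference_name = reference$name,
         null = if (keep_null) null else NULL,
         query = query, reference = reference, genome = genome),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test of overlap enrichment\n")
  cat(sprintf("  query:     %s (%d regions)\n", x$query_name, x$n_query))
  cat(sprintf("  reference: %s (%d regions)\n", x$reference_name, x$n_reference))
  cat(sprintf("  observed overlaps: %d   null: %.2f +/- %.2f (%d permutations, %s)\n",
              x$observed, x$null_mean, x$null_sd, x$n_perm, x$policy$strategy))
  ztxt <- if (is.na(x$z)) "undefined (degenerate null)" else sprintf("%.2f", x$z)
  cat(sprintf("  z = %s, empirical p = %.4g (alternative: %s)\n",
              ztxt, x$p_empirical, x$alternative))
  if (!is.na(x$threshold_count_at_p05)) {
    cat(sprintf("  overlap count at p = 0.05 threshold: %d\n", x$threshold_count_at_p05))
  }
  invisible(x)
}

#' @export
summary.perm_test <- function(object, ...) {
  print(object)
  if (!is.null(object$null)) {
    cat("  null distribution quantiles:\n")
    q <- stats::quantile(object$null, c(0, .25, .5, .75, .95, 1))
    cat("   ", paste(sprintf("%s=%g", names(q), q), collapse = "  "), "\n")
  }
  invisible(object)
}

#' Plot a permutation test as a null histogram with marker bars
#'
#' Gray histogram of the permutation null; a green line at the observed
#' overlap count, a black line at the null mean, and a red line at the
#' overlap count corresponding to the empirical p = 0.05 significance
#' threshold.
#'
#' @param x a `perm_test` (fitted with `keep_null = TRUE`).
#' @param ... passed to [graphics::hist()].
#' @export
plot.perm_test <- function(x, ...) {
  if (is.null(x$null)) stop("null vector not kept; refit with keep_null = TRUE")
  xlim <- range(c(x$null, x$observed, x$threshold_count_at_p05), na.rm = TRUE)
  graphics::hist(x$null, col = "gray", border = "white", xlim = xlim,
                 main = sprintf("%s vs %s", x$query_name, x$reference_name),
                 xlab = "overlap count", ...)
  graphics::abline(v = x$null_mean, col = "black", lwd = 2)
  graphics::abline(v = x$observed, col = "forestgreen", lwd = 2)
  if (!is.na(x$threshold_count_at_p05)) {
    graphics::abline(v = x$threshold_count_at_p05, col = "red", lwd = 2, lty = 2)
  }
  invisible(x)
}

#' Draw additional permutation null counts from a fitted test
#'
#' @param object a `perm_test`.
#' @param nsim number of additional null draws.
#' @param seed root seed for the new draws (default: the fitted policy seed
#'   offset by one stream so the draws are fresh).
#' @param ... unused.
#' @return Integer vector of `nsim` null overlap counts.
#' @export
simulate.perm_test <- function(object, nsim = object$n_perm, seed = NULL, ...) {
  pol <- object$policy
  pol$seed <- if (is.null(seed)) pol$seed else as.integer(seed)
  null_distribution(object$query, object$reference, object$genome, pol,
                    n_perm = nsim, min_overlap_bp = object$min_overlap_bp,
                    count = object$count, stream = if (is.null(seed)) 1L else 0L)
}
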