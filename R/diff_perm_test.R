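#' Differential permutation test for two query sets against one reference
#'
#' Tests whether the *difference* in overlap counts of two query region sets
#' against a common reference exceeds what random placement would produce.
#' The observed statistic is
#' `overlap(query_1, reference) - overlap(query_2, reference)`; the null is
#' built by independently randomizing *both* query sets in every permutation
#' and recording the difference of their overlap counts, giving the expected
#' distribution of count differences attributable only to the sizes and
#' numbers of regions in the sets.  A significant result (alternative
#' `"greater"`) means `query_1` intersects the reference more often than
#' `query_2` to a degree beyond random chance.
#'
#' The default null randomizes both query sets (the symmetric choice); set
#' `randomize = "first_only"` to hold `query_2` fixed at its observed count.
#' The variant used is recorded in the result.
#'
#' @param query_1,query_2 the two query `region_set`s.
#' @param reference the common reference `region_set`.
#' @param genome randomization universe (default: genome of `query_1`).
#' @param policy a [randomization_policy()].
#' @param n_perm number of permutations (>= 20; 1000 is a typical choice for
#'   this test).
#' @param alternative `"greater"` (default), `"less"` or `"two_sided"`.
#' @param min_overlap_bp,count forwarded to the overlap counting.
#' @param randomize `"both"` (default) or `"first_only"`.
#' @param keep_null keep the vector of null differences.
#' @return An object of class `diff_perm_test` with `observed_1`,
#'   `observed_2`, `observed_diff`, `null_mean`, `null_sd`, `z`,
#'   `p_empirical`, `p_z`, `n_perm`, `alternative`, `randomize`, `policy`
#'   and (if kept) `null`.
#' @export
diff_perm_test <- function(query_1, query_2, reference, genome = query_1$genome,
                           policy = randomization_policy(), n_perm = 1000L,
                           alternative = c("greater", "less", "two_sided"),
                           min_overlap_bp = 1L, count = c("once", "pairs"),
                           randomize = c("both", "first_only"),
                           keep_null = TRUE) {
  alternative <- match.arg(alternative)
  count <- match.arg(count)
  randomize <- match.arg(randomize)
  .check_pair(query_1, reference)
  .check_pair(query_2, reference)
  if (!.same_genome(query_1$genome, genome)) stop("query_1 bound to a different genome")
  if (n_perm < 20L) stop("n_perm must be >= 20")

  observed_1 <- overlap_count(query_1, reference, min_overlap_bp, count)$n_overlapping
  observed_2 <- overlap_count(query_2, reference, min_overlap_bp, count)$n_overlapping
  observed_diff <- observed_1 - observed_2

  # streams 1 and 2 keep the two query sets' randomizations independent
  null_1 <- null_distribution(query_1, reference, genome, policy, n_perm,
                              min_overlap_bp, count, stream = 1L)
  null_2 <- if (randomize == "both") {
    null_distribution(query_2, reference, genome, policy, n_perm,
                      min_overlap_bp, count, stream = 2L)
  } else {
    rep(observed_2, n_perm)
  }
  null <- null_1 - null_2

  null_mean <- mean(null)
  null_sd <- stats::sd(null)
  z <- if (null_sd > 0) (observed_diff - null_mean) / null_sd else NA_real_
  p_z <- if (is.na(z)) NA_real_ else switch(alternative,
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z),
    two_sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))

  structure(
    list(observed_1 = as.integer(observed_1), observed_2 = as.integer(observed_2),
         observed_diff = as.integer(observed_diff),
         null_mean = null_mean, null_sd = null_sd,
         z = z, p_empirical = .emp_p(null, observed_diff, alternative), p_z = p_z,
         n_perm = as.integer(n_perm), alternative = alternative,
         randomize = randomize, policy = policy,
         query_1_name = query_1$name, query_2_name = query_2$name,
         reference_name = reference$name,
         n_query_1 = n_regions(query_1), n_query_2 = n_regions(query_2),
         null = if (keep_null) null else NULL),
    class = "diff_perm_test"
  )
}

#' @export
print.diff_perm_test <- function(x, ...) {
  cat("Differential permutation test of overlap counts\n")
  cat(sprintf("  query 1: %s (%d regions), overlaps = %d\n",
              x$query_1_name, x$n_query_1, x$observed_1))
  cat(sprintf("  query 2: %s (%d regions), overlaps = %d\n",
              x$query_2_name, x$n_query_2, x$observed_2))
  cat(sprintf("  reference: %s\n", x$reference_name))
  cat(sprintf("  observed difference: %d   null: %.2f +/- %.2f (%d permutations, %s randomized)\n",
              x$observed_diff, x$null_mean, x$null_sd, x$n_perm, x$randomize))
  ztxt <- if (is.na(x$z)) "undefined (degenerate null)" else sprintf("%.2f", x$z)
  cat(sprintf("  z = %s, empirical p = %.4g (alternative: %s)\n",
              ztxt, x$p_empirical, x$alternative))
  invisible(x)
}

#' @export
summary.diff_perm_test <- function(object, ...) {
  print(object)
  if (!is.null(object$null)) {
    q <- stats::quantile(object$null, c(0, .25, .5, .75, .95, 1))
    cat("  null difference quantiles:\n")
    cat("   ", paste(sprintf("%s=%g", names(q), q), collapse = "  "), "\n")
  }
  invisible(object)
}

#' Plot the null of a differential permutation test
#'
#' Gray histogram of null overlap-count differences with the observed
#' difference (green) and null mean (black).
#'
#' @param x a `diff_perm_test` fitted with `keep_null = TRUE`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.diff_perm_test <- function(x, ...) {
  if (is.null(x$null)) stop("null vector not kept; refit with keep_null = TRUE")
  xlim <- range(c(x$null, x$observed_diff))
  graphics::hist(x$null, col = "gray", border = "white", xlim = xlim,
                 main = sprintf("%s - %s vs %s", x$query_1_name, x$query_2_name,
                                x$reference_name),
                 xlab = "difference in overlap counts", ...)
  graphics::abline(v = x$null_mean, col = "black", lwd = 2)
  graphics::abline(v = x$observed_diff, col = "forestgreen", lwd = 2)
  invisible(x)
}
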