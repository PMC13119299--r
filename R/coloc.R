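#' Colocalization contingency table for two region sets
#'
#' Builds the 2x2 table comparing how often regions of two sets co-localize
#' with one or more companion sets: rows are the two sets, columns are
#' (overlapping companions, not overlapping).  With `mode = "any"` a region
#' co-localizes if it overlaps at least one companion (equivalent to overlap
#' against the union of the companions); with `mode = "all"` it must overlap
#' every companion.
#'
#' @param set_1,set_2 `region_set`s to compare (both nonempty).
#' @param companions list of companion `region_set`s (at least one), all on
#'   the same genome.
#' @param mode `"any"` (default) or `"all"`.
#' @param min_overlap_bp minimum per-companion overlap in bp.
#' @return A 2x2 integer matrix of class `contingency_2x2` with dimnames
#'   (set names x `c("colocalized", "not_colocalized")`).
#' @export
colocalization_table <- function(set_1, set_2, companions, mode = c("any", "all"),
                                 min_overlap_bp = 1L) {
  mode <- match.arg(mode)
  if (inherits(companions, "region_set")) companions <- list(companions)
  if (length(companions) < 1L) stop("at least one companion set is required")
  if (n_regions(set_1) == 0L || n_regions(set_2) == 0L) {
    stop("set_1 and set_2 must be nonempty")
  }
  for (cmp in companions) .check_pair(set_1, cmp)
  .check_pair(set_1, set_2)

  hits <- function(s) {
    flags <- vapply(companions, function(cmp) .overlap_flags(s$regions, cmp, min_overlap_bp),
                    logical(n_regions(s)))
    flags <- matrix(flags, nrow = n_regions(s))
    if (mode == "any") rowSums(flags) > 0L else rowSums(flags) == length(companions)
  }
  a <- sum(hits(set_1)); b <- n_regions(set_1) - a
  c_ <- sum(hits(set_2)); d <- n_regions(set_2) - c_
  tab <- matrix(as.integer(c(a, b, c_, d)), nrow = 2L, byrow = TRUE,
                dimnames = list(c(set_1$name, set_2$name),
                                c("colocalized", "not_colocalized")))
  class(tab) <- c("contingency_2x2", class(tab))
  tab
}

#' Yates-corrected chi-square test of a 2x2 table
#'
#' Closed-form chi-square statistic with continuity correction,
#' `N * (max(|ad - bc| - N/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d))`, referred to
#' the chi-square distribution with 1 degree of freedom.  All four margins
#' must be strictly positive.
#'
#' @param table a `contingency_2x2` (or any 2x2 matrix of counts `a, b`
#'   over `c, d`).
#' @return List with `statistic`, `p`, `df = 1` and the input `table`.
#' @examples
#' tab <- matrix(c(30, 70, 10, 90), nrow = 2, byrow = TRUE)
#' yates_chi2(tab)$statistic  # 11.28125
#' @export
yates_chi2 <- function(table) {
  m <- unclass(as.matrix(table))
  if (!all(dim(m) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(m < 0) || any(m != floor(m))) stop("cell counts must be non-negative integers")
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  n <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) stop("chi-square undefined: zero margin")
  stat <- n * max(abs(a * d - b * c_) - n / 2, 0)^2 / prod(margins)
  structure(
    list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         df = 1L, table = m),
    class = "yates_chi2"
  )
}

#' @export
print.yates_chi2 <- function(x, ...) {
  cat("Yates-corrected chi-square test (df = 1)\n")
  print(x$table)
  cat(sprintf("  X-squared = %.5g, p = %.4g\n", x$statistic, x$p))
  invisible(x)
}
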