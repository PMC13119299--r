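test_that("empirical p uses the add-one estimator and respects alternatives", {
  null <- c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L)  # stand-in null vector
  expect_equal(regionperm:::.emp_p(null, 10, "greater"), 1 / 11)
  expect_equal(regionperm:::.emp_p(null, 0, "greater"), 11 / 11)
  expect_equal(regionperm:::.emp_p(null, 0, "less"), 2 / 11)
  expect_equal(regionperm:::.emp_p(null, 9, "two_sided"), min(1, 2 * 2 / 11))
  expect_equal(regionperm:::.emp_p(null, 5, "two_sided"), 1)  # capped
})

test_that("p05 threshold count is the smallest count reaching empirical p <= 0.05", {
  set.seed(9)
  for (rep in 1:50) {
    null <- as.integer(rpois(sample(c(99, 199, 500), 1), lambda = sample(3:30, 1)))
    thr <- regionperm:::.threshold_count(null, 0.05)
    # oracle: scan candidate counts directly
    cands <- 0:(max(null) + 2L)
    p <- vapply(cands, function(cc) (1 + sum(null >= cc)) / (length(null) + 1), numeric(1))
    ok <- cands[p <= 0.05]
    expect_identical(thr, as.integer(ok[1]))
  }
  expect_true(is.na(regionperm:::.threshold_count(rep(0L, 10), 0.05)))  # n too small
})

test_that("perm_test on a strongly planted scenario is maximally significant", {
  cfg <- desk_config(planted_fraction = 0.9, seed = 31)
  sc <- make_scenario("enriched", cfg)
  pol <- randomization_policy(seed = 32)
  pt <- suppressWarnings(perm_test(sc$query, sc$reference, policy = pol, n_perm = 199))
  expect_gt(pt$observed, max(pt$null))  # observed exceeds every null draw
  expect_equal(pt$p_empirical, 1 / 200)
  expect_gt(pt$z, 5)
  # z and the normal-tail p agree in direction with the empirical p
  expect_lt(pt$p_z, 0.001)
})

test_that("degenerate nulls report valid empirical p and an undefined z marker", {
  g <- toy_genome()
  q <- rand_region_set(g, 20, name = "q")
  empty <- region_set(character(), numeric(), numeric(), g, "empty")
  pt <- suppressWarnings(perm_test(q, empty, n_perm = 20))
  expect_equal(pt$observed, 0L)
  expect_true(all(pt$null == 0L))
  expect_equal(pt$p_empirical, 1)
  expect_true(is.na(pt$z))
  expect_true(is.na(pt$p_z))
})

test_that("perm_test is invariant under reordering of the query records", {
  g <- toy_genome()
  set.seed(77)
  q <- rand_region_set(g, 30, name = "q")
  r <- rand_region_set(g, 30, name = "r")
  perm <- sample(30)
  q2 <- region_set(q$regions$chrom[perm], q$regions$start[perm], q$regions$end[perm],
                   g, name = "q")
  pol <- randomization_policy(seed = 13)
  a <- perm_test(q, r, policy = pol, n_perm = 100)
  b <- perm_test(q2, r, policy = pol, n_perm = 100)
  expect_identical(a$null, b$null)
  expect_identical(a$p_empirical, b$p_empirical)
})

test_that("z-score and empirical p rank coherently across instances", {
  set.seed(55)
  cfg0 <- desk_config(n_reference = 200, n_query = 100)
  zs <- ps <- numeric(0)
  for (f in c(0, 0.1, 0.3, 0.6, 0.9)) {
    sc <- make_scenario("enriched", synthetic_config(
      n_reference = 200, n_query = 100, planted_fraction = f, seed = 60 + f * 10))
    pt <- perm_test(sc$query, sc$reference, policy = randomization_policy(seed = 3),
                    n_perm = 100)
    if (!is.na(pt$z)) { zs <- c(zs, pt$z); ps <- c(ps, pt$p_empirical) }
  }
  ord <- order(zs)
  expect_true(all(diff(-ps[ord]) >= -1e-12 | diff(zs[ord]) < 1e-9))
})

test_that("diff_perm_test of a set against itself has observed_diff exactly 0", {
  g <- toy_genome()
  set.seed(21)
  for (rep in 1:10) {
    q <- rand_region_set(g, sample.int(40, 1), name = "q")
    r <- rand_region_set(g, 30, name = "r")
    dt <- diff_perm_test(q, q, r, n_perm = 20)
    expect_identical(dt$observed_diff, 0L)
  }
})

test_that("differential test detects a planted difference at the exact minimal p", {
  cfg <- desk_config(planted_fraction = 0.9, seed = 71)
  sc <- make_scenario("differential", cfg)
  dt <- diff_perm_test(sc$query_1, sc$query_2, sc$reference,
                       policy = randomization_policy(seed = 72), n_perm = 199)
  expect_gt(dt$observed_diff, max(dt$null))
  expect_equal(dt$p_empirical, 1 / 200)
  expect_gt(dt$z, 5)
})

test_that("one-set randomization variant holds the second count fixed", {
  cfg <- desk_config(seed = 81)
  sc <- make_scenario("differential", cfg)
  dt <- diff_perm_test(sc$query_1, sc$query_2, sc$reference,
                       policy = randomization_policy(seed = 82), n_perm = 50,
                       randomize = "first_only")
  expect_equal(dt$randomize, "first_only")
  # null diffs are null_1 - observed_2, so adding observed_2 recovers counts >= 0
  expect_true(all(dt$null + dt$observed_2 >= 0))
})

test_that("colocalization table counts by brute force and mode=any equals union", {
  g <- toy_genome()
  set.seed(91)
  s1 <- rand_region_set(g, 40, name = "s1")
  s2 <- rand_region_set(g, 35, name = "s2")
  c1 <- rand_region_set(g, 25, name = "c1")
  c2 <- rand_region_set(g, 25, name = "c2")
  tab <- colocalization_table(s1, s2, list(c1, c2), mode = "any")
  un <- region_set(c(c1$regions$chrom, c2$regions$chrom),
                   c(c1$regions$start, c2$regions$start),
                   c(c1$regions$end, c2$regions$end), g, "union")
  expect_equal(tab[1, 1], bf_count_once(s1$regions, un$regions))
  expect_equal(tab[2, 1], bf_count_once(s2$regions, un$regions))
  expect_equal(sum(tab[1, ]), n_regions(s1))
  expect_equal(sum(tab[2, ]), n_regions(s2))
  tab_all <- colocalization_table(s1, s2, list(c1, c2), mode = "all")
  expect_equal(tab_all[1, 1],
               sum(bf_flags(s1$regions, c1$regions) & bf_flags(s1$regions, c2$regions)))
  expect_error(colocalization_table(s1, s2, list()), "at least one companion")
})

test_that("whole-genome companions saturate the table and chi-square then errors", {
  g <- toy_genome()
  s1 <- rand_region_set(g, 10, name = "s1")
  s2 <- rand_region_set(g, 10, name = "s2")
  whole <- region_set(g$chrom, rep(0, 3), unname(g$length), g, "whole")
  tab <- colocalization_table(s1, s2, list(whole))
  expect_equal(tab[1, 2], 0L)
  expect_equal(tab[2, 2], 0L)
  expect_error(yates_chi2(tab), "zero margin")
})

test_that("Yates chi-square matches the closed form and stats::chisq.test", {
  fix <- yates_chi2(matrix(c(30, 70, 10, 90), 2, byrow = TRUE))
  expect_equal(fix$statistic, 11.28125, tolerance = 1e-12)
  expect_equal(fix$df, 1L)
  # perfectly proportional table: continuity term clamps at zero
  expect_equal(yates_chi2(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_error(yates_chi2(matrix(c(5, 0, 5, 0), 2, byrow = TRUE)), "zero margin")
  set.seed(123)
  for (rep in 1:100) {
    m <- matrix(sample.int(200, 4, replace = TRUE), 2)
    ours <- yates_chi2(m)
    ref <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
})
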