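test_that("toy overlap counts match the hand-checked example", {
  g <- genome_def(c("chr1", "chr2"), c(1000, 500))
  q <- region_set(c("chr1", "chr1", "chr2"), c(100, 300, 50), c(200, 400, 60), g, "q")
  r <- region_set(c("chr1", "chr2"), c(150, 100), c(160, 200), g, "r")
  oc <- overlap_count(q, r)
  expect_equal(oc$n_overlapping, 1L)
  expect_equal(oc$n_query, 3L)
  expect_equal(overlap_fraction(q, r), 1 / 3)
  kept <- filter_overlapping(q, r, "overlapping")
  expect_equal(kept$regions$start, 100)
  expect_equal(kept$regions$end, 200)
})

test_that("degenerate overlap cases behave as stated", {
  g <- genome_def("chr1", 1000)
  q <- region_set(c("chr1", "chr1"), c(10, 500), c(20, 600), g, "q")
  empty <- region_set(character(), numeric(), numeric(), g, "empty")
  expect_equal(overlap_count(q, q)$n_overlapping, n_regions(q))  # self-overlap
  expect_equal(overlap_count(q, empty)$n_overlapping, 0L)
  expect_error(overlap_fraction(empty, q), "empty query")
  expect_equal(n_regions(filter_overlapping(q, q, "non_overlapping")), 0L)
  expect_equal(n_regions(filter_overlapping(q, empty, "overlapping")), 0L)
  # bookended intervals share no base under half-open arithmetic
  a <- region_set("chr1", 100, 200, g, "a")
  b <- region_set("chr1", 200, 300, g, "b")
  expect_equal(overlap_count(a, b)$n_overlapping, 0L)
  # mismatched genomes are refused
  g2 <- genome_def("chr1", 999)
  expect_error(overlap_count(q, region_set("chr1", 1, 2, g2)), "different genomes")
})

test_that("sweep counting agrees exactly with the brute-force oracle", {
  set.seed(101)
  g <- toy_genome()
  for (rep in 1:220) {
    q <- rand_region_set(g, sample.int(200, 1), max_len = sample(c(5, 40, 120), 1))
    r <- rand_region_set(g, sample.int(200, 1), max_len = sample(c(5, 40, 120), 1))
    expect_identical(overlap_count(q, r)$n_overlapping,
                     bf_count_once(q$regions, r$regions))
  }
})

test_that("min_overlap_bp and pairwise counting agree with brute force", {
  set.seed(202)
  g <- toy_genome()
  for (rep in 1:40) {
    q <- rand_region_set(g, sample.int(60, 1), max_len = 60)
    r <- rand_region_set(g, sample.int(60, 1), max_len = 60)
    m <- sample.int(20, 1)
    expect_identical(overlap_count(q, r, min_overlap_bp = m)$n_overlapping,
                     bf_count_once(q$regions, r$regions, min_bp = m))
    expect_identical(overlap_count(q, r, count = "pairs")$n_overlapping,
                     bf_count_pairs(q$regions, r$regions))
  }
})

test_that("overlap counting is monotone in the reference set", {
  set.seed(303)
  g <- toy_genome()
  for (rep in 1:30) {
    q <- rand_region_set(g, 50)
    r1 <- rand_region_set(g, 30)
    extra <- rand_region_set(g, 20)
    r2 <- region_set(c(r1$regions$chrom, extra$regions$chrom),
                     c(r1$regions$start, extra$regions$start),
                     c(r1$regions$end, extra$regions$end), g, "r2")
    expect_gte(overlap_count(q, r2)$n_overlapping,
               overlap_count(q, r1)$n_overlapping)
  }
})

test_that("filter partition identity holds on random inputs", {
  set.seed(404)
  g <- toy_genome()
  for (rep in 1:30) {
    q <- rand_region_set(g, sample.int(80, 1))
    r <- rand_region_set(g, sample.int(80, 1))
    n_in <- n_regions(filter_overlapping(q, r, "overlapping"))
    n_out <- n_regions(filter_overlapping(q, r, "non_overlapping"))
    expect_equal(n_in + n_out, n_regions(q))
    oracle <- q$regions[bf_flags(q$regions, r$regions), 1:3]
    rownames(oracle) <- NULL
    expect_identical(filter_overlapping(q, r, "overlapping")$regions[, 1:3], oracle)
  }
})

test_that("merge is idempotent, minimal, and merges adjacent intervals", {
  g <- genome_def("chr1", 1000)
  m1 <- merge_regions(region_set(c("chr1", "chr1"), c(100, 150), c(200, 250), g))
  expect_equal(m1$regions$start, 100)
  expect_equal(m1$regions$end, 250)
  m2 <- merge_regions(region_set(c("chr1", "chr1"), c(100, 200), c(200, 300), g))
  expect_equal(nrow(m2$regions), 1L)  # half-open adjacency merges
  expect_equal(m2$regions$end, 300)
  disj <- region_set(c("chr1", "chr1"), c(10, 500), c(20, 600), g)
  expect_identical(merge_regions(disj)$regions[, 1:3], disj$regions[, 1:3])
  mm <- merge_regions(merge_regions(rand_region_set(g, 40)))
  expect_identical(mm$regions[, 1:3], merge_regions(mm)$regions[, 1:3])
})

test_that("coverage agrees with per-base oracle and ignores record order", {
  set.seed(505)
  g <- toy_genome()
  for (rep in 1:60) {
    rs <- rand_region_set(g, sample.int(50, 1))
    expect_equal(coverage_bp(rs), bf_coverage(rs$regions, g))
    perm <- sample(n_regions(rs))
    shuffled <- region_set(rs$regions$chrom[perm], rs$regions$start[perm],
                           rs$regions$end[perm], g)
    expect_equal(coverage_bp(shuffled), coverage_bp(rs))
  }
  expect_equal(coverage_bp(region_set(character(), numeric(), numeric(), g)), 0)
  expect_equal(coverage_bp(region_set("chrA", 0, 1000, g)), 1000)
})
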