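test_that("sample_regions honors counts, length models and determinism", {
  g <- genome_def(c("chr1", "chr2"), c(1e6, 5e5))
  expect_equal(n_regions(sample_regions(g, 0, seed = 1)), 0L)
  fx <- sample_regions(g, 50, length_model("fixed", 300), seed = 2)
  expect_true(all(fx$regions$end - fx$regions$start == 300))
  un <- sample_regions(g, 200, length_model("uniform", min = 100, max = 200), seed = 3)
  lens <- un$regions$end - un$regions$start
  expect_true(all(lens >= 100 & lens <= 200))
  ln <- sample_regions(g, 100, length_model("lognormal", meanlog = 5.5, sdlog = 0.5,
                                            min = 100, max = 1000), seed = 4)
  lens <- ln$regions$end - ln$regions$start
  expect_true(all(lens >= 100 & lens <= 1000))
  expect_identical(sample_regions(g, 40, seed = 9)$regions,
                   sample_regions(g, 40, seed = 9)$regions)
})

test_that("chromosome choice frequencies are proportional to placeable length", {
  g <- genome_def(c("chr1", "chr2", "chr3"), c(6e5, 3e5, 1e5))
  rs <- sample_regions(g, 10000, length_model("fixed", 100), seed = 5)
  counts <- table(factor(rs$regions$chrom, levels = g$chrom))
  p <- (g$length - 100 + 1) / sum(g$length - 100 + 1)
  for (i in 1:3) {
    se <- sqrt(10000 * p[i] * (1 - p[i]))
    expect_lt(abs(counts[i] - 10000 * p[i]), 3 * se)
  }
})

test_that("planted queries always overlap their anchors; f bounds the overlap fraction", {
  cfg <- synthetic_config(planted_fraction = 1, jitter = 0, seed = 6)
  sc <- make_scenario("enriched", cfg)
  expect_equal(overlap_fraction(sc$query, sc$reference), 1)
  # jittered planting still guarantees >= 1 bp by clipping
  cfg2 <- synthetic_config(planted_fraction = 1, jitter = 5000, seed = 7)
  sc2 <- make_scenario("enriched", cfg2)
  expect_equal(overlap_fraction(sc2$query, sc2$reference), 1)
})

test_that("unplanted queries overlap at the analytic background collision rate", {
  # an unplanted query of length Lq hits a reference interval of length Lr
  # with probability ~ (Lq + Lr - 1) / G; aggregate over the reference set
  cfg <- synthetic_config(planted_fraction = 0, n_query = 2000, seed = 8)
  sc <- make_scenario("enriched", cfg)
  q <- sc$query; r <- sc$reference
  G <- genome_length(cfg$genome)
  lq <- mean(q$regions$end - q$regions$start)
  p_hit <- (coverage_bp(r) + n_regions(r) * (lq - 1)) / G  # union approximation
  obs <- overlap_count(q, r)$n_overlapping
  se <- sqrt(n_regions(q) * p_hit * (1 - p_hit))
  expect_lt(abs(obs - n_regions(q) * p_hit), 4 * se + 2)
})

test_that("truth vector planted counts are binomially consistent with f", {
  cfg <- synthetic_config(planted_fraction = 0.5, n_query = 1000, seed = 9)
  sc <- make_scenario("enriched", cfg)
  k <- sum(sc$query$regions$planted)
  expect_lt(abs(k - 500), 3 * sqrt(1000 * 0.25))
  # planted flags travel with their intervals through sorting
  planted_rows <- sc$query$regions[sc$query$regions$planted, ]
  ps <- region_set(planted_rows$chrom, planted_rows$start, planted_rows$end,
                   cfg$genome, "planted")
  expect_equal(overlap_fraction(ps, sc$reference), 1)
})

test_that("scenario bundles are reproducible and match their contracts", {
  cfg <- synthetic_config(seed = 10)
  a <- make_scenario("differential", cfg)
  b <- make_scenario("differential", cfg)
  expect_identical(a$reference$regions, b$reference$regions)
  expect_identical(a$query_1$regions, b$query_1$regions)
  expect_identical(a$query_2$regions, b$query_2$regions)
  expect_false(any(a$query_2$regions$planted))  # query_2 unplanted
  nl <- make_scenario("null", cfg)
  expect_false(any(nl$query_1$regions$planted) || any(nl$query_2$regions$planted))
  expect_error(synthetic_config(planted_fraction = 1.2), "planted_fraction")
  expect_error(synthetic_config(genome = c(chr1 = 100),
                                lengths = length_model("fixed", 500)),
               "exceed")
})

test_that("write_scenario produces a self-contained chrom.sizes + BED + truth bundle", {
  dir <- withr::local_tempdir()
  sc <- make_scenario("differential", synthetic_config(n_reference = 40, n_query = 30,
                                                       seed = 11))
  write_scenario(sc, dir)
  g <- read_chrom_sizes(file.path(dir, "genome.chrom.sizes"))
  expect_identical(g$chrom, sc$genome$chrom)
  q1 <- read_bed(file.path(dir, "query_1.bed"), g)
  expect_equal(n_regions(q1), 30L)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_setequal(unique(truth$set), c("query_1", "query_2"))
})
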