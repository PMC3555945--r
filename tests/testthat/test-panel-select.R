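test_that("quota allocation is proportional with exact class totals", {
  parts <- chrom_partition(c("c1", "c2"), c(1000000L, 1000000L),
                           c(400001L, 400001L), c(600000L, 600000L))
  plan <- allocate_quotas(parts, w_euch = 10L, w_het = 4L)
  e <- plan[plan$region_class == "euchromatic", ]
  expect_equal(e$quota, c(5L, 5L))                      # symmetry
  expect_equal(sum(plan$quota[plan$region_class == "heterochromatic"]), 4L)

  # largest remainder: W=1 over three chromosomes goes to the largest rest
  parts3 <- chrom_partition(c("a", "b", "c"), c(500000L, 300000L, 200000L),
                            c(100001L, 100001L, 50001L),
                            c(200000L, 150000L, 100000L))
  plan3 <- allocate_quotas(parts3, w_euch = 1L, w_het = 1L)
  e3 <- plan3[plan3$region_class == "euchromatic", ]
  expect_equal(sum(e3$quota), 1L)
  expect_equal(e3$quota[which.max(e3$raw - floor(e3$raw))], 1L)
})

test_that("published per-chromosome quota arithmetic reproduces at the stated density", {
  lens <- read.delim(system.file("extdata", "soybean_chrom_region_lengths.tsv",
                                 package = "panelforge"), comment.char = "#")
  gm02 <- lens$euchromatic_bp[lens$chrom == "Gm02"]
  expect_equal(gm02, 26316426L)
  expect_equal(expected_count_at_density(gm02, 111.3), 2929L)
})

test_that("thinning follows the smallest-gap / smallest-index rule", {
  # smallest gap 10-20; flanking indices 0.5 vs 0.9 -> drop the 0.5
  expect_equal(thin_by_iteration(c(10, 100, 200), c(0.5, 0.9, 0.7), 3), 1:3)
  expect_equal(thin_by_iteration(c(10, 20, 100), c(0.5, 0.9, 0.7), 2),
               c(2L, 3L))
  # tied indices: middle SNP has the smaller other-gap; terminal is unbounded
  expect_equal(thin_by_iteration(c(0, 10, 20), c(0.8, 0.8, 0.9), 2),
               c(1L, 3L))
  # quota == input -> identity; quota > input warns and keeps all
  expect_equal(thin_by_iteration(c(1, 5, 9), c(0.1, 0.2, 0.3), 3), 1:3)
  expect_warning(keep <- thin_by_iteration(c(1, 5), c(0.1, 0.2), 5),
                 "exceeds")
  expect_equal(keep, 1:2)
  expect_equal(thin_by_iteration(c(1, 5), c(0.1, 0.2), 0), integer(0))
  expect_error(thin_by_iteration(c(5, 1), c(0.1, 0.2), 1), "sorted")
})

random_thin_fixture <- function(seed, n_max = 120L) {
  withr::with_seed(seed, {
    n <- sample(5:n_max, 1L)
    # coarse grid creates plenty of tied gaps; coarse indices tie too
    pos <- sort(sample.int(n * 8L, n)) * 5L
    index <- sample(seq(0.1, 1, by = 0.1), n, replace = TRUE)
    quota <- sample.int(n, 1L)
    list(pos = pos, index = index, quota = quota)
  })
}

test_that("heap-based thinning equals the naive re-scan oracle", {
  for (s in 1:60) {
    f <- random_thin_fixture(s)
    expect_equal(thin_by_iteration(f$pos, f$index, f$quota),
                 naive_thin(f$pos, f$index, f$quota),
                 info = sprintf("seed %d", s))
  }
  # engineered pathological ties: equidistant SNPs, identical indices
  expect_equal(thin_by_iteration(seq(0, 90, by = 10), rep(0.5, 10), 3),
               naive_thin(seq(0, 90, by = 10), rep(0.5, 10), 3))
})

test_that("removed SNPs never out-rank the partner flanking the same gap", {
  # selected-set mean index should (statistically) exceed the input mean
  better <- 0L
  for (s in 1:40) {
    f <- random_thin_fixture(s + 500L)
    keep <- thin_by_iteration(f$pos, f$index, f$quota)
    if (mean(f$index[keep]) >= mean(f$index) - 1e-12) better <- better + 1L
  }
  expect_gte(better / 40, 0.95)
})

test_that("thinning evens spacing relative to random removal", {
  wins <- 0L
  for (s in 1:30) {
    f <- withr::with_seed(s, {
      pos <- sort(sample.int(100000L, 300L))
      list(pos = pos, index = runif(300), quota = 80L)
    })
    keep <- thin_by_iteration(f$pos, f$index, f$quota)
    rand <- withr::with_seed(s + 1000L, sort(sample.int(300L, f$quota)))
    if (sd(diff(f$pos[keep])) < sd(diff(f$pos[rand]))) wins <- wins + 1L
  }
  expect_gte(wins / 30, 0.9)
})

test_that("scaffold selection ranks by length and round-robins the budget", {
  cat1 <- make_catalog(paste0("s", 1:6),
                       rep(c("scafA", "scafB", "scafC"), each = 2L),
                       rep(c(100L, 900L), 3L), "A", "G")
  cat1$index_score <- c(0.9, 0.5, 0.4, 0.8, 0.6, 0.3)
  lens <- c(scafA = 20000L, scafB = 50000L, scafC = 30000L)
  # budget 3: one best SNP per scaffold, longest scaffold first
  sel3 <- select_scaffold_snps(cat1, lens, 3L)
  expect_equal(sel3$id, c("s4", "s5", "s1"))  # B (0.8), C (0.6), A (0.9)
  # two scaffolds, budget 3: longest contributes its second-best
  cat2 <- cat1[cat1$chrom != "scafC", , drop = FALSE]
  sel <- select_scaffold_snps(cat2, lens[c("scafA", "scafB")], 3L)
  expect_equal(sum(sel$chrom == "scafB"), 2L)
  expect_equal(sum(sel$chrom == "scafA"), 1L)
  expect_equal(nrow(select_scaffold_snps(cat1, lens, 0L)), 0L)
})

test_that("build_panel meets quotas, logs shortfalls and matches the oracle", {
  specs <- data.frame(name = c("chr1", "chr2", "chr3"),
                      length = c(200000L, 150000L, 120000L),
                      het_start = c(80001L, 60001L, 50001L),
                      het_end = c(140000L, 100000L, 80000L))
  ref <- generate_reference(31, specs)
  gen <- generate_candidates(31, ref, density_euch = 2000, density_het = 800,
                             clustered_fraction = 0, bad_type_fraction = 0,
                             nflank_fraction = 0, pool_bad_fraction = 0,
                             paralog_fraction = 0)
  cat1 <- gen$catalog
  cat1$index_score <- withr::with_seed(1, round(runif(nrow(cat1), 0.3, 1), 2))
  panel <- build_panel(cat1, ref$partitions, w_euch = 120L, w_het = 24L)
  expect_s3_class(panel, "snp_panel")
  expect_equal(nrow(panel$selected), 144L)
  counts <- table(panel$selected$region_class)
  expect_equal(unname(counts[["euchromatic"]]), 120L)
  expect_equal(unname(counts[["heterochromatic"]]), 24L)
  expect_true(all(panel$selected$id %in% cat1$id))

  # per chrom x region the heap path equals the naive oracle end to end
  plan <- panel$quota_plan
  for (r in seq_len(nrow(plan))) {
    sub <- cat1[cat1$chrom == plan$chrom[r], , drop = FALSE]
    rc <- region_class(ref$partitions, plan$chrom[r], sub$pos)
    sub <- sub[rc == plan$region_class[r], , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    keep <- naive_thin(sub$pos, sub$index_score, plan$quota[r])
    got <- panel$selected$id[panel$selected$chrom == plan$chrom[r] &
                               panel$selected$region_class == plan$region_class[r]]
    expect_setequal(got, sub$id[keep])
  }

  # a region with fewer candidates than quota keeps everything, with warning
  few <- cat1[cat1$chrom == "chr1", , drop = FALSE][1:5, ]
  expect_warning(
    p2 <- build_panel(few, ref$partitions[1, ], w_euch = 50L, w_het = 10L),
    "fewer candidates")
  expect_lte(nrow(p2$selected), 5L)
  expect_gt(nrow(p2$shortfalls), 0L)
})
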