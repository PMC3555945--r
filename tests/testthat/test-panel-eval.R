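test_that("gap statistics are computed within regions and skip singletons", {
  snps <- data.frame(chrom = "c1", pos = c(0L, 10L, 30L) + 1L,
                     region_class = "euchromatic")
  gs <- gap_statistics(snps)
  expect_equal(gs$gaps$gap, c(10L, 20L))
  expect_equal(gs$overall$mean_gap, 15)

  even <- data.frame(chrom = "c1", pos = seq(100L, 1000L, by = 100L),
                     region_class = "all")
  expect_equal(gap_statistics(even)$overall$sd_gap, 0)

  single <- data.frame(chrom = c("c1", "c1", "c2"), pos = c(1L, 50L, 10L),
                       region_class = "all")
  expect_message(gs2 <- gap_statistics(single), "skipped")
  expect_equal(gs2$skipped$chrom, "c2")
})

test_that("euchromatic arms never share a gap across the heterochromatin", {
  part <- chrom_partition("c1", 100000L, 40001L, 60000L)
  snps <- data.frame(chrom = "c1",
                     pos = c(10000L, 20000L, 30000L, 70000L, 80000L, 90000L))
  gs <- gap_statistics(snps, part)
  # without arm-splitting there would be a 40-kb spanning gap
  expect_equal(sort(gs$gaps$gap), rep(10000L, 4L))
})

write_test_gff <- function(path) {
  writeLines(c(
    "##gff-version 3",
    # plus-strand gene with CDS, UTRs, two exons
    "c1\ttest\tgene\t10000\t12000\t.\t+\t.\tID=geneP",
    "c1\ttest\texon\t10000\t10500\t.\t+\t.\tParent=geneP",
    "c1\ttest\texon\t11000\t12000\t.\t+\t.\tParent=geneP",
    "c1\ttest\tfive_prime_UTR\t10000\t10100\t.\t+\t.\tParent=geneP",
    "c1\ttest\tCDS\t10101\t10500\t.\t+\t0\tParent=geneP",
    "c1\ttest\tCDS\t11000\t11800\t.\t+\t0\tParent=geneP",
    "c1\ttest\tthree_prime_UTR\t11801\t12000\t.\t+\t.\tParent=geneP",
    # minus-strand gene: upstream lies at higher coordinates
    "c1\ttest\tgene\t30000\t32000\t.\t-\t.\tID=geneM",
    "c1\ttest\texon\t30000\t32000\t.\t-\t.\tParent=geneM",
    "c1\ttest\tCDS\t30000\t32000\t.\t-\t0\tParent=geneM"), path)
  path
}

test_that("genic annotation applies the precedence and strand conventions", {
  gff <- write_test_gff(withr::local_tempfile(fileext = ".gff3"))
  models <- read_gene_models(gff)
  snps <- data.frame(
    chrom = "c1",
    pos = c(10300L,  # CDS
            10050L,  # 5'UTR
            11900L,  # 3'UTR
            10700L,  # between exons -> intron
            9000L,   # 1000 bp 5' of plus-strand gene -> upstream
            33500L,  # 1500 bp above minus-strand gene end -> upstream
            29500L,  # 500 bp below minus-strand gene start -> downstream
            14001L,  # 2001 bp past geneP end -> intergenic
            50000L)) # far away
  cls <- annotate_genic(snps, models)
  expect_equal(cls, c("CDS", "5'UTR", "3'UTR", "intron", "2kb-upstream",
                      "2kb-upstream", "2kb-downstream", "intergenic",
                      "intergenic"))
  # classes partition the set: exactly one class per SNP
  expect_length(cls, nrow(snps))
  expect_warning(annotate_genic(data.frame(chrom = "cX", pos = 1L), models),
                 "absent")
})

test_that("call-rate bins, rates and correlations behave per contract", {
  # two populated bins with rates 0.5 and 1.0 -> correlation exactly 1
  outcomes <- data.frame(snp_id = sprintf("s%d", 1:40),
                         success = rep(c(TRUE, FALSE, TRUE, TRUE),
                                       each = 10L))
  scores <- data.frame(snp_id = sprintf("s%d", 1:40),
                       score = rep(c(0.45, 0.45, 0.95, 0.95), each = 10L))
  res <- call_rate_by_bins(outcomes, scores)
  filled <- res$bins[res$bins$n_success + res$bins$n_fail > 0, ]
  expect_equal(filled$rate, c(0.5, 1.0))
  expect_equal(res$correlation, 1.0)
  expect_true(any(grepl("empty bin", res$note)))

  # all successes: rate 1 everywhere, correlation undefined, reported as such
  res2 <- call_rate_by_bins(
    data.frame(snp_id = c("a", "b"), success = TRUE),
    data.frame(snp_id = c("a", "b"), score = c(0.5, 0.95)))
  expect_true(is.na(res2$correlation))
  expect_true(any(grepl("undefined", res2$note)))
})

test_that("success probability increasing with score yields positive correlation", {
  pos_cor <- 0L
  for (s in 1:30) {
    dat <- withr::with_seed(s, {
      score <- runif(300)
      success <- runif(300) < 0.55 + 0.4 * score
      list(score = score, success = success)
    })
    res <- call_rate_by_bins(
      data.frame(snp_id = seq_len(300), success = dat$success),
      data.frame(snp_id = seq_len(300), score = dat$score))
    if (!is.na(res$correlation) && res$correlation > 0) pos_cor <- pos_cor + 1L
  }
  expect_gte(pos_cor / 30, 0.95)
})

test_that("MAF respects call-based frequencies and bin edge conventions", {
  calls <- rbind(rep("AA", 10),                      # MAF 0
                 c(rep("AA", 4), rep("BB", 6)),      # p_alt 0.6 -> MAF 0.4
                 c("AB", rep("AA", 9)),              # MAF 0.05 boundary
                 c("AA", "BB", rep(NA, 8)))          # only 2 calls -> MAF 0.5
  colnames(calls) <- sprintf("s%02d", 1:10)
  gm <- genotype_matrix(calls,
                        data.frame(id = sprintf("l%d", 1:4), chrom = "c",
                                   pos = 1:4 * 100L),
                        setNames(rep("pop", 10), colnames(calls)))
  prof <- maf_profile(gm, "pop")
  expect_equal(unname(prof$maf), c(0, 0.4, 0.05, 0.5))
  expect_true(all(prof$maf <= 0.5))
  b <- prof$bins
  expect_equal(b$count[b$bin == "[0.00,0.05)"], 1L)   # MAF 0
  expect_equal(b$count[b$bin == "[0.05,0.10)"], 1L)   # 0.05 goes up, not down
  expect_equal(b$count[b$bin == "[0.40,0.50]"], 2L)   # 0.4 and the closed 0.5
  expect_equal(sum(b$count), prof$n_loci)             # totals conserved
})

test_that("genetic distance is the differing fraction of co-called loci", {
  calls <- matrix(NA_character_, 10, 3,
                  dimnames = list(NULL, c("x", "y", "z")))
  calls[, "x"] <- c(rep("AA", 7), rep("BB", 3))
  calls[, "y"] <- c(rep("AA", 4), rep("BB", 3), rep("AA", 3))
  gm <- genotype_matrix(calls,
                        data.frame(id = sprintf("l%d", 1:10), chrom = "c",
                                   pos = 1:10),
                        c(x = "p", y = "p", z = "p"))
  expect_equal(genetic_distance(gm, "x", "y"), 6 / 10)
  expect_equal(genetic_distance(gm, "x", "x"), 0)
  expect_equal(genetic_distance(gm, "x", "y"), genetic_distance(gm, "y", "x"))
  expect_warning(d <- genetic_distance(gm, "x", "z"), "no co-called")
  expect_true(is.na(d))
})

test_that("distance distribution enumerates pairs and degenerates cleanly", {
  calls <- matrix("AA", 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  gm <- genotype_matrix(calls,
                        data.frame(id = sprintf("l%d", 1:5), chrom = "c",
                                   pos = 1:5),
                        c(a = "p", b = "p", c = "p"))
  dd <- distance_distribution(gm, "p")
  expect_equal(nrow(dd$pairs), 3L)            # n(n-1)/2
  expect_equal(dd$mean, 0)
  expect_equal(unname(dd$poly_interval), c(0, 0))
  expect_error(distance_distribution(gm, "q"), ">= 2 samples")
})

test_that("mean distance recovers generator truth on simulated populations", {
  pp <- generate_populations(41, n_pops = 1L, n_samples = 30L, n_loci = 1500L,
                             target_fst = 0, pop_names = "land",
                             missing_rate = 0)
  dd <- distance_distribution(pp$gm, "land")
  # fully inbred, no drift: P(differ at locus) = 2 p (1-p)
  p <- pp$truth$ancestral
  expected <- mean(2 * p * (1 - p))
  se <- dd$sd / sqrt(nrow(dd$pairs))
  expect_lt(abs(dd$mean - expected), max(4 * se, 0.01))
})
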