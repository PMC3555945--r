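test_that("assay-type filter removes A/T, G/C and indels in any orientation", {
  cat1 <- make_catalog(paste0("s", 1:6), "chr1",
                       c(100L, 200L, 300L, 400L, 500L, 600L),
                       ref = c("A", "T", "C", "G", "A", "A"),
                       alt = c("T", "A", "G", "C", "G", "-"))
  part <- filter_assay_type(cat1)
  expect_equal(part$removed$id, c("s1", "s2", "s3", "s4", "s6"))
  expect_equal(part$kept$id, "s5")
})

test_that("flank ambiguity window is exactly 60 nt and short flanks fail", {
  flank70 <- strrep("ACGT", 18)          # 72 nt clean
  with_n <- function(offset_from_snp) {
    # offset 1 = base adjacent to the SNP, counted leftwards
    f <- flank70
    substr(f, nchar(f) - offset_from_snp + 1L, nchar(f) - offset_from_snp + 1L) <- "N"
    f
  }
  cat1 <- make_catalog(paste0("s", 1:4), "chr1", c(100L, 200L, 300L, 400L),
                       "A", "G")
  cat1$flank_left <- c(with_n(59), with_n(61), flank70, substr(flank70, 1, 59))
  cat1$flank_right <- flank70
  part <- filter_flank_ambiguity(cat1)
  expect_equal(part$removed$id, c("s1", "s4"))  # N inside window; short flank
  expect_equal(part$kept$id, c("s2", "s3"))     # N at 61 is outside the window
})

test_that("clustering removes both members at <= 25 bp and is symmetric", {
  cat1 <- make_catalog(paste0("s", 1:5), c("chr1", "chr1", "chr1", "chr1", "chr2"),
                       c(100L, 120L, 300L, 326L, 100L), "A", "G")
  part <- filter_clustered(cat1)
  expect_equal(sort(part$removed$pos), c(100L, 120L))   # distance 20: both go
  expect_true(all(c(300L, 326L) %in% part$kept$pos))    # distance 26: boundary keeps
  expect_true(100L %in% part$kept$pos[part$kept$chrom == "chr2"])  # singleton

  # relabeling/shuffling candidates never changes which positions go
  for (s in 1:5) {
    perm <- withr::with_seed(s, sample(nrow(cat1)))
    shuffled <- cat1[perm, , drop = FALSE]
    shuffled$id <- paste0("r", seq_len(nrow(shuffled)))
    part2 <- filter_clustered(shuffled)
    expect_setequal(paste(part2$removed$chrom, part2$removed$pos),
                    paste(part$removed$chrom, part$removed$pos))
  }
})

test_that("flank uniqueness counts forward and reverse-complement hits", {
  # 2-kb genome with an exact duplicated block and a reverse-complement copy
  g <- random_genome_chars(c(chrA = 2000L), seed = 99)
  # duplicate a 200-nt block: [301,500] -> [1201,1400]
  block <- substring(g[["chrA"]], 301, 500)
  substr(g[["chrA"]], 1201, 1400) <- block
  # plant the reverse complement of [601,700] at [1601,1700]
  rcblock <- oracle_revcomp(substring(g[["chrA"]], 601, 700))
  substr(g[["chrA"]], 1601, 1700) <- rcblock
  cat1 <- catalog_on_genome(g, "chrA", c(400L, 650L, 900L))
  part <- filter_flank_uniqueness(cat1, as_dss(g))
  # 400 sits in the duplicated block; 650 has a revcomp copy; 900 is unique
  expect_setequal(part$removed$pos, c(400L, 650L))
  expect_equal(part$kept$pos, 900L)

  # exhaustive 25-mer scan oracle agrees per candidate
  kmers <- oracle_kmer_table(g, 25L)
  for (i in seq_len(nrow(cat1))) {
    l25 <- substring(cat1$flank_left[i], 36, 60)
    r25 <- substring(cat1$flank_right[i], 1, 25)
    nl <- sum(kmers == l25) + sum(kmers == oracle_revcomp(l25))
    nr <- sum(kmers == r25) + sum(kmers == oracle_revcomp(r25))
    expect_equal(cat1$pos[i] %in% part$kept$pos, nl == 1L && nr == 1L)
  }
})

test_that("flank inconsistent with the reference at its own locus errors", {
  g <- random_genome_chars(c(chrA = 2000L), seed = 7)
  cat1 <- catalog_on_genome(g, "chrA", 1000L)
  # corrupt the 25 nt adjacent to the variant so the locus check must fire
  # (the true bases at 996..999 are CGAA for this seed)
  cat1$flank_left <- paste0(substring(cat1$flank_left, 1, 56), "GGGG")
  expect_error(filter_flank_uniqueness(cat1, as_dss(g)), "data-consistency")
})

test_that("paralog and pool-consistency rules fire as specified", {
  cat1 <- make_catalog(paste0("s", 1:3), "chr1", c(100L, 200L, 300L), "A", "G")
  cat1$mixed_pool_code <- c(NA, "R", "R")
  cat1$observations <- list(obs_df("g1", "both", 4L),     # paralog signal
                            obs_df("g1", "C", 4L),        # C not in R={A,G}
                            obs_df("g1", "A", 4L))        # consistent
  part <- filter_paralog_and_pool_consistency(cat1)
  expect_equal(part$removed$id, c("s1", "s2"))
  expect_equal(part$kept$id, "s3")
})

test_that("cascade attributes each removal to the first firing rule", {
  g <- random_genome_chars(c(chr1 = 3000L), seed = 3)
  cat1 <- catalog_on_genome(g, "chr1", c(300L, 600L, 620L, 1500L, 2500L))
  # make candidate 1 an A/T type
  cat1$ref[1] <- "A"; cat1$alt[1] <- "T"
  rep <- apply_filter_cascade(cat1, as_dss(g))
  expect_equal(unname(rep$removed_by_rule[c("assay_type", "clustered")]),
               c(1L, 2L))
  expect_equal(sum(rep$removed_by_rule), 3L)
  expect_equal(length(rep$retained), 2L)
  expect_equal(rep$input_count, length(rep$retained) + sum(rep$removed_by_rule))

  # all-clean and empty catalogs
  clean <- catalog_on_genome(g, "chr1", c(300L, 1500L, 2500L))
  rep2 <- apply_filter_cascade(clean, as_dss(g))
  expect_equal(length(rep2$retained), 3L)
  expect_equal(sum(rep2$removed_by_rule), 0L)
  rep3 <- apply_filter_cascade(clean[0, ], as_dss(g))
  expect_equal(rep3$input_count, 0L)
  expect_equal(sum(rep3$removed_by_rule), 0L)
})

test_that("per-candidate rules give the same retained set in shuffled order", {
  g <- random_genome_chars(c(chr1 = 4000L, chr2 = 3000L), seed = 21)
  pos1 <- seq(200L, 3800L, by = 90L)
  cat1 <- catalog_on_genome(g, "chr1", pos1)
  withr::with_seed(11, {
    # sprinkle violations
    k <- nrow(cat1)
    cat1$alt[sample(k, 4)] <- vapply(cat1$ref[sample(k, 4)], function(b) {
      switch(b, A = "T", T = "A", C = "G", G = "C")
    }, "")
    idx <- sample(k, 3)
    cat1$observations[idx] <- list(obs_df("g1", "both", 2L))
  })
  # the three per-candidate rules commute
  perms <- list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))
  rules <- list(filter_assay_type, filter_flank_ambiguity,
                filter_paralog_and_pool_consistency)
  retained <- lapply(perms, function(p) {
    cur <- cat1
    for (r in rules[p]) cur <- r(cur)$kept
    sort(cur$id)
  })
  expect_equal(retained[[1]], retained[[2]])
  expect_equal(retained[[1]], retained[[3]])
})
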