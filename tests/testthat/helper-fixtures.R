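# small fixture builders shared across test files

make_catalog <- function(id, chrom, pos, ref, alt, design_score = 0.9, ...) {
  snp_catalog(data.frame(id = id, chrom = chrom, pos = pos, ref = ref,
                         alt = alt, design_score = design_score, ...,
                         stringsAsFactors = FALSE))
}

# catalog whose flanks genuinely come from a supplied genome string
catalog_on_genome <- function(genome_chars, chrom, pos, alt = NULL,
                              design_score = 0.9) {
  g <- genome_chars[[chrom[1]]]
  ref <- substring(g, pos, pos)
  if (is.null(alt)) {
    alt <- vapply(ref, function(b) {
      switch(b, A = "G", G = "A", C = "T", T = "C")
    }, "")
  }
  snp_catalog(data.frame(
    id = sprintf("c%03d", seq_along(pos)),
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    design_score = design_score,
    flank_left = substring(g, pos - 60, pos - 1),
    flank_right = substring(g, pos + 1, pos + 60),
    stringsAsFactors = FALSE))
}

random_genome_chars <- function(lens, seed) {
  withr::with_seed(seed, {
    setNames(vapply(lens, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, ""), names(lens))
  })
}

as_dss <- function(genome_chars) Biostrings::DNAStringSet(unlist(genome_chars))

obs_df <- function(genotype_id, allele, depth) {
  data.frame(genotype_id = genotype_id, allele = allele,
             depth = as.integer(depth), stringsAsFactors = FALSE)
}

# one-row candidate with explicit evidence, for priority-group tests
cand_with_evidence <- function(ref = "A", alt = "G", obs = empty_obs(),
                               pool = NA_character_, known = FALSE) {
  cat1 <- make_catalog("x1", "chr1", 500L, ref, alt)
  cat1$mixed_pool_code <- pool
  cat1$known_validated <- known
  cat1$observations <- list(obs)
  cat1
}

empty_obs <- function() obs_df(character(), character(), integer())

# minimal three-population matrix built by hand
tiny_gm <- function() {
  calls <- matrix(c("AA", "AA", "BB", "BB",
                    "AA", "AB", "BB", NA,
                    "BB", "BB", "AA", "AA"),
                  nrow = 3, byrow = TRUE,
                  dimnames = list(NULL, c("s1", "s2", "s3", "s4")))
  genotype_matrix(calls,
                  data.frame(id = c("l1", "l2", "l3"), chrom = "chr1",
                             pos = c(1000L, 2000L, 3000L)),
                  c(s1 = "popA", s2 = "popA", s3 = "popB", s4 = "popB"))
}
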