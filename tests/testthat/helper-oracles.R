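# Independent reference implementations used as oracles. These deliberately
# share no code with the package: plain loops, full re-scans per iteration,
# character-level genome scans.

# --- thinning: naive re-scan per iteration --------------------------------
naive_thin <- function(pos, index, quota) {
  alive <- seq_along(pos)
  while (length(alive) > quota) {
    p <- pos[alive]
    idx <- index[alive]
    gaps <- diff(p)
    g <- min(gaps)
    gi <- which(gaps == g)
    cand <- sort(unique(c(gi, gi + 1L)))
    cand <- cand[idx[cand] == min(idx[cand])]
    if (length(cand) > 1L) {
      other <- vapply(cand, function(s) {
        lg <- if (s > 1L) p[s] - p[s - 1L] else Inf
        rg <- if (s < length(p)) p[s + 1L] - p[s] else Inf
        adj <- c(lg, rg)
        k <- which(adj == g)
        if (length(k) >= 2L) g else min(adj[-k[1L]])
      }, numeric(1))
      cand <- cand[other == min(other)]
      if (length(cand) > 1L) cand <- cand[which.min(p[cand])]
    }
    alive <- alive[-cand[1L]]
  }
  alive
}

# --- filter cascade: brute force on character vectors ---------------------
ORACLE_IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# all (overlapping) k-mers of every sequence in a named character vector
oracle_kmer_table <- function(genome_chars, k = 25L) {
  unlist(lapply(genome_chars, function(g) {
    n <- nchar(g)
    if (n < k) return(character(0))
    substring(g, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
}

oracle_filter_cascade <- function(catalog, genome_chars) {
  df <- as.data.frame(catalog)
  df$obs <- catalog$observations
  removed <- c(assay_type = 0L, flank_ambiguity = 0L, clustered = 0L,
               flank_uniqueness = 0L, paralog_pool = 0L)
  # 1. assay type
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    r <- df$ref[i]; a <- df$alt[i]
    snv <- r %in% c("A", "C", "G", "T") && a %in% c("A", "C", "G", "T")
    bad_pair <- (r == "A" && a == "T") || (r == "T" && a == "A") ||
      (r == "C" && a == "G") || (r == "G" && a == "C")
    keep[i] <- snv && !bad_pair
  }
  removed["assay_type"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  # 2. flank ambiguity within 60 nt
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    fl <- df$flank_left[i]; fr <- df$flank_right[i]
    okl <- !is.na(fl) && nchar(fl) >= 60 &&
      all(strsplit(toupper(substr(fl, nchar(fl) - 59, nchar(fl))), "")[[1]] %in%
            c("A", "C", "G", "T"))
    okr <- !is.na(fr) && nchar(fr) >= 60 &&
      all(strsplit(toupper(substr(fr, 1, 60)), "")[[1]] %in%
            c("A", "C", "G", "T"))
    keep[i] <- okl && okr
  }
  removed["flank_ambiguity"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  # 3. clustered (<= 25 bp, both members)
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i != j && df$chrom[i] == df$chrom[j] &&
          abs(df$pos[i] - df$pos[j]) <= 25) keep[i] <- FALSE
    }
  }
  removed["clustered"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  # 4. flank uniqueness: each 25-mer beside the SNP occurs exactly once
  kmers <- oracle_kmer_table(genome_chars, 25L)
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    fl <- df$flank_left[i]; fr <- df$flank_right[i]
    l25 <- substr(fl, nchar(fl) - 24, nchar(fl))
    r25 <- substr(fr, 1, 25)
    nl <- sum(kmers == l25) + sum(kmers == oracle_revcomp(l25))
    nr <- sum(kmers == r25) + sum(kmers == oracle_revcomp(r25))
    keep[i] <- nl == 1L && nr == 1L
  }
  removed["flank_uniqueness"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  # 5. paralog / pool consistency
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    obs <- df$obs[[i]]
    ok <- TRUE
    if (nrow(obs)) {
      if (any(obs$allele == "both")) ok <- FALSE
      code <- df$mixed_pool_code[i]
      if (ok && !is.na(code)) {
        allowed <- ORACLE_IUPAC[[toupper(code)]]
        if (any(!toupper(obs$allele[obs$allele != "both"]) %in% allowed)) {
          ok <- FALSE
        }
      }
    }
    keep[i] <- ok
  }
  removed["paralog_pool"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  list(retained = df$id, removed_by_rule = removed)
}

# --- Weir-Cockerham two-population theta from genotype counts -------------
# scalar arithmetic straight from the variance-component definitions
oracle_wc_fst <- function(nAA1, nAB1, nBB1, nAA2, nAB2, nBB2) {
  n1 <- nAA1 + nAB1 + nBB1
  n2 <- nAA2 + nAB2 + nBB2
  p1 <- (2 * nBB1 + nAB1) / (2 * n1)   # alt-allele frequency
  p2 <- (2 * nBB2 + nAB2) / (2 * n2)
  h1 <- nAB1 / n1
  h2 <- nAB2 / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}
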