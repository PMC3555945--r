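# synthetic_data: seeded generators for every pipeline input. Each
# generator is a pure function of (seed, parameters): identical calls give
# identical objects, and each returns a `truth` record sufficient to
# compute the expected output of the stage it feeds.

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a synthetic reference genome
#'
#' Random nucleotide chromosomes with known heterochromatic intervals,
#' optional unanchored scaffolds, and an optional planted duplicated block
#' (a 2-kb segment copied to a second locus) to exercise the
#' flank-uniqueness filter.
#'
#' @param seed RNG seed.
#' @param chrom_specs data.frame with `name`, `length`, `het_start`,
#'   `het_end` (lengths >= 10 kb).
#' @param n_scaffolds number of unanchored scaffolds.
#' @param scaffold_length_range length range the scaffolds are drawn from.
#' @param dup_block_len if > 0, a block of this length from the first
#'   chromosome is copied to a second position on the same chromosome.
#' @return list: `sequences` ([Biostrings::DNAStringSet]), `partitions`
#'   ([chrom_partition()]), `scaffold_lengths` (named), `truth` (het
#'   intervals, duplicated-block coordinates).
#' @export
generate_reference <- function(seed, chrom_specs,
                               n_scaffolds = 0L,
                               scaffold_length_range = c(10000L, 30000L),
                               dup_block_len = 0L) {
  stopifnot(all(chrom_specs$length >= 10000L))
  with_seed(sub_seed(seed, "reference"), {
    seqs <- lapply(chrom_specs$length, random_dna)
    names(seqs) <- chrom_specs$name
    dup <- NULL
    if (dup_block_len > 0L) {
      ch <- 1L
      len <- chrom_specs$length[ch]
      src <- sample.int(len %/% 3L - dup_block_len, 1L) + 100L
      dst <- sample.int(len %/% 3L - dup_block_len, 1L) + 2L * (len %/% 3L)
      block <- substr(seqs[[ch]], src, src + dup_block_len - 1L)
      substr(seqs[[ch]], dst, dst + dup_block_len - 1L) <- block
      dup <- list(chrom = chrom_specs$name[ch], src = src, dst = dst,
                  len = dup_block_len)
    }
    scaffold_lengths <- integer(0)
    if (n_scaffolds > 0L) {
      slen <- sample(scaffold_length_range[1]:scaffold_length_range[2],
                     n_scaffolds, replace = TRUE)
      snames <- sprintf("scaffold_%03d", seq_len(n_scaffolds))
      sseqs <- lapply(slen, random_dna)
      names(sseqs) <- snames
      seqs <- c(seqs, sseqs)
      scaffold_lengths <- setNames(as.integer(slen), snames)
    }
    list(sequences = Biostrings::DNAStringSet(unlist(seqs)),
         partitions = chrom_partition(chrom_specs$name, chrom_specs$length,
                                      chrom_specs$het_start,
                                      chrom_specs$het_end),
         scaffold_lengths = scaffold_lengths,
         truth = list(chrom_specs = chrom_specs, dup_block = dup))
  })
}

pick_other_base <- function(base, avoid_pairs = TRUE) {
  # a substitution partner that keeps the SNP assayable (no A/T, no G/C)
  opts <- switch(base, A = c("C", "G"), T = c("C", "G"),
                 C = c("A", "T"), G = c("A", "T"))
  sample(opts, 1L)
}

transversion_partner <- function(base) {
  # partner that makes the SNP A/T or G/C (assay-incompatible)
  switch(base, A = "T", T = "A", C = "G", G = "C")
}

make_observations <- function(alt, group, pool_needed) {
  # evidence consistent with an intended priority class
  n_geno <- switch(group, A = sample(1:2, 1L), B = sample(2:4, 1L),
                   C = 1L, D = 1L)
  depth <- switch(group,
                  A = sample(1:6, n_geno, replace = TRUE),
                  B = sample(1:8, n_geno, replace = TRUE),
                  C = sample(4:12, 1L),
                  D = sample(1:2, 1L))
  data.frame(genotype_id = sprintf("g%02d", sample(1:8, n_geno)),
             allele = rep(alt, n_geno), depth = as.integer(depth),
             stringsAsFactors = FALSE)
}

#' Generate a candidate SNP catalog with planted filter violations
#'
#' Candidates are placed along each chromosome by a Poisson process with a
#' per-region-class density; flanks are taken from the reference so they
#' are genuinely present (and, outside the planted duplicated block,
#' unique with overwhelming probability in random sequence). Stated
#' fractions of candidates are planted as rule violators: A/T or G/C allele
#' pairs, close pairs (`<= 25` bp apart), N-containing flanks,
#' pool-inconsistent observations and paralog-like ("both alleles in one
#' genotype") evidence. Every candidate carries a truth label.
#'
#' @param seed RNG seed.
#' @param reference list from [generate_reference()].
#' @param density_euch,density_het expected candidates per Mb in
#'   euchromatic/heterochromatic regions (the 5:1 default ratio mirrors the
#'   recombination-based design ratio).
#' @param group_probs priority-class mix of clean candidates; the default is
#'   the A/B/C/D composition of a realistic discovery set (16/34/40/10%).
#' @param design_shape `rbeta` shape parameters for the vendor design score.
#' @param clustered_fraction,bad_type_fraction,nflank_fraction,
#'   pool_bad_fraction,paralog_fraction violator fractions.
#' @param scaffold_density candidates per Mb on scaffolds.
#' @return list: `catalog` ([snp_catalog()]), `truth` (data.frame id,
#'   violation, intended_group).
#' @export
generate_candidates <- function(seed, reference,
                                density_euch = 500, density_het = 100,
                                group_probs = c(A = 0.16, B = 0.34,
                                                C = 0.40, D = 0.10),
                                design_shape = c(5, 1.5),
                                clustered_fraction = 0.05,
                                bad_type_fraction = 0.12,
                                nflank_fraction = 0.03,
                                pool_bad_fraction = 0.03,
                                paralog_fraction = 0.03,
                                scaffold_density = 200) {
  parts <- reference$partitions
  seqs <- reference$sequences
  with_seed(sub_seed(seed, "candidates"), {
    place <- function(chrom, lo, hi, density_per_mb) {
      span <- hi - lo + 1
      n <- rpois(1L, span / 1e6 * density_per_mb)
      if (!n) return(integer(0))
      sort(sample(seq.int(lo, hi), min(n, span), replace = FALSE))
    }
    rows <- list()
    margin <- 100L  # keep full flanks inside the sequence, incl. close pairs
    for (r in seq_len(nrow(parts))) {
      ch <- parts$chrom[r]; len <- parts$length_bp[r]
      hs <- parts$het_start[r]; he <- parts$het_end[r]
      pos <- c(place(ch, margin, max(hs - 1L, margin), density_euch),
               place(ch, hs, he, density_het),
               place(ch, min(he + 1L, len - margin), len - margin, density_euch))
      pos <- sort(unique(pos[pos >= margin & pos <= len - margin]))
      if (length(pos)) rows[[ch]] <- data.frame(chrom = ch, pos = pos)
    }
    for (sc in names(reference$scaffold_lengths)) {
      len <- reference$scaffold_lengths[[sc]]
      pos <- place(sc, margin, len - margin, scaffold_density)
      if (length(pos)) rows[[sc]] <- data.frame(chrom = sc, pos = pos)
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    # enforce > 25 bp spacing among the base set; planted pairs added later
    keep <- unlist(tapply(seq_len(nrow(df)), df$chrom, function(ix) {
      p <- df$pos[ix]
      ok <- rep(TRUE, length(p))
      last <- -Inf
      for (i in seq_along(p)) {
        if (p[i] - last <= 25) ok[i] <- FALSE else last <- p[i]
      }
      ix[ok]
    }), use.names = FALSE)
    df <- df[sort(keep), , drop = FALSE]
    # stay clear of the duplicated block except for planted dup-flank cases
    dup <- reference$truth$dup_block
    if (!is.null(dup)) {
      in_dup <- (df$chrom == dup$chrom &
                   ((df$pos >= dup$src - 30 & df$pos <= dup$src + dup$len + 30) |
                      (df$pos >= dup$dst - 30 & df$pos <= dup$dst + dup$len + 30)))
      df <- df[!in_dup, , drop = FALSE]
    }
    n <- nrow(df)
    violation <- rep("none", n)
    planned <- c(bad_type = bad_type_fraction, nflank = nflank_fraction,
                 pool_bad = pool_bad_fraction, paralog = paralog_fraction,
                 clustered = clustered_fraction)
    avail <- seq_len(n)
    for (v in names(planned)) {
      k <- rbinom(1L, n, planned[[v]])
      k <- min(k, length(avail))
      if (!k) next
      pick <- avail[sample.int(length(avail), k)]
      violation[pick] <- v
      avail <- setdiff(avail, pick)
    }
    # candidates inside the duplicated block: non-unique flanks by design
    if (!is.null(dup)) {
      n_dup <- max(1L, rbinom(1L, n, 0.02))
      dpos <- sort(sample(seq.int(dup$src + 30L, dup$src + dup$len - 30L), n_dup))
      df <- rbind(df, data.frame(chrom = dup$chrom, pos = dpos))
      violation <- c(violation, rep("dup_flank", n_dup))
    }
    n <- nrow(df)
    ref_base <- character(n); alt <- character(n)
    flank_l <- character(n); flank_r <- character(n)
    for (i in seq_len(n)) {
      s <- seqs[[df$chrom[i]]]
      p <- df$pos[i]
      ref_base[i] <- as.character(Biostrings::subseq(s, p, p))
      alt[i] <- if (violation[i] == "bad_type") transversion_partner(ref_base[i])
                else pick_other_base(ref_base[i])
      flank_l[i] <- as.character(Biostrings::subseq(s, p - 60L, p - 1L))
      flank_r[i] <- as.character(Biostrings::subseq(s, p + 1L, p + 60L))
      if (violation[i] == "nflank") {
        off <- sample(1:60, 1L)
        substr(flank_l[i], off, off) <- "N"
      }
    }
    group <- sample(names(group_probs), n, replace = TRUE, prob = group_probs)
    pool <- rep(NA_character_, n)
    obs <- vector("list", n)
    for (i in seq_len(n)) {
      g <- group[i]
      obs[[i]] <- make_observations(alt[i], g, pool_needed = g %in% c("A", "D"))
      if (g == "A") pool[i] <- iupac_code(c(ref_base[i], alt[i]))
      if (g == "D") {
        third <- setdiff(c("A", "C", "G", "T"), c(ref_base[i], alt[i]))[1]
        pool[i] <- iupac_code(c(alt[i], third))
      }
      if (violation[i] == "paralog") {
        obs[[i]]$allele[1] <- "both"
      } else if (violation[i] == "pool_bad") {
        # an observed allele outside the pool code
        pool[i] <- iupac_code(c(ref_base[i],
                                setdiff(c("A", "C", "G", "T"),
                                        c(ref_base[i], alt[i]))[1]))
      }
    }
    catalog <- snp_catalog(data.frame(
      id = sprintf("snp%05d", seq_len(n)),
      chrom = df$chrom, pos = df$pos, ref = ref_base, alt = alt,
      design_score = round(rbeta(n, design_shape[1], design_shape[2]), 3),
      flank_left = flank_l, flank_right = flank_r,
      mixed_pool_code = pool, known_validated = FALSE,
      stringsAsFactors = FALSE))
    catalog$observations <- obs
    # planted close pairs: duplicate a clean candidate `d` bp away
    clus <- which(violation == "clustered")
    if (length(clus)) {
      extra <- catalog[clus, , drop = FALSE]
      extra$pos <- extra$pos + sample(5:25, length(clus), replace = TRUE)
      extra$id <- sprintf("%s_pair", extra$id)
      for (j in seq_len(nrow(extra))) {
        s <- seqs[[extra$chrom[j]]]; p <- extra$pos[j]
        extra$ref[j] <- as.character(Biostrings::subseq(s, p, p))
        extra$alt[j] <- pick_other_base(extra$ref[j])
        extra$flank_left[j] <- as.character(Biostrings::subseq(s, p - 60L, p - 1L))
        extra$flank_right[j] <- as.character(Biostrings::subseq(s, p + 1L, p + 60L))
        extra$mixed_pool_code[j] <- NA_character_
        extra$observations[[j]]$allele <- rep(extra$alt[j],
                                              nrow(extra$observations[[j]]))
      }
      catalog <- rbind(catalog, extra)
      violation <- c(violation, rep("clustered", length(clus)))
      group <- c(group, group[clus])
    }
    o <- order(catalog$chrom, catalog$pos)
    catalog <- catalog[o, , drop = FALSE]
    class(catalog) <- c("snp_catalog", "data.frame")
    truth <- data.frame(id = catalog$id, violation = violation[o],
                        intended_group = group[o], stringsAsFactors = FALSE)
    list(catalog = catalog, truth = truth)
  })
}

#' Generate a Marey-map linkage map with known breakpoints
#'
#' Markers are placed uniformly along the chromosome; cumulative genetic
#' position follows a three-segment polyline (euchromatic arm /
#' recombination-suppressed heterochromatin / euchromatic arm) with
#' additive Gaussian noise, then made monotone (a cumulative map cannot
#' decrease).
#'
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @param length_bp chromosome length.
#' @param het_start,het_end true heterochromatic interval (the middle,
#'   low-slope segment).
#' @param slopes cM/Mb of the three segments (middle strictly smallest).
#' @param noise_sd marker noise in cM.
#' @param n_markers number of map points.
#' @return data.frame `marker`, `chrom`, `cm`, `bp`.
#' @export
generate_linkage_map <- function(seed, chrom, length_bp, het_start, het_end,
                                 slopes = c(3, 0.2, 3), noise_sd = 0.5,
                                 n_markers = 200L) {
  stopifnot(slopes[2] < slopes[1], slopes[2] < slopes[3])
  with_seed(sub_seed(seed, "linkage_map"), {
    bp <- sort(sample.int(length_bp, n_markers))
    per_bp <- slopes / 1e6
    cm_at <- function(x) {
      ifelse(x <= het_start, x * per_bp[1],
        ifelse(x <= het_end,
               het_start * per_bp[1] + (x - het_start) * per_bp[2],
               het_start * per_bp[1] + (het_end - het_start) * per_bp[2] +
                 (x - het_end) * per_bp[3]))
    }
    cm <- cm_at(bp) + rnorm(n_markers, 0, noise_sd)
    cm <- cummax(pmax(cm, 0))
    data.frame(marker = sprintf("m%04d", seq_len(n_markers)),
               chrom = chrom, cm = cm, bp = bp, stringsAsFactors = FALSE)
  })
}

#' Generate multi-population genotype matrices under Balding-Nichols
#'
#' Ancestral allele frequencies are drawn from `ancestral_range` (uniform);
#' each population's frequency is a Beta draw around the ancestral value
#' with variance `fst * p * (1-p)` (the Balding-Nichols model), so the
#' expected pairwise Weir-Cockerham differentiation between any two
#' populations equals `target_fst`. Individuals are inbred lines by default
#' (`inbreeding = 1`, no heterozygotes), matching self-pollinating crops;
#' set `inbreeding < 1` for partially outbred material.
#'
#' @param seed RNG seed.
#' @param n_pops number of populations.
#' @param n_samples samples per population (scalar or vector).
#' @param n_loci number of loci.
#' @param target_fst differentiation parameter, scalar or per-locus vector
#'   (use an elevated stretch to plant a selection signature).
#' @param ancestral_range uniform range of ancestral allele frequencies.
#' @param inbreeding probability that an individual is fully inbred at a
#'   locus (1 = no heterozygotes).
#' @param missing_rate per-call missing probability.
#' @param pop_names population labels.
#' @param chrom,positions chromosome name and locus positions (defaults to
#'   evenly spaced positions 1 kb apart on one chromosome).
#' @return list: `gm` ([genotype_matrix()]), `truth` (ancestral and
#'   per-population allele frequencies, per-locus fst parameter).
#' @export
generate_populations <- function(seed, n_pops = 3L, n_samples = 96L,
                                 n_loci = 2000L, target_fst = 0.2,
                                 ancestral_range = c(0.05, 0.95),
                                 inbreeding = 1, missing_rate = 0.01,
                                 pop_names = NULL,
                                 chrom = "chr1", positions = NULL) {
  if (is.null(pop_names)) {
    pop_names <- c("elite", "landrace", "wild",
                   sprintf("pop%d", seq_len(max(0L, n_pops - 3L))))[seq_len(n_pops)]
  }
  if (length(n_samples) == 1L) n_samples <- rep(n_samples, n_pops)
  fst <- rep_len(target_fst, n_loci)
  stopifnot(all(fst >= 0 & fst < 1))
  if (is.null(positions)) positions <- seq_len(n_loci) * 1000L
  with_seed(sub_seed(seed, "populations"), {
    pa <- runif(n_loci, ancestral_range[1], ancestral_range[2])
    pop_freq <- matrix(NA_real_, n_loci, n_pops,
                       dimnames = list(NULL, pop_names))
    for (k in seq_len(n_pops)) {
      pk <- pa
      drift <- fst > 0
      th <- (1 - fst[drift]) / fst[drift]
      pop_freq[drift, k] <- rbeta(sum(drift), pa[drift] * th,
                                  (1 - pa[drift]) * th)
      pop_freq[!drift, k] <- pa[!drift]
    }
    calls <- matrix(NA_character_, n_loci, sum(n_samples))
    sample_ids <- character(sum(n_samples))
    pops <- character(sum(n_samples))
    col <- 0L
    for (k in seq_len(n_pops)) {
      p <- pop_freq[, k]
      for (s in seq_len(n_samples[k])) {
        col <- col + 1L
        sample_ids[col] <- sprintf("%s_%03d", pop_names[k], s)
        pops[col] <- pop_names[k]
        ibd <- runif(n_loci) < inbreeding
        dose <- integer(n_loci)
        dose[ibd] <- 2L * rbinom(sum(ibd), 1L, p[ibd])
        dose[!ibd] <- rbinom(sum(!ibd), 2L, p[!ibd])
        g <- c("AA", "AB", "BB")[dose + 1L]
        g[runif(n_loci) < missing_rate] <- NA_character_
        calls[, col] <- g
      }
    }
    colnames(calls) <- sample_ids
    loci <- data.frame(id = sprintf("loc%05d", seq_len(n_loci)),
                       chrom = chrom, pos = positions,
                       stringsAsFactors = FALSE)
    gm <- genotype_matrix(calls, loci, setNames(pops, sample_ids))
    list(gm = gm,
         truth = list(ancestral = pa, pop_freq = pop_freq, fst = fst))
  })
}

#' Generate Sanger-style validation outcomes per priority group
#'
#' For each group, a `no_sequence_rate` fraction of loci yields no usable
#' amplicon (`no_good_sequence`); the rest validate with the group's true
#' rate.
#'
#' @param seed RNG seed.
#' @param group_sizes named loci counts per group; the default mirrors a
#'   767-locus verification experiment (A=89, B=233, C=390, D=55).
#' @param true_rates named per-group validation probabilities (defaults
#'   1.00 / 0.83 / 0.77 / 0.67).
#' @param no_sequence_rate probability of a failed amplicon.
#' @return list: `records` (data.frame `locus_id`, `priority_group`,
#'   `outcome`), `truth` (the arguments).
#' @export
generate_validation_outcomes <- function(seed,
                                         group_sizes = c(A = 89, B = 233,
                                                         C = 390, D = 55),
                                         true_rates = c(A = 1.00, B = 0.83,
                                                        C = 0.77, D = 0.67),
                                         no_sequence_rate = 0.18) {
  stopifnot(all(true_rates >= 0 & true_rates <= 1),
            no_sequence_rate >= 0 && no_sequence_rate < 1)
  with_seed(sub_seed(seed, "validation"), {
    rows <- lapply(names(group_sizes), function(g) {
      n <- group_sizes[[g]]
      ngs <- rbinom(1L, n, no_sequence_rate)
      good <- n - ngs
      val <- rbinom(1L, good, true_rates[[g]])
      data.frame(
        locus_id = sprintf("%s_loc%04d", g, seq_len(n)),
        priority_group = g,
        outcome = c(rep("no_good_sequence", ngs),
                    rep("validated", val),
                    rep("not_validated", good - val)),
        stringsAsFactors = FALSE)
    })
    records <- do.call(rbind, rows)
    list(records = records,
         truth = list(group_sizes = group_sizes, true_rates = true_rates,
                      no_sequence_rate = no_sequence_rate))
  })
}

#' Write a generated reference to FASTA
#' @param reference list from [generate_reference()].
#' @param path FASTA path.
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(reference$sequences, path)
  invisible(path)
}
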