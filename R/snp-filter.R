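# snp_filter: candidate-elimination cascade for Infinium II assay design.
#
# Rule order is fixed (assay_type, flank_ambiguity, clustered,
# flank_uniqueness, paralog_pool) so per-rule removal counts are
# reproducible; each removal is attributed to the first rule that fires.

FILTER_RULES <- c("assay_type", "flank_ambiguity", "clustered",
                  "flank_uniqueness", "paralog_pool")

partition_catalog <- function(catalog, removed_idx) {
  keep <- setdiff(seq_len(nrow(catalog)), removed_idx)
  list(kept = catalog[keep, , drop = FALSE],
       removed = catalog[removed_idx, , drop = FALSE])
}

#' Remove assay-incompatible variants (A/T, G/C, indels)
#'
#' Single-bead two-colour (Infinium II) chemistry reads both alleles of an
#' A/T or G/C SNP in the same colour channel, so those SNP types cannot be
#' assayed; indels are likewise excluded. Orientation does not matter
#' (T/A is removed like A/T).
#'
#' @param catalog a [snp_catalog()].
#' @return list with `kept` and `removed` catalogs.
#' @export
filter_assay_type <- function(catalog) {
  pair <- paste(pmin(catalog$ref, catalog$alt), pmax(catalog$ref, catalog$alt))
  is_snv <- catalog$ref %in% c("A", "C", "G", "T") &
    catalog$alt %in% c("A", "C", "G", "T")
  bad <- !is_snv | pair %in% c("A T", "C G")
  partition_catalog(catalog, which(bad))
}

#' Remove candidates with ambiguity in the 60-nt flanks
#'
#' A candidate is removed if any N or other IUPAC ambiguity character occurs
#' within 60 nt on either side of the variant. Flanks shorter than 60 nt
#' (e.g. near a chromosome end) are treated as ambiguous and removed: probe
#' design needs the full window.
#'
#' @inheritParams filter_assay_type
#' @param window flank window length in nt.
#' @return list with `kept` and `removed`.
#' @export
filter_flank_ambiguity <- function(catalog, window = 60L) {
  win_ok <- function(s, from_end) {
    if (is.na(s) || nchar(s) < window) return(FALSE)
    piece <- if (from_end) substr(s, nchar(s) - window + 1L, nchar(s))
             else substr(s, 1L, window)
    !grepl("[^ACGTacgt]", piece)
  }
  ok_l <- vapply(catalog$flank_left, win_ok, logical(1), from_end = TRUE)
  ok_r <- vapply(catalog$flank_right, win_ok, logical(1), from_end = FALSE)
  partition_catalog(catalog, which(!(ok_l & ok_r)))
}

#' Remove clustered candidates
#'
#' Any candidate with another candidate within `max_dist` bp on the same
#' chromosome is removed; both members of a close pair go (symmetric
#' reading of "residing within 25 bases of another SNP").
#'
#' @inheritParams filter_assay_type
#' @param max_dist maximum centre-to-centre distance (bp) that counts as
#'   clustered; distance `<= max_dist` removes.
#' @return list with `kept` and `removed`.
#' @export
filter_clustered <- function(catalog, max_dist = 25L) {
  bad <- logical(nrow(catalog))
  for (ch in unique(catalog$chrom)) {
    idx <- which(catalog$chrom == ch)
    if (length(idx) < 2L) next
    o <- idx[order(catalog$pos[idx])]
    d <- diff(catalog$pos[o])
    close_pair <- d <= max_dist
    bad[o[c(close_pair, FALSE)]] <- TRUE
    bad[o[c(FALSE, close_pair)]] <- TRUE
  }
  partition_catalog(catalog, which(bad))
}

count_kmer_hits <- function(patterns, reference) {
  # occurrences of each pattern in the reference, forward plus reverse
  # complement; patterns are plain ACGT 25-mers
  stopifnot(methods::is(reference, "DNAStringSet"))
  pats <- Biostrings::DNAStringSet(patterns)
  rc <- Biostrings::reverseComplement(pats)
  n <- integer(length(patterns))
  pd_ok <- !any(grepl("[^ACGT]", patterns))
  if (pd_ok) {
    pd_f <- Biostrings::PDict(pats)
    pd_r <- Biostrings::PDict(rc)
    n <- rowSums(Biostrings::vcountPDict(pd_f, reference)) +
      rowSums(Biostrings::vcountPDict(pd_r, reference))
  } else {
    for (j in seq_along(patterns)) {
      n[j] <- sum(Biostrings::vcountPattern(pats[[j]], reference)) +
        sum(Biostrings::vcountPattern(rc[[j]], reference))
    }
  }
  n
}

#' Remove candidates whose 25-nt flanks are not unique in the genome
#'
#' The 25-nt sequence immediately left and immediately right of the variant
#' must each occur exactly once in the reference, counting forward-strand
#' and reverse-complement matches (a flank present elsewhere only as a
#' reverse complement still removes the candidate). Matching is exact; no
#' mismatch tolerance.
#'
#' @inheritParams filter_assay_type
#' @param reference a [Biostrings::DNAStringSet] of the genome (chromosomes
#'   and scaffolds).
#' @param k flank k-mer length.
#' @return list with `kept` and `removed`.
#' @export
filter_flank_uniqueness <- function(catalog, reference, k = 25L) {
  if (!nrow(catalog)) return(list(kept = catalog, removed = catalog))
  left <- toupper(substr(catalog$flank_left,
                         pmax(nchar(catalog$flank_left) - k + 1L, 1L),
                         nchar(catalog$flank_left)))
  right <- toupper(substr(catalog$flank_right, 1L, k))
  too_short <- is.na(left) | is.na(right) | nchar(left) < k | nchar(right) < k
  # consistency check: the flank must be present at the candidate's own locus
  on_ref <- catalog$chrom %in% names(reference)
  if (any(on_ref & !too_short)) {
    idx <- which(on_ref & !too_short)
    for (i in idx) {
      s <- reference[[catalog$chrom[i]]]
      p <- catalog$pos[i]
      if (p - k >= 1L && p + k <= length(s)) {
        ref_l <- as.character(Biostrings::subseq(s, p - k, p - 1L))
        ref_r <- as.character(Biostrings::subseq(s, p + 1L, p + k))
        if (ref_l != left[i] || ref_r != right[i]) {
          stop("data-consistency error: flank of candidate ", catalog$id[i],
               " not found at its own locus")
        }
      }
    }
  }
  bad <- too_short
  todo <- which(!too_short)
  if (length(todo)) {
    nl <- count_kmer_hits(left[todo], reference)
    nr <- count_kmer_hits(right[todo], reference)
    bad[todo] <- nl != 1L | nr != 1L
  }
  partition_catalog(catalog, which(bad))
}

#' Remove paralog-like and pool-inconsistent candidates
#'
#' A candidate is removed if any single genotype shows both alleles
#' (`allele == "both"`, indicative of collapsed paralogous sequence), or if
#' a mixed-pool IUPAC code exists and any genotype's observed allele is not
#' among the bases that code stands for.
#'
#' @inheritParams filter_assay_type
#' @return list with `kept` and `removed`.
#' @export
filter_paralog_and_pool_consistency <- function(catalog) {
  bad <- vapply(seq_len(nrow(catalog)), function(i) {
    obs <- catalog$observations[[i]]
    if (!nrow(obs)) return(FALSE)
    if (any(obs$allele == "both")) return(TRUE)
    code <- catalog$mixed_pool_code[i]
    if (!is.na(code)) {
      allowed <- iupac_bases(code)
      single <- obs$allele[obs$allele != "both"]
      if (any(!toupper(single) %in% allowed)) return(TRUE)
    }
    FALSE
  }, logical(1))
  partition_catalog(catalog, which(bad))
}

#' Apply the full candidate-elimination cascade
#'
#' Rules run in the fixed order assay type, flank ambiguity, clustering,
#' flank uniqueness, paralog/pool consistency; each candidate's removal is
#' attributed to the first rule that fires. The report satisfies
#' `input_count == length(retained) + sum(removed_by_rule)`.
#'
#' @inheritParams filter_flank_uniqueness
#' @return list of class `filter_report`: `input_count`, `removed_by_rule`
#'   (named integer vector), `retained` (character ids), and `kept` (the
#'   retained [snp_catalog()]).
#' @export
apply_filter_cascade <- function(catalog, reference) {
  stopifnot(inherits(catalog, "snp_catalog"))
  removed <- setNames(integer(length(FILTER_RULES)), FILTER_RULES)
  cur <- catalog
  for (rule in FILTER_RULES) {
    part <- switch(rule,
      assay_type = filter_assay_type(cur),
      flank_ambiguity = filter_flank_ambiguity(cur),
      clustered = filter_clustered(cur),
      flank_uniqueness = filter_flank_uniqueness(cur, reference),
      paralog_pool = filter_paralog_and_pool_consistency(cur))
    removed[[rule]] <- nrow(part$removed)
    cur <- part$kept
  }
  structure(list(input_count = nrow(catalog),
                 removed_by_rule = removed,
                 retained = cur$id,
                 kept = cur),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d candidates in, %d retained\n",
              x$input_count, length(x$retained)))
  for (r in names(x$removed_by_rule)) {
    cat(sprintf("  removed by %-18s %d\n", paste0(r, ":"), x$removed_by_rule[[r]]))
  }
  invisible(x)
}

#' Serialize a filter report to JSON
#' @param report a `filter_report`.
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(
    list(input_count = report$input_count,
         removed_by_rule = as.list(report$removed_by_rule),
         retained = report$retained),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
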