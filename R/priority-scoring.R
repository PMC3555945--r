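# priority_scoring: evidence classes A-D, empirical validation rates R and
# the selection index I = R x D.

#' Assign the evidence-based priority group of one candidate
#'
#' Rules are tested in the order A, B, C, D (the classes overlap; listed
#' order wins, and A has the highest validation rate):
#'
#' * **A** - at least one genotype carries the non-reference allele with
#'   read depth >= 1 *and* both SNP alleles are consistent with the
#'   mixed-pool IUPAC code; or the SNP is a known, previously assayed marker
#'   (`known_validated`).
#' * **B** - the non-reference allele was observed in >= 2 genotypes.
#' * **C** - exactly one genotype, with read depth > 3.
#' * **D** - exactly one genotype with read depth < 3 and the non-reference
#'   allele present in the mixed pool. A single-genotype candidate with
#'   depth exactly 3 (covered by neither C nor D as stated) is assigned to D
#'   when pool-supported, otherwise left unassigned.
#'
#' @param candidate one-row [snp_catalog()] slice (or a list with fields
#'   `alt`, `ref`, `observations`, `mixed_pool_code`, `known_validated`).
#' @return one of `"A"`, `"B"`, `"C"`, `"D"`, or `NA` (unassignable).
#' @export
assign_priority_group <- function(candidate) {
  obs <- if (is.data.frame(candidate$observations)) candidate$observations
         else candidate$observations[[1]]
  ref <- toupper(candidate$ref[[1]])
  alt <- toupper(candidate$alt[[1]])
  code <- candidate$mixed_pool_code[[1]]
  known <- isTRUE(candidate$known_validated[[1]])
  sup <- obs[toupper(obs$allele) == alt & obs$depth >= 1L, , drop = FALSE]
  n_sup <- length(unique(sup$genotype_id))
  pool <- if (!is.na(code)) iupac_bases(code) else character()
  pool_both <- length(pool) > 0 && all(c(ref, alt) %in% pool)
  pool_alt <- length(pool) > 0 && alt %in% pool
  if ((n_sup >= 1L && pool_both) || known) return("A")
  if (n_sup >= 2L) return("B")
  if (n_sup == 1L) {
    depth <- max(sup$depth)
    if (depth > 3L) return("C")
    if (depth < 3L && pool_alt) return("D")
    if (depth == 3L && pool_alt) return("D")
  }
  NA_character_
}

#' Assign priority groups across a catalog
#'
#' @param catalog a [snp_catalog()].
#' @return the catalog with `priority_group` filled; unassignable
#'   candidates keep `NA` and their count is attached as attribute
#'   `n_unassigned` (and reported via a message).
#' @export
assign_priority_groups <- function(catalog) {
  stopifnot(inherits(catalog, "snp_catalog"))
  grp <- vapply(seq_len(nrow(catalog)), function(i) {
    assign_priority_group(catalog[i, , drop = FALSE])
  }, character(1))
  catalog$priority_group <- grp
  n_un <- sum(is.na(grp))
  if (n_un) message(n_un, " candidate(s) matched no priority rule")
  attr(catalog, "n_unassigned") <- n_un
  catalog
}

#' Estimate per-group priority scores from validation outcomes
#'
#' For each priority group, loci with "no good sequence" (null or multiple
#' amplicons in the Sanger assay) are set aside; the priority score R is the
#' fraction of the remaining (good-sequence) loci at which the SNP call was
#' validated.
#'
#' @param records data.frame with columns `locus_id`, `priority_group`
#'   (A-D) and `outcome` (`validated`, `not_validated`,
#'   `no_good_sequence`).
#' @return data.frame of class `priority_score_table` with one row per
#'   group: `group`, `n_total`, `n_no_good_sequence`, `n_good_sequence`,
#'   `n_validated`, `rate` (R, kept at full precision).
#' @export
estimate_priority_scores <- function(records) {
  stopifnot(all(c("locus_id", "priority_group", "outcome") %in% names(records)))
  bad <- !records$outcome %in% c("validated", "not_validated", "no_good_sequence")
  if (any(bad)) stop("unknown outcome value(s): ",
                     paste(unique(records$outcome[bad]), collapse = ", "))
  groups <- sort(unique(as.character(records$priority_group)))
  rows <- lapply(groups, function(g) {
    r <- records[records$priority_group == g, , drop = FALSE]
    n_tot <- nrow(r)
    n_ngs <- sum(r$outcome == "no_good_sequence")
    n_good <- n_tot - n_ngs
    if (n_good == 0L) {
      stop("priority group ", g, " has zero good-sequence loci")
    }
    n_val <- sum(r$outcome == "validated")
    data.frame(group = g, n_total = n_tot, n_no_good_sequence = n_ngs,
               n_good_sequence = n_good, n_validated = n_val,
               rate = n_val / n_good, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("priority_score_table", "data.frame")
  out
}

#' Compute the selection index I = R x D
#'
#' Candidates with a design score below `min_design_score` are excluded from
#' further selection (their assay is too likely to fail); the rest get
#' `index_score = rate(priority_group) * design_score`.
#'
#' @param catalog a [snp_catalog()] with `priority_group` assigned.
#' @param score_table a [estimate_priority_scores()] result (or any
#'   data.frame with `group` and `rate`).
#' @param min_design_score design-score cutoff; the default 0.4 is the
#'   vendor-recommended floor for Infinium probes.
#' @return list with `scored` (catalog with `index_score` set) and
#'   `excluded` (catalog rows removed by the design-score cutoff).
#' @export
compute_index <- function(catalog, score_table, min_design_score = 0.4) {
  stopifnot(inherits(catalog, "snp_catalog"))
  if (any(is.na(catalog$priority_group))) {
    stop("candidate(s) without priority group: ",
         paste(head(catalog$id[is.na(catalog$priority_group)], 5), collapse = ", "))
  }
  unknown <- setdiff(unique(catalog$priority_group), score_table$group)
  if (length(unknown)) {
    stop("no priority score for group(s): ", paste(unknown, collapse = ", "))
  }
  drop <- catalog$design_score < min_design_score
  kept <- catalog[!drop, , drop = FALSE]
  rate <- setNames(score_table$rate, score_table$group)
  kept$index_score <- unname(rate[kept$priority_group]) * kept$design_score
  list(scored = kept, excluded = catalog[drop, , drop = FALSE])
}
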