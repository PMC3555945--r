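# panel_eval: spacing statistics, genic annotation, call-rate association,
# MAF profiles and pairwise genetic distance.

#' Adjacent-gap statistics per chromosome region
#'
#' Gaps are distances between adjacent SNPs within one chromosome (and, if
#' `partitions` is given, within one region class — euchromatic and
#' heterochromatic stretches never share a gap). Regions with fewer than two
#' SNPs are skipped with a note.
#'
#' @param snps data.frame with `chrom` and `pos` (and optionally a
#'   pre-computed `region_class`).
#' @param partitions optional [chrom_partition()] for region splitting.
#' @return list: `per_region` (chrom, region_class, n_snps, n_gaps,
#'   mean_gap, sd_gap), `overall` (same per region class), `gaps`
#'   (data.frame of every gap), `skipped` (regions with < 2 SNPs).
#' @export
gap_statistics <- function(snps, partitions = NULL) {
  df <- data.frame(chrom = as.character(snps$chrom), pos = as.integer(snps$pos),
                   stringsAsFactors = FALSE)
  if (!is.null(snps$region_class) && is.null(partitions)) {
    df$region_class <- snps$region_class
    df$segment <- snps$region_class
  } else if (!is.null(partitions)) {
    # contiguous segments: the two euchromatic arms never share a gap
    df$region_class <- NA_character_
    df$segment <- NA_character_
    for (ch in intersect(unique(df$chrom), partitions$chrom)) {
      i <- df$chrom == ch
      df$region_class[i] <- region_class(partitions, ch, df$pos[i])
      hs <- partitions$het_start[partitions$chrom == ch]
      df$segment[i] <- ifelse(df$region_class[i] == "heterochromatic",
                              "heterochromatic",
                              ifelse(df$pos[i] < hs, "euchromatic_left",
                                     "euchromatic_right"))
    }
  } else {
    df$region_class <- "all"
    df$segment <- "all"
  }
  key <- interaction(df$chrom, df$segment, drop = TRUE)
  gaps <- list(); per <- list(); skipped <- list()
  for (k in levels(key)) {
    sub <- df[which(key == k), , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    if (nrow(sub) < 2L) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(chrom = sub$chrom[1], region_class = sub$region_class[1],
                   n_snps = nrow(sub))
      next
    }
    g <- diff(sub$pos)
    gaps[[length(gaps) + 1L]] <-
      data.frame(chrom = sub$chrom[1], region_class = sub$region_class[1],
                 gap = g, stringsAsFactors = FALSE)
    per[[length(per) + 1L]] <-
      data.frame(chrom = sub$chrom[1], region_class = sub$region_class[1],
                 n_snps = nrow(sub), n_gaps = length(g),
                 mean_gap = mean(g), sd_gap = stats::sd(g),
                 stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    message(length(skipped), " region(s) with < 2 SNPs skipped in gap statistics")
  }
  gaps <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(chrom = character(), region_class = character(), gap = numeric())
  per <- if (length(per)) do.call(rbind, per) else
    data.frame(chrom = character(), region_class = character(),
               n_snps = integer(), n_gaps = integer(),
               mean_gap = numeric(), sd_gap = numeric())
  overall <- do.call(rbind, lapply(split(gaps$gap, gaps$region_class), function(g) {
    data.frame(n_gaps = length(g), mean_gap = mean(g), sd_gap = stats::sd(g))
  }))
  if (!is.null(overall)) overall <- cbind(region_class = rownames(overall), overall,
                                          stringsAsFactors = FALSE)
  rownames(overall) <- NULL
  list(per_region = per, overall = overall, gaps = gaps,
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
}

#' Classify SNPs relative to gene models
#'
#' Each SNP gets exactly one class with precedence
#' CDS > 5'UTR > 3'UTR > intron > 2kb-upstream > 2kb-downstream >
#' intergenic. Introns are gene span minus exons; up/downstream windows are
#' strand-aware (upstream of a minus-strand gene lies at higher
#' coordinates). SNPs on chromosomes absent from the annotation are
#' intergenic, with a warning.
#'
#' @param snps data.frame with `chrom` and `pos`.
#' @param gene_models list from [read_gene_models()].
#' @param flank_bp up/downstream window size (bp).
#' @return character vector of classes, one per SNP.
#' @export
annotate_genic <- function(snps, gene_models, flank_bp = 2000L) {
  gr <- GenomicRanges::GRanges(as.character(snps$chrom),
                               IRanges::IRanges(as.integer(snps$pos), width = 1L))
  genes <- gene_models$genes
  missing_chr <- setdiff(unique(as.character(snps$chrom)),
                         GenomeInfoDb::seqlevels(genes))
  if (length(missing_chr)) {
    warning("chromosome(s) absent from annotation, SNPs there are intergenic: ",
            paste(missing_chr, collapse = ", "))
  }
  introns <- GenomicRanges::setdiff(GenomicRanges::reduce(genes),
                                    GenomicRanges::reduce(gene_models$exons),
                                    ignore.strand = TRUE)
  plus <- as.character(GenomicRanges::strand(genes)) != "-"
  up <- GenomicRanges::flank(genes, flank_bp, start = TRUE, ignore.strand = FALSE)
  down <- GenomicRanges::flank(genes, flank_bp, start = FALSE, ignore.strand = FALSE)
  up <- GenomicRanges::trim(up); down <- GenomicRanges::trim(down)
  classes <- list(CDS = gene_models$cds,
                  `5'UTR` = gene_models$five_utr,
                  `3'UTR` = gene_models$three_utr,
                  intron = introns,
                  `2kb-upstream` = up,
                  `2kb-downstream` = down)
  out <- rep("intergenic", length(gr))
  assigned <- logical(length(gr))
  for (cl in names(classes)) {
    set <- classes[[cl]]
    if (!length(set)) next
    # disjoint seqlevels are expected (we warn about them above)
    hit <- suppressWarnings(IRanges::overlapsAny(gr, set, ignore.strand = TRUE))
    take <- hit & !assigned
    out[take] <- cl
    assigned <- assigned | hit
  }
  out
}

#' Call-success rate by score bin
#'
#' Joins assay outcomes to scores by `snp_id`, bins the score (lower edge
#' closed, upper open; the top bin is closed at the score maximum), and
#' reports per-bin success counts and rates, the Pearson correlation of bin
#' midpoints with bin rates (empty bins excluded), and the per-SNP
#' point-biserial correlation. With fewer than two non-empty bins — or no
#' variation in rate and midpoint — the bin correlation is `NA` and a note
#' says so.
#'
#' @param outcomes data.frame `snp_id`, `success` (logical).
#' @param scores data.frame `snp_id`, `score`.
#' @param edges interior bin edges; default gives bins `<0.4`,
#'   `[0.4,0.5)`, ..., `[0.8,0.9)`, `>=0.9` on a score in `[0,1]`.
#' @param score_range closed range the score lives on (for midpoints of the
#'   outer bins).
#' @return list: `bins` (bin, midpoint, n_success, n_fail, rate),
#'   `correlation` (midpoints vs rates), `point_biserial`, `note`.
#' @export
call_rate_by_bins <- function(outcomes, scores,
                              edges = seq(0.4, 0.9, by = 0.1),
                              score_range = c(0, 1)) {
  m <- merge(outcomes, scores, by = "snp_id")
  if (!nrow(m)) stop("no snp_id in common between outcomes and scores")
  full <- c(score_range[1], edges, score_range[2])
  brk <- unique(full)
  lab <- character(length(brk) - 1L)
  lab[1] <- sprintf("<%.1f", brk[2])
  lab[length(lab)] <- sprintf(">=%.1f", brk[length(brk) - 1L])
  if (length(lab) > 2L) {
    for (i in 2:(length(lab) - 1L)) {
      lab[i] <- sprintf("[%.1f,%.1f)", brk[i], brk[i + 1L])
    }
  }
  bin <- cut(m$score, breaks = brk, right = FALSE, include.lowest = TRUE,
             labels = lab)
  mid <- (brk[-length(brk)] + brk[-1]) / 2
  tab <- data.frame(bin = lab, midpoint = mid,
                    n_success = as.integer(tapply(m$success, bin, sum, default = 0L)),
                    n_fail = as.integer(tapply(!m$success, bin, sum, default = 0L)),
                    stringsAsFactors = FALSE)
  tab$rate <- ifelse(tab$n_success + tab$n_fail > 0,
                     tab$n_success / (tab$n_success + tab$n_fail), NA_real_)
  used <- !is.na(tab$rate)
  note <- NULL
  if (any(!used)) note <- c(note, sprintf("%d empty bin(s) excluded from correlation",
                                          sum(!used)))
  r <- NA_real_
  if (sum(used) >= 2L && stats::sd(tab$rate[used]) > 0 &&
      stats::sd(tab$midpoint[used]) > 0) {
    r <- stats::cor(tab$midpoint[used], tab$rate[used])
  } else {
    note <- c(note, "bin correlation undefined (constant rate or < 2 bins)")
  }
  pb <- if (stats::sd(m$score) > 0 && stats::sd(as.numeric(m$success)) > 0) {
    stats::cor(m$score, as.numeric(m$success))
  } else NA_real_
  list(bins = tab, correlation = r, point_biserial = pb, note = note)
}

# allele/heterozygote counts per locus for a set of samples.
# calls coded as alt-allele dose: AA=0, AB=1, BB=2, NA missing.
call_dose <- function(calls) {
  d <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  d[calls == "AA"] <- 0
  d[calls == "AB"] <- 1
  d[calls == "BB"] <- 2
  d
}

#' Minor-allele-frequency profile of one population
#'
#' Allele frequencies are computed from called alleles only; a locus with
#' zero calls in the population is excluded from that population's totals.
#' The MAF is `min(p, 1 - p)`. Bins are left-closed, right-open, except the
#' final bin which is closed at 0.5.
#'
#' @param gm a [genotype_matrix()].
#' @param population population label, or `NULL` for all samples combined.
#' @param edges bin edges on `[0, 0.5]`.
#' @return list of class `maf_summary`: `maf` (named per-locus vector, `NA`
#'   for uncalled loci), `bins` (bin, count, fraction), `n_loci` (loci with
#'   at least one call).
#' @export
maf_profile <- function(gm, population = NULL,
                        edges = c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- if (is.null(population)) rep(TRUE, ncol(gm$calls))
          else gm$populations == population
  if (!any(keep)) stop("no samples in population ", population)
  d <- call_dose(gm$calls[, keep, drop = FALSE])
  n_called <- rowSums(!is.na(d))
  p_alt <- rowSums(d, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(p_alt, 1 - p_alt)
  maf[n_called == 0L] <- NA_real_
  lab <- character(length(edges) - 1L)
  for (i in seq_along(lab)) {
    closer <- if (i == length(lab)) "]" else ")"
    lab[i] <- sprintf("[%.2f,%.2f%s", edges[i], edges[i + 1L], closer)
  }
  bin <- cut(maf[!is.na(maf)], breaks = edges, right = FALSE,
             include.lowest = TRUE, labels = lab)
  # cut(right=FALSE, include.lowest=TRUE) closes the last bin at 0.5
  counts <- as.integer(table(bin))
  out <- list(maf = setNames(maf, gm$loci$id),
              bins = data.frame(bin = lab, count = counts,
                                fraction = counts / max(sum(counts), 1L),
                                stringsAsFactors = FALSE),
              n_loci = sum(!is.na(maf)))
  class(out) <- "maf_summary"
  out
}

#' @export
print.maf_summary <- function(x, ...) {
  cat(sprintf("<maf_summary> %d loci with calls\n", x$n_loci))
  print(x$bins)
  invisible(x)
}

#' Pairwise genetic distance between two samples
#'
#' The proportion of co-called loci at which the two genotype calls differ
#' (a heterozygote differs from either homozygote). Undefined when no locus
#' is called in both samples.
#'
#' @param gm a [genotype_matrix()].
#' @param a,b sample ids.
#' @return distance in `[0, 1]`, or `NA` (with a warning) if no co-called
#'   loci exist.
#' @export
genetic_distance <- function(gm, a, b) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ca <- gm$calls[, a]; cb <- gm$calls[, b]
  both <- !is.na(ca) & !is.na(cb)
  if (!any(both)) {
    warning("no co-called loci for pair ", a, " / ", b)
    return(NA_real_)
  }
  sum(ca[both] != cb[both]) / sum(both)
}

#' Distribution of pairwise genetic distances within a population
#'
#' All unordered sample pairs. Reports the binned distance distribution,
#' mean and standard deviation, and the empirical 2.5-97.5 percentile
#' interval of the per-pair polymorphic SNP counts (the number of co-called
#' loci with differing calls).
#'
#' @param gm a [genotype_matrix()].
#' @param population population label.
#' @param edges distance bin edges (left-closed; final bin closed).
#' @return list: `pairs` (a, b, n_cocalled, n_polymorphic, distance),
#'   `bins`, `mean`, `sd`, `poly_interval` (named 2.5%/97.5%),
#'   `mean_polymorphic`.
#' @export
distance_distribution <- function(gm, population,
                                  edges = c(0, 0.1, 0.2, 0.3, 0.4, 0.5)) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ids <- names(gm$populations)[gm$populations == population]
  if (length(ids) < 2L) stop("need >= 2 samples in population ", population)
  cc <- gm$calls[, ids, drop = FALSE]
  n <- length(ids)
  res <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    ci <- cc[, i]
    for (j in (i + 1L):n) {
      cj <- cc[, j]
      both <- !is.na(ci) & !is.na(cj)
      nb <- sum(both)
      np <- if (nb) sum(ci[both] != cj[both]) else NA_integer_
      k <- k + 1L
      res[[k]] <- c(nb, np)
    }
  }
  mat <- do.call(rbind, res)
  pairs <- data.frame(a = rep(ids[seq_len(n - 1L)], times = (n - 1L):1L),
                      b = unlist(lapply(2:n, function(i) ids[i:n])),
                      n_cocalled = mat[, 1L], n_polymorphic = mat[, 2L])
  pairs$distance <- ifelse(pairs$n_cocalled > 0,
                           pairs$n_polymorphic / pairs$n_cocalled, NA_real_)
  d <- pairs$distance[!is.na(pairs$distance)]
  mx <- max(edges[length(edges)], max(d, 0))
  brk <- unique(c(edges, mx))
  lab <- character(length(brk) - 1L)
  for (i in seq_along(lab)) {
    closer <- if (i == length(lab)) "]" else ")"
    lab[i] <- sprintf("[%.2g,%.2g%s", brk[i], brk[i + 1L], closer)
  }
  bin <- cut(d, breaks = brk, right = FALSE, include.lowest = TRUE, labels = lab)
  counts <- as.integer(table(bin))
  poly <- pairs$n_polymorphic[!is.na(pairs$n_polymorphic)]
  list(pairs = pairs,
       bins = data.frame(bin = lab, count = counts,
                         fraction = counts / max(sum(counts), 1L)),
       mean = mean(d), sd = stats::sd(d),
       poly_interval = stats::quantile(poly, c(0.025, 0.975), names = TRUE),
       mean_polymorphic = mean(poly))
}
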