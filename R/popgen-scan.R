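# popgen_scan: Weir-Cockerham F_st, permutation significance, windowed
# averages and selection-signature region flagging.

# Weir & Cockerham (1984) two-population variance components per locus,
# vectorized over loci. Inputs are per-population sample sizes (called
# individuals), alternate-allele frequencies and observed heterozygosities.
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

# per-locus n, p, h for one set of sample columns (dose matrix loci x samples)
pop_locus_stats <- function(dose) {
  n <- rowSums(!is.na(dose))
  p <- rowSums(dose, na.rm = TRUE) / (2 * n)
  h <- rowSums(dose == 1, na.rm = TRUE) / n
  list(n = n, p = p, h = h)
}

fst_from_components <- function(k) {
  den <- k$a + k$b + k$c
  fst <- ifelse(den > 0, k$a / den, 0)
  fst
}

#' Per-locus two-population F_st (Weir-Cockerham)
#'
#' Computes the Weir & Cockerham (1984) two-population estimator from
#' genotype counts. Loci with fewer than `min_called` called samples in
#' either population are excluded (their count is attached as attribute
#' `n_excluded`). Negative estimates are clamped to zero and loci
#' monomorphic in both populations get 0, so values lie in `[0, 1]`.
#'
#' @param gm a [genotype_matrix()].
#' @param pop_a,pop_b population labels.
#' @param min_called minimum called samples per population per locus.
#' @param clamp clamp negative estimates to 0 (default) or keep them.
#' @return data.frame `id`, `chrom`, `pos`, `fst` (NA for excluded loci),
#'   with attributes `n_excluded` and `components` (per-locus a, b, c for
#'   multi-locus combination).
#' @export
fst_per_locus <- function(gm, pop_a, pop_b, min_called = 2L, clamp = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ia <- gm$populations == pop_a
  ib <- gm$populations == pop_b
  if (!any(ia) || !any(ib)) stop("empty population: ",
                                 if (!any(ia)) pop_a else pop_b)
  da <- call_dose(gm$calls[, ia, drop = FALSE])
  db <- call_dose(gm$calls[, ib, drop = FALSE])
  sa <- pop_locus_stats(da)
  sb <- pop_locus_stats(db)
  ok <- sa$n >= min_called & sb$n >= min_called
  k <- wc_components(sa$n, sa$p, sa$h, sb$n, sb$p, sb$h)
  fst <- fst_from_components(k)
  if (clamp) fst <- pmin(pmax(fst, 0), 1)
  fst[!ok] <- NA_real_
  out <- data.frame(id = gm$loci$id, chrom = gm$loci$chrom, pos = gm$loci$pos,
                    fst = fst, stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!ok)
  attr(out, "components") <- data.frame(a = k$a, b = k$b, c = k$c)[ok, , drop = FALSE]
  out
}

#' Multi-locus F_st (ratio of summed variance components)
#'
#' The standard across-locus Weir-Cockerham combination: variance
#' components are summed over loci before taking the ratio. This is the
#' quantity to compare against a simulation's target differentiation; the
#' mean of per-locus ratios is not a consistent estimate of it (loci fixed
#' identically in both populations contribute zeros).
#'
#' @inheritParams fst_per_locus
#' @return single F_st estimate.
#' @export
fst_multilocus <- function(gm, pop_a, pop_b, min_called = 2L) {
  per <- fst_per_locus(gm, pop_a, pop_b, min_called = min_called)
  k <- attr(per, "components")
  sum(k$a) / sum(k$a + k$b + k$c)
}

#' Permutation test of per-locus F_st
#'
#' Individuals are permuted across the two population labels (sizes
#' preserved); the p-value uses the add-one correction
#' `p = (1 + #(perm >= observed)) / (n_perm + 1)`, so identical seeds give
#' identical p-values and the smallest attainable p is `1/(n_perm+1)`.
#'
#' @inheritParams fst_per_locus
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed (required, for reproducibility).
#' @return data.frame `id`, `chrom`, `pos`, `fst`, `p_value`.
#' @export
fst_permutation_test <- function(gm, pop_a, pop_b, n_perm = 999L, seed,
                                 min_called = 2L) {
  stopifnot(n_perm >= 100L)
  obs <- fst_per_locus(gm, pop_a, pop_b, min_called = min_called)
  ia <- which(gm$populations == pop_a)
  ib <- which(gm$populations == pop_b)
  pool <- c(ia, ib)
  na <- length(ia)
  dose <- call_dose(gm$calls[, pool, drop = FALSE])
  count_ge <- integer(nrow(dose))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample(length(pool))
      da <- dose[, idx[seq_len(na)], drop = FALSE]
      db <- dose[, idx[-seq_len(na)], drop = FALSE]
      sa <- pop_locus_stats(da)
      sb <- pop_locus_stats(db)
      k <- wc_components(sa$n, sa$p, sa$h, sb$n, sb$p, sb$h)
      f <- pmin(pmax(fst_from_components(k), 0), 1)
      ge <- !is.na(obs$fst) & f >= obs$fst
      count_ge <- count_ge + ge
    }
  })
  out <- obs
  out$p_value <- ifelse(is.na(obs$fst), NA_real_,
                        (1 + count_ge) / (n_perm + 1))
  out
}

#' Average per-locus F_st in fixed genomic windows
#'
#' Windows form a fixed grid `[1, w]`, `[w+1, 2w]`, ... per chromosome; the
#' window statistic is the unweighted mean of the loci inside. Windows with
#' no loci are kept (with `n_loci = 0` and `mean_fst = NA`) so the grid is
#' contiguous up to the last locus.
#'
#' @param fst data.frame with `chrom`, `pos`, `fst` (from
#'   [fst_per_locus()]); loci with `NA` fst are ignored.
#' @param window_size window width in bp.
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive),
#'   `n_loci`, `mean_fst`.
#' @export
window_average <- function(fst, window_size = 100000L) {
  df <- fst[!is.na(fst$fst), , drop = FALSE]
  out <- list()
  for (ch in unique(fst$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    n_win <- if (nrow(sub)) (max(sub$pos) - 1L) %/% window_size + 1L else 0L
    if (!n_win) next
    win <- (sub$pos - 1L) %/% window_size + 1L
    n_loci <- tabulate(win, nbins = n_win)
    means <- rep(NA_real_, n_win)
    if (nrow(sub)) {
      agg <- tapply(sub$fst, win, mean)
      means[as.integer(names(agg))] <- unname(agg)
    }
    out[[ch]] <- data.frame(
      chrom = ch,
      start = (seq_len(n_win) - 1L) * window_size + 1L,
      end = seq_len(n_win) * window_size,
      n_loci = n_loci, mean_fst = means, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_loci = integer(), mean_fst = numeric())
  rownames(res) <- NULL
  res
}

#' Flag and merge high-F_st windows into candidate selection regions
#'
#' Windows with `mean_fst >= threshold` are flagged; flagged windows on the
#' same chromosome separated by at most `merge_gap` unflagged windows merge
#' into one region. Returns both the flagged-window count and the merged
#' regions.
#'
#' @param windows data.frame from [window_average()].
#' @param threshold F_st threshold.
#' @param merge_gap maximum number of unflagged windows allowed inside a
#'   region (`1` allows one 100-kb hole; `0` merges only adjacent windows).
#' @return list: `regions` (chrom, start, end, n_windows — flagged windows
#'   inside), `n_flagged_windows`, `n_regions`.
#' @export
flag_regions <- function(windows, threshold = 0.6, merge_gap = 1L) {
  flagged <- !is.na(windows$mean_fst) & windows$mean_fst >= threshold
  wsize <- if (nrow(windows)) windows$end[1] - windows$start[1] + 1L else 0L
  regions <- list()
  for (ch in unique(windows$chrom)) {
    idx <- which(windows$chrom == ch & flagged)
    if (!length(idx)) next
    slot <- sort((windows$start[idx] - 1L) %/% wsize + 1L)  # 1-based grid slot
    brk <- c(0L, which(diff(slot) > merge_gap + 1L), length(slot))
    for (g in seq_len(length(brk) - 1L)) {
      members <- slot[(brk[g] + 1L):brk[g + 1L]]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch,
        start = (members[1] - 1L) * wsize + 1L,
        end = members[length(members)] * wsize,
        n_windows = length(members), stringsAsFactors = FALSE)
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_windows = integer())
  rownames(regions) <- NULL
  list(regions = regions,
       n_flagged_windows = sum(flagged),
       n_regions = nrow(regions))
}
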