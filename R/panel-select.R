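# panel_select: proportional per-region quotas and the iterative
# smallest-gap thinning algorithm.
#
# Thinning removes one SNP per iteration: locate the smallest gap between
# adjacent retained SNPs, then remove the flanking SNP with the smaller
# selection index. Ties cascade: equal indices -> the SNP with the smaller
# other adjacent gap goes (a terminal SNP's other gap is unbounded); several
# gaps tied for smallest -> the smallest-index SNP among all SNPs flanking
# those gaps; residual ties -> the smaller position. The hot path uses a
# binary heap over gaps with lazy invalidation plus doubly-linked neighbour
# arrays (O(n log n) overall); it is oracle-tested against a naive
# re-scan-per-iteration implementation.

#' Allocate per-chromosome, per-region SNP quotas
#'
#' The raw quota of region j of chromosome i is `L_ij / T_j * W_j`, where
#' `L_ij` is the region's sequence length, `T_j` the total length of that
#' region class over all chromosomes and `W_j` the total number of SNPs to
#' select in the class. Raw quotas are integerized by largest remainder so
#' that each class total is met exactly (remainder ties broken by larger
#' length, then chromosome order).
#'
#' @param partitions a [chrom_partition()].
#' @param w_euch,w_het total SNPs to select in euchromatic / heterochromatic
#'   regions (W_1, W_2).
#' @return data.frame of class `quota_plan`: `chrom`, `region_class`,
#'   `length_bp`, `raw`, `quota`.
#' @export
allocate_quotas <- function(partitions, w_euch, w_het) {
  stopifnot(w_euch > 0, w_het > 0)
  lens <- region_lengths(partitions)
  plan <- do.call(rbind, lapply(c("euchromatic", "heterochromatic"), function(rc) {
    w <- if (rc == "euchromatic") w_euch else w_het
    sub <- lens[lens$region_class == rc, , drop = FALSE]
    total <- sum(as.numeric(sub$length_bp))
    if (total <= 0) stop("zero total length for ", rc, " regions")
    raw <- sub$length_bp / total * w
    q <- floor(raw)
    left <- w - sum(q)
    if (left > 0) {
      o <- order(-(raw - q), -sub$length_bp, seq_len(nrow(sub)))
      q[o[seq_len(left)]] <- q[o[seq_len(left)]] + 1
    }
    sub$raw <- raw
    sub$quota <- as.integer(q)
    sub
  }))
  rownames(plan) <- NULL
  class(plan) <- c("quota_plan", "data.frame")
  plan
}

#' Expected SNP count of a region at a stated design density
#'
#' Convenience for checking quota arithmetic against a published per-Mb
#' density: `round(length_bp * density_per_mb / 1e6)`.
#'
#' @param length_bp region length in bp.
#' @param density_per_mb SNPs per Mb.
#' @return integer expected count.
#' @export
expected_count_at_density <- function(length_bp, density_per_mb) {
  as.integer(round(as.numeric(length_bp) * density_per_mb / 1e6))
}

# ---- binary min-heap on (gap, left-snp) with lazy invalidation ------------

heap_new <- function(cap) {
  env <- new.env(parent = emptyenv())
  env$g <- numeric(cap)    # gap value
  env$l <- integer(cap)    # left snp of the gap
  env$v <- integer(cap)    # version stamp of the entry
  env$n <- 0L
  env
}

heap_push <- function(h, gap, left, ver) {
  n <- h$n + 1L
  if (n > length(h$g)) {  # grow
    h$g <- c(h$g, numeric(length(h$g)))
    h$l <- c(h$l, integer(length(h$l)))
    h$v <- c(h$v, integer(length(h$v)))
  }
  h$g[n] <- gap; h$l[n] <- left; h$v[n] <- ver; h$n <- n
  i <- n
  while (i > 1L) {
    p <- i %/% 2L
    if (h$g[p] <= h$g[i]) break
    tg <- h$g[p]; h$g[p] <- h$g[i]; h$g[i] <- tg
    tl <- h$l[p]; h$l[p] <- h$l[i]; h$l[i] <- tl
    tv <- h$v[p]; h$v[p] <- h$v[i]; h$v[i] <- tv
    i <- p
  }
  invisible(h)
}

heap_pop <- function(h) {
  n <- h$n
  out <- c(h$g[1L], h$l[1L], h$v[1L])
  h$g[1L] <- h$g[n]; h$l[1L] <- h$l[n]; h$v[1L] <- h$v[n]
  h$n <- n - 1L
  n <- n - 1L
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L
    s <- i
    if (l <= n && h$g[l] < h$g[s]) s <- l
    if (r <= n && h$g[r] < h$g[s]) s <- r
    if (s == i) break
    tg <- h$g[s]; h$g[s] <- h$g[i]; h$g[i] <- tg
    tl <- h$l[s]; h$l[s] <- h$l[i]; h$l[i] <- tl
    tv <- h$v[s]; h$v[s] <- h$v[i]; h$v[i] <- tv
    i <- s
  }
  out
}

#' Iterative smallest-gap thinning of one chromosome region
#'
#' Removes SNPs one at a time (see the tie-break cascade above) until
#' `quota` remain. Positions must be sorted strictly increasing.
#'
#' @param pos integer positions, sorted increasing.
#' @param index selection index of each SNP.
#' @param quota number of SNPs to retain.
#' @return integer indices (into `pos`) of the retained SNPs, increasing.
#' @export
thin_by_iteration <- function(pos, index, quota) {
  n <- length(pos)
  stopifnot(length(index) == n, quota >= 0)
  if (n > 1L && any(diff(pos) <= 0)) stop("positions must be sorted, strictly increasing")
  if (quota >= n) {
    if (quota > n) warning("quota ", quota, " exceeds available SNPs (", n,
                           "); all retained")
    return(seq_len(n))
  }
  if (quota == 0L) return(integer(0))
  pos <- as.numeric(pos)
  alive <- rep(TRUE, n)
  prv <- c(0L, seq_len(n - 1L))
  nxt <- c(seq_len(n - 1L) + 1L, 0L)
  ver <- integer(n)                       # gap version per left snp
  gapv <- c(diff(pos), NA_real_)          # current gap to the right of i
  h <- heap_new(2L * n)
  for (i in seq_len(n - 1L)) heap_push(h, gapv[i], i, 0L)
  n_alive <- n

  adj_gaps <- function(s) {
    lg <- if (prv[s] > 0L) gapv[prv[s]] else Inf
    rg <- if (nxt[s] > 0L) gapv[s] else Inf
    c(lg, rg)
  }

  while (n_alive > quota) {
    # pop every valid entry tied at the current minimum gap
    repeat {
      e <- heap_pop(h)
      if (alive[e[2]] && nxt[e[2]] > 0L && e[3] == ver[e[2]]) break
    }
    gmin <- e[1]
    stash <- list(e)                     # valid entries tied at gmin
    while (h$n > 0L && h$g[1L] <= gmin) {
      e2 <- heap_pop(h)
      if (alive[e2[2]] && nxt[e2[2]] > 0L && e2[3] == ver[e2[2]]) {
        stash[[length(stash) + 1L]] <- e2
      }
    }
    tied_left <- as.integer(vapply(stash, `[`, numeric(1), 2L))
    cand <- unique(c(tied_left, nxt[tied_left]))
    # tie-break cascade: min index, then min other-gap, then min position
    ci <- index[cand]
    cand <- cand[ci == min(ci)]
    if (length(cand) > 1L) {
      other <- vapply(cand, function(s) {
        g2 <- adj_gaps(s)
        k <- which(g2 == gmin)
        if (length(k) >= 2L) gmin else min(g2[-k[1L]])
      }, numeric(1))
      cand <- cand[other == min(other)]
      if (length(cand) > 1L) cand <- cand[which.min(pos[cand])]
    }
    s <- cand[1L]
    # unlink s and form the bridged gap
    p <- prv[s]; q <- nxt[s]
    alive[s] <- FALSE
    ver[s] <- ver[s] + 1L
    if (p > 0L) {
      ver[p] <- ver[p] + 1L
      nxt[p] <- q
    }
    if (q > 0L) prv[q] <- p
    if (p > 0L && q > 0L) {
      gapv[p] <- pos[q] - pos[p]
      heap_push(h, gapv[p], p, ver[p])
    }
    # re-insert surviving tied entries (their gaps may still be minimal)
    for (e2 in stash) {
      if (alive[e2[2]] && nxt[e2[2]] > 0L && e2[3] == ver[e2[2]]) {
        heap_push(h, e2[1], e2[2], e2[3])
      }
    }
    n_alive <- n_alive - 1L
  }
  which(alive)
}

#' Select SNPs on unanchored scaffolds
#'
#' Scaffolds are ranked by length, longest first; the budget is spent
#' round-robin in that order, taking each scaffold's best remaining SNP by
#' selection index (ties by position) one pass at a time.
#'
#' @param catalog [snp_catalog()] of scaffold candidates with `index_score`.
#' @param scaffold_lengths named vector of scaffold lengths (bp).
#' @param budget number of SNPs to select.
#' @return the selected catalog rows.
#' @export
select_scaffold_snps <- function(catalog, scaffold_lengths, budget) {
  stopifnot(budget >= 0)
  if (budget == 0L || !nrow(catalog)) return(catalog[integer(0), , drop = FALSE])
  scaf <- intersect(names(sort(scaffold_lengths, decreasing = TRUE)),
                    unique(catalog$chrom))
  ranked <- lapply(scaf, function(s) {
    rows <- which(catalog$chrom == s)
    rows[order(-catalog$index_score[rows], catalog$pos[rows])]
  })
  picked <- integer(0)
  round <- 1L
  while (length(picked) < budget) {
    avail <- vapply(ranked, length, integer(1)) >= round
    if (!any(avail)) break
    for (k in which(avail)) {
      picked <- c(picked, ranked[[k]][round])
      if (length(picked) == budget) break
    }
    round <- round + 1L
  }
  catalog[picked, , drop = FALSE]
}

#' Build the full SNP panel
#'
#' Allocates quotas from the chromosome partitions, thins every
#' chromosome-by-region candidate set independently with
#' [thin_by_iteration()], and appends scaffold selections.
#'
#' @param catalog scored [snp_catalog()] (with `index_score`).
#' @param partitions a [chrom_partition()] covering the anchored
#'   chromosomes; candidates on other sequences are treated as scaffold
#'   candidates.
#' @param w_euch,w_het per-class selection totals.
#' @param scaffold_budget SNPs to select from unanchored scaffolds.
#' @param scaffold_lengths named lengths of the scaffolds (required when
#'   `scaffold_budget > 0`).
#' @return list of class `snp_panel`: `selected` (catalog with
#'   `region_class`), `quota_plan`, `shortfalls` (regions with fewer
#'   candidates than quota).
#' @export
build_panel <- function(catalog, partitions, w_euch, w_het,
                        scaffold_budget = 0L, scaffold_lengths = NULL) {
  stopifnot(inherits(catalog, "snp_catalog"))
  if (any(is.na(catalog$index_score))) {
    stop("all candidates need an index score; run compute_index() first")
  }
  anchored <- catalog$chrom %in% partitions$chrom
  plan <- allocate_quotas(partitions, w_euch, w_het)
  cat_a <- catalog[anchored, , drop = FALSE]
  cat_a$region_class <- NA_character_
  for (ch in unique(cat_a$chrom)) {
    i <- cat_a$chrom == ch
    cat_a$region_class[i] <- region_class(partitions, ch, cat_a$pos[i])
  }
  picked <- list()
  shortfalls <- list()
  for (r in seq_len(nrow(plan))) {
    ch <- plan$chrom[r]; rc <- plan$region_class[r]; q <- plan$quota[r]
    rows <- which(cat_a$chrom == ch & cat_a$region_class == rc)
    rows <- rows[order(cat_a$pos[rows])]
    if (length(rows) < q) {
      shortfalls[[length(shortfalls) + 1L]] <-
        data.frame(chrom = ch, region_class = rc, quota = q,
                   available = length(rows), stringsAsFactors = FALSE)
      picked[[length(picked) + 1L]] <- rows
      next
    }
    keep <- thin_by_iteration(cat_a$pos[rows], cat_a$index_score[rows], q)
    picked[[length(picked) + 1L]] <- rows[keep]
  }
  sel <- cat_a[sort(unlist(picked)), , drop = FALSE]
  if (scaffold_budget > 0L) {
    if (is.null(scaffold_lengths)) stop("scaffold_lengths required")
    scf <- select_scaffold_snps(catalog[!anchored, , drop = FALSE],
                                scaffold_lengths, scaffold_budget)
    if (nrow(scf)) {
      scf$region_class <- "scaffold"
      sel <- rbind(sel, scf)
    }
  }
  shortfalls <- if (length(shortfalls)) do.call(rbind, shortfalls) else
    data.frame(chrom = character(), region_class = character(),
               quota = integer(), available = integer())
  if (nrow(shortfalls)) {
    warning(nrow(shortfalls), " region(s) had fewer candidates than quota")
  }
  structure(list(selected = sel, quota_plan = plan, shortfalls = shortfalls),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  tab <- table(x$selected$region_class)
  cat(sprintf("<snp_panel> %d SNPs (%s)\n", nrow(x$selected),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
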