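# chromatin_partition: heterochromatin as the recombination-suppressed
# middle segment of the Marey map (cumulative cM against bp).
#
# "Inflection points" are operationalized as the two breakpoints of a
# continuous three-segment least-squares piecewise-linear fit, searched on
# the grid of observed marker positions; the middle segment must have the
# strictly smallest slope.

#' Construct a chromosome partition table
#'
#' @param chrom chromosome names.
#' @param length_bp chromosome lengths (bp).
#' @param het_start,het_end 1-based inclusive bounds of the single central
#'   heterochromatic interval.
#' @return data.frame of class `chrom_partition`.
#' @export
chrom_partition <- function(chrom, length_bp, het_start, het_end) {
  df <- data.frame(chrom = as.character(chrom),
                   length_bp = as.integer(length_bp),
                   het_start = as.integer(het_start),
                   het_end = as.integer(het_end),
                   stringsAsFactors = FALSE)
  bad <- df$het_start < 1L | df$het_end < df$het_start |
    df$het_end > df$length_bp
  if (any(bad)) stop("invalid heterochromatic interval for: ",
                     paste(df$chrom[bad], collapse = ", "))
  class(df) <- c("chrom_partition", "data.frame")
  df
}

# least-squares continuous 3-segment fit with hinge basis at (b1, b2);
# returns SSE and the three slopes
pwl_fit <- function(x, y, H, i, j) {
  X <- cbind(1, x, H[, i], H[, j])
  f <- .lm.fit(X, y)
  beta <- f$coefficients
  slopes <- c(beta[2], beta[2] + beta[3], beta[2] + beta[3] + beta[4])
  list(sse = sum(f$residuals^2), slopes = slopes)
}

#' Fit the euchromatin/heterochromatin partition of one chromosome
#'
#' Fits a continuous three-segment piecewise-linear model of genetic
#' position (cM) against physical position (bp), searching both breakpoints
#' over the observed marker positions, and requires the middle segment's
#' slope (recombination rate) to be strictly the smallest. The middle
#' segment is reported as the heterochromatic interval; its ends snap to
#' map points.
#'
#' @param points data.frame for one chromosome with columns `cm` and `bp`
#'   (as from [read_linkage_map()]); at least 6 points.
#' @param chrom_length chromosome length in bp.
#' @param chrom chromosome name recorded in the result (defaults to the
#'   `chrom` column of `points` if present).
#' @param min_points minimum number of map points per segment.
#' @return one-row [chrom_partition()] with attributes `sse` (fit residual
#'   sum of squares) and `slopes` (cM/bp per segment).
#' @export
fit_partition <- function(points, chrom_length, chrom = NULL,
                          min_points = 2L) {
  if (is.null(chrom)) chrom <- unique(as.character(points$chrom)) %||% "chr"
  stopifnot(length(chrom) == 1L)
  o <- order(points$bp)
  x <- as.numeric(points$bp[o])
  y <- as.numeric(points$cm[o])
  n <- length(x)
  if (n < 6L) stop("need at least 6 map points, got ", n)
  # hinge columns for every candidate breakpoint (= observed position)
  H <- outer(x, x, function(a, b) pmax(a - b, 0))
  lo <- min_points + 1L           # leave >= min_points on the left arm
  hi <- n - min_points            # ... and on the right arm
  best <- NULL
  for (i in lo:(hi - 1L)) {
    for (j in (i + 1L):hi) {
      f <- pwl_fit(x, y, H, i, j)
      s <- f$slopes
      tol <- 1e-9 * max(abs(s), 1e-12)
      if (s[2] < s[1] - tol && s[2] < s[3] - tol) {
        if (is.null(best) || f$sse < best$sse) {
          best <- list(sse = f$sse, i = i, j = j, slopes = s)
        }
      }
    }
  }
  if (is.null(best)) stop("no suppressed-recombination region detected")
  part <- chrom_partition(chrom, chrom_length, x[best$i], x[best$j])
  attr(part, "sse") <- best$sse
  attr(part, "slopes") <- best$slopes
  part
}

#' Fit partitions for every chromosome of a linkage map
#'
#' @param map data.frame from [read_linkage_map()].
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @inheritParams fit_partition
#' @return [chrom_partition()] with one row per chromosome.
#' @export
fit_partitions <- function(map, chrom_lengths, min_points = 2L) {
  chroms <- unique(map$chrom)
  missing_len <- setdiff(chroms, names(chrom_lengths))
  if (length(missing_len)) stop("no length for chromosome(s): ",
                                paste(missing_len, collapse = ", "))
  parts <- lapply(chroms, function(ch) {
    fit_partition(map[map$chrom == ch, , drop = FALSE],
                  chrom_lengths[[ch]], chrom = ch, min_points = min_points)
  })
  out <- do.call(rbind, parts)
  class(out) <- c("chrom_partition", "data.frame")
  out
}

#' Classify a position as euchromatic or heterochromatic
#'
#' @param partition a [chrom_partition()].
#' @param chrom chromosome name.
#' @param pos 1-based position(s).
#' @return character vector, `"euchromatic"` or `"heterochromatic"`;
#'   the heterochromatic interval is inclusive on both ends.
#' @export
region_class <- function(partition, chrom, pos) {
  row <- partition[partition$chrom == chrom, , drop = FALSE]
  if (nrow(row) != 1L) stop("no partition for chromosome ", chrom)
  if (any(pos < 1L | pos > row$length_bp)) {
    stop("position out of range for ", chrom)
  }
  ifelse(pos >= row$het_start & pos <= row$het_end,
         "heterochromatic", "euchromatic")
}

# per-region lengths used by quota allocation and gap statistics
region_lengths <- function(partition) {
  het <- partition$het_end - partition$het_start + 1L
  data.frame(chrom = rep(partition$chrom, 2L),
             region_class = rep(c("euchromatic", "heterochromatic"),
                                each = nrow(partition)),
             length_bp = c(partition$length_bp - het, het),
             stringsAsFactors = FALSE)
}
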