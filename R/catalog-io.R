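# catalog_io: file formats and the shared in-memory data model.
#
# Canonical containers:
#   snp_catalog      data.frame (one row per candidate) with an `observations`
#                    list-column of per-genotype evidence
#   chrom_partition  data.frame: chrom, length_bp, het_start, het_end
#   genotype_matrix  list: calls (loci x samples character matrix of
#                    AA/AB/BB/NA), loci (data.frame id, chrom, pos),
#                    populations (named character, sample -> population)
# All in-memory coordinates are 1-based inclusive; BED output is 0-based
# half-open.

CATALOG_REQUIRED <- c("id", "chrom", "pos", "ref", "alt", "design_score")
CATALOG_OPTIONAL <- c("flank_left", "flank_right", "observations",
                      "mixed_pool_code", "known_validated",
                      "priority_group", "index_score")

#' Construct a SNP candidate catalog
#'
#' @param df data.frame with at least columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`, `design_score`; optional `flank_left`, `flank_right`,
#'   `observations` (list-column of data.frames with `genotype_id`, `allele`,
#'   `depth`), `mixed_pool_code`, `known_validated`, `priority_group`,
#'   `index_score`.
#' @return the validated data.frame with class `snp_catalog`.
#' @export
snp_catalog <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(CATALOG_REQUIRED, names(df))
  if (length(missing_cols)) {
    stop("catalog is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$id <- as.character(df$id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  df$design_score <- as.numeric(df$design_score)
  n <- nrow(df)
  if (is.null(df$flank_left)) df$flank_left <- rep(NA_character_, n)
  if (is.null(df$flank_right)) df$flank_right <- rep(NA_character_, n)
  if (is.null(df$mixed_pool_code)) df$mixed_pool_code <- rep(NA_character_, n)
  if (is.null(df$known_validated)) df$known_validated <- rep(FALSE, n)
  df$known_validated[is.na(df$known_validated)] <- FALSE
  if (is.null(df$priority_group)) df$priority_group <- rep(NA_character_, n)
  if (is.null(df$index_score)) df$index_score <- rep(NA_real_, n)
  if (is.null(df$observations)) {
    df$observations <- replicate(nrow(df), empty_observations(), simplify = FALSE)
  }
  if (nrow(df)) {
    if (any(df$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
    same <- !is.na(df$ref) & !is.na(df$alt) & df$ref == df$alt
    if (any(same)) stop("ref and alt allele identical for: ",
                        paste(df$id[same], collapse = ", "))
    bad_d <- !is.na(df$design_score) &
      (df$design_score < 0 | df$design_score > 1)
    if (any(bad_d)) stop("design_score outside [0,1] for: ",
                         paste(df$id[bad_d], collapse = ", "))
  }
  canon <- c(CATALOG_REQUIRED, CATALOG_OPTIONAL)
  df <- df[c(canon, setdiff(names(df), canon))]
  rownames(df) <- NULL
  class(df) <- c("snp_catalog", "data.frame")
  df
}

empty_observations <- function() {
  data.frame(genotype_id = character(), allele = character(),
             depth = integer(), stringsAsFactors = FALSE)
}

#' @export
print.snp_catalog <- function(x, ...) {
  cat(sprintf("<snp_catalog> %d candidate(s) on %d sequence(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print(utils::head(as.data.frame(x)[setdiff(names(x), "observations")]))
  invisible(x)
}

# "g1:A:5;g2:G:2" <-> observations data.frame
parse_observations <- function(s) {
  if (is.na(s) || !nzchar(s)) return(empty_observations())
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad)) stop("malformed observation triplet: ",
                     paste(vapply(parts[bad], paste, "", collapse = ":"), collapse = "; "))
  data.frame(genotype_id = vapply(parts, `[`, "", 1L),
             allele = vapply(parts, `[`, "", 2L),
             depth = as.integer(vapply(parts, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

format_observations <- function(obs) {
  if (is.null(obs) || !nrow(obs)) return("")
  paste(sprintf("%s:%s:%d", obs$genotype_id, obs$allele, as.integer(obs$depth)),
        collapse = ";")
}

#' Read a candidate SNP catalog from TSV
#'
#' Tab-separated file with a header row; `#`-prefixed lines are comments.
#' Required columns: `id`, `chrom`, `pos`, `ref`, `alt`, `design_score`.
#' Optional: `flank_left`, `flank_right`, `observations` (semicolon-delimited
#' `genotype:allele:depth` triplets, `allele` a nucleotide or `both`),
#' `mixed_pool_code`, `known_validated`, `priority_group`, `index_score`.
#' Rows with a missing design score are dropped (the selection index is
#' undefined without one) and the count is reported via a message.
#'
#' @param path file path.
#' @return a [snp_catalog()].
#' @export
read_candidate_catalog <- function(path) {
  raw <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    colClasses = "character", stringsAsFactors = FALSE,
                    check.names = FALSE)
  missing_cols <- setdiff(CATALOG_REQUIRED, names(raw))
  if (length(missing_cols)) {
    stop("catalog format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!nrow(raw)) {
    return(snp_catalog(data.frame(id = character(), chrom = character(),
                                  pos = integer(), ref = character(),
                                  alt = character(), design_score = numeric())))
  }
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1 (comments aside)
  pos <- suppressWarnings(as.numeric(raw$pos))
  ds <- suppressWarnings(as.numeric(raw$design_score))
  ds[!nzchar(raw$design_score)] <- NA_real_
  bad_pos <- is.na(pos) | pos != floor(pos)
  bad_ds <- !is.na(raw$design_score) & nzchar(raw$design_score) &
    is.na(suppressWarnings(as.numeric(raw$design_score)))
  if (any(bad_pos) || any(bad_ds)) {
    msgs <- c(
      if (any(bad_pos)) sprintf("non-integer pos at line(s) %s",
                                paste(line_no[bad_pos], collapse = ", ")),
      if (any(bad_ds)) sprintf("non-numeric design_score at line(s) %s",
                               paste(line_no[bad_ds], collapse = ", ")))
    stop("catalog row error(s): ", paste(msgs, collapse = "; "))
  }
  drop <- is.na(ds)
  if (any(drop)) {
    message(sum(drop), " candidate(s) without design score excluded")
    raw <- raw[!drop, , drop = FALSE]
    pos <- pos[!drop]; ds <- ds[!drop]
  }
  obs_col <- if ("observations" %in% names(raw)) raw$observations else
    rep("", nrow(raw))
  obs_col[is.na(obs_col)] <- ""
  df <- data.frame(id = raw$id, chrom = raw$chrom, pos = as.integer(pos),
                   ref = raw$ref, alt = raw$alt, design_score = ds,
                   stringsAsFactors = FALSE)
  for (cc in c("flank_left", "flank_right", "mixed_pool_code", "priority_group")) {
    if (cc %in% names(raw)) {
      v <- raw[[cc]]
      v[!nzchar(v)] <- NA_character_
      df[[cc]] <- v
    }
  }
  if ("known_validated" %in% names(raw)) {
    df$known_validated <- toupper(raw$known_validated) %in% c("TRUE", "T", "1", "YES")
  }
  if ("index_score" %in% names(raw)) {
    v <- suppressWarnings(as.numeric(raw$index_score))
    df$index_score <- v
  }
  df$observations <- lapply(obs_col, parse_observations)
  snp_catalog(df)
}

#' Write a candidate catalog to TSV
#'
#' Inverse of [read_candidate_catalog()]; `write` then `read` round-trips the
#' catalog exactly.
#'
#' @param catalog a [snp_catalog()].
#' @param path output path.
#' @param seed seed recorded in the header comment (informational).
#' @export
write_candidate_catalog <- function(catalog, path, seed = NULL) {
  stopifnot(inherits(catalog, "snp_catalog"))
  out <- as.data.frame(catalog)
  out$observations <- vapply(catalog$observations, format_observations, "")
  out$known_validated <- ifelse(out$known_validated, "TRUE", "FALSE")
  cols <- c(CATALOG_REQUIRED, intersect(CATALOG_OPTIONAL, names(out)))
  write_tsv_with_header(out[cols], path, seed)
}

#' Read a linkage map (Marey-map input)
#'
#' TSV with columns `marker`, `chrom`, `cm`, `bp`. Points are sorted by
#' (chrom, bp); duplicate physical positions within a chromosome are
#' collapsed to the first occurrence with a warning. A genetic position that
#' decreases with bp by more than `tol` cM triggers a warning (map noise),
#' not an error.
#'
#' @param path file path.
#' @param tol tolerated cM decrease between consecutive markers.
#' @return data.frame `marker`, `chrom`, `cm`, `bp`, sorted.
#' @export
read_linkage_map <- function(path, tol = 1e-6) {
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "cm", "bp")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("linkage map missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!nrow(df)) stop("no map points")
  df$cm <- as.numeric(df$cm)
  df$bp <- as.integer(df$bp)
  df <- df[order(df$chrom, df$bp), , drop = FALSE]
  dup <- duplicated(df[c("chrom", "bp")])
  if (any(dup)) {
    warning(sum(dup), " duplicate physical position(s) dropped from map")
    df <- df[!dup, , drop = FALSE]
  }
  dec <- unlist(tapply(df$cm, df$chrom, function(x) c(FALSE, diff(x) < -tol)),
                use.names = FALSE)
  if (any(dec)) {
    warning(sum(dec), " map point(s) with decreasing genetic position (map noise)")
  }
  rownames(df) <- NULL
  df[need]
}

#' Construct a genotype matrix
#'
#' @param calls character matrix (loci x samples) with values `AA`, `AB`,
#'   `BB` or `NA`; rownames are locus ids, colnames sample ids.
#' @param loci data.frame with `id`, `chrom`, `pos` matching the rows.
#' @param populations named character vector mapping every sample to a
#'   population label.
#' @return list with class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, loci, populations) {
  stopifnot(is.matrix(calls), is.data.frame(loci))
  if (nrow(calls) != nrow(loci)) stop("calls/loci dimension mismatch")
  ok <- calls %in% c("AA", "AB", "BB") | is.na(calls)
  if (!all(ok)) stop("invalid genotype call(s): ",
                     paste(unique(calls[!ok]), collapse = ", "))
  samples <- colnames(calls)
  if (is.null(samples)) stop("calls must have sample column names")
  unlabeled <- setdiff(samples, names(populations))
  if (length(unlabeled)) {
    stop("sample(s) without population label: ",
         paste(unlabeled, collapse = ", "))
  }
  rownames(calls) <- loci$id
  structure(list(calls = calls,
                 loci = data.frame(id = as.character(loci$id),
                                   chrom = as.character(loci$chrom),
                                   pos = as.integer(loci$pos),
                                   stringsAsFactors = FALSE),
                 populations = populations[samples]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d loci x %d samples; populations: %s\n",
              nrow(x$calls), ncol(x$calls),
              paste(sprintf("%s=%d", names(table(x$populations)),
                            table(x$populations)), collapse = ", ")))
  invisible(x)
}

#' Read genotypes from VCF or a simple call matrix
#'
#' VCF input (diploid GT field) is converted to `AA` (homozygous reference),
#' `AB` (heterozygous), `BB` (homozygous alternate), missing to `NA`.
#' TSV input has columns `id`, `chrom`, `pos` followed by one column per
#' sample with values AA/AB/BB (empty or NA = missing). A population-label
#' TSV (`sample`, `population`) is required either way.
#'
#' @param path VCF (`.vcf`) or matrix TSV.
#' @param labels_path TSV with columns `sample`, `population`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, labels_path) {
  lab <- read.delim(labels_path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(lab))) {
    stop("label file needs columns: sample, population")
  }
  populations <- setNames(as.character(lab$population), as.character(lab$sample))
  first <- readLines(path, n = 1L)
  is_vcf <- grepl("\\.vcf$", path, ignore.case = TRUE) ||
    startsWith(first, "##fileformat=VCF")
  if (is_vcf) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    fix <- vcfR::getFIX(v)
    loci <- data.frame(id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                   paste0(fix[, "CHROM"], "_", fix[, "POS"]),
                                   fix[, "ID"]),
                       chrom = fix[, "CHROM"],
                       pos = as.integer(fix[, "POS"]),
                       stringsAsFactors = FALSE)
    calls <- matrix(NA_character_, nrow(gt), ncol(gt),
                    dimnames = dimnames(gt))
    g <- gsub("|", "/", gt, fixed = TRUE)
    calls[g %in% c("0/0")] <- "AA"
    calls[g %in% c("0/1", "1/0")] <- "AB"
    calls[g %in% c("1/1")] <- "BB"
  } else {
    df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                     colClasses = "character", stringsAsFactors = FALSE,
                     check.names = FALSE)
    need <- c("id", "chrom", "pos")
    if (!all(need %in% names(df))) {
      stop("genotype matrix TSV needs columns: id, chrom, pos, <samples...>")
    }
    loci <- data.frame(id = df$id, chrom = df$chrom, pos = as.integer(df$pos),
                       stringsAsFactors = FALSE)
    samp_cols <- setdiff(names(df), need)
    calls <- as.matrix(df[samp_cols])
    calls[calls == "" | calls == "NA"] <- NA_character_
  }
  genotype_matrix(calls, loci, populations)
}

#' Write a genotype matrix (plus labels) to TSV
#'
#' @param gm a [genotype_matrix()].
#' @param path matrix TSV path.
#' @param labels_path optional path for the population-label TSV.
#' @param seed recorded in the header comment.
#' @export
write_genotypes <- function(gm, path, labels_path = NULL, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  out <- cbind(gm$loci, as.data.frame(gm$calls, stringsAsFactors = FALSE))
  write_tsv_with_header(out, path, seed)
  if (!is.null(labels_path)) {
    write_tsv_with_header(
      data.frame(sample = names(gm$populations),
                 population = unname(gm$populations)),
      labels_path, seed)
  }
  invisible(path)
}

#' Write a selected panel to TSV
#'
#' Columns: `id`, `chrom`, `pos`, `group`, `index_score`, `region_class`.
#'
#' @param panel a `snp_panel` (see [build_panel()]) or a data.frame with
#'   those columns.
#' @param path output path.
#' @param seed recorded in the header comment.
#' @export
write_panel <- function(panel, path, seed = NULL) {
  sel <- if (inherits(panel, "snp_panel")) panel$selected else panel
  df <- data.frame(id = sel$id, chrom = sel$chrom, pos = sel$pos,
                   group = sel$priority_group %||% sel$group,
                   index_score = sel$index_score,
                   region_class = sel$region_class %||% NA_character_,
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, seed)
}

#' Read a panel TSV written by [write_panel()]
#' @param path file path.
#' @return data.frame `id`, `chrom`, `pos`, `group`, `index_score`,
#'   `region_class`.
#' @export
read_panel <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  df$pos <- as.integer(df$pos)
  df$index_score <- as.numeric(df$index_score)
  df
}

#' Write genomic regions as BED
#'
#' In-memory regions are 1-based inclusive (`chrom`, `start`, `end`); BED
#' output is 0-based half-open, so a region `[2700001, 2800000]` becomes
#' `2700000 2800000`.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (1-based inclusive)
#'   and optionally `name`.
#' @param path output path.
#' @param seed recorded in the header comment.
#' @export
write_regions <- function(regions, path, seed = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  bed <- data.frame(chrom = regions$chrom,
                    start = as.integer(regions$start) - 1L,
                    end = as.integer(regions$end),
                    stringsAsFactors = FALSE)
  if (!is.null(regions$name)) bed$name <- regions$name
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(pf_header(seed), con)
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into 1-based inclusive regions
#' @param path BED path (3+ columns; `#` comments ignored).
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive), `name` if
#'   present.
#' @export
read_regions <- function(path) {
  df <- read.delim(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]) + 1L,
                    end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$name <- as.character(df[[4]])
  out
}

#' Read gene models from GFF3
#'
#' Wraps [rtracklayer::import()] and restructures features into the interval
#' sets needed by [annotate_genic()]: gene spans, CDS, five/three prime UTRs
#' and exons (introns are derived as gene minus exon).
#'
#' @param path GFF3 path.
#' @return list of `GRanges`: `genes`, `cds`, `five_utr`, `three_utr`,
#'   `exons`.
#' @export
read_gene_models <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  type <- as.character(g$type)
  list(genes = g[type == "gene"],
       cds = g[type == "CDS"],
       five_utr = g[type %in% c("five_prime_UTR", "5UTR")],
       three_utr = g[type %in% c("three_prime_UTR", "3UTR")],
       exons = g[type == "exon"])
}
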