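# shared helpers: IUPAC codes, seeded RNG scoping, writer headers

#' Nucleotide set encoded by an IUPAC ambiguity code
#'
#' @param code single IUPAC character (case-insensitive).
#' @return character vector of the bases the code stands for.
#' @examples
#' iupac_bases("R") # A G
#' @export
iupac_bases <- function(code) {
  stopifnot(length(code) == 1L, is.character(code))
  map <- Biostrings::IUPAC_CODE_MAP
  code <- toupper(code)
  if (!code %in% names(map)) stop("not an IUPAC code: ", code)
  strsplit(map[[code]], "")[[1]]
}

#' IUPAC code for a set of nucleotides
#' @param bases character vector drawn from A,C,G,T.
#' @return single IUPAC character.
#' @export
iupac_code <- function(bases) {
  map <- Biostrings::IUPAC_CODE_MAP
  key <- paste(sort(unique(toupper(bases))), collapse = "")
  hit <- names(map)[vapply(map, function(x) {
    paste(sort(strsplit(x, "")[[1]]), collapse = "") == key
  }, logical(1))]
  if (length(hit) != 1L) stop("no IUPAC code for bases: ", key)
  hit
}

# Evaluate `expr` under a deterministic RNG state derived from `seed`,
# restoring the caller's RNG state afterwards. All generators and the
# permutation test route their randomness through this.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage sub-seed from a master seed; keeps values inside the
# 32-bit integer range.
sub_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(stage) == 1L)
  offs <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 7919 + offs) %% 2147483587) + 1L
}

# header comment emitted by every writer (tool version + seed if known)
pf_header <- function(seed = NULL) {
  v <- as.character(utils::packageVersion("panelforge"))
  s <- if (is.null(seed)) "NA" else as.character(seed)
  sprintf("# panelforge %s; seed=%s", v, s)
}

write_tsv_with_header <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(pf_header(seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
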