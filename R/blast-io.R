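blast_outfmt6_cols <- c(
  "query_id", "subject_id", "pct_identity", "aln_length", "mismatches",
  "gap_opens", "q_start", "q_end", "s_start", "s_end", "evalue", "bitscore"
)

#' Read BLAST tabular (outfmt 6) homology hits
#'
#' Parses the standard 12-column tab-separated BLAST output.  Each line is one
#' HSP; several HSPs per query/subject pair are retained as separate rows
#' (aggregation to per-contig gene assignments is done by
#' [best_hit_per_contig()]).  No e-value or identity filtering is applied at
#' read time.
#'
#' @param path Path to a tab-separated file in BLAST `-outfmt 6` layout.
#' @return A tibble with the 12 standard columns: `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("BLAST tabular file not found: ", path))
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(
      query_id = character(), subject_id = character(),
      pct_identity = double(), aln_length = integer(), mismatches = integer(),
      gap_opens = integer(), q_start = integer(), q_end = integer(),
      s_start = integer(), s_end = integer(), evalue = double(),
      bitscore = double()
    ))
  }
  fields <- stringr::str_split(lines, "\t")
  nf <- lengths(fields)
  if (any(nf != 12)) {
    bad <- which(nf != 12)[1]
    abort(paste0(
      "line ", bad, ": expected 12 tab-separated columns, found ", nf[bad]
    ))
  }
  m <- matrix(unlist(fields), ncol = 12, byrow = TRUE)
  colnames(m) <- blast_outfmt6_cols
  col <- function(name) unname(m[, name, drop = TRUE])
  num <- function(col, what) {
    x <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(x)) {
      bad <- which(is.na(x))[1]
      abort(paste0("line ", bad, ": non-numeric ", what, " '", m[bad, col], "'"))
    }
    unname(x)
  }
  hits <- tibble(
    query_id = col("query_id"),
    subject_id = col("subject_id"),
    pct_identity = num("pct_identity", "percent identity"),
    aln_length = as.integer(num("aln_length", "alignment length")),
    mismatches = as.integer(num("mismatches", "mismatch count")),
    gap_opens = as.integer(num("gap_opens", "gap open count")),
    q_start = as.integer(num("q_start", "query start")),
    q_end = as.integer(num("q_end", "query end")),
    s_start = as.integer(num("s_start", "subject start")),
    s_end = as.integer(num("s_end", "subject end")),
    evalue = num("evalue", "e-value"),
    bitscore = num("bitscore", "bit score")
  )
  if (any(hits$bitscore < 0) || any(hits$evalue < 0)) {
    abort("negative bit score or e-value in BLAST table")
  }
  hits
}

#' Write homology hits in BLAST tabular (outfmt 6) layout
#'
#' @param hits A hit tibble with the columns produced by [read_blast_tab()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  stopifnot(all(blast_outfmt6_cols %in% names(hits)))
  readr::write_tsv(hits[blast_outfmt6_cols], path, col_names = FALSE)
  invisible(path)
}
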