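#' Read a flat gene-to-GO-slim annotation table
#'
#' Reads a two-column tab-separated file of `(gene_id, term_id)` pairs, one
#' pair per line.  Repeated pairs are de-duplicated.  Term identifiers are
#' treated as opaque strings; no ontology-graph propagation is performed (GO
#' slim mapping is assumed to have been done upstream).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene_id` and `term`, one row per distinct
#'   pair.
#' @export
read_go_annotations <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("GO annotation file not found: ", path))
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(gene_id = character(), term = character()))
  }
  fields <- stringr::str_split(lines, "\t")
  nf <- lengths(fields)
  bad <- which(nf != 2 | vapply(fields, function(f) any(!nzchar(f)), logical(1)))
  if (length(bad) > 0) {
    abort(paste0("line ", bad[1], ": expected two non-empty tab-separated fields"))
  }
  m <- matrix(unlist(fields), ncol = 2, byrow = TRUE)
  tibble(gene_id = m[, 1], term = m[, 2]) %>% distinct()
}
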