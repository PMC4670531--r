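#' Read CD-HIT cluster membership (.clstr)
#'
#' Parses the CD-HIT `.clstr` dialect: `>Cluster N` headers followed by member
#' lines of the form `0  800nt, >contig_id... *` where the trailing `*` marks
#' the cluster representative.
#'
#' @param path Path to a `.clstr` file.
#' @return A tibble with columns `cluster` (integer, file order starting at 1),
#'   `member_id` and `is_representative` (logical).  A cluster may lack a
#'   marked representative; downstream selection then falls back to the longest
#'   member.
#' @export
read_clstr <- function(path) {
  if (!file.exists(path)) {
    abort(paste0(".clstr file not found: ", path))
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  if (length(lines) == 0) {
    return(tibble(
      cluster = integer(), member_id = character(),
      is_representative = logical()
    ))
  }
  is_header <- stringr::str_starts(lines, ">")
  if (!is_header[1]) {
    abort("line 1: cluster member line before any '>Cluster' header")
  }
  cluster <- cumsum(is_header)
  members <- lines[!is_header]
  ids <- stringr::str_match(members, ">([^.\\s]+)")[, 2]
  if (anyNA(ids)) {
    bad <- which(!is_header)[which(is.na(ids))[1]]
    abort(paste0("line ", bad, ": cannot parse member identifier"))
  }
  tibble(
    cluster = cluster[!is_header],
    member_id = ids,
    is_representative = stringr::str_ends(stringr::str_trim(members), "\\*")
  )
}

#' Write cluster membership in CD-HIT .clstr layout
#'
#' @param clusters Cluster tibble as produced by [read_clstr()] or
#'   [greedy_cluster()].
#' @param contigs Optional contig tibble supplying member lengths for the
#'   `nt` annotation (0 is written when absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clstr <- function(clusters, path, contigs = NULL) {
  stopifnot(all(c("cluster", "member_id", "is_representative") %in% names(clusters)))
  len <- if (is.null(contigs)) {
    rep(0L, nrow(clusters))
  } else {
    contigs$length[match(clusters$member_id, contigs$contig_id)]
  }
  len[is.na(len)] <- 0L
  out <- character(0)
  for (cl in unique(clusters$cluster)) {
    rows <- which(clusters$cluster == cl)
    out <- c(out, paste0(">Cluster ", cl - 1L))
    mark <- ifelse(clusters$is_representative[rows], " *", " at 100.00%")
    out <- c(out, paste0(
      seq_along(rows) - 1L, "\t", len[rows], "nt, >",
      clusters$member_id[rows], "...", mark
    ))
  }
  readr::write_lines(out, path)
  invisible(path)
}
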