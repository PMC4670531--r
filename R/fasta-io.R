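#' Read contigs or genes from a FASTA file
#'
#' Reads a nucleotide FASTA file into a contig table.  The sequence identifier
#' is the first whitespace-delimited token of the header line; the remainder of
#' the header is discarded.  Assembler-style identifiers (Trinity
#' `comp<i>_c<j>_seq<k>` or `TRINITY_DN<i>_c<j>_g<k>_i<l>`) are parsed into a
#' subcomponent key usable for isoform-level deduplication.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record and columns `contig_id`,
#'   `sequence`, `length` (bases) and `subcomponent_key`.  Row order follows
#'   file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1 some description", "ACGTACGT"), fa)
#' read_contig_fasta(fa)
read_contig_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  seqs <- Biostrings::readBStringSet(path)
  ids <- stringr::str_split_i(names(seqs), "\\s+", 1)
  if (anyNA(ids) || any(ids == "")) {
    abort("FASTA record with empty identifier")
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate FASTA identifier(s): ", paste(dup, collapse = ", ")))
  }
  sequence <- toupper(as.character(seqs))
  len <- Biostrings::width(seqs)
  if (any(len == 0)) {
    abort(paste0(
      "empty sequence for identifier(s): ",
      paste(ids[len == 0], collapse = ", ")
    ))
  }
  tibble(
    contig_id = unname(ids),
    sequence = unname(sequence),
    length = as.integer(len),
    subcomponent_key = parse_trinity_id(ids)
  )
}

#' Write a contig table to FASTA
#'
#' @param contigs A contig tibble as produced by [read_contig_fasta()]; only
#'   `contig_id` and `sequence` are used.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contig_fasta <- function(contigs, path) {
  stopifnot(all(c("contig_id", "sequence") %in% names(contigs)))
  set <- Biostrings::BStringSet(setNames(contigs$sequence, contigs$contig_id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Extract the subcomponent key from an assembler contig identifier
#'
#' Trinity groups putative isoforms of one transcribed locus into a
#' subcomponent and numbers the sequences within it.  Both common identifier
#' dialects are recognised: the classic `comp<i>_c<j>_seq<k>` (subcomponent
#' `comp<i>_c<j>`) and the newer `TRINITY_DN<i>_c<j>_g<k>_i<l>` (subcomponent
#' is everything before the trailing `_i<l>`).  Identifiers matching neither
#' scheme are returned unchanged, i.e. they form singleton subcomponents.
#'
#' @param contig_id Character vector of contig identifiers.
#' @return Character vector of subcomponent keys, same length as the input.
#' @export
#' @examples
#' parse_trinity_id(c("comp0_c0_seq1", "comp0_c0_seq2", "scaffold12"))
parse_trinity_id <- function(contig_id) {
  stopifnot(is.character(contig_id), all(nzchar(contig_id)))
  out <- contig_id
  classic <- stringr::str_detect(contig_id, "_seq\\d+$")
  out[classic] <- stringr::str_remove(contig_id[classic], "_seq\\d+$")
  newer <- !classic & stringr::str_detect(contig_id, "^TRINITY_DN\\d+_c\\d+_g\\d+_i\\d+$")
  out[newer] <- stringr::str_remove(contig_id[newer], "_i\\d+$")
  out
}
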