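#' Length-distribution summary of a contig or gene set
#'
#' Computes the count, minimum, median, N50 and mean length of a sequence set.
#' N50 follows the dominant convention: the length of the contig at which the
#' cumulative sum of descending-sorted lengths first reaches at least half of
#' the total assembled bases.  The median for an even number of sequences is
#' the lower middle value, so every reported statistic is an attained contig
#' length.  Mean length is reported unrounded; round for display.
#'
#' @param contigs Contig tibble with a `length` column, or a bare numeric
#'   vector of lengths.
#' @return A one-row tibble: `n`, `min_len`, `median_len`, `n50`, `mean_len`.
#' @export
#' @examples
#' summarize_lengths(c(2, 3, 4, 5, 6)) # N50 = 5
summarize_lengths <- function(contigs) {
  lens <- if (is.numeric(contigs)) contigs else contigs$length
  if (length(lens) == 0) {
    abort("cannot summarise an empty sequence set")
  }
  stopifnot(all(lens >= 1))
  sorted <- sort(lens, decreasing = TRUE)
  tibble(
    n = length(lens),
    min_len = min(lens),
    median_len = sorted[ceiling((length(lens) + 1) / 2)],
    n50 = contig_n50(lens),
    mean_len = mean(lens)
  )
}

#' @rdname summarize_lengths
#' @param lengths Numeric vector of sequence lengths.
#' @export
contig_n50 <- function(lengths) {
  stopifnot(length(lengths) >= 1, all(lengths >= 1))
  sorted <- sort(lengths, decreasing = TRUE)
  sorted[which(cumsum(sorted) >= sum(sorted) / 2)[1]]
}

#' Length summaries for several contig sets at once
#'
#' @param contig_sets Named list of contig tibbles (or length vectors).
#' @return A tibble with one row per set (column `contig_set` first), in the
#'   usual assembly-report column order.
#' @export
summarize_contig_sets <- function(contig_sets) {
  stopifnot(length(contig_sets) > 0, !is.null(names(contig_sets)))
  purrr::imap(contig_sets, function(x, nm) {
    summarize_lengths(x) %>% mutate(contig_set = nm, .before = 1)
  }) %>% bind_rows()
}
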