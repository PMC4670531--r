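#' Read per-feature read counts from a TSV table or a SAM/BAM file
#'
#' Two input styles are accepted.  A two-column tab-separated table
#' (`feature_id`, `count`) is read as-is; its library size defaults to the sum
#' of the listed counts.  A SAM or BAM file is counted directly: one count per
#' mapped, primary, non-supplementary alignment record (secondary `0x100` and
#' supplementary `0x800` records are excluded; each mate of a pair counts
#' once).  The library size `total_mapped` is the number of all such records in
#' the file, so records mapped to references outside `feature_ids` still
#' contribute to it; their number is kept as a warning tally.
#'
#' @param path Path to a 2-column TSV, or to a SAM/BAM file (extension `.sam`
#'   or `.bam`).
#' @param feature_ids Character vector of features the table must cover.  For
#'   TSV input it defaults to the listed features; for SAM input it defaults to
#'   the header reference names.  Features with no reads get count 0.
#' @param total_mapped Optional override for the library size (mapped reads in
#'   the library, which may exceed the sum over listed features).
#' @return A `count_table` object: a list with `counts` (tibble `feature_id`,
#'   `count`), `total_mapped` and `n_unknown_reference` (reads mapped to
#'   references outside `feature_ids`).
#' @export
read_counts <- function(path, feature_ids = NULL, total_mapped = NULL) {
  if (!file.exists(path)) {
    abort(paste0("count input not found: ", path))
  }
  if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) {
    read_counts_sam(path, feature_ids, total_mapped)
  } else {
    read_counts_tsv(path, feature_ids, total_mapped)
  }
}

read_counts_tsv <- function(path, feature_ids, total_mapped) {
  tab <- readr::read_tsv(
    path,
    col_names = c("feature_id", "count"),
    col_types = readr::cols(
      feature_id = readr::col_character(),
      count = readr::col_double()
    ),
    progress = FALSE
  )
  if (anyNA(tab$count) || any(tab$count < 0)) {
    abort("count table contains missing or negative counts")
  }
  counts <- tab %>% mutate(count = as.integer(round(.data$count)))
  if (is.null(feature_ids)) feature_ids <- counts$feature_id
  counts <- tibble(feature_id = feature_ids) %>%
    left_join(counts, by = "feature_id") %>%
    mutate(count = dplyr::coalesce(.data$count, 0L))
  new_count_table(
    counts,
    total_mapped %||% sum(counts$count),
    n_unknown = sum(!tab$feature_id %in% feature_ids)
  )
}

read_counts_sam <- function(path, feature_ids, total_mapped) {
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else {
    path
  }
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  param <- Rsamtools::ScanBamParam(flag = flags, what = "rname")
  rname <- as.character(Rsamtools::scanBam(bam, param = param)[[1]]$rname)
  if (is.null(feature_ids)) {
    hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    feature_ids <- names(hdr)
  }
  unknown <- sum(!rname %in% feature_ids)
  if (unknown > 0) {
    warn(paste0(
      unknown, " mapped record(s) on references outside the feature set; ",
      "counted toward total_mapped only"
    ))
  }
  counts <- tibble(feature_id = feature_ids) %>%
    left_join(
      tibble(feature_id = rname) %>% count(.data$feature_id, name = "count"),
      by = "feature_id"
    ) %>%
    mutate(count = dplyr::coalesce(.data$count, 0L))
  new_count_table(counts, total_mapped %||% length(rname), n_unknown = unknown)
}

new_count_table <- function(counts, total_mapped, n_unknown = 0L) {
  stopifnot(total_mapped >= 0)
  structure(
    list(
      counts = counts,
      total_mapped = as.double(total_mapped),
      n_unknown_reference = as.integer(n_unknown)
    ),
    class = "count_table"
  )
}

#' Build a count table from an in-memory tibble
#'
#' @param counts Tibble with columns `feature_id` and `count`.
#' @param total_mapped Library size; defaults to the sum of `count`.
#' @return A `count_table` object (see [read_counts()]).
#' @export
count_table <- function(counts, total_mapped = NULL) {
  stopifnot(all(c("feature_id", "count") %in% names(counts)))
  new_count_table(
    as_tibble(counts[c("feature_id", "count")]),
    total_mapped %||% sum(counts$count)
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(
    "<count_table> ", nrow(x$counts), " features, total_mapped = ",
    format(x$total_mapped, big.mark = ","), "\n",
    sep = ""
  )
  print(x$counts, n = 5)
  invisible(x)
}

#' @rdname read_counts
#' @param x A `count_table`.
#' @param ... Unused.
#' @export
tidy.count_table <- function(x, ...) x$counts

#' @rdname read_counts
#' @export
glance.count_table <- function(x, ...) {
  tibble(
    n_features = nrow(x$counts),
    total_counted = sum(x$counts$count),
    total_mapped = x$total_mapped,
    n_unknown_reference = x$n_unknown_reference
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
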