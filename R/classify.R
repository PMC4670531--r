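#' Assign each contig its best-hit gene
#'
#' Collapses HSP-level homology hits to one gene assignment per contig.  HSPs
#' of the same contig/gene pair are aggregated by their maximum single-HSP bit
#' score (not a sum); the contig is then assigned the gene with the highest
#' aggregated bit score.  Ties are broken by lower aggregated e-value, then by
#' lexicographically smaller gene identifier.  Deliberately, no e-value or
#' identity cut-off is applied: any homology at all makes a contig a hit
#' contig.
#'
#' @param hits Hit tibble from [read_blast_tab()] (columns `query_id`,
#'   `subject_id`, `bitscore`, `evalue` are used).
#' @return A tibble with one row per contig that has at least one hit:
#'   `contig_id`, `gene_id`, `best_bitscore`, `best_evalue`.
#' @export
best_hit_per_contig <- function(hits) {
  if (nrow(hits) == 0) {
    return(tibble(
      contig_id = character(), gene_id = character(),
      best_bitscore = double(), best_evalue = double()
    ))
  }
  hits %>%
    group_by(contig_id = .data$query_id, gene_id = .data$subject_id) %>%
    summarise(
      best_bitscore = max(.data$bitscore),
      best_evalue = min(.data$evalue),
      .groups = "drop"
    ) %>%
    group_by(.data$contig_id) %>%
    arrange(
      dplyr::desc(.data$best_bitscore), .data$best_evalue, .data$gene_id,
      .by_group = TRUE
    ) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$contig_id)
}

#' Classify contigs as unique-hit, multiple-hit or no-hit
#'
#' The three-way classification that quantifies assembly redundancy.  Contigs
#' with no gene assignment are `no_hit`.  Assigned contigs are grouped by their
#' assigned gene: the sole contig of a gene is a `unique` hit; two or more
#' contigs assigned to one gene are all `multiple` hits (they are redundant
#' copies of that gene).  The classification is a partition: every contig gets
#' exactly one label.
#'
#' @param contigs Contig tibble ([read_contig_fasta()]).
#' @param assignments Per-contig gene assignments from [best_hit_per_contig()].
#' @return A `contig_classification` object holding the per-contig label table
#'   and a count/percentage summary; see [tidy.contig_classification()] and
#'   [glance.contig_classification()].
#' @export
classify_contigs <- function(contigs, assignments) {
  unknown <- setdiff(assignments$contig_id, contigs$contig_id)
  if (length(unknown) > 0) {
    abort(paste0(
      "assignment(s) for contig(s) absent from the contig set: ",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  labels <- contigs %>%
    select("contig_id") %>%
    left_join(assignments %>% select("contig_id", "gene_id"), by = "contig_id") %>%
    group_by(.data$gene_id) %>%
    mutate(
      class = dplyr::case_when(
        is.na(.data$gene_id) ~ "no_hit",
        n() == 1 ~ "unique",
        TRUE ~ "multiple"
      )
    ) %>%
    ungroup()
  n_total <- nrow(labels)
  n_unique <- sum(labels$class == "unique")
  n_multiple <- sum(labels$class == "multiple")
  n_no_hit <- sum(labels$class == "no_hit")
  pct <- function(k) if (n_total == 0) 0 else 100 * k / n_total
  summary <- tibble(
    category = c("hit", "unique_hit", "multiple_hit", "no_hit", "total"),
    n = c(n_unique + n_multiple, n_unique, n_multiple, n_no_hit, n_total),
    percentage = pct(c(n_unique + n_multiple, n_unique, n_multiple, n_no_hit, n_total))
  )
  structure(
    list(labels = labels, summary = summary),
    class = "contig_classification"
  )
}

#' @export
print.contig_classification <- function(x, ...) {
  cat("<contig_classification> ", nrow(x$labels), " contigs\n", sep = "")
  print(
    x$summary %>% mutate(percentage = round(.data$percentage, 2))
  )
  invisible(x)
}

#' Tidiers for contig classifications
#'
#' `tidy()` returns the per-contig label table (`contig_id`, `gene_id`,
#' `class`); `glance()` returns a one-row summary with counts and percentages
#' of each category.
#'
#' @param x A `contig_classification` from [classify_contigs()].
#' @param ... Unused.
#' @export
tidy.contig_classification <- function(x, ...) x$labels

#' @rdname tidy.contig_classification
#' @export
glance.contig_classification <- function(x, ...) {
  s <- setNames(x$summary$n, x$summary$category)
  p <- setNames(x$summary$percentage, x$summary$category)
  tibble(
    n_total = s[["total"]],
    n_hit = s[["hit"]],
    n_unique_hit = s[["unique_hit"]],
    n_multiple_hit = s[["multiple_hit"]],
    n_no_hit = s[["no_hit"]],
    pct_hit = p[["hit"]],
    pct_unique_hit = p[["unique_hit"]],
    pct_multiple_hit = p[["multiple_hit"]],
    pct_no_hit = p[["no_hit"]]
  )
}

#' Write a classification summary as TSV
#'
#' One row per category (hit, unique hit, multiple hit, no hit, total) with
#' count and percentage (two decimal places), mirroring the usual published
#' layout of redundancy summaries.
#'
#' @param classification A `contig_classification`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification_tsv <- function(classification, path) {
  classification$summary %>%
    mutate(percentage = sprintf("%.2f", .data$percentage)) %>%
    readr::write_tsv(path)
  invisible(path)
}
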