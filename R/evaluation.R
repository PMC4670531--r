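#' Co-identity of differentially expressed contigs with gold-standard DEGs
#'
#' A differentially expressed contig (DEC) exhibits co-identity when the gene
#' it is assigned to by homology is itself a differentially expressed gene
#' (DEG) in the gold-standard set.  DECs with no gene assignment — erroneous
#' contigs — and DECs assigned to non-differential genes are non-identical.
#' Because a redundant set can hit one DEG with several DECs, two coverage
#' ratios are reported: the fraction of DECs that are identical, and the
#' fraction of DEGs covered by at least one DEC (distinct genes).
#'
#' @param dec_ids Character vector of differential contig identifiers.
#' @param deg_ids Character vector of differential gene identifiers.
#' @param assignments Contig-to-gene assignments ([best_hit_per_contig()]).
#' @return A one-row tibble: `n_dec_total`, `n_dec_identical`,
#'   `n_dec_nonidentical`, `pct_identical` (of DECs), `pct_nonidentical` (of
#'   DECs), `n_deg_total`, `n_deg_covered`, `pct_of_degs_covered`.
#' @export
co_identity <- function(dec_ids, deg_ids, assignments) {
  dec_ids <- unique(dec_ids)
  deg_ids <- unique(deg_ids)
  dec_gene <- assignments$gene_id[match(dec_ids, assignments$contig_id)]
  identical <- !is.na(dec_gene) & dec_gene %in% deg_ids
  n_total <- length(dec_ids)
  n_ident <- sum(identical)
  covered <- unique(dec_gene[identical])
  pct <- function(k, n) if (n == 0) 0 else 100 * k / n
  tibble(
    n_dec_total = n_total,
    n_dec_identical = n_ident,
    n_dec_nonidentical = n_total - n_ident,
    pct_identical = pct(n_ident, n_total),
    pct_nonidentical = pct(n_total - n_ident, n_total),
    n_deg_total = length(deg_ids),
    n_deg_covered = length(covered),
    pct_of_degs_covered = pct(length(covered), length(deg_ids))
  )
}

#' Per-term annotation counts for a gene set
#'
#' For each GO slim term in the annotation universe, counts how many of the
#' input genes carry that term.  Contig identifiers must be translated to
#' gene identifiers (via their homology assignment) before calling; genes
#' absent from the annotation map contribute nothing.
#'
#' @param gene_ids Character vector of gene identifiers (duplicates are
#'   collapsed).
#' @param go_map Annotation tibble (`gene_id`, `term`) from
#'   [read_go_annotations()]; its full term set defines the count universe.
#' @return A tibble (`term`, `count`) covering every term in `go_map`,
#'   zero-filled, sorted by term.
#' @export
go_term_counts <- function(gene_ids, go_map) {
  stopifnot(all(c("gene_id", "term") %in% names(go_map)))
  universe <- sort(unique(go_map$term))
  hits <- go_map %>%
    distinct() %>%
    filter(.data$gene_id %in% unique(gene_ids)) %>%
    count(.data$term, name = "count")
  tibble(term = universe) %>%
    left_join(hits, by = "term") %>%
    mutate(count = dplyr::coalesce(.data$count, 0L))
}

#' Two-sample Kolmogorov-Smirnov test on per-term annotation counts
#'
#' Treats the two per-term count vectors as two samples — one observation per
#' GO term, value equal to its annotation count, matching the construction of
#' a quantile-quantile comparison of the two distributions — and runs the
#' asymptotic two-sample KS test.  Under the null the DEG-derived and
#' DEC-derived term-count distributions are the same; identical (or permuted)
#' count vectors give statistic 0 and p-value 1.
#'
#' @param counts_a,counts_b Count tibbles from [go_term_counts()] over the
#'   same term universe (bare numeric vectors are also accepted).
#' @return A one-row tibble (`ks_statistic`, `ks_pvalue`).
#' @export
ks_distribution_test <- function(counts_a, counts_b) {
  a <- if (is.numeric(counts_a)) counts_a else counts_a$count
  b <- if (is.numeric(counts_b)) counts_b else counts_b$count
  if (length(a) == 0 || length(b) == 0) {
    abort("empty term universe: nothing to compare")
  }
  if (!is.numeric(counts_a) && !is.numeric(counts_b) &&
    !identical(sort(counts_a$term), sort(counts_b$term))) {
    abort("the two count tables cover different term universes")
  }
  res <- suppressWarnings(ks.test(a, b, exact = FALSE))
  tibble(
    ks_statistic = unname(res$statistic),
    ks_pvalue = min(1, unname(res$p.value))
  )
}

#' Per-term Fisher's exact tests between two annotated sets
#'
#' For each term the 2x2 table contrasts genes with and without the term in
#' the DEG set against the DEC-derived set:
#' `[[deg_count, n_deg - deg_count], [dec_count, n_dec - dec_count]]`,
#' tested two-sided.  No multiple-testing correction is applied; the reported
#' `n_significant` is the raw count of terms with `p < alpha`.
#'
#' @param deg_counts,dec_counts Count tibbles from [go_term_counts()] over a
#'   shared term universe.
#' @param n_deg,n_dec Total number of features (genes / DECs) in each set;
#'   every per-term count must be within its total.
#' @param alpha Significance level (default 0.05).
#' @return A list with `per_term` (tibble `term`, `deg_count`, `dec_count`,
#'   `fisher_p`, `significant`) and `n_significant`.
#' @export
fisher_per_term <- function(deg_counts, dec_counts, n_deg, n_dec, alpha = 0.05) {
  stopifnot(identical(sort(deg_counts$term), sort(dec_counts$term)))
  tbl <- deg_counts %>%
    rename(deg_count = "count") %>%
    left_join(dec_counts %>% rename(dec_count = "count"), by = "term")
  if (any(tbl$deg_count > n_deg) || any(tbl$dec_count > n_dec) ||
    n_deg < 0 || n_dec < 0) {
    abort("per-term count exceeds its set total (negative table margin)")
  }
  tbl <- tbl %>%
    mutate(
      fisher_p = purrr::map2_dbl(.data$deg_count, .data$dec_count, function(a, c) {
        fisher.test(matrix(c(a, n_deg - a, c, n_dec - c), nrow = 2, byrow = TRUE))$p.value
      }),
      significant = .data$fisher_p < alpha
    )
  list(per_term = tbl, n_significant = sum(tbl$significant))
}

#' Full GO slim distribution comparison between DEGs and DECs
#'
#' Convenience wrapper combining [go_term_counts()], [ks_distribution_test()]
#' and [fisher_per_term()] into one report object.
#'
#' @param deg_ids Differential gene identifiers (gold standard).
#' @param dec_gene_ids Gene identifiers the DECs translate to (one entry per
#'   DEC that has an assignment; duplicates collapsed for counting).
#' @param go_map Annotation tibble ([read_go_annotations()]).
#' @param alpha Per-term significance level (default 0.05, uncorrected).
#' @return A `go_comparison` object; `tidy()` gives the per-term table,
#'   `glance()` the KS statistic/p-value and significant-term count.
#' @export
compare_go_distributions <- function(deg_ids, dec_gene_ids, go_map, alpha = 0.05) {
  deg_ids <- unique(deg_ids)
  dec_gene_ids <- unique(dec_gene_ids[!is.na(dec_gene_ids)])
  deg_counts <- go_term_counts(deg_ids, go_map)
  dec_counts <- go_term_counts(dec_gene_ids, go_map)
  ks <- ks_distribution_test(deg_counts, dec_counts)
  fisher <- fisher_per_term(
    deg_counts, dec_counts,
    n_deg = length(deg_ids), n_dec = length(dec_gene_ids), alpha = alpha
  )
  structure(
    list(
      per_term = fisher$per_term,
      ks_statistic = ks$ks_statistic,
      ks_pvalue = ks$ks_pvalue,
      n_significant = fisher$n_significant,
      alpha = alpha,
      n_deg = length(deg_ids),
      n_dec = length(dec_gene_ids)
    ),
    class = "go_comparison"
  )
}

#' @export
print.go_comparison <- function(x, ...) {
  cat(
    "<go_comparison> ", nrow(x$per_term), " terms | KS D = ",
    signif(x$ks_statistic, 3), ", p = ", signif(x$ks_pvalue, 3), " | ",
    x$n_significant, " term(s) with Fisher p < ", x$alpha, "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidiers for GO distribution comparisons
#'
#' @param x A `go_comparison` from [compare_go_distributions()].
#' @param ... Unused.
#' @export
tidy.go_comparison <- function(x, ...) x$per_term

#' @rdname tidy.go_comparison
#' @export
glance.go_comparison <- function(x, ...) {
  tibble(
    n_terms = nrow(x$per_term),
    n_deg = x$n_deg,
    n_dec = x$n_dec,
    ks_statistic = x$ks_statistic,
    ks_pvalue = x$ks_pvalue,
    n_significant_terms = x$n_significant,
    alpha = x$alpha
  )
}
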